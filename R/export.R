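#' Flag previously validated interactors
#'
#' Marks each scored prey as known when its symbol (case-normalized to
#' upper case) appears in the supplied known-interactor list.
#'
#' @param scored a \linkS4class{ScoredInteractions}.
#' @param known character vector of known interactor symbols (e.g. from
#'   \code{\link{readKnownInteractors}}).
#' @return the scored object with a logical \code{is_known} column; the
#'   number of flagged preys is \code{sum(scoredData(x)$is_known)}.
#' @export
annotateKnown <- function(scored, known) {
  known <- unique(toupper(known))
  known <- known[!is.na(known) & known != ""]
  if (!length(known)) stop("known-interactor list is empty")
  df <- scoredData(scored)
  df$is_known <- toupper(df$prey) %in% known
  ScoredInteractions(df)
}

.borderTier <- function(bfdr) {
  # boundary values belong to the stricter tier: black <= 0.01, blue <= 0.05
  ifelse(bfdr <= 0.01, "black", ifelse(bfdr <= 0.05, "blue", "lightblue"))
}

#' Build a dot-plot matrix of control-subtracted spectral counts
#'
#' For each requested prey and each bait condition, computes the
#' control-subtracted spectral count max(0, avg - mean(control counts)), the
#' colour value (subtracted count capped at 20), the relative size (the
#' cell's subtracted count divided by the prey's maximum across bait
#' conditions) and the border tier encoding the BFDR (black <= 0.01,
#' blue <= 0.05, light blue above). Preys whose subtracted count is zero in
#' every condition are dropped with a warning. Preys absent from a condition
#' yield no cell for that condition.
#'
#' @param scoredByCondition named list of \linkS4class{ScoredInteractions},
#'   one per bait condition, with \code{bfdr} filled.
#' @param preySubset preys to plot; default all preys seen.
#' @param useNormalized use the \code{norm_count} column (after
#'   \code{\link{normalizeByBait}}) instead of \code{avg_count}; whether
#'   relative sizes are computed before or after bait normalization is a
#'   presentation choice this flag exposes.
#' @param path optional TSV output path for the cell table.
#' @param cap colour-value cap (default 20).
#' @return data.frame with columns prey, bait_condition, subtracted_count,
#'   color_value, relative_size, border_tier, bfdr.
#' @export
dotPlotMatrix <- function(scoredByCondition, preySubset = NULL,
                          useNormalized = FALSE, path = NULL, cap = 20) {
  stopifnot(is.list(scoredByCondition), length(scoredByCondition) > 0,
            !is.null(names(scoredByCondition)))
  cells <- do.call(rbind, lapply(names(scoredByCondition), function(cc) {
    df <- scoredData(scoredByCondition[[cc]])
    if (anyNA(df$bfdr)) stop("bfdr not computed for condition ", cc)
    cnt <- if (useNormalized) {
      if (is.null(df$norm_count)) stop("no norm_count column; run normalizeByBait")
      df$norm_count
    } else df$avg_count
    ctrl_mean <- vapply(df$control_counts,
                        function(v) if (length(v)) mean(v) else 0, 0)
    data.frame(prey = df$prey, bait_condition = cc,
               subtracted_count = pmax(0, cnt - ctrl_mean),
               bfdr = df$bfdr, stringsAsFactors = FALSE)
  }))
  if (!is.null(preySubset)) {
    missing <- setdiff(preySubset, cells$prey)
    if (length(missing) == length(preySubset))
      stop("none of the requested preys are present in any condition")
    if (length(missing))
      warning("prey(s) absent everywhere, dropped: ", paste(missing, collapse = ", "))
    cells <- cells[cells$prey %in% preySubset, , drop = FALSE]
  }
  mx <- tapply(cells$subtracted_count, cells$prey, max)
  zero <- names(mx)[mx == 0]
  if (length(zero)) {
    warning("prey(s) with zero control-subtracted counts everywhere, dropped: ",
            paste(zero, collapse = ", "))
    cells <- cells[!cells$prey %in% zero, , drop = FALSE]
  }
  cells$color_value <- pmin(cells$subtracted_count, cap)
  cells$relative_size <- as.numeric(cells$subtracted_count / mx[cells$prey])
  cells$border_tier <- .borderTier(cells$bfdr)
  cells <- cells[order(cells$prey, cells$bait_condition),
                 c("prey", "bait_condition", "subtracted_count", "color_value",
                   "relative_size", "border_tier", "bfdr")]
  rownames(cells) <- NULL
  if (!is.null(path))
    utils::write.table(cells, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cells
}

#' Export a network edge table
#'
#' Writes one edge per interaction passing the BFDR cutoff, for rendering in
#' external network tools. Columns: bait, prey, avg_count, bfdr, is_known.
#'
#' @param scored a \linkS4class{ScoredInteractions} with \code{bfdr} filled.
#' @param bfdrMax BFDR cutoff in (0, 1].
#' @param known optional known-interactor vector used to fill
#'   \code{is_known} (defaults to an existing \code{is_known} column, else
#'   all FALSE).
#' @param path optional TSV output path.
#' @return the edge data.frame; its row count is the number of edges.
#' @export
exportNetworkEdges <- function(scored, bfdrMax = 0.01, known = NULL,
                               path = NULL) {
  stopifnot(bfdrMax > 0, bfdrMax <= 1)
  if (!is.null(known)) scored <- annotateKnown(scored, known)
  df <- scoredData(scored)
  if (anyNA(df$bfdr)) stop("bfdr not computed; run computeBFDR first")
  if (is.null(df$is_known)) df$is_known <- FALSE
  edges <- df[df$bfdr <= bfdrMax,
              c("bait", "prey", "avg_count", "bfdr", "is_known"), drop = FALSE]
  rownames(edges) <- NULL
  if (!is.null(path))
    utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  edges
}
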