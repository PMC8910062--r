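#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Long-form spectral-count table for BioID runs
#'
#' Holds run-level prey spectral counts with bait, condition and replicate
#' labels. Control runs (cells expressing the promiscuous ligase tag alone)
#' carry the reserved condition label \code{"control"}. Counts are
#' non-negative; they are integers as read from a search pipeline, but may
#' become fractional after bait-abundance normalization (see
#' \code{\link{normalizeCountTable}}).
#'
#' @slot counts data.frame with columns \code{run_id}, \code{bait},
#'   \code{condition}, \code{replicate}, \code{prey}, \code{count}.
#' @export
setClass("SpectralCountTable", slots = c(counts = "data.frame"))

setValidity("SpectralCountTable", function(object) {
  df <- object@counts
  need <- c("run_id", "bait", "condition", "replicate", "prey", "count")
  if (!all(need %in% names(df)))
    return(paste("missing columns:", paste(setdiff(need, names(df)), collapse = ", ")))
  if (nrow(df) == 0) return(TRUE)
  if (anyDuplicated(df[, c("run_id", "prey")]))
    return("duplicate (run_id, prey) pairs")
  if (any(!is.finite(df$count)) || any(df$count < 0))
    return("counts must be finite and non-negative")
  if (any(df$replicate < 1))
    return("replicate indices must be >= 1")
  noctrl <- df$condition != "control"
  if (any(noctrl & (is.na(df$bait) | df$bait == "")))
    return("every non-control run must have a bait")
  TRUE
})

#' Construct a SpectralCountTable
#'
#' @param counts data.frame with columns \code{run_id}, \code{bait},
#'   \code{condition}, \code{replicate}, \code{prey}, \code{count}.
#' @return A \linkS4class{SpectralCountTable}.
#' @examples
#' tab <- SpectralCountTable(data.frame(
#'   run_id = "WT_b1t1", bait = "CFTR", condition = "WT",
#'   replicate = 1L, prey = "EZR", count = 12L))
#' @export
SpectralCountTable <- function(counts) {
  counts$run_id <- as.character(counts$run_id)
  counts$bait <- as.character(counts$bait)
  counts$condition <- as.character(counts$condition)
  counts$prey <- as.character(counts$prey)
  rownames(counts) <- NULL
  new("SpectralCountTable", counts = counts)
}

#' @describeIn SpectralCountTable counts data.frame accessor
#' @param x a SpectralCountTable
#' @export
countData <- function(x) {
  stopifnot(is(x, "SpectralCountTable"))
  x@counts
}

#' Runs present in a count table
#'
#' One row per run with its bait, condition, replicate and control flag.
#' @param x a \linkS4class{SpectralCountTable}
#' @return data.frame with columns run_id, bait, condition, replicate,
#'   is_control.
#' @export
runInfo <- function(x) {
  df <- countData(x)
  u <- unique(df[, c("run_id", "bait", "condition", "replicate")])
  u$is_control <- u$condition == "control"
  rownames(u) <- NULL
  u[order(u$run_id), , drop = FALSE]
}

setMethod("show", "SpectralCountTable", function(object) {
  df <- object@counts
  ri <- runInfo(object)
  cat("SpectralCountTable:", nrow(df), "count records,",
      nrow(ri), "runs (", sum(ri$is_control), "control ),",
      length(unique(df$prey)), "preys\n")
  cond <- table(ri$condition)
  cat("  conditions:", paste(sprintf("%s(%d)", names(cond), cond), collapse = ", "), "\n")
})

#' Scored prey-bait proximity interactions
#'
#' One row per (bait, condition, prey) with the average spectral count across
#' bait runs, the per-run control counts, the confidence probability from the
#' interaction scorer and, once \code{\link{computeBFDR}} has been run, the
#' Bayesian false discovery rate down the probability-ranked list.
#'
#' @slot data data.frame with columns \code{bait}, \code{condition},
#'   \code{prey}, \code{avg_count}, \code{prob}, \code{bfdr} and a list
#'   column \code{control_counts}; optionally \code{norm_count} (after
#'   \code{\link{normalizeByBait}}) and \code{is_known} (after
#'   \code{\link{annotateKnown}}).
#' @export
setClass("ScoredInteractions", slots = c(data = "data.frame"))

setValidity("ScoredInteractions", function(object) {
  df <- object@data
  need <- c("bait", "condition", "prey", "avg_count", "prob", "bfdr", "control_counts")
  if (!all(need %in% names(df)))
    return(paste("missing columns:", paste(setdiff(need, names(df)), collapse = ", ")))
  if (nrow(df) == 0) return(TRUE)
  if (any(df$prob < -1e-12 | df$prob > 1 + 1e-12, na.rm = TRUE))
    return("prob outside [0, 1]")
  ok <- is.na(df$bfdr) | (df$bfdr >= -1e-12 & df$bfdr <= 1 + 1e-12)
  if (!all(ok)) return("bfdr outside [0, 1]")
  if (any(df$avg_count < 0)) return("avg_count must be non-negative")
  if (!is.list(df$control_counts)) return("control_counts must be a list column")
  # within a bait-condition, bfdr must be non-decreasing when ranked by
  # decreasing prob (the SAINT convention)
  if (!anyNA(df$bfdr)) {
    for (bc in unique(paste(df$bait, df$condition))) {
      sub <- df[paste(df$bait, df$condition) == bc, ]
      o <- order(-sub$prob, -sub$avg_count, sub$prey)
      if (any(diff(sub$bfdr[o]) < -1e-9))
        return("bfdr not non-decreasing along the prob ranking")
    }
  }
  TRUE
})

#' Construct a ScoredInteractions object
#'
#' @param data data.frame as described in \linkS4class{ScoredInteractions}.
#' @return A \linkS4class{ScoredInteractions}.
#' @export
ScoredInteractions <- function(data) {
  if (!"bfdr" %in% names(data)) data$bfdr <- NA_real_
  data$prey <- as.character(data$prey)
  rownames(data) <- NULL
  new("ScoredInteractions", data = data)
}

#' @describeIn ScoredInteractions data.frame accessor
#' @param x a ScoredInteractions object
#' @export
scoredData <- function(x) {
  stopifnot(is(x, "ScoredInteractions"))
  x@data
}

#' @describeIn ScoredInteractions prey symbols, in ranking order
#' @export
preys <- function(x) scoredData(x)$prey

#' Bait-condition label of a scored interaction set
#'
#' @param x a \linkS4class{ScoredInteractions}
#' @return character vector \code{"<bait>:<condition>"} per row.
#' @export
baitCondition <- function(x) {
  df <- scoredData(x)
  paste(df$bait, df$condition, sep = ":")
}

setMethod("show", "ScoredInteractions", function(object) {
  df <- object@data
  cat("ScoredInteractions:", nrow(df), "preys for",
      paste(unique(paste(df$bait, df$condition, sep = ":")), collapse = ", "), "\n")
  if (nrow(df) > 0) {
    hc <- if (anyNA(df$bfdr)) "bfdr not yet computed"
          else paste(sum(df$bfdr <= 0.01), "at BFDR <= 0.01")
    cat("  prob range:", sprintf("[%.3g, %.3g];", min(df$prob), max(df$prob)), hc, "\n")
  }
})

#' A projected multi-channel microscopy field
#'
#' 16-bit intensities for the surface-labelled and total-reporter channels of
#' one field, with an optional nuclear channel and an optional boolean mask
#' demarcating a cell-free region used for background estimation.
#'
#' @slot surface numeric matrix of surface-channel intensities.
#' @slot total numeric matrix of total-channel intensities (same shape).
#' @slot nuclear optional matrix, same shape.
#' @slot backgroundMask optional logical matrix, TRUE for cell-free pixels.
#' @export
setClass("FieldImage", slots = c(
  surface = "matrix", total = "matrix",
  nuclear = "matrixOrNULL", backgroundMask = "matrixOrNULL"))

setValidity("FieldImage", function(object) {
  d <- dim(object@surface)
  if (!identical(d, dim(object@total)))
    return("surface and total channels must share shape")
  for (nm in c("nuclear", "backgroundMask")) {
    s <- slot(object, nm)
    if (!is.null(s) && !identical(d, dim(s)))
      return(paste(nm, "must share the channel shape"))
  }
  rng <- range(object@surface, object@total)
  if (rng[1] < 0 || rng[2] > 65535)
    return("intensities must lie in [0, 65535]")
  if (!is.null(object@backgroundMask) && !is.logical(object@backgroundMask))
    return("backgroundMask must be logical")
  TRUE
})

#' Construct a FieldImage
#'
#' @param surface,total numeric matrices of 16-bit intensities (same shape).
#' @param nuclear optional nuclear-channel matrix.
#' @param backgroundMask optional logical matrix marking cell-free pixels.
#' @return A \linkS4class{FieldImage}.
#' @export
FieldImage <- function(surface, total, nuclear = NULL, backgroundMask = NULL) {
  new("FieldImage", surface = surface, total = total,
      nuclear = nuclear, backgroundMask = backgroundMask)
}

setMethod("show", "FieldImage", function(object) {
  d <- dim(object@surface)
  cat(sprintf("FieldImage %dx%d px; nuclear: %s; background mask: %s\n",
              d[1], d[2],
              if (is.null(object@nuclear)) "absent" else "present",
              if (is.null(object@backgroundMask)) "absent"
              else sprintf("%d px", sum(object@backgroundMask))))
})

#' A FLIPR membrane-potential trace
#'
#' A single well's fluorescence time series with the times at which the
#' cAMP agonist (forskolin) and the CFTR inhibitor (inh-172) were added.
#' \code{\link{computeDFF0}} fills the \code{dff0} and \code{f0} slots.
#'
#' @slot time numeric, seconds, strictly increasing.
#' @slot fluorescence numeric, arbitrary units, non-negative.
#' @slot fskTime agonist addition time (s), after trace start.
#' @slot inhTime inhibitor addition time (s), after \code{fskTime} and within
#'   the trace.
#' @slot dff0 baseline-normalized trace (empty until computed).
#' @slot f0 mean baseline fluorescence (empty until computed).
#' @export
setClass("FLIPRTrace", slots = c(
  time = "numeric", fluorescence = "numeric",
  fskTime = "numeric", inhTime = "numeric",
  dff0 = "numeric", f0 = "numeric"))

setValidity("FLIPRTrace", function(object) {
  t <- object@time
  if (length(t) != length(object@fluorescence))
    return("time and fluorescence lengths differ")
  if (length(t) < 2 || any(diff(t) <= 0))
    return("time must be strictly increasing")
  if (any(object@fluorescence < 0))
    return("fluorescence must be non-negative")
  if (object@fskTime <= min(t))
    return("fskTime must fall after the trace start")
  if (object@inhTime <= object@fskTime || object@inhTime >= max(t))
    return("inhTime must lie after fskTime and within the trace")
  if (length(object@dff0) > 0 && length(object@dff0) != length(t))
    return("dff0 length must match time")
  TRUE
})

#' Construct a FLIPRTrace
#'
#' @param time numeric vector of sampling times (s), strictly increasing.
#' @param fluorescence numeric vector of raw fluorescence values.
#' @param fskTime forskolin addition time (s).
#' @param inhTime inh-172 addition time (s).
#' @return A \linkS4class{FLIPRTrace}.
#' @export
FLIPRTrace <- function(time, fluorescence, fskTime, inhTime) {
  new("FLIPRTrace", time = as.numeric(time),
      fluorescence = as.numeric(fluorescence),
      fskTime = as.numeric(fskTime), inhTime = as.numeric(inhTime),
      dff0 = numeric(0), f0 = numeric(0))
}

setMethod("show", "FLIPRTrace", function(object) {
  cat(sprintf("FLIPRTrace: %d samples over [%g, %g] s; Fsk @ %g s, inh-172 @ %g s; %s\n",
              length(object@time), min(object@time), max(object@time),
              object@fskTime, object@inhTime,
              if (length(object@dff0)) sprintf("dF/F0 computed (F0 = %.4g)", object@f0)
              else "raw"))
})
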