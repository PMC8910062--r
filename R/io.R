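#' Read a spectral-count table
#'
#' Two dialects are supported. \code{"long_tsv"} is the native format: one
#' tab-delimited file with header \code{run_id, bait, condition, replicate,
#' prey, count}. \code{"saint_triplet"} reads the three co-located
#' SAINTexpress-style input files \code{<path>_interaction.txt},
#' \code{<path>_bait.txt} and \code{<path>_prey.txt}; bait and condition are
#' carried in the bait-name field as \code{"<bait>|<condition>"} and
#' replicates are numbered in run-id order within each bait-condition.
#' Control runs are flagged by the bait file's \code{C} indicator
#' (saint_triplet) or by \code{condition == "control"} (long_tsv).
#'
#' @param path file path (long_tsv) or file prefix (saint_triplet).
#' @param dialect one of \code{"long_tsv"}, \code{"saint_triplet"}.
#' @return A \linkS4class{SpectralCountTable}.
#' @export
readCountTable <- function(path, dialect = c("long_tsv", "saint_triplet")) {
  dialect <- match.arg(dialect)
  if (dialect == "long_tsv") {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.delim(path, sep = "\t", header = TRUE,
                            colClasses = c(run_id = "character", bait = "character",
                                           condition = "character", prey = "character"),
                            stringsAsFactors = FALSE)
    need <- c("run_id", "bait", "condition", "replicate", "prey", "count")
    if (!all(need %in% names(df)))
      stop("malformed header: expected columns ", paste(need, collapse = ", "))
    bad <- which(!is.finite(df$count) | df$count < 0 |
                   abs(df$count - round(df$count)) > 1e-8)
    if (length(bad))
      stop("malformed row at line ", bad[1] + 1L, ": count must be a non-negative integer")
    df$bait[is.na(df$bait)] <- ""
    df$count <- as.integer(round(df$count))
    df$replicate <- as.integer(df$replicate)
    SpectralCountTable(df[need])
  } else {
    files <- paste0(path, c("_interaction.txt", "_bait.txt", "_prey.txt"))
    miss <- files[!file.exists(files)]
    if (length(miss)) stop("missing saint_triplet file(s): ", paste(miss, collapse = ", "))
    inter <- utils::read.delim(files[1], header = FALSE, stringsAsFactors = FALSE,
                               col.names = c("run_id", "bait_name", "prey", "count"),
                               colClasses = c("character", "character", "character", "numeric"))
    baitf <- utils::read.delim(files[2], header = FALSE, stringsAsFactors = FALSE,
                               col.names = c("run_id", "bait_name", "tc"),
                               colClasses = "character")
    bad <- which(!is.finite(inter$count) | inter$count < 0 |
                   abs(inter$count - round(inter$count)) > 1e-8)
    if (length(bad))
      stop("malformed row at line ", bad[1], " of ", files[1])
    if (!all(baitf$tc %in% c("T", "C")))
      stop("bait file test/control column must be T or C")
    key <- match(inter$run_id, baitf$run_id)
    if (anyNA(key)) stop("interaction file names runs absent from the bait file")
    tc <- baitf$tc[key]
    parts <- strsplit(inter$bait_name, "|", fixed = TRUE)
    bait <- vapply(parts, `[`, "", 1L)
    condition <- vapply(parts, function(p) if (length(p) > 1) p[2] else "", "")
    condition[tc == "C"] <- "control"
    condition[tc == "T" & condition == ""] <- bait[tc == "T" & condition == ""]
    # replicate = rank of the run within its bait-condition, in run_id order
    bcond <- paste(bait, condition, sep = "\r")
    runs <- unique(data.frame(run_id = inter$run_id, bcond = bcond,
                              stringsAsFactors = FALSE))
    runs <- runs[order(runs$bcond, runs$run_id), ]
    runs$replicate <- stats::ave(seq_len(nrow(runs)), runs$bcond,
                                 FUN = seq_along)
    rep <- runs$replicate[match(inter$run_id, runs$run_id)]
    SpectralCountTable(data.frame(
      run_id = inter$run_id, bait = bait, condition = condition,
      replicate = as.integer(rep), prey = inter$prey,
      count = as.integer(round(inter$count)), stringsAsFactors = FALSE))
  }
}

#' Write a spectral-count table
#'
#' Inverse of \code{\link{readCountTable}}: the written file(s) re-read with
#' the same dialect yield an equal table. Rows are written in a canonical
#' order (run_id, then prey) so repeated round trips are byte-stable.
#'
#' @param x a \linkS4class{SpectralCountTable}.
#' @param path file path (long_tsv) or prefix (saint_triplet).
#' @param dialect one of \code{"long_tsv"}, \code{"saint_triplet"}.
#' @return \code{path}, invisibly.
#' @export
writeCountTable <- function(x, path, dialect = c("long_tsv", "saint_triplet")) {
  dialect <- match.arg(dialect)
  df <- countData(x)
  df <- df[order(df$run_id, df$prey), , drop = FALSE]
  if (dialect == "long_tsv") {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  } else {
    ri <- runInfo(x)
    bait_name <- ifelse(ri$is_control, ri$bait,
                        paste(ri$bait, ri$condition, sep = "|"))
    inter <- data.frame(run_id = df$run_id,
                        bait_name = bait_name[match(df$run_id, ri$run_id)],
                        prey = df$prey, count = df$count)
    baitf <- data.frame(run_id = ri$run_id, bait_name = bait_name,
                        tc = ifelse(ri$is_control, "C", "T"))
    preyf <- data.frame(prey = sort(unique(df$prey)))
    preyf$length <- 0L
    preyf$gene <- preyf$prey
    utils::write.table(inter, paste0(path, "_interaction.txt"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    utils::write.table(baitf, paste0(path, "_bait.txt"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    utils::write.table(preyf, paste0(path, "_prey.txt"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a known-interactor list
#'
#' Two-column tab-delimited file (as exported from BioGRID-style databases)
#' with a header; the column named \code{gene} (or the first column) supplies
#' the symbols. Symbols are uppercased and de-duplicated.
#'
#' @param path file path.
#' @param source label recorded on the returned vector.
#' @return character vector of gene symbols with a \code{"source"} attribute.
#' @export
readKnownInteractors <- function(path, source = "BioGRID") {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  col <- if ("gene" %in% names(df)) "gene" else names(df)[1]
  genes <- unique(toupper(as.character(df[[col]])))
  genes <- genes[genes != "" & !is.na(genes)]
  if (!length(genes)) stop("known-interactor list is empty")
  structure(genes, source = source)
}

#' Read a compartment-marker compendium
#'
#' Long-form tab-delimited file with header \code{marker_bait, compartment,
#' prey}: one row per (marker bait, prey). Emulates a curated compendium of
#' proximity-labelling marker baits spanning the cell's compartments.
#'
#' @param path file path.
#' @return data.frame with columns marker_bait, compartment, prey.
#' @export
readCompendium <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("marker_bait", "compartment", "prey")
  if (!all(need %in% names(df)))
    stop("compendium must have columns ", paste(need, collapse = ", "))
  if (!nrow(df)) stop("compendium is empty")
  df[need]
}

#' Read FLIPR plate-reader traces
#'
#' The trace file is tab-delimited with header \code{time, well,
#' fluorescence}; the events sidecar has header \code{well, fsk_time,
#' inh_time} giving the agonist and inhibitor addition times per well.
#'
#' @param path trace file path.
#' @param eventsPath events sidecar path.
#' @return named list of \linkS4class{FLIPRTrace}, one per well.
#' @export
readFliprTraces <- function(path, eventsPath) {
  tr <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  ev <- utils::read.delim(eventsPath, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("time", "well", "fluorescence") %in% names(tr)))
    stop("trace file must have columns time, well, fluorescence")
  if (!all(c("well", "fsk_time", "inh_time") %in% names(ev)))
    stop("events file must have columns well, fsk_time, inh_time")
  out <- lapply(ev$well, function(w) {
    sub <- tr[tr$well == w, ]
    if (!nrow(sub)) stop("no trace samples for well ", w)
    sub <- sub[order(sub$time), ]
    e <- ev[ev$well == w, ]
    FLIPRTrace(sub$time, sub$fluorescence, e$fsk_time, e$inh_time)
  })
  names(out) <- ev$well
  out
}

#' Write FLIPR traces and their events sidecar
#'
#' @param traces named list of \linkS4class{FLIPRTrace}.
#' @param path,eventsPath output paths for the trace table and sidecar.
#' @return \code{path}, invisibly.
#' @export
writeFliprTraces <- function(traces, path, eventsPath) {
  stopifnot(length(traces) > 0, !is.null(names(traces)))
  tab <- do.call(rbind, lapply(names(traces), function(w) {
    tr <- traces[[w]]
    data.frame(time = tr@time, well = w, fluorescence = tr@fluorescence)
  }))
  ev <- do.call(rbind, lapply(names(traces), function(w)
    data.frame(well = w, fsk_time = traces[[w]]@fskTime,
               inh_time = traces[[w]]@inhTime)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ev, eventsPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a multi-channel field image from a 16-bit TIFF
#'
#' Reads a multi-page (directory-per-channel) TIFF in the given channel
#' order. An optional single-page mask TIFF marks the cell-free background
#' region (non-zero = background).
#'
#' @param path TIFF file path.
#' @param channels character vector naming the pages in order; must contain
#'   \code{"surface"} and \code{"total"}, optionally \code{"nuclear"}.
#' @param maskPath optional path of a mask TIFF.
#' @return A \linkS4class{FieldImage}.
#' @export
readFieldImage <- function(path, channels = c("surface", "total"),
                           maskPath = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (length(pages) < length(channels))
    stop("TIFF has ", length(pages), " pages but ", length(channels),
         " channels were requested")
  names(pages)[seq_along(channels)] <- channels
  mask <- NULL
  if (!is.null(maskPath)) {
    m <- tiff::readTIFF(maskPath, as.is = TRUE)
    mask <- m > 0
  }
  FieldImage(surface = pages[["surface"]], total = pages[["total"]],
             nuclear = if ("nuclear" %in% channels) pages[["nuclear"]] else NULL,
             backgroundMask = mask)
}

#' Write a field image as a multi-page 16-bit TIFF
#'
#' @param field a \linkS4class{FieldImage}.
#' @param path output TIFF path.
#' @param maskPath optional path for the background mask TIFF.
#' @return \code{path}, invisibly.
#' @export
writeFieldImage <- function(field, path, maskPath = NULL) {
  pages <- list(field@surface, field@total)
  if (!is.null(field@nuclear)) pages <- c(pages, list(field@nuclear))
  pages <- lapply(pages, function(m) round(m) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  if (!is.null(maskPath)) {
    if (is.null(field@backgroundMask)) stop("field has no background mask")
    tiff::writeTIFF(matrix(as.numeric(field@backgroundMask),
                           nrow(field@surface)) , maskPath,
                    bits.per.sample = 8L)
  }
  invisible(path)
}
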