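#' Estimate channel background as the most populated histogram bin
#'
#' Pixel values of the background region (a demarcated cell-free mask when
#' supplied, otherwise the whole image, which is valid when cells cover a
#' minority of pixels) are binned at \code{binWidth} intensity units; the
#' centre of the most populated bin is returned. Ties go to the lowest bin.
#' With the default bin width of 1 on integer data this is the modal pixel
#' value.
#'
#' @param image numeric matrix of intensities.
#' @param mask optional logical matrix selecting the background region.
#' @param binWidth histogram bin width in intensity units (default 1).
#' @param minPixels minimum region size (default 100).
#' @return estimated background level (numeric scalar).
#' @export
estimateBackground <- function(image, mask = NULL, binWidth = 1,
                               minPixels = 100) {
  stopifnot(binWidth >= 1)
  px <- if (is.null(mask)) as.vector(image) else image[mask]
  if (length(px) < minPixels)
    stop("background region too small (", length(px), " px, need >= ",
         minPixels, ")")
  idx <- floor(px / binWidth)
  tab <- table(idx)
  top <- as.numeric(names(tab)[which.max(tab)])  # which.max: first = lowest bin
  top * binWidth + (binWidth - 1) / 2
}

#' Threshold a channel against its background
#'
#' Subtracts the background and keeps only pixels whose
#' background-subtracted value strictly exceeds \code{k} times the
#' background ("k-fold over background"); all other pixels are discarded.
#' A zero background retains every positive pixel, with a warning.
#'
#' @param image numeric matrix of intensities.
#' @param background background level (from
#'   \code{\link{estimateBackground}}).
#' @param k fold-over-background cutoff (> 0).
#' @return list with \code{values} (retained background-subtracted pixel
#'   values) and \code{n} (their count).
#' @export
thresholdChannel <- function(image, background, k) {
  stopifnot(k > 0, background >= 0)
  if (background == 0)
    warning("background is 0: every positive pixel is retained")
  v <- as.vector(image) - background
  keep <- v > k * background
  list(values = v[keep], n = sum(keep))
}

#' Quantify one field: thresholded channel means and surface:total ratio
#'
#' Per channel, the background is estimated (most populated histogram bin of
#' the mask region or whole image), the channel is thresholded at its own
#' fold-over-background cutoff (a stringent 7x for the surface channel and
#' 20x for the total channel by default), and the mean of the retained
#' background-subtracted pixels is computed. The field's ratio is the mean
#' surface intensity divided by the mean total intensity (one ratio per
#' field). A field in which either channel retains no pixels is flagged
#' invalid with a warning and should be excluded from aggregation.
#'
#' @param field a \linkS4class{FieldImage}.
#' @param kSurface surface-channel cutoff (default 7).
#' @param kTotal total-channel cutoff (default 20).
#' @param binWidth background histogram bin width (default 1).
#' @return one-row data.frame: background_surface, background_total,
#'   mean_surface, mean_total, ratio, n_pixels_surface, n_pixels_total,
#'   valid.
#' @export
quantifyField <- function(field, kSurface = 7, kTotal = 20, binWidth = 1) {
  stopifnot(is(field, "FieldImage"))
  mask <- field@backgroundMask
  bs <- estimateBackground(field@surface, mask, binWidth)
  bt <- estimateBackground(field@total, mask, binWidth)
  ts <- thresholdChannel(field@surface, bs, kSurface)
  tt <- thresholdChannel(field@total, bt, kTotal)
  valid <- ts$n > 0 && tt$n > 0
  if (!valid)
    warning("field invalid: a channel retained no pixels above threshold")
  ms <- if (ts$n > 0) mean(ts$values) else NA_real_
  mt <- if (tt$n > 0) mean(tt$values) else NA_real_
  data.frame(background_surface = bs, background_total = bt,
             mean_surface = ms, mean_total = mt,
             ratio = if (valid) ms / mt else NA_real_,
             n_pixels_surface = ts$n, n_pixels_total = tt$n,
             valid = valid)
}

#' Aggregate field quantifications to condition-level summaries
#'
#' The aggregation hierarchy is pixels, then field, then experiment, then
#' condition: per experiment the mean over its (valid) fields is taken for
#' the surface mean, total mean and ratio; per condition the mean and
#' standard error over experiment means are computed and divided by the
#' control condition's mean, so the control normalizes to exactly 1.
#' Significance of each condition against the control is a two-sided
#' Student's t-test on the experiment-level means (matching error bars
#' drawn over n experiments).
#'
#' @param quants data.frame of per-field rows (as from
#'   \code{\link{quantifyField}}) with added \code{condition} and
#'   \code{experiment} columns.
#' @param controlCondition name of the control condition.
#' @return data.frame, one row per condition: n_experiments,
#'   surface_norm, surface_sem, total_norm, total_sem, ratio_norm,
#'   ratio_sem, p_surface, p_total, p_ratio (NA for the control row).
#' @export
aggregateExperiment <- function(quants, controlCondition) {
  stopifnot(all(c("condition", "experiment", "mean_surface", "mean_total",
                  "ratio", "valid") %in% names(quants)))
  if (!controlCondition %in% quants$condition)
    stop("control condition ", controlCondition, " missing")
  if (any(!quants$valid)) {
    warning(sum(!quants$valid), " invalid field(s) excluded")
    quants <- quants[quants$valid, , drop = FALSE]
  }
  key <- interaction(quants$condition, quants$experiment, drop = TRUE)
  expmeans <- do.call(rbind, lapply(split(quants, key), function(s)
    data.frame(condition = s$condition[1], experiment = s$experiment[1],
               surface = mean(s$mean_surface), total = mean(s$mean_total),
               ratio = mean(s$ratio))))
  ctrl <- expmeans[expmeans$condition == controlCondition, ]
  if (nrow(ctrl) < 2)
    warning("fewer than 2 control experiments: significance tests unreliable")
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  out <- do.call(rbind, lapply(split(expmeans, expmeans$condition), function(s) {
    isctrl <- s$condition[1] == controlCondition
    pfun <- function(metric) {
      if (isctrl) return(NA_real_)
      .welch(s[[metric]], ctrl[[metric]])
    }
    data.frame(
      condition = s$condition[1], n_experiments = nrow(s),
      surface_norm = mean(s$surface) / mean(ctrl$surface),
      surface_sem = sem(s$surface) / mean(ctrl$surface),
      total_norm = mean(s$total) / mean(ctrl$total),
      total_sem = sem(s$total) / mean(ctrl$total),
      ratio_norm = mean(s$ratio) / mean(ctrl$ratio),
      ratio_sem = sem(s$ratio) / mean(ctrl$ratio),
      p_surface = pfun("surface"), p_total = pfun("total"),
      p_ratio = pfun("ratio"), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
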