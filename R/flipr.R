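#' Baseline-normalize a FLIPR trace (dF/F0)
#'
#' F0 is the mean fluorescence over the baseline window [0, baselineWindow]
#' (3 minutes by default, the standard pre-agonist read); the normalized
#' trace is (F(t) - F0) / F0. Multiplying the raw trace by any positive
#' constant leaves dF/F0 unchanged.
#'
#' @param trace a \linkS4class{FLIPRTrace}.
#' @param baselineWindow baseline duration in seconds (default 180); must
#'   not extend past the agonist addition.
#' @return the trace with \code{dff0} and \code{f0} slots filled.
#' @export
computeDFF0 <- function(trace, baselineWindow = 180) {
  stopifnot(is(trace, "FLIPRTrace"))
  if (baselineWindow > trace@fskTime)
    stop("baseline window extends past the agonist addition")
  base <- trace@time >= 0 & trace@time <= baselineWindow
  if (sum(base) < 3) stop("fewer than 3 samples in the baseline window")
  f0 <- mean(trace@fluorescence[base])
  if (f0 <= 0) stop("baseline fluorescence F0 must be positive")
  trace@f0 <- f0
  trace@dff0 <- (trace@fluorescence - f0) / f0
  trace
}

#' Quantify the agonist response and inhibitor sensitivity of a trace
#'
#' The peak dF/F0 is the maximum normalized sample in the agonist window
#' (after forskolin addition, up to and including the inhibitor addition;
#' raw samples, no smoothing, unless \code{smoothWidth} > 1 applies a
#' centred moving average first). The post-inhibitor level is the mean over
#' the final \code{postWindowFrac} fraction of samples after the inhibitor,
#' and the inhibitor-sensitive fraction is (peak - post) / peak. A
#' non-positive peak marks the well as having no agonist response (the
#' uninduced / trafficking-defective phenotype); a fraction outside [0, 1]
#' is flagged but returned.
#'
#' @param trace a \linkS4class{FLIPRTrace} with \code{dff0} computed.
#' @param postWindowFrac fraction of post-inhibitor samples averaged for
#'   the post-inhibitor level (default 0.2, the final 20 percent).
#' @param smoothWidth optional moving-average width in samples (default 1 =
#'   no smoothing).
#' @return list: f0, peak_dff0, post_inhibitor_level,
#'   inhibitor_sensitive_fraction (NA when there is no agonist response),
#'   responsive (logical), fraction_in_range (logical or NA).
#' @export
quantifyResponse <- function(trace, postWindowFrac = 0.2, smoothWidth = 1) {
  stopifnot(is(trace, "FLIPRTrace"))
  if (!length(trace@dff0)) stop("dff0 not computed; run computeDFF0 first")
  stopifnot(postWindowFrac > 0, postWindowFrac <= 1, smoothWidth >= 1)
  y <- trace@dff0
  if (smoothWidth > 1) {
    k <- rep(1 / smoothWidth, smoothWidth)
    y <- as.numeric(stats::filter(y, k, sides = 2))
  }
  t <- trace@time
  win <- t > trace@fskTime & t <= trace@inhTime & !is.na(y)
  if (!any(win)) stop("no samples in the agonist window")
  peak <- max(y[win])
  post_idx <- which(t > trace@inhTime & !is.na(y))
  if (!length(post_idx)) stop("no samples after the inhibitor addition")
  ntail <- max(1L, ceiling(postWindowFrac * length(post_idx)))
  post <- mean(y[utils::tail(post_idx, ntail)])
  responsive <- peak > 0
  frac <- if (responsive) (peak - post) / peak else NA_real_
  list(f0 = trace@f0, peak_dff0 = peak, post_inhibitor_level = post,
       inhibitor_sensitive_fraction = frac, responsive = responsive,
       fraction_in_range = if (responsive) frac >= 0 && frac <= 1 else NA)
}
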