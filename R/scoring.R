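#' Replicate-correlation quality control
#'
#' Computes the squared Pearson correlation of per-prey spectral counts
#' between every pair of runs of one bait condition (preys absent from a run
#' count as zero) and passes the condition when the mean R-squared exceeds
#' the threshold. Counts are used raw, without transformation. Pairs whose
#' correlation is negative are additionally flagged anti-correlated, since
#' squaring would otherwise hide them.
#'
#' @param x a \linkS4class{SpectralCountTable}.
#' @param condition bait condition to check (not \code{"control"}).
#' @param qcThreshold minimum mean R-squared (default 0.9).
#' @return list with \code{pairs} (data.frame run_a, run_b, r, r_squared,
#'   anti_correlated), \code{mean_r_squared} and \code{pass}.
#' @export
replicateQC <- function(x, condition, qcThreshold = 0.9) {
  mat <- .runCountMatrix(x, condition)
  if (ncol(mat) < 2) stop("insufficient replicates for condition ", condition)
  combs <- utils::combn(colnames(mat), 2)
  r <- apply(combs, 2, function(p) {
    a <- mat[, p[1]]; b <- mat[, p[2]]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  })
  pairs <- data.frame(run_a = combs[1, ], run_b = combs[2, ],
                      r = r, r_squared = r^2,
                      anti_correlated = !is.na(r) & r < 0)
  m <- mean(pairs$r_squared, na.rm = TRUE)
  list(pairs = pairs, mean_r_squared = m, pass = is.finite(m) && m > qcThreshold)
}

# prey x run matrix of counts for one condition (absent = 0)
.runCountMatrix <- function(x, condition) {
  df <- countData(x)
  df <- df[df$condition == condition, , drop = FALSE]
  if (!nrow(df)) stop("no runs for condition ", condition)
  runs <- sort(unique(df$run_id))
  preysv <- sort(unique(df$prey))
  mat <- matrix(0, nrow = length(preysv), ncol = length(runs),
                dimnames = list(preysv, runs))
  mat[cbind(match(df$prey, preysv), match(df$run_id, runs))] <- df$count
  mat
}

#' Score prey-bait proximity interactions against control runs
#'
#' A documented stand-in for a SAINT-style spectral-count scorer. For each
#' prey the control runs define a Gamma posterior for the background rate
#' (prior Gamma(\code{pseudoRate}, \code{pseudoRate}), a weak symmetric
#' smoothing); the alternative model states that a genuine proximity
#' interactor is labelled at \code{enrichmentFold} times the background
#' rate. Both models are marginalized over the rate uncertainty, giving
#' negative-binomial predictive likelihoods for the bait-run counts, and the
#' posterior probability of interaction is computed under a two-component
#' mixture whose weight is estimated from the data by EM (bounded to
#' [\code{minWeight}, 0.5]). The log Bayes factor is linear in the summed
#' bait counts, so the probability is monotone non-decreasing in the
#' bait-run counts for fixed controls.
#'
#' Preys with zero counts in all bait runs are omitted. The result is ranked
#' by decreasing probability, ties broken by higher average count and then
#' prey name; \code{bfdr} is left \code{NA} until \code{\link{computeBFDR}}.
#'
#' @param x a \linkS4class{SpectralCountTable} containing at least one
#'   control run and at least one run of \code{condition}.
#' @param condition bait condition to score.
#' @param pseudoRate Gamma prior shape and rate for the control model
#'   (default 0.1).
#' @param enrichmentFold assumed fold-enrichment of a true interactor over
#'   the control background (default 20).
#' @param minWeight lower bound for the EM mixture weight (default 0.02).
#' @return A \linkS4class{ScoredInteractions}.
#' @export
scoreInteractions <- function(x, condition, pseudoRate = 0.1,
                              enrichmentFold = 20, minWeight = 0.02) {
  stopifnot(pseudoRate > 0, enrichmentFold > 1)
  df <- countData(x)
  if (!any(df$condition == "control")) stop("no control runs in table")
  if (!any(df$condition == condition)) stop("no runs for condition ", condition)
  bait <- unique(df$bait[df$condition == condition])
  if (length(bait) != 1)
    stop("condition ", condition, " mixes baits: ", paste(bait, collapse = ", "))

  bmat <- .runCountMatrix(x, condition)
  cmat <- .runCountMatrix(x, "control")
  keep <- rowSums(bmat) > 0
  bmat <- bmat[keep, , drop = FALSE]
  if (!nrow(bmat))
    return(ScoredInteractions(data.frame(
      bait = character(), condition = character(), prey = character(),
      avg_count = numeric(), prob = numeric(), bfdr = numeric(),
      control_counts = I(list()))))
  ctrl <- matrix(0, nrow(bmat), ncol(cmat),
                 dimnames = list(rownames(bmat), colnames(cmat)))
  shared <- intersect(rownames(bmat), rownames(cmat))
  ctrl[shared, ] <- cmat[shared, , drop = FALSE]

  n <- ncol(bmat); m <- ncol(cmat)
  Sx <- rowSums(bmat); Sc <- rowSums(ctrl)
  a0 <- Sc + pseudoRate
  b0 <- m + pseudoRate
  phi <- enrichmentFold
  lbf <- -a0 * log(phi) + (a0 + Sx) * log((b0 + n) / (b0 / phi + n))

  # mixture weight by direct maximum likelihood (concave in w)
  loglik <- function(w) sum(log(w * exp(pmin(lbf, 700)) + (1 - w)))
  w <- stats::optimize(loglik, c(minWeight, 0.5), maximum = TRUE,
                       tol = 1e-10)$maximum
  if (loglik(minWeight) >= loglik(w)) w <- minWeight
  if (loglik(0.5) >= loglik(w)) w <- 0.5
  prob <- stats::plogis(lbf + log(w / (1 - w)))

  avg <- Sx / n
  o <- order(-prob, -avg, rownames(bmat))
  ScoredInteractions(data.frame(
    bait = bait, condition = condition, prey = rownames(bmat)[o],
    avg_count = avg[o], prob = prob[o], bfdr = NA_real_,
    control_counts = I(lapply(o, function(i) unname(ctrl[i, ]))),
    stringsAsFactors = FALSE))
}

#' Compute the Bayesian false discovery rate down the ranked list
#'
#' The SAINT convention: after ranking by decreasing probability (ties
#' broken by higher average count, then prey name), the BFDR at rank k is
#' the mean of (1 - prob) over the top k interactions. The result is
#' non-decreasing down the ranking by construction; this is asserted on
#' every call.
#'
#' @param scored a \linkS4class{ScoredInteractions} with probabilities.
#' @return the same object, re-ranked, with \code{bfdr} filled.
#' @export
computeBFDR <- function(scored) {
  df <- scoredData(scored)
  if (!nrow(df)) return(scored)
  out <- lapply(split(df, paste(df$bait, df$condition, sep = "\r")), function(sub) {
    o <- order(-sub$prob, -sub$avg_count, sub$prey)
    sub <- sub[o, , drop = FALSE]
    sub$bfdr <- cumsum(1 - sub$prob) / seq_len(nrow(sub))
    stopifnot(all(diff(sub$bfdr) >= -1e-12))
    sub
  })
  ScoredInteractions(do.call(rbind, c(out, make.row.names = FALSE)))
}

#' Filter to high-confidence interactions
#'
#' Retains preys whose BFDR does not exceed \code{bfdrMax} (the
#' high-confidence gate; default 1\%), preserving the ranking order.
#'
#' @param scored a \linkS4class{ScoredInteractions} with \code{bfdr} filled.
#' @param bfdrMax BFDR cutoff in (0, 1] (default 0.01).
#' @return A \linkS4class{ScoredInteractions} subset.
#' @export
filterHighConfidence <- function(scored, bfdrMax = 0.01) {
  stopifnot(bfdrMax > 0, bfdrMax <= 1)
  df <- scoredData(scored)
  if (anyNA(df$bfdr)) stop("bfdr not computed; run computeBFDR first")
  ScoredInteractions(df[df$bfdr <= bfdrMax, , drop = FALSE])
}

#' High-confidence prey set
#'
#' Convenience accessor: the prey symbols passing the BFDR gate.
#' @param scored a \linkS4class{ScoredInteractions} with \code{bfdr} filled.
#' @param bfdrMax BFDR cutoff (default 0.01).
#' @return character vector of prey symbols.
#' @export
highConfidencePreys <- function(scored, bfdrMax = 0.01) {
  preys(filterHighConfidence(scored, bfdrMax))
}
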