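#' Bait self-count abundances per condition
#'
#' Mean spectral count of the bait protein itself (prey symbol equal to the
#' bait name) across each condition's runs, the denominator used to put
#' interactomes of differently abundant baits on a common scale.
#'
#' @param x a \linkS4class{SpectralCountTable}.
#' @return named numeric vector, one mean self-count per non-control
#'   condition.
#' @export
baitSelfCounts <- function(x) {
  df <- countData(x)
  df <- df[df$condition != "control", , drop = FALSE]
  conds <- unique(df$condition)
  out <- vapply(conds, function(cc) {
    sub <- df[df$condition == cc, ]
    bait <- unique(sub$bait)
    runs <- unique(sub$run_id)
    self <- sub[sub$prey %in% bait, ]
    sum(self$count) / length(runs)  # runs without a self row count as zero
  }, 0)
  names(out) <- conds
  out
}

#' Normalize scored interactomes by bait abundance
#'
#' Rescales each condition's average prey counts by the ratio of the
#' reference condition's bait self-count to its own, so that differences in
#' bait expression (e.g. a proteasome-inhibitor-stabilized mutant labelling
#' itself twice as much) do not masquerade as interaction changes. The
#' reference condition is left unchanged.
#'
#' @param scoredList named list of \linkS4class{ScoredInteractions}, one per
#'   condition.
#' @param abundances named numeric vector of bait self-count means (e.g.
#'   from \code{\link{baitSelfCounts}}).
#' @param reference name of the reference condition.
#' @return the list with a \code{norm_count} column added to each element.
#' @export
normalizeByBait <- function(scoredList, abundances, reference) {
  stopifnot(is.list(scoredList), !is.null(names(scoredList)))
  if (!reference %in% names(abundances))
    stop("bait not detected: no self-count for reference ", reference)
  miss <- setdiff(names(scoredList), names(abundances))
  if (length(miss))
    stop("bait not detected: no self-count for ", paste(miss, collapse = ", "))
  if (any(abundances[names(scoredList)] <= 0) || abundances[reference] <= 0)
    stop("bait not detected: zero self-count")
  ref <- abundances[[reference]]
  out <- lapply(names(scoredList), function(cc) {
    df <- scoredData(scoredList[[cc]])
    df$norm_count <- df$avg_count * ref / abundances[[cc]]
    ScoredInteractions(df)
  })
  names(out) <- names(scoredList)
  out
}

#' Normalize a count table by bait abundance, run-wise
#'
#' Scales every run's counts of each condition by the reference-to-condition
#' bait self-count ratio, yielding a table of (generally fractional)
#' normalized counts suitable for \code{\link{volcanoStats}} or re-scoring.
#'
#' @param x a \linkS4class{SpectralCountTable}.
#' @param reference reference condition name.
#' @param abundances optional named self-count vector; computed with
#'   \code{\link{baitSelfCounts}} when absent.
#' @return a \linkS4class{SpectralCountTable} with scaled counts (control
#'   runs unchanged).
#' @export
normalizeCountTable <- function(x, reference, abundances = NULL) {
  if (is.null(abundances)) abundances <- baitSelfCounts(x)
  if (!reference %in% names(abundances) || abundances[[reference]] <= 0)
    stop("bait not detected: no self-count for reference ", reference)
  df <- countData(x)
  fac <- rep(1, nrow(df))
  for (cc in setdiff(unique(df$condition), "control")) {
    if (!cc %in% names(abundances) || abundances[[cc]] <= 0)
      stop("bait not detected: no self-count for ", cc)
    fac[df$condition == cc] <- abundances[[reference]] / abundances[[cc]]
  }
  df$count <- df$count * fac
  SpectralCountTable(df)
}

#' Log2 fold change with pseudocount
#'
#' \code{log2((alt + pseudocount) / (ref + pseudocount))}; the pseudocount
#' keeps presence/absence contrasts finite.
#'
#' @param ref,alt non-negative (normalized) counts; vectorized.
#' @param pseudocount positive stabilizer (default 0.5).
#' @return numeric log2 fold change(s), alt over ref.
#' @export
computeLog2FC <- function(ref, alt, pseudocount = 0.5) {
  stopifnot(pseudocount > 0)
  log2((alt + pseudocount) / (ref + pseudocount))
}

.callCounts <- function(scored) {
  df <- scoredData(scored)
  cnt <- if (!is.null(df$norm_count)) df$norm_count else df$avg_count
  stats::setNames(cnt, df$prey)
}

.lookup <- function(v, nm) ifelse(nm %in% names(v), v[nm], 0)

#' Classify gained, lost and unchanged interactions between two conditions
#'
#' Preys high-confidence (BFDR at or below \code{bfdrMax}) in at least one
#' of the two conditions are compared by log2 fold change of their
#' (bait-normalized, when available) average counts: gained at or above
#' \code{+fcThreshold}, lost at or below \code{-fcThreshold} (boundaries
#' inclusive), unchanged otherwise. Preys seen in either interactome but
#' high-confidence in neither are excluded with a warning.
#'
#' @param ref,alt \linkS4class{ScoredInteractions} for the two conditions,
#'   with \code{bfdr} filled (and \code{norm_count} after
#'   \code{\link{normalizeByBait}}, which is used when present).
#' @param fcThreshold log2 fold-change threshold (default 1.0).
#' @param bfdrMax high-confidence gate (default 0.01).
#' @param pseudocount for \code{\link{computeLog2FC}} (default 0.5).
#' @return data.frame with columns prey, count_ref, count_alt, log2fc,
#'   class.
#' @export
classifyPairwise <- function(ref, alt, fcThreshold = 1, bfdrMax = 0.01,
                             pseudocount = 0.5) {
  hc <- union(highConfidencePreys(ref, bfdrMax),
              highConfidencePreys(alt, bfdrMax))
  seen <- union(preys(ref), preys(alt))
  dropped <- setdiff(seen, hc)
  if (length(dropped))
    warning(length(dropped), " prey(s) high-confidence in neither condition excluded")
  if (!length(hc))
    return(data.frame(prey = character(), count_ref = numeric(),
                      count_alt = numeric(), log2fc = numeric(),
                      class = character()))
  cr <- .lookup(.callCounts(ref), hc)
  ca <- .lookup(.callCounts(alt), hc)
  lfc <- computeLog2FC(cr, ca, pseudocount)
  cls <- ifelse(lfc >= fcThreshold, "gained",
                ifelse(lfc <= -fcThreshold, "lost", "unchanged"))
  out <- data.frame(prey = hc, count_ref = unname(cr), count_alt = unname(ca),
                    log2fc = unname(lfc), class = cls,
                    stringsAsFactors = FALSE)
  out[order(out$prey), , drop = FALSE]
}

#' Classify drug-restored, attenuated and non-responsive interactions
#'
#' Three-condition comparison of a wild-type interactome, a mutant
#' interactome and the mutant under corrector therapy, all scored and
#' normalized against a common reference. Per prey (over the union of the
#' three high-confidence sets):
#' \itemize{
#'   \item \emph{restored}: in the WT high-confidence set, lost from the
#'     mutant (not high-confidence there, or down by at least
#'     \code{fcThreshold} in log2), and high-confidence again under drug;
#'   \item \emph{attenuated}: elevated in the mutant relative to WT by at
#'     least \code{+fcThreshold} and reduced by the drug by at least
#'     \code{fcThreshold} in log2;
#'   \item \emph{non_responsive}: elevated in the mutant and essentially
#'     unchanged by the drug (absolute drug-vs-mutant log2 fold change
#'     below \code{fcThreshold});
#'   \item \emph{other}: everything else.
#' }
#' Classes are assigned in that priority order, so restored and attenuated
#' sets are disjoint by construction (asserted on every run).
#'
#' @param wt,mut,mutDrug \linkS4class{ScoredInteractions} with \code{bfdr}
#'   filled and (recommended) \code{norm_count} present.
#' @param fcThreshold log2 fold-change threshold (default 1.0).
#' @param bfdrMax high-confidence gate (default 0.01).
#' @param pseudocount for \code{\link{computeLog2FC}} (default 0.5).
#' @return data.frame with columns prey, count_wt, count_mut,
#'   count_mut_drug, lfc_mut_wt, lfc_drug_mut, class.
#' @export
classifyRestored <- function(wt, mut, mutDrug, fcThreshold = 1,
                             bfdrMax = 0.01, pseudocount = 0.5) {
  for (obj in list(wt, mut, mutDrug))
    if (anyNA(scoredData(obj)$bfdr)) stop("bfdr not computed; run computeBFDR")
  hc_wt <- highConfidencePreys(wt, bfdrMax)
  hc_mut <- highConfidencePreys(mut, bfdrMax)
  hc_drug <- highConfidencePreys(mutDrug, bfdrMax)
  all <- sort(union(hc_wt, union(hc_mut, hc_drug)))
  cw <- .lookup(.callCounts(wt), all)
  cm <- .lookup(.callCounts(mut), all)
  cd <- .lookup(.callCounts(mutDrug), all)
  lfc_mw <- computeLog2FC(cw, cm, pseudocount)
  lfc_dm <- computeLog2FC(cm, cd, pseudocount)
  restored <- (all %in% hc_wt) &
    (!(all %in% hc_mut) | lfc_mw <= -fcThreshold) &
    (all %in% hc_drug)
  attenuated <- lfc_mw >= fcThreshold & lfc_dm <= -fcThreshold
  nonresp <- lfc_mw >= fcThreshold & abs(lfc_dm) < fcThreshold
  cls <- rep("other", length(all))
  cls[nonresp] <- "non_responsive"
  cls[attenuated] <- "attenuated"
  cls[restored] <- "restored"
  stopifnot(length(intersect(all[cls == "restored"], all[cls == "attenuated"])) == 0)
  data.frame(prey = all, count_wt = unname(cw), count_mut = unname(cm),
             count_mut_drug = unname(cd), lfc_mut_wt = unname(lfc_mw),
             lfc_drug_mut = unname(lfc_dm), class = cls,
             stringsAsFactors = FALSE)
}

.welch <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  ma <- mean(a); mb <- mean(b)
  if (va == 0 && vb == 0) {
    if (isTRUE(all.equal(ma, mb))) return(1)
    warning("zero variance in both groups with unequal means; p floored")
    return(.Machine$double.xmin)
  }
  se2 <- va / na + vb / nb
  tt <- (ma - mb) / sqrt(se2)
  dfree <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  2 * stats::pt(-abs(tt), dfree)
}

#' Volcano statistics between two conditions
#'
#' Per prey (union over both conditions' runs, absent counts as zero):
#' the log2 fold change of mean counts (with pseudocount) and the two-sided
#' Welch t-test p-value on log2(count + 1) across replicates. Preys are
#' flagged red when the alternative condition has lower counts (log2FC at
#' or below \code{-flagThreshold}) and green when higher (at or above
#' \code{+flagThreshold}). Raw p-values are reported (volcano plots show
#' unadjusted -log10 p); Benjamini-Hochberg q-values are supplied alongside.
#' Pass a bait-normalized table (\code{\link{normalizeCountTable}}) to work
#' on normalized counts.
#'
#' @param x a \linkS4class{SpectralCountTable}.
#' @param condA,condB the two conditions (fold changes are B over A).
#' @param flagThreshold log2 fold-change flag threshold (default 0.4).
#' @param pseudocount for \code{\link{computeLog2FC}} (default 0.5).
#' @return data.frame with columns prey, mean_a, mean_b, log2fc, p_value,
#'   neg_log10_p, q_value, flag.
#' @export
volcanoStats <- function(x, condA, condB, flagThreshold = 0.4,
                         pseudocount = 0.5) {
  ma <- .runCountMatrix(x, condA)
  mb <- .runCountMatrix(x, condB)
  if (ncol(ma) < 2 || ncol(mb) < 2)
    stop("need >= 2 replicates per condition")
  allp <- sort(union(rownames(ma), rownames(mb)))
  fill <- function(mat) {
    out <- matrix(0, length(allp), ncol(mat), dimnames = list(allp, colnames(mat)))
    out[rownames(mat), ] <- mat
    out
  }
  ma <- fill(ma); mb <- fill(mb)
  pv <- vapply(seq_along(allp),
               function(i) .welch(log2(ma[i, ] + 1), log2(mb[i, ] + 1)), 0)
  lfc <- computeLog2FC(rowMeans(ma), rowMeans(mb), pseudocount)
  flag <- ifelse(lfc <= -flagThreshold, "red",
                 ifelse(lfc >= flagThreshold, "green", "none"))
  data.frame(prey = allp, mean_a = unname(rowMeans(ma)),
             mean_b = unname(rowMeans(mb)), log2fc = unname(lfc),
             p_value = pv, neg_log10_p = -log10(pv),
             q_value = stats::p.adjust(pv, "BH"), flag = flag,
             stringsAsFactors = FALSE)
}

#' Over-representation test on user-supplied categories
#'
#' One-sided hypergeometric tail test of each category's overlap with a
#' selected prey set against a universe, with Benjamini-Hochberg adjusted
#' q-values. A generic stand-in for web-service GO enrichment: the category
#' definitions are consumed as data, not fetched.
#'
#' @param selected character vector of selected genes (must lie in
#'   \code{universe}).
#' @param annotation data.frame with columns \code{category_id} and
#'   \code{gene} (optional \code{label}).
#' @param universe character vector of all eligible genes.
#' @return data.frame with columns category_id, label, size, overlap,
#'   expected, p_value, q_value.
#' @export
enrichmentTest <- function(selected, annotation, universe) {
  universe <- unique(toupper(universe))
  if (!length(universe)) stop("empty universe")
  selected <- unique(toupper(selected))
  if (!all(selected %in% universe))
    stop("selected genes must be a subset of the universe")
  stopifnot(all(c("category_id", "gene") %in% names(annotation)))
  if (is.null(annotation$label)) annotation$label <- annotation$category_id
  N <- length(universe); n <- length(selected)
  cats <- split(annotation, annotation$category_id)
  out <- do.call(rbind, lapply(cats, function(a) {
    genes <- intersect(unique(toupper(a$gene)), universe)
    K <- length(genes)
    ov <- length(intersect(genes, selected))
    p <- stats::phyper(ov - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(category_id = a$category_id[1], label = a$label[1],
               size = K, overlap = ov, expected = n * K / N, p_value = p,
               stringsAsFactors = FALSE)
  }))
  out$q_value <- stats::p.adjust(out$p_value, "BH")
  rownames(out) <- NULL
  out[order(out$p_value, out$category_id), , drop = FALSE]
}
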