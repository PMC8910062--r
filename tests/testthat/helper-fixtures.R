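# shared fixture builders; everything is generated in code

# quick long-form count table: counts is a named list bait_run -> named
# count vector; control runs are those whose condition is "control"
makeCountTable <- function(runs) {
  rows <- do.call(rbind, lapply(runs, function(r) {
    data.frame(run_id = r$run_id, bait = r$bait, condition = r$condition,
               replicate = r$replicate, prey = names(r$counts),
               count = as.integer(r$counts), stringsAsFactors = FALSE)
  }))
  SpectralCountTable(rows)
}

# one bait condition (4 runs) + controls (2 runs) from per-prey count rows
baitVsControlTable <- function(baitCounts, ctrlCounts,
                               condition = "WT", bait = "CFTR") {
  stopifnot(is.matrix(baitCounts), is.matrix(ctrlCounts))
  runs <- c(
    lapply(seq_len(ncol(baitCounts)), function(j)
      list(run_id = sprintf("%s_r%d", condition, j), bait = bait,
           condition = condition, replicate = j,
           counts = structure(baitCounts[, j], names = rownames(baitCounts)))),
    lapply(seq_len(ncol(ctrlCounts)), function(j)
      list(run_id = sprintf("ctrl_r%d", j), bait = "BirAFlag",
           condition = "control", replicate = j,
           counts = structure(ctrlCounts[, j], names = rownames(ctrlCounts)))))
  # drop zero counts like real search output
  tab <- countData(makeCountTable(runs))
  SpectralCountTable(tab[tab$count > 0, , drop = FALSE])
}

# ScoredInteractions builder for plumbing tests
makeScored <- function(prey, avg, prob = 1 - bfdr,
                       bfdr = rep(0, length(prey)),
                       ctrl = rep(list(c(0, 0)), length(prey)),
                       condition = "WT", bait = "CFTR") {
  ScoredInteractions(data.frame(
    bait = bait, condition = condition, prey = prey, avg_count = avg,
    prob = prob, bfdr = bfdr, control_counts = I(ctrl),
    stringsAsFactors = FALSE))
}

# random valid count table in the canonical form both dialects round-trip
randomCountTable <- function(seed, nRuns = 4, nPreys = 8) {
  set.seed(seed)
  preysv <- sprintf("P%02d", seq_len(nPreys))
  runs <- c(
    lapply(seq_len(nRuns), function(j)
      list(run_id = sprintf("WT_r%d", j), bait = "CFTR", condition = "WT",
           replicate = j,
           counts = structure(rpois(nPreys, 6), names = preysv))),
    lapply(1:2, function(j)
      list(run_id = sprintf("control_c%d", j), bait = "BirAFlag",
           condition = "control", replicate = j,
           counts = structure(rpois(nPreys, 2), names = preysv))))
  tab <- countData(makeCountTable(runs))
  SpectralCountTable(tab[tab$count > 0, , drop = FALSE])
}

# compendium of disjoint marker prey sets (pairwise Jaccard distance 1)
makeCompendium <- function(nMarkers = 20, setSize = 30) {
  do.call(rbind, lapply(seq_len(nMarkers), function(i)
    data.frame(marker_bait = sprintf("MARKER%02d", i),
               compartment = sprintf("compartment%02d", i),
               prey = sprintf("M%02dG%03d", i, seq_len(setSize)),
               stringsAsFactors = FALSE)))
}

sortedCounts <- function(x) {
  df <- countData(x)
  df <- df[order(df$run_id, df$prey), ]
  rownames(df) <- NULL
  df
}
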