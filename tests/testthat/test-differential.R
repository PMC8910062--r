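test_that("bait normalization rescales by self-count ratio and preserves ranks", {
  sc <- list(
    WT = makeScored(c("A", "B"), avg = c(8, 2)),
    dF508 = makeScored(c("A", "B"), avg = c(10, 4), condition = "dF508"))
  ab <- c(WT = 100, dF508 = 50)
  nn <- normalizeByBait(sc, ab, "WT")
  expect_equal(scoredData(nn$dF508)$norm_count, c(20, 8))  # x2
  expect_equal(scoredData(nn$WT)$norm_count, c(8, 2))      # reference unchanged

  # scale factor 1 is the identity
  id <- normalizeByBait(sc, c(WT = 100, dF508 = 100), "WT")
  expect_equal(scoredData(id$dF508)$norm_count, scoredData(sc$dF508)$avg_count)

  # rank order within a condition is preserved
  set.seed(12)
  avg <- runif(50, 0, 40)
  sc2 <- list(WT = makeScored("X", 1),
              M = makeScored(sprintf("P%02d", 1:50), avg, condition = "M"))
  nn2 <- normalizeByBait(sc2, c(WT = 120, M = 37), "WT")
  expect_equal(order(scoredData(nn2$M)$norm_count), order(avg))

  expect_error(normalizeByBait(sc, c(WT = 100), "WT"), "bait not detected")
  expect_error(normalizeByBait(sc, c(WT = 100, dF508 = 0), "WT"), "bait not detected")
})

test_that("normalization is invariant to joint rescaling of a condition", {
  sc <- list(WT = makeScored("A", 8),
             M = makeScored("A", 10, condition = "M"))
  base <- normalizeByBait(sc, c(WT = 100, M = 50), "WT")
  scaled <- list(WT = sc$WT, M = makeScored("A", 10 * 3, condition = "M"))
  out <- normalizeByBait(scaled, c(WT = 100, M = 50 * 3), "WT")
  expect_equal(scoredData(out$M)$norm_count, scoredData(base$M)$norm_count)
})

test_that("log2 fold change with pseudocount matches hand arithmetic", {
  expect_equal(computeLog2FC(8, 2, 0.5), log2(2.5 / 8.5))
  expect_equal(round(computeLog2FC(8, 2, 0.5), 3), -1.766)
  expect_equal(computeLog2FC(7, 7), 0)
  expect_equal(computeLog2FC(0, 0), 0)
  expect_error(computeLog2FC(1, 1, pseudocount = 0))
})

test_that("pairwise classification applies inclusive thresholds and drops
           preys high-confidence in neither condition", {
  ref <- makeScored(c("G", "L", "U", "N"), avg = c(2, 8, 5, 3),
                    bfdr = c(0, 0, 0, 0.5))
  alt <- makeScored(c("G", "L", "U", "N"), avg = c(2^1.2 * 2.5 - 0.5, 3.75, 5, 3),
                    bfdr = c(0, 0, 0, 0.5), condition = "M")
  expect_warning(calls <- classifyPairwise(ref, alt), "neither")
  got <- setNames(calls$class, calls$prey)
  expect_equal(got[["G"]], "gained")        # log2fc = +1.2
  expect_equal(calls$log2fc[calls$prey == "L"], -1)  # boundary ...
  expect_equal(got[["L"]], "lost")          # ... counts as lost
  expect_equal(got[["U"]], "unchanged")
  expect_false("N" %in% calls$prey)
})

test_that("gained and lost swap exactly under condition exchange", {
  set.seed(8)
  n <- 60
  a <- makeScored(sprintf("P%02d", 1:n), avg = runif(n, 0, 30),
                  bfdr = rep(0, n))
  b <- makeScored(sprintf("P%02d", 1:n), avg = runif(n, 0, 30),
                  bfdr = rep(0, n), condition = "M")
  ab <- classifyPairwise(a, b)
  ba <- classifyPairwise(b, a)
  expect_setequal(ab$prey[ab$class == "gained"], ba$prey[ba$class == "lost"])
  expect_setequal(ab$prey[ab$class == "lost"], ba$prey[ba$class == "gained"])
  expect_equal(ab$log2fc, -ba$log2fc[match(ab$prey, ba$prey)])
})

test_that("three-condition classification identifies restored interactions", {
  # present in WT, absent from the mutant, present again under drug
  wt <- makeScored(c("R", "K"), avg = c(12, 6), bfdr = c(0, 0))
  mut <- makeScored("K", avg = 6, bfdr = 0, condition = "mut")
  drug <- makeScored(c("R", "K"), avg = c(11, 6), bfdr = c(0, 0),
                     condition = "drug")
  out <- classifyRestored(wt, mut, drug)
  expect_equal(out$class[out$prey == "R"], "restored")
  expect_equal(out$class[out$prey == "K"], "other")
  # a prey absent everywhere never enters the table
  expect_false("GHOST" %in% out$prey)
})

test_that("attenuated and non-responsive mutant gains are separated", {
  wt <- makeScored(c("ATT", "NRS"), avg = c(2, 2), bfdr = c(0, 0))
  mut <- makeScored(c("ATT", "NRS"), avg = c(20, 20), bfdr = c(0, 0),
                    condition = "mut")
  drug <- makeScored(c("ATT", "NRS"), avg = c(2, 19), bfdr = c(0, 0),
                     condition = "drug")
  out <- classifyRestored(wt, mut, drug)
  expect_equal(out$class[out$prey == "ATT"], "attenuated")
  expect_equal(out$class[out$prey == "NRS"], "non_responsive")
  expect_length(intersect(out$prey[out$class == "restored"],
                          out$prey[out$class == "attenuated"]), 0)
})

test_that("volcano statistics: flags, degenerate variances and null p-values", {
  preysv <- c("SAME", "UP", "DOWN")
  mk <- function(cond, counts) lapply(1:4, function(r)
    list(run_id = sprintf("%s_r%d", cond, r), bait = "CFTR", condition = cond,
         replicate = r, counts = structure(counts[, r], names = preysv)))
  a <- matrix(c(5, 4, 16), 3, 4, dimnames = list(preysv, NULL))
  b <- matrix(c(5, 16, 4), 3, 4, dimnames = list(preysv, NULL))
  tab <- makeCountTable(c(mk("A", a), mk("B", b)))
  wrns <- testthat::capture_warnings(vs <- volcanoStats(tab, "A", "B"))
  expect_true(all(grepl("floored", wrns)))
  expect_length(wrns, 2)  # one per degenerate prey
  same <- vs[vs$prey == "SAME", ]
  expect_equal(same$log2fc, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$flag, "none")
  expect_equal(vs$flag[vs$prey == "UP"], "green")
  expect_equal(vs$flag[vs$prey == "DOWN"], "red")
  expect_equal(vs$p_value[vs$prey == "UP"], .Machine$double.xmin)
})

test_that("volcano p-values are roughly uniform under a Poisson null", {
  set.seed(42)
  mk <- function(cond) do.call(rbind, lapply(1:4, function(r)
    data.frame(run_id = paste0(cond, "_r", r), bait = "CFTR", condition = cond,
               replicate = r, prey = sprintf("P%03d", 1:500),
               count = rpois(500, 10), stringsAsFactors = FALSE)))
  tab <- SpectralCountTable(rbind(mk("A"), mk("B")))
  vs <- volcanoStats(tab, "A", "B")
  ks <- suppressWarnings(stats::ks.test(vs$p_value, "punif"))$statistic
  expect_lt(unname(ks), 0.1)
})

test_that("over-representation test matches exact enumeration", {
  universe <- c("A", "B", "C", "D", "E", "F")
  ann <- data.frame(category_id = "cat1", gene = c("A", "B", "C"))
  # selected equal to the category: maximal overlap, minimal p for the draw
  res <- enrichmentTest(c("A", "B", "C"), ann, universe)
  expect_equal(res$overlap, 3)
  expect_equal(res$p_value, 1 / choose(6, 3))
  # disjoint selection: p ~ 1
  res2 <- enrichmentTest(c("D", "E", "F"), ann, universe)
  expect_equal(res2$p_value, 1)

  # brute-force enumeration over all draws of size 3 from the universe
  sel <- c("A", "B", "D")
  res3 <- enrichmentTest(sel, ann, universe)
  draws <- combn(universe, 3)
  ge <- mean(apply(draws, 2, function(d)
    length(intersect(d, ann$gene)) >= res3$overlap))
  expect_equal(res3$p_value, ge, tolerance = 1e-12)

  expect_error(enrichmentTest("A", ann, character(0)), "empty universe")
  expect_error(enrichmentTest("Z", ann, universe), "subset")
})
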