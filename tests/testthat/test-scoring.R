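test_that("replicate QC recovers perfect, anti- and un-correlated runs", {
  counts <- matrix(c(1, 2, 3, 1, 2, 3), ncol = 2,
                   dimnames = list(c("A", "B", "C"), NULL))
  tab <- baitVsControlTable(counts, matrix(1, 3, 2, dimnames = list(c("A", "B", "C"), NULL)))
  qc <- replicateQC(tab, "WT")
  expect_equal(qc$mean_r_squared, 1)
  expect_true(qc$pass)
  expect_false(any(qc$pairs$anti_correlated))

  anti <- matrix(c(1, 2, 3, 3, 2, 1), ncol = 2,
                 dimnames = list(c("A", "B", "C"), NULL))
  qc2 <- replicateQC(baitVsControlTable(anti, matrix(1, 3, 2, dimnames = list(c("A", "B", "C"), NULL))), "WT")
  expect_equal(qc2$mean_r_squared, 1)  # squaring hides the sign ...
  expect_true(all(qc2$pairs$anti_correlated))  # ... so the flag reports it

  # independent Poisson runs decorrelate; compare against longhand Pearson
  set.seed(21)
  poisson2 <- matrix(rpois(400, 5), ncol = 2,
                     dimnames = list(sprintf("P%03d", 1:200), NULL))
  tab3 <- baitVsControlTable(poisson2, matrix(1, 1, 2, dimnames = list("P001", NULL)))
  qc3 <- replicateQC(tab3, "WT")
  expect_lt(qc3$mean_r_squared, 0.9)
  m <- proxitome:::.runCountMatrix(tab3, "WT")
  a <- m[, 1]; b <- m[, 2]
  r_hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(qc3$pairs$r_squared, r_hand^2, tolerance = 1e-12)
})

test_that("replicate QC needs at least two runs", {
  one <- matrix(1:3, ncol = 1, dimnames = list(c("A", "B", "C"), NULL))
  tab <- baitVsControlTable(one, matrix(1, 3, 2, dimnames = list(c("A", "B", "C"), NULL)))
  expect_error(replicateQC(tab, "WT"), "insufficient replicates")
})

test_that("scoring gives near-certain probability to strong enrichment and
           low probability to control-matched counts", {
  strong <- baitVsControlTable(
    matrix(10, 1, 4, dimnames = list("HIT", NULL)),
    matrix(0, 1, 2, dimnames = list("HIT", NULL)))
  # all-zero controls leave no control rows; add a contaminant to keep runs
  df <- countData(strong)
  ctrl <- data.frame(run_id = c("ctrl_r1", "ctrl_r2"), bait = "BirAFlag",
                     condition = "control", replicate = 1:2, prey = "JUNK",
                     count = c(3L, 2L))
  tab <- SpectralCountTable(rbind(df, ctrl))
  sc <- scoredData(scoreInteractions(tab, "WT"))
  expect_gt(sc$prob[sc$prey == "HIT"], 0.99)
  expect_equal(sc$control_counts[[which(sc$prey == "HIT")]], c(0, 0))
  expect_equal(sc$avg_count[sc$prey == "HIT"], 10)

  equal <- baitVsControlTable(
    matrix(5, 1, 4, dimnames = list("BGP", NULL)),
    matrix(5, 1, 2, dimnames = list("BGP", NULL)))
  sce <- scoredData(scoreInteractions(equal, "WT"))
  expect_lte(sce$prob[sce$prey == "BGP"], 0.5)
})

test_that("preys absent from all bait runs are omitted and inputs are checked", {
  tab <- baitVsControlTable(
    matrix(c(4, 4, 4, 4), 1, 4, dimnames = list("A", NULL)),
    matrix(c(2, 0, 3, 0), 2, 2, byrow = TRUE, dimnames = list(c("A", "ONLYCTRL"), NULL)))
  sc <- scoreInteractions(tab, "WT")
  expect_false("ONLYCTRL" %in% preys(sc))

  noctrl <- countData(tab)
  noctrl <- SpectralCountTable(noctrl[noctrl$condition != "control", ])
  expect_error(scoreInteractions(noctrl, "WT"), "no control runs")
  expect_error(scoreInteractions(tab, "missing"), "no runs for condition")
})

test_that("interaction probability is monotone in the bait counts", {
  for (ctrl in list(c(0, 0), c(2, 3), c(10, 12))) {
    probs <- vapply(c(0:30, seq(35, 120, by = 5)), function(k) {
      # filler preys keep every run present when A drops to zero counts
      tab <- baitVsControlTable(
        matrix(c(3, 3, 3, k, 2, 2, 2, 2), 2, 4, byrow = TRUE,
               dimnames = list(c("A", "FILL"), NULL)),
        matrix(c(ctrl, 1, 1), 2, 2, byrow = TRUE,
               dimnames = list(c("A", "JUNK"), NULL)))
      sc <- scoredData(scoreInteractions(tab, "WT"))
      sc$prob[sc$prey == "A"]
    }, 0)
    expect_true(all(diff(probs) >= -1e-12))
  }
})

test_that("BFDR is the cumulative mean of one minus probability", {
  sc <- makeScored(c("A", "B", "C"), avg = 3:1, prob = c(1, 1, 1), bfdr = NA_real_)
  expect_equal(scoredData(computeBFDR(sc))$bfdr, c(0, 0, 0))

  sc2 <- makeScored(c("A", "B"), avg = 2:1, prob = c(1, 0.8), bfdr = NA_real_)
  expect_equal(scoredData(computeBFDR(sc2))$bfdr, c(0, 0.1))

  # oracle: longhand mean over the top-k of the ranked list, 100 random lists
  set.seed(33)
  for (i in 1:100) {
    n <- sample(1:40, 1)
    probs <- runif(n)
    avg <- runif(n, 1, 50)
    sc3 <- makeScored(sprintf("P%02d", 1:n), avg = avg, prob = probs, bfdr = NA_real_)
    got <- scoredData(computeBFDR(sc3))
    o <- order(-probs, -avg, sprintf("P%02d", 1:n))
    brute <- vapply(seq_len(n), function(k) mean(1 - probs[o][1:k]), 0)
    expect_equal(got$bfdr, brute, tolerance = 1e-12)
    expect_true(all(diff(got$bfdr) >= -1e-12))
  }
})

test_that("the high-confidence filter keeps exactly the gated preys in order", {
  sc <- makeScored(c("A", "B", "C"), avg = 3:1, prob = c(1, 0.99, 0.9),
                   bfdr = c(0, 0.005, 0.02))
  expect_equal(preys(filterHighConfidence(sc, 0.01)), c("A", "B"))
  expect_equal(preys(filterHighConfidence(sc, 1.0)), c("A", "B", "C"))
  set.seed(5)
  bf <- sort(runif(30, 0, 0.2))
  sc2 <- makeScored(sprintf("P%02d", 1:30), avg = 30:1,
                    prob = seq(1, 0.5, length.out = 30), bfdr = bf)
  for (b in c(0.01, 0.05, 0.15))
    expect_equal(preys(filterHighConfidence(sc2, b)),
                 sprintf("P%02d", which(bf <= b)))
})
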