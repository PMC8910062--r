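test_that("background is the most populated histogram bin", {
  img <- matrix(100, 20, 20)
  expect_equal(estimateBackground(img), 100)

  # 90% at 50, 10% at 4000: the mode wins, not the mean
  px <- c(rep(50, 360), rep(4000, 40))
  expect_equal(estimateBackground(matrix(px, 20, 20)), 50)

  # discretized Normal(200, 10): mode lands near the centre
  for (seed in 1:20) {
    set.seed(seed)
    img2 <- matrix(round(rnorm(10000, 200, 10)), 100, 100)
    m <- estimateBackground(img2, binWidth = 1)
    expect_gte(m, 195); expect_lte(m, 205)
  }

  # mask restricts the region; small regions error
  img3 <- matrix(10, 20, 20)
  mask <- matrix(FALSE, 20, 20); mask[1:10, ] <- TRUE
  img3[!mask] <- 9999
  expect_equal(estimateBackground(img3, mask), 10)
  expect_error(estimateBackground(matrix(1, 5, 5)), "too small")
})

test_that("thresholding keeps pixels strictly above k-fold background", {
  img <- matrix(c(801, 800, 100, 5000), 2, 2)
  th <- thresholdChannel(img, background = 100, k = 7)
  expect_setequal(th$values, c(701, 4900))
  expect_equal(th$n, 2L)

  expect_equal(thresholdChannel(matrix(50, 3, 3), 100, 7)$n, 0L)
  expect_warning(th0 <- thresholdChannel(matrix(c(0, 3), 1, 2), 0, 7), "background is 0")
  expect_equal(th0$values, 3)

  set.seed(3)
  img2 <- matrix(sample(0:2000, 400, replace = TRUE), 20, 20)
  th2 <- thresholdChannel(img2, 120, 5)
  brute <- sum(vapply(as.vector(img2), function(v) (v - 120) > 5 * 120, NA))
  expect_equal(th2$n, brute)
})

test_that("field quantification recovers a constructed ratio exactly", {
  sim <- simulateFieldImage(imageSimConfig(ratio = 0.5, shotNoise = "none", seed = 2))
  q <- quantifyField(sim$field)
  expect_true(q$valid)
  expect_equal(q$background_surface, 100)
  expect_equal(q$ratio, 0.5)

  # a surface channel at background only invalidates the field
  flat <- FieldImage(surface = matrix(100, 96, 96),
                     total = sim$field@total,
                     backgroundMask = sim$field@backgroundMask)
  expect_warning(q2 <- quantifyField(flat), "invalid")
  expect_false(q2$valid)
  expect_true(is.na(q2$ratio))
})

test_that("ratios are invariant to channel scaling and background offset", {
  sim <- simulateFieldImage(imageSimConfig(ratio = 0.25, shotNoise = "none", seed = 4))
  f <- sim$field
  q <- quantifyField(f)
  scaled <- FieldImage(surface = f@surface * 1.5, total = f@total * 1.5,
                       backgroundMask = f@backgroundMask)
  expect_equal(quantifyField(scaled)$ratio, q$ratio)

  f2 <- simulateFieldImage(imageSimConfig(ratio = 0.5, shotNoise = "none",
                                          seed = 4))$field
  q <- quantifyField(f2)
  offset <- FieldImage(surface = f2@surface + 50, total = f2@total + 50,
                       backgroundMask = f2@backgroundMask)
  qo <- quantifyField(offset)
  expect_equal(qo$mean_surface, q$mean_surface)
  expect_equal(qo$mean_total, q$mean_total)
  expect_equal(qo$ratio, q$ratio)
})

test_that("experiment aggregation normalizes to control and tests by experiment", {
  fld <- function(cond, expi, s, tt) data.frame(
    condition = cond, experiment = expi, background_surface = 100,
    background_total = 100, mean_surface = s, mean_total = tt,
    ratio = s / tt, n_pixels_surface = 10, n_pixels_total = 10, valid = TRUE)
  # identical conditions: everything normalizes to 1, p-values ~ 1
  q <- rbind(fld("ctrl", 1, 10, 20), fld("ctrl", 2, 12, 24),
             fld("treat", 1, 10, 20), fld("treat", 2, 12, 24))
  s <- aggregateExperiment(q, "ctrl")
  expect_equal(s$surface_norm[s$condition == "ctrl"], 1)
  expect_equal(s$ratio_norm[s$condition == "treat"], 1)
  expect_equal(s$p_surface[s$condition == "treat"], 1)
  expect_true(is.na(s$p_surface[s$condition == "ctrl"]))

  # hand arithmetic: experiment means 0.8 and 0.6 against control 1.0, 1.0
  q2 <- rbind(fld("ctrl", 1, 1.0, 1), fld("ctrl", 2, 1.0, 1),
              fld("si", 1, 0.8, 1), fld("si", 2, 0.6, 1))
  s2 <- aggregateExperiment(q2, "ctrl")
  expect_equal(s2$surface_norm[s2$condition == "si"], 0.7)
  expect_equal(s2$surface_sem[s2$condition == "si"],
               stats::sd(c(0.8, 0.6)) / sqrt(2))

  # invalid fields are dropped with a warning; missing control errors
  q3 <- rbind(q, fld("treat", 1, NA, NA))
  q3$valid[nrow(q3)] <- FALSE
  expect_warning(aggregateExperiment(q3, "ctrl"), "invalid")
  expect_error(aggregateExperiment(q, "absent"), "missing")
})
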