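#' Configuration for the BioID spectral-count simulator
#'
#' The default scenario emulates the statistical structure the comparative
#' BioID analysis assumes: three bait conditions (a wild-type reference, a
#' mutant labelling itself twice as much, and the mutant under corrector
#' drug), 2 biological x 2 technical replicates per condition plus 2
#' tag-alone control runs; 60 true interactors with heavy-tailed base rates
#' absent from controls; 600 background contaminants at a common rate in
#' every run; and planted condition effects of |log2FC| = 3 forming gained,
#' lost, restored, attenuated, non-responsive and stable prey groups (ten
#' preys each).
#'
#' @param nBioReps,nTechReps biological / technical replicates per
#'   condition (default 2 x 2, i.e. 4 runs).
#' @param nControlRuns tag-alone control runs (default 2).
#' @param nTruePreys number of true interactors (default 60).
#' @param nBackgroundPreys number of contaminant preys (default 600).
#' @param baitSelfCount named positive vector of bait self-label rates per
#'   condition; the first name is the reference condition and bait-run prey
#'   rates scale with these (labelling is proportional to bait abundance).
#' @param baitName symbol used for the bait's own row (default "CFTR").
#' @param truePreyRateRange base-rate range for true preys; rates are drawn
#'   log-uniformly (default 5 to 300 spectral counts).
#' @param contaminantRate Poisson rate of background preys in every run,
#'   including controls (default 5).
#' @param bioRepSd standard deviation of the log-normal random effect
#'   shared by the technical replicates of one biological replicate
#'   (default 0.2).
#' @param plantedLog2fc magnitude of planted effects (default 3).
#' @param plantedEffects optional data.frame (prey, condition, log2fc)
#'   overriding the default planted design.
#' @param seed integer RNG seed; the generator is deterministic given it.
#' @return a list of class \code{"CountSimConfig"}.
#' @export
countSimConfig <- function(nBioReps = 2, nTechReps = 2, nControlRuns = 2,
                           nTruePreys = 60, nBackgroundPreys = 600,
                           baitSelfCount = c(WT = 300, dF508 = 600,
                                             dF508_Orkambi = 450),
                           baitName = "CFTR",
                           truePreyRateRange = c(5, 300),
                           contaminantRate = 5, bioRepSd = 0.2,
                           plantedLog2fc = 3, plantedEffects = NULL,
                           seed = 1L) {
  stopifnot(nBioReps >= 1, nTechReps >= 1, nControlRuns >= 1,
            nTruePreys >= 0, nBackgroundPreys >= 0,
            all(baitSelfCount > 0), length(names(baitSelfCount)) > 0,
            all(truePreyRateRange > 0), contaminantRate >= 0, bioRepSd >= 0)
  structure(list(nBioReps = nBioReps, nTechReps = nTechReps,
                 nControlRuns = nControlRuns, nTruePreys = nTruePreys,
                 nBackgroundPreys = nBackgroundPreys,
                 baitSelfCount = baitSelfCount, baitName = baitName,
                 truePreyRateRange = truePreyRateRange,
                 contaminantRate = contaminantRate, bioRepSd = bioRepSd,
                 plantedLog2fc = plantedLog2fc,
                 plantedEffects = plantedEffects, seed = as.integer(seed)),
            class = "CountSimConfig")
}

# default planted design: six equal groups of true preys; effects are
# log2FCs of the per-condition rate relative to the reference condition
.defaultPlantedDesign <- function(cfg) {
  conds <- names(cfg$baitSelfCount)
  ntrue <- cfg$nTruePreys
  fc <- cfg$plantedLog2fc
  groups <- c("GAIN", "LOST", "REST", "ATTN", "NRSP", "STBL")
  gsize <- diff(floor(seq(0, ntrue, length.out = length(groups) + 1)))
  grp <- rep(groups, gsize)
  prey <- sprintf("%s%03d", grp, stats::ave(seq_along(grp), grp, FUN = seq_along))
  lfc <- matrix(0, ntrue, length(conds), dimnames = list(prey, conds))
  if (length(conds) >= 2) {
    mut <- conds[2]
    lfc[grp == "GAIN", mut] <- fc
    lfc[grp == "LOST", mut] <- -fc
    lfc[grp == "REST", mut] <- -fc
    lfc[grp == "ATTN", mut] <- fc
    lfc[grp == "NRSP", mut] <- fc
  }
  if (length(conds) >= 3) {
    drug <- conds[3]
    lfc[grp == "GAIN", drug] <- fc    # mutant-specific gain, drug-insensitive
    lfc[grp == "LOST", drug] <- -fc   # lost and not restored by drug
    lfc[grp == "REST", drug] <- 0     # restored to the reference level
    lfc[grp == "ATTN", drug] <- 0     # mutant gain attenuated by drug
    lfc[grp == "NRSP", drug] <- fc    # mutant gain unresponsive to drug
  }
  list(group = grp, prey = prey, lfc = lfc)
}

#' Simulate a BioID spectral-count table with known ground truth
#'
#' True preys are Poisson-distributed in bait runs with rate proportional
#' to the condition's bait self-count (labelling scales with bait
#' abundance), the prey's base rate and 2^(planted log2FC); they are absent
#' from controls. Background preys are Poisson at the contaminant rate in
#' every run, including controls. The technical replicates of one
#' biological replicate share a per-prey log-normal random effect
#' (sd \code{bioRepSd}); control runs are independent. The bait itself
#' appears as a prey row at its self-count rate. Zero counts are not
#' written (absent preys read as zero downstream).
#'
#' @param cfg a \code{\link{countSimConfig}}.
#' @return list: \code{table} (a \linkS4class{SpectralCountTable}),
#'   \code{truth} (per-prey data.frame: role, group, base_rate, planted
#'   log2FCs \code{lfc_<condition>}, \code{pairwise_class_<condition>}
#'   relative to the reference, and \code{trio_class} for the planted
#'   restored / attenuated / non-responsive groups), and \code{config}.
#' @export
simulateBioidCounts <- function(cfg = countSimConfig()) {
  stopifnot(inherits(cfg, "CountSimConfig"))
  set.seed(cfg$seed)
  conds <- names(cfg$baitSelfCount)
  ref <- conds[1]
  design <- if (is.null(cfg$plantedEffects)) .defaultPlantedDesign(cfg) else {
    pe <- cfg$plantedEffects
    prey <- unique(pe$prey)
    lfc <- matrix(0, length(prey), length(conds),
                  dimnames = list(prey, conds))
    lfc[cbind(match(pe$prey, prey), match(pe$condition, conds))] <- pe$log2fc
    list(group = rep("custom", length(prey)), prey = prey, lfc = lfc)
  }
  ntrue <- length(design$prey)
  nbg <- cfg$nBackgroundPreys
  bg_prey <- sprintf("BG%04d", seq_len(nbg))
  base <- exp(stats::runif(ntrue, log(cfg$truePreyRateRange[1]),
                           log(cfg$truePreyRateRange[2])))

  rows <- list()
  emit <- function(run_id, bait, condition, replicate, prey, count) {
    keep <- count > 0
    if (!any(keep)) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      run_id = run_id, bait = bait, condition = condition,
      replicate = replicate, prey = prey[keep], count = count[keep],
      stringsAsFactors = FALSE)
  }

  for (cc in conds) {
    scale <- cfg$baitSelfCount[[cc]] / cfg$baitSelfCount[[ref]]
    rate_true <- base * scale * 2^design$lfc[, cc]
    repl <- 0L
    for (b in seq_len(cfg$nBioReps)) {
      eff_true <- exp(stats::rnorm(ntrue, 0, cfg$bioRepSd))
      eff_bg <- exp(stats::rnorm(nbg, 0, cfg$bioRepSd))
      eff_self <- exp(stats::rnorm(1, 0, cfg$bioRepSd))
      for (tt in seq_len(cfg$nTechReps)) {
        repl <- repl + 1L
        rid <- sprintf("%s_b%dt%d", cc, b, tt)
        emit(rid, cfg$baitName, cc, repl,
             c(design$prey, bg_prey, cfg$baitName),
             stats::rpois(ntrue + nbg + 1L,
                          c(rate_true * eff_true,
                            rep(cfg$contaminantRate, nbg) * eff_bg,
                            cfg$baitSelfCount[[cc]] * eff_self)))
      }
    }
  }
  for (k in seq_len(cfg$nControlRuns)) {
    emit(sprintf("control_c%d", k), "BirAFlag", "control", k,
         bg_prey, stats::rpois(nbg, cfg$contaminantRate))
  }
  table <- SpectralCountTable(do.call(rbind, rows))

  lfc_df <- as.data.frame(design$lfc)
  names(lfc_df) <- paste0("lfc_", conds)
  truth <- data.frame(prey = design$prey, role = "true",
                      group = design$group, base_rate = base,
                      lfc_df, row.names = NULL, stringsAsFactors = FALSE)
  for (cc in conds[-1]) {
    lfc <- design$lfc[, cc]
    truth[[paste0("pairwise_class_", cc)]] <-
      ifelse(lfc >= 1, "gained", ifelse(lfc <= -1, "lost", "unchanged"))
  }
  truth$trio_class <- NA_character_
  truth$trio_class[design$group == "REST"] <- "restored"
  truth$trio_class[design$group == "ATTN"] <- "attenuated"
  truth$trio_class[design$group == "NRSP"] <- "non_responsive"
  if (nbg > 0) {
    bg <- data.frame(prey = bg_prey, role = "contaminant", group = "BG",
                     base_rate = cfg$contaminantRate, stringsAsFactors = FALSE)
    for (nm in setdiff(names(truth), names(bg)))
      bg[[nm]] <- if (startsWith(nm, "pairwise_class")) "unchanged"
                  else if (nm == "trio_class") NA_character_ else 0
    truth <- rbind(truth, bg[names(truth)])
  }
  list(table = table, truth = truth, config = cfg)
}

#' Configuration for the synthetic field-image generator
#'
#' @param fieldShape image dimensions in pixels (default 96 x 96).
#' @param nCells cells per field (default 6).
#' @param cellRadius,ringWidth cell disk radius and membrane ring width in
#'   pixels (defaults 9 and 2).
#' @param ratio true surface:total intensity ratio (default 0.5).
#' @param totalIntensity interior intensity of the total channel above
#'   background (default 4000); the membrane ring in the surface channel is
#'   \code{ratio * totalIntensity}.
#' @param backgroundLevel uniform background added to both channels
#'   (default 100).
#' @param shotNoise \code{"poisson"} (pixel values Poisson-distributed
#'   about their expectation) or \code{"none"}.
#' @param nFields fields per condition set (default 25).
#' @param seed integer RNG seed.
#' @return a list of class \code{"ImageSimConfig"}.
#' @export
imageSimConfig <- function(fieldShape = c(96, 96), nCells = 6,
                           cellRadius = 9, ringWidth = 2, ratio = 0.5,
                           totalIntensity = 4000, backgroundLevel = 100,
                           shotNoise = c("poisson", "none"), nFields = 25,
                           seed = 1L) {
  shotNoise <- match.arg(shotNoise)
  stopifnot(length(fieldShape) == 2, all(fieldShape >= 16), nCells >= 0,
            cellRadius >= 2, ringWidth >= 1, ringWidth < cellRadius,
            ratio > 0, totalIntensity > 0, backgroundLevel >= 0,
            2 * (cellRadius + 2) < min(fieldShape),
            totalIntensity + backgroundLevel <= 65535)
  structure(list(fieldShape = fieldShape, nCells = nCells,
                 cellRadius = cellRadius, ringWidth = ringWidth,
                 ratio = ratio, totalIntensity = totalIntensity,
                 backgroundLevel = backgroundLevel, shotNoise = shotNoise,
                 nFields = nFields, seed = as.integer(seed)),
            class = "ImageSimConfig")
}

#' Simulate one field image with a known surface:total ratio
#'
#' Cells are placed as non-overlapping disks. The total channel carries the
#' disk interior at \code{totalIntensity}; the surface channel carries only
#' the membrane ring at \code{ratio * totalIntensity}. A uniform background
#' is added to both channels and optional Poisson shot noise is applied.
#' The cell-free region (outside all disks, with a safety margin) is
#' recorded as the background mask. With no noise and the default
#' thresholds, \code{\link{quantifyField}} recovers the constructed ratio
#' exactly.
#'
#' @param cfg an \code{\link{imageSimConfig}}.
#' @return list: \code{field} (a \linkS4class{FieldImage}) and
#'   \code{truthRatio}.
#' @export
simulateFieldImage <- function(cfg = imageSimConfig()) {
  stopifnot(inherits(cfg, "ImageSimConfig"))
  set.seed(cfg$seed)
  nr <- cfg$fieldShape[1]; nc <- cfg$fieldShape[2]
  r <- cfg$cellRadius
  centers <- matrix(numeric(0), 0, 2)
  tries <- 0L
  while (nrow(centers) < cfg$nCells) {
    tries <- tries + 1L
    if (tries > 200L * max(1L, cfg$nCells))
      stop("could not place ", cfg$nCells, " non-overlapping cells")
    cand <- c(stats::runif(1, r + 2, nr - r - 1),
              stats::runif(1, r + 2, nc - r - 1))
    if (nrow(centers) == 0 ||
        all(sqrt(rowSums((centers - rep(cand, each = nrow(centers)))^2)) >
            2 * r + 2))
      centers <- rbind(centers, cand)
  }
  rowg <- matrix(seq_len(nr), nr, nc)
  colg <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  dmin <- matrix(Inf, nr, nc)
  for (i in seq_len(nrow(centers))) {
    d <- sqrt((rowg - centers[i, 1])^2 + (colg - centers[i, 2])^2)
    dmin <- pmin(dmin, d)
  }
  disk <- dmin <= r
  ring <- dmin <= r & dmin > r - cfg$ringWidth
  S <- cfg$ratio * cfg$totalIntensity
  surface <- matrix(cfg$backgroundLevel, nr, nc) + ring * S
  total <- matrix(cfg$backgroundLevel, nr, nc) + disk * cfg$totalIntensity
  if (cfg$shotNoise == "poisson") {
    surface <- matrix(stats::rpois(nr * nc, surface), nr, nc)
    total <- matrix(stats::rpois(nr * nc, total), nr, nc)
  }
  surface <- pmin(surface, 65535)
  total <- pmin(total, 65535)
  mask <- dmin > r + 3
  list(field = FieldImage(surface = surface, total = total,
                          backgroundMask = mask),
       truthRatio = cfg$ratio)
}

#' Configuration for the FLIPR trace generator
#'
#' @param samplingInterval seconds between reads (default 5).
#' @param duration total trace length in seconds (default 600).
#' @param baselineLevel raw baseline fluorescence (default 1000).
#' @param responseAmplitude asymptotic agonist response as a fraction of
#'   baseline, i.e. the true plateau dF/F0 (default 0.5).
#' @param inhibitorResidualFraction fraction of the response remaining
#'   after full inhibition (default 0.2; 1 reproduces the
#'   inhibitor-insensitive phenotype).
#' @param noiseSd additive Gaussian noise, as a fraction of baseline
#'   (default 0.01).
#' @param fskTime,inhTime agonist and inhibitor addition times in seconds
#'   (defaults 180 and 400).
#' @param riseTau,decayTau first-order rise / decay time constants in
#'   seconds (defaults 20 and 30).
#' @param seed integer RNG seed.
#' @return a list of class \code{"TraceSimConfig"}.
#' @export
traceSimConfig <- function(samplingInterval = 5, duration = 600,
                           baselineLevel = 1000, responseAmplitude = 0.5,
                           inhibitorResidualFraction = 0.2, noiseSd = 0.01,
                           fskTime = 180, inhTime = 400, riseTau = 20,
                           decayTau = 30, seed = 1L) {
  stopifnot(samplingInterval > 0, duration > inhTime, baselineLevel > 0,
            responseAmplitude >= 0, inhibitorResidualFraction >= 0,
            noiseSd >= 0, fskTime > 0, inhTime > fskTime, riseTau > 0,
            decayTau > 0)
  structure(list(samplingInterval = samplingInterval, duration = duration,
                 baselineLevel = baselineLevel,
                 responseAmplitude = responseAmplitude,
                 inhibitorResidualFraction = inhibitorResidualFraction,
                 noiseSd = noiseSd, fskTime = fskTime, inhTime = inhTime,
                 riseTau = riseTau, decayTau = decayTau,
                 seed = as.integer(seed)),
            class = "TraceSimConfig")
}

#' Simulate a FLIPR trace with known response amplitude
#'
#' Piecewise kinetics: flat baseline; after agonist addition a first-order
#' rise toward baseline x (1 + amplitude); after inhibitor addition an
#' exponential decay toward baseline x (1 + amplitude x residual fraction).
#' Additive Gaussian noise of sd \code{noiseSd} x baseline, floored at
#' zero fluorescence.
#'
#' @param cfg a \code{\link{traceSimConfig}}.
#' @return list: \code{trace} (a \linkS4class{FLIPRTrace}) and \code{truth}
#'   (list with \code{peak_dff0}, the noiseless maximum of the agonist
#'   window, and \code{inhibitor_sensitive_fraction} at full decay).
#' @export
simulateFliprTrace <- function(cfg = traceSimConfig()) {
  stopifnot(inherits(cfg, "TraceSimConfig"))
  set.seed(cfg$seed)
  t <- seq(0, cfg$duration, by = cfg$samplingInterval)
  A <- cfg$responseAmplitude
  dff <- numeric(length(t))
  rise <- t > cfg$fskTime & t <= cfg$inhTime
  dff[rise] <- A * (1 - exp(-(t[rise] - cfg$fskTime) / cfg$riseTau))
  L <- A * (1 - exp(-(cfg$inhTime - cfg$fskTime) / cfg$riseTau))
  resid <- cfg$inhibitorResidualFraction * A
  post <- t > cfg$inhTime
  dff[post] <- resid + (L - resid) * exp(-(t[post] - cfg$inhTime) / cfg$decayTau)
  f <- cfg$baselineLevel * (1 + dff) +
    stats::rnorm(length(t), 0, cfg$noiseSd * cfg$baselineLevel)
  f <- pmax(f, 0)
  truth_peak <- L
  truth_frac <- if (truth_peak > 0) (truth_peak - resid) / truth_peak else NA_real_
  list(trace = FLIPRTrace(t, f, cfg$fskTime, cfg$inhTime),
       truth = list(peak_dff0 = truth_peak,
                    inhibitor_sensitive_fraction = truth_frac))
}
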