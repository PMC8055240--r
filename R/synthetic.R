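#' Configuration of the synthetic plan generator
#'
#' Collects the knobs of the synthetic treatment-plan generator, whose
#' defaults emulate a 15-case single-session vestibular schwannoma
#' cohort: 6 cases prescribed 12 Gy and 9 prescribed 13 Gy, 4--19
#' iso-centres per plan, total treatment times spanning 20.8--73.7 min,
#' dose grids on a 31x31x31 1 mm lattice, and Gaussian dose kernels with
#' widths emulating the 4/8/16 mm collimators.
#'
#' @param casesPerGroup named integer vector: cases per prescription
#'   group (names are the prescription doses in Gy).
#' @param nShotsRange iso-centre count range.
#' @param totalTimeRange total treatment time range (min).
#' @param latticeDim grid dimensions.
#' @param spacingMm voxel spacing (mm).
#' @param kernelSigmaRange allowed Gaussian kernel standard deviations
#'   (mm): the span of the 4 mm to 16 mm collimators
#'   (sigma = FWHM / 2.355, about 1.7 to 6.8 mm); per-shot widths are
#'   drawn as a fraction of the shot packing distance
#'   (`kernelWidthFrac`) and clamped to this span.
#' @param kernelWidthFrac range of the kernel width as a fraction of the
#'   inter-shot packing distance. Together with near-equal shot
#'   amplitudes this controls how strongly each prescription-shell voxel
#'   is dominated by its nearest iso-centre, which sets the plan's
#'   repair deficit and gap sensitivity.
#' @param rateHeterogeneity required minimum ratio between the largest
#'   and smallest per-shot mean shell dose-rate.
#' @param beamOffMin scheduled inter-shot beam-off (min).
#' @param shellMinVoxels minimum prescription-shell size a generated
#'   plan must reach.
#' @param targetShape `"ellipsoid"` (default) or `"elongated"` (a single
#'   long axis, the geometry on which the sequencing heuristics are
#'   expected to struggle).
#' @param maxRetries bounded regeneration attempts for infeasible draws.
#' @return a named list of class `"SyntheticConfig"`.
#' @export
syntheticConfig <- function(casesPerGroup = c("12" = 6L, "13" = 9L),
                            nShotsRange = c(4L, 19L),
                            totalTimeRange = c(20.8, 73.7),
                            latticeDim = c(31L, 31L, 31L),
                            spacingMm = c(0.5, 0.5, 0.5),
                            kernelSigmaRange = c(1.7, 6.8),
                            kernelWidthFrac = c(0.38, 0.48),
                            rateHeterogeneity = 3,
                            beamOffMin = 0.06,
                            shellMinVoxels = 30L,
                            targetShape = c("ellipsoid", "elongated"),
                            maxRetries = 80L) {
  targetShape <- match.arg(targetShape)
  stopifnot(all(casesPerGroup >= 1), nShotsRange[1] >= 1,
            diff(nShotsRange) >= 0, totalTimeRange[1] > 0,
            diff(totalTimeRange) >= 0, all(latticeDim >= 3),
            rateHeterogeneity >= 1, beamOffMin >= 0)
  structure(list(
    casesPerGroup = casesPerGroup, nShotsRange = nShotsRange,
    totalTimeRange = totalTimeRange, latticeDim = latticeDim,
    spacingMm = spacingMm, kernelSigmaRange = kernelSigmaRange,
    kernelWidthFrac = kernelWidthFrac,
    rateHeterogeneity = rateHeterogeneity, beamOffMin = beamOffMin,
    shellMinVoxels = shellMinVoxels, targetShape = targetShape,
    maxRetries = maxRetries
  ), class = "SyntheticConfig")
}

# separable anisotropic Gaussian kernel on the lattice, peak 1 at centre
.gaussKernel <- function(dimv, spacing, centre, sigma) {
  ax <- lapply(1:3, function(i) {
    x <- (seq_len(dimv[i]) - centre[i]) * spacing[i]
    exp(-x^2 / (2 * sigma[i]^2))
  })
  outer(outer(ax[[1]], ax[[2]]), ax[[3]])
}

# one draw of shot geometry + amplitudes; NULL if placement infeasible.
# Shots are packed inside an ellipsoidal target with a minimum mutual
# distance d0 (from the target volume and shot count), kernel widths are
# a fraction of d0 clamped to the collimator span, and amplitudes are
# near-equal -- so each margin voxel is dominated by its nearest shot,
# the dose structure real plans exhibit.
.drawPlan <- function(config, nShots, prescription, shrink = 1,
                      widen = 1) {
  dimv <- config$latticeDim
  sp <- config$spacingMm
  mid <- (dimv + 1) / 2
  # target ellipsoid semi-axes (mm)
  semi <- if (config$targetShape == "elongated") {
    c(stats::runif(1, 6.8, 7.4), stats::runif(2, 3.8, 4.6))
  } else {
    stats::runif(3, 5, 7.5)
  }
  d0 <- shrink * 0.9 * (4 / 3 * pi * prod(semi) / nShots)^(1 / 3)
  centres <- matrix(NA_real_, nShots, 3)
  placed <- 0
  for (att in seq_len(400 * nShots)) {
    u <- stats::runif(3, -1, 1)
    if (sum(u^2) > 1) next
    cand <- u * semi * 0.88
    if (placed > 0) {
      dd <- sqrt(colSums((t(centres[seq_len(placed), , drop = FALSE]) -
                            cand)^2))
      if (min(dd) < d0) next
    }
    placed <- placed + 1
    centres[placed, ] <- cand
    if (placed == nShots) break
  }
  if (placed < nShots) return(NULL)
  doses <- vector("list", nShots)
  for (k in seq_len(nShots)) {
    sigma <- stats::runif(1, config$kernelWidthFrac[1],
                          config$kernelWidthFrac[2]) * d0 * widen
    sigma <- min(max(sigma, config$kernelSigmaRange[1] * 0.9),
                 config$kernelSigmaRange[2])
    amp <- exp(stats::runif(1, log(0.6), log(1.7)))
    doses[[k]] <- amp *
      .gaussKernel(dimv, sp, mid + centres[k, ] / sp, rep(sigma, 3))
  }
  doses
}

#' Generate one synthetic treatment plan
#'
#' Draws a multi-iso-centre plan with the statistical structure of
#' clinical plan exports: anisotropic Gaussian dose kernels centred in an
#' ellipsoidal target, amplitudes rescaled so the summed dose carries a
#' prescription isodose shell of at least `shellMinVoxels` voxels at the
#' +/- 0.02 Gy tolerance, beam-on times drawn so the total treatment time
#' lands at `totalTime` (or uniformly in the configured range), and
#' per-shot mean shell dose-rates spanning at least the configured
#' heterogeneity factor. Infeasible draws are regenerated up to
#' `maxRetries` times.
#'
#' Fully deterministic for a given `seed`.
#'
#' @param config a [syntheticConfig()].
#' @param seed integer seed.
#' @param nShots iso-centre count; sampled from the configured range if
#'   `NULL`.
#' @param prescription prescription dose (Gy).
#' @param totalTime total treatment time (min); sampled if `NULL`.
#' @param caseId case label.
#' @return a [TreatmentPlan-class] object.
#' @export
#' @examples
#' p <- makePlan(seed = 7, nShots = 5, prescription = 12)
#' shellSize(extractShell(p))
makePlan <- function(config = syntheticConfig(), seed = 1, nShots = NULL,
                     prescription = 12, totalTime = NULL,
                     caseId = sprintf("synthetic-%d", seed)) {
  set.seed(seed)
  if (is.null(nShots)) {
    nShots <- sample(config$nShotsRange[1]:config$nShotsRange[2], 1)
  }
  stopifnot(nShots >= 1)
  tt <- if (is.null(totalTime)) {
    stats::runif(1, config$totalTimeRange[1], config$totalTimeRange[2])
  } else totalTime
  offTotal <- config$beamOffMin * (nShots - 1)
  if (tt <= offTotal) stop("totalTime too short for ", nShots, " shots")
  placeFails <- 0
  shellFails <- 0
  for (try in seq_len(config$maxRetries)) {
    doses <- .drawPlan(config, nShots, prescription,
                       shrink = 0.97^placeFails,
                       widen = min(1.5, 1 + 0.012 * shellFails))
    if (is.null(doses)) {
      placeFails <- placeFails + 1
      next
    }
    raw <- Reduce(`+`, doses)
    M <- max(raw)
    # place the prescription level on the kernel flanks, where the
    # isosurface is largest; pick the level with the fattest shell
    levels <- M * seq(0.2, 0.75, by = 0.01)
    counts <- vapply(levels, function(L) {
      sum(abs(raw - L) <= 0.02 * L / prescription)
    }, numeric(1))
    best <- which.max(counts)
    if (counts[best] < config$shellMinVoxels) {
      shellFails <- shellFails + 1
      next
    }
    scale <- prescription / levels[best]
    doses <- lapply(doses, `*`, scale)
    # beam-on times: loosely tied to the shot's dose contribution, with
    # the several-fold spread real shot weightings show; this, not the
    # dose geometry, carries most of the shell dose-rate heterogeneity
    w <- vapply(doses, max, numeric(1))
    b <- (w^0.3) * stats::runif(nShots, 0.4, 1.8)
    beamOn <- b / sum(b) * (tt - offTotal)
    plan <- treatmentPlan(doses, beamOn = beamOn,
                          beamOff = config$beamOffMin,
                          prescription = prescription,
                          spacing = config$spacingMm, caseId = caseId)
    shell <- extractShell(plan)
    if (shellSize(shell) < config$shellMinVoxels) {
      shellFails <- shellFails + 1
      next
    }
    if (nShots > 1) {
      rates <- shotMeanDoseRate(plan, shell)
      if (max(rates) / min(rates) < config$rateHeterogeneity) next
    }
    return(plan)
  }
  stop("no feasible plan after ", config$maxRetries,
       " draws (shell or dose-rate heterogeneity constraint)")
}

#' Generate a synthetic cohort
#'
#' Draws one plan per configured case (default 6 at 12 Gy plus 9 at
#' 13 Gy), with iso-centre counts sampled from the configured range and
#' total treatment times spread evenly (with jitter) across the
#' configured span so the cohort covers it; within each prescription
#' group the plans are ordered by total treatment time.
#'
#' @param config a [syntheticConfig()].
#' @param seed integer seed; per-case seeds are derived from it.
#' @return list with `plans` (list of [TreatmentPlan-class]) and `table`
#'   (data.frame scaffold with case, dose_gy, time_min, n_iso).
#' @export
makeCohort <- function(config = syntheticConfig(), seed = 1) {
  set.seed(seed)
  doses <- as.numeric(names(config$casesPerGroup))
  plans <- list()
  rows <- NULL
  caseNo <- 0
  for (gi in seq_along(doses)) {
    ng <- config$casesPerGroup[gi]
    # stratified total times: cover the configured span
    edges <- seq(config$totalTimeRange[1], config$totalTimeRange[2],
                 length.out = ng + 1)
    tts <- stats::runif(ng, edges[-(ng + 1)], edges[-1])
    ns <- sample(config$nShotsRange[1]:config$nShotsRange[2], ng,
                 replace = TRUE)
    caseSeeds <- sample.int(.Machine$integer.max - 1, ng)
    ord <- order(tts)
    for (i in ord) {
      caseNo <- caseNo + 1
      id <- sprintf("case%02d", caseNo)
      p <- makePlan(config, seed = caseSeeds[i], nShots = ns[i],
                    prescription = doses[gi], totalTime = tts[i],
                    caseId = id)
      plans[[id]] <- p
      rows <- rbind(rows, data.frame(
        case = id, dose_gy = doses[gi], time_min = totalTime(p),
        n_iso = nShots(p)))
    }
  }
  list(plans = plans, table = rows)
}
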