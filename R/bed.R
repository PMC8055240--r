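# Vectorised Phi over many voxels at once.
# R: nvox x n matrix of per-voxel rates; tOn: beam-on times; starts/ends:
# absolute schedule times. Returns the Phi vector (length nvox).
.phiMany <- function(R, tOn, starts, ends, mu) {
  n <- length(tOn)
  phi <- as.vector(R^2 %*% (2 / mu^2 * .h1(mu * tOn)))
  if (n > 1) {
    g <- .g1(mu * tOn)
    for (j in seq_len(n - 1)) {
      for (k in (j + 1):n) {
        tau <- starts[k] - ends[j]
        coef <- 2 / mu^2 * g[j] * g[k] * exp(-mu * tau)
        phi <- phi + coef * R[, j] * R[, k]
      }
    }
  }
  phi
}

# rate matrix (nvox x n) of a plan, rates in Gy/min
.rateMatrix <- function(plan, voxels = NULL) {
  n <- nShots(plan)
  tOn <- beamOn(plan)
  if (is.null(voxels)) {
    vapply(seq_len(n), function(k) as.vector(plan@doses[[k]]) / tOn[k],
           numeric(length(plan@doses[[1]])))
  } else {
    vapply(seq_len(n), function(k) plan@doses[[k]][voxels] / tOn[k],
           numeric(length(voxels)))
  }
}

# BED values for a subset of voxels (or all), given an explicit schedule
.bedVector <- function(plan, params, voxels = NULL, starts = NULL,
                       ends = NULL) {
  if (is.null(starts)) {
    tl <- buildTimeline(plan)
    starts <- tl$start
    ends <- tl$end
  }
  tOn <- ends - starts
  R <- .rateMatrix(plan, voxels)
  if (!is.matrix(R)) R <- matrix(R, ncol = nShots(plan))
  D <- as.vector(R %*% tOn)
  mu <- repairRates(params)
  cc <- params@partitionFast
  phi <- cc * .phiMany(R, tOn, starts, ends, mu[["fast"]])
  if (cc < 1) {
    phi <- phi + (1 - cc) * .phiMany(R, tOn, starts, ends, mu[["slow"]])
  }
  bed <- D + phi / params@alphaBeta
  bed[D == 0] <- 0
  bed
}

#' Per-voxel BED grid of a plan
#'
#' Evaluates the incomplete-repair BED model at every voxel of the plan's
#' lattice: each voxel sees its own dose-rate sequence (one segment per
#' iso-centre), and the per-pair repair intervals follow from the plan's
#' absolute delivery timeline. Voxels with zero total dose get BED 0.
#'
#' The evaluation is vectorised over voxels and exactly equals
#' [bedVoxel()] applied to [planExposure()] of each voxel.
#'
#' @param plan a [TreatmentPlan-class] object.
#' @param params a [RepairParams-class] object.
#' @return a [BEDGrid-class] object in Gy_{alpha/beta}.
#' @export
#' @examples
#' d <- array(runif(27), c(3, 3, 3))
#' p <- treatmentPlan(list(d, d), beamOn = c(2, 3), prescription = 1)
#' bedGrid(p, repairParams())
bedGrid <- function(plan, params = repairParams()) {
  stopifnot(is(plan, "TreatmentPlan"), is(params, "RepairParams"))
  bed <- .bedVector(plan, params)
  new("BEDGrid",
      values = array(bed, dim = dim(plan@doses[[1]])),
      alphaBeta = params@alphaBeta, spacing = voxelSpacing(plan))
}

# Shell-restricted cache for gap and sequence sweeps.
# Shell membership, total dose and all pair magnitudes are invariant under
# re-ordering and gap edits; only the exp(-mu * tau) attenuations change.
# Caches, per repair component, the shell means of the pair magnitudes
# m_jk = (2 R_j R_k / mu^2) g(mu t_j) g(mu t_k) and of the self terms, so
# one schedule evaluation is O(n^2) with no voxel loop.
.shellCache <- function(plan, shell, params) {
  stopifnot(is(plan, "TreatmentPlan"), is(shell, "Shell"),
            is(params, "RepairParams"))
  if (shellSize(shell) == 0) stop("empty shell: mean BED is undefined")
  R <- .rateMatrix(plan, shellIndices(shell))
  if (!is.matrix(R)) R <- matrix(R, ncol = nShots(plan))
  tOn <- beamOn(plan)
  mu <- repairRates(params)
  one <- function(m) {
    g <- .g1(m * tOn)
    selfMean <- mean(as.vector(R^2 %*% (2 / m^2 * .h1(m * tOn))))
    # shell-mean cross magnitudes, symmetric n x n
    M <- crossprod(R) / nrow(R)            # mean of R_j R_k over shell
    M <- 2 / m^2 * M * tcrossprod(g)
    list(selfMean = selfMean, M = M)
  }
  list(
    Dmean = mean(as.vector(R %*% tOn)),
    fast = one(mu[["fast"]]), slow = one(mu[["slow"]]),
    mu = mu, cc = params@partitionFast, alphaBeta = params@alphaBeta,
    beamOn = tOn, n = nShots(plan)
  )
}

# Shell-mean BED for a schedule: perm gives delivery order (shot indices),
# beamOff the slot gaps. O(n^2).
.cacheMeanBED <- function(cache, perm = seq_len(cache$n),
                          beamOff = NULL) {
  n <- cache$n
  tOn <- cache$beamOn[perm]
  if (is.null(beamOff)) beamOff <- rep(0.06, max(n - 1, 0))
  starts <- cumsum(c(0, tOn[-n] + beamOff))
  ends <- starts + tOn
  phi <- cache$cc * cache$fast$selfMean +
    (1 - cache$cc) * cache$slow$selfMean
  if (n > 1) {
    for (p in seq_len(n - 1)) {
      q <- (p + 1):n
      tau <- starts[q] - ends[p]
      jp <- perm[p]; jq <- perm[q]
      phi <- phi +
        cache$cc * sum(cache$fast$M[jp, jq] * exp(-cache$mu[["fast"]] * tau))
      if (cache$cc < 1) {
        phi <- phi + (1 - cache$cc) *
          sum(cache$slow$M[jp, jq] * exp(-cache$mu[["slow"]] * tau))
      }
    }
  }
  cache$Dmean + phi / cache$alphaBeta
}
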