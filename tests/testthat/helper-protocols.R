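# random exposure protocols and tiny plans used across tests

randomExposure <- function(nMax = 5, acute = FALSE) {
  n <- sample.int(nMax, 1)
  dur <- if (acute) rep(1e-6, n) else runif(n, 0.01, 10)
  voxelExposure(
    rates = runif(n, 0, 5),
    durations = dur,
    intervals = if (n > 1) runif(n - 1, 0, 60) else numeric(0)
  )
}

# an exposure made of effectively instantaneous doses (Gy) at given gaps
acuteExposure <- function(doses, intervals) {
  eps <- 1e-7
  voxelExposure(rates = doses / eps, durations = rep(eps, length(doses)),
                intervals = intervals)
}

# small random plan on a tiny lattice; doses have no special structure
tinyPlan <- function(nShots = 3, dim = c(4, 4, 4), prescription = 2,
                     beamOff = 0.06) {
  doses <- lapply(seq_len(nShots),
                  function(k) array(runif(prod(dim), 0, 2), dim))
  treatmentPlan(doses, beamOn = runif(nShots, 0.5, 3),
                beamOff = beamOff, prescription = prescription)
}

# single-voxel plan delivering the given near-acute doses (Gy)
acutePlan <- function(doses, beamOff = 0.06, prescription = sum(doses)) {
  eps <- 1e-6
  arrays <- lapply(doses, function(d) array(d, c(1, 1, 1)))
  treatmentPlan(arrays, beamOn = rep(eps, length(doses)),
                beamOff = beamOff, prescription = prescription)
}

# shell-mean BED computed the slow, direct way (full grid + shell mean)
directShellMean <- function(plan, params, shell = extractShell(plan)) {
  shellMeanBED(bedGrid(plan, params), shell)
}
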