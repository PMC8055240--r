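#' Construct a treatment plan
#'
#' @param doses list of 3D dose arrays (Gy), one per iso-centre, all on
#'   the same lattice.
#' @param beamOn beam-on time per iso-centre (min).
#' @param beamOff beam-off times between consecutive iso-centres (min);
#'   a single value is recycled to every inter-shot slot. The default
#'   0.06 min is the average repositioning gap of current delivery
#'   protocols.
#' @param prescription prescription dose (Gy).
#' @param spacing voxel spacing (mm), length 1 or 3.
#' @param caseId case label.
#' @param shotIds iso-centre labels.
#'
#' @return a [TreatmentPlan-class] object.
#' @export
#' @examples
#' d <- array(1, c(3, 3, 3))
#' treatmentPlan(list(d, 2 * d), beamOn = c(2, 3), prescription = 3)
treatmentPlan <- function(doses, beamOn, beamOff = 0.06, prescription,
                          spacing = c(1, 1, 1), caseId = "case",
                          shotIds = sprintf("shot%02d", seq_along(doses))) {
  n <- length(doses)
  if (length(beamOff) == 1 && n > 1) beamOff <- rep(beamOff, n - 1)
  if (n == 1) beamOff <- numeric(0)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  new("TreatmentPlan", doses = doses, beamOn = as.numeric(beamOn),
      beamOff = as.numeric(beamOff), shotIds = shotIds,
      prescription = prescription, spacing = as.numeric(spacing),
      caseId = caseId)
}

#' Absolute delivery timeline of a plan
#'
#' Start and end times of every iso-centre on the absolute treatment
#' clock: the first shot starts at 0, each subsequent shot starts at the
#' previous shot's end plus the intervening beam-off period.
#'
#' @param plan a [TreatmentPlan-class] object.
#' @return a data.frame with columns `shot`, `start`, `end` (min); the
#'   last `end` equals [totalTime()].
#' @export
#' @examples
#' d <- array(1, c(2, 2, 2))
#' p <- treatmentPlan(list(d, d), beamOn = c(2, 3), beamOff = 0.06,
#'                    prescription = 2)
#' buildTimeline(p)
buildTimeline <- function(plan) {
  stopifnot(is(plan, "TreatmentPlan"))
  t <- beamOn(plan)
  n <- length(t)
  starts <- cumsum(c(0, t[-n] + beamOff(plan)))
  data.frame(shot = shotIds(plan), start = starts, end = starts + t)
}

#' Exposure protocol of one voxel
#'
#' Builds the [VoxelExposure-class] a voxel experiences under a plan: one
#' segment per iso-centre with rate dose_k(voxel) / beamOn_k, in delivery
#' order, separated by the plan's beam-off intervals. Iso-centres that
#' deposit no dose at the voxel are retained as rate-0 segments; by
#' linearity of the protraction function this is equivalent to dropping
#' them.
#'
#' @param plan a [TreatmentPlan-class] object.
#' @param voxel either a length-3 subscript (i, j, k) or a single linear
#'   index into the lattice.
#' @param dropZero drop zero-rate segments (merging their duration and
#'   surrounding gaps into one interval)?
#' @return a [VoxelExposure-class] object.
#' @export
planExposure <- function(plan, voxel, dropZero = FALSE) {
  stopifnot(is(plan, "TreatmentPlan"))
  n <- nShots(plan)
  v <- if (length(voxel) == 3) {
    d <- dim(plan@doses[[1]])
    voxel[1] + d[1] * (voxel[2] - 1) + d[1] * d[2] * (voxel[3] - 1)
  } else voxel
  doses <- vapply(plan@doses, function(a) a[v], numeric(1))
  rates <- doses / beamOn(plan)
  if (dropZero && any(rates == 0)) {
    keep <- which(rates > 0)
    if (length(keep) == 0) {
      return(voxelExposure(numeric(0), numeric(0), numeric(0)))
    }
    tl <- buildTimeline(plan)
    ints <- if (length(keep) > 1) {
      tl$start[keep[-1]] - tl$end[keep[-length(keep)]]
    } else numeric(0)
    return(voxelExposure(rates[keep], beamOn(plan)[keep], ints))
  }
  voxelExposure(rates, beamOn(plan), beamOff(plan))
}
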