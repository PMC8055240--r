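#' @import methods
NULL

#' Radiobiological repair parameters
#'
#' Parameters of the linear-quadratic BED model with bi-exponential
#' sublethal-damage repair: the tissue alpha/beta ratio, the fast and slow
#' repair half-times, and the partition coefficient giving the fraction of
#' repairable damage assigned to the fast component.
#'
#' Defaults are the collective fit to rat spinal-cord iso-effect data from
#' which the alpha/beta ratio of 2.47 Gy derives: repair half-times of
#' 0.19 h (11.4 min, fast) and 2.16 h (129.6 min, slow) with partition
#' coefficient 0.98. Setting \code{partitionFast = 1} reduces the model to
#' mono-exponential repair at the fast rate.
#'
#' @slot alphaBeta alpha/beta ratio (Gy).
#' @slot halfTimeFast fast repair half-time (min).
#' @slot halfTimeSlow slow repair half-time (min).
#' @slot partitionFast fraction of repair capacity on the fast component,
#'   in [0, 1].
#'
#' @seealso [repairParams()], [bedVoxel()], [bedGrid()]
#' @exportClass RepairParams
setClass("RepairParams",
  representation(
    alphaBeta = "numeric",
    halfTimeFast = "numeric",
    halfTimeSlow = "numeric",
    partitionFast = "numeric"
  )
)

setValidity("RepairParams", function(object) {
  msg <- character()
  if (length(object@alphaBeta) != 1 || !is.finite(object@alphaBeta) ||
      object@alphaBeta <= 0) {
    msg <- c(msg, "alphaBeta must be a single positive number (Gy)")
  }
  for (s in c("halfTimeFast", "halfTimeSlow")) {
    v <- slot(object, s)
    if (length(v) != 1 || !is.finite(v) || v <= 0) {
      msg <- c(msg, sprintf("%s must be a single positive number (min)", s))
    }
  }
  if (length(msg) == 0 && object@halfTimeFast > object@halfTimeSlow) {
    msg <- c(msg, "halfTimeFast must not exceed halfTimeSlow")
  }
  c01 <- object@partitionFast
  if (length(c01) != 1 || !is.finite(c01) || c01 < 0 || c01 > 1) {
    msg <- c(msg, "partitionFast must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Per-voxel exposure protocol
#'
#' The irradiation protocol seen by one voxel: an ordered sequence of
#' continuous-irradiation segments (one per iso-centre), each with a
#' constant dose-rate and a duration, separated by beam-off intervals.
#'
#' @slot rates dose-rates (Gy/min), one per segment; zero allowed.
#' @slot durations beam-on durations (min), all positive.
#' @slot intervals beam-off times (min) between consecutive segments;
#'   length is one less than the number of segments.
#'
#' @seealso [voxelExposure()], [phiProtocol()], [bedVoxel()]
#' @exportClass VoxelExposure
setClass("VoxelExposure",
  representation(
    rates = "numeric",
    durations = "numeric",
    intervals = "numeric"
  )
)

setValidity("VoxelExposure", function(object) {
  msg <- character()
  n <- length(object@rates)
  if (length(object@durations) != n) {
    msg <- c(msg, "rates and durations must have equal length")
  }
  if (length(object@intervals) != max(n - 1L, 0L)) {
    msg <- c(msg, "intervals must have length one less than segments")
  }
  if (any(!is.finite(object@rates)) || any(object@rates < 0)) {
    msg <- c(msg, "rates must be finite and >= 0")
  }
  if (any(!is.finite(object@durations)) || any(object@durations <= 0)) {
    msg <- c(msg, "durations must be finite and > 0")
  }
  if (length(object@intervals) &&
      (any(!is.finite(object@intervals)) || any(object@intervals < 0))) {
    msg <- c(msg, "intervals must be finite and >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Multi-iso-centre treatment plan
#'
#' One Gamma Knife treatment: an ordered list of iso-centres ("shots"),
#' each contributing its own 3D dose grid (Gy) on a shared voxel lattice
#' and delivered over its own beam-on time, with beam-off repositioning
#' intervals between consecutive shots.
#'
#' @slot doses list of 3D numeric arrays, one per shot, identical
#'   dimensions, values in Gy.
#' @slot beamOn beam-on time per shot (min).
#' @slot beamOff beam-off time between consecutive shots (min);
#'   length one less than the number of shots.
#' @slot shotIds character labels, one per shot.
#' @slot prescription prescription dose (Gy).
#' @slot spacing voxel spacing (mm), length 3.
#' @slot caseId case label.
#'
#' @seealso [treatmentPlan()], [bedGrid()], [gapSweep()],
#'   [exhaustiveSearch()]
#' @exportClass TreatmentPlan
setClass("TreatmentPlan",
  representation(
    doses = "list",
    beamOn = "numeric",
    beamOff = "numeric",
    shotIds = "character",
    prescription = "numeric",
    spacing = "numeric",
    caseId = "character"
  )
)

setValidity("TreatmentPlan", function(object) {
  msg <- character()
  n <- length(object@doses)
  if (n < 1) msg <- c(msg, "a plan needs at least one iso-centre")
  if (length(object@beamOn) != n) {
    msg <- c(msg, "beamOn must have one entry per iso-centre")
  } else if (any(!is.finite(object@beamOn)) || any(object@beamOn <= 0)) {
    msg <- c(msg, "beamOn times must be finite and > 0")
  }
  if (length(object@beamOff) != max(n - 1L, 0L)) {
    msg <- c(msg, sprintf(
      "beamOff must have length %d (one per inter-iso-centre slot), got %d",
      max(n - 1L, 0L), length(object@beamOff)))
  } else if (length(object@beamOff) &&
             (any(!is.finite(object@beamOff)) || any(object@beamOff < 0))) {
    msg <- c(msg, "beamOff times must be finite and >= 0")
  }
  if (length(object@shotIds) != n) {
    msg <- c(msg, "shotIds must have one entry per iso-centre")
  }
  if (n >= 1) {
    d1 <- dim(object@doses[[1]])
    if (is.null(d1) || length(d1) != 3) {
      msg <- c(msg, "each dose grid must be a 3D array")
    } else {
      for (k in seq_len(n)) {
        dk <- dim(object@doses[[k]])
        if (!identical(dk, d1)) {
          msg <- c(msg, sprintf("dose grid %d lattice %s differs from %s",
                                k, paste(dk, collapse = "x"),
                                paste(d1, collapse = "x")))
          break
        }
        if (any(object@doses[[k]] < 0)) {
          msg <- c(msg, sprintf("dose grid %d has negative values", k))
          break
        }
      }
    }
  }
  if (length(object@prescription) != 1 || !is.finite(object@prescription) ||
      object@prescription <= 0) {
    msg <- c(msg, "prescription must be a single positive dose (Gy)")
  }
  if (length(object@spacing) != 3 || any(object@spacing <= 0)) {
    msg <- c(msg, "spacing must be three positive numbers (mm)")
  }
  if (length(msg)) msg else TRUE
})

#' Prescription isodose shell
#'
#' The set of voxels whose total physical dose lies within an absolute
#' tolerance of the prescription dose -- the voxels considered most
#' representative of the dose prescription, on which mean BED and per-shot
#' dose-rate summaries are computed.
#'
#' @slot indices linear (1-based) voxel indices into the plan lattice.
#' @slot dim lattice dimensions.
#' @slot prescription prescription dose (Gy).
#' @slot tolerance absolute dose window half-width (Gy).
#'
#' @seealso [extractShell()], [shellMeanBED()], [shotMeanDoseRate()]
#' @exportClass Shell
setClass("Shell",
  representation(
    indices = "integer",
    dim = "integer",
    prescription = "numeric",
    tolerance = "numeric"
  )
)

setValidity("Shell", function(object) {
  msg <- character()
  if (length(object@dim) != 3) msg <- c(msg, "dim must have length 3")
  if (length(object@indices) &&
      (min(object@indices) < 1 || max(object@indices) > prod(object@dim))) {
    msg <- c(msg, "indices out of lattice range")
  }
  if (object@tolerance < 0) msg <- c(msg, "tolerance must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Per-voxel BED grid
#'
#' Biologically effective dose evaluated voxel-by-voxel on a plan's
#' lattice. Values carry the alpha/beta ratio used, i.e. they are in
#' Gy_{alpha/beta}.
#'
#' @slot values 3D array of BED values (Gy_{alpha/beta}).
#' @slot alphaBeta the alpha/beta ratio (Gy) the values are referred to.
#' @slot spacing voxel spacing (mm).
#'
#' @seealso [bedGrid()], [shellMeanBED()]
#' @exportClass BEDGrid
setClass("BEDGrid",
  representation(
    values = "array",
    alphaBeta = "numeric",
    spacing = "numeric"
  )
)

setValidity("BEDGrid", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3) {
    msg <- c(msg, "values must be a 3D array")
  }
  if (any(object@values < 0)) msg <- c(msg, "BED values must be >= 0")
  if (length(object@alphaBeta) != 1 || object@alphaBeta <= 0) {
    msg <- c(msg, "alphaBeta must be a single positive number")
  }
  if (length(msg)) msg else TRUE
})
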