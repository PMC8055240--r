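#' Accessors for GammaBED objects
#'
#' Small accessor generics for the package's S4 classes; use these instead
#' of reaching into slots.
#'
#' @param x a [RepairParams-class], [TreatmentPlan-class],
#'   [Shell-class] or [BEDGrid-class] object.
#' @param k iso-centre index (1-based, schedule order).
#'
#' @return `nShots`: number of iso-centres. `beamOn`, `beamOff`: times in
#'   minutes. `shotDose`: the 3D dose array (Gy) of shot `k`.
#'   `totalDose`: elementwise sum of the shot dose grids. `totalTime`:
#'   sum of all beam-on and beam-off periods (min). `repairRates`: named
#'   vector of repair rate constants mu = ln 2 / half-time (1/min).
#'   `bedValues`: the BED array. `shellIndices`/`shellSize`: linear voxel
#'   indices of the shell and their count.
#'
#' @name accessors
#' @aliases nShots beamOn beamOff shotIds shotDose totalDose totalTime
#'   prescriptionDose caseId voxelSpacing alphaBeta repairRates bedValues
#'   shellIndices shellSize
#' @examples
#' p <- repairParams()
#' alphaBeta(p)
#' repairRates(p)
NULL

#' @rdname accessors
setMethod("nShots", "TreatmentPlan", function(x) length(x@doses))

#' @rdname accessors
setMethod("beamOn", "TreatmentPlan", function(x) x@beamOn)

#' @rdname accessors
setMethod("beamOff", "TreatmentPlan", function(x) x@beamOff)

#' @rdname accessors
setMethod("shotIds", "TreatmentPlan", function(x) x@shotIds)

#' @rdname accessors
setMethod("shotDose", "TreatmentPlan", function(x, k) {
  stopifnot(length(k) == 1, k >= 1, k <= length(x@doses))
  x@doses[[k]]
})

#' @rdname accessors
setMethod("totalDose", "TreatmentPlan", function(x) {
  Reduce(`+`, x@doses)
})

#' @rdname accessors
setMethod("totalTime", "TreatmentPlan", function(x) {
  sum(x@beamOn) + sum(x@beamOff)
})

#' @rdname accessors
setMethod("prescriptionDose", "TreatmentPlan", function(x) x@prescription)

#' @rdname accessors
setMethod("caseId", "TreatmentPlan", function(x) x@caseId)

#' @rdname accessors
setMethod("voxelSpacing", "TreatmentPlan", function(x) x@spacing)

#' @rdname accessors
setMethod("alphaBeta", "RepairParams", function(x) x@alphaBeta)

#' @rdname accessors
setMethod("alphaBeta", "BEDGrid", function(x) x@alphaBeta)

#' @rdname accessors
setMethod("repairRates", "RepairParams", function(x) {
  c(fast = repairRate(x@halfTimeFast), slow = repairRate(x@halfTimeSlow))
})

#' @rdname accessors
setMethod("bedValues", "BEDGrid", function(x) x@values)

#' @rdname accessors
setMethod("voxelSpacing", "BEDGrid", function(x) x@spacing)

#' @rdname accessors
setMethod("shellIndices", "Shell", function(x) x@indices)

#' @rdname accessors
setMethod("shellSize", "Shell", function(x) length(x@indices))

#' @rdname accessors
setMethod("prescriptionDose", "Shell", function(x) x@prescription)

setMethod("show", "RepairParams", function(object) {
  cat("RepairParams: alpha/beta =", object@alphaBeta, "Gy;",
      "repair half-times", object@halfTimeFast, "/",
      object@halfTimeSlow, "min (fast/slow);",
      "partition c =", object@partitionFast, "\n")
})

setMethod("show", "TreatmentPlan", function(object) {
  d <- dim(object@doses[[1]])
  cat("TreatmentPlan", sQuote(object@caseId), "\n",
      " ", length(object@doses), "iso-centres on a",
      paste(d, collapse = "x"), "lattice (",
      paste(object@spacing, collapse = "x"), "mm )\n",
      "  prescription:", object@prescription, "Gy;",
      "total time:", round(totalTime(object), 2), "min\n")
})

setMethod("show", "Shell", function(object) {
  cat("Shell:", length(object@indices), "voxels within +/-",
      object@tolerance, "Gy of", object@prescription, "Gy\n")
})

setMethod("show", "BEDGrid", function(object) {
  cat("BEDGrid", paste(dim(object@values), collapse = "x"),
      sprintf("(Gy_%.2f);", object@alphaBeta),
      "range", paste(signif(range(object@values), 4), collapse = " - "),
      "\n")
})

setMethod("show", "VoxelExposure", function(object) {
  cat("VoxelExposure:", length(object@rates), "segments, total dose",
      signif(sum(object@rates * object@durations), 4), "Gy\n")
})
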