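#' @rdname accessors
#' @export
setGeneric("nShots", function(x) standardGeneric("nShots"))

#' @rdname accessors
#' @export
setGeneric("beamOn", function(x) standardGeneric("beamOn"))

#' @rdname accessors
#' @export
setGeneric("beamOff", function(x) standardGeneric("beamOff"))

#' @rdname accessors
#' @export
setGeneric("shotIds", function(x) standardGeneric("shotIds"))

#' @rdname accessors
#' @export
setGeneric("shotDose", function(x, k) standardGeneric("shotDose"))

#' @rdname accessors
#' @export
setGeneric("totalDose", function(x) standardGeneric("totalDose"))

#' @rdname accessors
#' @export
setGeneric("totalTime", function(x) standardGeneric("totalTime"))

#' @rdname accessors
#' @export
setGeneric("prescriptionDose", function(x) standardGeneric("prescriptionDose"))

#' @rdname accessors
#' @export
setGeneric("caseId", function(x) standardGeneric("caseId"))

#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname accessors
#' @export
setGeneric("alphaBeta", function(x) standardGeneric("alphaBeta"))

#' @rdname accessors
#' @export
setGeneric("repairRates", function(x) standardGeneric("repairRates"))

#' @rdname accessors
#' @export
setGeneric("bedValues", function(x) standardGeneric("bedValues"))

#' @rdname accessors
#' @export
setGeneric("shellIndices", function(x) standardGeneric("shellIndices"))

#' @rdname accessors
#' @export
setGeneric("shellSize", function(x) standardGeneric("shellSize"))
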