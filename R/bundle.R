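#' Write a plan bundle to disk
#'
#' Serialises a plan as the package's bundle format: a JSON manifest
#' (`manifest.json` with case id, prescription dose, lattice shape and
#' spacing, per-shot beam-on times and dose file names, and the beam-off
#' durations) plus one float32 NIfTI volume per iso-centre. The format
#' stands in for clinical planning-system research exports of
#' per-iso-centre dose matrices and beam-on times.
#'
#' @param plan a [TreatmentPlan-class] object.
#' @param path directory to create/fill.
#' @return `path`, invisibly.
#' @seealso [readPlanBundle()]
#' @export
writePlanBundle <- function(plan, path) {
  stopifnot(is(plan, "TreatmentPlan"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  n <- nShots(plan)
  files <- sprintf("dose_%02d.nii.gz", seq_len(n))
  for (k in seq_len(n)) {
    img <- RNifti::asNifti(plan@doses[[k]])
    RNifti::pixdim(img) <- voxelSpacing(plan)
    RNifti::writeNifti(img, file.path(path, files[k]), datatype = "float")
  }
  manifest <- list(
    case_id = caseId(plan),
    prescription_dose_gy = prescriptionDose(plan),
    lattice = list(shape = dim(plan@doses[[1]]),
                   spacing_mm = voxelSpacing(plan)),
    shots = lapply(seq_len(n), function(k) {
      list(id = shotIds(plan)[k], beam_on_min = beamOn(plan)[k],
           dose_file = files[k])
    }),
    beam_off_min = beamOff(plan)
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a plan bundle from disk
#'
#' Reads a bundle written by [writePlanBundle()] (or assembled by hand in
#' the same format) and validates it: all dose volumes must exist and
#' share the manifest's lattice, beam-on times must be positive, and
#' `beam_off_min` must have one entry per inter-shot slot. Legacy bundles
#' without `beam_off_min` get the default 0.06 min repositioning gap.
#' Doses round-trip up to float32 precision.
#'
#' @param path bundle directory containing `manifest.json`.
#' @return a [TreatmentPlan-class] object.
#' @export
readPlanBundle <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", path)
  m <- jsonlite::read_json(mf, simplifyVector = TRUE)
  shots <- m$shots
  if (is.null(shots) || length(shots) == 0) {
    stop("manifest field 'shots' is missing or empty")
  }
  # read_json simplifies a homogeneous shots list to a data.frame
  if (!is.data.frame(shots)) {
    shots <- do.call(rbind, lapply(shots, as.data.frame))
  }
  n <- nrow(shots)
  shape <- as.integer(unlist(m$lattice$shape))
  if (length(shape) != 3) stop("manifest field 'lattice.shape' must be 3D")
  if (any(shots$beam_on_min <= 0)) {
    stop("manifest field 'beam_on_min' must be positive for every shot")
  }
  doses <- vector("list", n)
  for (k in seq_len(n)) {
    f <- file.path(path, shots$dose_file[k])
    if (!file.exists(f)) {
      stop("missing dose volume for shot ", shots$id[k], ": ",
           shots$dose_file[k])
    }
    a <- as.array(RNifti::readNifti(f))
    if (!identical(dim(a), shape)) {
      stop("lattice mismatch in ", shots$dose_file[k], ": volume is ",
           paste(dim(a), collapse = "x"), ", manifest says ",
           paste(shape, collapse = "x"))
    }
    doses[[k]] <- a
  }
  off <- unlist(m$beam_off_min)
  if (is.null(off) || length(off) == 0) {
    off <- rep(0.06, max(n - 1, 0))
  }
  if (length(off) != max(n - 1, 0)) {
    stop("manifest field 'beam_off_min' has length ", length(off),
         " but ", n, " shots need ", n - 1, " entries")
  }
  if (length(off) && any(off < 0)) {
    stop("manifest field 'beam_off_min' must be >= 0")
  }
  spacing <- as.numeric(unlist(m$lattice$spacing_mm))
  if (length(spacing) == 0) spacing <- c(1, 1, 1)
  treatmentPlan(doses, beamOn = shots$beam_on_min, beamOff = off,
                prescription = m$prescription_dose_gy, spacing = spacing,
                caseId = as.character(m$case_id), shotIds = shots$id)
}
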