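#' Extract the prescription isodose shell
#'
#' Selects all voxels whose total physical dose lies within an absolute
#' window of the prescription dose (inclusive comparison). The default
#' +/- 0.02 Gy window corresponds to dose deviations below 0.17% at 12 Gy
#' and 0.16% at 13 Gy. Shell membership depends only on the total dose
#' grid, so it is invariant under iso-centre re-ordering and gap edits and
#' can be reused across a case's whole analysis.
#'
#' @param x a [TreatmentPlan-class] object or a 3D total-dose array (Gy).
#' @param prescription prescription dose (Gy); defaults to the plan's.
#' @param tolerance absolute half-width of the dose window (Gy).
#' @return a [Shell-class] object; a warning is raised if it is empty.
#' @export
#' @examples
#' d <- array(c(11.99, 12.019, 12.021, 12.5, rep(0, 23)), c(3, 3, 3))
#' shellSize(extractShell(d, prescription = 12))  # 2
extractShell <- function(x, prescription = NULL, tolerance = 0.02) {
  if (is(x, "TreatmentPlan")) {
    if (is.null(prescription)) prescription <- prescriptionDose(x)
    x <- totalDose(x)
  }
  if (is.null(prescription)) stop("prescription dose is required")
  stopifnot(length(dim(x)) == 3)
  idx <- which(abs(x - prescription) <= tolerance)
  if (length(idx) == 0) {
    warning("empty shell: no voxel within +/-", tolerance, " Gy of ",
            prescription, " Gy")
  }
  new("Shell", indices = as.integer(idx), dim = dim(x),
      prescription = prescription, tolerance = tolerance)
}

#' Mean BED on the prescription isodose shell
#'
#' Arithmetic mean of the per-voxel BED values over the shell members
#' (the mean of BEDs, not the BED of the mean dose).
#'
#' @param bed a [BEDGrid-class] object.
#' @param shell a [Shell-class] object on the same lattice.
#' @return mean BED (Gy_{alpha/beta}).
#' @export
shellMeanBED <- function(bed, shell) {
  stopifnot(is(bed, "BEDGrid"), is(shell, "Shell"))
  if (shellSize(shell) == 0) {
    stop("empty shell: mean BED is undefined")
  }
  mean(bedValues(bed)[shellIndices(shell)])
}

#' Distribution summary of BED on the shell
#'
#' Order statistics of the shell's per-voxel BED values, matching the
#' box-plot presentation used for per-case BED distributions: minimum,
#' quartiles, median, mean and maximum.
#'
#' @inheritParams shellMeanBED
#' @return one-row data.frame with columns `n`, `mean`, `median`, `q25`,
#'   `q75`, `min`, `max`.
#' @export
shellStats <- function(bed, shell) {
  stopifnot(is(bed, "BEDGrid"), is(shell, "Shell"))
  if (shellSize(shell) == 0) stop("empty shell: statistics are undefined")
  v <- bedValues(bed)[shellIndices(shell)]
  q <- unname(stats::quantile(v, c(0.25, 0.5, 0.75)))
  data.frame(n = length(v), mean = mean(v), median = q[2],
             q25 = q[1], q75 = q[3], min = min(v), max = max(v))
}

#' Per-iso-centre mean dose-rate on the shell
#'
#' For each iso-centre, the mean over shell voxels of its dose-rate
#' dose_k(v) / beamOn_k (Gy/min). This per-shot profile drives the
#' sequencing heuristics: it correlates with how strongly a shot
#' interacts with its temporal neighbours on the shell.
#'
#' @param plan a [TreatmentPlan-class] object.
#' @param shell a [Shell-class] object.
#' @return numeric vector, one mean dose-rate per iso-centre, named by
#'   shot id.
#' @export
shotMeanDoseRate <- function(plan, shell) {
  stopifnot(is(plan, "TreatmentPlan"), is(shell, "Shell"))
  if (shellSize(shell) == 0) stop("empty shell: dose-rate is undefined")
  idx <- shellIndices(shell)
  r <- vapply(seq_len(nShots(plan)),
              function(k) mean(plan@doses[[k]][idx]) / beamOn(plan)[k],
              numeric(1))
  names(r) <- shotIds(plan)
  r
}
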