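#' Insert an unscheduled gap into a plan
#'
#' Lengthens one inter-iso-centre beam-off period by `duration` minutes,
#' emulating an unscheduled interruption (patient repositioning, medical
#' pause, re-imaging). The gap is additive to the scheduled beam-off, so
#' the total treatment time increases by exactly `duration`; dose grids
#' are untouched.
#'
#' @param plan a [TreatmentPlan-class] object.
#' @param position inter-iso-centre slot, 1 .. nShots - 1 (slot i sits
#'   between shots i and i + 1).
#' @param duration gap length (min), >= 0; default 15, roughly one fast
#'   repair half-time.
#' @return the modified [TreatmentPlan-class].
#' @export
insertGap <- function(plan, position, duration = 15) {
  stopifnot(is(plan, "TreatmentPlan"))
  n <- nShots(plan)
  if (length(position) != 1 || position < 1 || position > n - 1) {
    stop("position must be in 1..", n - 1)
  }
  if (duration < 0) stop("duration must be >= 0")
  plan@beamOff[position] <- plan@beamOff[position] + duration
  validObject(plan)
  plan
}

#' Sweep a gap over every inter-iso-centre position
#'
#' Simulates a single unscheduled gap of the given duration at each of
#' the nShots - 1 inter-iso-centre positions in turn and reports the
#' relative change of the shell-mean BED against the original plan,
#' 100 * (meanBED_gap - meanBED_orig) / meanBED_orig. Shell membership
#' is unchanged by gap edits, so one shell serves the whole sweep.
#'
#' @param plan a [TreatmentPlan-class] object.
#' @param params a [RepairParams-class] object.
#' @param duration gap length (min); default 15.
#' @param shell optional precomputed [Shell-class]; extracted from the
#'   plan at the default +/- 0.02 Gy tolerance if omitted.
#' @return data.frame with columns `position`, `meanBED` (with gap) and
#'   `relChangePct`, plus attributes `meanBEDOrig`, `argmin` (position of
#'   the largest reduction) and `argmax` (smallest reduction). Zero rows
#'   (with a message) for a single-shot plan.
#' @export
gapSweep <- function(plan, params = repairParams(), duration = 15,
                     shell = NULL) {
  stopifnot(is(plan, "TreatmentPlan"))
  n <- nShots(plan)
  if (n < 2) {
    message("single iso-centre plan: no inter-iso-centre position to sweep")
    out <- data.frame(position = integer(0), meanBED = numeric(0),
                      relChangePct = numeric(0))
    return(out)
  }
  if (is.null(shell)) shell <- extractShell(plan)
  cache <- .shellCache(plan, shell, params)
  base <- .cacheMeanBED(cache, beamOff = beamOff(plan))
  res <- vapply(seq_len(n - 1), function(i) {
    off <- beamOff(plan)
    off[i] <- off[i] + duration
    .cacheMeanBED(cache, beamOff = off)
  }, numeric(1))
  out <- data.frame(position = seq_len(n - 1), meanBED = res,
                    relChangePct = 100 * (res - base) / base)
  attr(out, "meanBEDOrig") <- base
  attr(out, "argmin") <- which.min(out$relChangePct)
  attr(out, "argmax") <- which.max(out$relChangePct)
  out
}
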