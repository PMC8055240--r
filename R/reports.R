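# provenance header written atop every CSV report; no timestamp, so
# deterministic stages rerun byte-identically
.reportHeader <- function(extra = character()) {
  c(sprintf("# GammaBED %s",
            as.character(utils::packageVersion("GammaBED"))),
    extra)
}

.writeReport <- function(df, path, extra = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.reportHeader(extra), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

.paramsHeader <- function(params) {
  sprintf(paste0("# repair: alpha/beta %.3f Gy, half-times %.2f/%.2f min,",
                 " partition %.3f"),
          params@alphaBeta, params@halfTimeFast, params@halfTimeSlow,
          params@partitionFast)
}

.asPlan <- function(x) {
  if (is(x, "TreatmentPlan")) x else readPlanBundle(x)
}

#' Run configuration from YAML
#'
#' Reads an optional YAML run configuration (repair parameters, shell
#' tolerance, gap duration, exhaustive search limit, seed) and fills
#' defaults for anything unspecified. All values are validated against
#' the module preconditions before use.
#'
#' @param path YAML file, or `NULL` for all defaults.
#' @return list with elements `params` ([RepairParams-class]),
#'   `shellTolerance`, `gapMin`, `exhaustiveLimit`, `seed`.
#' @export
readRunConfig <- function(path = NULL) {
  y <- if (is.null(path)) list() else yaml::read_yaml(path)
  rp <- y$repair
  params <- repairParams(
    alphaBeta = rp$alpha_beta_gy %||% 2.47,
    halfTimeFast = rp$half_time_fast_min %||% 11.4,
    halfTimeSlow = rp$half_time_slow_min %||% 129.6,
    partitionFast = rp$partition_fast %||% 0.98
  )
  cfg <- list(
    params = params,
    shellTolerance = y$shell_tolerance_gy %||% 0.02,
    gapMin = y$gap_min %||% 15,
    exhaustiveLimit = y$exhaustive_limit %||% 8,
    seed = y$seed %||% 1
  )
  stopifnot(cfg$shellTolerance >= 0, cfg$gapMin >= 0,
            cfg$exhaustiveLimit >= 1)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compute and report the BED distribution of a plan
#'
#' Evaluates the per-voxel BED grid of a plan, extracts the prescription
#' shell and its BED distribution summary, and (optionally) writes the
#' BED volume as NIfTI plus a shell-statistics CSV.
#'
#' @param bundle a [TreatmentPlan-class] or a bundle directory path.
#' @param config a [readRunConfig()] list.
#' @param outDir output directory, or `NULL` to skip writing.
#' @return list with `bed` ([BEDGrid-class]), `shell` ([Shell-class])
#'   and `stats` (one-row data.frame from [shellStats()]).
#' @export
runBED <- function(bundle, config = readRunConfig(), outDir = NULL) {
  plan <- .asPlan(bundle)
  bed <- bedGrid(plan, config$params)
  shell <- extractShell(plan, tolerance = config$shellTolerance)
  stats <- cbind(data.frame(case = caseId(plan),
                            dose_gy = prescriptionDose(plan),
                            time_min = totalTime(plan),
                            n_iso = nShots(plan)),
                 shellStats(bed, shell))
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    img <- RNifti::asNifti(bedValues(bed))
    RNifti::pixdim(img) <- voxelSpacing(plan)
    RNifti::writeNifti(img, file.path(outDir,
                                      paste0(caseId(plan), "_bed.nii.gz")))
    .writeReport(stats,
                 file.path(outDir, paste0(caseId(plan),
                                          "_shell_stats.csv")),
                 .paramsHeader(config$params))
  }
  list(bed = bed, shell = shell, stats = stats)
}

#' Sweep an unscheduled gap over a plan and report
#'
#' Runs [gapSweep()] on a plan and (optionally) writes the per-position
#' CSV: case, position, mean shell BED with the gap, relative change in
#' percent, and the gap-free mean BED.
#'
#' @inheritParams runBED
#' @return the [gapSweep()] data.frame, with a `case` column prepended.
#' @export
runGaps <- function(bundle, config = readRunConfig(), outDir = NULL) {
  plan <- .asPlan(bundle)
  shell <- extractShell(plan, tolerance = config$shellTolerance)
  sw <- gapSweep(plan, config$params, duration = config$gapMin,
                 shell = shell)
  out <- cbind(data.frame(case = rep(caseId(plan), nrow(sw))), sw,
               meanBEDOrig = rep(attr(sw, "meanBEDOrig") %||% NA_real_,
                                 nrow(sw)))
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    .writeReport(out, file.path(outDir, paste0(caseId(plan), "_gaps.csv")),
                 c(.paramsHeader(config$params),
                   sprintf("# gap: %.2f min", config$gapMin)))
  }
  out
}

#' Sequence-optimise a cohort and report
#'
#' For each plan, finds BED-minimising and BED-maximising delivery
#' sequences -- heuristically (any iso-centre count) or exhaustively
#' (iso-centre counts up to the configured limit; larger plans are
#' refused in exhaustive mode) -- and assembles the per-case cohort
#' table (case, dose, total time, iso-centre count, mean shell BED for
#' the original/min/max sequences, Delta_rel) plus the
#' [cohortSummary()] statistics including the paired min-vs-max t-tests.
#'
#' @param bundles list of [TreatmentPlan-class] objects (or bundle
#'   directory paths).
#' @param config a [readRunConfig()] list.
#' @param mode `"heuristic"` or `"exhaustive"`.
#' @param outDir output directory for the cohort CSV and summary JSON,
#'   or `NULL`.
#' @return list with `rows` (per-case data.frame) and `summary`
#'   (from [cohortSummary()]).
#' @export
runSequence <- function(bundles, config = readRunConfig(),
                        mode = c("heuristic", "exhaustive"),
                        outDir = NULL) {
  mode <- match.arg(mode)
  if (is(bundles, "TreatmentPlan")) bundles <- list(bundles)
  rows <- NULL
  for (b in bundles) {
    plan <- .asPlan(b)
    shell <- extractShell(plan, tolerance = config$shellTolerance)
    cache <- .shellCache(plan, shell, config$params)
    bedOrig <- .cacheMeanBED(cache, beamOff = beamOff(plan))
    if (mode == "exhaustive") {
      ex <- exhaustiveSearch(plan, config$params,
                             limit = config$exhaustiveLimit,
                             shell = shell)
      bedMin <- ex$min$meanBED
      bedMax <- ex$max$meanBED
    } else {
      rates <- shotMeanDoseRate(plan, shell)
      bedMin <- .cacheMeanBED(cache, heuristicMinSequence(rates),
                              beamOff = beamOff(plan))
      bedMax <- .cacheMeanBED(cache, heuristicMaxSequence(rates),
                              beamOff = beamOff(plan))
    }
    rows <- rbind(rows, data.frame(
      case = caseId(plan), dose_gy = prescriptionDose(plan),
      time_min = totalTime(plan), n_iso = nShots(plan),
      bed_orig = bedOrig, bed_min = bedMin, bed_max = bedMax,
      delta_rel_pct = deltaRel(bedOrig, bedMin, bedMax)))
  }
  summary <- cohortSummary(rows)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    .writeReport(rows, file.path(outDir, "cohort_sequence.csv"),
                 c(.paramsHeader(config$params),
                   sprintf("# mode: %s", mode)))
    jsonlite::write_json(summary,
                         file.path(outDir, "cohort_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(rows = rows, summary = summary)
}
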