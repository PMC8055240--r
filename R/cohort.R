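#' Read a per-case cohort results table
#'
#' Reads a CSV of per-case sequencing results (the "table ingest" mode):
#' columns `case`, `dose_gy`, `time_min`, `n_iso`, `bed_orig`, `bed_min`,
#' `bed_max` and optionally `delta_rel_pct` (recomputed with [deltaRel()]
#' when absent). This lets the cohort statistics be exercised on printed
#' per-case values independently of the BED engine.
#'
#' A 15-case vestibular schwannoma example table (6 cases at 12 Gy, 9 at
#' 13 Gy) ships with the package; see the example.
#'
#' @param path CSV file path.
#' @return data.frame of validated cohort rows.
#' @export
#' @examples
#' tab <- readCohortTable(system.file("extdata", "cohort_results.csv",
#'                                    package = "GammaBED"))
#' head(tab)
readCohortTable <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("case", "dose_gy", "time_min", "n_iso",
            "bed_orig", "bed_min", "bed_max")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("cohort table is missing columns: ", paste(miss, collapse = ", "))
  }
  if (is.null(tab$delta_rel_pct)) {
    tab$delta_rel_pct <- deltaRel(tab$bed_orig, tab$bed_min, tab$bed_max)
  }
  if (any(tab$bed_orig <= 0)) stop("bed_orig must be positive")
  tab
}

.groupSummary <- function(g) {
  data.frame(
    n = nrow(g),
    meanTime = mean(g$time_min),
    meanNIso = mean(g$n_iso),
    meanBedOrig = mean(g$bed_orig),
    meanBedMin = mean(g$bed_min),
    meanBedMax = mean(g$bed_max),
    meanDeltaRel = mean(g$delta_rel_pct),
    spreadPct = 100 * (max(g$bed_max) - min(g$bed_min)) / mean(g$bed_orig)
  )
}

#' Cohort-level sequencing statistics
#'
#' Summarises per-case re-sequencing results: per-prescription-group
#' means of treatment time, iso-centre count and the BED columns; the
#' min-to-max spread of achievable mean BED relative to the group's mean
#' original BED; the cohort-mean relative range Delta_rel; the mean
#' heuristic increase 100 (BED_max - BED_orig) / BED_orig and decrease
#' 100 (BED_orig - BED_min) / BED_orig; the ratio of mean original BEDs
#' between the two prescription groups; and paired two-sided t-tests of
#' BED_min against BED_max per group and for the whole cohort.
#'
#' @param rows data.frame of cohort rows as returned by
#'   [readCohortTable()] or [runSequence()].
#' @return list with `groups` (one summary row per prescription dose),
#'   `overall` (cohort means, heuristic increase/decrease percentages,
#'   and `groupRatioPct` when there are exactly two groups), and
#'   `tTests` (named list of [pairedTTest()] results).
#' @export
#' @examples
#' tab <- readCohortTable(system.file("extdata", "cohort_results.csv",
#'                                    package = "GammaBED"))
#' s <- cohortSummary(tab)
#' s$groups
cohortSummary <- function(rows) {
  if (nrow(rows) == 0) stop("empty cohort")
  doses <- sort(unique(rows$dose_gy))
  groups <- do.call(rbind, lapply(doses, function(d) {
    g <- rows[rows$dose_gy == d, ]
    cbind(data.frame(dose_gy = d), .groupSummary(g))
  }))
  safeT <- function(x, y) {
    if (length(x) < 2) return(NULL)
    tryCatch(pairedTTest(x, y), error = function(e) NULL)
  }
  tTests <- list()
  for (d in doses) {
    g <- rows[rows$dose_gy == d, ]
    tTests[[paste0("gy", d)]] <- safeT(g$bed_min, g$bed_max)
  }
  tTests$all <- safeT(rows$bed_min, rows$bed_max)
  overall <- list(
    meanDeltaRel = mean(rows$delta_rel_pct),
    heuristicIncreasePct =
      mean(100 * (rows$bed_max - rows$bed_orig) / rows$bed_orig),
    heuristicDecreasePct =
      mean(100 * (rows$bed_orig - rows$bed_min) / rows$bed_orig),
    meanBedOrig = mean(rows$bed_orig)
  )
  if (length(doses) == 2) {
    m <- groups$meanBedOrig
    overall$groupRatioPct <- 100 * (m[2] / m[1] - 1)
  }
  list(groups = groups, overall = overall, tTests = tTests)
}
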