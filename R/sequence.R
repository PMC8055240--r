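#' Re-order the iso-centre delivery sequence
#'
#' Applies a permutation to the delivery order: dose grids, beam-on times
#' and shot ids travel with their iso-centre, while beam-off durations
#' stay attached to the schedule slots (inert at the uniform default of
#' 0.06 min). The total physical dose grid is unchanged by construction.
#'
#' @param plan a [TreatmentPlan-class] object.
#' @param perm integer permutation of 1..nShots; `perm[p]` is the shot
#'   delivered in schedule position p.
#' @return the re-ordered [TreatmentPlan-class].
#' @export
applySequence <- function(plan, perm) {
  stopifnot(is(plan, "TreatmentPlan"))
  n <- nShots(plan)
  if (length(perm) != n || !setequal(perm, seq_len(n))) {
    stop("perm must be a permutation of 1..", n)
  }
  plan@doses <- plan@doses[perm]
  plan@beamOn <- plan@beamOn[perm]
  plan@shotIds <- plan@shotIds[perm]
  plan
}

# all permutations of 1..n as an (n! x n) integer matrix, lexicographic
.allPerms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .allPerms(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    block <- row:(row + nrow(sub) - 1L)
    out[block, 1L] <- first
    out[block, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
    row <- row + nrow(sub)
  }
  out
}

# shell-mean BED of every permutation in `perms` (rows), via the cached
# pair magnitudes: O(n^2) vector ops per pair of schedule positions.
.evalPerms <- function(cache, perms, beamOff) {
  P <- nrow(perms)
  n <- ncol(perms)
  tOn <- matrix(cache$beamOn[perms], P, n)
  starts <- matrix(0, P, n)
  if (n > 1) {
    for (p in 2:n) starts[, p] <- starts[, p - 1] + tOn[, p - 1] +
        beamOff[p - 1]
  }
  ends <- starts + tOn
  cc <- cache$cc
  phi <- rep(cc * cache$fast$selfMean + (1 - cc) * cache$slow$selfMean, P)
  if (n > 1) {
    for (p in seq_len(n - 1)) {
      for (q in (p + 1):n) {
        tau <- starts[, q] - ends[, p]
        ij <- cbind(perms[, p], perms[, q])
        phi <- phi + cc * cache$fast$M[ij] *
          exp(-cache$mu[["fast"]] * tau)
        if (cc < 1) {
          phi <- phi + (1 - cc) * cache$slow$M[ij] *
            exp(-cache$mu[["slow"]] * tau)
        }
      }
    }
  }
  cache$Dmean + phi / cache$alphaBeta
}

# lexicographically smallest row among near-ties of an extreme value
.pickExtreme <- function(perms, vals, which = c("min", "max")) {
  which <- match.arg(which)
  v0 <- if (which == "min") min(vals) else max(vals)
  tol <- 1e-12 * max(1, abs(v0))
  cand <- which(abs(vals - v0) <= tol)
  if (length(cand) > 1) {
    sub <- perms[cand, , drop = FALSE]
    ord <- do.call(order, as.data.frame(sub))
    cand <- cand[ord[1]]
  }
  list(permutation = perms[cand, ], meanBED = vals[cand])
}

#' Exhaustive search over iso-centre orderings
#'
#' Evaluates the shell-mean BED of every one of the n! delivery
#' sequences of a plan and returns the minimising and maximising
#' permutations. The objective is the mean BED over the prescription
#' shell; per-voxel pairwise interaction magnitudes are
#' permutation-independent and cached once, so each sequence costs only
#' the O(n^2) attenuation products.
#'
#' Plans with more iso-centres than `limit` (default 8, i.e. 8! = 40,320
#' sequences) are refused unless `override = TRUE`, reporting the number
#' of sequences the search would need.
#'
#' @param plan a [TreatmentPlan-class] object.
#' @param params a [RepairParams-class] object.
#' @param limit largest iso-centre count searched without override.
#' @param override force the search past `limit`.
#' @param shell optional precomputed [Shell-class].
#' @return list with elements `min` and `max` (each a list with
#'   `permutation` and `meanBED`; ties resolved to the lexicographically
#'   smallest permutation), `count` (= n!), and `meanBEDOrig` (original
#'   order).
#' @export
exhaustiveSearch <- function(plan, params = repairParams(), limit = 8,
                             override = FALSE, shell = NULL) {
  stopifnot(is(plan, "TreatmentPlan"))
  n <- nShots(plan)
  if (n > limit && !override) {
    stop(sprintf(paste0(
      "plan has %d iso-centres: exhaustive search would need ",
      "%.4e sequences (limit %d! = %d); use override = TRUE or the ",
      "heuristic sequences"), n, factorial(n), limit, factorial(limit)))
  }
  if (is.null(shell)) shell <- extractShell(plan)
  cache <- .shellCache(plan, shell, params)
  off <- beamOff(plan)
  perms <- .allPerms(n)
  vals <- .evalPerms(cache, perms, off)
  list(
    min = .pickExtreme(perms, vals, "min"),
    max = .pickExtreme(perms, vals, "max"),
    count = nrow(perms),
    meanBEDOrig = .cacheMeanBED(cache, beamOff = off)
  )
}

#' Pyramidal (BED-maximising) heuristic sequence
#'
#' Groups the high-dose-rate iso-centres contiguously mid-schedule:
#' shots are sorted ascending by their mean shell dose-rate and assigned
#' to schedule positions outside-in, alternating left/right, so the
#' largest rates end up adjacent in the middle ("pyramidal" rate
#' profile). Minimising the time between the strongest shots preserves
#' their mutual incomplete-repair interaction and maximises BED. Ties
#' are broken by the original shot index; with no rate variation the
#' original order is returned.
#'
#' @param rates per-shot mean dose-rates on the shell (Gy/min), e.g.
#'   from [shotMeanDoseRate()].
#' @return integer permutation (delivery order of shot indices).
#' @export
#' @examples
#' heuristicMaxSequence(c(1, 2, 3, 4, 5))  # 1 3 5 4 2
heuristicMaxSequence <- function(rates) {
  n <- length(rates)
  if (n <= 1 || diff(range(rates)) == 0) return(seq_len(n))
  asc <- order(rates, seq_len(n))
  out <- integer(n)
  left <- 1L
  right <- n
  for (i in seq_len(n)) {
    if (i %% 2 == 1) {
      out[left] <- asc[i]
      left <- left + 1L
    } else {
      out[right] <- asc[i]
      right <- right - 1L
    }
  }
  out
}

#' Spread-out (BED-minimising) heuristic sequence
#'
#' Spreads the high-dose-rate iso-centres across the delivery: the
#' schedule alternates the highest-remaining and lowest-remaining rate
#' shots, so strong shots are separated by weak ones and by the maximum
#' time, letting their mutual sublethal damage repair. Ties are broken
#' by the original shot index; with no rate variation the original order
#' is returned.
#'
#' @inheritParams heuristicMaxSequence
#' @return integer permutation (delivery order of shot indices).
#' @export
#' @examples
#' heuristicMinSequence(c(1, 2, 3, 4, 5))  # 5 1 4 2 3
heuristicMinSequence <- function(rates) {
  n <- length(rates)
  if (n <= 1 || diff(range(rates)) == 0) return(seq_len(n))
  asc <- order(rates, seq_len(n))
  desc <- rev(asc)
  out <- integer(n)
  hi <- 1L
  lo <- 1L
  for (i in seq_len(n)) {
    if (i %% 2 == 1) {
      out[i] <- desc[hi]
      hi <- hi + 1L
    } else {
      out[i] <- asc[lo]
      lo <- lo + 1L
    }
  }
  out
}

#' Relative range of achievable mean BED
#'
#' Delta_rel = 100 * (BED_max - BED_min) / BED_orig: the min-to-max range
#' of shell-mean BED attainable by re-sequencing, relative to the
#' originally planned sequence.
#'
#' @param bedOrig,bedMin,bedMax shell-mean BED of the original,
#'   minimising and maximising sequences (Gy_{alpha/beta}).
#' @return percentage.
#' @export
#' @examples
#' deltaRel(61.95, 60.67, 63.33)  # 4.29
deltaRel <- function(bedOrig, bedMin, bedMax) {
  if (any(bedOrig <= 0)) stop("bedOrig must be positive")
  100 * (bedMax - bedMin) / bedOrig
}

#' Paired t-test
#'
#' Classical two-sided paired t-test on the differences x - y, with
#' n - 1 degrees of freedom (wraps [stats::t.test()]).
#'
#' @param x,y paired numeric vectors of equal length >= 2.
#' @return list with `t`, `df` and two-sided `p`.
#' @export
#' @examples
#' pairedTTest(c(1, 2, 3), c(2, 4, 6))
pairedTTest <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  if (length(x) < 2) stop("need at least 2 pairs")
  d <- x - y
  if (stats::sd(d) == 0) {
    stop("zero-variance differences: paired t-test is degenerate")
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}
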