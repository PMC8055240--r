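#' Construct repair parameters
#'
#' @param alphaBeta alpha/beta ratio (Gy); default 2.47.
#' @param halfTimeFast fast repair half-time (min); default 11.4 (0.19 h).
#' @param halfTimeSlow slow repair half-time (min); default 129.6 (2.16 h).
#' @param partitionFast fast-component partition coefficient; default 0.98.
#'
#' @return a [RepairParams-class] object.
#' @export
#' @examples
#' repairParams()
#' repairParams(partitionFast = 1)  # mono-exponential, fast repair only
repairParams <- function(alphaBeta = 2.47, halfTimeFast = 11.4,
                         halfTimeSlow = 129.6, partitionFast = 0.98) {
  new("RepairParams", alphaBeta = alphaBeta, halfTimeFast = halfTimeFast,
      halfTimeSlow = halfTimeSlow, partitionFast = partitionFast)
}

#' Repair rate constant from a half-time
#'
#' mu = ln(2) / T_half, the first-order rate constant of exponential
#' sublethal-damage repair.
#'
#' @param halfTime repair half-time (min); must be positive.
#' @return rate constant (1/min).
#' @export
#' @examples
#' repairRate(11.4)
repairRate <- function(halfTime) {
  if (any(!is.finite(halfTime)) || any(halfTime <= 0)) {
    stop("halfTime must be positive and finite")
  }
  log(2) / halfTime
}

#' Construct a per-voxel exposure protocol
#'
#' @param rates dose-rates (Gy/min), one per segment.
#' @param durations beam-on durations (min).
#' @param intervals beam-off gaps between consecutive segments (min).
#' @return a [VoxelExposure-class] object.
#' @export
#' @examples
#' voxelExposure(rates = c(2, 1), durations = c(3, 4), intervals = 0.06)
voxelExposure <- function(rates, durations,
                          intervals = numeric(max(length(rates) - 1L, 0L))) {
  new("VoxelExposure", rates = as.numeric(rates),
      durations = as.numeric(durations), intervals = as.numeric(intervals))
}

# x - 1 + exp(-x), guarded against cancellation for small x
.h1 <- function(x) {
  out <- x - 1 + exp(-x)
  small <- x < 1e-4
  if (any(small)) {
    xs <- x[small]
    out[small] <- xs^2 / 2 - xs^3 / 6 + xs^4 / 24
  }
  out
}

# 1 - exp(-x) without cancellation
.g1 <- function(x) -expm1(-x)

#' Dose-protraction self term of one segment
#'
#' The intra-segment contribution to the protraction function Phi for a
#' constant dose-rate segment:
#' \deqn{\phi_{self} = \frac{2R^2}{\mu^2}\left(\mu t - 1 + e^{-\mu t}\right)
#'   = 2\int_0^t\!\!\int_0^{s} R^2 e^{-\mu(s - s')}\,ds'\,ds.}
#' In the no-repair limit (mu t -> 0) it tends to the acute value d^2 with
#' d = R t.
#'
#' @param rate dose-rate (Gy/min), >= 0.
#' @param duration beam-on time (min), > 0.
#' @param mu repair rate constant (1/min), > 0.
#' @return the self-interaction term (Gy^2).
#' @export
#' @examples
#' phiSelf(1, 1, 1)            # 2 * exp(-1)
#' phiSelf(2, 3, 1e-9)         # ~ (2*3)^2, acute limit
phiSelf <- function(rate, duration, mu) {
  if (any(mu <= 0)) stop("mu must be positive; the no-repair limit is d^2")
  if (any(duration <= 0)) stop("duration must be positive")
  if (any(rate < 0)) stop("rate must be >= 0")
  2 * rate^2 / mu^2 * .h1(mu * duration)
}

#' Dose-protraction cross term of two segments
#'
#' The incomplete-repair interaction between two constant-rate segments j
#' (delivered first) and k, separated by a beam-off interval tau measured
#' from the end of j to the start of k:
#' \deqn{\phi_{cross} = \frac{2 R_j R_k}{\mu^2}
#'   \left(1 - e^{-\mu t_j}\right)\left(1 - e^{-\mu t_k}\right) e^{-\mu\tau}.}
#' It decreases strictly in tau and vanishes as tau -> Inf (complete
#' repair); in the acute no-repair limit it tends to 2 d_j d_k.
#'
#' @param rateJ,durJ rate (Gy/min) and duration (min) of the earlier
#'   segment.
#' @param rateK,durK rate and duration of the later segment.
#' @param interval beam-off time tau (min) between the segments, >= 0.
#' @param mu repair rate constant (1/min), > 0.
#' @return the cross-interaction term (Gy^2).
#' @export
#' @examples
#' # near-acute 1 Gy segments one fast half-time apart: ~ 2*1*1*0.5
#' phiCross(1e6, 1e-6, 1e6, 1e-6, interval = 1, mu = log(2))
phiCross <- function(rateJ, durJ, rateK, durK, interval, mu) {
  if (any(interval < 0)) stop("interval must be >= 0")
  if (any(mu <= 0)) stop("mu must be positive")
  if (any(durJ <= 0) || any(durK <= 0)) stop("durations must be positive")
  2 * rateJ * rateK / mu^2 * .g1(mu * durJ) * .g1(mu * durK) *
    exp(-mu * interval)
}

# absolute start/end times of an exposure's segments
.exposureTimes <- function(exposure) {
  dur <- exposure@durations
  n <- length(dur)
  if (n == 0) return(list(start = numeric(0), end = numeric(0)))
  starts <- cumsum(c(0, dur[-n] + exposure@intervals))
  list(start = starts, end = starts + dur)
}

#' Protraction function of a whole protocol
#'
#' Evaluates the dose-protraction function Phi(Xi, mu) of an exposure
#' protocol Xi: the sum of all segment self terms plus all pairwise cross
#' terms, with each pair's repair interval taken from the absolute
#' timeline (so the gap between non-adjacent segments accumulates the
#' intermediate beam-on and beam-off periods).
#'
#' @param exposure a [VoxelExposure-class] object.
#' @param mu repair rate constant (1/min), > 0.
#' @return Phi (Gy^2); 0 for an empty protocol.
#' @seealso [phiNumericOracle()] for the quadrature reference.
#' @export
#' @examples
#' e <- voxelExposure(c(1, 1), c(1, 1), intervals = 1)
#' phiProtocol(e, mu = log(2))
phiProtocol <- function(exposure, mu) {
  stopifnot(is(exposure, "VoxelExposure"))
  if (any(mu <= 0)) stop("mu must be positive")
  r <- exposure@rates
  t <- exposure@durations
  n <- length(r)
  if (n == 0) return(0)
  total <- sum(phiSelf(r, t, mu))
  if (n > 1) {
    tm <- .exposureTimes(exposure)
    for (j in seq_len(n - 1)) {
      k <- (j + 1):n
      tau <- tm$start[k] - tm$end[j]
      total <- total +
        sum(phiCross(r[j], t[j], r[k], t[k], tau, mu))
    }
  }
  total
}

#' Quadrature reference for the protraction function
#'
#' Independent brute-force evaluation of
#' \deqn{\Phi = 2\iint_{s < s'} R(s) R(s') e^{-\mu (s' - s)}\, ds\, ds'}
#' for the piecewise-constant dose-rate function R(s) of the protocol
#' (rate 0 during beam-off), by adaptive 2D quadrature over each pair of
#' segment supports. Used as the oracle against which the closed-form
#' [phiProtocol()] is validated; far slower, never used in the pipeline.
#'
#' @param exposure a [VoxelExposure-class] object.
#' @param mu repair rate constant (1/min), > 0.
#' @param reltol relative quadrature tolerance.
#' @return Phi (Gy^2).
#' @export
phiNumericOracle <- function(exposure, mu, reltol = 1e-10) {
  stopifnot(is(exposure, "VoxelExposure"))
  if (any(mu <= 0)) stop("mu must be positive")
  r <- exposure@rates
  n <- length(r)
  if (n == 0) return(0)
  tm <- .exposureTimes(exposure)
  total <- 0
  for (j in seq_len(n)) {
    if (r[j] == 0) next
    for (k in j:n) {
      if (r[k] == 0) next
      if (j == k) {
        # triangle s' in segment, s in [start, s']
        f <- function(x, y) r[j]^2 * exp(-mu * (x - y))
        q <- pracma::integral2(f, tm$start[j], tm$end[j],
                               function(x) 0 * x + tm$start[j],
                               function(x) x, reltol = reltol)$Q
      } else {
        f <- function(x, y) r[j] * r[k] * exp(-mu * (y - x))
        q <- pracma::integral2(f, tm$start[j], tm$end[j],
                               tm$start[k], tm$end[k], reltol = reltol)$Q
      }
      total <- total + 2 * q
    }
  }
  total
}

#' BED of a single voxel
#'
#' Biologically effective dose of one voxel's exposure protocol under the
#' linear-quadratic model with bi-exponential incomplete repair:
#' \deqn{BED = D_T + \frac{c\,\Phi(\Xi,\mu_{fast}) +
#'   (1-c)\,\Phi(\Xi,\mu_{slow})}{\alpha/\beta}}
#' where D_T is the voxel's total dose and c the partition coefficient.
#' BED is bounded below by D_T (complete repair) and above by the acute
#' value D_T (1 + D_T / (alpha/beta)).
#'
#' @param exposure a [VoxelExposure-class] object.
#' @param params a [RepairParams-class] object.
#' @return BED in Gy_{alpha/beta}.
#' @export
#' @examples
#' p <- repairParams()
#' e <- voxelExposure(rates = c(4, 4), durations = c(1.5, 1.5),
#'                    intervals = 0.06)
#' bedVoxel(e, p)
bedVoxel <- function(exposure, params) {
  stopifnot(is(exposure, "VoxelExposure"), is(params, "RepairParams"))
  d <- sum(exposure@rates * exposure@durations)
  if (d == 0) return(0)
  mu <- repairRates(params)
  cc <- params@partitionFast
  phi <- cc * phiProtocol(exposure, mu[["fast"]])
  if (cc < 1) phi <- phi + (1 - cc) * phiProtocol(exposure, mu[["slow"]])
  d + phi / params@alphaBeta
}
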