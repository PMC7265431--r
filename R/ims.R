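#' Intrinsic mass spacing (IMS) coefficients
#'
#' A time-of-flight mass analyser samples ion arrival times at integer
#' multiples of a fixed sensor interval, so every observable m/z value lies
#' on a square-root lattice
#' \deqn{m/z(i) = [\alpha (i + \gamma) + \beta]^2,}
#' where \eqn{\alpha} (in \eqn{\sqrt{Da}} per index step) is set by the
#' sampling interval, accelerating potential and flight distance,
#' \eqn{\beta} (in \eqn{\sqrt{Da}}) absorbs the arrival-time offset, and
#' \eqn{\gamma} is an integer index offset used as a storage convention.
#' Only \eqn{\alpha} and the combined offset \eqn{\alpha\gamma + \beta} are
#' physically identified.
#'
#' @param alpha positive slope of the square-root lattice (\eqn{\sqrt{Da}}
#'   per index step).
#' @param beta lattice offset (\eqn{\sqrt{Da}}).
#' @param gamma integer index offset.
#' @return An object of class `ims_params`.
#' @examples
#' p <- ims_params(alpha = 1, beta = 0, gamma = 0)
#' mz_from_index(4, p) # 16
#' @export
ims_params <- function(alpha, beta = 0, gamma = 0L) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(beta), length(beta) == 1L, is.finite(beta),
            length(gamma) == 1L, gamma == round(gamma))
  if (alpha <= 0) stop("'alpha' must be > 0")
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta),
                 gamma = as.integer(gamma)),
            class = "ims_params")
}

#' @export
print.ims_params <- function(x, ...) {
  cat(sprintf("IMS parameters: alpha = %.12g, beta = %.12g, gamma = %d\n",
              x$alpha, x$beta, x$gamma))
  invisible(x)
}

#' Instrument timing parameters of a TOF analyser
#'
#' Describes the sensor timing and geometry from which the lattice
#' coefficients derive: arrival times are \eqn{t_i = \Delta t \cdot i + t'_0}
#' and \eqn{t_i = d/\sqrt{2U} \cdot \sqrt{m/z}}.
#'
#' @param delta_t sensor sampling interval (s), > 0.
#' @param t0_prime arrival-time offset (s).
#' @param U accelerating potential (consistent units), > 0.
#' @param d flight distance (consistent units), > 0.
#' @return An object of class `instrument_timing`.
#' @export
instrument_timing <- function(delta_t, t0_prime = 0, U, d) {
  stopifnot(delta_t > 0, U > 0, d > 0, is.finite(t0_prime))
  structure(list(delta_t = as.numeric(delta_t), t0_prime = as.numeric(t0_prime),
                 U = as.numeric(U), d = as.numeric(d)),
            class = "instrument_timing")
}

#' Convert integer index to m/z
#'
#' Evaluates the lattice transfer function \eqn{[\alpha(i+\gamma)+\beta]^2}.
#'
#' @param i integer index (vectorised).
#' @param params an [ims_params] object.
#' @return m/z values in Da.
#' @export
mz_from_index <- function(i, params) {
  stopifnot(inherits(params, "ims_params"))
  r <- params$alpha * (i + params$gamma) + params$beta
  if (any(r <= 0)) {
    stop("index outside physical range: alpha*(i+gamma)+beta must be > 0")
  }
  r * r
}

#' Convert m/z to the nearest integer lattice index
#'
#' Inverts [mz_from_index] and rounds to the nearest index. Ties at half an
#' index step round away from zero (relevant for perturbed, off-lattice
#' input; exact lattice points are unaffected).
#'
#' @param mz m/z values in Da, > 0 (vectorised).
#' @param params an [ims_params] object.
#' @return integer indices.
#' @export
index_from_mz <- function(mz, params) {
  stopifnot(inherits(params, "ims_params"))
  if (any(mz <= 0)) stop("'mz' must be > 0")
  x <- (sqrt(mz) - params$beta) / params$alpha - params$gamma
  round_half_away(x)
}

# round-half-away-from-zero; base round() is round-half-even
round_half_away <- function(x) {
  trunc(x + sign(x) * 0.5)
}

#' Derive IMS coefficients from instrument timing
#'
#' \eqn{\alpha = \Delta t \sqrt{2U}/d}, \eqn{\gamma = \lceil t'_0/\Delta t\rceil},
#' \eqn{\beta = \alpha (t'_0/\Delta t - \gamma)}.
#'
#' @param timing an [instrument_timing] object.
#' @return An [ims_params] object.
#' @export
ims_from_instrument <- function(timing) {
  stopifnot(inherits(timing, "instrument_timing"))
  alpha <- timing$delta_t * sqrt(2 * timing$U) / timing$d
  gamma <- as.integer(ceiling(timing$t0_prime / timing$delta_t))
  beta <- alpha * (timing$t0_prime / timing$delta_t - gamma)
  ims_params(alpha = alpha, beta = beta, gamma = gamma)
}

#' Estimate per-scan IMS coefficients from observed m/z values
#'
#' TOF profile m/z values of a single scan lie on a square-root lattice.
#' The estimator takes successive differences of \eqn{\sqrt{m/z}}, seeds the
#' step size with the minimum positive difference (on a lattice every
#' difference is an integer multiple of \eqn{\alpha}), assigns provisional
#' integer indices by rounding each difference to its nearest multiple, and
#' refines slope and intercept by least squares of \eqn{\sqrt{m/z}} against
#' the indices, iterating until the index assignment is stable (at most 10
#' rounds). The result is canonicalised to \eqn{\gamma = 0} with
#' \eqn{\beta \in [0, \alpha)}: whole multiples of \eqn{\alpha} in the
#' intercept are folded into the returned indices, which then approximate
#' the absolute TOF sample index.
#'
#' Per-scan estimation matters because TOF instruments apply in-line
#' calibration on top of routine lab calibration, so the coefficients drift
#' slowly from scan to scan; a single per-run (or per-window) set would not
#' reproduce the data exactly.
#'
#' @param mz sorted positive m/z values, at least 3 distinct.
#' @param seed_params optional [ims_params] warm start for the step size.
#' @param tolerance_ppm maximum acceptable reconstruction residual in ppm;
#'   above it the fit is declared a failure (default 5 ppm).
#' @return A list with elements `params` ([ims_params]), `indices`
#'   (integer vector, one per input value) and `max_residual_ppm`.
#' @export
estimate_scan_ims <- function(mz, seed_params = NULL, tolerance_ppm = 5) {
  mz <- as.numeric(mz)
  if (length(unique(mz)) < 3L) {
    stop("under-determined: need at least 3 distinct m/z values")
  }
  if (is.unsorted(mz, strictly = TRUE)) {
    mz <- sort(unique(mz))
  }
  if (any(mz <= 0)) stop("'mz' must be > 0")
  r <- sqrt(mz)
  d <- diff(r)

  alpha <- if (!is.null(seed_params)) {
    stopifnot(inherits(seed_params, "ims_params"))
    seed_params$alpha
  } else {
    # near-adjacent spacings estimate the step size; with noisy input a
    # single minimum difference can be biased low, so average the cluster
    md <- min(d)
    mean(d[d <= 1.5 * md])
  }
  if (alpha <= 0) stop("estimation failure: non-increasing sqrt(m/z)")

  # gap ladder: a gap of n steps can only be rounded to its integer count
  # once alpha's relative error is below ~0.4/n, so refine alpha on small
  # certified gaps first (regression through the origin on step counts)
  # and widen the certified range only as fast as the accumulated evidence
  # allows: with per-difference noise eta (in step units) and certified
  # step counts n_k, the refit precision is eta / sqrt(sum n_k^2)
  g_cap <- 1
  for (iter in seq_len(25L)) {
    steps <- d / alpha
    n <- pmax(1, round_half_away(steps))
    trusted <- n <= g_cap & abs(steps - n) < 0.35
    if (any(trusted)) {
      alpha <- sum(d[trusted] * n[trusted]) / sum(n[trusted]^2)
      steps <- d / alpha
      n <- pmax(1, round_half_away(steps))
      trusted <- n <= g_cap & abs(steps - n) < 0.35
    }
    if (all(n <= g_cap)) break
    # per-difference noise scale (robust, in step units) and the resulting
    # alpha precision bound the gap size that can be rounded safely;
    # when no further widening is certified the remaining gaps are rounded
    # best-effort and the residual guard below decides
    eta <- min(max(1e-3, 1.4826 * stats::median(abs(steps - n)[trusted])),
               0.2)
    eps <- eta / sqrt(sum(n[trusted]^2))
    g_next <- floor(max(0.05, 0.35 - 3 * eta) / max(eps, 1e-12))
    if (g_next <= g_cap) break
    g_cap <- g_next
  }

  idx_prev <- NULL
  beta <- 0
  for (iter in seq_len(10L)) {
    steps <- pmax(1, round_half_away(d / alpha))
    idx <- c(0, cumsum(steps))
    fit <- stats::lm.fit(cbind(1, idx), r)
    beta <- fit$coefficients[[1L]]
    alpha <- fit$coefficients[[2L]]
    if (!is.finite(alpha) || alpha <= 0) {
      stop("estimation failure: degenerate lattice fit")
    }
    if (!is.null(idx_prev) && identical(idx, idx_prev)) break
    idx_prev <- idx
  }

  # a lattice is only real if points sit far closer to the nodes than the
  # step size; residuals near half a step mean the fit merely saturated
  # (any point set can be interpolated by a fine enough lattice)
  step_resid <- max(abs(r - (beta + alpha * idx))) / alpha
  if (step_resid > 0.25) {
    stop(sprintf(
      "estimation failure: data do not sit on a lattice (worst residual %.2f of a step)",
      step_resid))
  }

  # canonical gamma = 0, beta in [0, alpha): fold alpha-multiples into index
  shift <- floor(beta / alpha)
  beta <- beta - shift * alpha
  idx <- idx + shift
  params <- ims_params(alpha = alpha, beta = beta, gamma = 0L)

  resid_ppm <- abs(mz_from_index(idx, params) / mz - 1) * 1e6
  max_resid <- max(resid_ppm)
  if (max_resid > tolerance_ppm) {
    stop(sprintf(
      "estimation failure: no consistent lattice within %g ppm (worst residual %.3g ppm)",
      tolerance_ppm, max_resid))
  }
  list(params = params, indices = as.integer(round(idx)),
       max_residual_ppm = max_resid)
}
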