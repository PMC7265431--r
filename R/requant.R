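#' Analytic 2D peak model parameters
#'
#' The peptide peak is modelled as log-normal along retention time
#' (chromatographic elution skews left) and Gaussian along the m/z index
#' axis (ion kinetic-energy spread in the TOF), with a shared
#' retention-time apex `t0` across fragments and a per-fragment index
#' centre `m0` to absorb calibration offsets:
#' \deqn{F_j = \frac{1}{t}\frac{a_j}{\sigma_t\sqrt{2\pi}}
#'   \exp\!\Big[-\frac{(\log t-\log t_0)^2}{2\sigma_t^2}
#'             -\frac{(m-m_{0,j})^2}{2\sigma_m^2}\Big] + C_j,}
#' with chemical noise \eqn{C_j = c_j \exp[-(m-m_{0,j})^2/(2\sigma_m^2)]}
#' added for MS1 fragments only. The amplitude \eqn{a_j} equals the peak's
#' integrated area along retention time, which is why it serves as the
#' re-quantified intensity.
#'
#' @param sigma_t log-retention-time spread, > 0.
#' @param sigma_m index-space spread, > 0.
#' @param t0 retention-time apex (s), > 0.
#' @param m0 index-space centre, one per fragment.
#' @param a amplitude per fragment, >= 0.
#' @param c chemical-noise amplitude per fragment (used only where
#'   `is_ms1` is TRUE), >= 0; defaults to 0.
#' @param is_ms1 logical per fragment; default all FALSE.
#' @return An object of class `peak_model_params`.
#' @export
peak_model_params <- function(sigma_t, sigma_m, t0, m0, a,
                              c = rep(0, length(m0)),
                              is_ms1 = rep(FALSE, length(m0))) {
  stopifnot(sigma_t > 0, sigma_m > 0, t0 > 0,
            length(m0) == length(a), length(c) == length(m0),
            length(is_ms1) == length(m0), all(a >= 0), all(c >= 0))
  structure(list(sigma_t = as.numeric(sigma_t), sigma_m = as.numeric(sigma_m),
                 t0 = as.numeric(t0), m0 = as.numeric(m0), a = as.numeric(a),
                 c = as.numeric(c), is_ms1 = as.logical(is_ms1)),
            class = "peak_model_params")
}

#' Evaluate the analytic peak model
#'
#' @param params a [peak_model_params].
#' @param t retention times (s), > 0; vectorised.
#' @param m m/z index coordinates; vectorised (recycled against `t`).
#' @param j fragment number (1-based).
#' @return model intensities.
#' @export
eval_peak_model <- function(params, t, m, j = 1L) {
  if (any(t <= 0)) stop("'t' must be > 0 (log-normal retention-time model)")
  gm <- exp(-(m - params$m0[j])^2 / (2 * params$sigma_m^2))
  f <- (1 / t) * (params$a[j] / (params$sigma_t * sqrt(2 * pi))) *
    exp(-(log(t) - log(params$t0))^2 / (2 * params$sigma_t^2)) * gm
  if (params$is_ms1[j]) f <- f + params$c[j] * gm
  f
}

#' Multi-fragment raster of observed intensities
#'
#' The raw data a peak fit consumes: a common retention-time axis `t`,
#' a common index axis `m`, and one scans-by-coords intensity matrix per
#' fragment.
#'
#' @param t retention times (s), > 0.
#' @param m index coordinates.
#' @param I list of matrices, one per fragment, dim `length(t)` x
#'   `length(m)`.
#' @param is_ms1 logical per fragment.
#' @return An object of class `fragment_raster`.
#' @export
fragment_raster <- function(t, m, I, is_ms1 = rep(FALSE, length(I))) {
  stopifnot(all(t > 0), length(I) >= 1, length(is_ms1) == length(I))
  for (M in I) {
    stopifnot(is.matrix(M), nrow(M) == length(t), ncol(M) == length(m))
  }
  structure(list(t = as.numeric(t), m = as.numeric(m), I = I,
                 is_ms1 = as.logical(is_ms1)), class = "fragment_raster")
}

# deterministic moment-based initial values
init_peak_params <- function(raster) {
  nf <- length(raster$I)
  tot <- Reduce(`+`, raster$I)
  xic <- rowSums(tot)
  apex <- which.max(xic)
  t0 <- raster$t[apex]
  wsum <- sum(tot)
  if (wsum <= 0) stop("degenerate input: all-zero raster")
  lt <- log(raster$t)
  wt <- rowSums(tot)
  mu_t <- sum(wt * lt) / wsum
  sigma_t <- sqrt(max(sum(wt * (lt - mu_t)^2) / wsum, 1e-6))
  sigma_t <- min(max(sigma_t, 1e-3), 2)
  m0 <- numeric(nf); a <- numeric(nf); sm <- numeric(nf)
  for (j in seq_len(nf)) {
    wj <- colSums(raster$I[[j]])
    if (sum(wj) > 0) {
      m0[j] <- sum(wj * raster$m) / sum(wj)
      sm[j] <- sqrt(max(sum(wj * (raster$m - m0[j])^2) / sum(wj), 0.01))
    } else {
      m0[j] <- stats::median(raster$m); sm[j] <- 1
    }
    apex_j <- max(raster$I[[j]][apex, ], 0)
    a[j] <- apex_j * sigma_t * t0 * sqrt(2 * pi)
  }
  sigma_m <- min(max(stats::median(sm), 0.1), 50)
  peak_model_params(sigma_t = sigma_t, sigma_m = sigma_m, t0 = t0,
                    m0 = m0, a = pmax(a, 1e-6), c = rep(0, nf),
                    is_ms1 = raster$is_ms1)
}

#' Fit the analytic 2D peak model to a fragment raster
#'
#' Minimises the summed squared residual between the model surface and the
#' observed intensities over all fragments jointly, with the
#' retention-time apex `t0` and spreads shared across fragments and the
#' index centre `m0` free per fragment. Optimisation is bounded nonlinear
#' least squares (Levenberg–Marquardt via \pkg{minpack.lm}), with bounds
#' `sigma_t` in `[1e-3, 2]`, `sigma_m` in `[0.1, 50]`, `a >= 0`, `c >= 0`.
#' Initial values come from weighted moments of the raster unless `init`
#' is supplied; the fit is deterministic (no random restarts).
#'
#' @param raster a [fragment_raster].
#' @param init optional [peak_model_params] starting point.
#' @param max_iter iteration budget (default 200).
#' @return An object of class `peak_fit` with methods `print`, `summary`,
#'   `coef`, `fitted`, `residuals` and `predict`. Components include
#'   `params` (the fitted [peak_model_params]), `residual_ss` (the achieved
#'   sum of squares G), `requant_intensity` (the fitted amplitudes, one per
#'   fragment), and `convergence` info.
#' @export
fit_peak <- function(raster, init = NULL, max_iter = 200L) {
  stopifnot(inherits(raster, "fragment_raster"))
  if (all(vapply(raster$I, function(M) all(M == 0), TRUE))) {
    stop("degenerate input: all-zero raster")
  }
  nf <- length(raster$I)
  npar <- 3L + 2L * nf + sum(raster$is_ms1)
  if (length(raster$t) * length(raster$m) * nf < npar) {
    stop("raster has fewer data points than model parameters")
  }
  if (is.null(init)) init <- init_peak_params(raster)

  ms1_idx <- which(raster$is_ms1)
  pack <- function(p) {
    c(p$sigma_t, p$sigma_m, p$t0, p$m0, p$a, p$c[ms1_idx])
  }
  unpack <- function(x) {
    m0 <- x[3L + seq_len(nf)]
    a <- x[3L + nf + seq_len(nf)]
    cc <- rep(0, nf)
    if (length(ms1_idx)) cc[ms1_idx] <- x[3L + 2L * nf + seq_along(ms1_idx)]
    peak_model_params(sigma_t = x[1L], sigma_m = x[2L], t0 = x[3L],
                      m0 = m0, a = a, c = cc, is_ms1 = raster$is_ms1)
  }
  grid_t <- rep(raster$t, times = length(raster$m))
  grid_m <- rep(raster$m, each = length(raster$t))
  resid_fn <- function(x) {
    p <- tryCatch(unpack(x), error = function(e) NULL)
    if (is.null(p)) return(rep(1e6, length(grid_t) * nf))
    unlist(lapply(seq_len(nf), function(j) {
      eval_peak_model(p, grid_t, grid_m, j) - as.vector(raster$I[[j]])
    }))
  }
  lower <- c(1e-3, 0.1, min(raster$t), rep(min(raster$m) - 5, nf),
             rep(0, nf), rep(0, length(ms1_idx)))
  upper <- c(2, 50, max(raster$t), rep(max(raster$m) + 5, nf),
             rep(Inf, nf), rep(Inf, length(ms1_idx)))
  x0 <- pmin(pmax(pack(init), lower), upper)
  fit <- minpack.lm::nls.lm(par = x0, lower = lower, upper = upper,
                            fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = max_iter, ftol = 1e-12,
                              ptol = 1e-12))
  params <- unpack(fit$par)
  rss <- sum(fit$fvec^2)
  if (fit$info == 0 || fit$info == 5) {
    cond <- structure(class = c("toffer_fit_failure", "error", "condition"),
                      list(message = sprintf(
                        "peak fit did not converge within %d iterations (residual %.4g)",
                        max_iter, rss),
                        call = sys.call(),
                        params = params, residual_ss = rss))
    stop(cond)
  }
  structure(list(params = params, residual_ss = rss,
                 requant_intensity = params$a,
                 raster = raster, init = init,
                 convergence = list(info = fit$info,
                                    message = fit$message,
                                    niter = fit$niter)),
            class = "peak_fit")
}

#' @export
print.peak_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "2D peak fit: t0 = %.3f s, sigma_t = %.4f, sigma_m = %.3f, %d fragment(s)\n",
    p$t0, p$sigma_t, p$sigma_m, length(p$a)))
  cat("re-quantified intensities (a_j):",
      paste(signif(x$requant_intensity, 6), collapse = ", "), "\n")
  cat(sprintf("residual sum of squares: %.6g (%d iterations)\n",
              x$residual_ss, x$convergence$niter))
  invisible(x)
}

#' @export
coef.peak_fit <- function(object, ...) {
  p <- object$params
  c(sigma_t = p$sigma_t, sigma_m = p$sigma_m, t0 = p$t0,
    stats::setNames(p$m0, sprintf("m0_%d", seq_along(p$m0))),
    stats::setNames(p$a, sprintf("a_%d", seq_along(p$a))),
    stats::setNames(p$c, sprintf("c_%d", seq_along(p$c))))
}

#' @export
fitted.peak_fit <- function(object, ...) {
  r <- object$raster
  lapply(seq_along(r$I), function(j) {
    matrix(eval_peak_model(object$params,
                           rep(r$t, times = length(r$m)),
                           rep(r$m, each = length(r$t)), j),
           nrow = length(r$t))
  })
}

#' @export
residuals.peak_fit <- function(object, ...) {
  f <- fitted(object)
  lapply(seq_along(f), function(j) object$raster$I[[j]] - f[[j]])
}

#' @export
predict.peak_fit <- function(object, t, m, j = 1L, ...) {
  eval_peak_model(object$params, t, m, j)
}

#' @export
summary.peak_fit <- function(object, ...) {
  structure(list(fit = object, coef = coef(object),
                 n_obs = length(object$raster$t) *
                   length(object$raster$m) * length(object$raster$I)),
            class = "summary.peak_fit")
}

#' @export
print.summary.peak_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("observations: %d; parameters: %d\n", x$n_obs, length(x$coef)))
  invisible(x)
}

#' Assemble the fit-ready raster of one peptide from a run
#'
#' Extracts the 2D data the peak fit consumes: the MS1 region around the
#' precursor m/z plus the matching MS2 window's region around each
#' fragment m/z, on a common retention-time axis (the MS2 window's scan
#' grid restricted to `expected_rt +/- rt_half_width`) and a common
#' relative index axis `-coord_half_width .. +coord_half_width` centred on
#' each ion's own trace, so the per-fragment centres `m0` absorb the
#' relative calibration offsets.
#'
#' @param run a [toffee_run].
#' @param query a [peptide_query].
#' @param coord_half_width channel half-width in index steps (default 10).
#' @return A [fragment_raster] whose first fragment is the MS1 precursor
#'   trace (`is_ms1 = TRUE`) followed by the query's fragments.
#' @export
peptide_raster <- function(run, query, coord_half_width = 10L) {
  wname <- find_ms2_window(run, query$precursor_mz)
  w2 <- run$windows[[wname]]
  w1 <- run$windows[["ms1"]]
  rts <- window_rt(w2)
  sel <- which(abs(rts - query$expected_rt) <= query$rt_half_width & rts > 0)
  if (!length(sel)) stop("no scans inside the retention-time box")
  sr <- c(min(sel) - 1L, max(sel))
  t_axis <- rts[sel]
  m_axis <- seq.int(-coord_half_width, coord_half_width)

  one <- function(w, centre_mz) {
    med <- ims_params(w$medianAlpha, w$medianBeta, w$gamma)
    c0 <- index_from_mz(centre_mz, med)
    extract_region(w, sr, c(c0 - coord_half_width,
                            c0 + coord_half_width + 1L))$values
  }
  I <- c(list(one(w1, query$precursor_mz)),
         lapply(query$fragment_mzs, function(f) one(w2, f)))
  fragment_raster(t = t_axis, m = m_axis, I = I,
                  is_ms1 = c(TRUE, rep(FALSE, length(query$fragment_mzs))))
}

#' Flag peaks whose fitted shape departs from the cohort
#'
#' Peak spread (`sigma_t`, `sigma_m`) and location (retention-time and
#' index offsets from their expected values) are largely systematic
#' features of a run, so fits that disagree strongly with their cohort
#' mark likely false identifications. Each feature is scored with a robust
#' z (median / MAD); a peak is flagged when any feature exceeds the
#' threshold.
#'
#' @param cohort data.frame with columns `sigma_t`, `sigma_m` and
#'   optionally `dt0` (fitted minus expected retention time, s) and `dm0`
#'   (largest absolute fitted-minus-library index offset); or a list of
#'   [peak_model_params] (then only the spread features are used).
#' @param threshold robust-z cut (default 5).
#' @return logical vector, TRUE for flagged entries.
#' @export
flag_outliers <- function(cohort, threshold = 5) {
  if (!is.data.frame(cohort)) {
    cohort <- data.frame(
      sigma_t = vapply(cohort, `[[`, 0, "sigma_t"),
      sigma_m = vapply(cohort, `[[`, 0, "sigma_m"))
  }
  if (nrow(cohort) < 10L) stop("cohort too small: need at least 10 fits")
  feats <- intersect(c("sigma_t", "sigma_m", "dt0", "dm0"), names(cohort))
  flags <- rep(FALSE, nrow(cohort))
  for (f in feats) {
    v <- cohort[[f]]
    med <- stats::median(v)
    s <- stats::mad(v)
    z <- if (s > 0) abs(v - med) / s else ifelse(v == med, 0, Inf)
    flags <- flags | (z > threshold)
  }
  flags
}
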