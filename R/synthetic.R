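# run body with a locally-seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic DIA run
#'
#' Defines a deterministic, grid-consistent synthetic SWATH acquisition
#' with known ground truth: every sample lies exactly on its scan's
#' square-root m/z lattice, peptide peaks follow the analytic 2D shape
#' (log-normal in retention time, Gaussian in m/z index, 3-point isotope
#' envelopes), lattice coefficients drift slowly from scan to scan
#' (emulating in-line recalibration), and background noise sits at uniform
#' lattice positions with exponentially distributed counts.
#'
#' Defaults emulate a small TripleTOF-like SWATH acquisition: 8
#' contiguous 25 Da isolation windows from 400 Da, 3.5 s cycle time,
#' lattice slope near 4e-5 sqrt(Da) per index step, fractional per-scan
#' drift 1e-6, peptide apex intensities of hundreds to thousands of
#' counts.
#'
#' @param seed integer RNG seed; the run is a pure function of the spec.
#' @param n_cycles number of acquisition cycles (default 60).
#' @param cycle_time cycle time in s (default 3.5).
#' @param ms2_windows 2-column matrix of (lower, upper) isolation bounds in
#'   Da, non-overlapping and ascending.
#' @param base_alpha,base_beta lattice coefficients shared by all windows
#'   before drift; `base_beta` must lie in `[0, base_alpha)` (the stored
#'   canonical form).
#' @param drift fractional per-scan drift bound for alpha and beta
#'   (default 1e-6; 0 disables drift).
#' @param peptides data.frame with columns `id`, `precursor_mz`, `charge`,
#'   `fragment_mzs` (semicolon-separated string), `rt`, `apex_intensity`,
#'   `sigma_t`, `sigma_m`; `NULL` draws `n_peptides` peptides from the
#'   seed.
#' @param n_peptides number of peptides drawn when `peptides` is NULL.
#' @param envelope 3-point isotope envelope ratios.
#' @param noise_density expected background samples per scan per window
#'   (default 20; 0 disables noise).
#' @param noise_mean mean background count of the exponential intensity
#'   law (default 5).
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L, n_cycles = 60L, cycle_time = 3.5,
                           ms2_windows = cbind(seq(400, 575, by = 25),
                                               seq(425, 600, by = 25)),
                           base_alpha = 4.07e-5, base_beta = 1.6e-5,
                           drift = 1e-6, peptides = NULL, n_peptides = 5L,
                           envelope = c(1, 0.55, 0.22),
                           noise_density = 20, noise_mean = 5) {
  ms2_windows <- matrix(as.numeric(ms2_windows), ncol = 2L)
  if (nrow(ms2_windows) > 1L) {
    if (any(diff(ms2_windows[, 1]) <= 0) ||
        any(ms2_windows[-1L, 1] < ms2_windows[-nrow(ms2_windows), 2])) {
      stop("ms2_windows must be ordered and non-overlapping")
    }
  }
  stopifnot(all(ms2_windows[, 1] < ms2_windows[, 2]), drift >= 0,
            base_alpha > 0, base_beta >= 0, base_beta < base_alpha,
            n_cycles >= 2, cycle_time > 0, length(envelope) == 3L)
  spec <- structure(list(
    seed = as.integer(seed), n_cycles = as.integer(n_cycles),
    cycle_time = cycle_time, ms2_windows = ms2_windows,
    base_alpha = base_alpha, base_beta = base_beta, drift = drift,
    peptides = peptides, envelope = envelope,
    noise_density = noise_density, noise_mean = noise_mean),
    class = "synthetic_spec")
  if (is.null(spec$peptides)) {
    spec$peptides <- with_seed(seed, draw_peptides(spec, n_peptides))
  }
  spec
}

draw_peptides <- function(spec, n) {
  if (n == 0L) {
    return(data.frame(id = character(0), precursor_mz = numeric(0),
                      charge = integer(0), fragment_mzs = character(0),
                      rt = numeric(0), apex_intensity = numeric(0),
                      sigma_t = numeric(0), sigma_m = numeric(0)))
  }
  span <- range(spec$ms2_windows)
  rt_max <- (spec$n_cycles - 1L) * spec$cycle_time
  data.frame(
    id = sprintf("PEP%03d", seq_len(n)),
    precursor_mz = stats::runif(n, span[1] + 2, span[2] - 2),
    charge = 2L,
    fragment_mzs = vapply(seq_len(n), function(i) {
      paste(signif(sort(stats::runif(6, 200, 1200)), 10), collapse = ";")
    }, ""),
    rt = stats::runif(n, 0.2 * rt_max, 0.8 * rt_max),
    apex_intensity = round(exp(stats::runif(n, log(200), log(5000)))),
    sigma_t = stats::runif(n, 0.03, 0.07),
    sigma_m = stats::runif(n, 1.5, 3),
    stringsAsFactors = FALSE)
}

parse_fragment_mzs <- function(s) {
  as.numeric(strsplit(s, ";", fixed = TRUE)[[1L]])
}

#' Generate a synthetic run with ground truth
#'
#' Deterministic in the spec (same spec, bit-identical run). Peptide
#' signal is sampled from the analytic 2D peak shape on each scan's exact
#' lattice, integerised (half-away rounding) and zero-truncated; the
#' returned truth table records every peptide's true parameters and
#' injected intensity totals, and the per-window noise totals, so
#' `total_intensity(run)` equals the sum of the truth totals.
#'
#' @param spec a [synthetic_spec].
#' @return list with `run` (a [toffee_run]) and `truth` (list with
#'   data.frame `peptides` and data.frame `noise`).
#' @export
generate_run <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, generate_run_impl(spec))
}

generate_run_impl <- function(spec) {
  nw <- nrow(spec$ms2_windows)
  ns <- spec$n_cycles
  wnames <- c("ms1", if (nw) sprintf("ms2-%03d", seq_len(nw)))

  # resolve each peptide's MS2 window; error if the precursor falls in a gap
  peps <- spec$peptides
  pep_win <- character(nrow(peps))
  for (i in seq_len(nrow(peps))) {
    hits <- which(peps$precursor_mz[i] >= spec$ms2_windows[, 1] &
                  peps$precursor_mz[i] < spec$ms2_windows[, 2])
    if (!length(hits)) {
      stop(sprintf("peptide '%s' precursor m/z %.3f outside all MS2 windows",
                   peps$id[i], peps$precursor_mz[i]))
    }
    pep_win[i] <- sprintf("ms2-%03d", hits[1L])
  }

  # per-window smooth drift phases
  phases <- stats::runif(2L * (nw + 1L), 0, 2 * pi)

  # per-window m/z coverage for background noise
  win_mz_range <- rbind(
    c(max(50, min(spec$ms2_windows) - 30), max(spec$ms2_windows) + 30),
    cbind(rep(100, nw), rep(1300, nw)))

  windows <- vector("list", nw + 1L)
  pep_rows <- list()
  noise_rows <- list()
  for (wi in seq_len(nw + 1L)) {
    wname <- wnames[wi]
    rt0 <- (wi - 1L) * spec$cycle_time / (nw + 1L)
    s_idx <- seq_len(ns) - 1L
    phase_a <- phases[2L * wi - 1L]; phase_b <- phases[2L * wi]
    alpha_s <- spec$base_alpha *
      (1 + spec$drift * sin(2 * pi * s_idx / ns + phase_a))
    beta_s <- spec$base_beta +
      spec$base_alpha * spec$drift * sin(2 * pi * s_idx / ns + phase_b)
    rts <- rt0 + s_idx * spec$cycle_time

    tr_scan <- integer(0); tr_coord <- numeric(0); tr_int <- numeric(0)

    # peptide signal
    for (pp in seq_len(nrow(peps))) {
      ions <- NULL
      if (wname == "ms1") {
        ions <- data.frame(mz = peps$precursor_mz[pp],
                           charge = peps$charge[pp], rel = 1)
      } else if (pep_win[pp] == wname) {
        fr <- parse_fragment_mzs(peps$fragment_mzs[pp])
        rel <- seq(1, 0.4, length.out = length(fr))
        ions <- data.frame(mz = fr, charge = 1L, rel = rel)
      }
      if (is.null(ions)) next
      total_pep <- 0
      for (ii in seq_len(nrow(ions))) {
        for (k in 0:2) {
          mz_c <- isotope_offsets(ions$mz[ii], ions$charge[ii], k)
          amp <- peps$apex_intensity[pp] * ions$rel[ii] * spec$envelope[k + 1L]
          t0 <- peps$rt[pp]
          sig_t <- peps$sigma_t[pp]; sig_m <- peps$sigma_m[pp]
          a <- amp * t0 * sig_t * sqrt(2 * pi)
          # scans where the log-normal still contributes meaningfully
          in_t <- which(abs(log(pmax(rts, 1e-9)) - log(t0)) <= 5 * sig_t)
          mhw <- ceiling(4 * sig_m)
          for (s in in_t) {
            p_s <- ims_params(alpha_s[s], beta_s[s], 0L)
            ic <- index_from_mz(mz_c, p_s)
            mm <- (ic - mhw):(ic + mhw)
            pm <- peak_model_params(sigma_t = sig_t, sigma_m = sig_m,
                                    t0 = t0, m0 = ic, a = a)
            vals <- round_half_away(eval_peak_model(pm, rts[s], mm, 1L))
            keep <- vals >= 1
            if (any(keep)) {
              tr_scan <- c(tr_scan, rep(s - 1L, sum(keep)))
              tr_coord <- c(tr_coord, mm[keep])
              tr_int <- c(tr_int, vals[keep])
              total_pep <- total_pep + sum(vals[keep])
            }
          }
        }
      }
      pep_rows[[length(pep_rows) + 1L]] <- data.frame(
        id = peps$id[pp], window = wname, rt = peps$rt[pp],
        precursor_mz = peps$precursor_mz[pp], sigma_t = peps$sigma_t[pp],
        sigma_m = peps$sigma_m[pp],
        apex_intensity = peps$apex_intensity[pp],
        total_intensity = total_pep, stringsAsFactors = FALSE)
    }

    # background noise on uniform lattice positions, exponential counts
    n_noise <- if (spec$noise_density > 0) {
      stats::rpois(1L, spec$noise_density * ns)
    } else 0L
    if (n_noise > 0) {
      # profile-like clusters of 3 adjacent lattice samples: a detector
      # registering counts above threshold reports contiguous profile
      # points, never isolated single samples
      p_med <- ims_params(spec$base_alpha, spec$base_beta, 0L)
      crange <- index_from_mz(win_mz_range[wi, ], p_med)
      nscan <- rep(sample.int(ns, n_noise, replace = TRUE) - 1L, each = 3L)
      centre <- crange[1] + floor(stats::runif(n_noise) *
                                    (crange[2] - crange[1] + 1))
      ncoord <- rep(centre, each = 3L) + rep(c(-1L, 0L, 1L), n_noise)
      apex <- pmax(1, round_half_away(stats::rexp(n_noise,
                                                  1 / spec$noise_mean)))
      nint <- pmax(1, round_half_away(rep(apex, each = 3L) *
                                        rep(c(0.5, 1, 0.5), n_noise)))
      tr_scan <- c(tr_scan, nscan)
      tr_coord <- c(tr_coord, ncoord)
      tr_int <- c(tr_int, nint)
      noise_rows[[length(noise_rows) + 1L]] <- data.frame(
        window = wname, n_samples = length(nint), total_intensity = sum(nint),
        stringsAsFactors = FALSE)
    }

    windows[[wi]] <- toffee_window(
      name = wname,
      precursor_lower = if (wname == "ms1") -1 else spec$ms2_windows[wi - 1L, 1],
      precursor_center = if (wname == "ms1") -1 else
        mean(spec$ms2_windows[wi - 1L, ]),
      precursor_upper = if (wname == "ms1") -1 else spec$ms2_windows[wi - 1L, 2],
      first_scan_rt = rt0, scan_cycle_time = spec$cycle_time,
      alpha_per_scan = alpha_s, beta_per_scan = beta_s, gamma = 0L,
      csr = build_csr(tr_scan, tr_coord, tr_int, n_scans = ns))
  }

  truth_pep <- if (length(pep_rows)) do.call(rbind, pep_rows) else
    data.frame(id = character(0), window = character(0), rt = numeric(0),
               precursor_mz = numeric(0), sigma_t = numeric(0),
               sigma_m = numeric(0), apex_intensity = numeric(0),
               total_intensity = numeric(0))
  truth_noise <- if (length(noise_rows)) do.call(rbind, noise_rows) else
    data.frame(window = character(0), n_samples = integer(0),
               total_intensity = numeric(0))
  list(run = toffee_run(windows,
                        metadata_xml = "<mzML><synthetic/></mzML>"),
       truth = list(peptides = truth_pep, noise = truth_noise))
}

#' Generate a noisy raster from the analytic peak model
#'
#' Evaluates the 2D peak model on a grid and adds seeded Gaussian noise,
#' zero-truncated; the fixture generator for peak-fit recovery tests.
#'
#' @param params a [peak_model_params].
#' @param t retention-time grid (s).
#' @param m index grid.
#' @param noise_sigma Gaussian noise standard deviation (0 = exact model).
#' @param seed RNG seed.
#' @return A [fragment_raster] with one matrix per fragment in `params`.
#' @export
generate_peak_raster <- function(params, t, m, noise_sigma = 0, seed = 1L) {
  stopifnot(length(t) >= 1, length(m) >= 1)
  nf <- length(params$m0)
  with_seed(seed, {
    I <- lapply(seq_len(nf), function(j) {
      M <- matrix(eval_peak_model(params, rep(t, times = length(m)),
                                  rep(m, each = length(t)), j),
                  nrow = length(t))
      if (noise_sigma > 0) {
        M <- M + matrix(stats::rnorm(length(M), 0, noise_sigma),
                        nrow = nrow(M))
      }
      pmax(M, 0)
    })
    fragment_raster(t = t, m = m, I = I, is_ms1 = params$is_ms1)
  })
}
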