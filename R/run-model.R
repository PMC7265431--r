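#' One acquisition window of a run
#'
#' Couples a window header (isolation bounds, retention-time model, IMS
#' coefficients) with the CSR triplet store of its raw data. A run has one
#' MS1 window (`name = "ms1"`, precursor bounds set to -1) and one window
#' per SWATH precursor isolation interval (`"ms2-001"`, ... ordered by
#' ascending precursor centre).
#'
#' Retention times follow the linear model
#' `rt(scan) = firstScanRetentionTimeOffset + scan * scanCycleTime`; the
#' format stores no per-scan retention times. IMS coefficients alpha and
#' beta are stored per scan (the instrument recalibrates in-line);
#' `medianAlpha`/`medianBeta` summarise them at the window level and gamma
#' is a single window-level integer.
#'
#' @param name window name: `"ms1"` or `"ms2-NNN"`.
#' @param precursor_lower,precursor_center,precursor_upper isolation window
#'   bounds in Da; all -1 for MS1.
#' @param first_scan_rt retention time of scan 0 (s).
#' @param scan_cycle_time time between consecutive scans of this window (s).
#' @param alpha_per_scan,beta_per_scan numeric vectors, one entry per scan.
#' @param gamma window-level integer index offset.
#' @param csr a [build_csr] map with the same number of scans.
#' @return An object of class `toffee_window`.
#' @export
toffee_window <- function(name, precursor_lower = -1, precursor_center = -1,
                          precursor_upper = -1, first_scan_rt, scan_cycle_time,
                          alpha_per_scan, beta_per_scan, gamma = 0L, csr) {
  w <- structure(list(
    name = name,
    precursorLower = as.numeric(precursor_lower),
    precursorCenter = as.numeric(precursor_center),
    precursorUpper = as.numeric(precursor_upper),
    firstScanRetentionTimeOffset = as.numeric(first_scan_rt),
    scanCycleTime = as.numeric(scan_cycle_time),
    medianAlpha = stats::median(alpha_per_scan),
    medianBeta = stats::median(beta_per_scan),
    gamma = as.integer(gamma),
    alphaPerScan = as.numeric(alpha_per_scan),
    betaPerScan = as.numeric(beta_per_scan),
    csr = csr), class = "toffee_window")
  validate_window(w)
  w
}

#' @export
print.toffee_window <- function(x, ...) {
  cat(sprintf("<toffee_window '%s'> %d scans, %d non-zero samples",
              x$name, n_scans(x$csr), length(x$csr$imsCoord)))
  if (x$precursorLower >= 0) {
    cat(sprintf(", precursors [%.2f, %.2f]", x$precursorLower, x$precursorUpper))
  }
  cat("\n")
  invisible(x)
}

validate_window <- function(w) {
  ns <- n_scans(w$csr)
  if (length(w$alphaPerScan) != ns || length(w$betaPerScan) != ns) {
    stop(sprintf("window '%s': per-scan IMS vectors must match scan count",
                 w$name))
  }
  if (any(w$alphaPerScan <= 0)) {
    stop(sprintf("window '%s': alphaPerScan must be > 0", w$name))
  }
  if (w$scanCycleTime <= 0) {
    stop(sprintf("window '%s': scanCycleTime must be > 0", w$name))
  }
  if (w$name != "ms1") {
    if (!grepl("^ms2-[0-9]{3,}$", w$name)) {
      stop(sprintf("invalid window name '%s'", w$name))
    }
    if (!(w$precursorLower < w$precursorCenter &&
          w$precursorCenter < w$precursorUpper)) {
      stop(sprintf("window '%s': precursor bounds must be increasing", w$name))
    }
  }
  validate_csr(w$csr, what = sprintf("window '%s'", w$name))
  invisible(TRUE)
}

#' Retention times of every scan in a window
#' @param w a [toffee_window].
#' @return numeric vector of scan retention times (s).
#' @export
window_rt <- function(w) {
  w$firstScanRetentionTimeOffset +
    (seq_len(n_scans(w$csr)) - 1L) * w$scanCycleTime
}

#' Lattice coefficients of one scan
#' @param w a [toffee_window].
#' @param scan_index 0-based scan index.
#' @return an [ims_params] with that scan's alpha/beta and the window gamma.
#' @export
scan_ims <- function(w, scan_index) {
  ims_params(alpha = w$alphaPerScan[scan_index + 1L],
             beta = w$betaPerScan[scan_index + 1L],
             gamma = w$gamma)
}

#' In-memory model of one toffee run
#'
#' The ordered collection of acquisition windows plus file-level metadata;
#' the in-memory image of one toffee HDF5 file.
#'
#' @param windows named list of [toffee_window] objects containing exactly
#'   one `"ms1"` window and contiguously numbered `"ms2-001"`, ... windows.
#' @param ims_type mass-analyser family the lattice model applies to
#'   (currently `"TOF"`).
#' @param metadata_xml mzML-style XML header string carried for provenance.
#' @param created_by library version string recorded in the file.
#' @param format_major,format_minor file format version integers.
#' @return An object of class `toffee_run`.
#' @export
toffee_run <- function(windows, ims_type = "TOF", metadata_xml = "",
                       created_by = NULL, format_major = 1L,
                       format_minor = 0L) {
  if (is.null(created_by)) {
    created_by <- paste0("toffer-", as.character(utils::packageVersion("toffer")))
  }
  names(windows) <- vapply(windows, `[[`, "", "name")
  run <- structure(list(
    createdByVersion = created_by,
    formatMajor = as.integer(format_major),
    formatMinor = as.integer(format_minor),
    imsType = ims_type,
    metadataXML = metadata_xml,
    windows = windows), class = "toffee_run")
  validate_run(run)
  run
}

validate_run <- function(run) {
  nm <- names(run$windows)
  if (sum(nm == "ms1") != 1L) stop("run must contain exactly one 'ms1' window")
  ms2 <- sort(nm[nm != "ms1"])
  expected <- sprintf("ms2-%03d", seq_along(ms2))
  if (length(ms2) && !identical(ms2, expected)) {
    stop("MS2 windows must be named contiguously 'ms2-001', 'ms2-002', ...")
  }
  for (w in run$windows) validate_window(w)
  invisible(TRUE)
}

#' @export
print.toffee_run <- function(x, ...) {
  cat(sprintf("<toffee_run> %d windows (%d MS2), format %d.%d, IMS type %s\n",
              length(x$windows), length(x$windows) - 1L,
              x$formatMajor, x$formatMinor, x$imsType))
  for (w in x$windows) print(w)
  invisible(x)
}

#' Total stored intensity of a run
#' @param run a [toffee_run].
#' @return sum of all intensities over all windows.
#' @export
total_intensity <- function(run) {
  sum(vapply(run$windows, function(w) sum(w$csr$intensity), 0))
}

#' Locate the MS2 window whose isolation interval contains a precursor m/z
#' @param run a [toffee_run].
#' @param precursor_mz precursor m/z in Da.
#' @return the window name, e.g. `"ms2-003"`.
#' @export
find_ms2_window <- function(run, precursor_mz) {
  for (w in run$windows) {
    if (w$name == "ms1") next
    if (precursor_mz >= w$precursorLower && precursor_mz < w$precursorUpper) {
      return(w$name)
    }
  }
  stop(sprintf("precursor m/z %.4f falls outside every MS2 isolation window",
               precursor_mz))
}
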