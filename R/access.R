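#' Extract one spectrum from a window
#'
#' Spectrum-centric random access: reconstructs the m/z and intensity
#' arrays of a single scan from the CSR store using that scan's own
#' lattice coefficients, so the result equals the corresponding spectrum
#' of [export_run].
#'
#' @param window a [toffee_window].
#' @param scan_index 0-based scan index.
#' @return list of class `toffee_spectrum` with `retention_time`, `mz`,
#'   `intensity`.
#' @export
extract_spectrum <- function(window, scan_index) {
  ns <- n_scans(window$csr)
  if (scan_index < 0 || scan_index >= ns) stop("scan index out of range")
  sl <- slice_scan(window$csr, scan_index)
  mz <- if (length(sl$coord)) {
    mz_from_index(sl$coord, scan_ims(window, scan_index))
  } else numeric(0)
  structure(list(
    retention_time = window$firstScanRetentionTimeOffset +
      scan_index * window$scanCycleTime,
    mz = mz, intensity = sl$intensity), class = "toffee_spectrum")
}

# integer coord bounds [lo, hi) of the half-open m/z band [mz_low, mz_high)
# under given lattice params: smallest i with mz(i) >= bound, corrected
# against the exact reconstruction predicate so boundary lattice points
# resolve identically to a brute-force scan
band_coord_bounds <- function(mz_low, mz_high, params) {
  smallest_at_least <- function(bound) {
    i <- ceiling((sqrt(bound) - params$beta) / params$alpha - params$gamma)
    mzi <- function(j) {
      r <- params$alpha * (j + params$gamma) + params$beta
      r * r
    }
    while (mzi(i - 1) >= bound) i <- i - 1
    while (mzi(i) < bound) i <- i + 1
    i
  }
  c(smallest_at_least(mz_low), smallest_at_least(mz_high))
}

#' Extract an ion chromatogram (XIC) over an m/z band
#'
#' Peptide-centric random access: per scan, sums the intensity of all
#' stored samples whose reconstructed m/z lies in the half-open band
#' `[mz_low, mz_high)`. By default the integer coordinate bounds are
#' computed from each scan's own lattice coefficients, so the band is
#' exact even under per-scan calibration drift; `use_median_ims = TRUE`
#' uses the window-median coefficients instead (a faster approximation,
#' accurate to the few-ppm level of the drift).
#'
#' @param window a [toffee_window].
#' @param mz_low,mz_high band bounds in Da, `mz_low < mz_high`.
#' @param scan_range optional half-open 0-based integer interval
#'   `c(first, end)`; default all scans.
#' @param use_median_ims logical; see above.
#' @return list of class `toffee_chromatogram` with `retention_time` and
#'   `intensity` vectors, one entry per scan in range.
#' @export
extract_xic <- function(window, mz_low, mz_high, scan_range = NULL,
                        use_median_ims = FALSE) {
  if (!(mz_low < mz_high)) stop("inverted band: mz_low must be < mz_high")
  ns <- n_scans(window$csr)
  if (is.null(scan_range)) scan_range <- c(0L, ns)
  if (scan_range[1] < 0 || scan_range[2] > ns || scan_range[1] >= scan_range[2]) {
    stop("invalid scan range")
  }
  scans <- seq.int(scan_range[1], scan_range[2] - 1L)
  med <- ims_params(window$medianAlpha, window$medianBeta, window$gamma)
  inten <- vapply(scans, function(s) {
    p <- if (use_median_ims) med else scan_ims(window, s)
    b <- band_coord_bounds(mz_low, mz_high, p)
    sl <- slice_scan(window$csr, s)
    if (!length(sl$coord)) return(0)
    i0 <- findInterval(b[1] - 0.5, sl$coord) + 1L
    i1 <- findInterval(b[2] - 0.5, sl$coord)
    if (i1 < i0) 0 else sum(sl$intensity[i0:i1])
  }, 0)
  structure(list(
    retention_time = window$firstScanRetentionTimeOffset +
      scans * window$scanCycleTime,
    intensity = inten), class = "toffee_chromatogram")
}

#' Extract a dense 2D region (scans x m/z indices)
#'
#' Returns the raw data of an axis-aligned box as a dense matrix — the
#' two-dimensional slice used for peak fitting and image rendering. Entry
#' (s, c) holds the stored intensity at scan `scan_range[1] + s - 1`,
#' coordinate `coord_range[1] + c - 1`, or 0 where no sample is stored.
#'
#' @param window a [toffee_window].
#' @param scan_range half-open 0-based interval `c(first, end)` of scans.
#' @param coord_range half-open interval `c(first, end)` of m/z indices.
#' @return list of class `region_raster`: `scan_range`, `coord_range`,
#'   `values` (scans x coords matrix).
#' @export
extract_region <- function(window, scan_range, coord_range) {
  ns <- n_scans(window$csr)
  if (scan_range[1] < 0 || scan_range[2] > ns || scan_range[1] >= scan_range[2]) {
    stop("scan range out of bounds")
  }
  if (coord_range[1] < 0 || coord_range[1] >= coord_range[2]) {
    stop("coord range out of bounds")
  }
  scans <- seq.int(scan_range[1], scan_range[2] - 1L)
  nc <- coord_range[2] - coord_range[1]
  vals <- matrix(0, nrow = length(scans), ncol = nc)
  for (k in seq_along(scans)) {
    sl <- slice_scan(window$csr, scans[k])
    if (!length(sl$coord)) next
    sel <- sl$coord >= coord_range[1] & sl$coord < coord_range[2]
    if (any(sel)) {
      vals[k, sl$coord[sel] - coord_range[1] + 1L] <- sl$intensity[sel]
    }
  }
  structure(list(scan_range = scan_range, coord_range = coord_range,
                 values = vals), class = "region_raster")
}
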