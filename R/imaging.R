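#' Isotope m/z offsets
#'
#' m/z of the k-th isotopologue trace of an ion: the monoisotopic m/z
#' shifted by k times the 13C-12C mass difference divided by the charge.
#'
#' @param mz monoisotopic m/z (Da).
#' @param charge ion charge, >= 1.
#' @param k isotope number (0 = monoisotope, 1, 2).
#' @return m/z of the isotope trace (Da).
#' @export
isotope_offsets <- function(mz, charge, k) {
  stopifnot(charge >= 1, all(k >= 0))
  mz + k * C13_C12_MASS_DIFF / charge
}

#' 13C-12C mass difference (Da), the spacing of peptide isotope envelopes
#' @export
C13_C12_MASS_DIFF <- 1.0033548378

#' Render a peptide-centric multi-channel image stack
#'
#' Builds the 2D rasters a vision model consumes: one slice for the
#' precursor (from MS1) and one per fragment (from the peptide's MS2
#' window), each with three channels holding the data around the
#' monoisotopic, +1 and +2 isotope m/z (channel k is extracted around
#' [isotope_offsets] with offset k). All slices share the retention-time
#' axis; each channel covers `2*coord_half_width + 1` m/z index steps
#' centred on its isotope trace (centres located with the window-median
#' lattice coefficients). No normalisation or quantisation is applied —
#' the numeric rasters are exact views of the stored counts.
#'
#' @param run a [toffee_run].
#' @param query a [peptide_query]; fragment isotope spacing uses charge 1
#'   unless `fragment_charges` says otherwise.
#' @param rt_window optional `c(lo, hi)` retention-time interval (s);
#'   default the full run ("zoomed out").
#' @param coord_half_width half-width of each channel in index steps
#'   (default 10).
#' @param fragment_charges optional integer vector, one per fragment.
#' @return An object of class `peptide_image`: list with `slices` (each a
#'   scans x coords x 3 array), `slice_names`, `rt_axis`, `coord_ranges`.
#' @export
render_peptide_image <- function(run, query, rt_window = NULL,
                                 coord_half_width = 10L,
                                 fragment_charges = NULL) {
  wname <- find_ms2_window(run, query$precursor_mz)
  if (is.null(fragment_charges)) {
    fragment_charges <- rep(1L, length(query$fragment_mzs))
  }
  stopifnot(length(fragment_charges) == length(query$fragment_mzs))

  ions <- data.frame(
    window = c("ms1", rep(wname, length(query$fragment_mzs))),
    mz = c(query$precursor_mz, query$fragment_mzs),
    charge = c(query$charge, fragment_charges),
    name = c("precursor", sprintf("fragment-%d",
                                  seq_along(query$fragment_mzs))),
    stringsAsFactors = FALSE)

  # common rt axis from the MS1 window's scan grid
  w1 <- run$windows[["ms1"]]
  rts <- window_rt(w1)
  scans <- if (is.null(rt_window)) c(0L, n_scans(w1$csr)) else {
    sel <- which(rts >= rt_window[1] & rts <= rt_window[2])
    if (!length(sel)) stop("empty retention-time window")
    c(min(sel) - 1L, max(sel))
  }
  rt_axis <- rts[(scans[1] + 1L):scans[2]]

  slices <- vector("list", nrow(ions))
  coord_ranges <- vector("list", nrow(ions))
  for (i in seq_len(nrow(ions))) {
    w <- run$windows[[ions$window[i]]]
    med <- ims_params(w$medianAlpha, w$medianBeta, w$gamma)
    nsc <- scans[2] - scans[1]
    arr <- array(0, dim = c(nsc, 2L * coord_half_width + 1L, 3L))
    centres <- integer(3L)
    for (k in 0:2) {
      mz_k <- isotope_offsets(ions$mz[i], ions$charge[i], k)
      c0 <- index_from_mz(mz_k, med)
      centres[k + 1L] <- c0
      cr <- c(max(0L, c0 - coord_half_width), c0 + coord_half_width + 1L)
      reg <- extract_region(w, scan_range = scans, coord_range = cr)
      off <- (cr[1] - (c0 - coord_half_width)) # left clipping, if any
      arr[, seq_len(ncol(reg$values)) + off, k + 1L] <- reg$values
    }
    slices[[i]] <- arr
    coord_ranges[[i]] <- centres
  }
  structure(list(slices = slices, slice_names = ions$name,
                 rt_axis = rt_axis, coord_centres = coord_ranges,
                 coord_half_width = as.integer(coord_half_width),
                 query = query), class = "peptide_image")
}

#' @export
print.peptide_image <- function(x, ...) {
  cat(sprintf(
    "<peptide_image '%s'> %d slices (precursor + %d fragments), %d scans x %d coords x 3 channels\n",
    x$query$identifier, length(x$slices), length(x$slices) - 1L,
    length(x$rt_axis), 2L * x$coord_half_width + 1L))
  invisible(x)
}

#' Export a peptide image stack to a PNG file
#'
#' Qualitative-inspection utility: the slices are stacked vertically
#' (precursor on top), each channel log-scaled as `log1p` and normalised
#' to the stack maximum. The numeric rasters from [render_peptide_image]
#' stay exact; only this export quantises.
#'
#' @param image a [render_peptide_image] result.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required for PNG export")
  }
  # stack slices vertically, m/z index vertical within each slice,
  # retention time horizontal
  nrows <- sum(vapply(image$slices, function(a) dim(a)[2], 0))
  arr <- array(0, dim = c(nrows, dim(image$slices[[1]])[1], 3L))
  r0 <- 0L
  for (a in image$slices) {
    h <- dim(a)[2]
    for (k in 1:3) arr[r0 + seq_len(h), , k] <- t(a[, , k])
    r0 <- r0 + h
  }
  arr <- log1p(arr)
  mx <- max(arr)
  if (mx > 0) arr <- arr / mx
  png::writePNG(arr, target = path)
  invisible(path)
}
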