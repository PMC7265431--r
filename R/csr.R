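#' Build a compressed sparse row (CSR) map from integer triplets
#'
#' The raw data of one acquisition window is a set of integer triplets
#' (scan index, m/z index, intensity) on a Cartesian grid, stored in CSR
#' layout: `retentionTimeIdx` holds, for each scan, the exclusive end
#' offset of that scan's slice of `imsCoord`/`intensity` (there is no
#' leading zero entry; the slice of scan i is
#' `[retentionTimeIdx[i-1], retentionTimeIdx[i])` with
#' `retentionTimeIdx[0] == 0` implied).
#'
#' Triplets sharing a (scan, coord) cell are summed; zero-intensity
#' entries are dropped; within each scan the coordinates are stored
#' strictly increasing. Empty scans are permitted.
#'
#' @param scan integer vector of 0-based scan indices.
#' @param coord integer vector of non-negative m/z indices.
#' @param intensity integer vector of non-negative intensities.
#' @param n_scans number of scans in the window.
#' @return An object of class `csr_map`: list with `retentionTimeIdx`,
#'   `imsCoord`, `intensity`.
#' @examples
#' m <- build_csr(scan = c(0, 0, 1, 1, 1), coord = c(10, 12, 3, 7, 9),
#'                intensity = c(5, 7, 2, 4, 1), n_scans = 2)
#' m$retentionTimeIdx # 2 5
#' @export
build_csr <- function(scan, coord, intensity, n_scans) {
  stopifnot(length(scan) == length(coord), length(coord) == length(intensity),
            n_scans >= 1)
  scan <- as.numeric(scan); coord <- as.numeric(coord)
  intensity <- as.numeric(intensity)
  if (length(scan) && (min(scan) < 0 || max(scan) >= n_scans)) {
    stop("scan index out of range [0, n_scans)")
  }
  if (length(coord) && min(coord) < 0) stop("'coord' must be >= 0")
  if (length(intensity) && min(intensity) < 0) stop("'intensity' must be >= 0")

  keep <- intensity > 0
  scan <- scan[keep]; coord <- coord[keep]; intensity <- intensity[keep]
  if (length(scan)) {
    ord <- order(scan, coord)
    scan <- scan[ord]; coord <- coord[ord]; intensity <- intensity[ord]
    # merge duplicate (scan, coord) cells
    new_cell <- c(TRUE, diff(scan) != 0 | diff(coord) != 0)
    grp <- cumsum(new_cell)
    intensity <- as.numeric(rowsum(intensity, grp, reorder = FALSE))
    scan <- scan[new_cell]; coord <- coord[new_cell]
    keep <- intensity > 0
    scan <- scan[keep]; coord <- coord[keep]; intensity <- intensity[keep]
  }
  rt_idx <- cumsum(tabulate(scan + 1, nbins = n_scans))
  structure(list(retentionTimeIdx = rt_idx,
                 imsCoord = coord,
                 intensity = intensity),
            class = "csr_map")
}

#' Number of scans in a CSR map
#' @param map a `csr_map`.
#' @return integer scan count.
#' @export
n_scans <- function(map) {
  length(map$retentionTimeIdx)
}

#' Extract one scan's slice from a CSR map
#'
#' @param map a `csr_map`.
#' @param scan_index 0-based scan index.
#' @return list with `coord` and `intensity` vectors (empty for empty scans).
#' @export
slice_scan <- function(map, scan_index) {
  ns <- n_scans(map)
  if (length(scan_index) != 1L || scan_index < 0 || scan_index >= ns) {
    stop("scan index out of range")
  }
  i <- as.integer(scan_index) + 1L
  start <- if (i == 1L) 0L else map$retentionTimeIdx[i - 1L]
  end <- map$retentionTimeIdx[i]
  if (end <= start) {
    list(coord = numeric(0), intensity = numeric(0))
  } else {
    sel <- (start + 1L):end
    list(coord = map$imsCoord[sel], intensity = map$intensity[sel])
  }
}

#' Validate the structural invariants of a CSR map
#' @param map a `csr_map`.
#' @param what label used in error messages.
#' @return invisibly TRUE; stops on violation.
#' @export
validate_csr <- function(map, what = "csr_map") {
  if (length(map$imsCoord) != length(map$intensity)) {
    stop(sprintf("%s: imsCoord and intensity differ in length", what))
  }
  rt <- map$retentionTimeIdx
  if (length(rt) == 0L) stop(sprintf("%s: no scans", what))
  if (is.unsorted(rt)) {
    stop(sprintf("%s: retentionTimeIdx must be non-decreasing", what))
  }
  if (rt[length(rt)] != length(map$imsCoord)) {
    stop(sprintf("%s: final retentionTimeIdx must equal data length", what))
  }
  if (length(map$intensity) && min(map$intensity) <= 0) {
    stop(sprintf("%s: intensities must be > 0", what))
  }
  start <- c(0, rt[-length(rt)])
  for (i in seq_along(rt)) {
    if (rt[i] - start[i] > 1L) {
      sel <- (start[i] + 1L):rt[i]
      if (is.unsorted(map$imsCoord[sel], strictly = TRUE)) {
        stop(sprintf("%s: imsCoord not strictly increasing within scan %d",
                     what, i - 1L))
      }
    }
  }
  invisible(TRUE)
}
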