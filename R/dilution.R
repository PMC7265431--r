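#' Peptide query parameters
#'
#' The precursor/fragment coordinates that drive peptide-centric
#' extraction, dilution construction, re-quantification and image
#' rendering.
#'
#' @param identifier peptide label (text).
#' @param precursor_mz precursor m/z (Da).
#' @param charge precursor charge, >= 1.
#' @param fragment_mzs non-empty vector of fragment m/z values (Da).
#' @param expected_rt expected retention time (s).
#' @param rt_half_width half-width of the retention-time extraction box
#'   (s; default 30).
#' @param mz_half_width_ppm half-width of the m/z extraction box in ppm
#'   (default 50).
#' @return An object of class `peptide_query`.
#' @export
peptide_query <- function(identifier, precursor_mz, charge, fragment_mzs,
                          expected_rt, rt_half_width = 30,
                          mz_half_width_ppm = 50) {
  stopifnot(length(fragment_mzs) >= 1, rt_half_width > 0,
            mz_half_width_ppm > 0, charge >= 1)
  structure(list(identifier = as.character(identifier),
                 precursor_mz = as.numeric(precursor_mz),
                 charge = as.integer(charge),
                 fragment_mzs = as.numeric(fragment_mzs),
                 expected_rt = as.numeric(expected_rt),
                 rt_half_width = as.numeric(rt_half_width),
                 mz_half_width_ppm = as.numeric(mz_half_width_ppm)),
            class = "peptide_query")
}

# m/z band [lo, hi) of half-width ppm around a centre
ppm_band <- function(mz, ppm) {
  c(mz * (1 - ppm * 1e-6), mz * (1 + ppm * 1e-6))
}

#' Extract a peptide's foreground signal from a run
#'
#' Collects the raw samples of one peptide — MS1 around the precursor m/z
#' and the matching MS2 window around each fragment m/z, in each case
#' covering the mono-isotopic, +1 and +2 isotope traces — inside a box of
#' `rt_half_width` seconds around the peptide's apex and
#' `mz_half_width_ppm` around each ion. The apex is the scan maximising
#' the summed fragment XIC within the expected-RT box. Samples are stored
#' with their reconstructed m/z (not the raw integer coordinate) so they
#' can be re-gridded onto any background file's lattice.
#'
#' @param run a [toffee_run].
#' @param query a [peptide_query].
#' @return An object of class `foreground_region`: data.frame `samples`
#'   with columns `source` ("ms1" or fragment number), `scan_offset`
#'   (scans relative to apex), `mz`, `intensity`; plus `apex_rt`,
#'   `cycle_time` and the `query`.
#' @export
extract_foreground <- function(run, query) {
  wname <- find_ms2_window(run, query$precursor_mz)
  w2 <- run$windows[[wname]]
  w1 <- run$windows[["ms1"]]

  rts <- window_rt(w2)
  in_rt <- which(abs(rts - query$expected_rt) <= query$rt_half_width)
  if (!length(in_rt)) in_rt <- which.min(abs(rts - query$expected_rt))
  sumxic <- numeric(length(in_rt))
  for (f in query$fragment_mzs) {
    b <- ppm_band(f, query$mz_half_width_ppm)
    x <- extract_xic(w2, b[1], b[2],
                     scan_range = c(min(in_rt) - 1L, max(in_rt)))
    sumxic <- sumxic + x$intensity
  }
  apex_scan <- in_rt[which.max(sumxic)] - 1L  # 0-based
  apex_rt <- rts[apex_scan + 1L]

  collect <- function(w, centers, sources, charges) {
    wrts <- window_rt(w)
    apex_w <- which.min(abs(wrts - apex_rt)) - 1L
    half_scans <- floor(query$rt_half_width / w$scanCycleTime)
    scans <- max(0L, apex_w - half_scans):min(n_scans(w$csr) - 1L,
                                              apex_w + half_scans)
    # cover the mono-isotope and the +1/+2 traces of every ion
    centers <- as.vector(vapply(seq_along(centers), function(ci) {
      isotope_offsets(centers[ci], charges[ci], 0:2)
    }, numeric(3)))
    sources <- rep(sources, each = 3L)
    out <- list()
    for (ci in seq_along(centers)) {
      b <- ppm_band(centers[ci], query$mz_half_width_ppm)
      for (s in scans) {
        p <- scan_ims(w, s)
        bb <- band_coord_bounds(b[1], b[2], p)
        sl <- slice_scan(w$csr, s)
        sel <- sl$coord >= bb[1] & sl$coord < bb[2]
        if (any(sel)) {
          out[[length(out) + 1L]] <- data.frame(
            source = sources[ci], scan_offset = s - apex_w,
            mz = mz_from_index(sl$coord[sel], p),
            intensity = sl$intensity[sel])
        }
      }
    }
    out
  }
  samples <- do.call(rbind, c(
    collect(w1, query$precursor_mz, "ms1", query$charge),
    collect(w2, query$fragment_mzs,
            sprintf("frag-%d", seq_along(query$fragment_mzs)),
            rep(1L, length(query$fragment_mzs)))))
  if (is.null(samples) || nrow(samples) == 0L) {
    warning(sprintf("empty foreground region for peptide '%s'",
                    query$identifier))
    samples <- data.frame(source = character(0), scan_offset = integer(0),
                          mz = numeric(0), intensity = numeric(0))
  }
  structure(list(samples = samples, apex_rt = apex_rt,
                 cycle_time = w2$scanCycleTime, query = query),
            class = "foreground_region")
}

#' Inject scaled foreground signal into a background run
#'
#' Builds one member of an in-silico dilution series: every foreground
#' sample's intensity is multiplied by `dilution_factor` and rounded
#' half-away-from-zero (values rounding to zero are dropped, emulating the
#' instrument's lower limit of detection), its m/z is re-gridded onto the
#' receiving background scan's own lattice, and the sample lands on the
#' background scan nearest to `target_rt` plus its scan offset. Collisions
#' with existing background samples sum; untouched cells are unchanged, so
#' the output total intensity is the background total plus the
#' scaled-and-rounded foreground total.
#'
#' @param background a [toffee_run].
#' @param region a [extract_foreground] result.
#' @param dilution_factor scale >= 0 (0 returns the background unchanged).
#' @param target_rt retention time (s) at which the apex is placed.
#' @return A new [toffee_run]; the input is not modified.
#' @export
inject <- function(background, region, dilution_factor, target_rt) {
  stopifnot(dilution_factor >= 0)
  if (dilution_factor == 0 || nrow(region$samples) == 0L) return(background)
  wname <- find_ms2_window(background, region$query$precursor_mz)
  run <- background
  for (dest in c("ms1", wname)) {
    w <- run$windows[[dest]]
    sel <- if (dest == "ms1") region$samples$source == "ms1" else
      region$samples$source != "ms1"
    sm <- region$samples[sel, , drop = FALSE]
    if (!nrow(sm)) next
    wrts <- window_rt(w)
    target_scan <- which.min(abs(wrts - target_rt)) - 1L
    scan <- target_scan + sm$scan_offset
    keep <- scan >= 0L & scan < n_scans(w$csr)
    sm <- sm[keep, , drop = FALSE]; scan <- scan[keep]
    inten <- round_half_away(sm$intensity * dilution_factor)
    keep <- inten >= 1
    sm <- sm[keep, , drop = FALSE]; scan <- scan[keep]; inten <- inten[keep]
    if (!nrow(sm)) next
    coord <- vapply(seq_len(nrow(sm)), function(i) {
      index_from_mz(sm$mz[i], scan_ims(w, scan[i]))
    }, 0)
    old_scan <- rep(seq_len(n_scans(w$csr)) - 1L,
                    diff(c(0, w$csr$retentionTimeIdx)))
    csr <- build_csr(scan = c(old_scan, scan),
                     coord = c(w$csr$imsCoord, coord),
                     intensity = c(w$csr$intensity, inten),
                     n_scans = n_scans(w$csr))
    w$csr <- csr
    run$windows[[dest]] <- w
  }
  run
}

#' Ground-truth entry of an in-silico dilution series
#' @param peptide a [peptide_query] (or its identifier).
#' @param injected_rt retention time at which the signal was placed (s).
#' @param dilution_factor theoretical dilution, >= 0.
#' @return list of class `ground_truth_entry`.
#' @export
ground_truth_entry <- function(peptide, injected_rt, dilution_factor) {
  stopifnot(dilution_factor >= 0)
  id <- if (inherits(peptide, "peptide_query")) peptide$identifier else
    as.character(peptide)
  structure(list(peptide = id, injected_rt = as.numeric(injected_rt),
                 dilution_factor = as.numeric(dilution_factor)),
            class = "ground_truth_entry")
}

#' Score detections against dilution ground truth
#'
#' A detection whose retention time falls within `rt_threshold` seconds of
#' its peptide's injected retention time is a true positive; detections
#' further away are false positives; truth entries with no true-positive
#' detection are false negatives. When a peptide has several detections,
#' only the one nearest in retention time can claim the true positive; the
#' rest are labelled on their own distance.
#'
#' @param detections data.frame with columns `peptide`, `rt`.
#' @param truth list of [ground_truth_entry] (or data.frame with columns
#'   `peptide`, `injected_rt`).
#' @param rt_threshold seconds (default 10).
#' @return named integer vector `c(TP, FP, FN)`.
#' @export
label_detections <- function(detections, truth, rt_threshold = 10) {
  if (!is.data.frame(truth)) {
    truth <- data.frame(
      peptide = vapply(truth, `[[`, "", "peptide"),
      injected_rt = vapply(truth, `[[`, 0, "injected_rt"))
  }
  stopifnot(all(c("peptide", "rt") %in% names(detections)))
  if (nrow(detections) &&
      !all(detections$peptide %in% truth$peptide)) {
    stop("detections contain peptide ids absent from the ground truth")
  }
  # per truth entry: one TP if any detection lies within the threshold
  # (duplicates within the threshold are redundant and not penalised);
  # every detection outside the threshold is an FP; no within-threshold
  # detection at all makes the entry an FN
  tp <- 0L; fp <- 0L; fn <- 0L
  for (i in seq_len(nrow(truth))) {
    det <- detections[detections$peptide == truth$peptide[i], , drop = FALSE]
    hit <- abs(det$rt - truth$injected_rt[i]) <= rt_threshold
    fp <- fp + sum(!hit)
    if (any(hit)) tp <- tp + 1L else fn <- fn + 1L
  }
  c(TP = tp, FP = fp, FN = fn)
}
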