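#' A single profile spectrum
#'
#' Plain in-memory representation of one mzML spectrum: acquisition level,
#' retention time, precursor isolation bounds (MS2 only) and the profile
#' m/z / intensity arrays. Lists of these records are the interchange
#' currency between mzML files and the toffee run model.
#'
#' @param ms_level 1 or 2.
#' @param retention_time scan retention time (s).
#' @param mz strictly increasing m/z vector (Da).
#' @param intensity non-negative intensity vector, same length as `mz`.
#' @param precursor_lower,precursor_center,precursor_upper isolation window
#'   bounds in Da (MS2 only; `NA` for MS1).
#' @return An object of class `spectrum_record`.
#' @export
spectrum_record <- function(ms_level, retention_time, mz, intensity,
                            precursor_lower = NA_real_,
                            precursor_center = NA_real_,
                            precursor_upper = NA_real_) {
  stopifnot(ms_level %in% c(1L, 2L), length(mz) == length(intensity))
  if (length(mz) > 1L && is.unsorted(mz, strictly = TRUE)) {
    stop("'mz' must be strictly increasing")
  }
  if (length(intensity) && min(intensity) < 0) {
    stop("'intensity' must be non-negative")
  }
  if (ms_level == 2L && !(isTRUE(precursor_lower < precursor_upper))) {
    stop("MS2 spectra need precursor_lower < precursor_upper")
  }
  structure(list(ms_level = as.integer(ms_level),
                 retention_time = as.numeric(retention_time),
                 precursor_lower = as.numeric(precursor_lower),
                 precursor_center = as.numeric(precursor_center),
                 precursor_upper = as.numeric(precursor_upper),
                 mz = as.numeric(mz), intensity = as.numeric(intensity)),
            class = "spectrum_record")
}

#' Convert an ordered list of profile spectra into a toffee run model
#'
#' Groups MS2 spectra into isolation windows by their exact
#' (lower, upper) precursor bounds, estimates the square-root-lattice IMS
#' coefficients independently for every scan (see [estimate_scan_ims]),
#' converts each spectrum to integer (scan, m/z index, intensity) triplets
#' and fits the linear retention-time model
#' `first offset + scan * cycle time` per window, with the cycle time taken
#' as the median inter-scan interval.
#'
#' Scans whose m/z values cannot be placed on a lattice within
#' `tolerance_ppm` raise a lossy-input error (centroided data typically
#' fails here; use profile data). Scans with fewer than 3 points reuse the
#' nearest preceding estimable scan's coefficients. Non-integral
#' intensities are rounded half-away-from-zero, with a warning when any
#' value deviates from an integer by more than 1e-6; retention times
#' deviating from the linear model by more than 10% of the cycle time also
#' warn (the uniform model is still written — the format stores no per-scan
#' retention times).
#'
#' @param spectra list of [spectrum_record] in acquisition order.
#' @param tolerance_ppm lattice-placement residual tolerance (default 5).
#' @param metadata_xml optional mzML-style header string to carry along.
#' @return A [toffee_run].
#' @export
import_run <- function(spectra, tolerance_ppm = 5, metadata_xml = "") {
  stopifnot(length(spectra) > 0)
  lev <- vapply(spectra, `[[`, 0L, "ms_level")
  lo <- vapply(spectra, `[[`, 0, "precursor_lower")
  up <- vapply(spectra, `[[`, 0, "precursor_upper")
  key <- ifelse(lev == 1L, "ms1", paste0("w:", lo, ":", up))

  groups <- split(seq_along(spectra), key)
  if (!("ms1" %in% names(groups))) stop("structure error: no MS1 spectra")
  n_per <- lengths(groups)
  if (length(unique(n_per)) != 1L) {
    stop(sprintf(
      "structure error: inconsistent window sets across cycles (scan counts %s)",
      paste(sort(unique(n_per)), collapse = "/")))
  }

  ms2_keys <- setdiff(names(groups), "ms1")
  centers <- vapply(ms2_keys, function(k) {
    i <- groups[[k]][1L]
    cc <- spectra[[i]]$precursor_center
    if (is.na(cc)) (spectra[[i]]$precursor_lower + spectra[[i]]$precursor_upper) / 2 else cc
  }, 0)
  ms2_keys <- ms2_keys[order(centers)]
  wnames <- c("ms1", if (length(ms2_keys)) sprintf("ms2-%03d", seq_along(ms2_keys)))
  keys <- c("ms1", ms2_keys)

  windows <- vector("list", length(keys))
  for (k in seq_along(keys)) {
    idx <- groups[[keys[k]]]
    ss <- spectra[idx]
    ns <- length(ss)
    rts <- vapply(ss, `[[`, 0, "retention_time")
    cycle <- if (ns > 1L) stats::median(diff(rts)) else 1
    if (cycle <= 0) stop("structure error: non-increasing retention times")
    model_rt <- rts[1L] + (seq_len(ns) - 1L) * cycle
    if (max(abs(rts - model_rt)) > 0.1 * cycle) {
      warning(sprintf(
        "window '%s': retention times deviate from the uniform model by more than 10%% of the cycle time; the uniform model is written",
        wnames[k]))
    }

    alphas <- numeric(ns); betas <- numeric(ns)
    tr_scan <- vector("list", ns)
    last_params <- NULL
    pending <- integer(0)
    for (s in seq_len(ns)) {
      sp <- ss[[s]]
      keep <- sp$intensity > 0
      mzv <- sp$mz[keep]
      inten <- sp$intensity[keep]
      ri <- round_half_away(inten)
      if (length(ri) && max(abs(inten - ri)) > 1e-6) {
        warning(sprintf(
          "window '%s' scan %d: non-integral intensities rounded to integers",
          wnames[k], s - 1L))
      }
      if (length(unique(mzv)) >= 3L) {
        est <- tryCatch(
          estimate_scan_ims(mzv, tolerance_ppm = tolerance_ppm),
          error = function(e) {
            if (grepl("estimation failure", conditionMessage(e))) {
              stop(sprintf(
                "lossy input: window '%s' scan %d not lattice-consistent (%s); profile-mode data is required",
                wnames[k], s - 1L, conditionMessage(e)), call. = FALSE)
            }
            stop(e)
          })
        last_params <- est$params
        alphas[s] <- est$params$alpha
        betas[s] <- est$params$beta
        tr_scan[[s]] <- list(coord = est$indices, intensity = ri)
      } else {
        # under-determined scan: inherit coefficients, resolve later if none yet
        if (is.null(last_params)) {
          pending <- c(pending, s)
          tr_scan[[s]] <- list(mz = mzv, intensity = ri)
        } else {
          alphas[s] <- last_params$alpha
          betas[s] <- last_params$beta
          tr_scan[[s]] <- list(coord = index_from_mz_checked(
            mzv, last_params, tolerance_ppm, wnames[k], s - 1L),
            intensity = ri)
        }
      }
    }
    if (length(pending)) {
      if (is.null(last_params)) {
        # no scan in the window was estimable; fall back to unit lattice
        last_params <- ims_params(alpha = 1, beta = 0, gamma = 0L)
      }
      first_est <- if (any(alphas > 0)) {
        s0 <- which(alphas > 0)[1L]
        ims_params(alphas[s0], betas[s0], 0L)
      } else last_params
      for (s in pending) {
        alphas[s] <- first_est$alpha
        betas[s] <- first_est$beta
        tr_scan[[s]]$coord <- index_from_mz_checked(
          tr_scan[[s]]$mz, first_est, tolerance_ppm, wnames[k], s - 1L)
        tr_scan[[s]]$mz <- NULL
      }
    }

    scan_vec <- rep(seq_len(ns) - 1L,
                    vapply(tr_scan, function(z) length(z$coord), 0L))
    csr <- build_csr(scan = scan_vec,
                     coord = unlist(lapply(tr_scan, `[[`, "coord")),
                     intensity = unlist(lapply(tr_scan, `[[`, "intensity")),
                     n_scans = ns)
    sp1 <- ss[[1L]]
    windows[[k]] <- toffee_window(
      name = wnames[k],
      precursor_lower = if (wnames[k] == "ms1") -1 else sp1$precursor_lower,
      precursor_center = if (wnames[k] == "ms1") -1 else {
        if (is.na(sp1$precursor_center))
          (sp1$precursor_lower + sp1$precursor_upper) / 2
        else sp1$precursor_center
      },
      precursor_upper = if (wnames[k] == "ms1") -1 else sp1$precursor_upper,
      first_scan_rt = rts[1L], scan_cycle_time = cycle,
      alpha_per_scan = alphas, beta_per_scan = betas, gamma = 0L, csr = csr)
  }
  toffee_run(windows, metadata_xml = metadata_xml)
}

index_from_mz_checked <- function(mz, params, tolerance_ppm, wname, scan) {
  if (!length(mz)) return(integer(0))
  idx <- index_from_mz(mz, params)
  ppm <- abs(mz_from_index(idx, params) / mz - 1) * 1e6
  if (max(ppm) > tolerance_ppm) {
    stop(sprintf(
      "lossy input: window '%s' scan %d not lattice-consistent (worst residual %.3g ppm)",
      wname, scan, max(ppm)), call. = FALSE)
  }
  idx
}

#' Reconstruct the ordered spectrum list of a run
#'
#' The inverse of [import_run]: m/z values are regenerated from each scan's
#' own lattice coefficients and the window gamma, retention times from the
#' linear model, and intensities verbatim. Spectra are interleaved in cycle
#' order — the MS1 scan of each cycle followed by the MS2 windows in name
#' order.
#'
#' @param run a [toffee_run].
#' @return list of [spectrum_record].
#' @export
export_run <- function(run) {
  wnames <- c("ms1", sort(setdiff(names(run$windows), "ms1")))
  per_window <- lapply(wnames, function(nm) {
    w <- run$windows[[nm]]
    rts <- window_rt(w)
    lapply(seq_along(rts), function(s) {
      sl <- slice_scan(w$csr, s - 1L)
      mz <- if (length(sl$coord)) {
        mz_from_index(sl$coord, scan_ims(w, s - 1L))
      } else numeric(0)
      spectrum_record(
        ms_level = if (nm == "ms1") 1L else 2L,
        retention_time = rts[s], mz = mz, intensity = sl$intensity,
        precursor_lower = if (nm == "ms1") NA_real_ else w$precursorLower,
        precursor_center = if (nm == "ms1") NA_real_ else w$precursorCenter,
        precursor_upper = if (nm == "ms1") NA_real_ else w$precursorUpper)
    })
  })
  ns <- max(vapply(per_window, length, 0L))
  out <- list()
  for (s in seq_len(ns)) {
    for (wi in seq_along(per_window)) {
      if (s <= length(per_window[[wi]])) {
        out[[length(out) + 1L]] <- per_window[[wi]][[s]]
      }
    }
  }
  out
}

#' Read profile spectra from an mzML file
#'
#' Thin wrapper over the `mzR` parser returning [spectrum_record] lists;
#' isolation bounds are taken from the standard isolation-window CV
#' parameters (target plus lower/upper offsets).
#'
#' @param path mzML file (indexed or plain).
#' @return list of [spectrum_record] in acquisition order.
#' @export
read_mzml <- function(path) {
  h <- NULL
  z <- mzR::openMSfile(path)
  on.exit(mzR::close(z), add = TRUE)
  h <- mzR::header(z)
  pk <- mzR::peaks(z)
  if (is.matrix(pk)) pk <- list(pk)
  lapply(seq_len(nrow(h)), function(i) {
    lev <- h$msLevel[i]
    target <- if (lev >= 2L) h$isolationWindowTargetMZ[i] else NA_real_
    lo_off <- if (lev >= 2L) h$isolationWindowLowerOffset[i] else NA_real_
    up_off <- if (lev >= 2L) h$isolationWindowUpperOffset[i] else NA_real_
    if (lev >= 2L && (is.na(target) || is.na(lo_off) || is.na(up_off))) {
      stop(sprintf("spectrum %d: MS2 spectrum lacks isolation window bounds", i))
    }
    spectrum_record(ms_level = lev, retention_time = h$retentionTime[i],
                    mz = pk[[i]][, 1L], intensity = pk[[i]][, 2L],
                    precursor_lower = target - lo_off,
                    precursor_center = target,
                    precursor_upper = target + up_off)
  })
}

#' Write spectra to an mzML file
#'
#' Thin wrapper over `mzR::writeMSData`; m/z and intensity arrays are
#' written at 64-bit precision so the lossless round trip holds at the
#' file level.
#'
#' @param spectra list of [spectrum_record].
#' @param path output mzML path.
#' @return `path`, invisibly.
#' @export
write_mzml <- function(spectra, path) {
  n <- length(spectra)
  stopifnot(n > 0)
  pk <- lapply(spectra, function(s) cbind(mz = s$mz, intensity = s$intensity))
  lev <- vapply(spectra, `[[`, 0L, "ms_level")
  rt <- vapply(spectra, `[[`, 0, "retention_time")
  lo <- vapply(spectra, `[[`, 0, "precursor_lower")
  ce <- vapply(spectra, `[[`, 0, "precursor_center")
  up <- vapply(spectra, `[[`, 0, "precursor_upper")
  npk <- vapply(pk, nrow, 0L)
  tic <- vapply(pk, function(p) sum(p[, 2L]), 0)
  bpi <- vapply(pk, function(p) if (nrow(p)) max(p[, 2L]) else 0, 0)
  bpm <- vapply(pk, function(p) if (nrow(p)) p[which.max(p[, 2L]), 1L] else 0, 0)
  last_ms1 <- 0L
  prec_scan <- integer(n)
  for (i in seq_len(n)) {
    if (lev[i] == 1L) last_ms1 <- i
    prec_scan[i] <- if (lev[i] == 1L) 0L else last_ms1
  }
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = lev,
    polarity = rep(1L, n), peaksCount = npk, totIonCurrent = tic,
    retentionTime = rt, basePeakMZ = bpm, basePeakIntensity = bpi,
    collisionEnergy = rep(0, n), ionisationEnergy = rep(0, n),
    lowMZ = vapply(pk, function(p) if (nrow(p)) min(p[, 1L]) else 0, 0),
    highMZ = vapply(pk, function(p) if (nrow(p)) max(p[, 1L]) else 0, 0),
    precursorScanNum = prec_scan,
    precursorMZ = ifelse(lev == 1L, 0, ce),
    precursorCharge = rep(0L, n), precursorIntensity = rep(0, n),
    mergedScan = rep(0L, n), mergedResultScanNum = rep(0L, n),
    mergedResultStartScanNum = rep(0L, n), mergedResultEndScanNum = rep(0L, n),
    injectionTime = rep(0, n), filterString = rep(NA_character_, n),
    spectrumId = sprintf("scan=%d", seq_len(n)),
    centroided = rep(FALSE, n), ionMobilityDriftTime = rep(NA_real_, n),
    isolationWindowTargetMZ = ifelse(lev == 1L, NA_real_, ce),
    isolationWindowLowerOffset = ifelse(lev == 1L, NA_real_, ce - lo),
    isolationWindowUpperOffset = ifelse(lev == 1L, NA_real_, up - ce),
    scanWindowLowerLimit = rep(NA_real_, n),
    scanWindowUpperLimit = rep(NA_real_, n),
    stringsAsFactors = FALSE)
  if (file.exists(path)) unlink(path)
  mzR::writeMSData(pk, path, header = hdr, outformat = "mzml")
  invisible(path)
}

#' Convert an mzML file to a toffee file
#' @param mzml_path input profile mzML.
#' @param toffee_path output toffee file.
#' @param tolerance_ppm lattice residual tolerance (default 5 ppm).
#' @param compression_level zlib level (default 6).
#' @return `toffee_path`, invisibly.
#' @export
mzml_to_toffee <- function(mzml_path, toffee_path, tolerance_ppm = 5,
                           compression_level = 6L) {
  run <- import_run(read_mzml(mzml_path), tolerance_ppm = tolerance_ppm)
  write_toffee(run, toffee_path, compression_level = compression_level)
}

#' Convert a toffee file back to mzML
#' @param toffee_path input toffee file.
#' @param mzml_path output mzML.
#' @return `mzml_path`, invisibly.
#' @export
toffee_to_mzml <- function(toffee_path, mzml_path) {
  write_mzml(export_run(read_toffee(toffee_path)), mzml_path)
}
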