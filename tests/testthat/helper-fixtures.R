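# shared fixtures and brute-force oracles, all generated in code

tiny_spec <- function(seed = 1, n_cycles = 12, n_peptides = 2,
                      windows = cbind(c(400, 425), c(425, 450)),
                      drift = 1e-6, noise_density = 4) {
  synthetic_spec(seed = seed, n_cycles = n_cycles, n_peptides = n_peptides,
                 ms2_windows = windows, drift = drift,
                 noise_density = noise_density)
}

# brute-force XIC: reconstruct every sample's m/z and filter
brute_xic <- function(w, lo, hi, scans = seq_len(n_scans(w$csr)) - 1L) {
  vapply(scans, function(s) {
    sl <- slice_scan(w$csr, s)
    if (!length(sl$coord)) return(0)
    mz <- mz_from_index(sl$coord, scan_ims(w, s))
    sum(sl$intensity[mz >= lo & mz < hi])
  }, 0)
}

# brute-force region sum over an axis-aligned box
brute_region_sum <- function(w, scan_range, coord_range) {
  total <- 0
  for (s in seq.int(scan_range[1], scan_range[2] - 1L)) {
    sl <- slice_scan(w$csr, s)
    sel <- sl$coord >= coord_range[1] & sl$coord < coord_range[2]
    total <- total + sum(sl$intensity[sel])
  }
  total
}

# brute-force confusion counts by all-pairs comparison
brute_confusion <- function(detections, truth_df, thr) {
  tp <- 0L; fp <- 0L; fn <- 0L
  for (i in seq_len(nrow(truth_df))) {
    d <- detections[detections$peptide == truth_df$peptide[i], , drop = FALSE]
    near <- abs(d$rt - truth_df$injected_rt[i]) <= thr
    fp <- fp + sum(!near)
    if (any(near)) tp <- tp + 1L else fn <- fn + 1L
  }
  c(TP = tp, FP = fp, FN = fn)
}

# first peptide of a spec as a query object
spec_query <- function(spec, i = 1, rt_half_width = 80) {
  p <- spec$peptides[i, ]
  peptide_query(p$id, p$precursor_mz, p$charge,
                as.numeric(strsplit(p$fragment_mzs, ";")[[1]]), p$rt,
                rt_half_width = rt_half_width)
}

# beta is the lattice intercept extrapolated to index 0 from coordinates
# near 1e6, so ulp-level fit noise on a data-poor scan amplifies by the
# index magnitude; 1e-8 sqrt(Da) on beta keeps reconstructed m/z within
# ~1e-9 relative while alpha and all integer fields compare exactly/tightly
expect_runs_equal <- function(a, b, alpha_tol = 1e-9, beta_tol = 1e-8,
                              rt_tol = 1e-8) {
  expect_identical(names(a$windows), names(b$windows))
  for (nm in names(a$windows)) {
    wa <- a$windows[[nm]]; wb <- b$windows[[nm]]
    expect_identical(as.numeric(wa$csr$retentionTimeIdx),
                     as.numeric(wb$csr$retentionTimeIdx))
    expect_identical(as.numeric(wa$csr$imsCoord), as.numeric(wb$csr$imsCoord))
    expect_identical(as.numeric(wa$csr$intensity),
                     as.numeric(wb$csr$intensity))
    expect_identical(wa$gamma, wb$gamma)
    # coefficients are only re-estimable for scans with >= 3 samples;
    # sparser scans inherit a neighbour's values on import by design
    est <- diff(c(0, wa$csr$retentionTimeIdx)) >= 3
    if (any(est)) {
      expect_lt(max(abs(wa$alphaPerScan[est] / wb$alphaPerScan[est] - 1)),
                alpha_tol)
      expect_lt(max(abs(wa$betaPerScan[est] - wb$betaPerScan[est])), beta_tol)
    }
    expect_lt(abs(wa$firstScanRetentionTimeOffset -
                    wb$firstScanRetentionTimeOffset), rt_tol)
    expect_lt(abs(wa$scanCycleTime - wb$scanCycleTime), rt_tol)
    expect_identical(c(wa$precursorLower, wa$precursorCenter, wa$precursorUpper),
                     c(wb$precursorLower, wb$precursorCenter, wb$precursorUpper))
  }
}

# profile-like scan indices: clusters of contiguous lattice samples, the
# density real TOF profile data has (isolated singletons under-determine
# the lattice register across wide gaps)
profile_indices <- function(n_clusters = 100, width = 9, span = 5000,
                            start = 500000) {
  starts <- start + sort(sample.int(span, n_clusters))
  sort(unique(as.vector(outer(0:(width - 1), starts, "+"))))
}
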