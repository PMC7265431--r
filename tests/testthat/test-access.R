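run_access <- generate_run(tiny_spec(seed = 71, n_cycles = 15))$run

test_that("extract_spectrum matches the exported spectra scan by scan", {
  for (nm in names(run_access$windows)) {
    w <- run_access$windows[[nm]]
    exported <- Filter(function(s) {
      (s$ms_level == 1L && nm == "ms1") ||
        (s$ms_level == 2L && !is.na(s$precursor_lower) &&
           isTRUE(all.equal(s$precursor_lower, w$precursorLower)))
    }, export_run(run_access))
    for (s in c(0L, 7L, 14L)) {
      got <- extract_spectrum(w, s)
      expect_identical(got$mz, exported[[s + 1L]]$mz)
      expect_identical(got$intensity, exported[[s + 1L]]$intensity)
      expect_equal(got$retention_time, exported[[s + 1L]]$retention_time)
    }
  }
  expect_error(extract_spectrum(run_access$windows$ms1, 15), "out of range")
})

test_that("empty scans give empty spectra with the right retention time", {
  w <- toffee_window(name = "ms1", first_scan_rt = 1, scan_cycle_time = 2,
                     alpha_per_scan = c(4e-5, 4e-5), beta_per_scan = c(0, 0),
                     csr = build_csr(0, 500000, 3, 2))
  s <- extract_spectrum(w, 1)
  expect_length(s$mz, 0)
  expect_identical(s$retention_time, 3)
  one <- extract_spectrum(w, 0)
  expect_equal(one$mz, mz_from_index(500000, scan_ims(w, 0)))
})

test_that("XICs equal the brute-force triplet-scan oracle on random bands", {
  set.seed(72)
  for (nm in names(run_access$windows)) {
    w <- run_access$windows[[nm]]
    for (rep in 1:25) {
      lo <- runif(1, 90, 1300)
      hi <- lo + runif(1, 0.005, 100)
      x <- extract_xic(w, lo, hi)
      expect_identical(as.numeric(x$intensity), brute_xic(w, lo, hi))
    }
  }
  expect_error(extract_xic(run_access$windows$ms1, 500, 400), "inverted")
})

test_that("full-band XIC equals the per-scan total ion current, empty band zero", {
  w <- run_access$windows$ms1
  tic <- vapply(seq_len(n_scans(w$csr)) - 1L,
                function(s) sum(slice_scan(w$csr, s)$intensity), 0)
  expect_identical(as.numeric(extract_xic(w, 1, 1e7)$intensity), tic)
  expect_true(all(extract_xic(w, 1, 1.001)$intensity == 0))
})

test_that("a partition of the m/z axis conserves per-scan intensity", {
  w <- run_access$windows[["ms2-001"]]
  cuts <- c(1, 150, 400, 800, 1e7)
  parts <- lapply(seq_len(length(cuts) - 1), function(i) {
    extract_xic(w, cuts[i], cuts[i + 1])$intensity
  })
  tic <- vapply(seq_len(n_scans(w$csr)) - 1L,
                function(s) sum(slice_scan(w$csr, s)$intensity), 0)
  expect_identical(as.numeric(Reduce(`+`, parts)), tic)
})

test_that("regions are dense exact views consistent with scans and XICs", {
  set.seed(73)
  w <- run_access$windows$ms1
  coords <- w$csr$imsCoord
  for (rep in 1:10) {
    sr <- sort(sample(0:15, 2)); if (sr[1] == sr[2]) sr[2] <- sr[1] + 1
    c0 <- sample(coords, 1) - sample.int(50, 1)
    cr <- c(c0, c0 + sample.int(200, 1))
    r <- extract_region(w, sr, cr)
    expect_equal(dim(r$values), c(sr[2] - sr[1], cr[2] - cr[1]))
    expect_identical(sum(r$values), brute_region_sum(w, sr, cr))
    # row s equals the sliced scan restricted to the coord range
    s <- sr[1]
    sl <- slice_scan(w$csr, s)
    sel <- sl$coord >= cr[1] & sl$coord < cr[2]
    row <- numeric(cr[2] - cr[1])
    row[sl$coord[sel] - cr[1] + 1] <- sl$intensity[sel]
    expect_identical(r$values[1, ], row)
  }
  expect_error(extract_region(w, c(0, 99), c(0, 10)), "out of bounds")
})

test_that("region of an empty window is a zero matrix", {
  w0 <- toffee_window(name = "ms1", first_scan_rt = 0, scan_cycle_time = 1,
                      alpha_per_scan = rep(4e-5, 3), beta_per_scan = rep(0, 3),
                      csr = build_csr(integer(0), integer(0), integer(0), 3))
  r <- extract_region(w0, c(0, 3), c(100, 110))
  expect_true(all(r$values == 0))
})

test_that("summing a region across coords reproduces the index-band XIC", {
  w <- run_access$windows[["ms2-002"]]
  # pick an index band and its exact m/z equivalent under the median lattice
  med <- ims_params(w$medianAlpha, w$medianBeta, w$gamma)
  c0 <- w$csr$imsCoord[1]
  cr <- c(c0 - 5, c0 + 40)
  r <- extract_region(w, c(0, n_scans(w$csr)), cr)
  x <- extract_xic(w, mz_from_index(cr[1], med), mz_from_index(cr[2], med),
                   use_median_ims = TRUE)
  expect_identical(as.numeric(rowSums(r$values)), as.numeric(x$intensity))
})

test_that("extraction does not mutate the window", {
  w <- run_access$windows$ms1
  before <- unserialize(serialize(w, NULL))
  invisible(extract_xic(w, 400, 500))
  invisible(extract_spectrum(w, 3))
  invisible(extract_region(w, c(0, 2), c(400000, 400100)))
  expect_identical(w, before)
})
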