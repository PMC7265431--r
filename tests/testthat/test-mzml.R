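test_that("import builds the expected window structure from interleaved spectra", {
  run <- generate_run(tiny_spec(seed = 51, n_cycles = 3))$run
  sp <- export_run(run)
  back <- import_run(sp)
  expect_identical(names(back$windows), c("ms1", "ms2-001", "ms2-002"))
  expect_identical(n_scans(back$windows$ms1$csr), 3L)
})

test_that("export(import(S)) reproduces every non-zero sample", {
  # the central losslessness property, checked at the spectrum level
  for (seed in c(61, 62)) {
    run <- generate_run(tiny_spec(seed = seed))$run
    sp <- export_run(run)
    sp2 <- export_run(import_run(sp))
    expect_identical(length(sp2), length(sp))
    for (i in seq_along(sp)) {
      expect_identical(sp2[[i]]$intensity, sp[[i]]$intensity)
      expect_identical(sp2[[i]]$ms_level, sp[[i]]$ms_level)
      if (length(sp[[i]]$mz)) {
        expect_lt(max(abs(sp2[[i]]$mz / sp[[i]]$mz - 1)), 1e-12)
      }
      expect_equal(sp2[[i]]$retention_time, sp[[i]]$retention_time)
    }
  }
})

test_that("import(export(run)) is the identity on the run model", {
  run <- generate_run(tiny_spec(seed = 63))$run
  expect_runs_equal(import_run(export_run(run)), run)
})

test_that("exported spectra are cycle-interleaved, MS1 first, RT sorted", {
  run <- generate_run(tiny_spec(seed = 64, n_cycles = 4))$run
  sp <- export_run(run)
  rt <- vapply(sp, `[[`, 0, "retention_time")
  lev <- vapply(sp, `[[`, 0L, "ms_level")
  expect_true(all(diff(rt) > 0))
  expect_identical(lev, rep(c(1L, 2L, 2L), 4))
})

test_that("off-lattice and structurally broken inputs are rejected", {
  run <- generate_run(tiny_spec(seed = 65, n_cycles = 4))$run
  sp <- export_run(run)
  # perturb one whole scan by up to 50 ppm: its points leave the lattice
  i <- which(vapply(sp, function(s) length(s$mz) >= 5, TRUE))[1]
  set.seed(66)
  sp[[i]]$mz <- sort(sp[[i]]$mz * (1 + runif(length(sp[[i]]$mz), -5e-5, 5e-5)))
  expect_error(import_run(sp), "lossy input")

  # drop one MS2 spectrum: window sets inconsistent across cycles
  sp <- export_run(run)
  sp[[3]] <- NULL
  expect_error(import_run(sp), "structure error")
})

test_that("single-scan and empty-window cases export correctly", {
  w <- toffee_window(name = "ms1", first_scan_rt = 12.5, scan_cycle_time = 2,
                     alpha_per_scan = 4e-5, beta_per_scan = 0,
                     csr = build_csr(0, 500000, 10, 1))
  sp <- export_run(toffee_run(list(w)))
  expect_length(sp, 1)
  expect_identical(sp[[1]]$retention_time, 12.5)

  w0 <- toffee_window(name = "ms1", first_scan_rt = 0, scan_cycle_time = 2,
                      alpha_per_scan = c(4e-5, 4e-5), beta_per_scan = c(0, 0),
                      csr = build_csr(integer(0), integer(0), integer(0), 2))
  sp0 <- export_run(toffee_run(list(w0)))
  expect_length(sp0, 2)
  expect_length(sp0[[1]]$mz, 0)
})

test_that("mzML files round trip through the toffee file format", {
  run <- generate_run(tiny_spec(seed = 66, n_cycles = 6))$run
  mz1 <- withr::local_tempfile(fileext = ".mzML")
  tof <- withr::local_tempfile(fileext = ".tof")
  mz2 <- withr::local_tempfile(fileext = ".mzML")

  write_mzml(export_run(run), mz1)
  mzml_to_toffee(mz1, tof)
  toffee_to_mzml(tof, mz2)

  a <- read_mzml(mz1); b <- read_mzml(mz2)
  expect_identical(length(a), length(b))
  for (i in seq_along(a)) {
    expect_identical(b[[i]]$intensity, a[[i]]$intensity)
    if (length(a[[i]]$mz)) {
      expect_lt(max(abs(b[[i]]$mz / a[[i]]$mz - 1)), 1e-12)
    }
  }
})

test_that("non-integral intensities and RT jitter warn but import", {
  run <- generate_run(tiny_spec(seed = 67, n_cycles = 4, n_peptides = 0))$run
  sp <- export_run(run)
  i <- which(vapply(sp, function(s) length(s$mz) >= 3, TRUE))[1]
  sp[[i]]$intensity[1] <- sp[[i]]$intensity[1] + 0.25
  expect_warning(import_run(sp), "non-integral")

  sp <- export_run(run)
  sp[[1]]$retention_time <- sp[[1]]$retention_time - 0.9 * 3.5
  expect_warning(import_run(sp), "uniform model")
})
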