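fg_spec <- tiny_spec(seed = 81, n_cycles = 24, n_peptides = 2,
                     noise_density = 0)
fg_gen <- generate_run(fg_spec)
fg_query <- spec_query(fg_spec, 1)

test_that("foreground extraction recovers exactly the peptide's samples", {
  # noise-free single-window run: the extraction box around the true apex
  # must contain all and only that peptide's non-zero samples
  region <- extract_foreground(fg_gen$run, fg_query)
  truth <- fg_gen$truth$peptides
  mine <- truth[truth$id == fg_query$identifier, ]
  expect_equal(sum(region$samples$intensity), sum(mine$total_intensity))
  expect_lt(abs(region$apex_rt - fg_query$expected_rt), fg_spec$cycle_time)
})

test_that("an rt box smaller than the cycle time keeps only the apex scan", {
  q <- fg_query
  q$rt_half_width <- 0.1
  region <- extract_foreground(fg_gen$run, q)
  expect_true(all(region$samples$scan_offset == 0))
})

test_that("queries outside every isolation window fail to resolve", {
  q <- peptide_query("nowhere", 933.2, 2, c(300, 400), 50)
  expect_error(extract_foreground(fg_gen$run, q), "outside every MS2")
})

test_that("injection conserves intensity and is additive", {
  region <- extract_foreground(fg_gen$run, fg_query)
  bg <- generate_run(tiny_spec(seed = 82, n_peptides = 0, n_cycles = 24))$run
  bt <- total_intensity(bg)

  expect_identical(inject(bg, region, 0, 40), bg)

  for (f in c(1, 0.5, 0.25)) {
    out <- inject(bg, region, f, target_rt = 40)
    scaled <- trunc(region$samples$intensity * f + 0.5)
    expect_identical(total_intensity(out), bt + sum(scaled[scaled >= 1]))
  }

  once <- inject(bg, region, 1, 40)
  twice <- inject(once, region, 1, 40)
  expect_identical(total_intensity(twice),
                   bt + 2 * sum(region$samples$intensity))
})

test_that("cells untouched by injection are bit-identical", {
  region <- extract_foreground(fg_gen$run, fg_query)
  bg <- generate_run(tiny_spec(seed = 83, n_peptides = 0, n_cycles = 24))$run
  out <- inject(bg, region, 1, 40)
  # ms2-002 receives nothing (peptide 1 lives in one window only)
  untouched <- setdiff(names(bg$windows),
                       c("ms1", find_ms2_window(bg, fg_query$precursor_mz)))
  for (nm in untouched) expect_identical(out$windows[[nm]], bg$windows[[nm]])
  # within a touched window, scans far from the target RT are unchanged
  wn <- find_ms2_window(bg, fg_query$precursor_mz)
  expect_identical(slice_scan(out$windows[[wn]]$csr, 0),
                   slice_scan(bg$windows[[wn]]$csr, 0))
})

test_that("apex XIC of an injected peptide is linear in the dilution factor", {
  region <- extract_foreground(fg_gen$run, fg_query)
  bg <- generate_run(tiny_spec(seed = 84, n_peptides = 0, n_cycles = 24,
                               noise_density = 0))$run
  wn <- find_ms2_window(bg, fg_query$precursor_mz)
  apex_sum <- function(run) {
    w <- run$windows[[wn]]
    tot <- 0
    for (fmz in fg_query$fragment_mzs) {
      b <- fmz * (1 + c(-1, 1) * 50e-6)
      tot <- tot + max(extract_xic(w, b[1], b[2])$intensity)
    }
    tot
  }
  base <- apex_sum(inject(bg, region, 1, 40))
  min_int <- 1
  for (f in c(0.5, 0.25, 0.125)) {
    got <- apex_sum(inject(bg, region, f, 40))
    # deviation from exact linearity is bounded by integer rounding:
    # each contributing sample can shift by at most 0.5 counts
    n_samp <- sum(region$samples$source != "ms1")
    expect_lt(abs(got - f * base), 0.5 * n_samp + 1)
  }
})

test_that("confusion labelling matches the all-pairs oracle", {
  expect_identical(
    label_detections(data.frame(peptide = "A", rt = 105),
                     list(ground_truth_entry("A", 100, 1))),
    c(TP = 1L, FP = 0L, FN = 0L))
  expect_identical(
    label_detections(data.frame(peptide = "A", rt = 130),
                     list(ground_truth_entry("A", 100, 1))),
    c(TP = 0L, FP = 1L, FN = 1L))

  set.seed(85)
  for (rep in 1:20) {
    ids <- sprintf("P%02d", 1:12)
    truth <- data.frame(peptide = ids, injected_rt = runif(12, 0, 600))
    det <- data.frame(
      peptide = sample(ids, 25, replace = TRUE),
      rt = runif(25, 0, 600))
    got <- label_detections(det, truth, rt_threshold = 10)
    expect_identical(got, brute_confusion(det, truth, 10))
  }
  expect_error(
    label_detections(data.frame(peptide = "ghost", rt = 1),
                     data.frame(peptide = "A", injected_rt = 1)),
    "absent")
})
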