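p3 <- peak_model_params(sigma_t = 0.05, sigma_m = 2, t0 = 100,
                        m0 = c(500, 505, 510), a = c(2e4, 1.5e4, 1e4),
                        c = c(3, 0, 0), is_ms1 = c(TRUE, FALSE, FALSE))
tgrid <- seq(80, 125, by = 2.5)
mgrid <- 492:518

test_that("the model surface has the stated apex, limit and symmetry", {
  p <- peak_model_params(sigma_t = 0.1, sigma_m = 1.5, t0 = 50,
                         m0 = 300, a = 1000)
  expect_equal(eval_peak_model(p, 50, 300), 1000 / (50 * 0.1 * sqrt(2 * pi)))

  # with chemical noise, the surface tends to c_j far from the elution peak
  pn <- peak_model_params(sigma_t = 0.1, sigma_m = 1.5, t0 = 50,
                          m0 = 300, a = 1000, c = 7, is_ms1 = TRUE)
  expect_equal(eval_peak_model(pn, 1e9, 300), 7, tolerance = 1e-6)
  # ... but only for MS1 fragments
  expect_lt(eval_peak_model(p, 1e9, 300), 1e-6)

  # even in m - m0
  expect_equal(eval_peak_model(p, 42, 300 + 2.3),
               eval_peak_model(p, 42, 300 - 2.3))
  expect_error(eval_peak_model(p, -1, 300), "> 0")
})

test_that("the amplitude equals the peak's integrated area over retention time", {
  # integrate F over t at m = m0 with c = 0: the log-normal in t integrates
  # to a_j by construction, justifying a_j as the re-quantified intensity
  p <- peak_model_params(sigma_t = 0.08, sigma_m = 2, t0 = 120, m0 = 400,
                         a = 5000)
  area <- stats::integrate(function(t) eval_peak_model(p, t, 400), 1, 1e4,
                           rel.tol = 1e-10)
  expect_equal(area$value, 5000, tolerance = 1e-6)
})

test_that("a noiseless raster is fit to machine-level residual", {
  ras <- generate_peak_raster(p3, tgrid, mgrid, noise_sigma = 0)
  fit <- fit_peak(ras)
  expect_lt(fit$residual_ss, 1e-6 * sum(unlist(ras$I)^2))
  expect_equal(fit$params$t0, 100, tolerance = 1e-6)
  expect_equal(fit$requant_intensity, p3$a, tolerance = 1e-6)
})

test_that("parameters are recovered from noisy rasters within tolerance", {
  apex <- eval_peak_model(p3, 100, 500, 1)
  ras <- generate_peak_raster(p3, tgrid, mgrid, noise_sigma = 0.01 * apex,
                              seed = 91)
  init <- p3
  init$t0 <- 104; init$sigma_t <- 0.08; init$m0 <- p3$m0 + 1
  fit <- fit_peak(ras, init = init)
  expect_lt(abs(fit$params$t0 / p3$t0 - 1), 0.02)
  expect_lt(abs(fit$params$sigma_t / p3$sigma_t - 1), 0.05)
  expect_lt(abs(fit$params$sigma_m / p3$sigma_m - 1), 0.05)
  expect_lt(max(abs(fit$params$a / p3$a - 1)), 0.02)
})

test_that("recovery error grows monotonically with noise", {
  apex <- eval_peak_model(p3, 100, 500, 1)
  errs <- vapply(c(0.002, 0.02, 0.1), function(lvl) {
    ras <- generate_peak_raster(p3, tgrid, mgrid, noise_sigma = lvl * apex,
                                seed = 92)
    fit <- fit_peak(ras)
    max(abs(fit$params$a / p3$a - 1))
  }, 0)
  expect_true(all(diff(errs) > 0))
})

test_that("the fit is equivariant under index-grid translation", {
  ras <- generate_peak_raster(p3, tgrid, mgrid, noise_sigma = 0)
  shifted <- ras
  shifted$m <- ras$m + 37
  f0 <- fit_peak(ras)
  f1 <- fit_peak(shifted)
  expect_equal(f1$params$m0, f0$params$m0 + 37, tolerance = 1e-6)
  expect_equal(f1$params$t0, f0$params$t0, tolerance = 1e-9)
  expect_equal(f1$requant_intensity, f0$requant_intensity, tolerance = 1e-6)
})

test_that("degenerate rasters are rejected", {
  z <- fragment_raster(tgrid, mgrid,
                       list(matrix(0, length(tgrid), length(mgrid))))
  expect_error(fit_peak(z), "all-zero")
  expect_error(fragment_raster(c(-1, 1), 1:3, list(matrix(0, 2, 3))), "t > 0")
})

test_that("peak_fit behaves like a fitted model object", {
  ras <- generate_peak_raster(p3, tgrid, mgrid, noise_sigma = 0)
  fit <- fit_peak(ras)
  expect_s3_class(fit, "peak_fit")
  cf <- coef(fit)
  expect_named(cf[1:3], c("sigma_t", "sigma_m", "t0"))
  expect_output(print(fit), "2D peak fit")
  f <- fitted(fit)
  r <- residuals(fit)
  expect_equal(f[[2]] + r[[2]], ras$I[[2]])
  expect_equal(predict(fit, 100, 500, 1),
               eval_peak_model(fit$params, 100, 500, 1))
  expect_output(print(summary(fit)), "observations")
})

test_that("cohort outlier flagging hits planted outliers, spares inliers", {
  expect_error(flag_outliers(data.frame(sigma_t = 1:5, sigma_m = 1:5)),
               "cohort too small")

  base <- data.frame(sigma_t = rep(0.05, 20), sigma_m = rep(2, 20))
  expect_true(all(!flag_outliers(base)))
  gross <- base
  gross$sigma_t[7] <- 0.5
  expect_identical(which(flag_outliers(gross)), 7L)

  set.seed(93)
  n <- 400
  cohort <- data.frame(
    sigma_t = rnorm(n, 0.05, 0.005),
    sigma_m = rnorm(n, 2, 0.2),
    dt0 = rnorm(n, 0, 2),
    dm0 = rnorm(n, 0, 0.5))
  planted <- sample.int(n, n * 0.05)
  feat <- sample(names(cohort), length(planted), replace = TRUE)
  scales <- c(sigma_t = 0.005, sigma_m = 0.2, dt0 = 2, dm0 = 0.5)
  for (k in seq_along(planted)) {
    cohort[[feat[k]]][planted[k]] <-
      cohort[[feat[k]]][planted[k]] + 6 * 1.4826 * scales[[feat[k]]] *
        sample(c(-1, 1), 1)
  }
  flags <- flag_outliers(cohort)
  sens <- mean(flags[planted])
  fpr <- mean(flags[-planted])
  expect_gte(sens, 0.9)
  expect_lte(fpr, 0.05)
})

test_that("peptide_raster feeds a fit that recovers the generated peak", {
  spec <- tiny_spec(seed = 94, n_cycles = 30, n_peptides = 1,
                    noise_density = 0)
  g <- generate_run(spec)
  q <- spec_query(spec, 1)
  ras <- peptide_raster(g$run, q)
  expect_s3_class(ras, "fragment_raster")
  expect_length(ras$I, 1 + length(q$fragment_mzs))
  expect_true(ras$is_ms1[1] && !any(ras$is_ms1[-1]))

  fit <- fit_peak(ras)
  truth <- spec$peptides[1, ]
  # count integerisation and truncation leave the apex and spreads close
  expect_lt(abs(fit$params$t0 - truth$rt), spec$cycle_time)
  expect_lt(abs(fit$params$sigma_m / truth$sigma_m - 1), 0.3)
  expect_lt(abs(fit$params$sigma_t / truth$sigma_t - 1), 0.3)
  expect_true(all(fit$requant_intensity[-1] > 0))
})
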