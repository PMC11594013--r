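test_that("noiseless simulation closes the loop with the generating model", {
  s <- simulate_drying_experiment(params = c(k = 0.6635, n = 1.0826),
                                  temperature_C = 70, noise_sd = 0,
                                  times = seq(0, 510, 30))
  truth <- attr(s, "truth")
  mr_back <- (s$moisture_db - truth$M_e) / (truth$M_0 - truth$M_e)
  expected <- pmax(evaluate_model("page", truth$params, s$time_min / 60),
                   truth$mr_floor)
  expect_equal(mr_back, expected, tolerance = 1e-12)
})

test_that("the same seed reproduces the same experiment exactly", {
  s1 <- simulate_drying_experiment(seed = 21)
  s2 <- simulate_drying_experiment(seed = 21)
  expect_identical(s1$moisture_db, s2$moisture_db)
  s3 <- simulate_drying_experiment(seed = 22)
  expect_false(identical(s1$moisture_db, s3$moisture_db))
})

test_that("seeded generation does not disturb the caller's RNG stream", {
  set.seed(33)
  a <- rnorm(1)
  set.seed(33)
  invisible(simulate_drying_experiment(seed = 5))
  b <- rnorm(1)
  expect_identical(a, b)
})

test_that("the equilibrium floor rises with drying temperature", {
  f50 <- attr(simulate_drying_experiment(temperature_C = 50, noise_sd = 0),
              "truth")$mr_floor
  f90 <- attr(simulate_drying_experiment(temperature_C = 90, noise_sd = 0,
              params = c(k = 0.9282, n = 1.1896)), "truth")$mr_floor
  expect_equal(f50, 3.5e-3)
  expect_equal(f90, 1.54e-2)
})

test_that("excessive noise is rejected as a configuration error", {
  expect_error(simulate_drying_experiment(noise_sd = 0.2, seed = 1),
               "below -0.1")
})

test_that("fitting simulated runs recovers the generating k with small bias", {
  truth <- c(k = 0.6635, n = 1.0826)
  ks <- vapply(1:100, function(i) {
    s <- simulate_drying_experiment(params = truth, temperature_C = 70,
                                    times = seq(0, 510, 30),
                                    noise_sd = 0.005, seed = 900 + i)
    mr <- moisture_ratio(s, M_e = attr(s, "truth")$M_e)
    fit_drying_model(mr, "page",
                     control = fit_control(n_starts = 2))$params[["k"]]
  }, numeric(1))
  expect_lt(abs(mean(ks) - truth[["k"]]) / truth[["k"]], 0.01)
})

test_that("Arrhenius sets regenerate their inputs and degenerate limits", {
  d <- simulate_arrhenius_set(1e-5, 34.90, noise_sd_logD = 0)
  fit <- fit_arrhenius(d)
  expect_lt(abs(fit$E_a - 34.90), 1e-8)
  # zero activation energy: all diffusivities equal the prefactor
  d0 <- simulate_arrhenius_set(3e-7, 0, noise_sd_logD = 0)
  expect_equal(d0$deff_m2s, rep(3e-7, 5))
  # noisy recovery is stable across reruns of the same seeds
  rmse <- function(run) sqrt(mean((vapply(1:50, function(i)
    fit_arrhenius(simulate_arrhenius_set(1e-5, 34.90, noise_sd_logD = 0.05,
                                         seed = run * 1000 + i))$E_a,
    numeric(1)) - 34.90)^2))
  expect_identical(rmse(7), rmse(7))
  expect_lt(rmse(7), 5)
})

test_that("dose-response simulation is logistic, seeded, and clipped", {
  dr <- simulate_dose_response(0.016, hill = 1, noise_sd_pct = 0)
  expect_equal(dr$inhibition,
               drypom:::logistic4(dr$concentration, 0.016, 1))
  # midpoint response
  dr2 <- simulate_dose_response(0.02, concentrations = c(0.005, 0.01, 0.02, 0.08),
                                noise_sd_pct = 0)
  expect_equal(dr2$inhibition[3], 50)
  # two-fold default grid is geometric and increasing
  expect_equal(unique(round(diff(log(dr$concentration)), 10)),
               round(log(2), 10))
  expect_identical(simulate_dose_response(0.016, noise_sd_pct = 2, seed = 4),
                   simulate_dose_response(0.016, noise_sd_pct = 2, seed = 4))
  big <- simulate_dose_response(0.016, noise_sd_pct = 30, seed = 5)
  expect_true(all(big$inhibition >= -5 & big$inhibition <= 105))
})

test_that("property tables hit their generating means", {
  means <- c(freeze_drying = 2.35, `50C` = 2.77, `60C` = 3.08, `70C` = 3.37,
             `80C` = 3.87, `90C` = 3.40)
  sds <- c(0.15, 0.36, 0.47, 0.19, 0.43, 0.16)
  # zero-SD replicates equal the means exactly
  gt0 <- simulate_property_table(means, 0, seed = 1)
  expect_equal(tapply(gt0$value, gt0$treatment, mean)[names(means)],
               means, tolerance = 1e-12, ignore_attr = TRUE)
  # same seed -> identical table
  expect_identical(simulate_property_table(means, sds, seed = 3)$value,
                   simulate_property_table(means, sds, seed = 3)$value)
  # sample means within 3 standard errors of truth almost always
  ok <- vapply(1:200, function(i) {
    gt <- simulate_property_table(means, sds, n_replicates = 3,
                                  seed = 2000 + i)
    m <- tapply(gt$value, gt$treatment, mean)[names(means)]
    all(abs(m - means) <= 3 * sds / sqrt(3))
  }, logical(1))
  expect_gte(mean(ok), 0.99)
  expect_error(simulate_property_table(means, -1), ">= 0")
})

test_that("written series round-trip through the reader with truth sidecar", {
  s <- simulate_drying_experiment(seed = 17)
  f <- withr::local_tempfile(fileext = ".csv")
  write_moisture_series(s, f)
  back <- read_moisture_series(f, temperature_C = 70)
  expect_equal(back$moisture_db, s$moisture_db, tolerance = 1e-12)
  expect_true(file.exists(paste0(f, ".truth.txt")))
  truth_lines <- readLines(paste0(f, ".truth.txt"))
  expect_true(any(grepl("params.k", truth_lines)))
})
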