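test_that("the statistic battery matches hand arithmetic", {
  # SSE = 0.01 + 0.0025 + 0.0025 = 0.015; AIC = 3 ln(0.005) + 4
  suppressWarnings(
    s <- goodness_of_fit(c(1.0, 0.6, 0.3), c(0.9, 0.65, 0.35), K = 2))
  expect_equal(s$SSE, 0.015)
  expect_equal(s$MSE, 0.005)
  expect_equal(s$RMSE, sqrt(0.005), tolerance = 1e-12)
  expect_equal(s$AIC, 3 * log(0.005) + 4, tolerance = 1e-12)
  # N = K + 1: the small-sample correction is undefined
  expect_warning(goodness_of_fit(c(1, 0.6, 0.3), c(0.9, 0.65, 0.35), K = 2),
                 "AICc undefined")
  expect_true(is.nan(s$AICc))
})

test_that("a perfect prediction reports R2 = 1 and a flagged -Inf AIC", {
  y <- c(1, 0.7, 0.4, 0.25, 0.1)
  s <- goodness_of_fit(y, y, K = 2)
  expect_equal(s$R2, 1)
  expect_equal(s$SSE, 0)
  expect_equal(s$RMSE, 0)
  expect_identical(s$AIC, -Inf)
  expect_true(s$perfect_fit)
})

test_that("a constant observed series has undefined R2", {
  expect_error(goodness_of_fit(rep(0.5, 4), c(0.5, 0.4, 0.5, 0.6), K = 2),
               "constant")
})

test_that("low predicted values are excluded from chi-square with a count", {
  y <- c(1, 0.5, 0.1, 0)
  pred <- c(1, 0.5, 0.1, 1e-9)
  expect_warning(s <- goodness_of_fit(y, pred, K = 2), "excluded")
  expect_equal(s$chi_sq_n_excluded, 1)
  expect_equal(s$chi_sq, sum((y[1:3] - pred[1:3])^2 / pred[1:3]))
})

test_that("AICc is strictly increasing in K at fixed SSE and N", {
  y <- c(1, 0.8, 0.55, 0.4, 0.28, 0.2, 0.13, 0.1)
  pred <- y + 0.01
  aicc <- vapply(1:4, function(K) goodness_of_fit(y, pred, K)$AICc, 0)
  expect_true(all(diff(aicc) > 0))
})

test_that("noiseless Page data are recovered to high precision", {
  mr <- page_mr(k = 0.9282, n = 1.1896)
  fit <- fit_drying_model(mr, "page")
  expect_lt(abs(fit$params[["k"]] - 0.9282), 1e-4)
  expect_lt(abs(fit$params[["n"]] - 1.1896), 1e-4)
  expect_lt(fit$stats$SSE, 1e-12)
  expect_gte(fit$stats$R2, 0.999999)
  expect_true(fit$converged)
})

test_that("every model refits its own noiseless data essentially perfectly", {
  tt <- seq(0, 420, 30)
  truths <- list(
    page = c(k = 0.6635, n = 1.0826),
    modified_page = c(k = 0.7738, n = 0.7738),
    henderson_pabis = c(a = 1.0189, k = 0.6095),
    logarithmic = c(a = 1.0189, k = 0.6095, c = 0.012),
    midilli = c(a = 1.019, k = 0.5643, n = 1.0784, b = -0.002)
  )
  for (m in names(truths)) {
    y <- evaluate_model(m, truths[[m]], tt / 60)
    fit <- fit_drying_model(mr_series(tt, y / y[1]), m)
    expect_lt(fit$stats$SSE, 1e-10)
  }
})

test_that("refitting from the optimum does not improve the SSE", {
  mr <- page_mr(k = 0.6635, n = 1.0826, total_min = 510)
  set.seed(4)
  noisy <- mr_series(mr$time_min, pmax(mr$mr + c(0, rnorm(nrow(mr) - 1, 0, 0.01)), 0))
  fit1 <- fit_drying_model(noisy, "page")
  # restart the optimizer from the returned optimum
  res <- minpack.lm::nls.lm(
    par = fit1$params,
    lower = tl_model("page")$lower, upper = tl_model("page")$upper,
    fn = function(p) evaluate_model("page", setNames(p, c("k", "n")),
                                    noisy$time_min / 60) - noisy$mr)
  expect_lt(fit1$stats$SSE - sum(res$fvec^2), 1e-10)
})

test_that("fitting is invariant to the order of observations", {
  mr <- page_mr(k = 0.5325, n = 1.0838, total_min = 600)
  set.seed(8)
  y <- pmax(mr$mr + c(0, rnorm(nrow(mr) - 1, 0, 0.008)), 0)
  perm <- sample(nrow(mr))
  d1 <- data.frame(time_min = mr$time_min, mr = y)
  d2 <- d1[perm, ]
  f1 <- fit_drying_model(d1, "page")
  f2 <- fit_drying_model(d2, "page")
  expect_equal(f1$params, f2$params, tolerance = 1e-8)
})

test_that("mean recovered k is within 2 % under Gaussian noise", {
  truth_k <- 0.6635; truth_n <- 1.0826
  tt <- seq(0, 570, 30)   # 20 observations
  clean <- evaluate_model("page", c(k = truth_k, n = truth_n), tt / 60)
  set.seed(101)
  ks <- replicate(200, {
    y <- clean + c(0, rnorm(length(tt) - 1, 0, 0.01))
    fit <- fit_drying_model(data.frame(time_min = tt, mr = pmax(y, 0)),
                            "page", control = fit_control(n_starts = 2))
    fit$params[["k"]]
  })
  expect_lt(abs(mean(ks) - truth_k) / truth_k, 0.02)
})

test_that("model ranking orders by AICc with RMSE and K tie-breaks", {
  mr <- page_mr(k = 0.5, n = 1.1, total_min = 510)
  set.seed(5)
  noisy <- mr_series(mr$time_min, pmax(mr$mr + c(0, rnorm(nrow(mr) - 1, 0, 0.01)), 0))
  fits <- lapply(c("page", "henderson_pabis"), function(m)
    fit_drying_model(noisy, m))
  ranked <- rank_models(fits)
  aicc <- vapply(ranked, function(f) f$stats$AICc, 0)
  expect_true(aicc[1] <= aicc[2])

  # synthetic tie: identical AICc broken by RMSE
  f1 <- fits[[1]]; f2 <- fits[[2]]
  f1$stats$AICc <- f2$stats$AICc <- -100
  f1$stats$RMSE <- 0.01; f2$stats$RMSE <- 0.02
  expect_equal(rank_models(list(f2, f1))[[1]]$stats$RMSE, 0.01)

  # different N is an invalid comparison
  short <- fit_drying_model(page_mr(0.5, 1.1, total_min = 300), "page")
  expect_error(rank_models(list(fits[[1]], short)), "different numbers")
})

test_that("the stretched-exponential family wins model recovery", {
  # data generated by the Page model with small noise: the Page form (or
  # its Midilli superset, which nests it) should rank first nearly always
  tt <- seq(0, 510, 30)
  clean <- evaluate_model("page", c(k = 0.6635, n = 1.0826), tt / 60)
  models <- names(thin_layer_models())
  set.seed(77)
  wins <- replicate(100, {
    y <- pmax(clean + c(0, rnorm(length(tt) - 1, 0, 0.005)), 0)
    d <- data.frame(time_min = tt, mr = y)
    fits <- lapply(models, function(m)
      fit_drying_model(d, m, control = fit_control(n_starts = 2)))
    suppressWarnings(rank_models(fits)[[1]]$model)
  })
  expect_gte(mean(wins %in% c("page", "midilli")), 0.9)
})

test_that("fit preconditions are enforced", {
  expect_error(fit_drying_model(data.frame(time_min = c(0, 30, 60),
                                           mr = c(1, 0.5, 0.2)), "midilli"),
               "at least K \\+ 2")
  expect_error(fit_drying_model(data.frame(time_min = c(0, 30, 60, 90),
                                           mr = c(1, NA, 0.5, 0.2)), "page"),
               "finite")
})
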