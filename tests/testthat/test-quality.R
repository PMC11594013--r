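test_that("percent change reproduces the headline treatment contrasts", {
  # SDF at 70 C vs freeze-dried control
  expect_equal(round(percent_change(2.35, 3.37), 2), 43.40)
  # swelling capacity pooled over the hottest treatments vs control
  expect_equal(round(percent_change(15.2, 7.0), 2), -53.95)
  expect_equal(percent_change(10, 10), 0)
  expect_error(percent_change(0, 1), "non-zero")
})

test_that("forward and reverse percent changes are reciprocal", {
  set.seed(3)
  r <- runif(25, 0.5, 20)
  o <- runif(25, 0.5, 20)
  d1 <- percent_change(r, o)
  d2 <- percent_change(o, r)
  expect_equal((1 + d1 / 100) * (1 + d2 / 100), rep(1, 25), tolerance = 1e-12)
})

test_that("pooled treatment means average the per-treatment means", {
  gt <- group_table(rep(c("50C", "60C", "70C", "80C"), each = 3),
                    rep(c(8.0, 8.3, 8.2, 7.7), each = 3))
  expect_equal(pooled_mean(gt, c("50C", "60C", "70C", "80C")), 8.05)
  expect_error(pooled_mean(gt, "100C"), "unknown treatment")
})

test_that("identical groups give F = 0 and p = 1", {
  gt <- group_table(rep(c("a", "b", "c"), each = 3), rep(c(1, 2, 3), 3))
  res <- anova_oneway(gt)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(6)
  x <- rnorm(6, 10, 1); y <- rnorm(5, 12, 1)
  gt <- group_table(c(rep("x", 6), rep("y", 5)), c(x, y))
  res <- anova_oneway(gt)
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)
})

test_that("the F decomposition matches textbook sums of squares", {
  gt <- group_table(rep(c("g1", "g2", "g3"), each = 3),
                    c(1, 2, 3, 2, 3, 4, 5, 6, 7))
  res <- anova_oneway(gt)
  # SSB = 26 on 2 df, SSW = 6 on 6 df -> F = 13
  expect_equal(res$F, 13, tolerance = 1e-12)
  expect_equal(res$df_between, 2)
  expect_equal(res$df_within, 6)
  expect_equal(res$p, pf(13, 2, 6, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("ANOVA F is invariant under adding a constant", {
  set.seed(9)
  gt <- group_table(rep(c("a", "b", "c"), each = 4), rnorm(12, 5, 1))
  gt2 <- group_table(gt$treatment, gt$value + 123.4)
  expect_equal(anova_oneway(gt)$F, anova_oneway(gt2)$F, tolerance = 1e-10)
})

test_that("degenerate zero-variance layouts are rejected", {
  gt <- group_table(rep(c("a", "b"), each = 3), rep(c(1, 2), each = 3))
  expect_error(anova_oneway(gt), class = "drypom_degenerate_error")
})

test_that("indistinguishable groups all share the letter a", {
  gt <- group_table(rep(c("a", "b", "c"), each = 3), rep(c(1, 2, 3), 3))
  tk <- tukey_letters(gt)
  expect_true(all(tk$letters == "a"))
})

test_that("clearly separated groups get distinct letters, highest mean = a", {
  set.seed(10)
  gt <- group_table(rep(c("lo", "hi"), each = 3),
                    c(rnorm(3, 0, 1), rnorm(3, 100, 1)))
  tk <- tukey_letters(gt)
  expect_equal(unname(tk$letters["hi"]), "a")
  expect_equal(unname(tk$letters["lo"]), "b")
})

test_that("letter sharing is consistent with the HSD critical range", {
  set.seed(11)
  for (rep_i in 1:20) {
    means <- runif(5, 0, 6)
    gt <- group_table(rep(paste0("t", 1:5), each = 3),
                      rnorm(15, rep(means, each = 3), 1))
    tk <- tukey_letters(gt)
    trt <- names(tk$means)
    for (i in 1:4) for (j in (i + 1):5) {
      share <- any(strsplit(tk$letters[trt[i]], "")[[1]] %in%
                     strsplit(tk$letters[trt[j]], "")[[1]])
      diff_ij <- abs(tk$means[trt[i]] - tk$means[trt[j]])
      if (share) expect_lte(diff_ij, tk$critical_range + 1e-10)
      else expect_gt(diff_ij, tk$critical_range - 1e-10)
    }
  }
})

test_that("letter partition agrees with the multcomp compact letter display", {
  skip_if_not_installed("multcomp")
  set.seed(13)
  for (rep_i in 1:10) {
    gt <- group_table(rep(paste0("t", 1:4), each = 3),
                      rnorm(12, rep(runif(4, 0, 5), each = 3), 0.8))
    tk <- tukey_letters(gt)
    fit <- aov(value ~ treatment, data = gt)
    mc <- multcomp::cld(multcomp::glht(fit,
           linfct = multcomp::mcp(treatment = "Tukey")))$mcletters$Letters
    trt <- names(tk$letters)
    for (i in seq_along(trt)) for (j in seq_along(trt)) {
      if (i >= j) next
      share_mine <- any(strsplit(tk$letters[trt[i]], "")[[1]] %in%
                          strsplit(tk$letters[trt[j]], "")[[1]])
      share_mc <- any(strsplit(mc[[trt[i]]], "")[[1]] %in%
                        strsplit(mc[[trt[j]]], "")[[1]])
      expect_equal(share_mine, share_mc)
    }
  }
})

test_that("the control separates from the mid-temperature WHC cluster", {
  # water-holding capacity layout: control well above four clustered
  # convective treatments; regenerated from mean/SD with n = 3
  means <- c(freeze_drying = 11.8, `50C` = 8.0, `60C` = 8.3, `70C` = 8.2,
             `80C` = 7.7, `90C` = 7.0)
  sds <- c(0.6, 0.2, 0.4, 0.5, 0.2, 0.5)
  hits <- vapply(1:200, function(i) {
    gt <- simulate_property_table(means, sds, n_replicates = 3,
                                  seed = 5000 + i, property = "WHC")
    tk <- tukey_letters(gt)
    fd <- strsplit(tk$letters[["freeze_drying"]], "")[[1]]
    cluster <- c("50C", "60C", "70C", "80C")
    all(vapply(cluster, function(tr)
      !any(fd %in% strsplit(tk$letters[[tr]], "")[[1]]), logical(1)))
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("advisory screens report but never gate", {
  set.seed(14)
  gt <- group_table(rep(c("a", "b", "c"), each = 5), rnorm(15))
  sc <- advisory_screens(gt)
  expect_true(is.numeric(sc$shapiro_p))
  expect_type(sc$normality_ok, "logical")
})

test_that("group tables validate replication and finiteness", {
  expect_error(group_table(c("a", "a", "b"), c(1, 2, 3)), ">= 2 replicates")
  expect_error(group_table(c("a", "a", "b", "b"), c(1, 2, 3, NA)), "finite")
})
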