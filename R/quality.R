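#' Construct a treatment-by-replicate group table
#'
#' Long-format replicate measurements of one powder property (dietary
#' fiber fraction, techno-functional attribute, bioactive content, ...)
#' across drying treatments, the unit the ANOVA and Tukey comparison
#' operate on.
#'
#' @param treatment Treatment labels (e.g. `"freeze_drying"`, `"50C"`),
#'   character or factor; each level needs >= 2 replicates.
#' @param value Numeric replicate measurements, all finite.
#' @param property Property label (e.g. `"WHC"`).
#' @param unit Measurement unit (e.g. `"mL/g db"`).
#' @return An object of class `group_table`: data frame with columns
#'   `treatment` (factor, levels in first-appearance order) and `value`,
#'   plus `property` and `unit` attributes.
#' @export
group_table <- function(treatment, value, property = "", unit = "") {
  value <- as.numeric(value)
  if (length(treatment) != length(value))
    stop_input("`treatment` and `value` must have the same length")
  if (any(!is.finite(value))) stop_input("all values must be finite")
  treatment <- factor(treatment, levels = unique(as.character(treatment)))
  n <- table(treatment)
  if (any(n < 2))
    stop_input("every treatment needs >= 2 replicates; offending: ",
               paste(names(n)[n < 2], collapse = ", "))
  structure(data.frame(treatment = treatment, value = value),
            property = property, unit = unit,
            class = c("group_table", "data.frame"))
}

#' Signed percent change of an observation relative to a reference
#'
#' 100 (observed - reference) / reference. Report-facing code rounds to
#' two decimals; the returned value is unrounded.
#'
#' @param reference Reference (control) value, non-zero.
#' @param observed Observed value (vectorized).
#' @return Signed percent change.
#' @export
#' @examples
#' percent_change(2.35, 3.37)   # +43.40 %
percent_change <- function(reference, observed) {
  if (any(reference == 0)) stop_input("`reference` must be non-zero")
  100 * (observed - reference) / reference
}

#' Mean of per-treatment means over a subset of treatments
#'
#' Helper for pooled comparisons of the form "property averaged over the
#' 50-80 C treatments vs the freeze-dried control": averages the
#' treatment means (not the pooled replicates, though with balanced
#' replication the two coincide).
#'
#' @param groups A [group_table()].
#' @param treatments Treatment labels to pool.
#' @return The pooled mean.
#' @export
pooled_mean <- function(groups, treatments) {
  stopifnot(inherits(groups, "group_table"))
  miss <- setdiff(treatments, levels(groups$treatment))
  if (length(miss))
    stop_input("unknown treatment(s): ", paste(miss, collapse = ", "))
  m <- tapply(groups$value, groups$treatment, mean)
  mean(m[treatments])
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA decomposition with the F test.
#'
#' @param groups A [group_table()].
#' @return List with `F`, `p`, `df_between`, `df_within`, `ms_between`,
#'   `ms_within` and the group means.
#' @export
#' @examples
#' gt <- group_table(rep(c("a", "b", "c"), each = 3),
#'                   c(1, 2, 3, 2, 3, 4, 5, 6, 7))
#' anova_oneway(gt)$F
anova_oneway <- function(groups) {
  stopifnot(inherits(groups, "group_table"))
  wvar <- tapply(groups$value, groups$treatment, stats::var)
  if (all(wvar == 0))
    stop(errorCondition("zero within-group variance everywhere",
                        class = c("drypom_degenerate_error", "error")))
  fit <- aov(value ~ treatment, data = groups)
  tab <- anova(fit)
  ms_w <- tab["Residuals", "Mean Sq"]
  list(F = tab["treatment", "F value"],
       p = tab["treatment", "Pr(>F)"],
       df_between = tab["treatment", "Df"],
       df_within = tab["Residuals", "Df"],
       ms_between = tab["treatment", "Mean Sq"],
       ms_within = ms_w,
       means = tapply(groups$value, groups$treatment, mean),
       aov = fit)
}

# Compact letter display by insert-and-absorb over a logical matrix of
# significant pairwise differences. `means` must be sorted descending.
cld_insert_absorb <- function(sig, means) {
  stopifnot(is.matrix(sig), nrow(sig) == length(means))
  trt <- names(means)
  cols <- list(trt)  # start: one column holding every treatment
  k <- length(trt)
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      if (!sig[trt[i], trt[j]]) next
      hit <- vapply(cols, function(cc) all(c(trt[i], trt[j]) %in% cc),
                    logical(1))
      if (!any(hit)) next
      new_cols <- list()
      for (idx in seq_along(cols)) {
        cc <- cols[[idx]]
        if (hit[idx]) {
          new_cols <- c(new_cols, list(setdiff(cc, trt[i])),
                        list(setdiff(cc, trt[j])))
        } else {
          new_cols <- c(new_cols, list(cc))
        }
      }
      new_cols <- new_cols[lengths(new_cols) > 0]
      # absorb: drop any column that is a subset of another
      keep <- rep(TRUE, length(new_cols))
      for (x in seq_along(new_cols)) {
        for (yy in seq_along(new_cols)) {
          if (x != yy && keep[yy] &&
              all(new_cols[[x]] %in% new_cols[[yy]]) &&
              !(all(new_cols[[yy]] %in% new_cols[[x]]) && x < yy)) {
            keep[x] <- FALSE
            break
          }
        }
      }
      cols <- unique(new_cols[keep])
    }
  }
  # order columns so the one containing the highest mean is lettered "a"
  first_rank <- vapply(cols, function(cc) min(match(cc, trt)), numeric(1))
  cols <- cols[order(first_rank)]
  letters_out <- setNames(rep("", k), trt)
  for (ci in seq_along(cols)) {
    lab <- letters[ci]
    for (tr in cols[[ci]]) {
      letters_out[tr] <- paste0(letters_out[tr], lab)
    }
  }
  vapply(letters_out, function(s) paste(sort(strsplit(s, "")[[1]]),
                                        collapse = ""), character(1))
}

#' Tukey HSD comparison with a compact letter display
#'
#' Runs Tukey's honestly-significant-difference test on a one-way layout
#' (via [stats::TukeyHSD()]) and condenses the pairwise outcomes into a
#' compact letter display using the insert-and-absorb algorithm. Letters
#' are assigned in order of descending group mean, so the highest mean
#' always carries the letter "a"; treatments sharing no letter differ
#' significantly at `alpha`.
#'
#' @param groups A [group_table()].
#' @param alpha Significance level in (0, 1); default 0.05.
#' @return An object of class `tukey_outcome`: list with `letters` (named
#'   by treatment, descending-mean order), `means`, `pairwise` (the
#'   TukeyHSD table with significance flags), `critical_range` (HSD for
#'   the balanced case, else NA) and `alpha`.
#' @export
#' @examples
#' gt <- group_table(rep(c("ctrl", "hot"), each = 3),
#'                   c(99, 100, 101, 0, 1, 2))
#' tukey_letters(gt)$letters
tukey_letters <- function(groups, alpha = 0.05) {
  stopifnot(inherits(groups, "group_table"))
  if (alpha <= 0 || alpha >= 1) stop_input("`alpha` must be in (0, 1)")
  a <- anova_oneway(groups)
  hsd <- TukeyHSD(a$aov, conf.level = 1 - alpha)$treatment
  means <- sort(a$means, decreasing = TRUE)
  trt <- names(means)
  sig <- matrix(FALSE, length(trt), length(trt),
                dimnames = list(trt, trt))
  pair_names <- rownames(hsd)
  for (r in seq_len(nrow(hsd))) {
    pr <- strsplit(pair_names[r], "-", fixed = TRUE)[[1]]
    s <- hsd[r, "p adj"] < alpha
    sig[pr[1], pr[2]] <- s
    sig[pr[2], pr[1]] <- s
  }
  n_per <- table(groups$treatment)
  crit <- if (length(unique(n_per)) == 1) {
    qtukey(1 - alpha, nmeans = length(trt), df = a$df_within) *
      sqrt(a$ms_within / n_per[1])
  } else NA_real_
  structure(list(
    letters = cld_insert_absorb(sig, means),
    means = means,
    pairwise = data.frame(pair = pair_names,
                          diff = hsd[, "diff"],
                          p_adj = hsd[, "p adj"],
                          significant = hsd[, "p adj"] < alpha),
    critical_range = unname(crit),
    alpha = alpha
  ), class = "tukey_outcome")
}

#' @export
print.tukey_outcome <- function(x, ...) {
  cat(sprintf("Tukey HSD at alpha = %g\n", x$alpha))
  print(data.frame(mean = round(x$means, 4), letters = x$letters))
  invisible(x)
}

#' Advisory normality and variance-homogeneity screens
#'
#' Shapiro-Wilk on the per-group residuals and (when the `car` package is
#' available) Levene's test on the groups. These are reported as advisory
#' flags only; they do not gate or alter the ANOVA.
#'
#' @param groups A [group_table()].
#' @param alpha Flagging level.
#' @return List with `shapiro_p`, `levene_p` (NA when unavailable or
#'   degenerate) and logical `normality_ok`, `homogeneity_ok`.
#' @export
advisory_screens <- function(groups, alpha = 0.05) {
  stopifnot(inherits(groups, "group_table"))
  res <- groups$value - ave(groups$value, groups$treatment)
  sh <- tryCatch(stats::shapiro.test(res)$p.value, error = function(e) NA_real_)
  lv <- if (requireNamespace("car", quietly = TRUE)) {
    tryCatch(
      car::leveneTest(value ~ treatment, data = groups)[1, "Pr(>F)"],
      error = function(e) NA_real_)
  } else NA_real_
  list(shapiro_p = sh, levene_p = lv,
       normality_ok = is.na(sh) || sh >= alpha,
       homogeneity_ok = is.na(lv) || lv >= alpha)
}

#' Read a long-format property table
#'
#' Expects columns `property, treatment, replicate, value` and returns one
#' [group_table()] per property.
#'
#' @param path Path to a comma-separated file with a header.
#' @return Named list of `group_table` objects, one per property.
#' @export
read_group_tables <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  d <- read.csv(path, check.names = FALSE)
  need <- c("property", "treatment", "value")
  if (!all(need %in% names(d)))
    stop_input("expected columns `property, treatment, replicate, value` in ",
               path)
  lapply(split(d, d$property), function(dd)
    group_table(dd$treatment, dd$value, property = dd$property[1]))
}
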