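test_that("Kruskal-Wallis H matches the hand rank computation", {
  kt <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  # ranks 1..6, no ties: H = 12/(6*7) * (6^2/3 + 15^2/3) - 3*7
  expect_equal(kt$statistic, 12 / 42 * (36 / 3 + 225 / 3) - 21, tolerance = 1e-12)
  expect_equal(kt$statistic, 3.857, tolerance = 1e-3)
  expect_identical(kt$df, 1L)
  expect_equal(kt$tie_correction, 1)
})

test_that("Kruskal-Wallis contracts: empty groups, constants, ties", {
  expect_error(kruskal_wallis(1:4, rep("a", 4)), "two non-empty groups")
  expect_error(kruskal_wallis(rep(2, 6), rep(c("a", "b"), 3)), "identical")
  kt <- kruskal_wallis(c(1, 1, 2, 2, 3, 3), rep(c("a", "b"), 3))
  expect_lt(kt$tie_correction, 1)
  expect_true(kt$p.value > 0 && kt$p.value <= 1)
})

test_that("per-taxon tests rank an injected group shift first", {
  tab <- separated_table()
  kw <- kw_all_taxa(tab)
  expect_identical(kw$taxon[1], "marker")
  expect_lt(kw$p[1], 0.01)
  # constant taxon reported as degenerate, not dropped silently
  tab$counts <- rbind(tab$counts,
                      flat = rep(5L, 14))
  kw2 <- kw_all_taxa(tab)
  expect_identical(kw2$note[kw2$taxon == "flat"], "degenerate")
  expect_true(is.na(kw2$p[kw2$taxon == "flat"]))
  kw3 <- kw_all_taxa(tab, adjust = "BH")
  expect_true(all(kw3$p_adjusted >= kw3$p, na.rm = TRUE))
})

test_that("Wilks' lambda equals det(W)/det(T) on hand-checked cases", {
  X <- matrix(c(1, 2, 3, 4, 5, 6), ncol = 1, dimnames = list(NULL, "x"))
  g <- rep(c("a", "b"), each = 3)
  # SSW = 2 + 2, SST = 17.5
  expect_equal(wilks_lambda(X, g), 4 / 17.5, tolerance = 1e-12)
  # equal group means with within-group spread: no separation, lambda = 1
  X2 <- matrix(c(1, 3, 1, 3), ncol = 1, dimnames = list(NULL, "x"))
  expect_equal(wilks_lambda(X2, c("a", "a", "b", "b")), 1, tolerance = 1e-12)
  expect_error(wilks_lambda(matrix(rep(2, 6), ncol = 1,
                                   dimnames = list(NULL, "x")), g),
               "singular")
})

test_that("Wilks' lambda agrees with manova and equals 1 - R^2 univariately", {
  set.seed(41)
  for (i in 1:5) {
    X <- matrix(rnorm(24), ncol = 3,
                dimnames = list(NULL, c("a", "b", "c")))
    g <- rep(c("x", "y"), each = 4)
    lam <- wilks_lambda(X, g)
    fit <- summary(stats::manova(X ~ factor(g)), test = "Wilks")
    expect_equal(lam, fit$stats[1, "Wilks"], tolerance = 1e-8)
    r2 <- summary(stats::lm(X[, 1] ~ factor(g)))$r.squared
    expect_equal(wilks_lambda(X, g, "a"), 1 - r2, tolerance = 1e-10)
  }
})

test_that("lambda never increases as predictors are added", {
  set.seed(42)
  for (i in 1:10) {
    X <- matrix(rnorm(30), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
    g <- rep(c("x", "y"), each = 5)
    l1 <- wilks_lambda(X, g, "a")
    l2 <- wilks_lambda(X, g, c("a", "b"))
    l3 <- wilks_lambda(X, g, c("a", "b", "c"))
    expect_lte(l2, l1 + 1e-10)
    expect_lte(l3, l2 + 1e-10)
  }
})

test_that("a dominant separator enters first, matching exhaustive search", {
  tab <- separated_table()
  fit <- stepwise_da(tab)
  expect_s3_class(fit, "stepwise_da")
  expect_identical(fit$trace$predictor[1], "marker")
  X <- t(tab$counts); g <- sample_groups(tab)
  lams <- vapply(colnames(X), function(v) wilks_lambda(X, g, v), numeric(1))
  expect_identical(fit$trace$predictor[1], names(which.min(lams)))
  expect_true(all(diff(fit$trace$lambda[fit$trace$action == "enter"]) <= 1e-10))
  # deterministic trace
  expect_identical(fit$trace, stepwise_da(tab)$trace)
})

test_that("Bartlett's chi-squared matches the hand computation", {
  X <- matrix(c(1, 2, 3, 4, 5, 6), ncol = 1, dimnames = list(NULL, "x"))
  g <- rep(c("a", "b"), each = 3)
  fit <- stepwise_da(X, g)
  expect_identical(fit$selected, "x")
  expect_equal(fit$lambda, 4 / 17.5, tolerance = 1e-12)
  expect_equal(fit$chisq, -(6 - 1 - 1.5) * log(4 / 17.5), tolerance = 1e-12)
  expect_equal(fit$chisq, 5.166, tolerance = 1e-3)
  expect_identical(fit$df, 1)
})

test_that("an unseparable table yields an empty model with a warning", {
  X <- matrix(c(1, 3, 1.1, 3.1, 0.9, 3, 1, 2.9), ncol = 2,
              dimnames = list(NULL, c("a", "b")))
  g <- c("x", "x", "y", "y")
  expect_warning(fit <- stepwise_da(X, g, f_enter = 1e6), "empty")
  expect_length(fit$selected, 0)
  expect_true(is.na(fit$chisq))
})

test_that("leave-one-out accuracy is 1 for separated groups, chance for noise", {
  tab <- separated_table()
  expect_equal(loo_crossvalidate(tab, predictors = "marker"), 1.0)
  # an uninformative constant predictor cannot beat the balanced-chance rate
  X <- cbind(flat = rep(3, 14))
  g <- rep(c("p", "u"), each = 7)
  expect_equal(loo_crossvalidate(X, g, "flat"), 0.5)
  expect_error(loo_crossvalidate(X[1:3, , drop = FALSE], g[c(1, 2, 8)], "flat"),
               "below 2 samples")
})

test_that("fitted models predict training groups and expose coefficients", {
  tab <- separated_table()
  fit <- stepwise_da(tab)
  pred <- predict(fit, tab)
  expect_identical(unname(pred), unname(sample_groups(tab)))
  expect_identical(names(coef(fit)), fit$selected)
  expect_output(print(fit), "Wilks' lambda")
  expect_output(summary(fit), "Stepwise trace")
})
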