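test_that("categorization honours inclusive interior endpoints", {
  specs <- default_category_specs()
  sv <- function(x) as.character(categorize(x, specs$sv_cat))
  expect_equal(sv(150), "91-199")
  expect_equal(sv(91), "91-199")
  expect_equal(sv(199), "91-199")
  expect_equal(sv(90.99), "<91")
  expect_equal(sv(199.01), ">199")
  dbh <- function(x) as.character(categorize(x, specs$dbh_cat))
  expect_equal(dbh(43.5), ">43.4")
  expect_equal(dbh(c(27.1, 43.4)), c("27.1-43.4", "27.1-43.4"))
  tn <- function(x) as.character(categorize(x, specs$tn_cat))
  expect_equal(tn(c(19, 20, 21)), c("<20", ">=20", ">=20"))
  alt <- function(x) as.character(categorize(x, specs$alt_cat))
  expect_equal(alt(c(499, 500, 1000, 1001)), c("low", "medium", "medium", "high"))
  expect_warning(out <- categorize(c(10, NA), specs$sv_cat), "missing")
  expect_true(is.na(out[2]))
  expect_error(category_spec("x", c(5, 5), c("a", "b", "c")), "increasing")
  expect_error(category_spec("x", c(1, 2), c("a", "b")), "one more label")
})

test_that("sum-contrast design: effects sum to zero, intercept is grand level mean", {
  # 12-row balanced toy table, checked against a one-hot OLS oracle
  dat <- data.frame(
    y = c(10, 12, 20, 22, 30, 32, 11, 13, 21, 23, 31, 33),
    f = factor(rep(rep(c("a", "b", "c"), each = 2), 2))
  )
  X <- sum_contrast_matrix(dat, "f")
  expect_equal(ncol(X), 3) # intercept + 2 contrast columns
  expect_true(all(X[, -1] %in% c(-1, 0, 1)))
  fit <- fit_carbon_model(dat, y ~ f)
  td <- tidy(fit)
  effects <- td$estimate[!is.na(td$factor)]
  expect_equal(sum(effects), 0, tolerance = 1e-10)
  level_means <- tapply(dat$y, dat$f, mean)
  expect_equal(td$estimate[td$term == "(Intercept)"], mean(level_means),
               tolerance = 1e-10)
  # adjusted means recover the crude level means in the balanced one-factor case
  cis <- contrast_cis(fit)
  expect_equal(cis$adjusted_mean, as.numeric(level_means[cis$level]),
               tolerance = 1e-10)
  expect_equal(cis$crude_mean, as.numeric(level_means[cis$level]))
})

test_that("adjusted means and CIs are invariant to level reordering", {
  sim <- simulate_subplots(sim_config(n_subplots = 300, n_outliers = 0), seed = 5)
  fit1 <- fit_carbon_model(sim)
  sim2 <- sim
  sim2$sv_cat <- factor(sim2$sv_cat, levels = rev(levels(sim$sv_cat)))
  sim2$region <- factor(sim2$region, levels = sample(levels(sim$region)))
  fit2 <- fit_carbon_model(sim2)
  for (f in c("sv_cat", "region")) {
    c1 <- contrast_cis(fit1, factors = f)
    c2 <- contrast_cis(fit2, factors = f)
    c2 <- c2[match(c1$level, c2$level), ]
    expect_equal(c1$adjusted_mean, c2$adjusted_mean, tolerance = 1e-10)
    expect_equal(c1$conf.low, c2$conf.low, tolerance = 1e-10)
    expect_equal(c1$conf.high, c2$conf.high, tolerance = 1e-10)
  }
})

test_that("OLS matches the normal-equations oracle on toy designs", {
  for (seed in 1:10) {
    dat <- random_toy_factors(n = sample(15:50, 1), seed = seed)
    fit <- fit_carbon_model(dat, y ~ f1 + f2)
    X <- sum_contrast_matrix(dat, c("f1", "f2"))
    oracle <- ols_oracle(X, dat$y)
    expect_equal(unname(coef(fit$lm)), unname(oracle$coef), tolerance = 1e-8)
    s <- summary(fit$lm)
    expect_equal(unname(s$coefficients[, "Std. Error"]), unname(oracle$se),
                 tolerance = 1e-8)
    expect_equal(unname(s$coefficients[, "Pr(>|t|)"]), unname(oracle$p),
                 tolerance = 1e-8)
    expect_equal(s$adj.r.squared, oracle$adj_r2, tolerance = 1e-10)
    expect_equal(unname(residuals(fit)), unname(oracle$resid), tolerance = 1e-8)
  }
})

test_that("a perfect linear structure fits exactly", {
  dat <- expand.grid(f1 = factor(c("a", "b", "c")), f2 = factor(c("u", "v")))
  dat <- dat[rep(seq_len(nrow(dat)), 4), ]
  eff1 <- c(a = 0, b = 5, c = 9)
  eff2 <- c(u = 0, v = -3)
  dat$y <- 40 + eff1[dat$f1] + eff2[dat$f2]
  fit <- fit_carbon_model(dat, y ~ f1 + f2)
  expect_equal(unname(residuals(fit)), rep(0, nrow(dat)), tolerance = 1e-10)
  g <- suppressWarnings(glance(fit)) # summary.lm warns on the perfect fit
  expect_equal(g$r.squared, 1, tolerance = 1e-10)
  expect_equal(g$adj.r.squared, 1, tolerance = 1e-10)
  # residuals of any intercept model sum to zero
  sim <- simulate_subplots(sim_config(n_subplots = 150), seed = 2)
  expect_equal(sum(residuals(fit_carbon_model(sim))), 0, tolerance = 1e-8)
})

test_that("model guards: missing columns, rank deficiency, single levels", {
  sim <- simulate_subplots(sim_config(n_subplots = 120, n_outliers = 0), seed = 9)
  expect_error(fit_carbon_model(sim, carbon_tC_ha ~ nope), "not found")
  # an aliased copy of a factor makes the design rank deficient
  sim$sv_copy <- sim$sv_cat
  expect_error(fit_carbon_model(sim, carbon_tC_ha ~ sv_cat + sv_copy),
               "rank deficient")
  sim$constant <- factor("only")
  expect_warning(fit <- fit_carbon_model(sim, carbon_tC_ha ~ sv_cat + constant),
                 "single level")
  expect_false("constant" %in% fit$factors)
  sim$carbon_tC_ha[3] <- NA
  expect_warning(fit_carbon_model(sim, carbon_tC_ha ~ sv_cat), "missing values excluded")
})

test_that("QQ coordinates use the (i - 1/2)/n plotting positions", {
  r <- c(3, -1, 2)
  qq <- qq_residuals(r)
  expect_equal(qq$theoretical, qnorm((1:3 - 0.5) / 3))
  expect_equal(qq$sample, sort((r - mean(r)) / sd(r)))
  # a symmetric residual set gives a point set symmetric about the origin
  r <- c(-5, -2, -1, 1, 2, 5)
  qq <- qq_residuals(r)
  expect_equal(qq$sample, -rev(qq$sample), tolerance = 1e-12)
  expect_equal(qq$theoretical, -rev(qq$theoretical), tolerance = 1e-12)
  # zero-variance residuals are handled without error
  qq0 <- qq_residuals(rep(2, 5))
  expect_equal(qq0$sample, rep(0, 5))
  expect_error(qq_residuals(c(1, 2)), "at least 3")
})

test_that("standard-normal residuals hug the QQ diagonal", {
  set.seed(123)
  qq <- qq_residuals(rnorm(1e4))
  central <- abs(qq$theoretical) < qnorm(0.99)
  expect_true(all(abs(qq$sample[central] - qq$theoretical[central]) < 0.1))
})

test_that("outlier pass removes exactly the planted high residuals once", {
  cfg <- sim_config(n_subplots = 300, residual_sd = 5, n_outliers = 10,
                    outlier_magnitude = 60)
  sim <- simulate_subplots(cfg, seed = 21)
  fit <- fit_carbon_model(sim)
  refit <- outlier_refit(fit, threshold = 40)
  expect_equal(refit$n_removed, 10)
  expect_setequal(refit$removed$subplot_id,
                  sim$subplot_id[attr(sim, "truth")$outlier_rows])
  expect_equal(nrow(refit$final$data), 290)
  # one pass only: the final fit keeps whatever residuals remain
  expect_identical(nrow(refit$final$data) + refit$n_removed, nrow(sim))
})

test_that("outlier pass is a no-op when nothing exceeds the threshold", {
  sim <- simulate_subplots(sim_config(n_subplots = 200, n_outliers = 0,
                                      residual_sd = 5), seed = 3)
  fit <- fit_carbon_model(sim)
  refit <- outlier_refit(fit, threshold = 40)
  expect_equal(refit$n_removed, 0)
  expect_identical(coef(refit$final$lm), coef(fit$lm))
  expect_error(outlier_refit(fit, threshold = -1), "positive")
})

test_that("one-sided rule keeps large negative residuals; two-sided drops them", {
  sim <- simulate_subplots(sim_config(n_subplots = 250, n_outliers = 0,
                                      residual_sd = 5), seed = 8)
  sim$carbon_tC_ha[1] <- sim$carbon_tC_ha[1] - 80 # gross negative error
  fit <- fit_carbon_model(sim)
  up <- outlier_refit(fit, threshold = 40, side = "upper")
  expect_equal(up$n_removed, 0)
  both <- outlier_refit(fit, threshold = 40, side = "both")
  expect_equal(both$n_removed, 1)
  expect_equal(both$removed$subplot_id, sim$subplot_id[1])
})

test_that("removal that would empty a factor level aborts", {
  # both records of the sparse level "c" sit +/-100 from their level mean,
  # so a two-sided pass would strip the whole level
  dat <- data.frame(
    y = c(rep(10, 12), 0, 200),
    f = factor(c(rep(c("a", "b"), 6), "c", "c"))
  )
  fit <- fit_carbon_model(dat, y ~ f)
  expect_error(outlier_refit(fit, threshold = 40, side = "both"), "empties level")
})

test_that("contrast CIs match the c'(X'X)^-1 c variance oracle", {
  dat <- random_toy_factors(n = 40, seed = 77)
  fit <- fit_carbon_model(dat, y ~ f1 + f2)
  X <- sum_contrast_matrix(dat, c("f1", "f2"))
  oracle <- ols_oracle(X, dat$y)
  cis <- contrast_cis(fit, factors = "f1")
  # build the oracle linear combinations: intercept + each level's effect
  combos <- rbind(c(1, 1, 0, 0), c(1, 0, 1, 0), c(1, -1, -1, 0))
  df <- nrow(X) - ncol(X)
  for (l in 1:3) {
    cc <- combos[l, ]
    est <- sum(cc * oracle$coef)
    se <- sqrt(drop(t(cc) %*% oracle$XtX_inv %*% cc) * oracle$s2)
    expect_equal(cis$adjusted_mean[l], est, tolerance = 1e-10)
    expect_equal(cis$conf.low[l], est - qt(0.975, df) * se, tolerance = 1e-10)
    expect_equal(cis$conf.high[l], est + qt(0.975, df) * se, tolerance = 1e-10)
  }
  # level effects (adjusted mean - intercept) sum to zero within each factor
  for (f in c("f1", "f2")) {
    ci <- contrast_cis(fit, factors = f)
    expect_equal(sum(ci$adjusted_mean - oracle$coef[1]), 0, tolerance = 1e-10)
  }
})

test_that("contrast CIs agree with an independent marginal-means package", {
  skip_if_not_installed("emmeans")
  sim <- simulate_subplots(sim_config(n_subplots = 250, n_outliers = 0), seed = 13)
  fit <- fit_carbon_model(sim)
  for (f in c("sv_cat", "tn_cat", "region")) {
    em <- as.data.frame(emmeans::emmeans(fit$lm, f))
    ci <- contrast_cis(fit, factors = f)
    em <- em[match(ci$level, as.character(em[[f]])), ]
    expect_equal(ci$adjusted_mean, em$emmean, tolerance = 1e-8)
    expect_equal(ci$conf.low, em$lower.CL, tolerance = 1e-8)
    expect_equal(ci$conf.high, em$upper.CL, tolerance = 1e-8)
  }
})

test_that("CI trichotomy is exhaustive, exclusive, and boundary-safe", {
  expect_equal(classify_ci(80, 90, 75), "above")
  expect_equal(classify_ci(70, 80, 75), "around")
  expect_equal(classify_ci(60, 70, 75), "below")
  # endpoints equal to the mean are 'around' by convention
  expect_equal(classify_ci(75, 80, 75), "around")
  expect_equal(classify_ci(70, 75, 75), "around")
  set.seed(4)
  lo <- runif(200, 0, 100); hi <- lo + runif(200, 0, 30)
  cls <- classify_ci(lo, hi, 50)
  expect_true(all(cls %in% c("above", "around", "below")))
  expect_equal(cls == "above", lo > 50)
  expect_equal(cls == "below", hi < 50)
  expect_error(classify_ci(10, 5, 7), "exceed")
})

test_that("baseline-style coefficients are differences from the first level", {
  sim <- simulate_subplots(sim_config(n_subplots = 300, n_outliers = 0), seed = 31)
  fit <- fit_carbon_model(sim)
  td_sum <- tidy(fit, type = "sum")
  td_base <- tidy(fit, type = "baseline")
  for (f in fit$factors) {
    eff <- td_sum$estimate[td_sum$factor %in% f]
    base <- td_base$estimate[td_base$factor %in% f]
    expect_equal(base, eff - eff[1], tolerance = 1e-10)
  }
  # reference rows carry no inference
  refs <- td_base[!is.na(td_base$factor) & td_base$estimate == 0, ]
  expect_true(all(is.na(refs$std.error)))
})
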