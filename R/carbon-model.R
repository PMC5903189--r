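#' Sum-contrast design matrix
#'
#' Builds the model matrix of an additive factor model with sum-to-zero
#' (deviation) contrasts: each L-level factor contributes L - 1 columns
#' coded +1 / 0 / -1 so the implied level effects sum to zero and the
#' intercept is the grand mean of level means. Single-level factors are
#' dropped with a warning.
#'
#' @param data Data frame holding the factors.
#' @param factors Character vector of factor column names.
#' @return The numeric model matrix (with `assign` and `contrasts`
#'   attributes as from [stats::model.matrix()]).
#' @export
sum_contrast_matrix <- function(data, factors) {
  data <- as.data.frame(data)
  keep <- character(0)
  for (f in factors) {
    data[[f]] <- droplevels(as.factor(data[[f]]))
    if (nlevels(data[[f]]) < 2) {
      warning("factor `", f, "` has a single level and is dropped", call. = FALSE)
    } else {
      keep <- c(keep, f)
    }
  }
  if (length(keep) == 0) stop("no usable factors", call. = FALSE)
  fml <- stats::reformulate(keep)
  ctr <- stats::setNames(replicate(length(keep), "contr.sum", simplify = FALSE), keep)
  stats::model.matrix(fml, data, contrasts.arg = ctr)
}

#' Fit the additive carbon factor model
#'
#' Ordinary least squares of subplot carbon (tC/ha) on categorized stand
#' and site factors, \eqn{y = \beta_0 + \beta_1 x_1 + \dots + \beta_n x_n +
#' \varepsilon}, with sum-to-zero contrasts on every factor so each level's
#' effect is a deviation from the grand level mean. Records with missing
#' values are excluded with a warning; single-level factors are dropped
#' with a warning; a rank-deficient design aborts, naming the aliased
#' columns.
#'
#' @param data Data frame of subplot summaries, typically from
#'   [aggregate_subplots()] + [apply_categories()] or
#'   [simulate_subplots()].
#' @param formula Model formula; the default uses the standard six factors.
#' @return A `carbon_fit` object (see [tidy.carbon_fit()],
#'   [glance.carbon_fit()], [contrast_cis()], [outlier_refit()]).
#' @examples
#' sim <- simulate_subplots(sim_config(n_subplots = 200, n_outliers = 0), seed = 1)
#' fit <- fit_carbon_model(sim)
#' glance(fit)
#' @export
fit_carbon_model <- function(data,
                             formula = carbon_tC_ha ~ sv_cat + dbh_cat +
                               tn_cat + alt_cat + region + ownership) {
  data <- as.data.frame(data)
  vars <- all.vars(formula)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols) > 0) {
    stop("columns not found in `data`: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  response <- vars[1]
  rhs <- vars[-1]

  complete <- stats::complete.cases(data[vars])
  if (!all(complete)) {
    warning(sum(!complete), " record(s) with missing values excluded", call. = FALSE)
    data <- data[complete, , drop = FALSE]
  }

  keep <- character(0)
  for (f in rhs) {
    data[[f]] <- droplevels(as.factor(data[[f]]))
    if (nlevels(data[[f]]) < 2) {
      warning("factor `", f, "` has a single level and is dropped", call. = FALSE)
    } else {
      keep <- c(keep, f)
    }
  }
  if (length(keep) == 0) stop("no usable factors on the right-hand side", call. = FALSE)
  formula <- stats::reformulate(keep, response = response)
  ctr <- stats::setNames(replicate(length(keep), "contr.sum", simplify = FALSE), keep)

  lm_fit <- stats::lm(formula, data = data, contrasts = ctr)
  if (anyNA(stats::coef(lm_fit))) {
    stop("design matrix is rank deficient; aliased columns: ",
         paste(names(stats::coef(lm_fit))[is.na(stats::coef(lm_fit))],
               collapse = ", "), call. = FALSE)
  }
  if (stats::df.residual(lm_fit) < 1) {
    stop("not enough observations for the number of model columns", call. = FALSE)
  }

  structure(
    list(lm = lm_fit, data = tibble::as_tibble(data), formula = formula,
         response = response, factors = keep),
    class = "carbon_fit"
  )
}

# column indices of each factor's contrast columns in the model matrix
factor_columns <- function(fit) {
  mm <- stats::model.matrix(fit$lm)
  asgn <- attr(mm, "assign")
  labs <- attr(stats::terms(fit$lm), "term.labels")
  stats::setNames(lapply(seq_along(labs), function(i) which(asgn == i)), labs)
}

# all-level sum-contrast effects of one factor, with the linear-combination
# rows needed for their standard errors (last level = minus the sum)
effect_rows <- function(fit, factor) {
  cols <- factor_columns(fit)[[factor]]
  p <- length(stats::coef(fit$lm))
  lev <- levels(fit$data[[factor]])
  L <- length(lev)
  rows <- matrix(0, nrow = L, ncol = p)
  for (l in seq_len(L - 1)) rows[l, cols[l]] <- 1
  rows[L, cols] <- -1
  list(levels = lev, rows = rows)
}

# estimate / SE / t / p for rows of linear combinations c'beta
lincomb_inference <- function(fit, rows, conf_level = 0.95) {
  beta <- stats::coef(fit$lm)
  V <- stats::vcov(fit$lm)
  est <- drop(rows %*% beta)
  se <- sqrt(rowSums((rows %*% V) * rows))
  df <- stats::df.residual(fit$lm)
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df)
  tibble::tibble(
    estimate = est, std.error = se,
    statistic = est / se,
    p.value = 2 * stats::pt(abs(est / se), df, lower.tail = FALSE),
    conf.low = est - tcrit * se, conf.high = est + tcrit * se
  )
}

#' Tidy the carbon factor model
#'
#' Coefficient table of a [fit_carbon_model()] fit. `type = "sum"` reports
#' the sum-to-zero level effects (all levels, the last recovered as minus
#' the sum of the others, each with its own standard error). `type =
#' "baseline"` reports each level's difference from the factor's first
#' level, the treatment-style scale coefficient tables are usually printed
#' on; reference levels appear with estimate 0 and no inference.
#'
#' @param x A `carbon_fit` object.
#' @param type `"sum"` (default) or `"baseline"`.
#' @param conf_level Confidence level for the interval columns.
#' @param ... Unused.
#' @return A tibble with `term`, `factor`, `level`, `estimate`,
#'   `std.error`, `statistic`, `p.value`, `conf.low`, `conf.high`.
#' @method tidy carbon_fit
#' @export
tidy.carbon_fit <- function(x, type = c("sum", "baseline"), conf_level = 0.95, ...) {
  type <- match.arg(type)
  p <- length(stats::coef(x$lm))
  intercept_row <- matrix(c(1, rep(0, p - 1)), nrow = 1)
  out <- dplyr::bind_cols(
    tibble::tibble(term = "(Intercept)", factor = NA_character_,
                   level = NA_character_),
    lincomb_inference(x, intercept_row, conf_level)
  )
  for (f in x$factors) {
    er <- effect_rows(x, f)
    L <- length(er$levels)
    if (type == "sum") {
      inf <- lincomb_inference(x, er$rows, conf_level)
      block <- dplyr::bind_cols(
        tibble::tibble(term = paste(f, er$levels, sep = ":"),
                       factor = f, level = er$levels),
        inf
      )
    } else {
      diff_rows <- er$rows[-1, , drop = FALSE] -
        matrix(er$rows[1, ], nrow = L - 1, ncol = p, byrow = TRUE)
      inf <- lincomb_inference(x, diff_rows, conf_level)
      ref <- tibble::tibble(
        term = paste(f, er$levels[1], sep = ":"), factor = f,
        level = er$levels[1], estimate = 0, std.error = NA_real_,
        statistic = NA_real_, p.value = NA_real_,
        conf.low = NA_real_, conf.high = NA_real_
      )
      block <- dplyr::bind_rows(
        ref,
        dplyr::bind_cols(
          tibble::tibble(term = paste(f, er$levels[-1], sep = ":"),
                         factor = f, level = er$levels[-1]),
          inf
        )
      )
    }
    out <- dplyr::bind_rows(out, block)
  }
  out
}

#' One-row summary of the carbon factor model
#'
#' @param x A `carbon_fit`.
#' @param ... Unused.
#' @return Tibble with `r.squared`, `adj.r.squared`, `sigma`, `statistic`,
#'   `p.value`, `df`, `df.residual`, `nobs`.
#' @method glance carbon_fit
#' @export
glance.carbon_fit <- function(x, ...) {
  s <- summary(x$lm)
  fstat <- s$fstatistic
  tibble::tibble(
    r.squared = s$r.squared,
    adj.r.squared = s$adj.r.squared,
    sigma = s$sigma,
    statistic = if (is.null(fstat)) NA_real_ else unname(fstat[1]),
    p.value = if (is.null(fstat)) NA_real_ else
      stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE),
    df = unname(if (is.null(fstat)) NA_real_ else fstat[2]),
    df.residual = stats::df.residual(x$lm),
    nobs = stats::nobs(x$lm)
  )
}

#' @export
print.carbon_fit <- function(x, ...) {
  cat("Additive carbon factor model (sum contrasts)\n")
  cat("  ", deparse(x$formula), "\n", sep = "")
  cat("  n =", stats::nobs(x$lm),
      " adj R^2 =", round(summary(x$lm)$adj.r.squared, 4), "\n")
  invisible(x)
}

#' @export
residuals.carbon_fit <- function(object, ...) stats::residuals(object$lm)

#' Residual QQ coordinates
#'
#' Pairs each sorted standardized residual with its theoretical normal
#' quantile at the plotting position \eqn{(i - 0.5)/n}, for normality
#' assessment before and after outlier removal. Residuals are standardized
#' by their sample mean and standard deviation; a zero-variance residual
#' vector maps to all-zero standardized values.
#'
#' @param residuals Numeric residual vector (length >= 3), or a
#'   `carbon_fit` whose residuals are used.
#' @return Tibble with `theoretical` and `sample` columns, sorted.
#' @export
qq_residuals <- function(residuals) {
  if (inherits(residuals, "carbon_fit")) residuals <- residuals(residuals)
  if (length(residuals) < 3) stop("need at least 3 residuals", call. = FALSE)
  n <- length(residuals)
  s <- stats::sd(residuals)
  z <- if (s > 0) (residuals - mean(residuals)) / s else rep(0, n)
  tibble::tibble(
    theoretical = stats::qnorm((seq_len(n) - 0.5) / n),
    sample = sort(z)
  )
}

#' Remove high-residual records and refit once
#'
#' One pass of residual-threshold outlier handling: fit, drop every record
#' whose raw residual exceeds `+threshold` (one-sided by default, matching
#' the practice of trimming only the upper extreme of the QQ plot;
#' `side = "both"` trims `|residual| > threshold`), and refit once on the
#' remainder. The pass is not iterated. Aborts if the removal empties a
#' factor level.
#'
#' @param fit A [fit_carbon_model()] object.
#' @param threshold Residual threshold in outcome units (tC/ha); default 40.
#' @param side `"upper"` (default) or `"both"`.
#' @return A `carbon_refit` object: list with `initial` and `final`
#'   `carbon_fit`s, `n_removed`, `removed` (the dropped rows), `threshold`,
#'   `side`. `tidy()`, `glance()`, `contrast_cis()` etc. act on the final fit.
#' @examples
#' sim <- simulate_subplots(sim_config(n_subplots = 200), seed = 1)
#' refit <- outlier_refit(fit_carbon_model(sim))
#' refit$n_removed
#' @export
outlier_refit <- function(fit, threshold = 40, side = c("upper", "both")) {
  stopifnot(inherits(fit, "carbon_fit"))
  side <- match.arg(side)
  if (!is.numeric(threshold) || threshold <= 0) {
    stop("`threshold` must be positive", call. = FALSE)
  }
  r <- stats::residuals(fit$lm)
  drop_idx <- if (side == "upper") which(r > threshold) else which(abs(r) > threshold)

  if (length(drop_idx) == 0) {
    final <- fit
  } else {
    kept <- fit$data[-drop_idx, , drop = FALSE]
    for (f in fit$factors) {
      lost <- setdiff(levels(fit$data[[f]]), unique(as.character(kept[[f]])))
      if (length(lost) > 0) {
        stop("outlier removal empties level(s) of `", f, "`: ",
             paste(lost, collapse = ", "), call. = FALSE)
      }
    }
    final <- fit_carbon_model(kept, formula = fit$formula)
  }

  structure(
    list(initial = fit, final = final,
         n_removed = length(drop_idx),
         removed = fit$data[drop_idx, , drop = FALSE],
         threshold = threshold, side = side),
    class = "carbon_refit"
  )
}

#' @export
print.carbon_refit <- function(x, ...) {
  cat("Outlier removal-and-refit (residual >", x$threshold,
      if (x$side == "upper") "one-sided" else "two-sided", ")\n")
  cat("  removed", x$n_removed, "of", nrow(x$initial$data),
      "records; final n =", stats::nobs(x$final$lm), "\n")
  invisible(x)
}

#' @rdname tidy.carbon_fit
#' @method tidy carbon_refit
#' @export
tidy.carbon_refit <- function(x, ...) tidy.carbon_fit(x$final, ...)

#' @rdname glance.carbon_fit
#' @method glance carbon_refit
#' @export
glance.carbon_refit <- function(x, ...) {
  dplyr::mutate(glance.carbon_fit(x$final), n_removed = x$n_removed)
}

#' @export
residuals.carbon_refit <- function(object, ...) stats::residuals(object$final$lm)

#' Classify a confidence interval against the overall mean
#'
#' The trichotomy used to read factor-level confidence intervals: an
#' interval entirely above the overall mean is `"above"`, entirely below is
#' `"below"`, anything touching or straddling it (including an endpoint
#' exactly equal to the mean) is `"around"`.
#'
#' @param conf_low,conf_high Interval endpoints. Vectorised.
#' @param overall_mean The reference mean.
#' @return Character vector in `c("above", "around", "below")`.
#' @examples
#' classify_ci(c(80, 70, 60), c(90, 80, 70), 75)
#' @export
classify_ci <- function(conf_low, conf_high, overall_mean) {
  if (any(conf_low > conf_high, na.rm = TRUE)) {
    stop("`conf_low` must not exceed `conf_high`", call. = FALSE)
  }
  dplyr::case_when(
    conf_low > overall_mean ~ "above",
    conf_high < overall_mean ~ "below",
    .default = "around"
  )
}

#' Adjusted level means with confidence intervals and classification
#'
#' For each level of each factor, the model-adjusted mean carbon stock
#' (intercept + sum-contrast level effect, all other factors held at their
#' contrast-balanced baseline), its t-based confidence interval from the
#' linear-combination variance \eqn{c'(X'X)^{-1}c\,s^2}, the crude level
#' mean from the analysed data, and the above/around/below classification
#' of the interval against the overall mean of the analysed outcome.
#'
#' @param fit A `carbon_fit` or `carbon_refit` (its final fit is used).
#' @param factors Factors to report (default: all in the model).
#' @param conf_level Confidence level (default 0.95).
#' @return Tibble with `factor`, `level`, `n`, `adjusted_mean`, `conf.low`,
#'   `conf.high`, `crude_mean`, `classification`; the overall mean is
#'   attached as attribute `overall_mean`.
#' @examples
#' sim <- simulate_subplots(sim_config(n_subplots = 300), seed = 2)
#' fit <- outlier_refit(fit_carbon_model(sim))
#' contrast_cis(fit, factors = "sv_cat")
#' @export
contrast_cis <- function(fit, factors = NULL, conf_level = 0.95) {
  if (inherits(fit, "carbon_refit")) fit <- fit$final
  stopifnot(inherits(fit, "carbon_fit"))
  if (is.null(factors)) factors <- fit$factors
  bad <- setdiff(factors, fit$factors)
  if (length(bad) > 0) {
    stop("factor(s) not in the model: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  y <- fit$data[[fit$response]]
  overall <- mean(y)
  p <- length(stats::coef(fit$lm))

  out <- purrr::map(factors, function(f) {
    er <- effect_rows(fit, f)
    rows <- er$rows
    rows[, 1] <- 1 # adjusted mean = intercept + level effect
    inf <- lincomb_inference(fit, rows, conf_level)
    crude <- tapply(y, fit$data[[f]], mean)
    nlev <- tapply(y, fit$data[[f]], length)
    tibble::tibble(
      factor = f, level = er$levels,
      n = as.integer(nlev[er$levels]),
      adjusted_mean = inf$estimate,
      conf.low = inf$conf.low, conf.high = inf$conf.high,
      crude_mean = as.numeric(crude[er$levels]),
      classification = classify_ci(inf$conf.low, inf$conf.high, overall)
    )
  })
  out <- dplyr::bind_rows(out)
  attr(out, "overall_mean") <- overall
  out
}
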