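#' Fit height-diameter curves by species group
#'
#' Fits a two-parameter saturating height-diameter curve
#' \eqn{h = 1.3 + A\,(1 - e^{-k\,d})} to the height-sampled trees of each
#' species group by nonlinear least squares. The 1.3 m offset is breast
#' height, so predicted heights always exceed the measurement height and
#' increase strictly with dbh. Groups with fewer than `min_obs` height
#' observations, or whose fit fails to converge, fall back to a single
#' pooled curve fitted to all height-sampled trees (with a warning); if
#' even the pooled fit is impossible the fit aborts.
#'
#' @param trees Data frame of trees with at least `dbh_cm` and `height_m`
#'   (height may be `NA` for trees that were not height-sampled; those rows
#'   are dropped) and the grouping column.
#' @param group Name of the grouping column (default `"hd_group"`). Use a
#'   constant column to fit one curve to everything.
#' @param min_obs Minimum height observations a group needs for its own
#'   curve (default 10).
#' @return An object of class `hd_model`: a list with `curves` (tibble of
#'   per-group `asymptote_m`, `rate_per_cm`, `n`, `pooled` flag),
#'   `pooled` (the fallback curve), and `group` (the grouping column name).
#' @examples
#' trees <- data.frame(
#'   dbh_cm = seq(5, 80, length.out = 60),
#'   height_m = 1.3 + 28 * (1 - exp(-0.05 * seq(5, 80, length.out = 60))),
#'   hd_group = "all"
#' )
#' fit <- fit_height_diameter(trees)
#' predict(fit, dbh_cm = 30, group = "all")
#' @export
fit_height_diameter <- function(trees, group = "hd_group", min_obs = 10) {
  stopifnot(is.data.frame(trees))
  if (!group %in% names(trees)) {
    stop("grouping column `", group, "` not found", call. = FALSE)
  }
  obs <- dplyr::filter(trees, !is.na(.data$height_m), !is.na(.data$dbh_cm))
  if (nrow(obs) < 3) {
    stop("need at least 3 height observations to fit a height-diameter curve",
         call. = FALSE)
  }

  fit_one <- function(d, h) {
    start <- list(A = max(max(h) - 1.3, 1), k = 0.05)
    fit <- try(minpack.lm::nlsLM(
      h ~ 1.3 + A * (1 - exp(-k * d)),
      start = start,
      lower = c(A = 1e-3, k = 1e-5),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ), silent = TRUE)
    if (inherits(fit, "try-error")) return(NULL)
    cf <- stats::coef(fit)
    list(A = unname(cf[["A"]]), k = unname(cf[["k"]]),
         sigma = stats::sigma(fit))
  }

  pooled <- fit_one(obs$dbh_cm, obs$height_m)
  if (is.null(pooled)) {
    stop("pooled height-diameter fit failed to converge", call. = FALSE)
  }

  groups <- split(obs, obs[[group]])
  curves <- purrr::imap(groups, function(g, name) {
    fit <- if (nrow(g) >= min_obs) fit_one(g$dbh_cm, g$height_m) else NULL
    if (is.null(fit)) {
      tibble::tibble(group = name, asymptote_m = pooled$A,
                     rate_per_cm = pooled$k, resid_sd_m = pooled$sigma,
                     n = nrow(g), pooled = TRUE)
    } else {
      tibble::tibble(group = name, asymptote_m = fit$A, rate_per_cm = fit$k,
                     resid_sd_m = fit$sigma, n = nrow(g), pooled = FALSE)
    }
  })
  curves <- dplyr::bind_rows(curves)
  if (any(curves$pooled)) {
    warning("height-diameter groups fitted with the pooled fallback curve: ",
            paste(curves$group[curves$pooled], collapse = ", "), call. = FALSE)
  }
  structure(
    list(curves = curves,
         pooled = tibble::tibble(group = ".pooled", asymptote_m = pooled$A,
                                 rate_per_cm = pooled$k,
                                 resid_sd_m = pooled$sigma,
                                 n = nrow(obs), pooled = TRUE),
         group = group),
    class = "hd_model"
  )
}

#' Predict tree heights from a fitted height-diameter model
#'
#' @param object An [fit_height_diameter()] fit.
#' @param dbh_cm Diameters (cm) to predict at.
#' @param group Group label per tree (recycled if length 1). Unknown groups
#'   use the pooled curve.
#' @param ... Unused.
#' @return Predicted heights (m).
#' @export
predict.hd_model <- function(object, dbh_cm, group = ".pooled", ...) {
  if (length(group) == 1) group <- rep(group, length(dbh_cm))
  stopifnot(length(group) == length(dbh_cm))
  lut <- rbind(object$curves, object$pooled)
  idx <- match(as.character(group), lut$group)
  idx[is.na(idx)] <- nrow(lut) # pooled fallback
  1.3 + lut$asymptote_m[idx] * (1 - exp(-lut$rate_per_cm[idx] * dbh_cm))
}

#' @export
print.hd_model <- function(x, ...) {
  cat("Height-diameter model (h = 1.3 + A(1 - exp(-k d))), ",
      nrow(x$curves), " group(s)\n", sep = "")
  print(x$curves, ...)
  invisible(x)
}

#' Tidy a height-diameter fit
#'
#' @param x An `hd_model` object.
#' @param ... Unused.
#' @return The per-group curve tibble.
#' @method tidy hd_model
#' @export
tidy.hd_model <- function(x, ...) x$curves
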