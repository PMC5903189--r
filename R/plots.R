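#' QQ plot of model residuals
#'
#' Normal quantile-quantile plot of the (standardized) residuals, the
#' diagnostic used to judge the normality assumption and to spot the upper
#' extreme that the outlier pass trims. For a `carbon_refit`, residuals
#' before and after removal are shown side by side.
#'
#' @param fit A `carbon_fit` or `carbon_refit`, or a numeric residual vector.
#' @return A ggplot object.
#' @export
plot_qq <- function(fit) {
  if (inherits(fit, "carbon_refit")) {
    df <- dplyr::bind_rows(
      dplyr::mutate(qq_residuals(stats::residuals(fit$initial$lm)),
                    stage = "before removal"),
      dplyr::mutate(qq_residuals(stats::residuals(fit$final$lm)),
                    stage = "after removal")
    )
    df$stage <- factor(df$stage, levels = c("before removal", "after removal"))
  } else {
    r <- if (inherits(fit, "carbon_fit")) stats::residuals(fit$lm) else fit
    df <- dplyr::mutate(qq_residuals(r), stage = "residuals")
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$theoretical, y = .data$sample)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey40") +
    ggplot2::geom_point(size = 1, alpha = 0.7) +
    ggplot2::facet_wrap(~stage) +
    ggplot2::labs(x = "Theoretical normal quantile",
                  y = "Standardized residual") +
    ggplot2::theme_minimal()
}

#' Confidence-interval plot of adjusted level means
#'
#' The classification display: adjusted means (points) with 95% CIs
#' (vertical bars) per factor level, the overall mean as a horizontal
#' line, and the crude level means as a second point series.
#'
#' @param cis A [contrast_cis()] table (the `overall_mean` attribute is
#'   used for the reference line).
#' @return A ggplot object, faceted by factor.
#' @export
plot_contrast_cis <- function(cis) {
  overall <- attr(cis, "overall_mean")
  ggplot2::ggplot(cis, ggplot2::aes(x = .data$level)) +
    ggplot2::geom_hline(yintercept = overall, colour = "red") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high),
      width = 0.15) +
    ggplot2::geom_point(ggplot2::aes(y = .data$adjusted_mean), size = 2) +
    ggplot2::geom_point(ggplot2::aes(y = .data$crude_mean),
                        colour = "darkgreen", shape = 17, size = 2) +
    ggplot2::facet_wrap(~factor, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "Carbon stock (tC/ha)") +
    ggplot2::theme_minimal()
}

#' @method autoplot carbon_fit
#' @export
autoplot.carbon_fit <- function(object, type = c("qq", "ci"), ...) {
  type <- match.arg(type)
  if (type == "qq") plot_qq(object) else plot_contrast_cis(contrast_cis(object))
}

#' @method autoplot carbon_refit
#' @export
autoplot.carbon_refit <- function(object, type = c("qq", "ci"), ...) {
  type <- match.arg(type)
  if (type == "qq") plot_qq(object) else plot_contrast_cis(contrast_cis(object))
}
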