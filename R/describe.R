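#' Descriptive statistics of subplot summaries
#'
#' Min / max / median / mean / sd (n - 1 denominator) for the standard
#' inventory variables: carbon, stem volume, mean dbh, altitude and tree
#' frequency — the table-style description that usually accompanies an
#' inventory analysis.
#'
#' @param subplots Data frame of subplot summaries.
#' @param variables Columns to describe; defaults to those of the standard
#'   set that are present.
#' @return Tibble with one row per variable: `variable`, `min`, `max`,
#'   `median`, `mean`, `sd`.
#' @examples
#' sim <- simulate_subplots(sim_config(n_subplots = 50), seed = 3)
#' descriptive_table(sim)
#' @export
descriptive_table <- function(subplots,
                              variables = intersect(
                                c("carbon_tC_ha", "stem_volume_m3_ha",
                                  "mean_dbh_cm", "altitude_m", "tree_count"),
                                names(subplots))) {
  stopifnot(is.data.frame(subplots), nrow(subplots) > 0)
  if (length(variables) == 0) stop("no variables to describe", call. = FALSE)
  purrr::map(variables, function(v) {
    x <- subplots[[v]]
    tibble::tibble(
      variable = v,
      min = min(x, na.rm = TRUE),
      max = max(x, na.rm = TRUE),
      median = stats::median(x, na.rm = TRUE),
      mean = mean(x, na.rm = TRUE),
      sd = stats::sd(x, na.rm = TRUE)
    )
  }) |> dplyr::bind_rows()
}

#' Share of a level in a categorical column (or of counts)
#'
#' Percentage of subplots in a given level, e.g. the community-managed
#' share of the forest. Either pass a data frame and column/level, or raw
#' counts via `count` and `total`.
#'
#' @param subplots Data frame (ignored when `count` is given).
#' @param column,level Column and level to tally.
#' @param count,total Direct counts, overriding the data frame.
#' @param digits Decimal places of the percentage (default 2).
#' @return Percentage (0-100), rounded to `digits`.
#' @examples
#' level_share(count = 249, total = 476) # 52.31
#' @export
level_share <- function(subplots = NULL, column = "ownership",
                        level = "community", count = NULL, total = NULL,
                        digits = 2) {
  if (is.null(count)) {
    stopifnot(is.data.frame(subplots), column %in% names(subplots))
    x <- subplots[[column]]
    count <- sum(x == level, na.rm = TRUE)
    total <- sum(!is.na(x))
  }
  if (total <= 0) stop("`total` must be positive", call. = FALSE)
  round(100 * count / total, digits)
}
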