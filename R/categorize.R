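#' Define a categorization rule for a continuous covariate
#'
#' A category spec turns a continuous subplot variable into an ordered
#' factor with `length(breaks) + 1` levels. Interior levels own their
#' endpoints: with breaks `c(91, 199)` the middle level is the closed
#' interval \[91, 199\], the bottom level is `< 91` and the top `> 199`.
#' With a single break (two levels) the boundary belongs to the upper
#' level, i.e. `c(20)` gives `< 20` and `>= 20`.
#'
#' @param variable Column the rule applies to.
#' @param breaks Strictly increasing numeric breakpoints.
#' @param labels Level labels, one more than `breaks`.
#' @param name Name of the derived factor column (default
#'   `paste0(variable, "_cat")`).
#' @return A `category_spec` object.
#' @examples
#' category_spec("stem_volume_m3_ha", c(91, 199),
#'               c("<91", "91-199", ">199"), name = "sv_cat")
#' @export
category_spec <- function(variable, breaks, labels, name = paste0(variable, "_cat")) {
  stopifnot(is.character(variable), length(variable) == 1)
  if (any(diff(breaks) <= 0)) {
    stop("`breaks` must be strictly increasing", call. = FALSE)
  }
  if (length(labels) != length(breaks) + 1) {
    stop("need exactly one more label than breaks", call. = FALSE)
  }
  structure(list(variable = variable, breaks = breaks,
                 labels = as.character(labels), name = name),
            class = "category_spec")
}

#' Categorize a continuous variable
#'
#' Applies a [category_spec()] to a numeric vector. Missing values stay
#' missing (with a warning) so the affected records can be excluded
#' downstream.
#'
#' @param x Numeric vector.
#' @param spec A [category_spec()].
#' @return Factor with the spec's labels as levels.
#' @examples
#' sv <- category_spec("sv", c(91, 199), c("low", "mid", "high"))
#' categorize(c(90, 91, 150, 199, 200), sv)
#' @export
categorize <- function(x, spec) {
  stopifnot(inherits(spec, "category_spec"))
  if (anyNA(x)) {
    warning(sum(is.na(x)), " missing value(s) in `", spec$variable,
            "` cannot be categorized; records should be excluded", call. = FALSE)
  }
  b <- spec$breaks
  nlev <- length(b) + 1
  idx <- findInterval(x, b, left.open = FALSE) + 1L # breakpoints go up
  if (nlev >= 3) {
    # interior levels own their endpoints: the last breakpoint belongs to
    # the level below the top, not the top
    idx[!is.na(x) & x == b[length(b)]] <- nlev - 1L
  }
  factor(spec$labels[idx], levels = spec$labels)
}

#' Default categorization rules for subplot summaries
#'
#' The standard cutpoints for the factor analysis: stem volume at its
#' quartile-based cuts 91 and 199 m^3/ha, mean dbh at 27.1 and 43.4 cm,
#' tree count at 20 stems/subplot, and altitude at 500 and 1000 m.
#'
#' @return Named list of [category_spec()] objects (`sv_cat`, `dbh_cat`,
#'   `tn_cat`, `alt_cat`).
#' @export
default_category_specs <- function() {
  list(
    sv_cat = category_spec("stem_volume_m3_ha", c(91, 199),
                           c("<91", "91-199", ">199"), name = "sv_cat"),
    dbh_cat = category_spec("mean_dbh_cm", c(27.1, 43.4),
                            c("<27.1", "27.1-43.4", ">43.4"), name = "dbh_cat"),
    tn_cat = category_spec("tree_count", 20, c("<20", ">=20"), name = "tn_cat"),
    alt_cat = category_spec("altitude_m", c(500, 1000),
                            c("low", "medium", "high"), name = "alt_cat")
  )
}

#' Add category columns to a subplot table
#'
#' @param data Data frame of subplot summaries.
#' @param specs List of [category_spec()] objects (default
#'   [default_category_specs()]). Specs whose variable is absent from
#'   `data` are skipped with a warning.
#' @return `data` as a tibble with one derived factor column per spec.
#' @export
apply_categories <- function(data, specs = default_category_specs()) {
  data <- tibble::as_tibble(data)
  for (spec in specs) {
    if (!spec$variable %in% names(data)) {
      warning("no column `", spec$variable, "`; skipping its categorization",
              call. = FALSE)
      next
    }
    data[[spec$name]] <- categorize(data[[spec$variable]], spec)
  }
  data
}
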