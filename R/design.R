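#' Area of a circular plot
#'
#' Area of the circle of radius `radius_m`, as used for the nested
#' concentric subplot circles of a forest inventory. Equivalent to
#' \eqn{\pi d^2/4} with diameter \eqn{d = 2r}.
#'
#' @param radius_m Circle radius in metres. Vectorised; must be `>= 0`.
#' @return Area in square metres.
#' @examples
#' circle_area(20) # outermost inventory circle, 1256.6 m^2
#' @export
circle_area <- function(radius_m) {
  if (!is.numeric(radius_m) || anyNA(radius_m) || any(radius_m < 0)) {
    stop("`radius_m` must be non-negative and non-missing", call. = FALSE)
  }
  pi * radius_m^2
}

#' Per-hectare expansion factor of a circular plot
#'
#' Multiplier converting a quantity observed inside a circle of radius
#' `radius_m` into a per-hectare rate: \eqn{10^4 / (\pi r^2)}.
#'
#' @inheritParams circle_area
#' @return Per-hectare expansion factor (dimensionless).
#' @examples
#' expansion_factor(20) # ~7.96 stems/ha per stem counted
#' @export
expansion_factor <- function(radius_m) {
  if (!is.numeric(radius_m) || anyNA(radius_m) || any(radius_m <= 0)) {
    stop("`radius_m` must be strictly positive", call. = FALSE)
  }
  1e4 / (pi * radius_m^2)
}

#' Nested-circle inclusion rules
#'
#' The dbh classes and the radius of the concentric circle in which each
#' class is enumerated. Classes are half-open `[low, high)` so the printed
#' "9.9"-style upper limits leave no gaps; stems below 5 cm dbh are not
#' enumerated.
#'
#' @return A tibble with columns `dbh_low_cm`, `dbh_high_cm`, `radius_m`.
#' @export
concentric_rules <- function() {
  tibble::tibble(
    dbh_low_cm  = c(5, 10, 20, 30),
    dbh_high_cm = c(10, 20, 30, Inf),
    radius_m    = c(4, 8, 15, 20)
  )
}

#' Inclusion radius for a stem of given dbh
#'
#' Radius (m) of the concentric circle in which a stem of diameter
#' `dbh_cm` is enumerated: 4 m for dbh in \[5, 10), 8 m for \[10, 20),
#' 15 m for \[20, 30) and 20 m for 30 cm and above. Stems below the 5 cm
#' caliper limit are not enumerable and return `NA` with a warning.
#'
#' @param dbh_cm Stem diameter at breast height in cm. Vectorised.
#' @return Radius in metres (`NA` for non-enumerable stems).
#' @examples
#' inclusion_radius(c(5, 19.95, 35))
#' @export
inclusion_radius <- function(dbh_cm) {
  if (!is.numeric(dbh_cm)) stop("`dbh_cm` must be numeric", call. = FALSE)
  rules <- concentric_rules()
  idx <- findInterval(dbh_cm, c(rules$dbh_low_cm, Inf))
  out <- ifelse(idx >= 1 & idx <= nrow(rules), rules$radius_m[pmax(idx, 1)], NA_real_)
  out[is.na(dbh_cm)] <- NA_real_
  if (anyNA(out)) {
    warning(sum(is.na(out)), " stem(s) below the 5 cm caliper limit are not enumerable",
            call. = FALSE)
  }
  out
}

#' Systematic 1-in-k selection
#'
#' Selects every k-th unit starting at the first, i.e. indices
#' 1, 1+k, 1+2k, ... <= n. Starting at the first unit is the convention
#' under which a 1-in-8 selection from 999 forest clusters yields 125.
#'
#' @param n Number of units available (positive integer).
#' @param k Sampling interval (positive integer).
#' @return A list with `indices` (integer vector) and `n_selected`
#'   (`== ceiling(n / k)`).
#' @examples
#' select_every_kth(999, 8)$n_selected # 125
#' @export
select_every_kth <- function(n, k) {
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1) {
    stop("`n` must be a positive count", call. = FALSE)
  }
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k < 1) {
    stop("`k` must be a positive integer", call. = FALSE)
  }
  idx <- seq.int(1L, as.integer(n), by = as.integer(k))
  list(indices = idx, n_selected = length(idx))
}

#' Cluster and subplot accounting of a two-phase design
#'
#' Arithmetic of the second sampling phase: from the systematically
#' selected clusters, drop the inaccessible ones and expand to subplots.
#'
#' @param selected Number of clusters selected in phase two.
#' @param inaccessible Number of selected clusters that could not be visited.
#' @param subplots_per_cluster Subplots laid out per cluster (default 6).
#' @param forest_total Optional total number of forest clusters in phase one;
#'   when given, the accessible share of it is reported as a percentage
#'   rounded to 1 decimal place.
#' @return A one-row tibble with `selected`, `inaccessible`, `accessible`,
#'   `subplots` and (if `forest_total` is given) `accessible_pct`.
#' @examples
#' cluster_accounting(125, 4, 6, forest_total = 999)
#' @export
cluster_accounting <- function(selected, inaccessible, subplots_per_cluster = 6,
                               forest_total = NULL) {
  counts <- c(selected, inaccessible, subplots_per_cluster)
  if (!is.numeric(counts) || anyNA(counts) || any(counts < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (inaccessible > selected) {
    stop("`inaccessible` cannot exceed `selected`", call. = FALSE)
  }
  accessible <- selected - inaccessible
  out <- tibble::tibble(
    selected = selected,
    inaccessible = inaccessible,
    accessible = accessible,
    subplots = accessible * subplots_per_cluster
  )
  if (!is.null(forest_total)) {
    out$accessible_pct <- round(100 * accessible / forest_total, 1)
  }
  out
}

#' Subplot layout around a grid knot
#'
#' The six subplots of a cluster form an "N" pattern: two columns 300 m
#' apart (west, then east), three rows 150 m apart, numbered 1-6 south to
#' north up the west column and then up the east column.
#'
#' @param knot_easting,knot_northing Planar coordinates (m) of the 4 km grid
#'   knot the cluster hangs on.
#' @return A tibble with `subplot_number`, `offset_east_m`, `offset_north_m`,
#'   `easting_m`, `northing_m`.
#' @export
layout_subplots <- function(knot_easting = 0, knot_northing = 0) {
  offs <- tidyr::expand_grid(
    offset_east_m = c(0, 300),
    offset_north_m = c(0, 150, 300)
  )
  offs <- dplyr::arrange(offs, .data$offset_east_m, .data$offset_north_m)
  dplyr::mutate(offs,
    subplot_number = dplyr::row_number(),
    easting_m = knot_easting + .data$offset_east_m,
    northing_m = knot_northing + .data$offset_north_m,
    .before = 1
  )
}

#' Print the sampling-design accounting
#'
#' Convenience summary of the full phase-two arithmetic: systematic 1-in-k
#' selection from the forest clusters, loss of inaccessible clusters, and
#' expansion to subplots.
#'
#' @param n_forest_clusters Forest clusters available in phase one.
#' @param k Systematic sampling interval.
#' @param inaccessible Selected clusters that could not be reached.
#' @param subplots_per_cluster Subplots per cluster.
#' @return A one-row tibble (invisibly printed components: selected,
#'   accessible, subplots, accessible percentage of forest clusters).
#' @examples
#' design_summary(999, 8, 4)
#' @export
design_summary <- function(n_forest_clusters, k = 8, inaccessible = 0,
                           subplots_per_cluster = 6) {
  sel <- select_every_kth(n_forest_clusters, k)
  cluster_accounting(sel$n_selected, inaccessible, subplots_per_cluster,
                     forest_total = n_forest_clusters)
}
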