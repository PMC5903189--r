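#' Aggregate tree records to per-hectare subplot summaries
#'
#' The estimation chain of the inventory: every enumerated stem gets a
#' predicted height from the height-diameter model, an allometric stem
#' volume from its species coefficients, and a per-hectare expansion factor
#' from the concentric circle its dbh class was enumerated in. Volumes
#' (and, on the biomass route, masses) are expanded and summed per subplot;
#' carbon is derived per hectare.
#'
#' Two carbon routes are supported. The default `"volume"` route applies a
#' carbon fraction (default 0.5) directly to the per-hectare stem volume,
#' the convention behind headline tC/ha figures. The `"biomass"` route goes
#' through species wood density: volume x density (air-dry, kg), x 0.91 to
#' oven-dry, x the carbon fraction (default 0.47), /1000 to tonnes.
#'
#' Heights are always model-predicted, including for trees whose height was
#' field-measured, so the same curve drives every stem's volume.
#'
#' @param trees Data frame of tree records: `subplot_id`, `species_code`,
#'   `dbh_cm` (or `circumference_cm`, converted via [dbh_from_circumference()]),
#'   optionally `height_m` for height-sampled trees.
#' @param species Data frame of species allometry: `species_code`, `vol_a`,
#'   `vol_b`, `vol_c`, `wood_density_kg_m3`, `hd_group`.
#' @param covariates Optional data frame of subplot covariates keyed by
#'   `subplot_id` (e.g. `cluster_id`, `altitude_m`, `region`, `ownership`);
#'   joined onto the output. Subplots present here but without any
#'   enumerable tree get an all-zero summary row with a warning.
#' @param hd_fit Optional [fit_height_diameter()] model. By default one is
#'   fitted to the height-sampled trees in `trees` (grouped by the species
#'   table's `hd_group`).
#' @param carbon_route `"volume"` (default) or `"biomass"`.
#' @param carbon_fraction Carbon fraction; defaults to 0.5 on the volume
#'   route and 0.47 on the biomass route.
#' @param biomass_mode Passed to [stem_biomass()] on the biomass route.
#' @param oven_dry_factor Air-dry to oven-dry factor (default 0.91).
#' @return A tibble with one row per subplot: `subplot_id`,
#'   `carbon_tC_ha`, `stem_volume_m3_ha`, `biomass_t_ha`, `mean_dbh_cm`,
#'   `tree_count`, `stems_per_ha`, plus any covariate columns.
#' @export
aggregate_subplots <- function(trees, species, covariates = NULL, hd_fit = NULL,
                               carbon_route = c("volume", "biomass"),
                               carbon_fraction = NULL,
                               biomass_mode = c("volume-scaled", "literal"),
                               oven_dry_factor = 0.91) {
  carbon_route <- match.arg(carbon_route)
  biomass_mode <- match.arg(biomass_mode)
  if (is.null(carbon_fraction)) {
    carbon_fraction <- if (carbon_route == "volume") 0.5 else 0.47
  }
  stopifnot(is.data.frame(trees), is.data.frame(species))
  need <- c("species_code", "vol_a", "vol_b", "vol_c", "wood_density_kg_m3", "hd_group")
  if (!all(need %in% names(species))) {
    stop("`species` must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }

  trees <- tibble::as_tibble(trees)
  if (!"dbh_cm" %in% names(trees)) {
    if (!"circumference_cm" %in% names(trees)) {
      stop("`trees` needs a `dbh_cm` or `circumference_cm` column", call. = FALSE)
    }
    trees$dbh_cm <- dbh_from_circumference(trees$circumference_cm)
  }
  if (!"height_m" %in% names(trees)) trees$height_m <- NA_real_

  if (nrow(trees) == 0) {
    trees_scored <- tibble::tibble(
      subplot_id = character(0), dbh_cm = numeric(0), ef = numeric(0),
      volume_m3 = numeric(0), carbon_kg = numeric(0), biomass_kg = numeric(0)
    )
  } else {
    radius <- suppressWarnings(inclusion_radius(trees$dbh_cm))
    if (anyNA(radius)) {
      warning("dropping ", sum(is.na(radius)),
              " stem(s) below the 5 cm caliper limit", call. = FALSE)
      trees <- trees[!is.na(radius), , drop = FALSE]
      radius <- radius[!is.na(radius)]
    }
    trees <- dplyr::left_join(trees, species, by = "species_code")
    if (anyNA(trees$vol_a)) {
      stop("species table is missing codes present in the tree records: ",
           paste(unique(trees$species_code[is.na(trees$vol_a)]), collapse = ", "),
           call. = FALSE)
    }
    if (is.null(hd_fit)) hd_fit <- fit_height_diameter(trees)
    trees$height_pred_m <- stats::predict(hd_fit, trees$dbh_cm, trees$hd_group)

    trees_scored <- dplyr::mutate(trees,
      ef = expansion_factor(radius),
      volume_m3 = stem_volume(.data$dbh_cm, .data$height_pred_m,
                              .data$vol_a, .data$vol_b, .data$vol_c),
      biomass_kg = stem_biomass(.data$volume_m3, .data$wood_density_kg_m3,
                                mode = biomass_mode)
    )
  }

  per_subplot <- trees_scored |>
    dplyr::group_by(.data$subplot_id) |>
    dplyr::summarise(
      stem_volume_m3_ha = sum(.data$volume_m3 * .data$ef),
      biomass_t_ha = sum(.data$biomass_kg * .data$ef) / 1000,
      mean_dbh_cm = mean(.data$dbh_cm),
      tree_count = dplyr::n(),
      stems_per_ha = sum(.data$ef),
      .groups = "drop"
    )

  per_subplot$carbon_tC_ha <- if (carbon_route == "volume") {
    carbon_from_biomass(per_subplot$stem_volume_m3_ha, carbon_fraction)
  } else {
    carbon_from_biomass(to_oven_dry(per_subplot$biomass_t_ha, oven_dry_factor),
                        carbon_fraction)
  }
  per_subplot <- dplyr::relocate(per_subplot, "carbon_tC_ha",
                                 .after = "subplot_id")

  if (!is.null(covariates)) {
    covariates <- tibble::as_tibble(covariates)
    out <- dplyr::left_join(covariates, per_subplot, by = "subplot_id")
    empty <- is.na(out$tree_count)
    if (any(empty)) {
      warning(sum(empty), " subplot(s) have no enumerable trees; ",
              "their per-hectare totals are reported as zero", call. = FALSE)
      zero_cols <- c("carbon_tC_ha", "stem_volume_m3_ha", "biomass_t_ha",
                     "tree_count", "stems_per_ha")
      out[empty, zero_cols] <- 0
    }
    out <- dplyr::relocate(out, dplyr::any_of(
      c("subplot_id", "carbon_tC_ha", "stem_volume_m3_ha", "biomass_t_ha",
        "mean_dbh_cm", "tree_count", "stems_per_ha")))
    return(out)
  }
  per_subplot
}
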