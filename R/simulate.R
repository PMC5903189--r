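#' Configuration of the synthetic inventory generator
#'
#' Builds the full parameter set both generators draw from. The defaults
#' emulate the field regime the package targets: 476 analysed subplots in
#' 121 clusters (of 726 laid out, 632 on forest land), right-skewed stem
#' diameters with mean 36.35 cm and sd 14.24 cm (moment-matched Weibull
#' truncated at the 5 cm caliper limit), zero-truncated negative-binomial
#' tree counts with mean 19.48 and sd 8.82 per subplot, altitudes on
#' \[124, 1632\] m with mean 513.3 m (moment-matched scaled Beta), 52.3%
#' community ownership, five development regions in proportion
#' 3:5:4:7:6, and a linear factor structure on subplot carbon whose level
#' effects have the magnitudes a field analysis of this design reports
#' (+37.0 and +82.7 tC/ha for the middle and top stem-volume levels, +12.7
#' and +19.9 for dbh, -10.8 for high tree count, small altitude / region /
#' ownership effects).
#'
#' The outcome noise is not a free dial: `residual_sd` is solved
#' analytically from the truth effects and the exact category
#' probabilities of the generating distributions so that the population
#' adjusted R^2 of the correctly specified factor model equals
#' `target_adj_r2` (default 0.838) at the calibration size (n = 462, 13
#' model columns). The intercept is likewise solved so the expected carbon
#' stock equals `mean_carbon` (default 76.67 tC/ha). Pass an explicit
#' `residual_sd` to override the calibration.
#'
#' @param n_subplots Records produced by [simulate_subplots()] (default 477,
#'   so the default outlier pass leaves 462).
#' @param n_clusters,subplots_per_cluster,n_forest_land,n_analysed Layout of
#'   the tree-level generator.
#' @param tree_count_mean,tree_count_sd Subplot tree-count moments.
#' @param dbh_mean,dbh_sd,dbh_min Stem-diameter moments and caliper limit (cm).
#' @param dbh_between_frac Fraction of the dbh standard deviation placed
#'   between subplots (stand-to-stand size heterogeneity); the remainder is
#'   within-subplot spread. The tree-level marginal keeps `dbh_mean` /
#'   `dbh_sd`, while subplot mean dbh spreads almost as widely — the
#'   plot-level regime descriptive tables report.
#' @param altitude_range,altitude_mean,altitude_sd Altitude regime (m).
#' @param p_community Community-ownership probability.
#' @param region_probs Named probabilities of the five regions.
#' @param n_species,n_hd_groups Species pool and height-diameter groups.
#' @param vol_a_range,vol_b_range,vol_c_range Species volume-coefficient ranges.
#' @param density_range Air-dry wood density range (kg/m^3).
#' @param hd_asymptote_range,hd_rate_range Height-diameter truth-curve ranges
#'   (m above breast height; per cm).
#' @param hd_noise_frac Height noise sd as a fraction of the true height.
#' @param effects Named list of truth level effects (tC/ha, first level 0).
#' @param mean_carbon Target mean carbon stock (tC/ha).
#' @param target_adj_r2 Adjusted R^2 the noise calibration aims at.
#' @param calibration_n,calibration_p Size the adjusted R^2 refers to.
#' @param residual_sd Outcome noise sd (tC/ha); `NULL` (default) = calibrated.
#' @param n_outliers,outlier_magnitude Planted gross errors: how many records
#'   get `outlier_magnitude` tC/ha added on top of their simulated value.
#' @return A `sim_config` list; derived quantities (distribution parameters,
#'   category probabilities, signal variance, residual sd, intercept) are
#'   stored under `$derived`.
#' @examples
#' cfg <- sim_config()
#' cfg$derived$residual_sd
#' @export
sim_config <- function(n_subplots = 477,
                       n_clusters = 121, subplots_per_cluster = 6,
                       n_forest_land = 632, n_analysed = 476,
                       tree_count_mean = 19.48, tree_count_sd = 8.82,
                       dbh_mean = 36.35, dbh_sd = 14.24, dbh_min = 5,
                       dbh_between_frac = 0.9,
                       altitude_range = c(124, 1632),
                       altitude_mean = 513.3, altitude_sd = 289.47,
                       p_community = 0.523,
                       region_probs = c(FW = 3, MW = 5, W = 4, C = 7, E = 6) / 25,
                       n_species = 30, n_hd_groups = 5,
                       vol_a_range = c(-10.7, -9.7),
                       vol_b_range = c(1.6, 1.9),
                       vol_c_range = c(0.95, 1.15),
                       density_range = c(400, 800),
                       hd_asymptote_range = c(15, 35),
                       hd_rate_range = c(0.04, 0.08),
                       hd_noise_frac = 0.10,
                       effects = list(
                         sv_cat = c(0, 37.0299, 82.7046),
                         dbh_cat = c(0, 12.6649, 19.8899),
                         tn_cat = c(0, -10.7735),
                         alt_cat = c(0, 3.1432, -3.5070),
                         region = c(0, -1.2887, 1.2523, 1.1656, 4.0286),
                         ownership = c(0, -0.6158)
                       ),
                       mean_carbon = 76.67,
                       target_adj_r2 = 0.838,
                       calibration_n = 462, calibration_p = 13,
                       residual_sd = NULL,
                       n_outliers = 15, outlier_magnitude = 60) {
  if (dbh_mean <= dbh_min) stop("`dbh_mean` must exceed the caliper limit", call. = FALSE)
  if (abs(sum(region_probs) - 1) > 1e-8) stop("`region_probs` must sum to 1", call. = FALSE)
  if (p_community < 0 || p_community > 1) stop("`p_community` must be in [0, 1]", call. = FALSE)
  if (tree_count_sd^2 <= tree_count_mean) {
    stop("tree counts need overdispersion (sd^2 > mean) for the negative binomial",
         call. = FALSE)
  }

  cfg <- as.list(environment())

  # Weibull moment-matched to the dbh mean/sd (truncation at 5 cm is
  # negligible mass but applied when sampling). The tree-level marginal is
  # split into a between-subplot component (subplot mean size) and a
  # within-subplot Weibull so plot means spread like real stand means do.
  wb <- weibull_from_moments(dbh_mean, dbh_sd)
  dbh_between_sd <- dbh_between_frac * dbh_sd
  dbh_within_sd <- sqrt(1 - dbh_between_frac^2) * dbh_sd

  # scaled Beta moment-matched to the altitude mean/sd on its range
  span <- diff(altitude_range)
  m <- (altitude_mean - altitude_range[1]) / span
  v <- (altitude_sd / span)^2
  if (v >= m * (1 - m)) stop("altitude sd too large for its range", call. = FALSE)
  ab <- m * (1 - m) / v - 1
  beta_shape1 <- m * ab
  beta_shape2 <- (1 - m) * ab

  # zero-truncated negative binomial for subplot tree counts
  nb_size <- tree_count_mean^2 / (tree_count_sd^2 - tree_count_mean)

  # exact level probabilities of the default categorization under the
  # generating distributions (outcome generator's covariates)
  specs <- default_category_specs()
  sv_shape <- (154.40 / 86.45)^2
  sv_rate <- sv_shape / 154.40
  p_sv <- diff(stats::pgamma(c(0, specs$sv_cat$breaks, Inf), sv_shape, sv_rate))
  ptn_dbh <- function(x) {
    lo <- stats::pnorm(dbh_min, dbh_mean, dbh_sd)
    (stats::pnorm(x, dbh_mean, dbh_sd) - lo) / (1 - lo)
  }
  b <- specs$dbh_cat$breaks
  p_dbh <- c(ptn_dbh(b[1]), ptn_dbh(b[2]) - ptn_dbh(b[1]), 1 - ptn_dbh(b[2]))
  p0 <- stats::dnbinom(0, size = nb_size, mu = tree_count_mean)
  p_lt <- (stats::pnbinom(specs$tn_cat$breaks - 1, size = nb_size,
                          mu = tree_count_mean) - p0) / (1 - p0)
  p_tn <- c(p_lt, 1 - p_lt)
  pb <- function(x) stats::pbeta((x - altitude_range[1]) / span,
                                 beta_shape1, beta_shape2)
  a <- specs$alt_cat$breaks
  p_alt <- c(pb(a[1]), pb(a[2]) - pb(a[1]), 1 - pb(a[2]))

  level_probs <- list(sv_cat = p_sv, dbh_cat = p_dbh, tn_cat = p_tn,
                      alt_cat = p_alt, region = unname(region_probs),
                      ownership = c(1 - p_community, p_community))

  signal_var <- sum(purrr::map2_dbl(effects, level_probs[names(effects)],
    function(d, p) sum(p * d^2) - sum(p * d)^2))

  if (is.null(residual_sd)) {
    r2 <- 1 - (1 - target_adj_r2) *
      (calibration_n - calibration_p) / (calibration_n - 1)
    residual_sd <- sqrt(signal_var * (1 - r2) / r2)
  }
  intercept <- mean_carbon - sum(purrr::map2_dbl(
    effects, level_probs[names(effects)], function(d, p) sum(p * d)))

  cfg$residual_sd <- residual_sd
  cfg$derived <- list(
    weibull_shape = wb$shape, weibull_scale = wb$scale,
    dbh_between_sd = dbh_between_sd, dbh_within_sd = dbh_within_sd,
    beta_shape1 = beta_shape1, beta_shape2 = beta_shape2,
    nb_size = nb_size,
    sv_gamma_shape = sv_shape, sv_gamma_rate = sv_rate,
    level_probs = level_probs,
    signal_var = signal_var,
    residual_sd = residual_sd,
    intercept = intercept
  )
  structure(cfg, class = "sim_config")
}

# Weibull shape/scale from a target mean and sd
weibull_from_moments <- function(mean, sd) {
  cv <- sd / mean
  shape <- stats::uniroot(
    function(k) sqrt(gamma(1 + 2 / k) / gamma(1 + 1 / k)^2 - 1) - cv,
    c(0.2, 100)
  )$root
  list(shape = shape, scale = mean / gamma(1 + 1 / shape))
}

# truncated-distribution samplers via inverse CDF (deterministic under seed)
rtrunc_weibull <- function(n, shape, scale, lower) {
  stats::qweibull(stats::runif(n, stats::pweibull(lower, shape, scale), 1),
                  shape, scale)
}
rtrunc_norm <- function(n, mean, sd, lower) {
  stats::qnorm(stats::runif(n, stats::pnorm(lower, mean, sd), 1), mean, sd)
}
rztnbinom <- function(n, size, mu) {
  stats::qnbinom(stats::runif(n, stats::dnbinom(0, size = size, mu = mu), 1),
                 size = size, mu = mu)
}

#' Simulate a species allometry table
#'
#' Draws a species pool with log-volume coefficients, air-dry wood density
#' and a height-diameter group assignment, plus the truth curve of each
#' group.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return List with `species` (tibble: `species_code`, `vol_a`, `vol_b`,
#'   `vol_c`, `wood_density_kg_m3`, `hd_group`) and `hd_truth` (tibble:
#'   `hd_group`, `asymptote_m`, `rate_per_cm`).
#' @export
simulate_species <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  ns <- config$n_species
  groups <- paste0("G", seq_len(config$n_hd_groups))
  species <- tibble::tibble(
    species_code = sprintf("SP%02d", seq_len(ns)),
    vol_a = stats::runif(ns, config$vol_a_range[1], config$vol_a_range[2]),
    vol_b = stats::runif(ns, config$vol_b_range[1], config$vol_b_range[2]),
    vol_c = stats::runif(ns, config$vol_c_range[1], config$vol_c_range[2]),
    wood_density_kg_m3 = stats::runif(ns, config$density_range[1],
                                      config$density_range[2]),
    hd_group = rep_len(groups, ns)
  )
  hd_truth <- tibble::tibble(
    hd_group = groups,
    asymptote_m = stats::runif(length(groups), config$hd_asymptote_range[1],
                               config$hd_asymptote_range[2]),
    rate_per_cm = stats::runif(length(groups), config$hd_rate_range[1],
                               config$hd_rate_range[2])
  )
  list(species = species, hd_truth = hd_truth)
}

#' Simulate a tree-level inventory
#'
#' Generates the full field-data surface the estimation chain consumes:
#' a cluster/subplot layout (with on-forest-land and analysed exclusion
#' flags), subplot covariates, a species allometry table, and tree records
#' with dbh from the truncated Weibull, species draws, and noisy heights
#' on the systematically height-sampled trees (every 5th, plus species
#' coverage).
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the same seed reproduces the datasets exactly.
#' @return List with `trees`, `species`, `subplots` (covariates incl.
#'   `analysed` / `on_forest_land` flags), and `truth` (hd curves + the
#'   config).
#' @examples
#' inv <- simulate_trees(sim_config(n_clusters = 4, n_forest_land = 20,
#'                                  n_analysed = 16), seed = 1)
#' nrow(inv$subplots)
#' @export
simulate_trees <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  sp <- simulate_species(config, seed)
  set.seed(seed + 1L)
  d <- config$derived

  n_total <- config$n_clusters * config$subplots_per_cluster
  if (config$n_analysed > config$n_forest_land ||
      config$n_forest_land > n_total) {
    stop("need n_analysed <= n_forest_land <= clusters x subplots", call. = FALSE)
  }

  layout <- layout_subplots(0, 0)
  subplots <- tidyr::expand_grid(
    cluster_id = seq_len(config$n_clusters),
    subplot_number = layout$subplot_number
  )
  subplots <- dplyr::left_join(subplots, layout, by = "subplot_number")
  subplots$subplot_id <- sprintf("C%03d-S%d", subplots$cluster_id,
                                 subplots$subplot_number)

  forest_land <- sort(sample.int(n_total, config$n_forest_land))
  analysed <- sort(sample(forest_land, config$n_analysed))
  subplots$on_forest_land <- seq_len(n_total) %in% forest_land
  subplots$analysed <- seq_len(n_total) %in% analysed

  regions <- names(config$region_probs)
  cluster_region <- sample(regions, config$n_clusters, replace = TRUE,
                           prob = config$region_probs)
  subplots$region <- factor(cluster_region[subplots$cluster_id], levels = regions)
  subplots$altitude_m <- config$altitude_range[1] +
    diff(config$altitude_range) *
    stats::rbeta(n_total, d$beta_shape1, d$beta_shape2)
  subplots$ownership <- factor(
    ifelse(stats::runif(n_total) < config$p_community, "community", "other"),
    levels = c("community", "other")
  )

  active <- subplots[subplots$analysed, , drop = FALSE]
  counts <- rztnbinom(nrow(active), d$nb_size, config$tree_count_mean)
  # subplot mean stem size, then within-subplot Weibull around it
  sub_mean <- rtrunc_norm(nrow(active), config$dbh_mean, d$dbh_between_sd,
                          2 * config$dbh_min)

  trees <- purrr::pmap(
    list(active$subplot_id, counts, sub_mean),
    function(sid, n, mu) {
      wb <- weibull_from_moments(mu, d$dbh_within_sd)
      tibble::tibble(
        subplot_id = sid,
        species_code = sample(sp$species$species_code, n, replace = TRUE),
        dbh_cm = rtrunc_weibull(n, wb$shape, wb$scale, config$dbh_min)
      )
    })
  trees <- dplyr::bind_rows(trees)
  trees$tree_id <- seq_len(nrow(trees))

  trees <- dplyr::left_join(
    trees, sp$species[c("species_code", "hd_group")], by = "species_code")
  truth_lut <- sp$hd_truth
  idx <- match(trees$hd_group, truth_lut$hd_group)
  h_true <- 1.3 + truth_lut$asymptote_m[idx] *
    (1 - exp(-truth_lut$rate_per_cm[idx] * trees$dbh_cm))

  # height sampling runs over the whole enumeration order (crews carry the
  # 1-in-5 count across subplots), plus first-of-species coverage
  trees$height_sampled <- sample_height_trees(trees$species_code)
  noise <- stats::rnorm(nrow(trees), 0, config$hd_noise_frac * h_true)
  trees$height_m <- ifelse(trees$height_sampled,
                           pmax(h_true + noise, 1.5), NA_real_)
  trees$hd_group <- NULL

  list(
    trees = trees[c("tree_id", "subplot_id", "species_code", "dbh_cm",
                    "height_sampled", "height_m")],
    species = sp$species,
    subplots = subplots[c("subplot_id", "cluster_id", "subplot_number",
                          "easting_m", "northing_m", "on_forest_land",
                          "analysed", "altitude_m", "region", "ownership")],
    truth = list(hd = sp$hd_truth, config = config)
  )
}

#' Simulate subplot summaries with a known linear factor structure
#'
#' The factor-model testbed: covariates are drawn independently from
#' distributions moment-matched to the target inventory regime, categorized
#' with the standard cutpoints, and the carbon outcome is built as
#' intercept + truth level effects + Gaussian noise, with `n_outliers`
#' records displaced upward by `outlier_magnitude` tC/ha as planted gross
#' errors. Covariates are mutually independent so every effect is
#' separately identifiable when scoring recovery.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return Tibble of subplot summaries (`subplot_id`, continuous
#'   covariates, derived `*_cat` factors, `region`, `ownership`,
#'   `carbon_tC_ha`, `is_outlier`) with the generating truth attached as
#'   attribute `"truth"` (intercept, per-factor effects, residual sd,
#'   outlier rows).
#' @examples
#' sim <- simulate_subplots(sim_config(n_subplots = 100, n_outliers = 0), seed = 7)
#' attr(sim, "truth")$residual_sd
#' @export
simulate_subplots <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- config$n_subplots
  d <- config$derived
  if (config$n_outliers > n) stop("more planted outliers than records", call. = FALSE)

  dat <- tibble::tibble(
    subplot_id = sprintf("P%04d", seq_len(n)),
    stem_volume_m3_ha = stats::rgamma(n, d$sv_gamma_shape, d$sv_gamma_rate),
    mean_dbh_cm = rtrunc_norm(n, config$dbh_mean, config$dbh_sd, config$dbh_min),
    tree_count = rztnbinom(n, d$nb_size, config$tree_count_mean),
    altitude_m = config$altitude_range[1] + diff(config$altitude_range) *
      stats::rbeta(n, d$beta_shape1, d$beta_shape2),
    region = factor(sample(names(config$region_probs), n, replace = TRUE,
                           prob = config$region_probs),
                    levels = names(config$region_probs)),
    ownership = factor(ifelse(stats::runif(n) < config$p_community,
                              "community", "other"),
                       levels = c("community", "other"))
  )
  dat <- apply_categories(dat)

  eff <- config$effects
  lp <- d$intercept +
    eff$sv_cat[as.integer(dat$sv_cat)] +
    eff$dbh_cat[as.integer(dat$dbh_cat)] +
    eff$tn_cat[as.integer(dat$tn_cat)] +
    eff$alt_cat[as.integer(dat$alt_cat)] +
    eff$region[as.integer(dat$region)] +
    eff$ownership[as.integer(dat$ownership)]

  carbon <- lp + stats::rnorm(n, 0, config$residual_sd)
  outlier_rows <- if (config$n_outliers > 0) {
    sort(sample.int(n, config$n_outliers))
  } else integer(0)
  carbon[outlier_rows] <- carbon[outlier_rows] + config$outlier_magnitude

  dat$carbon_tC_ha <- carbon
  dat$is_outlier <- seq_len(n) %in% outlier_rows

  attr(dat, "truth") <- list(
    intercept = d$intercept,
    effects = eff,
    residual_sd = config$residual_sd,
    outlier_rows = outlier_rows,
    outlier_magnitude = config$outlier_magnitude,
    seed = seed
  )
  dat
}
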