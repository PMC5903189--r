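#' Read tree / species / subplot tables from CSV
#'
#' Thin readr wrappers that validate the columns the estimation chain
#' needs, so a malformed input fails with a clear, stage-attributed error
#' instead of propagating `NA`s.
#'
#' @param path CSV file with a header row.
#' @return A tibble.
#' @name read_tables
NULL

read_checked <- function(path, required, what) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required, names(out))
  if (length(missing) > 0) {
    stop(what, " table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out
}

#' @rdname read_tables
#' @export
read_tree_table <- function(path) {
  out <- read_checked(path, "subplot_id", "tree")
  if (!any(c("dbh_cm", "circumference_cm") %in% names(out))) {
    stop("tree table ", path, " needs `dbh_cm` or `circumference_cm`",
         call. = FALSE)
  }
  out
}

#' @rdname read_tables
#' @export
read_species_table <- function(path) {
  read_checked(path, c("species_code", "vol_a", "vol_b", "vol_c",
                       "wood_density_kg_m3", "hd_group"), "species")
}

#' @rdname read_tables
#' @export
read_subplot_table <- function(path) {
  read_checked(path, "subplot_id", "subplot")
}

#' Run the full inventory-to-inference pipeline
#'
#' One reproducible run of the whole chain: simulate a tree-level
#' inventory, estimate per-hectare subplot carbon through the allometric
#' chain, fit the sum-contrast factor model with the one-pass outlier
#' removal, and write every stage's outputs (headered CSVs, QQ and CI
#' figures, a JSON run manifest) under `outdir`. Stages log to `message()`
#' and fail fast with the stage name attached.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed driving all randomness.
#' @param config A [sim_config()].
#' @param outlier_threshold Residual threshold (tC/ha) of the removal pass.
#' @param write_plots Write the PNG figures (default TRUE).
#' @return Invisibly, a list with the run `manifest` and the in-memory
#'   results (`subplots`, `fit`, `coefficients`, `contrasts`,
#'   `descriptives`).
#' @examples
#' \donttest{
#' res <- run_pipeline(tempfile("run"), seed = 1,
#'                     config = sim_config(n_clusters = 20, n_forest_land = 100,
#'                                         n_analysed = 80))
#' res$manifest$stages
#' }
#' @export
run_pipeline <- function(outdir, seed = 1, config = sim_config(),
                         outlier_threshold = 40, write_plots = TRUE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    seed = seed,
    package_version = as.character(utils::packageVersion("stemcarbon")),
    started = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
    outdir = normalizePath(outdir),
    config = config[setdiff(names(config), "derived")],
    stages = list(), files = list()
  )

  stage <- function(name, code) {
    message("[", name, "] ...")
    t0 <- Sys.time()
    out <- tryCatch(code, error = function(e) {
      stop("stage `", name, "` failed: ", conditionMessage(e), call. = FALSE)
    })
    manifest$stages[[name]] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 3)
    out
  }
  put <- function(name, data) {
    path <- file.path(outdir, name)
    readr::write_csv(data, path, progress = FALSE)
    manifest$files[[name]] <<- name
    path
  }

  inv <- stage("simulate", {
    inv <- simulate_trees(config, seed)
    put("trees.csv", inv$trees)
    put("species.csv", inv$species)
    put("covariates.csv", inv$subplots)
    jsonlite::write_json(
      list(hd_truth = inv$truth$hd,
           residual_sd = config$residual_sd,
           intercept = config$derived$intercept,
           effects = config$effects),
      file.path(outdir, "truth.json"), auto_unbox = TRUE, digits = NA)
    manifest$files[["truth.json"]] <- "truth.json"
    inv
  })

  subplots <- stage("estimate", {
    covs <- inv$subplots[inv$subplots$analysed,
                         c("subplot_id", "cluster_id", "altitude_m",
                           "region", "ownership")]
    sub <- aggregate_subplots(inv$trees, inv$species, covariates = covs)
    sub <- apply_categories(sub)
    put("subplots.csv", sub)
    sub
  })

  fit <- stage("model", {
    refit <- outlier_refit(fit_carbon_model(subplots),
                           threshold = outlier_threshold)
    put("coefficients.csv", tidy(refit, type = "baseline"))
    cis <- contrast_cis(refit)
    cis_out <- dplyr::mutate(cis, overall_mean = attr(cis, "overall_mean"))
    put("contrasts.csv", cis_out)
    put("model_summary.csv", glance(refit))
    if (write_plots) {
      ggplot2::ggsave(file.path(outdir, "qq.png"), plot_qq(refit),
                      width = 8, height = 4, dpi = 150)
      sig <- cis[cis$factor %in% c("sv_cat", "dbh_cat", "tn_cat"), ]
      attr(sig, "overall_mean") <- attr(cis, "overall_mean")
      oth <- cis[!cis$factor %in% c("sv_cat", "dbh_cat", "tn_cat"), ]
      attr(oth, "overall_mean") <- attr(cis, "overall_mean")
      ggplot2::ggsave(file.path(outdir, "ci_stand_factors.png"),
                      plot_contrast_cis(sig), width = 8, height = 4, dpi = 150)
      ggplot2::ggsave(file.path(outdir, "ci_site_factors.png"),
                      plot_contrast_cis(oth), width = 8, height = 4, dpi = 150)
      manifest$files <- c(manifest$files,
                          list(qq = "qq.png",
                               ci_stand = "ci_stand_factors.png",
                               ci_site = "ci_site_factors.png"))
    }
    refit
  })

  descriptives <- stage("report", {
    desc <- descriptive_table(subplots)
    put("descriptives.csv", desc)
    desc
  })

  manifest$finished <- format(Sys.time(), "%Y-%m-%d %H:%M:%S")
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(
    manifest = manifest,
    subplots = subplots,
    fit = fit,
    coefficients = tidy(fit, type = "baseline"),
    contrasts = contrast_cis(fit),
    descriptives = descriptives
  ))
}
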