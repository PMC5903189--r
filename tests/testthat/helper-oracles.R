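# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain loops and closed forms only.

# normal-equations OLS: coefficients, SEs, p-values, adjusted R^2
ols_oracle <- function(X, y) {
  XtX_inv <- solve(crossprod(X))
  beta <- drop(XtX_inv %*% crossprod(X, y))
  fitted <- drop(X %*% beta)
  resid <- y - fitted
  n <- nrow(X)
  p <- ncol(X)
  s2 <- sum(resid^2) / (n - p)
  se <- sqrt(diag(XtX_inv) * s2)
  tstat <- beta / se
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  list(
    coef = beta, se = se,
    p = 2 * pt(abs(tstat), n - p, lower.tail = FALSE),
    r2 = r2,
    adj_r2 = 1 - (1 - r2) * (n - 1) / (n - p),
    resid = resid, s2 = s2, XtX_inv = XtX_inv
  )
}

# per-tree loop over the estimation chain: nested-circle expansion,
# allometric volume, volume-route carbon (0.5 x m^3/ha)
brute_force_subplot <- function(trees, species, hd_fit) {
  split_trees <- split(trees, trees$subplot_id)
  out <- lapply(names(split_trees), function(sid) {
    tt <- split_trees[[sid]]
    sv <- 0; stems <- 0; dbh_sum <- 0
    for (i in seq_len(nrow(tt))) {
      d <- tt$dbh_cm[i]
      r <- if (d < 10) 4 else if (d < 20) 8 else if (d < 30) 15 else 20
      ef <- 1e4 / (pi * r^2)
      sp <- species[species$species_code == tt$species_code[i], ]
      h <- predict(hd_fit, d, sp$hd_group)
      v <- exp(sp$vol_a + sp$vol_b * log(d) + sp$vol_c * log(h))
      sv <- sv + v * ef
      stems <- stems + ef
      dbh_sum <- dbh_sum + d
    }
    data.frame(subplot_id = sid, stem_volume_m3_ha = sv,
               carbon_tC_ha = 0.5 * sv, stems_per_ha = stems,
               mean_dbh_cm = dbh_sum / nrow(tt), tree_count = nrow(tt))
  })
  do.call(rbind, out)
}

# random small factor dataset for OLS equivalence checks
random_toy_factors <- function(n, seed) {
  set.seed(seed)
  repeat {
    dat <- data.frame(
      y = rnorm(n, 50, 10),
      f1 = factor(sample(c("a", "b", "c"), n, replace = TRUE)),
      f2 = factor(sample(c("lo", "hi"), n, replace = TRUE))
    )
    # need every level present and a full-rank design
    if (nlevels(droplevels(dat$f1)) == 3 && nlevels(droplevels(dat$f2)) == 2) {
      return(dat)
    }
  }
}

# tiny deterministic tree inventory with a known height curve
toy_inventory <- function(n_subplots = 3, trees_per_subplot = 6, seed = 99) {
  set.seed(seed)
  species <- data.frame(
    species_code = c("AA", "BB"),
    vol_a = c(-9.5, -10.0), vol_b = c(1.8, 1.7), vol_c = c(1.0, 1.1),
    wood_density_kg_m3 = c(550, 700),
    hd_group = c("g1", "g1")
  )
  trees <- do.call(rbind, lapply(seq_len(n_subplots), function(s) {
    data.frame(
      subplot_id = sprintf("S%02d", s),
      species_code = sample(species$species_code, trees_per_subplot, replace = TRUE),
      dbh_cm = runif(trees_per_subplot, 6, 60)
    )
  }))
  # exact heights from a known curve so the H-D fit is deterministic
  trees$height_m <- 1.3 + 25 * (1 - exp(-0.06 * trees$dbh_cm))
  list(trees = trees, species = species,
       truth = list(asymptote = 25, rate = 0.06))
}
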