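#' Diameter at breast height from circumference
#'
#' Converts a stem circumference measured at 1.3 m to diameter,
#' \eqn{d = c / \pi}.
#'
#' @param circumference_cm Circumference in cm. Vectorised; must be `>= 0`.
#' @return Diameter in cm.
#' @examples
#' dbh_from_circumference(100)
#' @export
dbh_from_circumference <- function(circumference_cm) {
  if (!is.numeric(circumference_cm) || any(circumference_cm < 0, na.rm = TRUE)) {
    stop("`circumference_cm` must be non-negative", call. = FALSE)
  }
  circumference_cm / pi
}

#' Flag trees for height measurement
#'
#' Field crews measure height only on a systematic subsample: every 5th
#' tree in enumeration order (positions 5, 10, ...). So that every species
#' present is represented in the height sample, the first tree of any
#' species not already covered is flagged in addition.
#'
#' @param species_code Character/factor vector of species codes in the order
#'   the trees were enumerated.
#' @param interval Sampling interval (default 5).
#' @return Logical vector, `TRUE` where the tree is height-sampled.
#' @examples
#' sample_height_trees(rep("shorea", 10))
#' @export
sample_height_trees <- function(species_code, interval = 5) {
  n <- length(species_code)
  if (n == 0) return(logical(0))
  flag <- seq_len(n) %% interval == 0
  covered <- unique(species_code[flag])
  for (sp in setdiff(unique(species_code), covered)) {
    flag[match(sp, species_code)] <- TRUE
  }
  flag
}

#' Allometric stem volume
#'
#' Species-specific log-linear stem volume,
#' \eqn{\ln v = a + b \ln d + c \ln h}, with diameter `d` in cm and height
#' `h` in m. `a`, `b`, `c` are species coefficients.
#'
#' @param dbh_cm Diameter at breast height (cm), `> 0`. Vectorised.
#' @param height_m Total tree height (m), `> 0`. Vectorised.
#' @param a,b,c Species volume coefficients (intercept, diameter and height
#'   log-slopes).
#' @return Stem volume (m^3).
#' @examples
#' stem_volume(30, 20, a = -9, b = 1.75, c = 1.10)
#' @export
stem_volume <- function(dbh_cm, height_m, a, b, c) {
  if (any(dbh_cm <= 0, na.rm = TRUE) || any(height_m <= 0, na.rm = TRUE)) {
    stop("`dbh_cm` and `height_m` must be strictly positive", call. = FALSE)
  }
  exp(a + b * log(dbh_cm) + c * log(height_m))
}

#' Stem biomass from volume and wood density
#'
#' Air-dry stem biomass from stem volume and species wood density. The
#' default `"volume-scaled"` mode is the physically coherent product
#' \eqn{v \times \rho} (kg when `v` is m^3 and `rho` kg/m^3). The
#' `"literal"` mode computes \eqn{\ln(v) \times \rho} instead; it is kept
#' selectable because some published write-ups print the relation that way,
#' but it returns non-positive biomass for volumes of 1 m^3 or less (a
#' warning is raised when that happens).
#'
#' @param volume_m3 Stem volume (m^3), `> 0`. Vectorised.
#' @param density_kg_m3 Air-dry wood density (kg/m^3), `> 0`.
#' @param mode `"volume-scaled"` (default) or `"literal"`.
#' @return Air-dry biomass (kg).
#' @examples
#' stem_biomass(2, 500)
#' @export
stem_biomass <- function(volume_m3, density_kg_m3,
                         mode = c("volume-scaled", "literal")) {
  mode <- match.arg(mode)
  if (any(volume_m3 <= 0, na.rm = TRUE) || any(density_kg_m3 <= 0, na.rm = TRUE)) {
    stop("`volume_m3` and `density_kg_m3` must be strictly positive", call. = FALSE)
  }
  if (mode == "volume-scaled") {
    volume_m3 * density_kg_m3
  } else {
    if (any(volume_m3 <= 1, na.rm = TRUE)) {
      warning("literal mode yields non-positive biomass for volumes <= 1 m^3",
              call. = FALSE)
    }
    log(volume_m3) * density_kg_m3
  }
}

#' Air-dry to oven-dry biomass
#'
#' Applies the standard 0.91 conversion from air-dry to oven-dry mass.
#'
#' @param air_dry_mass Air-dry mass (any mass unit), `>= 0`.
#' @param factor Conversion factor (default 0.91).
#' @return Oven-dry mass in the same unit.
#' @export
to_oven_dry <- function(air_dry_mass, factor = 0.91) {
  if (any(air_dry_mass < 0, na.rm = TRUE)) {
    stop("`air_dry_mass` must be non-negative", call. = FALSE)
  }
  air_dry_mass * factor
}

#' Carbon from biomass (or volume-derived stock)
#'
#' Multiplies a stock by a carbon fraction. Two presets are in common use
#' and both are supported: 0.47 of oven-dry biomass (the biomass route) and
#' 0.5 of the volume-derived stock (the volume route used for headline
#' tC/ha figures).
#'
#' @param mass Stock to convert (mass, or volume-derived stock), `>= 0`.
#' @param fraction Carbon fraction in (0, 1); default 0.5.
#' @return Carbon stock in the same unit as `mass`.
#' @export
carbon_from_biomass <- function(mass, fraction = 0.5) {
  if (!is.numeric(fraction) || length(fraction) != 1 || is.na(fraction) ||
      fraction <= 0 || fraction >= 1) {
    stop("`fraction` must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (any(mass < 0, na.rm = TRUE)) stop("`mass` must be non-negative", call. = FALSE)
  mass * fraction
}
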