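# Parameter containers: species constants, wind constants, soil profile.

#' Species constants for the uprooting model
#'
#' Bundles the per-species constants used by the mechanistic model: the stem
#' stiffness coefficient `a` of the stem resistive moment \eqn{M_s = a D^3 H},
#' the anchorage fraction `f_r` (share of root-plate weight contributing to
#' root anchorage), and the allometric coefficients of the coarse-root biomass
#' model \eqn{G_{cr} = b_0 D^{b_1} H^{b_2}} together with the unit convention
#' under which that allometry is evaluated.
#'
#' Defaults: spruce `a = 3.315`, `f_r = 0.20`, allometry
#' `4.3020 * D^2.9132 * H^-0.3292` with D in decimetres and output in kg;
#' Korean pine `a = 3.589`, `f_r = 0.30`, allometry
#' `4.7202 * D^2.7794 * H^-0.0536` with D in centimetres and output in grams
#' (converted to kg). The allometric unit conventions were calibrated against
#' published per-tree coarse-root masses; see the methods vignette.
#'
#' @param species `"spruce"` or `"korean_pine"`.
#' @param stem_coefficient Coefficient `a` (> 0) of the stem moment.
#' @param anchorage_fraction `f_r`, in (0, 1].
#' @param allometric_b0,allometric_b1,allometric_b2 Coefficients of the
#'   coarse-root biomass allometry.
#' @param allometric_unit_convention `"dbh_dm_out_kg"` (D fed in decimetres,
#'   result already kg) or `"dbh_cm_out_g"` (D fed in centimetres, result in
#'   grams, divided by 1000).
#' @return An object of class `species_params`.
#' @export
#' @examples
#' species_params("spruce")$stem_coefficient  # 3.315
species_params <- function(species = c("spruce", "korean_pine"),
                           stem_coefficient = NULL,
                           anchorage_fraction = NULL,
                           allometric_b0 = NULL,
                           allometric_b1 = NULL,
                           allometric_b2 = NULL,
                           allometric_unit_convention = NULL) {
  species <- match.arg(species)
  def <- switch(species,
    spruce = list(stem_coefficient = 3.315, anchorage_fraction = 0.20,
                  allometric_b0 = 4.3020, allometric_b1 = 2.9132,
                  allometric_b2 = -0.3292,
                  allometric_unit_convention = "dbh_dm_out_kg"),
    korean_pine = list(stem_coefficient = 3.589, anchorage_fraction = 0.30,
                       allometric_b0 = 4.7202, allometric_b1 = 2.7794,
                       allometric_b2 = -0.0536,
                       allometric_unit_convention = "dbh_cm_out_g"))
  p <- list(
    species = species,
    stem_coefficient = stem_coefficient %||% def$stem_coefficient,
    anchorage_fraction = anchorage_fraction %||% def$anchorage_fraction,
    allometric_b0 = allometric_b0 %||% def$allometric_b0,
    allometric_b1 = allometric_b1 %||% def$allometric_b1,
    allometric_b2 = allometric_b2 %||% def$allometric_b2,
    allometric_unit_convention =
      allometric_unit_convention %||% def$allometric_unit_convention)
  if (!is.numeric(p$stem_coefficient) || p$stem_coefficient <= 0)
    stop("stem_coefficient must be > 0", call. = FALSE)
  if (!is.numeric(p$anchorage_fraction) ||
      p$anchorage_fraction <= 0 || p$anchorage_fraction > 1)
    stop("anchorage_fraction must be in (0, 1]", call. = FALSE)
  if (!p$allometric_unit_convention %in% c("dbh_dm_out_kg", "dbh_cm_out_g"))
    stop("unknown allometric_unit_convention: ",
         p$allometric_unit_convention, call. = FALSE)
  structure(p, class = "species_params")
}

#' @export
print.species_params <- function(x, ...) {
  cat("Species parameters [", x$species, "]\n", sep = "")
  cat("  stem coefficient a :", x$stem_coefficient, "\n")
  cat("  anchorage f_r      :", x$anchorage_fraction, "\n")
  cat("  allometry          : ", x$allometric_b0, " * D^", x$allometric_b1,
      " * H^", x$allometric_b2, "  (", x$allometric_unit_convention, ")\n",
      sep = "")
  invisible(x)
}

#' Wind constants and the derived factor mu
#'
#' Air density, crown drag coefficient and a reference wind speed. The derived
#' constant \eqn{\mu = \rho_a C_d v^2 / 6} multiplies the purely morphological
#' part of the overturning moment, so it rescales the resistance coefficient
#' `R_m` but cancels out of the wind-independent index Delta-prime and of the
#' hazard classification.
#'
#' @param air_density Air density, kg m^-3 (default 1.226).
#' @param drag_coefficient Dimensionless crown drag coefficient (default 0.29).
#' @param wind_speed Reference horizontal wind speed, m s^-1 (default 10).
#' @return An object of class `wind_params` with the derived element `mu`.
#' @export
#' @examples
#' wind_params()$mu
wind_params <- function(air_density = 1.226, drag_coefficient = 0.29,
                        wind_speed = 10) {
  if (!all(is.finite(c(air_density, drag_coefficient, wind_speed))) ||
      air_density <= 0 || drag_coefficient <= 0 || wind_speed <= 0)
    stop("air_density, drag_coefficient and wind_speed must all be > 0",
         call. = FALSE)
  structure(list(air_density = air_density,
                 drag_coefficient = drag_coefficient,
                 wind_speed = wind_speed,
                 mu = air_density * drag_coefficient * wind_speed^2 / 6),
            class = "wind_params")
}

#' @export
print.wind_params <- function(x, ...) {
  cat("Wind parameters: rho_a =", x$air_density, "kg/m^3, C_d =",
      x$drag_coefficient, ", v =", x$wind_speed, "m/s  =>  mu =",
      signif(x$mu, 6), "\n")
  invisible(x)
}

#' Layered soil profile with an effective bulk density
#'
#' Holds per-layer soil physical properties and derives the effective bulk
#' density used to convert root-plate volume into soil mass. The effective
#' value is the thickness-weighted mean of the layer bulk densities
#' (converted to kg m^-3), which is what a root plate spanning the profile
#' samples.
#'
#' @param layers data.frame with columns `depth_top_cm`, `depth_bottom_cm`,
#'   `bulk_density_g_cm3` and optionally `porosity_pct`, `water_content_pct`,
#'   `sand_pct`, `silt_pct`, `clay_pct`. Layers must be ordered and
#'   non-overlapping.
#' @param effective_bulk_density Optional override, kg m^-3; when `NULL` the
#'   thickness-weighted mean is used.
#' @return An object of class `soil_profile`.
#' @export
#' @examples
#' sp <- soil_profile(data.frame(
#'   depth_top_cm = c(0, 15, 30, 45), depth_bottom_cm = c(15, 30, 45, 60),
#'   bulk_density_g_cm3 = c(1.02, 0.92, 1.17, 1.24)))
#' sp$effective_bulk_density  # 1087.5 kg/m^3
soil_profile <- function(layers, effective_bulk_density = NULL) {
  req <- c("depth_top_cm", "depth_bottom_cm", "bulk_density_g_cm3")
  miss <- setdiff(req, names(layers))
  if (length(miss))
    stop("soil layers missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(layers) == 0) stop("soil profile needs at least one layer",
                              call. = FALSE)
  o <- order(layers$depth_top_cm)
  layers <- layers[o, , drop = FALSE]
  if (any(layers$depth_bottom_cm <= layers$depth_top_cm))
    stop("each layer must have depth_bottom_cm > depth_top_cm", call. = FALSE)
  if (nrow(layers) > 1 &&
      any(layers$depth_top_cm[-1] < layers$depth_bottom_cm[-nrow(layers)]))
    stop("soil layers overlap", call. = FALSE)
  if (any(!is.finite(layers$bulk_density_g_cm3) |
          layers$bulk_density_g_cm3 <= 0))
    stop("bulk densities must be > 0", call. = FALSE)
  if (is.null(effective_bulk_density)) {
    w <- layers$depth_bottom_cm - layers$depth_top_cm
    effective_bulk_density <-
      1000 * sum(w * layers$bulk_density_g_cm3) / sum(w)
  }
  if (!is.finite(effective_bulk_density) || effective_bulk_density <= 0)
    stop("effective_bulk_density must be > 0", call. = FALSE)
  structure(list(layers = layers,
                 effective_bulk_density = effective_bulk_density),
            class = "soil_profile")
}

#' @export
print.soil_profile <- function(x, ...) {
  cat("Soil profile with", nrow(x$layers), "layers; effective bulk density",
      signif(x$effective_bulk_density, 6), "kg/m^3\n")
  invisible(x)
}

# rlang-style default operator, kept internal
`%||%` <- function(a, b) if (is.null(a)) b else a

.norm_species <- function(species) {
  s <- tolower(trimws(as.character(species)))
  s[s %in% c("s", "spruce", "picea")] <- "spruce"
  s[s %in% c("k", "korean_pine", "korean pine", "koreanpine", "pine")] <-
    "korean_pine"
  bad <- setdiff(unique(s), c("spruce", "korean_pine"))
  if (length(bad))
    stop("unknown species: ", paste(bad, collapse = ", "), call. = FALSE)
  s
}
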