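# Core mechanistic model: wind overturning moment vs stem and root-plate
# resistive moments, half-ellipsoid root-plate mass, R_m and Delta-prime.
# All functions are vectorized over trees; SI units internally (m, kg, N, N m)
# except DBH, which enters tables in cm and is converted where stated.

#' Validate a tree morphology table
#'
#' Checks the standing-tree schema (`tree_id`, `species`, `dbh_cm`,
#' `height_m`, `crown_base_m`, `crown_ew_m`, `crown_ns_m`) and its
#' invariants: positive DBH and crown widths, `height_m > crown_base_m >= 0`.
#'
#' @param trees data.frame in the tree-table schema.
#' @return The validated data.frame with species normalized to
#'   `"spruce"`/`"korean_pine"`, invisibly usable downstream.
#' @export
validate_trees <- function(trees) {
  req <- c("tree_id", "species", "dbh_cm", "height_m", "crown_base_m",
           "crown_ew_m", "crown_ns_m")
  miss <- setdiff(req, names(trees))
  if (length(miss))
    stop("tree table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  trees$species <- .norm_species(trees$species)
  if (nrow(trees) == 0) return(trees)
  num <- setdiff(req, c("tree_id", "species"))
  for (cl in num) {
    v <- trees[[cl]]
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)))
      stop("tree table column ", cl, " must be finite numeric", call. = FALSE)
  }
  bad <- which(trees$dbh_cm <= 0 | trees$crown_ew_m <= 0 |
                 trees$crown_ns_m <= 0 | trees$crown_base_m < 0 |
                 trees$height_m <= trees$crown_base_m)
  if (length(bad))
    stop("tree table invariant violated (need dbh > 0, crown widths > 0, ",
         "height > crown base >= 0) in row(s): ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ..." else "",
         " [", paste(utils::head(trees$tree_id[bad], 10), collapse = ", "),
         "]", call. = FALSE)
  trees
}

#' Crown radius from the two measured crown widths
#'
#' The crown spread is measured along two perpendicular axes (east-west and
#' north-south); the model's crown radius R is half their mean width.
#'
#' @param crown_ew,crown_ns Crown widths, m; both > 0.
#' @return Crown radius, m.
#' @export
#' @examples
#' crown_radius(5.2, 5.8)  # 2.75
crown_radius <- function(crown_ew, crown_ns) {
  if (any(!is.finite(crown_ew) | crown_ew <= 0) ||
      any(!is.finite(crown_ns) | crown_ns <= 0))
    stop("crown widths must be finite and > 0", call. = FALSE)
  (crown_ew + crown_ns) / 4
}

#' Frontal area of a conical crown
#'
#' With a conical crown the silhouette facing the wind is a triangle of base
#' 2R and height (H - H0), giving \eqn{S_{tc} = R (H - H_0)}.
#'
#' @param radius Crown radius R, m (>= 0; 0 gives a degenerate zero area).
#' @param height Tree height H, m.
#' @param crown_base Height to crown base H0, m; must satisfy H > H0.
#' @return Frontal area, m^2.
#' @export
crown_frontal_area <- function(radius, height, crown_base) {
  if (any(!is.finite(radius) | radius < 0))
    stop("crown radius must be finite and >= 0", call. = FALSE)
  .check_crown_span(height, crown_base)
  radius * (height - crown_base)
}

.check_crown_span <- function(height, crown_base) {
  if (any(!is.finite(height) | !is.finite(crown_base) | crown_base < 0 |
            height <= crown_base))
    stop("need tree height > crown base height >= 0 (zero crown length is ",
         "degenerate and rejected)", call. = FALSE)
  invisible(TRUE)
}

#' Horizontal wind load on the crown
#'
#' \eqn{W_c = 0.5 \rho_a C_d R (H - H_0) v^2}: drag on the crown frontal area
#' at the reference wind speed.
#'
#' @inheritParams crown_frontal_area
#' @param wind A [wind_params()] object.
#' @return Wind load, N.
#' @export
wind_load <- function(radius, height, crown_base, wind = wind_params()) {
  stopifnot(inherits(wind, "wind_params"))
  0.5 * wind$air_density * wind$drag_coefficient *
    crown_frontal_area(radius, height, crown_base) * wind$wind_speed^2
}

#' Lever arm of the wind load about the stem base
#'
#' The resultant wind force acts at 2/3 of the crown length below the crown
#' top, i.e. at height \eqn{L = (H + 2 H_0)/3 = H_0 + (H - H_0)/3} above the
#' anchorage point at the stem base.
#'
#' @inheritParams crown_frontal_area
#' @return Lever arm, m.
#' @export
wind_lever_arm <- function(height, crown_base) {
  .check_crown_span(height, crown_base)
  (height + 2 * crown_base) / 3
}

#' Wind overturning moment about the stem base
#'
#' \eqn{M_w = W_c L = (\rho_a C_d R v^2 / 6)(H + 2H_0)(H - H_0)}.
#'
#' @inheritParams wind_load
#' @return Overturning moment, N m.
#' @export
overturning_moment <- function(radius, height, crown_base,
                               wind = wind_params()) {
  wind_load(radius, height, crown_base, wind) *
    wind_lever_arm(height, crown_base)
}

#' Stem resistive moment
#'
#' Elastic restoring moment of the bent stem, \eqn{M_s = a D^3 H} with the
#' species coefficient `a` and D, H in metres. The index is comparable only
#' under this fixed unit convention.
#'
#' @param dbh_m Diameter at breast height, m.
#' @param height Tree height, m.
#' @param params A [species_params()] object (or a numeric coefficient `a`).
#' @return Stem moment in model units.
#' @export
#' @examples
#' stem_resistive_moment(0.267, 7.8, species_params("spruce"))  # ~0.4922
stem_resistive_moment <- function(dbh_m, height, params) {
  a <- if (inherits(params, "species_params")) params$stem_coefficient
       else params
  if (!is.numeric(a) || any(a <= 0))
    stop("stem coefficient must be > 0", call. = FALSE)
  if (any(!is.finite(dbh_m) | dbh_m <= 0) ||
      any(!is.finite(height) | height <= 0))
    stop("dbh and height must be > 0", call. = FALSE)
  a * dbh_m^3 * height
}

#' Half-ellipsoid root-plate volume
#'
#' The root plate is modelled as the lower half of an ellipsoid whose full
#' horizontal axes are the plate length and width and whose vertical semi-axis
#' is the plate depth: \eqn{V_r = (\pi/6) D_{rp} H_{rp} W_{rp}}. Axes
#' (r, 2r, 2r) recover the half-sphere \eqn{(2/3)\pi r^3}. A directly
#' measured volume, when supplied, takes precedence over the formula.
#'
#' @param depth Plate depth (vertical semi-axis) D_rp, m.
#' @param length,width Full horizontal axes H_rp, W_rp, m.
#' @param measured_volume Optional measured volume, m^3; `NA` entries fall
#'   back to the formula.
#' @return Volume, m^3.
#' @export
#' @examples
#' root_plate_volume(1, 2, 2)  # 2*pi/3, half-sphere of radius 1
root_plate_volume <- function(depth, length, width, measured_volume = NULL) {
  if (any(!is.finite(depth) | depth <= 0) ||
      any(!is.finite(length) | length <= 0) ||
      any(!is.finite(width) | width <= 0))
    stop("root plate dimensions must all be > 0", call. = FALSE)
  v <- pi / 6 * depth * length * width
  if (!is.null(measured_volume)) {
    use <- !is.na(measured_volume)
    if (any(measured_volume[use] <= 0))
      stop("measured_volume must be > 0 where given", call. = FALSE)
    v[use] <- measured_volume[use]
  }
  v
}

#' Soil mass enclosed in the root plate
#'
#' \eqn{G_s = \rho_s V_r} with the effective soil bulk density over the plate
#' depth.
#'
#' @param volume Root-plate volume, m^3.
#' @param soil A [soil_profile()] object, or a bulk density in kg m^-3.
#' @return Soil mass, kg.
#' @export
soil_mass_in_plate <- function(volume, soil) {
  rho <- if (inherits(soil, "soil_profile")) soil$effective_bulk_density
         else soil
  if (is.null(rho) || !is.numeric(rho) || any(!is.finite(rho) | rho <= 0))
    stop("soil bulk density missing or not > 0", call. = FALSE)
  if (any(!is.finite(volume) | volume < 0))
    stop("volume must be >= 0", call. = FALSE)
  rho * volume
}

#' Coarse-root biomass from the species allometry
#'
#' Evaluates \eqn{G_{cr} = b_0 D^{b_1} H^{b_2}} under the species' documented
#' unit convention and returns kilograms. The spruce allometry takes D in
#' decimetres and returns kg directly; the Korean pine allometry takes D in
#' centimetres and returns grams, which are converted. The conventions are a
#' calibration (the source allometries do not state them) and reproduce
#' published per-tree coarse-root masses to within a few percent.
#'
#' @param dbh_cm Diameter at breast height, cm.
#' @param height Tree height, m.
#' @param params A [species_params()] object.
#' @return Coarse-root biomass, kg.
#' @export
#' @examples
#' coarse_root_biomass(26.7, 7.8, species_params("spruce"))  # ~38.2 kg
coarse_root_biomass <- function(dbh_cm, height, params) {
  stopifnot(inherits(params, "species_params"))
  if (any(!is.finite(dbh_cm) | dbh_cm <= 0) ||
      any(!is.finite(height) | height <= 0))
    stop("dbh and height must be > 0", call. = FALSE)
  d <- switch(params$allometric_unit_convention,
              dbh_dm_out_kg = dbh_cm / 10,
              dbh_cm_out_g = dbh_cm,
              stop("unknown allometric_unit_convention", call. = FALSE))
  g <- params$allometric_b0 * d^params$allometric_b1 *
    height^params$allometric_b2
  if (params$allometric_unit_convention == "dbh_cm_out_g") g <- g / 1000
  g
}

#' Combine coarse-root and soil mass into a root-plate mass account
#'
#' @param coarse_root_mass,soil_mass Component masses, kg; both >= 0 and not
#'   both zero.
#' @return data.frame with `coarse_root_mass`, `soil_mass`, `total` and
#'   `coarse_root_fraction` (percent of total).
#' @export
#' @examples
#' root_plate_mass(40.01, 310.29)  # total 350.30, fraction 11.42%
root_plate_mass <- function(coarse_root_mass, soil_mass) {
  if (any(!is.finite(coarse_root_mass) | coarse_root_mass < 0) ||
      any(!is.finite(soil_mass) | soil_mass < 0))
    stop("masses must be finite and >= 0", call. = FALSE)
  total <- coarse_root_mass + soil_mass
  if (any(total == 0))
    stop("coarse-root and soil mass cannot both be zero", call. = FALSE)
  data.frame(coarse_root_mass = coarse_root_mass, soil_mass = soil_mass,
             total = total,
             coarse_root_fraction = 100 * coarse_root_mass / total)
}

#' Root-plate resistive moment
#'
#' The plate's centre of gravity lies \eqn{L_r = 4 D_{rp} / (3\pi)} from the
#' hinge, and only the fraction `f_r` of the plate weight contributes to
#' anchorage: \eqn{M_r = f_r L_r (G_{cr} + G_s) g}.
#'
#' @param depth Plate depth D_rp, m.
#' @param total_mass Total plate mass G_cr + G_s, kg.
#' @param params A [species_params()] object (or numeric `f_r`). `f_r = 0` is
#'   permitted here as the degenerate no-anchorage limit.
#' @param gravity Gravitational acceleration, N kg^-1 (default 9.81).
#' @return Resistive moment, N m.
#' @export
root_plate_resistive_moment <- function(depth, total_mass, params,
                                        gravity = 9.81) {
  fr <- if (inherits(params, "species_params")) params$anchorage_fraction
        else params
  if (!is.numeric(fr) || any(fr < 0 | fr > 1))
    stop("anchorage fraction must be in [0, 1]", call. = FALSE)
  if (any(!is.finite(depth) | depth <= 0))
    stop("plate depth must be > 0", call. = FALSE)
  if (any(!is.finite(total_mass) | total_mass < 0))
    stop("total mass must be >= 0", call. = FALSE)
  fr * (4 * depth / (3 * pi)) * total_mass * gravity
}

#' Resistance coefficient R_m
#'
#' Ratio of the total resistive moment to the overturning moment,
#' \eqn{R_m = (M_s + M_r) / M_w}; larger values mean a more windfirm tree.
#'
#' @param stem_moment,root_moment,overturning Moments; `overturning` must
#'   be > 0.
#' @return Dimensionless R_m.
#' @export
resistance_coefficient <- function(stem_moment, root_moment, overturning) {
  if (any(!is.finite(overturning) | overturning <= 0))
    stop("overturning moment must be > 0", call. = FALSE)
  (stem_moment + root_moment) / overturning
}

#' Wind-independent uprooting resistance index Delta-prime
#'
#' \deqn{\Delta' = \frac{3\pi a D^3 H + 4 f_r D_{rp} (G_{cr} + \rho_s V_r) g}
#'                      {3\pi R (H + 2H_0)(H - H_0)}}
#' with D, H in metres. Delta-prime equals \eqn{\mu R_m} for any wind constant
#' \eqn{\mu > 0}, so it ranks trees by uprooting resistance without fixing a
#' wind speed.
#'
#' @param dbh_m DBH, m.
#' @param height,crown_base Tree height and crown-base height, m.
#' @param radius Crown radius, m; must be > 0.
#' @param plate_depth Root-plate depth D_rp, m.
#' @param coarse_root_mass Coarse-root biomass G_cr, kg.
#' @param soil_mass Soil mass in the plate G_s (= rho_s V_r), kg.
#' @param params A [species_params()] object.
#' @param gravity N kg^-1, default 9.81.
#' @return Dimensionless Delta-prime.
#' @export
delta_prime <- function(dbh_m, height, crown_base, radius, plate_depth,
                        coarse_root_mass, soil_mass, params,
                        gravity = 9.81) {
  stopifnot(inherits(params, "species_params"))
  if (any(!is.finite(radius) | radius <= 0))
    stop("crown radius must be > 0", call. = FALSE)
  .check_crown_span(height, crown_base)
  num <- 3 * pi * stem_resistive_moment(dbh_m, height, params) +
    4 * params$anchorage_fraction * plate_depth *
      (coarse_root_mass + soil_mass) * gravity
  den <- 3 * pi * radius * (height + 2 * crown_base) * (height - crown_base)
  num / den
}

#' Full per-tree moment breakdown
#'
#' Runs the whole mechanistic chain for a table of trees joined to their
#' root-plate geometry and returns every intermediate quantity: frontal area,
#' wind load, lever arms, overturning moment, stem and root-plate resistive
#' moments, plate volume/mass accounting, R_m and Delta-prime.
#'
#' @param trees Tree table (see [validate_trees()]).
#' @param plates data.frame with `tree_id`, `depth_m`, `length_m`, `width_m`
#'   and optionally `volume_m3` (a measured volume overriding the
#'   half-ellipsoid formula).
#' @param soil A [soil_profile()] or numeric bulk density, kg m^-3.
#' @param wind A [wind_params()] object.
#' @param gravity N kg^-1, default 9.81.
#' @return data.frame, one row per tree, with the moment breakdown.
#' @export
moment_breakdown <- function(trees, plates, soil, wind = wind_params(),
                             gravity = 9.81) {
  trees <- validate_trees(trees)
  preq <- c("tree_id", "depth_m", "length_m", "width_m")
  miss <- setdiff(preq, names(plates))
  if (length(miss))
    stop("root-plate table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  idx <- match(trees$tree_id, plates$tree_id)
  if (anyNA(idx))
    stop("no root-plate record for tree(s): ",
         paste(trees$tree_id[is.na(idx)], collapse = ", "), call. = FALSE)
  plates <- plates[idx, , drop = FALSE]

  out <- data.frame(tree_id = trees$tree_id, species = trees$species,
                    stringsAsFactors = FALSE)
  R <- crown_radius(trees$crown_ew_m, trees$crown_ns_m)
  out$crown_radius_m <- R
  out$frontal_area_m2 <- crown_frontal_area(R, trees$height_m,
                                            trees$crown_base_m)
  out$wind_load_n <- wind_load(R, trees$height_m, trees$crown_base_m, wind)
  out$lever_arm_m <- wind_lever_arm(trees$height_m, trees$crown_base_m)
  out$overturning_nm <- out$wind_load_n * out$lever_arm_m

  mv <- if ("volume_m3" %in% names(plates)) plates$volume_m3 else NULL
  out$plate_volume_m3 <- root_plate_volume(plates$depth_m, plates$length_m,
                                           plates$width_m, mv)
  out$root_lever_arm_m <- 4 * plates$depth_m / (3 * pi)

  for (sp in unique(trees$species)) {
    i <- trees$species == sp
    p <- species_params(sp)
    out$stem_moment[i] <-
      stem_resistive_moment(trees$dbh_cm[i] / 100, trees$height_m[i], p)
    out$coarse_root_kg[i] <-
      coarse_root_biomass(trees$dbh_cm[i], trees$height_m[i], p)
    out$soil_mass_kg[i] <- soil_mass_in_plate(out$plate_volume_m3[i], soil)
    out$plate_mass_kg[i] <- out$coarse_root_kg[i] + out$soil_mass_kg[i]
    out$root_moment_nm[i] <-
      root_plate_resistive_moment(plates$depth_m[i], out$plate_mass_kg[i],
                                  p, gravity)
    out$delta_prime[i] <-
      delta_prime(trees$dbh_cm[i] / 100, trees$height_m[i],
                  trees$crown_base_m[i], R[i], plates$depth_m[i],
                  out$coarse_root_kg[i], out$soil_mass_kg[i], p, gravity)
  }
  out$resistance_coefficient <-
    resistance_coefficient(out$stem_moment, out$root_moment_nm,
                           out$overturning_nm)
  out
}
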