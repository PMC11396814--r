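# Core mechanistic model: geometry, moments, plate mass, R_m, Delta-prime.

test_that("crown radius and frontal area follow the conical-crown geometry", {
  expect_equal(crown_radius(5.2, 5.8), 2.75)           # mean width 5.5 / 2
  expect_equal(crown_radius(2, 2), 1.0)
  expect_equal(crown_radius(8.6, 8.7), 4.325)
  expect_error(crown_radius(-1, 2), "> 0")

  expect_equal(crown_frontal_area(2, 10, 4), 12)
  expect_equal(crown_frontal_area(2.75, 7.8, 3.7), 11.275)
  expect_equal(crown_frontal_area(0, 10, 4), 0)        # degenerate crown
  expect_error(crown_frontal_area(2, 4, 4), "height")  # H <= H0
})

test_that("wind load and lever arm evaluate and scale correctly", {
  w1 <- wind_params(air_density = 1, drag_coefficient = 1, wind_speed = 1)
  expect_equal(wind_load(1, 2, 1, w1), 0.5)
  # v^2 scaling
  w2 <- wind_params(1, 1, 2)
  expect_equal(wind_load(1, 2, 1, w2), 4 * wind_load(1, 2, 1, w1))
  expect_equal(
    wind_load(2.75, 7.8, 3.7, wind_params(1.2, 0.3, 10)), 202.95,
    tolerance = 0.1 / 202.95)
  expect_error(wind_params(wind_speed = 0), "> 0")

  expect_equal(wind_lever_arm(10, 4), 6)
  expect_equal(wind_lever_arm(9, 0), 3)                # H/3 at ground crown
  expect_equal(wind_lever_arm(7.8, 3.7), (7.8 + 7.4) / 3)
  # identity L = H0 + (H - H0)/3
  expect_equal(wind_lever_arm(13.2, 4.1), 4.1 + (13.2 - 4.1) / 3)
})

test_that("overturning moment: product form equals closed form", {
  # mu = 1 via rho*Cd*v^2 = 6
  w <- wind_params(air_density = 6, drag_coefficient = 1, wind_speed = 1)
  expect_equal(overturning_moment(2.75, 7.8, 3.7, w),
               2.75 * (7.8 + 2 * 3.7) * (7.8 - 3.7), tolerance = 1e-12)
  # randomized identity, 100 trees
  tr <- random_trees(100, seed = 11)
  wr <- wind_params(1.1, 0.4, 13)
  R <- crown_radius(tr$crown_ew_m, tr$crown_ns_m)
  prod_form <- wind_load(R, tr$height_m, tr$crown_base_m, wr) *
    wind_lever_arm(tr$height_m, tr$crown_base_m)
  closed <- wr$mu * R * (tr$height_m + 2 * tr$crown_base_m) *
    (tr$height_m - tr$crown_base_m)
  expect_equal(prod_form, closed, tolerance = 1e-9)
})

test_that("stem resistive moment is a*D^3*H with cubic DBH scaling", {
  expect_equal(stem_resistive_moment(1, 1, 3.315), 3.315)
  expect_equal(stem_resistive_moment(2, 5, 3.315),
               8 * stem_resistive_moment(1, 5, 3.315))
  expect_equal(stem_resistive_moment(0.267, 7.8, species_params("spruce")),
               0.4922, tolerance = 1e-4)
  expect_error(species_params("larch"))
})

test_that("root plate volume is the half-ellipsoid with measured override", {
  expect_equal(root_plate_volume(1, 2, 2), 2 * pi / 3, tolerance = 1e-12)
  expect_equal(root_plate_volume(1, 1, 1), pi / 6)
  expect_equal(root_plate_volume(0.4, 1.5, 1.2, measured_volume = 0.28), 0.28)
  # NA measured volume falls back to the formula, vectorized
  expect_equal(root_plate_volume(c(1, 1), c(1, 2), c(1, 2), c(NA, 0.5)),
               c(pi / 6, 0.5))
  expect_error(root_plate_volume(0, 1, 1), "> 0")
  # half-sphere limit at other radii
  for (r in c(0.3, 1.7))
    expect_equal(root_plate_volume(r, 2 * r, 2 * r), 2 / 3 * pi * r^3,
                 tolerance = 1e-12)
})

test_that("soil mass is linear in volume and bulk density", {
  expect_equal(soil_mass_in_plate(2, 1100), 2200)
  expect_equal(soil_mass_in_plate(0, 1100), 0)
  expect_equal(soil_mass_in_plate(2.00, 1087.7), 2175.4)
  expect_error(soil_mass_in_plate(1, NULL), "missing")
  sp <- soil_profile(data.frame(depth_top_cm = c(0, 15, 30, 45),
                                depth_bottom_cm = c(15, 30, 45, 60),
                                bulk_density_g_cm3 = c(1.02, 0.92, 1.17, 1.24)))
  expect_equal(sp$effective_bulk_density, 1087.5)
  expect_equal(soil_mass_in_plate(2, sp), 2175)
})

test_that("soil profile rejects malformed layer stacks", {
  expect_error(soil_profile(data.frame(depth_top_cm = 0, depth_bottom_cm = 0,
                                       bulk_density_g_cm3 = 1)), "bottom")
  expect_error(soil_profile(data.frame(depth_top_cm = c(0, 10),
                                       depth_bottom_cm = c(15, 30),
                                       bulk_density_g_cm3 = c(1, 1))),
               "overlap")
  expect_error(soil_profile(data.frame(depth_top_cm = 0, depth_bottom_cm = 15,
                                       bulk_density_g_cm3 = -1)), "> 0")
})

test_that("coarse-root allometry reproduces reference masses per convention", {
  # published per-tree values, documented tolerance of a few percent
  expect_equal(coarse_root_biomass(26.7, 7.8, species_params("spruce")),
               40.01, tolerance = 0.05)
  expect_equal(coarse_root_biomass(91.7, 30.9, species_params("korean_pine")),
               1149.48, tolerance = 0.05)
  # constant allometry when exponents vanish
  p0 <- species_params("spruce", allometric_b1 = 0, allometric_b2 = 0)
  expect_equal(coarse_root_biomass(10, 5, p0), 4.302)
  expect_equal(coarse_root_biomass(77, 31, p0), 4.302)
  # strictly increasing in D
  g <- coarse_root_biomass(seq(10, 80, by = 5), 20, species_params("spruce"))
  expect_true(all(diff(g) > 0))
})

test_that("root plate mass accounting conserves mass and fractions", {
  m <- root_plate_mass(40.01, 310.29)
  expect_equal(m$total, 350.30)
  expect_equal(m$coarse_root_fraction, 11.42, tolerance = 1e-3)
  expect_equal(root_plate_mass(0, 100)$coarse_root_fraction, 0)
  m19 <- root_plate_mass(17.57, 302.04)
  expect_equal(m19$total, 319.61)
  expect_equal(m19$coarse_root_fraction, 5.50, tolerance = 1e-3)
  expect_error(root_plate_mass(-1, 10), ">= 0")
  expect_error(root_plate_mass(0, 0), "both")
  # exact conservation on random masses
  set.seed(3)
  a <- runif(50, 0, 500); b <- runif(50, 1, 5000)
  mm <- root_plate_mass(a, b)
  expect_identical(mm$total - mm$coarse_root_mass - mm$soil_mass,
                   rep(0, 50))
})

test_that("root plate resistive moment uses the 4*Drp/(3*pi) lever arm", {
  expect_equal(root_plate_resistive_moment(3 * pi / 4, 100, 0.2), 196.2)
  expect_equal(root_plate_resistive_moment(0.5, 100, 0), 0)
  expect_equal(root_plate_resistive_moment(0.5, 535.31, 0.3), 334.3,
               tolerance = 0.1 / 334.3)
  expect_error(root_plate_resistive_moment(0.5, 100, 1.5), "fraction")
})

test_that("resistance coefficient is the moment ratio", {
  expect_equal(resistance_coefficient(1, 1, 1), 2)
  expect_equal(resistance_coefficient(0, 0, 5), 0)
  expect_equal(resistance_coefficient(4.64, 1100, 1615), 0.6840,
               tolerance = 0.001 / 0.684)
  expect_error(resistance_coefficient(1, 1, 0), "> 0")
})

test_that("Delta-prime equals mu * R_m for random trees and mu values", {
  tr <- random_trees(100, seed = 7)
  plates <- data.frame(tree_id = tr$tree_id,
                       depth_m = runif(100, 0.2, 0.9),
                       length_m = runif(100, 1, 4),
                       width_m = runif(100, 1, 4))
  rho <- 1087.5
  for (v in c(5, 8, 12, 20, 31)) {
    w <- wind_params(1.226, 0.29, v)
    mb <- moment_breakdown(tr, plates, rho, w)
    expect_equal(mb$delta_prime, w$mu * mb$resistance_coefficient,
                 tolerance = 1e-9)
  }
})

test_that("Delta-prime is monotone in D, Drp, fr, rho_s and anti-monotone in R", {
  p <- species_params("spruce")
  base <- list(dbh = 0.35, h = 14, h0 = 6, R = 3.5, drp = 0.5,
               gcr = 70, gs = 2000)
  d0 <- delta_prime(base$dbh, base$h, base$h0, base$R, base$drp,
                    base$gcr, base$gs, p)
  expect_gt(delta_prime(0.40, base$h, base$h0, base$R, base$drp,
                        base$gcr, base$gs, p), d0)
  expect_gt(delta_prime(base$dbh, base$h, base$h0, base$R, 0.7,
                        base$gcr, base$gs, p), d0)
  p_hi <- species_params("spruce", anchorage_fraction = 0.3)
  expect_gt(delta_prime(base$dbh, base$h, base$h0, base$R, base$drp,
                        base$gcr, base$gs, p_hi), d0)
  expect_gt(delta_prime(base$dbh, base$h, base$h0, base$R, base$drp,
                        base$gcr, base$gs * 1.2, p), d0)  # rho_s via G_s
  expect_lt(delta_prime(base$dbh, base$h, base$h0, 4.5, base$drp,
                        base$gcr, base$gs, p), d0)
  expect_error(delta_prime(base$dbh, 6, 6, base$R, base$drp,
                           base$gcr, base$gs, p), "height")
})

test_that("moment_breakdown joins plates by tree id and rejects orphans", {
  tr <- rbind(toy_tree("A"), toy_tree("B", species = "korean_pine"))
  pl <- rbind(toy_plate("B"), toy_plate("A"))  # order should not matter
  mb <- moment_breakdown(tr, pl, 1087.5)
  expect_equal(mb$tree_id, c("A", "B"))
  expect_equal(mb$overturning_nm, mb$wind_load_n * mb$lever_arm_m)
  expect_error(moment_breakdown(tr, toy_plate("A"), 1087.5), "B")
})
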