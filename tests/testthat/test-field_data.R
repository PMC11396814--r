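# GPR density summaries, ANOVA, Tukey HSD letters, soil physics.

test_that("coarse root density is count over scanned area", {
  expect_equal(coarse_root_density(5, 2, 0.25), 10)
  expect_equal(coarse_root_density(0, 2, 0.25), 0)
  expect_equal(coarse_root_density(12, 3.14, 0.15), 25.478,
               tolerance = 0.001 / 25.478)
  expect_error(coarse_root_density(5, 0, 0.25), "> 0")
  # degree 1 in count, degree -1 in each area dimension
  expect_equal(coarse_root_density(10, 2, 0.25),
               2 * coarse_root_density(5, 2, 0.25))
  expect_equal(coarse_root_density(5, 4, 0.25),
               coarse_root_density(5, 2, 0.25) / 2)
})

test_that("density profile summarizes groups and the shallow fraction", {
  rec <- data.frame(species = "spruce", transect_radius_m = 0.5,
                    depth_bin = "0-15", scan_length_m = 2, short_axis_m = 0.25,
                    root_count = c(5, 5, 5))
  p <- density_profile(rec)
  expect_equal(p$by_transect$mean_density, 10)
  expect_equal(p$by_transect$se, 0)
  expect_equal(p$shallow_fraction$fraction_0_30, 1)

  # generator-driven gradient: transect means monotone decreasing
  st <- generate_stand(stand_spec(6, 6), seed = 21)
  scans <- generate_gpr_scans(st, base_intensity = 60, decay = 1.1,
                              shallow_fraction = 0.75, seed = 22)
  pr <- density_profile(scans)
  for (sp in c("spruce", "korean_pine")) {
    bt <- pr$by_transect[pr$by_transect$species == sp, ]
    bt <- bt[order(as.numeric(bt$group)), ]
    expect_true(all(diff(bt$mean_density) < 0))
    expect_gt(pr$shallow_fraction$fraction_0_30[
      pr$shallow_fraction$species == sp], 0.70)
  }
  expect_error(density_profile(rec[0, ]), "empty")
  expect_error(density_profile(transform(rec, depth_bin = "0-20")),
               "depth bin")
})

test_that("one-way ANOVA matches the stats::lm oracle", {
  g <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(5, 6, 7))
  res <- oneway_anova(g)
  oracle <- anova(lm(value ~ group,
                     data = data.frame(value = unlist(g),
                                       group = rep(names(g), lengths(g)))))
  expect_equal(res$f, oracle$`F value`[1], tolerance = 1e-9)
  expect_equal(res$p, oracle$`Pr(>F)`[1], tolerance = 1e-9)
  # unbalanced case against the same oracle
  g2 <- list(a = c(3.1, 2.8, 3.5, 2.2), b = c(4.0, 4.4), c = c(1.1, 2.0, 0.7))
  res2 <- oneway_anova(g2)
  oracle2 <- anova(lm(value ~ group,
                      data = data.frame(value = unlist(g2),
                                        group = rep(names(g2), lengths(g2)))))
  expect_equal(res2$f, oracle2$`F value`[1], tolerance = 1e-9)
  # identical groups -> F = 0; zero within-variance guard -> Inf
  expect_equal(oneway_anova(list(a = c(1, 2), b = c(1, 2)))$f, 0)
  degen <- oneway_anova(list(a = c(0, 0), b = c(1, 1)))
  expect_equal(degen$f, Inf)
  expect_equal(degen$p, 0)
  expect_error(oneway_anova(list(a = 1:3)), "2 groups")
  expect_error(oneway_anova(list(a = 1, b = 1:2)), "at least 2 values")
})

test_that("Tukey HSD p-values match the stats::TukeyHSD oracle", {
  set.seed(5)
  g <- list(a = rnorm(6, 0), b = rnorm(5, 1.2), c = rnorm(7, 1.4),
            d = rnorm(4, 4))
  res <- tukey_hsd(g)
  df <- data.frame(value = unlist(g), group = factor(rep(names(g),
                                                         lengths(g))))
  oracle <- TukeyHSD(aov(value ~ group, data = df))$group
  key <- paste(res$pairs$group2, res$pairs$group1, sep = "-")
  expect_equal(res$pairs$p, unname(oracle[key, "p adj"]), tolerance = 1e-6)
  # direct q-statistic oracle for one pair
  mse <- res$mse
  q_ab <- abs(mean(g$a) - mean(g$b)) / sqrt(mse / 2 * (1 / 6 + 1 / 5))
  i <- res$pairs$group1 == "a" & res$pairs$group2 == "b"
  expect_equal(res$pairs$q[i], q_ab, tolerance = 1e-12)
})

test_that("compact letters separate exactly the significant pairs", {
  # all identical -> one shared letter
  same <- tukey_hsd(list(a = c(1, 1.01), b = c(1, 1.01), c = c(1, 1.01)))
  expect_true(all(same$letters == same$letters[1]))
  # far-separated groups -> disjoint letters
  far <- tukey_hsd(list(a = c(0, 0.1, 0.05), b = c(10, 10.1, 10.05),
                        c = c(20, 20.1, 20.05)))
  expect_equal(unname(far$letters), c("a", "b", "c"))
  # property over random draws: share-no-letter <=> significant
  for (s in 1:5) {
    set.seed(100 + s)
    g <- lapply(setNames(nm = letters[1:4]),
                function(i) rnorm(5, sample(0:3, 1)))
    res <- tukey_hsd(g)
    for (r in seq_len(nrow(res$pairs))) {
      l1 <- strsplit(res$letters[[res$pairs$group1[r]]], "")[[1]]
      l2 <- strsplit(res$letters[[res$pairs$group2[r]]], "")[[1]]
      expect_identical(length(intersect(l1, l2)) == 0, res$pairs$significant[r])
    }
  }
  expect_error(tukey_hsd(list(a = 1:3)), "2 groups")
})

test_that("soil physics formulas and guards", {
  expect_equal(gravimetric_water_content(150, 100), 50)
  expect_equal(gravimetric_water_content(100, 100), 0)
  expect_equal(gravimetric_water_content(144.17, 100), 44.17)
  expect_error(gravimetric_water_content(10, 0), "> 0")
  expect_error(gravimetric_water_content(90, 100), ">=")

  expect_equal(bulk_density_from_core(102, 100), 1.02)
  expect_equal(bulk_density_from_core(92, 100), 0.92)
  expect_equal(bulk_density_from_core(55, 55), 1)
  expect_error(bulk_density_from_core(10, 0), "> 0")

  expect_equal(porosity_from_bulk_density(1.325), 50)
  expect_equal(porosity_from_bulk_density(1e-9), 100, tolerance = 1e-6)
  expect_equal(porosity_from_bulk_density(1.02), 61.50943, tolerance = 1e-6)
  expect_error(porosity_from_bulk_density(2.7), "particle")
  # strictly decreasing in bulk density
  expect_true(all(diff(porosity_from_bulk_density(seq(0.5, 2.5, 0.1))) < 0))
})
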