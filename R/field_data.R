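# Field-derived quantities: GPR coarse-root density per transect and depth
# bin with one-way ANOVA + Tukey HSD letters, and soil physical properties.

.depth_bins <- c("0-15", "15-30", "30-45", ">45")

#' Coarse-root density of one GPR scan
#'
#' Number of coarse roots picked along a scan divided by the scanned area,
#' the scan length times the short axis of the radar-formed ellipse (the
#' depth-bin extent), in roots per m^2.
#'
#' @param root_count Non-negative integer count of detected roots.
#' @param scan_length Scan length, m (> 0).
#' @param short_axis Short axis of the scanned area, m (> 0).
#' @return Density, roots m^-2.
#' @export
#' @examples
#' coarse_root_density(5, 2, 0.25)  # 10
coarse_root_density <- function(root_count, scan_length, short_axis) {
  if (any(!is.finite(scan_length) | scan_length <= 0) ||
      any(!is.finite(short_axis) | short_axis <= 0))
    stop("scan area dimensions must be > 0", call. = FALSE)
  if (any(!is.finite(root_count) | root_count < 0))
    stop("root_count must be >= 0", call. = FALSE)
  root_count / (scan_length * short_axis)
}

#' Density profile across transects and depth bins
#'
#' Computes the per-scan densities and summarizes them by species along the
#' horizontal (transect radius) and vertical (depth bin) directions: group
#' mean, standard error and n, plus the fraction of all detected roots in the
#' shallow 0-30 cm depth range.
#'
#' @param scans data.frame with columns `species`, `transect_radius_m`,
#'   `depth_bin` (one of `"0-15"`, `"15-30"`, `"30-45"`, `">45"`),
#'   `scan_length_m`, `short_axis_m`, `root_count`.
#' @return List with data.frames `by_transect`, `by_depth` (columns species,
#'   group, mean_density, se, n) and `shallow_fraction` (species, fraction of
#'   roots at 0-30 cm).
#' @export
density_profile <- function(scans) {
  req <- c("species", "transect_radius_m", "depth_bin", "scan_length_m",
           "short_axis_m", "root_count")
  miss <- setdiff(req, names(scans))
  if (length(miss))
    stop("scan table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(scans) == 0) stop("scan table is empty", call. = FALSE)
  bad <- setdiff(unique(as.character(scans$depth_bin)), .depth_bins)
  if (length(bad))
    stop("unknown depth bin(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(.depth_bins, collapse = ", "), ")",
         call. = FALSE)
  scans$species <- .norm_species(scans$species)
  scans$density <- coarse_root_density(scans$root_count, scans$scan_length_m,
                                       scans$short_axis_m)

  summarize <- function(key) {
    g <- interaction(scans$species, scans[[key]], drop = TRUE, sep = "\r")
    m <- tapply(scans$density, g, mean)
    s <- tapply(scans$density, g, stats::sd)
    n <- tapply(scans$density, g, length)
    parts <- do.call(rbind, strsplit(names(m), "\r", fixed = TRUE))
    out <- data.frame(species = parts[, 1], group = parts[, 2],
                      mean_density = as.numeric(m),
                      se = ifelse(n > 1, as.numeric(s) / sqrt(as.numeric(n)),
                                  NA_real_),
                      n = as.integer(n), stringsAsFactors = FALSE)
    out[order(out$species, out$group), , drop = FALSE]
  }
  by_transect <- summarize("transect_radius_m")
  by_depth <- summarize("depth_bin")
  # empty design cells are simply absent from the output; flag them
  for (sp in unique(scans$species)) {
    seen <- by_depth$group[by_depth$species == sp]
    gap <- setdiff(intersect(.depth_bins, unique(scans$depth_bin)), seen)
    if (length(gap))
      warning("species ", sp, " has no scans in depth bin(s): ",
              paste(gap, collapse = ", "), call. = FALSE)
  }

  shallow <- vapply(split(scans, scans$species), function(d) {
    sum(d$root_count[d$depth_bin %in% c("0-15", "15-30")]) /
      sum(d$root_count)
  }, numeric(1))
  list(by_transect = by_transect, by_depth = by_depth,
       shallow_fraction = data.frame(species = names(shallow),
                                     fraction_0_30 = as.numeric(shallow),
                                     stringsAsFactors = FALSE))
}

.as_groups <- function(groups) {
  if (is.data.frame(groups)) groups <- split(groups$value, groups$group)
  if (!is.list(groups) || length(groups) < 2)
    stop("need at least 2 groups", call. = FALSE)
  if (any(vapply(groups, length, 1L) < 2))
    stop("each group needs at least 2 values", call. = FALSE)
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  lapply(groups, as.numeric)
}

#' One-way ANOVA
#'
#' Classical fixed-effects one-way analysis of variance via between/within
#' sums of squares. Zero within-group variance with distinct group means is
#' reported explicitly as `F = Inf`, `p = 0` rather than failing.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each >= 2
#'   values), or a data.frame with columns `value` and `group`.
#' @return List: `f`, `p`, `df_between`, `df_within`, `ss_between`,
#'   `ss_within`.
#' @export
#' @examples
#' oneway_anova(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(5, 6, 7)))
oneway_anova <- function(groups) {
  g <- .as_groups(groups)
  k <- length(g)
  n <- vapply(g, length, 1L)
  N <- sum(n)
  means <- vapply(g, mean, 1)
  grand <- sum(unlist(g)) / N
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum(vapply(g, function(x) sum((x - mean(x))^2), 1))
  dfb <- k - 1L
  dfw <- N - k
  if (ssw == 0) {
    if (ssb == 0) return(list(f = 0, p = 1, df_between = dfb, df_within = dfw,
                              ss_between = 0, ss_within = 0))
    return(list(f = Inf, p = 0, df_between = dfb, df_within = dfw,
                ss_between = ssb, ss_within = 0))
  }
  f <- (ssb / dfb) / (ssw / dfw)
  list(f = f, p = stats::pf(f, dfb, dfw, lower.tail = FALSE),
       df_between = dfb, df_within = dfw, ss_between = ssb, ss_within = ssw)
}

#' Tukey HSD pairwise comparisons with a compact letter display
#'
#' All pairwise group comparisons by the studentized range statistic
#' \eqn{q = |\bar y_i - \bar y_j| / \sqrt{(MSE/2)(1/n_i + 1/n_j)}} with
#' Tukey-Kramer adjustment for unbalanced groups; p-values from `ptukey`.
#' Groups are then coded with letters such that two groups share no letter
#' exactly when they differ significantly at `alpha` (insert-and-absorb
#' algorithm, letters assigned over groups in alphabetical order).
#'
#' @inheritParams oneway_anova
#' @param alpha Familywise significance level (default 0.05).
#' @return List: `pairs` (data.frame group1, group2, diff, q, p,
#'   significant), `letters` (named character vector), `alpha`, `mse`, `df`.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  g <- .as_groups(groups)
  g <- g[order(names(g))]
  k <- length(g)
  n <- vapply(g, length, 1L)
  means <- vapply(g, mean, 1)
  dfw <- sum(n) - k
  mse <- sum(vapply(g, function(x) sum((x - mean(x))^2), 1)) / dfw

  cmb <- utils::combn(k, 2)
  diff <- means[cmb[1, ]] - means[cmb[2, ]]
  se <- sqrt(mse / 2 * (1 / n[cmb[1, ]] + 1 / n[cmb[2, ]]))
  q <- ifelse(se == 0, ifelse(diff == 0, 0, Inf), abs(diff) / se)
  p <- ifelse(is.infinite(q), 0,
              stats::ptukey(q, nmeans = k, df = dfw, lower.tail = FALSE))
  p[q == 0] <- 1
  pairs <- data.frame(group1 = names(g)[cmb[1, ]],
                      group2 = names(g)[cmb[2, ]],
                      diff = as.numeric(diff), q = as.numeric(q),
                      p = as.numeric(p), significant = p < alpha,
                      stringsAsFactors = FALSE)
  letters_out <- .compact_letters(names(g), pairs)
  list(pairs = pairs, letters = letters_out, alpha = alpha, mse = mse,
       df = dfw)
}

# Insert-and-absorb compact letter display: maintain a membership matrix of
# letter-columns; each significant pair splits every column containing both.
.compact_letters <- function(grp, pairs) {
  m <- matrix(TRUE, nrow = length(grp), ncol = 1, dimnames = list(grp, NULL))
  sig <- pairs[pairs$significant, , drop = FALSE]
  for (r in seq_len(nrow(sig))) {
    i <- sig$group1[r]; j <- sig$group2[r]
    both <- which(m[i, ] & m[j, ])
    for (cl in both) {
      m <- cbind(m, m[, cl])
      m[i, cl] <- FALSE
      m[j, ncol(m)] <- FALSE
    }
    # absorb columns that became subsets of another
    keep <- rep(TRUE, ncol(m))
    for (a in seq_len(ncol(m))) for (b in seq_len(ncol(m))) {
      if (a != b && keep[a] && keep[b] &&
          all(m[, a] <= m[, b]) && any(m[, a] != m[, b]))
        keep[a] <- FALSE
    }
    m <- m[, keep, drop = FALSE]
  }
  # order columns by first member so letters read alphabetically over groups
  m <- m[, order(apply(m, 2, which.max)), drop = FALSE]
  lab <- vapply(seq_len(nrow(m)), function(i)
    paste(letters[which(m[i, ])], collapse = ""), character(1))
  stats::setNames(lab, grp)
}

#' Gravimetric soil water content
#'
#' Mass lost on oven-drying (105 degrees C, 24 h) relative to the dry mass,
#' in percent: `100 * (wet - dry) / dry`.
#'
#' @param wet_mass,dry_mass Sample masses, g; `wet_mass >= dry_mass > 0`.
#' @return Water content, percent.
#' @export
gravimetric_water_content <- function(wet_mass, dry_mass) {
  if (any(!is.finite(dry_mass) | dry_mass <= 0))
    stop("dry_mass must be > 0", call. = FALSE)
  if (any(!is.finite(wet_mass) | wet_mass < dry_mass))
    stop("wet_mass must be >= dry_mass", call. = FALSE)
  100 * (wet_mass - dry_mass) / dry_mass
}

#' Bulk density from a soil core
#'
#' @param dry_mass Oven-dry mass, g.
#' @param core_volume Core volume, cm^3 (> 0).
#' @return Bulk density, g cm^-3.
#' @export
bulk_density_from_core <- function(dry_mass, core_volume) {
  if (any(!is.finite(core_volume) | core_volume <= 0))
    stop("core_volume must be > 0", call. = FALSE)
  if (any(!is.finite(dry_mass) | dry_mass <= 0))
    stop("dry_mass must be > 0", call. = FALSE)
  dry_mass / core_volume
}

#' Porosity from bulk density
#'
#' `100 * (1 - bulk / particle)` with an assumed particle density of
#' 2.65 g cm^-3. Strictly decreasing in bulk density.
#'
#' @param bulk Bulk density, g cm^-3; must satisfy `0 < bulk < particle`.
#' @param particle Particle density, g cm^-3 (default 2.65).
#' @return Porosity, percent.
#' @export
porosity_from_bulk_density <- function(bulk, particle = 2.65) {
  if (any(!is.finite(bulk) | bulk <= 0))
    stop("bulk density must be > 0", call. = FALSE)
  if (any(bulk >= particle))
    stop("bulk density must be below the particle density", call. = FALSE)
  100 * (1 - bulk / particle)
}
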