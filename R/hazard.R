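# Hazard-threshold calibration from uprooted-tree references and three-level
# classification of standing trees.

#' Uprooted-tree reference for threshold calibration
#'
#' Either raw Delta-prime values of actually uprooted trees or their summary
#' moments (mean, sd, n). Raw values are reduced to their sample mean/sd.
#'
#' @param species `"spruce"` or `"korean_pine"`.
#' @param values Optional numeric vector of per-tree Delta-prime values
#'   (finite, > 0, length >= 2).
#' @param mean,sd,n Summary moments when no raw values are given; `sd >= 0`,
#'   `n >= 2` (n is retained for provenance but unused by the default
#'   mean + z * sd calibration).
#' @param source Free-text provenance label.
#' @return Object of class `uprooted_reference`.
#' @export
uprooted_reference <- function(species, values = NULL, mean = NULL, sd = NULL,
                               n = NULL, source = "unspecified") {
  species <- .norm_species(species)
  if (!is.null(values)) {
    if (length(values) < 2 || any(!is.finite(values) | values <= 0))
      stop("reference values must be >= 2 finite positives", call. = FALSE)
    mean <- base::mean(values)
    sd <- stats::sd(values)
    n <- length(values)
  } else {
    if (is.null(mean) || is.null(sd))
      stop("supply either raw values or mean and sd", call. = FALSE)
    if (!is.finite(sd) || sd < 0) stop("sd must be >= 0", call. = FALSE)
    if (!is.null(n) && n < 2) stop("n must be >= 2", call. = FALSE)
  }
  structure(list(species = species, values = values, mean = mean, sd = sd,
                 n = n, source = source),
            class = "uprooted_reference")
}

#' Calibrate critical Delta-prime thresholds
#'
#' The mean Delta-prime of uprooted reference trees marks the typical failure
#' level; the 95% and 99% one-sided bands `mean + z * sd` (two-sided normal
#' quantiles z95 = 1.959964, z99 = 2.575829) define the hazard boundaries,
#' rounded to `rounding` decimals before use so that table replays are
#' bit-stable.
#'
#' @param ref An [uprooted_reference()] (or anything with `$mean`, `$sd`).
#' @param z95,z99 Normal multipliers; `z95 < z99` required.
#' @param rounding Decimal places applied to both thresholds (default 2).
#' @return Object of class `hazard_thresholds` with elements `t95`, `t99`,
#'   `species`, `rounding`.
#' @export
#' @examples
#' critical_thresholds(uprooted_reference("spruce", mean = 0.66, sd = 0.33))
#' # t95 = 1.31, t99 = 1.51
critical_thresholds <- function(ref, z95 = 1.959964, z99 = 2.575829,
                                rounding = 2) {
  if (!is.finite(ref$sd) || ref$sd < 0) stop("sd must be >= 0", call. = FALSE)
  if (!is.null(ref$n) && ref$n < 2)
    stop("reference needs n >= 2", call. = FALSE)
  if (z95 >= z99) stop("z95 must be < z99", call. = FALSE)
  t95 <- round(ref$mean + z95 * ref$sd, rounding)
  t99 <- round(ref$mean + z99 * ref$sd, rounding)
  structure(list(species = ref$species %||% NA_character_,
                 t95 = t95, t99 = t99, rounding = rounding),
            class = "hazard_thresholds")
}

#' @export
print.hazard_thresholds <- function(x, ...) {
  cat("Hazard thresholds", if (!is.na(x$species)) paste0("[", x$species, "]"),
      ": High <= ", x$t95, " < Moderate < ", x$t99, " <= Low\n", sep = "")
  invisible(x)
}

.hazard_levels <- c("High", "Moderate", "Low")

#' Classify trees into uprooting hazard levels
#'
#' High if `delta <= t95`; Moderate if `t95 < delta < t99`; Low if
#' `delta >= t99`. The upper boundary is assigned to Low so that a tree
#' sitting exactly on the 99% band is not flagged as at-risk; this matches
#' the published per-tree labels (see the methods vignette).
#'
#' @param delta Numeric vector of Delta-prime values (finite).
#' @param thresholds A `hazard_thresholds` object.
#' @return Ordered factor with levels High > Moderate > Low (in hazard).
#' @export
#' @examples
#' th <- critical_thresholds(uprooted_reference("spruce", mean = 0.66, sd = 0.33))
#' classify_tree(c(1.18, 1.40, 1.51), th)  # High, Moderate, Low
classify_tree <- function(delta, thresholds) {
  stopifnot(inherits(thresholds, "hazard_thresholds"))
  if (any(!is.finite(delta)))
    stop("Delta-prime values must be finite", call. = FALSE)
  lev <- ifelse(delta <= thresholds$t95, "High",
                ifelse(delta < thresholds$t99, "Moderate", "Low"))
  factor(lev, levels = .hazard_levels)
}

#' Per-species and total hazard counts for a stand
#'
#' @param deltas Numeric vector of Delta-prime values.
#' @param species Character vector, same length, `"spruce"`/`"korean_pine"`.
#' @param thresholds Named list of `hazard_thresholds`, one entry per species
#'   present.
#' @return List with `by_species` (data.frame species x level counts),
#'   `total` (named counts), `n`.
#' @export
summarize_stand <- function(deltas, species, thresholds) {
  if (length(deltas) != length(species))
    stop("deltas and species differ in length", call. = FALSE)
  if (length(deltas) == 0) {
    tot <- stats::setNames(rep(0L, 3), .hazard_levels)
    return(list(by_species = data.frame(species = character(),
                                        High = integer(), Moderate = integer(),
                                        Low = integer()),
                total = tot, n = 0L))
  }
  species <- .norm_species(species)
  need <- unique(species)
  miss <- setdiff(need, names(thresholds))
  if (length(miss))
    stop("no thresholds supplied for species: ",
         paste(miss, collapse = ", "), call. = FALSE)
  lev <- factor(rep(NA_character_, length(deltas)), levels = .hazard_levels)
  for (sp in need) {
    i <- species == sp
    lev[i] <- classify_tree(deltas[i], thresholds[[sp]])
  }
  tab <- table(species = species, level = lev)
  by_species <- as.data.frame.matrix(tab)
  by_species <- cbind(species = rownames(by_species), by_species,
                      stringsAsFactors = FALSE)
  rownames(by_species) <- NULL
  total <- stats::setNames(as.integer(colSums(tab)), colnames(tab))
  list(by_species = by_species, total = total, n = length(deltas),
       levels = lev)
}
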