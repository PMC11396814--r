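# CSV readers/writers, packaged reference tables, thresholds files and the
# end-to-end assessment pipeline. CSV dialect is fixed: UTF-8, comma
# separated, header row, "." decimal mark.

.read_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

.require_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  invisible(df)
}

.check_numeric_cols <- function(df, cols, what, allow_na = character()) {
  for (cl in cols) {
    v <- df[[cl]]
    if (is.character(v) || is.factor(v))
      v <- suppressWarnings(as.numeric(as.character(v)))
    bad <- which(!is.finite(v))
    if (cl %in% allow_na) bad <- which(!is.finite(v) & !is.na(df[[cl]]))
    if (length(bad))
      stop(what, ": non-numeric or non-finite value in column ", cl,
           ", row(s) ", paste(utils::head(bad, 10), collapse = ", "),
           call. = FALSE)
    df[[cl]] <- v
  }
  df
}

#' Read a standing-tree morphology table
#'
#' Expected columns: `tree_id`, `species`, `dbh_cm`, `height_m`,
#' `crown_base_m`, `crown_ew_m`, `crown_ns_m` (extra columns are kept).
#' Species labels are normalized; all type invariants are enforced with
#' row-targeted error messages.
#'
#' @param path CSV file path.
#' @return Validated data.frame of trees.
#' @export
read_tree_table <- function(path) {
  df <- .read_csv(path)
  .require_cols(df, c("tree_id", "species", "dbh_cm", "height_m",
                      "crown_base_m", "crown_ew_m", "crown_ns_m"),
                "tree table")
  if (nrow(df) == 0) return(validate_trees(df[0, , drop = FALSE]))
  df <- .check_numeric_cols(df, c("dbh_cm", "height_m", "crown_base_m",
                                  "crown_ew_m", "crown_ns_m"), "tree table")
  validate_trees(df)
}

#' Read a root-plate geometry table
#'
#' Expected columns: `tree_id`, `depth_m`, `length_m`, `width_m`, optional
#' `volume_m3` (a measured volume that overrides the half-ellipsoid formula;
#' blank cells fall back to the formula).
#'
#' @param path CSV file path.
#' @return data.frame of root plates.
#' @export
read_rootplate_table <- function(path) {
  df <- .read_csv(path)
  .require_cols(df, c("tree_id", "depth_m", "length_m", "width_m"),
                "root-plate table")
  if (nrow(df) == 0) return(df)
  df <- .check_numeric_cols(df, intersect(c("depth_m", "length_m", "width_m",
                                            "volume_m3"), names(df)),
                            "root-plate table", allow_na = "volume_m3")
  bad <- which(df$depth_m <= 0 | df$length_m <= 0 | df$width_m <= 0 |
                 (if ("volume_m3" %in% names(df))
                    !is.na(df$volume_m3) & df$volume_m3 <= 0 else FALSE))
  if (length(bad))
    stop("root-plate table: non-positive dimension in row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  df
}

#' Read a layered soil table into a soil profile
#'
#' @param path CSV with columns `depth_top_cm`, `depth_bottom_cm`,
#'   `bulk_density_g_cm3` (the packaged soil fixture qualifies).
#' @param effective_bulk_density Optional override, kg m^-3.
#' @return A [soil_profile()].
#' @export
read_soil_table <- function(path, effective_bulk_density = NULL) {
  soil_profile(.read_csv(path), effective_bulk_density)
}

#' Read a GPR scan table
#'
#' @param path CSV with columns `tree_id`, `species`, `transect_radius_m`,
#'   `depth_bin`, `scan_length_m`, `short_axis_m`, `root_count`.
#' @return data.frame of scan records.
#' @export
read_scan_table <- function(path) {
  df <- .read_csv(path)
  .require_cols(df, c("tree_id", "species", "transect_radius_m", "depth_bin",
                      "scan_length_m", "short_axis_m", "root_count"),
                "scan table")
  .check_numeric_cols(df, c("transect_radius_m", "scan_length_m",
                            "short_axis_m", "root_count"), "scan table")
}

#' Read an uprooted-tree reference table
#'
#' Accepts either per-tree values (columns `species`, `delta_u`) or summary
#' rows (columns `species`, `delta_u_mean`, `delta_u_sd`, as in the packaged
#' reference fixture).
#'
#' @param path CSV file path.
#' @return Named list of [uprooted_reference()] objects, one per species.
#' @export
read_uprooted_reference <- function(path) {
  df <- .read_csv(path)
  .require_cols(df, "species", "reference table")
  df$species <- .norm_species(df$species)
  out <- list()
  if ("delta_u" %in% names(df)) {
    for (sp in unique(df$species))
      out[[sp]] <- uprooted_reference(sp,
                                      values = df$delta_u[df$species == sp],
                                      source = path)
  } else if (all(c("delta_u_mean", "delta_u_sd") %in% names(df))) {
    for (i in seq_len(nrow(df)))
      out[[df$species[i]]] <- uprooted_reference(
        df$species[i], mean = df$delta_u_mean[i], sd = df$delta_u_sd[i],
        n = if ("n" %in% names(df)) df$n[i] else NULL, source = path)
  } else {
    stop("reference table needs either a delta_u column or ",
         "delta_u_mean/delta_u_sd columns", call. = FALSE)
  }
  out
}

.fixture_names <- c("table1_soil", "table2_rootplates",
                    "table3_uprooted_reference", "table4_delta_labels",
                    "table5_morphology")

#' Packaged reference tables
#'
#' Returns one of the reference tables shipped with the package, cell-for-cell
#' as printed in the source publication, with a `note` column flagging the
#' known anomalies (an off-band per-tree hazard label, a suspect root-plate
#' volume/mass column pair, a range/maximum mismatch). Anomalies are never
#' silently corrected.
#'
#' @param name One of `"table1_soil"`, `"table2_rootplates"`,
#'   `"table3_uprooted_reference"`, `"table4_delta_labels"`,
#'   `"table5_morphology"`.
#' @return data.frame.
#' @export
#' @examples
#' nrow(windfirm_fixture("table5_morphology"))  # 40
windfirm_fixture <- function(name = .fixture_names) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "windfirm",
                      mustWork = TRUE)
  .read_csv(path)
}

#' Export the packaged reference tables to a directory
#'
#' @param dir Target directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
export_fixtures <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(.fixture_names, function(nm) {
    src <- system.file("extdata", paste0(nm, ".csv"), package = "windfirm",
                       mustWork = TRUE)
    dst <- file.path(dir, basename(src))
    file.copy(src, dst, overwrite = TRUE)
    dst
  }, character(1))
  invisible(paths)
}

#' Write / read a hazard-thresholds file
#'
#' Thresholds are stored as JSON keyed by species with `t95`, `t99` and the
#' rounding used, so that a calibration can be archived and replayed
#' bit-identically.
#'
#' @param thresholds Named list of `hazard_thresholds` objects.
#' @param path File path.
#' @return `read_thresholds` returns the named list.
#' @export
write_thresholds <- function(thresholds, path) {
  x <- lapply(thresholds, function(t)
    list(t95 = t$t95, t99 = t$t99, rounding = t$rounding))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(names(x), function(sp)
    structure(list(species = sp, t95 = x[[sp]]$t95, t99 = x[[sp]]$t99,
                   rounding = x[[sp]]$rounding %||% 2),
              class = "hazard_thresholds"))
  stats::setNames(out, names(x))
}

#' Default hazard thresholds
#'
#' Thresholds calibrated from the published uprooted-tree reference moments:
#' spruce mean 0.66, sd 0.33 giving (1.31, 1.51); Korean pine mean 0.46,
#' sd 0.38 giving (1.20, 1.44).
#'
#' @return Named list of `hazard_thresholds`.
#' @export
default_thresholds <- function() {
  list(
    spruce = critical_thresholds(
      uprooted_reference("spruce", mean = 0.66, sd = 0.33)),
    korean_pine = critical_thresholds(
      uprooted_reference("korean_pine", mean = 0.46, sd = 0.38)))
}

#' Run the full uprooting-hazard assessment pipeline
#'
#' Computes the per-tree moment breakdown and Delta-prime, classifies each
#' tree against its species thresholds, and optionally writes the report as
#' CSV. The run is deterministic: identical inputs give a byte-identical
#' report.
#'
#' @param trees Tree table (data.frame or CSV path).
#' @param plates Root-plate table (data.frame or CSV path).
#' @param soil A [soil_profile()], numeric bulk density in kg m^-3, or CSV
#'   path to a soil table.
#' @param thresholds Named list of `hazard_thresholds` per species (default
#'   [default_thresholds()]).
#' @param wind A [wind_params()].
#' @param out Optional output CSV path for the per-tree report.
#' @return List: `report` (per-tree data.frame including `delta_prime` and
#'   `hazard_level`) and `summary` (per-species and total level counts).
#' @export
run_assessment <- function(trees, plates, soil, thresholds = default_thresholds(),
                           wind = wind_params(), out = NULL) {
  if (is.character(trees)) trees <- read_tree_table(trees)
  if (is.character(plates)) plates <- read_rootplate_table(plates)
  if (is.character(soil)) soil <- read_soil_table(soil)
  report <- moment_breakdown(trees, plates, soil, wind)
  summ <- summarize_stand(report$delta_prime, report$species, thresholds)
  report$hazard_level <- as.character(summ$levels)
  if (!is.null(out)) write_report(report, out)
  list(report = report, summary = summ[c("by_species", "total", "n")])
}

#' Write / read a per-tree hazard report
#'
#' Numeric columns are written at 6 significant digits; a write-then-read
#' round trip is the identity at that precision.
#'
#' @param report data.frame as produced by [run_assessment()].
#' @param path CSV file path.
#' @export
write_report <- function(report, path) {
  num <- vapply(report, is.numeric, TRUE)
  report[num] <- lapply(report[num], signif, digits = 6)
  utils::write.csv(report, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) .read_csv(path)
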