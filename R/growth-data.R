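#' Read annual tree measurements from a trial CSV
#'
#' Reads a long-format remeasurement table: one row per tree per year, with
#' clone identity, cross type (direct `DxM` or reciprocal `MxD`), block,
#' tree id, age (years since planting) and the two field measurements,
#' diameter at breast height (cm) and total height (m). The canonical header
#' is `clone_id, cross_type, block, tree_id, age, dbh_cm, height_m`;
#' files with other headers are read through `col_map`.
#'
#' Rows with non-positive diameter or height, a non-integer or non-positive
#' age, or an unknown cross type are rejected (not silently dropped): a
#' warning reports the count and the rejected rows are attached as the
#' `"rejected"` attribute with a `reason` column. A missing required column
#' or a duplicated (clone, block, tree, age) key is a hard error.
#'
#' @param path Path to a CSV file (UTF-8, `.` decimal separator).
#' @param col_map Optional named character vector mapping canonical column
#'   names to the headers used in the file, e.g.
#'   `c(dbh_cm = "DBH_cm", height_m = "H")`. Unmapped canonical names are
#'   expected verbatim.
#' @param quiet If `TRUE`, suppress the row-count message.
#'
#' @return A tibble with columns `clone_id`, `cross_type`, `block`,
#'   `tree_id`, `age`, `dbh`, `height` (measurements in cm and m), with
#'   attributes `rejected` (tibble of dropped rows) and `source` (the path).
#' @seealso [derive_traits()] to add HDR, basal area and volume;
#'   [write_traits()] for the inverse operation.
#' @export
read_measurements <- function(path, col_map = NULL, quiet = FALSE) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)

  canonical <- c("clone_id", "cross_type", "block", "tree_id",
                 "age", "dbh_cm", "height_m")
  if (!is.null(col_map)) {
    bad <- setdiff(names(col_map), canonical)
    if (length(bad) > 0L) {
      abort(paste0("col_map names must be canonical columns; unknown: ",
                   paste(bad, collapse = ", ")))
    }
    for (canon in names(col_map)) {
      alias <- col_map[[canon]]
      if (!alias %in% names(raw)) {
        abort(paste0("column '", alias, "' (mapped to ", canon,
                     ") not present in ", path))
      }
      names(raw)[names(raw) == alias] <- canon
    }
  }
  check_columns(raw, canonical, what = basename(path))

  data <- tibble::tibble(
    clone_id   = as.character(raw$clone_id),
    cross_type = as.character(raw$cross_type),
    block      = as.integer(raw$block),
    tree_id    = as.character(raw$tree_id),
    age        = suppressWarnings(as.numeric(raw$age)),
    dbh        = suppressWarnings(as.numeric(raw$dbh_cm)),
    height     = suppressWarnings(as.numeric(raw$height_m))
  )

  reason <- dplyr::case_when(
    is.na(data$dbh) | data$dbh <= 0 ~ "non-positive or missing dbh",
    is.na(data$height) | data$height <= 0 ~ "non-positive or missing height",
    is.na(data$age) | data$age <= 0 | data$age != round(data$age) ~
      "age not a positive integer",
    !data$cross_type %in% c("DxM", "MxD") ~ "unknown cross_type",
    .default = NA_character_
  )
  rejected <- dplyr::mutate(data[!is.na(reason), ], reason = reason[!is.na(reason)])
  data <- data[is.na(reason), ]
  data$age <- as.integer(data$age)

  key <- paste(data$clone_id, data$block, data$tree_id, data$age, sep = "\r")
  if (anyDuplicated(key) > 0L) {
    dup <- data[duplicated(key), c("clone_id", "block", "tree_id", "age")]
    abort(paste0(
      "duplicate (clone_id, block, tree_id, age) keys, e.g. ",
      paste(unlist(dup[1, ]), collapse = "/")
    ))
  }

  if (nrow(rejected) > 0L) {
    warn(paste0(nrow(rejected), " row(s) rejected (see attr(x, 'rejected'))"))
  }
  if (!quiet) {
    inform(paste0("read ", nrow(data), " measurement row(s) from ",
                  basename(path), "; ", nrow(rejected), " rejected"))
  }
  attr(data, "rejected") <- rejected
  attr(data, "source") <- path
  data
}

#' Derive stem traits from diameter and height
#'
#' Adds the three derived stem traits to a measurement table:
#' * `hdr` — height-to-diameter ratio, height (m) over DBH (cm). On this
#'   unit convention mature poplar values fall around 0.6-0.8; lower is a
#'   stockier, more wind-firm stem.
#' * `basal_area` — breast-height cross-section, \eqn{\pi\,(DBH/100)^2/4}{pi (DBH/100)^2 / 4} in m².
#' * `volume` — stem volume \eqn{V = G \cdot H \cdot F}{V = G * H * F} in m³, where `F` is the
#'   breast-height form factor reducing the basal-area cylinder to the stem.
#'
#' @param data Measurement tibble with `dbh` (cm) and `height` (m) columns,
#'   as returned by [read_measurements()] or [simulate_trial()].
#' @param form_factor Dimensionless breast-height form factor; default 0.44,
#'   the estimate used for the poplar trial this package models.
#'
#' @return `data` with columns `hdr`, `basal_area`, `volume` appended and a
#'   `form_factor` attribute recording the constant used.
#' @examples
#' trees <- tibble::tibble(
#'   clone_id = "DM-9-17", cross_type = "DxM", block = 1L,
#'   tree_id = "T1", age = 18L, dbh = 42, height = 26
#' )
#' derive_traits(trees)
#' @export
derive_traits <- function(data, form_factor = 0.44) {
  check_columns(data, c("dbh", "height"), what = "measurement table")
  if (!is.numeric(form_factor) || length(form_factor) != 1L || form_factor <= 0) {
    abort("form_factor must be a single positive number")
  }
  if (any(data$dbh <= 0, na.rm = TRUE) || any(data$height <= 0, na.rm = TRUE)) {
    abort("dbh and height must be strictly positive; validate on read")
  }
  out <- dplyr::mutate(
    data,
    hdr        = .data$height / .data$dbh,
    basal_area = pi * (.data$dbh / 100)^2 / 4,
    volume     = .data$basal_area * .data$height * form_factor
  )
  attr(out, "form_factor") <- form_factor
  out
}

#' Per-age group means of growth traits
#'
#' Population (cross-type) or clone mean trajectories: one row per group per
#' age with the arithmetic mean of each trait over the trees measured there.
#' Group mean volume is always the mean of per-tree volumes, never the
#' volume formula applied to mean DBH and height (the two differ because
#' volume is nonlinear in DBH).
#'
#' @param data Trait table from [derive_traits()] (raw measurement tables
#'   work too; only the columns present are averaged).
#' @param level `"clone"` (keeps `cross_type` alongside) or `"cross_type"`.
#'
#' @return A tibble with the grouping columns, `age`, the per-age means of
#'   `dbh`, `height`, `hdr`, `volume` (those present), and `n`, the number
#'   of contributing trees. Groups with no trees at an age are absent.
#' @export
aggregate_means <- function(data, level = c("clone", "cross_type")) {
  level <- match.arg(level)
  check_columns(data, c("cross_type", "age"), what = "trait table")
  if (nrow(data) == 0L) {
    warn("empty trait table; returning empty summary")
    return(tibble::tibble())
  }
  keys <- if (level == "clone") c("clone_id", "cross_type", "age") else
    c("cross_type", "age")
  traits <- intersect(c("dbh", "height", "hdr", "volume"), names(data))
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(traits), ~ mean(.x, na.rm = TRUE)),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(keys)))
}

#' Write a trait table to CSV
#'
#' Inverse of [read_measurements()]: writes the canonical header
#' `clone_id, cross_type, block, tree_id, age, dbh_cm, height_m` plus the
#' derived columns `hdr, basal_area_m2, volume_m3` when present, so that a
#' write-then-read round trip reproduces every field.
#'
#' @param data Measurement or trait tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_traits <- function(data, path) {
  check_columns(data, c("clone_id", "cross_type", "block", "tree_id",
                        "age", "dbh", "height"), what = "trait table")
  out <- dplyr::rename(data, dbh_cm = "dbh", height_m = "height")
  if ("basal_area" %in% names(out)) {
    out <- dplyr::rename(out, basal_area_m2 = "basal_area")
  }
  if ("volume" %in% names(out)) {
    out <- dplyr::rename(out, volume_m3 = "volume")
  }
  readr::write_csv(out, path)
  invisible(path)
}
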