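#' Read a cutting-survival table
#'
#' Reads the nursery survival census used to decide which clones enter the
#' field trial: one row per clone per cross type with the number of
#' cuttings planted and surviving. Computes `survival_rate` in percent.
#' Rows with zero cuttings planted are rejected with a warning. The key is
#' (`clone_id`, `cross_type`); a clone id that appears under both cross
#' types is legal but surfaced in the `"validation"` attribute so the
#' inconsistency is visible rather than silently resolved.
#'
#' @param path CSV with columns
#'   `clone_id, cross_type, cuttings_planted, cuttings_surviving`.
#' @return Tibble with `survival_rate` (percent) appended; attributes
#'   `rejected` and `validation` (cross-type duplicate ids).
#' @export
read_survival <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(raw, c("clone_id", "cross_type", "cuttings_planted",
                       "cuttings_surviving"), what = basename(path))
  data <- tibble::as_tibble(raw)
  bad <- is.na(data$cuttings_planted) | data$cuttings_planted <= 0 |
    is.na(data$cuttings_surviving) | data$cuttings_surviving < 0 |
    data$cuttings_surviving > data$cuttings_planted
  rejected <- data[bad, ]
  if (nrow(rejected) > 0L) {
    warn(paste0(nrow(rejected),
                " survival row(s) rejected (zero planted or bad counts)"))
  }
  data <- data[!bad, ]
  key <- paste(data$clone_id, data$cross_type)
  if (anyDuplicated(key) > 0L) {
    abort("duplicate (clone_id, cross_type) rows in survival table")
  }
  data$survival_rate <- 100 * data$cuttings_surviving / data$cuttings_planted
  dup_ids <- unique(data$clone_id[duplicated(data$clone_id)])
  if (length(dup_ids) > 0L) {
    warn(paste0("clone id(s) listed under both cross types: ",
                paste(dup_ids, collapse = ", ")))
  }
  attr(data, "rejected") <- rejected
  attr(data, "validation") <- tibble::tibble(
    issue = rep("clone id under both cross types", length(dup_ids)),
    clone_id = dup_ids
  )
  data
}

#' Filter clones by cutting survival rate
#'
#' Retains clones whose nursery survival rate meets the threshold —
#' inclusive by default, so a clone sitting exactly on the threshold stays
#' in, matching the census convention of the trial this package models.
#'
#' @param survival Tibble from [read_survival()] (or with the same
#'   columns; `survival_rate` is computed if absent).
#' @param threshold Percent survival required (default 60).
#' @param inclusive Retain rates equal to the threshold (default `TRUE`).
#' @param quiet Suppress the per-cross-type retention message.
#'
#' @return The retained rows, with `survival_rate`.
#' @export
filter_by_survival <- function(survival, threshold = 60, inclusive = TRUE,
                               quiet = FALSE) {
  check_columns(survival, c("clone_id", "cross_type"),
                what = "survival table")
  if (!"survival_rate" %in% names(survival)) {
    check_columns(survival, c("cuttings_planted", "cuttings_surviving"),
                  what = "survival table")
    survival$survival_rate <-
      100 * survival$cuttings_surviving / survival$cuttings_planted
  }
  keep <- if (inclusive) survival$survival_rate >= threshold else
    survival$survival_rate > threshold
  out <- survival[keep, ]
  if (!quiet) {
    tally <- dplyr::count(out, .data$cross_type)
    inform(paste0(
      "retained ", nrow(out), "/", nrow(survival), " clones (",
      paste(paste0(tally$cross_type, ": ", tally$n), collapse = ", "), ")"
    ))
  }
  out
}

#' Coefficient of variation of volume per group
#'
#' Volume stability index: \eqn{CV = 100 \cdot s / \bar{x}}{CV = 100 * s / mean} over tree-level
#' volumes at the reference age, with the sample standard deviation
#' (n - 1). A population's CV reflects how unevenly its members grow; a
#' selected clone's CV reflects ramet uniformity — low clone CVs alongside
#' a high population CV indicate that selection buys consistency.
#'
#' @param data Trait table with `volume`.
#' @param level `"cross_type"` or `"clone"`.
#' @param reference_age Age (years) at which volumes are compared; default
#'   the last measured age.
#'
#' @return Tibble `group, (cross_type,) n, mean_volume, cv_pct, flag`;
#'   groups with fewer than 2 trees get `NA` CV and flag
#'   `"insufficient_n"`. `cv_pct` is unrounded; display-round to whole
#'   percent as the trial reports do.
#' @export
volume_cv <- function(data, level = c("cross_type", "clone"),
                      reference_age = NULL) {
  level <- match.arg(level)
  check_columns(data, c("cross_type", "age", "volume"), what = "trait table")
  reference_age <- reference_age %||% max(data$age)
  sub <- dplyr::filter(data, .data$age == reference_age)
  if (nrow(sub) == 0L) {
    abort(paste0("no observations at reference age ", reference_age))
  }
  keys <- if (level == "clone") c("clone_id", "cross_type") else "cross_type"
  sub |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_volume = mean(.data$volume),
      cv_pct = dplyr::if_else(dplyr::n() >= 2L,
                              100 * sd(.data$volume) / mean(.data$volume),
                              NA_real_),
      .groups = "drop"
    ) |>
    dplyr::mutate(flag = dplyr::if_else(.data$n >= 2L, "ok",
                                        "insufficient_n"))
}

#' Rank clones and select the top fraction
#'
#' Ranks candidate clones by their clone-mean value of the criterion trait
#' at the reference age (descending) and selects the top
#' `floor(rate * n)`, with a minimum of one. Ties break deterministically:
#' higher mean DBH first, then lexicographic clone id. Each selected
#' clone's traits are flagged against its own cross-type population mean;
#' for the height-to-diameter ratio *below* the mean is favourable (a
#' stockier, more stable stem), so its flag is inverted.
#'
#' @param data Trait table from [derive_traits()] (tree level).
#' @param reference_age Age at which clones are compared; default the last
#'   measured age. Clones without data at this age are excluded with a
#'   warning.
#' @param rate Selection rate in (0, 1]; default 0.25.
#' @param criterion Trait to rank on; default `"volume"`.
#'
#' @return An object of class `selection_report`: a list with
#'   `selected` (per-clone means, ranks and above-mean flags),
#'   `clone_means` (all candidates), `population_means` (per cross type,
#'   tree level), `cv` (volume CV per cross type and per selected clone)
#'   and `params`. See [tidy.selection_report()] /
#'   [glance.selection_report()].
#' @examples
#' sim <- simulate_trial(seed = 1)
#' report <- sim$measurements |>
#'   derive_traits() |>
#'   select_top_clones(rate = 0.25)
#' tidy(report)
#' @export
select_top_clones <- function(data, reference_age = NULL, rate = 0.25,
                              criterion = "volume") {
  traits <- intersect(c("dbh", "height", "hdr", "volume"), names(data))
  check_columns(data, c("clone_id", "cross_type", "age", criterion),
                what = "trait table")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0 || rate > 1) {
    abort("rate must be in (0, 1]")
  }
  reference_age <- reference_age %||% max(data$age)

  all_clones <- unique(data$clone_id)
  at_ref <- dplyr::filter(data, .data$age == reference_age)
  missing <- setdiff(all_clones, unique(at_ref$clone_id))
  if (length(missing) > 0L) {
    warn(paste0("clone(s) without data at age ", reference_age,
                " excluded: ", paste(missing, collapse = ", ")))
  }
  if (nrow(at_ref) == 0L) {
    abort(paste0("no observations at reference age ", reference_age))
  }

  clone_means <- at_ref |>
    dplyr::group_by(.data$clone_id, .data$cross_type) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(traits), ~ mean(.x)),
      n_trees = dplyr::n(), .groups = "drop"
    )
  pop_means <- at_ref |>
    dplyr::group_by(.data$cross_type) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(traits), ~ mean(.x)),
                     n_trees = dplyr::n(), .groups = "drop")

  n_candidates <- nrow(clone_means)
  n_selected <- max(1L, floor(rate * n_candidates))

  ranked <- clone_means |>
    dplyr::arrange(dplyr::desc(.data[[criterion]]),
                   dplyr::desc(.data$dbh), .data$clone_id) |>
    dplyr::mutate(rank = dplyr::row_number())
  selected <- head(ranked, n_selected)

  # above-/below-population-mean flags (HDR: low is favourable)
  flag_one <- function(clone_row, trait) {
    pop <- pop_means[[trait]][pop_means$cross_type == clone_row$cross_type]
    if (trait == "hdr") clone_row[[trait]] < pop else clone_row[[trait]] > pop
  }
  for (tr in traits) {
    selected[[paste0(tr, "_favourable")]] <-
      vapply(seq_len(nrow(selected)),
             function(i) flag_one(selected[i, ], tr), logical(1))
  }

  cv <- dplyr::bind_rows(
    dplyr::mutate(volume_cv(data, "cross_type", reference_age),
                  group = .data$cross_type, .before = 1),
    volume_cv(dplyr::semi_join(data, selected, by = "clone_id"),
              "clone", reference_age) |>
      dplyr::mutate(group = .data$clone_id, .before = 1)
  )

  structure(
    list(
      selected = selected,
      clone_means = ranked,
      population_means = pop_means,
      cv = cv,
      params = list(reference_age = reference_age, rate = rate,
                    criterion = criterion, n_candidates = n_candidates,
                    n_selected = n_selected)
    ),
    class = "selection_report"
  )
}

#' @export
print.selection_report <- function(x, ...) {
  p <- x$params
  cat("<selection_report> ", p$n_selected, "/", p$n_candidates,
      " clones at rate ", p$rate, " on ", p$criterion,
      " (age ", p$reference_age, ")\n", sep = "")
  print(x$selected[, c("clone_id", "cross_type", "rank",
                       intersect(c("dbh", "height", "volume", "hdr"),
                                 names(x$selected)))])
  invisible(x)
}

#' Tidy a selection report
#'
#' @param x A `selection_report` from [select_top_clones()].
#' @param ... Unused.
#' @return The `selected` tibble: one row per selected clone with rank,
#'   clone-mean traits at the reference age and per-trait favourability
#'   flags.
#' @method tidy selection_report
#' @export
tidy.selection_report <- function(x, ...) x$selected

#' One-row summary of a selection report
#'
#' @param x A `selection_report` from [select_top_clones()].
#' @param ... Unused.
#' @return Tibble with the selection parameters and counts.
#' @method glance selection_report
#' @export
glance.selection_report <- function(x, ...) {
  tibble::tibble(
    reference_age = x$params$reference_age,
    rate = x$params$rate,
    criterion = x$params$criterion,
    n_candidates = x$params$n_candidates,
    n_selected = x$params$n_selected
  )
}
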