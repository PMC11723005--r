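#' Early selection efficiency from an age-age correlation
#'
#' \eqn{ESE = R_p \cdot t_e / t_l}{ESE = Rp * te / tl}: the age-age correlation scaled by the
#' ratio of the late (mature) reference age \eqn{t_e}{te} to the early selection
#' age \eqn{t_l}{tl}. The ratio rewards selecting early — the same correlation is
#' worth more the sooner it is available — so ESE falls with early age when
#' the correlation is flat, and `ESE = Rp` when the two ages coincide.
#'
#' @param rp Age-age correlation coefficient(s).
#' @param early_age,late_age Ages in years; vectorized.
#' @return Numeric ESE values.
#' @examples
#' early_selection_efficiency(0.88, early_age = 7, late_age = 14)  # 1.76
#' @export
early_selection_efficiency <- function(rp, early_age, late_age = 14) {
  if (any(early_age <= 0) || any(late_age <= 0)) {
    abort("ages must be positive")
  }
  rp * late_age / early_age
}

#' Age-age correlation table with early-selection efficiency
#'
#' For each cross type and each early age below the mature reference age,
#' correlates the trait's values at the early age with its values at the
#' reference age across genetic entries, and scores the early-selection
#' efficiency [early_selection_efficiency()]. The default unit is the
#' clone mean per age (stable against tree-level mortality); tree-level
#' pairing matches trees by clone, block and tree id.
#'
#' @param data Trait table (tree level) containing `trait`.
#' @param trait Trait column to correlate; default `"dbh"`, the easiest
#'   trait to measure precisely in the field and the strongest predictor
#'   of volume.
#' @param late_age Mature reference age in years (default 14, around late
#'   quantitative maturity in the trial this package models).
#' @param unit `"clone_mean"` or `"tree"`.
#'
#' @return A tibble with one row per cross type and early age:
#'   `cross_type, early_age, late_age, r, n, t_stat, p_value, stars, ese`.
#'   Early ages with fewer than 3 paired units are skipped with a warning.
#' @export
age_age_table <- function(data, trait = "dbh", late_age = 14,
                          unit = c("clone_mean", "tree")) {
  unit <- match.arg(unit)
  check_columns(data, c("clone_id", "cross_type", "age", trait),
                what = "trait table")
  if (!late_age %in% data$age) {
    abort(paste0("late_age ", late_age, " absent from data"))
  }

  id_cols <- if (unit == "clone_mean") "clone_id" else
    c("clone_id", "block", "tree_id")
  units_tbl <- data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c("cross_type", id_cols, "age")))) |>
    dplyr::summarise(value = mean(.data[[trait]]), .groups = "drop")

  early_ages <- sort(unique(units_tbl$age[units_tbl$age < late_age]))
  rows <- list()
  for (ct in sort(unique(units_tbl$cross_type))) {
    late <- units_tbl |>
      dplyr::filter(.data$cross_type == ct, .data$age == late_age) |>
      dplyr::select(dplyr::all_of(id_cols), late_value = "value")
    for (a in early_ages) {
      early <- units_tbl |>
        dplyr::filter(.data$cross_type == ct, .data$age == a) |>
        dplyr::select(dplyr::all_of(id_cols), early_value = "value")
      paired <- dplyr::inner_join(early, late, by = id_cols)
      if (nrow(paired) < 3L) {
        warn(paste0("fewer than 3 paired units for ", ct, " at age ", a,
                    "; skipped"))
        next
      }
      res <- pearson_cor(paired$early_value, paired$late_value)
      rows[[paste0(ct, ":", a)]] <- dplyr::mutate(
        res,
        cross_type = ct, early_age = a, late_age = late_age, .before = 1,
        ese = early_selection_efficiency(.data$r, a, late_age)
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Earliest qualifying window for early selection
#'
#' Scans an age-age correlation table for the earliest maximal run of
#' consecutive early ages at which selection is trustworthy: the
#' correlation at least `rp_min` (strong band), significant at 0.05 when
#' `require_significance`, and — optionally — early-selection efficiency at
#' least `ese_min`. In `"joint"` mode (the default when both cross types
#' are present) an age qualifies only if every cross type meets the
#' criteria there, so one population's moderate correlation excludes the
#' age for the programme as a whole.
#'
#' @param rows Output of [age_age_table()] (rows for one or both cross
#'   types).
#' @param rp_min Minimum correlation (default 0.50, the conventional lower
#'   edge of the "strong" band).
#' @param require_significance Require p < 0.05 at the age.
#' @param ese_min Optional minimum ESE; `NULL` (default) disables the ESE
#'   criterion.
#' @param mode `"joint"` (all cross types must qualify at an age) or
#'   `"single"` (rows must then contain one cross type only).
#'
#' @return One-row tibble `start_age, end_age, n_ages, min_rp, min_ese,
#'   flag`; ages are `NA` with flag `"none_qualifies"` when no age passes.
#' @export
optimal_window <- function(rows, rp_min = 0.50, require_significance = TRUE,
                           ese_min = NULL, mode = c("joint", "single")) {
  mode <- match.arg(mode)
  check_columns(rows, c("cross_type", "early_age", "r", "p_value", "ese"),
                what = "age-age table")
  rows <- dplyr::arrange(rows, .data$early_age)
  n_types <- length(unique(rows$cross_type))
  if (mode == "single" && n_types > 1L) {
    abort("mode = 'single' requires rows for a single cross type")
  }

  ok <- rows$r >= rp_min
  if (require_significance) ok <- ok & rows$p_value < 0.05
  if (!is.null(ese_min)) ok <- ok & rows$ese >= ese_min
  rows$qualifies <- ok

  by_age <- rows |>
    dplyr::group_by(.data$early_age) |>
    dplyr::summarise(
      qualifies = all(.data$qualifies) & dplyr::n() == n_types,
      min_rp = min(.data$r), min_ese = min(.data$ese),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$early_age)

  q_ages <- by_age$early_age[by_age$qualifies]
  if (length(q_ages) == 0L) {
    return(tibble::tibble(start_age = NA_integer_, end_age = NA_integer_,
                          n_ages = 0L, min_rp = NA_real_,
                          min_ese = NA_real_, flag = "none_qualifies"))
  }
  # earliest maximal run of consecutive qualifying ages
  run_id <- cumsum(c(1L, diff(q_ages) != 1L))
  first_run <- q_ages[run_id == run_id[1]]
  in_run <- by_age$early_age %in% first_run
  tibble::tibble(
    start_age = min(first_run), end_age = max(first_run),
    n_ages = length(first_run),
    min_rp = min(by_age$min_rp[in_run]),
    min_ese = min(by_age$min_ese[in_run]),
    flag = "ok"
  )
}
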