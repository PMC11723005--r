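#' Published summary tables of the poplar progeny trial
#'
#' The per-tree data of the 17-clone *Populus deltoides* 'DD-109' ×
#' *P. maximowiczii* reciprocal-cross trial are not deposited, but its
#' published summary tables are shipped as plain-text reference inputs:
#'
#' * `poplar_trial_survival()` — the nursery cutting-survival census of
#'   all 23 candidate clones (cuttings planted and surviving per clone and
#'   cross type). Note one clone id appears under both cross types, as in
#'   the original census; [read_survival()] surfaces it.
#' * `poplar_trial_age_age()` — the reported age-age correlations of DBH
#'   (early age 2-13 against the mature reference age) per cross type,
#'   with the published significance level (`ns`, `*`, `**`).
#' * `poplar_trial_mature_traits()` — mature (final-age) mean DBH, height,
#'   volume and height-to-diameter ratio for the two populations and the
#'   four selected clones.
#'
#' @return A tibble.
#' @name trial_reference
NULL

#' @rdname trial_reference
#' @export
poplar_trial_survival <- function() {
  read_survival(system.file("extdata", "trial_survival.csv",
                            package = "popgrowth", mustWork = TRUE))
}

#' @rdname trial_reference
#' @export
poplar_trial_age_age <- function() {
  readr::read_csv(system.file("extdata", "trial_age_age_rp.csv",
                              package = "popgrowth", mustWork = TRUE),
                  show_col_types = FALSE, progress = FALSE)
}

#' @rdname trial_reference
#' @export
poplar_trial_mature_traits <- function() {
  readr::read_csv(system.file("extdata", "trial_mature_traits.csv",
                              package = "popgrowth", mustWork = TRUE),
                  show_col_types = FALSE, progress = FALSE)
}
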