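#' Mean and periodic annual volume increments per clone
#'
#' Builds each clone's increment schedule from its mean-volume series:
#' * `mai(t) = V(t) / t` — mean annual increment, cumulative volume per
#'   year of stand age;
#' * `pai(t) = V(t) - V(t-1)` — periodic (current) annual increment,
#'   indexed to the later age of the one-year interval.
#'
#' `pai` is `NA` at each clone's first age and across any gap in the age
#' sequence (a missing year leaves the increments on both sides of the gap
#' undefined rather than silently spanning it). The schedule telescopes:
#' first volume plus the summed `pai` over consecutive ages returns the
#' last volume.
#'
#' @param data Either a tree-level trait table (from [derive_traits()]),
#'   which is first averaged to clone mean volume per age, or an
#'   already-aggregated table with one row per `clone_id` and `age` and a
#'   `volume` column.
#'
#' @return A tibble `clone_id, (cross_type,) age, volume, mai, pai` sorted
#'   by clone and age.
#' @export
compute_increments <- function(data) {
  check_columns(data, c("clone_id", "age", "volume"), what = "volume series")
  keys <- intersect(c("clone_id", "cross_type"), names(data))
  series <- data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "age")))) |>
    dplyr::summarise(volume = mean(.data$volume), .groups = "drop") |>
    dplyr::arrange(.data$clone_id, .data$age)

  short <- series |>
    dplyr::count(.data$clone_id) |>
    dplyr::filter(.data$n < 2L)
  if (nrow(short) > 0L) {
    abort(paste0("insufficient series (< 2 ages) for clone(s): ",
                 paste(short$clone_id, collapse = ", ")))
  }

  series |>
    dplyr::group_by(.data$clone_id) |>
    dplyr::mutate(
      mai = .data$volume / .data$age,
      pai = dplyr::if_else(
        .data$age - dplyr::lag(.data$age) == 1L,
        .data$volume - dplyr::lag(.data$volume),
        NA_real_
      )
    ) |>
    dplyr::ungroup()
}

# centred 3-point moving average; endpoints and NA neighbours left as-is
smooth_pai <- function(pai) {
  n <- length(pai)
  if (n < 3L) return(pai)
  out <- pai
  for (i in 2:(n - 1)) {
    w <- pai[(i - 1):(i + 1)]
    if (!anyNA(w)) out[i] <- mean(w)
  }
  out
}

#' Detect the quantitative maturity age of each clone
#'
#' The quantitative maturity age (QMA) — the maximum-sustained-yield
#' rotation age — is the age at which the periodic annual increment falls
#' back to the mean annual increment. Per clone, scanning ages upward, QMA
#' is the smallest age `t` with `pai(t) <= mai(t)` after at least one
#' earlier age with `pai > mai`. Requiring the prior exceedance keeps a
#' series that starts below MAI (concave from the outset) from receiving a
#' spurious maturity at its first age; such clones are flagged
#' `"immediate_decline"` instead. Clones whose PAI is still above MAI at
#' the last age are `"not_reached"`.
#'
#' Reporting is at integer ages, matching annual remeasurement; the
#' bracketing ages and a linearly interpolated real-valued crossing are
#' emitted for diagnostics.
#'
#' @param increments Output of [compute_increments()].
#' @param smooth If `TRUE`, apply a centred 3-point moving average to the
#'   PAI series before crossing detection (noise suppression for small
#'   clones); off by default.
#'
#' @return A tibble with one row per clone: `clone_id`, (`cross_type`,)
#'   `qma_age` (integer, `NA` when not reached), `volume_at_qma`,
#'   `bracket_lo`/`bracket_hi` (the ages straddling the crossing),
#'   `qma_interp` (linear interpolation of the PAI-MAI sign change) and
#'   `flag` (`"ok"`, `"not_reached"`, `"immediate_decline"`, `"no_pai"`).
#' @examples
#' sim <- simulate_trial(seed = 1)
#' sim$measurements |>
#'   derive_traits() |>
#'   compute_increments() |>
#'   detect_qma()
#' @export
detect_qma <- function(increments, smooth = FALSE) {
  check_columns(increments, c("clone_id", "age", "volume", "mai", "pai"),
                what = "increment table")
  keys <- intersect("cross_type", names(increments))

  one_clone <- function(d, key) {
    d <- dplyr::arrange(d, .data$age)
    pai <- if (smooth) smooth_pai(d$pai) else d$pai
    mai <- d$mai
    no_qma <- function(flag) tibble::tibble(
      qma_age = NA_integer_, volume_at_qma = NA_real_,
      bracket_lo = NA_integer_, bracket_hi = NA_integer_,
      qma_interp = NA_real_, flag = flag
    )
    defined <- which(!is.na(pai))
    if (length(defined) == 0L) {
      warn(paste0("clone ", key$clone_id[1], ": no consecutive ages, no PAI"))
      return(no_qma("no_pai"))
    }
    exceeded <- FALSE
    for (i in defined) {
      if (pai[i] > mai[i]) {
        exceeded <- TRUE
      } else if (exceeded) {
        # previous defined age had pai > mai; interpolate the sign change
        prev <- max(defined[defined < i])
        d_lo <- pai[prev] - mai[prev]
        d_hi <- pai[i] - mai[i]
        interp <- if (d_lo - d_hi > 0) {
          d$age[prev] + (d$age[i] - d$age[prev]) * d_lo / (d_lo - d_hi)
        } else {
          as.numeric(d$age[i])
        }
        return(tibble::tibble(
          qma_age = d$age[i], volume_at_qma = d$volume[i],
          bracket_lo = d$age[prev], bracket_hi = d$age[i],
          qma_interp = interp, flag = "ok"
        ))
      }
    }
    if (exceeded) no_qma("not_reached") else no_qma("immediate_decline")
  }

  increments |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("clone_id", keys)))) |>
    dplyr::group_modify(one_clone) |>
    dplyr::ungroup()
}
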