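#' Configuration for the progeny-trial growth simulator
#'
#' Bundles and validates every parameter of [simulate_trial()]. The defaults
#' emulate the 17-clone poplar trial the package models: 10 direct-cross
#' (DxM) and 7 reciprocal-cross (MxD) clones, 8 ramets per clone split 3/3/2
#' over three blocks, and annual measurements from age 2 to 18. Growth is a
#' three-parameter logistic in time for both DBH and height,
#' \eqn{x(t) = K / (1 + e^{-r (t - t_0)})}{x(t) = K / (1 + exp(-r (t - t0)))},
#' and stem volume emerges downstream through the form-factor volume
#' equation rather than being simulated directly.
#'
#' The default curve parameters place the direct cross above the reciprocal
#' cross in DBH, height and volume, give the reciprocal cross the higher
#' early height-to-diameter ratio, make HDR decline monotonically with age,
#' and put the noise-free maturity (MAI = PAI crossing) in the 12-16 year
#' band — the qualitative structure of the trial.
#'
#' @param n_clones Named integer vector: clones per cross type.
#' @param trees_per_block Integer vector of ramets per clone in each block.
#' @param ages Strictly increasing integer measurement ages.
#' @param dbh_curve,height_curve Named lists (`DxM`, `MxD`) of logistic
#'   parameters `c(K = asymptote, r = rate per year, t0 = inflection year)`;
#'   K in cm (DBH) or m (height).
#' @param clone_sd_K Relative SD of the clone-level multiplicative effect on
#'   both asymptotes (one draw per clone per trait).
#' @param clone_sd_t0 SD (years) of the clone-level additive shift of both
#'   inflection points (one draw per clone, shared by DBH and height, so a
#'   clone is early or late as a whole).
#' @param tree_sd_K Relative SD of the per-tree multiplicative asymptote
#'   effect (stable ramet quality).
#' @param noise_sd Named numeric: additive measurement-noise SD for `dbh`
#'   (cm) and `height` (m), drawn independently per tree-year.
#' @param mortality Per-tree-per-year death probability; a dead tree's
#'   series is truncated at its death year (no imputation).
#'
#' @return A validated list of class `growth_sim_config`.
#' @export
growth_sim_config <- function(n_clones = c(DxM = 10L, MxD = 7L),
                              trees_per_block = c(3L, 3L, 2L),
                              ages = 2:18,
                              dbh_curve = list(
                                DxM = c(K = 36,   r = 0.42, t0 = 7),
                                MxD = c(K = 32.5, r = 0.40, t0 = 7.5)
                              ),
                              height_curve = list(
                                DxM = c(K = 25.5, r = 0.45, t0 = 5),
                                MxD = c(K = 24.5, r = 0.45, t0 = 5.3)
                              ),
                              clone_sd_K = 0.10,
                              clone_sd_t0 = 0.8,
                              tree_sd_K = 0.04,
                              noise_sd = c(dbh = 0.6, height = 0.4),
                              mortality = 0.02) {
  chk_pos_int <- function(x, nm) {
    if (!is.numeric(x) || any(x <= 0) || any(x != round(x))) {
      abort(paste0("invalid config field '", nm, "': positive integers required"))
    }
  }
  chk_pos_int(n_clones, "n_clones")
  if (!all(c("DxM", "MxD") %in% names(n_clones))) {
    abort("invalid config field 'n_clones': needs named entries DxM and MxD")
  }
  chk_pos_int(trees_per_block, "trees_per_block")
  chk_pos_int(ages, "ages")
  if (length(ages) < 2L || any(diff(ages) <= 0)) {
    abort("invalid config field 'ages': strictly increasing, length >= 2")
  }
  for (nm in c("dbh_curve", "height_curve")) {
    curves <- get(nm)
    for (ct in c("DxM", "MxD")) {
      p <- curves[[ct]]
      if (is.null(p) || !all(c("K", "r", "t0") %in% names(p))) {
        abort(paste0("invalid config field '", nm, "': ", ct,
                     " needs K, r, t0"))
      }
      if (p[["K"]] <= 0 || p[["r"]] <= 0) {
        abort(paste0("invalid config field '", nm, "': K and r must be > 0"))
      }
    }
  }
  for (nm in c("clone_sd_K", "clone_sd_t0", "tree_sd_K")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 0) {
      abort(paste0("invalid config field '", nm, "': single sd >= 0 required"))
    }
  }
  if (!all(c("dbh", "height") %in% names(noise_sd)) || any(noise_sd < 0)) {
    abort("invalid config field 'noise_sd': named sds (dbh, height) >= 0")
  }
  if (!is.numeric(mortality) || length(mortality) != 1L ||
      mortality < 0 || mortality >= 1) {
    abort("invalid config field 'mortality': probability in [0, 1)")
  }
  structure(
    list(
      n_clones = as.integer(n_clones[c("DxM", "MxD")]) |>
        setNames(c("DxM", "MxD")),
      trees_per_block = as.integer(trees_per_block),
      ages = as.integer(ages),
      dbh_curve = dbh_curve, height_curve = height_curve,
      clone_sd_K = clone_sd_K, clone_sd_t0 = clone_sd_t0,
      tree_sd_K = tree_sd_K, noise_sd = noise_sd, mortality = mortality
    ),
    class = "growth_sim_config"
  )
}

logistic_curve <- function(t, K, r, t0) K / (1 + exp(-r * (t - t0)))

# noise-free volume curve of one clone at (possibly fractional) ages,
# through the same form-factor equation the analysis uses
truth_volume <- function(truth_row, t, form_factor = 0.44) {
  d <- logistic_curve(t, truth_row$K_dbh, truth_row$r_dbh, truth_row$t0_dbh)
  h <- logistic_curve(t, truth_row$K_height, truth_row$r_height,
                      truth_row$t0_height)
  pi * (d / 100)^2 / 4 * h * form_factor
}

#' Simulate a clonal progeny trial
#'
#' Draws a complete annual remeasurement table with the structure the
#' downstream analyses assume: cross-type mean logistic growth curves for
#' DBH and height, clone-level random effects (multiplicative on the
#' asymptotes, additive on the shared inflection year), a stable per-tree
#' asymptote effect, independent Gaussian measurement noise per tree-year
#' (truncated just above zero), and Bernoulli per-year mortality that
#' truncates a tree's series.
#'
#' All draws come from one root generator seeded by `seed`, in a fixed
#' stream order (clone effects in clone order, then per-tree effects, death
#' years, and measurement noise, clone by clone), so the same seed always
#' reproduces the same table.
#'
#' @param config A [growth_sim_config()].
#' @param seed Integer seed; required for reproducibility.
#'
#' @return A list of class `trial_sim`:
#' \describe{
#'   \item{measurements}{tibble `clone_id, cross_type, block, tree_id, age,
#'     dbh, height` — same shape as [read_measurements()] output.}
#'   \item{truth}{tibble of realized noise-free clone curve parameters
#'     (`K_dbh, r_dbh, t0_dbh, K_height, r_height, t0_height`), one row per
#'     clone — the oracle for [analytic_qma()].}
#'   \item{config, seed}{the inputs.}
#' }
#' @examples
#' sim <- simulate_trial(seed = 1)
#' dplyr::count(sim$measurements, cross_type)
#' @export
simulate_trial <- function(config = growth_sim_config(), seed = NULL) {
  if (!inherits(config, "growth_sim_config")) {
    abort("config must come from growth_sim_config()")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))

  clone_ids <- c(
    sprintf("DM-%02d", seq_len(config$n_clones[["DxM"]])),
    sprintf("MD-%02d", seq_len(config$n_clones[["MxD"]]))
  )
  cross <- rep(c("DxM", "MxD"), times = config$n_clones)

  # clone effects, drawn in clone order from the root stream
  truth <- purrr::map2_dfr(clone_ids, cross, function(id, ct) {
    kd <- config$dbh_curve[[ct]]
    kh <- config$height_curve[[ct]]
    mult_d <- max(0.4, 1 + rnorm(1, 0, config$clone_sd_K))
    mult_h <- max(0.4, 1 + rnorm(1, 0, config$clone_sd_K))
    shift  <- rnorm(1, 0, config$clone_sd_t0)
    tibble::tibble(
      clone_id = id, cross_type = ct,
      K_dbh = kd[["K"]] * mult_d, r_dbh = kd[["r"]],
      t0_dbh = kd[["t0"]] + shift,
      K_height = kh[["K"]] * mult_h, r_height = kh[["r"]],
      t0_height = kh[["t0"]] + shift
    )
  })

  ages <- config$ages
  blocks <- rep(seq_along(config$trees_per_block), config$trees_per_block)
  tree_seq <- unlist(lapply(config$trees_per_block, seq_len))

  measurements <- purrr::map_dfr(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    purrr::map_dfr(seq_along(blocks), function(j) {
      tree_mult_d <- max(0.4, 1 + rnorm(1, 0, config$tree_sd_K))
      tree_mult_h <- max(0.4, 1 + rnorm(1, 0, config$tree_sd_K))
      # death year: first age (after the first) at which the Bernoulli fires
      alive_through <- max(ages)
      if (config$mortality > 0) {
        deaths <- runif(length(ages)) < config$mortality
        if (any(deaths)) alive_through <- ages[which(deaths)[1]] - 1L
      }
      keep <- ages[ages <= alive_through]
      if (length(keep) == 0L) return(NULL)
      d_true <- logistic_curve(keep, tr$K_dbh * tree_mult_d, tr$r_dbh, tr$t0_dbh)
      h_true <- logistic_curve(keep, tr$K_height * tree_mult_h, tr$r_height,
                               tr$t0_height)
      d_obs <- pmax(d_true + rnorm(length(keep), 0, config$noise_sd[["dbh"]]), 0.1)
      h_obs <- pmax(h_true + rnorm(length(keep), 0, config$noise_sd[["height"]]), 0.1)
      tibble::tibble(
        clone_id = tr$clone_id, cross_type = tr$cross_type,
        block = blocks[j], tree_id = sprintf("B%d-T%d", blocks[j], tree_seq[j]),
        age = keep, dbh = d_obs, height = h_obs
      )
    })
  })

  structure(
    list(measurements = measurements, truth = truth,
         config = config, seed = seed),
    class = "trial_sim"
  )
}

#' @export
print.trial_sim <- function(x, ...) {
  cat("<trial_sim> ", nrow(x$truth), " clones, ",
      length(unique(paste(x$measurements$clone_id, x$measurements$block,
                          x$measurements$tree_id))),
      " trees, ages ", min(x$config$ages), "-", max(x$config$ages),
      ", seed ", x$seed %||% "unset", "\n", sep = "")
  invisible(x)
}

#' Analytic quantitative maturity age of noise-free simulated clones
#'
#' For each clone's noise-free volume curve \eqn{V(t)}{V(t)} (logistic DBH and height
#' pushed through the form-factor volume equation), finds the real-valued
#' age at which the one-year periodic increment first falls back to the
#' mean annual increment \eqn{V(t)/t}{V(t)/t}: a dense grid scan (default 0.01-year
#' steps) locates the sign change after a prior exceedance, and bisection
#' refines it. The periodic increment is indexed to the later age of its
#' one-year interval, \eqn{V(t) - V(t-1)}{V(t) - V(t-1)} — the same convention
#' [compute_increments()] uses on the annual schedule, so integer maturity
#' ages from [detect_qma()] on noise-free data land within one year of this
#' oracle. This is the parameter-recovery oracle for simulated trials.
#'
#' @param truth Truth tibble from [simulate_trial()] (or a `trial_sim`).
#' @param clone_id Optional clone subset; default all clones.
#' @param age_range Search range in years (crossing sought for `t` in
#'   `[min + 1, max]` so the one-year look-back stays inside the range).
#' @param step Grid resolution in years.
#' @param form_factor Passed to the volume equation; default 0.44.
#'
#' @return A tibble `clone_id, qma, flag`; `qma` is `NA` with flag
#'   `"not_reached"` when the increments do not cross in range.
#' @export
analytic_qma <- function(truth, clone_id = NULL, age_range = c(2, 18),
                         step = 0.01, form_factor = 0.44) {
  if (inherits(truth, "trial_sim")) truth <- truth$truth
  check_columns(truth, c("clone_id", "K_dbh", "r_dbh", "t0_dbh",
                         "K_height", "r_height", "t0_height"),
                what = "truth table")
  ids <- clone_id %||% truth$clone_id
  missing <- setdiff(ids, truth$clone_id)
  if (length(missing) > 0L) {
    abort(paste0("clone(s) not in truth: ", paste(missing, collapse = ", ")))
  }
  purrr::map_dfr(ids, function(id) {
    tr <- truth[truth$clone_id == id, ]
    f <- function(t) {
      v  <- truth_volume(tr, t, form_factor)
      v0 <- truth_volume(tr, t - 1, form_factor)
      (v - v0) - v / t     # PAI (later-age indexed) minus MAI
    }
    grid <- seq(age_range[1] + 1, age_range[2], by = step)
    vals <- f(grid)
    exceeded <- cumsum(vals > 0) > 0          # prior PAI > MAI somewhere
    idx <- which(exceeded & vals <= 0)
    if (length(idx) == 0L) {
      if (all(abs(vals) < 1e-12)) {
        # PAI identical to MAI everywhere (e.g. linear volume): earliest age
        return(tibble::tibble(clone_id = id, qma = grid[1], flag = "tie"))
      }
      return(tibble::tibble(clone_id = id, qma = NA_real_,
                            flag = "not_reached"))
    }
    i <- idx[1]
    lo <- grid[i - 1]; hi <- grid[i]
    # bisection on the bracketing grid cell
    for (k in 1:60) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) lo <- mid else hi <- mid
      if (hi - lo < 1e-10) break
    }
    tibble::tibble(clone_id = id, qma = (lo + hi) / 2, flag = "ok")
  })
}
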