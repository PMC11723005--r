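#' Pearson correlation with significance stars
#'
#' Simple correlation \eqn{r = \mathrm{cov}(x,y) / \sqrt{\sigma_x^2 \sigma_y^2}}{r = cov(x,y) / sqrt(var(x) var(y))}
#' with the two-sided test from \eqn{t = r \sqrt{n-2} / \sqrt{1-r^2}}{t = r sqrt(n-2) / sqrt(1-r^2)} against
#' Student's t with `n - 2` degrees of freedom. Pairs with a missing value
#' in either vector are deleted pairwise. Stars follow the two-level
#' convention: `*` for p < 0.05, `**` for p < 0.01.
#'
#' @param x,y Numeric vectors of equal length.
#' @return One-row tibble `r, n, t_stat, p_value, stars`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) abort("need at least 3 complete pairs")
  if (var(x) == 0 || var(y) == 0) {
    abort("degenerate variance: a vector is constant")
  }
  r <- cor(x, y)
  if (abs(r) >= 1 - 1e-15) {
    t_stat <- sign(r) * Inf
    p <- 0
  } else {
    t_stat <- r * sqrt(n - 2) / sqrt(1 - r^2)
    p <- 2 * pt(-abs(t_stat), df = n - 2)
  }
  tibble::tibble(r = r, n = n, t_stat = t_stat, p_value = p,
                 stars = stars_from_p(p))
}

#' Path-coefficient decomposition of a response onto correlated predictors
#'
#' Decomposes each predictor's simple correlation with the response into a
#' direct and an indirect part. The direct path coefficient is the
#' standardized partial regression coefficient
#' \eqn{DPC_i = B_i S_i / S_y}{DPC_i = B_i S_i / S_y}, with \eqn{B_i}{B_i} from the ordinary
#' least-squares fit of the response on all predictors jointly. The
#' indirect path of predictor *i* through mediator *j* is
#' \eqn{r_{ij}\,DPC_j}{r_ij * DPC_j}, and the reported IPC is their sum over all
#' mediators. The decomposition satisfies the path identity
#' \eqn{DPC_i + IPC_i = r(i, y)}{DPC_i + IPC_i = r(i, y)} on every finite sample.
#'
#' Significance: the DPC carries the partial-regression t test of
#' \eqn{B_i}{B_i}; the IPC carries the correlation test of \eqn{r(i,y)}{r(i, y)} (the total
#' association it completes).
#'
#' @param data Data frame holding the response and predictor columns;
#'   incomplete rows are dropped.
#' @param response Response column name (default `"volume"`).
#' @param predictors Predictor column names (default DBH, height, HDR).
#'
#' @return An object of class `path_fit`; see [tidy.path_fit()] and
#'   [glance.path_fit()].
#' @examples
#' sim <- simulate_trial(seed = 1)
#' traits <- derive_traits(sim$measurements)
#' fit <- path_decomposition(dplyr::filter(traits, age %in% 7:9))
#' tidy(fit)
#' @export
path_decomposition <- function(data, response = "volume",
                               predictors = c("dbh", "height", "hdr")) {
  check_columns(data, c(response, predictors), what = "trait table")
  d <- data[complete.cases(data[, c(response, predictors)]),
            c(response, predictors)]
  n <- nrow(d)
  p <- length(predictors)
  if (n <= p + 1L) abort("need n > number of predictors + 1")

  X <- as.matrix(d[, predictors])
  y <- d[[response]]
  sds <- apply(X, 2, sd)
  if (any(sds == 0) || sd(y) == 0) {
    abort("degenerate variance: constant column among predictors/response")
  }
  R <- cor(X)
  if (qr(R)$rank < p || rcond(R) < 1e-12) {
    abort(paste0("singular predictor correlation matrix; collinear set: ",
                 paste(predictors, collapse = ", ")))
  }

  fit <- lm(stats::reformulate(predictors, response = response), data = d)
  B <- coef(fit)[predictors]
  dpc <- as.numeric(unname(B) * sds / sd(y))
  coef_p <- summary(fit)$coefficients[predictors, "Pr(>|t|)"]

  r_y <- vapply(predictors, function(v) cor(d[[v]], y), numeric(1))
  r_y_p <- vapply(predictors, function(v) pearson_cor(d[[v]], y)$p_value,
                  numeric(1))

  # per-mediator indirect terms: ipc_matrix[i, j] = r_ij * dpc_j (j != i)
  ipc_matrix <- R * rep(dpc, each = p)
  diag(ipc_matrix) <- 0
  dimnames(ipc_matrix) <- list(predictors, predictors)
  ipc <- rowSums(ipc_matrix)

  structure(
    list(
      terms = tibble::tibble(
        predictor = predictors,
        b = unname(B),
        dpc = dpc,
        dpc_p = unname(coef_p),
        dpc_stars = stars_from_p(unname(coef_p)),
        ipc = unname(ipc),
        ipc_p = unname(r_y_p),
        ipc_stars = stars_from_p(unname(r_y_p)),
        r_response = unname(r_y)
      ),
      ipc_matrix = ipc_matrix,
      response = response,
      n = n,
      r_squared = summary(fit)$r.squared,
      adj_r_squared = summary(fit)$adj.r.squared,
      fit = fit
    ),
    class = "path_fit"
  )
}

#' @export
print.path_fit <- function(x, ...) {
  cat("<path_fit> response:", x$response, " n =", x$n,
      " R^2 =", signif(x$r_squared, 4), "\n")
  print(x$terms[, c("predictor", "dpc", "dpc_stars", "ipc", "ipc_stars",
                    "r_response")])
  invisible(x)
}

#' Tidy a path decomposition
#'
#' @param x A `path_fit` from [path_decomposition()].
#' @param ... Unused.
#' @return A tibble with one row per predictor: raw coefficient `b`, direct
#'   path `dpc` with its partial-test p-value and stars, total indirect
#'   path `ipc` with the correlation-test p-value and stars, and the simple
#'   correlation `r_response` (which equals `dpc + ipc`).
#' @method tidy path_fit
#' @export
tidy.path_fit <- function(x, ...) x$terms

#' One-row summary of a path decomposition
#'
#' @param x A `path_fit` from [path_decomposition()].
#' @param ... Unused.
#' @return Tibble with `r_squared`, `adj_r_squared`, `n`, `df_residual`.
#' @method glance path_fit
#' @export
glance.path_fit <- function(x, ...) {
  tibble::tibble(
    r_squared = x$r_squared,
    adj_r_squared = x$adj_r_squared,
    n = x$n,
    df_residual = x$fit$df.residual
  )
}

#' Path decomposition over pooled age windows, per cross type
#'
#' Pools tree-by-year observations within each age window separately for
#' each cross type and runs [path_decomposition()] on each pool, giving the
#' age trajectory of direct and indirect effects on volume.
#'
#' @param data Trait table from [derive_traits()].
#' @param windows Character vector of age windows, `"lo-hi"`; the default
#'   covers ages 2-18 in the trial's six windows.
#' @param response,predictors As in [path_decomposition()].
#'
#' @return A tibble of tidied results with `cross_type` and `window`
#'   prepended; the fitted `path_fit` objects are in the `"fits"` attribute
#'   (named `"<cross_type>:<window>"`). Empty windows are skipped with a
#'   warning.
#' @export
windowed_path_analysis <- function(data,
                                   windows = c("2-3", "4-6", "7-9", "10-12",
                                               "13-15", "16-18"),
                                   response = "volume",
                                   predictors = c("dbh", "height", "hdr")) {
  check_columns(data, c("cross_type", "age", response, predictors),
                what = "trait table")
  fits <- list()
  rows <- list()
  for (ct in sort(unique(data$cross_type))) {
    for (w in windows) {
      ages <- parse_age_window(w)
      sub <- dplyr::filter(data, .data$cross_type == ct, .data$age %in% ages)
      if (nrow(sub) == 0L) {
        warn(paste0("window ", w, " has no data for ", ct, "; skipped"))
        next
      }
      fit <- path_decomposition(sub, response = response,
                                predictors = predictors)
      fits[[paste0(ct, ":", w)]] <- fit
      rows[[paste0(ct, ":", w)]] <- dplyr::mutate(
        tidy(fit), cross_type = ct, window = w, .before = 1
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "fits") <- fits
  out
}

#' Per-age one-way ANOVA between the two cross-type populations
#'
#' For each trait and age, compares tree-level values of the direct and
#' reciprocal populations with a one-way ANOVA. With two groups the F
#' statistic equals the square of the pooled-variance t statistic. When
#' both within-group variances are zero but the means differ, F diverges;
#' the row is reported with `f_stat = Inf`, `p_value = 0` and flag
#' `"degenerate"`.
#'
#' @param data Trait table with both cross types.
#' @param traits Trait columns to test (defaults to those present among
#'   dbh, height, hdr, volume).
#' @param ages Ages to test; default every age at which both cross types
#'   have at least two trees. Requesting an age where a group is absent is
#'   an error.
#'
#' @return A tibble `age, trait, f_stat, df_between, df_within, p_value,
#'   stars, flag` (stars collapse p < 0.001 into `**`, the package's
#'   two-level convention).
#' @export
population_anova <- function(data,
                             traits = intersect(c("dbh", "height", "hdr",
                                                  "volume"), names(data)),
                             ages = NULL) {
  check_columns(data, c("cross_type", "age", traits), what = "trait table")
  check_cross_type(data$cross_type)

  counts <- data |>
    dplyr::count(.data$age, .data$cross_type) |>
    tidyr::pivot_wider(names_from = "cross_type", values_from = "n",
                       values_fill = 0L)
  for (ct in c("DxM", "MxD")) if (!ct %in% names(counts)) counts[[ct]] <- 0L

  if (is.null(ages)) {
    ages <- sort(counts$age[counts$DxM >= 2L & counts$MxD >= 2L])
  } else {
    ages <- sort(unique(as.integer(ages)))
    for (a in ages) {
      row <- counts[counts$age == a, ]
      if (nrow(row) == 0L || row$DxM == 0L || row$MxD == 0L) {
        abort(paste0("group missing: both cross types needed at age ", a))
      }
    }
  }

  grid <- tidyr::expand_grid(age = ages, trait = traits)
  purrr::pmap_dfr(grid, function(age, trait) {
    sub <- data[data$age == age, c("cross_type", trait)]
    names(sub)[2] <- "value"
    k <- length(unique(sub$cross_type))
    n <- nrow(sub)
    ssw <- sum(stats::ave(sub$value, sub$cross_type,
                          FUN = function(v) v - mean(v))^2)
    base <- tibble::tibble(age = age, trait = trait,
                           df_between = k - 1L, df_within = n - k)
    if (ssw < 1e-300) {
      means <- tapply(sub$value, sub$cross_type, mean)
      if (max(means) - min(means) > 0) {
        return(dplyr::mutate(base, f_stat = Inf, p_value = 0,
                             stars = "**", flag = "degenerate",
                             .after = "trait"))
      }
      return(dplyr::mutate(base, f_stat = 0, p_value = 1,
                           stars = "ns", flag = "degenerate",
                           .after = "trait"))
    }
    av <- anova(lm(value ~ cross_type, data = sub))
    f <- av$`F value`[1]
    p <- av$`Pr(>F)`[1]
    dplyr::mutate(base, f_stat = f, p_value = p,
                  stars = stars_from_p(p), flag = "ok", .after = "trait")
  })
}
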