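test_that("pearson correlation matches the direct formula and cor.test", {
  # exact linear relation
  x <- 1:10
  perfect <- pearson_cor(x, 2 * x + 1)
  expect_equal(perfect$r, 1.0)
  expect_equal(perfect$p_value, 0)

  # fixed 10-point fixture against a from-scratch sum formula
  xf <- c(3.1, 4.7, 5.2, 6.8, 7.7, 8.1, 9.6, 10.2, 11.9, 12.4)
  yf <- c(2.0, 5.1, 4.2, 7.9, 6.6, 9.3, 8.8, 12.0, 10.7, 13.5)
  n <- length(xf)
  r_oracle <- (sum(xf * yf) - n * mean(xf) * mean(yf)) /
    sqrt((sum(xf^2) - n * mean(xf)^2) * (sum(yf^2) - n * mean(yf)^2))
  got <- pearson_cor(xf, yf)
  expect_equal(got$r, r_oracle, tolerance = 1e-12)
  ct <- cor.test(xf, yf)
  expect_equal(got$t_stat, unname(ct$statistic), tolerance = 1e-12)
  expect_equal(got$p_value, ct$p.value, tolerance = 1e-12)

  # symmetry is exact
  expect_identical(pearson_cor(xf, yf)$r, pearson_cor(yf, xf)$r)

  # pairwise deletion
  xm <- c(xf, NA); ym <- c(yf, 99)
  expect_equal(pearson_cor(xm, ym)$n, 10L)
  expect_equal(pearson_cor(xm, ym)$r, r_oracle, tolerance = 1e-12)

  expect_error(pearson_cor(c(1, 1, 1), c(1, 2, 3)), "degenerate variance")
  expect_error(pearson_cor(1:2, 2:3), "at least 3")
})

# orthonormal centred basis for building samples with exact correlations
ortho_basis <- function(n, k, seed = 5) {
  set.seed(seed)
  A <- matrix(rnorm(n * k), n, k)
  A <- scale(A, center = TRUE, scale = FALSE)
  qr.Q(qr(A))
}

test_that("orthogonal predictors give DPC = r and zero IPC", {
  Q <- ortho_basis(40, 3)
  d <- tibble::tibble(
    x1 = Q[, 1], x2 = Q[, 2],
    y = 0.8 * Q[, 1] + 0.3 * Q[, 2] + 0.5 * Q[, 3]
  )
  fit <- path_decomposition(d, response = "y", predictors = c("x1", "x2"))
  td <- tidy(fit)
  expect_equal(td$ipc, c(0, 0), tolerance = 1e-10)
  expect_equal(td$dpc, td$r_response, tolerance = 1e-10)
})

test_that("two-predictor decomposition matches the hand-solved normal equations", {
  # exact sample correlations r12 = 0.5, r1y = 0.8, r2y = 0.6:
  # dpc1 = (0.8 - 0.5*0.6)/(1 - 0.25) = 2/3, dpc2 = 4/15,
  # ipc1 = 0.5 * 4/15 = 2/15, dpc1 + ipc1 = 0.8
  Q <- ortho_basis(30, 3)
  b2 <- (0.6 - 0.5 * 0.8) / sqrt(0.75)
  d <- tibble::tibble(
    x1 = Q[, 1],
    x2 = 0.5 * Q[, 1] + sqrt(0.75) * Q[, 2],
    y = 0.8 * Q[, 1] + b2 * Q[, 2] + sqrt(1 - 0.64 - b2^2) * Q[, 3]
  )
  expect_equal(cor(d$x1, d$x2), 0.5, tolerance = 1e-12)
  expect_equal(cor(d$x1, d$y), 0.8, tolerance = 1e-12)
  expect_equal(cor(d$x2, d$y), 0.6, tolerance = 1e-12)

  fit <- path_decomposition(d, response = "y", predictors = c("x1", "x2"))
  td <- tidy(fit)
  expect_equal(td$dpc, c(2 / 3, 4 / 15), tolerance = 1e-10)
  expect_equal(td$ipc, c(0.5 * 4 / 15, 0.5 * 2 / 3), tolerance = 1e-10)
  expect_equal(td$dpc + td$ipc, c(0.8, 0.6), tolerance = 1e-10)

  # independent oracle: standardized solve of the normal equations
  R <- cor(cbind(d$x1, d$x2))
  ry <- c(cor(d$x1, d$y), cor(d$x2, d$y))
  expect_equal(td$dpc, as.numeric(solve(R, ry)), tolerance = 1e-10)
})

test_that("the path identity holds on random samples", {
  set.seed(42)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    X <- matrix(rnorm(3 * n), n, 3)
    y <- X %*% rnorm(3) + rnorm(n)
    d <- tibble::tibble(a = X[, 1], b = X[, 2], c = X[, 3], y = as.numeric(y))
    td <- tidy(path_decomposition(d, "y", c("a", "b", "c")))
    expect_lt(max(abs(td$dpc + td$ipc - td$r_response)), 1e-10)
  }
})

test_that("collinear predictors are rejected by name", {
  set.seed(9)
  d <- tibble::tibble(x1 = rnorm(20), x2 = rnorm(20))
  d$x3 <- d$x1 + d$x2
  d$y <- rnorm(20)
  expect_error(path_decomposition(d, "y", c("x1", "x2", "x3")),
               "collinear.*x1, x2, x3")
  expect_error(
    path_decomposition(tibble::tibble(x = 1:2, y = rnorm(2)), "y", "x"),
    "n > number of predictors"
  )
})

test_that("windowed analysis pools correctly per cross type", {
  tr <- shared_traits()
  res <- windowed_path_analysis(tr)
  expect_equal(nrow(res), 2 * 6 * 3)  # cross types x windows x predictors
  expect_length(attr(res, "fits"), 12L)

  # single-age window equals a direct fit on that age
  one <- windowed_path_analysis(tr[tr$cross_type == "DxM", ], windows = "9")
  direct <- tidy(path_decomposition(
    tr[tr$cross_type == "DxM" & tr$age == 9, ]
  ))
  expect_equal(one$dpc, direct$dpc, tolerance = 1e-12)

  # pooled window equals a fit on the manually concatenated rows
  manual <- dplyr::bind_rows(
    tr[tr$cross_type == "MxD" & tr$age == 7, ],
    tr[tr$cross_type == "MxD" & tr$age == 8, ],
    tr[tr$cross_type == "MxD" & tr$age == 9, ]
  )
  pooled <- res[res$cross_type == "MxD" & res$window == "7-9", ]
  expect_equal(pooled$dpc, tidy(path_decomposition(manual))$dpc,
               tolerance = 1e-12)

  # DBH carries the dominant direct path under the trial's structure
  tops <- res |>
    dplyr::group_by(cross_type, window) |>
    dplyr::summarise(top = predictor[which.max(dpc)], .groups = "drop")
  expect_true(all(tops$top == "dbh"))

  expect_warning(
    windowed_path_analysis(tr[tr$age < 10 & tr$cross_type == "DxM", ],
                           windows = c("2-3", "16-18")),
    "no data"
  )
})

test_that("population ANOVA matches the sum-of-squares oracle and t^2", {
  d <- tibble::tibble(
    clone_id = "x", cross_type = rep(c("DxM", "MxD"), each = 6),
    age = 5L,
    volume = c(1.1, 1.3, 0.9, 1.2, 1.4, 1.0, 0.8, 0.7, 1.0, 0.9, 0.6, 0.85)
  )
  res <- population_anova(d, traits = "volume", ages = 5)
  # brute-force sum-of-squares decomposition
  g1 <- d$volume[1:6]; g2 <- d$volume[7:12]
  gm <- mean(d$volume)
  ssb <- 6 * (mean(g1) - gm)^2 + 6 * (mean(g2) - gm)^2
  ssw <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)
  f_oracle <- (ssb / 1) / (ssw / 10)
  expect_equal(res$f_stat, f_oracle, tolerance = 1e-12)
  expect_equal(res$p_value, pf(f_oracle, 1, 10, lower.tail = FALSE),
               tolerance = 1e-12)

  # two-group F equals the square of the pooled t statistic
  tt <- t.test(g1, g2, var.equal = TRUE)
  expect_equal(res$f_stat, unname(tt$statistic)^2, tolerance = 1e-10)

  # identical group means -> F = 0
  d0 <- dplyr::mutate(d, volume = rep(c(1, 2, 3), 4))
  expect_equal(population_anova(d0, "volume", ages = 5)$f_stat, 0,
               tolerance = 1e-12)

  # zero within-group variance, different means -> degenerate
  dd <- dplyr::mutate(d, volume = rep(c(1, 3), each = 6))
  deg <- population_anova(dd, "volume", ages = 5)
  expect_equal(deg$f_stat, Inf)
  expect_equal(deg$p_value, 0)
  expect_equal(deg$flag, "degenerate")

  # requesting an age where a group is absent errors
  expect_error(
    population_anova(d[d$cross_type == "DxM", ], "volume", ages = 5),
    "group missing"
  )
})

test_that("F = t^2 holds across simulated ages", {
  tr <- shared_traits()
  res <- population_anova(tr, traits = "dbh")
  for (a in c(2, 9, 18)) {
    g1 <- tr$dbh[tr$age == a & tr$cross_type == "DxM"]
    g2 <- tr$dbh[tr$age == a & tr$cross_type == "MxD"]
    tt <- t.test(g1, g2, var.equal = TRUE)
    expect_equal(res$f_stat[res$age == a], unname(tt$statistic)^2,
                 tolerance = 1e-10)
  }
})
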