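test_that("the survival census reads with rates, duplicates surfaced", {
  expect_warning(surv <- poplar_trial_survival(), "both cross types")
  expect_equal(nrow(surv), 23L)
  expect_equal(attr(surv, "validation")$clone_id, "MD-19")
  expect_equal(surv$survival_rate[surv$clone_id == "DM-9-22"], 90)
})

test_that("the survival filter retains 17 clones at the inclusive 60% rule", {
  surv <- suppressWarnings(poplar_trial_survival())
  kept <- filter_by_survival(surv, threshold = 60, quiet = TRUE)
  expect_equal(nrow(kept), 17L)
  expect_equal(sum(kept$cross_type == "DxM"), 10L)
  expect_equal(sum(kept$cross_type == "MxD"), 7L)
  expect_true("DM-9-22" %in% kept$clone_id)

  # exclusive threshold drops the clone sitting exactly at 60%
  strict <- filter_by_survival(surv, threshold = 60, inclusive = FALSE,
                               quiet = TRUE)
  expect_equal(nrow(strict), 16L)
  expect_false(any(strict$survival_rate == 60))

  # a perfect bar excludes every imperfect clone
  expect_equal(nrow(filter_by_survival(surv, threshold = 100, quiet = TRUE)),
               0L)
})

test_that("zero-planted survival rows are rejected on read", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "clone_id,cross_type,cuttings_planted,cuttings_surviving",
    "A,DxM,20,15",
    "B,DxM,0,0",
    "C,MxD,20,25"
  ), path)
  expect_warning(surv <- read_survival(path), "rejected")
  expect_equal(nrow(surv), 1L)
  expect_equal(nrow(attr(surv, "rejected")), 2L)
})

test_that("selection takes floor(rate * n) clones, minimum one, by ranked criterion", {
  tr <- shared_traits()
  report <- select_top_clones(tr, rate = 0.25)
  expect_equal(glance(report)$n_candidates, 17L)
  expect_equal(glance(report)$n_selected, 4L)

  # brute-force sort-and-slice oracle on clone means at the reference age
  at18 <- tr[tr$age == 18, ]
  cm <- tapply(at18$volume, at18$clone_id, mean)
  oracle <- names(sort(cm, decreasing = TRUE))[1:4]
  expect_setequal(tidy(report)$clone_id, oracle)
  expect_equal(tidy(report)$clone_id,
               names(sort(cm, decreasing = TRUE))[1:4])

  # saturating rate ranks everyone
  all_ranked <- select_top_clones(tr, rate = 1.0)
  expect_equal(glance(all_ranked)$n_selected, 17L)
  expect_equal(tidy(all_ranked)$rank, 1:17)

  # floor with minimum 1: n = 4 -> 1; n = 3 -> 1
  sub4 <- tr[tr$clone_id %in% unique(tr$clone_id)[1:4], ]
  expect_equal(glance(select_top_clones(sub4, rate = 0.25))$n_selected, 1L)
  sub3 <- tr[tr$clone_id %in% unique(tr$clone_id)[1:3], ]
  expect_equal(glance(select_top_clones(sub3, rate = 0.25))$n_selected, 1L)

  # idempotence: reselecting the selected subset at rate 1 returns the set
  sel_ids <- tidy(report)$clone_id
  again <- select_top_clones(tr[tr$clone_id %in% sel_ids, ], rate = 1.0)
  expect_setequal(tidy(again)$clone_id, sel_ids)

  expect_error(select_top_clones(tr, rate = 0), "rate")
  expect_error(select_top_clones(tr, rate = 1.5), "rate")
})

test_that("favourability flags compare to the own population mean, inverted for HDR", {
  # two clones per cross type; B has the bigger volume but a slimmer
  # (higher-HDR) stem than the DxM average
  d <- derive_traits(tibble::tibble(
    clone_id = rep(c("A", "B", "C", "D"), each = 2),
    cross_type = rep(c("DxM", "DxM", "MxD", "MxD"), each = 2),
    block = 1L, tree_id = rep(c("T1", "T2"), 4), age = 18L,
    dbh = c(40, 41, 38, 38.5, 30, 31, 28, 29),
    height = c(24, 24.2, 29, 29.3, 22, 22.4, 20, 20.2)
  ))
  rep1 <- select_top_clones(d, rate = 0.5)
  sel <- tidy(rep1)
  b <- sel[sel$clone_id == "B", ]
  expect_true(b$volume_favourable)
  expect_false(b$hdr_favourable)  # above the DxM mean HDR: unfavourable

  a_means <- rep1$population_means
  expect_equal(a_means$volume[a_means$cross_type == "DxM"],
               mean(d$volume[d$cross_type == "DxM"]))
})

test_that("ties break by dbh then clone id, deterministically", {
  d <- derive_traits(tibble::tibble(
    clone_id = c("Z", "M", "Q"), cross_type = "DxM", block = 1L,
    tree_id = "T1", age = 10L,
    dbh = c(20, 22, 22), height = c(12.1, 10, 10)
  ))
  # all three volumes are exactly equal (22^2 * 10 = 20^2 * 12.1), so the
  # order is decided by dbh (M, Q before Z) then clone id (M before Q)
  r <- select_top_clones(d, rate = 1.0)
  ranked <- tidy(r)
  expect_equal(length(unique(ranked$volume)), 1L)
  expect_equal(ranked$clone_id, c("M", "Q", "Z"))
})

test_that("volume CV matches hand computation and flags tiny groups", {
  d <- tibble::tibble(
    clone_id = c("A", "A", "B"), cross_type = "DxM",
    age = 18L, volume = c(0.9, 1.1, 1.0)
  )
  cv <- volume_cv(d, level = "clone", reference_age = 18)
  a <- cv[cv$clone_id == "A", ]
  expect_equal(a$cv_pct, 100 * sd(c(0.9, 1.1)) / 1.0, tolerance = 1e-12)
  expect_equal(round(a$cv_pct), 14)
  b <- cv[cv$clone_id == "B", ]
  expect_true(is.na(b$cv_pct))
  expect_equal(b$flag, "insufficient_n")

  same <- volume_cv(tibble::tibble(
    clone_id = "A", cross_type = "DxM", age = 18L, volume = rep(0.7, 5)
  ), level = "clone", reference_age = 18)
  expect_equal(same$cv_pct, 0)
})

test_that("population variability exceeds selected-clone variability in simulation", {
  tr <- shared_traits()
  report <- select_top_clones(tr, rate = 0.25)
  cv <- report$cv
  pop_cv <- cv$cv_pct[cv$group %in% c("DxM", "MxD")]
  clone_cv <- cv$cv_pct[!cv$group %in% c("DxM", "MxD")]
  expect_true(all(!is.na(clone_cv)))
  expect_true(all(max(pop_cv) > clone_cv))
  for (row in which(!cv$group %in% c("DxM", "MxD"))) {
    own_pop <- cv$cv_pct[cv$group == cv$cross_type[row]]
    expect_gt(own_pop, cv$cv_pct[row])
  }
})
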