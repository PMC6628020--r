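test_that("per-study indices reproduce hand arithmetic on a published row", {
  # GSE44076 healthy-control arm: 92/1/6/49
  idx <- study_indices(confusion_table(92, 1, 6, 49, "GSE44076 (1)"))
  expect_equal(idx$sens, 92 / 98)
  expect_equal(idx$spec, 49 / 50)
  expect_equal(idx$plr, (92 / 98) / (1 / 50), tolerance = 1e-12)
  expect_equal(idx$dor, (92 * 49) / (1 * 6), tolerance = 1e-12)
  expect_false(idx$corrected)
  expect_equal(idx$var_ln_dor, 1 / 92 + 1 + 1 / 6 + 1 / 49)
  expect_equal(idx$var_ln_plr, 1 / 92 - 1 / 98 + 1 / 1 - 1 / 50)
  expect_equal(idx$var_ln_nlr, 1 / 6 - 1 / 98 + 1 / 49 - 1 / 50)
})

test_that("zero cells trigger the half-count correction and stay finite", {
  idx <- study_indices(confusion_table(10, 0, 5, 20, "z"))
  expect_true(idx$corrected)
  expect_equal(idx$sens, 10.5 / 16)
  expect_equal(idx$spec, 20.5 / 21)
  expect_true(all(is.finite(unlist(idx[c("plr", "nlr", "dor",
                                         "ln_plr", "ln_nlr", "ln_dor")]))))
  expect_error(study_indices(confusion_table(0, 5, 0, 5, "m")), "margin")
})

test_that("DOR equals PLR/NLR on the same corrected counts", {
  set.seed(13)
  for (i in 1:20) {
    cells <- rpois(4, 15) + c(sample(0:1, 1), 0, 0, 0)
    t <- confusion_table(cells[1], cells[2], cells[3], cells[4], "r")
    if (t$tp + t$fn == 0 || t$fp + t$tn == 0) next
    idx <- study_indices(t)
    expect_equal(idx$dor, idx$plr / idx$nlr, tolerance = 1e-12)
  }
})

test_that("proportion pooling is the aggregate proportion with Cochran Q", {
  tabs <- chga_tables()
  sens <- pool_proportion(tabs, "sens")
  expect_equal(sens$estimate, 255 / 285, tolerance = 1e-12)
  spec <- pool_proportion(tabs, "spec")
  expect_equal(spec$estimate, 201 / 225, tolerance = 1e-12)
  expect_identical(sens$df, 4L)
  # identical studies are homogeneous
  same <- replicate(4, confusion_table(40, 5, 10, 45, "s"), simplify = FALSE)
  hom <- pool_proportion(same, "sens")
  expect_equal(hom$estimate, 0.8)
  expect_equal(hom$q_stat, 0, tolerance = 1e-12)
  expect_equal(hom$i2, 0)
})

test_that("aggregate pooling is invariant to splitting a study in two", {
  tabs <- list(confusion_table(40, 6, 10, 44, "a"),
               confusion_table(30, 8, 6, 36, "b"))
  split <- list(confusion_table(20, 3, 5, 22, "a1"),
                confusion_table(20, 3, 5, 22, "a2"),
                confusion_table(30, 8, 6, 36, "b"))
  expect_equal(pool_proportion(tabs, "sens")$estimate,
               pool_proportion(split, "sens")$estimate)
  expect_equal(pool_proportion(tabs, "spec")$estimate,
               pool_proportion(split, "spec")$estimate)
})

test_that("DerSimonian-Laird pooling matches metafor on the published tables", {
  tabs <- chga_tables()
  idx <- lapply(tabs, study_indices)
  for (which in c("plr", "nlr", "dor")) {
    y <- vapply(idx, `[[`, numeric(1), paste0("ln_", which))
    v <- vapply(idx, `[[`, numeric(1), paste0("var_ln_", which))
    ref <- metafor::rma(yi = y, vi = v, method = "DL")
    ours <- pool_log_ratio(idx, which, model = "random")
    expect_equal(ours$estimate, exp(as.numeric(ref$beta)), tolerance = 1e-8)
    expect_equal(ours$tau2, ref$tau2, tolerance = 1e-8)
    expect_equal(ours$q_stat, ref$QE, tolerance = 1e-8)
  }
})

test_that("random effects collapse onto fixed effects under homogeneity", {
  idx <- replicate(3, study_indices(confusion_table(40, 5, 10, 45, "s")),
                   simplify = FALSE)
  r <- pool_log_ratio(idx, "dor", model = "random")
  f <- pool_log_ratio(idx, "dor", model = "fixed")
  expect_equal(r$tau2, 0)
  expect_equal(r$estimate, f$estimate, tolerance = 1e-12)
  expect_equal(r$estimate, idx[[1]]$dor, tolerance = 1e-12)
})

test_that("pooled log-ratio estimates stay inside the per-study range and tau2 >= 0", {
  set.seed(47)
  for (i in 1:15) {
    tabs <- lapply(1:4, function(j) {
      confusion_table(rpois(1, 30) + 1, rpois(1, 6), rpois(1, 6) + 1,
                      rpois(1, 30) + 1, paste0("s", j))
    })
    idx <- lapply(tabs, study_indices)
    for (which in c("plr", "nlr", "dor")) {
      p <- pool_log_ratio(idx, which, model = "random")
      lo <- min(vapply(idx, `[[`, numeric(1), which))
      hi <- max(vapply(idx, `[[`, numeric(1), which))
      expect_gte(p$tau2, 0)
      expect_gte(p$estimate, lo - 1e-12)
      expect_lte(p$estimate, hi + 1e-12)
    }
  }
})

test_that("the continuity correction perturbs large studies by under 1 percent", {
  idx_raw <- study_indices(confusion_table(900, 100, 100, 900, "big"))
  corrected_dor <- (900.5 * 900.5) / (100.5 * 100.5)
  expect_lt(abs(corrected_dor - idx_raw$dor) / idx_raw$dor, 0.01)
})

test_that("forest data are sorted by effect size with normalised weights", {
  tabs <- chga_tables()
  idx <- lapply(tabs, study_indices)
  pooled <- pool_log_ratio(idx, "dor", model = "random")
  fd <- forest_data(idx, pooled)
  expect_identical(nrow(fd), 6L)
  study_rows <- fd[!fd$pooled, ]
  expect_identical(order(-study_rows$estimate), seq_len(5L))
  expect_equal(sum(study_rows$weight), 1, tolerance = 1e-9)
  # sorted order agrees with a direct comparison sort of the raw DORs
  dors <- sort(vapply(idx, `[[`, numeric(1), "dor"), decreasing = TRUE)
  expect_equal(study_rows$estimate, dors, tolerance = 1e-12)

  psens <- pool_proportion(tabs, "sens")
  fs <- forest_data(tabs, psens)
  expect_identical(fs$study_id[6], "POOLED")
  expect_equal(sum(fs$weight[!fs$pooled]), 1, tolerance = 1e-12)
})
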