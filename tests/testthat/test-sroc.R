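idx_from <- function(cells) {
  lapply(seq_along(cells), function(i) {
    c <- cells[[i]]
    study_indices(confusion_table(c[1], c[2], c[3], c[4], paste0("s", i)))
  })
}

test_that("a flat D profile yields slope 0 and intercept at the common ln DOR", {
  # constant ln DOR (logit sens + logit spec = 3) across spread thresholds
  idx <- idx_from(list(c(70, 10, 20, 40), c(60, 12, 25, 45), c(50, 15, 30, 50)))
  sens <- plogis(c(1, 1.5, 2))
  spec <- plogis(c(2, 1.5, 1))
  for (i in 1:3) {
    idx[[i]]$sens <- sens[i]
    idx[[i]]$spec <- spec[i]
  }
  m <- fit_moses(idx, weighted = FALSE)
  expect_equal(m$b, 0, tolerance = 1e-10)
  expect_equal(m$a, 3, tolerance = 1e-10)
})

test_that("three collinear points are interpolated exactly", {
  # build indices, then overwrite (S, D) with an exact line via sens/spec
  idx <- idx_from(list(c(70, 10, 20, 40), c(60, 12, 25, 45), c(50, 15, 30, 50)))
  s <- c(-2, 0, 2)
  d <- 1.5 + 0.25 * s
  sens <- plogis((d + s) / 2)
  fpr <- plogis((s - d) / 2)
  for (i in 1:3) {
    idx[[i]]$sens <- sens[i]
    idx[[i]]$spec <- 1 - fpr[i]
  }
  m <- fit_moses(idx, weighted = FALSE)
  expect_equal(m$a, 1.5, tolerance = 1e-9)
  expect_equal(m$b, 0.25, tolerance = 1e-9)
})

test_that("Moses coefficients match the normal-equations oracle on the published tables", {
  idx <- lapply(chga_tables(), study_indices)
  d <- vapply(idx, `[[`, numeric(1), "ln_dor")
  s <- qlogis(vapply(idx, `[[`, numeric(1), "sens")) +
    qlogis(1 - vapply(idx, `[[`, numeric(1), "spec"))
  for (weighted in c(FALSE, TRUE)) {
    w <- if (weighted) 1 / vapply(idx, `[[`, numeric(1), "var_ln_dor")
         else rep(1, 5)
    oracle <- normal_equations_moses(d, s, w)
    m <- fit_moses(idx, weighted = weighted)
    expect_equal(m$a, oracle[1], tolerance = 1e-9)
    expect_equal(m$b, oracle[2], tolerance = 1e-9)
  }
})

test_that("identical thresholds leave the slope undefined", {
  idx <- replicate(3, study_indices(confusion_table(40, 5, 10, 45, "s")),
                   simplify = FALSE)
  expect_error(fit_moses(idx), "slope is undefined")
})

test_that("the SROC curve obeys its closed forms", {
  m <- structure(list(a = 0, b = 0, se_a = 0.1, weighted = FALSE,
                      degenerate = FALSE), class = "sroc_model")
  fprs <- seq(0.05, 0.95, by = 0.05)
  expect_equal(sroc_curve(m, fprs), fprs, tolerance = 1e-12)

  m2 <- structure(list(a = 4.05, b = 0.2, se_a = 0.1, weighted = FALSE,
                       degenerate = FALSE), class = "sroc_model")
  # hand evaluation of tpr = expit(a/(1-b) + logit(fpr)(1+b)/(1-b)) at 0.1
  expect_equal(sroc_curve(m2, 0.1),
               plogis(4.05 / 0.8 + qlogis(0.1) * 1.2 / 0.8),
               tolerance = 1e-12)
  # Q* lies on the curve: tpr(1 - Q*) = Q*
  qs <- q_star(m2)
  expect_equal(sroc_curve(m2, 1 - qs), qs, tolerance = 1e-9)
  expect_error(sroc_curve(m2, 1.2), "inside")
})

test_that("AUC integration matches known values and converges", {
  m0 <- structure(list(a = 0, b = 0, se_a = 0.1, weighted = FALSE,
                       degenerate = FALSE), class = "sroc_model")
  expect_equal(sroc_auc(m0), 0.5, tolerance = 1e-6)
  expect_equal(q_star(m0), 0.5)

  mperf <- structure(list(a = 20, b = 0, se_a = 0.1, weighted = FALSE,
                          degenerate = FALSE), class = "sroc_model")
  expect_gt(sroc_auc(mperf), 0.999)

  masym <- structure(list(a = 3, b = 0.3, se_a = 0.1, weighted = FALSE,
                          degenerate = FALSE), class = "sroc_model")
  expect_lt(abs(sroc_auc(masym, step = 1e-4) - sroc_auc(masym, step = 5e-5)),
            1e-6)
  # dense independent integration
  ref <- stats::integrate(function(x) sroc_curve(masym, x), 0, 1,
                          rel.tol = 1e-10)$value
  expect_equal(sroc_auc(masym), ref, tolerance = 1e-6)
})

test_that("Q* has its closed form and swap symmetry maps AUC to its complement", {
  m <- structure(list(a = log(81), b = 0, se_a = 0.1, weighted = FALSE,
                      degenerate = FALSE), class = "sroc_model")
  expect_equal(q_star(m), plogis(log(9)))
  expect_equal(q_star(m), 0.9)

  masym <- structure(list(a = 2.2, b = 0.15, se_a = 0.1, weighted = FALSE,
                          degenerate = FALSE), class = "sroc_model")
  mswap <- masym
  mswap$a <- -masym$a
  expect_equal(sroc_auc(mswap), 1 - sroc_auc(masym), tolerance = 1e-6)
  # monotonicity for |b| < 1
  grid <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(diff(sroc_curve(masym, grid)) > 0))
})

test_that("degenerate slopes fall back to the symmetric summary curve", {
  idx <- lapply(chga_tables(), study_indices)
  m <- fit_moses(idx, weighted = TRUE)
  expect_true(m$degenerate)
  expect_error(sroc_curve(m, 0.1, symmetric = FALSE), "not monotone")
  # the reported AUC is the symmetric-curve area at the fitted intercept
  expect_equal(m$auc, sroc_auc(m, symmetric = TRUE), tolerance = 1e-12)
  expect_equal(m$q_star, plogis(m$a / 2), tolerance = 1e-12)
})
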