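#' Per-study diagnostic accuracy indices
#'
#' Computes sensitivity, specificity, positive/negative likelihood ratios and
#' the diagnostic odds ratio from a 2x2 table, together with delta-method
#' variances of the log ratios:
#' `var(ln DOR) = 1/TP + 1/FP + 1/FN + 1/TN`,
#' `var(ln PLR) = 1/TP - 1/(TP+FN) + 1/FP - 1/(FP+TN)`,
#' `var(ln NLR) = 1/FN - 1/(TP+FN) + 1/TN - 1/(FP+TN)`.
#' If any cell is zero, `correction` (default 0.5) is added to all four cells
#' first and the `corrected` flag is set, keeping every log index finite.
#'
#' @param t A `confusion_table`.
#' @param correction Continuity-correction constant for zero cells.
#' @return A `study_indices` object; also retains the raw counts, which
#'   proportion pooling uses uncorrected.
#' @export
study_indices <- function(t, correction = 0.5) {
  stopifnot(inherits(t, "confusion_table"))
  if (t$tp + t$fn == 0 || t$fp + t$tn == 0) {
    stop("study ", t$study_id, ": a margin is zero (no cases or no controls)")
  }
  corrected <- any(c(t$tp, t$fp, t$fn, t$tn) == 0)
  cc <- if (corrected) correction else 0
  tp <- t$tp + cc; fp <- t$fp + cc; fn <- t$fn + cc; tn <- t$tn + cc
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  plr <- sens / (1 - spec)
  nlr <- (1 - sens) / spec
  dor <- plr / nlr
  out <- list(
    study_id = t$study_id,
    sens = sens, spec = spec, plr = plr, nlr = nlr, dor = dor,
    ln_plr = log(plr), ln_nlr = log(nlr), ln_dor = log(dor),
    var_ln_plr = 1 / tp - 1 / (tp + fn) + 1 / fp - 1 / (fp + tn),
    var_ln_nlr = 1 / fn - 1 / (tp + fn) + 1 / tn - 1 / (fp + tn),
    var_ln_dor = 1 / tp + 1 / fp + 1 / fn + 1 / tn,
    corrected = corrected,
    raw = c(tp = t$tp, fp = t$fp, fn = t$fn, tn = t$tn))
  class(out) <- "study_indices"
  out
}

pooled_result <- function(index_name, estimate, ci_low, ci_high,
                          q_stat, df, tau2, i2, model) {
  structure(list(index_name = index_name, estimate = estimate,
                 ci_low = ci_low, ci_high = ci_high,
                 q_stat = q_stat, df = df, tau2 = tau2, i2 = i2,
                 model = model),
            class = "pooled_result")
}

#' @export
print.pooled_result <- function(x, ...) {
  cat(sprintf("pooled %s (%s): %.4f (95%% CI %.4f-%.4f); Q = %.3f (df %d), tau2 = %.4f, I2 = %.1f%%\n",
              x$index_name, x$model, x$estimate, x$ci_low, x$ci_high,
              x$q_stat, x$df, x$tau2, x$i2))
  invisible(x)
}

#' Pool sensitivity or specificity across studies
#'
#' The point estimate is the aggregate proportion: summed numerators over
#' summed denominators of the raw (uncorrected) counts — the convention of
#' classical DTA meta-analysis software, which simply adds the 2x2 tables for
#' the proportion indices. Heterogeneity uses Cochran's
#' `Q = sum w_i (p_i - p)^2` with study-specific binomial variances
#' `var_i = p_i (1 - p_i) / n_i` (continuity-corrected for boundary
#' proportions so weights stay finite), and `I2 = max(0, (Q - df)/Q) * 100`.
#' The 95% CI is the aggregate binomial normal interval truncated to [0, 1].
#'
#' @param tables List of `confusion_table` objects (>= 2; a single study
#'   passes through with `df = 0`, `i2 = 0`).
#' @param which `"sens"` or `"spec"`.
#' @return A `pooled_result`.
#' @export
pool_proportion <- function(tables, which = c("sens", "spec")) {
  which <- match.arg(which)
  num <- vapply(tables, function(t) if (which == "sens") t$tp else t$tn, numeric(1L))
  den <- vapply(tables, function(t) {
    if (which == "sens") t$tp + t$fn else t$tn + t$fp
  }, numeric(1L))
  if (any(den == 0)) stop("a study has an empty ", which, " margin")
  p_i <- num / den
  p_hat <- sum(num) / sum(den)
  k <- length(tables)
  if (k < 2L) {
    se <- sqrt(p_hat * (1 - p_hat) / sum(den))
    return(pooled_result(which, p_hat,
                         max(0, p_hat - 1.96 * se), min(1, p_hat + 1.96 * se),
                         q_stat = 0, df = 0L, tau2 = 0, i2 = 0,
                         model = "fixed"))
  }
  # boundary proportions get a half-count correction so 1/var_i is finite
  p_v <- (num + 0.5 * (p_i %in% c(0, 1))) / (den + 1 * (p_i %in% c(0, 1)))
  w <- den / (p_v * (1 - p_v))
  q <- sum(w * (p_i - p_hat)^2)
  df <- k - 1L
  i2 <- if (q > 0) max(0, (q - df) / q) * 100 else 0
  se <- sqrt(p_hat * (1 - p_hat) / sum(den))
  pooled_result(which, p_hat,
                max(0, p_hat - 1.96 * se), min(1, p_hat + 1.96 * se),
                q_stat = q, df = df, tau2 = 0, i2 = i2, model = "fixed")
}

#' Pool a log-scale ratio index across studies
#'
#' Inverse-variance pooling of `ln PLR`, `ln NLR` or `ln DOR`. The fixed
#' stage uses weights `1/var_i` and yields Cochran's Q; the random-effects
#' model adds the DerSimonian-Laird moment estimate
#' `tau2 = max(0, (Q - df) / (sum w - sum w^2 / sum w))` and reweights by
#' `1/(var_i + tau2)`. Estimates and 95% normal CIs are exponentiated back
#' to the ratio scale. Q and I2 always come from the fixed-weight stage.
#'
#' @param studies List of `study_indices`.
#' @param which `"plr"`, `"nlr"` or `"dor"`.
#' @param model `"random"` (default) or `"fixed"`.
#' @return A `pooled_result` on the ratio scale.
#' @export
pool_log_ratio <- function(studies, which = c("plr", "nlr", "dor"),
                           model = c("random", "fixed")) {
  which <- match.arg(which)
  model <- match.arg(model)
  y <- vapply(studies, `[[`, numeric(1L), paste0("ln_", which))
  v <- vapply(studies, `[[`, numeric(1L), paste0("var_ln_", which))
  if (!all(is.finite(y)) || !all(is.finite(v)) || any(v <= 0)) {
    stop("non-finite log index or variance; continuity correction should have fired upstream")
  }
  k <- length(y)
  w <- 1 / v
  y_fixed <- sum(w * y) / sum(w)
  q <- sum(w * (y - y_fixed)^2)
  df <- k - 1L
  i2 <- if (k >= 2L && q > 0) max(0, (q - df) / q) * 100 else 0
  tau2 <- 0
  if (model == "random" && k >= 2L) {
    tau2 <- max(0, (q - df) / (sum(w) - sum(w^2) / sum(w)))
  }
  w_star <- 1 / (v + tau2)
  est <- sum(w_star * y) / sum(w_star)
  se <- sqrt(1 / sum(w_star))
  pooled_result(which, exp(est), exp(est - 1.96 * se), exp(est + 1.96 * se),
                q_stat = if (k >= 2L) q else 0, df = max(df, 0L),
                tau2 = tau2, i2 = i2, model = model)
}

#' Forest-plot data: per-study rows plus the pooled row
#'
#' Rows are ordered from high to low effect size; study weights are the
#' pooling weights normalised to sum to 1 (random-effects weights when the
#' pooled result is random; denominator shares for proportion indices).
#'
#' @param studies List of `study_indices` (ratio indices) or
#'   `confusion_table` (proportions), matching how `pooled` was computed.
#' @param pooled The `pooled_result` computed from the same studies.
#' @return A data.frame with columns study_id, estimate, ci_low, ci_high,
#'   weight, pooled (logical).
#' @export
forest_data <- function(studies, pooled) {
  which <- pooled$index_name
  if (which %in% c("sens", "spec")) {
    num <- vapply(studies, function(t) if (which == "sens") t$tp else t$tn, numeric(1L))
    den <- vapply(studies, function(t) {
      if (which == "sens") t$tp + t$fn else t$tn + t$fp
    }, numeric(1L))
    est <- num / den
    se <- sqrt(pmax(est * (1 - est), 0.25 / den) / den)  # floor at p=0/1
    lo <- pmax(0, est - 1.96 * se)
    hi <- pmin(1, est + 1.96 * se)
    weight <- den / sum(den)
  } else {
    y <- vapply(studies, `[[`, numeric(1L), paste0("ln_", which))
    v <- vapply(studies, `[[`, numeric(1L), paste0("var_ln_", which))
    est <- exp(y)
    lo <- exp(y - 1.96 * sqrt(v))
    hi <- exp(y + 1.96 * sqrt(v))
    w <- 1 / (v + pooled$tau2)
    weight <- w / sum(w)
  }
  ids <- vapply(studies, `[[`, character(1L), "study_id")
  out <- data.frame(study_id = ids, estimate = est, ci_low = lo, ci_high = hi,
                    weight = weight, pooled = FALSE,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$estimate), , drop = FALSE]
  pooled_row <- data.frame(study_id = "POOLED", estimate = pooled$estimate,
                           ci_low = pooled$ci_low, ci_high = pooled$ci_high,
                           weight = NA_real_, pooled = TRUE,
                           stringsAsFactors = FALSE)
  rownames(out) <- NULL
  rbind(out, pooled_row)
}
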