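#' Fit a univariate logistic regression of case status on expression
#'
#' Maximum-likelihood fit of `P(case) = expit(beta0 + beta1 * x)` by
#' iteratively reweighted least squares ([stats::glm()], binomial family).
#' Under complete separation the iteration stops at `maxit` with
#' `converged = FALSE`; the fitted probabilities (near 0/1) remain usable for
#' classification, which is all the downstream 2x2 table needs. A constant
#' covariate degenerates to `beta1 = 0` with fitted probability equal to the
#' case prevalence.
#'
#' @param expression Numeric vector of expression values.
#' @param labels Character/factor vector of "case"/"control", same length.
#' @param maxit IRLS iteration cap (default 50).
#' @return A `logistic_fit` with `beta0`, `beta1`, `converged`, `n_iter`.
#' @export
fit_logistic <- function(expression, labels, maxit = 50L) {
  labels <- as.character(labels)
  if (length(expression) != length(labels)) {
    stop("expression and labels must have equal length")
  }
  if (!all(labels %in% c("case", "control"))) {
    stop("labels must be 'case' or 'control'")
  }
  y <- as.integer(labels == "case")
  if (length(unique(y)) < 2L) {
    stop("both classes must be present to fit a diagnostic model")
  }
  if (stats::var(expression) == 0) {
    fit <- list(beta0 = stats::qlogis(mean(y)), beta1 = 0,
                converged = TRUE, n_iter = 0L)
    class(fit) <- "logistic_fit"
    return(fit)
  }
  g <- suppressWarnings(
    stats::glm(y ~ expression, family = stats::binomial(),
               control = stats::glm.control(maxit = maxit))
  )
  fit <- list(beta0 = unname(stats::coef(g)[1L]),
              beta1 = unname(stats::coef(g)[2L]),
              converged = g$converged, n_iter = g$iter)
  class(fit) <- "logistic_fit"
  fit
}

#' Fitted case probabilities from a logistic fit
#'
#' @param object A `logistic_fit`.
#' @param expression Expression values to score.
#' @param ... Unused.
#' @return Vector of probabilities.
#' @export
predict.logistic_fit <- function(object, expression, ...) {
  stats::plogis(object$beta0 + object$beta1 * expression)
}

#' Construct a 2x2 diagnostic confusion table
#'
#' @param tp,fp,fn,tn Non-negative integer cell counts.
#' @param study_id Study label.
#' @return A `confusion_table`.
#' @export
confusion_table <- function(tp, fp, fn, tn, study_id = "") {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("confusion table cells must be non-negative integers")
  }
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn),
                 study_id = study_id),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("2x2 table [%s]: TP=%d FP=%d FN=%d TN=%d\n",
              x$study_id, x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Derive the 2x2 table from a fitted classifier
#'
#' Each sample is predicted "case" iff its fitted probability is at least
#' `threshold` (ties at the threshold go to "case"); the prediction is
#' cross-tabulated against the true label. Resubstitution (scoring the
#' training samples) is the intended use: each cohort's full sample is both
#' fit and tabulated.
#'
#' @param fit A `logistic_fit` from the same samples.
#' @param expression,labels The samples to tabulate.
#' @param threshold Probability cutoff, default 0.5.
#' @param study_id Study label carried into the table.
#' @return A `confusion_table` with `tp + fn = #cases`, `fp + tn = #controls`.
#' @export
confusion_from_fit <- function(fit, expression, labels, threshold = 0.5,
                               study_id = "") {
  labels <- as.character(labels)
  p <- predict(fit, expression)
  pred_case <- p >= threshold
  is_case <- labels == "case"
  confusion_table(tp = sum(pred_case & is_case),
                  fp = sum(pred_case & !is_case),
                  fn = sum(!pred_case & is_case),
                  tn = sum(!pred_case & !is_case),
                  study_id = study_id)
}

#' Classify one gene in one study into a 2x2 table
#'
#' Convenience wrapper: fit the univariate logistic model for `gene` on the
#' study's samples and tabulate at `threshold`.
#'
#' @param expr Expression matrix (genes x samples).
#' @param phenotype Phenotype data.frame (sample, group, stage).
#' @param gene Gene identifier (must be a row of `expr`).
#' @param threshold Probability cutoff.
#' @param study_id Study label.
#' @return A `confusion_table`.
#' @export
classify_study <- function(expr, phenotype, gene, threshold = 0.5,
                           study_id = "") {
  if (!gene %in% rownames(expr)) {
    stop("gene '", gene, "' absent from study '", study_id, "'")
  }
  x <- expr[gene, phenotype$sample]
  fit <- fit_logistic(x, phenotype$group)
  confusion_from_fit(fit, x, phenotype$group, threshold = threshold,
                     study_id = study_id)
}

#' Read / write 2x2 tables as CSV (study_id, TP, FP, FN, TN)
#'
#' @param path CSV path.
#' @return A list of `confusion_table` objects.
#' @export
read_confusion <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("study_id", "TP", "FP", "FN", "TN")
  if (!all(need %in% names(df))) {
    stop("confusion CSV must have columns: ", paste(need, collapse = ", "))
  }
  lapply(seq_len(nrow(df)), function(i) {
    confusion_table(df$TP[i], df$FP[i], df$FN[i], df$TN[i],
                    study_id = df$study_id[i])
  })
}

#' @rdname read_confusion
#' @param tables List of `confusion_table` objects.
#' @export
write_confusion <- function(tables, path) {
  df <- data.frame(
    study_id = vapply(tables, `[[`, character(1L), "study_id"),
    TP = vapply(tables, `[[`, integer(1L), "tp"),
    FP = vapply(tables, `[[`, integer(1L), "fp"),
    FN = vapply(tables, `[[`, integer(1L), "fn"),
    TN = vapply(tables, `[[`, integer(1L), "tn"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
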