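#' Fit the Moses-Littenberg summary ROC model
#'
#' Transforms each study to `D = logit(sens) - logit(1 - spec) = ln DOR` and
#' `S = logit(sens) + logit(1 - spec)` (a proxy for the positivity
#' threshold), and fits `D = a + b S` by least squares — inverse-variance
#' weighted by `1/var(ln DOR)` when `weighted = TRUE` (the default), equal
#' weights otherwise. `|b| >= 1` makes the implied ROC curve non-monotone;
#' such fits are flagged `degenerate` and summarised through the symmetric
#' curve (slope forced to 0 at the fitted intercept), which is also the
#' conventional headline summary of classical DTA software. Q* is always
#' `expit(a/2)`, the sensitivity = specificity point.
#'
#' @param studies List of `study_indices` (>= 3, from continuity-corrected
#'   counts where needed).
#' @param weighted Inverse-variance weighting flag.
#' @return An `sroc_model` with fields `a`, `b`, `se_a`, `weighted`,
#'   `degenerate`, `auc`, `q_star`.
#' @export
fit_moses <- function(studies, weighted = TRUE) {
  if (length(studies) < 3L) stop("Moses regression needs at least 3 studies")
  sens <- vapply(studies, `[[`, numeric(1L), "sens")
  spec <- vapply(studies, `[[`, numeric(1L), "spec")
  sens <- clamp_logit_arg(sens)
  spec <- clamp_logit_arg(spec)
  d <- stats::qlogis(sens) - stats::qlogis(1 - spec)
  s <- stats::qlogis(sens) + stats::qlogis(1 - spec)
  if (max(s) - min(s) < 1e-12) {
    stop("all studies share one threshold proxy S; the SROC slope is undefined")
  }
  w <- if (weighted) {
    1 / vapply(studies, `[[`, numeric(1L), "var_ln_dor")
  } else {
    rep(1, length(studies))
  }
  fit <- stats::lm(d ~ s, weights = w)
  a <- unname(stats::coef(fit)[1L])
  b <- unname(stats::coef(fit)[2L])
  # WLS standard error of the intercept (0 for an exact fit)
  X <- cbind(1, s)
  sigma2 <- sum(w * stats::residuals(fit)^2) / (length(d) - 2L)
  se_a <- sqrt(sigma2 * solve(t(X) %*% (w * X))[1L, 1L])
  model <- structure(
    list(a = a, b = b, se_a = se_a, weighted = weighted,
         degenerate = abs(b) >= 1, auc = NA_real_, q_star = NA_real_),
    class = "sroc_model")
  model$q_star <- q_star(model)
  model$auc <- sroc_auc(model)
  model
}

# logit arguments of exactly 0/1 should have been prevented by continuity
# correction; clamp at expit(+-36) with a warning if they slip through
clamp_logit_arg <- function(p) {
  lo <- stats::plogis(-36)
  if (any(p <= lo | p >= 1 - lo)) {
    warning("proportion at 0 or 1 reached the SROC stage; clamping at logit +-36")
  }
  pmin(pmax(p, lo), 1 - lo)
}

#' @export
print.sroc_model <- function(x, ...) {
  cat(sprintf("Moses SROC: a = %.4f (se %.4f), b = %.4f [%s%s]\n  AUC = %.4f, Q* = %.4f\n",
              x$a, x$se_a, x$b,
              if (x$weighted) "weighted" else "unweighted",
              if (x$degenerate) ", degenerate slope" else "",
              x$auc, x$q_star))
  invisible(x)
}

#' Evaluate the SROC curve
#'
#' Inverts the D/S transform: `tpr = expit(a/(1-b) + logit(fpr)*(1+b)/(1-b))`.
#' With `symmetric = TRUE` the slope is dropped (`tpr = expit(a + logit(fpr))`).
#'
#' @param model An `sroc_model`.
#' @param fpr False-positive rate(s) in (0, 1).
#' @param symmetric Use the symmetric (slope 0) curve; defaults to the
#'   model's `degenerate` flag so improper fits fall back automatically.
#' @return True-positive rate(s) in (0, 1).
#' @export
sroc_curve <- function(model, fpr, symmetric = model$degenerate) {
  if (any(fpr <= 0 | fpr >= 1)) stop("fpr must lie strictly inside (0, 1)")
  b <- if (symmetric) 0 else model$b
  if (abs(b) >= 1) stop("slope |b| >= 1: the asymmetric curve is not monotone")
  stats::plogis(model$a / (1 - b) + stats::qlogis(fpr) * (1 + b) / (1 - b))
}

#' Area under the SROC curve
#'
#' Trapezoidal integration of [sroc_curve()] over fpr in (0, 1) on a uniform
#' grid (default step 1e-4); the open endpoints are handled by their limits
#' (tpr -> 0 and 1 for a monotone curve). `range` restricts integration to an
#' observed fpr window if desired; the AUC is then the integral over that
#' window (not rescaled).
#'
#' @param model An `sroc_model`.
#' @param step Grid step.
#' @param symmetric As in [sroc_curve()].
#' @param range fpr integration window, default c(0, 1).
#' @return The area, in [0, 1] for the full range.
#' @export
sroc_auc <- function(model, step = 1e-4, symmetric = model$degenerate,
                     range = c(0, 1)) {
  stopifnot(length(range) == 2L, range[1] >= 0, range[2] <= 1,
            range[1] < range[2])
  inner <- seq(max(range[1], step), min(range[2], 1 - step), by = step)
  x <- c(range[1], inner, range[2])
  y <- c(if (range[1] == 0) 0 else sroc_curve(model, range[1], symmetric),
         sroc_curve(model, inner, symmetric),
         if (range[2] == 1) 1 else sroc_curve(model, range[2], symmetric))
  sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}

#' Q* point of the SROC curve
#'
#' The point where sensitivity equals specificity: there `S = 0`, so
#' `D = a` and `Q* = expit(a/2)` in closed form, independent of the slope.
#'
#' @param model An `sroc_model`.
#' @return Q* in (0, 1).
#' @export
q_star <- function(model) {
  stats::plogis(model$a / 2)
}
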