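# Shared fixtures and independent oracles.

# The five published CHGA 2x2 tables (two GSE44076 control arms).
chga_tables <- function() {
  read_confusion(system.file("extdata", "chga_2x2_tables.csv",
                             package = "dxmeta"))
}

# Independent MLE oracle: zoomed dense grid search over (beta0, beta1)
# maximising the exact Bernoulli log-likelihood.
grid_logistic_mle <- function(x, y, rounds = 6L, half_width = 20, n = 41L) {
  loglik <- function(b0, b1) {
    eta <- b0 + b1 * x
    sum(y * eta - log1p(exp(eta)))
  }
  centre <- c(0, 0)
  width <- half_width
  for (r in seq_len(rounds)) {
    b0s <- seq(centre[1] - width, centre[1] + width, length.out = n)
    b1s <- seq(centre[2] - width, centre[2] + width, length.out = n)
    ll <- outer(b0s, b1s, Vectorize(loglik))
    best <- arrayInd(which.max(ll), dim(ll))
    centre <- c(b0s[best[1]], b1s[best[2]])
    width <- width * 2 / (n - 1) * 2  # keep a margin around the best cell
  }
  centre
}

# Brute-force quantile normalisation with mean-of-tied-ranks handling,
# written directly from the definition (independent of limma).
brute_quantile_normalize <- function(m) {
  ref <- rowMeans(apply(m, 2L, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    rk <- rank(m[, j], ties.method = "average")
    # interpolate the reference distribution at (possibly fractional) ranks
    out[, j] <- stats::approx(seq_along(ref), ref, xout = rk)$y
  }
  out
}

# Closed-form expected resubstitution sensitivity/specificity for the
# equal-variance, equal-prior Gaussian model: the Bayes boundary is the
# midpoint of the class means.
bayes_sens_spec <- function(shift, sd) {
  pnorm(abs(shift) / (2 * sd))
}

# Direct weighted least squares via the normal equations for D = a + b S.
normal_equations_moses <- function(d, s, w = rep(1, length(d))) {
  X <- cbind(1, s)
  XtWX <- t(X) %*% (w * X)
  XtWd <- t(X) %*% (w * d)
  as.vector(solve(XtWX, XtWd))
}

# Small deterministic expression matrix for I/O and similarity tests.
toy_matrix <- function(n_genes = 5L, n_samples = 6L, seed = 7L) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples, 8, 1), n_genes, n_samples,
              dimnames = list(paste0("G", seq_len(n_genes)),
                              paste0("S", seq_len(n_samples))))
  m
}
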