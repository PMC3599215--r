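# Independent oracles used across the suite. These deliberately avoid the
# package's fitting code paths.

# Noiseless IVIM signal, written out in plain arithmetic.
oracle_biexp <- function(b, si0, d, d_star, fp) {
  si0 * ((1 - fp) * exp(-b * d) + fp * exp(-b * d_star))
}

# Chord slope of the log-signal between two b values: the exact ADC any
# two-point monoexponential calculation must return.
oracle_chord_adc <- function(b1, b2, si0, d, d_star, fp) {
  s1 <- oracle_biexp(b1, si0, d, d_star, fp)
  s2 <- oracle_biexp(b2, si0, d, d_star, fp)
  (log(s1) - log(s2)) / (b2 - b1)
}

# Independent mono least-squares oracle: profiling out the amplitude
# analytically (a(k) = sum(s e^{-bk}) / sum(e^{-2bk})) reduces the fit to a
# 1-D maximisation solved by golden-section search.
oracle_mono_ls_adc <- function(b, s) {
  profile_gain <- function(k) {
    e <- exp(-b * k)
    sum(s * e)^2 / sum(e^2)
  }
  k0 <- -stats::lm.fit(cbind(1, b), log(s))$coefficients[[2]]
  lo <- min(0.1 * k0, -1e-4); hi <- max(5 * k0, 5e-3)
  stats::optimize(profile_gain, c(lo, hi), maximum = TRUE,
                  tol = 1e-13)$maximum
}

# Exact two-sided Wilcoxon signed-rank p-value by full enumeration of the
# 2^n sign assignments (zero differences dropped, ranks of |d|).
oracle_signed_rank_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(1)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  # two-sided: double the smaller tail, capped at 1 (matches the exact
  # distribution convention of the standard test)
  p_ge <- mean(v_all >= v_obs)
  p_le <- mean(v_all <= v_obs)
  min(1, 2 * min(p_ge, p_le))
}

# Small noiseless phantom at fixed truth, handy default for fitting tests.
median_truth <- function() {
  list(si0 = 1000, d = 0.84e-3, d_star = 11.9e-3, fp = 0.16)
}

acquisition_b <- function() c(0, 50, 100, 250, 800)

median_truth_series <- function(b = acquisition_b()) {
  tr <- median_truth()
  tibble::tibble(
    b_value = b,
    signal = oracle_biexp(b, tr$si0, tr$d, tr$d_star, tr$fp)
  )
}
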