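# Independent oracles used across test files.

# Klein-Nishina differential cross section in cos(theta) (unnormalised) and
# quadrature moments, written directly from the formula so they are
# independent of the transport engine's sampler.
kn_pdf_unnorm <- function(cost, E, mec2 = 0.51099895) {
  x <- 1 / (1 + (E / mec2) * (1 - cost))   # E'/E
  x^2 * (x + 1 / x - (1 - cost^2))
}

kn_moment <- function(E, f) {
  norm <- stats::integrate(function(c) kn_pdf_unnorm(c, E), -1, 1,
                           rel.tol = 1e-10)$value
  stats::integrate(function(c) f(c) * kn_pdf_unnorm(c, E), -1, 1,
                   rel.tol = 1e-10)$value / norm
}

# mean E'/E by quadrature
kn_mean_x <- function(E, mec2 = 0.51099895) {
  kn_moment(E, function(c) 1 / (1 + (E / mec2) * (1 - c)))
}

# uncollided point-source fluence in an absorber, per source photon
uncollided_fluence <- function(mu_lin, r) exp(-mu_lin * r) / (4 * pi * r^2)

# 3-sigma-coverage comparison: sigma is estimated from `df + 1` batches, so
# the 99.73% (Gaussian 3-sigma) interval uses the matching Student-t quantile
# rather than 3 itself.
expect_within_3sigma <- function(value, expected, sigma, extra_rel = 0, df = 9) {
  k <- stats::qt(stats::pnorm(3), df)
  tol <- k * sigma + abs(expected) * extra_rel
  expect_lt(abs(value - expected), tol + 1e-15)
}
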