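# Atomic form factor parameterisation (four-Gaussian + constant, International
# Tables for Crystallography 1992 fits), used for form-factor-weighted Thomson
# sampling of coherent scattering.  The fits are valid for
# x = sin(theta/2)/lambda <= 2 1/A; beyond that F is continued with an x^-3
# tail from the fit-range boundary (a few fits have negative constant terms
# and diverge from the physical F -> 0 limit if evaluated outside range).
.it92 <- list(
  H = list(a = c(0.493002, 0.322912, 0.140191, 0.04081), b = c(10.5109, 26.1257, 3.14236, 57.7997), c = 0.003038),
  Li = list(a = c(1.1282, 0.7508, 0.6175, 0.4653), b = c(3.9546, 1.0524, 85.3905, 168.261), c = 0.0377),
  C = list(a = c(2.31, 1.02, 1.5886, 0.865), b = c(20.8439, 10.2075, 0.5687, 51.6512), c = 0.2156),
  N = list(a = c(12.2126, 3.1322, 2.0125, 1.1663), b = c(0.0057, 9.8933, 28.9975, 0.5826), c = -11.529),
  O = list(a = c(3.0485, 2.2868, 1.5463, 0.867), b = c(13.2771, 5.7011, 0.3239, 32.9089), c = 0.2508),
  Cl = list(a = c(11.4604, 7.1964, 6.2556, 1.6455), b = c(0.0104, 1.1662, 18.5194, 47.7784), c = -9.5574),
  K = list(a = c(8.2186, 7.4398, 1.0519, 0.8659), b = c(12.7949, 0.7748, 213.187, 41.6841), c = 1.4228),
  Br = list(a = c(17.1789, 5.2358, 5.6377, 3.9851), b = c(2.1723, 16.5796, 0.2609, 41.4328), c = 2.9557),
  Cs = list(a = c(20.3892, 19.1062, 10.662, 1.4953), b = c(3.569, 0.3107, 24.3879, 213.904), c = 3.3352)
)

.ff_xfit <- 2.0  # 1/A, fit validity boundary

#' Atomic form factor F(x, Z)
#'
#' @param element element symbol.
#' @param x momentum-transfer variable sin(theta/2)/lambda in 1/Angstrom
#'   (vectorised).
#' @return form factor in electron units; F(0) = Z.
#' @keywords internal
atomic_form_factor <- function(element, x) {
  p <- .it92[[element]]
  if (is.null(p)) stop("no form factor data for element '", element, "'")
  ffit <- function(xx) {
    v <- rep(p$c, length(xx))
    for (i in 1:4) v <- v + p$a[i] * exp(-p$b[i] * xx^2)
    pmax(v, 0)
  }
  fedge <- ffit(.ff_xfit)
  out <- numeric(length(x))
  inr <- x <= .ff_xfit
  out[inr] <- ffit(x[inr])
  out[!inr] <- fedge * (.ff_xfit / x[!inr])^3
  out
}

# Cumulative integral of the squared mixture form factor over x^2, tabulated
# for inverse-CDF sampling of the coherent scattering angle.  Returns
# list(x2, cum) with cum(x2) = int_0^{x2} F2_mix d(x'^2), F2_mix = sum of
# number-fraction-weighted squared atomic form factors.
.mixture_ff_cumulative <- function(mat, e_max_MeV, n = 4096L) {
  w <- .norm_w(mat)
  nfrac <- w / .atomic_A[names(w)]
  nfrac <- nfrac / sum(nfrac)
  hc_keV_A <- 12.3984193
  x2max <- (e_max_MeV * 1e3 / hc_keV_A)^2
  # concentrate nodes at small x^2 where F^2 varies fastest
  x2 <- c(0, exp(seq(log(1e-8 * x2max + 1e-12), log(x2max), length.out = n - 1L)))
  xx <- sqrt(x2)
  f2 <- 0
  for (el in names(nfrac))
    f2 <- f2 + nfrac[[el]] * atomic_form_factor(el, xx)^2
  dx2 <- diff(x2)
  cum <- c(0, cumsum(0.5 * (f2[-1] + f2[-length(f2)]) * dx2))
  list(x2 = x2, cum = cum)
}
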