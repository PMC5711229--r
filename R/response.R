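#' Convert a fluence tally to collision kerma
#'
#' Per shell, \eqn{K = \sum_{bins} \Phi(E)\, E\, (\mu_{en}/\rho)(E)} with the
#' mass energy-absorption coefficient of `mat` evaluated at bin midpoints.
#' Per-batch kerma values are kept (as attribute `"batch"`) so that ratios of
#' kermas derived from the same tally propagate the shared-fluence
#' correlation exactly.
#'
#' @param tally a `fluence_tally` from [simulate_transport()].
#' @param mat a [material()] (or built-in name) whose `mu_en_over_rho` is used.
#' @param tables elemental coefficient tables (default: bundled data).
#' @param coefficients optional [coefficient_table()] used instead of the
#'   material mixture (toy worlds).
#' @param normalize renormalise weight fractions (default TRUE).
#' @return data.frame with columns `distance_cm`, `kerma` (MeV g^-1 per
#'   source photon), `sigma`; attribute `"batch"` holds the shells x batches
#'   matrix, attribute `"material"` the material name.
#' @export
collision_kerma <- function(tally, mat, tables = element_tables(),
                            coefficients = NULL, normalize = TRUE) {
  stopifnot(inherits(tally, "fluence_tally"))
  if (is.character(mat)) mat <- get_material(mat)
  muen <- if (!is.null(coefficients))
    lookup_coefficient(coefficients, tally$e_mid, "mu_en_over_rho")
  else
    mixture_coefficient(mat, tally$e_mid, "mu_en_over_rho", tables, normalize)
  wt <- tally$e_mid * muen
  nb <- tally$batches
  kb <- vapply(seq_len(nb),
               function(b) as.vector(tally$batch_fluence[, , b] %*% wt),
               numeric(length(tally$distances)))
  kb <- matrix(kb, nrow = length(tally$distances))
  k <- rowMeans(kb)
  s <- apply(kb, 1, stats::sd) / sqrt(nb)
  out <- data.frame(distance_cm = tally$distances, kerma = k, sigma = s)
  attr(out, "batch") <- kb
  attr(out, "material") <- if (!is.null(coefficients)) coefficients$element else mat$name
  out
}

#' Co-60 reference ratio of a film
#'
#' The denominator of the response correction R: the film-to-water
#' mass energy-absorption coefficient ratio at the Co-60 reference quality.
#' Mode `"lines"` (default) weights the ratio over the two emission lines
#' (1.17, 1.33 MeV); mode `"1.25"` evaluates it at the mean energy 1.25 MeV.
#'
#' @param film a [material()] (or built-in name).
#' @param tables elemental coefficient tables.
#' @param mode `"lines"` or `"1.25"`.
#' @param normalize renormalise the film's weight fractions (default TRUE).
#' @return dimensionless scalar.
#' @export
co60_reference_ratio <- function(film, tables = element_tables(),
                                 mode = c("lines", "1.25"), normalize = TRUE) {
  mode <- match.arg(mode)
  if (is.character(film)) film <- get_material(film)
  water <- get_material("water")
  e <- if (mode == "lines") c(1.17, 1.33) else 1.25
  r <- mixture_coefficient(film, e, "mu_en_over_rho", tables, normalize) /
    mixture_coefficient(water, e, "mu_en_over_rho", tables)
  mean(r)
}

#' Relative absorbed-dose energy response correction R versus distance
#'
#' \eqn{R(d) = [K_{film}(d) / K_{water}(d)] / ref} where the kermas come from
#' the same fluence tally and `ref` is the Co-60 reference ratio.  When both
#' kerma inputs carry per-batch values from a common tally, R is formed per
#' batch and its 1-sigma error is the standard error of the batch means
#' (capturing the film/water correlation through the shared fluence);
#' otherwise uncorrelated quadrature of relative errors is used.
#'
#' @param kerma_film,kerma_water outputs of [collision_kerma()] on the same
#'   tally (same distances).
#' @param reference_ratio the [co60_reference_ratio()] of the film (> 0).
#' @param film,source,phantom_name optional labels stored in the result.
#' @return an object of class `response_curve`: data.frame with columns
#'   `distance_cm`, `R`, `sigma` plus attributes `film`, `source`, `phantom`,
#'   `reference_note`.
#' @export
relative_response <- function(kerma_film, kerma_water, reference_ratio,
                              film = attr(kerma_film, "material"),
                              source = NULL, phantom_name = NULL) {
  if (!isTRUE(all.equal(kerma_film$distance_cm, kerma_water$distance_cm)))
    stop("kerma inputs have mismatched distances")
  if (!is.finite(reference_ratio) || reference_ratio <= 0)
    stop("reference_ratio must be > 0")
  bf <- attr(kerma_film, "batch"); bw <- attr(kerma_water, "batch")
  if (!is.null(bf) && !is.null(bw) && identical(dim(bf), dim(bw))) {
    rb <- (bf / bw) / reference_ratio
    R <- rowMeans(rb)
    s <- apply(rb, 1, stats::sd) / sqrt(ncol(rb))
  } else {
    R <- (kerma_film$kerma / kerma_water$kerma) / reference_ratio
    s <- R * sqrt((kerma_film$sigma / kerma_film$kerma)^2 +
                  (kerma_water$sigma / kerma_water$kerma)^2)
  }
  out <- data.frame(distance_cm = kerma_film$distance_cm, R = R, sigma = s)
  class(out) <- c("response_curve", "data.frame")
  attr(out, "film") <- film
  attr(out, "source") <- source
  attr(out, "phantom") <- phantom_name
  attr(out, "reference_note") <-
    "denominator: film/water mu_en/rho ratio at the Co-60 reference quality"
  out
}

#' Analytic response correction R versus photon energy
#'
#' The monoenergetic charged-particle-equilibrium form:
#' \eqn{R(E) = [(\mu_{en}/\rho)_{film}/(\mu_{en}/\rho)_{wat}]_E / ref} with
#' `ref` the same Co-60 reference ratio used for the simulated curves.
#'
#' @param film a [material()] (or built-in name).
#' @param energies photon energies, MeV.
#' @param tables elemental coefficient tables.
#' @param mode reference mode, see [co60_reference_ratio()].
#' @param normalize renormalise weight fractions (default TRUE).
#' @return data.frame with columns `energy_MeV`, `R`.
#' @export
analytic_response_curve <- function(film, energies, tables = element_tables(),
                                    mode = "lines", normalize = TRUE) {
  if (is.character(film)) film <- get_material(film)
  water <- get_material("water")
  ref <- co60_reference_ratio(film, tables, mode, normalize)
  ratio <- mixture_coefficient(film, energies, "mu_en_over_rho", tables,
                               normalize) /
    mixture_coefficient(water, energies, "mu_en_over_rho", tables)
  data.frame(energy_MeV = energies, R = ratio / ref)
}

#' Fluence-weighted mean photon energy per shell
#'
#' \eqn{\bar E = \sum \Phi E / \sum \Phi} over the tallied spectrum (above
#' the transport cutoff).  Shells with zero total fluence yield `NA` (flagged
#' with a warning), not zero.
#'
#' @param tally a `fluence_tally`.
#' @return data.frame with columns `distance_cm`, `mean_energy_MeV`, `sigma`.
#' @export
mean_energy <- function(tally) {
  stopifnot(inherits(tally, "fluence_tally"))
  nb <- tally$batches
  eb <- vapply(seq_len(nb), function(b) {
    fl <- tally$batch_fluence[, , b, drop = FALSE][, , 1]
    fl <- matrix(fl, nrow = length(tally$distances))
    tot <- rowSums(fl)
    ifelse(tot > 0, as.vector(fl %*% tally$e_mid) / tot, NA_real_)
  }, numeric(length(tally$distances)))
  eb <- matrix(eb, nrow = length(tally$distances))
  m <- rowMeans(eb)
  s <- apply(eb, 1, stats::sd) / sqrt(nb)
  if (anyNA(m))
    warning("shell(s) with zero fluence: mean energy reported as NA")
  data.frame(distance_cm = tally$distances, mean_energy_MeV = m, sigma = s)
}

#' Ratio of two response curves (phantom-material influence)
#'
#' Elementwise \eqn{R_a/R_b} for curves of the same film and source computed
#' in different phantom materials, with uncorrelated error propagation
#' (the curves come from independent simulations).
#'
#' @param curve_a,curve_b `response_curve` objects on identical distances.
#' @return data.frame with columns `distance_cm`, `ratio`, `sigma`.
#' @export
phantom_ratio <- function(curve_a, curve_b) {
  if (!isTRUE(all.equal(curve_a$distance_cm, curve_b$distance_cm)))
    stop("response curves have mismatched distances")
  fa <- attr(curve_a, "film"); fb <- attr(curve_b, "film")
  if (!is.null(fa) && !is.null(fb) && !identical(fa, fb))
    stop("response curves are for different films: ", fa, " vs ", fb)
  sa <- attr(curve_a, "source"); sb <- attr(curve_b, "source")
  if (!is.null(sa) && !is.null(sb) && !identical(sa, sb))
    stop("response curves are for different sources: ", sa, " vs ", sb)
  ratio <- curve_a$R / curve_b$R
  sig <- ratio * sqrt((curve_a$sigma / curve_a$R)^2 +
                      (curve_b$sigma / curve_b$R)^2)
  data.frame(distance_cm = curve_a$distance_cm, ratio = ratio, sigma = sig)
}
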