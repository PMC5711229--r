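#' Pure-absorber toy world with closed-form fluence
#'
#' A flat, energy-independent absorber (every interaction photoelectric) and
#' a single emission line: the fluence at radius r is exactly the uncollided
#' \eqn{\Phi(r) = e^{-\mu\rho r} / (4\pi r^2)} and the collision kerma is
#' \eqn{E (\mu_{en}/\rho) \Phi(r)}.  Fixture objects carry their oracle
#' functions so tests are self-describing.
#'
#' @param mu total mass attenuation coefficient, cm^2/g.
#' @param density medium density, g/cm^3.
#' @param line emission energy, MeV.
#' @param mu_en mass energy-absorption coefficient, cm^2/g (default `mu`).
#' @return list with `coefficients` ([make_toy_table()]), `material`,
#'   `phantom`, `source`, and oracle functions `fluence(r)` and `kerma(r)`
#'   plus the parameter list `params`.
#' @export
pure_absorber_world <- function(mu = 1, density = 1, line = 1, mu_en = mu) {
  if (mu < 0 || density <= 0 || line <= 0) stop("mu >= 0, density > 0, line > 0 required")
  tabmu <- max(mu, 1e-12)  # engine needs mu > 0; 1e-12 is vacuum in practice
  tab <- make_toy_table(tabmu, min(mu_en, tabmu), 1)
  matl <- material("toy-absorber", c(H = 1), density)
  list(coefficients = tab,
       material = matl,
       phantom = phantom_spec(matl, radius = 20, height = 40),
       source = source_spectrum("toy-line", line, 1, "fixture single line"),
       fluence = function(r) exp(-mu * density * r) / (4 * pi * r^2),
       kerma = function(r) line * mu_en * exp(-mu * density * r) / (4 * pi * r^2),
       params = list(mu = mu, density = density, line = line, mu_en = mu_en))
}

#' Water-twin film fixture
#'
#' A "film" whose active composition equals water: its response correction R
#' must be identically 1 at every distance, for every source and phantom.
#'
#' @return a [material()] named `"water-twin"`.
#' @export
water_twin_film <- function() {
  material("water-twin", c(H = 0.112, O = 0.888), 1.0)
}

#' Write a deterministic regression bundle
#'
#' Runs two small fixed-seed simulations (a pure-absorber toy world and a
#' short Co-60 water run) and writes their tallies plus the water-twin
#' response curve as CSV files.  The same seed always produces a
#' byte-identical bundle.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @param histories histories per run (default 20000; sub-second).
#' @return invisibly, the vector of files written.
#' @export
regression_pack <- function(dir, seed, histories = 20000) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  # 1. pure absorber vs oracle
  w <- pure_absorber_world(mu = 0.5, density = 1, line = 1)
  sp <- shell_tally_spec(distances = c(1, 2, 4), bin_width = 0.05)
  t1 <- simulate_transport(w$source, w$phantom, sp, histories = histories,
                           seed = seed, coefficients = w$coefficients)
  f1 <- file.path(dir, "absorber_tally.csv")
  write_tally_csv(t1, f1)
  oracle <- data.frame(shell_cm = sp$distances,
                       expected_fluence = w$fluence(sp$distances),
                       tallied_fluence = rowSums(t1$fluence),
                       sigma = sqrt(rowSums(t1$sigma^2)))
  f1b <- file.path(dir, "absorber_oracle.csv")
  utils::write.csv(oracle, f1b, row.names = FALSE)
  # 2. water-twin response in a short co60 run
  t2 <- simulate_transport("co60", phantom_spec("water"),
                           shell_tally_spec(distances = c(1, 2, 4)),
                           histories = histories, seed = seed + 1L)
  kw <- collision_kerma(t2, "water")
  kf <- collision_kerma(t2, water_twin_film())
  rr <- relative_response(kf, kw, co60_reference_ratio(water_twin_film()),
                          source = "co60", phantom_name = "water")
  f2 <- file.path(dir, "water_twin_response.csv")
  utils::write.csv(as.data.frame(rr), f2, row.names = FALSE)
  invisible(c(f1, paste0(f1, ".json"), f1b, f2))
}
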