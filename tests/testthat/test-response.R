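test_that("collision kerma of simple tallies has the closed-form value", {
  # hand-built single-bin tally: Phi = 2 cm^-2 at E_mid = 3 MeV, mu_en = 0.5
  tl <- structure(list(distances = 1, e_mid = 3, e_edges = c(2.9995, 3.0005),
                       fluence = matrix(2, 1, 1), sigma = matrix(0, 1, 1),
                       batch_fluence = array(2, c(1, 1, 2)), histories = 1,
                       batches = 2L, seed = 1L, source = "toy",
                       phantom = "toy"),
                  class = "fluence_tally")
  tab <- make_toy_table(1, 0.5, 1)
  k <- collision_kerma(tl, material("m", c(H = 1), 1), coefficients = tab)
  expect_equal(k$kerma, 3.0)
  expect_equal(k$sigma, 0)
  # zero fluence gives exactly zero kerma
  tl$fluence[] <- 0; tl$batch_fluence[] <- 0
  expect_equal(collision_kerma(tl, material("m", c(H = 1), 1),
                               coefficients = tab)$kerma, 0)
})

test_that("simulated kerma in a pure absorber matches the analytic expression", {
  w <- pure_absorber_world(mu = 0.5, density = 1, line = 1, mu_en = 0.3)
  tl <- simulate_transport(w$source, w$phantom,
                           shell_tally_spec(distances = 2, bin_width = 0.05),
                           histories = 4e5, seed = 271,
                           coefficients = w$coefficients)
  k <- collision_kerma(tl, w$material, coefficients = w$coefficients)
  # bin-midpoint energy (1.0 tallied in bin [1.0, 1.05) -> mid 1.025) scales
  # the oracle kerma accordingly
  mid <- tl$e_mid[which.max(tl$fluence[1, ])]
  expect_within_3sigma(k$kerma, w$kerma(2) * mid / w$params$line, k$sigma,
                       extra_rel = 1e-9)
})

test_that("the Co-60 reference ratio behaves as a ratio should", {
  expect_equal(co60_reference_ratio(water_twin_film()), 1)
  expect_equal(co60_reference_ratio("ebt"), 0.983, tolerance = 0.01 / 0.983)
  # paper convention for the high-Z emulsion: unnormalised printed fractions
  expect_equal(co60_reference_ratio("xrqa", normalize = FALSE), 0.95,
               tolerance = 0.01 / 0.95)
  # line-weighted and 1.25 MeV modes agree closely in the Compton plateau
  expect_equal(co60_reference_ratio("xrt", mode = "lines"),
               co60_reference_ratio("xrt", mode = "1.25"), tolerance = 2e-3)
})

test_that("R is exactly 1 for a water-composition film and scale-invariant", {
  tl <- simulate_transport("co60", phantom_spec("water"),
                           shell_tally_spec(distances = c(1, 5, 10)),
                           histories = 5e4, seed = 77)
  kw <- collision_kerma(tl, "water")
  kt <- collision_kerma(tl, water_twin_film())
  rr <- relative_response(kt, kw, co60_reference_ratio(water_twin_film()))
  expect_equal(rr$R, rep(1, 3), tolerance = 1e-12)
  # rescaling all fluences by a constant leaves R unchanged
  tl2 <- tl
  tl2$fluence <- tl$fluence * 7; tl2$batch_fluence <- tl$batch_fluence * 7
  kx <- collision_kerma(tl2, "xrt"); kw2 <- collision_kerma(tl2, "water")
  r1 <- relative_response(collision_kerma(tl, "xrt"), kw,
                          co60_reference_ratio("xrt"))
  r2 <- relative_response(kx, kw2, co60_reference_ratio("xrt"))
  expect_equal(r1$R, r2$R, tolerance = 1e-12)
})

test_that("mismatched kerma inputs are rejected", {
  k1 <- data.frame(distance_cm = c(1, 2), kerma = c(1, 1), sigma = c(0, 0))
  k2 <- data.frame(distance_cm = c(1, 3), kerma = c(1, 1), sigma = c(0, 0))
  expect_error(relative_response(k1, k2, 1), "mismatched")
  expect_error(relative_response(k1, k1, -1), "reference_ratio")
})

test_that("analytic R(E) is 1 at the reference energy and tracks the emulsion Z", {
  water_curve <- analytic_response_curve(water_twin_film(), c(0.02, 0.1, 1.0))
  expect_equal(water_curve$R, rep(1, 3))
  ref_e <- analytic_response_curve("xrt", 1.25, mode = "1.25")
  expect_equal(ref_e$R, 1)
  a <- analytic_response_curve("xrqa", c(0.03, 1.0))
  expect_gt(a$R[1], 10 * a$R[2])  # photoelectric region boost
})

test_that("mean energy of an unscattered line tally equals the line energy", {
  w <- pure_absorber_world(mu = 0.2, density = 1, line = 0.8)
  tl <- simulate_transport(w$source, w$phantom,
                           shell_tally_spec(distances = 2, bin_width = 0.001),
                           histories = 5e4, seed = 55,
                           coefficients = w$coefficients)
  me <- mean_energy(tl)
  # the line sits on the top bin edge, so it is tallied in [0.799, 0.800)
  expect_equal(me$mean_energy_MeV, 0.7995, tolerance = 1e-3)
  expect_equal(me$sigma, 0)
})

test_that("zero-fluence shells give NA mean energy with a warning", {
  tl <- structure(list(distances = c(1, 2), e_mid = c(0.5, 0.6),
                       fluence = matrix(c(1, 0, 1, 0), 2, 2),
                       sigma = matrix(0, 2, 2),
                       batch_fluence = array(c(1, 0, 1, 0), c(2, 2, 2)),
                       histories = 1, batches = 2L, seed = 1L,
                       source = "toy", phantom = "toy"),
                  class = "fluence_tally")
  expect_warning(me <- mean_energy(tl), "zero fluence")
  expect_equal(me$mean_energy_MeV[1], 0.55)
  expect_true(is.na(me$mean_energy_MeV[2]))
})

test_that("phantom ratio is unity for identical curves and validates labels", {
  rr <- structure(data.frame(distance_cm = c(1, 5), R = c(1.2, 1.4),
                             sigma = c(0.01, 0.02)),
                  class = c("response_curve", "data.frame"))
  attr(rr, "film") <- "xrt"; attr(rr, "source") <- "co60"
  pr <- phantom_ratio(rr, rr)
  expect_equal(pr$ratio, c(1, 1))
  other <- rr; attr(other, "film") <- "hs"
  expect_error(phantom_ratio(rr, other), "different films")
  shifted <- rr; shifted$distance_cm <- c(1, 6)
  expect_error(phantom_ratio(rr, shifted), "mismatched")
})
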