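test_that("free-path sampling follows the exponential law", {
  set.seed(7)
  s <- sample_free_path(2, 1e5)
  expect_lt(abs(mean(s) - 0.5), 3 * 0.5 / sqrt(1e5))
  p <- mean(s > 0.5)
  expect_lt(abs(p - exp(-1)), 3 * sqrt(exp(-1) * (1 - exp(-1)) / 1e5))
  expect_error(sample_free_path(0), "mu_linear")
})

test_that("Klein-Nishina sampler matches kinematics and the quadrature oracle", {
  set.seed(11)
  for (E in c(0.05, 0.3, 1.25)) {
    sm <- sample_compton(E, 2e4)
    # kinematic identity to machine precision for every sample
    pred <- E / (1 + (E / 0.51099895) * (1 - sm[, "cos_theta"]))
    expect_equal(sm[, "energy_MeV"], pred, tolerance = 1e-12)
    # mean E'/E against numerical integration of the distribution
    mx <- mean(sm[, "energy_MeV"]) / E
    sdx <- sd(sm[, "energy_MeV"] / E) / sqrt(nrow(sm))
    expect_lt(abs(mx - kn_mean_x(E)), 3 * sdx)
  }
  # Thomson limit: symmetric angular distribution, mean cos(theta) -> 0
  set.seed(12)
  sm <- sample_compton(1e-4, 2e4)
  expect_lt(abs(mean(sm[, "cos_theta"])), 3 * sd(sm[, "cos_theta"]) / sqrt(2e4))
})

test_that("tallied fluence matches the closed-form oracle in a pure absorber", {
  w <- pure_absorber_world(mu = 0.5, density = 1, line = 1)
  tl <- simulate_transport(w$source, w$phantom,
                           shell_tally_spec(distances = c(1, 2, 4),
                                            bin_width = 0.05),
                           histories = 4e5, seed = 314,
                           coefficients = w$coefficients)
  got <- rowSums(tl$fluence)
  sig <- sqrt(rowSums(tl$sigma^2))
  for (i in 1:3)
    expect_within_3sigma(got[i], w$fluence(c(1, 2, 4))[i], sig[i])
  # all fluence sits in the emission-line bin (no scatter in a pure absorber)
  line_bin <- which.max(colSums(tl$fluence))
  expect_equal(sum(tl$fluence[, -line_bin]), 0)
})

test_that("vacuum limit recovers the inverse-square law", {
  w <- pure_absorber_world(mu = 1e-12, density = 1, line = 1)
  tl <- simulate_transport(w$source, w$phantom,
                           shell_tally_spec(distances = 1, bin_width = 0.1),
                           histories = 2e5, seed = 99,
                           coefficients = w$coefficients)
  expect_within_3sigma(sum(tl$fluence), 1 / (4 * pi),
                       sqrt(sum(tl$sigma^2)))
})

test_that("identical seeds give bit-identical tallies; different seeds do not", {
  ph <- phantom_spec("water")
  sp <- shell_tally_spec(distances = c(1, 3))
  a <- simulate_transport("cs137", ph, sp, histories = 2e4, seed = 5)
  b <- simulate_transport("cs137", ph, sp, histories = 2e4, seed = 5)
  expect_identical(a$batch_fluence, b$batch_fluence)
  d <- simulate_transport("cs137", ph, sp, histories = 2e4, seed = 6)
  expect_false(identical(a$batch_fluence, d$batch_fluence))
})

test_that("no tallied energy exceeds the maximum emission energy", {
  tl <- simulate_transport("cs137", phantom_spec("water"),
                           shell_tally_spec(distances = c(1, 5)),
                           histories = 5e4, seed = 21)
  above <- tl$e_mid > 0.662
  expect_equal(sum(tl$fluence[, above]), 0)
  expect_true(all(tl$fluence >= 0))
})

test_that("pair production feeds the annihilation bin in a toy pair world", {
  # toy world where every interaction above threshold is pair production
  tab <- coefficient_table("pairworld", c(1e-4, 100),
                           photoelectric = c(0, 0), incoherent = c(0, 0),
                           coherent = c(0, 0), pair = c(0.2, 0.2),
                           mu_en_over_rho = c(0.1, 0.1))
  matl <- material("pairtoy", c(H = 1), 1)
  src <- source_spectrum("hard", 1.4, 1)
  tl <- simulate_transport(src, phantom_spec(matl),
                           shell_tally_spec(distances = c(2, 5),
                                            bin_width = 0.01),
                           histories = 5e4, seed = 8,
                           coefficients = tab)
  ann <- which(tl$e_edges[-1] > 0.511 & tl$e_edges[-length(tl$e_edges)] <= 0.511)
  expect_gt(sum(tl$fluence[, ann]), 0)
  # only the primary line and the 0.511 MeV bin are populated
  pop <- colSums(tl$fluence) > 0
  expect_lte(sum(pop), 2L)
})

test_that("batch merging: two half-size runs agree with one full run within errors", {
  w <- pure_absorber_world(mu = 0.3, density = 1, line = 1)
  sp <- shell_tally_spec(distances = 2, bin_width = 0.1)
  a <- simulate_transport(w$source, w$phantom, sp, histories = 1e5, seed = 31,
                          coefficients = w$coefficients)
  b <- simulate_transport(w$source, w$phantom, sp, histories = 1e5, seed = 32,
                          coefficients = w$coefficients)
  full <- simulate_transport(w$source, w$phantom, sp, histories = 2e5, seed = 33,
                             coefficients = w$coefficients)
  merged <- (sum(a$fluence) + sum(b$fluence)) / 2
  sig <- sqrt((sum(a$sigma^2) + sum(b$sigma^2)) / 4 + sum(full$sigma^2))
  expect_lt(abs(merged - sum(full$fluence)), 3 * sig)
})

test_that("transport input validation catches misconfiguration", {
  expect_error(simulate_transport("cs137", phantom_spec("water"),
                                  shell_tally_spec(distances = 25),
                                  histories = 100, seed = 1),
               "inside the phantom")
  expect_error(simulate_transport("cs137", phantom_spec("water"),
                                  shell_tally_spec(distances = 1),
                                  histories = 5, seed = 1, batches = 10),
               "histories")
  expect_error(phantom_spec("water", radius = -1), "radius")
})
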