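test_that("scenario validation enforces the documented invariants", {
  expect_error(simulation_scenario(), "seed")
  expect_error(simulation_scenario(seed = 1, free_half_life = -2))
  expect_error(simulation_scenario(seed = 1, bound_species = data.frame(
    name = "a", kind = "Cys", branching = 0.5, half_life = Inf)),
    "sum to 1")
  bad_init <- c(free = 0.9, `Cys-adduct` = 0.5)
  expect_error(simulation_scenario(seed = 1,
                                   initial_fractions = bad_init),
               "sum to <= 1")
})

test_that("two-compartment kinetics match analytic special cases", {
  # no conversion: pure exponential with the stated degradation half-life
  sc <- small_scenario(seed = 1, times = c(0, 9, 18))
  sc$free_half_life <- 9
  sc$formation_half_time <- Inf
  ab <- simulate_species_kinetics(sc)
  free <- ab[ab$species == "free", ]
  expect_equal(free$abundance, c(1, 0.5, 0.25), tolerance = 1e-12)

  # no degradation anywhere: total abundance is conserved
  sc2 <- small_scenario(seed = 1, times = seq(0, 60, 10))
  sc2$free_half_life <- Inf
  sc2$formation_half_time <- 3
  ab2 <- simulate_species_kinetics(sc2)
  totals <- tapply(ab2$abundance, ab2$time_min, sum)
  expect_equal(as.vector(totals), rep(1, length(totals)), tolerance = 1e-12)
})

test_that("closed form agrees with a numerical ODE integrator", {
  skip_if_not_installed("deSolve")
  sc <- small_scenario(seed = 1, times = seq(0, 30, 2.5))
  sc$free_half_life <- 1.9
  sc$formation_half_time <- 3.1
  sc$bound_species$half_life <- c(40, 15)  # both pools degradable
  ab <- simulate_species_kinetics(sc)

  kd <- log(2) / sc$free_half_life
  kc <- log(2) / sc$formation_half_time
  ki <- log(2) / sc$bound_species$half_life
  br <- sc$bound_species$branching
  rhs <- function(t, y, p) {
    list(c(-(kd + kc) * y[1],
           br[1] * kc * y[1] - ki[1] * y[2],
           br[2] * kc * y[1] - ki[2] * y[3]))
  }
  num <- deSolve::ode(c(1, 0, 0), sc$times, rhs, NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  for (j in 1:3) {
    sp <- c("free", sc$bound_species$name)[j]
    expect_equal(ab$abundance[ab$species == sp], unname(num[, j + 1]),
                 tolerance = 1e-6)
  }
})

test_that("identical (scenario, seed) give identical peak lists", {
  a <- emit_peaklists(small_scenario(seed = 99, noise_cv = 0.1,
                                     decoy_density = 3,
                                     mz_jitter_ppm = 3))
  b <- emit_peaklists(small_scenario(seed = 99, noise_cv = 0.1,
                                     decoy_density = 3,
                                     mz_jitter_ppm = 3))
  expect_identical(a, b)
  c <- emit_peaklists(small_scenario(seed = 100, noise_cv = 0.1,
                                     decoy_density = 3,
                                     mz_jitter_ppm = 3))
  expect_false(identical(a, c))
})

test_that("decoy-only runs integrate to zero for every species", {
  sc <- small_scenario(seed = 55, decoy_density = 8)
  sc$initial_fractions[] <- 0
  runs <- emit_peaklists(sc)
  species <- attr(runs, "species")
  expect_true(all(vapply(runs, function(r) nrow(r$peaks) > 0, TRUE)))
  tc <- timecourse(runs, species, charges = 3, tolerance = 20)
  expect_true(all(tc$area == 0))
})

test_that("noise-free round trip recovers generating half-life end to end", {
  sc <- small_scenario(seed = 77, times = c(0, 1, 2.5, 5, 10, 15, 20))
  runs <- emit_peaklists(sc)
  species <- attr(runs, "species")
  tc <- timecourse(runs, species[species$label == "free", ],
                   charges = sc$charges_free, tolerance = 20)
  f <- fit_one_phase_decay(tc$time_min, tc$area)
  # free pool disappears with rate k_deg + k_conv
  expected <- log(2) / (log(2) / sc$free_half_life +
                          log(2) / sc$formation_half_time)
  expect_equal(f$half_life, expected, tolerance = 0.01)
})

test_that("activity tables reproduce the IC50 trajectory", {
  traj <- data.frame(time_min = c(0, 9, 18, 27),
                     ic50 = 100 * 2^(c(0, 9, 18, 27) / 9))
  tab <- simulate_activity_tables(traj, noise_cv = 0, seed = 3)
  for (i in seq_len(nrow(traj))) {
    d <- tab[tab$time_min == traj$time_min[i], ]
    f <- fit_ic50(d$conc_nM, d$response_pct)
    expect_equal(f$ic50, traj$ic50[i], tolerance = 1e-3)
  }
  # doubling IC50 every 9 min -> activity half-life 9 min
  fits <- lapply(split(tab, tab$time_min), function(d)
    fit_ic50(d$conc_nM, d$response_pct))
  f0 <- fits[["0"]]
  act <- vapply(fits, function(f)
    remaining_activity(f, f0)$remaining_pct, 0)
  hl <- activity_half_life(traj$time_min, act)
  expect_equal(hl$half_life, 9, tolerance = 0.02)
  # determinism under the seed
  tab2 <- simulate_activity_tables(traj, noise_cv = 0.05, seed = 3)
  tab3 <- simulate_activity_tables(traj, noise_cv = 0.05, seed = 3)
  expect_identical(tab2, tab3)
})
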