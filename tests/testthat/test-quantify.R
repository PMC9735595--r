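test_that("isotope patterns behave like the underlying distributions", {
  # tiny molecule: monoisotopic peak dominates
  g <- isotope_pattern(peptide_formula("G"), charge = 1)
  expect_equal(g$offset[attr(g, "most_intense")], 0L)
  expect_equal(attr(g, "retained"), 1, tolerance = 1e-3)
  expect_false(is.unsorted(g$offset, strictly = TRUE))

  # carbon-rich species: the A+1 peak overtakes the monoisotopic one
  # (A1/A0 ~ nC * 0.0107/0.9893 crosses 1 near nC = 92.5)
  expect_equal(isotope_pattern("C92")$offset[
    attr(isotope_pattern("C92"), "most_intense")], 0L)
  expect_equal(isotope_pattern("C95")$offset[
    attr(isotope_pattern("C95"), "most_intense")], 1L)

  # m/z ladder spacing is 1.00336/z from the monoisotopic m/z
  f <- formula_subtract(formula_add(peptide_formula(ALB_21_41),
                                    peptide_formula("VPCVS")), c(H = 2))
  for (z in c(3, 4)) {
    p <- isotope_pattern(f, charge = z)
    expect_equal(p$mz, mz(formula_mass(f), z) + p$offset * 1.00336 / z,
                 tolerance = 1e-9)
  }
  expect_error(isotope_pattern(f, charge = 0), "positive integer")
})

test_that("pattern of A+B equals the convolution of the patterns", {
  set.seed(5)
  for (i in 1:8) {
    fa <- peptide_formula(random_sequence(sample(2:8, 1)))
    fb <- peptide_formula(random_sequence(sample(2:8, 1)))
    pa <- isotope_pattern(fa, prune_below = 0)
    pb <- isotope_pattern(fb, prune_below = 0)
    pab <- isotope_pattern(formula_add(fa, fb), prune_below = 0)
    # direct product oracle: convolve the two abundance vectors
    n <- max(pab$offset) + 1L
    conv <- numeric(n + max(pb$offset))
    for (j in seq_along(pa$abundance)) {
      idx <- pa$offset[j] + pb$offset + 1L
      conv[idx] <- conv[idx] + pa$abundance[j] * pb$abundance
    }
    expect_equal(pab$abundance, conv[pab$offset + 1L], tolerance = 1e-6)
  }
})

test_that("most intense isotopologue of the crosslink agrees with a direct oracle", {
  f <- formula_subtract(formula_add(peptide_formula(ALB_21_41),
                                    peptide_formula("VPCVS")), c(H = 2))
  p <- isotope_pattern(f, charge = 3, prune_below = 0)
  # brute-force polynomial expansion over per-element binomial terms,
  # computed with dbinom/convolve rather than the package's routines
  dists <- list(C = c(0.9893, 0.0107), H = c(0.999885, 0.000115),
                N = c(0.99636, 0.00364), O = c(0.99757, 0.00038, 0.00205),
                S = c(0.9499, 0.0075, 0.0425, 0, 0.0001))
  acc <- 1
  for (el in names(f)) {
    d <- dists[[el]]
    for (k in seq_len(f[[el]])) {
      acc <- convolve(acc, rev(d), type = "open")
    }
  }
  acc <- acc / sum(acc)
  expect_equal(which.max(acc) - 1L, p$offset[attr(p, "most_intense")])
  expect_equal(p$abundance[1:8], acc[1:8], tolerance = 1e-8)
})

test_that("XIC construction sums within-window peaks per scan", {
  target <- 500
  peaks <- data.frame(
    rt_min = c(1, 1, 2, 3),
    mz = c(500.0000, 500.0050, 500.0001, 500.0500),
    intensity = c(10, 5, 7, 100))
  tr <- build_xic(peaks, target, tolerance = 20)
  # 500.0050 is 10 ppm away (inside); 500.05 is 100 ppm away (outside)
  expect_equal(tr$intensity, c(15, 7, 0))
  expect_equal(tr$rt_min, c(1, 2, 3))

  # empty input -> empty trace, not an error
  expect_equal(nrow(build_xic(peaks[0, ], target, 20)), 0L)

  # pointwise monotone non-decreasing in tolerance
  set.seed(6)
  rnd <- data.frame(rt_min = rep(1:5, each = 8),
                    mz = 500 * (1 + runif(40, -1e-4, 1e-4)),
                    intensity = runif(40, 0, 100))
  tols <- c(1, 5, 20, 50, 100)
  traces <- lapply(tols, function(tol) build_xic(rnd, target, tol)$intensity)
  for (i in seq_len(length(tols) - 1)) {
    expect_true(all(traces[[i + 1]] >= traces[[i]]))
  }
})

test_that("trapezoidal integration matches analytic areas", {
  rect <- data.frame(rt_min = seq(0, 2, 0.1), intensity = 10)
  expect_equal(integrate_area(rect), 20)
  zero <- data.frame(rt_min = seq(0, 2, 0.1), intensity = 0)
  expect_equal(integrate_area(zero), 0)
  # triangular peak height h, base b -> h*b/2
  tfine <- seq(0, 1, 1e-3)
  tri <- data.frame(rt_min = tfine,
                    intensity = 4 * pmax(0, 0.5 - abs(tfine - 0.5)))
  expect_equal(integrate_area(tri), 2 * 1 / 2, tolerance = 1e-5)
  # additive over disjoint windows; zero-intensity scans are no-ops
  expect_equal(integrate_area(tri, c(0, 0.5)) +
                 integrate_area(tri, c(0.5, 1)),
               integrate_area(tri), tolerance = 1e-9)
  padded <- rbind(data.frame(rt_min = -1, intensity = 0), tri,
                  data.frame(rt_min = 2, intensity = 0))
  expect_equal(integrate_area(padded), integrate_area(tri))
  expect_error(integrate_area(tri, c(1, 0)), "inverted")
})

test_that("timecourse recovers generator areas and rejects duplicates", {
  sc <- small_scenario(seed = 101)
  runs <- emit_peaklists(sc)
  manifest <- attr(runs, "manifest")
  species <- attr(runs, "species")
  tc_free <- timecourse(runs, species[species$label == "free", ],
                        charges = sc$charges_free, tolerance = 20)
  truth <- manifest[manifest$species == "free", ]
  got <- tc_free$area[match(truth$time_min, tc_free$time_min)]
  nz <- truth$true_area > 0
  expect_equal(got[nz], truth$true_area[nz], tolerance = 0.01)

  # a species absent from the runs integrates to zero everywhere
  ghost <- data.frame(label = "ghost", class = "free", mass = 1500,
                      formula = "C70H100N20O20", stringsAsFactors = FALSE)
  tc_ghost <- timecourse(runs, ghost, charges = 2, tolerance = 20)
  expect_true(all(tc_ghost$area == 0))

  dup <- c(runs, runs[1])
  expect_error(timecourse(dup, species, charges = 2), "duplicate")
})
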