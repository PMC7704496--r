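test_that("ligand-depletion isotherm matches the mass-balance oracle and its limits", {
  # no ligand, nothing bound
  expect_identical(fraction_bound(1e-3, 0, 2, 1e-9), 0)
  # tight-binding limit: half the protein consumed by N*c_B sites
  expect_equal(fraction_bound(1e-3, 0.25e-3, 2, 1e-15), 0.5, tolerance = 1e-9)
  # symmetric micromolar case against the independent bisection oracle
  p <- fraction_bound(1e-6, 1e-6, 1, 1e-6)
  expect_equal(p, bound_fraction_oracle(1e-6, 1e-6, 1, 1e-6),
               tolerance = 1e-10)
  # golden-ratio closed form for this symmetric case: (3 - sqrt(5)) / 2
  expect_equal(p, (3 - sqrt(5)) / 2, tolerance = 1e-12)

  # K_D -> 0 limit reproduces the tight-binding expression on a grid
  for (c_A in c(1e-6, 1e-4, 1e-3)) {
    for (ratio in c(0.1, 0.25, 0.5, 0.8)) {
      for (N in c(1, 2, 3)) {
        expect_equal(fraction_bound(c_A, ratio * c_A, N, 1e-12 * c_A),
                     fraction_bound_tight(c_A, ratio * c_A, N),
                     tolerance = 1e-6)
      }
    }
  }
})

test_that("isotherm agrees with the bisection oracle over random valid parameters", {
  set.seed(101)
  for (i in 1:1000) {
    c_A <- 10^runif(1, -9, -2)
    c_B <- 10^runif(1, -9, -2)
    N <- runif(1, 0.5, 4)
    K_D <- 10^runif(1, -12, -3)
    p <- fraction_bound(c_A, c_B, N, K_D)
    p_oracle <- bound_fraction_oracle(c_A, c_B, N, K_D)
    expect_true(p >= 0 && p <= 1)
    expect_lt(abs(p - p_oracle) / max(p_oracle, .Machine$double.xmin), 1e-10)
  }
})

test_that("bound fraction is monotone in ligand, affinity and site count", {
  set.seed(202)
  for (i in 1:200) {
    c_A <- 10^runif(1, -9, -3)
    N <- runif(1, 0.5, 4)
    K_D <- 10^runif(1, -11, -4)
    cb <- sort(10^runif(5, -9, -3))
    p <- fraction_bound(c_A, cb, N, K_D)
    expect_true(all(diff(p) >= -1e-15)) # non-decreasing in c_B
    kds <- sort(10^runif(4, -11, -4))
    pk <- vapply(kds, function(k) fraction_bound(c_A, cb[3], N, k), 1)
    expect_true(all(diff(pk) <= 1e-15)) # non-increasing in K_D
    ns <- sort(runif(4, 0.5, 4))
    pn <- vapply(ns, function(n) fraction_bound(c_A, cb[3], n, K_D), 1)
    expect_true(all(diff(pn) >= -1e-15)) # non-decreasing in N
  }
})

test_that("tight-binding curve is the stoichiometric kink with breakpoint 1/N", {
  expect_equal(fraction_bound_tight(1e-3, 0.25e-3, N = 2), 0.5)
  expect_equal(fraction_bound_tight(1e-3, 0.5e-3, N = 2), 1)
  expect_equal(fraction_bound_tight(1e-3, 0.625e-3, N = 2), 1)
  expect_identical(saturation_ratio(2), 0.5)
  expect_identical(saturation_ratio(1), 1)
})

test_that("fast-exchange shift is an affine interpolation between endpoints", {
  expect_identical(observed_shift_fast(0, 10.35, 10.536), 10.35)
  expect_identical(observed_shift_fast(1, 10.35, 10.536), 10.536)
  expect_equal(observed_shift_fast(0.5, 10.35, 10.536), 10.443)
  set.seed(3)
  for (i in 1:50) {
    p <- runif(1)
    d0 <- runif(1, 5, 11)
    d1 <- d0 + runif(1, -1, 1)
    obs <- observed_shift_fast(p, d0, d1)
    expect_true(obs >= min(d0, d1) - 1e-12 && obs <= max(d0, d1) + 1e-12)
    # normalized change equals the bound fraction
    if (d1 != d0) expect_equal((obs - d0) / (d1 - d0), p)
  }
  expect_error(observed_shift_fast(1.2, 10, 11),
               class = "nmrbind_invalid_input")
})

test_that("slow-exchange peak intensities are complementary populations", {
  expect_equal(slow_exchange_intensities(0), data.frame(free = 1, bound = 0))
  expect_equal(slow_exchange_intensities(0.3),
               data.frame(free = 0.7, bound = 0.3))
  # at a 1:2 oligonucleotide:protein ratio under tight binding, free signals
  # are completely abolished
  p_sat <- fraction_bound_tight(1e-3, 0.5e-3, N = 2)
  expect_equal(slow_exchange_intensities(p_sat)$free, 0)
  p <- runif(20)
  w <- slow_exchange_intensities(p)
  expect_equal(w$free + w$bound, rep(1, 20))
  expect_error(slow_exchange_intensities(-0.1),
               class = "nmrbind_invalid_input")
})

test_that("fluorescence quench model is bounded, monotone and mixes linearly", {
  expect_equal(fluorescence_quench(5e-9, 0, 2, 4e-9, F0 = 100, q = 0.8), 100)
  # saturating ligand drives intensity to F0 * (1 - q)
  expect_equal(fluorescence_quench(5e-9, 1e-3, 2, 4e-9, F0 = 100, q = 0.8),
               20, tolerance = 1e-4)
  # linear mixing at half saturation: F0 = 1, q = 0.6, P = 0.5 -> 0.7
  expect_equal(1 * (1 - 0.6 * 0.5), 0.7)
  cb <- seq(0, 2e-8, length.out = 30)
  y <- fluorescence_quench(5e-9, cb, 2, 4e-9, F0 = 1, q = 0.6)
  expect_true(all(diff(y) <= 1e-15))
  expect_true(all(y >= 1 * (1 - 0.6) - 1e-12 & y <= 1 + 1e-12))
})

test_that("linewidth scaling follows the cube root of the mass ratio", {
  expect_identical(linewidth_mass_scaling(1), 1)
  expect_equal(linewidth_mass_scaling(2), 2^(1 / 3))
  expect_equal(round(linewidth_mass_scaling(2), 2), 1.26)
  expect_identical(linewidth_mass_scaling(8), 2)
  expect_error(linewidth_mass_scaling(0), class = "nmrbind_invalid_input")
  expect_error(linewidth_mass_scaling(-1), class = "nmrbind_invalid_input")
})

test_that("invalid concentrations and system invariants are rejected", {
  expect_error(fraction_bound(-1e-3, 1e-4, 2, 1e-9),
               class = "nmrbind_invalid_input")
  expect_error(fraction_bound(1e-3, -1e-4, 2, 1e-9),
               class = "nmrbind_invalid_input")
  expect_error(fraction_bound(1e-3, NaN, 2, 1e-9),
               class = "nmrbind_invalid_input")
  expect_error(fraction_bound(1e-3, 1e-4, 2, -1e-9),
               class = "nmrbind_invalid_input")
  expect_error(binding_system(c_A = 0, c_B = 1e-4),
               class = "nmrbind_invalid_input")
  expect_error(binding_system(1e-3, 1e-4, N = 2.5, integer_N = TRUE),
               class = "nmrbind_invalid_input")
  sys <- binding_system(1e-3, 0.25e-3, N = 2, K_D = 4e-9)
  expect_equal(fraction_bound(sys), 0.5, tolerance = 1e-5)
  expect_equal(fraction_bound_tight(sys), 0.5)
})
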