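test_that("all generators are byte-deterministic under a fixed seed", {
  s1 <- simulate_hsqc_titration(simulation_spec(seed = 7))
  s2 <- simulate_hsqc_titration(simulation_spec(seed = 7))
  expect_identical(s1, s2)
  f1 <- simulate_fluorescence_titration(5e-9, K_D = 4e-9, seed = 7)
  f2 <- simulate_fluorescence_titration(5e-9, K_D = 4e-9, seed = 7)
  expect_identical(f1, f2)
  e1 <- simulate_epitope_profile(seed = 7)
  e2 <- simulate_epitope_profile(seed = 7)
  expect_identical(e1, e2)
  s3 <- simulate_hsqc_titration(simulation_spec(seed = 8))
  expect_false(identical(s1$peaks, s3$peaks))
})

test_that("noiseless HSQC titration lies on the tight-binding kink curve", {
  spec <- simulation_spec(c_A = 1e-3, N = 2, K_D = 4e-9,
                          noise = list(H = 0, N = 0), seed = 21)
  sim <- simulate_hsqc_titration(spec)
  series <- extract_shift_series(sim)
  expected <- fraction_bound_tight(1e-3, spec$ratios * 1e-3, 2)
  # 4-decimal shift rounding leaves per-point wobble well below 1%
  expect_equal(series$points$normalized_shift, expected, tolerance = 0.01)
  # shifts constant beyond the saturation ratio of 0.5
  beyond <- series$points$normalized_shift[spec$ratios >= 0.5]
  expect_equal(beyond, rep(1, length(beyond)), tolerance = 0.01)
})

test_that("exchange regimes produce the right peak bookkeeping", {
  spec <- simulation_spec(seed = 5)
  sim <- simulate_hsqc_titration(spec)
  slow_res <- which(spec$exchange_regime == "slow")
  dis_res <- which(spec$exchange_regime == "disappear")
  p <- sim$truth$p_bound
  mid <- which(p >= 0.2 & p <= 0.8)[1]
  pk_mid <- sim$peaks[[mid]]
  # intermediate-exchange residues vanish mid-titration ...
  expect_false(any(dis_res %in% pk_mid$residue_index))
  # ... and are present in the free reference spectrum
  expect_true(all(dis_res %in% sim$peaks[[1]]$residue_index))
  # slow-exchange residues carry two states whose intensities sum to 1
  rows <- pk_mid[pk_mid$residue_index == slow_res[1] & pk_mid$atom == "H", ]
  expect_setequal(rows$state, c("free", "bound"))
  expect_equal(sum(rows$intensity), 1, tolerance = 1e-5)
  # prolines never appear
  expect_false(any(spec$prolines %in%
                     unlist(lapply(sim$peaks, `[[`, "residue_index"))))
  # at the endpoint the free peaks of slow-exchange residues are abolished
  pk_end <- sim$peaks[[length(sim$peaks)]]
  end_rows <- pk_end[pk_end$residue_index %in% slow_res, ]
  expect_true(all(end_rows$state == "bound"))
})

test_that("simulated HSQC data round-trip through the stoichiometry fit", {
  spec <- simulation_spec(c_A = 1e-3, N = 2, K_D = 4e-9,
                          noise = list(H = 0, N = 0), seed = 13)
  series <- extract_shift_series(simulate_hsqc_titration(spec))
  fit <- fit_stoichiometry_nmr(series, K_D_fixed = 4e-9)
  expect_equal(coef(fit)[["N"]], 2, tolerance = 0.02)
  expect_equal(coef(fit)[["amplitude"]], 1, tolerance = 0.02)
})

test_that("fluorescence generator honours its quench model and schedule", {
  # zero quench amplitude: flat curve at F0
  flat <- simulate_fluorescence_titration(5e-9, K_D = 4e-9, F0 = 10, q = 0,
                                          noise_rel = 0, seed = 1)
  expect_equal(flat$curve$points$intensity,
               rep(10, nrow(flat$curve$points)), tolerance = 1e-6)
  # noiseless midpoint: the analytic inversion of the quadratic isotherm
  # puts half saturation at c_B = (0.5 c_A + K_D) / N, where the quench
  # model predicts F0 (1 - q/2)
  c_A <- 5e-9; K_D <- 4e-9; N <- 2
  sim <- simulate_fluorescence_titration(c_A, N, K_D, F0 = 1, q = 0.8,
                                         noise_rel = 0, seed = 1)
  cb_mid <- (0.5 * c_A + K_D) / N
  expect_equal(fraction_bound(c_A, cb_mid, N, K_D), 0.5, tolerance = 1e-9)
  expect_equal(fluorescence_quench(c_A, cb_mid, N, K_D, F0 = 1, q = 0.8),
               1 - 0.8 / 2, tolerance = 1e-9)
  # and the generated curve sits exactly on that quench model
  expect_equal(sim$curve$points$intensity,
               1 - 0.8 * sim$truth$p_bound, tolerance = 1e-5)
  # final point reaches >= 95% saturation by construction
  expect_gte(max(sim$truth$p_bound), 0.95)
  # short schedules warn, as does an unresolvable concentration regime
  expect_warning(
    simulate_fluorescence_titration(c_A, N, K_D, noise_rel = 0,
                                    schedule = c(0, 1e-10, 2e-10), seed = 1),
    "saturation")
  expect_warning(
    simulate_fluorescence_titration(1e-6, N, K_D = 1e-9, noise_rel = 0,
                                    seed = 1),
    "100")
})

test_that("epitope fixture plants exactly the configured signal", {
  # near-zero background, single epitope residue: that residue dominates
  sim <- simulate_epitope_profile(n_residues = 10, epitope_residues = 4,
                                  prolines = integer(0),
                                  background_sd = 1e-3,
                                  disappear_frac = 0, seed = 2)
  prof <- perturbation_profile(sim$free, sim$bound)
  expect_identical(prof$residue_index[which.max(prof$delta_comb)], 4L)
  expect_gt(prof$delta_comb[4], 3 * 1e-3)
  expect_true(all(prof$delta_comb[-4] < prof$delta_comb[4] / 2))
  expect_error(simulate_epitope_profile(epitope_residues = integer(0)),
               class = "nmrbind_invalid_input")
})
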