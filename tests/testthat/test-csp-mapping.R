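test_that("combined shift is the weighted Euclidean norm over available atoms", {
  expect_identical(combined_shift(c(H = 0, N = 0)), 0)
  expect_equal(combined_shift(c(H = 0.10)), 0.10)
  # backbone H and N with the conventional nitrogen weight
  expect_equal(combined_shift(c(H = 0.10, N = 0.50)),
               sqrt(0.01 + 0.0049))
  expect_equal(round(combined_shift(c(H = 0.10, N = 0.50)), 4), 0.1221)
  # side-chain indole atoms are first-class contributors
  expect_equal(combined_shift(c(HE1 = 0.2, NE1 = 1.0)),
               sqrt(0.04 + 0.0196))
  expect_error(combined_shift(c(H = 0.1, XX = 0.2)),
               class = "nmrbind_config_error")
  expect_error(combined_shift(numeric(0)), class = "nmrbind_invalid_input")
})

test_that("perturbation profile assigns measured/disappeared/not-evaluable status", {
  free <- data.frame(residue_index = c(1, 1, 2, 2, 3, 3, 5),
                     residue_code = c("A", "A", "W", "W", "K", "K", "G"),
                     atom = c("H", "N", "H", "N", "H", "N", "H"),
                     shift_ppm = c(8.0, 120, 9.1, 128, 7.5, 115, 8.4))
  bound <- free[free$residue_index != 3, ]
  bound$shift_ppm <- bound$shift_ppm + c(0.05, 0.2, 0, 0, 0.1)
  prof <- perturbation_profile(free, bound, residues = 1:5)
  expect_equal(prof$status,
               c("measured", "measured", "disappeared", "not-evaluable",
                 "measured"))
  expect_equal(prof$delta_comb[1], sqrt(0.05^2 + (0.14 * 0.2)^2),
               tolerance = 1e-10)
  expect_equal(prof$delta_comb[2], 0)
  expect_true(is.na(prof$delta_comb[3]))

  # identical endpoint lists: every measured residue has zero perturbation
  prof0 <- perturbation_profile(free, free)
  expect_true(all(prof0$delta_comb[prof0$status == "measured"] == 0))

  dup <- rbind(free, free[1, ])
  expect_error(perturbation_profile(dup, bound),
               class = "nmrbind_invalid_input")
})

test_that("sigma0 is the population standard deviation of measured residues", {
  prof <- structure(data.frame(residue_index = 1:4, residue_code = "X",
                               delta_comb = c(0, 0, 0, 0.4),
                               status = "measured"),
                    class = c("perturbation_profile", "data.frame"))
  expect_equal(sigma0(prof), sqrt(0.03))
  expect_equal(round(sigma0(prof), 4), 0.1732)
  prof$delta_comb <- rep(0.2, 4)
  expect_identical(sigma0(prof), 0)
  expect_error(sigma0(prof[1:2, ]), class = "nmrbind_invalid_input")
})

test_that("threshold classification follows the sigma0 / 2 sigma0 rule", {
  prof <- structure(
    data.frame(residue_index = 1:6, residue_code = "X",
               delta_comb = c(0, 0.09, 0.10, 0.19, 0.20, NA),
               status = c(rep("measured", 5), "disappeared")),
    class = c("perturbation_profile", "data.frame"))
  m <- classify_residues(prof, s0 = 0.10)
  expect_equal(as.character(m$class),
               c("none", "none", "moderate", "moderate", "high",
                 "disappeared-high"))
  # the boundary delta_comb == 2 sigma0 counts as high
  expect_equal(as.character(m$class[5]), "high")
  # disappeared residues get the imputed value 2 sigma0
  expect_equal(m$delta_comb[6], 0.20)
  expect_equal(attr(m, "sigma0"), 0.10)
})

test_that("classification is invariant under uniform scaling of the shifts", {
  sim <- simulate_epitope_profile(seed = 33)
  prof1 <- perturbation_profile(sim$free, sim$bound)
  k <- 3.7
  scaled_bound <- sim$bound
  i <- match(paste(scaled_bound$residue_index, scaled_bound$atom),
             paste(sim$free$residue_index, sim$free$atom))
  scaled_bound$shift_ppm <- sim$free$shift_ppm[i] +
    k * (sim$bound$shift_ppm - sim$free$shift_ppm[i])
  prof2 <- perturbation_profile(sim$free, scaled_bound)
  meas <- prof1$status == "measured"
  expect_equal(prof2$delta_comb[meas], k * prof1$delta_comb[meas],
               tolerance = 1e-10)
  expect_equal(sigma0(prof2), k * sigma0(prof1), tolerance = 1e-10)
  m1 <- classify_residues(prof1)
  m2 <- classify_residues(prof2)
  expect_identical(as.character(m1$class), as.character(m2$class))
})

test_that("consensus rule: high somewhere, at least moderate everywhere else", {
  m1 <- make_class_map(c("high", "high", "moderate", "none",
                         "disappeared-high", "moderate"), "dT7")
  m2 <- make_class_map(c("moderate", "none", "moderate", "high",
                         "moderate", "moderate"), "rU7")
  cons <- consensus_epitope(list(m1, m2))
  # high + moderate -> in; high + none -> out; moderate + moderate -> out;
  # none + high -> out; disappeared-high counts as high
  expect_equal(cons$in_consensus, c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE))
  # symmetric in map order
  cons_rev <- consensus_epitope(list(m2, m1))
  expect_equal(cons_rev$in_consensus, cons$in_consensus)
  # consensus is a subset of the union of the high sets
  high_union <- cons$residue_index[
    m1$class[order(m1$residue_index)] %in% c("high", "disappeared-high") |
    m2$class[order(m2$residue_index)] %in% c("high", "disappeared-high")]
  expect_true(all(cons$residue_index[cons$in_consensus] %in% high_union))

  expect_error(consensus_epitope(list(m1)), class = "nmrbind_invalid_input")
  m3 <- make_class_map(c("high", "none"), "short")
  expect_error(consensus_epitope(list(m1, m3)),
               class = "nmrbind_invalid_input")
})

test_that("planted epitopes are recovered with high sensitivity and low FPR", {
  sens <- fpr <- numeric(20)
  for (s in seq_len(20)) {
    sim <- simulate_epitope_profile(seed = 1000 + s)
    m <- classify_residues(perturbation_profile(sim$free, sim$bound))
    detected <- m$residue_index[
      m$class %in% c("moderate", "high", "disappeared-high")]
    truth <- sim$truth$epitope_residues
    background <- setdiff(m$residue_index[m$class != "not-evaluable"], truth)
    sens[s] <- mean(truth %in% detected)
    fpr[s] <- mean(background %in% detected)
  }
  expect_gte(mean(sens), 0.9)
  expect_lte(mean(fpr), 0.1)
  # residues flagged to disappear come back as disappeared-high downstream
  sim <- simulate_epitope_profile(seed = 4)
  m <- classify_residues(perturbation_profile(sim$free, sim$bound))
  dis <- m$residue_index[m$class == "disappeared-high"]
  expect_setequal(dis, sim$truth$disappeared)
})
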