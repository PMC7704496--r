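# Seeded generators for titration datasets with the statistical structure the
# analysis assumes: fast-exchange shift trajectories on the ligand-depletion
# isotherm, slow-exchange two-peak intensity transfer, disappearing peaks
# (intermediate exchange), and quadratic-isotherm fluorescence quench curves.

#' Default planted epitope for synthetic cold-shock-protein data
#'
#' Residue indices (on a 66-residue OB-fold cold shock protein) used as the
#' default ground-truth binding epitope by the generators: the end of
#' beta-strand 1, the beta1-beta2 loop and start of strand 2 (including the
#' RNP1 motif region), the aromatic pair closing strand 3, the long
#' beta3-beta4 loop, the beta4-beta5 loop and two strand-5 positions.
#'
#' @return integer vector of residue indices.
#' @export
default_epitope_residues <- function() {
  c(7L, 9L, 10L, 12L, 13L, 14L, 16L, 28L, 29L, 30L, 33L, 37L, 38L, 39L,
    41L, 53L, 55L, 63L, 65L)
}

.make_codes <- function(n_residues, prolines) {
  aa <- c("A", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "Q", "R",
          "S", "T", "V", "W", "Y")
  codes <- sample(aa, n_residues, replace = TRUE)
  codes[prolines] <- "P"
  codes
}

#' Specification for a synthetic HSQC titration
#'
#' Collects everything that determines a simulated 2D HSQC titration of a
#' protein with an oligonucleotide: concentrations, ground-truth binding
#' parameters, the per-residue exchange regime, noise levels and the seed.
#'
#' Defaults mirror a canonical cold-shock-protein NMR titration: 1 mM
#' protein, five equal ligand increments to a molar ratio of 0.625, two
#' sites per heptanucleotide, a nanomolar dissociation constant, and the
#' epitope of [default_epitope_residues()] with residue 57 as a proline.
#'
#' @param c_A total protein concentration (mol/L).
#' @param ratios ligand-to-protein molar ratios, non-negative increasing,
#'   starting at 0 (the free reference spectrum).
#' @param N ground-truth sites per oligonucleotide.
#' @param K_D ground-truth per-site dissociation constant (mol/L).
#' @param n_residues number of residues in the protein.
#' @param epitope_residues indices of perturbed (binding-site) residues.
#' @param prolines residue indices without backbone amides.
#' @param exchange_regime named character vector (`"fast"`, `"slow"`,
#'   `"disappear"`) per residue index, or `NULL` for the default: fast
#'   everywhere, with a few slow- and intermediate-exchange epitope
#'   residues.
#' @param noise list with per-atom Gaussian shift noise in ppm
#'   (`H`, `N`).
#' @param disappear_window bound-fraction window inside which an
#'   intermediate-exchange peak is broadened beyond detection and dropped.
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return a `simulation_spec` list.
#' @seealso [simulate_hsqc_titration()]
#' @export
simulation_spec <- function(c_A = 1e-3,
                            ratios = seq(0, 0.625, by = 0.125),
                            N = 2, K_D = 4e-9,
                            n_residues = 66,
                            epitope_residues = default_epitope_residues(),
                            prolines = 57L,
                            exchange_regime = NULL,
                            noise = list(H = 0.002, N = 0.02),
                            disappear_window = c(0.2, 0.8),
                            seed = 1L) {
  .check_pos(c_A, "c_A")
  .check_nonneg(ratios, "ratios")
  if (is.unsorted(ratios, strictly = TRUE))
    stop_invalid("'ratios' must be strictly increasing")
  if (ratios[1] != 0)
    stop_invalid("'ratios' must start at 0 (free reference spectrum)")
  .check_pos(N, "N")
  .check_nonneg(K_D, "K_D")
  if (any(epitope_residues < 1 | epitope_residues > n_residues))
    stop_invalid("'epitope_residues' out of range")
  if (any(epitope_residues %in% prolines))
    stop_invalid("a proline cannot be an amide-observed epitope residue")
  if (is.null(exchange_regime)) {
    exchange_regime <- rep("fast", n_residues)
    ne <- length(epitope_residues)
    exchange_regime[epitope_residues[seq(1, ne, by = 5)]] <- "slow"
    if (ne >= 2)
      exchange_regime[epitope_residues[seq(2, ne, by = 5)]] <- "disappear"
  }
  if (length(exchange_regime) != n_residues ||
      !all(exchange_regime %in% c("fast", "slow", "disappear")))
    stop_invalid("'exchange_regime' must give fast/slow/disappear per residue")
  structure(list(c_A = c_A, ratios = ratios, N = N, K_D = K_D,
                 n_residues = n_residues,
                 epitope_residues = as.integer(epitope_residues),
                 prolines = as.integer(prolines),
                 exchange_regime = exchange_regime,
                 noise = noise, disappear_window = disappear_window,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate a 2D HSQC titration as per-point peak lists
#'
#' Generates one peak list per titration point. Fast-exchange residues move
#' along the population-weighted average of their free and bound positions
#' ([observed_shift_fast()]) with the bound fraction from the
#' ligand-depletion isotherm; slow-exchange residues show two peaks (states
#' `free`/`bound`) whose intensities follow [slow_exchange_intensities()];
#' intermediate-exchange residues vanish while the bound fraction is inside
#' `disappear_window`. Epitope residues get large endpoint shift changes,
#' non-epitope residues small mean-zero background changes; prolines carry
#' no amide peak. Shifts are reported to 4 decimal places (about the
#' digital resolution of the experiment), intensities to 6 significant
#' digits.
#'
#' @param spec a [simulation_spec()].
#' @return a list of class `hsqc_titration`: `peaks` (named list of
#'   peak-list data.frames, one per ratio, with columns `residue_index`,
#'   `residue_code`, `atom`, `shift_ppm`, `intensity`, `state`), `spec`,
#'   and `truth` (endpoint shift changes, regimes, bound fractions).
#' @examples
#' sim <- simulate_hsqc_titration(simulation_spec(seed = 42))
#' names(sim$peaks)
#' @export
simulate_hsqc_titration <- function(spec) {
  if (!inherits(spec, "simulation_spec"))
    stop_invalid("'spec' must be a simulation_spec")
  set.seed(spec$seed)
  n <- spec$n_residues
  codes <- .make_codes(n, spec$prolines)
  observed <- setdiff(seq_len(n), spec$prolines)
  free_H <- stats::runif(n, 6.5, 10.5)
  free_N <- stats::runif(n, 103, 132)
  dH <- stats::rnorm(n, 0, 0.01)
  dN <- stats::rnorm(n, 0, 0.05)
  ne <- length(spec$epitope_residues)
  dH[spec$epitope_residues] <- sample(c(-1, 1), ne, TRUE) *
    stats::runif(ne, 0.05, 0.30)
  dN[spec$epitope_residues] <- sample(c(-1, 1), ne, TRUE) *
    stats::runif(ne, 0.30, 1.50)

  p_all <- fraction_bound(spec$c_A, spec$ratios * spec$c_A, spec$N, spec$K_D)
  peaks <- vector("list", length(spec$ratios))
  names(peaks) <- sprintf("ratio_%g", spec$ratios)
  for (k in seq_along(spec$ratios)) {
    p <- p_all[k]
    rows <- list()
    for (i in observed) {
      reg <- spec$exchange_regime[i]
      for (atom in c("H", "N")) {
        f0 <- if (atom == "H") free_H[i] else free_N[i]
        de <- if (atom == "H") dH[i] else dN[i]
        sdev <- spec$noise[[atom]]
        if (reg == "fast") {
          sh <- observed_shift_fast(p, f0, f0 + de) + stats::rnorm(1, 0, sdev)
          rows[[length(rows) + 1L]] <-
            data.frame(residue_index = i, residue_code = codes[i],
                       atom = atom, shift_ppm = sh, intensity = 1,
                       state = "obs")
        } else if (reg == "slow") {
          w <- slow_exchange_intensities(p)
          if (w$free > 1e-3)
            rows[[length(rows) + 1L]] <-
              data.frame(residue_index = i, residue_code = codes[i],
                         atom = atom,
                         shift_ppm = f0 + stats::rnorm(1, 0, sdev),
                         intensity = w$free, state = "free")
          if (w$bound > 1e-3)
            rows[[length(rows) + 1L]] <-
              data.frame(residue_index = i, residue_code = codes[i],
                         atom = atom,
                         shift_ppm = f0 + de + stats::rnorm(1, 0, sdev),
                         intensity = w$bound, state = "bound")
        } else { # disappear: intermediate exchange broadening
          if (p >= spec$disappear_window[1] && p <= spec$disappear_window[2])
            next
          pos <- if (p < spec$disappear_window[1]) f0 else f0 + de
          rows[[length(rows) + 1L]] <-
            data.frame(residue_index = i, residue_code = codes[i],
                       atom = atom,
                       shift_ppm = pos + stats::rnorm(1, 0, sdev),
                       intensity = 1, state = "obs")
        }
      }
    }
    pk <- do.call(rbind, rows)
    pk$shift_ppm <- round(pk$shift_ppm, 4)
    pk$intensity <- signif(pk$intensity, 6)
    peaks[[k]] <- pk
  }
  structure(list(peaks = peaks, spec = spec,
                 truth = list(N = spec$N, K_D = spec$K_D,
                              delta_end = data.frame(
                                residue_index = seq_len(n),
                                residue_code = codes, dH = dH, dN = dN),
                              regime = spec$exchange_regime,
                              p_bound = p_all)),
            class = "hsqc_titration")
}

#' Residue-averaged normalized shift series from a simulated HSQC titration
#'
#' Collapses the fast-exchange trajectories of an [simulate_hsqc_titration()]
#' result into one normalized titration curve: for every residue/atom that
#' shows a single peak at every titration point and moves by at least
#' `min_delta` (weighted ppm) overall, the shift change is normalized by
#' its value at the final titration point, then averaged over atoms and
#' residues. This is the observable used for stoichiometry fitting.
#'
#' @param sim an `hsqc_titration`.
#' @param min_delta minimal weighted endpoint shift change (ppm) for a
#'   trajectory to count as clearly observable.
#' @param weights atom weights used for the `min_delta` criterion.
#' @return a [normalized_shift_series()] (ratios as in the simulation).
#' @export
extract_shift_series <- function(sim, min_delta = 0.02,
                                 weights = shift_weights()) {
  if (!inherits(sim, "hsqc_titration"))
    stop_invalid("'sim' must be an hsqc_titration")
  ratios <- sim$spec$ratios
  np <- length(ratios)
  key <- function(pk) paste(pk$residue_index, pk$atom)
  # residue/atom trajectories with exactly one observed peak everywhere
  tab <- table(unlist(lapply(sim$peaks, function(pk)
    unique(key(pk[pk$state == "obs", ])))))
  full <- names(tab)[tab == np]
  if (length(full) == 0L)
    stop_invalid("no complete fast-exchange trajectories in this simulation")
  traj <- vapply(full, function(k) {
    vapply(sim$peaks, function(pk) {
      pk <- pk[pk$state == "obs", ]
      pk$shift_ppm[match(k, key(pk))]
    }, numeric(1))
  }, numeric(np))
  d_end <- traj[np, ] - traj[1, ]
  atom <- sub("^\\S+ ", "", colnames(traj))
  w <- weights[atom]
  keep <- is.finite(d_end) & abs(w * d_end) >= min_delta
  if (!any(keep))
    stop_invalid("no trajectory exceeds min_delta = %g ppm", min_delta)
  rel <- sweep(sweep(traj[, keep, drop = FALSE], 2, traj[1, keep], "-"),
               2, d_end[keep], "/")
  normalized_shift_series(ratio = ratios,
                          normalized_shift = rowMeans(rel),
                          c_A = sim$spec$c_A, averaged = TRUE)
}

#' Simulate a normalized shift titration series directly
#'
#' Draws a residue-averaged normalized shift series from the binding model:
#' `amplitude * P_AB(c_A, ratio * c_A, N, K_D)` plus Gaussian noise on the
#' normalized shifts. This is the compact generator used for
#' stoichiometry-recovery studies; [simulate_hsqc_titration()] +
#' [extract_shift_series()] produce the same observable from full peak
#' lists.
#'
#' @param c_A total protein concentration (mol/L); 1 mM by default, the
#'   concentration regime where nanomolar complexes titrate
#'   stoichiometrically.
#' @param ratios molar ratios `c_B/c_A`.
#' @param N ground-truth sites per oligonucleotide.
#' @param K_D ground-truth dissociation constant (mol/L).
#' @param amplitude normalization amplitude (1 when the final point is a
#'   true saturation endpoint).
#' @param noise_sd Gaussian noise on the normalized shifts.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return a [normalized_shift_series()] with a `truth` attribute.
#' @export
simulate_shift_series <- function(c_A = 1e-3,
                                  ratios = seq(0, 0.625, by = 0.125),
                                  N = 2, K_D = 4e-9, amplitude = 1,
                                  noise_sd = 0.03, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  .check_nonneg(noise_sd, "noise_sd")
  p <- fraction_bound(c_A, ratios * c_A, N, K_D)
  y <- amplitude * p + stats::rnorm(length(p), 0, noise_sd)
  out <- normalized_shift_series(ratio = ratios, normalized_shift = y,
                                 c_A = c_A, averaged = TRUE)
  attr(out, "truth") <- list(N = N, K_D = K_D, amplitude = amplitude,
                             noise_sd = noise_sd)
  out
}

#' Ligand schedule reaching a target saturation
#'
#' Log-spaced total ligand concentrations (plus a zero reference point)
#' spanning bound fractions from 5% to `saturation` under the
#' ligand-depletion isotherm, by analytic inversion of the isotherm for
#' `c_B` at given bound fraction.
#'
#' @inheritParams fraction_bound
#' @param n_points number of non-zero points.
#' @param saturation target final bound fraction.
#' @return vector of total ligand concentrations (mol/L), starting at 0.
#' @export
fluorescence_schedule <- function(c_A, N = 2, K_D = 0, n_points = 12,
                                  saturation = 0.99) {
  .check_pos(c_A, "c_A")
  .check_nonneg(K_D, "K_D")
  .check_prob(saturation, "saturation")
  cb_at <- function(p) (p * c_A + K_D * p / (1 - p)) / N
  c(0, exp(seq(log(cb_at(0.05)), log(cb_at(saturation)),
               length.out = n_points)))
}

#' Simulate a tryptophan fluorescence quench titration
#'
#' Intensities from [fluorescence_quench()] with multiplicative Gaussian
#' noise, on a schedule extending to (by default) 99% saturation. A warning
#' is issued when `c_A > 100 * K_D` (the titration then only constrains a
#' lower bound on the affinity) and when the schedule stops short of 95%
#' saturation.
#'
#' @inheritParams fluorescence_quench
#' @param noise_rel relative (multiplicative) Gaussian noise level.
#' @param schedule optional explicit `c_B` schedule (mol/L); defaults to
#'   [fluorescence_schedule()].
#' @param n_points points in the default schedule.
#' @param temperature_label free-text annotation stored in the curve.
#' @param seed integer seed, or `NULL`.
#' @return list with `curve` (a [fluorescence_curve()]) and `truth`.
#' @examples
#' sim <- simulate_fluorescence_titration(c_A = 5e-9, K_D = 4e-9, seed = 1)
#' sim$curve
#' @export
simulate_fluorescence_titration <- function(c_A, N = 2, K_D, F0 = 1,
                                            q = 0.8, noise_rel = 0.01,
                                            schedule = NULL, n_points = 12,
                                            temperature_label = NA_character_,
                                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  .check_pos(c_A, "c_A")
  .check_pos(K_D, "K_D")
  .check_nonneg(noise_rel, "noise_rel")
  if (c_A > 100 * K_D)
    warning("c_A exceeds 100 * K_D: the curve is stoichiometric and K_D ",
            "is poorly resolvable at this protein concentration")
  if (is.null(schedule))
    schedule <- fluorescence_schedule(c_A, N, K_D, n_points)
  p <- fraction_bound(c_A, schedule, N, K_D)
  if (max(p) < 0.95)
    warning(sprintf("schedule reaches only %.0f%% saturation", 100 * max(p)))
  mu <- fluorescence_quench(c_A, schedule, N, K_D, F0, q)
  y <- mu * (1 + stats::rnorm(length(mu), 0, noise_rel))
  y <- signif(pmax(y, .Machine$double.eps), 6)
  curve <- fluorescence_curve(schedule, y, c_A, temperature_label)
  list(curve = curve,
       truth = list(N = N, K_D = K_D, F0 = F0, q = q,
                    noise_rel = noise_rel, p_bound = p))
}

#' Simulate paired free/bound peak lists with a planted epitope
#'
#' Fixture generator for chemical-shift-perturbation mapping: every
#' non-proline residue gets backbone H and N peaks in the free list; in the
#' bound list, background residues are displaced by mean-zero Gaussian
#' shifts (standard deviation `background_sd` in weighted ppm), planted
#' epitope residues by effects drawn uniformly from
#' `effect_range * background_sd`, and a subset of the epitope disappears
#' (no bound peak), emulating intermediate exchange.
#'
#' Nitrogen shift changes are drawn on the 15N scale (divided by the
#' nitrogen weight) so that both nuclei contribute comparably to the
#' weighted norm.
#'
#' @param n_residues protein length.
#' @param epitope_residues planted binding-site residues.
#' @param prolines residues without amide peaks.
#' @param background_sd background perturbation scale (weighted ppm).
#' @param effect_range epitope effect size range, in multiples of
#'   `background_sd`.
#' @param disappear_frac fraction of the epitope whose bound peaks vanish.
#' @param weights atom weights (the nitrogen weight sets the 15N scale).
#' @param seed integer seed, or `NULL`.
#' @return list with `free` and `bound` peak-list data.frames and `truth`
#'   (`epitope_residues`, `disappeared`, `background_sd`).
#' @export
simulate_epitope_profile <- function(n_residues = 66,
                                     epitope_residues = default_epitope_residues(),
                                     prolines = 57L,
                                     background_sd = 0.01,
                                     effect_range = c(3, 8),
                                     disappear_frac = 0.25,
                                     weights = shift_weights(),
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(epitope_residues) == 0L)
    stop_invalid("'epitope_residues' must be non-empty")
  .check_pos(background_sd, "background_sd")
  codes <- .make_codes(n_residues, prolines)
  observed <- setdiff(seq_len(n_residues), prolines)
  wN <- weights[["N"]]
  free <- do.call(rbind, lapply(observed, function(i)
    data.frame(residue_index = i, residue_code = codes[i],
               atom = c("H", "N"),
               shift_ppm = c(stats::runif(1, 6.5, 10.5),
                             stats::runif(1, 103, 132)))))
  dH <- stats::rnorm(n_residues, 0, background_sd)
  dN <- stats::rnorm(n_residues, 0, background_sd / wN)
  ne <- length(epitope_residues)
  dH[epitope_residues] <- sample(c(-1, 1), ne, TRUE) * background_sd *
    stats::runif(ne, effect_range[1], effect_range[2])
  dN[epitope_residues] <- sample(c(-1, 1), ne, TRUE) * background_sd / wN *
    stats::runif(ne, effect_range[1], effect_range[2])
  n_dis <- round(disappear_frac * ne)
  disappeared <- if (n_dis > 0)
    sort(sample(epitope_residues, n_dis)) else integer(0)
  keep <- setdiff(observed, disappeared)
  bound <- free[free$residue_index %in% keep, ]
  d <- ifelse(bound$atom == "H", dH[bound$residue_index],
              dN[bound$residue_index])
  bound$shift_ppm <- bound$shift_ppm + d
  free$shift_ppm <- round(free$shift_ppm, 4)
  bound$shift_ppm <- round(bound$shift_ppm, 4)
  rownames(free) <- rownames(bound) <- NULL
  list(free = free, bound = bound,
       truth = list(epitope_residues = sort(epitope_residues),
                    disappeared = disappeared,
                    background_sd = background_sd))
}
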