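#' Binding system: total concentrations, site count and dissociation constant
#'
#' Bundles the quantities that determine a protein--oligonucleotide binding
#' equilibrium with `N` independent, identical protein-binding sites per
#' oligonucleotide: the total protein concentration `c_A`, the total
#' oligonucleotide concentration `c_B`, the site count `N` and the per-site
#' dissociation constant `K_D`. All concentrations are in mol/L.
#'
#' `N` may be any positive real (fitted stoichiometries are rarely exact
#' integers); set `integer_N = TRUE` to require an integer for forward
#' simulation.
#'
#' @param c_A total protein concentration (mol/L, > 0).
#' @param c_B total oligonucleotide concentration (mol/L, >= 0); may be a
#'   vector (a titration schedule).
#' @param N number of independent, identical binding sites per
#'   oligonucleotide (> 0).
#' @param K_D per-site dissociation constant (mol/L, >= 0).
#' @param integer_N require `N` to be a whole number.
#' @return an object of class `binding_system`.
#' @seealso [fraction_bound()], [fluorescence_quench()]
#' @examples
#' sys <- binding_system(c_A = 1e-3, c_B = 2.5e-4, N = 2, K_D = 4e-9)
#' fraction_bound(sys)
#' @export
binding_system <- function(c_A, c_B, N = 2, K_D = 0, integer_N = FALSE) {
  .check_pos(c_A, "c_A")
  .check_nonneg(c_B, "c_B")
  .check_pos(N, "N")
  .check_nonneg(K_D, "K_D")
  if (length(c_A) != 1L || length(N) != 1L || length(K_D) != 1L)
    stop_invalid("'c_A', 'N' and 'K_D' must be scalars")
  if (integer_N && N != round(N))
    stop_invalid("'N' must be a whole number when integer_N = TRUE")
  structure(list(c_A = c_A, c_B = c_B, N = N, K_D = K_D),
            class = "binding_system")
}

#' @export
print.binding_system <- function(x, ...) {
  cat("Binding system (N independent, identical sites per oligonucleotide)\n")
  cat(sprintf("  c_A  = %g M\n", x$c_A))
  cat(sprintf("  c_B  = %s M\n", paste(format(x$c_B), collapse = ", ")))
  cat(sprintf("  N    = %g sites\n", x$N))
  cat(sprintf("  K_D  = %g M\n", x$K_D))
  cat(sprintf("  P_AB = %s\n",
              paste(format(round(fraction_bound(x), 4)), collapse = ", ")))
  invisible(x)
}

.unpack_system <- function(c_A, c_B, N, K_D) {
  if (inherits(c_A, "binding_system")) {
    sys <- c_A
    list(c_A = sys$c_A, c_B = sys$c_B, N = sys$N, K_D = sys$K_D)
  } else {
    list(c_A = c_A, c_B = c_B, N = N, K_D = K_D)
  }
}

#' Fraction of protein bound under the ligand-depletion isotherm
#'
#' Probability `P_AB` that a protein molecule is bound to an oligonucleotide
#' carrying `N` independent, identical binding sites, from the exact solution
#' of the mass-balance quadratic:
#' \deqn{P_{AB} = \frac{1}{2 c_A}\left(c_A + N c_B + K_D -
#'   \sqrt{(c_A + N c_B + K_D)^2 - 4 N c_A c_B}\right).}
#' Because total concentrations enter explicitly, the expression remains
#' valid when the ligand is depleted by binding (tight-binding regime),
#' where the hyperbolic approximation fails.
#'
#' The root is evaluated in the rationalized form
#' `2 N c_B / (c_A + N c_B + K_D + sqrt(disc))`, with the discriminant
#' expanded as `(c_A - N c_B)^2 + 2 K_D (c_A + N c_B) + K_D^2` -- a sum of
#' nonnegative terms -- so the result is accurate even when `K_D` is many
#' orders of magnitude below the concentrations (nM dissociation constants
#' at mM NMR concentrations).
#'
#' @param c_A total protein concentration (mol/L, > 0), or a
#'   [binding_system()] (in which case the remaining arguments are ignored).
#' @param c_B total oligonucleotide concentration (mol/L, >= 0); vectorized.
#' @param N sites per oligonucleotide (> 0).
#' @param K_D per-site dissociation constant (mol/L, >= 0). `K_D = 0` gives
#'   the tight-binding limit exactly.
#' @return bound fraction(s) in \[0, 1\].
#' @seealso [fraction_bound_tight()] for the explicit tight-binding limit.
#' @examples
#' fraction_bound(c_A = 1e-6, c_B = 1e-6, N = 1, K_D = 1e-6)
#' # nM-affinity complex at mM concentrations: stoichiometric binding
#' fraction_bound(c_A = 1e-3, c_B = 2.5e-4, N = 2, K_D = 4e-9)
#' @export
fraction_bound <- function(c_A, c_B = NULL, N = 2, K_D = 0) {
  a <- .unpack_system(c_A, c_B, N, K_D)
  .check_pos(a$c_A, "c_A")
  .check_nonneg(a$c_B, "c_B")
  .check_pos(a$N, "N")
  .check_nonneg(a$K_D, "K_D")
  s <- a$c_A + a$N * a$c_B + a$K_D
  disc <- (a$c_A - a$N * a$c_B)^2 +
    2 * a$K_D * (a$c_A + a$N * a$c_B) + a$K_D^2
  p <- 2 * a$N * a$c_B / (s + sqrt(disc))
  pmin(pmax(p, 0), 1)
}

#' Bound fraction in the tight-binding (stoichiometric) limit
#'
#' Limit of [fraction_bound()] for `K_D` negligible against the total
#' concentrations:
#' \deqn{P_{AB} = \frac{1}{2 c_A}\left(c_A + N c_B - |c_A - N c_B|\right)
#'   = \min(1, N c_B / c_A).}
#' The titration curve is then a straight line of slope `N` (in the molar
#' ratio `c_B/c_A`) with a sharp kink at the saturation ratio `1/N`; the
#' position of the kink reveals the stoichiometry.
#'
#' @inheritParams fraction_bound
#' @return bound fraction(s) in \[0, 1\].
#' @examples
#' fraction_bound_tight(c_A = 1, c_B = c(0.1, 0.25, 0.5, 0.6), N = 2)
#' @export
fraction_bound_tight <- function(c_A, c_B = NULL, N = 2) {
  a <- .unpack_system(c_A, c_B, N, 0)
  .check_pos(a$c_A, "c_A")
  .check_nonneg(a$c_B, "c_B")
  .check_pos(a$N, "N")
  (a$c_A + a$N * a$c_B - abs(a$c_A - a$N * a$c_B)) / (2 * a$c_A)
}

#' Saturation breakpoint of the tight-binding titration curve
#'
#' Smallest ligand-to-protein molar ratio `c_B/c_A` at which the bound
#' fraction reaches 1 under the tight-binding limit; equals `1/N`.
#'
#' @param N sites per oligonucleotide (> 0).
#' @return the breakpoint molar ratio.
#' @examples
#' saturation_ratio(2) # shifts stop changing at a 0.5 molar ratio
#' @export
saturation_ratio <- function(N) {
  .check_pos(N, "N")
  1 / N
}

#' Observed chemical shift under fast exchange
#'
#' Under fast chemical exchange the observed resonance is the
#' population-weighted average of the free and bound shifts:
#' `delta = P_AB * delta_bound + (1 - P_AB) * delta_free`. Equivalently the
#' normalized change `(delta - delta_free) / (delta_bound - delta_free)`
#' equals the bound fraction, which is what makes shift trajectories direct
#' readouts of the binding curve.
#'
#' @param p_bound bound fraction(s) in \[0, 1\].
#' @param delta_free chemical shift of the free-protein resonance (ppm).
#' @param delta_bound chemical shift of the bound-state resonance (ppm).
#' @return observed shift(s), ppm.
#' @examples
#' observed_shift_fast(0.5, delta_free = 10.35, delta_bound = 10.536)
#' @export
observed_shift_fast <- function(p_bound, delta_free, delta_bound) {
  .check_prob(p_bound, "p_bound")
  .check_finite(delta_free, "delta_free")
  .check_finite(delta_bound, "delta_bound")
  p_bound * delta_bound + (1 - p_bound) * delta_free
}

#' Free- and bound-peak intensity fractions under slow exchange
#'
#' Under slow exchange a titration shows two resonances per nucleus, at the
#' free and bound positions, whose integrals trade off with the populations:
#' the free peak carries `1 - P_AB`, the bound peak `P_AB`. Differential
#' relaxation between the two states is ignored (intensity is proportional
#' to population only), which mirrors quantification from peak integrals.
#'
#' @param p_bound bound fraction(s) in \[0, 1\].
#' @return a data.frame with columns `free` and `bound` summing to 1 rowwise.
#' @examples
#' slow_exchange_intensities(c(0, 0.3, 1))
#' @export
slow_exchange_intensities <- function(p_bound) {
  .check_prob(p_bound, "p_bound")
  data.frame(free = 1 - p_bound, bound = p_bound)
}

#' Predicted tryptophan fluorescence during a quench titration
#'
#' Forward model for dissociation-constant determination by quenching of
#' intrinsic tryptophan fluorescence: the observed intensity is
#' `F0 * (1 - q * P_AB)`, with `F0` the intensity of fully free protein and
#' `q` the maximal fractional quench at saturation. `P_AB` comes from the
#' ligand-depletion isotherm ([fraction_bound()]), so the model is valid in
#' the tight-binding regime where protein and `K_D` are comparable. No
#' floating baseline or inner-filter correction is applied.
#'
#' @inheritParams fraction_bound
#' @param F0 fluorescence of fully free protein (arbitrary units, > 0).
#' @param q maximal fractional quench at saturation, in \[0, 1\].
#' @return predicted intensities, in `[F0 * (1 - q), F0]`.
#' @examples
#' fluorescence_quench(c_A = 5e-9, c_B = c(0, 2e-9, 1e-8), N = 2,
#'                     K_D = 4e-9, F0 = 100, q = 0.8)
#' @export
fluorescence_quench <- function(c_A, c_B = NULL, N = 2, K_D = 0,
                                F0 = 1, q = 0.8) {
  .check_pos(F0, "F0")
  .check_prob(q, "q")
  p <- fraction_bound(c_A, c_B, N, K_D)
  F0 * (1 - q * p)
}

#' Linewidth scaling with molecular mass for a rigid rotor
#'
#' Cube-root scaling rule for the approximate NMR linewidth change that
#' accompanies a change in molecular mass: the factor returned is
#' `mass_ratio^(1/3)`, i.e. the scaling of the particle's linear dimension
#' for a rigid sphere of mass-proportional volume. Doubling the mass (e.g.
#' by dimerization) broadens lines by `2^(1/3) = 1.26` under this rule,
#' which is the conventional back-of-envelope check used to decide whether
#' an observed broadening is consistent with complex formation.
#'
#' @param mass_ratio ratio of molecular masses (> 0).
#' @return the predicted linewidth scaling factor.
#' @examples
#' linewidth_mass_scaling(2) # dimerization: 1.26
#' @export
linewidth_mass_scaling <- function(mass_ratio) {
  .check_pos(mass_ratio, "mass_ratio")
  mass_ratio^(1 / 3)
}
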