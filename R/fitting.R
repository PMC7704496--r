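#' Fluorescence quench titration curve
#'
#' Container for a tryptophan-fluorescence titration: ordered ligand
#' concentrations with observed intensities, plus the total protein
#' concentration held (approximately) constant through the titration.
#'
#' @param c_B total oligonucleotide concentrations (mol/L), strictly
#'   increasing; a `c_B = 0` reference point is allowed and useful.
#' @param intensity observed fluorescence intensities (> 0, arbitrary
#'   units), same length as `c_B`.
#' @param c_A total protein concentration (mol/L, > 0).
#' @param temperature_label free-text temperature annotation, e.g. `"303 K"`.
#' @return an object of class `fluorescence_curve` with a `points`
#'   data.frame (`c_B`, `intensity`).
#' @seealso [fit_kd_fluorescence()], [simulate_fluorescence_titration()]
#' @export
fluorescence_curve <- function(c_B, intensity, c_A,
                               temperature_label = NA_character_) {
  .check_nonneg(c_B, "c_B")
  .check_pos(intensity, "intensity")
  .check_pos(c_A, "c_A")
  if (length(c_B) != length(intensity))
    stop_invalid("'c_B' and 'intensity' must have equal length")
  if (is.unsorted(c_B, strictly = TRUE))
    stop_invalid("'c_B' must be strictly increasing")
  structure(list(points = data.frame(c_B = c_B, intensity = intensity),
                 c_A = c_A, temperature_label = temperature_label),
            class = "fluorescence_curve")
}

#' @export
print.fluorescence_curve <- function(x, ...) {
  cat(sprintf("Fluorescence titration: %d points, c_A = %g M%s\n",
              nrow(x$points), x$c_A,
              if (is.na(x$temperature_label)) "" else
                paste0(", ", x$temperature_label)))
  print(utils::head(x$points, 6), row.names = FALSE)
  if (nrow(x$points) > 6) cat("  ...\n")
  invisible(x)
}

#' Normalized chemical-shift titration series
#'
#' Residue-averaged (or single-residue) relative chemical-shift changes as a
#' function of the ligand-to-protein molar ratio. The normalization
#' convention is that of stoichiometry titrations: shifts are divided by the
#' change at the highest ligand concentration, so the final point sits at
#' (about) 1.
#'
#' @param ratio molar ratios `c_B/c_A`, non-negative, strictly increasing.
#' @param normalized_shift relative shift changes (dimensionless).
#' @param c_A total protein concentration (mol/L, > 0).
#' @param averaged logical; `TRUE` if the series averages several residues.
#' @return an object of class `normalized_shift_series`.
#' @seealso [fit_stoichiometry_nmr()], [simulate_shift_series()]
#' @export
normalized_shift_series <- function(ratio, normalized_shift, c_A,
                                    averaged = TRUE) {
  .check_nonneg(ratio, "ratio")
  .check_finite(normalized_shift, "normalized_shift")
  .check_pos(c_A, "c_A")
  if (length(ratio) != length(normalized_shift))
    stop_invalid("'ratio' and 'normalized_shift' must have equal length")
  if (is.unsorted(ratio, strictly = TRUE))
    stop_invalid("'ratio' must be strictly increasing")
  structure(list(points = data.frame(ratio = ratio,
                                     normalized_shift = normalized_shift),
                 c_A = c_A, averaged = averaged),
            class = "normalized_shift_series")
}

#' @export
print.normalized_shift_series <- function(x, ...) {
  cat(sprintf("Normalized shift series: %d points, c_A = %g M (%s)\n",
              nrow(x$points), x$c_A,
              if (isTRUE(x$averaged)) "residue-averaged" else "per-residue"))
  print(x$points, row.names = FALSE)
  invisible(x)
}

.new_titration_fit <- function(model, estimates, std_errors, residual_norm,
                               converged, n_points, fixed, data_points,
                               refit, seed = NULL) {
  structure(list(model = model,
                 estimates = estimates,
                 std_errors = std_errors,
                 residual_norm = residual_norm,
                 converged = converged,
                 n_points = n_points,
                 fixed = fixed,
                 data_points = data_points,
                 refit = refit,
                 seed = seed),
            class = "titration_fit")
}

#' @export
print.titration_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Titration fit: %s (%d points)%s\n", x$model, x$n_points,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  if (length(x$fixed))
    cat("  fixed: ", paste(names(x$fixed), signif(unlist(x$fixed), digits),
                           sep = " = ", collapse = ", "), "\n", sep = "")
  est <- data.frame(estimate = signif(x$estimates, digits),
                    std_error = signif(x$std_errors[names(x$estimates)],
                                       digits))
  print(est)
  cat(sprintf("  residual sum of squares: %.4g\n", x$residual_norm))
  invisible(x)
}

#' @export
coef.titration_fit <- function(object, ...) object$estimates

#' Fit a dissociation constant to a fluorescence quench curve
#'
#' Estimates `K_D`, `F0` and the quench amplitude `q` by Levenberg-Marquardt
#' least squares on the ligand-depletion quench model
#' [fluorescence_quench()], with the site count `N` fixed (two protein
#' molecules per heptanucleotide in the canonical design). `K_D` is
#' optimized on a log10 scale with multiple starts spread over
#' `kd_range`, because plausible dissociation constants span several orders
#' of magnitude; the best of the converged starts is kept.
#'
#' Standard errors come from the local curvature (Jacobian) at the optimum;
#' the `K_D` error is mapped back from the log scale by the delta method.
#' For resampling-based uncertainties see [bootstrap_uncertainty()].
#'
#' @param curve a [fluorescence_curve()].
#' @param N_fixed assumed number of binding sites per oligonucleotide.
#' @param n_starts number of multi-start values for `K_D`, log-spaced over
#'   `kd_range`.
#' @param kd_range lower/upper bounds for `K_D` during optimization (mol/L).
#' @param start optional named list/vector with starting values for any of
#'   `K_D`, `F0`, `q` (used in place of the default heuristics; multi-starts
#'   in `K_D` are still added around it).
#' @return a `titration_fit` with estimates `K_D` (mol/L), `F0`, `q`.
#'   Non-convergence is flagged via `$converged`, not raised.
#' @examples
#' sim <- simulate_fluorescence_titration(c_A = 5e-9, K_D = 4e-9, N = 2,
#'                                        noise_rel = 0, seed = 1)
#' fit <- fit_kd_fluorescence(sim$curve)
#' coef(fit)[["K_D"]] # ~4e-9
#' @export
fit_kd_fluorescence <- function(curve, N_fixed = 2, n_starts = 8,
                                kd_range = c(1e-12, 1e-3), start = NULL) {
  if (!inherits(curve, "fluorescence_curve"))
    stop_invalid("'curve' must be a fluorescence_curve")
  .check_pos(N_fixed, "N_fixed")
  pts <- curve$points
  if (nrow(pts) < 5L)
    stop_invalid("at least 5 titration points are required for a 3-parameter fit (got %d)",
                 nrow(pts))
  c_A <- curve$c_A
  y <- pts$intensity
  cb <- pts$c_B
  lo <- c(lkd = log10(kd_range[1]), F0 = .Machine$double.eps, q = 0)
  hi <- c(lkd = log10(kd_range[2]), F0 = Inf, q = 1)

  resid_fun <- function(par) {
    y - fluorescence_quench(c_A, cb, N_fixed, 10^par[["lkd"]],
                            par[["F0"]], par[["q"]])
  }

  F0_start <- if (!is.null(start$F0)) start$F0 else max(y)
  q_start <- if (!is.null(start$q)) start$q else
    min(max(1 - min(y) / F0_start, 0.05), 0.95)
  lkd_starts <- seq(log10(kd_range[1]) + 0.5, log10(kd_range[2]) - 0.5,
                    length.out = n_starts)
  if (!is.null(start$K_D))
    lkd_starts <- unique(c(log10(start$K_D), lkd_starts))

  best <- NULL
  for (lkd0 in lkd_starts) {
    f <- try(minpack.lm::nls.lm(
      par = c(lkd = lkd0, F0 = F0_start, q = q_start),
      lower = lo, upper = hi, fn = resid_fun,
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(f, "try-error")) next
    if (is.null(best) || f$deviance < best$deviance) best <- f
  }

  if (is.null(best)) {
    est <- c(K_D = NA_real_, F0 = NA_real_, q = NA_real_)
    return(.new_titration_fit("fluorescence_quench", est, est, NA_real_,
                              FALSE, nrow(pts), list(N = N_fixed), pts,
                              refit = NULL))
  }

  par <- best$par
  est <- c(K_D = 10^par[["lkd"]], F0 = par[["F0"]], q = par[["q"]])
  se <- c(K_D = NA_real_, F0 = NA_real_, q = NA_real_)
  sm <- try(summary(best), silent = TRUE)
  if (!inherits(sm, "try-error")) {
    se_raw <- sm$coefficients[, "Std. Error"]
    se <- c(K_D = log(10) * est[["K_D"]] * se_raw[["lkd"]],
            F0 = se_raw[["F0"]], q = se_raw[["q"]])
  }
  converged <- best$info %in% 1:3
  refit <- function(points) {
    cv <- curve
    cv$points <- points[order(points$c_B), , drop = FALSE]
    fit_kd_fluorescence_points(cv, N_fixed, kd_range, est)
  }
  .new_titration_fit("fluorescence_quench", est, se, best$deviance,
                     converged, nrow(pts), list(N = N_fixed), pts, refit)
}

# Reduced-start refit used by the bootstrap: start at the full-data optimum
# plus two decades either side. Duplicate c_B values (case resampling) are
# allowed here, so validation bypasses the strict-monotonicity contract.
fit_kd_fluorescence_points <- function(curve, N_fixed, kd_range, start_est) {
  pts <- curve$points
  c_A <- curve$c_A
  y <- pts$intensity
  cb <- pts$c_B
  lo <- c(lkd = log10(kd_range[1]), F0 = .Machine$double.eps, q = 0)
  hi <- c(lkd = log10(kd_range[2]), F0 = Inf, q = 1)
  resid_fun <- function(par) {
    y - fluorescence_quench(c_A, cb, N_fixed, 10^par[["lkd"]],
                            par[["F0"]], par[["q"]])
  }
  lkd0 <- log10(start_est[["K_D"]])
  best <- NULL
  for (l in c(lkd0, lkd0 - 2, lkd0 + 2)) {
    l <- min(max(l, lo[["lkd"]]), hi[["lkd"]])
    f <- try(minpack.lm::nls.lm(
      par = c(lkd = l, F0 = start_est[["F0"]],
              q = min(max(start_est[["q"]], 0), 1)),
      lower = lo, upper = hi, fn = resid_fun,
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(f, "try-error")) next
    if (is.null(best) || f$deviance < best$deviance) best <- f
  }
  if (is.null(best))
    return(.new_titration_fit("fluorescence_quench",
                              c(K_D = NA_real_, F0 = NA_real_, q = NA_real_),
                              c(K_D = NA_real_, F0 = NA_real_, q = NA_real_),
                              NA_real_, FALSE, nrow(pts),
                              list(N = N_fixed), pts, NULL))
  est <- c(K_D = 10^best$par[["lkd"]], F0 = best$par[["F0"]],
           q = best$par[["q"]])
  .new_titration_fit("fluorescence_quench", est,
                     c(K_D = NA_real_, F0 = NA_real_, q = NA_real_),
                     best$deviance, best$info %in% 1:3, nrow(pts),
                     list(N = N_fixed), pts, NULL)
}

#' Fit the binding stoichiometry to a normalized NMR shift titration
#'
#' Estimates the number of independent binding sites `N` (and a
#' normalization amplitude) from a normalized chemical-shift series, with
#' `K_D` held fixed at the value determined independently (e.g. by
#' fluorescence quenching). The model is
#' `normalized_shift = amplitude * P_AB(c_A, ratio * c_A, N, K_D)`; at mM
#' protein concentrations and nM `K_D` this reduces to the tight-binding
#' kink curve, whose breakpoint at ratio `1/N` carries the stoichiometry.
#'
#' For fixed `N` the amplitude enters linearly and is profiled out
#' analytically, so the optimization is a robust 1-D search over `N`
#' (coarse grid, then golden-section refinement). Standard errors are
#' derived from the numerical Jacobian at the optimum.
#'
#' @param series a [normalized_shift_series()].
#' @param K_D_fixed fixed per-site dissociation constant (mol/L, >= 0).
#' @param N_range search interval for `N`.
#' @return a `titration_fit` with estimates `N` and `amplitude`.
#' @examples
#' s <- simulate_shift_series(c_A = 1e-3, N = 2, K_D = 4e-9,
#'                            noise_sd = 0, seed = 1)
#' fit_stoichiometry_nmr(s, K_D_fixed = 4e-9)
#' @export
fit_stoichiometry_nmr <- function(series, K_D_fixed, N_range = c(0.2, 8)) {
  if (!inherits(series, "normalized_shift_series"))
    stop_invalid("'series' must be a normalized_shift_series")
  .check_nonneg(K_D_fixed, "K_D_fixed")
  pts <- series$points
  y <- pts$normalized_shift
  if (all(y == 0)) stop_invalid("all normalized shifts are zero; nothing to fit")
  c_A <- series$c_A
  cb <- pts$ratio * c_A

  prof <- function(N) {
    p <- fraction_bound(c_A, cb, N, K_D_fixed)
    sp2 <- sum(p^2)
    if (sp2 == 0) return(list(ssq = sum(y^2), amp = 0))
    amp <- sum(y * p) / sp2
    list(ssq = sum((y - amp * p)^2), amp = amp)
  }
  grid <- exp(seq(log(N_range[1]), log(N_range[2]), length.out = 81))
  ssq_grid <- vapply(grid, function(N) prof(N)$ssq, numeric(1))
  i <- which.min(ssq_grid)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(function(N) prof(N)$ssq, c(lo, hi),
                         tol = .Machine$double.eps^0.5)
  N_hat <- opt$minimum
  pr <- prof(N_hat)
  est <- c(N = N_hat, amplitude = pr$amp)
  converged <- N_hat > N_range[1] * 1.001 && N_hat < N_range[2] * 0.999

  # curvature-based standard errors from the numerical Jacobian at (N, amp)
  se <- c(N = NA_real_, amplitude = NA_real_)
  n <- length(y)
  if (n > 2L) {
    h <- max(1e-6, 1e-6 * N_hat)
    p0 <- fraction_bound(c_A, cb, N_hat, K_D_fixed)
    p1 <- fraction_bound(c_A, cb, N_hat + h, K_D_fixed)
    J <- cbind(N = pr$amp * (p1 - p0) / h, amplitude = p0)
    s2 <- pr$ssq / (n - 2L)
    cv <- try(s2 * solve(crossprod(J)), silent = TRUE)
    if (!inherits(cv, "try-error") && all(diag(cv) >= 0))
      se <- sqrt(diag(cv))
  }
  refit <- function(points) {
    s2 <- series
    s2$points <- points[order(points$ratio), , drop = FALSE]
    fit_stoichiometry_nmr_points(s2, K_D_fixed, N_range)
  }
  .new_titration_fit("stoichiometry_nmr", est, se, pr$ssq, converged,
                     n, list(K_D = K_D_fixed), pts, refit)
}

# Bootstrap refit path: accepts duplicated ratios from case resampling.
fit_stoichiometry_nmr_points <- function(series, K_D_fixed, N_range) {
  pts <- series$points
  y <- pts$normalized_shift
  c_A <- series$c_A
  cb <- pts$ratio * c_A
  prof <- function(N) {
    p <- fraction_bound(c_A, cb, N, K_D_fixed)
    sp2 <- sum(p^2)
    if (sp2 == 0) return(list(ssq = sum(y^2), amp = 0))
    amp <- sum(y * p) / sp2
    list(ssq = sum((y - amp * p)^2), amp = amp)
  }
  grid <- exp(seq(log(N_range[1]), log(N_range[2]), length.out = 41))
  ssq_grid <- vapply(grid, function(N) prof(N)$ssq, numeric(1))
  i <- which.min(ssq_grid)
  opt <- stats::optimize(function(N) prof(N)$ssq,
                         c(grid[max(1L, i - 1L)],
                           grid[min(length(grid), i + 1L)]),
                         tol = .Machine$double.eps^0.5)
  pr <- prof(opt$minimum)
  .new_titration_fit("stoichiometry_nmr",
                     c(N = opt$minimum, amplitude = pr$amp),
                     c(N = NA_real_, amplitude = NA_real_),
                     pr$ssq, TRUE, length(y), list(K_D = K_D_fixed),
                     pts, NULL)
}

#' Case-resampling bootstrap uncertainties for a titration fit
#'
#' Resamples titration points with replacement, refits, and reports the
#' empirical standard deviation of each parameter. Resamples with fewer
#' unique points than model parameters are redrawn (with a retry cap), since
#' they cannot constrain the fit. Fully deterministic for a given seed.
#'
#' @param fit a `titration_fit` from [fit_kd_fluorescence()] or
#'   [fit_stoichiometry_nmr()].
#' @param n_boot number of bootstrap draws (>= 100).
#' @param seed RNG seed; the default gives reproducible reports without any
#'   user action.
#' @return a list with `std_errors` (named numeric), `draws` (matrix of
#'   bootstrap estimates), `n_boot`, `seed`.
#' @examples
#' sim <- simulate_fluorescence_titration(c_A = 5e-9, K_D = 4e-9,
#'                                        noise_rel = 0.01, seed = 7)
#' fit <- fit_kd_fluorescence(sim$curve)
#' bootstrap_uncertainty(fit, n_boot = 100, seed = 1)$std_errors
#' @export
bootstrap_uncertainty <- function(fit, n_boot = 1000, seed = 1729) {
  if (!inherits(fit, "titration_fit"))
    stop_invalid("'fit' must be a titration_fit")
  if (n_boot < 100) stop_invalid("'n_boot' must be >= 100")
  if (is.null(fit$refit))
    stop_invalid("this fit does not support refitting (bootstrap of a bootstrap?)")
  pts <- fit$data_points
  n <- nrow(pts)
  k <- length(fit$estimates)
  set.seed(seed)
  draws <- matrix(NA_real_, nrow = n_boot, ncol = k,
                  dimnames = list(NULL, names(fit$estimates)))
  for (b in seq_len(n_boot)) {
    idx <- NULL
    for (try_i in seq_len(100L)) {
      cand <- sample.int(n, n, replace = TRUE)
      if (length(unique(cand)) >= k) { idx <- cand; break }
    }
    if (is.null(idx))
      stop_invalid("could not draw a non-degenerate bootstrap resample")
    bf <- fit$refit(pts[idx, , drop = FALSE])
    draws[b, ] <- bf$estimates[colnames(draws)]
  }
  list(std_errors = apply(draws, 2, stats::sd, na.rm = TRUE),
       draws = draws, n_boot = n_boot, seed = seed)
}

#' Diagnostic plot of a titration fit
#'
#' Base-graphics overlay of the observed titration points and the fitted
#' model curve.
#'
#' @param x a `titration_fit`.
#' @param ... passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.titration_fit <- function(x, ...) {
  pts <- x$data_points
  if (x$model == "fluorescence_quench") {
    plot(pts$c_B, pts$intensity, xlab = "c_B (M)",
         ylab = "fluorescence intensity", ...)
    cb <- seq(min(pts$c_B), max(pts$c_B), length.out = 200)
    # c_A is recoverable from the stored refit environment
    c_A <- environment(x$refit)$curve$c_A
    graphics::lines(cb, fluorescence_quench(c_A, cb, x$fixed$N,
                                            x$estimates[["K_D"]],
                                            x$estimates[["F0"]],
                                            x$estimates[["q"]]))
  } else {
    plot(pts$ratio, pts$normalized_shift, xlab = "c_B / c_A",
         ylab = "relative shift change", ...)
    r <- seq(min(pts$ratio), max(pts$ratio), length.out = 200)
    c_A <- environment(x$refit)$series$c_A
    graphics::lines(r, x$estimates[["amplitude"]] *
                      fraction_bound(c_A, r * c_A, x$estimates[["N"]],
                                     x$fixed$K_D))
  }
  invisible(x)
}
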