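## Torsional elasticity: quadratic regression of the PMF, conversion to a
## torsional modulus via the homogeneous rod model, and the twist-only
## supercoiling-density conversion.

#' Fit the torsional force constant from a PMF
#'
#' Least-squares quadratic regression `F = K (delta - centre)^2 + c` over
#' the region within `half_range` of the PMF minimum on the per-bp-step
#' axis (the reference protocol uses +-2 degrees). The centre is fitted
#' freely and reported.
#'
#' @param pmf A `pmf_profile` (axis: twist change per bp step, degrees).
#' @param half_range Half-width of the fit region, degrees per bp step.
#' @return An `elastic_fit`: list with `K` (kcal mol^-1 deg^-2 on the
#'   per-bp-step axis), `centre`, `R2`, `half_range`, `n_bins`.
#' @export
fit_force_constant <- function(pmf, half_range = 2.0) {
  stopifnot(inherits(pmf, "pmf_profile"))
  ok <- is.finite(pmf$free_energy)
  x <- pmf$delta_twist_per_bp[ok]
  y <- pmf$free_energy[ok]
  x0 <- x[which.min(y)]
  sel <- abs(x - x0) <= half_range
  if (sum(sel) < 5)
    stop(sprintf("only %d sampled bins within +-%g deg/bp of the PMF minimum (need >= 5)",
                 sum(sel), half_range))
  fit <- stats::lm(y[sel] ~ x[sel] + I(x[sel]^2))
  co <- stats::coef(fit)
  K <- unname(co[3])
  if (!is.finite(K) || K <= 0)
    stop("PMF is not convex over the fit region (K <= 0)")
  ss_tot <- sum((y[sel] - mean(y[sel]))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(list(K = K, centre = unname(-co[2] / (2 * K)),
                 R2 = r2, half_range = half_range,
                 n_bins = sum(sel),
                 temperature = attr(pmf, "temperature"),
                 n_region_steps = attr(pmf, "n_region_steps")),
            class = "elastic_fit")
}

#' @export
print.elastic_fit <- function(x, ...) {
  cat(sprintf(
    "<elastic_fit> K = %.4f kcal/mol/deg^2 (per bp step), centre = %+.3f deg, R^2 = %.5f (%d bins, +-%g deg)\n",
    x$K, x$centre, x$R2, x$n_bins, x$half_range))
  invisible(x)
}

#' Torsional modulus from the homogeneous rod model
#'
#' Converts a per-bp-step force constant `K` (from `F(delta) = K delta^2`,
#' kcal mol^-1 deg^-2) into the torsional modulus expressed as a length:
#'   C = 2 K_rad L_bp / (n k_B T),
#' where `K_rad` is K in rad^-2 and n the number of restrained steps. For a
#' chain of independent steps this is algebraically identical to
#' `C = L_bp / Var(step twist in rad)`, the fluctuation form of the rod
#' model; both derivations are spelled out in the methods vignette.
#'
#' @param fit An `elastic_fit`, or a bare positive K value.
#' @param n_region_steps Number of restrained bp steps (default: from the
#'   fit, else 13).
#' @param L_bp Base-pair length, nm (default 0.34).
#' @param temperature Kelvin (default: from the fit, else 300).
#' @return A `torsional_modulus`: list with `C_nm`, `K`, `L_bp`,
#'   `temperature`, `n_region_steps`.
#' @export
torsional_modulus <- function(fit, n_region_steps = NULL, L_bp = L_BP_NM,
                              temperature = NULL) {
  if (inherits(fit, "elastic_fit")) {
    K <- fit$K
    if (is.null(n_region_steps)) n_region_steps <- fit$n_region_steps
    if (is.null(temperature)) temperature <- fit$temperature
  } else {
    K <- as.numeric(fit)
  }
  if (is.null(n_region_steps)) n_region_steps <- 13
  if (is.null(temperature)) temperature <- DEFAULT_TEMPERATURE
  if (!is.finite(K) || K <= 0) stop("force constant K must be positive")
  K_rad <- K * (180 / pi)^2
  C <- 2 * K_rad * L_bp / (n_region_steps * kbt(temperature))
  structure(list(C_nm = C, K = K, L_bp = L_bp, temperature = temperature,
                 n_region_steps = n_region_steps),
            class = "torsional_modulus")
}

#' @export
print.torsional_modulus <- function(x, ...) {
  cat(sprintf("<torsional_modulus> C = %.1f nm (K = %.4f kcal/mol/deg^2, n = %d, L = %.2f nm, T = %g K)\n",
              x$C_nm, x$K, x$n_region_steps, x$L_bp, x$temperature))
  invisible(x)
}

#' Twist-only supercoiling density
#'
#' `sigma = delta_per_bp / relaxed_per_bp`: the fractional change in twist,
#' neglecting writhe. At the protocol's maximal +-5 deg/bp against a
#' relaxed twist of ~34.3 deg/bp this gives sigma ~ +-0.15.
#'
#' @param delta_per_bp Twist change per bp step, degrees (vectorized).
#' @param relaxed_per_bp Relaxed twist per bp step, degrees (> 0).
#' @return Dimensionless sigma.
#' @export
supercoiling_density <- function(delta_per_bp, relaxed_per_bp) {
  stopifnot(relaxed_per_bp > 0)
  delta_per_bp / relaxed_per_bp
}

#' JSON elasticity report
#'
#' @param fit An `elastic_fit`.
#' @param modulus A `torsional_modulus`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_elasticity_json <- function(fit, modulus, path) {
  jsonlite::write_json(list(
    K_kcal_mol_deg2 = fit$K, centre_deg = fit$centre, R2 = fit$R2,
    fit_range_deg = fit$half_range, C_nm = modulus$C_nm,
    T_K = modulus$temperature, L_bp_nm = modulus$L_bp,
    n_steps = modulus$n_region_steps), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
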