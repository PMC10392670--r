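## The end-to-end-twist umbrella bias: a quadratic penalty on the summed
## helical twist of a contiguous run of bp steps. The literal convention
## K * (twist - twist_ref)^2 is used, with no 1/2 factor; a force constant k
## in the 1/2 k delta^2 convention therefore corresponds to k_tw = k / 2.

#' Construct a torsional restraint
#'
#' @param k_tw Force constant, kcal mol^-1 deg^-2 (>= 0). The value used in
#'   the reference protocol is 0.06.
#' @param twist_ref Reference end-to-end twist in degrees.
#' @param region Integer vector of restrained step indices (contiguous,
#'   1-based; step i joins bp i and i + 1).
#' @return Object of class `torsional_restraint`.
#' @export
torsional_restraint <- function(k_tw = 0.06, twist_ref, region) {
  stopifnot(is.numeric(k_tw), length(k_tw) == 1, k_tw >= 0,
            is.numeric(twist_ref), length(twist_ref) == 1,
            is.finite(twist_ref))
  region <- as.integer(region)
  if (length(region) == 0L) stop("restraint region must be non-empty")
  structure(list(k_tw = k_tw, twist_ref = twist_ref, region = region),
            class = "torsional_restraint")
}

#' @export
print.torsional_restraint <- function(x, ...) {
  cat(sprintf(
    "<torsional_restraint> k_tw = %g kcal/mol/deg^2, twist_ref = %g deg, %d steps (%d..%d)\n",
    x$k_tw, x$twist_ref, length(x$region), min(x$region), max(x$region)))
  invisible(x)
}

#' Restraint bias energy
#'
#' `k_tw * (twist_total - twist_ref)^2` in kcal/mol. Vectorized over
#' `twist_total`.
#'
#' @param restraint A `torsional_restraint`.
#' @param twist_total End-to-end twist of the restrained region, degrees.
#' @return Energy in kcal/mol.
#' @export
bias_energy <- function(restraint, twist_total) {
  stopifnot(inherits(restraint, "torsional_restraint"))
  restraint$k_tw * (twist_total - restraint$twist_ref)^2
}

#' Gradient of the bias energy with respect to per-step twists
#'
#' The collective variable is a plain sum of in-region step twists, so the
#' gradient is `2 k_tw (twist_total - twist_ref)` for every step in the
#' region and 0 outside.
#'
#' @param restraint A `torsional_restraint`.
#' @param twist_total End-to-end twist, degrees (scalar).
#' @param n_steps Total number of steps in the fragment (default: up to the
#'   last restrained step).
#' @return Numeric vector of length `n_steps`, kcal mol^-1 deg^-1.
#' @export
bias_gradient <- function(restraint, twist_total, n_steps = max(restraint$region)) {
  stopifnot(inherits(restraint, "torsional_restraint"),
            length(twist_total) == 1, is.finite(twist_total))
  g <- numeric(n_steps)
  g[restraint$region] <- 2 * restraint$k_tw * (twist_total - restraint$twist_ref)
  g
}
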