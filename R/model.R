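## Gaussian-mixture rigid-base-pair sequence model. Each bp step carries one
## or more harmonic substates (mean 6-vector, 6x6 stiffness, intrinsic
## energy); pyrimidine-purine steps default to two twist substates separated
## by 20 degrees ("twist capacitors"). The Boltzmann density is
##   p(x, s) propto exp(-beta * sum_i [ 1/2 (x_i - mu_{s_i})' F_{s_i}
##            (x_i - mu_{s_i}) + eps_{s_i} ] - beta * J * sum_i [s_i != s_{i+1}])
## with the nearest-neighbour label coupling J applied between adjacent
## multi-substate steps.

#' Construct a step substate
#'
#' @param mean Named or ordered 6-vector of step parameter means
#'   (`shift, slide, rise, tilt, roll, twist`; Angstrom / degrees).
#' @param stiffness 6x6 symmetric positive-definite stiffness matrix,
#'   kcal mol^-1 per (Angstrom or degree)^2; the harmonic energy is
#'   `1/2 (x - mean)' F (x - mean)`.
#' @param epsilon Intrinsic (free) energy offset of the substate, kcal/mol.
#' @return Object of class `step_substate`.
#' @export
step_substate <- function(mean, stiffness, epsilon = 0) {
  mean <- stats::setNames(as_param6(mean, STEP_PAR_NAMES), STEP_PAR_NAMES)
  stiffness <- unname(as.matrix(stiffness))
  stopifnot(all(dim(stiffness) == c(6, 6)))
  if (max(abs(stiffness - t(stiffness))) > 1e-8)
    stop("stiffness matrix must be symmetric")
  ev <- eigen(stiffness, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0))
    stop("stiffness matrix must be positive definite")
  structure(list(mean = mean, stiffness = stiffness, epsilon = epsilon),
            class = "step_substate")
}

#' Construct a rigid-base-pair sequence model
#'
#' @param sequence DNA sequence (ACGT), length >= 2.
#' @param steps List of length `nchar(sequence) - 1`; each element a list of
#'   one or more [step_substate()]s.
#' @param J Nearest-neighbour substate coupling in kcal/mol, applied as
#'   `J * [s_i != s_{i+1}]` between adjacent multi-substate steps.
#' @param temperature Temperature in Kelvin.
#' @return Object of class `sequence_model`.
#' @export
sequence_model <- function(sequence, steps, J = 0,
                           temperature = DEFAULT_TEMPERATURE) {
  sequence <- toupper(sequence)
  bases <- strsplit(sequence, "")[[1]]
  if (!all(bases %in% names(COMPLEMENT)))
    stop("sequence contains non-ACGT characters")
  if (length(steps) != length(bases) - 1L)
    stop("need exactly nchar(sequence) - 1 step definitions")
  for (st in steps) {
    if (!length(st)) stop("each step needs at least one substate")
    lapply(st, function(s) stopifnot(inherits(s, "step_substate")))
  }
  structure(list(sequence = sequence, steps = steps, J = J,
                 temperature = temperature),
            class = "sequence_model")
}

#' @export
print.sequence_model <- function(x, ...) {
  ns <- vapply(x$steps, length, integer(1))
  cat(sprintf("<sequence_model> %s\n  %d steps (%d bimodal), J = %g kcal/mol, T = %g K\n",
              x$sequence, length(x$steps), sum(ns > 1), x$J, x$temperature))
  invisible(x)
}

n_steps <- function(model) length(model$steps)

## Default fluctuation scales (synthetic; B-DNA-like magnitudes).
DEFAULT_SD <- c(shift = 0.40, slide = 0.45, rise = 0.30,
                tilt = 2.7, roll = 5.0, twist = 3.0)
DEFAULT_TWIST_ROLL_CORR <- -0.4
DEFAULT_TWIST_SLIDE_CORR <- 0.3
BIMODAL_SEPARATION <- 20  # degrees between twist substates at YpR steps
YPR_STEPS <- c("TA", "TG", "CA", "CG")

## Covariance -> stiffness for a substate with given per-parameter SDs and
## the default twist-roll / twist-slide couplings.
default_stiffness <- function(sds, temperature = DEFAULT_TEMPERATURE,
                              twist_roll = DEFAULT_TWIST_ROLL_CORR,
                              twist_slide = DEFAULT_TWIST_SLIDE_CORR) {
  C <- diag(6)
  C[2, 6] <- C[6, 2] <- twist_slide
  C[5, 6] <- C[6, 5] <- twist_roll
  S <- diag(sds) %*% C %*% diag(sds)
  kbt(temperature) * solve(S)
}

#' Default Gaussian-mixture model for a sequence
#'
#' Pyrimidine-purine (YpR) steps -- TA, TG, CA, CG -- receive two twist
#' substates separated by `bimodal_separation` degrees with equal intrinsic
#' energies (the twist-capacitor motif); all other steps are single-substate.
#' Per-substate fluctuations use the package default scales with the default
#' twist-roll anti-correlation (-0.4) and twist-slide correlation (+0.3).
#'
#' @param sequence DNA sequence (ACGT), length >= 2.
#' @param mean_twist Equilibrium twist per step, degrees.
#' @param twist_sd Within-substate twist standard deviation, degrees.
#' @param bimodal If FALSE all steps are single-substate (used for
#'   homogeneous control models).
#' @param bimodal_separation Twist separation of YpR substates, degrees.
#' @param J Nearest-neighbour substate coupling, kcal/mol.
#' @param temperature Kelvin.
#' @return A `sequence_model`.
#' @export
default_model <- function(sequence, mean_twist = 34.6,
                          twist_sd = DEFAULT_SD[["twist"]],
                          bimodal = TRUE,
                          bimodal_separation = BIMODAL_SEPARATION,
                          J = 0, temperature = DEFAULT_TEMPERATURE) {
  sequence <- toupper(sequence)
  bases <- strsplit(sequence, "")[[1]]
  if (!all(bases %in% names(COMPLEMENT)))
    stop("sequence contains non-ACGT characters")
  if (length(bases) < 2) stop("sequence must have length >= 2")
  sds <- DEFAULT_SD
  sds[["twist"]] <- twist_sd
  FF <- default_stiffness(sds, temperature)
  mu0 <- c(shift = 0, slide = 0, rise = 3.38, tilt = 0, roll = 0,
           twist = mean_twist)
  steps <- lapply(seq_len(length(bases) - 1L), function(i) {
    dimer <- paste0(bases[i], bases[i + 1])
    if (bimodal && dimer %in% YPR_STEPS) {
      lo <- hi <- mu0
      lo[["twist"]] <- mean_twist - bimodal_separation / 2
      hi[["twist"]] <- mean_twist + bimodal_separation / 2
      list(step_substate(lo, FF, 0), step_substate(hi, FF, 0))
    } else {
      list(step_substate(mu0, FF, 0))
    }
  })
  names(steps) <- vapply(seq_len(length(bases) - 1L), function(i)
    paste0(bases[i], bases[i + 1]), character(1))
  sequence_model(sequence, steps, J = J, temperature = temperature)
}

## Compile a sequence_model into the flat arrays the C++ sampler consumes.
compile_model <- function(model) {
  beta <- 1 / kbt(model$temperature)
  lapply(model$steps, function(st) {
    K <- length(st)
    means <- matrix(0, 6, K)
    Lc <- array(0, c(6, 6, K)); Fb <- array(0, c(6, 6, K))
    SigTw <- matrix(0, 6, K); sTT <- numeric(K)
    beps <- numeric(K); logw0 <- numeric(K)
    for (k in seq_len(K)) {
      FF <- st[[k]]$stiffness
      S <- kbt(model$temperature) * solve(FF)
      S <- (S + t(S)) / 2
      means[, k] <- st[[k]]$mean
      Lc[, , k] <- t(chol(S))
      Fb[, , k] <- beta * FF
      SigTw[, k] <- S[, TWIST_IDX]
      sTT[k] <- S[TWIST_IDX, TWIST_IDX]
      beps[k] <- beta * st[[k]]$epsilon
      logw0[k] <- -beps[k] + 0.5 * determinant(S)$modulus
    }
    list(K = K, means = means, L = Lc, Fbeta = Fb, SigTw = SigTw,
         sTT = sTT, beps = beps, logw0 = logw0)
  })
}

#' Analytic torsional modulus implied by a sequence model
#'
#' For independent steps (J = 0) the fragment twist variance is the sum of
#' per-step mixture variances; the homogeneous rod model then gives
#' `C = L_bp / Var(step twist in rad^2)` with the per-step variance taken as
#' the fragment variance divided by the number of steps. Substate weights
#' are the exact marginal Boltzmann weights `exp(-beta eps) |Sigma|^(1/2)`.
#'
#' @param model A `sequence_model` with `J = 0`.
#' @param region Step indices to include (default: all).
#' @param L_bp Base-pair length in nm (default 0.34).
#' @return Torsional modulus in nm.
#' @export
ground_truth_modulus <- function(model, region = NULL, L_bp = L_BP_NM) {
  stopifnot(inherits(model, "sequence_model"))
  if (model$J != 0)
    stop("analytic modulus requires independent steps (J = 0); ",
         "estimate it from a long unbiased simulation instead")
  if (is.null(region)) region <- seq_len(n_steps(model))
  comp <- compile_model(model)
  vars <- vapply(region, function(i) {
    cs <- comp[[i]]
    w <- exp(cs$logw0 - max(cs$logw0)); w <- w / sum(w)
    m <- cs$means[TWIST_IDX, ]
    sum(w * (cs$sTT + m^2)) - sum(w * m)^2
  }, numeric(1))
  var_eff_deg2 <- sum(vars) / length(region)
  L_bp / deg2rad(sqrt(var_eff_deg2))^2
}

#' Mean end-to-end twist of a model over a region
#'
#' Sum of per-step mixture-mean twists; the natural relaxed reference for an
#' umbrella schedule.
#'
#' @param model A `sequence_model`.
#' @param region Step indices (default: all).
#' @return Degrees.
#' @export
model_mean_twist <- function(model, region = NULL) {
  if (is.null(region)) region <- seq_len(n_steps(model))
  comp <- compile_model(model)
  sum(vapply(region, function(i) {
    cs <- comp[[i]]
    w <- exp(cs$logw0 - max(cs$logw0)); w <- w / sum(w)
    sum(w * cs$means[TWIST_IDX, ])
  }, numeric(1)))
}
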