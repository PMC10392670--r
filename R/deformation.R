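## Harmonic multi-substate deformation energy with nearest-neighbour Ising
## coupling over substate labels, evaluated exactly by a transfer matrix
## (log-sum over all substate chains) or by a minimum-chain (Viterbi) path.
## Works on 6-dimensional (inter-bp only) or 12-dimensional (inter + intra)
## step parameter vectors.

#' Construct a deformation-energy model
#'
#' Each step carries >= 1 harmonic substates (`mean` d-vector, `stiffness`
#' d x d SPD matrix, intrinsic energy `epsilon`); adjacent steps are coupled
#' through a label-pair energy matrix `J[s_i, s_{i+1}]` (kcal/mol). The
#' snapshot energy Boltzmann-sums over all substate chains:
#'   E(x) = -kT log sum_s exp(-beta [sum_i (1/2 dx' F dx + eps) + sum_i J]),
#' referenced so that the lowest-energy substate chain at its harmonic
#' minimum scores zero.
#'
#' @param steps List (one element per bp step) of lists of substates, each
#'   `list(mean =, stiffness =, epsilon =)`; all means must share one
#'   dimension d (6 or 12).
#' @param couplings Either NULL (no coupling), a single number J applied as
#'   `J * [s_i != s_{i+1}]`, or a list of `n_steps - 1` matrices
#'   `J[s_i, s_{i+1}]`.
#' @param temperature Kelvin.
#' @param provenance `"synthetic"` or `"user-supplied"`.
#' @return A `deformation_model`.
#' @export
deformation_model <- function(steps, couplings = NULL,
                              temperature = DEFAULT_TEMPERATURE,
                              provenance = "synthetic") {
  stopifnot(length(steps) >= 1)
  provenance <- match.arg(provenance, c("synthetic", "user-supplied"))
  d <- length(steps[[1]][[1]]$mean)
  if (!d %in% c(6L, 12L))
    stop("step parameter dimension must be 6 or 12")
  steps <- lapply(steps, function(st) lapply(st, function(s) {
    s$mean <- as.numeric(s$mean)
    s$stiffness <- unname(as.matrix(s$stiffness))
    if (is.null(s$epsilon)) s$epsilon <- 0
    if (length(s$mean) != d || !all(dim(s$stiffness) == c(d, d)))
      stop("inconsistent substate dimensions")
    if (max(abs(s$stiffness - t(s$stiffness))) > 1e-8)
      stop("stiffness matrix must be symmetric")
    ev <- eigen(s$stiffness, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 0)) stop("stiffness matrix must be positive definite")
    s
  }))
  K <- vapply(steps, length, integer(1))
  nj <- length(steps) - 1L
  Jlist <- if (is.null(couplings)) {
    lapply(seq_len(nj), function(i) matrix(0, K[i], K[i + 1]))
  } else if (is.numeric(couplings) && length(couplings) == 1) {
    lapply(seq_len(nj), function(i) {
      m <- matrix(couplings, K[i], K[i + 1])
      if (K[i] == K[i + 1]) diag(m) <- 0
      m
    })
  } else {
    stopifnot(is.list(couplings), length(couplings) == nj)
    lapply(seq_len(nj), function(i) {
      m <- as.matrix(couplings[[i]])
      stopifnot(all(dim(m) == c(K[i], K[i + 1])))
      m
    })
  }
  structure(list(steps = steps, couplings = Jlist, dim = d,
                 temperature = temperature, provenance = provenance),
            class = "deformation_model")
}

#' @export
print.deformation_model <- function(x, ...) {
  K <- vapply(x$steps, length, integer(1))
  cat(sprintf("<deformation_model> %d steps, dim %d, substates %s, T = %g K (%s)\n",
              length(x$steps), x$dim,
              paste(range(K), collapse = "-"), x$temperature, x$provenance))
  invisible(x)
}

#' Deformation model matching a sequence model
#'
#' Re-expresses a [sequence_model()] (6 inter-bp parameters per step) as a
#' `deformation_model`, so window ensembles can be scored by the evaluator
#' they were generated from.
#'
#' @param model A `sequence_model`.
#' @param region Step indices to include (default: all).
#' @return A `deformation_model` (dim 6, provenance "synthetic").
#' @export
as_deformation_model <- function(model, region = NULL) {
  stopifnot(inherits(model, "sequence_model"))
  if (is.null(region)) region <- seq_len(n_steps(model))
  steps <- lapply(model$steps[region], function(st)
    lapply(st, function(s)
      list(mean = s$mean, stiffness = s$stiffness, epsilon = s$epsilon)))
  deformation_model(steps, couplings = if (model$J != 0) model$J else NULL,
                    temperature = model$temperature)
}

## Ground-state (minimum over chains of eps + J) used as the zero reference.
chain_ground_energy <- function(model) {
  n <- length(model$steps)
  v <- vapply(model$steps[[1]], `[[`, numeric(1), "epsilon")
  if (n > 1) for (i in 2:n) {
    eps_i <- vapply(model$steps[[i]], `[[`, numeric(1), "epsilon")
    v <- vapply(seq_along(eps_i), function(k)
      eps_i[k] + min(v + model$couplings[[i - 1]][, k]), numeric(1))
  }
  min(v)
}

## Per-step, per-substate harmonic energies for a stack of frames.
## X: n_frames x n_steps x d array (or n_steps x d matrix for one frame).
substate_energies <- function(X, model) {
  if (is.matrix(X)) X <- array(X, c(1, dim(X)))
  n <- length(model$steps); d <- model$dim
  if (dim(X)[2] != n || dim(X)[3] != d)
    stop(sprintf("parameter array must be frames x %d steps x %d", n, d))
  nf <- dim(X)[1]
  lapply(seq_len(n), function(i) {
    st <- model$steps[[i]]
    matrix(vapply(st, function(s) {
      D <- sweep(matrix(X[, i, ], ncol = d), 2, s$mean)
      0.5 * rowSums((D %*% s$stiffness) * D) + s$epsilon
    }, numeric(nf)), nrow = nf)
  })
}

#' Snapshot deformation energy
#'
#' @param params Step parameters for one snapshot (`n_steps x d` matrix) or
#'   a stack (`n_frames x n_steps x d` array).
#' @param model A `deformation_model`.
#' @param method `"logsum"` (default; Boltzmann sum over substate chains by
#'   transfer matrix) or `"min"` (lowest-energy chain, Viterbi).
#' @param reference `"ground"` (default; zero at the lowest-energy substate
#'   chain's harmonic minimum) or `"none"`.
#' @return Energy in kcal/mol (one value per frame).
#' @export
snapshot_energy <- function(params, model, method = c("logsum", "min"),
                            reference = c("ground", "none")) {
  stopifnot(inherits(model, "deformation_model"))
  method <- match.arg(method)
  reference <- match.arg(reference)
  E <- substate_energies(params, model)   # list of n_frames x K_i
  n <- length(E)
  kT <- kbt(model$temperature)
  if (method == "logsum") {
    ## log-space transfer matrix over chains, vectorized across frames
    A <- -E[[1]] / kT                      # n_frames x K_1
    if (n > 1) for (i in 2:n) {
      J <- model$couplings[[i - 1]]
      Knext <- ncol(E[[i]])
      Anew <- matrix(0, nrow(A), Knext)
      for (k in seq_len(Knext)) {
        M <- sweep(A, 2, J[, k] / kT)      # A - beta*J[, k]
        mx <- do.call(pmax, c(as.data.frame(M), list(-Inf)))
        Anew[, k] <- mx + log(rowSums(exp(M - mx)))
      }
      A <- Anew - E[[i]] / kT
    }
    mx <- do.call(pmax, as.data.frame(A))
    out <- -kT * (mx + log(rowSums(exp(A - mx))))
  } else {
    A <- E[[1]]
    if (n > 1) for (i in 2:n) {
      J <- model$couplings[[i - 1]]
      Knext <- ncol(E[[i]])
      Anew <- matrix(0, nrow(A), Knext)
      for (k in seq_len(Knext))
        Anew[, k] <- do.call(pmin, as.data.frame(sweep(A, 2, -J[, k])))
      A <- Anew + E[[i]]
    }
    out <- do.call(pmin, as.data.frame(A))
  }
  if (reference == "ground") out <- out - chain_ground_energy(model)
  unname(out)
}

#' Window-averaged deformation energy
#'
#' Scores every stored frame of an ensemble (an `umbrella_window` sampled
#' with `keep = "region_params"`/`"all_params"`, an `ensemble_sample`, or a
#' bare parameter array) and returns per-frame energies with their mean and
#' standard deviation.
#'
#' @param ensemble Source of per-frame step parameters.
#' @param model A `deformation_model` whose steps align with the stored
#'   parameter columns.
#' @param ... Passed to [snapshot_energy()].
#' @return A `deformation_result`: list with `energies`, `mean`, `sd`, `n`.
#' @export
window_deformation <- function(ensemble, model, ...) {
  X <- if (is.array(ensemble) && length(dim(ensemble)) == 3) ensemble
       else if (!is.null(ensemble$params)) ensemble$params
       else stop("ensemble carries no stored step parameters; sample with keep = 'region_params' or 'all_params'")
  if (dim(X)[2] != length(model$steps))
    stop("ensemble steps do not align with model steps")
  e <- snapshot_energy(X, model, ...)
  structure(list(energies = e, mean = mean(e), sd = stats::sd(e),
                 n = length(e)), class = "deformation_result")
}

#' @export
print.deformation_result <- function(x, ...) {
  cat(sprintf("<deformation_result> mean = %.3f kcal/mol, sd = %.3f (n = %d)\n",
              x$mean, x$sd, x$n))
  invisible(x)
}

#' Read a deformation parameter file (JSON, keyed by step context)
#'
#' The file maps a dimer or tetranucleotide context to a list of substates
#' `{mean: [d], stiffness: [[d x d]], epsilon}`, with an optional
#' `couplings` entry (scalar J or per-context-pair matrices) and optional
#' `temperature`. A model is assembled for the given sequence by looking up
#' each step's context (tetranucleotide keys use the step's flanking
#' context; terminal steps fall back to the dimer key if present).
#'
#' @param path JSON file path.
#' @param sequence Sequence whose steps the model should cover.
#' @return A `deformation_model` with provenance "user-supplied".
#' @export
read_deformation_params <- function(path, sequence) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  pars <- spec$parameters
  if (is.null(pars)) stop("parameter file has no 'parameters' entry")
  bases <- strsplit(toupper(sequence), "")[[1]]
  n <- length(bases) - 1L
  key_for <- function(i) {
    dimer <- paste0(bases[i], bases[i + 1])
    tetra <- if (i > 1 && i < n)
      paste0(bases[i - 1], dimer, bases[i + 2]) else NA_character_
    if (!is.na(tetra) && tetra %in% names(pars)) tetra
    else if (dimer %in% names(pars)) dimer
    else stop("no parameters for step context ", dimer)
  }
  steps <- lapply(seq_len(n), function(i) {
    p <- pars[[key_for(i)]]
    means <- p$mean
    if (is.null(dim(means))) means <- matrix(means, nrow = 1)
    d <- ncol(means)
    stiff <- p$stiffness
    ## jsonlite yields a d x d matrix (one substate), a K x d x d array,
    ## or a list of d x d matrices
    get_stiff <- function(k) {
      if (is.list(stiff)) matrix(unlist(stiff[[k]]), d, d)
      else if (length(dim(stiff)) == 3) matrix(stiff[k, , ], d, d)
      else matrix(unlist(stiff), d, d)
    }
    eps <- if (is.null(p$epsilon)) numeric(nrow(means)) else p$epsilon
    lapply(seq_len(nrow(means)), function(k) list(
      mean = means[k, ], stiffness = get_stiff(k), epsilon = eps[k]))
  })
  J <- spec$couplings
  temperature <- if (is.null(spec$temperature)) DEFAULT_TEMPERATURE
                 else spec$temperature
  m <- deformation_model(steps, couplings = J, temperature = temperature)
  m$provenance <- "user-supplied"
  m
}
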