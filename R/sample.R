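## Ensemble generation: unbiased sampling of the sequence model and the
## cascade umbrella run under the end-to-end-twist restraint.

KEEP_MODES <- c(cv = 0L, region_twist = 1L, region_params = 2L,
                all_params = 3L)

#' Locate the restrained step region of a fragment within a sequence
#'
#' Steps are 1-based; step i joins bp i and i + 1, so a fragment of m bp
#' starting at bp p covers steps p .. p + m - 2.
#'
#' @param sequence Full duplex sequence.
#' @param fragment Contiguous sub-sequence to restrain.
#' @return Integer vector of step indices.
#' @export
restrained_region <- function(sequence, fragment) {
  p <- regexpr(toupper(fragment), toupper(sequence), fixed = TRUE)
  if (p < 0) stop("fragment not found in sequence")
  m <- nchar(fragment)
  if (m < 2) stop("fragment must span at least one step")
  seq.int(p, p + m - 2L)
}

window_seed <- function(seed, index) {
  as.integer((as.numeric(seed) + 104729 * index) %% 2147483647)
}

#' Sample the unbiased Boltzmann ensemble of a sequence model
#'
#' Frames are exact independent draws: substate labels come from the
#' marginal label chain (x integrated out; transfer-matrix sampling when
#' J != 0) and the 6-vectors from the conditional Gaussians.
#'
#' @param model A `sequence_model`.
#' @param n_frames Number of frames (>= 1).
#' @param seed Integer seed.
#' @return An `ensemble_sample`: `params` (n_frames x n_steps x 6 array),
#'   `labels` (n_frames x n_steps, 1-based), `occupancy`, `seed`.
#' @export
sample_unbiased <- function(model, n_frames, seed = 1) {
  stopifnot(inherits(model, "sequence_model"), n_frames >= 1)
  comp <- compile_model(model)
  set.seed(window_seed(seed, 0L))
  res <- sample_ensemble_cpp(comp, betaJ = model$J / kbt(model$temperature),
                             k_bias = 0, beta = 1 / kbt(model$temperature),
                             ref = 0, region1 = seq_len(n_steps(model)),
                             n_frames = as.integer(n_frames), burnin = 0L,
                             keep_mode = KEEP_MODES[["all_params"]],
                             keep_labels = TRUE,
                             start_x = matrix(numeric(0), 0, 0),
                             start_labels = integer(0), gibbs = FALSE)
  params <- res$params
  dimnames(params) <- list(NULL, names(model$steps), STEP_PAR_NAMES)
  structure(list(params = params, labels = res$labels,
                 occupancy = res$occupancy,
                 acceptance_rate = res$acceptance_rate,
                 cv = as.numeric(res$cv), seed = seed,
                 sequence = model$sequence,
                 temperature = model$temperature),
            class = "ensemble_sample")
}

#' Build the cascade umbrella schedule
#'
#' Starting from the relaxed reference, window references move outward in
#' increments of `increment` degrees per bp step (i.e. `increment *
#' n_region_steps` degrees of end-to-end twist per window) until
#' `max_offset` degrees per bp step is reached in both directions: two
#' one-sided cascades sharing the central relaxed window,
#' `2 * max_offset / increment + 1` windows in total.
#'
#' @param relaxed_ref Relaxed end-to-end twist of the restrained region,
#'   degrees (e.g. 450 for a 13-step region at ~34.6 deg/step).
#' @param increment Reference shift per bp step between windows, degrees
#'   (default 0.5).
#' @param max_offset Maximal over/underwinding per bp step, degrees
#'   (default 5).
#' @param n_region_steps Number of restrained steps (default 13).
#' @param n_frames Frames sampled per window (default 2e5).
#' @param sampling_time_per_window_us Nominal per-window sampling time
#'   book-kept alongside the schedule (default 0.5 microseconds).
#' @param sequential_seeding Start each window from the final configuration
#'   of the previous window of its cascade (default TRUE).
#' @return An `umbrella_schedule`: data.frame with columns `window`,
#'   `cascade`, `offset_per_bp`, `ref`, ordered as sampled, with schedule
#'   metadata in attributes (`n_windows`, `total_time_us`, ...).
#' @export
make_umbrella_schedule <- function(relaxed_ref, increment = 0.5,
                                   max_offset = 5.0, n_region_steps = 13,
                                   n_frames = 2e5,
                                   sampling_time_per_window_us = 0.5,
                                   sequential_seeding = TRUE) {
  stopifnot(increment > 0, max_offset > 0)
  k <- max_offset / increment
  if (abs(k - round(k)) > 1e-9)
    stop("increment must divide max_offset")
  k <- as.integer(round(k))
  offsets <- c(0, increment * seq_len(k), -increment * seq_len(k))
  cascade <- c(0L, rep(1L, k), rep(-1L, k))
  sched <- data.frame(window = seq_along(offsets), cascade = cascade,
                      offset_per_bp = offsets,
                      ref = relaxed_ref + offsets * n_region_steps)
  structure(sched,
            class = c("umbrella_schedule", "data.frame"),
            relaxed_ref = relaxed_ref, increment = increment,
            max_offset = max_offset, n_region_steps = n_region_steps,
            n_frames = n_frames,
            sampling_time_per_window_us = sampling_time_per_window_us,
            n_windows = length(offsets),
            total_time_us = length(offsets) * sampling_time_per_window_us,
            sequential_seeding = sequential_seeding)
}

#' Run the umbrella-sampling cascade
#'
#' Samples every window of a schedule under the model energy plus the
#' quadratic end-to-end-twist bias. With sequential seeding the final
#' configuration of each window starts the next window of its cascade (the
#' central window seeds both directions). Unimodal models (and all unbiased
#' windows) yield exact independent frames; multi-substate steps under bias
#' are sampled by Gibbs alternation between labels and parameters with a
#' 10% burn-in discarded.
#'
#' @param model A `sequence_model`.
#' @param schedule An `umbrella_schedule`.
#' @param k_tw Restraint force constant, kcal mol^-1 deg^-2 (default 0.06).
#' @param region Restrained step indices (default: centered
#'   `n_region_steps` of the schedule).
#' @param n_frames Frames kept per window (default: from the schedule).
#' @param seed Master seed; window i uses an independently derived stream.
#' @param keep What to store per window: `"region_twist"` (default;
#'   cv series + per-step twists of the region), `"cv"`, `"region_params"`
#'   (full 6-vectors of the region) or `"all_params"`.
#' @param burnin_frac Fraction of frames discarded as burn-in when Gibbs
#'   alternation is needed (default 0.1).
#' @param keep_labels Store substate labels per frame.
#' @return List of `umbrella_window` objects (class `umbrella_run`), in
#'   schedule order.
#' @export
run_umbrella <- function(model, schedule, k_tw = 0.06, region = NULL,
                         n_frames = NULL, seed = 1,
                         keep = c("region_twist", "cv", "region_params",
                                  "all_params"),
                         burnin_frac = 0.1, keep_labels = FALSE) {
  stopifnot(inherits(model, "sequence_model"),
            inherits(schedule, "umbrella_schedule"))
  keep <- match.arg(keep)
  nrs <- attr(schedule, "n_region_steps")
  if (is.null(region)) {
    ns <- n_steps(model)
    if (nrs > ns) stop("model has fewer steps than the schedule's region")
    start <- (ns - nrs) %/% 2 + 1L
    region <- seq.int(start, start + nrs - 1L)
  }
  region <- as.integer(region)
  if (is.null(n_frames)) n_frames <- attr(schedule, "n_frames")
  comp <- compile_model(model)
  multimodal <- any(vapply(comp, `[[`, integer(1), "K") > 1)
  gibbs <- multimodal && k_tw > 0
  burnin <- if (gibbs) as.integer(ceiling(burnin_frac * n_frames)) else 0L
  beta <- 1 / kbt(model$temperature)
  seq_seed <- isTRUE(attr(schedule, "sequential_seeding"))
  windows <- vector("list", nrow(schedule))
  state <- list(`0` = NULL)  # cascade start states keyed by cascade id
  center_state <- NULL
  for (w in seq_len(nrow(schedule))) {
    ref <- schedule$ref[w]
    casc <- as.character(schedule$cascade[w])
    start_x <- matrix(numeric(0), 0, 0)
    start_labels <- integer(0)
    if (seq_seed) {
      prev <- if (schedule$cascade[w] == 0L) NULL
              else if (!is.null(state[[casc]])) state[[casc]]
              else center_state
      if (!is.null(prev)) {
        start_x <- prev$x
        start_labels <- prev$labels
      }
    }
    set.seed(window_seed(seed, w))
    res <- sample_ensemble_cpp(comp, betaJ = model$J * beta,
                               k_bias = k_tw, beta = beta, ref = ref,
                               region1 = region,
                               n_frames = as.integer(n_frames),
                               burnin = burnin,
                               keep_mode = KEEP_MODES[[keep]],
                               keep_labels = keep_labels,
                               start_x = start_x,
                               start_labels = start_labels, gibbs = gibbs)
    if (gibbs && !is.na(res$acceptance_rate) && res$acceptance_rate < 0.01)
      warning(sprintf(
        "window %d (ref %.1f): substate-move acceptance %.2f%% < 1%%; run continues",
        w, ref, 100 * res$acceptance_rate))
    fin <- list(x = res$final_x, labels = res$final_labels)
    if (schedule$cascade[w] == 0L) center_state <- fin else state[[casc]] <- fin
    win <- list(restraint = torsional_restraint(k_tw, ref, region),
                ref = ref, offset_per_bp = schedule$offset_per_bp[w],
                cascade = schedule$cascade[w], window = schedule$window[w],
                cv = as.numeric(res$cv),
                step_twist_mean = as.numeric(res$step_twist_mean),
                occupancy = res$occupancy,
                acceptance_rate = res$acceptance_rate,
                n_frames = n_frames, burnin = burnin, region = region,
                temperature = model$temperature,
                seed = window_seed(seed, w))
    if (keep %in% c("region_twist", "region_params", "all_params"))
      win$twists <- res$twists
    if (keep %in% c("region_params", "all_params")) {
      win$params <- res$params
      dimnames(win$params) <- list(
        NULL,
        if (keep == "region_params") names(model$steps)[region]
        else names(model$steps),
        STEP_PAR_NAMES)
    }
    if (keep_labels) win$labels <- res$labels
    class(win) <- "umbrella_window"
    windows[[w]] <- win
  }
  structure(windows, class = "umbrella_run",
            schedule = schedule, seed = seed, k_tw = k_tw, region = region,
            sequence = model$sequence, temperature = model$temperature)
}

#' @export
print.umbrella_window <- function(x, ...) {
  cat(sprintf(
    "<umbrella_window> ref = %.1f deg (%+.1f deg/bp), %d frames, mean CV = %.2f deg\n",
    x$ref, x$offset_per_bp, x$n_frames, mean(x$cv)))
  invisible(x)
}

#' Export an umbrella run (or ensemble) as CSV + JSON metadata
#'
#' Writes `<prefix>_cv.csv` (window, frame, cv), `<prefix>_twists.csv`
#' (window, frame, step, twist; when stored) and `<prefix>_meta.json`.
#'
#' @param run An `umbrella_run`.
#' @param prefix Output path prefix.
#' @return Invisibly, the paths written.
#' @export
write_umbrella_csv <- function(run, prefix) {
  stopifnot(inherits(run, "umbrella_run"))
  paths <- character(0)
  cvd <- do.call(rbind, lapply(run, function(w)
    data.frame(window = w$window, ref = w$ref, frame = seq_along(w$cv),
               cv = w$cv)))
  p <- paste0(prefix, "_cv.csv")
  utils::write.csv(cvd, p, row.names = FALSE)
  paths <- c(paths, p)
  if (!is.null(run[[1]]$twists)) {
    twd <- do.call(rbind, lapply(run, function(w) {
      data.frame(window = w$window,
                 frame = rep(seq_len(nrow(w$twists)), ncol(w$twists)),
                 step = rep(w$region, each = nrow(w$twists)),
                 twist = as.numeric(w$twists))
    }))
    p <- paste0(prefix, "_twists.csv")
    utils::write.csv(twd, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  meta <- list(seed = attr(run, "seed"), k_tw = attr(run, "k_tw"),
               region = attr(run, "region"),
               sequence = attr(run, "sequence"),
               temperature = attr(run, "temperature"),
               n_windows = length(run),
               refs = vapply(run, `[[`, numeric(1), "ref"))
  p <- paste0(prefix, "_meta.json")
  jsonlite::write_json(meta, p, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)
  invisible(paths)
}
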