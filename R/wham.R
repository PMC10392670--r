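## Weighted histogram analysis method on the 1-D end-to-end-twist
## collective variable, and histogram-overlap quality control.

#' Reconstruct the twisting PMF from umbrella windows
#'
#' Standard self-consistent WHAM on the binned CV: window free-energy
#' shifts f_w are iterated to convergence of
#'   p(b) = sum_w n_w(b) / sum_w N_w exp(-beta (b_w(b) - f_w)),
#'   f_w = -kT log sum_b p(b) exp(-beta b_w(b)).
#' The PMF is -kT log p, zeroed at its minimum over sampled bins; bins with
#' zero total count are masked. The output axis is the average twist change
#' per bp step relative to the relaxed mean, `(cv - relaxed_mean) /
#' n_region_steps`, with the relaxed mean taken from the central (smallest
#' |offset|) window.
#'
#' @param windows An `umbrella_run` or list of `umbrella_window`s.
#' @param bin_width Histogram bin width on the total-twist axis, degrees
#'   (default 0.25).
#' @param tol Convergence tolerance on the shifts, kcal/mol (default 1e-7).
#' @param max_iter Maximum iterations (default 1e5).
#' @return A `pmf_profile`: data.frame columns `delta_twist_per_bp`
#'   (bin centres), `free_energy` (kcal/mol), `n_samples`, plus attributes
#'   `grid_cv`, `relaxed_mean`, `n_region_steps`, `shifts`, `iterations`,
#'   `final_change`.
#' @export
wham <- function(windows, bin_width = 0.25, tol = 1e-7, max_iter = 1e5) {
  stopifnot(length(windows) >= 1)
  temperature <- windows[[1]]$temperature
  kT <- kbt(temperature)
  n_region <- length(windows[[1]]$region)
  refs <- vapply(windows, `[[`, numeric(1), "ref")
  ks <- vapply(windows, function(w) w$restraint$k_tw, numeric(1))
  offsets <- vapply(windows, function(w)
    if (is.null(w$offset_per_bp)) NA_real_ else w$offset_per_bp, numeric(1))
  center <- if (all(is.na(offsets))) which.min(abs(refs - stats::median(refs)))
            else which.min(abs(offsets))
  relaxed_mean <- mean(windows[[center]]$cv)

  all_cv <- unlist(lapply(windows, `[[`, "cv"))
  lo <- floor(min(all_cv) / bin_width) * bin_width
  hi <- ceiling(max(all_cv) / bin_width) * bin_width
  breaks <- seq(lo, hi, by = bin_width)
  mids <- breaks[-1] - bin_width / 2
  nb <- length(mids)
  W <- length(windows)
  counts <- vapply(windows, function(w)
    tabulate(pmin(pmax(findInterval(w$cv, breaks, rightmost.closed = TRUE),
                       1L), nb), nbins = nb), numeric(nb))
  Ntot <- colSums(counts)
  ctot <- rowSums(counts)

  ## adjacent-window overlap check (windows ordered by ref)
  ord <- order(refs)
  for (i in seq_len(W - 1)) {
    a <- counts[, ord[i]] > 0; b <- counts[, ord[i + 1]] > 0
    if (!any(a & b))
      stop(sprintf(
        "no histogram overlap between adjacent windows at refs %.1f and %.1f deg",
        refs[ord[i]], refs[ord[i + 1]]))
  }

  ## B[b, w] = exp(-beta * bias_w(mid_b)), computed in log space
  logB <- -outer(mids, seq_len(W), function(x, w) ks[w] * (x - refs[w])^2) / kT
  f <- numeric(W)
  it <- 0L; change <- Inf
  logN <- log(Ntot)
  while (it < max_iter) {
    it <- it + 1L
    ## log denominator per bin: logsumexp over windows
    M <- sweep(logB, 2, logN + f / kT, `+`)
    mx <- apply(M, 1, max)
    log_denom <- mx + log(rowSums(exp(M - mx)))
    logp <- ifelse(ctot > 0, log(ctot) - log_denom, -Inf)
    ## new shifts
    A <- sweep(logB, 1, logp, `+`)
    amx <- apply(A, 2, max)
    fnew <- -kT * (amx + log(colSums(exp(sweep(A, 2, amx)))))
    fnew <- fnew - fnew[1]
    change <- max(abs(fnew - f))
    f <- fnew
    if (change < tol) break
  }
  if (change >= tol)
    stop(sprintf("WHAM did not converge in %d iterations (residual %.3g kcal/mol)",
                 as.integer(max_iter), change))
  M <- sweep(logB, 2, logN + f / kT, `+`)
  mx <- apply(M, 1, max)
  logp <- ifelse(ctot > 0, log(ctot) - (mx + log(rowSums(exp(M - mx)))), -Inf)
  fe <- -kT * logp
  fe <- fe - min(fe[is.finite(fe)])
  out <- data.frame(delta_twist_per_bp = (mids - relaxed_mean) / n_region,
                    free_energy = ifelse(ctot > 0, fe, NA_real_),
                    n_samples = ctot)
  structure(out, class = c("pmf_profile", "data.frame"),
            grid_cv = mids, bin_width = bin_width,
            relaxed_mean = relaxed_mean, n_region_steps = n_region,
            temperature = temperature, shifts = f, iterations = it,
            final_change = change)
}

#' Histogram overlap between adjacent umbrella windows
#'
#' For each adjacent pair (ordered by reference), the overlap fraction is
#' the summed bin-wise minimum of the two normalized CV histograms -- 1 for
#' identical distributions, 0 for disjoint support.
#'
#' @param windows An `umbrella_run` or list of `umbrella_window`s (>= 2).
#' @param bin_width Histogram bin width, degrees.
#' @return data.frame with columns `ref_lo`, `ref_hi`, `overlap`.
#' @export
overlap_report <- function(windows, bin_width = 0.25) {
  stopifnot(length(windows) >= 2)
  refs <- vapply(windows, `[[`, numeric(1), "ref")
  ord <- order(refs)
  all_cv <- unlist(lapply(windows, `[[`, "cv"))
  breaks <- seq(floor(min(all_cv) / bin_width) * bin_width,
                ceiling(max(all_cv) / bin_width) * bin_width, by = bin_width)
  nb <- length(breaks) - 1L
  H <- vapply(windows, function(w) {
    h <- tabulate(pmin(pmax(findInterval(w$cv, breaks,
                                         rightmost.closed = TRUE), 1L), nb),
                  nbins = nb)
    h / sum(h)
  }, numeric(nb))
  data.frame(
    ref_lo = refs[ord][-length(ord)],
    ref_hi = refs[ord][-1],
    overlap = vapply(seq_len(length(ord) - 1), function(i)
      sum(pmin(H[, ord[i]], H[, ord[i + 1]])), numeric(1)))
}

#' Write a PMF profile as CSV (+ JSON convergence metadata)
#'
#' @param pmf A `pmf_profile`.
#' @param path CSV output path; metadata goes to `<path>.json`.
#' @return Invisibly, the paths written.
#' @export
write_pmf_csv <- function(pmf, path) {
  stopifnot(inherits(pmf, "pmf_profile"))
  df <- data.frame(delta_twist_per_bp = pmf$delta_twist_per_bp,
                   free_energy_kcal_mol = pmf$free_energy,
                   n_samples = pmf$n_samples)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(bin_width = attr(pmf, "bin_width"),
               relaxed_mean = attr(pmf, "relaxed_mean"),
               n_region_steps = attr(pmf, "n_region_steps"),
               temperature = attr(pmf, "temperature"),
               iterations = attr(pmf, "iterations"),
               final_change = attr(pmf, "final_change"),
               shifts = attr(pmf, "shifts"))
  jp <- paste0(path, ".json")
  jsonlite::write_json(meta, jp, auto_unbox = TRUE, digits = NA)
  invisible(c(path, jp))
}
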