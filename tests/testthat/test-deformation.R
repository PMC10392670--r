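random_spd <- function(d, scale = 1) {
  A <- matrix(stats::rnorm(d * d), d)
  crossprod(A) / d * scale + diag(d) * 0.5
}

random_def_model <- function(n_steps, n_sub, d = 6, J = TRUE) {
  steps <- lapply(seq_len(n_steps), function(i)
    lapply(seq_len(n_sub), function(k)
      list(mean = stats::rnorm(d), stiffness = random_spd(d),
           epsilon = stats::runif(1, 0, 2))))
  coupl <- if (J) lapply(seq_len(n_steps - 1), function(i)
    matrix(stats::rnorm(n_sub^2, 0, 0.7), n_sub, n_sub)) else NULL
  deformation_model(steps, coupl)
}

## independent oracle: explicit enumeration over all substate chains
enumerate_energy <- function(x, model, method = "logsum") {
  kT <- kbt(model$temperature)
  Ks <- vapply(model$steps, length, integer(1))
  chains <- as.matrix(expand.grid(lapply(Ks, seq_len)))
  es <- apply(chains, 1, function(s) {
    e <- sum(vapply(seq_along(s), function(i) {
      st <- model$steps[[i]][[s[i]]]
      dlt <- x[i, ] - st$mean
      0.5 * sum(dlt * (st$stiffness %*% dlt)) + st$epsilon
    }, numeric(1)))
    if (length(s) > 1)
      e <- e + sum(vapply(seq_len(length(s) - 1), function(i)
        model$couplings[[i]][s[i], s[i + 1]], numeric(1)))
    e
  })
  if (method == "logsum") -kT * log(sum(exp(-es / kT))) else min(es)
}

test_that("single-substate energies reduce to the plain harmonic form", {
  set.seed(71)
  m <- random_def_model(5, 1, J = FALSE)
  mu <- t(vapply(m$steps, function(s) s[[1]]$mean, numeric(6)))
  expect_equal(snapshot_energy(mu, m), 0, tolerance = 1e-12)
  ## diagonal stiffness: energy is the quadratic sum
  FF <- diag(c(2, 3, 4, 0.1, 0.2, 0.3))
  md <- deformation_model(list(list(list(mean = rep(0, 6), stiffness = FF))))
  x <- matrix(c(0.5, -1, 0.2, 3, -2, 5), 1)
  expect_equal(snapshot_energy(x, md),
               0.5 * sum(diag(FF) * x^2), tolerance = 1e-12)
})

test_that("transfer matrix equals brute-force enumeration over substate chains", {
  set.seed(72)
  for (case in list(c(6, 2), c(8, 2), c(5, 3), c(8, 3), c(3, 2))) {
    m <- random_def_model(case[1], case[2])
    x <- matrix(stats::rnorm(case[1] * 6), case[1], 6)
    for (method in c("logsum", "min")) {
      got <- snapshot_energy(x, m, method = method, reference = "none")
      expect_equal(got, enumerate_energy(x, m, method), tolerance = 1e-10)
    }
  }
})

test_that("energies are invariant under substate relabelling and respect the J limit", {
  set.seed(73)
  m <- random_def_model(5, 3)
  x <- matrix(stats::rnorm(30), 5, 6)
  e0 <- snapshot_energy(x, m, reference = "none")
  ## permute substates of step 3 (and the adjacent coupling rows/columns)
  perm <- c(2, 3, 1)
  m2 <- m
  m2$steps[[3]] <- m$steps[[3]][perm]
  m2$couplings[[2]] <- m$couplings[[2]][, perm]
  m2$couplings[[3]] <- m$couplings[[3]][perm, ]
  expect_equal(snapshot_energy(x, m2, reference = "none"), e0,
               tolerance = 1e-10)
  ## large uniform off-diagonal J forbids switching: the Boltzmann sum
  ## approaches the best uniform-substate chain
  mu_model <- random_def_model(4, 2, J = FALSE)
  big <- deformation_model(mu_model$steps, couplings = 500)
  xx <- matrix(stats::rnorm(24), 4, 6)
  uniform_best <- min(vapply(1:2, function(k) {
    sum(vapply(1:4, function(i) {
      st <- mu_model$steps[[i]][[k]]
      dlt <- xx[i, ] - st$mean
      0.5 * sum(dlt * (st$stiffness %*% dlt)) + st$epsilon
    }, numeric(1)))
  }, numeric(1)))
  expect_equal(snapshot_energy(xx, big, reference = "none"), uniform_best,
               tolerance = 1e-6)
})

test_that("window averages satisfy equipartition and the degenerate case", {
  ## identical frames at the model minimum: mean 0, sd 0
  m <- default_model("GCGCAT", bimodal = FALSE)
  dm <- as_deformation_model(m)
  mu <- t(vapply(m$steps, function(s) s[[1]]$mean, numeric(6)))
  X <- array(rep(mu, each = 10), c(10, 5, 6))
  wd <- window_deformation(X, dm)
  expect_equal(wd$mean, 0, tolerance = 1e-10)
  expect_equal(wd$sd, 0, tolerance = 1e-10)
  ## unbiased ensemble: mean = dof/2 kT within 3 standard errors
  n <- 2e4
  ens <- sample_unbiased(m, n, seed = 74)
  wd2 <- window_deformation(ens, dm)
  dof <- 5 * 6
  se <- stats::sd(wd2$energies) / sqrt(n)
  expect_lt(abs(wd2$mean - dof / 2 * kbt(300)), 3 * se)
})

test_that("deformation energy rises from the relaxed window toward both extremes", {
  ## On the twist-capacitor model the response is nearly flat within
  ## +-2.5 deg/bp (substate switching absorbs the stress almost freely);
  ## the U-shape is asserted where it is statistically resolvable, with a
  ## non-inferiority guard on the inner windows.
  m <- default_model(SEQ23)
  region <- restrained_region(SEQ23, FRAG13)
  sch <- make_umbrella_schedule(model_mean_twist(m, region),
                                n_frames = 2e4)
  w <- run_umbrella(m, sch, region = region, seed = 75,
                    keep = "region_params")
  dm <- as_deformation_model(m, region)
  offsets <- vapply(w, `[[`, numeric(1), "offset_per_bp")
  probe <- c(-4.5, -2.5, 0, 2.5, 4.5)
  res <- lapply(probe, function(o)
    window_deformation(w[[which(offsets == o)]], dm))
  means <- stats::setNames(vapply(res, `[[`, numeric(1), "mean"),
                           as.character(probe))
  se <- max(vapply(res, function(r) r$sd / sqrt(r$n), numeric(1)))
  expect_gt(means[["-4.5"]], means[["0"]] + 3 * se)
  expect_gt(means[["4.5"]], means[["0"]] + 3 * se)
  expect_gt(means[["-4.5"]], means[["-2.5"]])
  expect_gt(means[["4.5"]], means[["2.5"]])
  expect_gt(means[["-2.5"]], means[["0"]] - 4 * se)
  expect_gt(means[["2.5"]], means[["0"]] - 4 * se)
})

test_that("parameter files round-trip through the JSON loader", {
  set.seed(76)
  FF <- random_spd(6)
  spec <- list(
    parameters = list(
      GC = list(mean = matrix(c(0, 0, 3.38, 0, 0, 34), 1),
                stiffness = list(FF), epsilon = 0),
      CA = list(mean = rbind(c(0, 0, 3.38, 0, 0, 24),
                             c(0, 0, 3.38, 0, 0, 44)),
                stiffness = list(FF, FF), epsilon = c(0, 0.5))),
    couplings = 0.3, temperature = 300)
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA)
  m <- read_deformation_params(path, "GCA")
  expect_equal(m$provenance, "user-supplied")
  expect_equal(length(m$steps), 2L)
  expect_equal(length(m$steps[[2]]), 2L)
  expect_equal(m$steps[[2]][[2]]$epsilon, 0.5)
  x <- rbind(c(0, 0, 3.38, 0, 0, 34), c(0, 0, 3.38, 0, 0, 24))
  expect_equal(snapshot_energy(x, m), enumerate_energy(x, m) -
                 dnatwist:::chain_ground_energy(m), tolerance = 1e-10)
  ## the bundled synthetic dimer-level set covers an arbitrary sequence
  shipped <- system.file("extdata", "synthetic_dimer_params.json",
                         package = "dnatwist")
  ms <- read_deformation_params(shipped, "GGCGAGTAGCACGTGCTACTCGC")
  expect_equal(length(ms$steps), 22L)
  expect_true(any(vapply(ms$steps, length, integer(1)) == 2L))
  mu22 <- t(vapply(ms$steps, function(s) s[[1]]$mean, numeric(6)))
  expect_true(all(is.finite(snapshot_energy(mu22, ms))))
})
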