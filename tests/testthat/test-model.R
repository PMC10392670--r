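test_that("default model assigns twist-capacitor substates to YpR steps", {
  m <- default_model(SEQ23)
  ns <- vapply(m$steps, length, integer(1))
  dimers <- names(m$steps)
  expect_equal(unname(ns > 1), dimers %in% c("TA", "TG", "CA", "CG"))
  ## the restrained fragment contains the E-box CA/CG/TG capacitors
  region <- restrained_region(SEQ23, FRAG13)
  expect_true(any(ns[region] > 1))
  ## substate twist means differ by exactly 20 degrees
  bi <- which(ns > 1)[1]
  tw <- vapply(m$steps[[bi]], function(s) s$mean[["twist"]], numeric(1))
  expect_equal(abs(diff(tw)), 20)
  ## two-base sequence: one step, one substate
  m2 <- default_model("GG")
  expect_equal(length(m2$steps), 1L)
  expect_equal(length(m2$steps[[1]]), 1L)
  expect_error(default_model("GNX"), "non-ACGT")
  ## non-positive-definite stiffness is rejected at validation
  expect_error(step_substate(rep(0, 6), diag(c(1, 1, 1, 1, 1, -1))),
               "positive definite")
})

test_that("unbiased sampling satisfies equipartition for a diagonal model", {
  FF <- diag(c(8, 6, 20, 0.1, 0.05, 0.08))
  mu <- c(0, 0, 3.38, 0, 0, 34.6)
  st <- list(list(step_substate(mu, FF)), list(step_substate(mu, FF)))
  m <- sequence_model("GCA", st)
  n <- 1e5
  e <- sample_unbiased(m, n, seed = 5)
  kT <- kbt(300)
  for (d in 1:6) {
    v <- stats::var(e$params[, 1, d])
    v_true <- kT / FF[d, d]
    se <- v_true * sqrt(2 / n)
    expect_lt(abs(v - v_true), 3 * se)
    expect_equal(mean(e$params[, 1, d]), mu[d],
                 tolerance = 5 * sqrt(v_true / n) + 1e-12)
  }
})

test_that("substate occupancies follow Boltzmann weights", {
  FF <- dnatwist:::default_stiffness(dnatwist:::DEFAULT_SD)
  mu1 <- c(0, 0, 3.38, 0, 0, 24.6)
  mu2 <- c(0, 0, 3.38, 0, 0, 44.6)
  mk <- function(e2) sequence_model("GCAT", list(
    list(step_substate(mu1, FF)),
    list(step_substate(mu1, FF, 0), step_substate(mu2, FF, e2)),
    list(step_substate(mu2, FF))))
  n <- 2e4
  ## equal intrinsic energies: 50/50 within binomial error
  e <- sample_unbiased(mk(0), n, seed = 6)
  p <- e$occupancy[1, 2]
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / n))
  ## delta eps = 1 kcal/mol: ratio exp(-beta * 1)
  e2 <- sample_unbiased(mk(1), n, seed = 7)
  p2 <- e2$occupancy[2, 2]
  p_true <- exp(-1 / kbt(300)) / (1 + exp(-1 / kbt(300)))
  expect_lt(abs(p2 - p_true), 3 * sqrt(p_true * (1 - p_true) / n))
})

test_that("coupled-label chain sampling matches exact Boltzmann probabilities", {
  ## two bimodal steps with J-coupling: empirical joint label frequencies
  ## against the exact transfer-matrix distribution
  FF <- dnatwist:::default_stiffness(dnatwist:::DEFAULT_SD)
  mu1 <- c(0, 0, 3.38, 0, 0, 24.6)
  mu2 <- c(0, 0, 3.38, 0, 0, 44.6)
  eps <- c(0, 0.3)
  J <- 0.8
  m <- sequence_model("TAG", list(
    list(step_substate(mu1, FF, eps[1]), step_substate(mu2, FF, eps[2])),
    list(step_substate(mu1, FF, eps[1]), step_substate(mu2, FF, eps[2]))),
    J = J)
  n <- 1e5
  e <- sample_unbiased(m, n, seed = 8)
  kT <- kbt(300)
  ## exact joint: w(s1,s2) propto exp(-beta(eps1+eps2+J[s1!=s2]))
  ## (equal stiffness: the Gaussian volume factors cancel)
  w <- outer(eps, eps, `+`) + J * (1 - diag(2))
  w <- exp(-w / kT); w <- w / sum(w)
  emp <- table(factor(e$labels[, 1], 1:2), factor(e$labels[, 2], 1:2)) / n
  for (a in 1:2) for (b in 1:2) {
    se <- sqrt(w[a, b] * (1 - w[a, b]) / n)
    expect_lt(abs(emp[a, b] - w[a, b]), 4 * se)
  }
})

test_that("analytic modulus matches the printed working examples and scaling", {
  m111 <- default_model(SEQ23, twist_sd = 3.171, bimodal = FALSE)
  expect_lt(abs(ground_truth_modulus(m111) - 111), 0.5)
  m168 <- default_model(SEQ23, twist_sd = 2.578, bimodal = FALSE)
  expect_lt(abs(ground_truth_modulus(m168) - 168), 0.5)
  ## halving the SD quadruples the modulus
  m_half <- default_model(SEQ23, twist_sd = 3.171 / 2, bimodal = FALSE)
  expect_equal(ground_truth_modulus(m_half) / ground_truth_modulus(m111), 4,
               tolerance = 1e-9)
  ## bimodal steps enter through the exact mixture variance
  mb <- default_model("GCAT", twist_sd = 3)
  comp <- dnatwist:::compile_model(mb)
  v_mix <- 3^2 + 10^2  # equal-weight substates +-10 deg around the mean
  v_eff <- (v_mix + 2 * 3^2) / 3
  expect_equal(ground_truth_modulus(mb),
               0.34 / (v_eff * (pi / 180)^2), tolerance = 1e-6)
  ## verified against a long unbiased simulation
  e <- sample_unbiased(m111, 5e4, seed = 9)
  v_sim <- mean(apply(e$params[, , "twist"], 2, stats::var))
  C_sim <- 0.34 / (v_sim * (pi / 180)^2)
  expect_lt(abs(C_sim - 111) / 111, 0.05)
  ## coupled labels refuse the analytic path
  mJ <- default_model("GCAT", J = 1)
  expect_error(ground_truth_modulus(mJ), "J = 0")
})

test_that("sampling is reproducible for a fixed seed", {
  m <- default_model("GTACGT")
  a <- sample_unbiased(m, 500, seed = 77)
  b <- sample_unbiased(m, 500, seed = 77)
  expect_identical(a$params, b$params)
  expect_identical(a$labels, b$labels)
  c_ <- sample_unbiased(m, 500, seed = 78)
  expect_false(identical(a$params, c_$params))
})
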