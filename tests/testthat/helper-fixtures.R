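## Shared helpers: random rigid frames, a quaternion-based random rotation,
## and memoized expensive fixtures (umbrella runs reused across test files).

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  matrix(c(
    1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] + q[1] * q[4]),
    2 * (q[2] * q[4] - q[1] * q[3]),
    2 * (q[2] * q[3] - q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
    2 * (q[3] * q[4] + q[1] * q[2]),
    2 * (q[2] * q[4] + q[1] * q[3]), 2 * (q[3] * q[4] - q[1] * q[2]),
    1 - 2 * (q[2]^2 + q[3]^2)), 3, 3)
}

random_frame <- function(spread = 5) {
  base_frame(stats::rnorm(3, 0, spread), random_rotation())
}

## Rotation about an arbitrary axis, degrees (independent re-implementation
## used as the matrix oracle in bending tests).
oracle_rotation <- function(axis, theta_deg) {
  th <- theta_deg * pi / 180
  n <- axis / sqrt(sum(axis^2))
  ct <- cos(th); st <- sin(th)
  K <- matrix(c(0, n[3], -n[2], -n[3], 0, n[1], n[2], -n[1], 0), 3, 3)
  diag(3) * ct + st * K + (1 - ct) * tcrossprod(n)
}

SEQ23 <- "GGCGAGTAGCACGTGCTACTCGC"
FRAG13 <- "GTAGCACGTGCTAC"

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

## A moderately sampled unimodal umbrella run shared by the WHAM and
## elasticity tests (per-step twist SD 3.171 deg -> 111 nm ground truth).
unimodal_run_fixture <- function() {
  fixture("unimodal_run", function() {
    model <- default_model(SEQ23, mean_twist = 34.6, twist_sd = 3.171,
                           bimodal = FALSE)
    region <- restrained_region(SEQ23, FRAG13)
    schedule <- make_umbrella_schedule(model_mean_twist(model, region),
                                       n_frames = 2e4)
    list(model = model, region = region, schedule = schedule,
         windows = run_umbrella(model, schedule, region = region,
                                seed = 42, keep = "cv"))
  })
}
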