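test_that("initial profile has the closed-form mass and calibrated quantile", {
  prof <- initial_profile(initial_profile_spec(1 / 1.065))
  st <- prof$support  # sigma_tilde = 1
  expect_equal(st, 1, tolerance = 1e-12)
  expect_equal(prof$density(st), 0)
  expect_equal(profile_total_mass(prof), 4 * pi * (1 / 3 - 1 / 16),
               tolerance = 1e-12)
  # the 95% quantile radius sits close to sigma_i for the default c, q
  for (si in c(0.264, 0.403, 0.733)) {
    prof <- initial_profile(initial_profile_spec(si))
    q <- profile_quantile_radius(prof, 0.95)
    expect_gt(q, 0.95 * si)
    expect_lt(q, 1.05 * si)
  }
})

test_that("discrete quantile radius follows the strict-threshold convention", {
  # single atom holds all mass at any quantile
  s <- particle_state(c(0, 1, 0, 0), R0 = 2)
  expect_equal(quantile_radius(s, 0.5), 1)
  expect_equal(quantile_radius(s, 0.95), 1)
  # 20 equal atoms at i/20: at the exact tie (cumulative mass at atom 19
  # equals 0.95 of the total, not exceeding it) the strict inf moves to the
  # next atom; just below the tie it returns atom 19
  s20 <- particle_state(rep(1, 20), R0 = 1)
  expect_equal(quantile_radius(s20, 0.95), 1)
  expect_equal(quantile_radius(s20, 0.949), 19 / 20)
  # brute-force cumulative sum agrees on random masses
  set.seed(5)
  for (k in 1:10) {
    m <- rexp(30)
    st <- particle_state(m, R0 = 3)
    i <- which(cumsum(m) > 0.95 * sum(m))[1]
    expect_equal(quantile_radius(st), st$locations[i])
  }
  expect_error(quantile_radius(particle_state(rep(0, 5), 1)), "zero total")
})

test_that("Laplace-smoothed radius stays within a grid cell of the plain one", {
  p <- v79_params()
  N <- 1000; R0 <- 2
  st <- init_masses(small_profile(0.403), N, R0)
  traj <- evolve(st, p, c(0, 5))
  s5 <- state_at(traj, 2)
  r_plain <- quantile_radius(s5)
  r_smooth <- quantile_radius(s5, smoothing_eps = R0 / (4 * N))
  expect_lt(abs(r_plain - r_smooth), R0 / N)
})

test_that("log likelihood matches closed forms and is scale invariant", {
  r <- c(0.5, 1, 2)
  # zero residuals
  expect_equal(log_likelihood(r, r, sigma_o = 0.3),
               3 * (-log(sqrt(2 * pi) * 0.3)))
  # one residual of exactly 1 in log space at sigma_o = 1
  expect_equal(log_likelihood(exp(1) * 2, 2, sigma_o = 1),
               -log(sqrt(2 * pi)) - 0.5)
  # common rescaling leaves the likelihood unchanged
  obs <- c(0.4, 0.9, 1.7)
  expect_equal(log_likelihood(obs, r, 0.2), log_likelihood(3 * obs, 3 * r, 0.2))
  expect_error(log_likelihood(c(-1, 1, 1), r, 0.2), "positive")
  expect_error(log_likelihood(obs, r, 0), "positive")
})

test_that("log likelihood peaks at the RMS log residual over sigma_o", {
  set.seed(8)
  obs <- exp(rnorm(10, 0, 0.2))
  mod <- rep(1, 10)
  resid <- log(obs)
  s_hat <- sqrt(mean(resid^2))
  f <- function(s) log_likelihood(obs, mod, s)
  expect_gt(f(s_hat), f(s_hat * 1.05))
  expect_gt(f(s_hat), f(s_hat * 0.95))
  # and diverges to -Inf as sigma_o -> 0 with nonzero residuals
  expect_lt(f(1e-4), f(0.01))
  expect_lt(f(0.01), f(s_hat))
})

test_that("growth CSV round-trips and halves diameters on ingest", {
  ds <- growth_dataset(c(0, 2, 4), c(0.4, 0.5, 0.62), cell_line = "V-79",
                       sd_mm = c(0.02, 0.03, 0.02))
  path <- withr::local_tempfile(fileext = ".csv")
  write_growth_csv(ds, path)            # writes diameter_mm
  back <- read_growth_csv(path)
  expect_equal(back$radii, ds$radii)
  expect_equal(back$times, ds$times)
  expect_equal(back$cell_line, "V-79")
  expect_equal(back$sd_mm, ds$sd_mm)
  write_growth_csv(ds, path, as_diameter = FALSE)
  expect_equal(read_growth_csv(path)$radii, ds$radii)
})

test_that("growth dataset validates its invariants", {
  expect_error(growth_dataset(c(0, 0), c(1, 1)), "increasing")
  expect_error(growth_dataset(c(0, 1), c(1, -1)), "positive")
  expect_error(growth_dataset(-1, 1), "nonnegative")
})

test_that("quantile radius is nondecreasing along solved trajectories", {
  set.seed(11)
  for (k in 1:5) {
    p <- model_params(runif(1, 0.5, 1.5), runif(1, 0.04, 0.09), 0.05,
                      runif(1, 0.25, 0.45))
    st <- init_masses(small_profile(p$sigma_i), 200,
                      default_R0(p$sigma_i, p$sigma_k, 1))
    traj <- evolve(st, p, seq(0, 10, 1))
    expect_true(all(diff(radius_trajectory(traj)) >= 0))
  }
})

test_that("radius differences across resolutions obey the Lipschitz-type bound", {
  # |G(mu) - G(nu)| <= C (2 R0 + 1) ||(mu - nu)/r||_BL* + exp(-R0/2) with a
  # single constant C across parameter draws
  set.seed(12)
  R0 <- 2
  ratios <- c()
  for (k in 1:5) {
    p <- model_params(runif(1, 0.5, 1.5), runif(1, 0.04, 0.09), 0.05,
                      runif(1, 0.25, 0.45))
    prof <- small_profile(p$sigma_i)
    states <- lapply(c(250, 500, 1000), function(N)
      state_at(evolve(init_masses(prof, N, R0), p, c(0, 5)), 2))
    for (i in 1:2) {
      dr <- abs(quantile_radius(states[[i]]) - quantile_radius(states[[i + 1]]))
      w <- flat_norm(states[[i]], states[[i + 1]], weight = "1/r")
      ratios <- c(ratios, (dr - exp(-R0 / 2)) / ((2 * R0 + 1) * w))
    }
  }
  expect_true(all(is.finite(ratios)))
  expect_lt(max(ratios), 10)  # one moderate constant covers all draws
})
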