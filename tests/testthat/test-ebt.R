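test_that("mass initialization reproduces closed-form cell integrals", {
  # sigma_tilde = 1, q = 13: total mass 4 pi (1/3 - 1/16)
  prof <- initial_profile(initial_profile_spec(1 / 1.065, c = 1.065, q = 13))
  st1 <- init_masses(prof, 2, 1)
  expect_equal(sum(st1$masses), 4 * pi * (1 / 3 - 1 / 16), tolerance = 1e-12)
  # zero profile
  zero <- radial_profile(function(r) 0 * r, support = 1)
  expect_equal(init_masses(zero, 10, 1)$masses, rep(0, 10))
  # telescoping: totals agree across N
  for (N in c(7, 64, 333))
    expect_equal(sum(init_masses(prof, N, 1)$masses),
                 sum(st1$masses), tolerance = 1e-10)
  # quadrature path (no closed form) agrees with the antiderivative path
  prof_q <- radial_profile(prof$density, prof$support)
  expect_equal(init_masses(prof_q, 50, 1)$masses,
               init_masses(prof, 50, 1)$masses, tolerance = 1e-9)
  neg <- radial_profile(function(r) -r, support = 1)
  expect_error(init_masses(neg, 10, 1), "negative")
})

test_that("initial masses respect the particle caps", {
  st <- init_masses(small_profile(), 200, 1)
  expect_true(all(st$masses <= particle_caps(st) * (1 + 1e-12)))
})

test_that("mass rates vanish for empty states and at the cap", {
  p <- v79_params()
  st0 <- particle_state(rep(0, 20), 1)
  expect_equal(ebt_rhs(st0, p), rep(0, 20))
  caps <- particle_caps(particle_state(rep(1, 20), 1))
  st_cap <- particle_state(caps, 1)
  expect_equal(max(abs(ebt_rhs(st_cap, p))), 0, tolerance = 1e-12)
})

test_that("mass rates match a hand-evaluated two-particle system", {
  p <- model_params(1.3, 0.5, 0.05, 0.4)
  R0 <- 1; N <- 2
  x <- c(0.5, 1)
  m <- c(0.1, 0.2)
  st <- particle_state(m, R0)
  L11 <- interaction_L(x[1], x[1], p$alpha, p$sigma_k)
  L12 <- interaction_L(x[1], x[2], p$alpha, p$sigma_k)
  L22 <- interaction_L(x[2], x[2], p$alpha, p$sigma_k)
  caps <- 4 * pi * x^2 * R0 / N
  expected <- c((caps[1] - m[1]) * (L11 * m[1] + L12 * m[2]),
                (caps[2] - m[2]) * (L12 * m[1] + L22 * m[2]))
  expect_equal(ebt_rhs(st, p), expected, tolerance = 1e-12)
})

test_that("compiled banded interaction matrix equals the dense R version", {
  for (cfg in list(c(N = 50, R0 = 1, a = 1.3, sk = 0.06),
                   c(N = 80, R0 = 2, a = 0.7, sk = 0.4))) {
    N <- cfg[["N"]]; R0 <- cfg[["R0"]]
    bd <- ebtgrowth:::.interaction_band_cpp(N, R0, cfg[["a"]], cfg[["sk"]])
    dense <- interaction_matrix(N, R0, cfg[["a"]], cfg[["sk"]])
    b <- bd$halfwidth
    rebuilt <- matrix(0, N, N)
    for (j in 1:N) {
      i0 <- max(1, j - b); i1 <- min(N, j + b)
      rebuilt[i0:i1, j] <- bd$band[(i0:i1) - j + b + 1, j]
    }
    expect_equal(rebuilt, dense, tolerance = 1e-13)
  }
})

test_that("evolution matches an independent ODE solver on a small system", {
  skip_if_not_installed("deSolve")
  p <- model_params(1.2, 0.3, 0.05, 0.4)
  st <- init_masses(small_profile(0.4), 40, 1.2)
  t_grid <- c(0, 0.5, 1, 2)
  traj <- evolve(st, p, t_grid)
  L <- interaction_matrix(40, 1.2, p$alpha, p$sigma_k)
  caps <- particle_caps(st)
  ref <- deSolve::ode(y = st$masses, times = t_grid,
                      func = function(t, m, parms)
                        list((caps - m) * as.numeric(L %*% m)),
                      rtol = 1e-10, atol = 1e-12)
  expect_equal(traj$masses[4, ], unname(ref[4, -1]), tolerance = 1e-6)
})

test_that("masses stay constant in the no-proliferation limit", {
  st <- init_masses(small_profile(), 100, 1)
  p <- model_params(1e-300, 0.06, 0.05, 0.264)  # effectively alpha = 0
  traj <- evolve(st, p, c(0, 5, 10))
  expect_equal(traj$masses[3, ], st$masses, tolerance = 1e-9)
})

test_that("evolution preserves nonnegativity, caps, and mass monotonicity", {
  set.seed(2)
  for (k in 1:20) {
    p <- model_params(runif(1, 0.3, 2), runif(1, 0.03, 0.1), 0.05,
                      runif(1, 0.2, 0.5))
    st <- init_masses(small_profile(p$sigma_i), 150,
                      default_R0(p$sigma_i, p$sigma_k))
    traj <- evolve(st, p, c(0, 2, 5))
    caps <- particle_caps(st)
    expect_true(all(traj$masses >= -1e-9 * max(caps)))
    expect_true(max(sweep(traj$masses, 2, caps, "/")) <= 1 + 1e-9)
    # below the cap all rates are nonnegative, so the radius cannot shrink
    r <- radius_trajectory(traj)
    expect_true(all(diff(r) >= 0))
  }
})

test_that("fixed-step RK4 runs are bit-identical", {
  p <- v79_params()
  st <- init_masses(small_profile(0.403), 100, 2)
  ctrl <- solver_control(method = "rk4", fixed_dt = 0.01)
  a <- evolve(st, p, c(0, 1, 3), ctrl)
  b <- evolve(st, p, c(0, 1, 3), ctrl)
  expect_identical(a$masses, b$masses)
})

test_that("tail mass stays negligible with the default truncation radius", {
  p <- v79_params()
  times <- seq(0, 20, 5)
  cfg <- forward_config(N = 300)
  r <- forward_radii(p, times, cfg)
  R0 <- default_R0(p$sigma_i, p$sigma_k, last_radius = max(r))
  st <- init_masses(small_profile(p$sigma_i), 300, R0)
  traj <- evolve(st, p, times)
  tail_frac <- vapply(seq_along(times), function(i) {
    m <- traj$masses[i, ]
    sum(m[traj$locations > 0.9 * R0]) / sum(m)
  }, numeric(1))
  expect_true(all(tail_frac < 1e-3))
})

test_that("evolve rejects invalid grids and oversized kernels", {
  p <- v79_params()
  st <- init_masses(small_profile(), 50, 1)
  expect_error(evolve(st, p, c(1, 2)), "start at")
  expect_error(evolve(st, p, c(0, 0)), "increasing")
  expect_error(evolve(st, model_params(1, 2, 0.05, 0.264), c(0, 1)),
               "truncation radius")
})

test_that("trajectory export is tidy", {
  p <- v79_params()
  st <- init_masses(small_profile(), 20, 1)
  traj <- evolve(st, p, c(0, 1))
  df <- as.data.frame(traj)
  expect_equal(nrow(df), 40)
  expect_named(df, c("time", "index", "location", "mass"))
  expect_equal(df$mass[df$time == 0], st$masses)
})
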