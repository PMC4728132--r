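test_that("periodic Laplacian is exact on its eigenfunctions and conservative", {
  N <- 48; L <- sqrt(25 * pi); h <- L / N
  expect_equal(periodic_laplacian(matrix(3.7, N, N), h),
               matrix(0, N, N))
  x <- (seq_len(N) - 1) * h
  f <- matrix(sin(2 * pi * x / L), N, N)   # varies along rows
  lap <- periodic_laplacian(f, h)
  # discrete symbol: -(2 - 2 cos(2 pi h / L)) / h^2 -> -(2 pi / L)^2 + O(h^2)
  expect_equal(lap, -(2 * pi / L)^2 * f, tolerance = 5e-3)
  set.seed(2)
  g <- matrix(runif(N * N), N, N)
  expect_lt(abs(sum(periodic_laplacian(g, h))), 1e-9)
  expect_error(periodic_laplacian(matrix(0, 4, 5), h), "square")
})

test_that("the stepper holds the homogeneous fixed point", {
  p <- default_parameters()
  ss <- homogeneous_steady_state(p, N = 32)
  cfg <- simulation_config(N = 32, dt = 0.02, T = 1, noise = FALSE)
  out <- step(ss, p, cfg, nsteps = 50)
  expect_lt(max(abs(out$fields - ss$fields)), 1e-10)
})

test_that("dt beyond the diffusion stability bound is rejected", {
  p <- model_parameters(Dm = 0.5)
  ss <- homogeneous_steady_state(p, N = 32)
  cfg <- simulation_config(N = 32, dt = 0.1, T = 1, noise = FALSE)
  expect_error(step(ss, p, cfg), "stability bound")
})

test_that("noise-free dynamics preserve the antipodal mirror symmetry", {
  p <- default_parameters()
  N <- 32
  ss <- homogeneous_steady_state(p, N = N)
  L <- ss$L
  st <- seed_perturbations(ss, list(c(L / 4, L / 4), c(3 * L / 4, 3 * L / 4)),
                           amplitude = 20, width = 0.7, params = p)
  cfg <- simulation_config(N = N, dt = 0.02, T = 60, noise = FALSE,
                           cadence = 20)
  tr <- simulate_trajectory(st, p, cfg)
  shift <- c((N / 2 + 1):N, 1:(N / 2))
  for (s2 in tr$states) {
    m <- membrane_cdc42(s2)
    expect_lt(max(abs(m - m[shift, shift])), 1e-9)
  }
})

test_that("trajectories are reproducible for a fixed seed and conserve mass with noise", {
  p <- default_parameters()
  ss <- homogeneous_steady_state(p, N = 32)
  cfg <- simulation_config(N = 32, dt = 0.02, T = 20, noise = TRUE,
                           cadence = 5)
  set.seed(99)
  tr1 <- simulate_trajectory(ss, p, cfg, keep_fields = FALSE)
  set.seed(99)
  tr2 <- simulate_trajectory(ss, p, cfg, keep_fields = FALSE)
  expect_identical(tr1$final$fields, tr2$final$fields)
  expect_identical(tr1$final$BemGEFc, tr2$final$BemGEFc)
  set.seed(100)
  tr3 <- simulate_trajectory(ss, p, cfg, keep_fields = FALSE)
  expect_false(identical(tr3$final$fields, tr1$final$fields))
  # noise exchange is mass-neutral: totals constant to rounding error
  s <- tr1$summary
  expect_lt(max(abs(s$total_cdc42 / s$total_cdc42[1] - 1)), 1e-12)
  expect_lt(max(abs(s$total_bemgef / s$total_bemgef[1] - 1)), 1e-12)
})

test_that("a zero-length run returns only the initial state", {
  p <- default_parameters()
  ss <- homogeneous_steady_state(p, N = 16)
  cfg <- simulation_config(N = 16, dt = 0.02, T = 0, noise = FALSE)
  tr <- simulate_trajectory(ss, p, cfg)
  expect_length(tr$states, 1L)
  expect_identical(tr$states[[1]], ss)
})

test_that("seeded perturbations are mass-neutral and localized", {
  p <- default_parameters()
  ss <- homogeneous_steady_state(p, N = 32)
  L <- ss$L
  expect_identical(seed_perturbations(ss, list(), params = p), ss)
  st <- seed_perturbations(ss, list(c(L / 4, L / 4), c(3 * L / 4, 3 * L / 4)),
                           amplitude = 20, width = 0.7, params = p)
  expect_equal(total_cdc42(st, p), total_cdc42(ss, p), tolerance = 1e-12)
  expect_equal(total_bemgef(st, p), total_bemgef(ss, p), tolerance = 1e-12)
  expect_error(seed_perturbations(ss, list(c(-1, 0)), params = p), "domain")
  # removing more cytosolic mass than available is refused
  expect_error(seed_perturbations(ss, list(c(L / 2, L / 2)),
                                  amplitude = 1e5, width = 2, params = p),
               "negative")
})

test_that("an unstable parameter set grows peaks from a noisy homogeneous start", {
  # with the predecessor GAP activity the homogeneous state sits inside a
  # Turing-unstable band (cross-checked against the dispersion relation),
  # so structure emerges from small random perturbations
  p <- model_parameters(k2b = 0.35)
  spec <- dispersion_relation_torus(p, q = 2 * pi * (1:8) / sqrt(p$area_A))
  expect_gt(max(spec$sigma), 0)
  st <- make_noisy_homogeneous_state(p, noise_amplitude = 0.002, seed = 5,
                                     N = 48)
  T0 <- homogeneous_steady_state(p, N = 8)$fields[1, 1, "Cdc42T"]
  cfg <- simulation_config(N = 48, dt = 0.02, T = 300, noise = FALSE,
                           cadence = 300)
  fin <- simulate_trajectory(st, p, cfg, keep_fields = FALSE)$final
  expect_gt(max(fin$fields[, , "Cdc42T"]), 5 * T0)
})

test_that("the single-peak profile converges under grid refinement", {
  p <- default_parameters()
  hgt <- vapply(c(48, 96), function(N) {
    ss <- homogeneous_steady_state(p, N = N)
    L <- ss$L
    st <- seed_perturbations(ss, list(c(L / 2, L / 2)), amplitude = 20,
                             width = 0.7, params = p)
    cfg <- simulation_config(N = N, dt = 0.015, T = 250, noise = FALSE,
                             cadence = 250)
    max(membrane_cdc42(simulate_trajectory(st, p, cfg,
                                           keep_fields = FALSE)$final))
  }, numeric(1))
  expect_lt(abs(hgt[2] / hgt[1] - 1), 0.05)
})

test_that("adaptive and plain Euler-Maruyama steppers agree at small dt", {
  p <- default_parameters()
  N <- 32
  ss <- homogeneous_steady_state(p, N = N)
  L <- ss$L
  st <- seed_perturbations(ss, list(c(L / 2, L / 2)), amplitude = 5,
                           width = 0.7, params = p)
  cfg_a <- simulation_config(N = N, dt = 0.002, T = 2, noise = FALSE,
                             stepper = "adaptive")
  cfg_e <- simulation_config(N = N, dt = 0.002, T = 2, noise = FALSE,
                             stepper = "euler")
  fa <- step(st, p, cfg_a, nsteps = 1000)
  fe <- step(st, p, cfg_e, nsteps = 1000)
  expect_equal(fa$fields, fe$fields, tolerance = 1e-4)
})

test_that("which peak wins is statistically even across seeds", {
  sides <- vapply(1:20, function(s) {
    if (s <= 10) fx_competition(s)$winner else fx_winner_side(s)
  }, integer(1))
  sides <- sides[!is.na(sides)]
  expect_gte(length(sides), 20)
  bt <- binom.test(sum(sides == 1L), length(sides))
  expect_gt(bt$p.value, 0.01)
})
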