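test_that("default parameters carry the published rate constants", {
  p <- default_parameters()
  expect_equal(p$k2b, 1.75)
  expect_equal(p$Dm, 0.0025)
  expect_equal(p$area_A, 25 * pi)
  expect_equal(p$eta, 0.01)
  expect_equal(p$total_cdc42, 1)
  expect_equal(p$total_bemgef, 0.017)
  expect_error(model_parameters(k2b = -1), "non-negative")
})

test_that("parameter config round-trips through a flat key-value file", {
  p <- model_parameters(k2b = 0.35, Dm = 0.01)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_parameters(p, f)
  q <- read_parameters(f)
  expect_equal(unclass(q), unclass(p))
  writeLines("bogus_key: 1", f)
  expect_error(read_parameters(f), "unknown parameter")
})

test_that("reaction rates implement the governing kinetics pointwise", {
  p <- default_parameters()
  # empty system is inert
  r0 <- reaction_rates(0, 0, 0, 0, 0, 0, p)
  expect_true(all(abs(unlist(r0)) == 0))
  # direct recruitment term k7 * BemGEFc * Cdc42T
  r <- reaction_rates(2, 0, 0, 0, 0, 0.01, p)
  expect_equal(r$BemGEF42, p$k7 * 0.01 * 2)
  expect_equal(r$BemGEF42, 0.2)
  expect_error(reaction_rates(-1, 0, 0, 0, 0, 0, p), "negative")
})

test_that("reaction rates match an independent term-by-term oracle on random states", {
  p <- default_parameters()
  oracle <- function(T, D, G, Bm, Dc, Bc) {
    list(Cdc42T = p$k2a * Bm * D + p$k3 * G * D - p$k2b * T -
           p$k4a * Bm * T - p$k7 * Bc * T + p$k4b * G,
         Cdc42Dm = p$k2b * T - p$k2a * Bm * D - p$k3 * G * D -
           p$k5b * D + p$k5a * Dc,
         BemGEF42 = p$k4a * Bm * T + p$k7 * Bc * T - p$k4b * G,
         BemGEFm = p$k1a * Bc - p$k1b * Bm + p$k4b * G - p$k4a * Bm * T)
  }
  set.seed(1)
  for (i in 1:20) {
    x <- runif(6, 0, 100)
    got <- reaction_rates(x[1], x[2], x[3], x[4], x[5], x[6], p)
    want <- oracle(x[1], x[2], x[3], x[4], x[5], x[6])
    expect_equal(got, want, tolerance = 1e-12)
  }
  # mass-action degree: doubling both partners of each bimolecular pair
  # quadruples only the bimolecular contributions
  x <- c(3, 7, 2, 5, 1, 0.4)
  g1 <- reaction_rates(x[1], x[2], x[3], x[4], x[5], x[6], p)$BemGEF42
  g2 <- reaction_rates(2 * x[1], x[2], x[3], 2 * x[4], x[5], 2 * x[6],
                       p)$BemGEF42
  bi <- p$k4a * x[4] * x[1] + p$k7 * x[6] * x[1]
  expect_equal(g2 - g1, 3 * bi - 0)  # linear term k4b*G unchanged
})

test_that("the reaction network conserves both totals algebraically", {
  p <- default_parameters()
  set.seed(7)
  for (i in 1:10) {
    x <- runif(6, 0, 200)
    r <- reaction_rates(x[1], x[2], x[3], x[4], x[5], x[6], p)
    dDc <- p$k5b * x[2] - p$k5a * x[5]
    dBc <- p$k1b * x[4] - p$k1a * x[6] - p$k7 * x[6] * x[1]
    expect_equal(r$Cdc42T + r$Cdc42Dm + r$BemGEF42 + dDc, 0,
                 tolerance = 1e-10)
    expect_equal(r$BemGEF42 + r$BemGEFm + dBc, 0, tolerance = 1e-10)
  }
})

test_that("totals follow the cytosol-equivalent convention", {
  p <- default_parameters()
  z <- array(0, dim = c(8, 8, 4))
  st <- full_state(z, Cdc42Dc = 1, BemGEFc = 0, params = p)
  expect_equal(total_cdc42(st, p), 1)
  expect_equal(total_bemgef(st, p), 0)
  st0 <- full_state(z, 0, 0, params = p)
  expect_equal(total_cdc42(st0, p), 0)
})

test_that("homogeneous steady state is a consistent fixed point", {
  p <- default_parameters()
  ss <- homogeneous_steady_state(p, N = 32)
  expect_equal(total_cdc42(ss, p), 1, tolerance = 1e-8)
  expect_equal(total_bemgef(ss, p), 0.017, tolerance = 1e-8)
  y <- ss$fields[1, 1, ]
  r <- reaction_rates(y[1], y[2], y[3], y[4], ss$Cdc42Dc, ss$BemGEFc, p)
  expect_lt(max(abs(unlist(r))), 1e-9)
  # stationary under time integration
  cfg <- simulation_config(N = 32, dt = 0.02, T = 100, noise = FALSE,
                           cadence = 100)
  out <- simulate_trajectory(ss, p, cfg, keep_fields = FALSE)$final
  expect_lt(max(abs(out$fields - ss$fields)), 1e-6)
  # zero totals give the empty state
  p0 <- model_parameters(total_cdc42 = 0, total_bemgef = 0)
  expect_equal(max(abs(homogeneous_steady_state(p0, N = 8)$fields)), 0)
})

test_that("analytic Jacobians match finite differences", {
  p <- default_parameters()
  y <- c(50, 30, 10, 2, 0.5, 0.01)
  f6 <- function(x) {
    r <- reaction_rates(x[1], x[2], x[3], x[4], x[5], x[6], p)
    rc <- polarcomp:::cytosol_rates_uniform(x[1], x[2], x[4], x[5], x[6], p)
    c(r$Cdc42T, r$Cdc42Dm, r$BemGEF42, r$BemGEFm, rc[1], rc[2])
  }
  Jn <- vapply(1:6, function(j) {
    e <- rep(0, 6); e[j] <- 1e-6
    (f6(y + e) - f6(y - e)) / 2e-6
  }, numeric(6))
  dimnames(Jn) <- NULL
  expect_equal(unname(reaction_jacobian_full(y, p)), Jn, tolerance = 1e-6)
})
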