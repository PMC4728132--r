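test_that("peak detection finds seeded maxima and ignores flat fields", {
  N <- 64; h <- sqrt(25 * pi) / N; L <- N * h
  expect_equal(nrow(detect_peaks(matrix(1, N, N), h, min_height = 2)), 0L)
  ctrs <- list(c(L / 4, L / 4), c(3 * L / 4, 3 * L / 4))
  f <- make_gaussian_field(N, h, ctrs, amplitude = 100, sigma = 0.5)
  pk <- detect_peaks(f, h, min_height = 10, min_separation = 1)
  expect_equal(nrow(pk), 2L)
  for (ct in ctrs) {
    d <- min(polarcomp:::periodic_dist(pk$x, pk$y, ct[1], ct[2], L))
    expect_lte(d, h * sqrt(2))
  }
  f1 <- make_gaussian_field(N, h, list(c(L / 3, L / 5)), 50, 0.4)
  pk1 <- detect_peaks(f1, h, 10)
  expect_equal(nrow(pk1), 1L)
  expect_lt(polarcomp:::periodic_dist(pk1$x, pk1$y, L / 3, L / 5, L),
            h * sqrt(2))
})

test_that("waistline radius reproduces the Gaussian half-width", {
  N <- 128; h <- sqrt(25 * pi) / N; L <- N * h
  sig <- 0.5
  f <- make_gaussian_field(N, h, list(c(L / 2, L / 2)), 100, sig)
  pk <- detect_peaks(f, h, 10)
  w <- waistline(f, pk[1, ], h)
  expect_equal(w, sig * sqrt(2 * log(2)), tolerance = 0.01)
  # half-maximal is scale-free
  w2 <- waistline(2 * f, pk[1, ], h)
  expect_equal(w2, w, tolerance = 1e-10)
  # broader peak, larger waistline
  fb <- make_gaussian_field(N, h, list(c(L / 2, L / 2)), 100, 0.8)
  expect_gt(waistline(fb, detect_peaks(fb, h, 10)[1, ], h), w)
  # a peak that never falls to half-maximum is an error
  expect_error(waistline(make_gaussian_field(N, h, list(c(L / 2, L / 2)),
                                             100, 10, baseline = 60),
                         pk[1, ], h), "half-max")
})

test_that("diffusive waistline flux matches the analytic Gaussian value", {
  p <- default_parameters()
  N <- 128; h <- sqrt(25 * pi) / N; L <- N * h
  sig <- 0.5; A <- 100
  f <- make_gaussian_field(N, h, list(c(L / 2, L / 2)), A, sig)
  pk <- detect_peaks(f, h, 10)
  res <- diffusive_flux_across_waistline(f, pk[1, ], h, p$Dm)
  # closed form at r = sigma sqrt(2 ln 2): flux = Dm 2 pi ln2 A,
  # content = pi sigma^2 A, loss = 100 Dm 2 ln2 / sigma^2
  expect_equal(res$flux, p$Dm * 2 * pi * log(2) * A, tolerance = 0.02)
  expect_equal(res$loss_pct, 100 * p$Dm * 2 * log(2) / sig^2,
               tolerance = 0.02)
  # radially constant field has no diffusive flux
  fc <- matrix(5, N, N)
  resc <- diffusive_flux_across_waistline(fc, list(x = L / 2, y = L / 2),
                                          h, p$Dm, radius = 1)
  expect_equal(resc$flux, 0, tolerance = 1e-9)
})

test_that("cytoplasmic recruitment flux vanishes at detailed balance", {
  p <- default_parameters()
  N <- 32
  ss <- homogeneous_steady_state(p, N = N)
  f <- ss$fields
  # empty disc
  f0 <- f; f0[, , "Cdc42Dm"] <- 0
  st0 <- full_state(f0, 0, ss$BemGEFc, params = p)
  expect_equal(cytoplasmic_flux_within_waistline(
    st0, list(x = ss$L / 2, y = ss$L / 2), p, radius = 1), 0)
  # uniform field with k5b Cdc42Dm = k5a Cdc42Dc
  fb <- f; fb[, , "Cdc42Dm"] <- p$k5a * 0.5 / p$k5b
  stb <- full_state(fb, 0.5, ss$BemGEFc, params = p)
  expect_equal(cytoplasmic_flux_within_waistline(
    stb, list(x = ss$L / 2, y = ss$L / 2), p, radius = 1), 0,
    tolerance = 1e-9)
})

test_that("recruitment and diffusive loss balance at both steady states", {
  p <- default_parameters()
  for (st in list(fx_two_peak(), fx_competition(101, TRUE)$final)) {
    field <- membrane_cdc42(st)
    pks <- detect_peaks(field, st$h, min_height = 2 * fx_homog_membrane(),
                        min_separation = 2)
    expect_gte(nrow(pks), 1L)
    for (k in seq_len(nrow(pks))) {
      w <- waistline(field, pks[k, ], st$h)
      dfl <- diffusive_flux_across_waistline(field, pks[k, ], st$h, p$Dm, w)
      cfl <- cytoplasmic_flux_within_waistline(st, pks[k, ], p, w)
      expect_lt(abs(cfl - dfl$flux) / max(abs(dfl$flux), abs(cfl)), 0.05)
    }
  }
})

test_that("during competition the smaller peak loses proportionally faster", {
  p <- default_parameters()
  cr <- fx_competition(101, TRUE)
  m0 <- fx_homog_membrane()
  checked <- 0L
  for (st in cr$states) {
    field <- membrane_cdc42(st)
    pks <- detect_peaks(field, st$h, min_height = 2 * m0,
                        min_separation = 2)
    if (nrow(pks) != 2L) next
    res <- lapply(1:2, function(k) {
      w <- tryCatch(waistline(field, pks[k, ], st$h),
                    error = function(e) NULL)
      if (is.null(w)) return(NULL)
      diffusive_flux_across_waistline(field, pks[k, ], st$h, p$Dm, w)
    })
    if (any(vapply(res, is.null, logical(1)))) next
    if (abs(res[[1]]$content / res[[2]]$content - 1) < 0.1) next
    small <- which.min(c(res[[1]]$content, res[[2]]$content))
    expect_gt(res[[small]]$loss_pct, res[[3 - small]]$loss_pct)
    checked <- checked + 1L
  }
  expect_gte(checked, 3L)
})

test_that("the rate-balance curve has the two-intersection structure", {
  p <- default_parameters()
  cr <- fx_competition(101, TRUE)
  states <- c(list(cr$two_peak_state), cr$states)
  rb <- rate_balance_curve(states, p)
  bp <- attr(rb, "balance_points")
  # a balance point at the winner's final content and one at the two-peak
  # content (each two-peak-state peak holds about half the winner's load)
  expect_true(any(abs(bp - 1) < 0.05))
  two_norm <- min(bp[bp > 0.2])
  expect_true(two_norm > 0.3 && two_norm < 0.8)
  d <- rb$recruit_flux - rb$diff_flux
  below <- rb$norm_content < two_norm - 0.1 & rb$norm_content > 0.15
  above <- rb$norm_content > two_norm + 0.1 & rb$norm_content < 0.9
  expect_gte(sum(below), 2L)
  expect_gte(sum(above), 2L)
  expect_true(all(d[below] < 0))   # shrinking branch
  expect_true(all(d[above] > 0))   # growing branch
})

test_that("an empty trajectory yields an empty rate-balance table", {
  p <- default_parameters()
  ss <- homogeneous_steady_state(p, N = 16)
  rb <- rate_balance_curve(list(ss), p)
  expect_equal(nrow(rb), 0L)
})

test_that("competition runs resolve to a stable single peak with sensible phases", {
  p <- default_parameters()
  cr <- fx_competition(101, TRUE)
  expect_false(cr$censored)
  expect_true(cr$winner %in% 1:2)
  last <- cr$series[nrow(cr$series), ]
  expect_equal(last$n_peaks, 1L)
  expect_equal(cr$growth_duration + cr$competition_duration,
               cr$coexistence_time)
  # loser content is non-increasing once the gap exceeds 10%
  loser <- 3L - cr$winner
  s <- cr$series
  lc <- s[[paste0("content", loser)]]
  wc <- s[[paste0("content", cr$winner)]]
  gap <- !is.na(lc) & !is.na(wc) & (wc - lc) > 0.1 * wc
  if (any(gap)) {
    idx <- which(gap)[1]:max(which(!is.na(lc)))
    expect_true(all(diff(lc[idx][!is.na(lc[idx])]) < 1e-6))
  }
  # the resolved single-peak state is stationary: 300 s more of noisy
  # integration changes the winner's content by < 2%
  st <- cr$final
  field <- membrane_cdc42(st)
  pk <- detect_peaks(field, st$h, 2 * fx_homog_membrane())[1, ]
  w <- waistline(field, pk, st$h)
  c0 <- peak_content(field, pk, st$h, w)
  cfg <- simulation_config(N = st$N, dt = 0.02, T = 300, noise = TRUE,
                           cadence = 300)
  set.seed(77)
  st2 <- step(st, p, cfg, nsteps = round(300 / 0.02))
  f2 <- membrane_cdc42(st2)
  pk2 <- detect_peaks(f2, st2$h, 2 * fx_homog_membrane())[1, ]
  c2 <- peak_content(f2, pk2, st2$h, waistline(f2, pk2, st2$h))
  expect_lt(abs(c2 / c0 - 1), 0.02)
})
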