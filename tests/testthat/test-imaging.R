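gauss_frame <- function(n, ctrs, amps, sigma, background = 10) {
  img <- matrix(background, n, n)
  for (k in seq_along(ctrs))
    img <- img + amps[k] *
      exp(-outer((seq_len(n) - ctrs[[k]][2])^2,
                 (seq_len(n) - ctrs[[k]][1])^2, "+") / (2 * sigma^2))
  img
}

test_that("spot segmentation applies both thresholds and the size filter", {
  expect_equal(nrow(segment_spots(matrix(1, 32, 32), 5, 20)), 0L)
  img <- gauss_frame(64, list(c(20, 20), c(45, 40)), c(100, 80), 1.5)
  img[10, 55] <- 200   # single-pixel speckle, below the size filter
  sp <- segment_spots(img, cell_threshold = 12, spot_threshold = 30,
                      filter_size_px2 = 4)
  expect_equal(nrow(sp), 2L)
  d1 <- min(sqrt((sp$x - 20)^2 + (sp$y - 20)^2))
  d2 <- min(sqrt((sp$x - 45)^2 + (sp$y - 40)^2))
  expect_lt(d1, 0.5)
  expect_lt(d2, 0.5)
  expect_error(segment_spots(img, 30, 12), "spot_threshold")
})

test_that("greedy nearest-neighbor tracking follows spots and honors blink bridging", {
  frames <- lapply(1:20, function(f)
    segment_spots(gauss_frame(48, list(c(24, 24)), 100, 1.5), 12, 30))
  trk <- track_spots(frames, target_radius_px = 4)
  expect_length(trk, 1L)
  expect_equal(nrow(trk[[1]]), 20L)

  # scripted 2-frame blink
  blink <- lapply(1:12, function(f) {
    if (f %in% c(6, 7)) return(segment_spots(matrix(10, 48, 48), 5, 30))
    segment_spots(gauss_frame(48, list(c(24, 24)), 100, 1.5), 12, 30)
  })
  on <- track_spots(blink, 4, remove_blinking = TRUE, max_gap = 2)
  off <- track_spots(blink, 4, remove_blinking = FALSE)
  expect_length(on, 1L)
  expect_length(off, 2L)

  # two well-separated spots never swap identity
  two <- lapply(1:15, function(f)
    segment_spots(gauss_frame(64, list(c(15 + 0.3 * f, 15),
                                       c(50, 50 - 0.3 * f)),
                              c(100, 90), 1.5), 12, 30))
  tt <- track_spots(two, target_radius_px = 5)
  expect_length(tt, 2L)
  for (tr in tt) {
    expect_equal(nrow(tr), 15L)
    expect_lt(max(abs(diff(tr$x))), 1)   # smooth path, no jumps
    expect_lt(max(abs(diff(tr$y))), 1)
  }
})

test_that("vicinity traces are background-corrected and normalizable", {
  # uniform image: trace = value - background (per-frame fallback median)
  dat <- array(7, dim = c(32, 32, 1, 5))
  stk <- image_stack(dat, frame_interval = 45)
  track <- data.frame(frame = 1:5, x = 16, y = 16, area = 9,
                      intensity_sum = 100)
  attr(track, "birth") <- 1L
  tr <- vicinity_trace(stk, track, radius_px = 4)
  expect_equal(unname(tr$ch1), rep(0, 5))   # median fallback equals value

  # scripted linear ramp with a pre-detection background frame
  n <- 48
  dat2 <- array(10, dim = c(n, n, 1, 8))
  for (f in 2:8)
    dat2[, , 1, f] <- gauss_frame(n, list(c(24, 24)), 20 * (f - 1), 1.5)
  stk2 <- image_stack(dat2, 45)
  track2 <- data.frame(frame = 2:8, x = 24, y = 24, area = 9,
                       intensity_sum = 1)
  attr(track2, "birth") <- 2L
  tr2 <- vicinity_trace(stk2, track2, radius_px = 3, normalize = TRUE)
  ramp <- tr2$ch1[2:8]
  expect_true(all(diff(ramp) > 0))
  expect_equal(ramp[7], 100)

  # channel 2 delayed by k frames crosses half-maximum k frames later
  k <- 3
  dat3 <- array(10, dim = c(n, n, 2, 12))
  for (f in 1:12) {
    a <- 100 / (1 + exp(-(f - 5)))
    dat3[, , 1, f] <- gauss_frame(n, list(c(24, 24)), a, 1.5)
    a2 <- 100 / (1 + exp(-((f - k) - 5)))
    dat3[, , 2, f] <- gauss_frame(n, list(c(24, 24)), a2, 1.5)
  }
  stk3 <- image_stack(dat3, 45)
  track3 <- data.frame(frame = 1:12, x = 24, y = 24, area = 9,
                       intensity_sum = 1)
  attr(track3, "birth") <- 1L
  tr3 <- vicinity_trace(stk3, track3, radius_px = 3, normalize = TRUE)
  cross <- function(v) which(v >= 50)[1]
  expect_equal(cross(tr3$ch2) - cross(tr3$ch1), k)
})

test_that("coexistence time follows the frame-count definition", {
  # first multi-spot frame is 2, first single-spot frame after it is 5:
  # three frame intervals
  cx <- coexistence_time(c(1, 2, 2, 2, 1, 1), 45)
  expect_equal(cx$time, 135)
  expect_equal(cx$status, "resolved")
  expect_equal(coexistence_time(c(1, 1, 1), 45)$status, "none")
  expect_equal(coexistence_time(c(2, 2, 2), 45)$status, "censored")
})

test_that("FLIP normalization matches the printed formula and is affine-invariant", {
  expect_equal(as.numeric(flip_normalize(100, 90, 10)), 1.125)
  v <- flip_normalize(c(50, 40), c(50, 40), c(10, 10))
  expect_equal(as.numeric(v), c(1, 1))
  # whole-stack affine rescaling a*x + b cancels in the ratio
  f <- c(100, 80, 60); nb <- c(90, 85, 80); b <- c(10, 10, 10)
  r1 <- as.numeric(flip_normalize(f, nb, b))
  r2 <- as.numeric(flip_normalize(3 * f + 7, 3 * nb + 7, 3 * b + 7))
  expect_equal(r1, r2)
  flagged <- flip_normalize(c(50, 50), c(40, 5), c(10, 10))
  expect_equal(attr(flagged, "flagged"), 2L)
  expect_true(is.na(flagged[2]))
})

test_that("FLIP traces from a known exchange rate return that rate", {
  fl <- make_flip_traces(0.2, noise_sd = 0.3, seed = 4)
  nrm <- flip_normalize(fl$I_focus, fl$I_neighbor, fl$I_background)
  fit <- lm(log(nrm) ~ fl$times)
  expect_lt(abs(-coef(fit)[2] / 0.2 - 1), 0.1)
  # no exchange: flat normalized trace
  fl0 <- make_flip_traces(0, noise_sd = 0)
  nrm0 <- flip_normalize(fl0$I_focus, fl0$I_neighbor, fl0$I_background)
  expect_lt(max(abs(nrm0 / nrm0[1] - 1)), 1e-9)
})

test_that("FRAP half-times are recovered from double-exponential traces", {
  ft <- make_frap_trace(frap_script(k_slow = 0.2, k_fast = 2,
                                    noise_sd = 0.01), seed = 11)
  fh <- frap_halftime(ft$trace, ft$times)
  # a single noisy draw: the < 5% bias property is asserted over
  # replicates in the acceptance suite
  expect_equal(fh$half_time, log(2) / 0.2, tolerance = 0.15)
  # zero noise: near-exact recovery
  ft0 <- make_frap_trace(frap_script(noise_sd = 0), seed = 1)
  fh0 <- frap_halftime(ft0$trace, ft0$times)
  expect_equal(fh0$half_time, log(2) / 0.2, tolerance = 1e-3)
  expect_gt(fh0$r_squared, 0.999)
  # pure single exponential: components collapse to the single rate
  ft1 <- make_frap_trace(frap_script(k_fast = 0.5, k_slow = 0.5,
                                     A_fast = 0, A_slow = 0.7,
                                     noise_sd = 0), seed = 1)
  fh1 <- frap_halftime(ft1$trace, ft1$times)
  expect_equal(fh1$half_time, log(2) / 0.5, tolerance = 0.05)
})

test_that("multi-cluster scoring returns percentages with confidence bounds", {
  r <- multi_cluster_fraction(c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(r$percent, 25)
  expect_equal(multi_cluster_fraction(rep(FALSE, 10))$percent, 0)
  set.seed(12)
  cohort <- runif(60) < 0.5
  r2 <- multi_cluster_fraction(cohort)
  expect_true(r2$ci[1] <= 50 && 50 <= r2$ci[2])
  expect_error(multi_cluster_fraction(logical(0)))
})

test_that("cortical ring intensity ratio picks up membrane enrichment", {
  n <- 40
  img <- matrix(1, n, n)
  img[10:30, 10:30] <- 5          # cell interior
  img[10, 10:30] <- 20; img[30, 10:30] <- 20
  img[10:30, 10] <- 20; img[10:30, 30] <- 20   # bright cortex
  expect_gt(cortical_interior_ratio(img, cell_threshold = 4), 2)
})
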