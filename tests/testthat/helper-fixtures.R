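# Shared, lazily computed fixtures. The relaxed two-peak state and the
# competition runs are deterministic given their seeds, so they are built
# once per test session and reused across files.
.fixtures <- new.env(parent = emptyenv())

fx <- function(key, fun) {
  if (!exists(key, envir = .fixtures)) assign(key, fun(), envir = .fixtures)
  get(key, envir = .fixtures)
}

fx_params <- function() default_parameters()

fx_homog_membrane <- function() {
  fx("m0", function() {
    ss <- homogeneous_steady_state(fx_params(), N = 8)
    sum(ss$fields[1, 1, c("Cdc42T", "Cdc42Dm", "BemGEF42")])
  })
}

fx_two_peak <- function() {
  fx("two_peak", function() make_two_peak_state(fx_params()))
}

fx_competition <- function(seed, keep_states = FALSE) {
  fx(paste0("comp_", seed, "_", keep_states), function()
    run_competition_experiment(fx_params(), seed = seed,
                               two_peak_state = fx_two_peak(),
                               keep_states = keep_states, cadence = 15))
}

# Light-weight winner call: integrate with noise until the height gap
# exceeds 5%; once a gap that large exists, the larger peak always wins.
fx_winner_side <- function(seed) {
  fx(paste0("winner_", seed), function() {
    p <- fx_params()
    st <- fx_two_peak()
    N <- st$N
    cfg <- simulation_config(N = N, dt = 0.02, T = 30, noise = TRUE,
                             cadence = 30)
    set.seed(seed)
    half <- seq_len(N) <= N / 2
    for (i in 1:100) {
      st <- step(st, p, cfg, nsteps = round(30 / cfg$dt))
      m <- membrane_cdc42(st)
      hA <- max(m[half, ]); hB <- max(m[!half, ])
      if (abs(hA - hB) > 0.05 * max(hA, hB)) return(if (hA > hB) 1L else 2L)
    }
    NA_integer_
  })
}

make_gaussian_field <- function(N, h, centers, amplitude, sigma,
                                baseline = 0) {
  L <- N * h
  xy <- (seq_len(N) - 1) * h
  f <- matrix(baseline, N, N)
  if (!is.list(centers)) centers <- list(centers)
  for (ct in centers) {
    dx <- abs(xy - ct[1]); dx <- pmin(dx, L - dx)
    dy <- abs(xy - ct[2]); dy <- pmin(dy, L - dy)
    f <- f + amplitude * exp(-outer(dx^2, dy^2, "+") / (2 * sigma^2))
  }
  f
}
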