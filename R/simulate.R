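#' Simulation configuration
#'
#' @param N Grid size (points per side of the periodic square).
#' @param dt Macro time step (s). Must satisfy the explicit diffusion bound
#'   `dt <= h^2/(4 Dm)`; with the adaptive stepper the reactions are
#'   substepped per grid point, with plain `"euler"` the same `dt` is also
#'   the reaction step and must resolve the fastest local rate.
#' @param T Total simulated time (s).
#' @param noise Apply the stochastic Bem1-GEF attachment term?
#' @param cadence Observer cadence (s): snapshots are recorded every
#'   `cadence` seconds (and at the final time).
#' @param stepper `"adaptive"` (default: explicit diffusion + per-point
#'   substepped reactions) or `"euler"` (global-dt explicit
#'   Euler-Maruyama, for validation).
#' @param theta Target `dt_sub * rate` for the adaptive reaction substeps.
#' @return A `polar_sim_config` list.
#' @export
simulation_config <- function(N = 64, dt = 0.02, T = 600, noise = TRUE,
                              cadence = 5, stepper = c("adaptive", "euler"),
                              theta = 0.2) {
  stepper <- match.arg(stepper)
  stopifnot(N >= 8, dt > 0, T >= 0, cadence > 0, theta > 0, theta < 1)
  structure(list(N = N, dt = dt, T = T, noise = noise, cadence = cadence,
                 stepper = stepper, theta = theta),
            class = "polar_sim_config")
}

#' Periodic (torus) 5-point Laplacian
#'
#' @param field Square matrix.
#' @param h Grid spacing (um).
#' @return Matrix of the same shape: discrete Laplacian with wraparound in
#'   both axes. Its grid sum is zero to rounding error (divergence theorem
#'   on the torus).
#' @export
periodic_laplacian <- function(field, h) {
  if (!is.matrix(field) || nrow(field) != ncol(field))
    stop("field must be a square matrix")
  stopifnot(h > 0)
  up <- rbind(field[-1, , drop = FALSE], field[1, , drop = FALSE])
  dn <- rbind(field[nrow(field), , drop = FALSE], field[-nrow(field), , drop = FALSE])
  lf <- cbind(field[, -1, drop = FALSE], field[, 1, drop = FALSE])
  rt <- cbind(field[, ncol(field), drop = FALSE], field[, -ncol(field), drop = FALSE])
  (up + dn + lf + rt - 4 * field) / h^2
}

check_dt <- function(state, params, config) {
  bound <- state$h^2 / (4 * params$Dm)
  if (config$dt > bound)
    stop(sprintf("dt = %g exceeds the diffusion stability bound %g s",
                 config$dt, bound))
}

#' Advance the state by a fixed number of macro steps
#'
#' Thin wrapper over the compiled core; consumes the R random number stream
#' (so `set.seed()` gives bit-identical trajectories).
#'
#' @param state A `polar_state`.
#' @param params `polar_params`.
#' @param config `polar_sim_config`.
#' @param nsteps Number of macro steps of size `config$dt` (default 1).
#' @return The advanced `polar_state`.
#' @export
step <- function(state, params, config, nsteps = 1L) {
  check_dt(state, params, config)
  res <- advance_rd(state$fields, state$Cdc42Dc, state$BemGEFc,
                    unclass(params), state$h, config$dt, as.integer(nsteps),
                    config$noise, config$stepper == "adaptive", config$theta)
  full_state(res$fields, res$Cdc42Dc, res$BemGEFc,
             t = state$t + nsteps * config$dt, params = params)
}

#' Simulate a trajectory
#'
#' Integrates from `state0` for `config$T` seconds, recording a snapshot
#' every `config$cadence` seconds together with both conserved totals.
#'
#' @inheritParams step
#' @param state0 Initial `polar_state`.
#' @param keep_fields Keep full field snapshots (`TRUE`) or only the summary
#'   table and the final state (`FALSE`, lighter).
#' @return A `polar_trajectory`: list with `states` (list of `polar_state`,
#'   empty if `keep_fields = FALSE` except the last), `summary` (data.frame
#'   of t, totals, max summed-membrane Cdc42), and `final` state.
#' @export
simulate_trajectory <- function(state0, params, config, keep_fields = TRUE) {
  check_dt(state0, params, config)
  steps_per_obs <- max(1L, round(config$cadence / config$dt))
  nobs <- if (config$T == 0) 0L else ceiling(config$T / config$dt / steps_per_obs)

  states <- vector("list", nobs + 1L)
  states[[1L]] <- state0
  rows <- vector("list", nobs + 1L)
  rows[[1L]] <- traj_row(state0, params)
  st <- state0
  done <- 0L
  total_steps <- round(config$T / config$dt)
  for (i in seq_len(nobs)) {
    n <- min(steps_per_obs, total_steps - done)
    if (n <= 0) { states <- states[1:i]; rows <- rows[1:i]; break }
    st <- step(st, params, config, nsteps = n)
    done <- done + n
    states[[i + 1L]] <- st
    rows[[i + 1L]] <- traj_row(st, params)
  }
  summary <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  keep <- !vapply(states, is.null, logical(1))
  states <- states[keep]
  final <- states[[length(states)]]
  if (!keep_fields) states <- list(final)
  structure(list(states = states, summary = summary, final = final,
                 params = params, config = config),
            class = "polar_trajectory")
}

traj_row <- function(state, params) {
  data.frame(t = state$t,
             total_cdc42 = total_cdc42(state, params),
             total_bemgef = total_bemgef(state, params),
             max_cdc42 = max(membrane_cdc42(state)),
             Cdc42Dc = state$Cdc42Dc, BemGEFc = state$BemGEFc)
}

#' @export
print.polar_trajectory <- function(x, ...) {
  s <- x$summary
  cat(sprintf("polar_trajectory: %d snapshots, t in [%g, %g] s\n",
              nrow(s), min(s$t), max(s$t)))
  cat(sprintf("  total Cdc42 drift: %.3g%%  total BemGEF drift: %.3g%%\n",
              100 * abs(s$total_cdc42[nrow(s)] / s$total_cdc42[1] - 1),
              100 * abs(s$total_bemgef[nrow(s)] / s$total_bemgef[1] - 1)))
  invisible(x)
}

#' Seed Gaussian perturbations at given locations, mass-neutrally
#'
#' Adds identical Gaussian bumps to `Cdc42T` (amplitude `amplitude`, s.d.
#' `width`, periodic distance) at each center, plus proportional bumps to
#' `BemGEF42` scaled by the ratio of the Bem1-GEF to Cdc42 totals; the
#' cytosol-equivalent mass of each bump is removed from the matching
#' cytosolic pool so both conserved totals are unchanged.
#'
#' @param state A `polar_state`.
#' @param centers List (or n x 2 matrix) of (x, y) positions in um.
#' @param amplitude Peak amplitude added to `Cdc42T` (uM).
#' @param width Gaussian standard deviation (um).
#' @param params `polar_params`.
#' @return Perturbed `polar_state`.
#' @export
seed_perturbations <- function(state, centers, amplitude = 20, width = 0.7,
                               params = default_parameters()) {
  if (is.matrix(centers)) centers <- asplit(centers, 1)
  if (length(centers) == 0L) return(state)
  N <- state$N; L <- state$L; h <- state$h
  xy <- (seq_len(N) - 1) * h
  bump <- matrix(0, N, N)
  for (ctr in centers) {
    if (any(ctr < 0) || any(ctr >= L)) stop("center outside the domain")
    dx <- abs(xy - ctr[1]); dx <- pmin(dx, L - dx)
    dy <- abs(xy - ctr[2]); dy <- pmin(dy, L - dy)
    bump <- bump + amplitude * exp(-(outer(dx^2, dy^2, "+")) / (2 * width^2))
  }
  ratio <- params$total_bemgef / params$total_cdc42
  f <- state$fields
  f[, , "Cdc42T"] <- f[, , "Cdc42T"] + bump
  f[, , "BemGEF42"] <- f[, , "BemGEF42"] + ratio * bump
  # the BemGEF42 bump carries both Cdc42 and Bem1-GEF mass
  dDc <- params$eta * mean(bump) * (1 + ratio)
  dBc <- params$eta * mean(ratio * bump)
  if (state$Cdc42Dc < dDc || state$BemGEFc < dBc)
    stop("perturbation would drive a cytosolic pool negative")
  full_state(f, state$Cdc42Dc - dDc, state$BemGEFc - dBc,
             t = state$t, params = params)
}
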