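#' Bem1-GEF recruitment rate at the peak center
#'
#' The rate at which cytosolic Bem1-GEF complexes are recruited by active
#' Cdc42: `k7 * BemGEFc * Cdc42T`. Linear in Cdc42T at fixed cytosolic
#' concentration, which is why larger peaks recruit faster.
#'
#' @param BemGEFc Cytosolic Bem1-GEF (uM).
#' @param Cdc42T GTP-Cdc42 at the peak center (uM).
#' @param params `polar_params`.
#' @return Recruitment rate (uM/s).
#' @export
recruitment_rate <- function(BemGEFc, Cdc42T, params = default_parameters()) {
  stopifnot(all(BemGEFc >= 0), all(Cdc42T >= 0))
  params$k7 * BemGEFc * Cdc42T
}

# Exact trajectory of a 2-species linear ODE x' = M x, summed pool p = x1+x2,
# on a fixed time grid; eigen-decomposition (falls back to lsoda if the
# eigenbasis is ill-conditioned).
linear_decay_pool <- function(M, x0, times) {
  e <- eigen(M)
  if (rcond(e$vectors) > 1e-10) {
    a <- solve(e$vectors, x0)
    pool <- vapply(times, function(t)
      Re(sum(e$vectors %*% (a * exp(e$values * t)))), numeric(1))
  } else {
    f <- function(t, y, p) list(as.numeric(M %*% y))
    sol <- deSolve::lsoda(x0, times, f, NULL, rtol = 1e-10, atol = 1e-12)
    pool <- rowSums(sol[, -1, drop = FALSE])
  }
  pool
}

half_time_from_curve <- function(times, pool) {
  target <- pool[1] / 2
  below <- which(pool <= target)
  if (length(below) == 0L)
    stop("pool did not reach half of its initial value on the time grid")
  k <- below[1]
  if (k == 1L) return(0)
  times[k - 1] + (target - pool[k - 1]) / (pool[k] - pool[k - 1]) *
    (times[k] - times[k - 1])
}

decay_result <- function(species, partner_label, partner, init, times, pool) {
  ht <- half_time_from_curve(times, pool)
  structure(list(species = species, partner_label = partner_label,
                 partner = partner, init = init, times = times,
                 pool = pool, half_time = ht, k_effective = log(2) / ht),
            class = "polar_decay")
}

#' @export
print.polar_decay <- function(x, ...) {
  cat(sprintf("%s decay at %s = %g uM: T1/2 = %.4g s (k_eff = %.4g 1/s)\n",
              x$species, x$partner_label, x$partner, x$half_time,
              x$k_effective))
  invisible(x)
}

#' Simulated Bem1-GEF dwell time at the peak center
#'
#' Integrates the two-species subsystem of membrane Bem1-GEF (`BemGEFm`)
#' and its GTP-Cdc42-bound form (`BemGEF42`) with the local GTP-Cdc42
#' concentration clamped:
#' `BemGEFm' = -k1b BemGEFm - k4a BemGEFm Cdc42T + k4b BemGEF42`,
#' `BemGEF42' = k4a BemGEFm Cdc42T - k4b BemGEF42`.
#' Only detachment (`k1b`) removes complexes to the cytoplasm, but complexes
#' sequestered as BemGEF42 are protected, so the dwell time grows with
#' GTP-Cdc42. The initial pool is pre-equilibrated between the two forms at
#' the clamped Cdc42T (removing the fast initial transient); the decay of
#' the summed pool and its half-time (dwell time) are returned.
#'
#' @param Cdc42T_fixed Clamped GTP-Cdc42 (uM).
#' @param params `polar_params`.
#' @param bemgef_init Initial total Bem1-GEF pool (uM).
#' @param n_grid Output time-grid size (spanning 10x the closed-form
#'   half-time).
#' @return A `polar_decay` (fields: `times`, `pool`, `half_time`,
#'   `k_effective`).
#' @export
bemgef_dwell_sim <- function(Cdc42T_fixed, params = default_parameters(),
                             bemgef_init = 70, n_grid = 2000) {
  stopifnot(Cdc42T_fixed >= 0, bemgef_init > 0)
  p <- params
  M <- matrix(c(-p$k1b - p$k4a * Cdc42T_fixed, p$k4b,
                p$k4a * Cdc42T_fixed, -p$k4b), 2, 2, byrow = TRUE)
  frac <- p$k4a * Cdc42T_fixed / p$k4b      # BemGEF42 : BemGEFm at QSSA
  x0 <- bemgef_init * c(1, frac) / (1 + frac)
  horizon <- 10 * bemgef_dwell_qssa(Cdc42T_fixed, p)
  times <- seq(0, horizon, length.out = n_grid)
  pool <- linear_decay_pool(M, x0, times)
  decay_result("BemGEF", "Cdc42T", Cdc42T_fixed, bemgef_init, times, pool)
}

#' Quasi-steady-state Bem1-GEF dwell time
#'
#' With binding/unbinding (`k4a`/`k4b`) fast compared to detachment, the
#' pool decays as a single exponential with effective rate
#' `k1b k4b / (k4b + k4a Cdc42T)`, giving
#' `T1/2 = ln2 (k4a Cdc42T / (k1b k4b) + 1/k1b)`: linear in GTP-Cdc42.
#'
#' @inheritParams bemgef_dwell_sim
#' @param Cdc42T Clamped GTP-Cdc42 (uM), vectorized.
#' @return Half-time(s) in seconds.
#' @export
bemgef_dwell_qssa <- function(Cdc42T, params = default_parameters()) {
  p <- params
  log(2) * (p$k4a * Cdc42T / (p$k1b * p$k4b) + 1 / p$k1b)
}

#' Simulated Cdc42 dwell time at the peak center
#'
#' Considers only GAP-mediated hydrolysis and the competing GEF and GDI
#' reactions, with the local Bem1-GEF-Cdc42 complex concentration clamped:
#' `Cdc42T' = k3 BemGEF42 Cdc42Dm - k2b Cdc42T`,
#' `Cdc42Dm' = k2b Cdc42T - k3 BemGEF42 Cdc42Dm - k5b Cdc42Dm`.
#' Only GDP-Cdc42 can be extracted by the GDI (`k5b`), so GEF activity,
#' which keeps Cdc42 GTP-loaded, protects the pool and the dwell time grows
#' with GEF. The initial pool is pre-equilibrated between the two forms.
#'
#' @param BemGEF42_fixed Clamped Bem1-GEF-Cdc42 complex (uM).
#' @param params `polar_params`.
#' @param cdc42_init Initial total Cdc42 pool (uM).
#' @param n_grid Output time-grid size.
#' @return A `polar_decay`.
#' @export
cdc42_dwell_sim <- function(BemGEF42_fixed, params = default_parameters(),
                            cdc42_init = 300, n_grid = 2000) {
  stopifnot(BemGEF42_fixed >= 0, cdc42_init > 0)
  p <- params
  M <- matrix(c(-p$k2b, p$k3 * BemGEF42_fixed,
                p$k2b, -p$k3 * BemGEF42_fixed - p$k5b), 2, 2, byrow = TRUE)
  frac <- p$k3 * BemGEF42_fixed / p$k2b     # Cdc42T : Cdc42Dm at QSSA
  x0 <- cdc42_init * c(frac, 1) / (1 + frac)
  horizon <- 10 * cdc42_dwell_qssa(BemGEF42_fixed, p)
  times <- seq(0, horizon, length.out = n_grid)
  pool <- linear_decay_pool(M, x0, times)
  decay_result("Cdc42", "BemGEF42", BemGEF42_fixed, cdc42_init, times, pool)
}

#' Quasi-steady-state Cdc42 dwell time
#'
#' `T1/2 = ln2 (k3 BemGEF42 / (k2b k5b) + 1/k5b)`: linear in the GEF
#' concentration.
#'
#' @inheritParams cdc42_dwell_sim
#' @param BemGEF42 Clamped Bem1-GEF-Cdc42 complex (uM), vectorized.
#' @return Half-time(s) in seconds.
#' @export
cdc42_dwell_qssa <- function(BemGEF42, params = default_parameters()) {
  p <- params
  log(2) * (p$k3 * BemGEF42 / (p$k2b * p$k5b) + 1 / p$k5b)
}

#' Dwell-time sweep table
#'
#' Simulated versus closed-form half-times over a range of clamped partner
#' concentrations, for plotting or regression.
#'
#' @param species `"BemGEF"` (partner: Cdc42T) or `"Cdc42"` (partner:
#'   BemGEF42).
#' @param partner Partner concentrations (uM).
#' @param params `polar_params`.
#' @return data.frame (partner, t_half_sim, t_half_qssa).
#' @export
dwell_time_sweep <- function(species = c("BemGEF", "Cdc42"),
                             partner = seq(0, 450, by = 50),
                             params = default_parameters()) {
  species <- match.arg(species)
  sim <- if (species == "BemGEF") bemgef_dwell_sim else cdc42_dwell_sim
  qssa <- if (species == "BemGEF") bemgef_dwell_qssa else cdc42_dwell_qssa
  data.frame(partner = partner,
             t_half_sim = vapply(partner, function(v)
               sim(v, params)$half_time, numeric(1)),
             t_half_qssa = qssa(partner, params))
}
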