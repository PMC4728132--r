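#' @useDynLib polarcomp, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm sd coef lm nls uniroot median setNames
#' @importFrom stats predict residuals binom.test
NULL

SPECIES <- c("Cdc42T", "Cdc42Dm", "BemGEF42", "BemGEFm")

#' Full model state: membrane fields plus well-mixed cytosolic pools
#'
#' The membrane is a square periodic grid (a torus) of `N x N` points over a
#' domain of side `L = sqrt(area_A)`; the four membrane species are carried
#' as an `N x N x 4` array of shell concentrations (uM). The cytoplasm is
#' well mixed: two scalar pools, cytosolic GDP-Cdc42 (`Cdc42Dc`) and
#' cytosolic Bem1-GEF complex (`BemGEFc`), in uM.
#'
#' @param fields `N x N x 4` array (third dimension ordered
#'   `Cdc42T`, `Cdc42Dm`, `BemGEF42`, `BemGEFm`), all entries >= 0.
#' @param Cdc42Dc,BemGEFc Cytosolic pools (uM, >= 0).
#' @param t Simulation time (s).
#' @param params `polar_params` supplying the membrane area.
#' @return An object of class `polar_state`.
#' @export
full_state <- function(fields, Cdc42Dc, BemGEFc, t = 0,
                       params = default_parameters()) {
  stopifnot(is.array(fields), length(dim(fields)) == 3L,
            dim(fields)[1] == dim(fields)[2], dim(fields)[3] == 4L,
            Cdc42Dc >= 0, BemGEFc >= 0)
  if (min(fields) < -1e-9)
    stop("negative membrane concentration: ", min(fields))
  dimnames(fields) <- list(NULL, NULL, SPECIES)
  N <- dim(fields)[1]
  L <- sqrt(params$area_A)
  structure(list(fields = fields, Cdc42Dc = Cdc42Dc, BemGEFc = BemGEFc,
                 t = t, N = N, L = L, h = L / N),
            class = "polar_state")
}

#' Uniform state from six scalar concentrations
#' @param conc Named numeric of length 6: the four membrane species plus
#'   `Cdc42Dc`, `BemGEFc`.
#' @param N Grid size.
#' @inheritParams full_state
#' @return A `polar_state`.
#' @export
uniform_state <- function(conc, N = 64, t = 0, params = default_parameters()) {
  stopifnot(all(c(SPECIES, "Cdc42Dc", "BemGEFc") %in% names(conc)))
  fields <- array(rep(conc[SPECIES], each = N * N), dim = c(N, N, 4))
  full_state(fields, conc[["Cdc42Dc"]], conc[["BemGEFc"]], t, params)
}

#' @export
print.polar_state <- function(x, ...) {
  cat(sprintf("polar_state: %dx%d grid (h=%.4f um), t=%.2f s\n",
              x$N, x$N, x$h, x$t))
  for (s in SPECIES)
    cat(sprintf("  %-9s mean %.4g  max %.4g uM\n", s,
                mean(x$fields[, , s]), max(x$fields[, , s])))
  cat(sprintf("  cytosol: Cdc42Dc=%.4g  BemGEFc=%.4g uM\n",
              x$Cdc42Dc, x$BemGEFc))
  invisible(x)
}

#' Pointwise reaction rates of the membrane species
#'
#' Evaluates the reaction parts (no diffusion, no noise) of the four
#' membrane equations, elementwise over arrays or scalars:
#' \deqn{Cdc42T' = (k_{2a} BemGEFm + k_3 BemGEF42) Cdc42Dm - k_{2b} Cdc42T
#'   - (k_{4a} BemGEFm + k_7 BemGEFc) Cdc42T + k_{4b} BemGEF42}
#' \deqn{Cdc42Dm' = k_{2b} Cdc42T - (k_{2a} BemGEFm + k_3 BemGEF42) Cdc42Dm
#'   - k_{5b} Cdc42Dm + k_{5a} Cdc42Dc}
#' \deqn{BemGEF42' = (k_{4a} BemGEFm + k_7 BemGEFc) Cdc42T - k_{4b} BemGEF42}
#' \deqn{BemGEFm' = k_{1a} BemGEFc - k_{1b} BemGEFm + k_{4b} BemGEF42
#'   - k_{4a} BemGEFm \cdot Cdc42T}
#'
#' @param Cdc42T,Cdc42Dm,BemGEF42,BemGEFm Membrane concentrations (uM),
#'   scalars or equal-shaped arrays, all >= 0.
#' @param Cdc42Dc,BemGEFc Cytosolic pools (uM).
#' @param params `polar_params`.
#' @return List of the four time-derivatives (uM/s), same shape as inputs.
#' @export
reaction_rates <- function(Cdc42T, Cdc42Dm, BemGEF42, BemGEFm,
                           Cdc42Dc, BemGEFc, params) {
  if (min(Cdc42T, Cdc42Dm, BemGEF42, BemGEFm, Cdc42Dc, BemGEFc) < 0)
    stop("negative concentration passed to reaction_rates()")
  p <- params
  exch  <- p$k2a * BemGEFm + p$k3 * BemGEF42   # GEF-catalyzed GDP->GTP
  bind  <- p$k4a * BemGEFm + p$k7 * BemGEFc    # Bem1-GEF capture by Cdc42T
  list(
    Cdc42T   = exch * Cdc42Dm - p$k2b * Cdc42T - bind * Cdc42T +
               p$k4b * BemGEF42,
    Cdc42Dm  = p$k2b * Cdc42T - exch * Cdc42Dm - p$k5b * Cdc42Dm +
               p$k5a * Cdc42Dc,
    BemGEF42 = bind * Cdc42T - p$k4b * BemGEF42,
    BemGEFm  = p$k1a * BemGEFc - p$k1b * BemGEFm + p$k4b * BemGEF42 -
               p$k4a * BemGEFm * Cdc42T
  )
}

#' Cytosolic pool rates for a uniform (well-mixed) state
#'
#' For spatially uniform fields the area integrals reduce to the local
#' values: `Cdc42Dc' = eta (k5b Cdc42Dm - k5a Cdc42Dc)` and
#' `BemGEFc' = eta (k1b BemGEFm - k1a BemGEFc - k7 BemGEFc Cdc42T)`.
#' @keywords internal
cytosol_rates_uniform <- function(Cdc42T, Cdc42Dm, BemGEFm,
                                  Cdc42Dc, BemGEFc, params) {
  p <- params
  c(Cdc42Dc = p$eta * (p$k5b * Cdc42Dm - p$k5a * Cdc42Dc),
    BemGEFc = p$eta * (p$k1b * BemGEFm - p$k1a * BemGEFc -
                         p$k7 * BemGEFc * Cdc42T))
}

#' Conserved totals (cytosol-equivalent convention)
#'
#' The conserved amount of Cdc42 is
#' `eta * mean(Cdc42T + Cdc42Dm + BemGEF42) + Cdc42Dc` and of Bem1-GEF
#' `eta * mean(BemGEFm + BemGEF42) + BemGEFc`, where the spatial mean runs
#' over the membrane grid. Both are constant along noise-free trajectories
#' and, with the mass-neutral noise pairing, along noisy ones too.
#'
#' @param state A `polar_state`.
#' @param params `polar_params`.
#' @return Total in uM (cytosol-equivalent).
#' @export
total_cdc42 <- function(state, params) {
  f <- state$fields
  params$eta * mean(f[, , "Cdc42T"] + f[, , "Cdc42Dm"] + f[, , "BemGEF42"]) +
    state$Cdc42Dc
}

#' @rdname total_cdc42
#' @export
total_bemgef <- function(state, params) {
  f <- state$fields
  params$eta * mean(f[, , "BemGEFm"] + f[, , "BemGEF42"]) + state$BemGEFc
}

well_mixed_ode <- function(t, y, params) {
  r <- reaction_rates(y[1], y[2], y[3], y[4], y[5], y[6], params)
  rc <- cytosol_rates_uniform(y[1], y[2], y[4], y[5], y[6], params)
  list(c(r$Cdc42T, r$Cdc42Dm, r$BemGEF42, r$BemGEFm, rc[1], rc[2]))
}

#' Homogeneous steady state of the full system
#'
#' Finds the spatially uniform fixed point consistent with both conserved
#' totals: integrates the well-mixed six-species ODE system to near-
#' stationarity, then polishes with Newton iteration on the four membrane
#' rate equations plus the two conservation constraints, using the analytic
#' Jacobian.
#'
#' @param params `polar_params`.
#' @param N Grid size of the returned uniform state.
#' @param tol Maximum allowed residual norm (uM/s) of the polished root.
#' @return A `polar_state` (uniform) with attribute `"residual"`.
#' @export
homogeneous_steady_state <- function(params, N = 64, tol = 1e-10) {
  p <- params
  if (p$total_cdc42 == 0 && p$total_bemgef == 0) {
    z <- setNames(numeric(6), c(SPECIES, "Cdc42Dc", "BemGEFc"))
    st <- uniform_state(z, N = N, params = p)
    attr(st, "residual") <- 0
    return(st)
  }
  y0 <- c(0, 0, 0, 0, p$total_cdc42, p$total_bemgef)
  sol <- deSolve::lsoda(y0, times = c(0, 2000), func = well_mixed_ode,
                        parms = p, rtol = 1e-10, atol = 1e-12)
  y <- pmax(as.numeric(sol[nrow(sol), -1]), 0)

  resid_fun <- function(y) {
    r <- reaction_rates(y[1], y[2], y[3], y[4], y[5], y[6], params = p)
    c(r$Cdc42T, r$Cdc42Dm, r$BemGEF42, r$BemGEFm,
      p$eta * (y[1] + y[2] + y[3]) + y[5] - p$total_cdc42,
      p$eta * (y[3] + y[4]) + y[6] - p$total_bemgef)
  }
  jac_fun <- function(y) {
    J <- reaction_jacobian_full(y, p)
    J[5, ] <- c(p$eta, p$eta, p$eta, 0, 1, 0)
    J[6, ] <- c(0, 0, p$eta, p$eta, 0, 1)
    J
  }
  for (it in 1:50) {
    F <- resid_fun(y)
    if (max(abs(F)) < tol / 10) break
    dy <- tryCatch(solve(jac_fun(y), F), error = function(e) NULL)
    if (is.null(dy)) break
    y <- y - dy
  }
  res <- max(abs(resid_fun(y)))
  if (res > tol)
    stop(sprintf("steady-state root finding did not converge: residual %.3g",
                 res))
  y <- pmax(y, 0)
  st <- uniform_state(setNames(y, c(SPECIES, "Cdc42Dc", "BemGEFc")),
                      N = N, params = p)
  attr(st, "residual") <- res
  st
}

#' Analytic Jacobian of the reaction system
#'
#' `reaction_jacobian_membrane()` returns the 4x4 Jacobian of the membrane
#' reaction rates with the cytosolic pools held fixed (the operator seen by
#' nonzero spatial modes, since a well-mixed cytosol cannot respond to
#' zero-mean perturbations); `reaction_jacobian_full()` the 6x6 Jacobian of
#' the uniform (well-mixed) system including the eta-coupled cytosol rows.
#'
#' @param y Numeric length-6 state
#'   `(Cdc42T, Cdc42Dm, BemGEF42, BemGEFm, Cdc42Dc, BemGEFc)`.
#' @param params `polar_params`.
#' @return A 4x4 or 6x6 matrix (1/s entries).
#' @export
reaction_jacobian_membrane <- function(y, params) {
  p <- params
  T <- y[1]; D <- y[2]; G <- y[3]; Bm <- y[4]; Bc <- y[6]
  exch <- p$k2a * Bm + p$k3 * G
  bind <- p$k4a * Bm + p$k7 * Bc
  matrix(c(
    -p$k2b - bind,  exch,            p$k3 * D + p$k4b,  p$k2a * D - p$k4a * T,
    p$k2b,          -exch - p$k5b,   -p$k3 * D,         -p$k2a * D,
    bind,           0,               -p$k4b,            p$k4a * T,
    -p$k4a * Bm,    0,               p$k4b,             -p$k1b - p$k4a * T),
    nrow = 4, byrow = TRUE,
    dimnames = list(SPECIES, SPECIES))
}

#' @rdname reaction_jacobian_membrane
#' @export
reaction_jacobian_full <- function(y, params) {
  p <- params
  T <- y[1]; D <- y[2]; G <- y[3]; Bm <- y[4]; Dc <- y[5]; Bc <- y[6]
  J <- matrix(0, 6, 6, dimnames = list(c(SPECIES, "Cdc42Dc", "BemGEFc"),
                                       c(SPECIES, "Cdc42Dc", "BemGEFc")))
  J[1:4, 1:4] <- reaction_jacobian_membrane(y, p)
  J[1, 6] <- -p$k7 * T            # Cdc42T loses to direct recruitment
  J[2, 5] <- p$k5a
  J[3, 6] <- p$k7 * T
  J[4, 6] <- p$k1a
  J[5, 2] <- p$eta * p$k5b
  J[5, 5] <- -p$eta * p$k5a
  J[6, 1] <- -p$eta * p$k7 * Bc
  J[6, 4] <- p$eta * p$k1b
  J[6, 6] <- -p$eta * (p$k1a + p$k7 * T)
  J
}

state_as_vector <- function(state) {
  c(Cdc42T = mean(state$fields[, , 1]), Cdc42Dm = mean(state$fields[, , 2]),
    BemGEF42 = mean(state$fields[, , 3]), BemGEFm = mean(state$fields[, , 4]),
    Cdc42Dc = state$Cdc42Dc, BemGEFc = state$BemGEFc)
}

#' Summed membrane Cdc42 field
#'
#' The "Cdc42 concentration" used for peak detection, waistlines and flux
#' accounting: `Cdc42T + Cdc42Dm + BemGEF42` (all membrane Cdc42-carrying
#' species) by default, switchable to active Cdc42 only.
#'
#' @param state A `polar_state`.
#' @param which `"all"` (default) or `"Cdc42T"`.
#' @return `N x N` matrix (uM).
#' @export
membrane_cdc42 <- function(state, which = c("all", "Cdc42T")) {
  which <- match.arg(which)
  f <- state$fields
  if (which == "all")
    f[, , "Cdc42T"] + f[, , "Cdc42Dm"] + f[, , "BemGEF42"]
  else f[, , "Cdc42T"]
}
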