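#' Dispersion relation of the torus model
#'
#' Linearizes the membrane-cytosol system about the homogeneous steady
#' state. For a spatial wavenumber `q > 0` on the torus the well-mixed
#' cytosol cannot respond (a zero-mean spatial mode integrates to zero), so
#' the relevant operator is `J4 - Dm q^2 I` with `J4` the 4x4 Jacobian of
#' the membrane reactions at the steady state with the cytosolic pools
#' frozen; for `q = 0` the full six-variable Jacobian including the
#' (eta/A)-coupled cytosol rows is used (its two zero eigenvalues are the
#' conservation constraints).
#'
#' @param params `polar_params`.
#' @param q Wavenumbers (1/um). Defaults to the admissible radial
#'   magnitudes `2 pi m / L`, m = 0..12.
#' @param abundance_scale Scale factor applied to both conserved totals
#'   before computing the steady state (volume/abundance correction).
#' @return A `polar_dispersion` data.frame (q, sigma = leading eigenvalue
#'   real part, 1/s) with the parameter set, scale and `Dm` as attributes.
#' @export
dispersion_relation_torus <- function(params, q = NULL,
                                      abundance_scale = 1) {
  p <- params
  if (abundance_scale != 1) {
    p$total_cdc42 <- p$total_cdc42 * abundance_scale
    p$total_bemgef <- p$total_bemgef * abundance_scale
  }
  L <- sqrt(p$area_A)
  if (is.null(q)) q <- 2 * pi * (0:12) / L
  y <- state_as_vector(homogeneous_steady_state(p, N = 8))
  J4 <- reaction_jacobian_membrane(y, p)
  J6 <- reaction_jacobian_full(y, p)
  sigma <- vapply(q, function(qi) {
    if (qi == 0) max(Re(eigen(J6, only.values = TRUE)$values))
    else max(Re(eigen(J4 - p$Dm * qi^2 * diag(4),
                      only.values = TRUE)$values))
  }, numeric(1))
  out <- data.frame(q = q, sigma = sigma)
  attr(out, "params") <- p
  attr(out, "domain") <- "torus"
  attr(out, "abundance_scale") <- abundance_scale
  attr(out, "Dm") <- p$Dm
  class(out) <- c("polar_dispersion", "data.frame")
  out
}

#' Admissible torus mode lattice
#'
#' Integer pairs `(m, n)` (excluding the uniform mode) with their
#' wavenumber magnitude `q = 2 pi sqrt(m^2 + n^2) / L`. Degenerate
#' symmetric modes are individual lattice points and are counted
#' individually.
#'
#' @param L Domain side (um).
#' @param m_max Largest index per axis.
#' @return data.frame (m, n, q), one row per lattice point.
#' @export
torus_mode_lattice <- function(L, m_max = 12) {
  g <- expand.grid(m = -m_max:m_max, n = -m_max:m_max)
  g <- g[!(g$m == 0 & g$n == 0), ]
  g$q <- 2 * pi * sqrt(g$m^2 + g$n^2) / L
  rownames(g) <- NULL
  g
}

#' Count unstable modes of a spectrum on the admissible lattice
#'
#' Given leading eigenvalues indexed by wavenumber magnitude, counts the
#' admissible lattice modes whose leading eigenvalue is positive. More than
#' one positive eigenvalue is a necessary condition for competition
#' between peaks.
#'
#' @param spectrum A `polar_dispersion` (or data.frame with `q`, `sigma`).
#' @param L Domain side (um); taken from the spectrum's parameters when
#'   available.
#' @param m_max Lattice extent.
#' @return Integer count of unstable lattice modes.
#' @export
unstable_mode_count <- function(spectrum, L = NULL, m_max = 12) {
  if (is.null(L)) {
    p <- attr(spectrum, "params")
    if (is.null(p)) stop("supply the domain side L")
    L <- sqrt(p$area_A)
  }
  lat <- torus_mode_lattice(L, m_max)
  qs <- sort(unique(round(lat$q, 12)))
  sig <- setNames(rep(NA_real_, length(qs)), format(qs, digits = 15))
  for (i in seq_along(qs)) {
    j <- which.min(abs(spectrum$q - qs[i]))
    if (abs(spectrum$q[j] - qs[i]) > 1e-9)
      stop("spectrum does not cover the admissible lattice; ",
           "evaluate it at torus_mode_lattice() wavenumbers")
    sig[i] <- spectrum$sigma[j]
  }
  sum(sig[match(format(round(lat$q, 12), digits = 15), names(sig))] > 0)
}

#' Unstable-mode count for the torus model at given parameters
#'
#' Convenience wrapper: evaluates the dispersion relation on the admissible
#' lattice magnitudes and counts positive modes.
#'
#' @param params `polar_params`.
#' @param Dm Membrane diffusion coefficient (um^2/s); overrides the
#'   parameter set.
#' @param abundance_scale Scale factor on both conserved totals.
#' @param m_max Lattice extent.
#' @return Integer count.
#' @export
torus_unstable_mode_count <- function(params, Dm = params$Dm,
                                      abundance_scale = 1, m_max = 12) {
  p <- params
  p$Dm <- Dm
  L <- sqrt(p$area_A)
  lat <- torus_mode_lattice(L, m_max)
  qs <- sort(unique(lat$q))
  spec <- dispersion_relation_torus(p, q = qs,
                                    abundance_scale = abundance_scale)
  unstable_mode_count(spec, L = L, m_max = m_max)
}

#' Sweep unstable-mode counts over diffusion and abundance
#'
#' Mirrors the stability-analysis parameter sweeps: slowing membrane
#' diffusion and/or raising protein abundance enlarges the set of modes
#' with positive growth rate, the necessary condition for multi-peak
#' intermediates.
#'
#' @param params `polar_params`.
#' @param Dm_values Diffusion coefficients (um^2/s).
#' @param abundance_scales Total-abundance scale factors.
#' @param m_max Lattice extent.
#' @return data.frame (Dm, scale, n_unstable, max_sigma).
#' @export
lsa_sweep <- function(params, Dm_values = c(0.0025, 0.005, 0.01, 0.03),
                      abundance_scales = c(1, 2, 4, 5.86), m_max = 12) {
  rows <- list()
  for (sc in abundance_scales) for (Dm in Dm_values) {
    p <- params; p$Dm <- Dm
    L <- sqrt(p$area_A)
    qs <- sort(unique(torus_mode_lattice(L, m_max)$q))
    spec <- dispersion_relation_torus(p, q = qs, abundance_scale = sc)
    rows[[length(rows) + 1]] <-
      data.frame(Dm = Dm, scale = sc,
                 n_unstable = unstable_mode_count(spec, L = L,
                                                  m_max = m_max),
                 max_sigma = max(spec$sigma[spec$q > 0]))
  }
  do.call(rbind, rows)
}

#' Volume correction of molecular abundances
#'
#' Scales abundances by the ratio of the model-cell volume to the real-cell
#' volume, so that concentrations are preserved when the model geometry is
#' larger than the cell it represents.
#'
#' @param molecule_numbers Numeric vector of abundances.
#' @param v_model_fL Model cell volume (fL).
#' @param v_cell_fL Real cell volume (fL).
#' @return List with `numbers` (scaled) and `factor` (`v_model / v_cell`).
#' @export
abundance_volume_correction <- function(molecule_numbers, v_model_fL = 258,
                                        v_cell_fL = 44) {
  if (v_model_fL <= 0 || v_cell_fL <= 0) stop("volumes must be positive")
  factor <- v_model_fL / v_cell_fL
  list(numbers = molecule_numbers * factor, factor = factor)
}

# ---- sphere-harmonic mode analysis ------------------------------------

# log-derivative factor g(sigma) = kappa i_l'(kappa R)/i_l(kappa R) of the
# radial cytosolic solution regular at the origin; continued to sigma <= 0
# (kappa imaginary turns modified into ordinary spherical Bessel functions).
sphere_radial_logderiv <- function(sigma, Dc, R, l) {
  if (sigma == 0) return(l / R)
  if (sigma > 0) {
    x <- sqrt(sigma / Dc) * R
    # i_l'(x)/i_l(x) = i_{l-1}(x)/i_l(x) - (l+1)/x; the sqrt(pi/(2x))
    # prefactors of the spherical forms cancel in the consecutive-order
    # ratio, so half-integer besselI can be used directly.
    r_ratio <- if (l == 0) 1 / tanh(x) - 1 / x
    else besselI(x, l - 0.5) / besselI(x, l + 0.5) - (l + 1) / x
    return(sqrt(sigma / Dc) * r_ratio)
  }
  # sigma < 0: kappa is imaginary and the modified functions turn into
  # ordinary spherical Bessel functions j_l
  x <- sqrt(-sigma / Dc) * R
  r_ratio <- if (l == 0) 1 / tan(x) - 1 / x
  else besselJ(x, l - 0.5) / besselJ(x, l + 0.5) - (l + 1) / x
  sqrt(-sigma / Dc) * r_ratio
}

#' Sphere-harmonic linear stability analysis with cytosolic diffusion
#'
#' Generic machinery for membrane-cytosol systems on a sphere of radius
#' `R`: membrane species diffuse laterally (eigenvalue `-l(l+1) Dm/R^2`
#' for spherical-harmonic mode `l`), cytosolic species diffuse in the ball
#' with coefficient `Dc`, and perturbations of the cytosol are radial
#' profiles proportional to modified spherical Bessel functions of the
#' first kind (regular at the origin). Matching the radial diffusive flux
#' at the membrane to the linearized binding/unbinding flux yields, per
#' mode `l`, a characteristic equation whose real roots are located by
#' sign-scanning the determinant and refined with Brent's method.
#'
#' @param kinetics A list describing the linearized kinetics at the
#'   homogeneous steady state: `A` (n_m x n_m membrane reaction Jacobian,
#'   cytosol frozen), `B` (n_m x n_c derivative of membrane rates with
#'   respect to the cytosolic concentrations at the membrane surface),
#'   `F_u` (n_c x n_m) and `F_c` (n_c x n_c), the derivatives of the net
#'   adsorption flux onto the membrane (uM um/s per unit perturbation),
#'   and `Dc` (length-n_c cytosolic diffusion coefficients, um^2/s).
#'   See [sphere_kinetics_polarity()] for the shipped instance.
#' @param R Sphere radius (um).
#' @param Dm Membrane diffusion coefficient (um^2/s).
#' @param l_max Largest spherical-harmonic degree.
#' @param sigma_range Search interval for real eigenvalues (1/s).
#' @param n_scan Scan resolution.
#' @return A `polar_dispersion` data.frame (l, sigma = leading real root;
#'   NA when no root is bracketed in `sigma_range`).
#' @export
sphere_mode_growth <- function(kinetics, R, Dm, l_max = 8,
                               sigma_range = c(-30, 10), n_scan = 600) {
  A <- kinetics$A; B <- kinetics$B
  F_u <- kinetics$F_u; F_c <- kinetics$F_c
  Dc <- kinetics$Dc
  n_m <- nrow(A); n_c <- length(Dc)
  stopifnot(ncol(B) == n_c, nrow(F_u) == n_c, ncol(F_u) == n_m,
            all(dim(F_c) == n_c))
  lead <- vapply(0:l_max, function(l) {
    Al <- A - l * (l + 1) * Dm / R^2 * diag(n_m)
    charfun <- function(sigma) {
      g <- vapply(seq_len(n_c), function(j)
        sphere_radial_logderiv(sigma, Dc[j], R, l), numeric(1))
      # flux match: -Dc_j g_j c_j = [F_u u + F_c c]_j
      Mc <- -diag(Dc * g, n_c) - F_c
      K <- tryCatch(solve(Mc, F_u), error = function(e) NULL)
      if (is.null(K)) return(NA_real_)
      det(Al + B %*% K - sigma * diag(n_m))
    }
    sg <- seq(sigma_range[2], sigma_range[1], length.out = n_scan)
    vals <- vapply(sg, charfun, numeric(1))
    for (i in seq_len(length(sg) - 1)) {
      if (!is.finite(vals[i]) || !is.finite(vals[i + 1])) next
      if (vals[i] == 0) return(sg[i])
      if (vals[i] * vals[i + 1] < 0) {
        r <- tryCatch(uniroot(charfun, c(sg[i + 1], sg[i]),
                              tol = 1e-10)$root,
                      error = function(e) NA_real_)
        if (!is.na(r)) return(r)
      }
    }
    NA_real_
  }, numeric(1))
  out <- data.frame(l = 0:l_max, sigma = lead)
  attr(out, "domain") <- "sphere"
  attr(out, "R") <- R
  attr(out, "Dm") <- Dm
  class(out) <- c("polar_dispersion", "data.frame")
  out
}

#' Linearized sphere kinetics of the polarity model
#'
#' Builds the [sphere_mode_growth()] kinetics description for the shipped
#' Cdc42/Bem1-GEF model at its homogeneous steady state: membrane Jacobian
#' with cytosol frozen, cytosol-surface coupling, and adsorption-flux
#' derivatives. The effective membrane shell thickness is
#' `delta = eta R / 3` (so that the membrane-to-cytoplasm volume ratio of
#' the sphere matches `eta`). The cytosolic diffusion coefficient is a
#' required input: the flat-model cytoplasm is well mixed, which is the
#' `Dc -> Inf` limit of this analysis.
#'
#' @param params `polar_params`.
#' @param R Sphere radius (um); the default preserves the membrane area.
#' @param Dc Cytosolic diffusion coefficient (um^2/s), no default
#'   physical value is implied by the flat model.
#' @param abundance_scale Scale factor on both conserved totals.
#' @return Kinetics list for [sphere_mode_growth()].
#' @export
sphere_kinetics_polarity <- function(params, Dc,
                                     R = sqrt(params$area_A / (4 * pi)),
                                     abundance_scale = 1) {
  p <- params
  if (abundance_scale != 1) {
    p$total_cdc42 <- p$total_cdc42 * abundance_scale
    p$total_bemgef <- p$total_bemgef * abundance_scale
  }
  y <- state_as_vector(homogeneous_steady_state(p, N = 8))
  A <- reaction_jacobian_membrane(y, p)
  T0 <- y[["Cdc42T"]]; Bc0 <- y[["BemGEFc"]]
  delta <- p$eta * R / 3
  # membrane-rate sensitivity to cytosol surface concentrations
  B <- matrix(0, 4, 2, dimnames = list(SPECIES, c("Cdc42Dc", "BemGEFc")))
  B["Cdc42Dm", "Cdc42Dc"] <- p$k5a
  B["Cdc42T", "BemGEFc"] <- -p$k7 * T0
  B["BemGEF42", "BemGEFc"] <- p$k7 * T0
  B["BemGEFm", "BemGEFc"] <- p$k1a
  # net adsorption flux onto the membrane (uM um/s)
  F_u <- matrix(0, 2, 4, dimnames = list(c("Cdc42Dc", "BemGEFc"), SPECIES))
  F_u["Cdc42Dc", "Cdc42Dm"] <- -delta * p$k5b
  F_u["BemGEFc", "BemGEFm"] <- -delta * p$k1b
  F_u["BemGEFc", "Cdc42T"]  <- delta * p$k7 * Bc0
  F_c <- matrix(0, 2, 2, dimnames = list(c("Cdc42Dc", "BemGEFc"),
                                         c("Cdc42Dc", "BemGEFc")))
  F_c["Cdc42Dc", "Cdc42Dc"] <- delta * p$k5a
  F_c["BemGEFc", "BemGEFc"] <- delta * (p$k1a + p$k7 * T0)
  list(A = A, B = B, F_u = F_u, F_c = F_c, Dc = c(Dc, Dc))
}

#' Seed a single Fourier mode on a uniform state
#'
#' Adds `eps * v * cos(2 pi (m x + n y)/L)` to the four membrane fields,
#' where `v` is the (normalized, real) leading eigenvector of
#' `J4 - Dm q^2 I` at `q = 2 pi sqrt(m^2+n^2)/L`; seeding along the
#' eigenvector makes the early-time response a single exponential. The
#' perturbation has zero spatial mean, so totals are unchanged.
#'
#' @param state Uniform `polar_state` (homogeneous steady state).
#' @param params `polar_params` (matching the state).
#' @param m,n Mode indices.
#' @param eps Perturbation amplitude (uM).
#' @return List: `state` (perturbed), `eigenvalue` (leading, 1/s),
#'   `eigenvector`, `mode` (the cosine pattern matrix).
#' @export
seed_fourier_mode <- function(state, params, m, n = 0, eps = 1e-3) {
  N <- state$N; L <- state$L
  y <- state_as_vector(state)
  q <- 2 * pi * sqrt(m^2 + n^2) / L
  J <- reaction_jacobian_membrane(y, params) - params$Dm * q^2 * diag(4)
  e <- eigen(J)
  k <- which.max(Re(e$values))
  v <- Re(e$vectors[, k]); v <- v / sqrt(sum(v^2))
  x <- (seq_len(N) - 1) * L / N
  pattern <- cos(2 * pi * (outer(x * m, x * n, "+")) / L)
  f <- state$fields
  for (sp in 1:4) f[, , sp] <- f[, , sp] + eps * v[sp] * pattern
  list(state = full_state(f, state$Cdc42Dc, state$BemGEFc, t = state$t,
                          params = params),
       eigenvalue = Re(e$values[k]), eigenvector = v, mode = pattern)
}

#' Measure a mode's growth rate by noise-free simulation
#'
#' Seeds one Fourier mode at small amplitude on the homogeneous steady
#' state, integrates noise-free, projects each snapshot onto the seeded
#' pattern/eigenvector and fits the log-amplitude slope: an independent,
#' fully nonlinear check of the dispersion relation while the perturbation
#' stays in the linear regime.
#'
#' @param params `polar_params`.
#' @param m,n Mode indices.
#' @param abundance_scale Scale factor on both totals.
#' @param eps Seed amplitude (uM).
#' @param T Integration time (s).
#' @param N Grid size.
#' @param dt Macro step (s).
#' @return List: `measured` (1/s), `eigenvalue` (1/s), `rel_err`.
#' @export
simulated_mode_growth_rate <- function(params, m, n = 0,
                                       abundance_scale = 1, eps = 1e-3,
                                       T = 40, N = 64, dt = 0.02) {
  p <- params
  if (abundance_scale != 1) {
    p$total_cdc42 <- p$total_cdc42 * abundance_scale
    p$total_bemgef <- p$total_bemgef * abundance_scale
  }
  ss <- homogeneous_steady_state(p, N = N)
  sd <- seed_fourier_mode(ss, p, m, n, eps)
  cfg <- simulation_config(N = N, dt = dt, T = T, noise = FALSE,
                           cadence = max(T / 8, dt))
  tr <- simulate_trajectory(sd$state, p, cfg)
  amp <- vapply(tr$states, function(s2) {
    a <- vapply(1:4, function(sp)
      2 * mean((s2$fields[, , sp] - mean(s2$fields[, , sp])) * sd$mode),
      numeric(1))
    sum(a * sd$eigenvector)
  }, numeric(1))
  tt <- vapply(tr$states, function(s2) s2$t, numeric(1))
  slope <- unname(coef(lm(log(abs(amp)) ~ tt))[2])
  list(measured = slope, eigenvalue = sd$eigenvalue,
       rel_err = abs(slope / sd$eigenvalue - 1))
}
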