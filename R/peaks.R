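periodic_delta <- function(a, b, L) {
  d <- (a - b) %% L
  ifelse(d > L / 2, d - L, d)
}

periodic_dist <- function(x1, y1, x2, y2, L) {
  sqrt(periodic_delta(x1, x2, L)^2 + periodic_delta(y1, y2, L)^2)
}

#' Detect polarity peaks on a periodic field
#'
#' Local maxima (8-neighborhood, periodic wraparound) above `min_height`;
#' maxima closer than `min_separation` (periodic distance) are merged,
#' keeping the highest. Grid coordinates are converted to um with the
#' convention that grid point (i, j) sits at ((i-1) h, (j-1) h).
#'
#' @param field Square matrix (summed membrane Cdc42, uM).
#' @param h Grid spacing (um).
#' @param min_height Minimum height to count as a peak (uM).
#' @param min_separation Merge radius (um).
#' @return data.frame with columns `x`, `y` (um), `i`, `j` (grid indices),
#'   `height` (uM), sorted by decreasing height; zero rows if none.
#' @export
detect_peaks <- function(field, h, min_height, min_separation = 1) {
  stopifnot(is.matrix(field), nrow(field) == ncol(field))
  N <- nrow(field)
  sh <- function(di, dj) field[(seq_len(N) + di - 1) %% N + 1,
                               (seq_len(N) + dj - 1) %% N + 1]
  is_max <- field >= min_height
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    is_max <- is_max & (field >= sh(di, dj))
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(data.frame(x = numeric(0), y = numeric(0), i = integer(0),
                      j = integer(0), height = numeric(0)))
  pk <- data.frame(x = (idx[, 1] - 1) * h, y = (idx[, 2] - 1) * h,
                   i = idx[, 1], j = idx[, 2],
                   height = field[idx])
  pk <- pk[order(-pk$height), , drop = FALSE]
  L <- N * h
  keep <- rep(TRUE, nrow(pk))
  for (a in seq_len(nrow(pk))) {
    if (!keep[a]) next
    if (a < nrow(pk)) for (b in (a + 1):nrow(pk)) {
      if (keep[b] &&
          periodic_dist(pk$x[a], pk$y[a], pk$x[b], pk$y[b], L) < min_separation)
        keep[b] <- FALSE
    }
  }
  rownames(pk) <- NULL
  pk[keep, , drop = FALSE]
}

#' Bilinear periodic interpolation of a field
#' @keywords internal
interp_periodic <- function(field, xs, ys, h) {
  N <- nrow(field)
  gx <- (xs / h) %% N; gy <- (ys / h) %% N
  i0 <- floor(gx); j0 <- floor(gy)
  fx <- gx - i0; fy <- gy - j0
  i0 <- i0 %% N; j0 <- j0 %% N
  i1 <- (i0 + 1) %% N; j1 <- (j0 + 1) %% N
  f00 <- field[cbind(i0 + 1, j0 + 1)]; f10 <- field[cbind(i1 + 1, j0 + 1)]
  f01 <- field[cbind(i0 + 1, j1 + 1)]; f11 <- field[cbind(i1 + 1, j1 + 1)]
  f00 * (1 - fx) * (1 - fy) + f10 * fx * (1 - fy) +
    f01 * (1 - fx) * fy + f11 * fx * fy
}

#' Azimuthally averaged radial profile around a point
#'
#' Samples the field by bilinear interpolation on `n_angles` rays and
#' averages over angle at each radius.
#'
#' @param field Square matrix.
#' @param center c(x, y) in um.
#' @param h Grid spacing (um).
#' @param r Radii (um) at which to evaluate.
#' @param n_angles Angular samples per radius.
#' @return Numeric vector, the mean profile at each `r`.
#' @export
azimuthal_profile <- function(field, center, h, r, n_angles = 72) {
  th <- seq(0, 2 * pi, length.out = n_angles + 1L)[-1L]
  vapply(r, function(ri) {
    if (ri == 0) return(interp_periodic(field, center[1], center[2], h))
    mean(interp_periodic(field, center[1] + ri * cos(th),
                         center[2] + ri * sin(th), h))
  }, numeric(1))
}

#' Waistline radius of a polarity peak
#'
#' The waistline is the circle around the peak centroid at which the
#' azimuthally averaged summed-membrane-Cdc42 profile first falls to half
#' the peak value (the circle diameter is the peak width at half-height).
#'
#' @param field Square matrix (uM).
#' @param peak One row of [detect_peaks()] output (or a list with `x`, `y`).
#' @param h Grid spacing (um).
#' @param dr Radial sampling step (um), default `h/4`.
#' @return Radius in um.
#' @export
waistline <- function(field, peak, h, dr = h / 4) {
  N <- nrow(field); L <- N * h
  ctr <- c(peak$x, peak$y)
  r <- seq(0, L / 2 - h, by = dr)
  prof <- azimuthal_profile(field, ctr, h, r)
  half <- prof[1] / 2
  below <- which(prof <= half)
  if (length(below) == 0L)
    stop("profile never falls to half-maximum: peak overlaps the domain")
  k <- below[1]
  if (k == 1L) return(0)
  # linear interpolation between bracketing radii
  r[k - 1] + (half - prof[k - 1]) / (prof[k] - prof[k - 1]) * dr
}

disc_mask <- function(N, h, center, radius) {
  xy <- (seq_len(N) - 1) * h
  L <- N * h
  dx <- abs(xy - center[1]); dx <- pmin(dx, L - dx)
  dy <- abs(xy - center[2]); dy <- pmin(dy, L - dy)
  outer(dx^2, dy^2, "+") <= radius^2
}

#' Membrane Cdc42 content within the waistline disc
#'
#' Grid sum of the field over points within periodic distance `radius` of
#' the centroid, times the cell area `h^2` (uM um^2, eta-unweighted
#' membrane content).
#'
#' @inheritParams waistline
#' @param radius Disc radius (um), typically the waistline.
#' @return Content (uM um^2).
#' @export
peak_content <- function(field, peak, h, radius) {
  m <- disc_mask(nrow(field), h, c(peak$x, peak$y), radius)
  sum(field[m]) * h^2
}

#' Diffusive escape of Cdc42 across the waistline
#'
#' Line integral of `-Dm dC/dr` around the waistline circle, evaluated from
#' the azimuthally averaged profile: `flux = -Dm * 2 pi r * P'(r)`, also
#' expressed as percent of the content within the waistline per second.
#'
#' @inheritParams waistline
#' @param Dm Membrane diffusion coefficient (um^2/s).
#' @param radius Waistline radius (um); computed if missing.
#' @return List with `flux` (uM um^2 / s, positive = outward), `loss_pct`
#'   (%/s), `content` (uM um^2), `radius` (um).
#' @export
diffusive_flux_across_waistline <- function(field, peak, h, Dm,
                                            radius = NULL) {
  if (is.null(radius)) radius <- waistline(field, peak, h)
  dr <- h / 4
  ctr <- c(peak$x, peak$y)
  p2 <- azimuthal_profile(field, ctr, h, c(radius - dr, radius + dr))
  dPdr <- (p2[2] - p2[1]) / (2 * dr)
  flux <- -Dm * 2 * pi * radius * dPdr
  content <- peak_content(field, peak, h, radius)
  list(flux = flux, loss_pct = 100 * flux / content,
       content = content, radius = radius)
}

#' Net cytoplasmic Cdc42 recruitment within the waistline
#'
#' Disc integral of `k5a Cdc42Dc - k5b Cdc42Dm`, the only membrane-cytosol
#' Cdc42 exchange in the model (GDI shuttling).
#'
#' @param state A `polar_state`.
#' @param peak One row of [detect_peaks()].
#' @param params `polar_params`.
#' @param radius Disc radius (um); computed from the summed-membrane field
#'   if missing.
#' @return Net influx (uM um^2 / s, positive = into the membrane disc).
#' @export
cytoplasmic_flux_within_waistline <- function(state, peak, params,
                                              radius = NULL) {
  field <- membrane_cdc42(state)
  if (is.null(radius)) radius <- waistline(field, peak, state$h)
  m <- disc_mask(state$N, state$h, c(peak$x, peak$y), radius)
  Dmem <- state$fields[, , "Cdc42Dm"]
  sum(params$k5a * state$Cdc42Dc - params$k5b * Dmem[m]) * state$h^2
}

#' Per-peak flux summaries for one state
#' @keywords internal
peak_flux_summary <- function(state, params, min_height, min_separation = 1) {
  field <- membrane_cdc42(state)
  pks <- detect_peaks(field, state$h, min_height, min_separation)
  if (nrow(pks) == 0L) return(NULL)
  rows <- lapply(seq_len(nrow(pks)), function(k) {
    pk <- pks[k, ]
    w <- tryCatch(waistline(field, pk, state$h), error = function(e) NA_real_)
    if (is.na(w)) return(NULL)
    df <- diffusive_flux_across_waistline(field, pk, state$h, params$Dm, w)
    cf <- cytoplasmic_flux_within_waistline(state, pk, params, w)
    data.frame(t = state$t, peak = k, x = pk$x, y = pk$y,
               height = pk$height, radius = w, content = df$content,
               diff_flux = df$flux, diff_loss_pct = df$loss_pct,
               recruit_flux = cf)
  })
  do.call(rbind, rows)
}

#' Rate-balance curve from a competition trajectory
#'
#' For every recorded snapshot and every detected peak, computes the Cdc42
#' content within the waistline, the net cytoplasmic recruitment flux and
#' the diffusive outflux; contents are normalized to the winning peak's
#' final content. Flux-balance points (contents where recruitment and
#' diffusive loss cross) are located from the sign changes of their
#' difference along the content axis.
#'
#' @param trajectory A `polar_trajectory` with field snapshots, or a list
#'   of `polar_state`s.
#' @param params `polar_params`.
#' @param min_height Peak detection threshold (uM); default twice the
#'   homogeneous summed-membrane level.
#' @return data.frame (t, peak, content, norm_content, recruit_flux,
#'   diff_flux) with attribute `"balance_points"`: the normalized contents
#'   where `recruit_flux - diff_flux` changes sign.
#' @export
rate_balance_curve <- function(trajectory, params, min_height = NULL) {
  states <- if (inherits(trajectory, "polar_trajectory"))
    trajectory$states else trajectory
  if (is.null(min_height)) {
    ss <- homogeneous_steady_state(params, N = 8)
    min_height <- 2 * sum(state_as_vector(ss)[1:3])
  }
  rows <- lapply(states, peak_flux_summary, params = params,
                 min_height = min_height)
  tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(tab) || nrow(tab) == 0L)
    return(data.frame(t = numeric(0), peak = integer(0),
                      content = numeric(0), norm_content = numeric(0),
                      recruit_flux = numeric(0), diff_flux = numeric(0)))
  final_t <- max(tab$t)
  fin <- tab[tab$t == final_t, ]
  winner_content <- max(fin$content)
  tab$norm_content <- tab$content / winner_content
  ord <- tab[order(tab$norm_content), ]
  dlt <- ord$recruit_flux - ord$diff_flux
  sgn <- sign(dlt)
  cross <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  bp <- vapply(cross, function(i) {
    x1 <- ord$norm_content[i]; x2 <- ord$norm_content[i + 1]
    y1 <- dlt[i]; y2 <- dlt[i + 1]
    x1 - y1 * (x2 - x1) / (y2 - y1)
  }, numeric(1))
  out <- tab[, c("t", "peak", "content", "norm_content",
                 "recruit_flux", "diff_flux")]
  attr(out, "balance_points") <- unique(round(bp, 6))
  out
}
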