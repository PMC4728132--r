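#' Homogeneous steady state with mass-neutral random perturbations
#'
#' Adds zero-mean Gaussian perturbations to each membrane field (the
#' per-field spatial mean of the perturbation is removed, so both
#' conserved totals are unchanged exactly).
#'
#' @param params `polar_params`.
#' @param noise_amplitude Perturbation s.d. (uM).
#' @param seed RNG seed.
#' @param N Grid size.
#' @return A `polar_state`.
#' @export
make_noisy_homogeneous_state <- function(params, noise_amplitude, seed,
                                         N = 64) {
  stopifnot(noise_amplitude >= 0)
  ss <- homogeneous_steady_state(params, N = N)
  if (noise_amplitude == 0) return(ss)
  set.seed(seed)
  f <- ss$fields
  for (k in 1:4) {
    z <- matrix(rnorm(N * N, sd = noise_amplitude), N, N)
    z <- z - mean(z)
    if (min(f[, , k] + z) < 0)
      stop("noise amplitude drives a membrane field negative")
    f[, , k] <- f[, , k] + z
  }
  full_state(f, ss$Cdc42Dc, ss$BemGEFc, t = 0, params = params)
}

#' Script for a synthetic spot movie
#'
#' Describes a two-channel (or single-channel) time-lapse of
#' diffraction-limited polarity spots: Gaussian profiles on a noisy
#' background that appear, move along scripted paths, optionally blink,
#' and disappear.
#'
#' @param n_frames,frame_interval Frames and interval (s).
#' @param size_px Image side (px).
#' @param pixel_size Pixel size (um).
#' @param background Background level.
#' @param noise_sd Additive Gaussian noise s.d.
#' @param spots List of per-spot scripts; each a list with `birth`,
#'   `death` (frames), `path` (n_frames x 2 matrix of centroids, px; or a
#'   single c(x, y)), `amplitude` (scalar or per-frame vector),
#'   `sigma_px` (PSF s.d.), optional `blink_frames`.
#' @param n_channels Channels rendered.
#' @param channel_delay Frames by which channel 2 lags channel 1.
#' @param channel_scale Amplitude scale of channel 2 relative to channel 1.
#' @return A `movie_script` list.
#' @export
movie_script <- function(n_frames = 20, frame_interval = 45, size_px = 64,
                         pixel_size = 0.1, background = 10, noise_sd = 1,
                         spots = list(), n_channels = 1, channel_delay = 0,
                         channel_scale = 1) {
  for (sp in spots) {
    stopifnot(sp$birth >= 1, sp$death <= n_frames, sp$birth <= sp$death,
              all(unlist(sp["amplitude"]) >= 0))
  }
  structure(list(n_frames = n_frames, frame_interval = frame_interval,
                 size_px = size_px, pixel_size = pixel_size,
                 background = background, noise_sd = noise_sd,
                 spots = spots, n_channels = n_channels,
                 channel_delay = channel_delay,
                 channel_scale = channel_scale),
            class = "movie_script")
}

#' Two-spot competition movie preset
#'
#' Two spots born together; the loser's amplitude ramps linearly to zero
#' at `loser_death_frame` (emulating a losing cluster shrinking while the
#' winner persists), giving a scripted coexistence interval for
#' end-to-end recovery tests.
#'
#' @param n_frames,frame_interval,size_px Movie geometry.
#' @param loser_death_frame Last frame at which the loser is visible.
#' @param amplitude Peak amplitude of both spots at birth.
#' @param sigma_px PSF s.d. (px).
#' @param background,noise_sd Background level and noise s.d.
#' @param n_channels,channel_delay,channel_scale Channel layout.
#' @return A `movie_script` with attribute `"coexistence_frames"` =
#'   `loser_death_frame`: both spots are present in frames
#'   `1..loser_death_frame`, so the first single-spot frame is
#'   `loser_death_frame + 1` and the scripted interval spans
#'   `loser_death_frame` frames.
#' @export
competition_movie_script <- function(n_frames = 24, frame_interval = 45,
                                     size_px = 64, loser_death_frame = 12,
                                     amplitude = 100, sigma_px = 1.5,
                                     background = 10, noise_sd = 1,
                                     n_channels = 1, channel_delay = 0,
                                     channel_scale = 1) {
  stopifnot(loser_death_frame >= 2, loser_death_frame < n_frames)
  winner <- list(birth = 1, death = n_frames,
                 path = c(size_px * 0.3, size_px * 0.3),
                 amplitude = amplitude, sigma_px = sigma_px)
  ramp <- amplitude * seq(1, 0.35, length.out = loser_death_frame)
  loser <- list(birth = 1, death = loser_death_frame,
                path = c(size_px * 0.7, size_px * 0.7),
                amplitude = c(ramp, rep(0, n_frames - loser_death_frame)),
                sigma_px = sigma_px)
  sc <- movie_script(n_frames = n_frames, frame_interval = frame_interval,
                     size_px = size_px, background = background,
                     noise_sd = noise_sd, spots = list(winner, loser),
                     n_channels = n_channels,
                     channel_delay = channel_delay,
                     channel_scale = channel_scale)
  attr(sc, "coexistence_frames") <- loser_death_frame
  sc
}

render_spot <- function(img, ctr, amplitude, sigma) {
  ny <- nrow(img); nx <- ncol(img)
  ys <- seq_len(ny); xs <- seq_len(nx)
  img + amplitude * exp(-outer((ys - ctr[2])^2, (xs - ctr[1])^2, "+") /
                          (2 * sigma^2))
}

spot_frame_values <- function(sp, f, n_frames) {
  present <- f >= sp$birth && f <= sp$death &&
    !(f %in% (sp$blink_frames %||% integer(0)))
  amp <- if (length(sp$amplitude) > 1) sp$amplitude[f] else sp$amplitude
  ctr <- if (is.matrix(sp$path)) sp$path[f, ] else sp$path
  list(present = present && amp > 0, amplitude = amp, ctr = ctr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render a synthetic spot movie with ground truth
#'
#' @param script A `movie_script`.
#' @param seed RNG seed (noise realization).
#' @return List: `stack` (a `polar_stack`), `truth` (data.frame with one
#'   row per spot per frame: frame, spot, present, x, y, amplitude,
#'   intensity_sum) and `counts` (true per-frame spot counts).
#' @export
make_spot_movie <- function(script, seed = 1) {
  stopifnot(inherits(script, "movie_script"))
  set.seed(seed)
  n <- script$size_px
  dat <- array(0, dim = c(n, n, script$n_channels, script$n_frames))
  truth <- list()
  for (f in seq_len(script$n_frames)) {
    for (ch in seq_len(script$n_channels)) {
      img <- matrix(script$background, n, n)
      fe <- if (ch == 2) f - script$channel_delay else f
      scale <- if (ch == 2) script$channel_scale else 1
      if (fe >= 1) for (si in seq_along(script$spots)) {
        sp <- script$spots[[si]]
        v <- spot_frame_values(sp, fe, script$n_frames)
        if (v$present)
          img <- render_spot(img, v$ctr, scale * v$amplitude, sp$sigma_px)
        if (ch == 1)
          truth[[length(truth) + 1]] <- data.frame(
            frame = f, spot = si, present = v$present,
            x = v$ctr[1], y = v$ctr[2], amplitude = v$amplitude,
            intensity_sum = if (v$present)
              2 * pi * sp$sigma_px^2 * v$amplitude else 0)
      }
      img <- img + matrix(rnorm(n * n, sd = script$noise_sd), n, n)
      dat[, , ch, f] <- pmax(img, 0)
    }
  }
  truth <- do.call(rbind, truth)
  counts <- vapply(seq_len(script$n_frames), function(f)
    sum(truth$present[truth$frame == f]), integer(1))
  list(stack = image_stack(dat, script$frame_interval, script$pixel_size),
       truth = truth, counts = counts)
}

#' Script for a synthetic FRAP trace
#'
#' @param k_fast,k_slow Recovery rate constants (1/s), `k_fast > k_slow`.
#' @param A_fast,A_slow Recovery amplitudes (fractions of pre-bleach).
#' @param bleach_depth Post-bleach floor (fraction of pre-bleach).
#' @param pre_bleach_frames Frames acquired before the bleach.
#' @param n_post Post-bleach acquisitions.
#' @param frame_interval Pre-bleach frame interval (s).
#' @param adapted_times Use adapted post-bleach intervals (quadratically
#'   spaced over `span`), dense early to resolve the fast component, as
#'   recovery acquisitions are in practice? Otherwise uniform at
#'   `frame_interval`.
#' @param span Total post-bleach acquisition time (s); default covers
#'   several slow half-lives.
#' @param noise_sd Relative Gaussian noise s.d.
#' @return A `trace_script`.
#' @export
frap_script <- function(k_fast = 2, k_slow = 0.2, A_fast = 0.25,
                        A_slow = 0.55, bleach_depth = 0.15,
                        pre_bleach_frames = 3, n_post = 23,
                        frame_interval = 0.5, adapted_times = TRUE,
                        span = 6 / k_slow, noise_sd = 0.01) {
  stopifnot(k_fast > 0, k_slow > 0, pre_bleach_frames >= 3)
  structure(list(k_fast = k_fast, k_slow = k_slow, A_fast = A_fast,
                 A_slow = A_slow, bleach_depth = bleach_depth,
                 pre_bleach_frames = pre_bleach_frames, n_post = n_post,
                 frame_interval = frame_interval,
                 adapted_times = adapted_times, span = span,
                 noise_sd = noise_sd),
            class = "trace_script")
}

#' Synthetic FRAP trace with known kinetics
#'
#' Pre-bleach plateau at 1, bleach drop, then
#' `bleach_depth + A_fast (1 - exp(-k_fast t)) + A_slow (1 - exp(-k_slow t))`
#' plus relative Gaussian noise.
#'
#' @param script A [frap_script()].
#' @param seed RNG seed.
#' @return List: `trace`, `times` (s), `truth` (the script plus the true
#'   slow half-time `ln 2 / k_slow`).
#' @export
make_frap_trace <- function(script, seed = 1) {
  stopifnot(inherits(script, "trace_script"))
  set.seed(seed)
  s <- script
  t_post <- if (isTRUE(s$adapted_times))
    s$span * ((seq_len(s$n_post) - 1) / (s$n_post - 1))^2
  else (seq_len(s$n_post) - 1) * s$frame_interval
  recov <- s$bleach_depth + s$A_fast * (1 - exp(-s$k_fast * t_post)) +
    s$A_slow * (1 - exp(-s$k_slow * t_post))
  trace <- c(rep(1, s$pre_bleach_frames), recov)
  trace <- trace * (1 + rnorm(length(trace), sd = s$noise_sd))
  times <- c((seq_len(s$pre_bleach_frames) - 1) * s$frame_interval,
             (s$pre_bleach_frames - 1) * s$frame_interval + s$frame_interval +
               t_post)
  list(trace = trace, times = times,
       truth = c(unclass(s), list(half_time = log(2) / s$k_slow)))
}

#' Synthetic FLIP traces with known exchange rate
#'
#' Repeated bleaching of a cytoplasmic zone drains the polarity focus at
#' the membrane-cytosol exchange rate: the focus trace decays as
#' `exp(-loss_rate * t)` from its pre-bleach value, while a neighbor-cell
#' control trace decays only with the (slow) indirect bleaching rate and
#' the background stays constant.
#'
#' @param loss_rate Focus exchange/loss rate (1/s).
#' @param n_frames Number of bleach/image cycles.
#' @param frame_interval Cycle interval (s).
#' @param focus0,neighbor0,background Initial focus and neighbor
#'   intensities and the constant background level.
#' @param indirect_rate Indirect photobleaching rate applied to both focus
#'   and neighbor (1/s).
#' @param noise_sd Additive Gaussian noise s.d.
#' @param seed RNG seed.
#' @return List: `I_focus`, `I_neighbor`, `I_background`, `times`,
#'   `truth` (loss_rate).
#' @export
make_flip_traces <- function(loss_rate, n_frames = 36, frame_interval = 0.5,
                             focus0 = 100, neighbor0 = 80, background = 10,
                             indirect_rate = 0.002, noise_sd = 0,
                             seed = 1) {
  stopifnot(loss_rate >= 0)
  set.seed(seed)
  times <- (seq_len(n_frames) - 1) * frame_interval
  indirect <- exp(-indirect_rate * times)
  I_focus <- background + (focus0 - background) * exp(-loss_rate * times) *
    indirect + rnorm(n_frames, sd = noise_sd)
  I_neighbor <- background + (neighbor0 - background) * indirect +
    rnorm(n_frames, sd = noise_sd)
  list(I_focus = I_focus, I_neighbor = I_neighbor,
       I_background = rep(background, n_frames), times = times,
       truth = list(loss_rate = loss_rate))
}
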