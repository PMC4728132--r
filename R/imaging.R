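#' Time-lapse image stack
#'
#' Carrier for two-channel summed-projection movies: a 4-D array indexed
#' `[y, x, channel, frame]` with uniform frame interval and pixel size.
#'
#' @param data Numeric array `[y, x, channel, frame]`, non-negative.
#' @param frame_interval Frame interval (s).
#' @param pixel_size Pixel size (um).
#' @param channels Channel labels.
#' @return A `polar_stack`.
#' @export
image_stack <- function(data, frame_interval, pixel_size = 0.1,
                        channels = NULL) {
  if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L, 1L)
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data)[1:2], 1L, dim(data)[3])
  stopifnot(length(dim(data)) == 4L, min(data) >= 0,
            frame_interval > 0, pixel_size > 0)
  if (is.null(channels)) channels <- paste0("ch", seq_len(dim(data)[3]))
  structure(list(data = data, frame_interval = frame_interval,
                 pixel_size = pixel_size, channels = channels,
                 n_frames = dim(data)[4], n_channels = dim(data)[3]),
            class = "polar_stack")
}

#' @export
print.polar_stack <- function(x, ...) {
  cat(sprintf("polar_stack: %dx%d px, %d channel(s), %d frames @ %g s\n",
              dim(x$data)[1], dim(x$data)[2], x$n_channels, x$n_frames,
              x$frame_interval))
  invisible(x)
}

label_components <- function(mask) {
  # 8-connected component labeling by flood fill
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- matrix(0L, ny, nx)
  cur <- 0L
  idx <- which(mask)
  for (s in idx) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    lab[s] <- cur
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      py <- (p - 1L) %% ny + 1L; px <- (p - 1L) %/% ny + 1L
      for (dy in -1:1) for (dx in -1:1) {
        qy <- py + dy; qx <- px + dx
        if (qy < 1L || qy > ny || qx < 1L || qx > nx) next
        q <- (qx - 1L) * ny + qy
        if (mask[q] && lab[q] == 0L) { lab[q] <- cur; stack <- c(stack, q) }
      }
    }
  }
  lab
}

#' Segment polarity spots in one frame
#'
#' Two thresholds: the lower separates cells from background, the higher
#' defines polarity spots within cells. Spots are 8-connected components
#' above the spot threshold whose pixels lie inside the cell mask and
#' whose area is at least `filter_size_px2` (a nonzero filter size
#' excludes small noise speckles).
#'
#' @param frame Matrix `[y, x]` of intensities.
#' @param cell_threshold Cell/background threshold.
#' @param spot_threshold Spot threshold (> `cell_threshold`).
#' @param filter_size_px2 Minimum spot area (px^2).
#' @return data.frame (x, y intensity-weighted centroid in px, area,
#'   intensity_sum, intensity_max), sorted by decreasing intensity_sum.
#' @export
segment_spots <- function(frame, cell_threshold, spot_threshold,
                          filter_size_px2 = 4) {
  stopifnot(is.matrix(frame), spot_threshold > cell_threshold)
  mask <- frame >= spot_threshold & frame >= cell_threshold
  lab <- label_components(mask)
  n <- max(lab)
  if (n == 0L)
    return(data.frame(x = numeric(0), y = numeric(0), area = integer(0),
                      intensity_sum = numeric(0), intensity_max = numeric(0)))
  rows <- lapply(seq_len(n), function(k) {
    pix <- which(lab == k, arr.ind = TRUE)
    if (nrow(pix) < filter_size_px2) return(NULL)
    w <- frame[pix]
    data.frame(x = sum(pix[, 2] * w) / sum(w),
               y = sum(pix[, 1] * w) / sum(w),
               area = nrow(pix), intensity_sum = sum(w),
               intensity_max = max(w))
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    return(data.frame(x = numeric(0), y = numeric(0), area = integer(0),
                      intensity_sum = numeric(0), intensity_max = numeric(0)))
  out <- out[order(-out$intensity_sum), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Track spots across frames by greedy nearest-neighbor linking
#'
#' Each spot at frame `t+1` is linked to the nearest track whose last
#' position lies within `target_radius_px`; spots are processed in order
#' of decreasing intensity (ties by lowest track id). Unlinked spots start
#' new tracks. With `remove_blinking`, a track that temporarily loses its
#' spot stays eligible for re-linking for up to `max_gap` frames.
#'
#' @param spots_by_frame List (one entry per frame) of [segment_spots()]
#'   data.frames.
#' @param target_radius_px Linking radius (px).
#' @param remove_blinking Bridge gaps of up to `max_gap` frames?
#' @param max_gap Largest bridgeable gap (frames).
#' @return List of tracks (class `polar_tracks`); each track is a
#'   data.frame (frame, x, y, area, intensity_sum) with attributes `birth`
#'   and `death` (first/last frame present).
#' @export
track_spots <- function(spots_by_frame, target_radius_px,
                        remove_blinking = FALSE, max_gap = 2) {
  stopifnot(target_radius_px > 0)
  tracks <- list()   # each: list(rows = data.frame, last_frame)
  for (f in seq_along(spots_by_frame)) {
    sp <- spots_by_frame[[f]]
    if (is.null(sp) || nrow(sp) == 0L) next
    sp <- sp[order(-sp$intensity_sum), , drop = FALSE]
    claimed <- rep(FALSE, length(tracks))
    for (k in seq_len(nrow(sp))) {
      best <- 0L; best_d <- Inf
      for (ti in seq_along(tracks)) {
        if (claimed[ti]) next
        tr <- tracks[[ti]]
        gap <- f - tr$last_frame
        if (gap < 1L) next
        if (gap > 1L && (!remove_blinking || gap > max_gap + 1L)) next
        last <- tr$rows[nrow(tr$rows), ]
        d <- sqrt((sp$x[k] - last$x)^2 + (sp$y[k] - last$y)^2)
        if (d <= target_radius_px &&
            (d < best_d || (d == best_d && ti < best))) {
          best <- ti; best_d <- d
        }
      }
      row <- data.frame(frame = f, x = sp$x[k], y = sp$y[k],
                        area = sp$area[k], intensity_sum = sp$intensity_sum[k])
      if (best > 0L) {
        tracks[[best]]$rows <- rbind(tracks[[best]]$rows, row)
        tracks[[best]]$last_frame <- f
        claimed[best] <- TRUE
      } else {
        tracks[[length(tracks) + 1L]] <- list(rows = row, last_frame = f)
        claimed <- c(claimed, TRUE)
      }
    }
  }
  out <- lapply(tracks, function(tr) {
    r <- tr$rows
    attr(r, "birth") <- r$frame[1]
    attr(r, "death") <- r$frame[nrow(r)]
    r
  })
  class(out) <- "polar_tracks"
  out
}

#' @export
print.polar_tracks <- function(x, ...) {
  cat(sprintf("polar_tracks: %d track(s)\n", length(x)))
  for (i in seq_along(x))
    cat(sprintf("  track %d: frames %d-%d (%d present)\n", i,
                attr(x[[i]], "birth"), attr(x[[i]], "death"), nrow(x[[i]])))
  invisible(x)
}

track_position <- function(track, frame) {
  i <- which(track$frame == frame)
  if (length(i)) return(c(track$x[i[1]], track$y[i[1]]))
  j <- which.min(abs(track$frame - frame))
  c(track$x[j], track$y[j])
}

#' Intensity trace in the vicinity of a tracked spot
#'
#' The vicinity is a circular region centered on the spot centroid (a
#' pixel belongs to the circle if its center lies within the radius). Per
#' frame and channel, the `mean` or `sum` of the non-background pixels
#' (those at or above `cell_threshold`) in the circle is reported, minus
#' the background level. The background is the mean in-cell intensity one
#' frame before the spot is first detected; when no pre-detection frame
#' exists, the per-frame cell-interior median is used instead. With
#' `normalize = TRUE` each channel is rescaled to percent of its maximum
#' over the trace.
#'
#' @param stack A `polar_stack`.
#' @param track One track from [track_spots()].
#' @param radius_px Vicinity radius (px).
#' @param statistic `"mean"` or `"sum"`.
#' @param cell_threshold Non-background criterion within the circle.
#' @param normalize Report percent-of-maximum?
#' @return data.frame (frame, t, one column per channel); attribute
#'   `"background"` holds the per-channel background used.
#' @export
vicinity_trace <- function(stack, track, radius_px,
                           statistic = c("mean", "sum"),
                           cell_threshold = 0, normalize = FALSE) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(stack, "polar_stack"), radius_px > 0)
  if (nrow(track) == 0L) stop("track is never present")
  ny <- dim(stack$data)[1]; nx <- dim(stack$data)[2]
  birth <- attr(track, "birth")
  bg <- vapply(seq_len(stack$n_channels), function(ch) {
    if (!is.null(birth) && birth > 1L) {
      fr <- stack$data[, , ch, birth - 1L]
      cell <- fr[fr >= cell_threshold]
      if (length(cell)) mean(cell) else 0
    } else NA_real_
  }, numeric(1))
  out <- data.frame(frame = seq_len(stack$n_frames),
                    t = (seq_len(stack$n_frames) - 1L) * stack$frame_interval)
  for (ch in seq_len(stack$n_channels)) {
    vals <- vapply(seq_len(stack$n_frames), function(f) {
      ctr <- track_position(track, f)
      ys <- pmax(1, floor(ctr[2] - radius_px)):pmin(ny, ceiling(ctr[2] + radius_px))
      xs <- pmax(1, floor(ctr[1] - radius_px)):pmin(nx, ceiling(ctr[1] + radius_px))
      sub <- stack$data[ys, xs, ch, f, drop = FALSE]
      dist2 <- outer((ys - ctr[2])^2, (xs - ctr[1])^2, "+")
      inside <- dist2 <= radius_px^2
      pix <- sub[cbind(which(inside, arr.ind = TRUE), 1, 1)]
      pix <- pix[pix >= cell_threshold]
      if (!length(pix)) return(NA_real_)
      b <- bg[ch]
      if (is.na(b)) {
        fr <- stack$data[, , ch, f]
        cell <- fr[fr >= cell_threshold]
        b <- if (length(cell)) median(cell) else 0
      }
      if (statistic == "mean") mean(pix) - b else sum(pix - b)
    }, numeric(1))
    if (normalize) vals <- 100 * vals / max(vals, na.rm = TRUE)
    out[[stack$channels[ch]]] <- vals
  }
  attr(out, "background") <- bg
  out
}

#' Coexistence time from per-frame spot counts
#'
#' The interval between the first frame in which more than one spot is
#' detected and the first subsequent frame in which exactly one spot is
#' detected.
#'
#' @param counts Integer vector of per-frame spot counts.
#' @param frame_interval_s Frame interval (s).
#' @return List with `time` (s, `NA` unless resolved) and `status`:
#'   `"resolved"`, `"none"` (never more than one spot) or `"censored"`
#'   (multi-spot state never resolves).
#' @export
coexistence_time <- function(counts, frame_interval_s) {
  onset <- which(counts > 1L)[1]
  if (is.na(onset)) return(list(time = NA_real_, status = "none"))
  after <- which(counts == 1L & seq_along(counts) > onset)[1]
  if (is.na(after)) return(list(time = NA_real_, status = "censored"))
  list(time = (after - onset) * frame_interval_s, status = "resolved")
}

#' FLIP trace normalization
#'
#' `(I_focus - I_background) / (I_neighbor - I_background)`, elementwise;
#' the neighbor-cell trace corrects for indirect bleaching during the
#' repeated bleach events. Frames with non-positive denominator are
#' returned as `NA` and flagged.
#'
#' @param I_focus,I_neighbor,I_background Equal-length intensity vectors.
#' @return Normalized trace; attribute `"flagged"` lists bad frames.
#' @export
flip_normalize <- function(I_focus, I_neighbor, I_background) {
  stopifnot(length(I_focus) == length(I_neighbor))
  den <- I_neighbor - I_background
  bad <- which(den <= 0)
  out <- (I_focus - I_background) / den
  out[bad] <- NA_real_
  attr(out, "flagged") <- bad
  out
}

#' FRAP recovery half-time from a double-exponential fit
#'
#' Normalizes the trace to the pre-bleach mean, then fits the post-bleach
#' recovery with `I0 + A1 (1 - exp(-k1 t)) + A2 (1 - exp(-k2 t))`
#' (`k1 > k2 > 0`): the fast component captures recovery of bleached
#' cytoplasm inside the bleach zone, the slow one exchange of the membrane
#' signal. The recovery half-time is `ln 2 / k_slow`. If the slow
#' component's amplitude is degenerate (< 5% of the recovered amplitude)
#' the fit falls back to a single exponential.
#'
#' @param trace Intensity vector (background-subtracted).
#' @param times Acquisition times (s); default `0, 1, 2, ...`.
#' @param pre_bleach_frames Number of leading pre-bleach frames (>= 3).
#' @return List: `half_time` (s), `k_fast`, `k_slow` (1/s), `r_squared`,
#'   `flagged` (TRUE when the fit fell back or hit bounds), `fit`.
#' @export
frap_halftime <- function(trace, times = seq_along(trace) - 1,
                          pre_bleach_frames = 3) {
  stopifnot(pre_bleach_frames >= 3, length(trace) == length(times))
  pre <- mean(trace[seq_len(pre_bleach_frames)])
  if (pre <= 0) stop("non-positive pre-bleach reference")
  y <- trace / pre
  post <- (pre_bleach_frames + 1L):length(y)
  tp <- times[post] - times[post[1]]
  yp <- y[post]

  I0 <- yp[1]
  plateau <- mean(yp[max(1, length(yp) - 3):length(yp)])
  amp <- max(plateau - I0, 1e-3)
  half_idx <- which(yp >= I0 + amp / 2)[1]
  k_guess <- if (!is.na(half_idx) && tp[half_idx] > 0)
    log(2) / tp[half_idx] else 1 / max(tp) * 2

  single <- function() {
    fit <- minpack.lm::nlsLM(
      yp ~ I0f + Af * (1 - exp(-kf * tp)),
      start = list(I0f = I0, Af = amp, kf = k_guess),
      lower = c(-Inf, 0, 1e-6), control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- coef(fit)
    list(k_fast = cf[["kf"]], k_slow = cf[["kf"]], fit = fit, flagged = TRUE)
  }
  # double-exponential least squares from several starting rate pairs;
  # keep the lowest-SSR converged fit (the surface has degenerate
  # single-exponential ridges that trap single-start optimizers)
  best <- NULL
  for (f1 in c(3, 10, 30)) for (f2 in c(0.5, 1)) {
    fit <- tryCatch(minpack.lm::nlsLM(
      yp ~ I0f + A1 * (1 - exp(-k1 * tp)) + A2 * (1 - exp(-k2 * tp)),
      start = list(I0f = I0, A1 = amp * 0.4, k1 = k_guess * f1,
                   A2 = amp * 0.6, k2 = k_guess * f2),
      lower = c(-Inf, 0, 1e-6, 0, 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(residuals(fit)^2)
    if (is.null(best) || ssr < best$ssr) best <- list(fit = fit, ssr = ssr)
  }
  res <- if (is.null(best)) single() else {
    cf <- coef(best$fit)
    ks <- c(cf[["k1"]], cf[["k2"]]); As <- c(cf[["A1"]], cf[["A2"]])
    slow <- which.min(ks)
    if (As[slow] < 0.05 * sum(As) || abs(diff(ks)) < 1e-8 * max(ks))
      single()
    else
      list(k_fast = max(ks), k_slow = min(ks), fit = best$fit,
           flagged = FALSE)
  }

  pred <- predict(res$fit)
  r2 <- 1 - sum((yp - pred)^2) / sum((yp - mean(yp))^2)
  list(half_time = log(2) / res$k_slow, k_fast = res$k_fast,
       k_slow = res$k_slow, r_squared = r2, flagged = res$flagged,
       fit = res$fit)
}

#' Fraction of cells with multi-cluster intermediates
#'
#' @param multi Logical vector, one entry per cell (`TRUE` when more than
#'   one cluster was detected in that cell's movie).
#' @param conf_level Confidence level of the binomial interval.
#' @return List: `percent`, `ci` (percent, Clopper-Pearson), `n`.
#' @export
multi_cluster_fraction <- function(multi, conf_level = 0.95) {
  stopifnot(length(multi) >= 1, is.logical(multi))
  bt <- stats::binom.test(sum(multi), length(multi), conf.level = conf_level)
  list(percent = 100 * mean(multi), ci = 100 * as.numeric(bt$conf.int),
       n = length(multi))
}

#' Cortical-to-internal intensity ratio (simple approximation)
#'
#' Ratio of the mean intensity on the cell-mask boundary ring (cortex) to
#' the mean over the eroded interior. A deliberately simple mask-based
#' approximation, not a calibrated cortical/cytoplasmic index.
#'
#' @param frame Intensity matrix.
#' @param cell_threshold Cell mask threshold.
#' @return Ratio (cortex mean / interior mean).
#' @export
cortical_interior_ratio <- function(frame, cell_threshold) {
  mask <- frame >= cell_threshold
  er <- mask
  ny <- nrow(mask); nx <- ncol(mask)
  for (dy in -1:1) for (dx in -1:1) {
    sh <- matrix(FALSE, ny, nx)
    ys <- pmin(pmax(seq_len(ny) + dy, 1), ny)
    xs <- pmin(pmax(seq_len(nx) + dx, 1), nx)
    er <- er & mask[ys, xs]
  }
  ring <- mask & !er
  if (!any(ring) || !any(er)) stop("cell mask too small for a cortex ring")
  mean(frame[ring]) / mean(frame[er])
}
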