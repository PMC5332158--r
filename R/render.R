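#' Render a synthetic kymograph image stack
#'
#' Turns a \code{\link{cell_trajectory}} into a multi-frame grayscale image
#' stack emulating out-of-focus white-light imaging of a catch channel: the
#' cell is a dark horizontal rod on a bright background, anchored at the
#' channel notch and extending toward the central trench by its current
#' length. A darker septum band is drawn at the newly formed pole for a few
#' frames after each division. Imaging nuisances are then applied in order:
#' a global field rotation, a per-frame integer stage jitter (recorded in
#' the ground truth) and additive Gaussian noise.
#'
#' @param traj A \code{\link{cell_trajectory}} sampled on a uniform grid.
#' @param imaging An \code{\link{imaging_params}}.
#' @param seed Integer seed for jitter and noise.
#' @return An object of class \code{"kymograph_stack"}: \code{frames}
#'   (array rows x cols x time), \code{timestamps} (hours), \code{imaging},
#'   and \code{truth} (generating trajectory, applied per-frame shifts,
#'   applied rotation).
#' @export
render_kymograph_stack <- function(traj, imaging = imaging_params(), seed = 1L) {
  stopifnot(inherits(traj, "cell_trajectory"), inherits(imaging, "imaging_params"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  im <- imaging
  nr <- im$frame_shape[1]; nc <- im$frame_shape[2]
  nt <- length(traj$times)
  len_px <- round(traj$lengths / im$pixel_size)
  if (any(im$notch_col + len_px - 1 > nc))
    stopf("frame-geometry error: cell length %.1f um exceeds frame extent (%d px at %.2f um/px)",
          max(traj$lengths), nc - im$notch_col + 1, im$pixel_size)

  half_h <- max(2L, round(1.75 / im$pixel_size))   # ~3.5 um cell diameter
  r0 <- max(1L, im$channel_center_row - half_h)
  r1 <- min(nr, im$channel_center_row + half_h)
  bg <- 1.0; cell_int <- 0.3; septum_int <- 0.08; wall_int <- 0.55

  # Static channel geometry: PDMS fills the field outside the catch channel,
  # with darker channel-boundary ridges at regular spacing and a dead-end
  # notch wall. This static structure dominates the cross-correlation, so
  # registration locks onto the device rather than the growing cell, as in
  # real fields of view.
  base <- matrix(bg, nr, nc)
  ch_lo <- max(1L, r0 - 2L); ch_hi <- min(nr, r1 + 2L)
  pdms_rows <- setdiff(seq_len(nr), ch_lo:ch_hi)
  if (length(pdms_rows) > 0) {
    base[pdms_rows, ] <- wall_int
    ridge_cols <- seq(im$notch_col, nc - 1L, by = 16L)
    base[pdms_rows, c(ridge_cols, ridge_cols + 1L)] <- 0.2
  }
  base[, max(1L, im$notch_col - 3L):(im$notch_col - 1L)] <- 0.2

  # frames showing a septum band: within 3 frames after each division
  dt <- traj$sampling_interval / 60
  div_frame <- vapply(traj$division_times,
                      function(td) which.min(abs(traj$times - td)), integer(1))

  frames <- array(bg, dim = c(nr, nc, nt))
  jit <- matrix(0L, nt, 2)
  if (im$max_jitter > 0 && nt > 1) {
    span <- 2L * as.integer(im$max_jitter) + 1L
    jit[-1, 1] <- as.integer(sample.int(span, nt - 1L, replace = TRUE) -
                               as.integer(im$max_jitter) - 1L)
    jit[-1, 2] <- as.integer(sample.int(span, nt - 1L, replace = TRUE) -
                               as.integer(im$max_jitter) - 1L)
  }
  for (t in seq_len(nt)) {
    f <- base
    if (len_px[t] >= 1) {
      c1 <- im$notch_col; c2 <- im$notch_col + len_px[t] - 1L
      f[r0:r1, c1:c2] <- cell_int
      # septum band just inside the new pole shortly after division
      recent <- div_frame[t - div_frame >= 0 & t - div_frame <= 3]
      if (length(recent) > 0 && len_px[t] > 4) {
        sc <- min(c2, nc)
        f[r0:r1, max(c1, sc - 3L):(sc - 2L)] <- septum_int
      }
    }
    f <- blur_optics(f)
    if (im$rotation_deg != 0)
      f <- ebimage_rotate(f, im$rotation_deg, bg)
    if (any(jit[t, ] != 0L))
      f <- shift_matrix(f, jit[t, 1], jit[t, 2], fill = bg)
    if (im$noise_sd > 0)
      f <- f + matrix(rnorm(nr * nc, 0, im$noise_sd), nr, nc)
    frames[, , t] <- f
  }
  structure(list(frames = frames, timestamps = traj$times, imaging = im,
                 truth = list(trajectory = traj, shifts = jit,
                              rotation_deg = im$rotation_deg)),
            class = "kymograph_stack")
}

#' @export
print.kymograph_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Kymograph stack: %d frames of %d x %d px, %.1f h\n",
              d[3], d[1], d[2], max(x$timestamps)))
  invisible(x)
}

# small separable Gaussian blur emulating the deliberately out-of-focus
# acquisition used for septum-resolved contrast; also keeps edge profiles
# band-limited so interpolation round trips cleanly
blur_optics <- function(m, sigma = 0.7) {
  k <- exp(-((-2):2)^2 / (2 * sigma^2)); k <- k / sum(k)
  pad <- function(x) rbind(x[c(1, 1), ], x, x[nrow(x) + c(0, 0), ])
  conv_rows <- function(x) {
    xp <- pad(x)
    k[1] * xp[1:nrow(x), ] + k[2] * xp[2:(nrow(x) + 1), ] +
      k[3] * xp[3:(nrow(x) + 2), ] + k[4] * xp[4:(nrow(x) + 3), ] +
      k[5] * xp[5:(nrow(x) + 4), ]
  }
  t(conv_rows(t(conv_rows(m))))
}

# rotate a matrix about its centre, preserving shape
ebimage_rotate <- function(m, angle, bg) {
  EBImage::rotate(m, angle, filter = "bilinear",
                  output.dim = dim(m), bg.col = bg)
}

# integer translation with constant fill; positive dr moves content down,
# positive dc moves content right
shift_matrix <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  sr <- seq_len(nr); sc <- seq_len(nc)
  dst_r <- sr + dr; dst_c <- sc + dc
  ok_r <- dst_r >= 1 & dst_r <= nr; ok_c <- dst_c >= 1 & dst_c <= nc
  out[dst_r[ok_r], dst_c[ok_c]] <- m[sr[ok_r], sc[ok_c]]
  out
}
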