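#' Correct a global field rotation
#'
#' Applies the inverse of a measured field rotation to every frame of a
#' stack, so that the long axis of the catch channel is horizontal in all
#' subsequent analyses. Bilinear interpolation; frame shape is preserved.
#'
#' @param stack A \code{\link{render_kymograph_stack}} stack (or any
#'   \code{kymograph_stack}).
#' @param measured_angle The measured rotation in degrees (|angle| < 45);
#'   each frame is rotated by \code{-measured_angle} about its centre.
#' @return The corrected stack.
#' @export
correct_rotation <- function(stack, measured_angle) {
  stopifnot(inherits(stack, "kymograph_stack"))
  if (abs(measured_angle) >= 45) stopf("|measured_angle| must be < 45 degrees")
  if (measured_angle == 0) return(stack)
  bg <- stats::median(stack$frames[, c(1, ncol(stack$frames[, , 1])), 1])
  for (t in seq_len(dim(stack$frames)[3]))
    stack$frames[, , t] <- ebimage_rotate(stack$frames[, , t], -measured_angle, bg)
  stack
}

#' Register a stack against its first frame
#'
#' Estimates the integer (row, column) translation of every frame relative
#' to the first frame by the peak of the FFT cross-correlation, and removes
#' it. This undoes the stage jitter introduced when the microscope revisits
#' a field of view.
#'
#' @param stack A \code{kymograph_stack} with at least 2 frames.
#' @return A list of class \code{"registration_result"} with \code{shifts}
#'   (n x 2 integer matrix, frame 1 = (0,0)) and \code{registered}, the
#'   shift-corrected stack.
#' @export
register_stack <- function(stack) {
  stopifnot(inherits(stack, "kymograph_stack"))
  nt <- dim(stack$frames)[3]
  if (nt < 2) stopf("registration needs at least 2 frames")
  ref <- stack$frames[, , 1]
  if (sd(ref) == 0) stopf("degenerate-correlation error: reference frame is constant")
  shifts <- matrix(0L, nt, 2)
  bg <- stats::median(ref[, c(1, ncol(ref))])
  for (t in 2:nt) {
    fr <- stack$frames[, , t]
    if (sd(fr) == 0) stopf("degenerate-correlation error: frame %d is constant", t)
    shifts[t, ] <- xcorr_shift(ref, fr)
    if (any(shifts[t, ] != 0L))
      stack$frames[, , t] <- shift_matrix(fr, -shifts[t, 1], -shifts[t, 2], fill = bg)
  }
  structure(list(shifts = shifts, registered = stack),
            class = "registration_result")
}

# integer displacement (dr, dc) of frame b relative to frame a, from the
# peak of the circular FFT cross-correlation; b ~ a shifted by (dr, dc)
xcorr_shift <- function(a, b) {
  A <- fft(a - mean(a)); B <- fft(b - mean(b))
  cc <- Re(fft(Conj(A) * B, inverse = TRUE))
  k <- which.max(cc)
  nr <- nrow(a); nc <- ncol(a)
  i0 <- (k - 1) %% nr          # 0-based
  j0 <- (k - 1) %/% nr
  dr <- if (i0 > nr / 2) i0 - nr else i0
  dc <- if (j0 > nc / 2) j0 - nc else j0
  as.integer(c(dr, dc))
}

#' Build a 2-D kymograph from a registered stack
#'
#' Extracts, from each frame, the line of pixels along the catch-channel
#' centreline starting at the notch and extending toward the central
#' trench, and stacks the lines as rows. Time increases down rows; column 1
#' is the notch (old-pole anchor).
#'
#' @param stack A registered \code{kymograph_stack}.
#' @param notch_position Pixel column of the notch (defaults to the stack's
#'   imaging parameters).
#' @param centerline_row Pixel row of the channel centreline (defaults to
#'   the stack's imaging parameters).
#' @return An object of class \code{"kymograph"}: \code{intensity} (time x
#'   position matrix), \code{timestamps}, \code{pixel_size}.
#' @export
build_kymograph <- function(stack, notch_position = NULL, centerline_row = NULL) {
  stopifnot(inherits(stack, "kymograph_stack"))
  notch_position <- notch_position %||% stack$imaging$notch_col
  centerline_row <- centerline_row %||% stack$imaging$channel_center_row
  d <- dim(stack$frames)
  if (centerline_row < 1 || centerline_row > d[1] ||
      notch_position < 1 || notch_position > d[2])
    stopf("geometry error: centreline or notch outside frame")
  ky <- t(stack$frames[centerline_row, notch_position:d[2], , drop = TRUE])
  structure(list(intensity = ky, timestamps = stack$timestamps,
                 pixel_size = stack$imaging$pixel_size,
                 truth = stack$truth),
            class = "kymograph")
}

#' Annotate a kymograph by edge detection
#'
#' Programmatic stand-in for interactive pole/septum annotation: for each
#' time point, the old pole is fixed at the notch (position 0) and the cell
#' edge is the last position whose (lightly smoothed) intensity falls below
#' a threshold midway between cell and background intensity.
#'
#' @param kym A \code{\link{build_kymograph}} kymograph.
#' @param threshold Intensity threshold separating cell from background.
#' @param smooth Width (pixels) of the moving-average smoothing applied to
#'   each intensity profile before thresholding.
#' @return Annotation \code{data.frame} with \code{time}, \code{pole_px},
#'   \code{septum_px} (pixel offsets from the notch).
#' @export
annotate_kymograph <- function(kym, threshold = 0.65, smooth = 5) {
  stopifnot(inherits(kym, "kymograph"))
  nt <- nrow(kym$intensity)
  septum <- numeric(nt)
  kern <- rep(1 / smooth, smooth)
  for (t in seq_len(nt)) {
    prof <- kym$intensity[t, ]
    if (smooth > 1)
      prof <- as.numeric(stats::filter(prof, kern, sides = 2))
    dark <- which(!is.na(prof) & prof < threshold)
    septum[t] <- if (length(dark) == 0) 0 else max(dark)
  }
  data.frame(time = kym$timestamps, pole_px = 0, septum_px = septum)
}

#' Trace cell length from kymograph annotations
#'
#' Converts pole/septum annotations into a per-timepoint length trace in
#' micrometres. Sparse annotations (e.g. marked only at divisions) are
#' linearly interpolated onto the kymograph time grid.
#'
#' @param kym A \code{kymograph}.
#' @param annotations \code{data.frame} with \code{time}, \code{pole_px},
#'   \code{septum_px}; may be sparse.
#' @return An object of class \code{"length_trace"}: \code{times} (hours),
#'   \code{lengths} (um), annotation positions, and quality flags.
#' @export
trace_lengths <- function(kym, annotations = NULL) {
  stopifnot(inherits(kym, "kymograph"))
  if (is.null(annotations)) annotations <- annotate_kymograph(kym)
  stopifnot(all(c("time", "pole_px", "septum_px") %in% names(annotations)))
  tt <- kym$timestamps
  pole <- if (nrow(annotations) == length(tt)) annotations$pole_px else
    stats::approx(annotations$time, annotations$pole_px, xout = tt, rule = 2)$y
  sept <- if (nrow(annotations) == length(tt)) annotations$septum_px else
    stats::approx(annotations$time, annotations$septum_px, xout = tt, rule = 2)$y
  if (any(sept < pole))
    stopf("annotation error: septum left of old pole at %d time point(s)",
          sum(sept < pole))
  if (all(sept == pole))
    stopf("annotation error: pole and septum coincide everywhere")
  structure(list(times = tt, lengths = (sept - pole) * kym$pixel_size,
                 pole_px = pole, septum_px = sept,
                 pixel_size = kym$pixel_size,
                 ejection_suspected = FALSE),
            class = "length_trace")
}

#' Detect divisions as local minima of a length trace
#'
#' Divisions appear as sawtooth resets of the cell length. The trace is
#' smoothed with a moving median, local minima are screened by requiring a
#' substantial relative drop from the preceding running maximum (divisions
#' roughly halve the length; small-noise wiggles do not), and accepted
#' minima closer together than a minimum generation time are merged,
#' keeping the deepest. The replicative age is the number of accepted
#' minima.
#'
#' @param trace A \code{\link{trace_lengths}} trace, or a numeric vector of
#'   lengths (then \code{times} must be given).
#' @param smoothing_window Moving-median window in time points.
#' @param min_generation_time Minimum time between divisions, hours.
#' @param min_drop_frac Minimum relative drop from the preceding maximum
#'   for a minimum to count as a division.
#' @param times Time grid (hours) when \code{trace} is a bare vector.
#' @return A list: \code{division_times}, \code{division_indices},
#'   \code{generation_count}, \code{division_lengths} (peak length just
#'   before each reset), \code{doubling_times} (intervals between
#'   consecutive divisions).
#' @export
detect_divisions <- function(trace, smoothing_window = 5,
                             min_generation_time = 0.5,
                             min_drop_frac = 0.25, times = NULL) {
  if (inherits(trace, "length_trace")) {
    x <- trace$lengths; tt <- trace$times
  } else {
    x <- as.numeric(trace); tt <- times
    if (is.null(tt)) stopf("times must be supplied for a bare length vector")
  }
  n <- length(x)
  if (n == 0) stopf("empty trace")
  if (n < 3) stopf("trace too short for division detection (need >= 3 points)")
  s <- moving_median(x, smoothing_window)

  cand <- local_minima(s)
  # screen by relative drop from the running maximum of the current segment
  acc <- integer(0)
  seg_start <- 1L
  for (i in cand) {
    prev_max <- max(s[seg_start:i])
    if (prev_max > 0 && (prev_max - s[i]) / prev_max >= min_drop_frac) {
      acc <- c(acc, i)
      seg_start <- i
    }
  }
  # merge accepted minima closer than min_generation_time, keeping deepest
  if (length(acc) > 1) {
    repeat {
      gaps <- diff(tt[acc])
      j <- which(gaps < min_generation_time)
      if (length(j) == 0) break
      j <- j[1]
      drop_idx <- if (s[acc[j]] <= s[acc[j + 1]]) j + 1 else j
      acc <- acc[-drop_idx]
      if (length(acc) < 2) break
    }
  }
  div_len <- vapply(seq_along(acc), function(k) {
    lo <- if (k == 1) 1L else acc[k - 1]
    max(x[lo:acc[k]])
  }, numeric(1))
  list(division_times = tt[acc], division_indices = acc,
       generation_count = length(acc), division_lengths = div_len,
       doubling_times = if (length(acc) > 1) diff(tt[acc]) else numeric(0))
}

# indices of strict-or-plateau local minima; a minimal plateau is reported
# at its first index, so division times align with the reset frame
local_minima <- function(s) {
  n <- length(s)
  if (n < 3) return(integer(0))
  d <- diff(s)
  sgn <- sign(d)
  # carry the previous non-zero sign across plateaus
  for (i in seq_along(sgn)) if (sgn[i] == 0 && i > 1) sgn[i] <- sgn[i - 1]
  idx <- which(diff(sgn) > 0) + 1L
  idx <- idx[idx > 1 & idx < n]
  # walk back to the start of an equal-valued plateau
  vapply(idx, function(i) {
    while (i > 1 && s[i - 1] == s[i]) i <- i - 1L
    as.integer(i)
  }, integer(1))
}

#' Screen a length trace for ejection / re-loading events
#'
#' A captured cell that is ejected and replaced by another produces an
#' abrupt between-frame change in the traced length. Any single-frame
#' relative change exceeding \code{drop_threshold} is flagged unless it is
#' division-consistent: close to an accepted division minimum \emph{and}
#' leaving a post/pre length ratio inside \code{division_band} (medial
#' fission leaves very nearly half the length; a reload does not).
#'
#' @param trace A \code{length_trace}.
#' @param drop_threshold Relative between-frame change that triggers the
#'   flag.
#' @param divisions Optional \code{\link{detect_divisions}} result; computed
#'   with defaults if missing.
#' @param division_band Post/pre length-ratio interval treated as a
#'   division halving.
#' @return A list: \code{flagged} (logical), \code{first_suspect_time},
#'   \code{suspect_indices}.
#' @export
detect_ejection <- function(trace, drop_threshold = 0.35, divisions = NULL,
                            division_band = c(0.41, 0.59)) {
  stopifnot(inherits(trace, "length_trace"))
  x <- trace$lengths; tt <- trace$times
  n <- length(x)
  if (n < 2) return(list(flagged = FALSE, first_suspect_time = NA_real_,
                         suspect_indices = integer(0)))
  if (is.null(divisions))
    divisions <- detect_divisions(trace)
  rel <- abs(diff(x)) / pmax(x[-n], .Machine$double.eps)
  suspect <- which(rel > drop_threshold) + 1L
  near_div <- unique(as.vector(outer(divisions$division_indices, -2:2, `+`)))
  ratio <- x[suspect] / x[suspect - 1L]
  exempt <- suspect %in% near_div &
    ratio >= division_band[1] & ratio <= division_band[2]
  suspect <- suspect[!exempt]
  list(flagged = length(suspect) > 0,
       first_suspect_time = if (length(suspect) > 0) tt[suspect[1]] else NA_real_,
       suspect_indices = suspect)
}

#' Detect the NETO breakpoint within one generation
#'
#' Fits a continuous two-segment piecewise-linear model to a normalised
#' single-generation length trace by profiling the breakpoint over a grid
#' and solving each conditional fit by least squares. New end take-off
#' (NETO) appears as a slope increase partway through the cycle.
#'
#' @param x Normalised length (or raw length) for one complete generation.
#' @param t Normalised time in [0, 1] (defaults to an equispaced grid).
#' @param grid Candidate breakpoint locations (fractions of the cycle).
#' @param min_slope_change Minimum relative slope change below which the
#'   breakpoint is reported as unidentifiable.
#' @return A list: \code{breakpoint} (fraction of the cycle, NA if
#'   unidentifiable), \code{slope_pre}, \code{slope_post},
#'   \code{identifiable}.
#' @export
detect_neto <- function(x, t = NULL, grid = seq(0.10, 0.90, by = 0.01),
                        min_slope_change = 0.10) {
  x <- as.numeric(x)
  if (length(x) < 10) stopf("insufficient data: NETO detection needs >= 10 points")
  if (is.null(t)) t <- seq(0, 1, length.out = length(x))
  t <- (t - min(t)) / (max(t) - min(t))
  best <- NULL; best_rss <- Inf
  for (cp in grid) {
    h <- pmax(t - cp, 0)
    fit <- lm(x ~ t + h)
    rss <- sum(resid(fit)^2)
    if (rss < best_rss) { best_rss <- rss; best <- list(cp = cp, fit = fit) }
  }
  b <- coef(best$fit)
  slope_pre <- unname(b["t"])
  slope_post <- unname(b["t"] + b["h"])
  ref <- max(abs(slope_pre), abs(slope_post), .Machine$double.eps)
  identifiable <- abs(slope_post - slope_pre) / ref >= min_slope_change
  list(breakpoint = if (identifiable) best$cp else NA_real_,
       slope_pre = slope_pre, slope_post = slope_post,
       identifiable = identifiable)
}

#' Quantify a stack end to end
#'
#' Full quantification chain for one catch-channel stack: rotation
#' correction (using the stack's recorded or a supplied angle), jitter
#' registration, kymograph construction, edge-based length tracing,
#' ejection screening and division detection.
#'
#' @param stack A \code{kymograph_stack}.
#' @param measured_angle Field rotation to undo (degrees); defaults to the
#'   stack's recorded rotation.
#' @param ... Passed to \code{\link{detect_divisions}}.
#' @return A list: \code{trace}, \code{divisions}, \code{ejection},
#'   \code{registration}.
#' @export
quantify_stack <- function(stack, measured_angle = NULL, ...) {
  stopifnot(inherits(stack, "kymograph_stack"))
  measured_angle <- measured_angle %||% (stack$truth$rotation_deg %||% 0)
  if (measured_angle != 0) stack <- correct_rotation(stack, measured_angle)
  reg <- register_stack(stack)
  kym <- build_kymograph(reg$registered)
  trace <- trace_lengths(kym)
  div <- detect_divisions(trace, ...)
  ej <- detect_ejection(trace, divisions = div)
  trace$ejection_suspected <- ej$flagged
  list(trace = trace, divisions = div, ejection = ej, registration = reg)
}
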