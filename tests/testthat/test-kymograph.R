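test_that("rotation correction undoes a rendered field rotation", {
  g <- noiseless_growth()
  tr <- simulate_trajectory(g, 2, phenotype = "short", seed = 1)
  st0 <- render_kymograph_stack(tr, imaging_params(), seed = 1)
  st5 <- render_kymograph_stack(tr, imaging_params(rotation_deg = 5), seed = 1)
  fixed <- correct_rotation(st5, 5)
  # centreline edge profile matches the unrotated render within 1 px
  k0 <- build_kymograph(st0); k5 <- build_kymograph(fixed)
  e0 <- trace_lengths(k0)$lengths
  e5 <- trace_lengths(k5)$lengths
  expect_lt(max(abs(e0 - e5)), 2 * 0.2)  # within ~1 px either side
  # identity at angle 0 and inverse-pair round trip (field interior;
  # rotation fills the extreme corners with background)
  expect_identical(correct_rotation(st0, 0), st0)
  rt <- correct_rotation(correct_rotation(st0, -3), 3)
  d <- dim(st0$frames)
  ri <- 9:(d[1] - 8); ci <- 9:(d[2] - 8)
  expect_gt(cor(as.vector(rt$frames[ri, ci, ]),
                as.vector(st0$frames[ri, ci, ])), 0.99)
})

test_that("registration recovers recorded integer jitter exactly", {
  g <- growth_params()
  tr <- simulate_trajectory(g, 3, phenotype = "short", seed = 2)
  # jitter only
  st <- render_kymograph_stack(tr, imaging_params(max_jitter = 3), seed = 3)
  reg <- register_stack(st)
  expect_identical(reg$shifts, st$truth$shifts)
  # jitter up to 5 px with noise at 10% of contrast
  st2 <- render_kymograph_stack(tr, imaging_params(max_jitter = 5,
                                                   noise_sd = 0.07), seed = 4)
  reg2 <- register_stack(st2)
  expect_identical(reg2$shifts, st2$truth$shifts)
  # zero-jitter stack: all shifts (0,0)
  st3 <- render_kymograph_stack(tr, imaging_params(), seed = 5)
  expect_true(all(register_stack(st3)$shifts == 0L))
})

test_that("cross-correlation shift has the documented sign convention", {
  a <- matrix(0, 32, 40); a[10, 12] <- 1
  b <- replispan:::shift_matrix(a, 3, -2, fill = 0)
  expect_identical(replispan:::xcorr_shift(a, b), c(3L, -2L))
  expect_error(register_stack(structure(list(
    frames = array(1, dim = c(8, 8, 3)), timestamps = 1:3,
    imaging = imaging_params(frame_shape = c(8, 8), channel_center_row = 4,
                             notch_col = 2)),
    class = "kymograph_stack")), "degenerate")
})

test_that("kymograph construction preserves geometry and growth", {
  g <- noiseless_growth()
  tr <- simulate_trajectory(g, 5, phenotype = "short", seed = 6)
  st <- render_kymograph_stack(tr, imaging_params(), seed = 6)
  ky <- build_kymograph(st)
  expect_identical(nrow(ky$intensity), length(tr$times))
  # constant stack -> constant kymograph
  stc <- st; stc$frames <- array(0.5, dim = dim(st$frames))
  kyc <- build_kymograph(stc)
  expect_equal(max(kyc$intensity) - min(kyc$intensity), 0)
  # edge position increases between divisions, resets at divisions
  trc <- trace_lengths(ky)
  dv <- detect_divisions(trc)
  expect_identical(dv$generation_count, 5L)
  expect_error(build_kymograph(st, centerline_row = 1000), "geometry")
})

test_that("rendering rejects cells longer than the frame", {
  g <- noiseless_growth(division_length_mean = 60, birth_length_mean = 30)
  tr <- simulate_trajectory(g, 1, phenotype = "short", seed = 1)
  expect_error(render_kymograph_stack(tr, imaging_params(), seed = 1),
               "frame-geometry")
})

test_that("traced lengths match ground truth within one pixel (noiseless)", {
  g <- growth_params()
  for (s in 1:3) {
    tr <- simulate_trajectory(g, 3, phenotype = "short", seed = 30 + s)
    st <- render_kymograph_stack(tr, imaging_params(), seed = s)
    trace <- trace_lengths(build_kymograph(st))
    expect_lt(max(abs(trace$lengths - tr$lengths)), 0.2 + 1e-9)
  }
})

test_that("annotation validation rejects degenerate pole/septum input", {
  g <- noiseless_growth()
  tr <- simulate_trajectory(g, 2, phenotype = "short", seed = 8)
  ky <- build_kymograph(render_kymograph_stack(tr, imaging_params(), seed = 8))
  ann <- annotate_kymograph(ky)
  ann$septum_px <- 0
  expect_error(trace_lengths(ky, ann), "annotation error")
  ann2 <- annotate_kymograph(ky)
  ann2$septum_px[3] <- -5
  expect_error(trace_lengths(ky, ann2), "annotation error")
})

test_that("division detection finds sawtooth resets and tolerates noise", {
  # exact sawtooth, period 2.05 h, 5 periods
  dt <- 2 / 60
  tt <- seq(0, 5 * 2.05 + 1, by = dt)
  phase <- (tt %% 2.05) / 2.05
  x <- 8 + 8 * phase
  dv <- detect_divisions(x, times = tt)
  expect_identical(dv$generation_count, 5L)
  expect_equal(dv$division_times, 2.05 * (1:5), tolerance = 0.05)
  expect_equal(dv$doubling_times, rep(2.05, 4), tolerance = 0.05)
  expect_equal(dv$division_lengths, rep(16, 5), tolerance = 0.2)

  # division count invariant to 5%-of-mean-length noise
  set.seed(77)
  for (r in 1:5) {
    xn <- x + rnorm(length(x), 0, 0.05 * mean(x))
    expect_identical(detect_divisions(xn, times = tt)$generation_count, 5L)
  }
  expect_error(detect_divisions(numeric(0), times = numeric(0)), "empty")
})

test_that("ejection screening flags reloads but not divisions", {
  g <- growth_params()
  tr <- simulate_trajectory(g, 4, phenotype = "short", seed = 9)
  st <- render_kymograph_stack(tr, imaging_params(), seed = 9)
  trace <- trace_lengths(build_kymograph(st))
  expect_false(detect_ejection(trace)$flagged)

  # inject a 60% drop mid-generation
  bad <- trace
  mid <- which(trace$times > tr$division_times[1] + 0.8 &
               trace$times < tr$division_times[2] - 0.8)[1]
  bad$lengths[mid:length(bad$lengths)] <- bad$lengths[mid:length(bad$lengths)] * 0.4
  ej <- detect_ejection(bad)
  expect_true(ej$flagged)
  expect_equal(ej$first_suspect_time, trace$times[mid], tolerance = 1e-9)

  # no false positives across a small cohort (division halvings exempt)
  for (s in 1:6) {
    trc <- simulate_trajectory(g, 3, phenotype = "short", seed = 50 + s)
    stc <- render_kymograph_stack(trc, imaging_params(noise_sd = 0.05), seed = s)
    expect_false(quantify_stack(stc)$ejection$flagged)
  }
})

test_that("NETO breakpoint detection inverts the bilinear generator", {
  t <- seq(0, 1, length.out = 60)
  x <- ifelse(t <= 0.3, 0.35 * t, 0.35 * 0.3 + (t - 0.3))
  nb <- detect_neto(x, t)
  expect_true(nb$identifiable)
  expect_equal(nb$breakpoint, 0.30, tolerance = 0.02)
  # pure linear input: slopes equal, breakpoint unidentifiable
  lin <- detect_neto(0.2 + 0.8 * t, t)
  expect_false(lin$identifiable)
  expect_true(is.na(lin$breakpoint))
  expect_equal(lin$slope_pre, lin$slope_post, tolerance = 1e-6)
  expect_error(detect_neto(1:5), "insufficient")

  # mean breakpoint over default simulator generations ~ 0.3
  g <- growth_params()
  bps <- c()
  for (s in 1:12) {
    tr <- simulate_trajectory(g, 2, phenotype = "short", seed = 100 + s)
    sel <- tr$times >= tr$generations$t_start[2] &
      tr$times < tr$generations$t_start[3]
    nb <- detect_neto(tr$lengths[sel])
    if (nb$identifiable) bps <- c(bps, nb$breakpoint)
  }
  expect_equal(mean(bps), 0.3, tolerance = 0.05)
})

test_that("full round trip recovers generation counts under mixed nuisance", {
  g <- growth_params()
  n_ok <- 0; n <- 25
  for (i in seq_len(n)) {
    L <- 1 + (i %% 5)
    tr <- simulate_trajectory(g, L, phenotype = "short", seed = 400 + i)
    im <- switch(1 + i %% 3,
                 imaging_params(),
                 imaging_params(max_jitter = 3),
                 imaging_params(rotation_deg = 4, max_jitter = 3, noise_sd = 0.07))
    q <- quantify_stack(render_kymograph_stack(tr, im, seed = i))
    n_ok <- n_ok + (q$divisions$generation_count == L)
  }
  expect_gte(n_ok / n, 0.95)
})
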