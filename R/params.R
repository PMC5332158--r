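#' Cell growth parameters
#'
#' Parameters of the bilinear (NETO) growth model used by
#' \code{\link{simulate_trajectory}}. Fission yeast grows by linear tip
#' extension: monopolar (old pole only) from birth until new end take-off
#' (NETO) at roughly 30\% of the cell cycle, then bipolar and faster until
#' medial fission. Defaults are the wild-type values measured in
#' catch-channel assays: birth length 8.3 +/- 1.5 um, division length
#' 16 +/- 2.2 um, doubling time 2.05 +/- 0.45 hr, sampling every 2 minutes.
#'
#' @param birth_length_mean,birth_length_sd Birth length (um).
#' @param division_length_mean,division_length_sd Length at division (um).
#' @param doubling_time_mean,doubling_time_sd Generation time (hours).
#' @param neto_fraction Fraction of the cycle at which NETO occurs, in (0,1).
#' @param monopolar_rate_share Ratio of the monopolar (pre-NETO) to the
#'   bipolar (post-NETO) elongation rate, in (0,1); values below 1 give the
#'   growth acceleration at NETO seen in single-cell traces.
#' @param sampling_interval Imaging interval in minutes.
#' @return An object of class \code{"growth_params"}.
#' @export
growth_params <- function(birth_length_mean = 8.3, birth_length_sd = 1.5,
                          division_length_mean = 16, division_length_sd = 2.2,
                          doubling_time_mean = 2.05, doubling_time_sd = 0.45,
                          neto_fraction = 0.3, monopolar_rate_share = 0.35,
                          sampling_interval = 2) {
  p <- list(birth_length_mean = birth_length_mean,
            birth_length_sd = birth_length_sd,
            division_length_mean = division_length_mean,
            division_length_sd = division_length_sd,
            doubling_time_mean = doubling_time_mean,
            doubling_time_sd = doubling_time_sd,
            neto_fraction = neto_fraction,
            monopolar_rate_share = monopolar_rate_share,
            sampling_interval = sampling_interval)
  for (f in c("birth_length_mean", "division_length_mean",
              "doubling_time_mean", "sampling_interval"))
    if (!is.numeric(p[[f]]) || p[[f]] <= 0)
      stopf("growth_params: %s must be positive", f)
  for (f in c("birth_length_sd", "division_length_sd", "doubling_time_sd"))
    if (!is.numeric(p[[f]]) || p[[f]] < 0)
      stopf("growth_params: %s must be non-negative", f)
  if (division_length_mean <= birth_length_mean)
    stopf("growth_params: division_length_mean must exceed birth_length_mean")
  if (neto_fraction <= 0 || neto_fraction >= 1)
    stopf("growth_params: neto_fraction must lie in (0,1)")
  if (monopolar_rate_share <= 0 || monopolar_rate_share >= 1)
    stopf("growth_params: monopolar_rate_share must lie in (0,1)")
  structure(p, class = "growth_params")
}

#' Terminal phenotype probabilities
#'
#' Probabilities of the categorical outcomes attached to dying cells: the
#' terminal morphology (short: death before reaching the normal division
#' length; elongated: hyper-elongation past three mean doubling times
#' without division), the fate of the last sibling produced by the final
#' division, and the chromosome/rDNA segregation class of divisions.
#' Defaults are the wild-type tallies: 72\%/28\% short/elongated,
#' last-sibling fates 66\%/14\%/20\% (never divided / divided once /
#' divided multiple times), and segregation-defect rates of 7\% over all
#' divisions versus 40\% in terminal divisions.
#'
#' @param p_short_death,p_elongated_death Terminal-morphology probabilities;
#'   must sum to 1.
#' @param sibling_fate_probs Named numeric triple over
#'   \code{never_divided}, \code{divided_once}, \code{divided_multiple}.
#' @param defect_class_probs Named probabilities over segregation classes
#'   \code{normal}, \code{multi}, \code{unequal}, \code{bridge} for healthy
#'   divisions.
#' @param defect_class_probs_dying Same map for terminal divisions.
#' @return An object of class \code{"phenotype_probs"}.
#' @export
phenotype_probs <- function(p_short_death = 0.72, p_elongated_death = 0.28,
                            sibling_fate_probs = c(never_divided = 0.66,
                                                   divided_once = 0.14,
                                                   divided_multiple = 0.20),
                            defect_class_probs = c(normal = 0.93, multi = 0.02,
                                                   unequal = 0.03, bridge = 0.02),
                            defect_class_probs_dying = c(normal = 0.60, multi = 0.16,
                                                         unequal = 0.14, bridge = 0.10)) {
  check_simplex <- function(x, what, nms) {
    if (!all(nms %in% names(x)))
      stopf("phenotype_probs: %s must be named with %s", what,
            paste(nms, collapse = ", "))
    x <- x[nms]
    if (any(x < 0) || abs(sum(x) - 1) > 1e-9)
      stopf("phenotype_probs: %s must be non-negative and sum to 1", what)
    x
  }
  if (p_short_death < 0 || p_elongated_death < 0 ||
      abs(p_short_death + p_elongated_death - 1) > 1e-9)
    stopf("phenotype_probs: p_short_death + p_elongated_death must equal 1")
  structure(list(
    p_short_death = p_short_death,
    p_elongated_death = p_elongated_death,
    sibling_fate_probs = check_simplex(sibling_fate_probs, "sibling_fate_probs",
      c("never_divided", "divided_once", "divided_multiple")),
    defect_class_probs = check_simplex(defect_class_probs, "defect_class_probs",
      c("normal", "multi", "unequal", "bridge")),
    defect_class_probs_dying = check_simplex(defect_class_probs_dying,
      "defect_class_probs_dying", c("normal", "multi", "unequal", "bridge"))),
    class = "phenotype_probs")
}

#' Imaging nuisance parameters for the kymograph renderer
#'
#' Geometry and nuisance settings for \code{\link{render_kymograph_stack}}:
#' pixel calibration, frame size, a global field rotation, per-frame integer
#' stage jitter, and additive Gaussian intensity noise. The rendered cell is
#' a dark rod on a bright background, anchored at the catch-channel notch,
#' mimicking the out-of-focus white-light contrast used for septum-resolved
#' kymographs.
#'
#' @param pixel_size Micrometres per pixel.
#' @param frame_shape Integer (rows, cols) of each frame.
#' @param rotation_deg Global rotation of the field in degrees (|deg| < 15).
#' @param max_jitter Maximum per-frame integer translation in pixels.
#' @param noise_sd Additive Gaussian noise sd, intensity units (contrast is 1).
#' @param channel_center_row Pixel row of the catch-channel centreline.
#' @param notch_col Pixel column of the channel notch (old-pole anchor).
#' @return An object of class \code{"imaging_params"}.
#' @export
imaging_params <- function(pixel_size = 0.2, frame_shape = c(48, 256),
                           rotation_deg = 0, max_jitter = 0, noise_sd = 0,
                           channel_center_row = 24, notch_col = 12) {
  if (pixel_size <= 0) stopf("imaging_params: pixel_size must be positive")
  if (abs(rotation_deg) >= 15) stopf("imaging_params: |rotation_deg| must be < 15")
  if (max_jitter < 0) stopf("imaging_params: max_jitter must be >= 0")
  if (noise_sd < 0) stopf("imaging_params: noise_sd must be >= 0")
  frame_shape <- as.integer(frame_shape)
  if (length(frame_shape) != 2 || any(frame_shape < 8))
    stopf("imaging_params: frame_shape must be two integers >= 8")
  if (channel_center_row < 1 || channel_center_row > frame_shape[1])
    stopf("imaging_params: channel_center_row outside frame")
  if (notch_col < 1 || notch_col > frame_shape[2])
    stopf("imaging_params: notch_col outside frame")
  structure(list(pixel_size = pixel_size, frame_shape = frame_shape,
                 rotation_deg = rotation_deg, max_jitter = max_jitter,
                 noise_sd = noise_sd, channel_center_row = channel_center_row,
                 notch_col = notch_col),
            class = "imaging_params")
}
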