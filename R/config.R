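#' Default run configuration
#'
#' The documented defaults for a full simulate/quantify/fit/report run:
#' wild-type exponential mortality with a 2\% per-generation hazard,
#' wild-type growth parameters, the measured terminal-phenotype and
#' defect-class frequencies, no imaging nuisances, and a 1000-resample
#' bootstrap.
#'
#' @return A nested list of class \code{"run_config"}.
#' @export
default_config <- function() {
  structure(list(
    master_seed = 1L,
    simulator = list(
      n_cells = 100L,
      n_render = 0L,
      mortality = list(kind = "exponential", alpha = 0.02, beta = 0),
      growth = list(birth_length_mean = 8.3, birth_length_sd = 1.5,
                    division_length_mean = 16, division_length_sd = 2.2,
                    doubling_time_mean = 2.05, doubling_time_sd = 0.45,
                    neto_fraction = 0.3, monopolar_rate_share = 0.35,
                    sampling_interval = 2),
      phenotypes = list(p_short_death = 0.72, p_elongated_death = 0.28,
                        sibling_fate_probs = list(never_divided = 0.66,
                                                  divided_once = 0.14,
                                                  divided_multiple = 0.20),
                        defect_class_probs = list(normal = 0.93, multi = 0.02,
                                                  unequal = 0.03, bridge = 0.02),
                        defect_class_probs_dying = list(normal = 0.60, multi = 0.16,
                                                        unequal = 0.14, bridge = 0.10)),
      imaging = list(pixel_size = 0.2, frame_shape = c(48L, 256L),
                     rotation_deg = 0, max_jitter = 0, noise_sd = 0,
                     channel_center_row = 24L, notch_col = 12L)),
    fit = list(model = "auto", n_boot = 1000L,
               weighting = "inverse_survival"),
    report = list(k_max = 5L, age_bins = 4L)),
    class = "run_config")
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration file, fills unset keys with the documented
#' defaults, rejects unknown keys (typo protection), and validates every
#' section against its type invariants before any computation. An empty or
#' missing-section file yields the full default configuration.
#'
#' @param path Path to a YAML file.
#' @return A validated \code{run_config}.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- merge_config(default_config(), user, prefix = NULL)
  class(cfg) <- "run_config"
  validate_config(cfg)
  cfg
}

# recursive merge of user keys onto defaults; unknown keys are hard errors
merge_config <- function(def, user, prefix = NULL) {
  for (k in names(user)) {
    full <- paste(c(prefix, k), collapse = ".")
    if (!k %in% names(def))
      stopf("config error: unknown key `%s`", full)
    if (is.list(def[[k]]) && !is.null(names(def[[k]]))) {
      if (!is.list(user[[k]]))
        stopf("config error: `%s` must be a section", full)
      def[[k]] <- merge_config(def[[k]], user[[k]], prefix = c(prefix, k))
    } else {
      def[[k]] <- user[[k]]
    }
  }
  def
}

validate_config <- function(cfg) {
  wrap <- function(field, expr) {
    tryCatch(expr, error = function(e)
      stopf("config error in `%s`: %s", field, conditionMessage(e)))
  }
  s <- cfg$simulator
  wrap("simulator.mortality",
       mortality_model(s$mortality$kind, s$mortality$alpha, s$mortality$beta %||% 0))
  wrap("simulator.growth", do.call(growth_params, s$growth))
  ph <- s$phenotypes
  wrap("simulator.phenotypes",
       phenotype_probs(ph$p_short_death, ph$p_elongated_death,
                       unlist(ph$sibling_fate_probs),
                       unlist(ph$defect_class_probs),
                       unlist(ph$defect_class_probs_dying)))
  wrap("simulator.imaging", do.call(imaging_params, s$imaging))
  if (!cfg$fit$model %in% c("auto", "exponential", "gompertz"))
    stopf("config error in `fit.model`: must be auto, exponential or gompertz")
  if (cfg$fit$n_boot < 0) stopf("config error in `fit.n_boot`: must be >= 0")
  if (cfg$simulator$n_cells < 1)
    stopf("config error in `simulator.n_cells`: must be >= 1")
  if (cfg$report$k_max < 1) stopf("config error in `report.k_max`: must be >= 1")
  invisible(cfg)
}

#' Save a run configuration to YAML
#'
#' @param config A \code{run_config}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# typed objects from a validated config
config_mortality <- function(cfg)
  mortality_model(cfg$simulator$mortality$kind, cfg$simulator$mortality$alpha,
                  cfg$simulator$mortality$beta %||% 0)
config_growth <- function(cfg) do.call(growth_params, cfg$simulator$growth)
config_phenotypes <- function(cfg) {
  ph <- cfg$simulator$phenotypes
  phenotype_probs(ph$p_short_death, ph$p_elongated_death,
                  unlist(ph$sibling_fate_probs),
                  unlist(ph$defect_class_probs),
                  unlist(ph$defect_class_probs_dying))
}
config_imaging <- function(cfg) do.call(imaging_params, cfg$simulator$imaging)
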