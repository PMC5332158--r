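#' Run the simulate / quantify / fit / report pipeline
#'
#' Executes the requested stages in order against an output directory,
#' writing versioned CSV/JSON artifacts and a manifest listing every
#' output file with its MD5 hash, the master seed and per-stage timing.
#' Re-running with the same configuration and seed reproduces identical
#' tables.
#'
#' Stages: \code{simulate} writes the lifespan table, trajectory traces and
#' per-generation table (and, if \code{simulator$n_render > 0}, TIFF stacks
#' with ground-truth sidecars); \code{quantify} quantifies the rendered
#' stacks into traced lifespans; \code{fit} fits the survival model(s) to
#' the simulated lifespans; \code{report} writes the death-aligned
#' distributions, KS comparisons, sibling-fate table, defect tallies and
#' the RLS contour grid.
#'
#' @param config A \code{\link{load_config}} / \code{\link{default_config}}
#'   configuration.
#' @param stages Subset of c("simulate", "quantify", "fit", "report").
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list of the artifact paths per stage.
#' @export
run_pipeline <- function(config = default_config(),
                         stages = c("simulate", "fit", "report"),
                         out_dir = tempfile("replispan_run_")) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, c("simulate", "quantify", "fit", "report"),
                      several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$master_seed
  manifest <- list(master_seed = seed, stages = list())
  artifacts <- list()
  log_line <- function(...) message(sprintf(...))

  if ("simulate" %in% stages) {
    t0 <- proc.time()[["elapsed"]]
    coh <- simulate_cohort(config_mortality(config), config_growth(config),
                           config_phenotypes(config),
                           n_cells = config$simulator$n_cells, seed = seed)
    paths <- c(lifespans = file.path(out_dir, "lifespans.csv"),
               traces = file.path(out_dir, "traces.csv"),
               generations = file.path(out_dir, "generations.csv"))
    write_lifespans(coh$lifespans, paths[["lifespans"]])
    write_trajectories(coh$trajectories, paths[["traces"]])
    write_generations(coh$trajectories, paths[["generations"]])
    n_render <- config$simulator$n_render
    if (n_render > 0) {
      im <- config_imaging(config)
      stack_dir <- file.path(out_dir, "stacks")
      dir.create(stack_dir, showWarnings = FALSE)
      for (i in seq_len(min(n_render, length(coh$trajectories)))) {
        sp <- file.path(stack_dir, sprintf("cell_%03d.tif", i))
        tp <- file.path(stack_dir, sprintf("cell_%03d_truth.csv", i))
        write_stack(render_kymograph_stack(coh$trajectories[[i]], im,
                                           seed = derive_seed(seed, 10000L + i)),
                    sp, truth_path = tp)
        paths[[sprintf("stack_%03d", i)]] <- sp
        paths[[sprintf("stack_truth_%03d", i)]] <- tp
      }
    }
    artifacts$simulate <- paths
    manifest$stages$simulate <- stage_entry(paths, seed,
                                            n = config$simulator$n_cells,
                                            t0 = t0)
    log_line("simulate: %d cells -> %s", config$simulator$n_cells, out_dir)
  }

  if ("quantify" %in% stages) {
    t0 <- proc.time()[["elapsed"]]
    stack_dir <- file.path(out_dir, "stacks")
    tifs <- if (dir.exists(stack_dir))
      list.files(stack_dir, pattern = "^cell_\\d+\\.tif$", full.names = TRUE)
    else character(0)
    if (length(tifs) == 0)
      stopf("dependency error: no rendered stacks found under %s (run simulate with simulator.n_render > 0)",
            stack_dir)
    im <- config_imaging(config)
    rows <- lapply(tifs, function(p) {
      tp <- sub("\\.tif$", "_truth.csv", p)
      st <- read_stack(p, imaging = im, truth_path = tp)
      q <- quantify_stack(st)
      data.frame(stack = basename(p),
                 generations = q$divisions$generation_count,
                 ejection_suspected = q$ejection$flagged,
                 mean_doubling_time = if (length(q$divisions$doubling_times))
                   mean(q$divisions$doubling_times) else NA_real_,
                 mean_division_length = if (length(q$divisions$division_lengths))
                   mean(q$divisions$division_lengths) else NA_real_)
    })
    qt <- do.call(rbind, rows)
    excl <- sum(qt$ejection_suspected)
    if (excl > 0)
      log_line("quantify: %d cell(s) flagged ejection_suspected and excluded", excl)
    qp <- file.path(out_dir, "quantified.csv")
    write.csv(qt, qp, row.names = FALSE)
    artifacts$quantify <- c(quantified = qp)
    manifest$stages$quantify <- stage_entry(c(quantified = qp), seed,
                                            n = length(tifs), t0 = t0)
  }

  if ("fit" %in% stages) {
    t0 <- proc.time()[["elapsed"]]
    lp <- file.path(out_dir, "lifespans.csv")
    if (!file.exists(lp))
      stopf("dependency error: %s not found (run simulate first)", lp)
    lt <- read_lifespans(lp)
    curve <- km_estimate(lt)
    fit <- switch(config$fit$model,
      auto = select_model(curve, weighting = config$fit$weighting,
                          n_boot = config$fit$n_boot,
                          seed = derive_seed(seed, 20000L)),
      fit_survival(curve, config$fit$model, weighting = config$fit$weighting,
                   n_boot = config$fit$n_boot, seed = derive_seed(seed, 20000L)))
    paths <- c(fit = file.path(out_dir, "fit.json"),
               survival = file.path(out_dir, "survival.csv"),
               hazard = file.path(out_dir, "hazard.csv"))
    write_fit(fit, paths[["fit"]])
    write.csv(as.data.frame(curve), paths[["survival"]], row.names = FALSE)
    eh <- empirical_hazard(curve)
    fh <- hazard_from_fit(fit, eh$generations)
    write.csv(data.frame(generation = eh$generations,
                         hazard_empirical = eh$hazard,
                         hazard_fitted = fh$hazard),
              paths[["hazard"]], row.names = FALSE)
    artifacts$fit <- paths
    manifest$stages$fit <- stage_entry(paths, seed, n = curve$n_total, t0 = t0)
    log_line("fit: %s model, RLS %.2f generations", fit$kind, fit$rls)
  }

  if ("report" %in% stages) {
    t0 <- proc.time()[["elapsed"]]
    gp <- file.path(out_dir, "generations.csv")
    lp <- file.path(out_dir, "lifespans.csv")
    if (!file.exists(gp) || !file.exists(lp))
      stopf("dependency error: simulate artifacts missing under %s", out_dir)
    gt <- read.csv(gp, stringsAsFactors = FALSE)
    lt <- read_lifespans(lp)
    paths <- character(0)

    dists <- post_synchronize_to_death(gt, k_max = config$report$k_max)
    pp <- file.path(out_dir, "death_aligned.csv")
    write.csv(as.data.frame(unclass(dists)[c("k", "cell_id", "division_length",
                                             "doubling_time")]),
              pp, row.names = FALSE)
    paths["death_aligned"] <- pp
    ks <- ks_generation_comparison(dists)
    if (!is.null(ks)) {
      kp <- file.path(out_dir, "ks_comparisons.csv")
      write.csv(ks, kp, row.names = FALSE)
      paths["ks_comparisons"] <- kp
    }
    if (any(lt$sibling_fate != "none")) {
      sf <- sibling_fate_by_age(lt, age_bins = config$report$age_bins,
                                n_boot = 200, seed = derive_seed(seed, 30000L))
      sp <- file.path(out_dir, "sibling_fates.csv")
      write.csv(cbind(bin = rownames(sf$proportions),
                      as.data.frame.matrix(sf$proportions)),
                sp, row.names = FALSE)
      paths["sibling_fates"] <- sp
    }
    if (any(lt$defect_class != "none")) {
      ev <- data.frame(population = "terminal", class = lt$defect_class[
        lt$status == "died" & lt$defect_class != "none"])
      dp <- file.path(out_dir, "defect_terminal.csv")
      write.csv(ev, dp, row.names = FALSE)
      paths["defect_terminal"] <- dp
    }
    cg <- rls_contour_grid()
    cp <- file.path(out_dir, "rls_contours.csv")
    write.csv(data.frame(alpha = rep(cg$alpha_values, times = length(cg$beta_values)),
                         beta = rep(cg$beta_values, each = length(cg$alpha_values)),
                         rls = as.vector(cg$rls_matrix)),
              cp, row.names = FALSE)
    paths["rls_contours"] <- cp
    artifacts$report <- paths
    manifest$stages$report <- stage_entry(paths, seed, n = nrow(lt), t0 = t0)
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(artifacts, list(out_dir = out_dir,
                              manifest = file.path(out_dir, "manifest.json"))))
}

stage_entry <- function(paths, seed, n, t0) {
  list(seed = seed, n = n,
       elapsed_s = round(proc.time()[["elapsed"]] - t0, 3),
       outputs = lapply(as.list(paths), function(p)
         list(path = p, md5 = unname(tools::md5sum(p)))))
}
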