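#' Sample per-cell replicative lifespans
#'
#' Draws the generation at death for \code{n_cells} independent cells under
#' a \code{\link{mortality_model}}. Generations are discrete: the death
#' generation \eqn{g^*} is sampled by inverse-CDF on the probability mass
#' \eqn{S(g-1) - S(g)}, so that the implied survivor function matches the
#' model exactly at integer ages, \eqn{P(g^* > g) = S(g)}. For the
#' exponential model this is a geometric draw with per-generation death
#' probability \eqn{1 - e^{-\alpha}}.
#'
#' @param model A \code{\link{mortality_model}}.
#' @param n_cells Number of cells (>= 1).
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return A lifespan table: \code{data.frame} with columns \code{cell_id},
#'   \code{generations_at_death}, \code{status} (all \code{"died"}),
#'   \code{terminal_phenotype}, \code{sibling_fate}, \code{defect_class}
#'   (all \code{"none"} until \code{\link{assign_terminal_phenotypes}}).
#' @examples
#' lt <- sample_lifespans(mortality_model("exponential", 0.02), 500, seed = 1)
#' mean(lt$generations_at_death)
#' @export
sample_lifespans <- function(model, n_cells, seed = 1L) {
  stopifnot(inherits(model, "mortality_model"))
  if (!is.numeric(n_cells) || n_cells < 1) stopf("n_cells must be >= 1")
  n_cells <- as.integer(n_cells)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  v <- runif(n_cells)              # survival quantile: die at first g with S(g) <= v
  a <- model$alpha; b <- model$beta
  g <- if (model$kind == "exponential" || b == 0) {
    ceiling(-log(v) / a)
  } else {
    ceiling(log1p(-(b / a) * log(v)) / b)
  }
  g <- pmax(1L, as.integer(g))
  data.frame(cell_id = seq_len(n_cells),
             generations_at_death = g,
             status = "died",
             terminal_phenotype = "none",
             sibling_fate = "none",
             defect_class = "none",
             stringsAsFactors = FALSE)
}

# save/restore .Random.seed so seeded package functions do not disturb the
# caller's RNG stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Assign terminal phenotypes, sibling fates and defect classes
#'
#' Draws, for every \code{died} row of a lifespan table, a terminal
#' morphology (short vs elongated), a last-sibling fate and a segregation
#' defect class from a \code{\link{phenotype_probs}} configuration. Draws
#' are independent of replicative age, reflecting the null of
#' age-independent death phenotypes.
#'
#' @param table A lifespan table (see \code{\link{sample_lifespans}}).
#' @param probs A \code{\link{phenotype_probs}}.
#' @param seed Integer seed.
#' @return The table with \code{terminal_phenotype}, \code{sibling_fate} and
#'   \code{defect_class} filled in for dying cells.
#' @export
assign_terminal_phenotypes <- function(table, probs, seed = 1L) {
  stopifnot(is.data.frame(table), inherits(probs, "phenotype_probs"))
  if (nrow(table) == 0) stopf("lifespan table is empty")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  died <- which(table$status == "died")
  n <- length(died)
  table$terminal_phenotype[died] <-
    sample(c("short", "elongated"), n, replace = TRUE,
           prob = c(probs$p_short_death, probs$p_elongated_death))
  table$sibling_fate[died] <-
    sample(names(probs$sibling_fate_probs), n, replace = TRUE,
           prob = probs$sibling_fate_probs)
  table$defect_class[died] <-
    sample(names(probs$defect_class_probs_dying), n, replace = TRUE,
           prob = probs$defect_class_probs_dying)
  table
}

#' Simulate one cell's length trajectory
#'
#' Generates a single-cell length-versus-time trace under the bilinear
#' (NETO) growth model. Each generation draws a birth length (the first from
#' the configured distribution, later ones as a medial-fission split of the
#' previous division length), a division length and a doubling time; length
#' grows piecewise-linearly, with the monopolar (pre-NETO) rate equal to
#' \code{monopolar_rate_share} times the bipolar rate and NETO at
#' \code{neto_fraction} of the cycle. The terminal segment implements the
#' death phenotype: \code{"short"} cells die partway through a normal cycle
#' before reaching the division length; \code{"elongated"} cells keep
#' elongating for more than three mean doubling times without dividing.
#'
#' @param growth A \code{\link{growth_params}}.
#' @param lifespan Number of completed divisions before the terminal
#'   generation (>= 1).
#' @param phenotype Terminal phenotype: "short", "elongated" or "none"
#'   (cell observed until the end of its last completed division).
#' @param seed Integer seed.
#' @return An object of class \code{"cell_trajectory"}: times (hours, on the
#'   uniform sampling grid), lengths (um), division_times, generation_count,
#'   phenotype, and a per-generation ground-truth table
#'   (\code{$generations}).
#' @export
simulate_trajectory <- function(growth, lifespan,
                                phenotype = c("none", "short", "elongated"),
                                seed = 1L) {
  stopifnot(inherits(growth, "growth_params"))
  phenotype <- match.arg(phenotype)
  if (!is.numeric(lifespan) || lifespan < 1) stopf("lifespan must be >= 1")
  lifespan <- as.integer(lifespan)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  g <- growth
  n_gen <- lifespan + 1L   # lifespan completed divisions + terminal segment
  Lb <- numeric(n_gen); Ld <- numeric(n_gen); Tg <- numeric(n_gen)
  Lb[1] <- rnorm_trunc(1, g$birth_length_mean, g$birth_length_sd)
  for (i in seq_len(n_gen)) {
    Tg[i] <- rnorm_trunc(1, g$doubling_time_mean, g$doubling_time_sd)
    repeat {
      Ld[i] <- rnorm_trunc(1, g$division_length_mean, g$division_length_sd)
      if (Ld[i] > Lb[i]) break
    }
    if (i < n_gen)
      Lb[i + 1] <- Ld[i] * rnorm_trunc(1, 0.5, 0.02, lower = 0.4, upper = 0.6)
  }

  # terminal segment duration by phenotype
  term_T <- switch(phenotype,
    short = Tg[n_gen] * runif(1, 0.25, 0.85),
    elongated = g$doubling_time_mean * runif(1, 3.3, 5.0),
    none = 0.5 * Tg[n_gen])
  dur <- c(Tg[seq_len(lifespan)], term_T)
  t_start <- cumsum(c(0, dur[-n_gen]))
  division_times <- t_start[-1]                  # lifespan division events
  total_T <- sum(dur)

  dt <- g$sampling_interval / 60                 # hours
  times <- seq(0, total_T, by = dt)
  gen_idx <- findInterval(times, t_start)        # 1..n_gen
  lengths <- numeric(length(times))
  f <- g$neto_fraction; m <- g$monopolar_rate_share
  for (i in seq_len(n_gen)) {
    sel <- gen_idx == i
    if (!any(sel)) next
    tt <- times[sel] - t_start[i]
    Ti <- Tg[i]
    dL <- Ld[i] - Lb[i]
    # bipolar rate r2 so that m*r2*(f*T) + r2*((1-f)*T) = dL over one cycle
    r2 <- dL / (Ti * (m * f + (1 - f)))
    r1 <- m * r2
    ext <- ifelse(tt <= f * Ti, r1 * tt,
                  r1 * f * Ti + r2 * (tt - f * Ti))
    lengths[sel] <- Lb[i] + ext
  }
  structure(list(cell_id = NA_integer_, times = times, lengths = lengths,
                 division_times = division_times,
                 generation_count = lifespan, phenotype = phenotype,
                 sampling_interval = g$sampling_interval,
                 generations = data.frame(
                   gen = seq_len(n_gen), t_start = t_start, duration = dur,
                   birth_length = Lb, division_length = Ld,
                   doubling_time = Tg,
                   completed = c(rep(TRUE, lifespan), FALSE))),
            class = "cell_trajectory")
}

#' @export
print.cell_trajectory <- function(x, ...) {
  cat(sprintf("Cell trajectory: %d divisions over %.1f h (%d samples), terminal phenotype '%s'\n",
              x$generation_count, max(x$times), length(x$times), x$phenotype))
  invisible(x)
}

#' Simulate a cohort of cells
#'
#' Convenience wrapper chaining \code{\link{sample_lifespans}},
#' \code{\link{assign_terminal_phenotypes}} and
#' \code{\link{simulate_trajectory}} for a whole cohort. Per-cell random
#' streams are derived from the master seed by stable hashing of the cell
#' id, so any subset of cells reproduces identically.
#'
#' @param model A \code{\link{mortality_model}}.
#' @param growth A \code{\link{growth_params}}.
#' @param probs A \code{\link{phenotype_probs}}.
#' @param n_cells Cohort size.
#' @param seed Master integer seed.
#' @param trajectories If \code{FALSE}, skip trajectory simulation and
#'   return only the lifespan table (much faster for survival-only work).
#' @return A list with \code{lifespans} (table) and \code{trajectories}
#'   (list of \code{cell_trajectory}, or \code{NULL}).
#' @export
simulate_cohort <- function(model, growth = growth_params(),
                            probs = phenotype_probs(), n_cells = 100,
                            seed = 1L, trajectories = TRUE) {
  lt <- sample_lifespans(model, n_cells, seed = derive_seed(seed, 0L))
  lt <- assign_terminal_phenotypes(lt, probs, seed = derive_seed(seed, 1L))
  trajs <- NULL
  if (trajectories) {
    trajs <- lapply(seq_len(n_cells), function(i) {
      tr <- simulate_trajectory(growth, lt$generations_at_death[i],
                                phenotype = lt$terminal_phenotype[i],
                                seed = derive_seed(seed, i + 1L))
      tr$cell_id <- i
      tr
    })
  }
  list(lifespans = lt, trajectories = trajs)
}
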