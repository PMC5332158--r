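#' RLS contour grid over the Gompertz coefficients
#'
#' Evaluates the closed-form replicative lifespan on a dense grid of the
#' age-independent hazard scale \eqn{\alpha} and the age-dependent rate
#' \eqn{\beta}. The \eqn{\beta = 0} boundary uses the exponential limit
#' \eqn{\ln 2/\alpha}. The resulting map shows that the measured RLS
#' confounds aging and stochastic death: the same lifespan can be reached
#' by many \eqn{(\alpha, \beta)} combinations.
#'
#' @param alpha_range Length-2 positive range of \eqn{\alpha}.
#' @param beta_range Length-2 non-negative range of \eqn{\beta}.
#' @param resolution Grid points per axis.
#' @param log_alpha Space the alpha grid logarithmically (typical, since
#'   hazard scales span decades).
#' @param strain_points Optional \code{data.frame} with \code{label},
#'   \code{alpha}, \code{beta} markers to overlay on plots.
#' @return An object of class \code{"contour_grid"}: \code{alpha_values},
#'   \code{beta_values}, \code{rls_matrix} (alpha by beta),
#'   \code{strain_points}.
#' @export
rls_contour_grid <- function(alpha_range = c(0.001, 0.2),
                             beta_range = c(0, 0.5), resolution = 101,
                             log_alpha = TRUE, strain_points = NULL) {
  if (any(alpha_range <= 0)) stopf("alpha_range must be positive")
  if (any(beta_range < 0)) stopf("beta_range must be non-negative")
  av <- if (log_alpha)
    exp(seq(log(alpha_range[1]), log(alpha_range[2]), length.out = resolution))
  else seq(alpha_range[1], alpha_range[2], length.out = resolution)
  bv <- seq(beta_range[1], beta_range[2], length.out = resolution)
  m <- outer(av, bv, function(a, b)
    ifelse(b == 0, log(2) / a, log(1 + b * log(2) / a) / b))
  structure(list(alpha_values = av, beta_values = bv, rls_matrix = m,
                 strain_points = strain_points),
            class = "contour_grid")
}

#' Classify a population as aging or non-aging
#'
#' A population is called non-aging when the exponential (constant-hazard)
#' model is selected over the Gompertz model by adjusted r-squared, or when
#' the Gompertz age-dependent rate \eqn{\beta} is not distinguishable from
#' zero (its bootstrap CI includes 0). Both fits must be on the same curve.
#'
#' @param fit_exp Exponential \code{survival_fit}.
#' @param fit_gom Gompertz \code{survival_fit} on the same curve.
#' @return A list: \code{verdict} ("aging" or "non_aging") and
#'   \code{evidence} (beta estimate and CI, the two adjusted r-squared
#'   values, which model was selected).
#' @export
classify_aging <- function(fit_exp, fit_gom) {
  stopifnot(inherits(fit_exp, "survival_fit"), inherits(fit_gom, "survival_fit"))
  if (fit_exp$kind != "exponential" || fit_gom$kind != "gompertz")
    stopf("classify_aging expects an exponential and a gompertz fit, in that order")
  selected <- if (fit_gom$adjusted_r2 - fit_exp$adjusted_r2 > 1e-4)
    "gompertz" else "exponential"
  beta <- fit_gom$coef[["beta"]]
  beta_ci <- if (!is.null(fit_gom$ci)) fit_gom$ci["beta", ] else c(lower = NA, upper = NA)
  beta_zero <- !is.na(beta_ci[["lower"]]) && beta_ci[["lower"]] <= 1e-6
  verdict <- if (selected == "exponential" || beta_zero) "non_aging" else "aging"
  list(verdict = verdict,
       evidence = list(beta = beta, beta_ci = beta_ci,
                       adjusted_r2_exponential = fit_exp$adjusted_r2,
                       adjusted_r2_gompertz = fit_gom$adjusted_r2,
                       selected = selected))
}

#' Per-generation table from simulated trajectories
#'
#' Flattens a list of \code{cell_trajectory} objects into one row per
#' completed generation, with its division length and doubling time.
#'
#' @param trajectories List of \code{\link{simulate_trajectory}} objects.
#' @return \code{data.frame} with \code{cell_id}, \code{gen},
#'   \code{division_length}, \code{doubling_time},
#'   \code{generation_count}, \code{phenotype}.
#' @export
generation_table <- function(trajectories) {
  out <- lapply(trajectories, function(tr) {
    gg <- tr$generations[tr$generations$completed, , drop = FALSE]
    if (nrow(gg) == 0) return(NULL)
    data.frame(cell_id = tr$cell_id, gen = gg$gen,
               division_length = gg$division_length,
               doubling_time = gg$doubling_time,
               generation_count = tr$generation_count,
               phenotype = tr$phenotype, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Post-synchronize cells to the time of death
#'
#' Re-indexes each dying cell's completed generations backwards from death
#' (k = 1 is the last completed division, k = 2 the one before, ...) and
#' collects the division length and doubling time distributions for the
#' k_max generations preceding death. Cells with fewer than k completed
#' generations skip bin k. In an aging population these distributions drift
#' as death approaches; in a non-aging one they stay flat.
#'
#' @param gen_tab A \code{\link{generation_table}} (or list of
#'   trajectories, which is converted).
#' @param k_max Number of generations before death to collect.
#' @return An object of class \code{"death_aligned"}: a \code{data.frame}
#'   with \code{k}, \code{cell_id}, \code{division_length},
#'   \code{doubling_time}, plus per-bin sample sizes in
#'   \code{attr(, "n_per_bin")}.
#' @export
post_synchronize_to_death <- function(gen_tab, k_max = 5) {
  if (is.list(gen_tab) && !is.data.frame(gen_tab))
    gen_tab <- generation_table(gen_tab)
  stopifnot(is.data.frame(gen_tab))
  rows <- lapply(seq_len(k_max), function(k) {
    sel <- gen_tab$gen == gen_tab$generation_count - k + 1 &
      gen_tab$generation_count >= k
    d <- gen_tab[sel, , drop = FALSE]
    if (nrow(d) == 0) return(NULL)
    data.frame(k = k, cell_id = d$cell_id,
               division_length = d$division_length,
               doubling_time = d$doubling_time)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_per_bin") <- table(factor(out$k, levels = seq_len(k_max)))
  class(out) <- c("death_aligned", class(out))
  out
}

#' Kolmogorov-Smirnov comparison of sequential death-aligned generations
#'
#' Two-sample KS tests between each pair of adjacent bins (k+1 vs k) of a
#' death-aligned distribution set, for both division length and doubling
#' time. Stars mirror the usual annotation (* p < 0.05, ** p < 0.01); raw
#' p-values are reported without multiplicity correction, with a
#' Holm-corrected column alongside.
#'
#' @param dists A \code{\link{post_synchronize_to_death}} result.
#' @param metrics Which columns to compare.
#' @return \code{data.frame} with \code{metric}, \code{pair},
#'   \code{n_older}, \code{n_younger}, \code{D}, \code{p}, \code{stars},
#'   \code{p_holm}.
#' @export
ks_generation_comparison <- function(dists,
                                     metrics = c("division_length", "doubling_time")) {
  stopifnot(inherits(dists, "death_aligned"))
  ks <- sort(unique(dists$k))
  out <- list()
  for (m in metrics) {
    for (i in seq_len(length(ks) - 1)) {
      k_young <- ks[i]; k_old <- ks[i + 1]   # larger k = further from death
      a <- dists[[m]][dists$k == k_old]
      b <- dists[[m]][dists$k == k_young]
      if (length(a) < 2 || length(b) < 2) next
      kt <- suppressWarnings(ks.test(a, b))
      out[[length(out) + 1]] <- data.frame(
        metric = m, pair = sprintf("k=%d vs k=%d", k_old, k_young),
        n_older = length(a), n_younger = length(b),
        D = unname(kt$statistic), p = kt$p.value,
        stars = if (kt$p.value < 0.01) "**" else if (kt$p.value < 0.05) "*" else "",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  if (!is.null(out)) out$p_holm <- stats::p.adjust(out$p, method = "holm")
  out
}

#' Classify the terminal death phenotype of a trajectory
#'
#' Dying fission yeast fall into two classes: \code{"short"} cells die
#' before reaching the normal division length (< 16.2 um by default) and
#' \code{"elongated"} cells keep elongating for more than three mean
#' doubling times without dividing (a hallmark of checkpoint
#' dysregulation). When both criteria are met, elongated wins, since
#' hyper-elongation is the marked phenotype.
#'
#' @param traj A \code{cell_trajectory} of a died cell.
#' @param normal_division_length Threshold length in um.
#' @param mean_doubling_time Population mean doubling time in hours.
#' @return "short" or "elongated".
#' @export
classify_death_phenotype <- function(traj, normal_division_length = 16.2,
                                     mean_doubling_time = 2.05) {
  stopifnot(inherits(traj, "cell_trajectory"))
  if (traj$phenotype == "none")
    stopf("not applicable: cell survived to the end of observation")
  term <- traj$generations[!traj$generations$completed, , drop = FALSE]
  term_duration <- term$duration[nrow(term)]
  term_length <- traj$lengths[length(traj$lengths)]
  if (term_duration > 3 * mean_doubling_time) "elongated"
  else if (term_length < normal_division_length) "short"
  else "short"   # died at normal size without hyper-elongation: not the marked class
}

#' Last-sibling fate proportions by replicative age
#'
#' Bins dying cells by the old-pole replicative age at death (quartile bins
#' by default) and tabulates the fate of the last sibling produced by the
#' terminal division (never divided / divided once / divided multiple
#' times), with bootstrap standard deviations from cell-level resampling
#' and a global chi-square test of fate-age independence.
#'
#' @param table Lifespan table with \code{sibling_fate} assigned.
#' @param age_bins Either a number of quantile bins or a vector of
#'   breakpoints; default 4 (quartiles).
#' @param n_boot Bootstrap resamples for the per-class SDs.
#' @param seed Integer seed.
#' @return A list: \code{proportions} (bin x fate), \code{sd} (bootstrap
#'   SDs), \code{counts}, \code{chisq_p} (independence test),
#'   \code{bin_labels}.
#' @export
sibling_fate_by_age <- function(table, age_bins = 4, n_boot = 500, seed = 1L) {
  d <- table[table$status == "died" & table$sibling_fate != "none", , drop = FALSE]
  if (nrow(d) == 0) stopf("no died cells with sibling_fate assigned")
  fates <- c("never_divided", "divided_once", "divided_multiple")
  g <- d$generations_at_death
  brk <- if (length(age_bins) == 1)
    unique(quantile(g, probs = seq(0, 1, length.out = age_bins + 1)))
  else unique(sort(age_bins))
  if (length(brk) < 2) brk <- c(min(g) - 0.5, max(g) + 0.5)
  bin <- cut(g, breaks = brk, include.lowest = TRUE)
  fate <- factor(d$sibling_fate, levels = fates)
  counts <- table(bin, fate)
  props <- prop.table(counts + 0, margin = 1)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  n <- nrow(d)
  boot_arr <- array(NA_real_, dim = c(n_boot, nrow(counts), length(fates)))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    tb <- table(bin[idx], fate[idx])
    pb <- prop.table(tb + 0, margin = 1)
    pb[!is.finite(pb)] <- NA
    boot_arr[b, , ] <- pb
  }
  sds <- apply(boot_arr, c(2, 3), sd, na.rm = TRUE)
  dimnames(sds) <- dimnames(props)
  chi_p <- tryCatch(suppressWarnings(chisq.test(counts)$p.value),
                    error = function(e) NA_real_)
  list(proportions = props, sd = sds, counts = counts, chisq_p = chi_p,
       bin_labels = levels(bin))
}

#' Tally segregation defects in healthy versus terminal divisions
#'
#' Counts segregation classes (\code{normal}, \code{multi},
#' \code{unequal}, \code{bridge}) separately for all divisions and for the
#' divisions immediately preceding death, and reports the fold enrichment
#' of the overall defect rate (1 - P(normal)) in terminal divisions.
#'
#' @param events \code{data.frame} with columns \code{population}
#'   ("all" or "terminal") and \code{class}.
#' @return An object of class \code{"defect_tally"}: \code{counts},
#'   \code{proportions}, \code{defect_rate} per population,
#'   \code{fold_enrichment}.
#' @export
tally_segregation_defects <- function(events) {
  stopifnot(is.data.frame(events), all(c("population", "class") %in% names(events)))
  classes <- c("normal", "multi", "unequal", "bridge")
  bad <- setdiff(unique(events$class), classes)
  if (length(bad) > 0)
    stopf("unknown defect class label(s): %s", paste(bad, collapse = ", "))
  bad_pop <- setdiff(unique(events$population), c("all", "terminal"))
  if (length(bad_pop) > 0)
    stopf("unknown population label(s): %s", paste(bad_pop, collapse = ", "))
  counts <- table(factor(events$population, levels = c("all", "terminal")),
                  factor(events$class, levels = classes))
  props <- prop.table(counts + 0, margin = 1)
  rate <- 1 - props[, "normal"]
  fold <- if (is.na(rate[["all"]]) || rate[["all"]] == 0) NA_real_
          else unname(rate[["terminal"]] / rate[["all"]])
  structure(list(counts = counts, proportions = props, defect_rate = rate,
                 fold_enrichment = fold),
            class = "defect_tally")
}

#' @export
print.defect_tally <- function(x, ...) {
  cat("Segregation-defect tally (proportions):\n")
  print(round(x$proportions, 3))
  cat(sprintf("Defect rate: all %.1f%%, terminal %.1f%% (fold enrichment %s)\n",
              100 * x$defect_rate[["all"]], 100 * x$defect_rate[["terminal"]],
              if (is.na(x$fold_enrichment)) "n/a" else
                sprintf("%.2f", x$fold_enrichment)))
  invisible(x)
}

#' Per-class death probability after a segregation defect
#'
#' For events labelled with their subsequent survival outcome, estimates
#' P(death | defect class) with an exact binomial confidence interval.
#' Classes with zero events are omitted.
#'
#' @param events \code{data.frame} with columns \code{class} and
#'   \code{died} (logical).
#' @param level Confidence level.
#' @return \code{data.frame} with \code{class}, \code{n}, \code{deaths},
#'   \code{p_death}, \code{lower}, \code{upper}.
#' @export
defect_lethality <- function(events, level = 0.95) {
  stopifnot(is.data.frame(events), all(c("class", "died") %in% names(events)))
  out <- lapply(split(events, events$class), function(d) {
    n <- nrow(d); k <- sum(d$died)
    if (n == 0) return(NULL)
    bt <- binom.test(k, n, conf.level = level)
    data.frame(class = d$class[1], n = n, deaths = k, p_death = k / n,
               lower = bt$conf.int[1], upper = bt$conf.int[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
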