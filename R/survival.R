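#' Kaplan-Meier survival estimate for complete lifespan data
#'
#' Estimates the survivor function from a lifespan table. Lost or ejected
#' cells are excluded rather than censored; with complete data the
#' Kaplan-Meier product-limit estimate reduces exactly to the empirical
#' survivor fraction \eqn{\hat S(g) = \#\{lifespan > g\}/n}, which is what
#' this function computes.
#'
#' @param lifespans A lifespan table (see \code{\link{sample_lifespans}})
#'   or a bare integer vector of generations at death.
#' @param censor_lost If \code{TRUE}, rows with status other than
#'   \code{"died"} are right-censored at their recorded generation and the
#'   product-limit estimator is used; by default they are excluded, the
#'   standard treatment when losses are rare.
#' @return An object of class \code{"survival_curve"}: \code{generations}
#'   (0..max), \code{survival}, \code{at_risk} (cells alive entering each
#'   generation), \code{deaths}, \code{n_total}.
#' @examples
#' km_estimate(c(1, 2, 2, 3))$survival   # 1.00 0.75 0.25 0.00
#' @export
km_estimate <- function(lifespans, censor_lost = FALSE) {
  if (is.data.frame(lifespans)) {
    died <- lifespans$status == "died"
    g <- lifespans$generations_at_death[died]
    g_cens <- if (censor_lost) lifespans$generations_at_death[!died] else integer(0)
  } else {
    g <- as.integer(lifespans)
    g_cens <- integer(0)
  }
  if (length(g) == 0) stopf("no died cells in lifespan table")
  if (any(g < 1)) stopf("generations_at_death must be >= 1")
  n <- length(g) + length(g_cens)
  gmax <- max(g)
  gens <- 0:gmax
  deaths <- c(0L, tabulate(g, nbins = gmax))     # no deaths at generation 0
  censored <- c(0L, tabulate(g_cens, nbins = gmax))
  at_risk <- n - cumsum(c(0L, (deaths + censored)[-length(deaths)]))
  surv <- if (length(g_cens) == 0) {
    # complete data: the product-limit estimate telescopes to the
    # empirical survivor fraction; compute it directly
    vapply(gens, function(k) sum(g > k) / n, numeric(1))
  } else {
    cumprod(ifelse(at_risk > 0, 1 - deaths / at_risk, 1))
  }
  structure(list(generations = gens, survival = surv,
                 at_risk = as.integer(at_risk), deaths = as.integer(deaths),
                 n_total = n),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("Survival curve: n = %d cells, max lifespan %d generations, median %s\n",
              x$n_total, max(x$generations),
              format(x$generations[which(x$survival <= 0.5)[1]])))
  invisible(x)
}

#' @export
as.data.frame.survival_curve <- function(x, ...) {
  data.frame(generation = x$generations, survival = x$survival,
             at_risk = x$at_risk, deaths = x$deaths)
}

#' Empirical per-generation hazard
#'
#' \eqn{\hat\lambda(g)} = deaths during generation \eqn{g} / cells at risk
#' entering generation \eqn{g}. Generations with no cells at risk are
#' omitted.
#'
#' @param curve A \code{\link{km_estimate}} curve.
#' @return An object of class \code{"hazard_curve"}: \code{generations},
#'   \code{hazard}, \code{source = "empirical"}.
#' @export
empirical_hazard <- function(curve) {
  stopifnot(inherits(curve, "survival_curve"))
  keep <- curve$at_risk > 0 & curve$generations >= 1
  structure(list(generations = curve$generations[keep],
                 hazard = curve$deaths[keep] / curve$at_risk[keep],
                 source = "empirical"),
            class = "hazard_curve")
}

#' Fit a survival model to a Kaplan-Meier curve
#'
#' Nonlinear least squares of the exponential (\eqn{S(g) = e^{-\alpha g}})
#' or Gompertz (\eqn{S(g) = e^{(\alpha/\beta)(1 - e^{\beta g})}}) survival
#' function to the estimated curve at integer generations. By default the
#' points are weighted at \eqn{1/\hat S(g)} to increase the influence of
#' older cells; points with \eqn{\hat S = 0} are excluded (their weight is
#' undefined). Confidence intervals, when requested, come from a cell-level
#' percentile bootstrap (\code{\link{bootstrap_cis}}), with the lifespan
#' multiset reconstructed from the curve's death counts (exact for complete
#' data).
#'
#' @param curve A \code{survival_curve}.
#' @param kind "exponential" or "gompertz".
#' @param weighting "inverse_survival" (default) or "none".
#' @param n_boot Bootstrap resamples for CIs; 0 skips CIs.
#' @param seed Seed for the bootstrap.
#' @return An object of class \code{"survival_fit"}: fitted
#'   \code{\link{mortality_model}}, coefficients, adjusted r-squared,
#'   closed-form RLS, CIs (if bootstrapped), bootstrap replicates, and the
#'   input curve.
#' @export
fit_survival <- function(curve, kind = c("exponential", "gompertz"),
                         weighting = c("inverse_survival", "none"),
                         n_boot = 0, seed = 1L) {
  stopifnot(inherits(curve, "survival_curve"))
  kind <- match.arg(kind)
  weighting <- match.arg(weighting)
  keep <- curve$survival > 0
  g <- curve$generations[keep]
  s <- curve$survival[keep]
  if (length(unique(g)) < 3) stopf("fit needs >= 3 distinct generations with S > 0")
  if (kind == "gompertz" && length(unique(g)) < 4)
    stopf("under-determined: gompertz fit needs >= 4 points")
  w <- if (weighting == "inverse_survival") 1 / s else rep(1, length(s))

  co <- fit_surv_points(g, s, w, kind)
  model <- if (kind == "exponential") mortality_model("exponential", co[["alpha"]])
           else mortality_model("gompertz", co[["alpha"]], co[["beta"]])
  fitted_s <- survival_fn(model, g)
  p <- if (kind == "exponential") 1L else 2L
  r2w <- r_squared_weighted(s, fitted_s, w)
  nn <- length(s)
  adj <- 1 - (1 - r2w) * (nn - 1) / (nn - p - 1)

  fit <- structure(list(model = model, kind = kind,
                        coef = co, r_squared = r2w, adjusted_r2 = adj,
                        rls = rls(model), n_cells = curve$n_total,
                        weighting = weighting, curve = curve,
                        ci = NULL, boot = NULL),
                   class = "survival_fit")
  if (n_boot > 0) {
    lifespans <- rep(curve$generations, curve$deaths)
    bs <- bootstrap_cis(lifespans, kind = kind, n_boot = n_boot, seed = seed,
                        weighting = weighting)
    fit$ci <- bs$ci
    fit$boot <- bs$replicates
  }
  fit
}

# weighted NLS of a survival family on (g, s) points; a flat all-ones curve
# (point-mass lifespan data) carries no decay information and collapses to
# the zero-hazard boundary
fit_surv_points <- function(g, s, w, kind) {
  if (sd(s) == 0)
    return(c(alpha = 1e-12, beta = if (kind == "gompertz") 1e-12 else 0))
  if (kind == "exponential") {
    a0 <- max(1e-6, -unname(coef(lm(log(s) ~ 0 + g, weights = w))[1]))
    ft <- minpack.lm::nlsLM(s ~ exp(-a * g), start = list(a = a0), weights = w,
                            lower = 1e-12, upper = 10,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
    c(alpha = unname(coef(ft)[["a"]]), beta = 0)
  } else {
    a0 <- max(1e-6, -unname(coef(lm(log(s) ~ 0 + g, weights = w))[1]))
    # seed from the log-hazard implied by the curve: -d log S is piecewise
    # constant and log-linear in g under the gompertz model
    lam <- -diff(log(s)) / diff(g)
    gm <- head(g, -1)
    hz <- lam > 0 & is.finite(lam)
    start_hz <- if (sum(hz) >= 3) {
      hc <- coef(lm(log(lam[hz]) ~ gm[hz]))
      list(a = max(1e-8, min(5, exp(unname(hc[1])))),
           b = max(1e-8, min(2, unname(hc[2]))))
    } else NULL
    starts <- c(if (!is.null(start_hz)) list(start_hz),
                list(list(a = a0, b = 0.05), list(a = a0 / 2, b = 0.2),
                     list(a = a0, b = 1e-4), list(a = a0 / 10, b = 0.5),
                     list(a = a0 / 2, b = 0.01)))
    ft <- NULL; err <- NULL
    for (st in starts) {
      ft <- tryCatch(
        minpack.lm::nlsLM(s ~ exp((a / b) * (1 - exp(b * g))),
                          start = st, weights = w,
                          lower = c(1e-12, 1e-12), upper = c(10, 5),
                          control = minpack.lm::nls.lm.control(maxiter = 500)),
        error = function(e) { err <<- e; NULL })
      if (!is.null(ft)) break
    }
    if (is.null(ft))
      stopf("gompertz fit did not converge: %s", conditionMessage(err))
    c(alpha = unname(coef(ft)[["a"]]), beta = unname(coef(ft)[["b"]]))
  }
}

r_squared_weighted <- function(obs, fitted, w) {
  mu <- sum(w * obs) / sum(w)
  1 - sum(w * (obs - fitted)^2) / sum(w * (obs - mu)^2)
}

#' @export
print.survival_fit <- function(x, ...) {
  cat(sprintf("%s survival fit (n = %d cells, weighting: %s)\n",
              x$kind, x$n_cells, x$weighting))
  cat(sprintf("  alpha = %.5g", x$coef[["alpha"]]))
  if (x$kind == "gompertz") cat(sprintf(", beta = %.5g", x$coef[["beta"]]))
  cat(sprintf("\n  adjusted r^2 = %.4f, RLS = %.2f generations\n",
              x$adjusted_r2, x$rls))
  if (!is.null(x$ci)) {
    cat(sprintf("  95%% CI: alpha (%.4g, %.4g), RLS (%.2f, %.2f)\n",
                x$ci["alpha", "lower"], x$ci["alpha", "upper"],
                x$ci["rls", "lower"], x$ci["rls", "upper"]))
  }
  invisible(x)
}

#' Hazard curve implied by a fitted survival model
#'
#' Constant \eqn{\alpha} for the exponential fit; \eqn{\alpha e^{\beta g}}
#' for the Gompertz fit.
#'
#' @param fit A \code{\link{fit_survival}} fit.
#' @param generations Generations at which to evaluate (defaults to the
#'   fitted curve's range).
#' @return A \code{hazard_curve} with \code{source = "fitted"}.
#' @export
hazard_from_fit <- function(fit, generations = NULL) {
  stopifnot(inherits(fit, "survival_fit"))
  generations <- generations %||% fit$curve$generations
  structure(list(generations = generations,
                 hazard = hazard_fn(fit$model, generations),
                 source = "fitted"),
            class = "hazard_curve")
}

#' Replicative lifespan from a fitted model
#'
#' Closed-form RLS at which the fitted survival function crosses one half:
#' \eqn{\ln 2/\alpha} (exponential) or
#' \eqn{\ln(1 + \beta\ln 2/\alpha)/\beta} (Gompertz).
#'
#' @param fit A \code{survival_fit}.
#' @return RLS in generations.
#' @export
rls_from_fit <- function(fit) {
  stopifnot(inherits(fit, "survival_fit"))
  rls(fit$model)
}

#' Select the better-supported survival model
#'
#' Fits both the exponential and the Gompertz survival function and returns
#' the fit with the higher adjusted r-squared; ties within 1e-4 resolve to
#' the exponential model (fewer parameters). Both fits are kept in
#' \code{$alternatives}.
#'
#' @inheritParams fit_survival
#' @return The selected \code{survival_fit} with an \code{$alternatives}
#'   list containing both fits.
#' @export
select_model <- function(curve, weighting = c("inverse_survival", "none"),
                         n_boot = 0, seed = 1L) {
  weighting <- match.arg(weighting)
  fe <- tryCatch(fit_survival(curve, "exponential", weighting, n_boot, seed),
                 error = function(e) e)
  fg <- tryCatch(fit_survival(curve, "gompertz", weighting, n_boot, seed),
                 error = function(e) e)
  if (inherits(fe, "error") && inherits(fg, "error"))
    stopf("both survival fits failed: %s / %s",
          conditionMessage(fe), conditionMessage(fg))
  pick <- if (inherits(fg, "error")) fe
          else if (inherits(fe, "error")) fg
          else if (fg$adjusted_r2 - fe$adjusted_r2 > 1e-4) fg else fe
  pick$alternatives <- list(exponential = fe, gompertz = fg)
  pick
}

#' Bootstrap confidence intervals for survival-fit coefficients and RLS
#'
#' Percentile intervals from refitting the survival model on cell-level
#' resamples (with replacement) of the lifespan data. Deterministic given
#' the seed.
#'
#' @param lifespans Lifespan table or integer vector of generations at
#'   death.
#' @param kind Model family to refit.
#' @param n_boot Number of resamples (>= 100 recommended).
#' @param seed Integer seed.
#' @param weighting Fit weighting, as in \code{\link{fit_survival}}.
#' @param level Confidence level.
#' @return A list: \code{ci} (matrix with rows alpha, beta, rls and columns
#'   lower/upper) and \code{replicates} (data.frame of per-resample alpha,
#'   beta, rls).
#' @export
bootstrap_cis <- function(lifespans, kind = c("exponential", "gompertz"),
                          n_boot = 1000, seed = 1L,
                          weighting = c("inverse_survival", "none"),
                          level = 0.95) {
  kind <- match.arg(kind)
  weighting <- match.arg(weighting)
  g <- if (is.data.frame(lifespans))
    lifespans$generations_at_death[lifespans$status == "died"]
  else as.integer(lifespans)
  if (length(g) == 0) stopf("no died cells to resample")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  n <- length(g)
  reps <- matrix(NA_real_, n_boot, 3,
                 dimnames = list(NULL, c("alpha", "beta", "rls")))
  for (b in seq_len(n_boot)) {
    gb <- g[sample.int(n, n, replace = TRUE)]
    fit <- tryCatch({
      cb <- km_estimate(gb)
      fit_survival(cb, kind, weighting, n_boot = 0)
    }, error = function(e) NULL)
    if (!is.null(fit))
      reps[b, ] <- c(fit$coef[["alpha"]], fit$coef[["beta"]], fit$rls)
  }
  reps <- as.data.frame(reps[complete.cases(reps), , drop = FALSE])
  if (nrow(reps) < max(10, 0.5 * n_boot))
    warning("more than half of the bootstrap refits failed", call. = FALSE)
  a <- (1 - level) / 2
  ci <- t(vapply(reps, function(v) quantile(v, c(a, 1 - a), names = FALSE),
                 numeric(2)))
  colnames(ci) <- c("lower", "upper")
  list(ci = ci, replicates = reps)
}

#' Hazard fold-changes relative to a reference strain
#'
#' Ratio of the age-independent hazard scale \eqn{\alpha} of each fit to
#' that of a reference fit, with a percentile CI from the ratio of
#' bootstrap resamples when both fits carry replicates.
#'
#' @param fits A named list of \code{survival_fit} objects.
#' @param reference The reference \code{survival_fit} (e.g. wild type).
#' @return \code{data.frame} with \code{strain}, \code{fold_change},
#'   \code{lower}, \code{upper}.
#' @export
normalize_hazard <- function(fits, reference) {
  stopifnot(inherits(reference, "survival_fit"))
  if (inherits(fits, "survival_fit")) fits <- list(fits)
  if (reference$coef[["alpha"]] == 0) stopf("reference hazard is zero")
  nm <- names(fits) %||% paste0("strain_", seq_along(fits))
  out <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    fc <- f$coef[["alpha"]] / reference$coef[["alpha"]]
    lo <- hi <- NA_real_
    if (!is.null(f$boot) && !is.null(reference$boot)) {
      m <- min(nrow(f$boot), nrow(reference$boot))
      ratio <- f$boot$alpha[seq_len(m)] / reference$boot$alpha[seq_len(m)]
      qs <- quantile(ratio, c(0.025, 0.975), names = FALSE)
      lo <- qs[1]; hi <- qs[2]
    }
    data.frame(strain = nm[i], fold_change = fc, lower = lo, upper = hi,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
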