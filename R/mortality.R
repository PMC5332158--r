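#' Mortality model for per-generation survival
#'
#' Constructs a mortality model describing the per-generation risk of death
#' of a replicating cell. Two families are supported: \code{"exponential"}
#' (constant hazard \eqn{\lambda(g) = \alpha}, survival
#' \eqn{S(g) = e^{-\alpha g}}, a non-aging population) and \code{"gompertz"}
#' (hazard \eqn{\lambda(g) = \alpha e^{\beta g}}, survival
#' \eqn{S(g) = e^{(\alpha/\beta)(1 - e^{\beta g})}}, an aging population).
#' \eqn{\alpha} is the age-independent hazard scale and \eqn{\beta} the
#' age-dependent rate; as \eqn{\beta \to 0} the Gompertz model degenerates
#' to the exponential one.
#'
#' @param kind "exponential" or "gompertz".
#' @param alpha Age-independent hazard scale per generation; must be > 0.
#' @param beta Age-dependent rate per generation; must be >= 0. Ignored
#'   (treated as 0) for \code{kind = "exponential"}.
#' @return An object of class \code{"mortality_model"}.
#' @examples
#' wt <- mortality_model("exponential", alpha = 0.02)
#' rls(wt)                       # ln(2)/0.02 = 34.66 generations
#' aging <- mortality_model("gompertz", alpha = 0.005, beta = 0.15)
#' survival_fn(aging, 0:10)
#' @export
mortality_model <- function(kind = c("exponential", "gompertz"),
                            alpha, beta = 0) {
  kind <- match.arg(kind)
  if (!is.numeric(alpha) || length(alpha) != 1 || !is.finite(alpha) || alpha <= 0)
    stopf("invalid mortality model: alpha must be a single positive number, got %s",
          format(alpha))
  if (!is.numeric(beta) || length(beta) != 1 || !is.finite(beta) || beta < 0)
    stopf("invalid mortality model: beta must be a single number >= 0, got %s",
          format(beta))
  if (kind == "gompertz" && beta == 0) {
    warning("gompertz model with beta = 0 falls back to exponential semantics",
            call. = FALSE)
    kind <- "exponential"
  }
  if (kind == "exponential") beta <- 0
  structure(list(kind = kind, alpha = alpha, beta = beta),
            class = "mortality_model")
}

#' @export
print.mortality_model <- function(x, ...) {
  cat(sprintf("Mortality model: %s (alpha = %g%s)\n", x$kind, x$alpha,
              if (x$kind == "gompertz") sprintf(", beta = %g", x$beta) else ""))
  cat(sprintf("  RLS (S = 1/2): %.3f generations\n", rls(x)))
  invisible(x)
}

#' Survival function S(g)
#'
#' Probability that a cell is still alive after completing \code{g}
#' divisions, under the given mortality model.
#'
#' @param model A \code{\link{mortality_model}}.
#' @param g Generations (vector, >= 0; need not be integer).
#' @return Numeric vector of survival probabilities.
#' @export
survival_fn <- function(model, g) {
  stopifnot(inherits(model, "mortality_model"))
  if (model$kind == "exponential" || model$beta == 0) {
    exp(-model$alpha * g)
  } else {
    exp((model$alpha / model$beta) * (1 - exp(model$beta * g)))
  }
}

#' Hazard function lambda(g)
#'
#' Instantaneous per-generation risk of death at replicative age \code{g}:
#' constant \eqn{\alpha} for the exponential model, \eqn{\alpha e^{\beta g}}
#' for the Gompertz model.
#'
#' @inheritParams survival_fn
#' @return Numeric vector of hazard rates (per generation).
#' @export
hazard_fn <- function(model, g) {
  stopifnot(inherits(model, "mortality_model"))
  if (model$kind == "exponential" || model$beta == 0) {
    rep(model$alpha, length(g))
  } else {
    model$alpha * exp(model$beta * g)
  }
}

#' Replicative lifespan (RLS) of a mortality model
#'
#' The replicative lifespan is the age \eqn{g} at which the survival
#' function crosses one half. Closed forms: \eqn{RLS = \ln 2 / \alpha}
#' for the exponential model and
#' \eqn{RLS = \ln(1 + \beta \ln 2 / \alpha) / \beta} for the Gompertz
#' model (which tends to the exponential form as \eqn{\beta \to 0}).
#'
#' @param model A \code{\link{mortality_model}}.
#' @return RLS in generations.
#' @export
rls <- function(model) {
  stopifnot(inherits(model, "mortality_model"))
  if (model$kind == "exponential" || model$beta == 0) {
    log(2) / model$alpha
  } else {
    log(1 + model$beta * log(2) / model$alpha) / model$beta
  }
}
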