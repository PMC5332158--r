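# shared fixtures and independent oracles

# independent lifespan sampler: sequential per-generation Bernoulli walk
# using conditional death probabilities 1 - S(g)/S(g-1); shares no code
# path with the inverse-CDF sampler it cross-checks
walk_lifespans <- function(model, n, seed) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    g <- 0L
    repeat {
      g <- g + 1L
      p_die <- 1 - survival_fn(model, g) / survival_fn(model, g - 1L)
      if (runif(1) < p_die) return(g)
      if (g > 10000L) stop("walk did not terminate")
    }
  }, integer(1))
}

# survival curve object from exact model values (no sampling noise)
exact_curve <- function(model, gmax = 50, n_total = 1000L) {
  gg <- 0:gmax
  structure(list(generations = gg, survival = survival_fn(model, gg),
                 at_risk = rep(n_total, gmax + 1L),
                 deaths = rep(0L, gmax + 1L), n_total = n_total),
            class = "survival_curve")
}

# noiseless growth configuration (degenerate sds)
noiseless_growth <- function(...) {
  growth_params(birth_length_sd = 0, division_length_sd = 0,
                doubling_time_sd = 0, ...)
}
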