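# internal helpers: seeded streams, truncated draws, moving median

# Derive a per-unit random seed from a master seed and an index, keeping the
# result a valid 32-bit integer. Multiplicative hashing keeps streams for
# different cells decorrelated while remaining reproducible.
derive_seed <- function(master_seed, index) {
  s <- (as.double(master_seed) %% 2147483647) + 1
  h <- (s * 48271 + as.double(index) * 69621) %% 2147483647
  as.integer(h)
}

# Normal draw truncated to positive values (or to an interval) by redrawing.
# Used for all positive-valued biological parameters; prevents unphysical
# negative lengths/times without distorting the bulk of the distribution.
rnorm_trunc <- function(n, mean, sd, lower = 0, upper = Inf) {
  if (sd == 0) return(rep(mean, n))
  out <- rnorm(n, mean, sd)
  bad <- which(out <= lower | out >= upper)
  guard <- 0L
  while (length(bad) > 0) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= lower | out[bad] >= upper]
    guard <- guard + 1L
    if (guard > 1000L) stop("truncated-normal redraw did not terminate; check bounds")
  }
  out
}

# Centered moving median with edge padding; window forced odd.
moving_median <- function(x, window) {
  window <- as.integer(window)
  if (window <= 1L || length(x) < 3L) return(x)
  if (window %% 2L == 0L) window <- window + 1L
  half <- window %/% 2L
  n <- length(x)
  xp <- c(rep(x[1], half), x, rep(x[n], half))
  vapply(seq_len(n), function(i) median(xp[i:(i + window - 1L)]), numeric(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
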