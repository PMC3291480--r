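# Independent oracles used across the suite.

# Brute-force base-level activation: explicit per-use loop, no shared code
# with chunk_activation()/chunk_strength().
brute_activation <- function(use_steps, now, d) {
  total <- 0
  for (u in use_steps) {
    t <- now - u
    if (t < 1) t <- 1
    total <- total + t^(-d)
  }
  log(total)
}

# Exact Wilcoxon matched-pairs by full enumeration of the 2^n sign
# assignments (zero differences dropped, mid-ranks kept).
brute_wilcoxon <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(V = NA_real_, p = NA_real_))
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  ws <- vapply(0:(2^n - 1), function(mask) {
    signs <- bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L
    sum(r[signs])
  }, numeric(1))
  p_le <- mean(ws <= w_obs)
  p_ge <- mean(ws >= w_obs)
  list(V = min(w_obs, sum(r) - w_obs), p = min(1, 2 * min(p_le, p_ge)))
}

# A store with random cache/recovery history at a handful of sites.
random_store <- function(n_events = 20, n_sites = 6) {
  store <- memory_store()
  for (i in seq_len(n_events)) {
    if (stats::runif(1) < 0.5) {
      store <- encode_event(store, "cache", sample.int(n_sites, 1))
    } else {
      store <- encode_event(store, "recovery", sample.int(n_sites, 1),
                            success = stats::runif(1) < 0.5)
    }
  }
  store
}
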