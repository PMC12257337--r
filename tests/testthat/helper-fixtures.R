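# Shared fixtures. Expensive simulations are built once per test run and
# cached here; all randomness is seeded through simulation_config.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# noise-free volume at the standard contrasts
noise_free_volume <- function() {
  cached("noise_free_vol",
         simulate_volume(simulation_config(snr = Inf, seed = 11)))
}

# a segmented noise-free LCOD slice (slice 11, 5.1% contrast)
noise_free_seg <- function() {
  cached("noise_free_seg", {
    sl <- normalize_slice(get_slice(noise_free_volume(), 11))
    list(slice = sl, mask = segment_inner_disk(sl))
  })
}

# independent normal-equations OLS oracle: betas, t, two-sided p
ols_oracle <- function(X, y) {
  xtx_inv <- solve(t(X) %*% X)
  beta <- xtx_inv %*% t(X) %*% y
  res <- y - X %*% beta
  dof <- nrow(X) - ncol(X)
  s2 <- sum(res^2) / dof
  se <- sqrt(s2 * unname(diag(xtx_inv)))
  t_stat <- as.vector(beta) / se
  list(betas = as.vector(beta), t = t_stat,
       p = 2 * pt(-abs(t_stat), dof), dof = dof, rss = sum(res^2))
}

# exhaustive Benjamini-Hochberg step-up oracle
bh_oracle <- function(p, q) {
  m <- length(p)
  if (m == 0) return(logical(0))
  ord <- order(p)
  ps <- p[ord]
  ks <- which(ps <= seq_len(m) * q / m)
  reject <- logical(m)
  if (length(ks)) {
    k_star <- max(ks)
    # reject everything with p <= the boundary value (ties included)
    reject <- p <= ps[k_star]
  }
  reject
}
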