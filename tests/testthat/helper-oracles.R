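# Independent brute-force oracles used to cross-check the vectorized
# implementations. These are deliberately written as plain double loops /
# straight-line code, independent of the package's internals.

# Pearson correlation matrix by explicit double loop.
brute_cor <- function(fields) {
  n <- ncol(fields)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      out[i, j] <- stats::cor(fields[, i], fields[, j])
    }
  }
  out
}

# Per-window population PO/OSI by explicit loop over windows and neurons.
brute_selectivity <- function(binned, theta, min_active = 5) {
  nw <- nrow(binned)
  po <- osi <- rep(NA_real_, nw)
  valid <- logical(nw)
  for (w in seq_len(nw)) {
    r <- binned[w, ]
    if (sum(r > 0) >= min_active && sum(r) > 0) {
      z <- 0 + 0i
      for (j in seq_along(r)) z <- z + r[j] * exp(2i * theta[j])
      z <- z / sum(r)
      po[w] <- (Arg(z) / 2) %% pi
      osi[w] <- Mod(z)
      valid[w] <- TRUE
    }
  }
  list(po = po, osi = osi, valid = valid)
}

# ST index computed directly from a brute selectivity result.
brute_sti <- function(sel, osi_threshold = 0.5, n_bins = 24) {
  keep <- sel$valid & sel$osi > osi_threshold
  if (!any(keep)) return(0)
  brks <- seq(0, pi, length.out = n_bins + 1)
  h <- numeric(n_bins)
  for (p in sel$po[keep]) {
    b <- min(n_bins, max(1, ceiling(p / (pi / n_bins))))
    if (p == 0) b <- 1
    h[b] <- h[b] + 1
  }
  centres <- (brks[-1] + brks[-(n_bins + 1)]) / 2
  h_osi <- Mod(sum(h * exp(2i * centres)) / sum(h))
  (1 - h_osi) * mean(sel$osi[keep])
}

# Straight-line R reference of the LIF network, drawing external Poisson
# counts in the same order (neuron-major per step) as the simulator so that
# a shared seed yields identical event streams.
reference_lif <- function(W, rate_hz, tau_m, v_th, v_reset, j_ext, dt,
                          t_end, seed) {
  n <- nrow(W)
  lam <- rate_hz * dt / 1000
  if (length(lam) == 1) lam <- rep(lam, n)
  decay <- exp(-dt / tau_m)
  v <- numeric(n)
  spiked_prev <- integer(0)
  neuron <- numeric(0); time <- numeric(0)
  n_steps <- round(t_end / dt)
  set.seed(seed)
  for (step in seq_len(n_steps)) {
    v <- v * decay
    for (j in spiked_prev) v <- v + W[, j]
    k <- stats::rpois(n, lam)
    v <- v + j_ext * k
    sp <- which(v >= v_th)
    v[sp] <- v_reset
    spiked_prev <- sp
    if (length(sp)) {
      neuron <- c(neuron, sp)
      time <- c(time, rep(step * dt, length(sp)))
    }
  }
  data.frame(neuron = neuron, time = time)
}

# Steady-state response difference by solving the full stationary system
# r = W r + s twice (linear regime oracle).
brute_response <- function(W, n_e, s, ds_i) {
  n <- nrow(W)
  ds <- c(numeric(n_e), ds_i)
  r0 <- solve(diag(n) - W, s)
  r1 <- solve(diag(n) - W, s + ds)
  (r1 - r0)[(n_e + 1):n]
}

# Small deterministic ring network with evenly spaced orientations.
# Defaults give (at any n_e, weights scale as 40/n_e): uniform E eigenvalue
# 6, specific E eigenvalue 3 (> 1: ISN along the specific mode), inhibition
# dominance g = 1.5, stable full spectrum; the closed-form specific slope is
# (1 - 3)/(1 + 0.5 * 3) = -0.8.
toy_ring <- function(n_e = 40, n_i = 40, J = c(EE = 0.15, IE = 0.15,
                                               EI = -0.225, II = -0.225),
                     m = 1) {
  theta <- rep(seq(0, pi, length.out = n_e + 1)[-(n_e + 1)],
               length.out = n_e + n_i)
  params <- block_params(J * (40 / n_e), m = m, zeta = FALSE)
  build_ring_weights(theta, n_e, params, seed = 1)
}
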