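#' Slope of inhibitory response change versus input perturbation
#'
#' Ordinary least squares of per-neuron response changes `dr` on the input
#' perturbations `ds`, with the two-sided t-test p-value of the slope. A
#' significantly negative slope is the specific paradoxical effect; a mean
#' response change opposite in sign to the mean perturbation is the
#' nonspecific (average) paradoxical effect.
#'
#' @param dr Per-neuron response changes of the inhibitory population.
#' @param ds Per-neuron input perturbations (same length, not all equal).
#' @param alpha Significance level for the specific flag (default 0.05).
#' @return An object of class `slope_result`: `slope`, `intercept`,
#'   `p_value`, `mean_dr`, `mean_ds`, and the flags
#'   `nonspecific_paradoxical`, `specific_paradoxical`.
#' @export
perturbation_slope <- function(dr, ds, alpha = 0.05) {
  stopifnot(length(dr) == length(ds))
  if (length(dr) < 3) stop("need at least 3 points")
  if (stats::var(ds) == 0) stop("degenerate regressor: `ds` is constant")
  fit <- stats::lm(dr ~ ds)
  cf <- summary(fit)$coefficients
  slope <- cf["ds", "Estimate"]
  p <- cf["ds", "Pr(>|t|)"]
  m_dr <- mean(dr); m_ds <- mean(ds)
  structure(
    list(slope = slope, intercept = cf["(Intercept)", "Estimate"],
         p_value = p, mean_dr = m_dr, mean_ds = m_ds,
         nonspecific_paradoxical = sign(m_dr) == -sign(m_ds) && m_ds != 0,
         specific_paradoxical = slope < 0 && p < alpha),
    class = "slope_result"
  )
}

#' Windowed population preferred orientation and selectivity
#'
#' For each time window, the circular mean of the population activity on the
#' doubled orientation circle:
#' `R = sum_j r_j exp(2 i theta*_j) / sum_j r_j` over the active excitatory
#' neurons. The population preferred orientation is `arg(R) / 2` mapped to
#' `[0, pi)` (the halving undoes the angle doubling) and the population OSI
#' is `|R|`. Windows with fewer than `min_active` active neurons are masked.
#' `doubled = FALSE` uses `exp(2 pi i theta*)` instead of the doubled-angle
#' convention.
#'
#' @param binned A `n_windows x n` activity matrix (spike counts from
#'   [bin_spikes()], or window-mean rates); only the columns in `neurons`
#'   are used.
#' @param theta_star Preferred orientations of those neurons (radians).
#' @param neurons Column indices to use (default: all columns; pass the
#'   excitatory indices for spiking records that contain both populations).
#' @param min_active Minimum number of active (nonzero) neurons per window
#'   (default 5).
#' @param doubled Use the doubled-angle circular mean (default `TRUE`).
#' @return An object of class `selectivity_trace`: a data frame with
#'   `window`, `po` (radians, `[0, pi)`), `osi`, `n_active`, `valid`.
#' @export
population_selectivity <- function(binned, theta_star, neurons = NULL,
                                   min_active = 5, doubled = TRUE) {
  if (!is.null(neurons)) binned <- binned[, neurons, drop = FALSE]
  stopifnot(ncol(binned) == length(theta_star))
  n_active <- rowSums(binned > 0)
  tot <- rowSums(binned)
  phase <- if (doubled) exp(2i * theta_star) else exp(2i * pi * theta_star)
  z <- as.vector(binned %*% phase)
  z <- ifelse(tot > 0, z / tot, NA_complex_)
  po <- (Arg(z) / 2) %% pi
  osi <- Mod(z)
  valid <- n_active >= min_active & tot > 0
  structure(
    data.frame(window = seq_len(nrow(binned)), po = po, osi = osi,
               n_active = n_active, valid = valid),
    class = c("selectivity_trace", "data.frame")
  )
}

#' Spontaneous-transition (ST) index
#'
#' Quantifies transitions between selective population states. Selective
#' windows are the valid windows with population OSI above `osi_threshold`.
#' `H(theta)` is the histogram of their population POs in `n_bins` bins of
#' width `pi / n_bins` over `[0, pi)`; its own circular selectivity `H_osi`
#' (computed on the doubled circle at the bin centres) measures how
#' concentrated the visited states are. The ST index is
#' `STI = (1 - H_osi) * <pop OSI>`, with the OSI average taken over the
#' selective windows (set `average = "valid"` to average over all valid
#' windows instead). With no selective window the STI is 0 and the result is
#' flagged degenerate.
#'
#' @param trace A [population_selectivity()] result.
#' @param osi_threshold Selectivity threshold (default 0.5).
#' @param n_bins Number of PO bins (default 24, bin width `pi/24`).
#' @param average `"selective"` or `"valid"`.
#' @return An object of class `st_result`: `sti`, `h_osi`, `mean_osi`,
#'   `histogram`, `n_selective`, `degenerate`.
#' @export
st_index <- function(trace, osi_threshold = 0.5, n_bins = 24,
                     average = c("selective", "valid")) {
  average <- match.arg(average)
  sel <- trace$valid & !is.na(trace$osi) & trace$osi > osi_threshold
  if (!any(sel)) {
    return(structure(
      list(sti = 0, h_osi = NA_real_, mean_osi = NA_real_,
           histogram = rep(0L, n_bins), n_selective = 0L, degenerate = TRUE),
      class = "st_result"))
  }
  brks <- seq(0, pi, length.out = n_bins + 1)
  h <- as.integer(table(cut(trace$po[sel], breaks = brks,
                            include.lowest = TRUE)))
  centres <- (brks[-1] + brks[-(n_bins + 1)]) / 2
  h_osi <- Mod(sum(h * exp(2i * centres)) / sum(h))
  mean_osi <- if (average == "selective") {
    mean(trace$osi[sel])
  } else {
    mean(trace$osi[trace$valid], na.rm = TRUE)
  }
  structure(
    list(sti = (1 - h_osi) * mean_osi, h_osi = h_osi, mean_osi = mean_osi,
         histogram = h, n_selective = sum(sel), degenerate = FALSE),
    class = "st_result"
  )
}

#' Bootstrapped ST index against a time-shuffle null
#'
#' Shuffles every neuron's activity independently across time windows
#' (destroying temporal coordination while preserving each neuron's activity
#' distribution), recomputes the ST index for each of `n_shuffles` shuffles,
#' and reports the observed STI minus the null mean.
#'
#' @param binned `n_windows x n` activity matrix (see [bin_spikes()]).
#' @param theta_star Preferred orientations of the used neurons.
#' @param neurons Columns of `binned` to use (e.g. the excitatory indices).
#' @param n_shuffles Number of shuffles (default 100).
#' @param seed Integer seed.
#' @param ... Passed to [population_selectivity()] and [st_index()]
#'   (`min_active`, `osi_threshold`, ...).
#' @return An `st_result` augmented with `null_mean`, `null_sd`,
#'   `sti_boot = sti - null_mean` and the null STI draws.
#' @export
bootstrap_st <- function(binned, theta_star, neurons = NULL,
                         n_shuffles = 100, seed = 1, min_active = 5,
                         osi_threshold = 0.5, n_bins = 24) {
  if (!is.null(neurons)) binned <- binned[, neurons, drop = FALSE]
  obs <- st_index(population_selectivity(binned, theta_star,
                                         min_active = min_active),
                  osi_threshold = osi_threshold, n_bins = n_bins)
  set.seed(seed)
  nw <- nrow(binned)
  null_sti <- numeric(n_shuffles)
  sh <- binned
  for (k in seq_len(n_shuffles)) {
    for (j in seq_len(ncol(binned))) sh[, j] <- binned[sample.int(nw), j]
    null_sti[k] <- st_index(
      population_selectivity(sh, theta_star, min_active = min_active),
      osi_threshold = osi_threshold, n_bins = n_bins)$sti
  }
  obs$null_mean <- mean(null_sti)
  obs$null_sd <- stats::sd(null_sti)
  obs$sti_boot <- obs$sti - obs$null_mean
  obs$null_sti <- null_sti
  obs
}

#' Pattern correlation as a function of time interval
#'
#' Average Pearson correlation between the population activity vectors of
#' window pairs separated by a given number of windows, as a function of
#' that interval. Measures how quickly the population pattern decorrelates.
#'
#' @param binned `n_windows x n` activity matrix (e.g. excitatory columns of
#'   [bin_spikes()] output).
#' @param max_lag Largest interval in windows (default `n_windows - 1`).
#' @param min_pairs Intervals with fewer valid pairs are masked (`NA`).
#' @return A data frame with `lag` (windows), `mean_cor`, `n_pairs`.
#' @export
pattern_interval_correlation <- function(binned, max_lag = NULL,
                                         min_pairs = 3) {
  nw <- nrow(binned)
  if (is.null(max_lag)) max_lag <- nw - 1
  max_lag <- min(max_lag, nw - 1)
  mu <- rowMeans(binned)
  sd_w <- apply(binned, 1, stats::sd)
  ok <- sd_w > 0
  Z <- (binned - mu) / ifelse(sd_w > 0, sd_w, 1)
  C <- tcrossprod(Z) / (ncol(binned) - 1)
  C[!ok, ] <- NA; C[, !ok] <- NA
  out <- data.frame(lag = 0:max_lag, mean_cor = NA_real_, n_pairs = 0L)
  for (d in 0:max_lag) {
    idx <- seq_len(nw - d)
    vals <- C[cbind(idx, idx + d)]
    vals <- vals[!is.na(vals)]
    out$n_pairs[d + 1] <- length(vals)
    if (length(vals) >= min_pairs) out$mean_cor[d + 1] <- mean(vals)
  }
  out
}

#' Reference-cell sweep of similarity-patterned perturbations
#'
#' For every responsive inhibitory reference cell, builds the
#' similarity-patterned perturbation `-gamma exp(kappa psi_k)` from that
#' cell's similarity vector, runs the paired perturbation experiment against
#' a shared baseline, fits the response-change-versus-perturbation slope and
#' classifies it. Reports the fraction of reference cells with a significant
#' negative slope (specific paradoxical effect) among those with a
#' significant slope of either sign.
#'
#' All reference cells share one baseline simulation, and the perturbed
#' steady states are integrated as one batch.
#'
#' @param net An `isn_network`.
#' @param similarity `n_i x n_i` similarity matrix (RF or response
#'   correlations).
#' @param responsive Indices (within the inhibitory population) of the
#'   reference cells to sweep; default all.
#' @param gamma,kappa Perturbation parameters (defaults 0.25 and 2).
#' @param alpha Significance level (default 0.05).
#' @param s_base Baseline input vector.
#' @param tau,n_power,dt Rate-dynamics parameters.
#' @param t_base,t_pert Baseline and perturbation window lengths
#'   (defaults 300 and 400).
#' @param discard_fraction Transient fraction discarded (default 1/3).
#' @return A list: per-reference `slope`, `p_value`, the index of each
#'   reference, `fraction_specific` (significant negative among significant),
#'   `fraction_positive`, `n_significant`.
#' @export
reference_sweep <- function(net, similarity, responsive = NULL,
                            gamma = 0.25, kappa = 2, alpha = 0.05,
                            s_base = NULL, tau = 10, n_power = 1, dt = 0.1,
                            t_base = 300, t_pert = 400,
                            discard_fraction = 1 / 3) {
  stopifnot(inherits(net, "isn_network"))
  n <- net$n_e + net$n_i
  if (is.null(responsive)) responsive <- seq_len(net$n_i)
  if (is.null(s_base)) s_base <- rep(2, n)
  base <- steady_state_batch(net$W, matrix(s_base, n, 1), tau = tau,
                             n_power = n_power, dt = dt, t_end = t_base,
                             discard_fraction = discard_fraction)
  r_base <- base$mean[, 1]
  # one perturbed column per reference cell
  P <- -gamma * exp(kappa * similarity[, responsive, drop = FALSE])
  S <- matrix(s_base, n, length(responsive))
  S[net$n_e + seq_len(net$n_i), ] <-
    S[net$n_e + seq_len(net$n_i), ] + P
  pert <- steady_state_batch(net$W, S, tau = tau, n_power = n_power,
                             dt = dt, t_end = t_pert,
                             r0 = base$final[, 1],
                             discard_fraction = discard_fraction)
  i_idx <- net$n_e + seq_len(net$n_i)
  slopes <- numeric(length(responsive))
  pvals <- numeric(length(responsive))
  for (k in seq_along(responsive)) {
    sr <- perturbation_slope(pert$mean[i_idx, k] - r_base[i_idx], P[, k],
                             alpha = alpha)
    slopes[k] <- sr$slope
    pvals[k] <- sr$p_value
  }
  sig <- pvals < alpha
  if (!any(sig)) {
    warning("no reference cell yields a significant slope")
  }
  list(reference = responsive, slope = slopes, p_value = pvals,
       n_significant = sum(sig),
       fraction_specific = if (any(sig)) sum(sig & slopes < 0) / sum(sig)
                           else NA_real_,
       fraction_positive = if (any(sig)) sum(sig & slopes > 0) / sum(sig)
                           else NA_real_)
}
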