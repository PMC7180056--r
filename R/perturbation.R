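new_pattern <- function(ds, protocol, gamma = NA, kappa = NA, seed = NA,
                        reference = NA, fraction = 1) {
  structure(as.numeric(ds), class = "perturbation_pattern",
            protocol = protocol, gamma = gamma, kappa = kappa, seed = seed,
            reference = reference, fraction = fraction)
}

#' Nonspecific perturbation pattern
#'
#' Independent per-neuron input offsets uniform on `[-2 gamma, 0]`: negative
#' (input-reducing) perturbations ignoring neuronal identity. The support
#' matches that of the orientation-patterned protocol so that slope
#' comparisons between the two are like-for-like.
#'
#' @param n_i Number of inhibitory neurons.
#' @param gamma Perturbation magnitude (>= 0); the pattern mean is `-gamma`.
#' @param seed Integer seed.
#' @return A `perturbation_pattern` (numeric vector of length `n_i`).
#' @export
pattern_nonspecific <- function(n_i, gamma, seed = 1) {
  stopifnot(gamma >= 0)
  set.seed(seed)
  new_pattern(stats::runif(n_i, -2 * gamma, 0), "nonspecific",
              gamma = gamma, seed = seed)
}

#' Orientation-patterned (1D ring) perturbation
#'
#' Input offsets set by the preferred orientation of each inhibitory neuron:
#' `delta_s = gamma * (sin(2 theta*) - 1)`, which is zero at
#' `theta* = pi/4` and most negative (`-2 gamma`) at `theta* = 3 pi/4`, so
#' the input is always reduced. `printed_sign = TRUE` flips the overall sign
#' (a nonnegative, input-increasing variant).
#'
#' @param theta_i Preferred orientations of the inhibitory neurons, radians.
#' @param gamma Perturbation magnitude (>= 0).
#' @param printed_sign Use the sign-flipped variant (default `FALSE`).
#' @return A `perturbation_pattern`.
#' @export
pattern_ring_1d <- function(theta_i, gamma, printed_sign = FALSE) {
  stopifnot(gamma >= 0)
  ds <- gamma * (sin(2 * theta_i) - 1)
  if (printed_sign) ds <- -ds
  new_pattern(ds, "ring_1d", gamma = gamma)
}

#' Similarity-patterned perturbation
#'
#' Input offsets set by the similarity of each inhibitory neuron to a
#' reference cell k: `delta_s = -gamma * exp(kappa * psi_k)`, strictly
#' negative and most negative for the most similar neurons. `psi_k` can be
#' RF correlation or response correlation; the protocol is identical.
#'
#' @param psi_ref Similarity of every inhibitory neuron to the reference
#'   cell, in `[-1, 1]`.
#' @param gamma Perturbation magnitude (default 0.25).
#' @param kappa Similarity exponent (default 2).
#' @param reference Optional reference-cell id stored with the pattern.
#' @return A `perturbation_pattern`.
#' @export
pattern_similarity <- function(psi_ref, gamma = 0.25, kappa = 2,
                               reference = NA) {
  stopifnot(gamma >= 0, all(abs(psi_ref) <= 1 + 1e-8))
  new_pattern(-gamma * exp(kappa * psi_ref), "similarity",
              gamma = gamma, kappa = kappa, reference = reference)
}

#' Shuffle a perturbation pattern over neurons
#'
#' Random permutation of the entries: the multiset of perturbation values
#' (hence mean and variance) is preserved exactly while the alignment with
#' neuronal identity is destroyed. This is the randomized control used
#' against every patterned protocol.
#'
#' @param pattern A `perturbation_pattern`.
#' @param seed Integer seed.
#' @return The shuffled `perturbation_pattern`.
#' @export
shuffle_pattern <- function(pattern, seed = 1) {
  set.seed(seed)
  out <- new_pattern(sample(as.numeric(pattern)),
                     paste0(attr(pattern, "protocol"), "_shuffled"),
                     gamma = attr(pattern, "gamma"),
                     kappa = attr(pattern, "kappa"), seed = seed)
  out
}

#' Partial perturbation
#'
#' Keeps the pattern value on `ceiling(f * n)` neurons and zeroes the rest.
#' The retained subset is random by default; `"most_similar"` keeps the most
#' negative entries (the neurons most similar to the pattern's target),
#' mimicking targeting of the most functionally similar units.
#'
#' @param pattern A `perturbation_pattern`.
#' @param fraction Perturbed fraction `f` in `(0, 1]`.
#' @param seed Integer seed (random selection mode).
#' @param selection_mode `"random"` or `"most_similar"`.
#' @return A `perturbation_pattern` with `ceiling(f * n)` nonzero entries
#'   (fewer if the pattern has natural zeros).
#' @export
partial_pattern <- function(pattern, fraction, seed = 1,
                            selection_mode = c("random", "most_similar")) {
  selection_mode <- match.arg(selection_mode)
  if (fraction <= 0 || fraction > 1) stop("`fraction` must be in (0, 1]")
  n <- length(pattern)
  k <- ceiling(fraction * n)
  keep <- if (selection_mode == "random") {
    set.seed(seed)
    sample(n, k)
  } else {
    order(as.numeric(pattern))[seq_len(k)]
  }
  ds <- numeric(n)
  ds[keep] <- as.numeric(pattern)[keep]
  out <- new_pattern(ds, paste0(attr(pattern, "protocol"), "_partial"),
                     gamma = attr(pattern, "gamma"),
                     kappa = attr(pattern, "kappa"), seed = seed)
  attr(out, "fraction") <- fraction
  out
}

#' Rescale and/or sign-flip a pattern
#'
#' @param pattern A `perturbation_pattern`.
#' @param factor Positive scale factor.
#' @param sign `"negative"` keeps the sign, `"positive"` flips all entries
#'   (input-increasing perturbation).
#' @return The transformed `perturbation_pattern`.
#' @export
scale_and_sign <- function(pattern, factor = 1,
                           sign = c("negative", "positive")) {
  sign <- match.arg(sign)
  stopifnot(factor > 0)
  f <- if (sign == "positive") -factor else factor
  out <- new_pattern(f * as.numeric(pattern), attr(pattern, "protocol"),
                     gamma = attr(pattern, "gamma"),
                     kappa = attr(pattern, "kappa"))
  attr(out, "scale") <- factor
  attr(out, "sign") <- sign
  out
}

#' Run a paired baseline/perturbation experiment
#'
#' Simulates the network through a baseline window followed by a
#' perturbation window in which the external input of each inhibitory neuron
#' is offset by the pattern, and returns the window-averaged rates and the
#' per-neuron response change `dr = perturbed - baseline`.
#'
#' For rate networks one run with the default schedule (baseline `[0, 300)`,
#' perturbation `[300, 700)`) is performed. For spiking networks `n_reps`
#' paired repetitions are run; the pattern is interpreted as a relative
#' offset of the baseline external Poisson rate
#' (`rate <- rate_ext * (1 + delta_s)`, floored at 0) and `dr` is averaged
#' over repetitions.
#'
#' @param net An `isn_network`.
#' @param pattern A `perturbation_pattern` of length `n_i`.
#' @param s_base Baseline input vector (rate networks; see
#'   [baseline_input()]).
#' @param dynamics `"rate"` or `"spiking"`.
#' @param tau,n_power,dt Rate-dynamics parameters.
#' @param breaks Schedule `c(0, t_base, t_end)`; defaults `c(0, 300, 700)`
#'   (rate, simulation time units) or `c(0, 2000, 4000)` (spiking, ms).
#' @param discard_fraction Transient fraction discarded in each window.
#' @param lif A [lif_params()] (spiking only).
#' @param seed Seed (spiking only).
#' @param n_reps Spiking repetitions (default 10).
#' @return An object of class `perturbation_experiment` with `baseline`,
#'   `perturbed`, `dr` (per-neuron vectors over all neurons), the pattern and
#'   partition sizes.
#' @export
run_perturbation_experiment <- function(net, pattern, s_base = NULL,
                                        dynamics = c("rate", "spiking"),
                                        tau = 10, n_power = 1, dt = 0.1,
                                        breaks = NULL,
                                        discard_fraction = 1 / 3,
                                        lif = lif_params(), seed = 1,
                                        n_reps = 10) {
  dynamics <- match.arg(dynamics)
  stopifnot(inherits(net, "isn_network"), length(pattern) == net$n_i)
  n <- net$n_e + net$n_i
  ds_full <- c(numeric(net$n_e), as.numeric(pattern))
  if (dynamics == "rate") {
    if (is.null(breaks)) breaks <- c(0, 300, 700)
    if (is.null(s_base)) s_base <- rep(2, n)
    sched <- rate_schedule(list(s_base, s_base + ds_full), breaks)
    rec <- simulate_rate(net, sched, tau = tau, n_power = n_power, dt = dt)
    means <- steady_rates(rec, discard_fraction = discard_fraction)
    base <- means[[1]]; pert <- means[[2]]
  } else {
    if (is.null(breaks)) breaks <- c(0, 2000, 4000)
    rate0 <- rep(lif$rate_ext, n)
    rate1 <- pmax(lif$rate_ext * (1 + ds_full), 0)
    recs <- simulate_lif(net, lif, cbind(rate0, rate1), breaks = breaks,
                         seed = seed, n_reps = n_reps)
    if (inherits(recs, "spike_record")) recs <- list(recs)
    base_m <- sapply(recs, function(r)
      spike_rates(r, breaks[1:2], discard_fraction))
    pert_m <- sapply(recs, function(r)
      spike_rates(r, breaks[2:3], discard_fraction))
    base <- rowMeans(base_m); pert <- rowMeans(pert_m)
  }
  structure(
    list(baseline = base, perturbed = pert, dr = pert - base,
         pattern = pattern, n_e = net$n_e, n_i = net$n_i,
         dynamics = dynamics, breaks = breaks),
    class = "perturbation_experiment"
  )
}

#' Response similarity from a stimulus ensemble
#'
#' Presents a sequence of stimuli to the rate network (each for `stim_ms`
#' time units, drive `s_base * (1 + beta * cor(RF, stimulus))`), collects the
#' per-neuron mean response to each stimulus after discarding the initial
#' third of each presentation, and correlates the per-neuron response traces
#' across the whole ensemble. Inhibitory neurons with mean activity above
#' the given percentile of the inhibitory population are flagged responsive;
#' at least 3 are required.
#'
#' Each presentation is integrated to its post-transient response from the
#' shared baseline state, so per-stimulus responses are independent of
#' presentation order and can be computed in one batched integration.
#'
#' @param net An `isn_network` built from the RF bank.
#' @param bank The `rf_bank` (same neuron ordering as the network).
#' @param stimuli A `stimulus_set`.
#' @param beta Drive modulation depth (0.5 for RF-statistics stimuli,
#'   1 for gratings).
#' @param s_base Baseline input vector.
#' @param responsiveness_percentile Activity percentile defining responsive
#'   units (default 0.2, i.e. above the 20th percentile).
#' @param stim_ms Presentation duration in simulation time units
#'   (default 200).
#' @param tau,n_power,dt Rate-dynamics parameters.
#' @return A list: `similarity` (response correlations among all inhibitory
#'   neurons), `responsive` (indices, within the inhibitory population, of
#'   responsive units), `activity` (neuron x stimulus mean responses) and
#'   `drive`.
#' @export
response_similarity <- function(net, bank, stimuli, beta = 0.5,
                                s_base = NULL,
                                responsiveness_percentile = 0.2,
                                stim_ms = 200, tau = 10, n_power = 1,
                                dt = 0.1) {
  stopifnot(inherits(net, "isn_network"))
  n <- net$n_e + net$n_i
  if (is.null(s_base)) s_base <- rep(2, n)
  D <- stimulus_drive(bank, stimuli, beta)
  stopifnot(nrow(D) == n)
  S <- s_base * D
  # shared baseline steady state
  base <- steady_state_batch(net$W, matrix(s_base, n, 1), tau = tau,
                             n_power = n_power, dt = dt, t_end = 300)
  resp <- steady_state_batch(net$W, S, tau = tau, n_power = n_power,
                             dt = dt, t_end = stim_ms,
                             r0 = base$final[, 1])
  A <- resp$mean
  a_i <- A[net$n_e + seq_len(net$n_i), , drop = FALSE]
  mean_act <- rowMeans(a_i)
  thr <- stats::quantile(mean_act, responsiveness_percentile)
  responsive <- which(mean_act > thr)
  if (length(responsive) < 3) stop("fewer than 3 responsive inhibitory units")
  sds <- apply(a_i, 1, stats::sd)
  sim <- matrix(0, net$n_i, net$n_i)
  ok <- sds > 0
  if (any(ok)) sim[ok, ok] <- stats::cor(t(a_i[ok, , drop = FALSE]))
  diag(sim) <- 1
  list(similarity = sim, responsive = responsive, activity = A, drive = D,
       baseline_state = base$final[, 1], baseline_mean = base$mean[, 1],
       s_base = s_base)
}
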