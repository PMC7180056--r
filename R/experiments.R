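#' Standard rate-network configurations
#'
#' The four standard rate-based parameter columns: the strongly specific
#' ring network (`ring_specific`), its weak-weight non-ISN control
#' (`ring_weak`), the nonspecific control (`ring_nonspecific`, m = 0) and
#' the RF-correlation network (`rf`, m = 0.5, eta = 2). All use
#' `n_e = n_i = 400` and base weights `J_EE = J_IE = 0.05`,
#' `J_EI = J_II = -0.075` (weak network: 0.001 / -0.0015).
#'
#' At the strong Table-style weights, per-synapse multiplicative noise
#' uniform on `[0, 2]` alone contributes a spectral radius above 1 (the
#' noise bulk of an 800-neuron matrix with these weight magnitudes), making
#' the interior fixed point linearly unstable and silencing about half the
#' population through rectification. The standard rate configurations
#' therefore use the deterministic kernels; `zeta = TRUE` opts into the
#' noisy variant.
#'
#' @param name Configuration name.
#' @param zeta Apply per-synapse multiplicative randomization (default
#'   `FALSE`; see Details).
#' @param hetero Heterogeneous per-synapse specificity (default `FALSE`).
#' @return An [isn_config()].
#' @export
rate_config <- function(name = c("ring_specific", "ring_weak",
                                 "ring_nonspecific", "rf"),
                        zeta = FALSE, hetero = FALSE) {
  name <- match.arg(name)
  J_strong <- c(EE = 0.05, IE = 0.05, EI = -0.075, II = -0.075)
  J_weak <- c(EE = 0.001, IE = 0.001, EI = -0.0015, II = -0.0015)
  switch(name,
    ring_specific = isn_config(400, 400,
      block_params(J_strong, m = 1, zeta = zeta, hetero = hetero), "ring"),
    ring_weak = isn_config(400, 400,
      block_params(J_weak, m = 1, zeta = zeta, hetero = hetero), "ring"),
    ring_nonspecific = isn_config(400, 400,
      block_params(J_strong, m = 0, zeta = zeta, hetero = hetero), "ring"),
    rf = isn_config(400, 400,
      block_params(J_strong, m = 0.5, eta = 2, zeta = zeta,
                   hetero = hetero), "rf")
  )
}

#' Standard spiking-network configuration
#'
#' The leaky integrate-and-fire network: 500 excitatory and 500 inhibitory
#' neurons, synaptic jumps `J_EE = J_IE = 2` mV and `J_EI = J_II = -4` mV,
#' with ring (orientation-specific) connectivity of specificity `m`.
#'
#' @param m Connection specificity in `[0, 1]` (default 1).
#' @param zeta Per-synapse multiplicative randomization (default `TRUE`).
#' @return An [isn_config()].
#' @export
spiking_config <- function(m = 1, zeta = TRUE) {
  isn_config(500, 500,
    block_params(c(EE = 2, IE = 2, EI = -4, II = -4), m = m, zeta = zeta),
    "ring")
}

#' Orientation-tuned external input
#'
#' Mixes an untuned component with a raised-cosine tuned component, with the
#' tuned component normalized to unit mean so that the input fraction
#' controls specificity without changing the total drive:
#' `drive_j = base * ((1 - fraction) + fraction * (1 + cos(2 (theta*_j -
#' theta_stim))))`. `fraction = 0` is the spontaneous (untuned) condition;
#' at `fraction = 1` the drive is `2 base` at the stimulus orientation and
#' zero at the orthogonal one, with population mean `base` at every
#' fraction (for uniformly distributed preferred orientations).
#'
#' @param theta_stim Stimulus orientation in radians.
#' @param fraction Tuned fraction of the input, in `[0, 1]`.
#' @param theta_star Preferred orientations of the neurons.
#' @param base Baseline drive magnitude.
#' @return Per-neuron drive vector.
#' @export
tuned_input <- function(theta_stim, fraction, theta_star, base = 1) {
  stopifnot(fraction >= 0, fraction <= 1)
  base * ((1 - fraction) +
            fraction * (1 + cos(2 * (theta_star - theta_stim))))
}

slope_of_experiment <- function(exp, alpha = 0.05) {
  i_idx <- exp$n_e + seq_len(exp$n_i)
  perturbation_slope(exp$dr[i_idx], as.numeric(exp$pattern), alpha = alpha)
}

ring_experiment <- function(config, pattern_fun, seed, gamma = 0.25,
                            n_power = 1, s_base_mag = 2) {
  net <- build_network(config, seed = seed)
  n <- net$n_e + net$n_i
  s_base <- baseline_input(n, s_base = s_base_mag, seed = seed + 1000L)
  theta_i <- net$identities$theta[net$n_e + seq_len(net$n_i)]
  pattern <- pattern_fun(theta_i, gamma)
  exp <- run_perturbation_experiment(net, pattern, s_base = s_base,
                                     n_power = n_power)
  list(net = net, s_base = s_base, pattern = pattern, experiment = exp,
       slope = slope_of_experiment(exp))
}

#' Run a named experiment preset
#'
#' Figure-level pipelines at their standard parameters. Each preset builds
#' its network(s), runs the simulation/perturbation chain and returns a
#' result bundle whose components (slope results, ST indices, sweeps) are
#' deterministic given `(name, seed)`.
#'
#' Presets: `fig2_rate_1d` (specific ring, patterned vs shuffled vs
#' nonspecific perturbation), `fig2s_nonISN` (weak weights),
#' `fig2s_nonspecific` (m = 0), `fig2s_posneg` (positive/negative at two
#' magnitudes), `fig2s_ei_ratio` (80/20 E-I with 4x inhibitory weights),
#' `fig2s_broad_inh` (broader inhibitory connectivity, recalibrated),
#' `fig2s_hetero` (per-synapse specificity), `fig2s_nonlinear` (power-law
#' nonlinearity), `fig2s_partial` (partial perturbed fractions), `fig3_rf`
#' (RF-correlation network, 1D vs RF-similarity vs shuffled patterns),
#' `fig4_response_similarity` (response-similarity reference sweep,
#' RF-statistics stimuli), `fig4s_gratings` (same with fixed-SF gratings),
#' `fig5_spiking` (spiking patterned perturbation, 10 repetitions),
#' `fig6_7_transitions` (spontaneous/evoked ST landscape at m = 0 and 1),
#' `fig8_sweep` (specificity sweep: slope vs ST), `theory_checks`
#' (linear-response oracle comparison).
#'
#' @param name Preset name.
#' @param seed Integer seed.
#' @param ... Preset-specific overrides (e.g. `n_power` for
#'   `fig2s_nonlinear`, `fractions` for `fig2s_partial`, `m_broad` for
#'   `fig2s_broad_inh`).
#' @return A named list; components vary per preset (documented fields
#'   include `slope`, `slopes`, `sweep`, `st`, `fraction_specific`).
#' @export
run_preset <- function(name, seed = 1, ...) {
  dots <- list(...)
  gamma <- dots$gamma %||% 0.25
  switch(name,
    fig2_rate_1d = {
      cfg <- rate_config("ring_specific")
      res_p <- ring_experiment(cfg, function(th, g) pattern_ring_1d(th, g),
                               seed, gamma)
      sh <- shuffle_pattern(res_p$pattern, seed = seed + 7L)
      exp_s <- run_perturbation_experiment(res_p$net, sh,
                                           s_base = res_p$s_base)
      ns <- pattern_nonspecific(cfg$n_i, gamma, seed = seed + 8L)
      exp_n <- run_perturbation_experiment(res_p$net, ns,
                                           s_base = res_p$s_base)
      list(net = res_p$net,
           patterned = res_p$slope,
           shuffled = slope_of_experiment(exp_s),
           nonspecific = slope_of_experiment(exp_n),
           experiment = res_p$experiment)
    },
    fig2s_nonISN = {
      res <- ring_experiment(rate_config("ring_weak"),
                             function(th, g) pattern_ring_1d(th, g),
                             seed, gamma)
      res["net"] <- NULL
      res
    },
    fig2s_nonspecific = {
      cfg <- rate_config("ring_nonspecific")
      res_p <- ring_experiment(cfg, function(th, g) pattern_ring_1d(th, g),
                               seed, gamma)
      sh <- shuffle_pattern(res_p$pattern, seed = seed + 7L)
      exp_s <- run_perturbation_experiment(res_p$net, sh,
                                           s_base = res_p$s_base)
      list(patterned = res_p$slope, shuffled = slope_of_experiment(exp_s))
    },
    fig2s_posneg = {
      cfg <- rate_config("ring_specific")
      net <- build_network(cfg, seed = seed)
      n <- net$n_e + net$n_i
      s_base <- baseline_input(n, seed = seed + 1000L)
      theta_i <- net$identities$theta[net$n_e + seq_len(net$n_i)]
      base_pat <- pattern_ring_1d(theta_i, gamma)
      run_one <- function(p) {
        slope_of_experiment(
          run_perturbation_experiment(net, p, s_base = s_base))
      }
      list(
        negative_full = run_one(base_pat),
        negative_tenth = run_one(scale_and_sign(base_pat, 0.1, "negative")),
        positive_full = run_one(scale_and_sign(base_pat, 1, "positive")),
        positive_tenth = run_one(scale_and_sign(base_pat, 0.1, "positive"))
      )
    },
    fig2s_ei_ratio = {
      cfg <- apply_ei_ratio_variant(rate_config("ring_specific"))
      ring_experiment(cfg, function(th, g) pattern_ring_1d(th, g),
                      seed, gamma)
    },
    fig2s_broad_inh = {
      m_broad <- dots$m_broad %||% 0.95
      cfg <- apply_broad_inhibition_variant(rate_config("ring_specific"),
                                            m_broad, seed = seed)
      res <- ring_experiment(cfg, function(th, g) pattern_ring_1d(th, g),
                             seed, gamma)
      res$calibration_factor <- attr(cfg, "calibration_factor")
      res
    },
    fig2s_hetero = {
      cfg <- rate_config("ring_specific", hetero = TRUE)
      ring_experiment(cfg, function(th, g) pattern_ring_1d(th, g),
                      seed, gamma)
    },
    fig2s_nonlinear = {
      n_power <- dots$n_power %||% 2
      cfg <- rate_config("ring_specific")
      ring_experiment(cfg, function(th, g) pattern_ring_1d(th, g),
                      seed, gamma, n_power = n_power)
    },
    fig2s_partial = {
      fractions <- dots$fractions %||% c(0.1, 0.5, 0.7)
      cfg <- rate_config("ring_specific")
      net <- build_network(cfg, seed = seed)
      n <- net$n_e + net$n_i
      s_base <- baseline_input(n, seed = seed + 1000L)
      theta_i <- net$identities$theta[net$n_e + seq_len(net$n_i)]
      full <- pattern_ring_1d(theta_i, gamma)
      # the response-change regression runs over the perturbed cells: the
      # zeroed remainder has no protocol-driven abscissa and only dilutes
      # the fit with network-mediated noise
      slopes <- lapply(fractions, function(f) {
        p <- partial_pattern(full, f, seed = seed + round(100 * f))
        exp <- run_perturbation_experiment(net, p, s_base = s_base)
        i_idx <- exp$n_e + seq_len(exp$n_i)
        sub <- as.numeric(p) != 0
        perturbation_slope(exp$dr[i_idx][sub], as.numeric(p)[sub])
      })
      names(slopes) <- paste0("f_", fractions)
      list(slopes = slopes, fractions = fractions)
    },
    fig3_rf = {
      bank <- sample_rf_bank(400, 400, seed = seed)
      psi <- rf_correlation(bank)
      cfg <- rate_config("rf")
      net <- build_rf_weights(psi, 400, cfg$params, seed = seed + 1L,
                              identities = list(theta = bank$params$theta))
      n <- net$n_e + net$n_i
      s_base <- baseline_input(n, seed = seed + 1000L)
      theta_i <- bank$params$theta[net$n_e + seq_len(net$n_i)]
      i_idx <- net$n_e + seq_len(net$n_i)
      ref <- dots$reference %||% 1L
      psi_ii <- psi[i_idx, i_idx]
      pat_1d <- pattern_ring_1d(theta_i, gamma)
      pat_rf <- pattern_similarity(psi_ii[, ref], gamma = gamma, kappa = 2,
                                   reference = ref)
      pat_sh <- shuffle_pattern(pat_rf, seed = seed + 7L)
      run_one <- function(p) slope_of_experiment(
        run_perturbation_experiment(net, p, s_base = s_base))
      rf_sweep <- reference_sweep(net, psi_ii, gamma = gamma, kappa = 2,
                                  s_base = s_base)
      list(net = net, bank = bank, psi = psi,
           slope_1d = run_one(pat_1d),
           slope_rf = run_one(pat_rf),
           slope_shuffled = run_one(pat_sh),
           rf_sweep = rf_sweep)
    },
    fig4_response_similarity = ,
    fig4s_gratings = {
      kind <- if (name == "fig4s_gratings") {
        dots$kind %||% "grating_fixed_sf"
      } else "rf_like"
      beta <- dots$beta %||% if (kind == "rf_like") 0.5 else 1
      bank <- sample_rf_bank(400, 400, seed = seed)
      psi <- rf_correlation(bank)
      cfg <- rate_config("rf")
      net <- build_rf_weights(psi, 400, cfg$params, seed = seed + 1L,
                              identities = list(theta = bank$params$theta))
      stimuli <- make_stimuli(kind, n = dots$n_stimuli %||% 200,
                              grid = bank$grid, seed = seed + 2L)
      n <- net$n_e + net$n_i
      s_base <- baseline_input(n, seed = seed + 1000L)
      rs <- response_similarity(net, bank, stimuli, beta = beta,
                                s_base = s_base)
      refs <- dots$references %||% rs$responsive
      sweep <- reference_sweep(net, rs$similarity, responsive = refs,
                               gamma = gamma, kappa = 2, s_base = s_base)
      list(net = net, bank = bank, similarity = rs$similarity,
           responsive = rs$responsive, sweep = sweep,
           fraction_specific = sweep$fraction_specific)
    },
    fig5_spiking = {
      cfg <- spiking_config(m = 1)
      net <- build_network(cfg, seed = seed)
      lif <- lif_params()
      theta_i <- net$identities$theta[net$n_e + seq_len(net$n_i)]
      pat <- pattern_ring_1d(theta_i, dots$gamma_rel %||% 0.15)
      exp <- run_perturbation_experiment(net, pat, dynamics = "spiking",
                                         lif = lif, seed = seed + 10L,
                                         n_reps = dots$n_reps %||% 10)
      list(net = net, pattern = pat, experiment = exp,
           slope = slope_of_experiment(exp))
    },
    fig6_7_transitions = {
      sweep_specificity(m_grid = dots$m_grid %||% c(0, 1),
                        input_fraction_grid = dots$input_grid %||% c(0, 1),
                        seed = seed, t_spont = dots$t_spont %||% 10000,
                        slopes = FALSE)
    },
    fig8_sweep = {
      sweep_specificity(
        m_grid = dots$m_grid %||% c(0, 0.1, 0.25, 0.5, 0.75, 1),
        input_fraction_grid = 0, seed = seed,
        t_spont = dots$t_spont %||% 10000, slopes = TRUE)
    },
    theory_checks = {
      # linear-response validity needs an interior (unrectified) fixed
      # point: deterministic kernel and near-uniform baseline input
      cfg <- rate_config("ring_specific", zeta = FALSE)
      net <- build_network(cfg, seed = seed)
      n <- net$n_e + net$n_i
      s_base <- baseline_input(n, jitter = dots$jitter %||% 0.01,
                               seed = seed + 1000L)
      theta_i <- net$identities$theta[net$n_e + seq_len(net$n_i)]
      pat <- pattern_ring_1d(theta_i, dots$gamma %||% 0.01)
      exp <- run_perturbation_experiment(net, pat, s_base = s_base)
      i_idx <- net$n_e + seq_len(net$n_i)
      pred <- linear_response(net, as.numeric(pat))
      # interior = no unit near the rectification floor in either state
      floor_tol <- 1e-3 * mean(exp$baseline)
      interior <- min(exp$baseline, exp$perturbed) > floor_tol
      list(net = net, pattern = pat, experiment = exp,
           predicted = pred, simulated = exp$dr[i_idx],
           interior = interior,
           rel_error = sqrt(sum((exp$dr[i_idx] - pred)^2) /
                              sum(pred^2)))
    },
    stop("unknown preset: ", name)
  )
}

#' Specificity-by-input-tuning sweep of spiking networks
#'
#' For every combination of connection specificity `m` and tuned-input
#' fraction, simulates the spiking network, computes the ST index with its
#' 100-shuffle bootstrap null from the excitatory raster, and (optionally,
#' for the spontaneous condition) the normalized slope of patterned
#' perturbations: response changes normalized by the mean baseline rate
#' against input perturbations expressed relative to the baseline input.
#' `spec_isn` normalizes each slope by the slope of the most specific
#' network in the grid.
#'
#' @param m_grid Specificities to simulate.
#' @param input_fraction_grid Tuned-input fractions (0 = spontaneous).
#' @param seed Integer seed.
#' @param lif A [lif_params()].
#' @param t_spont Spontaneous/evoked simulation length in ms
#'   (default 10000).
#' @param t_pert Baseline and perturbation window length for the slope runs
#'   in ms (default 5000 each).
#' @param gamma_rel Relative magnitude of the patterned perturbation
#'   (default 0.15).
#' @param theta_stim Evoked stimulus orientation (default `pi/2`).
#' @param window_ms Analysis window (default 10).
#' @param n_shuffles Bootstrap shuffles (default 100).
#' @param slopes Also measure perturbation slopes per `m` (default `TRUE`).
#' @return A list: `st` (data frame over the grid with `sti`, `sti_boot`,
#'   `null_mean`, `null_sd`, mean rates) and, when `slopes`, `slope` (data
#'   frame over `m` with normalized slope, p-value and `spec_isn`).
#' @export
sweep_specificity <- function(m_grid, input_fraction_grid = 0, seed = 1,
                              lif = lif_params(), t_spont = 10000,
                              t_pert = 5000, gamma_rel = 0.15,
                              theta_stim = pi / 2, window_ms = 10,
                              n_shuffles = 100, slopes = TRUE) {
  st_rows <- list()
  slope_rows <- list()
  for (mi in seq_along(m_grid)) {
    m <- m_grid[mi]
    net <- build_network(spiking_config(m = m), seed = seed + mi)
    theta <- net$identities$theta
    theta_e <- theta[seq_len(net$n_e)]
    theta_i <- theta[net$n_e + seq_len(net$n_i)]
    e_idx <- seq_len(net$n_e)
    for (fr in input_fraction_grid) {
      drive <- tuned_input(theta_stim, fr, theta, base = lif$rate_ext)
      rec <- simulate_lif(net, lif, drive, t_end = t_spont,
                          seed = seed + 100L * mi + round(100 * fr))
      binned <- bin_spikes(rec, window_ms = window_ms)
      bs <- bootstrap_st(binned, theta_e, neurons = e_idx,
                         n_shuffles = n_shuffles, seed = seed + mi)
      st_rows[[length(st_rows) + 1L]] <- data.frame(
        m = m, input_fraction = fr, sti = bs$sti, sti_boot = bs$sti_boot,
        null_mean = bs$null_mean, null_sd = bs$null_sd,
        n_selective = bs$n_selective,
        mean_rate_e = sum(binned[, e_idx]) /
          (net$n_e * t_spont / 1000))
    }
    if (slopes) {
      pat <- pattern_ring_1d(theta_i, gamma_rel)
      exp <- run_perturbation_experiment(
        net, pat, dynamics = "spiking", lif = lif,
        breaks = c(0, t_pert, 2 * t_pert), seed = seed + 5000L + mi,
        n_reps = 1)
      i_idx <- net$n_e + seq_len(net$n_i)
      base_mean <- mean(exp$baseline[i_idx])
      sr <- perturbation_slope(exp$dr[i_idx] / max(base_mean, 1e-9),
                               as.numeric(pat))
      slope_rows[[length(slope_rows) + 1L]] <- data.frame(
        m = m, slope_norm = sr$slope, p_value = sr$p_value,
        mean_dr = sr$mean_dr, mean_base = base_mean)
    }
  }
  st <- do.call(rbind, st_rows)
  out <- list(st = st)
  if (slopes) {
    sl <- do.call(rbind, slope_rows)
    ref <- sl$slope_norm[which.max(sl$m)]
    sl$spec_isn <- if (abs(ref) > 0) sl$slope_norm / ref else NA_real_
    out$slope <- sl
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
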