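#' Leaky integrate-and-fire parameters
#'
#' Membrane and input parameters of the spiking networks. Defaults follow
#' the standard spiking configuration: membrane time constant 20 ms,
#' threshold 20 mV, reset 0 mV, simulation step 0.1 ms. The external drive is
#' an independent Poisson source per neuron delivering excitatory jumps of
#' `j_ext` mV; its baseline rate (`rate_ext`, events/s) is a calibration
#' choice placing baseline excitatory rates in the low spikes-per-second
#' range.
#'
#' @param tau_m Membrane time constant (ms).
#' @param v_th Spike threshold (mV).
#' @param v_reset Reset potential (mV).
#' @param dt Simulation step (ms).
#' @param j_ext External synaptic jump (mV).
#' @param rate_ext Baseline external Poisson rate (events/s).
#' @return An object of class `lif_params`.
#' @export
lif_params <- function(tau_m = 20, v_th = 20, v_reset = 0, dt = 0.1,
                       j_ext = 2, rate_ext = 800) {
  stopifnot(tau_m > 0, v_th > v_reset, dt > 0)
  structure(list(tau_m = tau_m, v_th = v_th, v_reset = v_reset, dt = dt,
                 j_ext = j_ext, rate_ext = rate_ext),
            class = "lif_params")
}

#' Simulate a spiking network
#'
#' Exact-integration leaky integrate-and-fire dynamics: between events the
#' membrane decays as `V <- V exp(-dt/tau_m)`; each presynaptic spike adds
#' its weight (mV) to all postsynaptic membranes in the next simulation step;
#' external Poisson events add `j_ext` mV. Crossing threshold emits a spike
#' and resets the membrane.
#'
#' @param net An `isn_network` (weights in mV) or plain matrix.
#' @param params A [lif_params()].
#' @param ext_rate External Poisson rates in events/s: a vector (constant in
#'   time) or an `n x n_windows` matrix with one column per schedule window.
#' @param breaks Window boundaries in ms (required when `ext_rate` has
#'   several columns); `c(0, t_end)` otherwise.
#' @param t_end Total simulated time in ms (ignored when `breaks` given).
#' @param seed Integer seed.
#' @param n_reps Number of independent repetitions (seeds `seed`,
#'   `seed + 1`, ...).
#' @return A list of `n_reps` objects of class `spike_record`, each with a
#'   `spikes` data frame (`neuron`, `time` in ms), the population sizes and
#'   the schedule; a single record if `n_reps = 1`.
#' @export
simulate_lif <- function(net, params, ext_rate, breaks = NULL, t_end = NULL,
                         seed = 1, n_reps = 1) {
  W <- if (inherits(net, "isn_network")) net$W else net
  n_e <- if (inherits(net, "isn_network")) net$n_e else NA_integer_
  stopifnot(inherits(params, "lif_params"))
  n <- nrow(W)
  if (is.null(dim(ext_rate))) ext_rate <- matrix(ext_rate, n, 1)
  stopifnot(nrow(ext_rate) == n)
  if (is.null(breaks)) {
    if (is.null(t_end)) stop("give either `breaks` or `t_end`")
    breaks <- c(0, t_end)
  }
  stopifnot(length(breaks) == ncol(ext_rate) + 1)
  rate_ms <- ext_rate / 1000  # events/ms
  run_one <- function(s) {
    set.seed(s)
    out <- lif_kernel(W, numeric(n), rate_ms, breaks, params$tau_m,
                      params$v_th, params$v_reset, params$j_ext, params$dt)
    structure(
      list(spikes = data.frame(neuron = out$neuron, time = out$time),
           n = n, n_e = n_e, breaks = breaks, params = params, seed = s,
           v_final = out$v_final),
      class = "spike_record"
    )
  }
  recs <- lapply(seed + seq_len(n_reps) - 1L, run_one)
  if (n_reps == 1) recs[[1]] else recs
}

#' Per-neuron firing rates in a time window
#'
#' @param record A `spike_record`.
#' @param window `c(t0, t1)` in ms.
#' @param discard_fraction Fraction of the window discarded as transient.
#' @return Rates in spikes/s, length `record$n`.
#' @export
spike_rates <- function(record, window, discard_fraction = 0) {
  stopifnot(inherits(record, "spike_record"))
  t0 <- window[1] + discard_fraction * (window[2] - window[1])
  sel <- record$spikes$time > t0 & record$spikes$time <= window[2]
  counts <- tabulate(record$spikes$neuron[sel], nbins = record$n)
  counts / ((window[2] - t0) / 1000)
}

#' Bin spikes into a window-by-neuron count matrix
#'
#' The windowed population activity used by the selectivity and transition
#' metrics: spike counts of every neuron in consecutive windows of
#' `window_ms` milliseconds.
#'
#' @param record A `spike_record`, or a data frame with `neuron` and `time`
#'   columns plus `n` and `t_end` given explicitly.
#' @param window_ms Window length in ms (default 10).
#' @param n,t_range Number of neurons and `c(t0, t1)` (taken from the record
#'   when omitted).
#' @return A `n_windows x n` matrix of spike counts; window start times in
#'   attribute `t_start`.
#' @export
bin_spikes <- function(record, window_ms = 10, n = NULL, t_range = NULL) {
  if (inherits(record, "spike_record")) {
    spikes <- record$spikes
    if (is.null(n)) n <- record$n
    if (is.null(t_range)) t_range <- range(record$breaks)
  } else {
    spikes <- record
    if (is.null(n) || is.null(t_range)) {
      stop("`n` and `t_range` required for data frame input")
    }
  }
  n_win <- floor((t_range[2] - t_range[1]) / window_ms)
  if (n_win < 1) stop("time range shorter than one window")
  sel <- spikes$time > t_range[1] & spikes$time <= t_range[1] + n_win * window_ms
  wi <- ceiling((spikes$time[sel] - t_range[1]) / window_ms)
  wi[wi < 1] <- 1L
  counts <- matrix(0L, n_win, n)
  idx <- (spikes$neuron[sel] - 1L) * n_win + wi
  tab <- tabulate(idx, nbins = n_win * n)
  counts[] <- tab
  attr(counts, "t_start") <- t_range[1] + (seq_len(n_win) - 1) * window_ms
  attr(counts, "window_ms") <- window_ms
  counts
}
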