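#' Piecewise-constant input schedule
#'
#' Describes the external input `s(t)` as a sequence of windows with constant
#' per-neuron input. The default perturbation schedule is a baseline window
#' `[0, 300)` followed by a perturbation window `[300, 700)`.
#'
#' @param inputs A list of numeric vectors (one per window, length = number
#'   of neurons) or a matrix with one column per window.
#' @param breaks Window boundaries, length `length(inputs) + 1`, starting
#'   at 0.
#' @return An object of class `rate_schedule`.
#' @export
rate_schedule <- function(inputs, breaks) {
  if (is.matrix(inputs)) inputs <- lapply(seq_len(ncol(inputs)), function(j) inputs[, j])
  stopifnot(length(breaks) == length(inputs) + 1, !is.unsorted(breaks))
  structure(list(inputs = inputs, breaks = breaks), class = "rate_schedule")
}

#' Simulate rate dynamics
#'
#' Forward-Euler integration of the rate equations
#' `tau dr/dt = -r + ([W r + s]+)^n`, where `[.]+` is half-wave
#' rectification and `n` the power of the expansive nonlinearity (`n = 1` is
#' threshold-linear). Any rate exceeding `ceiling` aborts with an
#' instability error, which networks with too strong nonlinearity can
#' trigger.
#'
#' @param net An `isn_network` or a plain weight matrix.
#' @param schedule A [rate_schedule()].
#' @param tau Time constant (default 10, simulation time units).
#' @param n_power Nonlinearity exponent `n >= 1`.
#' @param dt Euler step (default 0.1; must satisfy `dt < tau`).
#' @param r0 Initial rates (default 0).
#' @param record_every Record the state every `record_every` time units
#'   (default 1).
#' @param ceiling Divergence guard (default 1e6).
#' @return An object of class `rate_record`: `times`, a `time x neuron` rate
#'   matrix `rates`, and the window annotations.
#' @export
simulate_rate <- function(net, schedule, tau = 10, n_power = 1, dt = 0.1,
                          r0 = NULL, record_every = 1, ceiling = 1e6) {
  W <- if (inherits(net, "isn_network")) net$W else net
  stopifnot(inherits(schedule, "rate_schedule"), dt > 0, dt < tau,
            n_power >= 1)
  n <- nrow(W)
  r <- if (is.null(r0)) numeric(n) else r0
  stopifnot(length(r) == n)
  breaks <- schedule$breaks
  t_end <- breaks[length(breaks)]
  n_steps <- round(t_end / dt)
  keep <- max(1L, round(record_every / dt))
  rec_idx <- seq(0L, n_steps, by = keep)
  rates <- matrix(0, length(rec_idx), n)
  times <- rec_idx * dt
  rates[1, ] <- r
  rec <- 2L
  win <- 1L
  a <- dt / tau
  for (step in seq_len(n_steps)) {
    t_now <- (step - 1) * dt
    while (win < length(breaks) - 1 && t_now >= breaks[win + 1]) win <- win + 1L
    s <- schedule$inputs[[win]]
    drive <- pmax(W %*% r + s, 0)
    if (n_power != 1) drive <- drive^n_power
    r <- r + a * (drive - r)
    if (rec <= length(rec_idx) && step == rec_idx[rec]) {
      rates[rec, ] <- r
      rec <- rec + 1L
    }
    if (max(r) > ceiling) {
      stop(structure(class = c("isn_instability", "error", "condition"),
                     list(message = sprintf(
                       "rate exceeded ceiling %g at t = %g (unstable dynamics)",
                       ceiling, step * dt), call = sys.call(-1))))
    }
  }
  structure(
    list(times = times, rates = rates, breaks = breaks, tau = tau,
         n_power = n_power, dt = dt),
    class = "rate_record"
  )
}

#' Window-averaged steady rates
#'
#' Time-averaged per-neuron rates within a schedule window after discarding
#' the initial transient (a fraction of the window).
#'
#' @param record A `rate_record`.
#' @param window Numeric `c(t0, t1)`; defaults to each schedule window in
#'   turn (a list is returned in that case).
#' @param discard_fraction Fraction of the window discarded as transient
#'   (default 1/3).
#' @return A numeric vector of per-neuron means (or a list of them when
#'   `window` is `NULL`, one per schedule window).
#' @export
steady_rates <- function(record, window = NULL, discard_fraction = 1 / 3) {
  stopifnot(inherits(record, "rate_record"),
            discard_fraction >= 0, discard_fraction < 1)
  one <- function(w) {
    t0 <- w[1] + discard_fraction * (w[2] - w[1])
    sel <- record$times > t0 & record$times <= w[2]
    if (!any(sel)) stop("empty window after transient discard")
    colMeans(record$rates[sel, , drop = FALSE])
  }
  if (is.null(window)) {
    b <- record$breaks
    lapply(seq_len(length(b) - 1), function(k) one(c(b[k], b[k + 1])))
  } else {
    one(window)
  }
}

# Batched steady-state integrator: integrates K independent copies of the
# rate equation, one column of S per copy, all sharing W. Returns the
# time-mean of each copy over the post-transient part of [0, t_end] and the
# final state. Columns are independent, so results do not depend on how the
# copies are grouped. Used for stimulus ensembles and reference-cell sweeps
# where hundreds of steady states share one weight matrix.
steady_state_batch <- function(W, S, tau = 10, n_power = 1, dt = 0.1,
                               t_end = 400, r0 = NULL,
                               discard_fraction = 1 / 3, ceiling = 1e6) {
  n <- nrow(W); k <- ncol(S)
  R <- if (is.null(r0)) matrix(0, n, k) else matrix(r0, n, k)
  n_steps <- round(t_end / dt)
  first_keep <- floor(discard_fraction * n_steps) + 1L
  acc <- matrix(0, n, k)
  kept <- 0L
  a <- dt / tau
  for (step in seq_len(n_steps)) {
    drive <- pmax(W %*% R + S, 0)
    if (n_power != 1) drive <- drive^n_power
    R <- R + a * (drive - R)
    if (step >= first_keep) {
      acc <- acc + R
      kept <- kept + 1L
    }
    if (step %% 200L == 0L && max(R) > ceiling) {
      stop("batched rate integration diverged (rate above ceiling)")
    }
  }
  list(mean = acc / kept, final = R)
}

#' Baseline external input with frozen jitter
#'
#' Constant baseline drive with a per-neuron multiplicative jitter uniform on
#' `[1 - jitter, 1 + jitter]`, frozen under the seed. The default magnitude 2
#' gives the standard rate networks positive baseline rates with headroom for
#' negative perturbations.
#'
#' @param n Number of neurons.
#' @param s_base Baseline magnitude (default 2).
#' @param jitter Relative jitter half-width (default 0.1).
#' @param seed Integer seed.
#' @return Numeric vector of per-neuron baseline inputs.
#' @export
baseline_input <- function(n, s_base = 2, jitter = 0.1, seed = 1) {
  set.seed(seed)
  s_base * stats::runif(n, 1 - jitter, 1 + jitter)
}
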