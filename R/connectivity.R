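#' Block parameters of the E/I weight matrix
#'
#' Per-block base weights `J` and connection specificities `m` for the four
#' blocks of the excitatory/inhibitory weight matrix. Blocks are named by
#' (postsynaptic, presynaptic) population in the conventional order: `EE`
#' (E to E), `IE` (E to I), `EI` (I to E), `II` (I to I). Excitatory base
#' weights must be nonnegative and inhibitory base weights nonpositive
#' (Dale's law); `m` lies in `[0, 1]`.
#'
#' @param J Named numeric vector `c(EE=, IE=, EI=, II=)` of base weights
#'   (arbitrary units for rate networks, mV for spiking networks).
#' @param m Named numeric vector of block specificities in `[0, 1]`, or a
#'   single value recycled to all blocks.
#' @param eta Sharpness of the exponential dependence of weights on RF
#'   correlation (RF-correlation rule only; default 2).
#' @param zeta If `TRUE`, each synapse is additionally multiplied by an
#'   independent random factor uniform on `[0, 2]`, which preserves mean
#'   weights and signs.
#' @param hetero If `TRUE`, the block specificity is replaced per synapse by
#'   an independent draw uniform on `[0, 1]` (heterogeneous specificity).
#' @return An object of class `block_params`.
#' @export
block_params <- function(J, m, eta = 2, zeta = TRUE, hetero = FALSE) {
  blocks <- c("EE", "IE", "EI", "II")
  if (length(m) == 1 && is.null(names(m))) m <- stats::setNames(rep(m, 4), blocks)
  if (!all(blocks %in% names(J)) || !all(blocks %in% names(m))) {
    stop("`J` and `m` must be named vectors with entries EE, IE, EI, II")
  }
  J <- J[blocks]; m <- m[blocks]
  if (J["EE"] < 0 || J["IE"] < 0) stop("excitatory base weights must be >= 0")
  if (J["EI"] > 0 || J["II"] > 0) stop("inhibitory base weights must be <= 0")
  if (!hetero && (any(m < 0) || any(m > 1))) stop("`m` must lie in [0, 1]")
  if (eta <= 0) stop("`eta` must be positive")
  structure(list(J = J, m = m, eta = eta, zeta = zeta, hetero = hetero),
            class = "block_params")
}

# Block index helper: list of row/column index pairs for each block of the
# (E then I) x (E then I) matrix.
block_index <- function(n_e, n_i) {
  e <- seq_len(n_e); i <- n_e + seq_len(n_i)
  list(EE = list(e, e), IE = list(i, e), EI = list(e, i), II = list(i, i))
}

finish_weights <- function(W, n_e, n_i, params, type, identities, seed) {
  n <- n_e + n_i
  if (params$zeta) {
    W <- W * matrix(stats::runif(n * n, 0, 2), n, n)
  }
  diag(W) <- 0  # no autapses
  structure(
    list(W = W, n_e = n_e, n_i = n_i, params = params, type = type,
         identities = identities, seed = seed),
    class = "isn_network"
  )
}

#' Build a ring (1D orientation-specific) weight matrix
#'
#' All-to-all weights modulated by the difference in preferred orientation of
#' the pre- and postsynaptic neurons:
#' `w_ij = J_block * (1 + m_block * cos(2 (theta_i - theta_j)))`,
#' optionally multiplied per synapse by an independent factor uniform on
#' `[0, 2]` (`zeta`), and with per-synapse specificity uniform on `[0, 1]`
#' when `hetero` is set. Self-connections are zero.
#'
#' @param theta Preferred orientations in radians, `[0, pi)`, length
#'   `n_e + n_i` with excitatory neurons first.
#' @param n_e Number of excitatory neurons (the first `n_e` entries).
#' @param params A [block_params()] object.
#' @param seed Integer seed for the `zeta` / heterogeneity draws.
#' @return An object of class `isn_network` holding the dense weight matrix
#'   `W` (rows postsynaptic, columns presynaptic, E before I), the partition
#'   sizes and the generative parameters.
#' @export
build_ring_weights <- function(theta, n_e, params, seed = 1) {
  stopifnot(inherits(params, "block_params"))
  n <- length(theta); n_i <- n - n_e
  stopifnot(n_e > 0, n_i > 0)
  set.seed(seed)
  D <- cos(2 * outer(theta, theta, "-"))
  W <- matrix(0, n, n)
  idx <- block_index(n_e, n_i)
  for (b in names(idx)) {
    r <- idx[[b]][[1]]; c <- idx[[b]][[2]]
    m_b <- if (params$hetero) {
      matrix(stats::runif(length(r) * length(c)), length(r), length(c))
    } else {
      params$m[b]
    }
    W[r, c] <- params$J[b] * (1 + m_b * D[r, c])
  }
  finish_weights(W, n_e, n_i, params, "ring", list(theta = theta), seed)
}

#' Build an RF-correlation weight matrix
#'
#' All-to-all weights modulated by the pairwise correlation of the neurons'
#' 2D receptive fields:
#' `w_ij = J_block * (0.1 + m_block * exp(eta * psi_ij))`, with the same
#' optional `zeta` randomization and heterogeneous specificity as the ring
#' rule.
#'
#' @param psi Pairwise RF correlation matrix (from [rf_correlation()]),
#'   ordered E before I.
#' @param n_e Number of excitatory neurons.
#' @param params A [block_params()] object (`eta` is taken from it).
#' @param seed Integer seed.
#' @param identities Optional identity metadata (e.g. preferred orientations
#'   from the RF bank) stored with the network.
#' @return An `isn_network`.
#' @export
build_rf_weights <- function(psi, n_e, params, seed = 1, identities = NULL) {
  stopifnot(inherits(params, "block_params"))
  if (any(abs(psi) > 1 + 1e-8)) stop("`psi` entries must lie in [-1, 1]")
  n <- nrow(psi); n_i <- n - n_e
  stopifnot(n_e > 0, n_i > 0, ncol(psi) == n)
  set.seed(seed)
  K <- exp(params$eta * psi)
  W <- matrix(0, n, n)
  idx <- block_index(n_e, n_i)
  for (b in names(idx)) {
    r <- idx[[b]][[1]]; c <- idx[[b]][[2]]
    m_b <- if (params$hetero) {
      matrix(stats::runif(length(r) * length(c)), length(r), length(c))
    } else {
      params$m[b]
    }
    W[r, c] <- params$J[b] * (0.1 + m_b * K[r, c])
  }
  finish_weights(W, n_e, n_i, params, "rf", identities, seed)
}

#' Network configuration
#'
#' A plain description of a network to be built: population sizes, block
#' parameters and the connectivity rule. Variant transformations
#' ([apply_ei_ratio_variant()], [apply_broad_inhibition_variant()]) operate
#' on configurations before the matrix is instantiated.
#'
#' @param n_e,n_i Population sizes.
#' @param params A [block_params()] object.
#' @param rule `"ring"` or `"rf"`.
#' @return An object of class `isn_config`.
#' @export
isn_config <- function(n_e, n_i, params, rule = c("ring", "rf")) {
  rule <- match.arg(rule)
  structure(list(n_e = n_e, n_i = n_i, params = params, rule = rule),
            class = "isn_config")
}

#' Instantiate a network from a configuration
#'
#' For the ring rule, preferred orientations are drawn uniformly on
#' `[0, pi)`. For the RF rule a `psi` matrix (and optionally identities)
#' must be supplied.
#'
#' @param config An [isn_config()].
#' @param seed Integer seed (orientation draws and synaptic randomness).
#' @param psi RF correlation matrix (RF rule only).
#' @param identities Identity metadata for the RF rule.
#' @return An `isn_network`.
#' @export
build_network <- function(config, seed = 1, psi = NULL, identities = NULL) {
  stopifnot(inherits(config, "isn_config"))
  if (config$rule == "ring") {
    set.seed(seed)
    theta <- stats::runif(config$n_e + config$n_i, 0, pi)
    build_ring_weights(theta, config$n_e, config$params, seed = seed + 1L)
  } else {
    if (is.null(psi)) stop("the RF rule needs a `psi` correlation matrix")
    build_rf_weights(psi, config$n_e, config$params, seed = seed,
                     identities = identities)
  }
}

#' 80/20 E-I ratio variant
#'
#' Reduces the inhibitory population to one quarter of the excitatory one
#' (80% E, 20% I) and compensates by making inhibitory weights four times
#' stronger, preserving the total inhibitory weight onto each cell.
#'
#' @param config An [isn_config()].
#' @return The modified configuration.
#' @export
apply_ei_ratio_variant <- function(config) {
  stopifnot(inherits(config, "isn_config"))
  if (config$n_e %% 4 != 0) {
    warning("n_e not divisible by 4; rounding n_i")
  }
  config$n_i <- as.integer(round(config$n_e / 4))
  config$params$J["EI"] <- 4 * config$params$J["EI"]
  config$params$J["II"] <- 4 * config$params$J["II"]
  config
}

#' Broad-inhibition variant with stability recalibration
#'
#' Sets the specificity of the inhibitory-related blocks (`IE`, `EI`, `II`)
#' to `m_broad < m_EE` (broader tuning of inhibitory connectivity), then
#' rescales the magnitudes of `J_EI` and `J_II` by a common factor, found by
#' bisection, until the instantiated network's leading eigenvalue real part
#' drops below `1 - margin` (the fixed-point stability condition of the rate
#' dynamics). Note that purely nonspecific inhibition cannot stabilize a
#' strongly specific excitatory kernel: with the ring rule the specific
#' excitatory eigenvalue `n_e J_EE m_EE / 2` is only reducible to
#' `n_e J_EE (m_EE - m_broad) / 2`, so `m_broad` must stay close enough to
#' `m_EE` for a stable calibration to exist.
#'
#' @param config A ring-rule [isn_config()].
#' @param m_broad Broad specificity for the IE/EI/II blocks.
#' @param margin Stability margin (default 0.05).
#' @param seed Seed used for the trial networks during calibration.
#' @param max_factor Upper bound of the bisection bracket (default 64).
#' @return The modified configuration with recalibrated inhibitory weights
#'   and an attribute `calibration_factor`.
#' @export
apply_broad_inhibition_variant <- function(config, m_broad, margin = 0.05,
                                           seed = 1, max_factor = 64) {
  stopifnot(inherits(config, "isn_config"))
  if (m_broad > config$params$m["EE"]) {
    stop("`m_broad` must not exceed m_EE")
  }
  if (m_broad == config$params$m["EE"]) return(config)
  config$params$m["IE"] <- m_broad
  config$params$m["EI"] <- m_broad
  config$params$m["II"] <- m_broad
  base_J <- config$params$J
  lead_at <- function(f) {
    cfg <- config
    cfg$params$J["EI"] <- f * base_J["EI"]
    cfg$params$J["II"] <- f * base_J["II"]
    net <- build_network(cfg, seed = seed)
    max(Re(eigen(net$W, only.values = TRUE)$values))
  }
  # stability is not monotone in the scaling (without autapses, scaling up
  # uniform inhibition also removes ever larger self-inhibition terms), so
  # scan a geometric grid and keep the smallest stabilizing factor
  grid <- exp(seq(0, log(max_factor), length.out = 20))
  found <- NA_real_
  for (f in grid) {
    if (lead_at(f) < 1 - margin) { found <- f; break }
  }
  if (is.na(found)) {
    stop("calibration failed: no inhibition scaling up to x", max_factor,
         " stabilizes the network (m_broad too far below m_EE)")
  }
  config$params$J["EI"] <- found * base_J["EI"]
  config$params$J["II"] <- found * base_J["II"]
  attr(config, "calibration_factor") <- found
  config
}

#' Stability and ISN classification of a weight matrix
#'
#' Reports the leading eigenvalue real parts of the full matrix and of the
#' excitatory-to-excitatory block alone. With linear rate dynamics
#' `tau dr/dt = -r + [W r + s]+`, an interior fixed point is stable iff all
#' eigenvalues of `W` have real part below 1; the network is
#' inhibition-stabilized (ISN) if the excitatory subnetwork alone is
#' unstable, i.e. the leading eigenvalue of `W_EE` exceeds 1.
#'
#' @param net An `isn_network`, or a plain square matrix together with `n_e`.
#' @param n_e Number of excitatory neurons (ignored for `isn_network` input).
#' @return A list with `lead_re_full`, `lead_re_ee`, `isn`, `stable`.
#' @export
stability_report <- function(net, n_e = NULL) {
  if (inherits(net, "isn_network")) {
    W <- net$W; n_e <- net$n_e
  } else {
    W <- net
    if (is.null(n_e)) stop("`n_e` required for raw matrix input")
  }
  stopifnot(nrow(W) == ncol(W))
  lead_full <- max(Re(eigen(W, only.values = TRUE)$values))
  lead_ee <- if (n_e > 0) {
    max(Re(eigen(W[seq_len(n_e), seq_len(n_e), drop = FALSE],
                 only.values = TRUE)$values))
  } else {
    -Inf
  }
  list(lead_re_full = lead_full, lead_re_ee = lead_ee,
       isn = lead_ee > 1, stable = lead_full < 1)
}
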