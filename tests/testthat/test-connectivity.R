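test_that("ring weights implement the cosine rule with Dale-consistent signs", {
  theta <- c(0, pi / 4, pi / 2, 0, pi / 4, pi / 2)
  params <- block_params(c(EE = 0.05, IE = 0.05, EI = -0.075, II = -0.075),
                         m = 1, zeta = FALSE)
  net <- build_ring_weights(theta, 3, params, seed = 1)
  W <- net$W
  expect_equal(W[2, 1], 0.05 * (1 + cos(2 * (pi / 4 - 0))))  # E->E
  expect_equal(W[4, 1], 0.05 * (1 + 1))                      # same-theta E->I: 0.10
  expect_equal(W[3, 1], 0.05 * (1 + cos(pi)))                # orthogonal: 0
  expect_equal(W[1, 4], -0.075 * 2)                          # I->E same theta
  expect_equal(diag(W), rep(0, 6))
  # Dale by column
  expect_true(all(W[, 1:3] >= 0) && all(W[, 4:6] <= 0))
  expect_error(block_params(params$J, m = 1.5), "\\[0, 1\\]")
})

test_that("zeta randomization preserves mean weights and never flips signs", {
  theta <- runif(300, 0, pi)
  params_det <- block_params(c(EE = 0.05, IE = 0.05, EI = -0.075,
                               II = -0.075), m = 1, zeta = FALSE)
  params_z <- block_params(params_det$J, m = 1, zeta = TRUE)
  det <- build_ring_weights(theta, 150, params_det, seed = 4)$W
  noisy <- build_ring_weights(theta, 150, params_z, seed = 4)$W
  off <- row(det) != col(det) & det != 0
  ratio <- noisy[off] / det[off]
  expect_true(all(ratio >= 0 & ratio <= 2))
  mc_sd <- 1 / sqrt(3 * sum(off))
  expect_lt(abs(mean(ratio) - 1), 5 * mc_sd)
  expect_true(all(sign(noisy[off]) == sign(det[off])))
})

test_that("RF-correlation weights follow the exponential rule and increase with similarity", {
  psi <- matrix(c(1, 0, 0.5, 0, 1, -0.2, 0.5, -0.2, 1), 3, 3)
  params <- block_params(c(EE = 0.05, IE = 0.05, EI = -0.075, II = -0.075),
                         m = 0.5, eta = 2, zeta = FALSE)
  net <- build_rf_weights(psi, 2, params, seed = 1)
  expect_equal(net$W[2, 1], 0.05 * (0.1 + 0.5 * exp(2 * 0)))   # psi = 0 -> 0.03
  expect_equal(net$W[3, 1], 0.05 * (0.1 + 0.5 * exp(2 * 0.5))) # psi = 0.5
  w_of <- function(p) 0.05 * (0.1 + 0.5 * exp(2 * p))
  expect_equal(w_of(1), 0.05 * (0.1 + 0.5 * exp(2)))
  ps <- sort(runif(10, -1, 1))
  expect_true(all(diff(w_of(ps)) > 0))
  expect_error(build_rf_weights(matrix(c(1, 2, 2, 1), 2), 1, params),
               "\\[-1, 1\\]")
})

test_that("constant-block (m = 0) spectra match the uniform-mode prediction", {
  theta <- runif(120, 0, pi)
  params <- block_params(c(EE = 0.05, IE = 0.05, EI = -0.075, II = -0.075),
                         m = 0, zeta = FALSE)
  net <- build_ring_weights(theta, 60, params, seed = 2)
  ev <- eigen(net$W, only.values = TRUE)$values
  # uniform 2x2 reduction: eigenvalues n_e*J_EE + n_i*J_EI-type combinations
  M2 <- matrix(c(60 * 0.05, 60 * 0.05, 60 * -0.075, 60 * -0.075), 2, 2)
  pred <- eigen(M2, only.values = TRUE)$values
  # zero-diagonal shifts the spectrum by O(J) only
  expect_lt(abs(max(Re(ev)) - max(Re(pred))), 0.15)
})

test_that("stability report classifies ISN and non-ISN configurations", {
  theta <- runif(200, 0, pi)
  # strong weights: E-subnetwork alone unstable (leading eig ~ n_e * J_EE)
  strong <- build_ring_weights(theta, 100,
    block_params(c(EE = 0.2, IE = 0.2, EI = -0.3, II = -0.3), m = 0,
                 zeta = FALSE), seed = 1)
  rep_s <- stability_report(strong)
  expect_equal(rep_s$lead_re_ee, 99 * 0.2, tolerance = 0.01)
  expect_true(rep_s$isn)
  expect_true(rep_s$stable)
  # weak weights: non-ISN
  weak <- build_ring_weights(theta, 100,
    block_params(c(EE = 0.004, IE = 0.004, EI = -0.006, II = -0.006),
                 m = 1, zeta = FALSE), seed = 1)
  rep_w <- stability_report(weak)
  expect_lt(rep_w$lead_re_ee, 1)
  expect_false(rep_w$isn)
  # zero matrix: stable, non-ISN
  rep_0 <- stability_report(matrix(0, 10, 10), n_e = 5)
  expect_true(rep_0$stable)
  expect_false(rep_0$isn)
})

test_that("E-I ratio variant preserves the total inhibitory weight per cell", {
  cfg <- isn_config(400, 400,
    block_params(c(EE = 0.05, IE = 0.05, EI = -0.075, II = -0.075), m = 1),
    "ring")
  v <- apply_ei_ratio_variant(cfg)
  expect_equal(v$n_i, 100L)
  expect_equal(unname(v$params$J["EI"]), -0.3)
  expect_equal(v$n_i * v$params$J["EI"], cfg$n_i * cfg$params$J["EI"])
  cfg2 <- cfg; cfg2$n_e <- 402
  expect_warning(apply_ei_ratio_variant(cfg2), "divisible")
})

test_that("broad-inhibition calibration yields a stable network and is identity at m_broad = m_EE", {
  cfg <- isn_config(100, 100,
    block_params(c(EE = 0.2, IE = 0.2, EI = -0.3, II = -0.3), m = 1,
                 zeta = FALSE), "ring")
  expect_identical(apply_broad_inhibition_variant(cfg, m_broad = 1), cfg)
  v <- apply_broad_inhibition_variant(cfg, m_broad = 0.95, seed = 3)
  expect_true(v$params$m["EI"] == 0.95 && v$params$m["II"] == 0.95)
  net <- build_network(v, seed = 3)
  expect_true(stability_report(net)$stable)
  # far-below-m_EE broadening cannot be stabilized by scaling inhibition
  expect_error(apply_broad_inhibition_variant(cfg, m_broad = 0.2, seed = 3),
               "calibration failed")
})

test_that("heterogeneous specificity keeps weights within the admissible envelope", {
  theta <- runif(80, 0, pi)
  params <- block_params(c(EE = 0.05, IE = 0.05, EI = -0.075, II = -0.075),
                         m = 1, zeta = FALSE, hetero = TRUE)
  W <- build_ring_weights(theta, 40, params, seed = 9)$W
  D <- cos(2 * outer(theta, theta, "-"))
  off <- row(W) != col(W)
  # per-synapse m in [0,1]: weights between J and J(1 + cos) envelopes
  lo <- pmin(0.05 * (1 + D), 0.05 + 0 * D)
  hi <- pmax(0.05 * (1 + D), 0.05 + 0 * D)
  sub <- off[, 1:40]
  we <- W[, 1:40]
  expect_true(all(we[sub] >= lo[, 1:40][sub] - 1e-12 &
                    we[sub] <= hi[, 1:40][sub] + 1e-12))
})
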