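test_that("the perturbation slope classifies specific and nonspecific paradoxical effects", {
  # exact negative line: specific paradoxical
  s1 <- perturbation_slope(c(2, 1, 0) + c(1e-9, -2e-9, 1e-9), c(-2, -1, 0))
  expect_equal(s1$slope, -1, tolerance = 1e-6)
  expect_true(s1$specific_paradoxical)
  expect_true(s1$nonspecific_paradoxical)
  # flat response with negative mean perturbation: nonspecific only
  s2 <- perturbation_slope(c(1, 1, 1) + c(1e-9, -2e-9, 1e-9), c(-2, -1, 0))
  expect_equal(s2$slope, 0, tolerance = 1e-6)
  expect_false(s2$specific_paradoxical)
  expect_true(s2$nonspecific_paradoxical)
  expect_error(perturbation_slope(1:2, 1:2), "3 points")
  expect_error(perturbation_slope(1:5, rep(1, 5)), "degenerate")
  # slope sign is invariant under affine rescaling of the perturbation axis
  set.seed(1)
  ds <- runif(50, -1, 0); dr <- -0.7 * ds + rnorm(50, 0, 0.05)
  a <- perturbation_slope(dr, ds)
  b <- perturbation_slope(dr, 0.1 * ds)
  expect_equal(b$slope, a$slope / 0.1, tolerance = 1e-9)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-9)
})

test_that("population PO/OSI match the doubled-angle circular mean and the brute-force loop", {
  # all active neurons share theta* = pi/2
  binned <- matrix(c(3, 2, 0, 1), 1, 4)
  th <- c(pi / 2, pi / 2, 0.3, pi / 2)
  tr <- population_selectivity(binned, th, min_active = 3)
  expect_equal(tr$po, pi / 2)
  expect_equal(tr$osi, 1)
  # equal weight at orthogonal orientations: antipodal on the doubled circle
  tr2 <- population_selectivity(matrix(c(2, 2), 1, 2), c(0, pi / 2),
                                min_active = 2)
  expect_equal(tr2$osi, 0, tolerance = 1e-12)
  # exact agreement with the brute-force double loop on a random toy raster
  set.seed(8)
  toy <- matrix(rpois(50 * 20, 0.4), 50, 20)
  th20 <- runif(20, 0, pi)
  fast <- population_selectivity(toy, th20, min_active = 5)
  slow <- brute_selectivity(toy, th20, min_active = 5)
  expect_equal(fast$valid, slow$valid)
  expect_equal(fast$po[fast$valid], slow$po[slow$valid], tolerance = 1e-12)
  expect_equal(fast$osi[fast$valid], slow$osi[slow$valid],
               tolerance = 1e-12)
})

test_that("the ST index is 0 for a single visited state, 1 for uniform coverage, and matches brute force", {
  mk_trace <- function(po, osi) {
    structure(data.frame(window = seq_along(po), po = po, osi = osi,
                         n_active = 10, valid = TRUE),
              class = c("selectivity_trace", "data.frame"))
  }
  centres <- (seq(0, pi, length.out = 25)[-25] +
                seq(0, pi, length.out = 25)[-1]) / 2
  one <- st_index(mk_trace(rep(centres[3], 30), rep(1, 30)))
  expect_equal(one$h_osi, 1, tolerance = 1e-12)
  expect_equal(one$sti, 0, tolerance = 1e-12)
  unif <- st_index(mk_trace(rep(centres, 2), rep(1, 48)))
  expect_equal(unif$h_osi, 0, tolerance = 1e-12)
  expect_equal(unif$sti, 1, tolerance = 1e-12)
  # zero selective windows: defined degenerate result
  none <- st_index(mk_trace(runif(10, 0, pi), rep(0.2, 10)))
  expect_equal(none$sti, 0)
  expect_true(none$degenerate)
  # bounds and brute-force agreement on a random raster
  set.seed(9)
  toy <- matrix(rpois(60 * 15, 0.8), 60, 15)
  th <- runif(15, 0, pi)
  tr <- population_selectivity(toy, th, min_active = 5)
  st <- st_index(tr)
  expect_true(st$sti >= 0 && st$sti <= 1)
  expect_equal(st$sti, brute_sti(brute_selectivity(toy, th, 5)),
               tolerance = 1e-12)
})

test_that("the time-shuffle bootstrap is unbiased on a stationary raster", {
  set.seed(10)
  binned <- matrix(rpois(400 * 30, 0.5), 400, 30)
  th <- runif(30, 0, pi)
  bs <- bootstrap_st(binned, th, n_shuffles = 100, seed = 4, min_active = 5)
  expect_equal(length(bs$null_sti), 100)
  expect_lt(abs(bs$sti_boot), 3 * bs$null_sd)
  bs2 <- bootstrap_st(binned, th, n_shuffles = 100, seed = 4, min_active = 5)
  expect_identical(bs$null_sti, bs2$null_sti)
})

test_that("pattern-interval correlations detect self-similarity and periodicity", {
  set.seed(11)
  iid <- matrix(rnorm(200 * 25), 200, 25)
  pic <- pattern_interval_correlation(iid, max_lag = 50)
  expect_equal(pic$mean_cor[pic$lag == 0], 1, tolerance = 1e-12)
  expect_lt(max(abs(pic$mean_cor[pic$lag > 0])), 0.15)
  # periodic raster: correlation 1 at the period
  block <- matrix(rnorm(5 * 25), 5, 25)
  per <- do.call(rbind, replicate(20, block, simplify = FALSE))
  pp <- pattern_interval_correlation(per, max_lag = 12)
  expect_equal(pp$mean_cor[pp$lag == 5], 1, tolerance = 1e-12)
  expect_equal(pp$mean_cor[pp$lag == 10], 1, tolerance = 1e-12)
  expect_lt(pp$mean_cor[pp$lag == 2], 0.9)
})

test_that("the reference sweep recovers negative slopes on a specific network and none on shuffled similarity", {
  # similarity-matched network: weights built from the same similarity
  # structure the patterns are drawn from (a ring of evenly spaced
  # orientations under the exponential RF-correlation rule)
  th <- rep(seq(0, pi, length.out = 61)[-61], 2)
  psi <- cos(2 * outer(th, th, "-"))
  params <- block_params(c(EE = 0.06, IE = 0.06, EI = -0.09, II = -0.09),
                         m = 0.5, eta = 2, zeta = FALSE)
  net <- build_rf_weights(psi, 60, params, seed = 1)
  sim <- psi[61:120, 61:120]
  s_base <- rep(2, 120)
  sw <- reference_sweep(net, sim, gamma = 0.1, kappa = 2, s_base = s_base)
  expect_gt(sw$fraction_specific, 0.8)
  # shuffled similarity vectors destroy the alignment
  set.seed(12)
  sim_sh <- apply(sim, 2, sample)
  sw_sh <- reference_sweep(net, sim_sh, gamma = 0.1, kappa = 2,
                           s_base = s_base)
  expect_lt(sw_sh$fraction_specific, 0.2)
})
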