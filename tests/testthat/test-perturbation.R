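test_that("perturbation patterns follow their defining formulas", {
  # 1D orientation pattern: zero at pi/4, most negative at 3pi/4
  th <- c(pi / 4, 3 * pi / 4, 0, pi / 2)
  p <- pattern_ring_1d(th, gamma = 0.25)
  expect_equal(as.numeric(p), 0.25 * (sin(2 * th) - 1))
  expect_equal(p[1], 0)
  expect_equal(p[2], -0.5)
  expect_true(all(p >= -0.5 & p <= 0))
  expect_true(all(pattern_ring_1d(th, 0.25, printed_sign = TRUE) >= 0))
  # nonspecific: uniform on [-2 gamma, 0] with mean -gamma
  pn <- pattern_nonspecific(1e5, gamma = 0.3, seed = 2)
  expect_true(all(pn <= 0 & pn >= -0.6))
  expect_lt(abs(mean(pn) + 0.3), 5 * 0.6 / sqrt(12 * 1e5))
  expect_equal(as.numeric(pattern_nonspecific(10, 0, seed = 1)), rep(0, 10))
  # similarity: -gamma exp(kappa psi), strictly decreasing in psi
  psis <- seq(-1, 1, by = 0.25)
  ps <- pattern_similarity(psis, gamma = 0.25, kappa = 2)
  expect_equal(ps[psis == 1], -0.25 * exp(2))
  expect_equal(ps[psis == 0], -0.25)
  expect_true(all(diff(as.numeric(ps)) < 0))
  expect_true(all(ps < 0))
})

test_that("shuffling preserves the multiset and is seed-reproducible", {
  p <- pattern_similarity(runif(50, -1, 1), 0.25, 2)
  s1 <- shuffle_pattern(p, seed = 3)
  s2 <- shuffle_pattern(p, seed = 3)
  expect_identical(as.numeric(s1), as.numeric(s2))
  expect_equal(sort(as.numeric(s1)), sort(as.numeric(p)))
  expect_equal(mean(s1), mean(p))
  expect_false(identical(as.numeric(s1), as.numeric(p)))
})

test_that("partial patterns zero the complement and respect the selection mode", {
  p <- pattern_similarity(seq(-1, 1, length.out = 40), 0.25, 2)
  expect_equal(as.numeric(partial_pattern(p, 1)), as.numeric(p))
  half <- partial_pattern(p, 0.5, seed = 1)
  expect_equal(sum(half != 0), 20L)
  kept <- which(as.numeric(half) != 0)
  expect_equal(as.numeric(half)[kept], as.numeric(p)[kept])
  half2 <- partial_pattern(p, 0.5, seed = 2)
  expect_false(identical(which(half2 != 0), kept))
  ms <- partial_pattern(p, 0.25, selection_mode = "most_similar")
  expect_setequal(which(as.numeric(ms) != 0), order(as.numeric(p))[1:10])
  expect_error(partial_pattern(p, 0), "fraction")
})

test_that("scaling and sign flips compose as expected", {
  th <- runif(30, 0, pi)
  p <- pattern_ring_1d(th, 0.25)
  tenth <- scale_and_sign(p, 0.1, "negative")
  expect_equal(as.numeric(tenth), as.numeric(pattern_ring_1d(th, 0.025)))
  pos <- scale_and_sign(p, 1, "positive")
  expect_true(all(pos >= 0))
  expect_equal(as.numeric(scale_and_sign(pos, 1, "positive")),
               -as.numeric(pos))
})

test_that("a zero pattern produces no response change and responses are linear in the pattern", {
  net <- toy_ring()
  s_base <- rep(2, 80)
  z <- specisn:::new_pattern(numeric(40), "zero")
  e0 <- run_perturbation_experiment(net, z, s_base = s_base)
  expect_lt(max(abs(e0$dr)), 1e-5)
  # linear regime: doubling the pattern doubles the response
  th_i <- net$identities$theta[41:80]
  p1 <- pattern_ring_1d(th_i, 0.005)
  p2 <- pattern_ring_1d(th_i, 0.01)
  e1 <- run_perturbation_experiment(net, p1, s_base = s_base)
  e2 <- run_perturbation_experiment(net, p2, s_base = s_base)
  expect_gt(min(e1$baseline), 0)
  expect_equal(e2$dr[41:80], 2 * e1$dr[41:80], tolerance = 1e-3)
})

test_that("response similarity flags responsive units above the activity percentile", {
  grid <- grid_spec(half_extent = 5, ppd = 2)
  bank <- sample_rf_bank(30, 30, grid, seed = 5)
  psi <- rf_correlation(bank)
  params <- block_params(c(EE = 0.6, IE = 0.6, EI = -0.9, II = -0.9) / 30,
                         m = 0.5, eta = 2, zeta = FALSE)
  net <- build_rf_weights(psi, 30, params, seed = 6)
  st <- make_stimuli("rf_like", n = 40, grid, seed = 7)
  rs <- response_similarity(net, bank, st, beta = 0.5,
                            s_base = rep(2, 60))
  expect_equal(dim(rs$similarity), c(30L, 30L))
  expect_equal(diag(rs$similarity), rep(1, 30))
  # 20th-percentile rule keeps about 80% of the population
  expect_equal(length(rs$responsive), 24L, tolerance = 1)
  # two neurons with identical RFs (hence identical drive and incoming
  # weights) have response correlation ~ 1
  bank2 <- bank
  bank2$fields[, 31] <- bank2$fields[, 32]
  bank2$params[31, c("theta", "phi", "omega", "x0", "y0")] <-
    bank2$params[32, c("theta", "phi", "omega", "x0", "y0")]
  net2 <- build_rf_weights(rf_correlation(bank2), 30, params, seed = 6)
  rs2 <- response_similarity(net2, bank2, st, beta = 0.5,
                             s_base = rep(2, 60))
  expect_gt(rs2$similarity[1, 2], 0.98)
})
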