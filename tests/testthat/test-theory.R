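test_that("linear response reproduces the scalar circuit and the identity limit", {
  W <- matrix(c(2, 2, -4, -4), 2, 2)
  expect_equal(linear_response(W, -1, n_e = 1), 1 / 3, tolerance = 1e-12)
  W0 <- matrix(0, 6, 6)
  ds <- rnorm(3)
  expect_equal(linear_response(W0, ds, n_e = 3), ds, tolerance = 1e-12)
  # singular (I - W_EE)
  Ws <- matrix(0, 2, 2); Ws[1, 1] <- 1
  expect_error(linear_response(Ws, 0.1, n_e = 1), "singular \\(I - W_EE\\)")
})

test_that("linear response equals the brute-force solve of the full stationary system", {
  set.seed(13)
  n_e <- 7; n_i <- 5; n <- n_e + n_i
  W <- matrix(rnorm(n * n, 0, 0.2), n, n)
  W <- W * 0.8 / max(Mod(eigen(W, only.values = TRUE)$values))
  s <- runif(n, 1, 2)
  ds_i <- rnorm(n_i, 0, 0.1)
  expect_equal(linear_response(W, ds_i, n_e = n_e),
               brute_response(W, n_e, s, ds_i), tolerance = 1e-10)
})

test_that("the closed-form slope has the specific-ISN sign structure", {
  expect_equal(closed_form_slope(2, 2), -1 / 3)
  expect_equal(closed_form_slope(1, 5), 0)
  expect_equal(closed_form_slope(0.5, 2), 1 / 3)
  expect_error(closed_form_slope(2, 0.5), "pole")
  # negative iff lambda > 1 and g > 1
  for (lam in c(0.5, 1.5, 3)) {
    for (g in c(1.2, 2)) {
      expect_equal(closed_form_slope(lam, g) < 0, lam > 1)
    }
  }
})

test_that("rank-one constructions recover the closed form analytically and by simulation", {
  set.seed(14)
  n <- 40
  v <- cos(2 * seq(0, pi, length.out = n + 1)[-(n + 1)])
  v <- v / sqrt(sum(v^2))
  for (lam in c(2, 4)) {
    for (g in c(1.5, 2)) {
      net <- rank_one_network(v, lam, g)
      ds <- 0.01 * v
      pred <- linear_response(net, ds)
      fit <- stats::lm(pred ~ ds)
      expect_equal(unname(coef(fit)[2]), closed_form_slope(lam, g),
                   tolerance = 1e-8)
      # sign theorem: for lambda > 1, g > 1 the response is anti-parallel
      # to the perturbed mode
      if (lam > 1 && g > 1) {
        expect_equal(stats::cor(pred, v), -1, tolerance = 1e-9)
      }
    }
  }
  # simulated recovery at lambda = 2, g = 2 (expected slope -1/3)
  net <- rank_one_network(v, 2, 2)
  s_base <- rep(2, 80)
  pat <- specisn:::new_pattern(0.05 * v, "mode")
  exp <- run_perturbation_experiment(net, pat, s_base = s_base)
  expect_gt(min(exp$baseline), 0)
  sl <- perturbation_slope(exp$dr[41:80], as.numeric(pat))
  expect_equal(sl$slope, -1 / 3, tolerance = 0.05 / 3)
})

test_that("randomized-block spectra expose the specific excitatory modes", {
  net <- toy_ring(n_e = 60, n_i = 60)
  # m = 0 (constant blocks): no specific mode beyond the uniform ones
  net0 <- toy_ring(n_e = 60, n_i = 60, m = 0)
  sp0 <- specific_mode_spectrum(net0, seed = 3)
  expect_lt(Re(sp0$values[1]), 1)
  # ring m = 1: the E-block specific eigenvalue is n_e J m / 2 (a circulant
  # cosine kernel carries a doubly degenerate Fourier mode at that value),
  # up to the small zero-autapse shift
  J_eff <- 0.15 * (40 / 60)
  ee <- net$W[1:60, 1:60]
  ev_ee <- sort(Re(eigen(ee, only.values = TRUE)$values),
                decreasing = TRUE)
  expect_equal(ev_ee[2], 60 * J_eff / 2, tolerance = 0.1)
  expect_equal(ev_ee[3], 60 * J_eff / 2, tolerance = 0.1)
  # after randomizing the inhibitory-related blocks the specific E modes
  # lead the full spectrum
  sp <- specific_mode_spectrum(net, seed = 3)
  expect_equal(Re(sp$values[1]), 60 * J_eff / 2, tolerance = 0.15)
  # eigenvector sign convention: largest E-component positive, unit norm
  v1 <- sp$vectors[, 1]
  expect_equal(sum(Mod(v1)^2), 1, tolerance = 1e-9)
  expect_gt(Re(v1[which.max(Mod(v1[1:60]))]), 0)
})

test_that("block permutation preserves each block's entry multiset exactly", {
  set.seed(15)
  n_e <- 8; n_i <- 6; n <- n_e + n_i
  W <- matrix(rnorm(n * n), n, n)
  W[, (n_e + 1):n] <- -abs(W[, (n_e + 1):n])
  net <- structure(list(W = W, n_e = n_e, n_i = n_i), class = "isn_network")
  # re-run the permutation with the same seed to reconstruct the matrix
  set.seed(21)
  Wm <- W
  idx <- specisn:::block_index(n_e, n_i)
  for (b in c("IE", "EI", "II")) {
    r <- idx[[b]][[1]]; cc <- idx[[b]][[2]]
    Wm[r, cc] <- matrix(sample(as.vector(W[r, cc])), length(r), length(cc))
  }
  sp <- specific_mode_spectrum(net, seed = 21)
  expect_equal(sort(Re(sp$values)),
               sort(Re(eigen(Wm, only.values = TRUE)$values)),
               tolerance = 1e-9)
  for (b in c("IE", "EI", "II")) {
    r <- idx[[b]][[1]]; cc <- idx[[b]][[2]]
    expect_equal(sort(as.vector(Wm[r, cc])), sort(as.vector(W[r, cc])))
  }
})

test_that("eigenvector profiles rank similarity orderings correctly", {
  set.seed(16)
  n_e <- 50
  psi_ref <- runif(n_e, -1, 1)
  v <- exp(2 * psi_ref)
  prof <- eigenvector_similarity_profile(c(v, rnorm(n_e)), n_e,
                                         psi_ref = psi_ref)
  expect_equal(unname(prof$cor_similarity["spearman"]), 1)
  vr <- rnorm(n_e)
  prof_r <- eigenvector_similarity_profile(vr, n_e, psi_ref = psi_ref,
                                           theta = runif(n_e, 0, pi))
  expect_lt(abs(prof_r$cor_similarity["spearman"]), 0.35)
  expect_lt(abs(prof_r$cor_orientation["spearman"]), 0.35)
  expect_warning(
    eigenvector_similarity_profile(complex(real = vr, imaginary = vr),
                                   n_e, psi_ref = psi_ref), "imaginary")
})

test_that("on an RF-correlation network the leading specific mode aligns with RF similarity, not orientation", {
  grid <- grid_spec(half_extent = 6, ppd = 2)
  bank <- sample_rf_bank(80, 80, grid, seed = 19)
  psi <- rf_correlation(bank)
  params <- block_params(c(EE = 0.25, IE = 0.25, EI = -0.375,
                           II = -0.375), m = 0.5, eta = 2, zeta = FALSE)
  net <- build_rf_weights(psi, 80, params, seed = 20)
  sp <- specific_mode_spectrum(net, seed = 20, n_modes = 1)
  v1 <- Re(sp$vectors[1:80, 1])
  ref <- which.max(abs(v1))
  if (v1[ref] < 0) v1 <- -v1
  prof <- eigenvector_similarity_profile(
    v1, 80, psi_ref = psi[1:80, ref], theta = bank$params$theta[1:80],
    theta_ref = bank$params$theta[ref])
  expect_gt(abs(prof$cor_similarity["spearman"]),
            abs(prof$cor_orientation["spearman"]))
  expect_gt(prof$cor_similarity["spearman"], 0.4)
})
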