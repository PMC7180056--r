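split_blocks <- function(W, n_e) {
  n <- nrow(W); n_i <- n - n_e
  e <- seq_len(n_e); i <- n_e + seq_len(n_i)
  list(EE = W[e, e, drop = FALSE], IE = W[i, e, drop = FALSE],
       EI = W[e, i, drop = FALSE], II = W[i, i, drop = FALSE],
       n_e = n_e, n_i = n_i)
}

#' Linear-response matrix of the inhibitory population
#'
#' At an interior fixed point of the linear rate dynamics
#' (`r = W r + s`, no rectified unit), a perturbation of the inhibitory
#' input alone changes the inhibitory rates as `dr_I = M ds_I` with
#' `M = [I - W_IE (I - W_EE)^{-1} W_EI - W_II]^{-1}`.
#'
#' @param W Full weight matrix (E before I).
#' @param n_e Number of excitatory neurons.
#' @return The `n_i x n_i` response matrix `M`.
#' @export
linear_response_matrix <- function(W, n_e) {
  if (inherits(W, "isn_network")) { n_e <- W$n_e; W <- W$W }
  b <- split_blocks(W, n_e)
  Ie <- diag(b$n_e); Ii <- diag(b$n_i)
  A <- tryCatch(solve(Ie - b$EE, b$EI),
                error = function(e) stop("singular (I - W_EE)"))
  bracket <- Ii - b$IE %*% A - b$II
  tryCatch(solve(bracket),
           error = function(e) stop("singular response bracket"))
}

#' Predicted inhibitory response change
#'
#' `dr_I = M ds_I` with `M` from [linear_response_matrix()]: the
#' linear-response prediction for the change of inhibitory rates under an
#' inhibitory input perturbation, valid when no unit is rectified in either
#' state.
#'
#' @param W Full weight matrix or `isn_network`.
#' @param ds_i Perturbation vector of length `n_i`.
#' @param n_e Number of excitatory neurons (taken from the network object
#'   when given).
#' @return Predicted `dr_I`, length `n_i`.
#' @export
linear_response <- function(W, ds_i, n_e = NULL) {
  if (inherits(W, "isn_network")) { n_e <- W$n_e; W <- W$W }
  if (is.null(n_e)) stop("`n_e` required")
  M <- linear_response_matrix(W, n_e)
  stopifnot(length(ds_i) == nrow(M))
  as.vector(M %*% ds_i)
}

#' Closed-form slope along a specific eigenmode
#'
#' When the perturbation is aligned with a specific eigenvector of the
#' excitatory kernel with eigenvalue `lambda`, and inhibitory outgoing
#' weights share the excitatory profile up to an inhibition-dominance factor
#' `-g`, the response change per unit perturbation is
#' `(1 - lambda) / (1 - (1 - g) lambda)`. It is negative exactly when
#' `lambda > 1` (specific excitation alone unstable) and `g > 1` (dominant
#' specific inhibition): the specific-ISN condition.
#'
#' @param lambda Specific-mode eigenvalue.
#' @param g Inhibition-dominance factor.
#' @return The slope (scalar); an error at the pole
#'   `1 - (1 - g) lambda = 0`.
#' @export
closed_form_slope <- function(lambda, g) {
  denom <- 1 - (1 - g) * lambda
  if (abs(denom) < 1e-12) stop("pole: 1 - (1 - g) * lambda = 0")
  (1 - lambda) / denom
}

#' Spectrum isolating the specific excitatory eigenmodes
#'
#' Randomizes the E-to-I, I-to-E and I-to-I blocks by permuting their
#' entries within each block (preserving each block's multiset of weights,
#' hence its mean, variance and signs) while leaving the E-to-E block
#' intact, then eigendecomposes the modified matrix. The permutation washes
#' out the specific structure of the inhibitory-related blocks while keeping
#' their nonspecific (uniform) stabilization, so the leading eigenvalues of
#' the modified matrix expose the specific excitatory eigenmodes.
#'
#' @param net An `isn_network` (or matrix plus `n_e`).
#' @param n_e Number of excitatory neurons (matrix input).
#' @param seed Integer seed for the permutations.
#' @param n_modes Number of leading eigenvectors to return (default 2).
#' @return A list: `values` (eigenvalues sorted by decreasing real part),
#'   `vectors` (the `n_modes` leading eigenvectors as columns, unit norm,
#'   sign fixed so the largest-magnitude E-component is positive), `seed`.
#' @export
specific_mode_spectrum <- function(net, n_e = NULL, seed = 1, n_modes = 2) {
  if (inherits(net, "isn_network")) { W <- net$W; n_e <- net$n_e }
  else { W <- net; if (is.null(n_e)) stop("`n_e` required") }
  n <- nrow(W); n_i <- n - n_e
  set.seed(seed)
  Wm <- W
  idx <- block_index(n_e, n_i)
  for (b in c("IE", "EI", "II")) {
    r <- idx[[b]][[1]]; c <- idx[[b]][[2]]
    blk <- Wm[r, c]
    Wm[r, c] <- matrix(sample(as.vector(blk)), length(r), length(c))
  }
  eg <- eigen(Wm)
  ord <- order(Re(eg$values), decreasing = TRUE)
  vals <- eg$values[ord]
  n_modes <- min(n_modes, n)
  vecs <- eg$vectors[, ord[seq_len(n_modes)], drop = FALSE]
  for (k in seq_len(n_modes)) {
    v <- vecs[, k]
    v <- v / sqrt(sum(Mod(v)^2))
    je <- which.max(Mod(v[seq_len(n_e)]))
    ph <- v[je]
    if (Mod(ph) > 0) v <- v * Conj(ph) / Mod(ph)  # largest E-component real positive
    vecs[, k] <- v
  }
  list(values = vals, vectors = vecs, seed = seed, n_e = n_e)
}

#' Eigenvector profile along similarity orderings
#'
#' Pairs the excitatory components of an eigenvector with (a) the RF
#' similarity of each excitatory cell to a reference cell and (b) the cells'
#' preferred orientations, and reports the rank (Spearman) and Pearson
#' correlation of the components with each ordering. A specific eigenmode
#' concentrated on cells similar to the reference has a high correlation
#' with the similarity ordering; orientation alone typically orders it much
#' less well. For the orientation axis the circular similarity
#' `cos(2 (theta - theta_ref))` to the reference cell's orientation is used.
#'
#' @param v Eigenvector (length `n_e + n_i` or `n_e`); an imaginary part
#'   above `1e-6` relative magnitude triggers a warning and the real part is
#'   used.
#' @param n_e Number of excitatory neurons.
#' @param psi_ref RF similarity of each excitatory cell to the reference
#'   cell (length `n_e`), or `NULL`.
#' @param theta RF preferred orientations (length `n_e`), or `NULL`.
#' @param theta_ref Reference orientation (defaults to the orientation of
#'   the cell with the largest eigenvector component).
#' @return A list with the component vector and, per available ordering,
#'   `cor_similarity` / `cor_orientation` (each a vector with `pearson` and
#'   `spearman` entries).
#' @export
eigenvector_similarity_profile <- function(v, n_e, psi_ref = NULL,
                                           theta = NULL, theta_ref = NULL) {
  if (length(v) < n_e) stop("eigenvector shorter than n_e")
  ve <- v[seq_len(n_e)]
  if (is.complex(ve)) {
    if (max(Mod(Im(ve))) > 1e-6 * max(Mod(ve))) {
      warning("eigenvector has a non-negligible imaginary part; using Re()")
    }
    ve <- Re(ve)
  }
  out <- list(components = ve)
  both <- function(x, y) c(
    pearson = stats::cor(x, y),
    spearman = stats::cor(x, y, method = "spearman"))
  if (!is.null(psi_ref)) {
    stopifnot(length(psi_ref) == n_e)
    out$cor_similarity <- both(ve, psi_ref)
  }
  if (!is.null(theta)) {
    stopifnot(length(theta) == n_e)
    if (is.null(theta_ref)) theta_ref <- theta[which.max(abs(ve))]
    out$cor_orientation <- both(ve, cos(2 * (theta - theta_ref)))
    out$theta_ref <- theta_ref
  }
  out
}

#' Rank-one specific-mode network
#'
#' Constructs the idealized block structure used by the closed-form theory:
#' `W_EE = W_IE = lambda v v^T` and `W_EI = W_II = -g lambda v v^T` for a
#' unit vector `v`, so the specific mode has eigenvalue `lambda` and
#' inhibition dominance `g`. Useful as an analytic test bed: the predicted
#' response to a perturbation along `v` is exactly
#' `closed_form_slope(lambda, g) * ds`.
#'
#' @param v Unit-norm mode vector (length n; used for both populations).
#' @param lambda Specific-mode eigenvalue.
#' @param g Inhibition dominance.
#' @return An `isn_network` with `n_e = n_i = length(v)`.
#' @export
rank_one_network <- function(v, lambda, g) {
  v <- v / sqrt(sum(v^2))
  K <- lambda * tcrossprod(v)
  W <- rbind(cbind(K, -g * K), cbind(K, -g * K))
  n <- length(v)
  structure(
    list(W = W, n_e = n, n_i = n, params = NULL, type = "rank_one",
         identities = list(v = v, lambda = lambda, g = g), seed = NA),
    class = "isn_network"
  )
}
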