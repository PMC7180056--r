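#' Visual-field grid specification
#'
#' Defines the square pixel grid on which receptive fields and stimuli are
#' rasterized. The default is a 200 x 200 pixel field spanning 50 degrees of
#' visual angle in total (25 degrees to each side of the centre) at a
#' resolution of 4 pixels per degree.
#'
#' @param half_extent Half-width of the field in degrees (default 25).
#' @param ppd Resolution in pixels per degree (default 4).
#' @return An object of class `grid_spec` with the pixel-centre coordinate
#'   axis (degrees) and pixel dimensions.
#' @export
grid_spec <- function(half_extent = 25, ppd = 4) {
  stopifnot(half_extent > 0, ppd > 0)
  npix <- as.integer(round(2 * half_extent * ppd))
  axis <- (seq_len(npix) - 0.5) / ppd - half_extent
  structure(
    list(half_extent = half_extent, ppd = ppd, npix = npix, axis = axis),
    class = "grid_spec"
  )
}

#' Gabor receptive-field parameters
#'
#' @param theta Orientation in radians, in `[0, pi)`.
#' @param phi Spatial phase in radians, in `[0, pi)`.
#' @param sigma Envelope standard deviation in degrees (> 0).
#' @param gamma_aspect Dimensionless aspect ratio of the envelope (> 0).
#' @param omega Spatial frequency in cycles per degree (> 0); the wavelength
#'   is `1 / omega`.
#' @param x0,y0 Centre of the field in degrees.
#' @return An object of class `gabor_params`.
#' @export
gabor_params <- function(theta, phi, sigma = 2.5, gamma_aspect = 0.5,
                         omega = 0.08, x0 = 0, y0 = 0) {
  if (!is.finite(sigma) || sigma <= 0) stop("`sigma` must be positive")
  if (!is.finite(omega) || omega <= 0) stop("`omega` must be positive")
  if (!is.finite(gamma_aspect) || gamma_aspect <= 0) {
    stop("`gamma_aspect` must be positive")
  }
  structure(
    list(theta = theta %% pi, phi = phi %% pi, sigma = sigma,
         gamma_aspect = gamma_aspect, omega = omega, x0 = x0, y0 = y0),
    class = "gabor_params"
  )
}

#' Rasterize a Gabor field
#'
#' Evaluates a 2D Gabor function on the grid:
#' `exp(-(x'^2 + gamma^2 y'^2) / (2 sigma^2)) * cos(2 pi x' / lambda + phi)`,
#' where `(x', y')` are the coordinates rotated by `theta` about the field
#' centre `(x0, y0)`. The squared aspect ratio in the envelope is the standard
#' Gabor parameterization; `squared_aspect = FALSE` switches to an envelope
#' with `gamma * y'^2` instead.
#'
#' @param params A [gabor_params()] object.
#' @param grid A [grid_spec()] object.
#' @param squared_aspect Use `gamma^2 y'^2` in the envelope (default `TRUE`).
#' @return A `npix x npix` numeric matrix (rows index y, columns index x).
#' @export
make_gabor <- function(params, grid, squared_aspect = TRUE) {
  stopifnot(inherits(params, "gabor_params"), inherits(grid, "grid_spec"))
  xr <- grid$axis - params$x0
  yr <- grid$axis - params$y0
  X <- matrix(xr, grid$npix, grid$npix, byrow = TRUE)
  Y <- matrix(yr, grid$npix, grid$npix)
  ct <- cos(params$theta); st <- sin(params$theta)
  xp <- X * ct + Y * st
  yp <- -X * st + Y * ct
  g2 <- if (squared_aspect) params$gamma_aspect^2 else params$gamma_aspect
  env <- exp(-(xp^2 + g2 * yp^2) / (2 * params$sigma^2))
  env * cos(2 * pi * params$omega * xp + params$phi)
}

# Shared generative model for RF parameters and RF-statistics stimuli:
# theta, phi ~ U[0, pi); omega ~ Gamma(shape 2, scale 0.04) cycles/deg
# (mean 0.08); centres jittered uniformly within [-1.25, 1.25] degrees.
sample_gabor_params <- function(n, sigma = 2.5, gamma_aspect = 0.5,
                                jitter = 1.25) {
  data.frame(
    theta = stats::runif(n, 0, pi),
    phi = stats::runif(n, 0, pi),
    sigma = sigma,
    gamma_aspect = gamma_aspect,
    omega = stats::rgamma(n, shape = 2, scale = 0.04),
    x0 = stats::runif(n, -jitter, jitter),
    y0 = stats::runif(n, -jitter, jitter)
  )
}

rasterize_params <- function(par_tab, grid, squared_aspect = TRUE) {
  fields <- matrix(0, grid$npix^2, nrow(par_tab))
  for (i in seq_len(nrow(par_tab))) {
    p <- gabor_params(par_tab$theta[i], par_tab$phi[i], par_tab$sigma[i],
                      par_tab$gamma_aspect[i], par_tab$omega[i],
                      par_tab$x0[i], par_tab$y0[i])
    fields[, i] <- as.vector(make_gabor(p, grid, squared_aspect))
  }
  fields
}

#' Sample a bank of Gabor receptive fields
#'
#' Draws Gabor parameters for `n_e` excitatory and `n_i` inhibitory neurons
#' and rasterizes each field on the grid. Orientations and phases are uniform
#' on `[0, pi)`, `sigma = 2.5` degrees, aspect ratio 0.5, spatial frequency
#' drawn from a gamma distribution with shape 2 and scale 0.04 (mean 0.08
#' cycles/degree), and centres jittered uniformly within
#' `[-1.25, 1.25]` degrees of the field centre.
#'
#' @param n_e,n_i Number of excitatory / inhibitory neurons.
#' @param grid A [grid_spec()] object.
#' @param seed Integer seed; draws are reproducible under a fixed seed.
#' @param squared_aspect Envelope convention passed to [make_gabor()].
#' @return An object of class `rf_bank`: a parameter table (one row per
#'   neuron, excitatory first), the rasterized fields as a
#'   `npix^2 x (n_e + n_i)` matrix, and the grid.
#' @export
sample_rf_bank <- function(n_e, n_i, grid = grid_spec(), seed = 1,
                           squared_aspect = TRUE) {
  stopifnot(n_e > 0, n_i > 0)
  set.seed(seed)
  par_tab <- sample_gabor_params(n_e + n_i)
  par_tab$pop <- rep(c("E", "I"), c(n_e, n_i))
  fields <- rasterize_params(par_tab, grid, squared_aspect)
  structure(
    list(params = par_tab, fields = fields, grid = grid,
         n_e = n_e, n_i = n_i, seed = seed),
    class = "rf_bank"
  )
}

#' Pairwise receptive-field correlation matrix
#'
#' Pearson correlation of the flattened rasterized fields of every neuron
#' pair; symmetric with unit diagonal. Fields are implicitly z-scored by the
#' correlation, so the result is invariant to affine rescaling of any field.
#'
#' @param bank An [sample_rf_bank()] object (or any object with a `fields`
#'   matrix, pixels in rows and neurons in columns).
#' @return The `n x n` correlation matrix `psi`.
#' @export
rf_correlation <- function(bank) {
  fields <- if (is.matrix(bank)) bank else bank$fields
  sds <- apply(fields, 2, stats::sd)
  if (any(sds == 0)) {
    stop("correlation undefined: field(s) ",
         paste(which(sds == 0), collapse = ", "), " have zero variance")
  }
  psi <- stats::cor(fields)
  diag(psi) <- 1
  psi
}

#' Generate a stimulus ensemble
#'
#' Three generative kinds are supported. `rf_like` reuses the receptive-field
#' generative model (identical parameter distributions, independent draws), so
#' the stimulus ensemble has the same statistics as the neuronal RFs.
#' `grating_fixed_sf` and `grating_var_sf` are full-field sinusoidal gratings
#' with orientation and phase uniform on `[0, pi)` and spatial frequency
#' either fixed at 0.04 cycles/degree or drawn from the RF frequency
#' distribution (gamma, shape 2, scale 0.04).
#'
#' @param kind One of `"rf_like"`, `"grating_fixed_sf"`, `"grating_var_sf"`.
#' @param n Number of stimuli (default 200).
#' @param grid A [grid_spec()] object (must match the RF bank grid).
#' @param seed Integer seed.
#' @param squared_aspect Envelope convention for `rf_like` stimuli.
#' @return An object of class `stimulus_set` with the parameter table and the
#'   rasterized stimuli (`npix^2 x n` matrix).
#' @export
make_stimuli <- function(kind = c("rf_like", "grating_fixed_sf",
                                  "grating_var_sf"),
                         n = 200, grid = grid_spec(), seed = 1,
                         squared_aspect = TRUE) {
  kind <- match.arg(kind)
  set.seed(seed)
  if (kind == "rf_like") {
    par_tab <- sample_gabor_params(n)
    fields <- rasterize_params(par_tab, grid, squared_aspect)
  } else {
    par_tab <- data.frame(
      theta = stats::runif(n, 0, pi),
      phi = stats::runif(n, 0, pi),
      omega = if (kind == "grating_fixed_sf") rep(0.04, n)
              else stats::rgamma(n, shape = 2, scale = 0.04)
    )
    fields <- matrix(0, grid$npix^2, n)
    X <- matrix(grid$axis, grid$npix, grid$npix, byrow = TRUE)
    Y <- matrix(grid$axis, grid$npix, grid$npix)
    for (i in seq_len(n)) {
      xp <- X * cos(par_tab$theta[i]) + Y * sin(par_tab$theta[i])
      fields[, i] <- as.vector(
        cos(2 * pi * par_tab$omega[i] * xp + par_tab$phi[i])
      )
    }
  }
  structure(
    list(kind = kind, params = par_tab, fields = fields, grid = grid,
         n_stimuli = n, seed = seed),
    class = "stimulus_set"
  )
}

#' Load user-supplied grayscale images as stimuli
#'
#' Optional convenience loader: reads PNG images, converts to grayscale,
#' centre-crops to the grid's pixel dimensions and stacks them as a stimulus
#' set. Not required by any analysis; the RF-statistics generator
#' ([make_stimuli()] with `kind = "rf_like"`) is the study's stimulus source.
#'
#' @param paths Character vector of PNG file paths.
#' @param grid A [grid_spec()] object.
#' @return A `stimulus_set` of kind `"user_images"`.
#' @export
load_image_stimuli <- function(paths, grid = grid_spec()) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required to read images")
  }
  fields <- matrix(0, grid$npix^2, length(paths))
  for (i in seq_along(paths)) {
    img <- png::readPNG(paths[i])
    if (length(dim(img)) == 3) img <- apply(img[, , 1:3], c(1, 2), mean)
    if (any(dim(img) < grid$npix)) {
      stop("image ", paths[i], " is smaller than the grid")
    }
    r0 <- floor((nrow(img) - grid$npix) / 2)
    c0 <- floor((ncol(img) - grid$npix) / 2)
    fields[, i] <- as.vector(img[r0 + seq_len(grid$npix),
                                 c0 + seq_len(grid$npix)])
  }
  structure(
    list(kind = "user_images", params = data.frame(path = paths),
         fields = fields, grid = grid, n_stimuli = length(paths), seed = NA),
    class = "stimulus_set"
  )
}

#' Per-neuron stimulus drive
#'
#' The external input of neuron j under stimulus i is modulated by the
#' correlation between its RF and the stimulus field:
#' `drive[j, i] = 1 + beta * cor(RF_j, stimulus_i)`, where `beta` is the
#' modulation depth (0.5 for RF-statistics stimuli, 1 for gratings).
#'
#' @param bank An `rf_bank`.
#' @param stimuli A `stimulus_set` on the same grid.
#' @param beta Modulation depth.
#' @return A `(n_e + n_i) x n_stimuli` drive matrix.
#' @export
stimulus_drive <- function(bank, stimuli, beta = 0.5) {
  stopifnot(inherits(bank, "rf_bank"), inherits(stimuli, "stimulus_set"))
  if (bank$grid$npix != stimuli$grid$npix ||
      bank$grid$ppd != stimuli$grid$ppd) {
    stop("RF bank and stimulus set live on different grids")
  }
  1 + beta * stats::cor(bank$fields, stimuli$fields)
}

#' Receptive-field parameter table
#'
#' One row per neuron with the generative Gabor parameters, suitable for
#' writing to a delimited file.
#'
#' @param bank An `rf_bank`.
#' @return A data frame with columns `pop`, `theta`, `phi`, `sigma`,
#'   `gamma_aspect`, `omega`, `x0`, `y0`.
#' @export
rf_params_table <- function(bank) {
  stopifnot(inherits(bank, "rf_bank"))
  bank$params[, c("pop", "theta", "phi", "sigma", "gamma_aspect",
                  "omega", "x0", "y0")]
}
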