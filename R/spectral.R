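#' Endpoint-inclusive collocation grid on [0, L]
#'
#' Equispaced collocation points `x_j = j L / (N_x - 1)`, j = 0, ...,
#' N_x - 1, the natural grid for the type-I cosine expansion that
#' diagonalizes the Laplacian under zero-Neumann (no-flux) boundary
#' conditions. The Neumann eigenvalues are the continuum values
#' `lambda_k = (k pi / L)^2`.
#'
#' @param L domain length (um).
#' @param n_x number of grid points (>= 2).
#' @return An object of class `grid_1d` with elements `L`, `n_x`, `x`,
#'   `dx` and `lambda`.
#' @export
grid_1d <- function(L, n_x) {
  stopifnot(L > 0, n_x >= 2)
  n_x <- as.integer(n_x)
  structure(list(L = L, n_x = n_x,
                 x = seq(0, L, length.out = n_x),
                 dx = L / (n_x - 1),
                 lambda = (pi * (seq_len(n_x) - 1) / L)^2),
            class = "grid_1d")
}

#' Tensor-product collocation grid on [0, L] x [0, L]
#'
#' @param L side length (um).
#' @param n_x,n_y grid-point counts per axis.
#' @return An object of class `grid_2d`; `lambda_x`/`lambda_y` are the
#'   per-axis Neumann eigenvalues, combined additively for the 2-D
#'   Laplacian.
#' @export
grid_2d <- function(L, n_x, n_y = n_x) {
  stopifnot(L > 0, n_x >= 2, n_y >= 2)
  n_x <- as.integer(n_x); n_y <- as.integer(n_y)
  structure(list(L = L, n_x = n_x, n_y = n_y,
                 x = seq(0, L, length.out = n_x),
                 y = seq(0, L, length.out = n_y),
                 dx = L / (n_x - 1), dy = L / (n_y - 1),
                 lambda_x = (pi * (seq_len(n_x) - 1) / L)^2,
                 lambda_y = (pi * (seq_len(n_y) - 1) / L)^2),
            class = "grid_2d")
}

#' Uniform time discretization
#'
#' @param T final time (s).
#' @param n_t number of time steps; the step is `dt = T / n_t`.
#' @return An object of class `time_grid`.
#' @export
time_grid <- function(T, n_t) {
  stopifnot(T > 0, n_t >= 1)
  n_t <- as.integer(n_t)
  structure(list(T = T, n_t = n_t, dt = T / n_t), class = "time_grid")
}

# Even-extension index for the type-I cosine transform: a field of n points
# on the endpoint-inclusive grid extends to a periodic sequence of length
# 2(n-1) that is even about both endpoints.
even_index <- function(n) {
  if (n > 2) c(seq_len(n), seq(n - 1, 2)) else seq_len(n)
}

# Wavenumber index of each entry of the extended sequence (0..n-1 mirrored).
even_wavenumber <- function(n) {
  if (n > 2) c(0:(n - 1), seq(n - 2, 1)) else 0:(n - 1)
}

#' Type-I discrete cosine transform on the endpoint-inclusive grid
#'
#' Forward transform of a field sampled at `x_j = j L/(n-1)` into cosine-mode
#' coefficients `a_k`, normalized so that
#' `f_j = a_0 + 2 sum_{k=1}^{n-2} a_k cos(pi k j/(n-1)) + a_{n-1} cos(pi j)`
#' and [idct1()] is the exact inverse. The `k = 0` coefficient is the
#' (endpoint-half-weighted) mean of the field.
#'
#' @param f numeric vector (length >= 2).
#' @return coefficient vector of the same length.
#' @export
dct1 <- function(f) {
  n <- length(f)
  stopifnot(n >= 2)
  m <- 2L * (n - 1L)
  Re(stats::fft(f[even_index(n)]))[seq_len(n)] / m
}

#' Inverse of [dct1()]
#'
#' @param a cosine coefficients as produced by [dct1()].
#' @return the reconstructed field.
#' @export
idct1 <- function(a) {
  n <- length(a)
  stopifnot(n >= 2)
  ext <- a[even_index(n)]
  Re(stats::fft(ext, inverse = TRUE))[seq_len(n)]
}

# Per-mode amplification factors of the implicit Euler diffusion substep
# (f* - f)/dt = D Lap f*: every mode k is damped by 1/(1 + D dt lambda_k),
# the mean mode (lambda_0 = 0) is untouched.
diffusion_multiplier <- function(n, L, D, dt) {
  kk <- even_wavenumber(n)
  1 / (1 + D * dt * (pi * kk / L)^2)
}

#' Implicit cosine-spectral diffusion substep
#'
#' Advances a field by one implicit Euler diffusion step
#' `(f* - f)/dt = D Lap f*` under zero-Neumann boundary conditions:
#' forward cosine transform, damp mode k by `1/(1 + D dt lambda_k)`,
#' inverse transform. Unconditionally stable; no mode grows and constants
#' are exact fixed points. `D = 0` returns the field unchanged.
#'
#' @param field numeric vector (on a [grid_1d()]) or matrix (on a
#'   [grid_2d()], rows indexing x, columns y).
#' @param grid the matching grid object.
#' @param D diffusion coefficient (um^2/s), non-negative.
#' @param dt time step (s), positive.
#' @return the diffused field, same shape as the input.
#' @export
diffusion_step <- function(field, grid, D, dt) {
  stopifnot(D >= 0, dt > 0)
  if (D == 0) return(field)
  if (inherits(grid, "grid_1d")) {
    stopifnot(length(field) == grid$n_x)
    idx <- even_index(grid$n_x)
    mult <- diffusion_multiplier(grid$n_x, grid$L, D, dt)
    g <- stats::fft(field[idx]) * mult
    Re(stats::fft(g, inverse = TRUE))[seq_len(grid$n_x)] / length(mult)
  } else if (inherits(grid, "grid_2d")) {
    stopifnot(nrow(field) == grid$n_x, ncol(field) == grid$n_y)
    ix <- even_index(grid$n_x); iy <- even_index(grid$n_y)
    kx <- even_wavenumber(grid$n_x); ky <- even_wavenumber(grid$n_y)
    lam <- outer((pi * kx / grid$L)^2, (pi * ky / grid$L)^2, `+`)
    mult <- 1 / (1 + D * dt * lam)
    g <- stats::fft(field[ix, iy, drop = FALSE]) * mult
    Re(stats::fft(g, inverse = TRUE))[seq_len(grid$n_x), seq_len(grid$n_y),
                                      drop = FALSE] / length(mult)
  } else stop("'grid' must be a grid_1d or grid_2d", call. = FALSE)
}

# Diffuse two fields sharing one coefficient in a single complex FFT pass.
# Valid because the multiplier is real and symmetric under k -> M - k, so
# the real and imaginary parts stay decoupled.
diffusion_step_pair <- function(f1, f2, ext_idx, mult, n_keep) {
  g <- stats::fft(f1[ext_idx] + 1i * f2[ext_idx]) * mult
  w <- stats::fft(g, inverse = TRUE) / length(mult)
  list(Re(w)[n_keep], Im(w)[n_keep])
}

#' Trapezoid spatial average of a field
#'
#' Mean value over the domain computed with trapezoid weights (half weight
#' at the endpoints), the quadrature consistent with the endpoint-inclusive
#' collocation grid. A constant field averages to itself exactly.
#'
#' @param field numeric vector (1-D) or matrix (2-D).
#' @param grid the matching [grid_1d()] or [grid_2d()].
#' @return the spatial average (same units as the field).
#' @export
spatial_average <- function(field, grid) {
  if (inherits(grid, "grid_1d")) {
    stopifnot(length(field) == grid$n_x)
    w <- trapezoid_weights(grid$n_x)
    sum(w * field) / sum(w)
  } else if (inherits(grid, "grid_2d")) {
    stopifnot(nrow(field) == grid$n_x, ncol(field) == grid$n_y)
    wx <- trapezoid_weights(grid$n_x); wy <- trapezoid_weights(grid$n_y)
    sum(outer(wx, wy) * field) / (sum(wx) * sum(wy))
  } else stop("'grid' must be a grid_1d or grid_2d", call. = FALSE)
}

trapezoid_weights <- function(n) {
  w <- rep(1, n); w[c(1L, n)] <- 0.5; w
}
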