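#' @section Scenario registry:
#' The package ships a deterministic registry of study conditions, each a
#' complete bundle of initial-condition fields, kinetic parameters,
#' diffusion coefficients and discretization. See [list_scenarios()].
#' @name scenarios
NULL

# Single-enzyme parameter set used by the homogeneous/tanh-step scenarios:
# k_f = 3.4e6 /M/s converted to /uM/s, K_M ~ 18.6 uM.
rc_single_fast <- function() rate_constants(k_f = 3.4, k_b = 60, k_cat = 3.2)

# Slow-turnover set used by the localized-enzyme (organelle) scenarios:
# k_f = 6.7e5 /M/s, K_M ~ 0.985 uM.
rc_single_slow <- function() rate_constants(k_f = 0.67, k_b = 0.53, k_cat = 0.13)

rc_gk_default <- function() gk_rate_constants(k_fe = 2.22, k_be = 1.84, k_e = 0.38)

scenario_registry <- function() {
  list(
    fig2A = list(
      model = "rd1d", description = "homogeneous, low enzyme: MM valid everywhere",
      rc = rc_single_fast, D = function() diffusion_coefficients(0.2),
      L = 30, n_x = 100L, T = 1.25, n_t = 2730L,
      ic = function(x) list(S = rep(2, length(x)), E = rep(2, length(x)))),
    fig2D = list(
      model = "rd1d", description = "tanh step: S and E co-localized near x = 30 um",
      rc = rc_single_fast, D = function() diffusion_coefficients(0.2),
      L = 30, n_x = 100L, T = 1.25, n_t = 2730L,
      ic = function(x) {
        f <- 18.5 * (tanh(20 * x / 3 - 190) + 1) + 1e-4
        list(S = f, E = f)
      }),
    fig2G = list(
      model = "rd1d", description = "homogeneous, high enzyme: MM invalid everywhere",
      rc = rc_single_fast, D = function() diffusion_coefficients(0.2),
      L = 30, n_x = 100L, T = 1.25, n_t = 2730L,
      ic = function(x) list(S = rep(300, length(x)), E = rep(400, length(x)))),
    fig2J = list(
      model = "rd1d", description = "tanh steps: S and E segregated to opposite ends",
      rc = rc_single_fast, D = function() diffusion_coefficients(0.2),
      L = 30, n_x = 100L, T = 1.25, n_t = 2730L,
      ic = function(x) list(S = 290 * (tanh(10 - 2 * x / 3) + 1) + 10,
                            E = 300 * (tanh(2 * x / 3 - 10) + 1) + 100)),
    fig3B = list(
      model = "rd1d", description = "enzyme Gaussian-localized at x = 15 um (sigma = 0.2 um), immobile",
      rc = rc_single_slow,
      D = function() diffusion_coefficients(D_S = 0.2, D_E = 0, D_C = 0, D_P = 0.2),
      L = 30, n_x = 300L, T = 12, n_t = 11921L, sigma = 0.2,
      ic = NULL),  # built from sigma below
    fig3E = list(
      model = "rd1d", description = "homogenized partner of fig3B (in-vitro-like)",
      rc = rc_single_slow,
      D = function() diffusion_coefficients(D_S = 0.2, D_E = 0, D_C = 0, D_P = 0.2),
      L = 30, n_x = 300L, T = 12, n_t = 11921L,
      ic = function(x) list(S = rep(39, length(x)), E = rep(5, length(x)))),
    fig3H = list(
      model = "rd1d", description = "localized-enzyme family parameterized by sigma",
      rc = rc_single_slow,
      D = function() diffusion_coefficients(D_S = 0.2, D_E = 0, D_C = 0, D_P = 0.2),
      L = 30, n_x = 300L, T = 12, n_t = 11921L, sigma = 0.2,
      ic = NULL),
    fig4B = list(
      model = "gk2d", description = "GK cycle: S_T step in y, E_T gradient in x",
      rc = rc_gk_default, D = function() gk_diffusion(0.2),
      L = 30, n_x = 30L, n_y = 30L, T = 1100, n_t = 100000L,
      ic2 = function(x, y) list(
        S = outer(x, y, function(x, y) 500 * tanh(3.3 * y - 50) + 520),
        E = outer(x, y, function(x, y) 10 * tanh(0.2 * x - 3) + 20),
        D = matrix(20, length(x), length(y)))),
    fig4D = list(
      model = "gk2d", description = "GK cycle: cosine stripes (S_T in y, E_T in x)",
      rc = rc_gk_default, D = function() gk_diffusion(0.2),
      L = 30, n_x = 50L, n_y = 50L, T = 8.33, n_t = 200000L,
      ic2 = function(x, y) list(
        S = outer(x, y, function(x, y) 40 * cos(2 * y / 3) + 100),
        E = outer(x, y, function(x, y) 5 * cos(2 * x / 3) + 100),
        D = matrix(100, length(x), length(y)))),
    s1 = list(
      model = "rd1d", description = "diffusion sweep base: fig2D ICs with D_* overridable",
      rc = rc_single_fast, D = function() diffusion_coefficients(0.2),
      L = 30, n_x = 100L, T = 1.25, n_t = 2730L,
      ic = function(x) {
        f <- 18.5 * (tanh(20 * x / 3 - 190) + 1) + 1e-4
        list(S = f, E = f)
      })
  )
}

#' List the registered study scenarios
#'
#' @return A data frame with one row per scenario id: the model family
#'   (`rd1d` single-enzyme 1-D, `gk2d` Goldbeter-Koshland 2-D), grid and
#'   time discretization, and a short description.
#' @export
list_scenarios <- function() {
  reg <- scenario_registry()
  data.frame(
    id = names(reg),
    model = vapply(reg, `[[`, "", "model"),
    n_x = vapply(reg, `[[`, 0L, "n_x"),
    T = vapply(reg, `[[`, 0, "T"),
    n_t = vapply(reg, `[[`, 0L, "n_t"),
    description = vapply(reg, `[[`, "", "description"),
    row.names = NULL)
}

#' Construct a study scenario
#'
#' Builds the initial-condition fields, parameters and discretization of a
#' registered scenario, sampling the closed-form IC formulas on the scenario's
#' collocation grid. Everything is deterministic: regenerating a scenario
#' is bit-identical.
#'
#' @param id scenario id; see [list_scenarios()].
#' @param sigma Gaussian width (um) for the localized-enzyme family
#'   (`fig3B`/`fig3H`); defaults to the registered value.
#' @param overrides named list of discretization/parameter overrides for
#'   refinement studies: any of `n_x`, `n_y`, `n_t`, `T`, `D` (a
#'   [diffusion_coefficients()]/[gk_diffusion()] object or a single value
#'   applied to all mobile species), `save_frames`.
#' @return An object of class `qssa_scenario`: list with `id`, `model`,
#'   `rc`, `D`, `grid`, `tg`, `ic` (named fields), `sigma`.
#' @examples
#' sc <- make_scenario("fig2A")
#' spatial_average(sc$ic$E, sc$grid)  # 2 uM
#' @export
make_scenario <- function(id, sigma = NULL, overrides = list()) {
  reg <- scenario_registry()
  if (!id %in% names(reg))
    stop(sprintf("unknown scenario id '%s'; see list_scenarios()", id),
         call. = FALSE)
  entry <- reg[[id]]
  bad <- setdiff(names(overrides), c("n_x", "n_y", "n_t", "T", "D"))
  if (length(bad))
    stop(sprintf("unknown override key(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  n_x <- as.integer(overrides$n_x %||% entry$n_x)
  n_t <- as.integer(overrides$n_t %||% entry$n_t)
  Tfin <- overrides$T %||% entry$T
  tg <- time_grid(Tfin, n_t)
  D <- overrides$D %||% entry$D()
  sigma <- sigma %||% entry$sigma

  if (entry$model == "rd1d") {
    grid <- grid_1d(entry$L, n_x)
    if (is.numeric(D) && length(D) == 1L) D <- diffusion_coefficients(D)
    stopifnot(inherits(D, "diffusion_coefficients"))
    if (is.null(entry$ic)) {
      # localized-enzyme family: uniform substrate, Gaussian enzyme
      ic <- list(S = rep(39, n_x), E = localized_enzyme_ic(sigma, grid))
    } else {
      ic <- entry$ic(grid$x)
    }
    ic$C <- ic$C %||% rep(0, n_x)
    ic$P <- ic$P %||% rep(0, n_x)
  } else {
    n_y <- as.integer(overrides$n_y %||% entry$n_y)
    grid <- grid_2d(entry$L, n_x, n_y)
    if (is.numeric(D) && length(D) == 1L) D <- gk_diffusion(D)
    stopifnot(inherits(D, "gk_diffusion"))
    ic <- entry$ic2(grid$x, grid$y)
    zero <- matrix(0, n_x, n_y)
    ic$Sp <- ic$Sp %||% zero
    ic$ES <- ic$ES %||% zero
    ic$DSp <- ic$DSp %||% zero
  }
  for (f in ic)
    if (any(!is.finite(f)) || any(f < 0))
      stop("scenario ICs must be finite and non-negative", call. = FALSE)
  structure(list(id = id, model = entry$model, rc = entry$rc(), D = D,
                 grid = grid, tg = tg, ic = ic, sigma = sigma,
                 description = entry$description),
            class = "qssa_scenario")
}

#' @export
print.qssa_scenario <- function(x, ...) {
  cat(sprintf("Scenario '%s' (%s): %s\n", x$id, x$model, x$description))
  if (x$model == "rd1d")
    cat(sprintf("  grid: %d points on [0, %g] um; T = %g s, n_t = %d (dt = %.4g s)\n",
                x$grid$n_x, x$grid$L, x$tg$T, x$tg$n_t, x$tg$dt))
  else
    cat(sprintf("  grid: %d x %d on [0, %g]^2 um; T = %g s, n_t = %d (dt = %.4g s)\n",
                x$grid$n_x, x$grid$n_y, x$grid$L, x$tg$T, x$tg$n_t, x$tg$dt))
  avg <- vapply(x$ic, spatial_average, 0, grid = x$grid)
  cat("  IC spatial averages (uM):",
      paste(sprintf("%s = %.4g", names(avg), avg), collapse = ", "), "\n")
  invisible(x)
}

#' Gaussian-localized enzyme initial condition
#'
#' Enzyme profile concentrated at the domain midpoint (x = 15 um on the
#' default 30-um domain): a Gaussian density of width `sigma`, normalized
#' on the finite domain by trapezoid quadrature on the scenario grid
#' (truncating the tails), and scaled so the spatial average is exactly
#' `mean_level` for every `sigma`. The total enzyme content
#' (integral over the domain) is therefore identical across widths, and
#' the profile tends to the homogeneous level as `sigma` grows.
#'
#' @param sigma Gaussian standard deviation (um), positive.
#' @param grid a [grid_1d()].
#' @param mean_level spatial-average enzyme concentration (uM), default 5.
#' @param center peak position (um), default `L/2`.
#' @return the enzyme field (uM) on the grid.
#' @export
localized_enzyme_ic <- function(sigma, grid, mean_level = 5,
                                center = grid$L / 2) {
  stopifnot(inherits(grid, "grid_1d"))
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("'sigma' must be a positive length (um)", call. = FALSE)
  f0 <- stats::dnorm(grid$x, mean = center, sd = sigma)
  mean_level * f0 / spatial_average(f0, grid)
}

#' Heterogeneity index of a localized enzyme profile
#'
#' Decibel-like index `10 log10(sigma_max / sigma)` for the Gaussian width
#' `sigma`: 0 at `sigma_max` (effectively homogeneous) and increasing as
#' the profile narrows.
#'
#' @param sigma Gaussian width (um), positive.
#' @param sigma_max reference width at which the profile is essentially
#'   uniform (um); default 25.
#' @return the index (dimensionless); negative values (sigma above
#'   `sigma_max`) are allowed but flagged with a warning.
#' @export
heterogeneity <- function(sigma, sigma_max = 25) {
  stopifnot(sigma > 0, sigma_max > 0)
  h <- 10 * log10(sigma_max / sigma)
  if (any(h < 0))
    warning("sigma exceeds sigma_max: negative heterogeneity index")
  h
}
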