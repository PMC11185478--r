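#' Diffusion coefficients for the single-enzyme 1-D model
#'
#' @param D_S,D_E,D_C,D_P diffusion coefficients of substrate, enzyme,
#'   complex and product (um^2/s); non-negative. A single unnamed value
#'   recycles to all four species.
#' @return An object of class `diffusion_coefficients`.
#' @export
diffusion_coefficients <- function(D_S, D_E = D_S, D_C = D_S, D_P = D_S) {
  vals <- c(D_S = D_S, D_E = D_E, D_C = D_C, D_P = D_P)
  stopifnot(is.numeric(vals), all(is.finite(vals)), all(vals >= 0))
  structure(as.list(vals), class = "diffusion_coefficients")
}

#' One-dimensional concentration state
#'
#' Concentration fields of the four species on a shared [grid_1d()].
#' Derived pointwise totals: `E_T = E + C`, `S_hat = S + C`,
#' `S_T = S + C + P`.
#'
#' @param grid a [grid_1d()].
#' @param S,E,C,P numeric fields (uM), scalars recycle across the grid.
#' @return An object of class `state_1d`.
#' @export
state_1d <- function(grid, S, E, C = 0, P = 0) {
  stopifnot(inherits(grid, "grid_1d"))
  expand <- function(f) {
    f <- rep_len(as.numeric(f), grid$n_x)
    if (any(!is.finite(f)) || any(f < 0))
      stop("state fields must be finite and non-negative", call. = FALSE)
    f
  }
  structure(list(grid = grid, S = expand(S), E = expand(E),
                 C = expand(C), P = expand(P)),
            class = "state_1d")
}

# Post-substep field hygiene. Machine-scale undershoot (within -1e-9 uM)
# is clamped to zero. Larger but small negative excursions -- the Gibbs
# ringing the cosine-spectral interpolant produces on under-resolved
# fronts -- are left in place: clamping them would inject mass and break
# the conservation of spatial totals, and every reaction formula degrades
# gracefully for slightly negative concentrations. Negativity beyond 1% of
# the field's own scale can only come from an unstable explicit reaction
# step and aborts.
clamp_nonneg <- function(f, what) {
  low <- min(f)
  scale <- max(abs(f), 1e-12)
  if (is.na(low) || low < -(1e-9 + 0.01 * scale))
    stop(sprintf("unstable step: field '%s' reached %.3g uM (reduce dt)",
                 what, low), call. = FALSE)
  f[f < 0 & f >= -1e-9] <- 0
  f
}

# Unchecked QSS kernels for use inside the steppers, where spectral
# ringing can push fields a little below zero. Algebraically identical to
# sqss_complex()/tqss_complex() but without the domain guards.
qss_sq_raw <- function(S, E_T, K_M) {
  denom <- K_M + S
  ifelse(denom > 0, E_T * S / denom, 0)
}

qss_tq_raw <- function(S_hat, E_T, K_M) {
  b <- E_T + S_hat + K_M
  disc <- pmax(b * b - 4 * E_T * S_hat, 0)
  denom <- b + sqrt(disc)
  ifelse(denom > 0, 2 * E_T * S_hat / denom, 0)
}

#' Advance the 1-D model by one Lie-split step
#'
#' One full time step: first the implicit cosine-spectral diffusion substep
#' applied to each of S, E, C, P with its own coefficient (species with
#' `D = 0` bypass the transform), then an explicit Euler reaction substep
#' evaluated at the diffused (starred) fields:
#'
#' * `full` -- the mass-action terms of the four-species network;
#' * `sqssa` -- `E_T* = E* + C*`, the standard-QSS complex
#'   `C*(S*) = E_T* S*/(S* + K_M)` drives `dS = -dP = -k_cat C* dt`, then
#'   C and E are reconstructed from the QSS formula at the new S;
#' * `tqssa` -- the total substrate `S_hat* = S* + C*` is advanced with the
#'   quadratic complex [tqss_complex()], then C, E, S are reconstructed.
#'
#' Fields are clamped to zero within a -1e-9 uM tolerance after the
#' reaction; larger negativity aborts with a stability error.
#'
#' @param state a [state_1d()].
#' @param variant `"full"`, `"sqssa"` or `"tqssa"` (suffix `_p` accepted).
#' @param rc a [rate_constants()] object.
#' @param D a [diffusion_coefficients()] object.
#' @param dt time step (s).
#' @return the advanced `state_1d`.
#' @export
step_1d <- function(state, variant, rc, D, dt) {
  variant <- canonical_variant(variant)
  stopifnot(inherits(state, "state_1d"),
            inherits(D, "diffusion_coefficients"), dt > 0)
  g <- state$grid
  K_M <- derived_constants(rc)$K_M
  f <- diffuse_species_1d(list(S = state$S, E = state$E, C = state$C,
                               P = state$P),
                          c(D$D_S, D$D_E, D$D_C, D$D_P), g, dt)
  if (variant == "full") {
    bind <- rc$k_f * f$E * f$S
    unbind <- rc$k_b * f$C
    catal <- rc$k_cat * f$C
    S1 <- f$S + dt * (-bind + unbind)
    E1 <- f$E + dt * (-bind + unbind + catal)
    C1 <- f$C + dt * (bind - unbind - catal)
    P1 <- f$P + dt * catal
  } else if (variant == "sqssa") {
    E_T <- f$E + f$C
    Cs <- qss_sq_raw(f$S, E_T, K_M)
    S1 <- f$S - dt * rc$k_cat * Cs
    P1 <- f$P + dt * rc$k_cat * Cs
    C1 <- qss_sq_raw(S1, E_T, K_M)
    E1 <- E_T - C1
  } else {
    E_T <- f$E + f$C
    S_hat <- f$S + f$C
    Ct <- qss_tq_raw(S_hat, E_T, K_M)
    S_hat1 <- S_hat - dt * rc$k_cat * Ct
    P1 <- f$P + dt * rc$k_cat * Ct
    C1 <- qss_tq_raw(S_hat1, E_T, K_M)
    E1 <- E_T - C1
    S1 <- S_hat1 - C1
  }
  state$S <- clamp_nonneg(S1, "S")
  state$E <- clamp_nonneg(E1, "E")
  state$C <- clamp_nonneg(C1, "C")
  state$P <- clamp_nonneg(P1, "P")
  state
}

# Implicit diffusion of several fields; fields sharing a coefficient are
# packed in pairs into one complex FFT. D = 0 species bypass the transform.
diffuse_species_1d <- function(fields, D, grid, dt) {
  keep <- seq_len(grid$n_x)
  idx <- even_index(grid$n_x)
  for (Dv in unique(D[D > 0])) {
    which_f <- which(D == Dv)
    mult <- diffusion_multiplier(grid$n_x, grid$L, Dv, dt)
    i <- 1L
    while (i + 1L <= length(which_f)) {
      a <- which_f[i]; b <- which_f[i + 1L]
      res <- diffusion_step_pair(fields[[a]], fields[[b]], idx, mult, keep)
      fields[[a]] <- res[[1]]; fields[[b]] <- res[[2]]
      i <- i + 2L
    }
    if (i == length(which_f)) {
      a <- which_f[i]
      gg <- stats::fft(fields[[a]][idx]) * mult
      fields[[a]] <- Re(stats::fft(gg, inverse = TRUE))[keep] / length(mult)
    }
  }
  fields
}

#' Simulate a 1-D reaction-diffusion scenario
#'
#' Advances a scenario's initial fields over its time grid with [step_1d()]
#' and records equispaced snapshots (always including t = 0 and t = T).
#' The pipeline is fully deterministic.
#'
#' @param scenario a [make_scenario()] object (model `"rd1d"`).
#' @param variant `"full"`, `"sqssa"` or `"tqssa"`.
#' @param save_frames number of interior snapshots to keep in addition to
#'   the endpoints (default 100).
#' @return An object of class `rd_sim`: list with `times` (saved times, s),
#'   `data` (array time x space x species, uM), `grid`, `variant`,
#'   `scenario_id`, `rc`, `D`, `tg`.
#' @examples
#' sc <- make_scenario("fig2A", overrides = list(n_t = 200, T = 0.1))
#' sim <- simulate_rd(sc, "tqssa", save_frames = 10)
#' sim
#' @export
simulate_rd <- function(scenario, variant, save_frames = 100L) {
  stopifnot(inherits(scenario, "qssa_scenario"),
            identical(scenario$model, "rd1d"))
  variant <- canonical_variant(variant)
  g <- scenario$grid; tg <- scenario$tg
  state <- state_1d(g, scenario$ic$S, scenario$ic$E,
                    scenario$ic$C, scenario$ic$P)
  save_at <- snapshot_steps(tg$n_t, save_frames)
  species <- c("S", "E", "C", "P")
  data <- array(NA_real_, dim = c(length(save_at), g$n_x, length(species)),
                dimnames = list(NULL, NULL, species))
  slot <- 1L
  record <- function(st, slot) {
    for (s in seq_along(species)) data[slot, , s] <<- st[[species[s]]]
  }
  record(state, slot); slot <- slot + 1L
  for (n in seq_len(tg$n_t)) {
    state <- step_1d(state, variant, scenario$rc, scenario$D, tg$dt)
    if (n == save_at_step(save_at, slot)) {
      record(state, slot); slot <- slot + 1L
    }
  }
  structure(list(times = save_at * tg$dt, data = data, grid = g,
                 variant = variant, scenario_id = scenario$id,
                 rc = scenario$rc, D = scenario$D, tg = tg, model = "rd1d"),
            class = "rd_sim")
}

snapshot_steps <- function(n_t, save_frames) {
  steps <- unique(round(seq(0, n_t, length.out = min(n_t, save_frames) + 1L)))
  sort(as.integer(steps))
}

save_at_step <- function(save_at, slot) {
  if (slot <= length(save_at)) save_at[slot] else -1L
}
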