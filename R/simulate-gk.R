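#' Diffusion coefficients for the Goldbeter-Koshland model
#'
#' The kinase E and phosphatase D are immobile (membrane- or
#' scaffold-bound); only the substrate forms diffuse.
#'
#' @param d_S,d_Sp,d_ES,d_DSp diffusion coefficients (um^2/s) of the free
#'   substrate, phosphorylated substrate, kinase-substrate complex and
#'   phosphatase-substrate complex.
#' @return An object of class `gk_diffusion`.
#' @export
gk_diffusion <- function(d_S, d_Sp = d_S, d_ES = d_S, d_DSp = d_S) {
  vals <- c(d_S = d_S, d_Sp = d_Sp, d_ES = d_ES, d_DSp = d_DSp)
  stopifnot(is.numeric(vals), all(is.finite(vals)), all(vals >= 0))
  structure(as.list(vals), class = "gk_diffusion")
}

#' Two-dimensional Goldbeter-Koshland state
#'
#' Concentration fields of the six species on a shared [grid_2d()]
#' (matrices, rows indexing x and columns y). Derived pointwise totals:
#' `S_T = S + S_p + ES + DS_p`, `E_T = E + ES`, `D_T = D + DS_p`,
#' `S_hat = S + ES`, `S_hat_p = S_p + DS_p`.
#'
#' @param grid a [grid_2d()].
#' @param S,Sp,E,D,ES,DSp fields (uM); scalars recycle.
#' @return An object of class `gk_state`.
#' @export
gk_state <- function(grid, S, Sp, E, D, ES = 0, DSp = 0) {
  stopifnot(inherits(grid, "grid_2d"))
  expand <- function(f) {
    if (length(f) == 1L) f <- matrix(f, grid$n_x, grid$n_y)
    f <- as.matrix(f)
    stopifnot(nrow(f) == grid$n_x, ncol(f) == grid$n_y)
    if (any(!is.finite(f)) || any(f < 0))
      stop("state fields must be finite and non-negative", call. = FALSE)
    f
  }
  structure(list(grid = grid, S = expand(S), Sp = expand(Sp), E = expand(E),
                 D = expand(D), ES = expand(ES), DSp = expand(DSp)),
            class = "gk_state")
}

#' Advance the Goldbeter-Koshland model by one Lie-split step
#'
#' Diffusion substep (implicit cosine-spectral, 2-D) on the four mobile
#' fields S, S_p, ES, DS_p only -- the enzymes E and D never diffuse --
#' followed by the explicit reaction substep of the chosen variant:
#'
#' * `full` -- mass-action updates; the bimolecular terms use the
#'   pre-diffusion enzyme fields E^n, D^n as written in the update scheme
#'   (identical to the starred fields since the enzymes are immobile);
#' * `sqssa` -- per-arm standard-QSS complexes
#'   `ES(S) = E_T S/(S + K_ME)`, `DS_p(S_p) = D_T S_p/(S_p + K_MD)` drive
#'   the phosphorylation/dephosphorylation exchange, after which complexes
#'   and free enzymes are reconstructed from the totals;
#' * `tqssa` -- the totals `S_hat = S + ES`, `S_hat_p = S_p + DS_p` are
#'   advanced with the per-arm quadratic complexes ([tqss_complex()]),
#'   then `ES`, `DS_p`, `S`, `S_p`, `E`, `D` are reconstructed in that
#'   order and clamped non-negative.
#'
#' @param state a [gk_state()].
#' @param variant `"full"`, `"sqssa"` or `"tqssa"`.
#' @param rc a [gk_rate_constants()] object.
#' @param D a [gk_diffusion()] object.
#' @param dt time step (s).
#' @return the advanced `gk_state`.
#' @export
gk_step <- function(state, variant, rc, D, dt) {
  variant <- canonical_variant(variant)
  stopifnot(inherits(state, "gk_state"), inherits(rc, "gk_rate_constants"),
            inherits(D, "gk_diffusion"), dt > 0)
  g <- state$grid
  f <- diffuse_species_2d(list(S = state$S, Sp = state$Sp, ES = state$ES,
                               DSp = state$DSp),
                          c(D$d_S, D$d_Sp, D$d_ES, D$d_DSp), g, dt)
  En <- state$E; Dn <- state$D
  if (variant == "full") {
    bindE <- rc$k_fe * f$S * En
    bindD <- rc$k_fd * f$Sp * Dn
    S1   <- f$S   + dt * (-bindE + rc$k_be * f$ES + rc$k_d * f$DSp)
    Sp1  <- f$Sp  + dt * (-bindD + rc$k_bd * f$DSp + rc$k_e * f$ES)
    E1   <- En    + dt * (-bindE + (rc$k_be + rc$k_e) * f$ES)
    D1   <- Dn    + dt * (-bindD + (rc$k_bd + rc$k_d) * f$DSp)
    ES1  <- f$ES  + dt * (bindE - (rc$k_be + rc$k_e) * f$ES)
    DSp1 <- f$DSp + dt * (bindD - (rc$k_bd + rc$k_d) * f$DSp)
  } else if (variant == "sqssa") {
    E_T <- En + f$ES
    D_T <- Dn + f$DSp
    ESq <- qss_sq_raw(f$S, E_T, rc$K_ME)
    DSq <- qss_sq_raw(f$Sp, D_T, rc$K_MD)
    flux <- dt * (rc$k_e * ESq - rc$k_d * DSq)
    S1  <- f$S - flux
    Sp1 <- f$Sp + flux
    ES1 <- qss_sq_raw(S1, E_T, rc$K_ME)
    DSp1 <- qss_sq_raw(Sp1, D_T, rc$K_MD)
    E1 <- E_T - ES1
    D1 <- D_T - DSp1
  } else {
    E_T <- En + f$ES
    D_T <- Dn + f$DSp
    S_hat <- f$S + f$ES
    S_hat_p <- f$Sp + f$DSp
    ESt <- qss_tq_raw(S_hat, E_T, rc$K_ME)
    DSt <- qss_tq_raw(S_hat_p, D_T, rc$K_MD)
    flux <- dt * (rc$k_e * ESt - rc$k_d * DSt)
    S_hat1 <- S_hat - flux
    S_hat_p1 <- S_hat_p + flux
    ES1 <- qss_tq_raw(S_hat1, E_T, rc$K_ME)
    DSp1 <- qss_tq_raw(S_hat_p1, D_T, rc$K_MD)
    S1 <- S_hat1 - ES1
    Sp1 <- S_hat_p1 - DSp1
    E1 <- E_T - ES1
    D1 <- D_T - DSp1
  }
  state$S <- clamp_nonneg(S1, "S")
  state$Sp <- clamp_nonneg(Sp1, "Sp")
  state$E <- clamp_nonneg(E1, "E")
  state$D <- clamp_nonneg(D1, "D")
  state$ES <- clamp_nonneg(ES1, "ES")
  state$DSp <- clamp_nonneg(DSp1, "DSp")
  state
}

diffuse_species_2d <- function(fields, D, grid, dt) {
  nx <- grid$n_x; ny <- grid$n_y
  ix <- even_index(nx); iy <- even_index(ny)
  kx <- even_wavenumber(nx); ky <- even_wavenumber(ny)
  lam <- outer((pi * kx / grid$L)^2, (pi * ky / grid$L)^2, `+`)
  for (Dv in unique(D[D > 0])) {
    which_f <- which(D == Dv)
    mult <- 1 / (1 + Dv * dt * lam)
    m <- length(mult)
    i <- 1L
    while (i + 1L <= length(which_f)) {
      a <- which_f[i]; b <- which_f[i + 1L]
      z <- fields[[a]][ix, iy, drop = FALSE] +
        1i * fields[[b]][ix, iy, drop = FALSE]
      w <- stats::fft(stats::fft(z) * mult, inverse = TRUE) / m
      fields[[a]] <- Re(w)[seq_len(nx), seq_len(ny), drop = FALSE]
      fields[[b]] <- Im(w)[seq_len(nx), seq_len(ny), drop = FALSE]
      i <- i + 2L
    }
    if (i == length(which_f)) {
      a <- which_f[i]
      z <- fields[[a]][ix, iy, drop = FALSE]
      w <- stats::fft(stats::fft(z) * mult, inverse = TRUE) / m
      fields[[a]] <- Re(w)[seq_len(nx), seq_len(ny), drop = FALSE]
    }
  }
  fields
}

#' Simulate a 2-D Goldbeter-Koshland scenario
#'
#' @param scenario a [make_scenario()] object with model `"gk2d"`.
#' @param variant `"full"`, `"sqssa"` or `"tqssa"`.
#' @param save_frames number of snapshots in addition to the endpoints.
#' @return An object of class `rd_sim` with `data` an array
#'   time x x-index x y-index x species (species S, Sp, E, D, ES, DSp).
#' @export
gk_simulate <- function(scenario, variant, save_frames = 50L) {
  stopifnot(inherits(scenario, "qssa_scenario"),
            identical(scenario$model, "gk2d"))
  variant <- canonical_variant(variant)
  g <- scenario$grid; tg <- scenario$tg
  state <- gk_state(g, scenario$ic$S, scenario$ic$Sp, scenario$ic$E,
                    scenario$ic$D, scenario$ic$ES, scenario$ic$DSp)
  save_at <- snapshot_steps(tg$n_t, save_frames)
  species <- c("S", "Sp", "E", "D", "ES", "DSp")
  data <- array(NA_real_,
                dim = c(length(save_at), g$n_x, g$n_y, length(species)),
                dimnames = list(NULL, NULL, NULL, species))
  slot <- 1L
  record <- function(st, slot) {
    for (s in seq_along(species)) data[slot, , , s] <<- st[[species[s]]]
  }
  record(state, slot); slot <- slot + 1L
  for (n in seq_len(tg$n_t)) {
    state <- gk_step(state, variant, scenario$rc, scenario$D, tg$dt)
    if (n == save_at_step(save_at, slot)) {
      record(state, slot); slot <- slot + 1L
    }
  }
  structure(list(times = save_at * tg$dt, data = data, grid = g,
                 variant = variant, scenario_id = scenario$id,
                 rc = scenario$rc, D = scenario$D, tg = tg, model = "gk2d"),
            class = "rd_sim")
}

#' Phosphorylated fraction map
#'
#' Fraction of total substrate that is phosphorylated at a saved frame:
#' `(S_p + DS_p)/S_T` for the full and total-QSSA models, and `S_p/S_T`
#' for the standard-QSSA model (whose derivation treats the
#' phosphatase-substrate complex as negligible).
#'
#' @param sim an `rd_sim` from [gk_simulate()].
#' @param time snapshot time (s); the nearest saved frame is used.
#'   Defaults to the final frame.
#' @return A matrix of values in `[0, 1]` (x by y).
#' @export
phospho_fraction <- function(sim, time = NULL) {
  stopifnot(inherits(sim, "rd_sim"), identical(sim$model, "gk2d"))
  i <- nearest_frame(sim, time)
  S <- sim$data[i, , , "S"]; Sp <- sim$data[i, , , "Sp"]
  ES <- sim$data[i, , , "ES"]; DSp <- sim$data[i, , , "DSp"]
  S_T <- S + Sp + ES + DSp
  if (any(S_T <= 0))
    stop("phospho_fraction: total substrate is zero at some grid point",
         call. = FALSE)
  num <- if (sim$variant == "sqssa") Sp else Sp + DSp
  pmin(pmax(num / S_T, 0), 1)
}

nearest_frame <- function(sim, time = NULL) {
  if (is.null(time)) return(length(sim$times))
  which.min(abs(sim$times - time))
}
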