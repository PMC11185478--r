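#' Diffusion-coefficient sweep
#'
#' Re-runs the co-localized tanh-step scenario (`fig2D` initial
#' conditions) across a range of common diffusion coefficients and records
#' the final spatial-average product of each model variant, together with
#' the reduced models' relative error against the full model. As diffusion
#' accelerates past the slowest reaction time scale (`L^2/D` below
#' `1/k_cat`), the initial heterogeneity homogenizes before appreciable
#' turnover and the Michaelis-Menten reduction becomes accurate again.
#'
#' @param D_values diffusion coefficients to sweep (um^2/s); default a
#'   log-spaced decade grid from 2e-5 to 2e4.
#' @param variants model variants to run.
#' @param scenario_id base scenario (default `"s1"`, the tanh-step ICs).
#' @return A data frame with columns `D`, `diffusion_time` (`L^2/D`, s),
#'   `variant`, `pbar_T` (uM) and `err_rel` (sup-norm relative error of
#'   the `Pbar` trajectory vs the full model; 0 for the full model).
#' @export
sweep_diffusion <- function(D_values = 2 * 10^seq(-5, 4),
                            variants = c("full", "sqssa", "tqssa"),
                            scenario_id = "s1") {
  rows <- list()
  for (D in D_values) {
    sc <- make_scenario(scenario_id, overrides = list(D = D))
    runs <- lapply(variants, function(v) simulate_rd(sc, v))
    names(runs) <- vapply(variants, canonical_variant, "")
    full <- runs[["full"]]
    for (v in names(runs)) {
      pb <- pbar_series(runs[[v]])
      err <- if (v == "full" || is.null(full)) 0
      else compare_runs(runs[[v]], full)$sup_rel
      rows[[length(rows) + 1L]] <- data.frame(
        D = D, diffusion_time = sc$grid$L^2 / D, variant = v,
        pbar_T = pb$value[nrow(pb)], err_rel = err)
    }
  }
  do.call(rbind, rows)
}

#' Enzyme-heterogeneity sweep
#'
#' Runs the localized-enzyme scenario family across Gaussian widths
#' `sigma` and records the initial velocity (`Pbar(12 s)/12 s`) of each
#' model variant, together with the heterogeneity index
#' `10 log10(sigma_max/sigma)`. The enzyme's spatial average is held fixed
#' across widths, so the sweep isolates the effect of localization.
#'
#' @param sigmas Gaussian widths (um); default spans homogeneous
#'   (`sigma = 25`) to sharply localized (`sigma = 0.2`).
#' @param variants model variants to run.
#' @param window velocity window (s), default 12.
#' @return A data frame with columns `sigma`, `heterogeneity`, `variant`,
#'   `velocity` (uM/s).
#' @export
sweep_heterogeneity <- function(sigmas = c(25, 7.9, 2.5, 0.79, 0.25, 0.2),
                                variants = c("full", "sqssa", "tqssa"),
                                window = 12) {
  rows <- list()
  for (sg in sigmas) {
    sc <- make_scenario("fig3H", sigma = sg)
    for (v in variants) {
      sim <- simulate_rd(sc, v)
      rows[[length(rows) + 1L]] <- data.frame(
        sigma = sg, heterogeneity = heterogeneity(sg),
        variant = canonical_variant(v),
        velocity = initial_velocity(sim, window))
    }
  }
  do.call(rbind, rows)
}
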