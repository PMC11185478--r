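#' Spatial-average product trajectory
#'
#' Trapezoid spatial average of the product field at each saved time --
#' the headline summary for the 1-D scenarios. Non-decreasing for these
#' irreversible kinetics.
#'
#' @param sim an `rd_sim` from [simulate_rd()].
#' @return A data frame of class `summary_series` with columns `time` (s)
#'   and `value` (uM) and a `label` attribute.
#' @export
pbar_series <- function(sim) {
  stopifnot(inherits(sim, "rd_sim"), identical(sim$model, "rd1d"))
  vals <- apply(sim$data[, , "P", drop = FALSE], 1, spatial_average,
                grid = sim$grid)
  structure(data.frame(time = sim$times, value = vals),
            label = "Pbar", variant = sim$variant,
            class = c("summary_series", "data.frame"))
}

#' Initial reaction velocity
#'
#' Average product-formation velocity over an initial window:
#' `Pbar(t = window) / window`, with the window defaulting to 12 s. The
#' average concentration at the window edge is linearly interpolated
#' between saved frames.
#'
#' @param sim an `rd_sim` from [simulate_rd()].
#' @param window averaging window (s); the simulation horizon must reach it.
#' @return velocity (uM/s).
#' @export
initial_velocity <- function(sim, window = 12) {
  pb <- pbar_series(sim)
  if (max(pb$time) < window * (1 - 1e-9))
    stop(sprintf("initial_velocity: horizon %.3g s is shorter than the %g s window",
                 max(pb$time), window), call. = FALSE)
  # guard against T*(n/n) rounding a hair below the window
  stats::approx(pb$time, pb$value, xout = min(window, max(pb$time)))$y / window
}

#' Pointwise validity map of the standard QSSA
#'
#' Evaluates the sQSSA validity ratio from a scenario's initial fields at
#' every grid point: `E_T/(S_T + K_M)` for the single-enzyme model, and
#' the phosphatase-arm ratio `D_T/(K_MD + S_T)` for the
#' Goldbeter-Koshland model. Values much below 1 (by convention, below
#' `threshold`) mark the region where the Michaelis-Menten reduction is
#' locally trustworthy; the threshold is a reporting convention only and
#' never enters the solvers.
#'
#' @param scenario a [make_scenario()] object.
#' @param threshold reporting threshold for the "valid" region
#'   (default 0.1).
#' @return the ratio field (vector or matrix) with attribute `valid`
#'   (logical field `ratio < threshold`).
#' @export
validity_map <- function(scenario, threshold = 0.1) {
  stopifnot(inherits(scenario, "qssa_scenario"))
  ic <- scenario$ic
  if (scenario$model == "rd1d") {
    K_M <- derived_constants(scenario$rc)$K_M
    E_T <- ic$E + ic$C
    S_T <- ic$S + ic$C + ic$P
    ratio <- E_T / (S_T + K_M)
  } else {
    D_T <- ic$D + ic$DSp
    S_T <- ic$S + ic$Sp + ic$ES + ic$DSp
    ratio <- D_T / (scenario$rc$K_MD + S_T)
  }
  structure(ratio, valid = ratio < threshold)
}

#' Compare a reduced-model run against the full model
#'
#' Error measures of a reduced model's summary relative to the full
#' model's: for 1-D runs, the spatial-average product trajectory; for
#' Goldbeter-Koshland runs, the phosphorylated-fraction map at the final
#' saved frame. Both runs must share the grid and saved times. Relative
#' errors are normalized by the maximum of the full model's summary (which
#' avoids dividing by near-zero early values).
#'
#' @param reduced,full `rd_sim` objects; `full` is the reference.
#' @return An object of class `error_report`: list with `sup_rel`
#'   (sup-norm relative error), `int_rel` (time-integrated relative
#'   error; `NA` for 2-D map comparisons), `overestimates` (is the
#'   reduced final value above the full model's?), `variant`.
#' @export
compare_runs <- function(reduced, full) {
  stopifnot(inherits(reduced, "rd_sim"), inherits(full, "rd_sim"),
            identical(reduced$model, full$model))
  if (!isTRUE(all.equal(reduced$times, full$times)) ||
      !identical(dim(reduced$data), dim(full$data)))
    stop("compare_runs: discretizations do not match", call. = FALSE)
  if (reduced$model == "rd1d") {
    pr <- pbar_series(reduced)$value
    pf <- pbar_series(full)$value
    scale <- max(abs(pf))
    if (scale == 0) scale <- 1
    dt_w <- diff(full$times)
    mids <- function(v) (v[-1] + v[-length(v)]) / 2
    sup_rel <- max(abs(pr - pf)) / scale
    int_rel <- sum(mids(abs(pr - pf)) * dt_w) /
      max(sum(mids(abs(pf)) * dt_w), .Machine$double.eps)
    over <- pr[length(pr)] > pf[length(pf)]
  } else {
    fr <- phospho_fraction(reduced)
    ff <- phospho_fraction(full)
    scale <- max(abs(ff)); if (scale == 0) scale <- 1
    sup_rel <- max(abs(fr - ff)) / scale
    int_rel <- NA_real_
    over <- mean(fr) > mean(ff)
  }
  structure(list(sup_rel = sup_rel, int_rel = int_rel,
                 overestimates = over, variant = reduced$variant),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("Reduced-model error (%s vs full): sup %.3g, integrated %.3g%s\n",
              x$variant, x$sup_rel, x$int_rel,
              if (isTRUE(x$overestimates)) " (overestimates)" else ""))
  invisible(x)
}

#' Ultrasensitivity steepness along a row
#'
#' Maximum absolute x-derivative of the phosphorylated fraction along a
#' fixed y-row (central differences), quantifying how switch-like the
#' response to the kinase/phosphatase ratio is.
#'
#' @param sim a Goldbeter-Koshland `rd_sim`.
#' @param y row position (um); nearest grid row is used.
#' @param time snapshot time (s); nearest saved frame, default final.
#' @return steepness (1/um).
#' @export
steepness <- function(sim, y, time = NULL) {
  frac <- phospho_fraction(sim, time)
  j <- which.min(abs(sim$grid$y - y))
  row <- frac[, j]
  max(abs(diff(row))) / sim$grid$dx
}

#' Anisotropy of a phosphorylated-fraction map
#'
#' Decomposes the variation of the fraction map into an x-direction part
#' (variance of the column means, i.e. of the profile along x) and a
#' y-direction part (variance of the row-mean profile along y). A map that
#' varies only as horizontal stripes has essentially zero x-variance;
#' a grid pattern shows up as substantial variance in both directions.
#'
#' @param sim a Goldbeter-Koshland `rd_sim`.
#' @param time snapshot time (s); nearest saved frame, default final.
#' @return list with `x_var`, `y_var` and their ratio `x_over_y`.
#' @export
anisotropy_index <- function(sim, time = NULL) {
  frac <- phospho_fraction(sim, time)
  profile_x <- rowMeans(frac)  # varies along x
  profile_y <- colMeans(frac)  # varies along y
  x_var <- stats::var(profile_x)
  y_var <- stats::var(profile_y)
  list(x_var = x_var, y_var = y_var,
       x_over_y = x_var / max(y_var, .Machine$double.eps))
}
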