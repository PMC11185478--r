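#' @export
print.rd_sim <- function(x, ...) {
  dims <- if (x$model == "rd1d")
    sprintf("%d x-points", x$grid$n_x)
  else
    sprintf("%d x %d points", x$grid$n_x, x$grid$n_y)
  cat(sprintf("<rd_sim> %s model, variant '%s', scenario '%s'\n",
              if (x$model == "rd1d") "1-D single-enzyme" else "2-D Goldbeter-Koshland",
              x$variant, x$scenario_id))
  cat(sprintf("  %d saved frames over [0, %g] s on %s\n",
              length(x$times), max(x$times), dims))
  invisible(x)
}

#' @export
summary.rd_sim <- function(object, ...) {
  if (object$model == "rd1d") {
    pb <- pbar_series(object)
    cat(sprintf("Final spatial averages (t = %g s, uM):\n", max(object$times)))
    i <- length(object$times)
    for (sp in dimnames(object$data)[[3]])
      cat(sprintf("  %-3s %.6g\n", sp,
                  spatial_average(object$data[i, , sp], object$grid)))
    cat(sprintf("  Pbar trajectory: 0 -> %.6g uM\n", pb$value[length(pb$value)]))
  } else {
    frac <- phospho_fraction(object)
    cat(sprintf("Phosphorylated fraction at t = %g s: range [%.4g, %.4g], mean %.4g\n",
                max(object$times), min(frac), max(frac), mean(frac)))
  }
  invisible(object)
}

#' Tidy data frame of a simulation result
#'
#' @param x an `rd_sim`.
#' @param ... unused.
#' @return Long-format data frame with columns `time`, `x` (and `y` for
#'   2-D runs), `species`, `value` (uM).
#' @export
as.data.frame.rd_sim <- function(x, ...) {
  if (x$model == "rd1d") {
    species <- dimnames(x$data)[[3]]
    out <- expand.grid(time = x$times, x = x$grid$x, species = species,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    out$value <- as.vector(x$data)
  } else {
    species <- dimnames(x$data)[[4]]
    out <- expand.grid(time = x$times, x = x$grid$x, y = x$grid$y,
                       species = species,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    out$value <- as.vector(x$data)
  }
  out
}

#' Write a simulation result as tidy CSV
#'
#' @param sim an `rd_sim`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_simulation <- function(sim, file) {
  utils::write.csv(format(as.data.frame(sim), digits = 12, trim = TRUE,
                          scientific = NA),
                   file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Plot a simulation summary
#'
#' For 1-D runs, the spatial-average product trajectory; for 2-D
#' Goldbeter-Koshland runs, an image of the phosphorylated-fraction map at
#' the final frame.
#'
#' @param x an `rd_sim`.
#' @param ... passed to the underlying base-graphics call.
#' @export
plot.rd_sim <- function(x, ...) {
  if (x$model == "rd1d") {
    pb <- pbar_series(x)
    graphics::plot(pb$time, pb$value, type = "l",
                   xlab = "time (s)", ylab = "mean P (uM)",
                   main = sprintf("%s / %s", x$scenario_id, x$variant), ...)
  } else {
    graphics::image(x$grid$x, x$grid$y, phospho_fraction(x),
                    xlab = "x (um)", ylab = "y (um)",
                    main = sprintf("phosphorylated fraction (%s / %s)",
                                   x$scenario_id, x$variant), ...)
  }
  invisible(x)
}
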