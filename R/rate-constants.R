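#' Kinetic rate constants for a single enzyme-catalyzed reaction
#'
#' Bundles the mass-action rate constants of the reaction
#' \eqn{S + E \rightleftharpoons C \rightarrow E + P}: the bimolecular binding
#' rate `k_f`, the unbinding rate `k_b`, and the catalytic rate `k_cat`.
#' Internal units are uM, um and s throughout the package, so bimolecular
#' constants quoted in 1/M/s must be divided by 1e6 before use.
#'
#' @param k_f binding rate constant (1/uM/s); must be strictly positive.
#' @param k_b unbinding rate constant (1/s); non-negative.
#' @param k_cat catalytic rate constant (1/s); non-negative.
#' @return An object of class `rate_constants`.
#' @examples
#' rc <- rate_constants(k_f = 3.4, k_b = 60, k_cat = 3.2)
#' derived_constants(rc)$K_M  # Michaelis constant, ~18.6 uM
#' @export
rate_constants <- function(k_f, k_b, k_cat) {
  stopifnot(is.numeric(k_f), is.numeric(k_b), is.numeric(k_cat),
            length(k_f) == 1L, length(k_b) == 1L, length(k_cat) == 1L,
            is.finite(k_f), is.finite(k_b), is.finite(k_cat))
  if (k_f <= 0) stop("'k_f' must be strictly positive", call. = FALSE)
  if (k_b < 0 || k_cat < 0) stop("rate constants must be non-negative", call. = FALSE)
  structure(list(k_f = k_f, k_b = k_b, k_cat = k_cat),
            class = "rate_constants")
}

#' @export
print.rate_constants <- function(x, ...) {
  dc <- derived_constants(x)
  cat("Enzyme kinetics rate constants (uM, s):\n")
  cat(sprintf("  k_f = %g /uM/s, k_b = %g /s, k_cat = %g /s\n",
              x$k_f, x$k_b, x$k_cat))
  cat(sprintf("  K_M = %.4g uM, K = k_cat/k_f = %.4g uM\n", dc$K_M, dc$K))
  invisible(x)
}

#' Michaelis constant and Van Slyke-Cullen constant
#'
#' @param rc a [rate_constants()] object.
#' @return A list with `K_M = (k_b + k_cat)/k_f` and `K = k_cat/k_f`,
#'   both in uM.
#' @export
derived_constants <- function(rc) {
  stopifnot(inherits(rc, "rate_constants"))
  list(K_M = (rc$k_b + rc$k_cat) / rc$k_f, K = rc$k_cat / rc$k_f)
}

#' Rate constants for the Goldbeter-Koshland cycle
#'
#' Two interlocked enzyme-catalyzed arms acting on one substrate: a kinase
#' arm (`k_fe`, `k_be`, `k_e`) phosphorylating S, and a phosphatase arm
#' (`k_fd`, `k_bd`, `k_d`) dephosphorylating S_p.
#'
#' @param k_fe,k_be,k_e kinase-arm binding (1/uM/s), unbinding (1/s) and
#'   catalytic (1/s) rate constants.
#' @param k_fd,k_bd,k_d phosphatase-arm counterparts.
#' @return An object of class `gk_rate_constants` carrying the six rates
#'   plus the derived Michaelis constants `K_ME = (k_be + k_e)/k_fe` and
#'   `K_MD = (k_bd + k_d)/k_fd`.
#' @export
gk_rate_constants <- function(k_fe, k_be, k_e, k_fd = k_fe, k_bd = k_be,
                              k_d = k_e) {
  vals <- c(k_fe = k_fe, k_be = k_be, k_e = k_e,
            k_fd = k_fd, k_bd = k_bd, k_d = k_d)
  stopifnot(is.numeric(vals), all(is.finite(vals)), all(vals >= 0))
  if (k_fe <= 0 || k_fd <= 0)
    stop("binding rates 'k_fe' and 'k_fd' must be strictly positive",
         call. = FALSE)
  structure(list(k_fe = k_fe, k_be = k_be, k_e = k_e,
                 k_fd = k_fd, k_bd = k_bd, k_d = k_d,
                 K_ME = (k_be + k_e) / k_fe,
                 K_MD = (k_bd + k_d) / k_fd),
            class = "gk_rate_constants")
}

#' @export
print.gk_rate_constants <- function(x, ...) {
  cat("Goldbeter-Koshland rate constants (uM, s):\n")
  cat(sprintf("  kinase:      k_fe = %g, k_be = %g, k_e = %g  (K_ME = %.4g uM)\n",
              x$k_fe, x$k_be, x$k_e, x$K_ME))
  cat(sprintf("  phosphatase: k_fd = %g, k_bd = %g, k_d = %g  (K_MD = %.4g uM)\n",
              x$k_fd, x$k_bd, x$k_d, x$K_MD))
  invisible(x)
}
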