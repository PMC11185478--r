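#' Standard quasi-steady-state complex concentration
#'
#' Complex concentration under the standard QSSA, obtained by solving
#' dC/dt = 0 at fixed free substrate S:
#' \deqn{C(S) = E_T S / (K_M + S).}
#' This is the complex implicit in the Michaelis-Menten rate law.
#'
#' @param S free substrate concentration (uM); vectorized.
#' @param E_T total enzyme concentration (uM).
#' @param K_M Michaelis constant (uM).
#' @return Complex concentration in `[0, E_T]`; the `S = K_M = 0` corner is
#'   defined as 0 by continuity.
#' @export
sqss_complex <- function(S, E_T, K_M) {
  stopifnot(all(S >= 0), all(E_T >= 0), all(K_M >= 0))
  denom <- K_M + S
  out <- ifelse(denom > 0, E_T * S / denom, 0)
  # K_M = 0, S > 0 is the saturation limit C = E_T; handled by the ratio
  out
}

#' Total quasi-steady-state complex concentration
#'
#' Complex concentration under the total QSSA, the smaller root of the
#' quadratic \eqn{k_f(\hat{S} - C)(E_T - C) = (k_b + k_{cat}) C} in terms of
#' the total substrate \eqn{\hat{S} = S + C}:
#' \deqn{C(\hat S) = \tfrac12\left[b - \sqrt{b^2 - 4 E_T \hat S}\right],
#'       \quad b = E_T + \hat S + K_M.}
#' Evaluated in the cancellation-safe form
#' \eqn{2 E_T \hat S / (b + \sqrt{b^2 - 4 E_T \hat S})} so the small root is
#' accurate when \eqn{E_T \hat S \ll b^2}. A numerically negative
#' discriminant within `-1e-12 * b^2` is clamped to zero (mathematically the
#' discriminant is non-negative); anything more negative signals a domain
#' error.
#'
#' @param S_hat total substrate `S + C` (uM); vectorized.
#' @param E_T total enzyme concentration (uM).
#' @param K_M Michaelis constant (uM).
#' @return Complex concentration in `[0, min(E_T, S_hat)]`.
#' @export
tqss_complex <- function(S_hat, E_T, K_M) {
  stopifnot(all(S_hat >= 0), all(E_T >= 0), all(K_M >= 0))
  n <- max(length(S_hat), length(E_T), length(K_M))
  S_hat <- rep_len(S_hat, n); E_T <- rep_len(E_T, n); K_M <- rep_len(K_M, n)
  b <- E_T + S_hat + K_M
  disc <- b * b - 4 * E_T * S_hat
  bad <- disc < -1e-12 * b * b
  if (any(bad))
    stop("tqss_complex: negative discriminant beyond tolerance", call. = FALSE)
  disc[disc < 0] <- 0
  denom <- b + sqrt(disc)
  out <- numeric(n)
  pos <- denom > 0
  out[pos] <- 2 * E_T[pos] * S_hat[pos] / denom[pos]
  # denom = 0 only when E_T = S_hat = K_M = 0, where C = 0
  out
}

#' Validity factors for the QSSA reductions
#'
#' The three dimensionless small parameters governing the accuracy of the
#' reductions for a well-mixed reaction:
#' * `eps_sqssa = E_T / (S_T + K_M)` -- the standard QSSA is accurate when
#'   this is small (enzyme much below total substrate plus K_M);
#' * `eps_tqssa = (K / (2 S_T)) [b / sqrt(b^2 - 4 E_T S_T) - 1]` with
#'   `b = E_T + K_M + S_T` and `K = k_cat / k_f` -- the total QSSA factor,
#'   bounded above by 1/4 for all admissible rate constants, which is why
#'   the total QSSA is trustworthy across essentially the whole parameter
#'   space; evaluated in the equivalent cancellation-safe form
#'   `2 K E_T / (sqrt(d) (b + sqrt(d)))` with `d` the discriminant;
#' * `eps_es = k_cat E_T / (k_f (K_M + E_T)^2)` -- the Eilertsen-Schnell
#'   factor delimiting the (small) region where even the total QSSA fails.
#'
#' @param E_T total enzyme (uM).
#' @param S_T total substrate + product (uM); must be positive for the
#'   total-QSSA factor.
#' @param K_M Michaelis constant (uM).
#' @param rc a [rate_constants()] object supplying `k_f` and `k_cat`.
#' @return An object of class `validity_report` (a list with elements
#'   `eps_sqssa`, `eps_tqssa`, `eps_es`).
#' @export
validity_factors <- function(E_T, S_T, K_M, rc) {
  stopifnot(inherits(rc, "rate_constants"), E_T >= 0, S_T >= 0, K_M >= 0)
  if (S_T <= 0)
    stop("validity_factors: 'S_T' must be positive for the tQSSA factor",
         call. = FALSE)
  K <- rc$k_cat / rc$k_f
  b <- E_T + K_M + S_T
  disc <- max(b * b - 4 * E_T * S_T, 0)
  # K = 0 forces k_cat = 0, where the factor vanishes; otherwise K_M >= K > 0
  # keeps the discriminant strictly positive
  eps_tqssa <- if (E_T == 0 || K == 0) 0
  else 2 * K * E_T / (sqrt(disc) * (b + sqrt(disc)))
  structure(list(
    eps_sqssa = E_T / (S_T + K_M),
    eps_tqssa = eps_tqssa,
    eps_es    = rc$k_cat * E_T / (rc$k_f * (K_M + E_T)^2)
  ), class = "validity_report")
}

#' @export
print.validity_report <- function(x, ...) {
  cat("QSSA validity factors (values << 1 indicate a valid reduction):\n")
  cat(sprintf("  sQSSA  E_T/(S_T+K_M)        : %.4g\n", x$eps_sqssa))
  cat(sprintf("  tQSSA  factor (< 1/4 always): %.4g\n", x$eps_tqssa))
  cat(sprintf("  Eilertsen-Schnell factor    : %.4g\n", x$eps_es))
  invisible(x)
}
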