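# Independent root-finding oracle for the total-QSS complex: the smaller
# root of (S_hat - C)(E_T - C) = K_M * C, bracketed on [0, min(S_hat, E_T)]
# and polished with Newton steps. Deliberately does not share code with
# tqss_complex().
tqss_root_oracle <- function(S_hat, E_T, K_M) {
  if (S_hat == 0 || E_T == 0) return(0)
  g <- function(C) (S_hat - C) * (E_T - C) - K_M * C
  hi <- min(S_hat, E_T)
  if (g(hi) == 0) return(hi)
  C <- stats::uniroot(g, c(0, hi), tol = .Machine$double.eps^0.75)$root
  for (i in 1:3) {
    dg <- -(S_hat - C) - (E_T - C) - K_M
    C <- C - g(C) / dg
  }
  min(max(C, 0), hi)
}

# Standard-QSS oracle: root of k_f S (E_T - C) = (k_b + k_cat) C at fixed S,
# via bisection on C.
sqss_root_oracle <- function(S, E_T, K_M) {
  if (S == 0 && K_M == 0) return(0)
  g <- function(C) S * (E_T - C) - K_M * C
  if (g(E_T) >= 0) return(E_T)
  stats::uniroot(g, c(0, E_T), tol = .Machine$double.eps^0.75)$root
}

# One explicit-Euler reaction step of the well-mixed mass-action model,
# written out by hand as the 0-D oracle for the PDE reaction substep.
euler_full_0d <- function(S, E, C, P, rc, dt) {
  bind <- rc$k_f * E * S; unb <- rc$k_b * C; cat_ <- rc$k_cat * C
  c(S = S + dt * (-bind + unb),
    E = E + dt * (-bind + unb + cat_),
    C = C + dt * (bind - unb - cat_),
    P = P + dt * cat_)
}

run_three_variants <- function(scenario, save_frames = 100L) {
  runs <- lapply(c("full", "sqssa", "tqssa"),
                 function(v) simulate_rd(scenario, v, save_frames))
  names(runs) <- c("full", "sqssa", "tqssa")
  runs
}
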