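# Deterministic part of the network: Hill kinetics, the Nanog gate on the
# differentiation signal, and the four-variable drift.

hill_act <- function(x, k, n) {
  ifelse(x <= 0, 0, x^n / (k^n + x^n))
}

#' Intracellular activity of the differentiation signal
#'
#' The extrinsic signal `Y` is transmitted into the cell through a gate
#' controlled by Nanog: `Y_in = Y * k_Y^h / (k_Y^h + N^h)`. The gate is a
#' decreasing S-shaped (Hill) function of the Nanog concentration, so only
#' cells with low Nanog experience the full signal (`Y_in -> Y` as `N -> 0`)
#' while high Nanog blocks transmission (`Y_in -> 0` as `N -> Inf`). This is
#' Nanog's gate-keeper function: the signal can only act on cells that have
#' first lost Nanog. `k_Y` sets where the gate closes (it changes the slope
#' of the curve in `N`, not its range), `h` its sharpness.
#'
#' @param N Nanog concentration(s), a.u., >= 0 (vectorised).
#' @param Y extrinsic signal level, >= 0.
#' @param k_Y gate half-saturation constant, a.u., > 0.
#' @param h gate Hill coefficient, >= 1.
#' @return `Y_in`, same length as `N`, bounded in `[0, Y]`, equal to `Y/2`
#'   at `N = k_Y`.
#' @examples
#' compute_Yin(N = 0, Y = 5, k_Y = 100) # the full signal passes: 5
#' compute_Yin(N = 300, Y = 2, k_Y = 100) # 2 * 100^2 / (100^2 + 300^2) = 0.2
#' @export
compute_Yin <- function(N, Y, k_Y, h = 2) {
  if (!all(is.finite(N)) || !all(is.finite(c(Y, k_Y, h))))
    abort("compute_Yin: all inputs must be finite")
  if (any(N < 0) || Y < 0) abort("compute_Yin: N and Y must be >= 0")
  if (k_Y <= 0) abort("compute_Yin: k_Y must be > 0")
  if (h < 1) abort("compute_Yin: h must be >= 1")
  Y * k_Y^h / (k_Y^h + N^h)
}

#' Deterministic drift of the four-variable network
#'
#' Evaluates the right-hand side of the deterministic part of the model at a
#' cell state `(OS, N, R, E)`:
#' \deqn{f_{OS} = s_{12} H(OS) - d_{OS} (1 + i_{OS} Y_{in}) OS}
#' \deqn{f_N = [s_3 H(OS) + s_4 H(N)] \, G_p(E) - d_N (1 + i_N Y_{in}) N}
#' \deqn{f_R = s_5 H(OS) + s_6 H(N) - d_R (1 + i_R Y_{in}) R}
#' \deqn{f_E = s_7 H(OS) - d_E E}
#' with the shared activating Hill term `H(x) = x^n / (k^n + x^n)`, the Erk
#' repression factor `G_p(E) = 1 / (1 + p H(E))` acting on both Nanog
#' production terms, and `Y_in` from [compute_Yin()]. With `p = 0` the
#' FGF4/Erk feedback is absent and `f_N` does not depend on `E`.
#'
#' Negative concentrations are an error here: keeping states non-negative is
#' the integrator's job (it clamps at zero after each step), not the drift's.
#'
#' @param state numeric length-4 vector `(OS, N, R, E)` of concentrations
#'   (a.u.), all >= 0; names are optional but order is fixed.
#' @param params an [ng_params()] object.
#' @return Named numeric vector `c(OS=, N=, R=, E=)` of rates (a.u./min).
#' @export
deterministic_drift <- function(state, params) {
  stopifnot(inherits(params, "ng_params"))
  state <- as.numeric(state)
  if (length(state) != 4 || !all(is.finite(state)))
    abort("state must be 4 finite concentrations (OS, N, R, E)")
  if (any(state < 0))
    abort("negative concentrations are invalid; clamping is the integrator's job")
  OS <- state[1]; N <- state[2]; R <- state[3]; E <- state[4]
  pr <- params
  hOS <- hill_act(OS, pr$k, pr$n)
  hN <- hill_act(N, pr$k, pr$n)
  hE <- hill_act(E, pr$k, pr$n)
  yin <- if (pr$Y > 0) compute_Yin(N, pr$Y, pr$k_Y, pr$h) else 0
  gp <- 1 / (1 + pr$p * hE)
  c(OS = pr$s12 * hOS - pr$d_OS * (1 + pr$i_OS * yin) * OS,
    N = (pr$s3 * hOS + pr$s4 * hN) * gp - pr$d_N * (1 + pr$i_N * yin) * N,
    R = pr$s5 * hOS + pr$s6 * hN - pr$d_R * (1 + pr$i_R * yin) * R,
    E = pr$s7 * hOS - pr$d_E * E)
}
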