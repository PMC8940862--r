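# History-dependent damage evolution for one fibre family.
#
# Two internal variables drive an exponential saturation law:
#   beta  = < beta_tilde - beta_tilde_ini >  with
#           beta_tilde = int_0^t < dPsi_eff/ds > ds   (accumulated positive
#           effective-energy rate; produces the cycle-by-cycle approach),
#   gamma = max over history of < Psi_eff - Psi_ini >  (peak load level;
#           fixes the per-load damage ceiling).
#
#   D_s(gamma) = D_inf [1 - exp(ln(1 - r_inf)/gamma_inf * gamma)]
#   D(beta)    = D_s   [1 - exp(ln(1 - r_s)/beta_s * beta)]
#
# gamma_inf controls the saturated damage level ("degradation intensity"),
# beta_s how fast it is approached ("degradation rate"). The saturation
# criterion phi = <Psi_eff - Psi_ini> - gamma <= 0 holds after every update.

#' Fixed-load damage ceiling
#'
#' Maximally reachable damage for a given peak load level `gamma`:
#' \eqn{D_s(\gamma) = D_\infty [1 - \exp(\ln(1-r_\infty)/\gamma_\infty\,\gamma)]}.
#' Strictly increasing in `gamma`, with \eqn{D_s(\gamma_\infty) = r_\infty D_\infty}
#' and limit \eqn{D_\infty}.
#'
#' @param gamma Peak-load internal variable (kPa), >= 0; vectorised.
#' @param p [damage_params()].
#' @return Damage ceiling values in \[0, `D_inf`).
#' @export
saturation_limit <- function(gamma, p) {
  if (any(!is.finite(gamma)) || any(gamma < 0)) {
    stop("gamma must be finite and non-negative", call. = FALSE)
  }
  p$D_inf * (1 - exp(log(1 - p$r_inf) / p$gamma_inf * gamma))
}

#' Damage value from accumulated energy
#'
#' \eqn{D(\beta) = D_s [1 - \exp(\ln(1-r_s)/\beta_s\,\beta)]}; strictly
#' increasing in `beta` with \eqn{D(\beta_s) = r_s D_s}.
#'
#' @param beta Accumulated-energy internal variable (kPa), >= 0; vectorised.
#' @param Ds Damage ceiling in \[0, `D_inf`).
#' @param p [damage_params()].
#' @return Damage values in \[0, `Ds`).
#' @export
damage_value <- function(beta, Ds, p) {
  if (any(!is.finite(beta)) || any(beta < 0)) {
    stop("beta must be finite and non-negative", call. = FALSE)
  }
  if (any(!is.finite(Ds)) || any(Ds < 0) || any(Ds >= p$D_inf + 1e-15)) {
    stop("Ds must lie in [0, D_inf)", call. = FALSE)
  }
  Ds * (1 - exp(log(1 - p$r_s) / p$beta_s * beta))
}

#' Fresh per-family damage state
#'
#' History variables for one fibre family: the accumulated positive
#' effective-energy rate `beta_tilde`, its value at damage initiation
#' `beta_tilde_ini`, the peak-load variable `gamma`, the effective energy at
#' initiation `psi_ini`, the current damage `D` and ceiling `Ds`, and the
#' activation flag. `psi_prev` caches the last effective energy so the rate
#' integral can be accumulated incrementally.
#'
#' @return An object of class `damage_state`.
#' @export
damage_state <- function() {
  structure(list(beta_tilde = 0, beta_tilde_ini = 0, gamma = 0,
                 psi_ini = 0, psi_prev = 0, D = 0, Ds = 0, active = FALSE),
            class = "damage_state")
}

#' Activate damage evolution
#'
#' Marks the transition from physiological to supra-physiological loading:
#' the initiation threshold `beta_tilde_ini` is set to the current
#' accumulated history and `psi_ini` to the current effective energy, so
#' damage grows only for loading beyond the activation state. The threshold
#' is a state of the loading history, not a material parameter; drivers
#' expose it as "activate after cycle N" or as an energy threshold.
#'
#' @param state A `damage_state`, not yet active.
#' @param psi_effective_current Effective (undamaged) fibre energy at the
#'   activation instant (kPa).
#' @return The activated `damage_state`.
#' @export
damage_activate <- function(state, psi_effective_current) {
  stopifnot(inherits(state, "damage_state"))
  if (state$active) stop("damage state is already active", call. = FALSE)
  if (!is.finite(psi_effective_current) || psi_effective_current < 0) {
    stop("effective energy must be finite and non-negative", call. = FALSE)
  }
  state$beta_tilde_ini <- state$beta_tilde
  state$psi_ini <- psi_effective_current
  state$psi_prev <- psi_effective_current
  state$active <- TRUE
  state
}

#' Advance the damage state by one load increment
#'
#' Discrete update of the history integrals: the positive part of the
#' effective-energy increment is added to `beta_tilde` (Macaulay-filtered
#' rate, so unloading leaves the history untouched); `gamma` records the
#' running maximum of the energy excess over the initiation state; the
#' ceiling `Ds` and damage `D` follow from the two saturation laws. Must be
#' called once per increment in increment order (the caller's contract).
#' Before activation only the history integral advances and `D` stays 0.
#'
#' @param state A `damage_state`.
#' @param psi_effective_new Effective fibre energy at the new increment (kPa).
#' @param p [damage_params()].
#' @return The updated `damage_state`; the saturation criterion
#'   \eqn{\phi = \langle\Psi - \Psi_{ini}\rangle - \gamma \le 0} holds on
#'   return.
#' @export
damage_update <- function(state, psi_effective_new, p) {
  stopifnot(inherits(state, "damage_state"))
  if (!is.finite(psi_effective_new) || psi_effective_new < 0) {
    stop("effective energy must be finite and non-negative", call. = FALSE)
  }
  state$beta_tilde <- state$beta_tilde +
    max(psi_effective_new - state$psi_prev, 0)
  state$psi_prev <- psi_effective_new
  if (state$active) {
    state$gamma <- max(state$gamma,
                       max(psi_effective_new - state$psi_ini, 0))
    state$Ds <- saturation_limit(state$gamma, p)
    beta <- max(state$beta_tilde - state$beta_tilde_ini, 0)
    state$D <- damage_value(beta, state$Ds, p)
  }
  state
}

#' Saturation criterion residual
#'
#' \eqn{\phi = \langle \Psi_{eff} - \Psi_{ini} \rangle - \gamma}; the update
#' rule keeps \eqn{\phi \le 0}, which pins the ceiling `Ds` during cyclic
#' loading at a fixed amplitude.
#'
#' @param state A `damage_state`.
#' @param psi_effective Effective fibre energy (kPa).
#' @return Numeric residual (kPa), \eqn{\le 0} after a consistent update.
#' @export
saturation_criterion <- function(state, psi_effective) {
  max(psi_effective - state$psi_ini, 0) - state$gamma
}

#' @export
print.damage_state <- function(x, ...) {
  cat(sprintf(
    "Damage state: D = %.6g (ceiling Ds = %.6g), gamma = %.6g kPa, beta_tilde = %.6g kPa, %s\n",
    x$D, x$Ds, x$gamma, x$beta_tilde,
    if (x$active) "active" else "inactive"))
  invisible(x)
}
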