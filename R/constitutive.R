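# Strain-energy evaluation and stress computation for the fibre-reinforced
# arterial wall model:
#
#   Psi = Psi_iso + Psi_vol + sum_i Psi_ti_i
#   Psi_iso = c1 (I1 / I3^{1/3} - 3)                 (Neo-Hookean matrix)
#   Psi_vol = eps1 (I3^{eps2} + I3^{-eps2} - 2)      (volumetric penalty)
#   Psi_ti_i = alpha1 < (1 - D_i) [kappa I1 + (1 - 1.5 kappa) K3^i] - 2 >^alpha2
#
# with < > the Macaulay bracket. Stresses: S = 2 dPsi/dC (second
# Piola-Kirchhoff), sigma = J^{-1} F S F^T (Cauchy).

# Fast internal core shared by strain_energy()/pk2_stress() and the
# material-point drivers; no SPD validation (callers validate once).
# fibers: list of fiber_family; D: numeric damage per family.
.energy_core <- function(C, fibers, D, p) {
  I1 <- C[1, 1] + C[2, 2] + C[3, 3]
  cofC <- cof3(C)
  I3 <- C[1, 1] * cofC[1, 1] + C[1, 2] * cofC[1, 2] + C[1, 3] * cofC[1, 3]
  trcof <- cofC[1, 1] + cofC[2, 2] + cofC[3, 3]
  nf <- length(fibers)
  K3 <- numeric(nf)
  arg <- numeric(nf)      # damaged fibre argument
  arg0 <- numeric(nf)     # effective (undamaged) argument
  for (i in seq_len(nf)) {
    K3[i] <- trcof - sum(cofC * fibers[[i]]$M)
    base <- p$kappa * I1 + (1 - 1.5 * p$kappa) * K3[i]
    arg[i] <- (1 - D[i]) * base - 2
    arg0[i] <- base - 2
  }
  psi_ti <- ifelse(arg > 0, p$alpha1 * arg^p$alpha2, 0)
  psi_ti0 <- ifelse(arg0 > 0, p$alpha1 * arg0^p$alpha2, 0)
  J13 <- I3^(1 / 3)
  list(I1 = I1, I3 = I3, cofC = cofC, K3 = K3, arg = arg, arg0 = arg0,
       psi_iso = p$c1 * (I1 / J13 - 3),
       psi_vol = p$eps1 * (I3^p$eps2 + I3^(-p$eps2) - 2),
       psi_ti = psi_ti, psi_ti0 = psi_ti0)
}

.pk2_core <- function(C, fibers, D, p) {
  e <- .energy_core(C, fibers, D, p)
  I3 <- e$I3
  Cinv <- e$cofC / I3
  Id <- diag(3)
  # isochoric Neo-Hookean part: 2 c1 I3^{-1/3} (1 - (I1/3) C^{-1})
  S <- 2 * p$c1 * I3^(-1 / 3) * (Id - (e$I1 / 3) * Cinv)
  # volumetric penalty: 2 eps1 eps2 (I3^{eps2} - I3^{-eps2}) C^{-1}
  S <- S + 2 * p$eps1 * p$eps2 * (I3^p$eps2 - I3^(-p$eps2)) * Cinv
  # fibre parts, tension-only (Macaulay); derivative of K3 uses
  # dK3/dC = I3 [ tr(C^{-1} B) C^{-1} - C^{-1} B C^{-1} ],  B = 1 - M
  for (i in seq_along(fibers)) {
    if (e$arg[i] > 0) {
      B <- Id - fibers[[i]]$M
      CB <- Cinv %*% B
      dK3 <- I3 * (sum(diag(CB)) * Cinv - CB %*% Cinv)
      dK3 <- (dK3 + t(dK3)) / 2
      coef <- 2 * p$alpha1 * p$alpha2 * e$arg[i]^(p$alpha2 - 1) * (1 - D[i])
      S <- S + coef * (p$kappa * Id + (1 - 1.5 * p$kappa) * dK3)
    }
  }
  (S + t(S)) / 2
}

check_fibers_damage <- function(fibers, D) {
  stopifnot(is.list(fibers), length(D) == length(fibers))
  if (any(!is.finite(D)) || any(D < 0) || any(D >= 1)) {
    stop("damage values D must lie in [0, 1)", call. = FALSE)
  }
  for (f in fibers) {
    if (!inherits(f, "fiber_family")) {
      stop("fibers must be a list of fiber_family objects", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Strain-energy breakdown
#'
#' Evaluates the total strain energy and its parts at a deformation state
#' `C` for two (or more) fibre families with per-family damage `D`.
#' `psi_ti_effective` is the fictitiously undamaged fibre energy (the
#' damaged term evaluated at `D = 0`), the quantity driving the damage
#' internal variables.
#'
#' @param C 3x3 symmetric positive definite right Cauchy-Green tensor.
#' @param fibers List of [fiber_family()] objects.
#' @param D Numeric damage values in \[0, 1), one per family.
#' @param params [material_params()].
#' @return List of class `energy_breakdown` with `psi_iso`, `psi_vol`,
#'   `psi_ti`, `psi_ti_effective` (vectors per family, kPa) and
#'   `psi_total`.
#' @export
strain_energy <- function(C, fibers, D, params) {
  check_spd(C)
  check_fibers_damage(fibers, D)
  e <- .energy_core(C, fibers, D, params)
  structure(list(psi_iso = e$psi_iso, psi_vol = e$psi_vol,
                 psi_ti = e$psi_ti, psi_ti_effective = e$psi_ti0,
                 psi_total = e$psi_iso + e$psi_vol + sum(e$psi_ti)),
            class = "energy_breakdown")
}

#' Second Piola-Kirchhoff stress
#'
#' Analytic stress \eqn{S = 2\,\partial\Psi/\partial C} (kPa). All parts
#' vanish at the reference state `C = I`; the fibre parts switch on only
#' when the damaged fibre argument is positive (tension-only response).
#'
#' @inheritParams strain_energy
#' @return 3x3 symmetric stress tensor in kPa.
#' @export
pk2_stress <- function(C, fibers, D, params) {
  check_spd(C)
  check_fibers_damage(fibers, D)
  .pk2_core(C, fibers, D, params)
}

#' Cauchy stress from a second Piola-Kirchhoff stress
#'
#' \eqn{\sigma = (\det F)^{-1} F S F^T} (kPa).
#'
#' @param F 3x3 deformation gradient with positive determinant.
#' @param S 3x3 symmetric second Piola-Kirchhoff stress (kPa).
#' @return 3x3 symmetric Cauchy stress (kPa).
#' @export
cauchy_stress <- function(F, S) {
  check_tensor3(F, "F")
  check_tensor3(S, "S")
  J <- det(F)
  if (J <= 0) stop("invalid deformation: det(F) must be positive",
                   call. = FALSE)
  sig <- F %*% S %*% t(F) / J
  (sig + t(sig)) / 2
}

# Symmetric-pair (Voigt) ordering used by tangent_numeric(): the six
# independent components of a symmetric tensor in the order
# 11, 22, 33, 12, 13, 23.
voigt_pairs <- function() {
  list(c(1L, 1L), c(2L, 2L), c(3L, 3L), c(1L, 2L), c(1L, 3L), c(2L, 3L))
}

#' Numerical material tangent (frozen damage)
#'
#' Central finite differences of [pk2_stress()] in `C`, with the damage
#' variables held fixed during differentiation. Returned as a 6x6 matrix
#' `CC[p, q] = dS_p / dC_q` in the symmetric-pair ordering
#' (11, 22, 33, 12, 13, 23); for off-diagonal columns both symmetric
#' entries of `C` are perturbed and the column is halved, so `CC` carries
#' the plain tensor components \eqn{2\,\partial^2\Psi/\partial C \partial C}
#' and is symmetric (major symmetry). A symmetric stress increment is
#' predicted by `dS_voigt = CC %*% dC_voigt` with the off-diagonal entries
#' of `dC_voigt` doubled (engineering-style strain vector).
#'
#' @inheritParams strain_energy
#' @param h Relative finite-difference step.
#' @return 6x6 numeric matrix (kPa).
#' @export
tangent_numeric <- function(C, fibers, D, params, h = 1e-6) {
  check_spd(C)
  check_fibers_damage(fibers, D)
  pairs <- voigt_pairs()
  CC <- matrix(0, 6, 6)
  for (q in 1:6) {
    kl <- pairs[[q]]
    step <- h * (1 + abs(C[kl[1], kl[2]]))
    dC <- matrix(0, 3, 3)
    dC[kl[1], kl[2]] <- step
    dC[kl[2], kl[1]] <- step      # keep the perturbed C symmetric
    Sp <- .pk2_core(C + dC, fibers, D, params)
    Sm <- .pk2_core(C - dC, fibers, D, params)
    dS <- (Sp - Sm) / (2 * step)
    col <- vapply(pairs, function(ij) dS[ij[1], ij[2]], numeric(1))
    CC[, q] <- if (kl[1] == kl[2]) col else col / 2
  }
  CC
}
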