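# Tensor kinematics for 3x3 deformation states: right Cauchy-Green tensor,
# polyconvex invariants (I1, I3, cofC, K3), Macaulay bracket.

#' Macaulay bracket (positive part)
#'
#' \eqn{\langle x \rangle = (x + |x|)/2}, i.e. `max(x, 0)` applied
#' elementwise. Used to gate tension-only fibre response and to filter
#' positive energy rates in the damage evolution law.
#'
#' @param x Numeric vector; must be finite.
#' @return Numeric vector of the same length with negative entries zeroed.
#' @export
#' @examples
#' macaulay(c(-3, 0, 2.5))
macaulay <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("macaulay(): input must be finite numeric", call. = FALSE)
  }
  (x + abs(x)) / 2
}

#' Right Cauchy-Green deformation tensor
#'
#' Computes \eqn{C = F^T F} from a deformation gradient `F` with positive
#' determinant. `C` is symmetric positive definite whenever `F` is
#' invertible.
#'
#' @param F 3x3 deformation gradient, `det(F) > 0`.
#' @return 3x3 symmetric matrix `C`.
#' @export
#' @examples
#' right_cauchy_green(diag(c(2, 1 / sqrt(2), 1 / sqrt(2))))
right_cauchy_green <- function(F) {
  check_tensor3(F, "F")
  if (det(F) <= 0) {
    stop("invalid deformation: det(F) must be positive", call. = FALSE)
  }
  C <- crossprod(F)           # F^T F, symmetric by construction
  (C + t(C)) / 2
}

# 3x3 cofactor matrix by explicit adjugate (closed form, no factorization).
# For symmetric C this equals cof(C) = det(C) * C^{-1}.
cof3 <- function(A) {
  matrix(c(
    A[2, 2] * A[3, 3] - A[2, 3] * A[3, 2],
    A[2, 3] * A[3, 1] - A[2, 1] * A[3, 3],
    A[2, 1] * A[3, 2] - A[2, 2] * A[3, 1],
    A[1, 3] * A[3, 2] - A[1, 2] * A[3, 3],
    A[1, 1] * A[3, 3] - A[1, 3] * A[3, 1],
    A[1, 2] * A[3, 1] - A[1, 1] * A[3, 2],
    A[1, 2] * A[2, 3] - A[1, 3] * A[2, 2],
    A[1, 3] * A[2, 1] - A[1, 1] * A[2, 3],
    A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
  ), 3, 3, byrow = TRUE)
}

# Inverse of a symmetric 3x3 via the adjugate; deterministic and fast.
inv3_sym <- function(A, detA = det(A)) {
  cof3(A) / detA
}

check_tensor3 <- function(A, name) {
  if (!is.matrix(A) || !identical(dim(A), c(3L, 3L)) || any(!is.finite(A))) {
    stop(sprintf("invalid deformation: %s must be a finite 3x3 matrix", name),
         call. = FALSE)
  }
  invisible(A)
}

# SPD validation: symmetric eigenvalue check, tolerance 1e-12 on the minimum
# eigenvalue. Failures raise; values are never clamped.
check_spd <- function(C, name = "C", tol = 1e-12) {
  check_tensor3(C, name)
  if (max(abs(C - t(C))) > 1e-8 * (1 + max(abs(C)))) {
    stop(sprintf("invalid deformation: %s must be symmetric", name),
         call. = FALSE)
  }
  ev <- eigen((C + t(C)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= tol) {
    stop(sprintf("invalid deformation: %s must be positive definite", name),
         call. = FALSE)
  }
  invisible(C)
}

#' Polyconvex invariants of the right Cauchy-Green tensor
#'
#' Returns the invariants entering the strain-energy function:
#' \eqn{I_1 = \mathrm{tr}\,C}, \eqn{I_3 = \det C}, the cofactor
#' \eqn{\mathrm{cof}\,C = \det C \cdot C^{-1}}, and for each fibre
#' structural tensor \eqn{M_i = A_i \otimes A_i} the anisotropic invariant
#' \eqn{K_3^i = \mathrm{tr}[\mathrm{cof}\,C \,(1 - M_i)]}, which measures
#' the areal stretch of planes containing the fibre and is the polyconvex
#' building block of the fibre energy.
#'
#' @param C 3x3 symmetric positive definite matrix.
#' @param M list of 3x3 structural tensors (rank-one, unit trace); may be
#'   empty.
#' @return A list with components `I1`, `I3`, `cofC` (3x3), and `K3`
#'   (numeric vector, one entry per structural tensor).
#' @export
#' @examples
#' invariants(diag(3), list(diag(c(1, 0, 0))))
invariants <- function(C, M = list()) {
  check_spd(C)
  I3 <- det(C)
  cofC <- cof3(C)   # = det(C) C^{-1} for symmetric C
  K3 <- vapply(M, function(Mi) {
    check_tensor3(Mi, "M")
    sum(diag(cofC)) - sum(cofC * Mi)   # tr(cofC) - cofC : M
  }, numeric(1))
  list(I1 = sum(diag(C)), I3 = I3, cofC = cofC, K3 = K3)
}
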