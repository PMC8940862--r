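# Fibre families and their construction on a spherical aneurysm dome.
# At a surface point G of a sphere centred at O with pole Z, two collagen
# fibre families lie in the tangent plane, symmetric about the
# latitude-like tangent direction zeta1 at +/- beta_f.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

norm3 <- function(v) sqrt(sum(v * v))

#' Fibre family
#'
#' A unit fibre direction `A` and its structural tensor
#' \eqn{M = A \otimes A} (rank one, idempotent, unit trace).
#'
#' @param A Numeric 3-vector; normalised internally, must be non-zero.
#' @return An object of class `fiber_family` with components `A` and `M`.
#' @export
fiber_family <- function(A) {
  stopifnot(is.numeric(A), length(A) == 3, all(is.finite(A)))
  n <- norm3(A)
  if (n < 1e-14) stop("fibre direction must be non-zero", call. = FALSE)
  A <- A / n
  structure(list(A = A, M = tcrossprod(A)), class = "fiber_family")
}

#' Tangent frame at a point of a sphere
#'
#' For sphere centre `O`, pole `Z` and surface point `G`, builds the
#' tangent directions \eqn{\zeta_1 = V_{OZ} \times V_{OG}} (latitude-like)
#' and \eqn{\zeta_2 = V_{OG} \times \zeta_1} (meridian-like), both
#' normalised. When `G` lies at a pole (\eqn{V_{OG} \parallel V_{OZ}}) the
#' cross product degenerates and `zeta1` falls back to a fixed tangent
#' direction, \eqn{(1,1,0)/\sqrt{2}} by default.
#'
#' @param O,Z,G Numeric 3-vectors: centre, pole and surface point (cm).
#' @param parallel_fallback Unit vector used for `zeta1` at the poles.
#' @return An object of class `sphere_frame` with `zeta1`, `zeta2`, and the
#'   outward radial unit vector `radial`.
#' @export
sphere_frame <- function(O, Z, G,
                         parallel_fallback = c(1, 1, 0) / sqrt(2)) {
  stopifnot(length(O) == 3, length(Z) == 3, length(G) == 3)
  v_oz <- Z - O
  v_og <- G - O
  if (norm3(v_og) < 1e-14 || norm3(v_oz) < 1e-14) {
    stop("degenerate points: G and Z must differ from O", call. = FALSE)
  }
  cr <- cross3(v_oz, v_og)
  if (norm3(cr) < 1e-10 * norm3(v_oz) * norm3(v_og)) {
    zeta1 <- parallel_fallback / norm3(parallel_fallback)
  } else {
    zeta1 <- cr / norm3(cr)
  }
  zeta2 <- cross3(v_og, zeta1)
  zeta2 <- zeta2 / norm3(zeta2)
  structure(list(zeta1 = zeta1, zeta2 = zeta2, radial = v_og / norm3(v_og)),
            class = "sphere_frame")
}

#' Symmetric fibre families in a tangent frame
#'
#' \eqn{A_{1,2} = \cos(\beta_f)\,\zeta_1 \pm \sin(\beta_f)\,\zeta_2}: two
#' unit directions in the tangent plane, symmetric about `zeta1`, with
#' included angle \eqn{2\beta_f}.
#'
#' @param frame A [sphere_frame()].
#' @param beta_f Half-angle between the families, degrees, in (0, 90).
#' @return List of two [fiber_family()] objects.
#' @export
fiber_families <- function(frame, beta_f) {
  stopifnot(inherits(frame, "sphere_frame"))
  if (!is.finite(beta_f) || beta_f <= 0 || beta_f >= 90) {
    stop("beta_f must lie in (0, 90) degrees", call. = FALSE)
  }
  b <- beta_f * pi / 180
  list(fiber_family(cos(b) * frame$zeta1 + sin(b) * frame$zeta2),
       fiber_family(cos(b) * frame$zeta1 - sin(b) * frame$zeta2))
}

#' Fibre field over a sphere
#'
#' Samples `n` points on a sphere with a deterministic Fibonacci lattice
#' and constructs the two tangent fibre families at each point.
#'
#' @param n Number of surface points.
#' @param radius Sphere radius (cm).
#' @param center Sphere centre, 3-vector (cm).
#' @param pole Pole direction, 3-vector (normalised internally).
#' @param beta_f Half-angle of the fibre families (degrees).
#' @return Data frame with point coordinates `x, y, z` and the two unit
#'   fibre directions `a1x..a1z`, `a2x..a2z`.
#' @export
fiber_field <- function(n, radius = 0.5, center = c(0, 0, 0),
                        pole = c(0, 0, 1), beta_f = 40) {
  stopifnot(n >= 1, radius > 0)
  i <- seq_len(n) - 0.5
  golden <- pi * (3 - sqrt(5))
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  th <- golden * i
  pts <- cbind(r * cos(th), r * sin(th), z) * radius
  pts <- sweep(pts, 2, center, `+`)
  Z <- center + pole / norm3(pole) * radius
  out <- matrix(NA_real_, n, 9)
  for (k in seq_len(n)) {
    fr <- sphere_frame(center, Z, pts[k, ])
    fam <- fiber_families(fr, beta_f)
    out[k, ] <- c(pts[k, ], fam[[1]]$A, fam[[2]]$A)
  }
  df <- as.data.frame(out)
  names(df) <- c("x", "y", "z", "a1x", "a1y", "a1z", "a2x", "a2y", "a2z")
  df
}

# Fibre pair for the uniaxial cube test: both families in the plane spanned
# by the loading axis (e1) and the first lateral axis (e2), at +/- beta_f
# to the loading axis, so the included angle is 2 beta_f.
#' Fibre families for the uniaxial cube test
#'
#' Places the two families in the e1-e2 plane at \eqn{\pm\beta_f} to the
#' loading axis e1. The response is orthotropic: the in-plane and
#' out-of-plane lateral stretches differ and are solved for independently.
#'
#' @param beta_f Half-angle to the loading axis (degrees).
#' @return List of two [fiber_family()] objects.
#' @export
cube_fibers <- function(beta_f = 39.87) {
  b <- beta_f * pi / 180
  list(fiber_family(c(cos(b), sin(b), 0)),
       fiber_family(c(cos(b), -sin(b), 0)))
}
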