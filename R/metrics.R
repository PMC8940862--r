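# Time-averaged wall metrics: TAWSS, generic time averages, relative
# percentage change between degraded and non-degraded fields, von Mises
# stress, and Green-Lagrange strain magnitude.

#' Time-averaged wall shear stress (TAWSS)
#'
#' \eqn{\mathrm{TAWSS} = (1/T) \int_0^T |\tau_w(t)|\,dt}: the average
#' magnitude of the wall-shear-stress vector over one cardiac cycle,
#' computed by the trapezoidal rule on the sampled magnitudes.
#'
#' @param t Sample times (s), strictly increasing, spanning one period.
#' @param tau Matrix with one row per sample and 3 columns (vector
#'   components, dyn/cm^2), or a numeric vector of magnitudes.
#' @param T Period (s); defaults to the sampled span. A warning is issued
#'   when the samples do not span the stated period.
#' @return Non-negative scalar (dyn/cm^2).
#' @export
tawss <- function(t, tau, T = t[length(t)] - t[1]) {
  if (length(t) < 2) stop("need at least 2 samples", call. = FALSE)
  if (any(diff(t) <= 0)) stop("times must be strictly increasing",
                              call. = FALSE)
  if (is.matrix(tau)) {
    stopifnot(nrow(tau) == length(t), ncol(tau) == 3)
    mag <- sqrt(rowSums(tau^2))
  } else {
    stopifnot(length(tau) == length(t))
    mag <- abs(tau)
  }
  span <- t[length(t)] - t[1]
  if (abs(span - T) > 1e-6 * T) {
    warning("samples do not span one full period; TAWSS normalised by T")
  }
  trapz(t, mag) / T
}

#' TAWSS over a long-format field series
#'
#' Applies [tawss()] per position to a long-format data frame with columns
#' `position_id`, `t`, `vx`, `vy`, `vz`.
#'
#' @param df Long-format data frame of wall-shear vectors.
#' @param T Period (s).
#' @return Data frame with columns `position_id`, `tawss`.
#' @export
tawss_field <- function(df, T) {
  stopifnot(all(c("position_id", "t", "vx", "vy", "vz") %in% names(df)))
  ids <- unique(df$position_id)
  vals <- vapply(ids, function(id) {
    d <- df[df$position_id == id, ]
    d <- d[order(d$t), ]
    tawss(d$t, as.matrix(d[, c("vx", "vy", "vz")]), T)
  }, numeric(1))
  data.frame(position_id = ids, tawss = vals)
}

#' Time average of a scalar series
#'
#' \eqn{(1/T)\int_0^T f\,dt} by the trapezoidal rule; used for near-wall
#' pressure, von Mises stress and strain magnitude.
#'
#' @param t Sample times (s), strictly increasing.
#' @param x Scalar samples.
#' @param T Period (s); defaults to the sampled span.
#' @return Scalar average.
#' @export
time_average <- function(t, x, T = t[length(t)] - t[1]) {
  if (length(t) < 2 || length(x) != length(t)) {
    stop("need matching t and x with at least 2 samples", call. = FALSE)
  }
  if (any(diff(t) <= 0)) stop("times must be strictly increasing",
                              call. = FALSE)
  trapz(t, x) / T
}

#' Relative percentage change between degraded and baseline fields
#'
#' \eqn{\Delta f = (f^d - f^{nd}) / f^{nd} \times 100} per position.
#' Positions whose baseline magnitude falls below `floor` are masked
#' (returned as `NA`) rather than producing unbounded ratios.
#'
#' @param f_d Degraded field values.
#' @param f_nd Non-degraded (baseline) field values, same length.
#' @param floor Non-negative baseline magnitude below which the change is
#'   undefined; default 1e-8 (field units).
#' @return Numeric vector of percentages, `NA` where masked.
#' @export
relative_change <- function(f_d, f_nd, floor = 1e-8) {
  if (length(f_d) != length(f_nd)) stop("field shapes differ", call. = FALSE)
  stopifnot(floor >= 0)
  out <- (f_d - f_nd) / f_nd * 100
  out[abs(f_nd) < floor] <- NA_real_
  out
}

#' Von Mises equivalent stress
#'
#' \eqn{\sigma_{vM} = \sqrt{3/2\, \mathrm{dev}\,\sigma : \mathrm{dev}\,\sigma}}:
#' zero for hydrostatic states, equal to the axial stress for uniaxial
#' tension, and \eqn{\sqrt{3}\,\tau} for pure shear.
#'
#' @param sigma 3x3 symmetric stress tensor (kPa); asymmetry beyond 1e-10
#'   (relative) is rejected.
#' @return Non-negative scalar (kPa).
#' @export
von_mises <- function(sigma) {
  check_tensor3(sigma, "sigma")
  if (max(abs(sigma - t(sigma))) > 1e-10 * (1 + max(abs(sigma)))) {
    stop("stress tensor must be symmetric", call. = FALSE)
  }
  dev <- sigma - diag(3) * sum(diag(sigma)) / 3
  sqrt(1.5 * sum(dev * dev))
}

#' Green-Lagrange strain magnitude
#'
#' Frobenius norm of the Green-Lagrange strain \eqn{E = (C - I)/2}. This
#' is the package's definition of "strain magnitude" for time-averaged
#' wall strain reporting.
#'
#' @param C 3x3 right Cauchy-Green tensor, or a deformation gradient `F`
#'   when `from_F = TRUE`.
#' @param from_F Interpret the input as `F` and form `C` first.
#' @return Non-negative scalar (dimensionless).
#' @export
strain_magnitude <- function(C, from_F = FALSE) {
  if (from_F) C <- right_cauchy_green(C)
  check_tensor3(C, "C")
  E <- (C - diag(3)) / 2
  sqrt(sum(E * E))
}
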