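# Material and damage parameter containers, the packaged carotid profile,
# unit-conversion constants, and YAML/JSON config I/O.

#' Unit conversion constants
#'
#' Solid-side stresses and energies are carried in kPa; the Windkessel module
#' works in CGS (dyn/cm^2) and reports pressures in mmHg.
#'
#' @format Named numeric constants:
#' \describe{
#'   \item{DYN_PER_CM2_PER_KPA}{1 kPa = 1e4 dyn/cm^2}
#'   \item{DYN_PER_CM2_PER_MMHG}{1 mmHg = 1333.22 dyn/cm^2}
#'   \item{KPA_PER_MMHG}{1 mmHg = 0.133322 kPa}
#' }
#' @name unit-constants
#' @aliases DYN_PER_CM2_PER_KPA DYN_PER_CM2_PER_MMHG KPA_PER_MMHG
#' @export DYN_PER_CM2_PER_KPA DYN_PER_CM2_PER_MMHG KPA_PER_MMHG
DYN_PER_CM2_PER_KPA <- 1e4
#' @rdname unit-constants
DYN_PER_CM2_PER_MMHG <- 1333.22
#' @rdname unit-constants
KPA_PER_MMHG <- 0.133322

#' Elastic material parameters
#'
#' Constants of the strain-energy function: a Neo-Hookean ground matrix
#' (elastin), a volumetric penalty enforcing near-incompressibility, and a
#' tension-only transversely isotropic fibre term (collagen) with dispersion
#' parameter `kappa`.
#'
#' @param c1 Neo-Hookean matrix stiffness (kPa), > 0.
#' @param eps1 Volumetric penalty magnitude (kPa), > 0.
#' @param eps2 Volumetric penalty exponent (dimensionless), > 0.
#' @param alpha1 Fibre stiffness scale (kPa), > 0.
#' @param alpha2 Fibre stiffening exponent (dimensionless), > 1 so the
#'   tension-only power term is continuously differentiable at recruitment.
#' @param kappa Fibre dispersion parameter (dimensionless), in \[0, 1/3\].
#' @param beta_f Fibre angle from the circumferential-like tangent direction
#'   (degrees), in (0, 90).
#' @return An object of class `material_params`.
#' @export
#' @examples
#' material_params()  # human carotid defaults
material_params <- function(c1 = 9.02, eps1 = 499.8, eps2 = 2.4,
                            alpha1 = 1400, alpha2 = 2.2, kappa = 1e-8,
                            beta_f = 39.87) {
  stopifnot(c1 > 0, eps1 > 0, eps2 > 0, alpha1 > 0, alpha2 > 1,
            kappa >= 0, kappa <= 1 / 3, beta_f > 0, beta_f < 90)
  structure(list(c1 = c1, eps1 = eps1, eps2 = eps2, alpha1 = alpha1,
                 alpha2 = alpha2, kappa = kappa, beta_f = beta_f),
            class = "material_params")
}

#' Damage evolution parameters
#'
#' Constants of the two exponential saturation laws. `D_inf` is the limit
#' damage value; `gamma_inf` is the value of the load-level internal variable
#' at which the fixed-load ceiling reaches the fraction `r_inf` of `D_inf`
#' (degradation intensity); `beta_s` is the value of the accumulated-energy
#' internal variable at which damage reaches the fraction `r_s` of its
#' ceiling (degradation rate). `r_s` and `r_inf` are interpretation
#' constants, not material parameters.
#'
#' @param D_inf Limit damage (dimensionless), in \[0, 1).
#' @param gamma_inf Load-level saturation scale (kPa), > 0.
#' @param beta_s Accumulation saturation scale (kPa), > 0.
#' @param r_s,r_inf Saturation fractions in (0, 1); default 0.99 each.
#' @return An object of class `damage_params`.
#' @export
damage_params <- function(D_inf = 0.96, gamma_inf = 17.98, beta_s = 0.06,
                          r_s = 0.99, r_inf = 0.99) {
  stopifnot(D_inf >= 0, D_inf < 1, gamma_inf > 0, beta_s > 0,
            r_s > 0, r_s < 1, r_inf > 0, r_inf < 1)
  structure(list(D_inf = D_inf, gamma_inf = gamma_inf, beta_s = beta_s,
                 r_s = r_s, r_inf = r_inf),
            class = "damage_params")
}

#' Packaged parameter profiles
#'
#' `material_profile("carotid_table1")` returns the human carotid artery
#' parameter set used throughout the examples: material and damage
#' constants for the aneurysmal wall.
#'
#' @param name Profile name; currently only `"carotid_table1"`.
#' @return A list with components `material` (`material_params`) and
#'   `damage` (`damage_params`).
#' @export
material_profile <- function(name = "carotid_table1") {
  switch(name,
    carotid_table1 = list(material = material_params(),
                          damage = damage_params()),
    stop(sprintf("unknown parameter profile '%s'", name), call. = FALSE)
  )
}

#' Read a run configuration file
#'
#' Reads a YAML configuration with sections `material`, `damage`,
#' `protocol`, and `windkessel`. Unknown sections or keys are rejected so
#' that typos never silently fall back to defaults. Missing keys take the
#' packaged carotid defaults.
#'
#' @param path Path to a YAML file.
#' @return A list with `material`, `damage`, `protocol`, `windkessel`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("material", "damage", "protocol", "windkessel")
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop(sprintf("unknown config section(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  fill <- function(section, ctor) {
    given <- raw[[section]]
    ok <- names(formals(ctor))
    bad <- setdiff(names(given), ok)
    if (length(bad)) {
      stop(sprintf("unknown key(s) in [%s]: %s", section,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    do.call(ctor, given %||% list())
  }
  proto_defaults <- list(load_max_ramp = 100, load_max_cyclic = 20,
                        n_cycles = 10, steps_per_segment = 200,
                        activate_after_cycle = 1)
  proto <- raw$protocol %||% list()
  badp <- setdiff(names(proto), names(proto_defaults))
  if (length(badp)) {
    stop(sprintf("unknown key(s) in [protocol]: %s",
                 paste(badp, collapse = ", ")), call. = FALSE)
  }
  wk_defaults <- list(R_tot = 5.7e4, k_d = 0.9, C = 1e-6,
                      Q_mean = 2.3, Q_min = 1.5, Q_max = 3.45,
                      period = 0.8, n_samples = 200, n_cycles = 10, seed = 1)
  wk <- raw$windkessel %||% list()
  badw <- setdiff(names(wk), names(wk_defaults))
  if (length(badw)) {
    stop(sprintf("unknown key(s) in [windkessel]: %s",
                 paste(badw, collapse = ", ")), call. = FALSE)
  }
  list(material = fill("material", material_params),
       damage = fill("damage", damage_params),
       protocol = utils::modifyList(proto_defaults, proto),
       windkessel = utils::modifyList(wk_defaults, wk))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.material_params <- function(x, ...) {
  cat("Material parameters (kPa unless dimensionless):\n")
  cat(sprintf("  c1 = %g, eps1 = %g, eps2 = %g, alpha1 = %g, alpha2 = %g\n",
              x$c1, x$eps1, x$eps2, x$alpha1, x$alpha2))
  cat(sprintf("  kappa = %g, beta_f = %g deg\n", x$kappa, x$beta_f))
  invisible(x)
}

#' @export
print.damage_params <- function(x, ...) {
  cat(sprintf(
    "Damage parameters: D_inf = %g, gamma_inf = %g kPa, beta_s = %g kPa (r_s = %g, r_inf = %g)\n",
    x$D_inf, x$gamma_inf, x$beta_s, x$r_s, x$r_inf))
  invisible(x)
}
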