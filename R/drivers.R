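# Quasi-static material-point drivers for the uniaxial cube test.
#
# The deformation is homogeneous and diagonal, F = diag(l1, l2, l3), with
# the two fibre families in the e1-e2 plane at +/- beta_f to the loading
# axis e1; the +/- symmetry cancels all shear stress components, so the
# diagonal ansatz is exact for this boundary-value problem. "Load" is the
# axial first Piola-Kirchhoff (nominal) traction on the cube face; the
# lateral faces are traction-free. Damage is frozen during each Newton
# solve and updated once on convergence.

#' Fresh material-point state
#'
#' Reference state of the cube test: unit stretches, two inactive damage
#' states.
#'
#' @return An object of class `material_point_state` with components
#'   `lambda` (length-3 stretch vector) and `damage` (list of two
#'   [damage_state()]).
#' @export
material_point_state <- function() {
  structure(list(lambda = c(1, 1, 1),
                 damage = list(damage_state(), damage_state())),
            class = "material_point_state")
}

# Nominal (first Piola-Kirchhoff) diagonal stresses for diagonal stretches.
.nominal_residual <- function(lambda, target, fibers, D, params) {
  C <- diag(lambda^2)
  S <- .pk2_core(C, fibers, D, params)
  P <- lambda * diag(S)        # P_ii = lambda_i * S_ii for diagonal F
  c(P[1] - target, P[2], P[3])
}

#' Stress-controlled uniaxial solve
#'
#' Newton iteration on the three principal stretches so that the axial
#' nominal stress equals `target_load` and both lateral nominal stresses
#' vanish (residual tolerance 1e-10 kPa). The Jacobian is assembled by
#' forward finite differences of the residual (step 1e-7); a step-halving
#' line search guards against overshooting the fibre recruitment kink.
#' Damage values are held at their current state during the iteration and
#' the two damage states are advanced once with the converged effective
#' fibre energies.
#'
#' @param target_load Axial nominal traction (kPa), >= 0.
#' @param state A [material_point_state()] (previous converged state; its
#'   stretches seed the iteration).
#' @param params [material_params()].
#' @param fibers List of two [fiber_family()] (see [cube_fibers()]).
#' @param dparams [damage_params()].
#' @param evolve_damage If `FALSE` the damage states are not advanced
#'   (pure hyperelastic backbone).
#' @param tol Residual tolerance (kPa).
#' @param maxit Maximum Newton iterations.
#' @return The updated `material_point_state` with fields `sigma_axial`
#'   (Cauchy, kPa), `psi_eff` (per-family effective fibre energy, kPa) and
#'   `load` attached.
#' @export
solve_stress_controlled <- function(target_load, state, params, fibers,
                                    dparams = damage_params(),
                                    evolve_damage = TRUE,
                                    tol = 1e-10, maxit = 50L) {
  stopifnot(inherits(state, "material_point_state"), target_load >= 0)
  D <- c(state$damage[[1]]$D, state$damage[[2]]$D)
  lam <- state$lambda
  r <- .nominal_residual(lam, target_load, fibers, D, params)
  h <- 1e-7
  for (it in seq_len(maxit)) {
    if (max(abs(r)) < tol) break
    J <- matrix(0, 3, 3)
    for (k in 1:3) {
      lp <- lam
      lp[k] <- lp[k] + h
      J[, k] <- (.nominal_residual(lp, target_load, fibers, D, params) - r) / h
    }
    dlam <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(dlam)) {
      stop("stepping error: singular Jacobian; use smaller load increments",
           call. = FALSE)
    }
    # line search: halve until the residual norm does not increase
    alpha <- 1
    repeat {
      lam_try <- lam + alpha * dlam
      if (all(lam_try > 0.05)) {
        r_try <- .nominal_residual(lam_try, target_load, fibers, D, params)
        if (max(abs(r_try)) < max(abs(r)) || alpha < 1 / 64) break
      }
      alpha <- alpha / 2
      if (alpha < 1e-6) {
        stop("stepping error: line search failed; use smaller load increments",
             call. = FALSE)
      }
    }
    lam <- lam_try
    r <- r_try
    if (it == maxit && max(abs(r)) >= tol) {
      stop("stepping error: no convergence in 50 iterations; use smaller load increments",
           call. = FALSE)
    }
  }
  if (max(abs(r)) >= tol) {
    stop("stepping error: no convergence; use smaller load increments",
         call. = FALSE)
  }
  C <- diag(lam^2)
  e <- .energy_core(C, fibers, D, params)
  psi_eff <- e$psi_ti0
  if (evolve_damage) {
    for (i in 1:2) {
      state$damage[[i]] <- damage_update(state$damage[[i]], psi_eff[i],
                                         dparams)
    }
  }
  state$lambda <- lam
  state$sigma_axial <- lam[1]^2 * .pk2_core(C, fibers,
                                            c(state$damage[[1]]$D,
                                              state$damage[[2]]$D),
                                            params)[1, 1] / prod(lam)
  state$psi_eff <- psi_eff
  state$load <- target_load
  state
}

# Lateral equilibrium at fixed axial stretch: Newton on (l2, l3) so both
# lateral nominal stresses vanish; used by the recruitment-stretch solve.
.lateral_solve <- function(lam1, lat_guess, fibers, D, params,
                           tol = 1e-10, maxit = 60L) {
  lat <- lat_guess
  res <- function(lat) {
    .nominal_residual(c(lam1, lat), 0, fibers, D, params)[2:3]
  }
  r <- res(lat)
  h <- 1e-7
  for (it in seq_len(maxit)) {
    if (max(abs(r)) < tol) break
    J <- matrix(0, 2, 2)
    for (k in 1:2) {
      lp <- lat
      lp[k] <- lp[k] + h
      J[, k] <- (res(lp) - r) / h
    }
    dlat <- solve(J, -r)
    alpha <- 1
    repeat {
      lat_try <- lat + alpha * dlat
      if (all(lat_try > 0.05)) {
        r_try <- res(lat_try)
        if (max(abs(r_try)) < max(abs(r)) || alpha < 1 / 256) break
      }
      alpha <- alpha / 2
      if (alpha < 1e-8) stop("lateral solve failed to converge",
                             call. = FALSE)
    }
    lat <- lat_try
    r <- r_try
  }
  if (max(abs(r)) >= tol) {
    stop("lateral solve failed to converge", call. = FALSE)
  }
  lat
}

#' Fibre stress-free (recruitment) stretch of the damaged material
#'
#' The damage model carries remnant strain within the fibre families: with
#' damage `D > 0` the damaged fibre argument \eqn{(1-D)[\kappa I_1 +
#' (1-1.5\kappa)K_3] - 2} vanishes at an axial stretch greater than one, so
#' after unloading the fibres are stress-free over a finite stretch range
#' and only re-engage beyond it. This function returns that stretch for the
#' uniaxial cube kinematics: the axial stretch at which the first family's
#' damaged argument crosses zero, with the lateral stretches in traction-free
#' equilibrium. Returns exactly 1 for `D = 0`.
#'
#' @param D Damage values per family (the first family's argument is
#'   tracked; the cube-test families are symmetric).
#' @param params [material_params()].
#' @param fibers Fibre families; default [cube_fibers()].
#' @param lambda_max Upper bracket for the root search.
#' @return Axial recruitment stretch (>= 1).
#' @export
fiber_recruitment_stretch <- function(D, params = material_params(),
                                      fibers = cube_fibers(params$beta_f),
                                      lambda_max = 50) {
  stopifnot(all(D >= 0), all(D < 1))
  if (max(D) == 0) return(1)
  # At the recruitment point the fibre stress vanishes, so the lateral
  # equilibrium there is exactly the matrix-only one; solving the laterals
  # with the fibres disabled is exact at the crossing and avoids the
  # ill-conditioned symmetry-breaking bifurcation at fibre activation.
  arg1 <- function(lam1) {
    lat <- .lateral_solve(lam1, rep(1 / sqrt(lam1), 2), list(), numeric(0),
                          params)
    C <- diag(c(lam1, lat)^2)
    e <- .energy_core(C, fibers, D, params)
    e$arg[1]
  }
  lo <- 1
  hi <- 1.5
  while (arg1(hi) < 0 && hi < lambda_max) {
    lo <- hi
    hi <- hi * 1.5
  }
  if (hi >= lambda_max) {
    stop("fibre recruitment stretch exceeds lambda_max", call. = FALSE)
  }
  stats::uniroot(arg1, c(lo, hi), tol = 1e-10)$root
}

.record_row <- function(state, step, load, cycle = NA_integer_,
                        phase = NA_character_) {
  d1 <- state$damage[[1]]
  d2 <- state$damage[[2]]
  data.frame(step = step, cycle = cycle, phase = phase,
             load_kPa = load,
             stretch_axial = state$lambda[1],
             stretch_lat1 = state$lambda[2],
             stretch_lat2 = state$lambda[3],
             sigma_axial_kPa = state$sigma_axial,
             psi_eff1_kPa = state$psi_eff[1],
             psi_eff2_kPa = state$psi_eff[2],
             beta_tilde1_kPa = d1$beta_tilde, beta_tilde2_kPa = d2$beta_tilde,
             gamma1_kPa = d1$gamma, gamma2_kPa = d2$gamma,
             Ds1 = d1$Ds, Ds2 = d2$Ds, D1 = d1$D, D2 = d2$D)
}

#' Uniaxial ramp test
#'
#' Ramps the axial nominal load linearly from 0 to `load_max` in `steps`
#' increments. With `damage_on = TRUE` damage evolution is active from the
#' start of the ramp (the reference state is the physiological limit);
#' with `damage_on = FALSE` the run is the pure hyperelastic backbone.
#'
#' @param load_max Final axial nominal load (kPa); default 100.
#' @param steps Number of load increments; default 1000.
#' @param params [material_params()].
#' @param fibers Fibre families; default [cube_fibers()] at the angle in
#'   `params`.
#' @param dparams [damage_params()].
#' @param damage_on Logical; activate damage evolution.
#' @return Data frame with one row per increment: load, stretches, axial
#'   Cauchy stress, per-family internal variables and damage.
#' @export
run_ramp <- function(load_max = 100, steps = 1000, params = material_params(),
                     fibers = cube_fibers(params$beta_f),
                     dparams = damage_params(), damage_on = TRUE) {
  stopifnot(load_max > 0, steps >= 2)
  state <- material_point_state()
  if (damage_on) {
    for (i in 1:2) state$damage[[i]] <- damage_activate(state$damage[[i]], 0)
  }
  loads <- seq(0, load_max, length.out = steps + 1)
  rows <- vector("list", length(loads))
  for (s in seq_along(loads)) {
    state <- solve_stress_controlled(loads[s], state, params, fibers, dparams,
                                     evolve_damage = damage_on)
    rows[[s]] <- .record_row(state, s - 1L, loads[s])
  }
  do.call(rbind, rows)
}

#' Cyclic uniaxial test with damage saturation
#'
#' Imposes `n_cycles` load cycles 0 -> `load_max` -> 0 (each segment in
#' `steps_per_segment` increments). Damage evolution is switched on at the
#' end of cycle `activate_after_cycle` (default 1), or alternatively when
#' the effective fibre energy first exceeds `activation_threshold` (kPa).
#' A cycle counts as saturated when its maximum damage exceeds the previous
#' cycle's by less than `saturation_tol`.
#'
#' @param load_max Peak nominal load per cycle (kPa); default 20.
#' @param n_cycles Number of cycles, >= 2; default 10.
#' @param steps_per_segment Increments per loading/unloading segment,
#'   >= 200; default 200.
#' @param params,fibers,dparams As in [run_ramp()].
#' @param activate_after_cycle Cycle index after which damage evolution
#'   starts; ignored when `activation_threshold` is given.
#' @param activation_threshold Optional effective-energy threshold (kPa)
#'   triggering activation.
#' @param saturation_tol Cycle-to-cycle damage increase below which a cycle
#'   is reported saturated; default 1e-6.
#' @return A list with `curves` (per-increment data frame including cycle
#'   and phase), `summary` (per-cycle: peak damage per family, the tissue
#'   stretch at zero load, the fibre-level remnant stretch from
#'   [fiber_recruitment_stretch()], and the damage increase vs the previous
#'   cycle) and `first_saturated_cycle` (integer or `NA`).
#'
#' @details The model carries remnant strain within the fibre families:
#'   after damaging cycles the fibres are stress-free up to the recruitment
#'   stretch reported as `fiber_remnant_stretch` (> 1 once damage is
#'   positive). The tissue-level stretch at exactly zero applied load
#'   (`zero_load_stretch`) returns to one, because the tension-only fibres
#'   cannot hold the ground matrix off its natural state.
#' @export
run_cyclic <- function(load_max = 20, n_cycles = 10, steps_per_segment = 200,
                       params = material_params(),
                       fibers = cube_fibers(params$beta_f),
                       dparams = damage_params(),
                       activate_after_cycle = 1,
                       activation_threshold = NULL,
                       saturation_tol = 1e-6) {
  stopifnot(load_max > 0, n_cycles >= 2, steps_per_segment >= 200)
  state <- material_point_state()
  rows <- list()
  step <- 0L
  up <- seq(0, load_max, length.out = steps_per_segment + 1)[-1]
  down <- rev(seq(0, load_max, length.out = steps_per_segment + 1))[-1]
  # reference record
  state <- solve_stress_controlled(0, state, params, fibers, dparams)
  rows[[1]] <- .record_row(state, step, 0, 0L, "ref")
  activated <- FALSE
  if (is.null(activation_threshold) && activate_after_cycle == 0) {
    for (i in 1:2) {
      state$damage[[i]] <- damage_activate(state$damage[[i]], state$psi_eff[i])
    }
    activated <- TRUE
  }
  for (cyc in seq_len(n_cycles)) {
    for (phase in c("load", "unload")) {
      targets <- if (phase == "load") up else down
      for (tg in targets) {
        state <- solve_stress_controlled(tg, state, params, fibers, dparams)
        if (!activated && !is.null(activation_threshold) &&
            max(state$psi_eff) >= activation_threshold) {
          for (i in 1:2) {
            state$damage[[i]] <- damage_activate(state$damage[[i]],
                                                 state$psi_eff[i])
          }
          activated <- TRUE
        }
        step <- step + 1L
        rows[[step + 1L]] <- .record_row(state, step, tg, cyc, phase)
      }
    }
    if (!activated && is.null(activation_threshold) &&
        cyc == activate_after_cycle) {
      for (i in 1:2) {
        state$damage[[i]] <- damage_activate(state$damage[[i]],
                                             state$psi_eff[i])
      }
      activated <- TRUE
    }
  }
  curves <- do.call(rbind, rows)
  per_cycle <- lapply(seq_len(n_cycles), function(cyc) {
    cc <- curves[!is.na(curves$cycle) & curves$cycle == cyc, ]
    last <- cc[nrow(cc), ]
    data.frame(cycle = cyc,
               D1_max = max(cc$D1), D2_max = max(cc$D2),
               zero_load_stretch = last$stretch_axial,
               fiber_remnant_stretch =
                 fiber_recruitment_stretch(c(last$D1, last$D2), params,
                                           fibers),
               peak_stretch = max(cc$stretch_axial))
  })
  summary <- do.call(rbind, per_cycle)
  dmax <- pmax(summary$D1_max, summary$D2_max)
  summary$D_increase <- c(NA, diff(dmax))
  sat <- which(!is.na(summary$D_increase) &
                 summary$D_increase < saturation_tol &
                 seq_len(n_cycles) > activate_after_cycle + 1)
  list(curves = curves, summary = summary,
       first_saturated_cycle = if (length(sat)) min(sat) else NA_integer_)
}
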