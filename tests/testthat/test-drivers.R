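p_def <- material_params()
fib <- cube_fibers()
dp <- damage_params()

test_that("stress-controlled solve recovers the reference and loads monotonically", {
  s0 <- solve_stress_controlled(0, material_point_state(), p_def, fib, dp)
  expect_equal(s0$lambda, c(1, 1, 1), tolerance = 1e-12)
  expect_equal(s0$sigma_axial, 0, tolerance = 1e-10)

  s10 <- solve_stress_controlled(10, s0, p_def, fib, dp,
                                 evolve_damage = FALSE)
  s20 <- solve_stress_controlled(20, s10, p_def, fib, dp,
                                 evolve_damage = FALSE)
  expect_gt(s10$lambda[1], 1)
  expect_gt(s20$lambda[1], s10$lambda[1])
  # converged states are traction-free laterally
  C <- diag(s20$lambda^2)
  S <- pk2_stress(C, fib, c(0, 0), p_def)
  expect_lt(max(abs(s20$lambda[2:3] * diag(S)[2:3])), 1e-9)
})

test_that("Newton solution matches an independent nested-bisection solve", {
  # oracle: bisection on the axial stretch, with the two lateral stretches
  # resolved by nested scalar bisections on the lateral nominal stresses
  target <- 15
  nominal <- function(lam) {
    S <- pk2_stress(diag(lam^2), fib, c(0, 0), p_def)
    lam * diag(S)
  }
  solve_l3 <- function(l1, l2) {
    lo <- 0.4; hi <- 1.6
    for (k in 1:50) {
      mid <- (lo + hi) / 2
      if (nominal(c(l1, l2, mid))[3] < 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  solve_l2 <- function(l1) {
    lo <- 0.4; hi <- 1.6
    for (k in 1:50) {
      mid <- (lo + hi) / 2
      if (nominal(c(l1, mid, solve_l3(l1, mid)))[2] < 0) lo <- mid
      else hi <- mid
    }
    (lo + hi) / 2
  }
  lo <- 1; hi <- 1.3
  for (k in 1:40) {
    mid <- (lo + hi) / 2
    l2 <- solve_l2(mid)
    if (nominal(c(mid, l2, solve_l3(mid, l2)))[1] < target) lo <- mid
    else hi <- mid
  }
  lam_oracle <- (lo + hi) / 2

  s <- material_point_state()
  for (tg in c(5, 10, 15)) {
    s <- solve_stress_controlled(tg, s, p_def, fib, dp,
                                 evolve_damage = FALSE)
  }
  expect_equal(s$lambda[1], lam_oracle, tolerance = 1e-8)
})

test_that("ramp without activation reproduces the hyperelastic backbone", {
  off <- ramp_undamaged()
  # same protocol with the damage machinery engaged but never activated
  state <- material_point_state()
  loads <- seq(0, 100, length.out = 301)
  stretch <- vapply(loads, function(tg) {
    state <<- solve_stress_controlled(tg, state, p_def, fib, dp,
                                      evolve_damage = TRUE)
    state$lambda[1]
  }, numeric(1))
  expect_equal(stretch, off$stretch_axial, tolerance = 1e-12)
  expect_equal(state$damage[[1]]$D, 0)
  # the undamaged backbone is monotone in stress and stretch
  expect_true(all(diff(off$sigma_axial_kPa) > 0))
  expect_true(all(diff(off$stretch_axial) > 0))
})

test_that("the damaged ramp softens: stress at-or-below the virgin curve", {
  off <- ramp_undamaged()
  on <- ramp_damaged()
  # at equal load the damaged specimen is never less stretched
  expect_true(all(on$stretch_axial >= off$stretch_axial - 1e-10))
  # at equal stretch (interpolating the damaged curve) stress never exceeds
  # the virgin curve
  common <- off$stretch_axial >= min(on$stretch_axial) &
    off$stretch_axial <= max(on$stretch_axial)
  sig_on <- approx(on$stretch_axial, on$sigma_axial_kPa,
                   xout = off$stretch_axial[common])$y
  expect_true(all(sig_on <= off$sigma_axial_kPa[common] + 1e-8))
  expect_gt(max(on$D1), 0)
})

test_that("halving the ramp step count leaves the final state unchanged", {
  coarse <- run_ramp(100, steps = 150, damage_on = TRUE)
  fine <- run_ramp(100, steps = 300, damage_on = TRUE)
  expect_lt(abs(tail(coarse$stretch_axial, 1) - tail(fine$stretch_axial, 1)) /
              tail(fine$stretch_axial, 1), 1e-4)
})

test_that("undamaged cycling is path independent (loops close)", {
  res <- run_cyclic(20, 2, 200, activate_after_cycle = 99)
  cc <- res$curves
  c1 <- cc[!is.na(cc$cycle) & cc$cycle == 1, ]
  c2 <- cc[!is.na(cc$cycle) & cc$cycle == 2, ]
  expect_equal(c2$stretch_axial, c1$stretch_axial, tolerance = 1e-8)
  # loading and unloading branches coincide at equal load (no hysteresis)
  ld <- c1[c1$phase == "load" & c1$load_kPa <= max(c1$load_kPa[c1$phase ==
                                                                 "unload"]), ]
  ul <- c1[c1$phase == "unload", ]
  st_ul <- approx(ul$load_kPa, ul$stretch_axial, xout = ld$load_kPa)$y
  expect_equal(st_ul, ld$stretch_axial, tolerance = 1e-7)
  expect_equal(max(c2$D1), 0)
})

test_that("cyclic damage saturates quickly and carries fibre-level remnant strain", {
  res <- default_cyclic()
  expect_lte(res$first_saturated_cycle, 5)
  expect_gte(res$first_saturated_cycle, 2)
  s <- res$summary
  # damage appears only after activation (cycle 1 is physiological)
  expect_equal(s$D1_max[1], 0)
  expect_gt(s$D1_max[2], 0)
  expect_true(all(diff(pmax(s$D1_max, s$D2_max)) >= 0))
  # both families damage identically by symmetry
  expect_equal(s$D1_max, s$D2_max, tolerance = 1e-10)
  # remnant strain lives in the fibre families: their stress-free stretch
  # exceeds one after every damaging cycle, while the tissue itself returns
  # to the reference stretch at exactly zero load
  post <- s[s$cycle >= 2, ]
  expect_true(all(post$fiber_remnant_stretch > 1))
  expect_true(all(abs(s$zero_load_stretch - 1) < 1e-8))
  # hysteresis appears in the damaging cycle: somewhere along the loop the
  # unloading branch is more compliant than the loading branch was (the
  # softening happens early in the loading phase, so the gap opens at low
  # loads)
  cc <- res$curves
  c2 <- cc[!is.na(cc$cycle) & cc$cycle == 2, ]
  ld <- c2[c2$phase == "load" & c2$load_kPa <= max(c2$load_kPa[c2$phase ==
                                                                 "unload"]), ]
  ul <- c2[c2$phase == "unload", ]
  st_ul <- approx(ul$load_kPa, ul$stretch_axial, xout = ld$load_kPa)$y
  expect_gt(max(st_ul - ld$stretch_axial), 1e-3)
})

test_that("the saturated cyclic response depends on gamma_inf but not beta_s", {
  a <- cyclic_g10(0.06)
  b <- cyclic_g10(0.13)
  fa <- a$curves[!is.na(a$curves$cycle) & a$curves$cycle == 10, ]
  fb <- b$curves[!is.na(b$curves$cycle) & b$curves$cycle == 10, ]
  expect_equal(fb$stretch_axial, fa$stretch_axial, tolerance = 1e-3)
  expect_lte(a$first_saturated_cycle, 5)
  expect_lte(b$first_saturated_cycle, 5)
})

test_that("fibre recruitment stretch grows from one with damage", {
  expect_equal(fiber_recruitment_stretch(c(0, 0)), 1)
  r1 <- fiber_recruitment_stretch(c(0.1, 0.1))
  r2 <- fiber_recruitment_stretch(c(0.3, 0.3))
  expect_gt(r1, 1)
  expect_gt(r2, r1)
  # at the recruitment stretch the damaged fibre argument vanishes
  lam1 <- r2
  lat <- vasculodamage:::.lateral_solve(lam1, rep(1 / sqrt(lam1), 2),
                                        list(), numeric(0), p_def)
  e <- vasculodamage:::.energy_core(diag(c(lam1, lat)^2), fib,
                                    c(0.3, 0.3), p_def)
  expect_equal(e$arg[1], 0, tolerance = 1e-8)
})
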