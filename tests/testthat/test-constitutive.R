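fib2 <- cube_fibers()
p_def <- material_params()

test_that("energy parts vanish at the reference state and obey the printed forms", {
  e <- strain_energy(diag(3), fib2, c(0, 0), p_def)
  expect_equal(e$psi_iso, 0)
  expect_equal(e$psi_vol, 0)
  expect_equal(e$psi_ti, c(0, 0))
  expect_equal(e$psi_total, 0)

  # pure dilation with I3 = 2: volumetric part by direct scalar evaluation
  C <- diag(rep(2^(1 / 3), 3))
  e2 <- strain_energy(C, fib2, c(0, 0), p_def)
  expect_equal(e2$psi_vol, 499.8 * (2^2.4 + 2^(-2.4) - 2), tolerance = 1e-12)

  # with no damage the fibre energy equals its effective counterpart
  set.seed(3)
  C <- rand_spd(0.9, 2.2)
  e3 <- strain_energy(C, fib2, c(0, 0), p_def)
  expect_identical(e3$psi_ti, e3$psi_ti_effective)
  # and the total is the sum of its parts
  expect_equal(e3$psi_total, e3$psi_iso + e3$psi_vol + sum(e3$psi_ti))

  expect_error(strain_energy(C, fib2, c(1, 0), p_def), "\\[0, 1\\)")
})

test_that("the reference state is stress free for any admissible parameters", {
  set.seed(21)
  for (rep in 1:20) {
    p <- material_params(c1 = runif(1, 1, 50), eps1 = runif(1, 10, 1000),
                         eps2 = runif(1, 0.5, 5), alpha1 = runif(1, 100, 3000),
                         alpha2 = runif(1, 1.1, 4), kappa = runif(1, 0, 1 / 3),
                         beta_f = runif(1, 10, 80))
    D <- runif(2, 0, 0.9)
    S <- pk2_stress(diag(3), cube_fibers(p$beta_f), D, p)
    expect_lt(max(abs(S)), 1e-12)
  }
})

test_that("analytic stress matches finite differences of the energy", {
  set.seed(42)
  n_checked <- 0
  n_active <- 0
  while (n_checked < 200) {
    C <- rand_spd(0.7, 2.8)
    D <- runif(2, 0, 0.6)
    e <- strain_energy(C, fib2, D, p_def)
    if (any(e$psi_ti > 0)) n_active <- n_active + 1
    S <- pk2_stress(C, fib2, D, p_def)
    Snum <- matrix(0, 3, 3)
    for (i in 1:3) for (j in i:3) {
      h <- 1e-6 * (1 + abs(C[i, j]))
      dC <- matrix(0, 3, 3)
      dC[i, j] <- dC[i, j] + h / 2
      dC[j, i] <- dC[j, i] + h / 2
      ep <- strain_energy(C + dC, fib2, D, p_def)$psi_total
      em <- strain_energy(C - dC, fib2, D, p_def)$psi_total
      Snum[i, j] <- Snum[j, i] <- 2 * (ep - em) / (2 * h)
    }
    expect_lt(max(abs(Snum - S)) / max(max(abs(S)), 1), 1e-6)
    n_checked <- n_checked + 1
  }
  # the sample must exercise both sides of the tension-only switch
  expect_gt(n_active, 20)
  expect_lt(n_active, 200)
})

test_that("fibre term activates exactly at the Macaulay switch point", {
  # kappa = 0, fibres along e1, isochoric uniaxial C = diag(l^2, 1/l, 1/l):
  # K3(l) = 2 l, so the fibre argument K3 - 2 crosses zero at l* solved by
  # bisection, independently of the energy implementation.
  p0 <- material_params(kappa = 1e-300, beta_f = 45)  # kappa -> 0 limit
  fib_ax <- list(fiber_family(c(1, 0, 0)), fiber_family(c(1, 0, 0)))
  K3_of <- function(l) {
    invariants(diag(c(l^2, 1 / l, 1 / l)), list(fib_ax[[1]]$M))$K3
  }
  lo <- 0.5
  hi <- 2
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (K3_of(mid) - 2 < 0) lo <- mid else hi <- mid
  }
  l_star_oracle <- (lo + hi) / 2

  psi_fib <- function(l) {
    strain_energy(diag(c(l^2, 1 / l, 1 / l)), fib_ax, c(0, 0), p0)$psi_ti[1]
  }
  lo <- 0.5
  hi <- 2
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (psi_fib(mid) == 0) lo <- mid else hi <- mid
  }
  expect_equal((lo + hi) / 2, l_star_oracle, tolerance = 1e-10)
  expect_equal(l_star_oracle, 1, tolerance = 1e-10)  # K3 = 2l crosses at 1
})

test_that("Cauchy stress is frame indifferent and reduces to S at F = I", {
  set.seed(5)
  C <- rand_spd(0.8, 2)
  S <- pk2_stress(C, fib2, c(0.1, 0.3), p_def)
  expect_equal(cauchy_stress(diag(3), S), S)
  expect_equal(cauchy_stress(rand_rotation(), matrix(0, 3, 3)),
               matrix(0, 3, 3))
  for (rep in 1:25) {
    F <- diag(3) + 0.3 * matrix(rnorm(9), 3)
    if (det(F) <= 0) next
    Cf <- right_cauchy_green(F)
    S <- pk2_stress(Cf, fib2, c(0.2, 0.1), p_def)
    sig <- cauchy_stress(F, S)
    Q <- rand_rotation()
    # rotated motion QF: C unchanged, sigma rotates objectively
    sig_rot <- cauchy_stress(Q %*% F, S)
    expect_equal(sig_rot, Q %*% sig %*% t(Q), tolerance = 1e-10)
  }
  expect_error(cauchy_stress(diag(c(-1, 1, 1)), S), "det")
})

test_that("fibre energy and stress soften monotonically in the damage variable", {
  # fixed stretched state with the fibre term active
  lam <- c(1.6, 0.85, 0.9)
  C <- diag(lam^2)
  Ds <- seq(0, 0.6, by = 0.05)
  psi <- vapply(Ds, function(d) {
    sum(strain_energy(C, fib2, c(d, d), p_def)$psi_ti)
  }, numeric(1))
  expect_gt(psi[1], 0)
  expect_true(all(diff(psi) <= 1e-12))
  # fibre contribution to stress = total minus the matrix-only response
  S_mat <- pk2_stress(C, fib2, c(0.999999, 0.999999), p_def)
  fibre_norm <- vapply(Ds, function(d) {
    norm(pk2_stress(C, fib2, c(d, d), p_def) - S_mat, "F")
  }, numeric(1))
  expect_true(all(diff(fibre_norm) <= 1e-9 * max(fibre_norm)))
})

test_that("numerical tangent has major symmetry and first-order predictivity", {
  set.seed(9)
  C <- rand_spd(0.9, 2.2)
  D <- c(0.15, 0.25)
  CC <- tangent_numeric(C, fib2, D, p_def)
  expect_lt(max(abs(CC - t(CC))) / max(abs(CC)), 1e-6)

  # at the reference state with no damage the tangent is positive
  # semidefinite (checked in the Mandel scaling, which preserves the sign
  # of the quadratic form on symmetric increments)
  CC0 <- tangent_numeric(diag(3), fib2, c(0, 0), p_def)
  W <- diag(c(1, 1, 1, sqrt(2), sqrt(2), sqrt(2)))
  ev <- eigen(W %*% ((CC0 + t(CC0)) / 2) %*% W, symmetric = TRUE,
              only.values = TRUE)$values
  expect_gt(min(ev), -1e-6 * max(abs(ev)))

  # Taylor check: contracted with a small symmetric dC it predicts dS to
  # first order, with remainder O(||dC||^2)
  pairs <- list(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3))
  dC_dir <- matrix(rnorm(9), 3)
  dC_dir <- (dC_dir + t(dC_dir)) / 2
  dC_dir <- dC_dir / norm(dC_dir, "F")
  err <- vapply(c(1e-3, 5e-4, 2.5e-4), function(eps) {
    dC <- eps * dC_dir
    dS_true <- pk2_stress(C + dC, fib2, D, p_def) -
      pk2_stress(C, fib2, D, p_def)
    v <- vapply(seq_along(pairs), function(q) {
      ij <- pairs[[q]]
      dC[ij[1], ij[2]] * if (ij[1] == ij[2]) 1 else 2
    }, numeric(1))
    dS_pred <- CC %*% v
    dS_true_v <- vapply(pairs, function(ij) dS_true[ij[1], ij[2]], numeric(1))
    max(abs(dS_pred - dS_true_v))
  }, numeric(1))
  # quadratic decay of the remainder: quartering eps (x4) cuts error ~x16
  expect_lt(err[3], err[1] / 8)
})
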