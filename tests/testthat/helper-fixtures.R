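# Shared fixtures: random tensor generators and cached driver runs (the
# cyclic protocols are the expensive fixtures; several test files and the
# acceptance checks share them).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, expr, envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# random rotation (det +1) via QR of a Gaussian matrix
rand_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]  # flip a reflection into a rotation
  Q
}

# random SPD C with eigenvalues (squared stretches) in [lo, hi]
rand_spd <- function(lo = 0.5, hi = 2.5) {
  Q <- rand_rotation()
  Q %*% diag(runif(3, lo, hi)) %*% t(Q)
}

default_cyclic <- function() {
  cached("cyclic_default", run_cyclic(20, 10, 200))
}

cyclic_g10 <- function(beta_s) {
  cached(sprintf("cyclic_g10_bs%g", beta_s),
         run_cyclic(20, 10, 200,
                    dparams = damage_params(gamma_inf = 10,
                                            beta_s = beta_s)))
}

ramp_undamaged <- function() {
  cached("ramp_off", run_ramp(100, steps = 300, damage_on = FALSE))
}

ramp_damaged <- function() {
  cached("ramp_on", run_ramp(100, steps = 300, damage_on = TRUE))
}
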