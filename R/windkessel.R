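# Three-element Windkessel (RCR) outflow model in CGS units, with a
# synthetic pulsatile inflow generator. Governing relations (proximal
# resistor in series with a parallel distal resistor/capacitor):
#
#   p(t) = R_p Q(t) + p_c(t),      C dp_c/dt = Q(t) - p_c(t) / R_d
#
# Q in ml/s (= cm^3/s), resistances in g cm^-4 s^-1, capacitance in
# cm^4 s^2 g^-1, pressures in dyn/cm^2 (1 mmHg = 1333.22 dyn/cm^2).

#' Windkessel parameters
#'
#' @param R_p Proximal resistance (g cm^-4 s^-1), > 0.
#' @param R_d Distal resistance (g cm^-4 s^-1), > 0.
#' @param C Capacitance (cm^4 s^2 g^-1), > 0.
#' @return An object of class `windkessel_params`.
#' @export
windkessel_params <- function(R_p, R_d, C) {
  stopifnot(R_p > 0, R_d > 0, C > 0)
  structure(list(R_p = R_p, R_d = R_d, C = C), class = "windkessel_params")
}

#' Split a total resistance into distal and proximal parts
#'
#' \eqn{R_d = k_d R_{tot}}, \eqn{R_p = (1 - k_d) R_{tot}}, where `k_d` is
#' the distal fraction of the total resistance.
#'
#' @param R_tot Total resistance (g cm^-4 s^-1), > 0.
#' @param k_d Distal fraction, in (0, 1); 0.9 is the carotid default.
#' @return List with `R_p` and `R_d`; their sum is exactly `R_tot`.
#' @export
split_total_resistance <- function(R_tot, k_d = 0.9) {
  stopifnot(R_tot > 0)
  if (!is.finite(k_d) || k_d <= 0 || k_d >= 1) {
    stop("k_d must lie strictly between 0 and 1", call. = FALSE)
  }
  R_d <- k_d * R_tot
  list(R_p = R_tot - R_d, R_d = R_d)   # sum reconstructs R_tot exactly
}

#' Periodic flow waveform
#'
#' Uniform samples of one cardiac cycle, stored with both endpoints so that
#' `Q[1] == Q[n + 1]` (periodic closure).
#'
#' @param T Period (s), > 0.
#' @param Q Flow samples (ml/s) at `t = seq(0, T, length.out = length(Q))`;
#'   at least 100 samples per period, first and last equal.
#' @return An object of class `waveform` with fields `T`, `t`, `Q`.
#' @export
waveform <- function(T, Q) {
  stopifnot(T > 0, length(Q) >= 101, all(is.finite(Q)))
  if (abs(Q[1] - Q[length(Q)]) > 1e-9 * (1 + max(abs(Q)))) {
    stop("waveform must be periodic: first and last samples must match",
         call. = FALSE)
  }
  structure(list(T = T, t = seq(0, T, length.out = length(Q)), Q = Q),
            class = "waveform")
}

#' Summary statistics of a waveform
#'
#' Mean over one period (uniform samples, periodic closure), minimum and
#' maximum.
#'
#' @param w A [waveform()].
#' @return Named list `mean`, `min`, `max` (ml/s).
#' @export
waveform_stats <- function(w) {
  stopifnot(inherits(w, "waveform"))
  n <- length(w$Q) - 1L
  list(mean = mean(w$Q[seq_len(n)]), min = min(w$Q), max = max(w$Q))
}

#' Synthetic pulsatile inflow waveform
#'
#' Generates a smooth periodic flow curve with a systolic peak in the first
#' half of the cycle and a smaller dicrotic shoulder, whose sample mean,
#' minimum and maximum match the requested targets (mean to better than
#' 1e-3 relative; min and max exactly at sample points). The base pulse is
#' perturbed by a few low-order harmonics with seeded random amplitudes and
#' phases, so different seeds give different shapes with identical summary
#' statistics. The carotid defaults reproduce the printed inlet statistics:
#' mean 4.6 ml/s, range 3.0-6.9 ml/s, period 0.8 s.
#'
#' @param mean,min,max Target flow statistics (ml/s), `min < mean < max`
#'   (or all equal for a constant waveform).
#' @param T Cycle duration (s); default 0.8.
#' @param n_samples Samples per period (>= 100); default 200.
#' @param seed Integer seed for the shape perturbation.
#' @return A [waveform()].
#' @export
synthetic_inflow <- function(mean = 4.6, min = 3.0, max = 6.9, T = 0.8,
                             n_samples = 200, seed = 1) {
  stopifnot(T > 0, n_samples >= 100)
  if (min == max) {
    if (mean != min) stop("infeasible constraints: min = max != mean",
                          call. = FALSE)
    return(waveform(T, rep(mean, n_samples + 1)))
  }
  if (!(min < mean && mean < max)) {
    stop("infeasible constraints: need min < mean < max", call. = FALSE)
  }
  u <- seq(0, 1, length.out = n_samples + 1)[-(n_samples + 1)]
  # base pulse: systolic peak near 0.28 T plus a dicrotic shoulder,
  # wrapped over neighbouring periods so the curve is exactly periodic
  bump <- function(u, c0, w) {
    rowSums(sapply(c(-1, 0, 1), function(k) exp(-((u - c0 + k) / w)^2)))
  }
  s <- bump(u, 0.28, 0.11) + 0.35 * bump(u, 0.55, 0.16)
  # seeded low-order harmonic perturbation (shape only, kept small so the
  # global maximum stays in the first half of the cycle)
  rs <- local({
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
    list(a = stats::runif(3, 0, 0.06), phi = stats::runif(3, 0, 2 * pi))
  })
  for (j in 1:3) {
    s <- s + rs$a[j] * sin(2 * pi * (j + 1) * u + rs$phi[j])
  }
  # normalise to [0, 1], then a monotone power remap u^pw pins min and max
  # while a one-parameter root solve matches the mean
  s <- (s - base::min(s)) / (base::max(s) - base::min(s))
  target <- (mean - min) / (max - min)
  f <- function(lp) base::mean(s^exp(lp)) - target
  lo <- -10; hi <- 10
  if (f(lo) * f(hi) > 0) stop("infeasible constraints for mean", call. = FALSE)
  pw <- exp(stats::uniroot(f, c(lo, hi), tol = 1e-12)$root)
  Q <- min + (max - min) * s^pw
  waveform(T, c(Q, Q[1]))
}

#' Integrate the RCR Windkessel model
#'
#' Drives the three-element Windkessel with a periodic inflow for
#' `n_cycles` cycles. The flow is taken piecewise linear between samples
#' and the capacitor pressure is advanced by the exact exponential
#' solution of the linear ODE on each interval (particular solution
#' \eqn{p_c^* = R_d Q(t) - R_d^2 C \dot Q} plus exponential decay of the
#' homogeneous part), which is unconditionally stable, deterministic, and
#' reproduces the resistive limit \eqn{p = Q (R_p + R_d)} pointwise as
#' \eqn{C \to 0}. The run is flagged converged to a periodic steady state
#' when the last two cycle means differ by less than 0.1%.
#'
#' @param w A [waveform()] (ml/s).
#' @param p [windkessel_params()].
#' @param n_cycles Number of cycles to integrate, >= 2; transients decay
#'   over the early cycles.
#' @return List with `t` (s) and `p_dyn`, `p_mmHg` (outlet pressure over
#'   the final cycle), `p_c_dyn` (capacitor pressure), `cycle_means_mmHg`,
#'   and `converged`.
#' @export
integrate_rcr <- function(w, p, n_cycles = 10) {
  stopifnot(inherits(w, "waveform"), inherits(p, "windkessel_params"),
            n_cycles >= 2)
  n <- length(w$Q) - 1L
  dt <- w$T / n
  decay <- exp(-dt / (p$R_d * p$C))
  pc <- w$Q[1] * p$R_d          # warm start at the resistive equilibrium
  cycle_means <- numeric(n_cycles)
  p_last <- numeric(n + 1L)
  pc_last <- numeric(n + 1L)
  for (cyc in seq_len(n_cycles)) {
    p_last[1] <- p$R_p * w$Q[1] + pc
    pc_last[1] <- pc
    for (k in seq_len(n)) {
      b <- (w$Q[k + 1L] - w$Q[k]) / dt    # flow slope on [t_k, t_{k+1}]
      drift <- p$R_d^2 * p$C * b
      pstar0 <- p$R_d * w$Q[k] - drift
      pstar1 <- p$R_d * w$Q[k + 1L] - drift
      pc <- pstar1 + (pc - pstar0) * decay
      p_last[k + 1L] <- p$R_p * w$Q[k + 1L] + pc
      pc_last[k + 1L] <- pc
    }
    cycle_means[cyc] <- trapz(w$t, p_last) / w$T / DYN_PER_CM2_PER_MMHG
  }
  drift <- abs(cycle_means[n_cycles] - cycle_means[n_cycles - 1L]) /
    abs(cycle_means[n_cycles])
  list(t = w$t, p_dyn = p_last, p_mmHg = p_last / DYN_PER_CM2_PER_MMHG,
       p_c_dyn = pc_last, cycle_means_mmHg = cycle_means,
       converged = drift < 1e-3)
}

#' Cycle-mean pressure in mmHg
#'
#' Time average of a pressure trace over one full cycle (trapezoidal rule)
#' converted with 1 mmHg = 1333.22 dyn/cm^2.
#'
#' @param t Sample times spanning one period (s).
#' @param p_dyn Pressure samples (dyn/cm^2).
#' @param T Period (s); defaults to the time span.
#' @return Mean pressure (mmHg).
#' @export
cycle_mean_pressure <- function(t, p_dyn, T = t[length(t)] - t[1]) {
  stopifnot(length(t) == length(p_dyn), length(t) >= 2)
  if (t[length(t)] - t[1] < T * (1 - 1e-6)) {
    stop("pressure series shorter than one period", call. = FALSE)
  }
  trapz(t, p_dyn) / T / DYN_PER_CM2_PER_MMHG
}

#' Branch flow from an inlet waveform
#'
#' Convenience transform for a symmetric bifurcation: each branch carries
#' half the inlet flow, `Q_b = 0.5 Q_in`.
#'
#' @param w Inlet [waveform()].
#' @return Branch [waveform()].
#' @export
branch_flow <- function(w) {
  stopifnot(inherits(w, "waveform"))
  waveform(w$T, w$Q / 2)
}

# trapezoidal quadrature on possibly non-uniform samples
trapz <- function(t, y) {
  n <- length(t)
  sum((t[-1] - t[-n]) * (y[-1] + y[-n])) / 2
}
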