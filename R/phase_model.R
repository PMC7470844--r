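# Coupled phase-oscillator lattice: the explicit infinite-period reference
# model against which the two-module waves are compared.

#' Phase-lattice configuration
#'
#' A 1D lattice of phase oscillators
#' \deqn{\dot\theta_i = \omega(x_i, t) + \frac{K}{2}\bigl[\sin(\theta_{i+1}
#'   - \theta_i) + \sin(\theta_{i-1} - \theta_i)\bigr]}
#' with no-flux ends. The frequency profile equals `omega_max` in the
#' posterior and decreases to 0 behind a front moving at speed `speed`
#' (default: a linear ramp of width `1/steepness`, the same front geometry
#' as [morphogen_front()]); a custom `frequency_profile(x, t)` can be
#' injected.
#'
#' @param n_oscillators number of lattice sites.
#' @param omega_max posterior angular frequency (rad / time).
#' @param coupling coupling strength K (>= 0); default weak coupling,
#'   `0.1 * omega_max`.
#' @param speed,steepness,offset front parameters of the default frequency
#'   profile.
#' @param frequency_profile optional function `(x, t) -> omega >= 0`.
#' @param dt Euler time step.
#' @param t_max total simulated time (default: until the front has cleared
#'   the lattice plus two posterior periods).
#' @param seed integer seed (kept for manifest reproducibility; the model
#'   is deterministic).
#' @return object of class `"phase_lattice_config"`.
#' @export
phase_lattice_config <- function(n_oscillators = 150, omega_max = 2 * pi,
                                 coupling = 0.1 * omega_max, speed = 24,
                                 steepness = 0.02, offset = 0,
                                 frequency_profile = NULL, dt = 0.005,
                                 t_max = NULL, seed = 1L) {
  stopifnot(n_oscillators >= 2, omega_max > 0, coupling >= 0, dt > 0,
            speed > 0, steepness > 0)
  structure(list(n_oscillators = as.integer(n_oscillators),
                 omega_max = omega_max, coupling = coupling, speed = speed,
                 steepness = steepness, offset = offset,
                 frequency_profile = frequency_profile, dt = dt,
                 t_max = t_max, seed = as.integer(seed)),
            class = "phase_lattice_config")
}

.phase_omega <- function(config, x, t) {
  if (!is.null(config$frequency_profile)) {
    w <- config$frequency_profile(x, t)
    if (any(w < 0)) stop("frequency profile must be non-negative")
    return(w)
  }
  u <- config$steepness * (x - config$offset - config$speed * t)
  config$omega_max * pmin(pmax(u + 0.5, 0), 1)
}

#' Simulate the coupled phase-oscillator lattice
#'
#' Fixed-step Euler integration of the phase lattice under the imposed
#' frequency profile. Phases are reported modulo \eqn{2\pi}; the pattern
#' variable is \eqn{\sin\theta}.
#'
#' @param config a [phase_lattice_config()].
#' @return object of class `c("phase_kymograph", "kymograph")`: `times`,
#'   `positions`, `states` (time x cell x \{phase, pattern\}), `g_values`
#'   (the normalised frequency profile \eqn{\omega/\omega_{max}}).
#' @export
simulate_phase_lattice <- function(config = phase_lattice_config()) {
  if (!inherits(config, "phase_lattice_config"))
    stop("'config' must be a phase_lattice_config")
  n <- config$n_oscillators
  x <- seq(0, n - 1)
  t_max <- config$t_max
  if (is.null(t_max))
    t_max <- (max(x) - config$offset + 0.5 / config$steepness) / config$speed +
      4 * pi / config$omega_max
  nsteps <- ceiling(t_max / config$dt)
  save_every <- max(1L, floor(nsteps / 600))
  nsave <- nsteps %/% save_every + 1
  states <- array(NA_real_, c(nsave, n, 2),
                  dimnames = list(NULL, NULL, c("phase", "pattern")))
  gvals <- matrix(NA_real_, nsave, n)
  times <- numeric(nsave)
  theta <- numeric(n)
  K2 <- config$coupling / 2
  isave <- 1L
  for (step in 0:nsteps) {
    t <- step * config$dt
    if (step %% save_every == 0) {
      times[isave] <- t
      states[isave, , 1] <- theta %% (2 * pi)
      states[isave, , 2] <- sin(theta)
      gvals[isave, ] <- .phase_omega(config, x, t) / config$omega_max
      isave <- isave + 1L
    }
    if (step == nsteps) break
    w <- .phase_omega(config, x, t)
    # no-flux coupling: missing neighbours contribute zero phase difference
    dplus <- c(theta[-1], theta[n]) - theta
    dminus <- c(theta[1], theta[-n]) - theta
    theta <- theta + config$dt * (w + K2 * (sin(dplus) + sin(dminus)))
  }
  structure(list(times = times[seq_len(isave - 1)], positions = x,
                 states = states[seq_len(isave - 1), , , drop = FALSE],
                 g_values = gvals[seq_len(isave - 1), , drop = FALSE],
                 config = config,
                 model = list(kind = "phase", var_names = c("phase", "pattern"))),
            class = c("phase_kymograph", "kymograph"))
}

#' Discretise frozen phases into fates
#'
#' Bins each oscillator's final phase into `n_fates` equal bins of
#' \eqn{[0, 2\pi)}; intended for frozen profiles (frequency ~ 0
#' everywhere).
#'
#' @param phases numeric vector of phases.
#' @param n_fates number of fate bins.
#' @return object of class `"fate_pattern"`.
#' @export
phase_pattern <- function(phases, n_fates = 3) {
  stopifnot(n_fates >= 1)
  ph <- phases %% (2 * pi)
  bin <- pmin(floor(ph / (2 * pi / n_fates)), n_fates - 1) + 1L
  lev <- paste0("phase_", seq_len(n_fates))
  fates <- factor(lev[bin], levels = lev)
  pos <- seq_along(phases) - 1
  ch <- which(fates[-1] != fates[-length(fates)])
  structure(list(fates = fates, boundaries = (pos[ch] + pos[ch + 1]) / 2,
                 positions = pos, ties = integer(0)),
            class = "fate_pattern")
}
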