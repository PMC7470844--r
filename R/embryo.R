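#' Regressing morphogen front
#'
#' The control parameter experienced by a cell at position `x` and time `t`
#' is \eqn{g(x, t) = H(s (x - x_0 - v t))}, clamped to \[0, 1\]. `H` is an
#' increasing profile (logistic \eqn{1/(1+e^{-u})} or a linear ramp of width
#' \eqn{1/s} centred at 0), so `g` is 1 far posterior (large `x`), decreases
#' over time at every fixed position, and tends to 0 everywhere at long
#' times as the front regresses with speed `v`.
#'
#' @param steepness spatial steepness `s` (> 0).
#' @param speed front speed `v` (domain units per time, > 0).
#' @param shape `"logistic"` or `"piecewise_linear"`.
#' @param offset front position `x0` at `t = 0`.
#' @return object of class `"morphogen_front"`.
#' @export
morphogen_front <- function(steepness = 1, speed = 1,
                            shape = c("logistic", "piecewise_linear"),
                            offset = 0) {
  shape <- match.arg(shape)
  stopifnot(is.numeric(steepness), steepness > 0,
            is.numeric(speed), speed > 0, is.numeric(offset))
  structure(list(steepness = steepness, speed = speed, shape = shape,
                 offset = offset),
            class = "morphogen_front")
}

#' @export
print.morphogen_front <- function(x, ...) {
  cat("<morphogen_front>", x$shape, "s =", x$steepness, "v =", x$speed,
      "x0 =", x$offset, "\n")
  invisible(x)
}

#' Evaluate the morphogen front
#'
#' @param x position(s).
#' @param t time(s).
#' @param front a [morphogen_front()].
#' @return value(s) of `g` in \[0, 1\].
#' @export
morphogen_value <- function(x, t, front) {
  if (!inherits(front, "morphogen_front")) stop("'front' must be a morphogen_front")
  if (any(!is.finite(x)) || any(!is.finite(t))) stop("'x' and 't' must be finite")
  u <- front$steepness * (x - front$offset - front$speed * t)
  g <- switch(front$shape,
              logistic = 1 / (1 + exp(-u)),
              piecewise_linear = u + 0.5)
  pmin(pmax(g, 0), 1)
}

# front time after which g(x, t) < g_target
.front_clear_time <- function(front, x, g_target = 0.01) {
  u <- switch(front$shape,
              logistic = log(g_target / (1 - g_target)),
              piecewise_linear = g_target - 0.5)
  (x - front$offset - u / front$steepness) / front$speed
}

#' Embryo simulation configuration
#'
#' @param n_cells number of cells (>= 2).
#' @param domain_length physical length of the cell line; cells sit at
#'   equally spaced positions from 0 to `domain_length`. Defaults to
#'   `n_cells - 1` (unit cell spacing).
#' @param dt integration time step; defaults to a model-dependent value
#'   (see [simulate_embryo()]).
#' @param t_max total simulated time; by default the run lasts until
#'   `g < 0.01` in every cell plus five posterior clock periods.
#' @param diffusion diffusion coupling constant `D` (>= 0, per squared cell
#'   spacing).
#' @param omega copy-number scale \eqn{\Omega}; noise variance scales as
#'   \eqn{1/\Omega}. `Inf` (default) disables noise and the integration is
#'   purely deterministic.
#' @param noise_floor noise amplitude scale of the geometric family, whose
#'   noise \eqn{\sigma =} `noise_floor` \eqn{/\sqrt\Omega} is constant in
#'   space and state.
#' @param seed integer seed used for stochastic runs.
#' @param initial_condition `"posterior_cycle_phase"` starts every cell at
#'   the same point of the posterior (g = 1) attractor; `"explicit"` uses
#'   `init_state`.
#' @param init_state matrix (`n_cells` x n variables) or vector recycled
#'   across cells, used when `initial_condition = "explicit"`.
#' @param save_every save every `save_every`-th step (default: aim for
#'   about 500 saved frames).
#' @return object of class `"embryo_config"`.
#' @export
embryo_config <- function(n_cells = 100, domain_length = NULL, dt = NULL,
                          t_max = NULL, diffusion = 0, omega = Inf,
                          noise_floor = 1, seed = 1L,
                          initial_condition = c("posterior_cycle_phase",
                                                "explicit"),
                          init_state = NULL, save_every = NULL) {
  initial_condition <- match.arg(initial_condition)
  stopifnot(n_cells >= 2, diffusion >= 0, noise_floor >= 0)
  if (!is.numeric(omega) || length(omega) != 1L || omega <= 0)
    stop("'omega' must be a positive number (or Inf)")
  if (is.null(domain_length)) domain_length <- n_cells - 1
  stopifnot(domain_length > 0)
  if (!is.null(dt)) stopifnot(dt > 0)
  if (!is.null(t_max)) stopifnot(t_max > 0)
  if (initial_condition == "explicit" && is.null(init_state))
    stop("'init_state' is required when initial_condition = 'explicit'")
  structure(list(n_cells = as.integer(n_cells), domain_length = domain_length,
                 dt = dt, t_max = t_max, diffusion = diffusion, omega = omega,
                 noise_floor = noise_floor, seed = as.integer(seed),
                 initial_condition = initial_condition,
                 init_state = init_state, save_every = save_every),
            class = "embryo_config")
}

# default Euler step keeping dt * (stiffest rate) well below 0.1
.default_dt <- function(model) {
  if (model$kind == "gene") {
    rate <- model$degradation +
      (model$beta_dyn + model$beta_stat) * max(model$h_dyn, model$h_stat) /
      min(model$K_dyn, model$K_stat[1, 2], na.rm = TRUE)
  } else {
    rate <- max(model$lambda_radial, model$omega0 * (1 + model$rho),
                4 * model$mu_intermediate)
    if (model$variant == "hopf_subcritical")
      rate <- max(rate, model$sub_lambda *
                    abs(model$sub_nu + 3 * model$sub_b - 5 * model$sub_c))
  }
  signif(0.05 / rate, 1)
}

# memo cache for per-model quantities that are expensive to recompute
# (posterior period and burn-in state); keyed on the model parameters
.segwave_cache <- new.env(parent = emptyenv())

.model_key <- function(model) {
  flat <- unlist(model[setdiff(names(model), "weights")], use.names = TRUE)
  w <- model$weights
  paste(c(model$kind, format(flat, digits = 15),
          w$family, format(unlist(w[-1]), digits = 15)), collapse = "|")
}

# period of the pure dynamic module (g = 1); closed form for the geometric
# oscillator, numerical for the gene clock
.posterior_period <- function(model) {
  if (model$kind == "geometric")
    return(2 * pi / (model$omega0 * sqrt(1 - model$rho^2)))
  key <- paste0("T0|", .model_key(model))
  hit <- .segwave_cache[[key]]
  if (!is.null(hit)) return(hit)
  cyc <- find_limit_cycle(model, g = 1)
  if (is.null(cyc)) stop("no posterior limit cycle found for this model")
  .segwave_cache[[key]] <- cyc$period
  cyc$period
}

# state on the posterior attractor after a deterministic burn-in
.posterior_state <- function(model, t_burn = NULL) {
  key <- paste0("P0|", .model_key(model), "|", format(t_burn))
  hit <- .segwave_cache[[key]]
  if (!is.null(hit)) return(hit)
  T0 <- .posterior_period(model)
  if (is.null(t_burn)) t_burn <- 30 * T0
  y0 <- if (model$kind == "gene") c(2, 0.5, 0.1) else c(0, 1)
  out <- deSolve::lsoda(y0, c(0, t_burn),
                        function(t, y, p) list(.model_deriv(model, y, 1)),
                        rtol = 1e-9, atol = 1e-9)
  res <- as.numeric(out[nrow(out), -1])
  .segwave_cache[[key]] <- res
  res
}

.resolve_config <- function(model, config, front) {
  cfg <- config
  if (is.null(cfg$dt)) cfg$dt <- .default_dt(model)
  positions <- seq(0, cfg$domain_length, length.out = cfg$n_cells)
  T0 <- .posterior_period(model)
  if (is.null(cfg$t_max)) {
    t_clear <- .front_clear_time(front, max(positions), 0.01)
    cfg$t_max <- max(t_clear, 0) + 5 * T0
  }
  nsteps <- ceiling(cfg$t_max / cfg$dt)
  if (is.null(cfg$save_every))
    cfg$save_every <- max(1L, floor(nsteps / 500))
  cfg$positions <- positions
  cfg$nsteps <- as.integer(nsteps)
  cfg$T0 <- T0
  cfg
}

.initial_matrix <- function(model, cfg) {
  nv <- .model_nvar(model)
  if (cfg$initial_condition == "posterior_cycle_phase") {
    matrix(.posterior_state(model), cfg$n_cells, nv, byrow = TRUE)
  } else {
    st <- cfg$init_state
    if (is.null(dim(st))) st <- matrix(st, cfg$n_cells, nv, byrow = TRUE)
    st <- as.matrix(st)
    if (!all(dim(st) == c(cfg$n_cells, nv)))
      stop("'init_state' must be n_cells x ", nv)
    st
  }
}

.front_code <- function(front) {
  list(shape = match(front$shape, c("logistic", "piecewise_linear")),
       s = front$steepness, v = front$speed, x0 = front$offset)
}

#' Simulate a 1D embryo
#'
#' Integrates the per-cell dynamics under the local control parameter
#' \eqn{g(x, t)} imposed by the morphogen front. With `omega = Inf` and
#' `diffusion = 0` the scheme is a fixed-step deterministic Euler
#' integration; with finite `omega` it is an Euler-Maruyama scheme whose
#' noise amplitude follows [noise_sigma()], with diffusive coupling between
#' nearest neighbours (no-flux boundaries) and gene concentrations clipped
#' at 0 after each step. Stochastic runs are reproducible from
#' `config$seed`.
#'
#' @param model a [gene_network_model()] or [geometric_model()].
#' @param config an [embryo_config()].
#' @param front a [morphogen_front()].
#' @return object of class `"kymograph"`: list with `times` (saved frame
#'   times), `positions`, `states` (time x cell x variable array),
#'   `g_values` (time x cell matrix), and the resolved `model`, `config`,
#'   `front`.
#' @export
simulate_embryo <- function(model, config = embryo_config(),
                            front = morphogen_front()) {
  if (!inherits(model, "segwave_model")) stop("'model' must be a segwave model")
  if (!inherits(config, "embryo_config")) stop("'config' must be an embryo_config")
  if (!inherits(front, "morphogen_front")) stop("'front' must be a morphogen_front")
  cfg <- .resolve_config(model, config, front)
  P0 <- .initial_matrix(model, cfg)
  wc <- .weights_code(model$weights)
  fc <- .front_code(front)
  stochastic <- is.finite(cfg$omega)
  if (stochastic) set.seed(cfg$seed)
  res <- if (model$kind == "gene") {
    sim_gene_cpp(P0, cfg$positions, cfg$dt, cfg$nsteps, cfg$save_every,
                 model$beta_dyn, model$K_dyn, model$h_dyn,
                 model$beta_stat, .kstat_filled(model), model$h_stat,
                 model$degradation,
                 wc$family, wc$exponent, wc$hill_k, wc$hill_n,
                 wc$ienabled, wc$iscale,
                 fc$shape, fc$s, fc$v, fc$x0, -1,
                 cfg$omega, cfg$diffusion)
  } else {
    sim_geo_cpp(P0, cfg$positions, cfg$dt, cfg$nsteps, cfg$save_every,
                model$lambda_radial, model$omega0, model$rho,
                model$static_strength, model$stable_y[1], model$stable_y[2],
                model$unstable_y, model$mu_intermediate,
                as.integer(model$variant == "hopf_subcritical"),
                model$sub_nu, model$sub_b, model$sub_c, model$sub_lambda,
                wc$family, wc$exponent, wc$hill_k, wc$hill_n,
                wc$ienabled, wc$iscale,
                fc$shape, fc$s, fc$v, fc$x0, -1,
                cfg$omega, cfg$diffusion, cfg$noise_floor)
  }
  dimnames(res$states) <- list(NULL, NULL, .model_var_names(model))
  structure(list(times = res$times, positions = cfg$positions,
                 states = res$states, g_values = res$g_values,
                 model = model, config = cfg, front = front),
            class = "kymograph")
}

# K_stat with the unused diagonal replaced by 1 for the C++ call
.kstat_filled <- function(model) {
  K <- model$K_stat
  diag(K) <- 1
  K
}

#' @export
print.kymograph <- function(x, ...) {
  d <- dim(x$states)
  cat("<kymograph>", d[1], "frames x", d[2], "cells x", d[3], "variables;",
      "t in [", signif(min(x$times), 4), ",", signif(max(x$times), 4), "]\n")
  invisible(x)
}

#' Kymograph heat map of one variable
#'
#' @param x a kymograph.
#' @param variable variable index or name to display.
#' @param ... passed to [graphics::image()].
#' @export
plot.kymograph <- function(x, variable = 1, ...) {
  graphics::image(x$times, x$positions, x$states[, , variable],
                  xlab = "time", ylab = "position",
                  main = paste("variable", variable), ...)
  invisible(x)
}

#' Noise amplitude of the stochastic model
#'
#' For gene-network models the noise approximates independent birth-death
#' shot noise (tau-leaping style): per-gene standard deviation
#' \eqn{\sigma_i = \sqrt{(\mathrm{production}_i + \delta P_i)/\Omega}} per
#' unit square-root time. For geometric models the amplitude is constant in
#' space and state, \eqn{\sigma =} `noise_floor` \eqn{/ \sqrt\Omega}. In
#' both cases \eqn{\sigma \to 0} as \eqn{\Omega \to \infty}.
#'
#' @param state a [cell_state()].
#' @param model a segwave model.
#' @param omega copy-number scale (> 0).
#' @param noise_floor geometric-model amplitude scale.
#' @return per-variable standard deviation.
#' @export
noise_sigma <- function(state, model, omega, noise_floor = 1) {
  if (!inherits(state, "cell_state")) stop("'state' must be a cell_state")
  if (!is.numeric(omega) || length(omega) != 1L || omega <= 0)
    stop("'omega' must be positive")
  if (is.infinite(omega)) return(rep(0, .model_nvar(model)))
  if (model$kind == "gene") {
    if (any(state$variables < 0)) stop("concentrations must be non-negative")
    prod <- .gene_production(state$variables, state$g, model)
    sqrt((prod + model$degradation * state$variables) / omega)
  } else {
    rep(noise_floor / sqrt(omega), 2)
  }
}

#' One Euler-Maruyama step for all cells (reference implementation)
#'
#' Pure-R stepper used as the readable reference for the compiled
#' integration core: deterministic field times `dt`, plus
#' \eqn{\sigma \sqrt{dt}} times standard-normal deviates, plus diffusive
#' nearest-neighbour coupling with no-flux boundaries; gene concentrations
#' are clipped at 0. Draws deviates column-major (all cells of variable 1,
#' then variable 2, ...) so a run reproduces the compiled stepper
#' draw-for-draw under the same seed.
#'
#' @param states matrix (cells x variables) of current states.
#' @param t current time.
#' @param dt time step.
#' @param model a segwave model.
#' @param config an [embryo_config()].
#' @param front a [morphogen_front()].
#' @return updated state matrix.
#' @export
step_stochastic <- function(states, t, dt, model, config, front) {
  n <- nrow(states)
  nv <- ncol(states)
  positions <- seq(0, config$domain_length, length.out = config$n_cells)
  if (n != config$n_cells) stop("'states' must have n_cells rows")
  g <- morphogen_value(positions, t, front)
  deriv <- matrix(0, n, nv)
  sigma <- matrix(0, n, nv)
  for (i in seq_len(n)) {
    deriv[i, ] <- .model_deriv(model, states[i, ], g[i])
    sigma[i, ] <- noise_sigma(cell_state(pmax(states[i, ], 0), g[i]), model,
                              config$omega, config$noise_floor)
  }
  lap <- rbind(states[c(1, seq_len(n - 1)), , drop = FALSE]) -
    2 * states + states[c(seq_len(n - 1) + 1, n), , drop = FALSE]
  upd <- states + dt * (deriv + config$diffusion * lap)
  if (is.finite(config$omega))
    upd <- upd + sqrt(dt) * sigma * matrix(rnorm(n * nv), n, nv)
  if (model$kind == "gene") upd[upd < 0] <- 0
  if (any(!is.finite(upd))) {
    bad <- which(!is.finite(upd), arr.ind = TRUE)[1, 1]
    stop("non-finite state at t = ", t + dt, " in cell ", bad)
  }
  upd
}

#' Read cell fates from the final simulated state
#'
#' Gene models: the fate of a cell is the gene with the highest
#' concentration at the last saved frame (ties broken in gene order and
#' recorded in the `ties` attribute). Geometric models: `"high"` if the
#' final `y` is positive, `"low"` otherwise. If the front has not cleared
#' (final `g > 0.05` somewhere) a warning is issued and fates are returned
#' anyway.
#'
#' @param kymograph a [simulate_embryo()] result.
#' @param model the model (defaults to the one stored in the kymograph).
#' @return object of class `"fate_pattern"`: list with `fates` (factor per
#'   cell), `boundaries` (positions of label changes) and `positions`.
#' @export
call_fates <- function(kymograph, model = kymograph$model) {
  st <- kymograph$states
  nt <- dim(st)[1]
  final <- st[nt, , , drop = TRUE]
  if (is.null(dim(final))) final <- matrix(final, ncol = dim(st)[3])
  gfin <- kymograph$g_values[nt, ]
  if (any(gfin > 0.05))
    warning("final g exceeds 0.05 in ", sum(gfin > 0.05),
            " cell(s); pattern may not be frozen yet")
  if (model$kind == "gene") {
    lev <- model$gene_names
    idx <- apply(final, 1, which.max)
    ties <- which(apply(final, 1, function(p) sum(p == max(p)) > 1))
    fates <- factor(lev[idx], levels = lev)
  } else {
    lev <- c("high", "low")
    fates <- factor(ifelse(final[, 1] > 0, "high", "low"), levels = lev)
    ties <- which(final[, 1] == 0)
  }
  pos <- kymograph$positions
  ch <- which(fates[-1] != fates[-length(fates)])
  boundaries <- (pos[ch] + pos[ch + 1]) / 2
  structure(list(fates = fates, boundaries = boundaries, positions = pos,
                 ties = ties),
            class = "fate_pattern")
}

#' @export
print.fate_pattern <- function(x, ...) {
  runs <- rle(as.character(x$fates))
  cat("<fate_pattern>", length(x$fates), "cells,",
      length(runs$lengths), "runs:",
      paste(head(runs$values, 12), collapse = " "),
      if (length(runs$values) > 12) "...\n" else "\n")
  invisible(x)
}
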