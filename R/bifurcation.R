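# Numerical bifurcation analysis: fixed points, limit cycles, per-g
# diagrams and classification of the clock-arrest transition.

# central-difference Jacobian of the model field
.model_jacobian <- function(model, x, g, eps = 1e-6) {
  nv <- length(x)
  J <- matrix(0, nv, nv)
  for (j in seq_len(nv)) {
    e <- numeric(nv); e[j] <- eps * max(1, abs(x[j]))
    J[, j] <- (.model_deriv(model, x + e, g) - .model_deriv(model, x - e, g)) /
      (2 * e[j])
  }
  J
}

# damped Newton iteration on the field; returns root or NULL
.newton_root <- function(model, g, x0, tol = 1e-11, maxit = 60) {
  x <- x0
  f <- .model_deriv(model, x, g)
  for (it in seq_len(maxit)) {
    nf <- sqrt(sum(f^2))
    if (nf < tol) return(x)
    J <- .model_jacobian(model, x, g)
    step <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    lambda <- 1
    repeat {
      xn <- x - lambda * step
      fn <- tryCatch(.model_deriv(model, xn, g), error = function(e) NULL)
      if (!is.null(fn) && all(is.finite(fn)) && sqrt(sum(fn^2)) < nf) break
      lambda <- lambda / 2
      if (lambda < 1e-4) { xn <- x - step; fn <- .model_deriv(model, xn, g); break }
    }
    x <- xn; f <- fn
  }
  if (sqrt(sum(f^2)) < 1e-8) x else NULL
}

.stability_label <- function(ev, tol = 1e-7) {
  re <- Re(ev)
  focus <- any(abs(Im(ev)) > 1e-8)
  if (max(re) < -tol) return(if (focus) "stable_focus" else "stable_node")
  if (min(re) > tol) return(if (focus) "unstable_focus" else "unstable_node")
  "saddle"
}

# deterministic low-discrepancy sequence (van der Corput) for extra seeds
.vdc <- function(i, base) {
  f <- 1; r <- 0
  while (i > 0) { f <- f / base; r <- r + f * (i %% base); i <- i %/% base }
  r
}

.default_box <- function(model) {
  if (model$kind == "gene") {
    # theta_d + theta_s <= 1 for the power families, so production never
    # exceeds the larger module scale
    hi <- 1.15 * max(model$beta_dyn, model$beta_stat) / model$degradation
    cbind(rep(0, 3), rep(hi, 3))
  } else {
    hw <- 1.3 * max(1, abs(model$stable_y), abs(model$unstable_y))
    cbind(rep(-hw, 2), rep(hw, 2))
  }
}

#' Find the fixed points of a model at fixed g
#'
#' Runs a damped Newton iteration from a regular grid of seeds (plus
#' low-discrepancy extras) inside `search_box`, deduplicates the converged
#' roots, and classifies each root from the eigenvalues of a
#' central-difference Jacobian.
#'
#' @param model a segwave model.
#' @param g control-parameter value in \[0, 1\].
#' @param search_box matrix (n variables x 2) of lower/upper bounds;
#'   defaults to a box covering the physical state space.
#' @param n_seeds total number of Newton starts (>= 27 for gene models,
#'   >= 25 for geometric ones).
#' @param extra_seeds optional matrix of additional Newton starts (one row
#'   per seed), e.g. fixed-point locations found at a nearby g during a
#'   continuation sweep.
#' @return object of class `"fixed_point_set"`: list with `g` and `points`,
#'   each point a list with `location`, `eigenvalues`, `stability`.
#'   Non-convergence of all seeds yields an empty set, not an error.
#' @export
find_fixed_points <- function(model, g, search_box = NULL, n_seeds = NULL,
                              extra_seeds = NULL) {
  if (!inherits(model, "segwave_model")) stop("'model' must be a segwave model")
  if (g < 0 || g > 1) stop("'g' must lie in [0, 1]")
  nv <- .model_nvar(model)
  if (is.null(search_box)) search_box <- .default_box(model)
  if (is.null(n_seeds)) n_seeds <- if (nv == 3L) 40L else 35L
  per_dim <- if (nv == 3L) 3L else 5L
  grid1 <- lapply(seq_len(nv), function(j)
    seq(search_box[j, 1], search_box[j, 2], length.out = per_dim + 2)[-c(1, per_dim + 2)])
  seeds <- unname(as.matrix(expand.grid(grid1)))
  n_extra <- max(0L, n_seeds - nrow(seeds))
  if (n_extra > 0) {
    bases <- c(2, 3, 5)[seq_len(nv)]
    extra <- t(vapply(seq_len(n_extra), function(i)
      search_box[, 1] + (search_box[, 2] - search_box[, 1]) *
        vapply(bases, function(b) .vdc(i, b), numeric(1)),
      numeric(nv)))
    seeds <- rbind(seeds, extra)
  }
  scale <- max(abs(search_box))
  roots <- list()
  try_seed <- function(x0) {
    r <- .newton_root(model, g, x0)
    if (is.null(r)) return(invisible())
    if (any(r < search_box[, 1] - 1e-6 * scale) ||
        any(r > search_box[, 2] + 1e-6 * scale)) return(invisible())
    dup <- any(vapply(roots, function(p) sqrt(sum((p - r)^2)) < 1e-6 * max(1, scale),
                      logical(1)))
    if (!dup) roots[[length(roots) + 1L]] <<- r
    invisible()
  }
  if (!is.null(extra_seeds)) {
    extra_seeds <- matrix(as.numeric(extra_seeds), ncol = nv)
    # warm starts first: they converge fastest and anchor the dedup set
    seeds <- rbind(extra_seeds, seeds)
  }
  for (k in seq_len(nrow(seeds))) try_seed(seeds[k, ])
  # completion pass: restart from images of the found roots under the
  # model's (approximate) symmetries, which catches roots the coarse grid
  # missed (cyclic gene permutations; point reflection for planar models)
  extra_from <- function(r) {
    if (nv == 3L) list(r[c(2, 3, 1)], r[c(3, 1, 2)]) else list(-r)
  }
  for (r in roots) for (s in extra_from(r)) try_seed(s)
  points <- lapply(roots, function(r) {
    ev <- eigen(.model_jacobian(model, r, g), only.values = TRUE)$values
    list(location = r, eigenvalues = ev, stability = .stability_label(ev))
  })
  structure(list(g = g, points = points, var_names = .model_var_names(model)),
            class = "fixed_point_set")
}

#' @export
as.data.frame.fixed_point_set <- function(x, ...) {
  if (!length(x$points))
    return(data.frame(g = numeric(0)))
  loc <- t(vapply(x$points, `[[`, numeric(length(x$var_names)), "location"))
  colnames(loc) <- x$var_names
  data.frame(g = x$g, loc,
             stability = vapply(x$points, `[[`, character(1), "stability"),
             max_re = vapply(x$points, function(p) max(Re(p$eigenvalues)),
                             numeric(1)))
}

#' @export
print.fixed_point_set <- function(x, ...) {
  cat("<fixed_point_set> g =", x$g, ":", length(x$points), "fixed point(s)\n")
  if (length(x$points)) print(as.data.frame(x), digits = 4)
  invisible(x)
}

# linearization time scale of the oscillation, used to size integrations
.period_scale <- function(model) {
  if (model$kind == "geometric")
    return(2 * pi / (model$omega0 * sqrt(1 - model$rho^2)))
  # gene clock: 2*pi / imaginary part at the symmetric repressilator point
  f <- function(p) model$beta_dyn / (1 + (p / model$K_dyn)^model$h_dyn) -
    model$degradation * p
  p <- uniroot(f, c(1e-9, 1e3))$root
  ev <- eigen(.model_jacobian(model, rep(p, 3), 1), only.values = TRUE)$values
  im <- max(abs(Im(ev)))
  if (im < 1e-8) 5 else 2 * pi / im
}

#' Locate a limit cycle at fixed g by long integration
#'
#' Integrates the model (forward in time for stable cycles, backward for
#' unstable ones) with an adaptive ODE solver, discards a transient, and
#' measures the period from interpolated upward crossings of the reference
#' variable through its mid-range (a Poincare section). Returns `NULL` when
#' the trajectory converges to a fixed point or shows no recurrence within
#' the integration horizon.
#'
#' @param model a segwave model.
#' @param g control-parameter value.
#' @param direction `"forward"` (stable cycle) or `"backward"` (unstable
#'   cycle, time-reversed integration; meaningful for planar models).
#' @param seed_state starting state (default: a generic state, or a point
#'   on the unit circle for geometric models). Pass a sample from a nearby
#'   cycle for continuation.
#' @param t_transient transient discarded before measuring (default 30
#'   linearization periods).
#' @param t_max measurement horizon (default 250 linearization periods);
#'   bounds the longest detectable period.
#' @param ref_var index of the reference variable.
#' @param amp_tol oscillation amplitude below which the trajectory is
#'   declared converged to a fixed point.
#' @return `NULL`, or a list of class `"limit_cycle"` with `g`, `period`,
#'   `amplitude` (max - min of the reference variable), `var_min`,
#'   `var_max`, `stability`, and `samples` (states over one period).
#' @export
find_limit_cycle <- function(model, g, direction = c("forward", "backward"),
                             seed_state = NULL, t_transient = NULL,
                             t_max = NULL, ref_var = 1, amp_tol = 1e-3) {
  direction <- match.arg(direction)
  if (!inherits(model, "segwave_model")) stop("'model' must be a segwave model")
  if (g < 0 || g > 1) stop("'g' must lie in [0, 1]")
  Ts <- .period_scale(model)
  continuation <- !is.null(seed_state)
  if (is.null(t_transient)) t_transient <- if (continuation) 10 * Ts else 25 * Ts
  if (is.null(t_max)) t_max <- 250 * Ts
  sgn <- if (direction == "forward") 1 else -1
  flow <- function(t, y, p) list(sgn * .model_deriv(model, y, g))
  if (is.null(seed_state))
    seed_state <- if (model$kind == "gene") c(2, 0.5, 0.1) else c(0.05, 0.7)
  lim <- 10 * max(abs(.default_box(model)))

  run <- function(y0, times) {
    out <- tryCatch(
      deSolve::lsoda(y0, times, flow, rtol = 1e-9, atol = 1e-9),
      warning = function(w) NULL, error = function(e) NULL)
    if (is.null(out) || nrow(out) < length(times)) return(NULL)
    out
  }
  tr <- run(seed_state, seq(0, t_transient, length.out = 100))
  if (is.null(tr)) return(NULL)
  y1 <- as.numeric(tr[nrow(tr), -1])
  if (any(abs(y1) > lim)) return(NULL)

  # escalating measurement horizon: a short window suffices away from the
  # SNIC; near it the period diverges and a longer window is needed. A
  # decaying-amplitude check rejects slowly converging spirals (damped
  # oscillations past a Hopf point) that would otherwise mimic a cycle.
  dt_s <- Ts / 200
  states <- NULL; times <- NULL; u <- NULL; up <- integer(0); mid <- NA
  horizon <- min(30 * Ts, t_max)
  decay_retries <- 0L
  repeat {
    times <- seq(0, horizon, by = dt_s)
    out <- run(y1, times)
    if (is.null(out)) return(NULL)
    states <- out[, -1, drop = FALSE]
    if (any(abs(states[nrow(states), ]) > lim)) return(NULL)
    u <- states[, ref_var]
    ntail <- max(2L, round(length(u) * 0.1))
    tail_rng <- diff(range(u[(length(u) - ntail + 1):length(u)]))
    # a quiescent tail means a fixed point only if the field has actually
    # vanished; in a saddle-node bottleneck the state creeps but |f| > 0
    settled <- function() {
      yf <- states[nrow(states), ]
      sqrt(sum(.model_deriv(model, yf, g)^2)) < 1e-7 * max(1, max(abs(yf)))
    }
    if (diff(range(u)) < amp_tol && tail_rng < amp_tol && settled())
      return(NULL)
    mid <- (max(u) + min(u)) / 2
    up <- which(u[-length(u)] < mid & u[-1] >= mid)
    if (length(up) >= 3) {
      # a genuine cycle repeats: constant per-loop amplitude, regular
      # return times, and recurrent section states. Decaying spirals and
      # trajectories creeping into a just-born fixed point fail these.
      a_first <- diff(range(u[up[1]:up[2]]))
      a_last <- diff(range(u[up[length(up) - 1]:up[length(up)]]))
      tc0 <- times[up] + dt_s * (mid - u[up]) / (u[up + 1] - u[up])
      pers <- tail(diff(tc0), 3)
      irregular <- length(pers) >= 2 && max(pers) / min(pers) > 1.02
      cross_state <- function(k) {  # section state, interpolated in time
        frac <- (mid - u[up[k]]) / (u[up[k] + 1] - u[up[k]])
        states[up[k], ] + frac * (states[up[k] + 1, ] - states[up[k], ])
      }
      drift <- sqrt(sum((cross_state(length(up)) -
                           cross_state(length(up) - 1))^2)) /
        max(1, max(abs(states)))
      if (a_last < amp_tol) return(NULL)
      if (a_last < 0.95 * a_first || irregular || drift > 1e-3) {
        if (decay_retries >= 3L) return(NULL)   # persistent: not a cycle
        decay_retries <- decay_retries + 1L
        y1 <- as.numeric(states[nrow(states), ])
        next
      }
      break
    }
    if (tail_rng < amp_tol * 1e-2 && settled())
      return(NULL)                               # settled onto a fixed point
    if (horizon >= t_max) return(NULL)           # no recurrence in horizon
    horizon <- min(horizon * 6, t_max)
  }
  # interpolated crossing times
  tc <- times[up] + dt_s * (mid - u[up]) / (u[up + 1] - u[up])
  periods <- diff(tc)
  period <- mean(tail(periods, min(3, length(periods))))
  # recurrence check across the final period
  i2 <- up[length(up)]; i1 <- up[length(up) - 1]
  scale <- max(1, max(abs(states)))
  recur <- sqrt(sum((cross_state(length(up)) -
                       cross_state(length(up) - 1))^2)) / scale
  idx <- seq(i1, i2)
  cyc_states <- states[idx, , drop = FALSE]
  if (nrow(cyc_states) > 400)
    cyc_states <- cyc_states[round(seq(1, nrow(cyc_states), length.out = 400)), ,
                             drop = FALSE]
  colnames(cyc_states) <- .model_var_names(model)
  structure(list(g = g, period = period,
                 amplitude = diff(range(states[idx, ref_var])),
                 var_min = apply(cyc_states, 2, min),
                 var_max = apply(cyc_states, 2, max),
                 stability = if (direction == "forward") "stable" else "unstable",
                 samples = cyc_states, recurrence = recur,
                 ref_var = ref_var),
            class = "limit_cycle")
}

#' @export
print.limit_cycle <- function(x, ...) {
  cat("<limit_cycle>", x$stability, "at g =", signif(x$g, 6),
      "| period", signif(x$period, 6),
      "| amplitude", signif(x$amplitude, 4), "\n")
  invisible(x)
}

# distance from a point to the nearest sample of a cycle
.dist_to_cycle <- function(pt, cycle) {
  if (is.null(cycle)) return(Inf)
  d2 <- colSums((t(cycle$samples) - pt)^2)
  sqrt(min(d2))
}

# match the points of set b against set a by greedy nearest-neighbour
# assignment (each a-point claims one b-point); the surplus b-points are
# "new" even when they are born arbitrarily close to an existing point
# (pitchforks and saddle-nodes create points on top of old structure)
.new_points <- function(a, b, tol) {
  nb <- length(b$points)
  if (!nb) return(integer(0))
  na <- length(a$points)
  if (!na) return(seq_len(nb))
  d <- matrix(Inf, na, nb)
  for (i in seq_len(na)) for (j in seq_len(nb))
    d[i, j] <- sqrt(sum((a$points[[i]]$location - b$points[[j]]$location)^2))
  used_a <- rep(FALSE, na); used_b <- rep(FALSE, nb)
  for (k in seq_len(min(na, nb))) {
    ij <- which(d == min(d), arr.ind = TRUE)[1, ]
    if (!is.finite(d[ij[1], ij[2]])) break
    used_a[ij[1]] <- TRUE; used_b[ij[2]] <- TRUE
    d[ij[1], ] <- Inf; d[, ij[2]] <- Inf
  }
  which(!used_b)
}

.is_stable <- function(p) p$stability %in% c("stable_node", "stable_focus")

# the fixed point (present on both sides) with the largest imaginary part;
# used to test for a complex pair crossing the imaginary axis
.focus_re_flip <- function(hi_set, lo_set, tol) {
  if (!length(hi_set$points) || !length(lo_set$points)) return(FALSE)
  for (p in hi_set$points) {
    im <- max(abs(Im(p$eigenvalues)))
    if (im < 1e-6) next
    dists <- vapply(lo_set$points, function(q)
      sqrt(sum((q$location - p$location)^2)), numeric(1))
    j <- which.min(dists)
    if (dists[j] > tol) next
    q <- lo_set$points[[j]]
    re_hi <- max(Re(p$eigenvalues[abs(Im(p$eigenvalues)) > 1e-8]))
    imq <- abs(Im(q$eigenvalues))
    if (!any(imq > 1e-8)) next
    re_lo <- max(Re(q$eigenvalues[imq > 1e-8]))
    if (re_hi > 0 && re_lo < 0) return(TRUE)
  }
  FALSE
}

#' Per-g bifurcation diagram
#'
#' Sweeps the control parameter from high to low g, collecting fixed points
#' and the stable limit cycle at each grid value (with continuation of the
#' cycle seed), then localises qualitative changes -- fixed-point count
#' changes and cycle termination -- by bisection to `delta_g`, and
#' classifies each event:
#' \itemize{
#'   \item `snic`: a stable/saddle pair is born within `oncycle_tol` of the
#'     last stable cycle;
#'   \item `saddle_node`: a pair is born away from the cycle;
#'   \item `pitchfork`: the fixed-point count changes 1 to 3 with a
#'     symmetric new pair and a stability flip of the central point;
#'   \item `hopf_super`: the cycle amplitude collapses while a complex
#'     eigenvalue pair of the enclosed fixed point crosses the imaginary
#'     axis;
#'   \item `snlc`: the stable cycle dies at finite amplitude by merging
#'     with an unstable cycle (found by backward-time integration).
#' }
#' Symmetric models generate several simultaneous events (within `delta_g`);
#' they are reported as separate records sharing a `g_star`.
#'
#' @param model a segwave model.
#' @param g_grid decreasing grid of g values (default 101 points on \[1,0\]).
#' @param delta_g bisection resolution for event localisation.
#' @param oncycle_tol distance below which a new fixed point counts as
#'   lying on the cycle.
#' @param hopf_amp_frac fraction of the posterior amplitude below which a
#'   terminating cycle counts as collapsing (Hopf-like).
#' @param t_max_factor measurement horizon for cycles, in linearization
#'   periods.
#' @param snic_refine refine SNIC events further (down to `delta_g`/100)
#'   to observe the period divergence; stored in the event record.
#' @param verbose print progress.
#' @return object of class `"bifurcation_diagram"`.
#' @export
bifurcation_diagram <- function(model, g_grid = seq(1, 0, length.out = 101),
                                delta_g = 1e-3, oncycle_tol = 1e-2,
                                hopf_amp_frac = 0.25, t_max_factor = 250,
                                snic_refine = TRUE, verbose = FALSE) {
  if (!inherits(model, "segwave_model")) stop("'model' must be a segwave model")
  g_grid <- sort(unique(g_grid), decreasing = TRUE)
  Ts <- .period_scale(model)
  t_max <- t_max_factor * Ts

  fps <- vector("list", length(g_grid))
  cycles <- vector("list", length(g_grid))
  seed <- NULL
  locs_of <- function(set) {
    if (!length(set$points)) return(NULL)
    t(vapply(set$points, `[[`, numeric(.model_nvar(model)), "location"))
  }
  prev_locs <- NULL
  for (i in seq_along(g_grid)) {
    g <- g_grid[i]
    fps[[i]] <- find_fixed_points(model, g, extra_seeds = prev_locs)
    prev_locs <- locs_of(fps[[i]])
    cycles[i] <- list(find_limit_cycle(model, g, seed_state = seed,
                                       t_max = t_max))
    if (!is.null(cycles[[i]])) seed <- cycles[[i]]$samples[1, ]
    if (verbose) cat(sprintf("g = %.4f : %d fp, cycle %s\n", g,
                             length(fps[[i]]$points),
                             if (is.null(cycles[[i]])) "-" else
                               signif(cycles[[i]]$period, 4)))
  }

  # events concern the cycle branch connected to the posterior (g = 1);
  # apparent re-detections below its first gap are long-lived transients
  # (e.g. loops creeping into just-born fixed points), not attractors
  first_gap <- which(vapply(cycles, is.null, logical(1)))[1]
  if (!is.na(first_gap) && first_gap <= length(cycles))
    for (j in seq(first_gap, length(cycles))) cycles[j] <- list(NULL)

  scale <- max(abs(.default_box(model)))
  match_tol <- 0.03 * scale
  events <- list()
  add_event <- function(type, g_star, location = NULL, detail = list())
    events[[length(events) + 1L]] <<- c(list(type = type, g_star = g_star,
                                             location = location), detail)

  cycle_cache <- list()
  cyc_at <- function(g, seed) {
    key <- sprintf("%.10f", g)
    if (!is.null(cycle_cache[[key]])) return(cycle_cache[[key]]$value)
    v <- find_limit_cycle(model, g, seed_state = seed, t_max = t_max)
    cycle_cache[[key]] <<- list(value = v)
    v
  }

  for (i in seq_len(length(g_grid) - 1)) {
    g_hi <- g_grid[i]; g_lo <- g_grid[i + 1]
    fp_hi <- fps[[i]]; fp_lo <- fps[[i + 1]]
    cyc_hi <- cycles[[i]]; cyc_lo <- cycles[[i + 1]]

    fp_sig <- function(set)
      c(length(set$points), sum(vapply(set$points, .is_stable, logical(1))))
    fp_changed <- any(fp_sig(fp_hi) != fp_sig(fp_lo))
    cyc_changed <- is.null(cyc_hi) != is.null(cyc_lo)
    if (!fp_changed && !cyc_changed) next

    # --- refine fixed-point event by bisection on the count/stability
    # signature; point identities are only compared across the refined
    # interval, where fixed points barely move
    if (fp_changed) {
      a <- g_hi; b <- g_lo; set_a <- fp_hi; set_b <- fp_lo
      while (a - b > delta_g) {
        m <- (a + b) / 2
        set_m <- find_fixed_points(model, m,
                                   extra_seeds = rbind(locs_of(set_a),
                                                       locs_of(set_b)))
        if (all(fp_sig(set_m) == fp_sig(set_a))) {
          a <- m; set_a <- set_m
        } else { b <- m; set_b <- set_m }
      }
      g_star <- (a + b) / 2
      new_idx <- .new_points(set_a, set_b, match_tol)
      new_pts <- set_b$points[new_idx]
      new_stable <- Filter(.is_stable, new_pts)
      # reference cycle just above the event (a SNIC-side cycle dwells at
      # the birth location, so the refined cycle is the faithful
      # reference); near a SNIC its period is huge, hence the long horizon
      ref_cycle <- if (!is.null(cyc_hi))
        find_limit_cycle(model, a, seed_state = cyc_hi$samples[1, ],
                         t_max = 6 * t_max) else NULL
      if (is.null(ref_cycle)) ref_cycle <- cyc_hi
      central_flip <- .focus_re_flip(set_a, set_b, match_tol) ||
        .stab_flip(set_a, set_b, match_tol)
      symmetric_pair <- length(new_stable) == 2 && model$kind == "geometric" &&
        { ys <- vapply(new_stable, function(p) p$location[1], numeric(1))
          abs(sum(ys - model$unstable_y)) < 0.2 * abs(diff(ys)) }
      if (length(new_pts) && symmetric_pair && central_flip &&
          length(set_a$points) == 1) {
        add_event("pitchfork", g_star,
                  location = new_stable[[1]]$location,
                  detail = list(n_new = length(new_pts)))
      } else if (length(new_stable)) {
        for (p in new_stable) {
          d <- .dist_to_cycle(p$location, ref_cycle)
          add_event(if (d < oncycle_tol) "snic" else "saddle_node", g_star,
                    location = p$location,
                    detail = list(dist_to_cycle = d))
        }
      }
    }

    # --- cycle termination not produced by an on-cycle fixed-point birth
    snic_here <- any(vapply(events, function(e)
      e$type == "snic" && e$g_star <= g_hi + 1e-12 && e$g_star >= g_lo - 1e-12,
      logical(1)))
    if (cyc_changed && !is.null(cyc_hi) && !snic_here) {
      centre <- colMeans(cyc_hi$samples)
      # supercritical Hopf: locate the event from the complex eigenvalue
      # pair of the enclosed fixed point crossing the imaginary axis (the
      # numerical amplitude cut-off is less precise than the eigenvalues)
      re_at <- function(g) .central_re(model, g, centre)
      re_hi <- re_at(g_hi); re_lo <- re_at(g_lo)
      if (is.finite(re_hi) && is.finite(re_lo) && re_hi > 0 && re_lo < 0) {
        a <- g_hi; b <- g_lo
        while (a - b > delta_g / 10) {
          m <- (a + b) / 2
          if (re_at(m) > 0) a <- m else b <- m
        }
        g_star <- (a + b) / 2
        add_event("hopf_super", g_star,
                  detail = list(amplitude_end = cyc_hi$amplitude,
                                period_end = cyc_hi$period,
                                eig_crossing = TRUE))
      } else {
        # finite-amplitude termination: bisect on cycle existence and look
        # for a coexisting unstable cycle (saddle-node of limit cycles)
        a <- g_hi; b <- g_lo; last_cyc <- cyc_hi
        while (a - b > delta_g) {
          m <- (a + b) / 2
          cm <- cyc_at(m, last_cyc$samples[1, ])
          if (!is.null(cm)) { a <- m; last_cyc <- cm } else b <- m
        }
        g_star <- (a + b) / 2
        amp_ref <- cycles[[1]]$amplitude
        collapsing <- !is.null(amp_ref) &&
          last_cyc$amplitude < hopf_amp_frac * amp_ref
        unst <- NULL
        if (model$kind == "geometric")
          unst <- find_limit_cycle(model, min(1, g_star + delta_g),
                                   direction = "backward",
                                   seed_state = c(0.4 * scale / 1.3, 0),
                                   t_max = 80 * Ts)
        if (!is.null(unst) && !collapsing) {
          add_event("snlc", g_star,
                    detail = list(amplitude_end = last_cyc$amplitude,
                                  unstable_amplitude = unst$amplitude,
                                  period = last_cyc$period))
        } else {
          add_event("hopf_super", g_star,
                    detail = list(amplitude_end = last_cyc$amplitude,
                                  period_end = last_cyc$period,
                                  eig_crossing = FALSE))
        }
      }
    }
  }

  # subcritical Hopf of the central point: unstable cycle collapsing is not
  # tracked grid-wide; detect a stability flip of a persisting central point
  # without cycle termination at that g (planar models only)
  # (the snlc event above carries the hysteresis evidence)

  # --- SNIC period-divergence refinement
  if (snic_refine) {
    snic_gs <- unique(vapply(Filter(function(e) e$type == "snic", events),
                             `[[`, numeric(1), "g_star"))
    T1 <- if (!is.null(cycles[[1]])) cycles[[1]]$period else Ts
    for (gs in snic_gs) {
      # sharpen g* by bisection on the stable fixed-point count, then walk
      # the period ladder just above it: on a SNIC branch the period grows
      # without bound as g -> g*+
      a <- min(1, gs + delta_g); b <- max(0, gs - delta_g)
      nst <- function(g) sum(vapply(find_fixed_points(model, g)$points,
                                    .is_stable, logical(1)))
      n_hi <- nst(a)
      while (a - b > delta_g * 1e-4) {
        m <- (a + b) / 2
        if (nst(m) > n_hi) b <- m else a <- m
      }
      t_long <- 4.5 * t_max
      max_period <- -Inf; amp_end <- NA; seed2 <- NULL
      for (dg in delta_g * c(0.5, 0.1, 0.02, 0.004, 8e-4)) {
        cm <- find_limit_cycle(model, min(1, a + dg), seed_state = seed2,
                               t_max = t_long)
        if (!is.null(cm)) {
          max_period <- max(max_period, cm$period)
          amp_end <- cm$amplitude
          seed2 <- cm$samples[1, ]
        }
        if (max_period > 150 * T1) break
      }
      if (!is.finite(max_period)) next
      for (k in seq_along(events))
        if (events[[k]]$type == "snic" && events[[k]]$g_star == gs) {
          events[[k]]$max_period <- max_period
          events[[k]]$amplitude_end <- amp_end
        }
    }
  }

  cb <- do.call(rbind, lapply(cycles[!vapply(cycles, is.null, logical(1))],
    function(cyc) data.frame(g = cyc$g, period = cyc$period,
                             amplitude = cyc$amplitude,
                             min = cyc$var_min[cyc$ref_var],
                             max = cyc$var_max[cyc$ref_var],
                             stability = cyc$stability)))

  ev_df <- if (length(events)) {
    do.call(rbind, lapply(events, function(e)
      data.frame(type = e$type, g_star = e$g_star,
                 max_period = if (!is.null(e$max_period)) e$max_period else NA,
                 amplitude_end = if (!is.null(e$amplitude_end)) e$amplitude_end else NA,
                 dist_to_cycle = if (!is.null(e$dist_to_cycle)) e$dist_to_cycle else NA)))
  } else data.frame(type = character(0), g_star = numeric(0),
                    max_period = numeric(0), amplitude_end = numeric(0),
                    dist_to_cycle = numeric(0))

  structure(list(g_grid = g_grid, fixed_points = fps, cycles = cycles,
                 cycle_branch = cb, events = ev_df, event_details = events,
                 fp_branches = .link_fp_branches(fps, match_tol),
                 model = model,
                 settings = list(delta_g = delta_g, oncycle_tol = oncycle_tol,
                                 hopf_amp_frac = hopf_amp_frac,
                                 t_max_factor = t_max_factor)),
            class = "bifurcation_diagram")
}

# largest real part of the complex eigenvalue pair of the fixed point
# nearest 'centre'; NA when no focus is found there
.central_re <- function(model, g, centre) {
  set <- find_fixed_points(model, g)
  if (!length(set$points)) return(NA_real_)
  d <- vapply(set$points, function(p) sqrt(sum((p$location - centre)^2)),
              numeric(1))
  p <- set$points[[which.min(d)]]
  im <- abs(Im(p$eigenvalues))
  if (!any(im > 1e-8)) return(NA_real_)
  max(Re(p$eigenvalues[im > 1e-8]))
}

# a stable<->unstable flip of a matched (non-focus) central point
.stab_flip <- function(hi_set, lo_set, tol) {
  if (!length(hi_set$points) || !length(lo_set$points)) return(FALSE)
  for (p in hi_set$points) {
    dists <- vapply(lo_set$points, function(q)
      sqrt(sum((q$location - p$location)^2)), numeric(1))
    j <- which.min(dists)
    if (dists[j] > tol) next
    if (.is_stable(p) != .is_stable(lo_set$points[[j]])) return(TRUE)
  }
  FALSE
}

# nearest-neighbour linking of fixed points across the grid
.link_fp_branches <- function(fps, link_tol) {
  rows <- list(); branches <- list()  # branches: list of last locations
  next_id <- 1L
  for (set in fps) {
    used <- rep(FALSE, length(branches))
    for (p in set$points) {
      d <- vapply(seq_along(branches), function(k)
        if (used[k]) Inf else sqrt(sum((branches[[k]] - p$location)^2)),
        numeric(1))
      if (length(d) && min(d) < link_tol) {
        k <- which.min(d); used[k] <- TRUE
        id <- k
      } else {
        branches[[next_id]] <- p$location
        used <- c(used, TRUE)
        id <- next_id
        next_id <- next_id + 1L
      }
      branches[[id]] <- p$location
      rows[[length(rows) + 1L]] <-
        data.frame(branch_id = id, g = set$g,
                   t(setNames(p$location, set$var_names)),
                   stability = p$stability)
    }
  }
  if (length(rows)) do.call(rbind, rows) else data.frame()
}

#' @export
print.bifurcation_diagram <- function(x, ...) {
  cat("<bifurcation_diagram>", length(x$g_grid), "g values;",
      nrow(x$cycle_branch), "cycle records;", nrow(x$events), "event(s)\n")
  if (nrow(x$events)) print(x$events, digits = 4)
  invisible(x)
}

#' Bifurcation diagram plot
#'
#' Cycle min/max envelope of the reference variable in black, stable fixed
#' points in green, unstable in red, events as vertical dashed lines.
#'
#' @param x a [bifurcation_diagram()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.bifurcation_diagram <- function(x, ...) {
  fb <- x$fp_branches
  cb <- x$cycle_branch
  vn <- .model_var_names(x$model)[1]
  yl <- range(c(if (nrow(cb)) c(cb$min, cb$max), if (nrow(fb)) fb[[vn]]),
              na.rm = TRUE)
  graphics::plot(NA, xlim = rev(range(x$g_grid)), ylim = yl,
                 xlab = "g", ylab = vn, ...)
  if (nrow(cb)) {
    graphics::lines(cb$g, cb$max); graphics::lines(cb$g, cb$min)
  }
  if (nrow(fb)) {
    stab <- fb$stability %in% c("stable_node", "stable_focus")
    graphics::points(fb$g[stab], fb[[vn]][stab], col = "darkgreen", pch = 16,
                     cex = 0.4)
    graphics::points(fb$g[!stab], fb[[vn]][!stab], col = "red", pch = 1,
                     cex = 0.4)
  }
  if (nrow(x$events))
    graphics::abline(v = x$events$g_star, lty = 2, col = "grey40")
  invisible(x)
}

#' Classify the clock-arrest transition of a diagram
#'
#' Aggregates the events of a [bifurcation_diagram()] into a single label
#' for the route from the oscillatory regime (g = 1) to the multistable
#' regime (g = 0):
#' \itemize{
#'   \item `"SNIC"`: stable fixed points are born on the cycle, the period
#'     grows beyond `period_factor` times the posterior period while the
#'     amplitude stays above `amp_frac` of its posterior value;
#'   \item `"HOPF_SUPER"`: the cycle amplitude collapses to zero at finite
#'     period with a complex eigenvalue pair crossing the imaginary axis
#'     (co-labelled `"PITCHFORK"` when a pitchfork event accompanies it);
#'   \item `"HOPF_SUB"`: the stable cycle dies at finite amplitude by
#'     merging with an unstable cycle (saddle-node of limit cycles);
#'   \item `"UNCLASSIFIED"` otherwise.
#' }
#' The period-divergence and on-cycle thresholds are operational choices
#' (exposed as arguments) separating a genuine SNIC from a Hopf followed
#' immediately by saddle-nodes; they are reported alongside the label.
#'
#' @param diagram a [bifurcation_diagram()].
#' @param period_factor period-divergence multiple for the SNIC test.
#' @param amp_frac minimal amplitude fraction for the SNIC test.
#' @return object of class `"transition_class"`: list with `class`,
#'   `colabels`, `evidence`.
#' @export
classify_transition <- function(diagram, period_factor = 100, amp_frac = 0.5) {
  ev <- diagram$events
  cb <- diagram$cycle_branch
  colabels <- character(0)
  cls <- "UNCLASSIFIED"
  evidence <- list()
  if (nrow(cb)) {
    T1 <- cb$period[which.max(cb$g)]
    A1 <- cb$amplitude[which.max(cb$g)]
    evidence$posterior_period <- T1
    evidence$posterior_amplitude <- A1
    snic <- ev[ev$type == "snic", , drop = FALSE]
    if (nrow(snic)) {
      maxp <- suppressWarnings(max(c(snic$max_period, cb$period), na.rm = TRUE))
      aend <- snic$amplitude_end[which.max(snic$g_star)]
      if (is.na(aend)) aend <- cb$amplitude[which.min(cb$g)]
      evidence$max_period <- maxp
      evidence$amplitude_at_event <- aend
      if (maxp > period_factor * T1 && aend >= amp_frac * A1)
        cls <- "SNIC"
    } else if (any(ev$type == "snlc")) {
      cls <- "HOPF_SUB"
      evidence$amplitude_at_event <- ev$amplitude_end[ev$type == "snlc"][1]
    } else if (any(ev$type == "hopf_super")) {
      cls <- "HOPF_SUPER"
      evidence$amplitude_at_event <-
        ev$amplitude_end[ev$type == "hopf_super"][1]
    }
    if (any(ev$type == "pitchfork")) colabels <- c(colabels, "PITCHFORK")
  }
  structure(list(class = cls, colabels = colabels, evidence = evidence,
                 events = ev),
            class = "transition_class")
}

#' @export
print.transition_class <- function(x, ...) {
  cat("<transition_class>", x$class,
      if (length(x$colabels)) paste("+", paste(x$colabels, collapse = " + ")),
      "\n")
  invisible(x)
}
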