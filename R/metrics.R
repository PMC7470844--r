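# Patterning-performance and wave-shape metrics.

#' Plug-in mutual information of a joint count table
#'
#' \eqn{I = \sum_{x,y} p(x,y) \log_2 \frac{p(x,y)}{p(x)p(y)}} with the
#' convention \eqn{0 \log 0 = 0}. For a perfect one-to-one readout of k
#' equiprobable classes this equals \eqn{\log_2 k}.
#'
#' @param joint_counts matrix of non-negative counts (rows: ideal fate,
#'   columns: realized fate).
#' @return mutual information in bits.
#' @examples
#' mutual_information(diag(3) * 10)  # log2(3)
#' @export
mutual_information <- function(joint_counts) {
  m <- as.matrix(joint_counts)
  if (!is.numeric(m) || any(m < 0)) stop("'joint_counts' must be non-negative")
  total <- sum(m)
  if (length(m) == 0 || total <= 0) stop("'joint_counts' must have positive total")
  p <- m / total
  px <- rowSums(p); py <- colSums(p)
  terms <- p * log2(p / outer(px, py))
  sum(terms[p > 0])
}

# deterministic per-stage child seeds derived from a base seed
.child_seed <- function(seed, stage, i = 0L) {
  s <- (as.numeric(seed) * 48271 + as.numeric(stage) * 30269 +
          as.numeric(i) * 1009) %% 2147483629
  as.integer(s + 1)
}

#' Reference conditions for the noise-robustness (MI) study
#'
#' The standard embryo and front used by the package for the mutual-
#' information comparison between clock-arrest routes: 100 cells, a
#' logistic front whose passage through the intermediate regime is slow
#' (steepness 0.012 per cell, speed of 33 cells per posterior period,
#' offset placed far enough left that every cell starts in the posterior
#' regime), and diffusion 0.2 per squared cell spacing. Under a front this
#' shallow the
#' Hopf-route model dwells long in its single-fixed-point window, where
#' noise erases the phase memory the oscillator carries; the SNIC-route
#' model keeps its phase pinned to the forming fixed points. The pattern
#' repeat is 33 cells, so a 100-cell embryo carries three repeats.
#'
#' @param model a gene-network model (used to measure the posterior
#'   period).
#' @param n_cells number of cells.
#' @param diffusion diffusion constant.
#' @param steepness,speed_cells_per_period,offset front geometry;
#'   `speed_cells_per_period` is converted to domain units per time via
#'   the model's posterior period.
#' @return list with `front` (a [morphogen_front()]) and `config` (an
#'   [embryo_config()]).
#' @export
mi_reference_conditions <- function(model, n_cells = 100, diffusion = 0.2,
                                    steepness = 0.012,
                                    speed_cells_per_period = 33,
                                    offset = NULL) {
  if (is.null(offset)) offset <- -(0.5 / steepness + 110)
  T0 <- .posterior_period(model)
  list(front = morphogen_front(steepness = steepness,
                               speed = speed_cells_per_period / T0,
                               offset = offset),
       config = embryo_config(n_cells = n_cells, diffusion = diffusion))
}

#' Phase-to-fate mutual-information experiment
#'
#' Measures how precisely the phase of the posterior clock is read into the
#' final fate pattern. The noise-free simulation defines the *ideal* fate
#' of every cell (the deterministic phase readout); stochastic replicates
#' at each copy-number scale \eqn{\Omega} give the *realized* fates. Counts
#' are pooled over cells and replicates into a joint table per
#' \eqn{\Omega}, and the plug-in mutual information is returned for each.
#'
#' @param model a segwave model.
#' @param config an [embryo_config()]; its `diffusion` and `seed` are used
#'   (`omega` is overridden per sweep point).
#' @param front a [morphogen_front()].
#' @param omegas copy-number scales to sweep.
#' @param n_replicates stochastic replicates per \eqn{\Omega}.
#' @param seed base seed; replicate seeds are derived deterministically so
#'   adding sweep points never changes earlier replicates.
#' @return list of `"mi_result"` objects: `bits`, `joint_counts`,
#'   `n_replicates`, `omega`, `diffusion`.
#' @export
mi_experiment <- function(model, config = embryo_config(),
                          front = morphogen_front(), omegas = c(1e3, 1e4),
                          n_replicates = 50, seed = config$seed) {
  cfg_det <- config
  cfg_det$omega <- Inf
  kym_det <- simulate_embryo(model, cfg_det, front)
  ideal <- call_fates(kym_det)$fates
  lev <- levels(ideal)
  lapply(seq_along(omegas), function(k) {
    om <- omegas[k]
    counts <- matrix(0L, length(lev), length(lev), dimnames = list(lev, lev))
    for (r in seq_len(n_replicates)) {
      cfg <- config
      cfg$omega <- om
      cfg$seed <- .child_seed(seed, k, r)
      realized <- call_fates(simulate_embryo(model, cfg, front))$fates
      counts <- counts + table(ideal, realized)
    }
    structure(list(bits = mutual_information(counts), joint_counts = counts,
                   n_replicates = n_replicates, omega = om,
                   diffusion = config$diffusion),
              class = "mi_result")
  })
}

#' @export
print.mi_result <- function(x, ...) {
  cat("<mi_result>", signif(x$bits, 4), "bits | omega", x$omega,
      "| D", x$diffusion, "|", x$n_replicates, "replicates\n")
  invisible(x)
}

#' Distribution of the reference variable at fixed g
#'
#' Samples the attractor of a single cell held at a fixed control-parameter
#' value (after a deterministic burn-in) and summarises the distribution of
#' the reference variable: histogram, inter-quantile spread and modality.
#' Past a Hopf bifurcation the attractor is a single focus and the
#' distribution collapses to a narrow unimodal peak; on the SNIC route the
#' relaxation-like cycle dwells near the future fixed points and the
#' distribution is bimodal.
#'
#' @param model a segwave model.
#' @param g fixed control-parameter value.
#' @param n_samples number of samples along the attractor.
#' @param burn_in burn-in time (default 40 linearization periods).
#' @param ref_var reference variable index.
#' @return list with `samples`, `histogram` ([graphics::hist()] object,
#'   not plotted), `spread` (10--90% inter-quantile range), `n_modes`.
#' @export
state_distribution <- function(model, g, n_samples = 2000, burn_in = NULL,
                               ref_var = 1) {
  Ts <- .period_scale(model)
  if (is.null(burn_in)) burn_in <- 40 * Ts
  y0 <- if (model$kind == "gene") c(2, 0.5, 0.1) else c(0.05, 0.7)
  flow <- function(t, y, p) list(.model_deriv(model, y, g))
  tr <- deSolve::lsoda(y0, c(0, burn_in), flow, rtol = 1e-8, atol = 1e-8)
  y1 <- as.numeric(tr[nrow(tr), -1])
  times <- seq(0, 20 * Ts, length.out = n_samples)
  out <- deSolve::lsoda(y1, times, flow, rtol = 1e-8, atol = 1e-8)
  u <- out[, ref_var + 1]
  h <- graphics::hist(u, breaks = 40, plot = FALSE)
  spread <- diff(quantile(u, c(0.1, 0.9), names = FALSE))
  # modality from a smoothed histogram with a prominence filter
  dens <- h$counts
  if (length(dens) >= 3)
    dens <- stats::filter(c(dens[1], dens, dens[length(dens)]), rep(1 / 3, 3))[
      2:(length(dens) + 1)]
  dens <- as.numeric(dens)
  n_modes <- if (diff(range(u)) < 1e-6) 1L else {
    # zero-padding lets mass piled against the histogram edges (dwell near
    # the extreme states) count as modes
    pk <- .find_peaks(c(0, dens, 0), prominence = 0.1 * max(dens))
    max(1L, length(pk))
  }
  list(samples = u, histogram = h, spread = spread, n_modes = n_modes, g = g)
}

# indices of local maxima with a minimal prominence (fall on both sides)
.find_peaks <- function(u, prominence) {
  n <- length(u)
  if (n < 3) return(integer(0))
  cand <- which(diff(sign(diff(u))) < 0) + 1L
  keep <- vapply(cand, function(i) {
    left <- min(u[1:i]); right <- min(u[i:n])
    (u[i] - max(left, right)) >= prominence
  }, logical(1))
  cand[keep]
}

# accept a numeric vector or list(x, value) as a spatial profile
.as_profile <- function(profile) {
  if (is.list(profile) && !is.null(profile$value)) {
    x <- if (!is.null(profile$x)) profile$x else seq_along(profile$value)
    list(x = x, value = as.numeric(profile$value))
  } else {
    list(x = seq_along(profile), value = as.numeric(profile))
  }
}

#' Extract a spatial wave profile from a kymograph
#'
#' Takes the spatial profile of one variable at a chosen time and restricts
#' it to the region where waves are actually present: cells whose local
#' oscillation amplitude (over a window of one posterior period around the
#' chosen time) exceeds `min_amp_frac` of the maximal amplitude, and whose
#' control parameter lies inside `g_range`. This excludes both the frozen
#' anterior pattern and regions where the oscillation has collapsed (the
#' damped transition zone of Hopf-type models).
#'
#' @param kymograph a [simulate_embryo()] or [simulate_phase_lattice()]
#'   result.
#' @param time_frac time of the snapshot, as a fraction of the simulated
#'   interval.
#' @param variable variable index for the profile.
#' @param g_range keep cells with local g inside this range.
#' @param min_amp_frac minimal local amplitude, as a fraction of the
#'   largest local amplitude at that time.
#' @return list with `x` (positions) and `value` (profile), suitable for
#'   [wave_asymmetry()] and [measure_wavelength()].
#' @export
wave_profile <- function(kymograph, time_frac = 0.5, variable = 1,
                         g_range = c(0.02, 0.98), min_amp_frac = 0.2) {
  times <- kymograph$times
  it <- which.min(abs(times - max(times) * time_frac))
  T0 <- if (!is.null(kymograph$config$T0)) kymograph$config$T0
  else if (!is.null(kymograph$config$omega_max))
    2 * pi / kymograph$config$omega_max
  else diff(range(times)) / 20
  win <- which(abs(times - times[it]) <= T0 / 2)
  amp <- apply(kymograph$states[win, , variable, drop = FALSE], 2,
               function(u) diff(range(u)))
  g <- kymograph$g_values[it, ]
  sel <- amp >= min_amp_frac * max(amp) & g >= g_range[1] & g <= g_range[2]
  if (!any(sel)) stop("no cells with active waves in the requested window")
  list(x = kymograph$positions[sel],
       value = kymograph$states[it, sel, variable], time = times[it])
}

#' Sawtooth asymmetry of a spatial wave profile
#'
#' For each full period of the profile (traversed in the direction of
#' increasing position, anterior to posterior) the index is the ratio of
#' the steepest descending slope to the steepest ascending slope; the
#' median over periods is returned. Mirror-symmetric waves (a sine) give 1;
#' relaxation-like waves, which fall fast and recover slowly (or vice
#' versa), give an index away from 1.
#'
#' @param profile numeric vector, or list with `x` and `value`.
#' @param smooth_window moving-average window (samples) applied before
#'   differentiation.
#' @return positive asymmetry index.
#' @export
wave_asymmetry <- function(profile, smooth_window = 3) {
  p <- .as_profile(profile)
  u <- p$value
  if (smooth_window > 1 && length(u) > smooth_window) {
    k <- rep(1 / smooth_window, smooth_window)
    sm <- stats::filter(u, k)
    u[!is.na(sm)] <- sm[!is.na(sm)]
  }
  mid <- (max(u) + min(u)) / 2
  up <- which(u[-length(u)] < mid & u[-1] >= mid)
  down <- which(u[-length(u)] > mid & u[-1] <= mid)
  if (length(up) + length(down) < 2)
    stop("profile must cross its mid-level at least twice")
  if (length(up) < 2) stop("profile must span at least one full wavelength")
  slopes <- diff(u) / diff(p$x)
  idx <- vapply(seq_len(length(up) - 1), function(k) {
    seg <- up[k]:up[k + 1]
    s <- slopes[seg[-length(seg)]]
    fall <- -min(s); rise <- max(s)
    if (rise <= 0) return(NA_real_)
    fall / rise
  }, numeric(1))
  idx <- idx[is.finite(idx)]
  if (!length(idx)) stop("no complete period with both flanks found")
  median(idx)
}

#' Measured local wavelength of a spatial profile
#'
#' Detects peaks on a lightly smoothed profile (moving average, prominence
#' filter) and returns the spacing between consecutive peaks, assigned to
#' the midpoint between them.
#'
#' @param profile numeric vector, or list with `x` and `value`.
#' @param smooth_window moving-average window in samples.
#' @param prominence_frac minimal peak prominence as a fraction of the
#'   profile range.
#' @return object of class `"wavelength_series"`: list with `positions`
#'   (midpoints), `spacing` (local wavelength), `peaks` (peak positions).
#' @export
measure_wavelength <- function(profile, smooth_window = 3,
                               prominence_frac = 0.1) {
  p <- .as_profile(profile)
  u <- p$value
  if (smooth_window > 1 && length(u) > smooth_window) {
    k <- rep(1 / smooth_window, smooth_window)
    sm <- stats::filter(u, k)
    u[!is.na(sm)] <- sm[!is.na(sm)]
  }
  pk <- .find_peaks(u, prominence = prominence_frac * diff(range(u)))
  if (length(pk) < 2) stop("need at least 2 peaks to measure a wavelength")
  xp <- p$x[pk]
  structure(list(positions = (xp[-1] + xp[-length(xp)]) / 2,
                 spacing = diff(xp), peaks = xp),
            class = "wavelength_series")
}

#' @export
print.wavelength_series <- function(x, ...) {
  cat("<wavelength_series>", length(x$spacing), "spacings, range",
      paste(signif(range(x$spacing), 4), collapse = " - "), "\n")
  invisible(x)
}

#' Predicted local wavelength from the period profile
#'
#' For a clock-and-wavefront pattern laid down by a front moving at
#' constant speed, the local wavelength at a position with local period
#' \eqn{T(x)} is \deqn{S(x) = \frac{S}{1 - T_0 / T(x)},} where \eqn{S} is
#' the final pattern repeat (somite size) and \eqn{T_0} the posterior
#' period. Where the clock still runs at the posterior period
#' (\eqn{T(x) = T_0}) the wavelength is infinite (locally synchronised
#' cells); as \eqn{T(x) \to \infty} it converges to the pattern repeat
#' \eqn{S}.
#'
#' @param S somite (pattern repeat) size.
#' @param T0 posterior period.
#' @param Tx local period(s), each >= `T0`.
#' @return predicted wavelength(s); `Inf` where `Tx == T0`.
#' @export
predicted_wavelength <- function(S, T0, Tx) {
  stopifnot(S > 0, T0 > 0)
  if (any(Tx < T0)) stop("local period 'Tx' cannot be below the posterior period")
  ifelse(is.infinite(Tx), S, S / (1 - T0 / Tx))
}
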