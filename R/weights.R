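#' Module weight scheme
#'
#' Defines how the influence of the dynamic (clock) and static (fate) modules
#' is weighted as a function of the control parameter \eqn{g \in [0,1]}.
#' Every family satisfies the boundary identities
#' \eqn{\theta_D(0) = 0}, \eqn{\theta_D(1) = 1}, \eqn{\theta_S(0) = 1},
#' \eqn{\theta_S(1) = 0}, and both weights are monotone on \eqn{[0,1]}.
#'
#' The power families use \eqn{\theta_D(g) = g^e} and
#' \eqn{\theta_S(g) = (1-g)^e} with exponent \eqn{e} = 1 (linear), 2
#' (quadratic), 3 (cubic), 4 (quartic), or a user value
#' (`custom_exponent`). The `hill` family uses the normalised sigmoid
#' \eqn{\theta_D(g) = g^n (1 + K^n) / (g^n + K^n)} (and the mirror image in
#' \eqn{1-g} for \eqn{\theta_S}), so that shifting the threshold `K` moves
#' the crossover of the weights along \eqn{g}: a larger `K` depresses both
#' weights at intermediate \eqn{g}, carving out an intermediate regime where
#' degradation (or the intermediate module) dominates.
#'
#' An optional intermediate-module weight
#' \eqn{\theta_I(g) = c \, g (1 - g)} (with \eqn{c} = `intermediate_scale`)
#' vanishes at both ends of the \eqn{g} range, so the pure clock and pure
#' fate landscapes are unaffected by the intermediate module.
#'
#' @param family one of `"linear"`, `"quadratic"`, `"cubic"`, `"quartic"`,
#'   `"hill"`, `"custom_exponent"`.
#' @param exponent positive exponent, used only by `"custom_exponent"`.
#' @param hill_threshold threshold `K` in (0, 1) of the `"hill"` family.
#' @param hill_coefficient positive Hill coefficient `n` of the `"hill"`
#'   family.
#' @param intermediate_enabled logical; if `TRUE` the intermediate-module
#'   weight \eqn{\theta_I} is active.
#' @param intermediate_scale positive scale `c` of \eqn{\theta_I}.
#' @return an object of class `"weight_scheme"`.
#' @seealso [evaluate_weights()]
#' @examples
#' evaluate_weights(0.5, weight_scheme("quadratic"))
#' @export
weight_scheme <- function(family = c("linear", "quadratic", "cubic", "quartic",
                                     "hill", "custom_exponent"),
                          exponent = NULL,
                          hill_threshold = 0.5,
                          hill_coefficient = 4,
                          intermediate_enabled = FALSE,
                          intermediate_scale = 4) {
  family <- match.arg(family)
  if (family == "custom_exponent") {
    if (is.null(exponent) || !is.numeric(exponent) || length(exponent) != 1L ||
        !is.finite(exponent) || exponent <= 0)
      stop("'exponent' must be a single positive number for family 'custom_exponent'")
  }
  if (family == "hill") {
    if (!is.numeric(hill_threshold) || length(hill_threshold) != 1L ||
        hill_threshold <= 0 || hill_threshold >= 1)
      stop("'hill_threshold' must lie in (0, 1)")
    if (!is.numeric(hill_coefficient) || length(hill_coefficient) != 1L ||
        hill_coefficient <= 0)
      stop("'hill_coefficient' must be positive")
  }
  if (!is.logical(intermediate_enabled) || length(intermediate_enabled) != 1L)
    stop("'intermediate_enabled' must be TRUE or FALSE")
  if (!is.numeric(intermediate_scale) || length(intermediate_scale) != 1L ||
      intermediate_scale <= 0)
    stop("'intermediate_scale' must be positive")
  structure(
    list(family = family,
         exponent = if (family == "custom_exponent") as.numeric(exponent) else NULL,
         hill_threshold = as.numeric(hill_threshold),
         hill_coefficient = as.numeric(hill_coefficient),
         intermediate_enabled = intermediate_enabled,
         intermediate_scale = as.numeric(intermediate_scale)),
    class = "weight_scheme")
}

#' @export
print.weight_scheme <- function(x, ...) {
  cat("<weight_scheme> family:", x$family)
  if (x$family == "custom_exponent") cat(" (exponent ", x$exponent, ")", sep = "")
  if (x$family == "hill")
    cat(" (K = ", x$hill_threshold, ", n = ", x$hill_coefficient, ")", sep = "")
  if (x$intermediate_enabled)
    cat(" + intermediate (scale ", x$intermediate_scale, ")", sep = "")
  cat("\n")
  invisible(x)
}

# exponent of the power families; NA for hill
.weight_exponent <- function(scheme) {
  switch(scheme$family,
         linear = 1, quadratic = 2, cubic = 3, quartic = 4,
         custom_exponent = scheme$exponent,
         hill = NA_real_)
}

#' Evaluate module weights at a control-parameter value
#'
#' Returns the weights of the dynamic, static and intermediate modules at
#' `g`. The intermediate weight is 0 when the scheme does not enable the
#' intermediate module.
#'
#' @param g value(s) of the control parameter, each in \[0, 1\].
#' @param scheme a [weight_scheme()].
#' @return a list with numeric components `theta_d`, `theta_s`, `theta_i`
#'   (same length as `g`).
#' @examples
#' evaluate_weights(c(0, 0.5, 1), weight_scheme("cubic", intermediate_enabled = TRUE,
#'                                              intermediate_scale = 1))
#' @export
evaluate_weights <- function(g, scheme) {
  if (!inherits(scheme, "weight_scheme")) stop("'scheme' must be a weight_scheme")
  if (!is.numeric(g) || any(!is.finite(g))) stop("'g' must be finite numeric")
  if (any(g < 0 | g > 1)) stop("'g' must lie in [0, 1]")
  if (scheme$family == "hill") {
    K <- scheme$hill_threshold
    n <- scheme$hill_coefficient
    norm <- 1 + K^n
    theta_d <- g^n * norm / (g^n + K^n)
    theta_s <- (1 - g)^n * norm / ((1 - g)^n + K^n)
  } else {
    e <- .weight_exponent(scheme)
    theta_d <- g^e
    theta_s <- (1 - g)^e
  }
  theta_i <- if (scheme$intermediate_enabled)
    scheme$intermediate_scale * g * (1 - g) else rep(0, length(g))
  list(theta_d = theta_d, theta_s = theta_s, theta_i = theta_i)
}

# integer code + parameter vector handed to the C++ stepper
.weights_code <- function(scheme) {
  fam <- match(scheme$family,
               c("linear", "quadratic", "cubic", "quartic", "hill",
                 "custom_exponent"))
  list(family = fam,
       exponent = if (fam == 6L) scheme$exponent else as.numeric(fam),
       hill_k = scheme$hill_threshold,
       hill_n = scheme$hill_coefficient,
       ienabled = as.integer(scheme$intermediate_enabled),
       iscale = scheme$intermediate_scale)
}
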