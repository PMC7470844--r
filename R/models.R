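#' 3-gene two-module network model
#'
#' A cell-autonomous model of three genes (A, B, C) under the control of two
#' transcriptional modules. The dynamic module \eqn{D(P)} is a repressilator:
#' gene \eqn{i} is repressed by its cyclic predecessor (A by C, B by A, C by
#' B) through a decreasing Hill function with threshold `K_dyn` and
#' coefficient `h_dyn`, scaled by `beta_dyn`. The static module \eqn{S(P)}
#' encodes a tristable landscape by mutual repression: gene \eqn{i} is
#' repressed by *both* other genes, a product of decreasing Hill functions
#' with per-pair thresholds `K_stat[i, j]`, scaled by `beta_stat`. Linear
#' degradation closes the system:
#' \deqn{\dot P_i = \theta_D(g) \frac{\beta_D}{1 + (P_{i-1}/K_D)^{h_D}}
#'   + \theta_S(g) \frac{\beta_S}{\prod_{j \ne i} 1 + (P_j/K_{ij})^{h_S}}
#'   - \delta P_i.}
#'
#' With the default constants the pure clock (`g = 1`) has a stable limit
#' cycle and the pure landscape (`g = 0`) has three stable fixed points
#' related by cyclic permutation of the genes; with quadratic weights the
#' clock dies in a supercritical Hopf bifurcation near `g = 0.72` while with
#' linear weights the three fates are born directly on the cycle (SNIC).
#'
#' @param beta_dyn maximal production rate of the dynamic module.
#' @param K_dyn repression threshold of the repressilator.
#' @param h_dyn Hill coefficient of the dynamic module (>= 2).
#' @param beta_stat maximal production rate of the static module.
#' @param K_stat 3x3 matrix of positive repression thresholds;
#'   `K_stat[i, j]` is the threshold at which gene `j` represses gene `i`
#'   in the static module (off-diagonal entries only). A scalar is recycled.
#' @param h_stat Hill coefficient of the static module (>= 2).
#' @param degradation first-order degradation rate (same for all genes).
#' @param weights a [weight_scheme()].
#' @param gene_names names of the three genes.
#' @return object of class `c("gene_network_model", "segwave_model")`.
#' @seealso [make_fixture()], [gene_field()], [simulate_embryo()]
#' @export
gene_network_model <- function(beta_dyn = 3.4, K_dyn = 1, h_dyn = 4,
                               beta_stat = 3.4, K_stat = 1, h_stat = 3,
                               degradation = 1,
                               weights = weight_scheme("quadratic"),
                               gene_names = c("A", "B", "C")) {
  stopifnot(is.numeric(beta_dyn), beta_dyn > 0,
            is.numeric(K_dyn), K_dyn > 0,
            is.numeric(h_dyn), h_dyn >= 2,
            is.numeric(beta_stat), beta_stat > 0,
            is.numeric(h_stat), h_stat >= 2,
            is.numeric(degradation), degradation > 0,
            length(gene_names) == 3L)
  if (length(K_stat) == 1L) K_stat <- matrix(K_stat, 3, 3)
  K_stat <- as.matrix(K_stat)
  if (!all(dim(K_stat) == c(3L, 3L)) || any(K_stat[row(K_stat) != col(K_stat)] <= 0))
    stop("'K_stat' must be a 3x3 matrix with positive off-diagonal entries")
  diag(K_stat) <- NA_real_  # self-thresholds are never used
  if (!inherits(weights, "weight_scheme")) stop("'weights' must be a weight_scheme")
  structure(
    list(kind = "gene", gene_names = as.character(gene_names),
         beta_dyn = beta_dyn, K_dyn = K_dyn, h_dyn = h_dyn,
         beta_stat = beta_stat, K_stat = K_stat, h_stat = h_stat,
         degradation = degradation, weights = weights),
    class = c("gene_network_model", "segwave_model"))
}

#' Planar geometric (gene-free) two-module model
#'
#' Abstract 2D model in variables \eqn{(y, z)}. The dynamic module is a
#' non-harmonic oscillator on the unit circle, in polar form
#' \eqn{\dot r = \lambda r (1 - r)},
#' \eqn{\dot\theta = \omega_0 (1 - \rho \cos\theta)}: the circle is an
#' attracting limit cycle traversed at a non-uniform angular speed (slow
#' near \eqn{\theta = 0} for \eqn{\rho > 0}). The static module is a
#' one-dimensional cubic landscape along \eqn{y} with stable points at
#' `stable_y` and an unstable point at `unstable_y` (plus \eqn{\dot z = -z}):
#' \deqn{S(y, z) = k\,\bigl(-(y - y_s^+)(y - y_s^-)(y - y_u),\; -z\bigr).}
#' The optional intermediate module \eqn{I(y, z) = \mu(-y, -z)} is a single
#' globally attracting sink at the origin; its weight
#' \eqn{\theta_I = c\,g(1-g)} is controlled by the weight scheme.
#'
#' `variant = "hopf_subcritical"` replaces the radial relaxation of the
#' dynamic module with the subcritical normal form
#' \eqn{\dot r = \lambda_s r(\nu + b r^2 - c r^4)} (defaults \eqn{\nu = -2},
#' \eqn{b = 10}, \eqn{c = 8}: stable cycle at \eqn{r = 1}, unstable cycle at
#' \eqn{r = 0.5}, stable origin), which turns the clock-arrest
#' sequence into a saddle-node of limit cycles followed by saddle-nodes of
#' fixed points. `"snic"` and `"hopf_supercritical"` share the standard
#' dynamic module; the supercritical-Hopf phenotype is produced by the
#' weight scheme (cubic/quartic weights plus intermediate module).
#'
#' @param lambda_radial relaxation rate toward the unit circle.
#' @param omega0 mean angular speed (rad / time).
#' @param rho non-harmonicity of the angular speed, in \[0, 1).
#' @param static_strength scale of the static landscape.
#' @param stable_y positions of the two stable fixed points along y.
#' @param unstable_y position of the unstable fixed point along y (between
#'   the stable ones).
#' @param mu_intermediate strength of the intermediate sink at the origin.
#' @param variant `"snic"`, `"hopf_supercritical"` or `"hopf_subcritical"`.
#' @param sub_nu,sub_b,sub_c,sub_lambda parameters of the subcritical radial term.
#' @param weights a [weight_scheme()].
#' @return object of class `c("geometric_model", "segwave_model")`.
#' @seealso [make_fixture()], [geometric_field()]
#' @export
geometric_model <- function(lambda_radial = 10, omega0 = 2 * pi, rho = 0.7,
                            static_strength = 1, stable_y = c(1, -1),
                            unstable_y = 0, mu_intermediate = 4,
                            variant = c("snic", "hopf_supercritical",
                                        "hopf_subcritical"),
                            sub_nu = -2, sub_b = 10, sub_c = 8, sub_lambda = 2,
                            weights = weight_scheme("linear")) {
  variant <- match.arg(variant)
  stopifnot(lambda_radial > 0, omega0 > 0, rho >= 0, rho < 1,
            static_strength > 0, length(stable_y) == 2L, mu_intermediate > 0)
  sy <- sort(as.numeric(stable_y), decreasing = TRUE)  # (y_s^+, y_s^-)
  if (!(unstable_y < sy[1] && unstable_y > sy[2]))
    stop("'unstable_y' must lie between the two stable positions")
  if (!inherits(weights, "weight_scheme")) stop("'weights' must be a weight_scheme")
  structure(
    list(kind = "geometric", var_names = c("y", "z"),
         lambda_radial = lambda_radial, omega0 = omega0, rho = rho,
         static_strength = static_strength, stable_y = sy,
         unstable_y = as.numeric(unstable_y),
         mu_intermediate = mu_intermediate, variant = variant,
         sub_nu = sub_nu, sub_b = sub_b, sub_c = sub_c, sub_lambda = sub_lambda,
         weights = weights),
    class = c("geometric_model", "segwave_model"))
}

#' @export
print.gene_network_model <- function(x, ...) {
  cat("<gene_network_model> genes", paste(x$gene_names, collapse = ","),
      "| beta_dyn", x$beta_dyn, "h_dyn", x$h_dyn,
      "| beta_stat", x$beta_stat, "h_stat", x$h_stat,
      "| degradation", x$degradation, "\n  weights:")
  print(x$weights)
  invisible(x)
}

#' @export
print.geometric_model <- function(x, ...) {
  cat("<geometric_model> variant", x$variant,
      "| lambda", x$lambda_radial, "omega0", signif(x$omega0, 4),
      "rho", x$rho, "| stable_y", paste(signif(x$stable_y, 4), collapse = "/"),
      "unstable_y", x$unstable_y, "\n  weights:")
  print(x$weights)
  invisible(x)
}

#' Cell state
#'
#' Bundles the per-cell dynamical variables with the local value of the
#' control parameter. Gene-model states are concentrations (length 3,
#' non-negative); geometric states are \eqn{(y, z)} coordinates (length 2).
#'
#' @param variables numeric vector of state variables.
#' @param g control parameter in \[0, 1\].
#' @export
cell_state <- function(variables, g) {
  if (!is.numeric(variables) || any(!is.finite(variables)))
    stop("'variables' must be finite numeric")
  if (!is.numeric(g) || length(g) != 1L || !is.finite(g) || g < 0 || g > 1)
    stop("'g' must be a single value in [0, 1]")
  structure(list(variables = as.numeric(variables), g = g),
            class = "cell_state")
}

# cyclic predecessor of each gene: A <- C, B <- A, C <- B
.gene_pred <- c(3L, 1L, 2L)
.gene_others <- list(c(2L, 3L), c(3L, 1L), c(1L, 2L))

.hill_rep <- function(x, K, h) 1 / (1 + (x / K)^h)

# production terms of the two modules (always >= 0), used by the field and
# by the copy-number noise amplitude
.gene_production <- function(P, g, model) {
  w <- evaluate_weights(g, model$weights)
  D <- model$beta_dyn * .hill_rep(P[.gene_pred], model$K_dyn, model$h_dyn)
  S <- vapply(1:3, function(i) {
    js <- .gene_others[[i]]
    model$beta_stat *
      .hill_rep(P[js[1]], model$K_stat[i, js[1]], model$h_stat) *
      .hill_rep(P[js[2]], model$K_stat[i, js[2]], model$h_stat)
  }, numeric(1))
  w$theta_d * D + w$theta_s * S
}

.gene_deriv <- function(P, g, model) {
  .gene_production(P, g, model) - model$degradation * P
}

.geo_dynamic <- function(yz, model) {
  y <- yz[1]; z <- yz[2]
  r <- sqrt(y^2 + z^2)
  if (r == 0) return(c(0, 0))
  radial <- if (model$variant == "hopf_subcritical")
    model$sub_lambda * (model$sub_nu + model$sub_b * r^2 - model$sub_c * r^4)
  else
    model$lambda_radial * (1 - r)
  ang <- model$omega0 * (1 - model$rho * y / r)
  c(radial * y - ang * z, radial * z + ang * y)
}

.geo_static <- function(yz, model) {
  y <- yz[1]; z <- yz[2]
  s <- model$stable_y
  model$static_strength *
    c(-(y - s[1]) * (y - s[2]) * (y - model$unstable_y), -z)
}

.geo_deriv <- function(yz, g, model) {
  w <- evaluate_weights(g, model$weights)
  out <- w$theta_d * .geo_dynamic(yz, model) +
    w$theta_s * .geo_static(yz, model)
  if (w$theta_i > 0)
    out <- out + w$theta_i * model$mu_intermediate * c(-yz[1], -yz[2])
  out
}

# single dispatch point used by the bifurcation and metrics code
.model_deriv <- function(model, P, g) {
  if (model$kind == "gene") .gene_deriv(P, g, model) else .geo_deriv(P, g, model)
}

.model_nvar <- function(model) if (model$kind == "gene") 3L else 2L

.model_var_names <- function(model)
  if (model$kind == "gene") model$gene_names else model$var_names

#' Evaluate the 3-gene vector field
#'
#' Combined field \eqn{\theta_D D(P) + \theta_S S(P) - \delta P} of a
#' [gene_network_model()] at a [cell_state()].
#'
#' @param state a [cell_state()] with three non-negative concentrations.
#' @param model a [gene_network_model()].
#' @return numeric vector of three time-derivatives.
#' @export
gene_field <- function(state, model) {
  if (!inherits(state, "cell_state")) stop("'state' must be a cell_state")
  if (!inherits(model, "gene_network_model"))
    stop("'model' must be a gene_network_model")
  if (length(state$variables) != 3L) stop("gene-model states have 3 variables")
  if (any(state$variables < 0)) stop("concentrations must be non-negative")
  .gene_deriv(state$variables, state$g, model)
}

#' Evaluate the geometric vector field
#'
#' Combined field \eqn{\theta_D D + \theta_S S + \theta_I I} of a
#' [geometric_model()] at a [cell_state()].
#'
#' @param state a [cell_state()] with variables \eqn{(y, z)}.
#' @param model a [geometric_model()].
#' @return numeric vector of two time-derivatives.
#' @export
geometric_field <- function(state, model) {
  if (!inherits(state, "cell_state")) stop("'state' must be a cell_state")
  if (!inherits(model, "geometric_model"))
    stop("'model' must be a geometric_model")
  if (length(state$variables) != 2L) stop("geometric states have 2 variables")
  .geo_deriv(state$variables, state$g, model)
}

#' Reference model fixtures
#'
#' Fully parameterised instances of the model families used throughout the
#' package:
#' \describe{
#'   \item{`gene_model1`}{3-gene model, quadratic weights. The clock stops
#'     through a supercritical Hopf bifurcation (near g = 0.72 with the
#'     default constants), followed by three simultaneous saddle-nodes.}
#'   \item{`gene_model2`}{3-gene model, linear weights. The three fates are
#'     born on the cycle (three simultaneous SNIC bifurcations).}
#'   \item{`geo_model1`}{geometric model, cubic weights plus intermediate
#'     module: supercritical Hopf.}
#'   \item{`geo_model2`}{geometric model, linear weights, no intermediate
#'     module: SNIC.}
#'   \item{`geo_model3`}{geometric model, subcritical dynamic module, cubic
#'     weights plus intermediate module: saddle-node of limit cycles.}
#'   \item{`gene_model1_asym`, `gene_model2_asym`}{as above with the
#'     repression thresholds of gene A by genes B and C lowered (stronger
#'     repression of A), breaking the three-fold symmetry of the static
#'     landscape.}
#'   \item{`geo_asym_unstable`}{`geo_model2` with the unstable fixed point
#'     of the static landscape moved along y.}
#'   \item{`geo_asym_stable`}{`geo_model2` with one stable fixed point moved
#'     off the unit circle.}
#' }
#'
#' @param name fixture name.
#' @return a [gene_network_model()] or [geometric_model()].
#' @export
make_fixture <- function(name = c("gene_model1", "gene_model2",
                                  "geo_model1", "geo_model2", "geo_model3",
                                  "gene_model1_asym", "gene_model2_asym",
                                  "geo_asym_unstable", "geo_asym_stable")) {
  name <- match.arg(name)
  asym_K <- function() {
    K <- matrix(1, 3, 3)
    K[1, 2] <- K[1, 3] <- 0.75  # gene A repressed more strongly by B and C
    K
  }
  switch(name,
    gene_model1 = gene_network_model(weights = weight_scheme("quadratic")),
    gene_model2 = gene_network_model(weights = weight_scheme("linear")),
    gene_model1_asym = gene_network_model(weights = weight_scheme("quadratic"),
                                          K_stat = asym_K()),
    gene_model2_asym = gene_network_model(weights = weight_scheme("linear"),
                                          K_stat = asym_K()),
    geo_model1 = geometric_model(variant = "hopf_supercritical",
                                 weights = weight_scheme("cubic",
                                                         intermediate_enabled = TRUE)),
    geo_model2 = geometric_model(variant = "snic",
                                 weights = weight_scheme("linear")),
    geo_model3 = geometric_model(variant = "hopf_subcritical",
                                 weights = weight_scheme("cubic",
                                                         intermediate_enabled = TRUE)),
    geo_asym_unstable = geometric_model(variant = "snic", unstable_y = 0.3,
                                        weights = weight_scheme("linear")),
    geo_asym_stable = geometric_model(variant = "snic",
                                      stable_y = c(1.4, -1),
                                      weights = weight_scheme("linear")))
}
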