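# Configuration round-tripping, tidy CSV output and figure-level
# experiment recipes.

.SCHEMA_VERSION <- "1"

.config_type <- function(obj) {
  if (inherits(obj, "gene_network_model")) "gene_network_model"
  else if (inherits(obj, "geometric_model")) "geometric_model"
  else if (inherits(obj, "weight_scheme")) "weight_scheme"
  else if (inherits(obj, "morphogen_front")) "morphogen_front"
  else if (inherits(obj, "embryo_config")) "embryo_config"
  else if (inherits(obj, "phase_lattice_config")) "phase_lattice_config"
  else if (inherits(obj, "experiment_recipe")) "experiment_recipe"
  else stop("unsupported object type")
}

.obj_to_list <- function(obj) {
  out <- unclass(obj)
  if (!is.null(out$weights)) out$weights <- .obj_to_list(out$weights)
  if (!is.null(out$K_stat)) {
    K <- out$K_stat; diag(K) <- 1
    out$K_stat <- lapply(seq_len(nrow(K)), function(i) as.numeric(K[i, ]))
  }
  if (!is.null(out$frequency_profile)) out$frequency_profile <- NULL
  out <- out[!vapply(out, is.null, logical(1))]
  c(list(schema_version = .SCHEMA_VERSION, type = .config_type(obj)), out)
}

#' Write a configuration object
#'
#' Serialises a model, front, embryo, phase-lattice or recipe object to
#' YAML (`.yaml`/`.yml`) or JSON (`.json`), with an explicit schema
#' version, so that [load_config()] reproduces an equal object.
#'
#' @param obj the object to write.
#' @param path output path; the extension picks the format.
#' @return `path`, invisibly.
#' @export
write_config <- function(obj, path) {
  lst <- .obj_to_list(obj)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(lst, path, precision = 15)
  } else if (ext == "json") {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  } else stop("unsupported config extension: ", ext)
  invisible(path)
}

# constructor registry with the exact accepted fields per type
.config_builders <- function() list(
  weight_scheme = list(
    fields = c("family", "exponent", "hill_threshold", "hill_coefficient",
               "intermediate_enabled", "intermediate_scale"),
    build = function(a) do.call(weight_scheme, a)),
  gene_network_model = list(
    fields = c("kind", "gene_names", "beta_dyn", "K_dyn", "h_dyn",
               "beta_stat", "K_stat", "h_stat", "degradation", "weights"),
    build = function(a) {
      a$kind <- NULL
      if (!is.null(a$K_stat)) a$K_stat <- do.call(rbind, lapply(a$K_stat, unlist))
      if (!is.null(a$weights)) a$weights <- .build_config(a$weights)
      do.call(gene_network_model, a)
    }),
  geometric_model = list(
    fields = c("kind", "var_names", "lambda_radial", "omega0", "rho",
               "static_strength", "stable_y", "unstable_y",
               "mu_intermediate", "variant", "sub_nu", "sub_b", "sub_c", "sub_lambda",
               "weights"),
    build = function(a) {
      a$kind <- NULL; a$var_names <- NULL
      if (!is.null(a$stable_y)) a$stable_y <- unlist(a$stable_y)
      if (!is.null(a$weights)) a$weights <- .build_config(a$weights)
      do.call(geometric_model, a)
    }),
  morphogen_front = list(
    fields = c("steepness", "speed", "shape", "offset"),
    build = function(a) do.call(morphogen_front, a)),
  embryo_config = list(
    fields = c("n_cells", "domain_length", "dt", "t_max", "diffusion",
               "omega", "noise_floor", "seed", "initial_condition",
               "init_state", "save_every"),
    build = function(a) {
      if (!is.null(a$omega) && is.character(a$omega)) a$omega <- Inf
      do.call(embryo_config, a)
    }),
  phase_lattice_config = list(
    fields = c("n_oscillators", "omega_max", "coupling", "speed",
               "steepness", "offset", "dt", "t_max", "seed"),
    build = function(a) do.call(phase_lattice_config, a)),
  experiment_recipe = list(
    fields = c("name", "overrides", "seed"),
    build = function(a) do.call(experiment_recipe, a))
)

.build_config <- function(lst) {
  if (is.null(lst$type)) stop("config is missing the 'type' field")
  ver <- lst$schema_version
  if (!is.null(ver) && !identical(as.character(ver), .SCHEMA_VERSION))
    stop("config schema version mismatch: found ", ver,
         ", expected ", .SCHEMA_VERSION)
  reg <- .config_builders()
  b <- reg[[lst$type]]
  if (is.null(b)) stop("unknown config type: ", lst$type)
  args <- lst[setdiff(names(lst), c("schema_version", "type"))]
  unknown <- setdiff(names(args), b$fields)
  if (length(unknown))
    stop("unknown field(s) in ", lst$type, " config: ",
         paste(unknown, collapse = ", "))
  tryCatch(b$build(args), error = function(e)
    stop("invalid ", lst$type, " config: ", conditionMessage(e), call. = FALSE))
}

#' Load and validate a configuration file
#'
#' Reads a YAML or JSON file written by [write_config()] (or by hand),
#' checks the schema version and the `type` field, rejects unknown keys,
#' and rebuilds the object through its constructor so that all invariants
#' are re-validated and defaults are applied to omitted fields.
#'
#' @param path path to a `.yaml`, `.yml` or `.json` file.
#' @return the validated object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  lst <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE,
                                              simplifyMatrix = FALSE)
  else stop("unsupported config extension: ", ext)
  .build_config(lst)
}

#' Tidy CSV export of a kymograph
#'
#' Long format with columns `time`, `cell_index`, `position`, `g`, and one
#' column per state variable.
#'
#' @param kymograph a kymograph.
#' @param path output CSV path.
#' @param thin keep every `thin`-th frame.
#' @return `path`, invisibly.
#' @export
write_kymograph_csv <- function(kymograph, path, thin = 1L) {
  keep <- seq(1, length(kymograph$times), by = thin)
  vn <- dimnames(kymograph$states)[[3]]
  n <- length(kymograph$positions)
  df <- data.frame(
    time = rep(kymograph$times[keep], each = n),
    cell_index = rep(seq_len(n), times = length(keep)),
    position = rep(kymograph$positions, times = length(keep)),
    g = as.vector(t(kymograph$g_values[keep, , drop = FALSE])))
  for (j in seq_along(vn))
    df[[vn[j]]] <- as.vector(t(kymograph$states[keep, , j]))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' CSV export of a fate pattern
#' @param pattern a [call_fates()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_fates_csv <- function(pattern, path) {
  write.csv(data.frame(cell_index = seq_along(pattern$fates),
                       position = pattern$positions,
                       fate = as.character(pattern$fates)),
            path, row.names = FALSE)
  invisible(path)
}

#' CSV + JSON export of a bifurcation diagram
#' @param diagram a [bifurcation_diagram()].
#' @param csv_path tidy CSV of the cycle branch and fixed-point branches.
#' @param json_path JSON with events and settings.
#' @return invisibly, the two paths.
#' @export
write_diagram <- function(diagram, csv_path, json_path) {
  cb <- diagram$cycle_branch
  rows <- list()
  if (nrow(cb))
    rows$cycle <- data.frame(branch = "cycle", branch_id = 0L, g = cb$g,
                             min = cb$min, max = cb$max, period = cb$period,
                             stability = cb$stability)
  fb <- diagram$fp_branches
  if (nrow(fb)) {
    vn <- .model_var_names(diagram$model)[1]
    rows$fp <- data.frame(branch = "fixed_point", branch_id = fb$branch_id,
                          g = fb$g, min = fb[[vn]], max = fb[[vn]],
                          period = NA_real_, stability = fb$stability)
  }
  write.csv(do.call(rbind, rows), csv_path, row.names = FALSE)
  jsonlite::write_json(list(schema_version = .SCHEMA_VERSION,
                            events = diagram$events,
                            settings = diagram$settings),
                       json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(c(csv_path, json_path))
}

#' Experiment recipe
#'
#' A named, fully deterministic figure-level experiment: given a seed, a
#' recipe produces a fixed set of CSV/JSON artifacts via [run_recipe()].
#'
#' @param name one of `"fig2"`, `"fig3"`, `"fig4"`, `"fig5_steep"`,
#'   `"fig5_shallow"`, `"fig6"`, `"fig7"`, `"weight_family_sweep"`,
#'   `"random_threshold_sweep"`.
#' @param overrides named list of per-recipe parameter overrides (sizes,
#'   replicate counts, grids).
#' @param seed base seed.
#' @export
experiment_recipe <- function(name = c("fig2", "fig3", "fig4", "fig5_steep",
                                       "fig5_shallow", "fig6", "fig7",
                                       "weight_family_sweep",
                                       "random_threshold_sweep"),
                              overrides = list(), seed = 1L) {
  name <- match.arg(name)
  if (!is.list(overrides)) stop("'overrides' must be a list")
  structure(list(name = name, overrides = overrides, seed = as.integer(seed)),
            class = "experiment_recipe")
}

# gene-model front/config defaults shared by the deterministic recipes:
# a steep front (the baseline regime, where both clock-arrest routes
# produce the same pattern) moving at 12 cells per clock period
.recipe_gene_setup <- function(model, n_cells = 60, omega = Inf, D = 0,
                               seed = 1L, steepness = 2) {
  T0 <- .posterior_period(model)
  v <- 12 / T0
  front <- morphogen_front(steepness = steepness, speed = v,
                           shape = "logistic", offset = 0)
  config <- embryo_config(n_cells = n_cells, omega = omega, diffusion = D,
                          seed = seed)
  list(front = front, config = config)
}

.recipe_registry <- function() list(
  fig2 = function(dir, seed, ov) {
    files <- character(0)
    for (nm in c("gene_model1", "gene_model2")) {
      model <- make_fixture(nm)
      su <- .recipe_gene_setup(model, seed = .child_seed(seed, 1))
      kym <- simulate_embryo(model, su$config, su$front)
      files <- c(files,
                 write_kymograph_csv(kym, file.path(dir, paste0(nm, "_kymograph.csv")),
                                     thin = 2L),
                 write_fates_csv(call_fates(kym),
                                 file.path(dir, paste0(nm, "_fates.csv"))))
      dg <- bifurcation_diagram(model, g_grid = seq(1, 0, length.out = 41),
                                t_max_factor = 150)
      files <- c(files, write_diagram(dg,
                                      file.path(dir, paste0(nm, "_diagram.csv")),
                                      file.path(dir, paste0(nm, "_events.json"))))
    }
    files
  },
  fig3 = function(dir, seed, ov) {
    omegas <- ov$omegas %||% c(1000, 3000, 10000, 30000)
    nrep <- ov$n_replicates %||% 10
    rows <- list()
    for (nm in c("gene_model1", "gene_model2")) {
      model <- make_fixture(nm)
      su <- mi_reference_conditions(model,
                                    n_cells = ov$n_cells %||% 100,
                                    diffusion = ov$diffusion %||% 0.2)
      mi <- mi_experiment(model, su$config, su$front, omegas = omegas,
                          n_replicates = nrep, seed = .child_seed(seed, 2))
      rows[[nm]] <- data.frame(model = nm,
                               omega = vapply(mi, `[[`, numeric(1), "omega"),
                               diffusion = su$config$diffusion,
                               replicates = nrep,
                               bits = vapply(mi, `[[`, numeric(1), "bits"))
    }
    path <- file.path(dir, "mi_sweep.csv")
    write.csv(do.call(rbind, rows), path, row.names = FALSE)
    path
  },
  fig4 = function(dir, seed, ov) {
    files <- character(0)
    for (nm in c("geo_model1", "geo_model2")) {
      model <- make_fixture(nm)
      T0 <- .posterior_period(model)
      front <- morphogen_front(steepness = 0.25, speed = 12 / T0)
      config <- embryo_config(n_cells = 60)
      kym <- simulate_embryo(model, config, front)
      files <- c(files,
                 write_kymograph_csv(kym, file.path(dir, paste0(nm, "_kymograph.csv")),
                                     thin = 2L),
                 write_fates_csv(call_fates(kym),
                                 file.path(dir, paste0(nm, "_fates.csv"))))
      dg <- bifurcation_diagram(model, g_grid = seq(1, 0, length.out = 41),
                                t_max_factor = 150)
      files <- c(files, write_diagram(dg,
                                      file.path(dir, paste0(nm, "_diagram.csv")),
                                      file.path(dir, paste0(nm, "_events.json"))))
    }
    files
  },
  fig5_steep = function(dir, seed, ov) .asym_gene_recipe(dir, seed, steep = TRUE),
  fig5_shallow = function(dir, seed, ov) .asym_gene_recipe(dir, seed, steep = FALSE),
  fig6 = function(dir, seed, ov) {
    files <- character(0)
    for (nm in c("geo_asym_unstable", "geo_asym_stable")) {
      model <- make_fixture(nm)
      T0 <- .posterior_period(model)
      kym <- simulate_embryo(model, embryo_config(n_cells = 60),
                             morphogen_front(steepness = 0.25, speed = 12 / T0))
      files <- c(files,
                 write_kymograph_csv(kym, file.path(dir, paste0(nm, "_kymograph.csv")),
                                     thin = 2L),
                 write_fates_csv(call_fates(kym),
                                 file.path(dir, paste0(nm, "_fates.csv"))))
    }
    files
  },
  fig7 = function(dir, seed, ov) {
    pk <- simulate_phase_lattice(phase_lattice_config())
    f1 <- write_kymograph_csv(pk, file.path(dir, "phase_lattice_kymograph.csv"),
                              thin = 2L)
    # wave-shape comparison: phase model vs the SNIC geometric model under
    # a shallow front (several active waves span the transition zone)
    model <- make_fixture("geo_model2")
    T0 <- .posterior_period(model)
    kym <- simulate_embryo(model, embryo_config(n_cells = ov$n_cells %||% 300),
                           morphogen_front(steepness = 0.05, speed = 12 / T0,
                                           offset = -60))
    asym <- data.frame(
      model = c("phase_lattice", "geo_model2"),
      asymmetry = c(wave_asymmetry(wave_profile(pk, 0.5, variable = 2,
                                                g_range = c(0, 0.98),
                                                min_amp_frac = 0)),
                    median(vapply(c(0.35, 0.45, 0.55), function(fr)
                      wave_asymmetry(wave_profile(kym, fr,
                                                  min_amp_frac = 0.5)),
                      numeric(1)), na.rm = TRUE)))
    f2 <- file.path(dir, "wave_asymmetry.csv")
    write.csv(asym, f2, row.names = FALSE)
    c(f1, f2)
  },
  weight_family_sweep = function(dir, seed, ov) {
    fams <- ov$families %||% c("linear", "quadratic", "cubic", "quartic")
    rows <- lapply(fams, function(fam) {
      model <- geometric_model(
        variant = if (fam == "linear") "snic" else "hopf_supercritical",
        weights = weight_scheme(fam, intermediate_enabled = fam != "linear"))
      dg <- bifurcation_diagram(model, g_grid = seq(1, 0, length.out = 41),
                                t_max_factor = 150)
      tc <- classify_transition(dg)
      data.frame(family = fam, class = tc$class,
                 colabels = paste(tc$colabels, collapse = "+"))
    })
    path <- file.path(dir, "weight_family_classes.csv")
    write.csv(do.call(rbind, rows), path, row.names = FALSE)
    path
  },
  random_threshold_sweep = function(dir, seed, ov) {
    n_draws <- ov$n_draws %||% 20
    nrep <- ov$n_replicates %||% 5
    omega <- ov$omega %||% 2000
    sd_log <- ov$sd_log %||% 0.1
    rows <- list()
    for (d in seq_len(n_draws)) {
      set.seed(.child_seed(seed, 3, d))
      K <- matrix(exp(rnorm(9, 0, sd_log)), 3, 3)
      for (nm in c("gene_model1", "gene_model2")) {
        base <- make_fixture(nm)
        model <- gene_network_model(K_stat = K, weights = base$weights)
        su <- mi_reference_conditions(model, n_cells = ov$n_cells %||% 60)
        mi <- mi_experiment(model, su$config, su$front, omegas = omega,
                            n_replicates = nrep,
                            seed = .child_seed(seed, 4, d))
        rows[[paste(nm, d)]] <- data.frame(draw = d, model = nm,
                                           omega = omega, bits = mi[[1]]$bits)
      }
    }
    path <- file.path(dir, "random_threshold_mi.csv")
    write.csv(do.call(rbind, rows), path, row.names = FALSE)
    path
  }
)

.asym_gene_recipe <- function(dir, seed, steep) {
  files <- character(0)
  for (nm in c("gene_model1_asym", "gene_model2_asym")) {
    model <- make_fixture(nm)
    su <- .recipe_gene_setup(model, steepness = if (steep) 2 else 0.1)
    kym <- simulate_embryo(model, su$config, su$front)
    files <- c(files,
               write_kymograph_csv(kym, file.path(dir, paste0(nm, "_kymograph.csv")),
                                   thin = 2L),
               write_fates_csv(call_fates(kym),
                               file.path(dir, paste0(nm, "_fates.csv"))))
  }
  files
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a named experiment recipe
#'
#' Executes the deterministic pipeline of the recipe, writes its artifacts
#' under `out_dir`, and records a manifest (`manifest.json`) with the
#' recipe name, seed, package version, parameter hash and the MD5 checksum
#' of every produced file. Re-running with the same seed reproduces
#' byte-identical files. Per-stage seeds are derived from the base seed
#' with a counter scheme so that adding a stage never perturbs earlier
#' stages.
#'
#' @param recipe an [experiment_recipe()] or a recipe name.
#' @param out_dir output directory (created if needed).
#' @param seed base seed (overrides the recipe's).
#' @return the manifest, invisibly.
#' @export
run_recipe <- function(recipe, out_dir, seed = NULL) {
  if (is.character(recipe)) recipe <- experiment_recipe(recipe)
  if (!inherits(recipe, "experiment_recipe"))
    stop("'recipe' must be an experiment_recipe or a recipe name")
  if (is.null(seed)) seed <- recipe$seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fn <- .recipe_registry()[[recipe$name]]
  files <- fn(out_dir, seed, recipe$overrides)
  files <- sort(unique(as.character(files)))
  manifest <- list(
    schema_version = .SCHEMA_VERSION,
    recipe = recipe$name,
    seed = seed,
    package_version = as.character(utils::packageVersion("segwave")),
    parameter_hash = unname(.param_hash(recipe)),
    files = lapply(files, function(f)
      list(name = basename(f), md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

.param_hash <- function(recipe) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(recipe[c("name", "overrides")],
                              auto_unbox = TRUE), tmp)
  tools::md5sum(tmp)
}
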