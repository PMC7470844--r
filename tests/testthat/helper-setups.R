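# Shared fixtures and small helpers for the test suite.

# a front frozen near g = 1 for the whole run (posterior regime everywhere)
frozen_posterior_front <- function() {
  morphogen_front(steepness = 1, speed = 1e-6, offset = -1e6)
}

# steep baseline front used for deterministic pattern comparisons
steep_front <- function(model, cells_per_period = 12) {
  morphogen_front(steepness = 2,
                  speed = cells_per_period / segwave:::.posterior_period(model))
}

# shallow front for wave-shape work: several active waves span the
# transition zone
wave_front <- function(model, cells_per_period = 12) {
  morphogen_front(steepness = 0.05, offset = -60,
                  speed = cells_per_period / segwave:::.posterior_period(model))
}

# number of cells at which two fate patterns differ
fate_mismatch <- function(a, b) sum(as.character(a$fates) != as.character(b$fates))

# lazily computed, memoised expensive objects shared across test blocks
.memo <- new.env(parent = emptyenv())
memo <- function(key, expr) {
  if (is.null(.memo[[key]])) .memo[[key]] <- force(expr)
  .memo[[key]]
}

full_diagram <- function(name, n_grid = 51) {
  memo(paste0("diagram_", name, "_", n_grid),
       bifurcation_diagram(make_fixture(name),
                           g_grid = seq(1, 0, length.out = n_grid)))
}
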