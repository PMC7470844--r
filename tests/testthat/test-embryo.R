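test_that("morphogen front has the right geometry and limits", {
  fr <- morphogen_front(steepness = 0.5, speed = 2, offset = 3)
  expect_equal(morphogen_value(3 + 2 * 5, 5, fr), 0.5)
  expect_equal(morphogen_value(0, 1e6, fr), 0)
  expect_equal(morphogen_value(1e6, 0, fr), 1)
  # non-increasing in time at fixed position
  g <- morphogen_value(10, seq(0, 50, by = 0.5), fr)
  expect_true(all(diff(g) <= 0))
  # piecewise-linear ramp hits the same centre value
  frl <- morphogen_front(steepness = 0.5, speed = 2, offset = 3,
                         shape = "piecewise_linear")
  expect_equal(morphogen_value(3, 0, frl), 0.5)
  expect_equal(morphogen_value(3.5, 0, frl), 0.75)  # inside the ramp
  expect_equal(morphogen_value(13, 0, frl), 1)      # clamped above
})

test_that("cells with identical g histories stay identical", {
  m <- make_fixture("gene_model2")
  k <- simulate_embryo(m, embryo_config(n_cells = 6, t_max = 8),
                       frozen_posterior_front())
  for (it in seq(1, length(k$times), by = 20)) {
    frame <- k$states[it, , ]
    expect_equal(frame, matrix(frame[1, ], 6, 3, byrow = TRUE),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("a frozen posterior front reproduces the single-cell clock period", {
  m <- make_fixture("gene_model2")
  T0 <- segwave:::.posterior_period(m)
  k <- simulate_embryo(m, embryo_config(n_cells = 3, t_max = 10 * T0,
                                        save_every = 5),
                       frozen_posterior_front())
  u <- k$states[, 2, 1]
  mid <- (max(u) + min(u)) / 2
  up <- which(u[-length(u)] < mid & u[-1] >= mid)
  periods <- diff(k$times[up])
  expect_equal(mean(tail(periods, 5)), T0, tolerance = 0.01)
})

test_that("noise amplitude follows the birth-death and geometric rules", {
  m <- make_fixture("gene_model1")
  st <- cell_state(c(0, 0, 0), 1)
  expect_equal(noise_sigma(st, m, Inf), c(0, 0, 0))
  # at the empty state only dynamic-module production contributes at g = 1
  expect_equal(noise_sigma(st, m, 2000), rep(sqrt(m$beta_dyn / 2000), 3))
  gm <- make_fixture("geo_model2")
  s1 <- noise_sigma(cell_state(c(0.3, 0.1), 0.7), gm, 1000, noise_floor = 1)
  s2 <- noise_sigma(cell_state(c(-0.9, 0.4), 0.2), gm, 1000, noise_floor = 1)
  expect_equal(s1, s2)  # independent of state (and hence of position)
  expect_equal(s1, rep(1 / sqrt(1000), 2))
  expect_error(noise_sigma(st, m, -1), "positive")
})

test_that("the Euler-Maruyama step reduces exactly to deterministic Euler", {
  m <- make_fixture("gene_model2")
  fr <- steep_front(m)
  cfg <- embryo_config(n_cells = 5, omega = Inf, diffusion = 0)
  P <- matrix(c(2, 0.3, 0.1), 5, 3, byrow = TRUE)
  cfg$domain_length <- 4
  stepped <- step_stochastic(P, 1, 0.01, m, cfg, fr)
  g <- morphogen_value(seq(0, 4), 1, fr)
  manual <- t(vapply(1:5, function(i)
    P[i, ] + 0.01 * segwave:::.gene_deriv(P[i, ], g[i], m), numeric(3)))
  expect_identical(stepped, manual)
})

test_that("spatially uniform states feel zero diffusion flux", {
  m <- make_fixture("gene_model2")
  fr <- frozen_posterior_front()
  cfg0 <- embryo_config(n_cells = 7, omega = Inf, diffusion = 0)
  cfgD <- embryo_config(n_cells = 7, omega = Inf, diffusion = 5)
  cfg0$domain_length <- cfgD$domain_length <- 6
  P <- matrix(c(1.5, 0.7, 0.2), 7, 3, byrow = TRUE)
  expect_identical(step_stochastic(P, 0, 0.005, m, cfg0, fr),
                   step_stochastic(P, 0, 0.005, m, cfgD, fr))
})

test_that("stochastic runs are seed-reproducible and match the R stepper", {
  m <- make_fixture("gene_model2")
  fr <- steep_front(m)
  cfg <- embryo_config(n_cells = 6, t_max = 0.5, dt = 0.005, omega = 500,
                       diffusion = 0.1, seed = 21, save_every = 100)
  k1 <- simulate_embryo(m, cfg, fr)
  k2 <- simulate_embryo(m, cfg, fr)
  expect_identical(k1$states, k2$states)
  cfg3 <- cfg; cfg3$seed <- 22L
  expect_false(identical(simulate_embryo(m, cfg3, fr)$states, k1$states))
  # the compiled stepper agrees with the reference R stepper draw-for-draw
  P <- segwave:::.initial_matrix(m, segwave:::.resolve_config(m, cfg, fr))
  cfg$domain_length <- 5
  set.seed(21)
  for (s in 0:99) P <- step_stochastic(P, s * 0.005, 0.005, m, cfg, fr)
  expect_identical(unname(P), unname(k1$states[dim(k1$states)[1], , ]))
})

test_that("the ensemble mean at small noise tracks the deterministic path", {
  m <- make_fixture("gene_model2")
  fr <- frozen_posterior_front()
  cfg_det <- embryo_config(n_cells = 2, t_max = 2, dt = 0.005, save_every = 400)
  det <- simulate_embryo(m, cfg_det, fr)
  final_det <- det$states[dim(det$states)[1], 1, ]
  n_rep <- 120
  finals <- matrix(NA_real_, n_rep, 3)
  for (r in seq_len(n_rep)) {
    cfg <- cfg_det; cfg$omega <- 1e5; cfg$seed <- 1000L + r
    k <- simulate_embryo(m, cfg, fr)
    finals[r, ] <- k$states[dim(k$states)[1], 1, ]
  }
  mu <- colMeans(finals)
  se <- apply(finals, 2, sd) / sqrt(n_rep)
  expect_true(all(abs(mu - final_det) < 4 * se + 1e-3))
})

test_that("fates are read as the dominant gene / the sign of y", {
  m <- make_fixture("gene_model2")
  # one frame, three cells: A, B, C dominant respectively
  kym <- list(states = aperm(array(c(0.9, 0.1, 0.2, 0.05, 0.8, 0.1,
                                     0.05, 0.1, 0.7), c(3, 3, 1)),
                             c(3, 1, 2)),
              g_values = matrix(0.01, 1, 3), positions = 0:2, model = m)
  fp <- call_fates(kym, m)
  expect_equal(as.character(fp$fates), c("A", "B", "C"))
  expect_equal(fp$boundaries, c(0.5, 1.5))
  gm <- make_fixture("geo_model2")
  kg <- list(states = aperm(array(c(-0.97, 0.5, 0.1, -0.1), c(2, 2, 1)),
                            c(3, 1, 2)),
             g_values = matrix(0.01, 1, 2), positions = 0:1, model = gm)
  expect_equal(as.character(call_fates(kg, gm)$fates), c("low", "high"))
  kw <- kym; kw$g_values <- matrix(0.2, 1, 3)
  expect_warning(call_fates(kw, m), "frozen")
})

test_that("deterministic runs give a repeating 3-fate pattern robust to dt", {
  m <- make_fixture("gene_model2")
  fr <- steep_front(m)
  cfg <- embryo_config(n_cells = 36)
  f1 <- call_fates(simulate_embryo(m, cfg, fr))
  runs <- rle(as.character(f1$fates))
  inner <- runs$lengths[-c(1, length(runs$lengths))]
  expect_true(all(abs(inner - 4) <= 1))  # 12-cell repeat, 3 fates
  expect_equal(unique(sort(runs$values)), c("A", "B", "C"))
  cfg2 <- cfg; cfg2$dt <- segwave:::.default_dt(m) / 2
  f2 <- call_fates(simulate_embryo(m, cfg2, fr))
  expect_lte(fate_mismatch(f1, f2), length(f1$boundaries))
})
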