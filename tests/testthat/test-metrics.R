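test_that("plug-in mutual information matches closed-form values", {
  expect_equal(mutual_information(diag(3) * 10), log2(3))
  # independent joint table gives exactly zero
  p <- outer(c(30, 20, 10), c(5, 10, 25))
  expect_equal(mutual_information(p), 0)
  # hand-evaluated four-term sum for [[30,10],[10,30]]:
  # I = 0.75*log2(1.5) + 0.25*log2(0.5)
  expect_equal(mutual_information(matrix(c(30, 10, 10, 30), 2)),
               0.75 * log2(1.5) + 0.25 * log2(0.5))
  expect_equal(mutual_information(matrix(c(30, 10, 10, 30), 2)),
               0.1887219, tolerance = 1e-6)
})

test_that("mutual information is bounded and maximal only for permutation tables", {
  set.seed(5)
  for (k in 1:20) {
    tab <- matrix(rpois(9, 20), 3)
    mi <- mutual_information(tab)
    expect_gte(mi, 0)
    expect_lte(mi, log2(3) + 1e-12)
  }
  perm <- diag(3)[c(2, 3, 1), ] * 7
  expect_equal(mutual_information(perm), log2(3))
  expect_error(mutual_information(matrix(0, 2, 2)), "positive total")
  expect_error(mutual_information(matrix(-1, 2, 2)), "non-negative")
})

test_that("a noise-free experiment reproduces the ideal phase readout", {
  m <- make_fixture("gene_model2")
  fr <- steep_front(m)
  cfg <- embryo_config(n_cells = 24)
  mi <- mi_experiment(m, cfg, fr, omegas = Inf, n_replicates = 2, seed = 1)
  ideal <- call_fates(simulate_embryo(m, cfg, fr))$fates
  p <- table(ideal) / length(ideal)
  expect_equal(mi[[1]]$bits, -sum(p * log2(p)))  # identity channel
  expect_true(all(mi[[1]]$joint_counts[row(diag(3)) != col(diag(3))] == 0))
})

test_that("the predicted wavelength has the right limits and monotonicity", {
  expect_identical(predicted_wavelength(1, 2, 2), Inf)
  expect_equal(predicted_wavelength(3, 2, Inf), 3)
  expect_equal(predicted_wavelength(1, 1, 2), 2)
  Tx <- c(2.01, 2.5, 4, 10, 100)
  s <- predicted_wavelength(5, 2, Tx)
  expect_true(all(diff(s) < 0))       # decays toward S
  expect_true(all(s > 5))
  expect_error(predicted_wavelength(1, 2, 1.5), "posterior period")
})

test_that("measured wavelength recovers uniform and chirped spacings", {
  x <- seq(0, 200, by = 0.5)
  ws <- measure_wavelength(list(x = x, value = sin(2 * pi * x / 40)))
  expect_equal(ws$spacing, rep(40, length(ws$spacing)), tolerance = 0.02)
  # chirp with a prescribed instantaneous wavelength 1/(a + b x)
  a <- 1 / 50; b <- 1e-4
  phase <- 2 * pi * (a * x + b * x^2 / 2)
  ws <- measure_wavelength(list(x = x, value = sin(phase)))
  pred <- 1 / (a + b * ws$positions)
  expect_true(all(abs(ws$spacing - pred) / pred < 0.05))
  expect_error(measure_wavelength(list(x = 1:10, value = rep(1, 10))), "peaks")
})

test_that("the asymmetry index is exactly 1 for mirror-symmetric waves", {
  x <- seq(0, 160, by = 0.25)
  expect_equal(wave_asymmetry(list(x = x, value = sin(2 * pi * x / 40))), 1,
               tolerance = 0.01)
  tri <- 2 * abs((x / 40) %% 1 - 0.5)  # triangle wave, even-symmetric
  expect_equal(wave_asymmetry(list(x = x, value = tri), smooth_window = 1), 1)
  expect_error(wave_asymmetry(rep(0.5, 50)), "mid-level")
})

test_that("a Van der Pol wave read through a slowing phase is asymmetric", {
  # limit cycle of a Van der Pol oscillator, parameterised by phase
  vdp <- deSolve::lsoda(c(2, 0), seq(0, 120, by = 0.01),
                        function(t, y, p) list(c(y[2],
                                                 3 * (1 - y[1]^2) * y[2] - y[1])),
                        rtol = 1e-8, atol = 1e-8)
  x <- vdp[, 2]
  up <- which(x[-length(x)] < 0 & x[-1] >= 0)
  cyc <- x[up[length(up) - 1]:up[length(up)]]          # one full period
  xv <- approxfun(seq(0, 2 * pi, length.out = length(cyc)), cyc)
  # map time to space with the non-uniform phase speed of a clock close
  # to arrest (slow near a pinned phase, as in the infinite-period route);
  # a mirror-symmetric wave keeps index 1 only under uniform phase speed
  phi <- numeric(4000); dx <- 0.01
  for (i in 2:length(phi))
    phi[i] <- phi[i - 1] + dx * 2 * (1.05 - cos(phi[i - 1] - 0.8))
  u <- xv(phi %% (2 * pi))
  idx <- wave_asymmetry(list(x = seq_along(u) * dx, value = u),
                        smooth_window = 1)
  expect_gt(abs(log(idx)), log(1.1))      # more than 10% from symmetric
  # the same Van der Pol waveform under uniform phase speed is symmetric
  # (the oscillator is odd-symmetric), confirming the slowing is what
  # breaks the wave symmetry
  u0 <- xv((seq_along(u) * dx * 2) %% (2 * pi))
  expect_lt(abs(log(wave_asymmetry(list(x = seq_along(u0) * dx, value = u0),
                                   smooth_window = 1))), log(1.05))
})

test_that("the state distribution separates SNIC dwell from Hopf collapse", {
  snic <- state_distribution(make_fixture("geo_model2"), 0.25)
  expect_gte(snic$n_modes, 2)
  ref <- state_distribution(make_fixture("geo_model2"), 1)
  expect_gt(snic$spread, 0.5 * ref$spread)
  hopf <- state_distribution(make_fixture("geo_model1"), 0.4)
  hopf_ref <- state_distribution(make_fixture("geo_model1"), 1)
  expect_equal(hopf$n_modes, 1)
  expect_lt(hopf$spread, 0.1 * hopf_ref$spread)
  frozen <- state_distribution(make_fixture("geo_model2"), 0)
  expect_lt(frozen$spread, 1e-6)          # point mass at the reached state
})
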