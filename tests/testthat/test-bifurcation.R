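test_that("geometric fixed points at g = 0 are the configured landscape", {
  m <- make_fixture("geo_model2")
  fp <- as.data.frame(find_fixed_points(m, 0))
  fp <- fp[order(fp$y), ]
  expect_equal(nrow(fp), 3)
  expect_equal(fp$y, c(-1, 0, 1), tolerance = 1e-8)
  expect_equal(fp$z, rep(0, 3), tolerance = 1e-8)
  expect_equal(fp$stability, c("stable_node", "saddle", "stable_node"))
  # closed-form static Jacobian at the origin: +1 along y, -1 along z
  J <- segwave:::.model_jacobian(m, c(0, 0), 0)
  expect_equal(diag(J), c(m$static_strength, -m$static_strength),
               tolerance = 1e-6)
})

test_that("the pure dynamic regime has a single repelling point inside the cycle", {
  m <- make_fixture("geo_model2")
  fp <- find_fixed_points(m, 1)
  expect_length(fp$points, 1)
  expect_equal(fp$points[[1]]$location, c(0, 0), tolerance = 1e-6)
  expect_match(fp$points[[1]]$stability, "unstable")
})

test_that("symmetric gene fixed points are invariant under gene permutation", {
  m <- make_fixture("gene_model2")
  fp <- as.data.frame(find_fixed_points(m, 0))
  locs <- as.matrix(fp[, c("A", "B", "C")])
  for (i in seq_len(nrow(locs))) {
    d <- sqrt(colSums((t(locs) - locs[i, c(2, 3, 1)])^2))
    expect_lt(min(d), 1e-6)
  }
})

test_that("no limit cycle exists in the multistable regime", {
  expect_null(find_limit_cycle(make_fixture("geo_model2"), 0))
  expect_null(find_limit_cycle(make_fixture("gene_model1"), 0))
})

test_that("eigenvalue stability agrees with a brute-force basin test", {
  cases <- list(list(m = make_fixture("geo_model2"), g = 0.1),
                list(m = make_fixture("gene_model2"), g = 0.05))
  set.seed(8)
  for (cs in cases) {
    fp <- find_fixed_points(cs$m, cs$g)
    for (p in fp$points) {
      if (!(p$stability %in% c("stable_node", "stable_focus", "saddle"))) next
      n_back <- 0; n_try <- 12
      for (k in seq_len(n_try)) {
        y0 <- p$location + rnorm(length(p$location), 0, 0.02)
        out <- deSolve::lsoda(y0, c(0, 30), function(t, y, q)
          list(segwave:::.model_deriv(cs$m, y, cs$g)),
          rtol = 1e-8, atol = 1e-8)
        yf <- out[nrow(out), -1]
        if (sqrt(sum((yf - p$location)^2)) < 0.05) n_back <- n_back + 1
      }
      if (p$stability %in% c("stable_node", "stable_focus")) {
        expect_equal(n_back, n_try)
      } else {
        expect_lt(n_back, n_try)  # a saddle loses almost all perturbations
      }
    }
  }
})

test_that("a windowed scan localises the supercritical Hopf of the geometric model", {
  m <- make_fixture("geo_model1")
  d <- bifurcation_diagram(m, g_grid = seq(0.85, 0.55, length.out = 16))
  ev <- d$events
  expect_true(any(ev$type == "hopf_super"))
  g_h <- ev$g_star[ev$type == "hopf_super"][1]
  # independent localisation: sign change of the origin's complex-pair
  # real part
  re_at <- function(g) segwave:::.central_re(m, g, c(0, 0))
  oracle <- uniroot(re_at, c(0.75, 0.6))$root
  expect_lt(abs(g_h - oracle), 2e-3)
  # cycle amplitude collapses as the event is approached
  cb <- d$cycle_branch
  expect_lt(cb$amplitude[which.min(cb$g)], 0.3 * cb$amplitude[which.max(cb$g)])
})

test_that("cycle period and amplitude grow monotonically toward a SNIC", {
  m <- make_fixture("geo_model2")
  gs <- c(0.5, 0.35, 0.25, 0.21)
  cyc <- lapply(gs, function(g) find_limit_cycle(m, g))
  expect_true(all(!vapply(cyc, is.null, logical(1))))
  periods <- vapply(cyc, `[[`, numeric(1), "period")
  expect_true(all(diff(periods) > 0))
  amps <- vapply(cyc, `[[`, numeric(1), "amplitude")
  expect_gt(min(amps), 0.5 * find_limit_cycle(m, 1)$amplitude)
})

test_that("backward-time integration finds the coexisting unstable cycle", {
  m <- make_fixture("geo_model3")
  st <- find_limit_cycle(m, 1)
  un <- find_limit_cycle(m, 1, direction = "backward", seed_state = c(0.45, 0))
  expect_equal(st$amplitude, 2, tolerance = 0.02)       # stable cycle r = 1
  expect_equal(un$amplitude, 1, tolerance = 0.02)       # unstable cycle r = 0.5
  expect_identical(un$stability, "unstable")
})
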