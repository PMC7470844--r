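test_that("gene field reduces to maximal production at the empty state", {
  m <- make_fixture("gene_model1")
  f <- gene_field(cell_state(c(0, 0, 0), 1), m)
  expect_equal(f, rep(m$beta_dyn, 3))
  f0 <- gene_field(cell_state(c(0, 0, 0), 0), m)
  expect_equal(f0, rep(m$beta_stat, 3))
})

test_that("the symmetric gene field commutes with cyclic gene permutation", {
  m <- make_fixture("gene_model2")
  set.seed(4)
  perm <- c(2, 3, 1)
  for (k in 1:10) {
    P <- runif(3, 0, 4)
    g <- runif(1)
    f <- gene_field(cell_state(P, g), m)
    fp <- gene_field(cell_state(P[perm], g), m)
    expect_equal(fp, f[perm], tolerance = 1e-12)
  }
})

test_that("gene field matches term-by-term Hill arithmetic at a hand point", {
  m <- make_fixture("gene_model1")  # quadratic weights, defaults
  P <- c(1, 1, 1); g <- 0.5
  # independent arithmetic: P = (1,1,1), K = 1 so every Hill factor is 1/2
  D <- m$beta_dyn * 0.5
  S <- m$beta_stat * 0.25
  expected <- rep(0.25 * D + 0.25 * S - 1, 3)
  expect_equal(gene_field(cell_state(P, g), m), expected, tolerance = 1e-12)
  # asymmetric state, worked through the same formulas independently
  P <- c(2, 0.5, 0.25); g <- 0.3
  hill <- function(x, K, h) 1 / (1 + (x / K)^h)
  D <- m$beta_dyn * hill(P[c(3, 1, 2)], 1, 4)
  S <- m$beta_stat * c(hill(P[2], 1, 3) * hill(P[3], 1, 3),
                       hill(P[3], 1, 3) * hill(P[1], 1, 3),
                       hill(P[1], 1, 3) * hill(P[2], 1, 3))
  expected <- 0.09 * D + 0.49 * S - P
  expect_equal(gene_field(cell_state(P, g), m), expected, tolerance = 1e-12)
})

test_that("gene field rejects negative concentrations", {
  m <- make_fixture("gene_model1")
  expect_error(gene_field(cell_state(c(-0.1, 1, 1), 0.5), m), "non-negative")
})

test_that("geometric static landscape has its fixed points where configured", {
  m <- make_fixture("geo_model2")
  expect_equal(geometric_field(cell_state(c(1, 0), 0), m), c(0, 0))
  expect_equal(geometric_field(cell_state(c(-1, 0), 0), m), c(0, 0))
  expect_equal(geometric_field(cell_state(c(0, 0), 0), m), c(0, 0))
  ma <- make_fixture("geo_asym_unstable")
  expect_equal(geometric_field(cell_state(c(ma$unstable_y, 0), 0), ma), c(0, 0))
})

test_that("the unit circle is invariant for the pure dynamic module", {
  m <- make_fixture("geo_model2")
  for (th in seq(0.1, 2 * pi, length.out = 7)) {
    yz <- c(cos(th), sin(th))
    f <- geometric_field(cell_state(yz, 1), m)
    expect_equal(sum(f * yz), 0, tolerance = 1e-12)  # no radial component
    # angular speed strictly positive and non-uniform
    expect_gt(f[1] * (-sin(th)) + f[2] * cos(th), 0)
  }
})

test_that("linear weights mix the two module fields as an arithmetic mean", {
  m <- make_fixture("geo_model2")  # linear weights, no intermediate
  st <- c(0.3, -0.2)
  f_mid <- geometric_field(cell_state(st, 0.5), m)
  f_dyn <- geometric_field(cell_state(st, 1), m)
  f_stat <- geometric_field(cell_state(st, 0), m)
  expect_equal(f_mid, (f_dyn + f_stat) / 2, tolerance = 1e-12)
})

test_that("the geometric field at g = 0 is odd when the landscape is symmetric", {
  m <- make_fixture("geo_model2")
  set.seed(2)
  for (k in 1:8) {
    yz <- runif(2, -1.2, 1.2)
    expect_equal(geometric_field(cell_state(-yz, 0), m),
                 -geometric_field(cell_state(yz, 0), m), tolerance = 1e-12)
  }
})

test_that("fixtures carry the documented weight schemes and perturbations", {
  expect_identical(make_fixture("gene_model1")$weights$family, "quadratic")
  expect_identical(make_fixture("gene_model2")$weights$family, "linear")
  g1 <- make_fixture("geo_model1")
  expect_identical(g1$weights$family, "cubic")
  expect_true(g1$weights$intermediate_enabled)
  expect_false(make_fixture("geo_model2")$weights$intermediate_enabled)
  expect_identical(make_fixture("geo_model3")$variant, "hopf_subcritical")
  au <- make_fixture("geo_asym_unstable")
  expect_true(au$unstable_y != 0)
  expect_equal(au$stable_y, c(1, -1))
  asym <- make_fixture("gene_model1_asym")
  expect_true(all(asym$K_stat[1, 2:3] < 1))
  expect_error(make_fixture("no_such_model"), "arg")
})

test_that("the geometric posterior period matches the angular-speed quadrature", {
  m <- make_fixture("geo_model2")
  cyc <- find_limit_cycle(m, 1)
  oracle <- integrate(function(th) 1 / (m$omega0 * (1 - m$rho * cos(th))),
                      0, 2 * pi)$value
  expect_lt(abs(cyc$period - oracle) / oracle, 0.005)
  expect_equal(cyc$amplitude, 2, tolerance = 0.01)
})

test_that("the gene clock period is reproducible across restarts", {
  m <- make_fixture("gene_model2")
  c1 <- find_limit_cycle(m, 1, seed_state = c(2, 0.5, 0.1))
  c2 <- find_limit_cycle(m, 1, seed_state = c(0.3, 1.5, 2.5))
  expect_lt(abs(c1$period - c2$period) / c1$period, 1e-3)
})

test_that("the pure static regime is multistable from generic starts", {
  gm <- make_fixture("gene_model2")
  ends <- sapply(list(c(3, 0.2, 0.5), c(0.5, 3, 0.2), c(0.1, 0.4, 2)),
                 function(y0) {
    out <- deSolve::lsoda(y0, c(0, 60), function(t, y, p)
      list(segwave:::.gene_deriv(y, 0, gm)), rtol = 1e-8, atol = 1e-8)
    which.max(out[nrow(out), -1])
  })
  expect_setequal(ends, 1:3)  # each start reaches the matching pure fate
  geo <- make_fixture("geo_model2")
  for (y0 in list(c(0.4, 0.3), c(-0.2, -0.5))) {
    out <- deSolve::lsoda(y0, c(0, 60), function(t, y, p)
      list(segwave:::.geo_deriv(y, 0, geo)), rtol = 1e-8, atol = 1e-8)
    expect_equal(unname(abs(out[nrow(out), 2])), 1, tolerance = 1e-5)
  }
})
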