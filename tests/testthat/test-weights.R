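test_that("every weight family satisfies the boundary identities exactly", {
  schemes <- list(
    weight_scheme("linear"), weight_scheme("quadratic"),
    weight_scheme("cubic"), weight_scheme("quartic"),
    weight_scheme("hill", hill_threshold = 0.5),
    weight_scheme("hill", hill_threshold = 0.75, hill_coefficient = 6),
    weight_scheme("custom_exponent", exponent = 2.5),
    weight_scheme("cubic", intermediate_enabled = TRUE))
  for (sc in schemes) {
    w0 <- evaluate_weights(0, sc)
    w1 <- evaluate_weights(1, sc)
    expect_identical(w0$theta_d, 0)
    expect_identical(w0$theta_s, 1)
    expect_identical(w1$theta_d, 1)
    expect_identical(w1$theta_s, 0)
    expect_identical(w0$theta_i, 0)
    expect_identical(w1$theta_i, 0)
  }
})

test_that("weights are monotone and bounded on [0, 1] for every family", {
  g <- seq(0, 1, by = 0.01)
  schemes <- list(
    weight_scheme("linear"), weight_scheme("quadratic"),
    weight_scheme("quartic"),
    weight_scheme("hill", hill_threshold = 0.6, hill_coefficient = 3),
    weight_scheme("custom_exponent", exponent = 1.7))
  for (sc in schemes) {
    w <- evaluate_weights(g, sc)
    expect_true(all(diff(w$theta_d) >= 0))
    expect_true(all(diff(w$theta_s) <= 0))
    expect_true(all(w$theta_d >= 0 & w$theta_d <= 1))
    expect_true(all(w$theta_s >= 0 & w$theta_s <= 1))
  }
})

test_that("weight values match the defining formulas at g = 0.5", {
  expect_equal(evaluate_weights(1, weight_scheme("linear")),
               list(theta_d = 1, theta_s = 0, theta_i = 0))
  w <- evaluate_weights(0.5, weight_scheme("quadratic"))
  expect_equal(w$theta_d, 0.25)
  expect_equal(w$theta_s, 0.25)
  w <- evaluate_weights(0.5, weight_scheme("cubic", intermediate_enabled = TRUE,
                                           intermediate_scale = 1))
  expect_equal(w$theta_d, 0.125)
  expect_equal(w$theta_s, 0.125)
  expect_equal(w$theta_i, 0.25)
})

test_that("the intermediate weight vanishes at both ends and peaks mid-range", {
  sc <- weight_scheme("cubic", intermediate_enabled = TRUE,
                      intermediate_scale = 4)
  g <- seq(0, 1, by = 0.05)
  ti <- evaluate_weights(g, sc)$theta_i
  expect_equal(ti, 4 * g * (1 - g))
  expect_equal(which.max(ti), which.min(abs(g - 0.5)))
})

test_that("invalid weight inputs are rejected", {
  expect_error(evaluate_weights(1.2, weight_scheme("linear")), "\\[0, 1\\]")
  expect_error(evaluate_weights(-0.1, weight_scheme("linear")), "\\[0, 1\\]")
  expect_error(weight_scheme("sigmoid"), "arg")
  expect_error(weight_scheme("custom_exponent"), "exponent")
  expect_error(weight_scheme("hill", hill_threshold = 1.5), "0, 1")
  expect_error(weight_scheme("linear", intermediate_scale = -1), "positive")
})
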