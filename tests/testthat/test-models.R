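test_that("constructor enforces design-specific parameter contracts", {
  expect_error(oscillator_model("design_x"), "unknown design")
  expect_error(oscillator_model("design3", sigma_prime = 1),
               "sigma_prime")
  expect_error(oscillator_model("atkinson", n = 3), "fixed Hill exponents")
  expect_error(oscillator_model("design1", n = 3), "fixed Hill exponents")
  expect_error(oscillator_model("generalized", n = 2.5),
               "positive integer")
  expect_error(oscillator_model("design3", beta = -1), "nonnegative")
  expect_error(oscillator_model("design3", delta = 0), "delta")
  # aliases resolve to the same design
  expect_identical(oscillator_model("III")$design,
                   oscillator_model("design3")$design)
  expect_identical(oscillator_model("smolen")$params$m, 1L)
  expect_identical(oscillator_model("atkinson")$params$n, 4L)
})

test_that("model JSON round-trip is lossless", {
  m <- oscillator_model("design2", alpha = 50, beta = 0.3, gamma = 0.04,
                        sigma_prime = 2, delta = 7)
  m2 <- model_from_json(model_to_json(m))
  expect_equal(m2, m)
})

test_that("rate laws match hand-computed values at (1, 1)", {
  # all designs at alpha = 50, beta = gamma = sigma = sigma' = 1,
  # delta = 10, state (1, 1); values computed by direct substitution into
  # the production/degradation laws
  cases <- list(
    #       design        dx                      dy
    list("design1", 10 * (51 / 3 - 1),     10 * 25.5 - 1),
    list("design2", 10 * (25.5 - 2),       10 * 25.5 - 1),
    list("design3", 10 * (51 / 4 - 1),     10 * 25.5 - 1),
    list("atkinson", 10 * (51 / 3 - 1),    10 * 25.5 - 1),
    list("smolen",  10 * (51 / 3 - 1),     10 * 17 - 1))
  for (cs in cases) {
    m <- oscillator_model(cs[[1]], alpha = 50, beta = 1, gamma = 1,
                          sigma = if (cs[[1]] == "design2") 1 else 1,
                          delta = 10)
    v <- drop(osc_rhs(m, 1, 1))
    expect_equal(unname(v[1]), cs[[2]], tolerance = 1e-12, label = cs[[1]])
    expect_equal(unname(v[2]), cs[[3]], tolerance = 1e-12, label = cs[[1]])
  }
  # production is nonnegative and rates finite on the admissible quadrant
  st <- random_admissible_states(50)
  for (d in c("design1", "design2", "design3", "atkinson", "smolen")) {
    m <- oscillator_model(d, alpha = 50, beta = 0.5, gamma = 0.1,
                          delta = 10)
    v <- osc_rhs(m, st[, 1], st[, 2])
    expect_true(all(is.finite(v)))
  }
  expect_error(osc_rhs(oscillator_model("design3"), -1, 1), "nonnegative")
})

test_that("sigma = 0 collapses competitive and non-competitive designs", {
  st <- random_admissible_states(100)
  m1 <- oscillator_model("design1", alpha = 50, beta = 0.7, gamma = 0.05,
                         sigma = 0, delta = 10)
  m3 <- oscillator_model("design3", alpha = 50, beta = 0.7, gamma = 0.05,
                         sigma = 0, delta = 10)
  expect_equal(osc_rhs(m1, st[, 1], st[, 2]),
               osc_rhs(m3, st[, 1], st[, 2]), tolerance = 1e-14)
})

test_that("generalized model nests design3; Atkinson is quartic design1", {
  st <- random_admissible_states(60)
  mg <- oscillator_model("generalized", alpha = 50, beta = 0.9,
                         gamma = 0.06, delta = 10, n = 2, m = 2)
  m3 <- oscillator_model("design3", alpha = 50, beta = 0.9, gamma = 0.06,
                         delta = 10)
  expect_equal(osc_rhs(mg, st[, 1], st[, 2]),
               osc_rhs(m3, st[, 1], st[, 2]), tolerance = 1e-14)
  # Atkinson against the quartic competition law written out by hand
  ma <- oscillator_model("atkinson", alpha = 50, beta = 0.9, gamma = 0.06,
                         delta = 10)
  x <- st[, 1]; y <- st[, 2]
  dx <- 10 * (0.9 * (1 + 50 * x^4) / (1 + x^4 + y^4) - x)
  dy <- 10 * 0.06 * (1 + 50 * x^4) / (1 + x^4) - y
  v <- osc_rhs(ma, x, y)
  expect_equal(unname(v[, 1]), unname(dx), tolerance = 1e-12)
  expect_equal(unname(v[, 2]), unname(dy), tolerance = 1e-12)
})

test_that("analytic Jacobians agree with central finite differences", {
  st <- random_admissible_states(200, seed = 7)
  designs <- c("design1", "design2", "design3", "generalized", "atkinson",
               "smolen")
  worst <- 0
  for (d in designs) {
    m <- oscillator_model(d, alpha = 50, beta = 0.8, gamma = 0.07,
                          delta = 10,
                          n = if (d == "generalized") 3 else NULL,
                          m = if (d == "generalized") 1 else NULL)
    for (k in seq_len(nrow(st))) {
      J <- osc_jacobian(m, st[k, 1], st[k, 2])
      Jfd <- oscdesign:::.fd_jacobian(m, st[k, 1], st[k, 2])
      rel <- max(abs(J - Jfd)) / max(abs(Jfd), 1)
      worst <- max(worst, rel)
    }
  }
  expect_lt(worst, 1e-5)
})

test_that("nullclines solve the rate laws and obey the known relations", {
  xg <- 10^seq(-2, 1, length.out = 80)
  m3 <- oscillator_model("design3", alpha = 50, beta = 1, gamma = 0.05,
                         delta = 10)
  nc <- nullclines(m3, xg)
  # repressor nullcline limits: delta*gamma at x = 0, alpha*delta*gamma
  # at large x
  expect_equal(nullclines(m3, 1e-8)$y_y, 10 * 0.05, tolerance = 1e-6)
  expect_equal(nullclines(m3, 1e6)$y_y, 50 * 10 * 0.05, tolerance = 1e-3)
  # activator nullcline at x = 1: algebraic inversion gives
  # y = sqrt(beta(1+alpha)/(x(1+x^2)) - 1) = sqrt(24.5)
  expect_equal(nullclines(m3, 1)$y_x, sqrt(51 / 2 - 1), tolerance = 1e-12)
  # post-translational nullcline is the square of the non-competitive one
  m2 <- oscillator_model("design2", alpha = 50, beta = 1, gamma = 0.05,
                         sigma_prime = 1, delta = 10)
  nc2 <- nullclines(m2, xg)
  ok <- !is.na(nc$y_x)
  expect_equal(nc2$y_x[ok], nc$y_x[ok]^2, tolerance = 1e-10)
  # nullcline intersections coincide with located fixed points
  fps <- find_fixed_points(m3)
  for (fp in fps) {
    ncx <- nullclines(m3, fp$x)
    expect_equal(ncx$y_y, fp$y, tolerance = 1e-8)
    expect_equal(ncx$y_x, fp$y, tolerance = 1e-6)
  }
  expect_error(nullclines(m3, numeric(0)), "empty")
})

test_that("nondimensional periods convert to hours by 1/delta_R", {
  expect_equal(to_hours(2.0, 0.02), 100)
  expect_equal(to_hours(3.7, 1.0), 3.7)
  expect_equal(to_hours(6.283, 0.1), 62.83)
  expect_error(to_hours(1, 0), "positive")
})

test_that("trajectories stay nonnegative from nonnegative starts", {
  set.seed(11)
  for (d in c("design1", "design3", "smolen")) {
    m <- oscillator_model(d, alpha = 50, beta = 10^stats::runif(1, -1, 0.5),
                          gamma = 10^stats::runif(1, -2, -0.5), delta = 10)
    orb <- integrate_orbit(m, init = c(stats::runif(1, 0, 2),
                                       stats::runif(1, 0, 2)),
                           t_end = 50)
    expect_gte(min(orb[, c("x", "y")]), -1e-8)
  }
})
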