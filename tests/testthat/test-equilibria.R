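test_that("beta = 0 gives the unique basal equilibrium (0, delta*gamma)", {
  for (d in c("design1", "design2", "design3")) {
    m <- oscillator_model(d, alpha = 50, beta = 0, gamma = 0.05,
                          delta = 10)
    fps <- find_fixed_points(m)
    expect_length(fps, 1L)
    expect_equal(fps[[1]]$x, 0)
    expect_equal(fps[[1]]$y, 10 * 0.05, tolerance = 1e-10)
    # activator decay rate: Delta, plus the catalytic term Delta*sigma'*y
    # for the post-translational design
    lam_x <- if (d == "design2") -10 * (1 + 0.5) else -10
    expect_equal(sort(Re(fps[[1]]$eigenvalues)), c(lam_x, -1))
    expect_identical(fps[[1]]$stability, "stable-node")
  }
})

test_that("multistable window of the competition design is resolved", {
  # three crossings: two unstable states and a stable one coexist
  m <- oscillator_model("design1", alpha = 50, beta = 0.2, gamma = 0.01,
                        delta = 10)
  fps <- find_fixed_points(m)
  expect_length(fps, 3L)
  expect_true(any(vapply(fps, function(f)
    startsWith(f$stability, "stable"), logical(1))))
  # residual and separation contracts
  for (fp in fps) expect_lt(fp$residual, 1e-9)
  xs <- vapply(fps, `[[`, numeric(1), "x")
  expect_true(all(diff(sort(xs)) > 1e-6))
})

test_that("fixed points match a nullcline-crossing brute-force oracle", {
  for (pars in list(c(beta = 0.2, gamma = 0.05),
                    c(beta = 0.5, gamma = 0.01),
                    c(beta = 1.58, gamma = 0.079))) {
    m <- oscillator_model("design3", alpha = 50, beta = pars["beta"],
                          gamma = pars["gamma"], delta = 10)
    xg <- 10^seq(-6, 3, length.out = 20000)
    nc <- nullclines(m, xg)
    d <- nc$y_x - nc$y_y
    d[is.na(d)] <- -1  # no activator-nullcline solution: dx/dt < 0 there
    crossings <- which(d[-1] * d[-length(d)] < 0)
    fps <- find_fixed_points(m)
    expect_length(fps, length(crossings))
    xs <- sort(vapply(fps, `[[`, numeric(1), "x"))
    for (k in seq_along(crossings))
      expect_equal(xs[k], xg[crossings[k]], tolerance = 1e-3)
  }
})

test_that("eigenvalue classes agree with long-run integration", {
  set.seed(3)
  n_checked <- 0
  for (k in 1:25) {
    m <- oscillator_model("design3", alpha = 50,
                          beta = 10^stats::runif(1, -2, 1),
                          gamma = 10^stats::runif(1, -3, 0), delta = 10)
    fps <- find_fixed_points(m)
    stable <- Filter(function(f) startsWith(f$stability, "stable"), fps)
    if (length(fps) != 1L) next
    orb <- integrate_orbit(m, t_end = 300)
    endpt <- orb[nrow(orb), c("x", "y")]
    if (length(stable) == 1L) {
      # unique stable equilibrium: the trajectory must settle onto it
      expect_equal(unname(endpt["x"]), stable[[1]]$x, tolerance = 1e-4)
    } else {
      # no stable equilibrium: bounded planar flow must oscillate
      s <- summarize_orbit(orb)
      expect_identical(s$verdict, "sustained")
    }
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 15)
  expect_error(classify_fixed_point(oscillator_model("design3"), c(2, 2)),
               "not an equilibrium")
})

test_that("stability class is consistent with the trace-determinant plane", {
  set.seed(5)
  for (k in 1:40) {
    m <- oscillator_model(sample(c("design1", "design3"), 1), alpha = 50,
                          beta = 10^stats::runif(1, -2, 1),
                          gamma = 10^stats::runif(1, -3, 0), delta = 10)
    for (fp in find_fixed_points(m)) {
      J <- osc_jacobian(m, fp$x, fp$y)
      tr <- sum(diag(J)); dt <- det(J); disc <- tr^2 - 4 * dt
      expected <- if (dt < 0) "saddle"
        else if (disc >= 0) {
          if (tr < 0) "stable-node" else "unstable-node"
        } else if (tr < 0) "stable-focus" else "unstable-focus"
      expect_identical(fp$stability, expected)
    }
  }
})

test_that("generic parameter draws have an odd number of fixed points", {
  set.seed(8)
  for (k in 1:30) {
    m <- oscillator_model(sample(c("design1", "design3"), 1), alpha = 50,
                          beta = 10^stats::runif(1, -2, 1),
                          gamma = 10^stats::runif(1, -3, 0), delta = 10)
    expect_identical(length(find_fixed_points(m)) %% 2L, 1L)
  }
})

test_that("damped-oscillation onset is located by bisection", {
  m <- oscillator_model("design3", alpha = 50, gamma = 0.01, delta = 10)
  # upper flank of the oscillatory band: damped oscillations begin where
  # stability returns with complex eigenvalues
  onset <- damped_onset(m, "beta", c(0.1, 1))
  expect_equal(onset, 0.22583, tolerance = 1e-3)
  # dense-scan oracle: first beta (above the band) whose stable fixed
  # point has a nonzero imaginary part
  bs <- seq(0.1, 1, length.out = 2000)
  damped <- vapply(bs, function(b) {
    fps <- find_fixed_points(set_params(m, beta = b))
    st <- Filter(function(f) startsWith(f$stability, "stable"), fps)
    length(st) > 0 &&
      any(vapply(st, function(f) abs(Im(f$eigenvalues[1])) > 1e-9,
                 logical(1)))
  }, logical(1))
  first <- which(damped)[1]
  expect_true(onset > bs[first - 1] && onset <= bs[first] + 1e-9)
  # a range with no complexification reports none
  expect_true(is.na(damped_onset(m, "beta", c(1.5, 3))))
})

test_that("stability maps label the plane and favor non-competition", {
  g1 <- 10^seq(-1.2, 0.5, length.out = 8)
  g2 <- 10^seq(-2.2, -0.5, length.out = 8)
  sm3 <- stability_map(oscillator_model("design3", alpha = 50, delta = 10),
                       c("beta", "gamma"), g1, g2)
  sm1 <- stability_map(oscillator_model("design1", alpha = 50, delta = 10),
                       c("beta", "gamma"), g1, g2)
  osc_area <- function(sm) sum(sm$class %in% c("damped",
                                               "sustained-candidate"))
  expect_gte(osc_area(sm3), osc_area(sm1))
  # a 1x1 grid degenerates to single-point classification
  sm0 <- stability_map(oscillator_model("design3", alpha = 50, delta = 10),
                       c("beta", "gamma"), 1.58, 0.079)
  fp <- find_fixed_points(oscillator_model("design3", alpha = 50,
                                           beta = 1.58, gamma = 0.079,
                                           delta = 10))
  expect_identical(unname(sm0$class[1, 1]),
                   if (all(!startsWith(vapply(fp, `[[`, character(1),
                                              "stability"), "stable")))
                     "sustained-candidate" else "damped")
  df <- as.data.frame(sm3)
  expect_identical(nrow(df), 64L)
})
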