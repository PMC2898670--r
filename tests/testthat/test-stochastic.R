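test_that("degenerate networks behave as closed-form birth-death chains", {
  # no production at all: counts are frozen at zero
  m0 <- oscillator_model("design3", alpha = 50, beta = 0, gamma = 0,
                         delta = 1)
  tr <- ssa_run(build_network(m0, omega = 100), t_end = 5, seed = 1,
                init = c(0, 0))
  expect_true(all(tr$A == 0) && all(tr$R == 0))
  expect_identical(attr(tr, "n_events"), 0)

  # beta = 0: the repressor is an immigration-death process with
  # stationary mean omega * delta * gamma (rate ratio)
  m1 <- oscillator_model("design3", alpha = 50, beta = 0, gamma = 0.2,
                         delta = 1)
  tr1 <- ssa_run(build_network(m1, omega = 200), t_end = 500, seed = 2,
                 init = c(0, 0))
  burn <- tr1$time > 20
  mu <- 200 * 1 * 0.2
  n_eff <- sum(burn) * 0.02 / 2  # autocorrelation time is 1
  expect_lt(abs(mean(tr1$R[burn]) - mu), 3 * sqrt(mu / n_eff))

  # alpha = 1 removes autoregulation: the activator is immigration-death
  # with stationary mean omega * beta
  m2 <- oscillator_model("design3", alpha = 1, beta = 0.1, gamma = 0,
                         delta = 10)
  tr2 <- ssa_run(build_network(m2, omega = 500), t_end = 200, seed = 3,
                 init = c(0, 0))
  burn2 <- tr2$time > 5
  mu2 <- 500 * 0.1
  n_eff2 <- sum(burn2) * 0.02 / (2 / 10)
  expect_lt(abs(mean(tr2$A[burn2]) - mu2), 3 * sqrt(mu2 / n_eff2))
})

test_that("seeded runs are bit-identical and designs merge at sigma = 0", {
  m <- fig6_model("design3")
  net <- build_network(m, omega = 300)
  a <- ssa_run(net, t_end = 10, seed = 7)
  b <- ssa_run(net, t_end = 10, seed = 7)
  expect_identical(a, b)
  c <- ssa_run(net, t_end = 10, seed = 8)
  expect_false(identical(a$A, c$A))
  # sigma = 0: competitive and non-competitive networks have identical
  # propensities, hence identical seeded event sequences
  n1 <- build_network(oscillator_model("design1", alpha = 50, beta = 1,
                                       gamma = 0.05, sigma = 0,
                                       delta = 10), omega = 200)
  n3 <- build_network(oscillator_model("design3", alpha = 50, beta = 1,
                                       gamma = 0.05, sigma = 0,
                                       delta = 10), omega = 200)
  t1 <- ssa_run(n1, t_end = 20, seed = 11)
  t3 <- ssa_run(n3, t_end = 20, seed = 11)
  expect_identical(t1$A, t3$A)
  expect_identical(t1$R, t3$R)
})

test_that("the jump process converges to the deterministic mean field", {
  m <- fig6_model("design3")
  # short horizon (one cycle) so ensemble phase diffusion stays small
  orb <- integrate_orbit(m, init = c(0.1, 0.1), t_end = 2, dt = 0.02)
  errs <- vapply(c(100, 1000, 10000), function(omega) {
    net <- build_network(m, omega = omega)
    runs <- lapply(1:8, function(k)
      ssa_run(net, t_end = 2, seed = 100 * omega + k,
              init = round(omega * c(0.1, 0.1)), dt_sample = 0.02)$A)
    mean_x <- Reduce(`+`, runs) / (8 * omega)
    max(abs(mean_x - orb[, "x"])) / max(orb[, "x"])
  }, numeric(1))
  expect_true(all(diff(errs) < 0))  # error shrinks with system size
  expect_lt(errs[3], 0.05)
})

test_that("peak calling recovers periods from noisy traces", {
  set.seed(21)
  tt <- seq(0, 100, by = 0.02)
  x <- 50 * (sin(2 * pi * tt / 5) + 1.2) + rnorm(length(tt), 0, 6)
  tr <- data.frame(time = tt, A = x)
  pk <- ssa_peaks(tr, expected_period = 5)
  expect_equal(mean(diff(pk)), 5, tolerance = 0.03)
  expect_equal(length(pk), 20, tolerance = 0.1)
})

test_that("noise comparison runs reproducibly on a reduced ensemble", {
  nc <- noise_induced_analysis(omega = 200, n_runs = 12, t_end = 40,
                               seed = 5)
  expect_identical(nrow(nc$summary), 3L)
  expect_true(all(nc$summary$n_intervals > 30))
  expect_true(all(is.finite(nc$summary$cv)))
  # deterministic given the seed
  nc2 <- noise_induced_analysis(omega = 200, n_runs = 12, t_end = 40,
                                seed = 5)
  expect_identical(nc$summary, nc2$summary)
  # the chosen parameters are genuinely sub-threshold
  for (nm in names(nc$intervals)) {
    b <- nc$summary$beta_test[nc$summary$design == nm]
    tmpl <- oscillator_model(nm, alpha = 50, gamma = 0.05, delta = 10,
                             sigma_prime = if (nm == "design2") 1 else NULL)
    fps <- find_fixed_points(set_params(tmpl, beta = b))
    expect_true(any(vapply(fps, function(f)
      startsWith(f$stability, "stable"), logical(1))))
  }
})
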