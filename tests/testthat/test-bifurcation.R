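test_that("the supercritical Hopf normal form is detected and classified", {
  d <- scan_control(hopf_normal_form, "mu",
                    seq(-0.2, 0.3, length.out = 26), init = c(0.5, 0))
  kinds <- vapply(d$events, `[[`, character(1), "kind")
  expect_identical(kinds, "hopf_super")
  ev <- d$events[[1]]
  expect_equal(ev$control_value, 0, tolerance = 0.01)
  expect_lt(abs(ev$evidence$amplitude_exponent - 0.5), 0.15)
  expect_false(ev$evidence$hysteresis)
})

test_that("the SNIC normal form shows the inverse-square-root period law", {
  d <- scan_control(snic_normal_form, "mu",
                    seq(0.7, 1.6, length.out = 25), init = c(1, 0))
  kinds <- vapply(d$events, `[[`, character(1), "kind")
  expect_true("snic" %in% kinds)
  ev <- d$events[[which(kinds == "snic")[1]]]
  expect_equal(ev$control_value, 1, tolerance = 0.01)
  expect_lt(abs(ev$evidence$period_exponent + 0.5), 0.1)
  # equilibrium count drops by two at the event
  expect_equal(abs(diff(ev$evidence$n_fp)), 2)
  # closed form: period = 2*pi/sqrt(mu^2 - 1)
  s <- summarize_orbit(integrate_orbit(snic_normal_form(1.2),
                                       init = c(1, 0), t_end = 400))
  expect_equal(s$period, 2 * pi / sqrt(1.2^2 - 1), tolerance = 0.02)
  # no damped precursor on the steady side of a SNIC
  expect_identical(nrow(damped_band(d)), 0L)
})

test_that("non-competition band is Hopf-bounded with damped flanks", {
  d <- diagram_design3_g05()
  kinds <- vapply(d$events, `[[`, character(1), "kind")
  expect_identical(length(kinds), 2L)
  expect_true(all(startsWith(kinds, "hopf")))
  # damped bands adjacent to both Hopf edges
  db <- damped_band(d)
  expect_gte(nrow(db), 2L)
  mu1 <- d$events[[1]]$control_value
  mu2 <- d$events[[2]]$control_value
  expect_lt(min(abs(db$hi - mu1)) / mu1, 0.1)
  expect_lt(min(abs(db$lo - mu2)) / mu2, 0.1)
  # at every Hopf event the cycle frequency at onset matches |Im lambda|
  # (soft onsets only: a subcritical cycle is born at finite amplitude,
  # away from the focus, so its frequency is not tied to Im lambda)
  checked <- 0
  for (ev in d$events) {
    if (!identical(ev$kind, "hopf_super")) next
    for (side in c(1.005, 0.995)) {
      mside <- set_params(d$model, beta = ev$control_value * side)
      s <- classify_asymptotics(mside, t_start = 300)
      if (!identical(s$verdict, "sustained")) next
      fps <- find_fixed_points(mside)
      im <- max(vapply(fps, function(f) abs(Im(f$eigenvalues[1])),
                       numeric(1)))
      expect_equal(2 * pi / s$period, im, tolerance = 0.05)
      checked <- checked + 1
      break
    }
  }
  expect_gte(checked, 1)
})

test_that("competition band exits through a SNIC without damped flank", {
  d <- diagram_design1_g05()
  kinds <- vapply(d$events, `[[`, character(1), "kind")
  expect_identical(kinds[length(kinds)], "snic")
  ev <- d$events[[length(d$events)]]
  expect_equal(ev$control_value, 0.99921, tolerance = 1e-3)
  expect_equal(abs(ev$evidence$n_fp_change_at_event), 2)
  expect_lt(abs(ev$evidence$period_exponent + 0.5), 0.1)
  # no damped band borders the SNIC exit
  db <- damped_band(d)
  if (nrow(db))
    expect_gt(min(abs(db$lo - ev$control_value)),
              0.05 * ev$control_value)
})

test_that("damped band edges agree with the bisected damped onset", {
  d <- diagram_design3_g01()
  kinds <- vapply(d$events, `[[`, character(1), "kind")
  # exit through a (subcritical) Hopf at the value the damped band starts
  expect_true(any(startsWith(kinds, "hopf")))
  hopf <- d$events[[which(startsWith(kinds, "hopf"))[1]]]
  onset <- damped_onset(d$model, "beta", c(0.1, 1))
  expect_equal(hopf$control_value, onset, tolerance = 1e-3)
})

test_that("degradation-ratio scans show both bifurcation routes", {
  # at beta = 1.58, gamma = 0.079 the non-competition design enters
  # through a Hopf in Delta while the competition design enters through
  # a saddle-node collision with diverging period
  d3 <- cached("dIII_delta", function()
    scan_control(oscillator_model("design3", alpha = 50, beta = 1.58,
                                  gamma = 0.079, delta = 10),
                 "delta", seq(2, 16, length.out = 57)))
  k3 <- vapply(d3$events, `[[`, character(1), "kind")
  expect_true(startsWith(k3[1], "hopf"))
  expect_equal(d3$events[[1]]$control_value, 4.34, tolerance = 0.02)
  d1 <- cached("dI_delta", function()
    scan_control(oscillator_model("design1", alpha = 50, beta = 1.58,
                                  gamma = 0.079, delta = 10),
                 "delta", seq(2, 16, length.out = 57)))
  k1 <- vapply(d1$events, `[[`, character(1), "kind")
  expect_true(d1$events[[1]]$evidence$saddle_node)
  # the competition design is born with a much longer period
  expect_gt(min(d1$period, na.rm = TRUE), 2 * max(d3$period[d3$values < 6],
                                                  na.rm = TRUE))
})
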