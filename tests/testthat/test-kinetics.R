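times4 <- c(2, 24, 48, 168)

test_that("slow clearance below physical decay raises a warning", {
  # effective slow half-life longer than the 159.5-h physical half-life
  expect_warning(fit_low_curve(times4, 100 * exp(-0.002 * times4)),
                 "physical decay")
})

test_that("mono-exponential data are recovered through the biexponential path", {
  a <- 100 * exp(-0.01 * times4)
  fit <- fit_low_curve(times4, a)
  expect_true(isTRUE(fit$mono))
  expect_lt(abs((fit$a1 + fit$a2) / 100 - 1), 1e-8)
  expect_lt(abs(fit$lambda2 / 0.01 - 1), 1e-8)
})

test_that("noiseless biexponential parameters are recovered", {
  truth <- tac_biexponential(80, 0.2, 20, 0.005)
  fit <- fit_low_curve(times4, predict(truth, times4))
  expect_lt(abs(fit$a1 / 80 - 1), 1e-6)
  expect_lt(abs(fit$lambda1 / 0.2 - 1), 1e-6)
  expect_lt(abs(fit$a2 / 20 - 1), 1e-6)
  expect_lt(abs(fit$lambda2 / 0.005 - 1), 1e-6)
})

test_that("fit input validation rejects bad samples", {
  expect_error(fit_low_curve(times4, c(10, -1, 5, 2)), "positive")
  expect_error(fit_low_curve(c(2, 24, 24, 168), c(4, 3, 2, 1)),
               "strictly increasing")
  expect_error(fit_high_curve(times4, c(1, 2, 0, 1)), "positive")
})

test_that("high-uptake piecewise fit matches the hand log-linear regression", {
  fit <- suppressMessages(fit_high_curve(times4, c(50, 72, 60, 30)))
  expect_equal(fit$slope, 1.0)
  expect_equal(fit$lambda_tail, 0.00598, tolerance = 1e-3)
  # amplitude back-extrapolated to t = 0
  a0 <- fit$tail_value * exp(fit$lambda_tail * fit$t2)
  expect_equal(a0, 81.7, tolerance = 1e-3)
  # hand piecewise integral: 98 + 1342 + tail
  expect_equal(integrate_curve(fit), 1.327e4, tolerance = 1e-3)
  # tail slope equals the closed-form regression slope on the logs
  y <- log(c(72, 60, 30)); t <- c(24, 48, 168)
  slope_cf <- sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
  expect_equal(fit$lambda_tail, -slope_cf, tolerance = 1e-12)
})

test_that("single-exponential samples give a consistent piecewise curve", {
  a <- 90 * exp(-0.015 * times4)
  fit <- suppressMessages(fit_high_curve(times4, a))
  # tail reproduces the generating exponential exactly
  tt <- c(24, 60, 100, 400)
  expect_equal(predict(fit, tt), 90 * exp(-0.015 * tt), tolerance = 1e-9)
  # linear part is the chord of the same curve
  expect_equal(predict(fit, 10), a[1] + fit$slope * 8, tolerance = 1e-12)
})

test_that("flat activities clamp the tail rate with a warning", {
  expect_warning(fit <- fit_high_curve(times4, rep(20, 4)), "clamping")
  expect_equal(fit$slope, 0)
  expect_equal(fit$lambda_tail, 1e-6)
})

test_that("analytic integrals match closed forms and quadrature", {
  mono <- tac_biexponential(100, 0.1)
  expect_equal(integrate_curve(mono), 1000)

  set.seed(21)
  for (i in 1:30) {
    curve <- if (i %% 2 == 0) {
      tac_biexponential(runif(1, 1, 100), runif(1, 0.05, 0.5),
                        runif(1, 1, 100), runif(1, 0.002, 0.02))
    } else {
      a1 <- runif(1, 20, 80)
      tac_piecewise(2, a1, 24, runif(1, -1, 2), runif(1, 30, 120),
                    runif(1, 0.004, 0.03))
    }
    expect_equal(integrate_curve(curve), quad_tia(curve),
                 tolerance = 1e-3)
  }
})

test_that("integration is linear in the curve amplitude", {
  set.seed(5)
  for (i in 1:10) {
    k <- runif(1, 0.1, 10)
    b <- tac_biexponential(runif(1, 1, 50), runif(1, 0.05, 0.4),
                           runif(1, 1, 50), runif(1, 0.003, 0.02))
    bk <- tac_biexponential(k * b$a1, b$lambda1, k * b$a2, b$lambda2)
    expect_equal(integrate_curve(bk), k * integrate_curve(b),
                 tolerance = 1e-12)
  }
})

test_that("weakly identified biexponentials still recover the integral", {
  set.seed(33)
  worst <- 0
  for (i in 1:50) {
    a1 <- runif(1, 1, 100); a2 <- runif(1, 1, 100)
    l1 <- runif(1, 0.05, 0.5); l2 <- runif(1, 0.002, 0.02)
    truth <- tac_biexponential(a1, l1, a2, l2)
    fit <- suppressWarnings(fit_low_curve(times4, predict(truth, times4)))
    rel <- abs(integrate_curve(fit) / integrate_curve(truth) - 1)
    worst <- max(worst, rel)
  }
  expect_lt(worst, 0.005)
})

test_that("concentration curves are the activity curves scaled by mass", {
  curve <- tac_biexponential(640, 0.01)  # integral 64000 MBq*h
  conc <- to_concentration(curve, 64000)
  expect_equal(integrate_curve(conc), 1.0)
  set.seed(9)
  t <- runif(10, 0, 300)
  expect_equal(predict(conc, t) * 64000, predict(curve, t))
  expect_error(to_concentration(curve, 0), "positive")
})
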