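test_that("effective rate blends occupancy-weighted components", {
  kp <- kineticParams()
  expect_equal(effectiveRate(kp, 0), 0.01)
  expect_equal(effectiveRate(kp, 1e9), 0.50 + 0.10, tolerance = 1e-6)
  # frozen closed-form arithmetic at 1 ng/ml:
  # (1/3)*0.5 + (2/3)*0.01 + (1/21)*0.1
  expect_equal(effectiveRate(kp, 1), 0.1780952, tolerance = 1e-6)
  inh <- kineticParams(kinaseInhibited = TRUE)
  expect_equal(effectiveRate(inh, 1e9), 0.01 * 0 + 0.10, tolerance = 1e-4)
  egf <- seq(0, 100, by = 0.5)
  expect_true(all(diff(effectiveRate(kp, egf)) >= 0))
  expect_true(all(diff(effectiveRate(inh, egf)) >= 0))
  expect_error(effectiveRate(kp, -1), "non-negative")
})

test_that("fraction time course matches the closed form and an ODE oracle", {
  kp <- kineticParams()
  tc <- simulateFraction(kp, 4, seq(0, 30, by = 2.5))
  expect_equal(tc$f_endo[1], 0)
  # frozen: k(4 ng/ml) = 0.3533333/min, kRec = 0.05 => f(15) = 0.8739675
  expect_equal(tc$f_endo[tc$time_min == 15], 0.8739675, tolerance = 1e-6)
  # kRec = 0 reduces to 1 - exp(-kt)
  kp0 <- kineticParams(kRec = 0)
  tc0 <- simulateFraction(kp0, 4, c(0, 5, 10))
  k <- effectiveRate(kp0, 4)
  expect_equal(tc0$f_endo, 1 - exp(-k * c(0, 5, 10)), tolerance = 1e-12)
  expect_error(simulateFraction(kp, 4, c(5, 1)), "sorted")
  # independent numerical integration of the two-pool system
  set.seed(31)
  for (i in 1:10) {
    kpi <- kineticParams(keOccCme = runif(1, 0.1, 0.8),
                         keCieMax = runif(1, 0, 0.2),
                         keBasal = runif(1, 0, 0.05),
                         kRec = runif(1, 0, 0.2))
    egf <- runif(1, 0, 50)
    times <- seq(0, 30, by = 1)
    ki <- effectiveRate(kpi, egf)
    ode <- deSolve::ode(c(S = 1, E = 0), times, function(t, y, p) {
      list(c(-ki * y["S"] + kpi@kRec * y["E"],
             ki * y["S"] - kpi@kRec * y["E"]))
    }, NULL, rtol = 1e-10, atol = 1e-12)
    expect_lt(max(abs(ode[, "E"] - simulateFraction(kpi, egf, times)$f_endo)),
              1e-8)
    # mass conservation in the integrated system
    expect_lt(max(abs(ode[, "S"] + ode[, "E"] - 1)), 1e-8)
  }
})

test_that("dose response shows kinase-dependent low-dose and residual high-dose uptake", {
  kp <- kineticParams(); sp <- sensorParams(); comp <- compartmentPH()
  base <- simulateDoseResponse(kp, sp, comp, concs = 0)
  expect_equal(base$f_endo,
               simulateFraction(kineticParams(), 0, c(0, 15))$f_endo[2])
  dr <- simulateDoseResponse(kp, sp, comp, concs = c(0, 0.5, 1, 2, 4, 20, 200))
  expect_true(all(diff(dr$ratio) >= 0))
  inhLow <- simulateDoseResponse(kp, sp, comp, concs = 1, inhibited = TRUE)
  expect_lt(abs(inhLow$ratio / base$ratio - 1), 0.10)
  inhHigh <- simulateDoseResponse(kp, sp, comp, concs = 200, inhibited = TRUE)
  expect_gt(inhHigh$ratio - base$ratio, 0)
  expect_error(simulateDoseResponse(kp, sp, comp, concs = 1, t = 0),
               "positive")
})

test_that("uptake simulation is seeded, linear and noise-controlled", {
  s <- simulateUptake(0.5, 1:5, noiseCv = 0, seed = 3)
  expect_equal(s$internal / s$surface, 0.5 * (1:5), tolerance = 1e-12)
  expect_identical(simulateUptake(0.5, 1:5, seed = 9),
                   simulateUptake(0.5, 1:5, seed = 9))
  expect_false(identical(simulateUptake(0.5, 1:5, seed = 9),
                         simulateUptake(0.5, 1:5, seed = 10)))
  expect_true(all(simulateUptake(0, 1:5, seed = 1)$internal == 0))
  expect_error(simulateUptake(0.5, numeric(0)), "non-empty")
})

test_that("In/Sur slope estimator recovers the internalization rate constant", {
  expect_equal(estimateKe(simulateUptake(0.5, 1:5, noiseCv = 0, seed = 1)),
               0.5)
  zero <- simulateUptake(0, 1:5, noiseCv = 0, seed = 1)
  expect_equal(estimateKe(zero), 0)
  bad <- data.frame(time_min = 1:3, internal = c(1, 2, 3),
                    surface = c(10, 0, 10))
  expect_error(estimateKe(bad, nPoints = 3), "positive")
  expect_error(estimateKe(simulateUptake(0.5, 1:5, seed = 1), nPoints = 1),
               ">= 2")
  # 20-seed mean at 1% CV sits in the published window for CME rates
  est <- vapply(1:20, function(s)
    estimateKe(simulateUptake(0.5, 1:5, noiseCv = 0.01, seed = s)),
    numeric(1))
  expect_gte(mean(est), 0.49)
  expect_lte(mean(est), 0.51)
  # near-unbiased under many seeds
  est2 <- vapply(1:1000, function(s)
    estimateKe(simulateUptake(0.5, 1:5, noiseCv = 0.01, seed = s)),
    numeric(1))
  expect_lt(abs(mean(est2) / 0.5 - 1), 0.01)
})

test_that("plateau detection finds the earliest settled sample", {
  flat <- data.frame(time_min = c(0, 5, 10), f_endo = c(0, 0, 0))
  expect_equal(plateauTime(flat), 0)
  # frozen from the closed form: lambda = 0.4033/min => settled at 7.5 min
  tc <- simulateFraction(kineticParams(), 4, seq(0, 30, by = 2.5))
  expect_equal(plateauTime(tc, relTol = 0.05), 7.5)
  # a still-rising trajectory only settles at its final sample
  rising <- data.frame(time_min = 0:5, f_endo = c(0, 0.2, 0.4, 0.6, 0.8, 1))
  expect_equal(plateauTime(rising, relTol = 0.05), 5)
  expect_error(plateauTime(tc, relTol = 1.5), "relTol")
})
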