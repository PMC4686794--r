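# LEP wild-type probe rate constants, used throughout as realistic truth
KA <- 2.3e3
KD <- 1.8e-4

test_that("k_obs is linear in concentration with intercept kd", {
  expect_equal(kObs(KA, KD, 0), KD)
  expect_equal(kObs(KA, KD, 60e-9), 3.18e-4)  # 2.3e3 * 6e-8 + 1.8e-4
  L <- c(10, 20, 40, 60) * 1e-9
  k <- kObs(KA, KD, L)
  expect_equal(diff(k) / diff(L), rep(KA, 3))
  expect_error(kObs(-1, KD, 1e-8), "ka")
})

test_that("association curve starts at zero and plateaus at L/(L + KD)", {
  expect_equal(associationCurve(KA, KD, 60e-9, 1, 0), 0)
  # L = 60 nM against K*D = 78 nM exactly: equilibrium bound fraction 60/138
  expect_equal(associationCurve(KA, 78e-9 * KA, 60e-9, 1, 1e9), 60 / 138,
               tolerance = 1e-9)
  tseq <- seq(0, 10800, length.out = 50)
  y <- associationCurve(KA, KD, 40e-9, 2.5, tseq)
  expect_true(all(diff(y) >= 0))
  expect_error(associationCurve(KA, KD, 60e-9, 1, -5), "negative time")
  expect_warning(associationCurve(KA, KD, 2e-9, 1, 100, receptor = 0.3e-9),
                 "pseudo-first-order")
})

test_that("curve matches numerical integration of the binding ODE", {
  skip_if_not_installed("deSolve")
  set.seed(41)
  for (rep in 1:10) {
    ka <- 10^runif(1, 3, 6)
    kd <- 10^runif(1, -5, -3)
    L <- runif(1, 5e-9, 1e-7)
    amp <- runif(1, 0.5, 3)
    tseq <- seq(0, 3 * 3600, length.out = 25)
    # d[C]/dt = ka L ([R] - [C]) - kd [C], trace receptor R
    R0 <- 1
    ode <- deSolve::lsoda(c(C = 0), tseq,
                          function(t, y, p) list(ka * L * (R0 - y[1]) - kd * y[1]),
                          parms = NULL, rtol = 1e-10, atol = 1e-12)
    closed <- associationCurve(ka, kd, L, amp, tseq)
    expect_equal(closed[-1], amp * ode[-1, "C"] / R0, tolerance = 1e-6)
  }
})

test_that("simulation is seed-reproducible with calibrated noise", {
  tseq <- seq(0, 10800, length.out = 12)
  clean <- simulateTimeCourse(KA, KD, 40e-9, 1, tseq, noise_sd = 0, seed = 7)
  expect_equal(clean$signal, associationCurve(KA, KD, 40e-9, 1, tseq))
  a <- simulateTimeCourse(KA, KD, 40e-9, 1, tseq, 0.02, seed = 7)
  b <- simulateTimeCourse(KA, KD, 40e-9, 1, tseq, 0.02, seed = 7)
  expect_identical(a$signal, b$signal)
  big <- simulateTimeCourse(KA, KD, 40e-9, 1, seq_len(1e4), 0.05, seed = 8)
  resid <- big$signal - associationCurve(KA, KD, 40e-9, 1, seq_len(1e4))
  expect_equal(sd(resid), 0.05, tolerance = 0.05)  # within 5%
  # the caller's RNG stream is untouched
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(simulateTimeCourse(KA, KD, 1e-8, 1, 0:10, 1, seed = 3))
  expect_identical(rnorm(1), before)
})

test_that("global fit recovers exact parameters from noiseless curves", {
  tseq <- seq(0, 10800, length.out = 12)
  tc <- do.call(rbind, lapply(c(10, 20, 40, 60) * 1e-9, function(L)
    simulateTimeCourse(KA, KD, L, 1.7, tseq, 0, seed = 1,
                       label = sprintf("%g", L))))
  fit <- fitKinetics(tc)
  k <- rateConstants(fit)
  expect_equal(unname(k[["ka"]]), KA, tolerance = 1e-6)
  expect_equal(unname(k[["kd"]]), KD, tolerance = 1e-6)
  expect_equal(fit@amplitude, 1.7, tolerance = 1e-6)
  # derived block identical to deriveConstants on the fitted pair
  expect_identical(derivedConstants(fit),
                   deriveConstants(k[["ka"]], k[["kd"]], fit@temperature))
})

test_that("noisy-fit recovery stays within three standard errors", {
  sim <- simulateExperiment(KA, KD, noise_frac = 0.02, seed = 42)
  fit <- fitKinetics(sim)
  se <- standardErrors(fit)
  expect_lt(abs(rateConstants(fit)[["ka"]] - KA), 3 * se[["ka"]])
  expect_lt(abs(rateConstants(fit)[["kd"]] - KD), 3 * se[["kd"]])
})

test_that("fit is invariant to curve input order", {
  sim <- simulateExperiment(KA, KD, noise_frac = 0.02, seed = 5)
  fit1 <- fitKinetics(sim)
  fit2 <- fitKinetics(sim[rev(seq_len(nrow(sim))), ])
  expect_equal(rateConstants(fit1), rateConstants(fit2), tolerance = 1e-8)
})

test_that("degenerate kinetics inputs raise informative errors", {
  tseq <- seq(0, 10800, length.out = 12)
  one <- simulateTimeCourse(KA, KD, 40e-9, 1, tseq, 0, seed = 1)
  expect_error(fitKinetics(one), "two distinct concentrations")
  two <- rbind(one, simulateTimeCourse(KA, KD, 20e-9, 1, tseq, 0, 1, label = "b"))
  zero <- two; zero$signal <- 0
  expect_error(fitKinetics(zero), "no binding")
  short <- two[c(1:3, 13:24), ]
  expect_error(fitKinetics(short), "5 time points")
})

test_that("derived constants reproduce the wild-type probe row", {
  d <- deriveConstants(KA, KD)  # 25 C
  expect_equal(unname(d[["kStarD"]]) * 1e9, 78, tolerance = 0.005)
  expect_equal(unname(d[["tHalf"]]) / 60, 64, tolerance = 0.005)
  expect_equal(unname(d[["minusDeltaG"]]), 9.7, tolerance = 0.001)
  expect_equal(unname(deriveConstants(1, log(2) / 60)[["tHalf"]]), 60)
  same <- deriveConstants(5e-4, 5e-4)
  expect_equal(unname(same[["kStarD"]]), 1)
  expect_equal(unname(same[["minusDeltaG"]]), 0)
  expect_error(deriveConstants(-1, 1), "positive")
})

test_that("time-course CSV round trips through the nM dialect", {
  sim <- simulateExperiment(KA, KD, seed = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  writeTimeCourses(sim, f)
  back <- readTimeCourses(f)
  expect_equal(back$conc, sim$conc, tolerance = 1e-12)
  expect_equal(back$signal, sim$signal, tolerance = 1e-12)
  js <- kineticsFitJson(fitKinetics(back))
  expect_true(jsonlite::validate(js))
})
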