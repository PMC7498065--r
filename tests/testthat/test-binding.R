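# Single-cycle kinetics simulation/fitting, 4PL dose-response and
# Cheng-Prusoff conversion.

test_that("the canonical dilution series runs 1 uM down to 1.37 nM", {
  p <- makeSckProtocol()
  expect_equal(length(p@concentrations), 7L)
  expect_equal(min(p@concentrations), 1e-6 / 3^6, tolerance = 1e-12)
  expect_equal(min(p@concentrations), 1.3717e-9, tolerance = 1e-4)
  expect_equal(max(p@concentrations), 1e-6)
  ratios <- p@concentrations[-1] / p@concentrations[-7]
  expect_equal(ratios, rep(3, 6L), tolerance = 1e-12)

  single <- makeSckProtocol(nInjections = 1L)
  expect_equal(single@concentrations, 1e-6)
  expect_error(makeSckProtocol(dilution = 1), "> 1")
  expect_error(makeSckProtocol(topConc = 0), "> 0")
})

test_that("the closed-form trace honours Langmuir limits", {
  # slow dissociation, one long injection: monotone approach to Rmax
  m <- kineticsModel(kon = 1e6, koff = 1e-9, Rmax = 80)
  p <- makeSckProtocol(topConc = 1e-6, nInjections = 1L,
                       contactTime = 5000, finalDissociationTime = 1,
                       samplingRate = 0.5)
  sg <- simulateSck(m, p)
  inj <- sensorResponse(sg)[sensorTime(sg) <= 5000]
  expect_true(all(diff(inj) >= -1e-9))
  expect_lt(max(inj), 80 + 1e-6)
  expect_equal(max(inj), 80, tolerance = 1e-3)

  # long-contact plateau equals Rmax C / (C + KD)
  m2 <- kineticsModel(kon = 1e5, koff = 1e-2, Rmax = 100)
  C <- 1e-7
  p2 <- makeSckProtocol(topConc = C, nInjections = 1L, contactTime = 5000,
                        finalDissociationTime = 1, samplingRate = 0.5)
  sg2 <- simulateSck(m2, p2)
  plateau <- max(sensorResponse(sg2))
  expect_equal(plateau, 100 * C / (C + KD(m2)), tolerance = 1e-6)

  # noiseless response never exceeds Rmax across a full protocol
  sg3 <- simulateSck(kineticsModel(2e5, 5e-4, 120), makeSckProtocol())
  expect_true(all(sensorResponse(sg3) <= 120 + 1e-9))

  # Req increases strictly with concentration
  Req <- function(C) 1e5 * C * 100 / (1e5 * C + 1e-3)
  cs <- makeSckProtocol()@concentrations
  expect_true(all(diff(vapply(cs, Req, numeric(1))) > 0))

  # determinism with noise
  a <- simulateSck(m2, p2, noiseSd = 1, seed = 7L)
  b <- simulateSck(m2, p2, noiseSd = 1, seed = 7L)
  expect_identical(sensorResponse(a), sensorResponse(b))
})

test_that("the closed form agrees with numeric ODE integration", {
  m <- kineticsModel(kon = 1e5, koff = 1e-3, Rmax = 100)
  p <- makeSckProtocol(samplingRate = 0.1)
  sg <- simulateSck(m, p)
  numeric_trace <- oracleSckTrace(1e5, 1e-3, 100, p, dt = 0.05)
  expect_equal(sensorResponse(sg), numeric_trace, tolerance = 1e-4)
})

test_that("noiseless fits recover kinetic parameters within 0.1%", {
  m <- kineticsModel(kon = 1e5, koff = 1e-3, Rmax = 100)
  sg <- simulateSck(m, makeSckProtocol())
  fit <- fitSck(sg)
  expect_true(fit$converged)
  expect_lt(abs(fit$model@kon - 1e5) / 1e5, 1e-3)
  expect_lt(abs(fit$model@koff - 1e-3) / 1e-3, 1e-3)
  expect_lt(abs(fit$model@Rmax - 100) / 100, 1e-3)
  expect_equal(fit$KD, KD(fit$model))
  expect_length(fit$flags, 0L)
})

test_that("fits below the instrument koff limit are flagged", {
  sg <- simulateSck(kineticsModel(1e5, 5e-6, 100),
                    makeSckProtocol(samplingRate = 0.5))
  fit <- fitSck(sg)
  expect_true("koff_below_limit" %in% fit$flags)
})

test_that("KD recovery is accurate and unbiased at 1 RU noise", {
  m <- kineticsModel(kon = 1e5, koff = 1e-3, Rmax = 100)
  p <- makeSckProtocol(samplingRate = 0.2)
  relErr <- signedErr <- numeric(50L)
  for (r in seq_len(50L)) {
    sg <- simulateSck(m, p, noiseSd = 1, seed = r)
    fit <- fitSck(sg)
    relErr[r] <- abs(fit$KD - 1e-8) / 1e-8
    signedErr[r] <- (fit$KD - 1e-8) / 1e-8
  }
  expect_lt(median(relErr), 0.10)
  expect_lt(abs(median(signedErr)), 0.05)
})

test_that("fitted KD is invariant to rescaling Rmax jointly with signal", {
  m <- kineticsModel(kon = 1e5, koff = 1e-3, Rmax = 100)
  p <- makeSckProtocol(samplingRate = 0.5)
  sg <- simulateSck(m, p)
  scaled <- new("Sensorgram", time = sensorTime(sg),
                response = sensorResponse(sg) * 3, protocol = p)
  fit <- fitSck(scaled)
  expect_equal(fit$KD, 1e-8, tolerance = 1e-3)
  expect_equal(fit$model@Rmax, 300, tolerance = 1e-3)
})

test_that("4PL fitting recovers parameters and the midpoint property", {
  x <- 10^seq(-10.5, -6, length.out = 11L)
  y <- .0 + (100 - 0) / (1 + (x / 1e-8)^(-1))
  fit <- fit4pl(x, y)
  expect_lt(abs(fit@bottom - 0), 1e-3)
  expect_lt(abs(fit@top - 100) / 100, 1e-3)
  expect_lt(abs(fit@midpoint - 1e-8) / 1e-8, 1e-3)
  expect_lt(abs(fit@hill - 1), 1e-3)
  expect_true(fit@hillInRange)
  # y at the midpoint equals (top + bottom) / 2
  yMid <- fit@bottom + (fit@top - fit@bottom) /
    (1 + (fit@midpoint / fit@midpoint)^(-fit@hill))
  expect_equal(yMid, (fit@top + fit@bottom) / 2)

  # an inhibition curve fits with a negative Hill slope
  yInh <- 5 + (90 - 5) / (1 + (x / 3e-8)^(1.2))
  fitInh <- fit4pl(x, yInh)
  expect_lt(fitInh@hill, 0)
  expect_equal(fitInh@midpoint, 3e-8, tolerance = 1e-3)
  expect_true(fitInh@hillInRange)

  # steep slopes are flagged out of range
  ySteep <- 100 / (1 + (x / 1e-8)^(-4))
  expect_false(fit4pl(x, ySteep)@hillInRange)

  expect_error(fit4pl(rep(1e-8, 6L), rnorm(6)), "degenerate")
  expect_error(fit4pl(x[1:3], y[1:3]), ">= 5")

  # background wells are mean-subtracted before fitting
  fitBg <- fit4pl(x, y + 10, backgroundWells = c(9, 10, 11))
  expect_lt(abs(fitBg@bottom), 1e-3)
})

test_that("Cheng-Prusoff conversion and its limits hold", {
  expect_equal(chengPrusoff(10e-9, 5e-9, 5e-9), 5e-9)    # [R] = KDapp
  expect_equal(chengPrusoff(10e-9, 0, 5e-9), 10e-9)      # no competition
  expect_equal(chengPrusoff(12, 12, 4), 3)
  # Ki <= IC50 always; Ki -> IC50 as [R] -> 0
  set.seed(71)
  for (k in 1:20) {
    ic50 <- 10^runif(1, -10, -6)
    r <- 10^runif(1, -10, -6)
    kd <- 10^runif(1, -10, -6)
    expect_lte(chengPrusoff(ic50, r, kd), ic50)
  }
  expect_equal(chengPrusoff(1e-8, 1e-15, 1e-9), 1e-8, tolerance = 1e-5)
  expect_error(chengPrusoff(1e-8, 1e-9, 0), "> 0")
  expect_error(chengPrusoff(0, 1e-9, 1e-9), "> 0")

  # attachKi wires the conversion into a FretFit
  x <- 10^seq(-10, -6.5, length.out = 9L)
  y <- 90 + (5 - 90) / (1 + (x / 2e-8)^(1))
  fit <- fit4pl(x, y)
  withKi <- attachKi(fit, rConc = fit@midpoint, kdApp = fit@midpoint)
  expect_equal(withKi@Ki, fit@midpoint / 2, tolerance = 1e-6)
})
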