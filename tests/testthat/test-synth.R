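test_that("kinetic model validity catches malformed parameterizations", {
  expect_s4_class(kineticModel(), "KineticModel")
  expect_error(kineticModel(A = matrix(c(0.9, 0.2, 0.05, 0.95), 2,
                                       byrow = TRUE)),
               "sum to 1")
  expect_error(kineticModel(noiseSd = 0), "noiseSd")
  expect_error(kineticModel(dt = -1), "dt")
  expect_error(kineticModel(pi0 = c(0.5, 0.4)), "pi0")
})

test_that("a frozen chain stays in its initial state with expected FRET", {
  m <- kineticModel(A = diag(2), pi0 = c(1, 0),
                    donorMean = c(300, 700), acceptorMean = c(700, 300),
                    noiseSd = 1e-9)
  tr <- simulateTrace(m, nPoints = 50, seed = 2)
  expect_identical(unique(traceValues(tr)$state), 0)
  expect_equal(mean(traceValues(tr)$fret), 700 / 1000, tolerance = 1e-6)
})

test_that("a single-frame trace has all channels of length one", {
  tr <- simulateTrace(kineticModel(), nPoints = 1, seed = 1)
  expect_length(tr, 1L)
  expect_identical(traceIndex(tr), 0)
  expect_true(all(lengths(traceValues(tr)) == 1L))
})

test_that("the index is an arithmetic time base in seconds", {
  m <- kineticModel(dt = 0.25)
  tr <- simulateTrace(m, nPoints = 4, seed = 9)
  expect_equal(traceIndex(tr), c(0, 0.25, 0.5, 0.75))
})

test_that("equal seeds give bit-identical traces and datasets", {
  m <- kineticModel()
  expect_identical(smdId(simulateTrace(m, 100, seed = 7)),
                   smdId(simulateTrace(m, 100, seed = 7)))
  d1 <- simulateDataset(m, nTraces = 4, nPoints = 30, seed = 11)
  d2 <- simulateDataset(m, nTraces = 4, nPoints = 30, seed = 11)
  expect_identical(smdToJSON(d1), smdToJSON(d2))
  expect_identical(smdId(d1), smdId(d2))
})

test_that("different seeds give different dataset ids", {
  m <- kineticModel()
  ids <- vapply(1:12, function(s)
    smdId(simulateDataset(m, nTraces = 2, nPoints = 20, seed = s)),
    character(1L))
  expect_identical(anyDuplicated(ids), 0L)
})

test_that("simulated traces carry seed, model parameters and null count", {
  tr <- simulateTrace(kineticModel(), 25, seed = 5)
  at <- traceAttr(tr)
  expect_identical(at$seed, 5L)
  expect_identical(at$sim_K, 2L)
  expect_equal(at$sim_A, c(0.98, 0.02, 0.05, 0.95))
  expect_true(at$n_fret_null >= 0L)
})

test_that("fret is computed from the noisy intensities, null on bad frames", {
  ## emission means straddle zero so some frames have non-positive total
  m <- kineticModel(A = diag(2), pi0 = c(1, 0),
                    donorMean = c(0, 100), acceptorMean = c(0, 100),
                    noiseSd = 50)
  tr <- simulateTrace(m, nPoints = 400, seed = 3)
  v <- traceValues(tr)
  expect_identical(sum(is.na(v$fret)), traceAttr(tr)$n_fret_null)
  expect_gt(traceAttr(tr)$n_fret_null, 0L)
  ok <- !is.na(v$fret)
  expect_equal(v$fret[ok], (v$acceptor / (v$donor + v$acceptor))[ok])
})

test_that("simulated datasets validate strictly and round trip unchanged", {
  d <- simulateDataset(nTraces = 3, nPoints = 40, seed = 8)
  expect_true(validateSMD(d, mode = "strict")$valid)
  expect_true(all(verifyIds(d)$match))
  expect_smd_equal(d, readSMD(smdToJSON(d)))
  expect_identical(summarizeDataset(d)$nPointsTotal, 120L)
  expect_identical(channelTypes(d)[["state"]], "int")
})

test_that("transition counting is exact on deterministic paths", {
  alternating <- SMDTrace(0:9 / 10,
                          list(state = as.numeric(rep(c(0, 1), 5))))
  d <- SMDDataset(list(alternating), "alternating")
  rk <- recoverKinetics(d)
  expect_identical(rk$A, matrix(c(0, 1, 1, 0), 2, byrow = TRUE))
  expect_identical(rk$occupancy, c(0.5, 0.5))

  constant <- SMDDataset(list(SMDTrace(0:4 / 10,
                                       list(state = rep(0, 5)))),
                         "constant", types = c(state = "int"))
  rk2 <- recoverKinetics(constant, K = 2)
  expect_identical(rk2$occupancy, c(1, 0))
  expect_identical(rk2$undefinedRows, 2L)
  expect_true(all(is.nan(rk2$A[2, ])))
})

test_that("recoverKinetics rejects non-integer state channels", {
  d <- simulateDataset(nTraces = 1, nPoints = 10, seed = 2)
  expect_error(recoverKinetics(d, stateChannel = "fret"), "integer")
  expect_error(recoverKinetics(d, stateChannel = "nope"), "no channel")
})

test_that("recovered transition rates converge to the generating matrix", {
  m <- kineticModel()
  d <- simulateDataset(m, nTraces = 20, nPoints = 500, seed = 17)
  rk <- recoverKinetics(d)
  A <- m@A
  nFrom <- rowSums(rk$counts)
  se <- sqrt(A * (1 - A) / nFrom)
  expect_true(all(abs(rk$A - A) <= 3 * se))
})

test_that("occupancy approaches the stationary distribution", {
  m <- kineticModel()
  pi <- stationaryDistribution(m@A)
  expect_equal(pi, c(5 / 7, 2 / 7))  # closed form for the default model
  d <- simulateDataset(m, nTraces = 20, nPoints = 500, seed = 23)
  occ <- recoverKinetics(d)$occupancy
  ## occupancy samples are autocorrelated; the chain's asymptotic
  ## variance inflates the binomial term by (1+l2)/(1-l2), l2 the
  ## second eigenvalue of A
  l2 <- sum(diag(m@A)) - 1
  n <- summarizeDataset(d)$nPointsTotal
  se <- sqrt(pi * (1 - pi) / n * (1 + l2) / (1 - l2))
  expect_true(all(abs(occ - pi) <= 3 * se))
})

test_that("mean dwell time approaches 1 / (1 - A[i,i]) frames", {
  m <- kineticModel()
  d <- simulateDataset(m, nTraces = 20, nPoints = 500, seed = 31)
  dw <- dwellTimes(d, K = 2)
  for (k in 1:2) {
    expected <- 1 / (1 - m@A[k, k])
    runs <- dw[[as.character(k - 1)]]
    ## dwells are geometric: sd = sqrt(1-p)/p per draw
    p <- 1 - m@A[k, k]
    se <- sqrt(1 - p) / p / sqrt(length(runs))
    ## censored first/last dwells bias slightly low; allow 4 se
    expect_lt(abs(mean(runs) - expected), 4 * se + 1)
  }
})
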