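test_that("B1 fitting inverts the preparation-pulse cosine", {
  ref <- makeVol(100, dims = c(4, 4, 4))
  prep <- makeVol(100 * cos(45 * pi / 180), dims = c(4, 4, 4))
  b1 <- fitB1Map(ref, prep)
  expect_equal(volData(b1)[validMask(b1)], rep(1, 64), tolerance = 1e-12)
  prep2 <- makeVol(100 * cos(36 * pi / 180), dims = c(4, 4, 4))
  b1b <- fitB1Map(ref, prep2)
  expect_equal(volData(b1b)[1], 0.8, tolerance = 1e-12)
  refZero <- makeVol(array(c(0, rep(100, 63)), c(4, 4, 4)))
  b1c <- fitB1Map(refZero, prep)
  expect_false(validMask(b1c)[1, 1, 1])
  expect_true(all(validMask(b1c)[-1]))
})

test_that("VFA T1 fitting inverts noiseless forward signals, with and without B1", {
  t1True <- array(seq(700, 2000, length.out = 27), c(3, 3, 3))
  m0 <- 80
  params <- vfaParams()
  for (b1val in c(1, 0.9)) {
    sLow <- makeVol(spgrSignal(m0, t1True, params@flipAngle[1] * b1val,
                               params@tr), dims = c(3, 3, 3))
    sHigh <- makeVol(spgrSignal(m0, t1True, params@flipAngle[2] * b1val,
                                params@tr), dims = c(3, 3, 3))
    b1 <- makeVol(array(b1val, c(3, 3, 3)), kind = "B1")
    fit <- fitT1Vfa(sLow, sHigh, params, b1 = b1)
    expect_equal(volData(fit$t1), t1True, tolerance = 1e-6)
    expect_equal(volData(fit$m0), array(m0, c(3, 3, 3)), tolerance = 1e-6)
  }
  ## degenerate zero signals are invalid
  zero <- makeVol(0, dims = c(3, 3, 3))
  fit0 <- suppressWarnings(fitT1Vfa(zero, zero, params))
  expect_false(any(validMask(fit0$t1)))
  ## missing B1 falls back to 1 with a warning
  expect_warning(fitT1Vfa(makeVol(5, dims = c(3, 3, 3)),
                          makeVol(9, dims = c(3, 3, 3)), params),
                 "B1")
})

test_that("VFA T1 is invariant under joint rescaling of both signals", {
  t1True <- array(1300, c(2, 2, 2))
  p <- vfaParams()
  s1 <- spgrSignal(50, t1True, p@flipAngle[1], p@tr)
  s2 <- spgrSignal(50, t1True, p@flipAngle[2], p@tr)
  f1 <- suppressWarnings(fitT1Vfa(makeVol(s1, dims = c(2, 2, 2)),
                                  makeVol(s2, dims = c(2, 2, 2)), p))
  f2 <- suppressWarnings(fitT1Vfa(makeVol(s1 * 37, dims = c(2, 2, 2)),
                                  makeVol(s2 * 37, dims = c(2, 2, 2)), p))
  expect_equal(volData(f1$t1), volData(f2$t1), tolerance = 1e-12)
})

test_that("multi-echo T2 fitting inverts the mono-exponential decay", {
  tes <- c(13, 67, 93, 106)
  echoes <- lapply(tes, function(te)
    makeVol(100 * exp(-te / 80), dims = c(3, 3, 3)))
  fit <- fitT2MultiEcho(echoes, tes)
  expect_equal(volData(fit$t2)[1], 80, tolerance = 1e-6 * 80)
  expect_equal(volData(fit$s0)[1], 100, tolerance = 1e-4)

  ## two echoes reduce to the closed-form two-point solution
  t2v <- 55; s0v <- 42
  two <- fitT2MultiEcho(list(makeVol(s0v * exp(-13 / t2v),
                                     dims = c(2, 2, 2)),
                             makeVol(s0v * exp(-67 / t2v),
                                     dims = c(2, 2, 2))),
                        c(13, 67))
  closedForm <- (67 - 13) / log(exp(-13 / t2v) / exp(-67 / t2v))
  expect_equal(volData(two$t2)[1], closedForm, tolerance = 1e-12)
  expect_equal(volData(two$t2)[1], t2v, tolerance = 1e-10)

  ## non-positive signal at any echo invalidates the voxel
  bad <- lapply(tes, function(te) {
    d <- array(100 * exp(-te / 80), c(2, 2, 2))
    if (te == 106) d[1, 1, 1] <- 0
    makeVol(d, dims = c(2, 2, 2))
  })
  fitBad <- fitT2MultiEcho(bad, tes)
  expect_false(validMask(fitBad$t2)[1, 1, 1])
  expect_true(all(validMask(fitBad$t2)[-1]))
  expect_error(fitT2MultiEcho(bad[1:3], tes), "TE count mismatch")
})

test_that("two-echo T2* closed form and degenerate cases", {
  s1 <- makeVol(100, dims = c(2, 2, 2))
  s2 <- makeVol(100 / exp((11 - 4.3) / 50), dims = c(2, 2, 2))
  fit <- fitT2StarTwoEcho(s1, s2)
  expect_equal(volData(fit)[1], 50, tolerance = 1e-12)
  expect_false(any(validMask(fitT2StarTwoEcho(s1, s1))))       # S1 = S2
  expect_false(any(validMask(fitT2StarTwoEcho(s2, s1))))       # S2 > S1
})

test_that("receive-profile estimation recovers constants and linear fields", {
  dims <- c(12, 12, 12)
  model <- makeVol(array(runif(prod(dims), 50, 60), dims), dims = dims)
  mask <- array(TRUE, dims)
  ## constant ratio -> field identically 1 after normalization
  rcp1 <- estimateRcp(makeVol(3.7 * volData(model), dims = dims),
                      model, mask)
  expect_equal(volData(rcp1), array(1, dims), tolerance = 1e-9)
  ## linear gradient is inside the polynomial span
  g <- expand.grid(x = seq(-1, 1, length.out = dims[1]),
                   y = seq(-1, 1, length.out = dims[2]),
                   z = seq(-1, 1, length.out = dims[3]))
  field <- array(1 + 0.2 * g$x - 0.1 * g$y + 0.05 * g$z, dims)
  rcp2 <- estimateRcp(makeVol(field * volData(model), dims = dims),
                      model, mask)
  expect_equal(volData(rcp2), field / mean(field), tolerance = 1e-6)
  expect_error(estimateRcp(model, model, array(FALSE, dims)),
               "empty mask")
})

test_that("receive-profile recovery under Rician noise stays within 2% RMS", {
  set.seed(11)
  dims <- c(16, 16, 16)
  g <- expand.grid(x = seq(-1, 1, length.out = dims[1]),
                   y = seq(-1, 1, length.out = dims[2]),
                   z = seq(-1, 1, length.out = dims[3]))
  field <- array(1 + 0.15 * g$x + 0.1 * g$y * g$z, dims)
  modelDat <- array(55, dims)
  signal <- addNoise(field * modelDat, mean(field * modelDat) / 50)
  rcp <- estimateRcp(makeVol(signal, dims = dims),
                     makeVol(modelDat, dims = dims), array(TRUE, dims))
  ref <- field / mean(field)
  expect_lt(sqrt(mean((volData(rcp) - ref)^2)), 0.02)
})

test_that("PD computation inverts the forward chain and is RCP-scale invariant", {
  dims <- c(4, 4, 4)
  pdTrue <- array(seq(60, 100, length.out = prod(dims)), dims)
  t1True <- array(1100, dims); t2sTrue <- array(50, dims)
  b1True <- array(0.95, dims)
  p <- vfaParams()
  rcpTrue <- array(1.2, dims)
  sig <- rcpTrue * spgrSignal(pdTrue, t1True, p@flipAngle[1] * b1True,
                              p@tr) * exp(-p@te / t2sTrue)
  ref <- array(FALSE, dims); ref[pdTrue > 90] <- TRUE
  args <- list(makeVol(sig, dims = dims),
               makeVol(t1True, "T1", dims = dims),
               makeVol(t2sTrue, "T2star", dims = dims),
               makeVol(b1True, "B1", dims = dims))
  pd <- computePd(args[[1]], args[[2]], args[[3]], args[[4]],
                  makeVol(rcpTrue, dims = dims), p, refMask = ref)
  scale <- 100 / mean(pdTrue[ref])
  expect_equal(volData(pd), pdTrue * scale, tolerance = 1e-9)
  ## doubling the RCP leaves PD unchanged (absorbed by normalization? no:
  ## computePd uses the profile as given, so doubling halves PD before the
  ## reference scaling and the scaling restores it)
  pd2 <- computePd(args[[1]], args[[2]], args[[3]], args[[4]],
                   makeVol(2 * rcpTrue, dims = dims), p, refMask = ref)
  expect_equal(volData(pd2), volData(pd), tolerance = 1e-9)
  ## T2* -> infinity removes the decay correction
  sigInf <- rcpTrue * spgrSignal(pdTrue, t1True, p@flipAngle[1] * b1True,
                                 p@tr)
  pdInf <- computePd(makeVol(sigInf, dims = dims), args[[2]],
                     makeVol(array(1e12, dims), "T2star", dims = dims),
                     args[[4]], makeVol(rcpTrue, dims = dims), p,
                     refMask = ref)
  expect_equal(volData(pdInf), pdTrue * scale, tolerance = 1e-6)
})

test_that("Fatouros pseudo-PD evaluates the configured relation and is monotone", {
  t1 <- makeVol(1000, "T1", dims = c(2, 2, 2))
  pd <- fatourosPseudoPd(t1, fatourosConstants(a = 0.3, b = 866))
  expect_equal(volData(pd)[1], 1 / (0.3 + 866 / 1000), tolerance = 1e-12)
  tvals <- array(seq(400, 4000, length.out = 8), c(2, 2, 2))
  pd2 <- volData(fatourosPseudoPd(makeVol(tvals, "T1", dims = c(2, 2, 2))))
  expect_true(all(diff(as.numeric(pd2)) > 0))
  huge <- fatourosPseudoPd(makeVol(1e12, "T1", dims = c(2, 2, 2)))
  expect_equal(volData(huge)[1], 1 / 0.916, tolerance = 1e-6)
})

test_that("MP-RAGE synthesis matches a scalar recursion oracle and its properties", {
  params <- mprageParams(nTrain = 32L, centerIndex = 16L)
  ## independent, deliberately simple scalar recursion
  oracle <- function(t1, pd) {
    esp <- 8.1; a <- 9 * pi / 180
    tStart <- 900 - 15 * esp
    tEnd <- 1900 - tStart - 32 * esp
    rel <- function(mz, dt) 1 + (mz - 1) * exp(-dt / t1)
    mz <- 1
    for (cyc in 1:30) {
      mz <- -mz
      mz <- rel(mz, tStart)
      for (e in 1:32) {
        if (e == 16) centre <- mz
        mz <- mz * cos(a)
        mz <- rel(mz, esp)
      }
      mz <- rel(mz, tEnd)
    }
    pd * centre * sin(a)
  }
  for (t1v in c(700, 900, 1400, 3000))
    expect_equal(mprageSignal(t1v, 80, params), oracle(t1v, 80),
                 tolerance = 1e-12)
  ## WM brighter than GM at equal PD; zero PD gives zero; linear in PD
  expect_gt(mprageSignal(900, 80, params), mprageSignal(1400, 80, params))
  expect_identical(mprageSignal(1200, 0, params), 0)
  expect_equal(mprageSignal(1200, 160, params),
               2 * mprageSignal(1200, 80, params), tolerance = 1e-12)
  ## steady state is independent of the initial magnetization
  expect_equal(mprageSignal(1400, 80, params, m0init = -0.3),
               mprageSignal(1400, 80, params, m0init = 1),
               tolerance = 1e-9)
  ## volume wrapper: signal proportional to PD, invalid where T1 invalid
  t1 <- makeVol(array(c(NA, rep(1000, 7)), c(2, 2, 2)), "T1",
                dims = c(2, 2, 2))
  pd <- makeVol(80, "PD", dims = c(2, 2, 2))
  syn <- synthesizeMprage(t1, pd, params)
  expect_false(validMask(syn)[1, 1, 1])
  expect_true(all(validMask(syn)[-1]))
})

test_that("acquisition parameter validation rejects non-physical values", {
  expect_error(acquisitionParams(tr = -5), "positive")
  expect_error(acquisitionParams(flipAngle = 190), "angles")
  expect_error(fatourosConstants(a = -1), "positive")
})
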