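test_that("depth points interpolate the white->pial vector, including mirrors", {
  ph <- buildSlabPhantom()
  m <- ph@surface
  v <- 10
  expect_equal(depthPoint(m, v, 0)[1, ], whiteVertices(m)[v, ])
  expect_equal(depthPoint(m, v, 1)[1, ], pialVertices(m)[v, ])
  expect_equal(depthPoint(m, v, -0.3)[1, ],
               whiteVertices(m)[v, ] -
                 0.3 * (pialVertices(m)[v, ] - whiteVertices(m)[v, ]))
  expect_error(depthPoint(m, v, 1.2), "fraction")
})

test_that("shell depth points lie at the analytic radius", {
  ph <- buildShellPhantom()
  m <- ph@surface
  for (f in c(-0.5, 0, 0.4, 1)) {
    p <- depthPoint(m, 1:50, f)
    r <- sqrt(rowSums(p^2))
    expect_equal(r, rep(15 + f * 2.5, 50), tolerance = 1e-9)
  }
  expect_equal(thicknessValues(m), rep(2.5, nVertices(m)))
})

test_that("band means are exact for constant and depth-linear volumes", {
  ph <- buildSlabPhantom()
  const <- makeVol(42, dims = dim(ph@labels))
  const@affine <- ph@affine
  b <- sampleBand(const, ph@surface, 0.2, 0.4)
  expect_equal(overlayValues(b)[overlayValid(b)],
               rep(42, sum(overlayValid(b))))
  ## volume linear in z: the band mean equals the value at the band centre
  dims <- dim(ph@labels)
  g <- expand.grid(i = 0:(dims[1] - 1), j = 0:(dims[2] - 1),
                   k = 0:(dims[3] - 1))
  zWorld <- g$k - (dims[3] - 1) / 2
  ramp <- QuantitativeVolume(array(10 * zWorld + 100, dims), ph@affine,
                             "SIGNAL")
  b2 <- sampleBand(ramp, ph@surface, 0.2, 0.4)
  zc <- 0 + 0.3 * 2.5                   # junction z=0, thickness 2.5
  ok <- overlayValid(b2)
  expect_equal(overlayValues(b2)[ok], rep(10 * zc + 100, sum(ok)),
               tolerance = 1e-9)
  ## a band reaching outside the grid invalidates the vertex
  thin <- QuantitativeVolume(array(1, c(dims[1], dims[2], 3)),
                             ph@affine, "SIGNAL")
  b3 <- sampleBand(thin, ph@surface, -0.8, -0.6)
  expect_false(any(overlayValid(b3)))
})

test_that("four positions bracket a sharp junction as (b, b, a, a)", {
  ph <- thickSlab()   # bands clear the pial surface: no CSF partial volume
  fp <- fourPositionValues(ph@truth$t1, ph@surface)
  ok <- fp@valid
  expect_true(any(ok))
  expect_false(any(fp@valid & !cortexLabel(ph@surface)))  # medial wall out
  vals <- fp@values[ok, ]
  expect_equal(unname(vals[, "cortexDeep"]), rep(1400, sum(ok)),
               tolerance = 1e-9)
  expect_equal(unname(vals[, "cortexSuperficial"]), rep(1400, sum(ok)),
               tolerance = 1e-9)
  expect_equal(unname(vals[, "wmShallow"]), rep(900, sum(ok)),
               tolerance = 1e-9)
  expect_equal(unname(vals[, "wmDeep"]), rep(900, sum(ok)),
               tolerance = 1e-9)

  const <- makeVol(7, dims = dim(ph@labels)); const@affine <- ph@affine
  fpc <- fourPositionValues(const, ph@surface)
  expect_equal(unname(fpc@values[fpc@valid, ]),
               matrix(7, sum(fpc@valid), 4))
})

test_that("vertex SD follows the population convention and a two-pass oracle", {
  mk <- function(m) new("FourPositionSample",
                        values = m, valid = rep(TRUE, nrow(m)),
                        parameter = "T1")
  expect_equal(overlayValues(vertexSd(mk(matrix(5, 3, 4)))), rep(0, 3))
  expect_equal(overlayValues(vertexSd(mk(matrix(c(1, 1, 3, 3), 1)))), 1)
  set.seed(99)
  m <- matrix(runif(4000, 0, 10), ncol = 4)
  sd1 <- overlayValues(vertexSd(mk(m)))
  oracle <- apply(m, 1, twoPassSd)
  expect_lt(max(abs(sd1 - oracle)), 1e-12)
})

test_that("vertex SD is shift invariant and scales linearly", {
  set.seed(3)
  m <- matrix(rnorm(400), ncol = 4)
  mk <- function(m) new("FourPositionSample",
                        values = m, valid = rep(TRUE, nrow(m)),
                        parameter = "T1")
  base <- overlayValues(vertexSd(mk(m)))
  expect_equal(overlayValues(vertexSd(mk(m + 17))), base,
               tolerance = 1e-12)
  expect_equal(overlayValues(vertexSd(mk(m * 3))), 3 * base,
               tolerance = 1e-12)
})

test_that("junction SD matches |a-b|/2 on the sharp phantom and falls with blur", {
  ph <- thickSlab()
  sd0 <- vertexSd(fourPositionValues(ph@truth$t1, ph@surface))
  core <- overlayValid(sd0)
  expect_equal(overlayValues(sd0)[core], rep(250, sum(core)),
               tolerance = 1e-9)

  ## monotone decrease of the lesion-centre SD with the blur width
  lesionVerts <- function(ph) {
    w <- whiteVertices(ph@surface)
    which(sqrt((w[, 1] - 8)^2 + w[, 2]^2) < 3 & cortexLabel(ph@surface))
  }
  med <- sapply(c(0, 1, 2, 3), function(wmm) {
    ph2 <- insertLesion(buildSlabPhantom(),
                        lesionSpec(blurWidth = wmm, thickeningDelta = 0,
                                   subcorticalT2Delta = 0))
    sdw <- vertexSd(fourPositionValues(ph2@truth$t1, ph2@surface))
    median(overlayValues(sdw)[lesionVerts(ph2)])
  })
  expect_true(all(diff(med) < 0))
})
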