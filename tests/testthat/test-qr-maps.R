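mkOverlay <- function(values, valid = NULL)
  VertexOverlay(values, valid %||% is.finite(values))
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("Q combines the SD product with thickness and the offset", {
  q <- computeQ(mkOverlay(50), mkOverlay(10), mkOverlay(2),
                mkOverlay(2.5))
  expect_equal(overlayValues(q), 400 + 1e-4, tolerance = 1e-12)
  qz <- computeQ(mkOverlay(0), mkOverlay(10), mkOverlay(2), mkOverlay(2.5))
  expect_equal(overlayValues(qz), 1e-4, tolerance = 1e-15)
  ## doubling the thickness halves (Q - offset)
  qd <- computeQ(mkOverlay(50), mkOverlay(10), mkOverlay(2), mkOverlay(5))
  expect_equal(overlayValues(qd) - 1e-4,
               (overlayValues(q) - 1e-4) / 2, tolerance = 1e-12)
  ## invalid inputs propagate; zero thickness at a valid vertex is an error
  qi <- computeQ(mkOverlay(c(50, 50), c(TRUE, FALSE)),
                 mkOverlay(c(10, 10)), mkOverlay(c(2, 2)),
                 mkOverlay(c(2.5, 2.5)))
  expect_identical(overlayValid(qi), c(TRUE, FALSE))
  expect_error(computeQ(mkOverlay(50), mkOverlay(10), mkOverlay(2),
                        mkOverlay(0)), "zero thickness")
})

test_that("quotient filtering maps Q through Q0/Q with the cap rule", {
  dat <- array(0, c(3, 3, 3))
  dat[1:4] <- c(500, 250, 1e-4, 2000)
  qvol <- makeVol(dat, "Q", dims = c(3, 3, 3))
  out <- quotientFilter(qvol)
  expect_equal(volData(out)[1:4], c(1, 2, 0, 0.25))  # 5e6 capped to 0
  expect_equal(volData(out)[5], 0)                   # non-ribbon stays 0
})

test_that("the R map is the unit-offset smoothed quotient, monotone in its input", {
  zero <- makeVol(0, dims = c(9, 9, 9))
  expect_equal(volData(makeRMap(zero)), array(1, c(9, 9, 9)))
  dat <- array(0, c(25, 25, 25)); dat[13, 13, 13] <- 4
  r <- makeRMap(makeVol(dat, dims = c(25, 25, 25)))
  k <- exp(-((-12):12)^2 / 18); k <- k / sum(k)
  expect_equal(r@data[13, 13, 13], 1 + 4 * k[13]^3, tolerance = 1e-12)
  expect_true(all(volData(r) >= 1))
  dat2 <- dat; dat2[13, 13, 13] <- 5; dat2[5, 5, 5] <- 1
  r2 <- makeRMap(makeVol(dat2, dims = c(25, 25, 25)))
  expect_true(all(volData(r2) >= volData(r) - 1e-12))
})

test_that("projection fills the cortical ribbon with nearest-vertex values", {
  ph <- buildSlabPhantom()
  ref <- ph@truth$t1
  n <- nVertices(ph@surface)
  const <- VertexOverlay(rep(3, n), cortexLabel(ph@surface))
  proj <- projectOverlayToVolume(const, ph@surface, ref)
  vals <- volData(proj)
  expect_setequal(unique(as.numeric(vals)), c(0, 3))
  ## ribbon voxels under the mesh interior carry the value
  dims <- dim(vals)
  g <- expand.grid(i = 0:(dims[1] - 1), j = 0:(dims[2] - 1),
                   k = 0:(dims[3] - 1))
  w <- cbind(g$i, g$j, g$k) + rep(-(dims - 1) / 2, each = nrow(g))
  inner <- abs(w[, 1]) < 10 & abs(w[, 2]) < 10 & w[, 3] > 0.6 &
    w[, 3] < 1.9
  expect_true(all(vals[inner == TRUE] == 3))
  outside <- w[, 3] < -1.5 | w[, 3] > 4.5
  expect_true(all(vals[outside] == 0))

  ## a single valid vertex produces one local cluster
  single <- VertexOverlay(rep(1, n), seq_len(n) == 150)
  proj1 <- projectOverlayToVolume(single, ph@surface, ref)
  hit <- which(volData(proj1) == 1, arr.ind = TRUE)
  expect_gt(nrow(hit), 0)
  ctr <- fcdenhance:::.voxelToWorld(ph@affine, hit - 1)
  target <- whiteVertices(ph@surface)[150, ]
  expect_true(all(sqrt((ctr[, 1] - target[1])^2 +
                         (ctr[, 2] - target[2])^2) < 3))
})

test_that("projected phantom Q read back at the lesion centroid matches the vertex value", {
  ph <- noiselessLesionSlab()
  maps <- list(t1 = ph@truth$t1, t2 = ph@truth$t2, pd = ph@truth$pd)
  sds <- sdOverlays(maps, ph@surface)
  q <- computeQ(sds$t1, sds$t2, sds$pd, thicknessValues(ph@surface))
  qvol <- projectOverlayToVolume(q, ph@surface, ph@truth$t1)
  w <- whiteVertices(ph@surface)
  vLesion <- which.min((w[, 1] - 8)^2 + w[, 2]^2)
  mid <- depthPoint(ph@surface, vLesion, 0.5)[1, ]
  roiVal <- roiMean(QuantitativeVolume(volData(qvol), ph@affine, "Q"),
                    RoiSpec(mid, c(1.2, 1.2, 1)))
  expect_lt(abs(roiVal - overlayValues(q)[vLesion]) /
              overlayValues(q)[vLesion], 0.05)
})

test_that("the R pair is identical for identical inputs and a noiseless thick slab", {
  ph <- thickSlab()
  maps <- list(t1 = ph@truth$t1, t2 = ph@truth$t2, pd = ph@truth$pd)
  pair <- computeRPair(maps, maps, ph@surface)
  expect_identical(volData(pair$rU), volData(pair$rS))

  ## compartmental smoothing is the identity on the piecewise-constant
  ## phantom, so R_s equals R_u through the full chain
  smoothed <- list(
    t1 = smoothCompartments(maps$t1, ph@wmMask),
    t2 = smoothCompartments(maps$t2, ph@wmMask),
    pd = smoothCompartments(maps$pd, ph@wmMask, t1 = maps$t1))
  pair2 <- computeRPair(maps, smoothed, ph@surface)
  expect_equal(volData(pair2$rS), volData(pair2$rU), tolerance = 1e-9)
})

test_that("a lesion phantom yields mean R above 1 over its ribbon", {
  ph <- noiselessLesionSlab()
  maps <- list(t1 = ph@truth$t1, t2 = ph@truth$t2, pd = ph@truth$pd)
  smoothed <- list(
    t1 = smoothCompartments(maps$t1, ph@wmMask),
    t2 = smoothCompartments(maps$t2, ph@wmMask),
    pd = smoothCompartments(maps$pd, ph@wmMask, t1 = maps$t1))
  pair <- computeRPair(maps, smoothed, ph@surface)
  sel <- which(ph@labels == 2L)
  dims <- dim(ph@labels)
  g <- arrayInd(sel, dims)
  w <- fcdenhance:::.voxelToWorld(ph@affine, g - 1)
  near <- sqrt((w[, 1] - 8)^2 + w[, 2]^2) < 4
  rMean <- mean(0.5 * (volData(pair$rU)[sel[near]] +
                         volData(pair$rS)[sel[near]]))
  expect_gt(rMean, 1.05)
})
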