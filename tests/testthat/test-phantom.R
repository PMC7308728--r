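test_that("slab phantom geometry, labels and surfaces are mutually consistent", {
  ph <- buildSlabPhantom(cortexThicknessMm = 3)
  expect_equal(thicknessValues(ph@surface),
               rep(3, nVertices(ph@surface)))
  ## GM-labelled voxel centres lie between the white and pial planes
  sel <- which(ph@labels == 2L)
  z <- fcdenhance:::.voxelToWorld(ph@affine,
                                  arrayInd(sel, dim(ph@labels)) - 1)[, 3]
  expect_true(mean(z >= 0 & z <= 3) >= 0.99)
  ## tissue values match the label map
  expect_equal(unique(volData(ph@truth$t1)[ph@labels == 1L]), 900)
  expect_equal(unique(volData(ph@truth$t1)[ph@labels == 2L]), 1400)
  expect_equal(unique(volData(ph@truth$t2)[ph@labels == 3L]), 2000)
  expect_error(buildSlabPhantom(cortexThicknessMm = 0.5),
               "thinner than one voxel")
})

test_that("shell phantom radii, mirror symmetry and validation", {
  ph <- buildShellPhantom()
  expect_equal(thicknessValues(ph@surface),
               rep(2.5, nVertices(ph@surface)))
  ## contralateral mirror of a lesion ROI lands in homologous tissue
  ph2 <- insertLesion(ph, lesionSpec(center = c(10, 6, 8), radius = 5))
  roi <- ph2@roi
  mir <- mirrorRoi(roi)
  expect_equal(sqrt(sum(mir@center^2)), sqrt(sum(roi@center^2)),
               tolerance = 1e-9)
  lab <- function(p) {
    v <- fcdenhance:::.worldToVoxel(ph2@affine, matrix(p, 1))
    ph2@labels[round(v[1]) + 1, round(v[2]) + 1, round(v[3]) + 1]
  }
  expect_equal(lab(mir@center), lab(c(-10, 6, 8) /
                                      sqrt(200) * sqrt(225)))
  expect_error(buildShellPhantom(radii = c(white = 18, pial = 16)),
               "radii inverted")
  expect_error(buildShellPhantom(radii = c(white = 20, pial = 40)),
               "fit in the grid")
})

test_that("the identity lesion leaves the phantom unchanged", {
  ph <- buildSlabPhantom()
  ph0 <- insertLesion(ph, lesionSpec(blurWidth = 0, thickeningDelta = 0,
                                     subcorticalT2Delta = 0))
  for (nm in names(ph@truth))
    expect_equal(volData(ph0@truth[[nm]]), volData(ph@truth[[nm]]))
  expect_identical(ph0@labels, ph@labels)
  expect_equal(pialVertices(ph0@surface), pialVertices(ph@surface))
  expect_s4_class(ph0@roi, "RoiSpec")
})

test_that("lesion effects: blur flattens the junction, thickening raises thickness, T2 rises subcortically", {
  ph <- buildSlabPhantom()
  sdAt <- function(ph) {
    sd <- vertexSd(fourPositionValues(ph@truth$t1, ph@surface))
    w <- whiteVertices(ph@surface)
    v <- which.min((w[, 1] - 8)^2 + w[, 2]^2)
    overlayValues(sd)[v]
  }
  base <- sdAt(insertLesion(ph, lesionSpec(blurWidth = 0,
                                           thickeningDelta = 0,
                                           subcorticalT2Delta = 0)))
  blurred <- sdAt(insertLesion(ph, lesionSpec(blurWidth = 3,
                                              thickeningDelta = 0,
                                              subcorticalT2Delta = 0)))
  expect_lt(blurred, base)

  thick <- insertLesion(ph, lesionSpec(thickeningDelta = 2))
  w <- whiteVertices(thick@surface)
  v <- which.min((w[, 1] - 8)^2 + w[, 2]^2)
  expect_equal(thicknessValues(thick@surface)[v], 4.5, tolerance = 0.1)
  rim <- which(sqrt((w[, 1] - 8)^2 + w[, 2]^2) > 8)
  expect_equal(thicknessValues(thick@surface)[rim],
               rep(2.5, length(rim)))
  expect_error(insertLesion(ph, lesionSpec(center = c(30, 0, 0))),
               "outside the cortical mesh")

  t2l <- insertLesion(ph, lesionSpec())
  sel <- ph@wmMask & t2l@wmMask
  expect_gt(max(volData(t2l@truth$t2)[sel] -
                  volData(ph@truth$t2)[sel]), 20)
})

test_that("simulated acquisitions are deterministic given the seed", {
  ph <- buildSlabPhantom()
  a <- simulateAcquisitions(ph, snr = 50, seed = 7)
  b <- simulateAcquisitions(ph, snr = 50, seed = 7)
  expect_identical(volData(a@acquisitions$spgrLow),
                   volData(b@acquisitions$spgrLow))
  expect_identical(volData(a@acquisitions$flair),
                   volData(b@acquisitions$flair))
  c <- simulateAcquisitions(ph, snr = 50, seed = 8)
  expect_false(identical(volData(a@acquisitions$spgrLow),
                         volData(c@acquisitions$spgrLow)))
})

test_that("noiseless acquisitions invert to the ground truth through the fit chain", {
  ph <- noiselessSlab()
  maps <- fitQmriMaps(ph@acquisitions, csfMask = ph@labels == 3L,
                      rcp = ph@fields$rcp, b1SmoothFwhmMm = 0)
  for (nm in c("t1", "t2", "t2star", "pd")) {
    ok <- validMask(maps[[nm]]) & validMask(ph@truth[[nm]])
    expect_true(all(ok))
    relErr <- abs(volData(maps[[nm]])[ok] -
                    volData(ph@truth[[nm]])[ok]) /
      volData(ph@truth[[nm]])[ok]
    expect_lt(max(relErr), 1e-6)
  }
  ok <- validMask(maps$b1)
  expect_lt(max(abs(volData(maps$b1)[ok] -
                      volData(ph@fields$b1)[ok])), 1e-9)
})

test_that("the FLAIR forward model suppresses CSF and brightens high subcortical T2", {
  p <- flairParams()
  csf <- flairSignal(100, 4000, 2000, p)
  wm <- flairSignal(69, 900, 70, p)
  wmLesion <- flairSignal(69, 900, 100, p)
  expect_lt(csf, 3 * wm)            # strong suppression of free water
  expect_gt(wmLesion, 2 * wm)       # subcortical T2 rise is hyperintense
})
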