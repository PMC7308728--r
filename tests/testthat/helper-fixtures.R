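## Shared fixture builders.  Everything is generated in code at test time;
## expensive objects are memoised per test file via a local cache.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixtureCache[[key]])) .fixtureCache[[key]] <- force(expr)
  .fixtureCache[[key]]
}

## a small volume with a centred affine and the given constant or array
makeVol <- function(data, kind = "SIGNAL", voxelMm = c(1, 1, 1),
                    dims = c(8, 8, 8)) {
  if (length(data) == 1) data <- array(data, dims)
  aff <- diag(4)
  aff[1:3, 1:3] <- diag(voxelMm, 3)
  aff[1:3, 4] <- -(dim(data) - 1) / 2 * voxelMm
  QuantitativeVolume(data, aff, kind)
}

## deterministic array filled from voxel indices (distinct values)
indexVol <- function(dims = c(8, 8, 8), kind = "SIGNAL") {
  g <- expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                   k = seq_len(dims[3]))
  makeVol(array(g$i + 100 * g$j + 10000 * g$k, dims), kind)
}

## noiseless slab phantom with simulated acquisitions (memoised)
noiselessSlab <- function() cached("noiselessSlab", {
  ph <- buildSlabPhantom()
  simulateAcquisitions(ph, snr = Inf, seed = 1)
})

## thick-cortex slab (6 mm): all four depth bands clear the pial surface
## by more than a voxel, so band samples are free of CSF partial volume
thickSlab <- function() cached("thickSlab", {
  buildSlabPhantom(gridShape = c(44, 44, 48), cortexThicknessMm = 6)
})

## noiseless slab phantom with a default lesion (memoised)
noiselessLesionSlab <- function() cached("noiselessLesionSlab", {
  ph <- insertLesion(buildSlabPhantom(), lesionSpec())
  simulateAcquisitions(ph, snr = Inf, seed = 1)
})

## independently coded two-pass standard deviation (population) oracle
twoPassSd <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / length(x))
}

## brute-force exact Wilcoxon signed-rank by enumeration of all 2^n sign
## assignments (the independent oracle for the convolution implementation)
enumWilcoxon <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  r <- rank(abs(d))
  wObs <- sum(r[d > 0])
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w <- as.numeric(signs %*% r)
  pLow <- mean(w <= wObs)
  pHigh <- mean(w >= wObs)
  min(1, 2 * min(pLow, pHigh))
}
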