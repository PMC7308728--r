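test_that("FLAIR enhancement is the voxel-wise product with the averaged R", {
  flair <- indexVol(c(6, 6, 6))
  one <- makeVol(1, "R", dims = c(6, 6, 6))
  expect_equal(volData(enhanceFlair(flair, one, one)), volData(flair))
  r3 <- makeVol(3, "R", dims = c(6, 6, 6))
  expect_equal(volData(enhanceFlair(flair, one, r3)),
               2 * volData(flair))
  zero <- makeVol(0, dims = c(6, 6, 6))
  expect_equal(volData(enhanceFlair(zero, r3, r3)),
               array(0, c(6, 6, 6)))
})

test_that("ROI means cover exactly the analytic voxel set", {
  vol <- indexVol(c(8, 8, 8))          # value = i + 100 j + 10000 k
  expect_equal(roiMean(vol, RoiSpec(c(0, 0, 0), c(8, 8, 8))),
               mean(volData(vol)))
  ## centres at half-integers: a 2 x 2 x 1 box at the origin covers
  ## i,j in {4,5} (world -0.5, +0.5) and k = 4 (world -0.5)
  expected <- mean(outer(c(4, 5), 100 * c(4, 5), "+")) + 10000 * 4
  expect_equal(roiMean(vol, RoiSpec(c(0, 0, 0))), expected)
  expect_error(roiMean(vol, RoiSpec(c(3.6, 0, 0))), "outside the image grid")
  const <- makeVol(6.5, dims = c(8, 8, 8))
  expect_equal(roiMean(const, RoiSpec(c(1, -1, 0))), 6.5)
})

test_that("ROI mirroring reflects x, flips the side and is an involution", {
  roi <- RoiSpec(c(12, 5, 5), side = "right")
  m <- mirrorRoi(roi)
  expect_equal(m@center, c(-12, 5, 5))
  expect_identical(m@side, "left")
  expect_equal(mirrorRoi(m)@center, roi@center)
  expect_identical(mirrorRoi(m)@side, "right")
  onPlane <- mirrorRoi(RoiSpec(c(0, 1, 2)))
  expect_equal(onPlane@center, c(0, 1, 2))
  shifted <- mirrorRoi(roi, midsagittalX = 2)
  expect_equal(shifted@center[1], -8)
})

test_that("exact Wilcoxon matches brute-force enumeration for n <= 12", {
  set.seed(2024)
  for (rep in 1:20) {
    n <- sample(5:12, 1)
    a <- rnorm(n)
    b <- rnorm(n)
    if (rep %% 3 == 0) b[1:2] <- a[1:2] + c(1, -1)  # force tied |d|
    res <- wilcoxonSignedRank(a, b)
    expect_equal(res$pExact, enumWilcoxon(a, b), tolerance = 1e-12)
  }
})

test_that("all-positive differences at n = 10 give the exact two-sided 2/1024", {
  a <- 1:10 + 0.5
  b <- 1:10 - seq(0.1, 1, length.out = 10)
  res <- wilcoxonSignedRank(a, b)
  expect_equal(res$pExact, 2 / 1024, tolerance = 1e-15)
  ## two-sided symmetry under swapping the samples
  expect_equal(wilcoxonSignedRank(b, a)$pExact, res$pExact)
  ## agreement with the reference implementation when it can be exact
  set.seed(1)
  x <- rnorm(10); y <- rnorm(10)
  expect_equal(wilcoxonSignedRank(x, y)$pExact,
               stats::wilcox.test(x, y, paired = TRUE,
                                  exact = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("degenerate Wilcoxon inputs are rejected", {
  expect_error(wilcoxonSignedRank(1:4, 2:5), "too few")
  expect_error(wilcoxonSignedRank(1:10, 1:10), "zero")
  x <- c(1, 2, 3, 4, 5, 6)
  y <- x; y[1] <- 0
  expect_error(wilcoxonSignedRank(x, y), "too few non-zero")
  expect_error(wilcoxonSignedRank(1:6, 1:5), "equal length")
})

## FLAIR with a mild left-right gradient so contralateral ROIs differ
mkSub <- function(rfac, flairVal, dims = c(12, 12, 12)) {
  g <- expand.grid(i = 0:(dims[1] - 1), j = 0:(dims[2] - 1),
                   k = 0:(dims[3] - 1))
  x <- g$i - (dims[1] - 1) / 2
  flair <- makeVol(array(flairVal * (1 + 0.03 * x), dims), dims = dims)
  r <- makeVol(rfac, "R", dims = dims)
  list(conventional = flair, enhanced = enhanceFlair(flair, r, r),
       roi = RoiSpec(c(2, 0, 0)))
}

test_that("the cohort report computes increases, SEMs and homogeneity", {
  ## neutral enhancement: zero relative increase, degenerate first test
  subs <- lapply(rep(40, 6), function(f) mkSub(1, f))
  rep0 <- buildReport(subs)
  expect_equal(rep0@perSubject$relativeIncreasePercent, rep(0, 6))
  expect_true(is.na(rep0@group$wilcoxonEnhVsConv$pExact))
  expect_equal(rep0@group$nIncreased, 0)
  ## SEM against the two-pass oracle (sample SD / sqrt(n))
  rfacs <- c(1.1, 1.2, 1.3, 1.15, 1.25, 1.4)
  subs2 <- lapply(rfacs, function(r) mkSub(r, 50))
  rep2 <- buildReport(subs2)
  inc <- rep2@perSubject$relativeIncreasePercent
  expect_equal(inc, 100 * (rfacs - 1), tolerance = 1e-9)
  expect_equal(rep2@group$semRelativeIncrease,
               sqrt(sum((inc - mean(inc))^2) / 5) / sqrt(6),
               tolerance = 1e-12)
  expect_equal(rep2@group$meanRelativeIncrease, mean(inc))
  ## scaling the FLAIR leaves relative increases unchanged
  subs3 <- lapply(rfacs, function(r) mkSub(r, 50 * 7))
  rep3 <- buildReport(subs3)
  expect_equal(rep3@perSubject$relativeIncreasePercent, inc,
               tolerance = 1e-9)
  expect_equal(rep3@perSubject$roiMeanEnhanced,
               7 * rep2@perSubject$roiMeanEnhanced, tolerance = 1e-9)
  expect_error(buildReport(subs2[1:3]), "at least 5")
})

test_that("reports serialize to TSV and JSON", {
  subs <- lapply(c(1.1, 1.3, 1.2, 1.4, 1.05, 1.2), function(r)
    mkSub(r, 50))
  rep <- buildReport(subs)
  tsv <- tempfile(fileext = ".tsv"); js <- tempfile(fileext = ".json")
  writeReport(rep, tsv, js)
  tab <- read.table(tsv, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), 6)
  parsed <- jsonlite::read_json(js)
  expect_equal(parsed$meanRelativeIncrease,
               rep@group$meanRelativeIncrease, tolerance = 1e-9)
})
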