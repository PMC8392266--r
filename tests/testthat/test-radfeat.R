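# Feature registry, discretization and the five feature families, each
# validated against its brute-force oracle.

test_that("the registry enumerates exactly 1763 uniquely named features", {
  reg <- featureRegistry()
  expect_equal(nrow(reg), 1763L)
  expect_false(anyDuplicated(reg$name) > 0)
  counts <- table(reg$contrast)
  expect_equal(unname(counts[c("T1w", "T1c", "T2w")]), rep(585L, 3),
               ignore_attr = TRUE)
  expect_equal(unname(counts["mask"]), 8L, ignore_attr = TRUE)
  # 9 image sets x 65 features per contrast, 16 histogram + 49 texture
  perSet <- table(reg$filter[reg$contrast == "T1w"])
  expect_equal(unname(perSet), rep(65L, 9), ignore_attr = TRUE)
  fam <- table(reg$family[reg$contrast == "T1w" & reg$filter == "LLH"])
  expect_equal(fam[["histogram"]], 16L)
  expect_equal(fam[["glcm"]] + fam[["glrlm"]] + fam[["lbp"]], 49L)
})

test_that("discretization follows equal-width right-closed binning", {
  v <- array(c(0, 0.5, 1, 99), c(4, 1, 1))
  m <- array(c(TRUE, TRUE, TRUE, FALSE), c(4, 1, 1))
  roi <- discretizeROI(v, m, 2)
  expect_equal(as.vector(roi@levels[1:3]), c(1L, 2L, 2L))
  # constant ROI and nLevels = 1 collapse to level 1
  expect_true(all(discretizeROI(array(5, c(2, 2, 1)),
                                array(TRUE, c(2, 2, 1)), 8)@levels == 1L))
  expect_true(all(discretizeROI(v, m, 1)@levels[1:3] == 1L))
  expect_error(discretizeROI(v, array(FALSE, c(4, 1, 1))), "empty mask")
})

test_that("histogram features match direct arithmetic", {
  m <- array(TRUE, c(2, 2, 1))
  f <- histogramFeatures(array(1:4, c(2, 2, 1)), m, nLevels = 4)
  expect_equal(f[["minimum"]], 1)
  expect_equal(f[["maximum"]], 4)
  expect_equal(f[["mean"]], 2.5)
  expect_equal(f[["range"]], 3)
  expect_equal(f[["energy"]], sum((1:4)^2))
  expect_equal(f[["entropy"]], log2(4))   # uniform over 4 occupied bins
  expect_equal(f[["uniformity"]], 4 * 0.25^2)
  expect_equal(f[["variance"]], mean((1:4 - 2.5)^2))
  expect_equal(f[["mad"]], 1)
  # constant ROI: degenerate conventions
  fc <- histogramFeatures(array(2, c(2, 2, 2)), array(TRUE, c(2, 2, 2)))
  expect_equal(fc[["variance"]], 0)
  expect_equal(fc[["skewness"]], 0)
  expect_equal(fc[["kurtosis"]], 0)
})

test_that("constant ROIs give the degenerate single-level GLCM conventions", {
  roi <- discretizeROI(array(1, c(3, 3, 3)), array(TRUE, c(3, 3, 3)))
  f <- glcmFeatures(roi)
  expect_equal(f[["contrast"]], 0)
  expect_equal(f[["homogeneity1"]], 1)
  expect_equal(f[["imc1"]], 0)
  expect_equal(f[["energy"]], 1)
  expect_equal(f[["correlation"]], 0)
})

test_that("a 2x2x1 two-level ROI matches the pair-enumeration oracle", {
  lev <- array(c(1L, 1L, 2L, 2L), c(2, 2, 1))   # column-major: [[1,2],[1,2]]
  roi <- new("DiscretizedROI", levels = lev, nLevels = 2L)
  f <- glcmFeatures(roi)
  o <- oracleGLCMAveraged(lev, 2L, oracleDirections)
  expect_equal(f, o[names(f)], tolerance = 1e-9)
})

test_that("checkerboard alternation gives correlation -1 in face directions", {
  co <- as.matrix(expand.grid(1:4, 1:4, 1:4))
  lev <- array(1L + (rowSums(co) %% 2L), c(4, 4, 4))
  P <- oracleGLCMMatrix(lev, c(1, 0, 0), 2L)
  o <- oracleGLCMFeatures(P)
  expect_equal(o[["correlation"]], -1)
  # and the direction-averaged implementation agrees with the oracle
  roi <- new("DiscretizedROI", levels = lev, nLevels = 2L)
  f <- glcmFeatures(roi)
  oAvg <- oracleGLCMAveraged(lev, 2L, oracleDirections)
  expect_equal(f, oAvg[names(f)], tolerance = 1e-9)
})

test_that("GLCM features match the oracle on random masked fixtures", {
  set.seed(17)
  for (rep in 1:4) {
    dims <- sample(3:6, 3, replace = TRUE)
    ng <- sample(2:5, 1)
    lev <- randomROIFixture(dims, ng)
    roi <- new("DiscretizedROI", levels = lev, nLevels = as.integer(ng))
    f <- glcmFeatures(roi)
    o <- oracleGLCMAveraged(lev, ng, oracleDirections)
    expect_equal(f, o[names(f)], tolerance = 1e-9)
  }
})

test_that("single runs give the textbook run-length values", {
  # 1x1x4 line of one level: single run of length 4 in the axial direction
  lev <- array(1L, c(1, 1, 4))
  runs <- oracleRuns(lev, c(0, 0, 1))
  f <- oracleGLRLMFeatures(runs$levels, runs$lengths, 4)
  expect_equal(f[["sre"]], 1 / 16)
  expect_equal(f[["lre"]], 16)
  expect_equal(f[["rp"]], 1 / 4)
  # alternating levels: all runs length 1
  lev2 <- array(rep(c(1L, 2L), 3), c(1, 1, 6))
  runs2 <- oracleRuns(lev2, c(0, 0, 1))
  expect_true(all(runs2$lengths == 1))
  f2 <- oracleGLRLMFeatures(runs2$levels, runs2$lengths, 6)
  expect_equal(f2[["sre"]], 1)
  expect_equal(f2[["rp"]], 1)
})

test_that("GLRLM features match the line-walking oracle on random fixtures", {
  set.seed(23)
  for (rep in 1:4) {
    dims <- sample(3:6, 3, replace = TRUE)
    ng <- sample(2:4, 1)
    lev <- randomROIFixture(dims, ng)
    roi <- new("DiscretizedROI", levels = lev, nLevels = as.integer(ng))
    f <- glrlmFeatures(roi)
    nVox <- sum(!is.na(lev))
    acc <- NULL; nd <- 0
    for (r in seq_len(nrow(oracleDirections))) {
      runs <- oracleRuns(lev, oracleDirections[r, ])
      if (length(runs$levels) == 0) next
      ff <- oracleGLRLMFeatures(runs$levels, runs$lengths, nVox)
      acc <- if (is.null(acc)) ff else acc + ff
      nd <- nd + 1
    }
    expect_equal(f, (acc / nd)[names(f)], tolerance = 1e-9)
  }
})

test_that("LBP codes and histograms match bitstring enumeration", {
  # constant slice: all neighbours >= centre, 8 ones, uniform -> bin 8
  v <- array(1, c(5, 5, 1))
  f <- lbpFeatures(v, array(TRUE, c(5, 5, 1)))
  expect_equal(f[["riu2_8"]], 1)
  expect_equal(sum(f), 1)
  # centre 0 with neighbours 1: code 8 as well (all >=)
  v2 <- array(1, c(3, 3, 1)); v2[2, 2, 1] <- 0
  expect_equal(oracleLBPCode(v2[, , 1], 2, 2), 8L)
  # random slices: histogram equals pooled oracle codes
  set.seed(41)
  v3 <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
  m3 <- array(runif(6 * 6 * 2) < 0.7, c(6, 6, 2))
  m3[2, 2, 1] <- TRUE  # ensure nonempty interior
  f3 <- lbpFeatures(v3, m3)
  codes <- integer(0)
  for (z in 1:2) for (r in 2:5) for (cc in 2:5)
    if (m3[r, cc, z]) codes <- c(codes, oracleLBPCode(v3[, , z], r, cc))
  expect_equal(as.vector(f3), tabulate(codes + 1L, 10) / length(codes),
               tolerance = 1e-12)
  expect_equal(sum(f3), 1)
})

test_that("geometry features match face counting and pairwise distances", {
  f1 <- geometryFeatures(array(TRUE, c(1, 1, 1)), c(1, 1, 1))
  expect_equal(f1[["volume_mm3"]], 1)
  expect_equal(f1[["surface_area_mm2"]], 6)
  expect_equal(f1[["max_diameter_3d_mm"]], 0)
  m <- array(FALSE, c(4, 4, 4)); m[2:3, 2:3, 2:3] <- TRUE
  f2 <- geometryFeatures(m, c(1, 1, 1))
  expect_equal(f2[["volume_mm3"]], 8)
  expect_equal(f2[["surface_area_mm2"]], 24)
  expect_equal(f2[["max_diameter_3d_mm"]], sqrt(3))
  expect_equal(f2[["surface_to_volume_ratio"]], 3)
  expect_equal(f2[["compactness2"]], 36 * pi * 64 / 24^3)
  # anisotropic spacing: faces weighted by their physical area
  f3 <- geometryFeatures(array(TRUE, c(1, 1, 1)), c(1, 2, 3))
  expect_equal(f3[["volume_mm3"]], 6)
  expect_equal(f3[["surface_area_mm2"]], 2 * (2 * 3 + 1 * 3 + 1 * 2))
})

test_that("shape descriptors behave as face counting predicts", {
  # under exposed-face surface areas a cube is exact: sphericity has the
  # closed form (36*pi)^(1/3)/6 and compactness2 = pi/6
  side <- 6
  cube <- array(FALSE, c(8, 8, 8)); cube[1:side, 1:side, 1:side] <- TRUE
  fc <- geometryFeatures(cube, c(1, 1, 1))
  expect_equal(fc[["sphericity"]], (36 * pi)^(1 / 3) / 6, tolerance = 1e-12)
  expect_equal(fc[["compactness2"]], pi / 6, tolerance = 1e-12)
  # a digital ball's staircase surface is overestimated by a factor that
  # approaches 3/2, pushing its face-counted sphericity below the cube's
  dims <- c(15, 15, 15)
  co <- as.matrix(expand.grid(1:15, 1:15, 1:15))
  ball <- array(rowSums(sweep(co, 2, c(8, 8, 8))^2) <= 36, dims)
  fb <- geometryFeatures(ball, c(1, 1, 1))
  rEff <- (3 * fb[["volume_mm3"]] / (4 * pi))^(1 / 3)
  ratio <- fb[["surface_area_mm2"]] / (4 * pi * rEff^2)
  expect_gt(ratio, 1.3); expect_lt(ratio, 1.7)
  expect_lt(fb[["sphericity"]], fc[["sphericity"]])
  # and the elongation ordering is scale-free: a 2:1 box is less spherical
  box <- array(FALSE, c(14, 8, 8)); box[1:12, 1:side, 1:side] <- TRUE
  expect_lt(geometryFeatures(box, c(1, 1, 1))[["sphericity"]],
            fc[["sphericity"]])
})

test_that("the full extractor returns 1763 finite features in registry order", {
  cohort <- fixtureTextureCohort()
  lid <- cohort@clinical$lesion_id[1]
  p <- cohort@clinical$patient_id[1]
  vols <- lapply(cohort@volumes[[p]], zscoreNormalize)
  fv <- extractAllFeatures(vols$T1w, vols$T1c, vols$T2w, cohort@masks[[lid]])
  expect_length(fv, 1763L)
  expect_true(all(is.finite(fv)))
  expect_identical(names(fv), featureRegistry()$name)
  expect_equal(sum(startsWith(names(fv), "T1c.")), 585L)
  # the geometry block reflects the mask
  expect_equal(fv[["mask.none.geometry.volume_mm3"]],
               sum(voxelData(cohort@masks[[lid]])))
})

test_that("extraction is finite on a constant lesion (degenerate fixture)", {
  dims <- c(10, 10, 10)
  m <- array(FALSE, dims); m[4:7, 4:7, 4:7] <- TRUE
  base <- array(0, dims)
  vols <- lapply(c("T1w", "T1c", "T2w"), function(ct) {
    x <- base; x[m] <- 1  # constant inside the lesion
    imageVolume(x, contrast = ct)
  })
  fv <- extractAllFeatures(vols[[1]], vols[[2]], vols[[3]],
                           imageVolume(array(as.numeric(m), dims),
                                       contrast = "mask"))
  expect_true(all(is.finite(fv)))
})

test_that("direction averaging makes texture features axis-permutation invariant", {
  set.seed(55)
  dims <- c(6, 6, 6)
  lev <- randomROIFixture(dims, 4)
  roi1 <- new("DiscretizedROI", levels = lev, nLevels = 4L)
  levP <- aperm(lev, c(3, 1, 2))
  roi2 <- new("DiscretizedROI", levels = levP, nLevels = 4L)
  expect_equal(glcmFeatures(roi1), glcmFeatures(roi2), tolerance = 1e-6)
  expect_equal(glrlmFeatures(roi1), glrlmFeatures(roi2), tolerance = 1e-6)
})

test_that("GLCM/GLRLM are invariant to 90-degree in-grid rotation of a lesion", {
  cohort <- fixtureTextureCohort()
  lid <- cohort@clinical$lesion_id[1]
  p <- cohort@clinical$patient_id[1]
  v <- zscoreNormalize(cohort@volumes[[p]]$T1c)
  m <- cohort@masks[[lid]]
  rot90 <- function(a) aperm(a[, dim(a)[2]:1, , drop = FALSE], c(2, 1, 3))
  roi1 <- discretizeROI(voxelData(v), voxelData(m))
  roi2 <- discretizeROI(rot90(voxelData(v)), rot90(voxelData(m)))
  expect_equal(glcmFeatures(roi1), glcmFeatures(roi2), tolerance = 1e-6)
  expect_equal(glrlmFeatures(roi1), glrlmFeatures(roi2), tolerance = 1e-6)
})
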