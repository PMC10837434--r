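# A reusable random positive cohort for function-level checks.
randomCohort <- function(n, V, seed) {
  set.seed(seed)
  matrixCohort(matrix(runif(n * V, 0.1, 1), n, V))
}

test_that("seed-voxel associations match a scalar-correlation loop oracle", {
  n <- 30; V <- 300
  cm <- randomCohort(n, V, 91)
  set.seed(92)
  seeds <- matrix(runif(n * 2), n, 2)
  A <- seedVoxelAssociation(cm, seeds)
  expect_equal(unname(A[, ]), bruteAssoc(densityMatrix(cm), seeds),
               tolerance = 1e-10)

  # a voxel identical to the anterior seed correlates exactly 1
  X <- densityMatrix(cm)
  X[, 1] <- seeds[, 1]
  cm2 <- matrixCohort(X)
  A2 <- seedVoxelAssociation(cm2, seeds)
  expect_equal(unname(A2[1, 1]), 1, tolerance = 1e-12)

  # zero-variance voxel: association 0 and flagged
  X[, 2] <- 0.5
  A3 <- seedVoxelAssociation(matrixCohort(X), seeds)
  expect_equal(unname(A3[, 2]), c(0, 0))
  expect_true(attr(A3, "flagged")[2])
  expect_false(attr(A3, "flagged")[3])
})

test_that("independent voxels show near-zero associations at n = 500", {
  n <- 500; V <- 400
  cm <- randomCohort(n, V, 93)
  set.seed(94)
  seeds <- matrix(runif(n * 2), n, 2)
  A <- seedVoxelAssociation(cm, seeds)
  # null correlations are ~ N(0, 1/sqrt(n - 3)); a 99.5%-quantile bound
  # should hold for at least 98% of voxels
  bound <- qnorm(0.995) / sqrt(n - 3)
  expect_gte(mean(abs(A) < bound), 0.98)
  expect_lt(max(abs(A)), 0.25)
})

test_that("non-rotated PLS projects the contrast as specified", {
  assoc <- rbind(c(1, 0, 0.5), c(0, 1, 0.5))
  lv <- nonrotatedPLS(assoc, c(1, -1))
  expect_equal(lv$saliences, c(1, -1, 0) / sqrt(2), tolerance = 1e-12)
  expect_equal(lv$singularValue, 1, tolerance = 1e-12)

  # identical rows cancel under the difference contrast
  same <- rbind(c(0.3, 0.7, 0.1), c(0.3, 0.7, 0.1))
  lv0 <- nonrotatedPLS(same, c(1, -1))
  expect_equal(lv0$singularValue, 0, tolerance = 1e-12)

  # sign flip negates saliences, leaves the singular value
  lvNeg <- nonrotatedPLS(assoc, c(-1, 1))
  expect_equal(lvNeg$saliences, -lv$saliences)
  expect_equal(lvNeg$singularValue, lv$singularValue)
  expect_error(nonrotatedPLS(assoc, c(0, 0)), "nonzero")
})

test_that("non-rotated PLS equals the brute-force definition on larger
           random cohorts", {
  n <- 50; V <- 5000
  cm <- randomCohort(n, V, 95)
  set.seed(96)
  seeds <- matrix(runif(n * 2), n, 2)
  lv <- nonrotatedPLS(seedVoxelAssociation(cm, seeds), c(1, -1))
  bf <- bruteAssoc(densityMatrix(cm), seeds)
  bfSal <- as.numeric((c(1, -1) / sqrt(2)) %*% bf)
  expect_equal(lv$saliences, bfSal, tolerance = 1e-10)
  expect_equal(lv$singularValue, sqrt(sum(bfSal^2)), tolerance = 1e-10)
})

test_that("permutation test flags perfect signal and uses the plain
           proportion convention", {
  n <- 100
  set.seed(97)
  seeds <- matrix(runif(n * 2), n, 2)
  X <- cbind(seeds, matrix(runif(n * 50), n, 50))
  cm <- matrixCohort(X)
  pt <- permutationTest(cm, seeds, n_perm = 200, rng_seed = 7)
  expect_lt(pt$permP, 0.05)
  # observed exceeds every permuted value -> p exactly 0 (plain proportion)
  expect_equal(pt$permP, mean(pt$permuted >= pt$observed))
  if (all(pt$permuted < pt$observed)) expect_equal(pt$permP, 0)
  ptAdd <- permutationTest(cm, seeds, n_perm = 200, rng_seed = 7,
                           convention = "add_one")
  expect_equal(ptAdd$permP, (sum(pt$permuted >= pt$observed) + 1) / 201)
})

test_that("permutation p is stable under joint subject relabeling", {
  n <- 60
  cm <- randomCohort(n, 200, 98)
  set.seed(99)
  seeds <- matrix(runif(n * 2), n, 2)
  p1 <- permutationTest(cm, seeds, n_perm = 400, rng_seed = 5)
  perm <- sample.int(n)
  cm2 <- matrixCohort(densityMatrix(cm)[perm, ])
  p2 <- permutationTest(cm2, seeds[perm, ], n_perm = 400, rng_seed = 5)
  # the observed statistic is exactly invariant; the Monte Carlo p agrees
  # to within resampling error
  expect_equal(p1$observed, p2$observed, tolerance = 1e-12)
  expect_lt(abs(p1$permP - p2$permP),
            2 * sqrt(0.5 * 0.5 / 400) + 1e-12)
})

test_that("bootstrap ratios are reproducible and separate planted from
           noise voxels", {
  co <- generateCohort(smallConfig(n_subjects = 100, rng_seed = 55))
  agg <- aggregateSubfields(co@truth$labels)
  amask <- buildAnalysisMask(co@gmImages, 0.1)
  keep <- gridData(amask) > 0 & gridData(agg$anterior) == 0 &
    gridData(agg$posterior) == 0
  cm <- buildCohortMatrix(co@gmImages, VoxelGrid(keep + 0, gridAffine(amask)))
  seeds <- seedDensities(co@gmImages, agg$anterior, agg$posterior)
  bt <- bootstrapBSR(cm, seeds[, c("ahpc", "phpc")], n_boot = 300,
                     rng_seed = 3)
  bt2 <- bootstrapBSR(cm, seeds[, c("ahpc", "phpc")], n_boot = 300,
                      rng_seed = 3)
  expect_identical(bt$bsr, bt2$bsr)

  lin <- voxelCoords(cm)$linear
  isNet <- gridData(co@truth$networkMask)[lin] > 0
  # planted network voxels are reliably positive at the canonical cutoff
  expect_gte(mean(bt$bsr[isNet] >= 3.3), 0.95)
  expect_gte(max(bt$bsr[isNet]), 3.3)
  # pure-noise voxels essentially never cross it
  expect_gte(mean(abs(bt$bsr[!isNet]) < 3.3), 0.99)
  expect_error(bootstrapBSR(cm, seeds[, c("ahpc", "phpc")], n_boot = 1,
                            rng_seed = 1), "n_boot")
})

test_that("brain scores are the salience-weighted dot product and linear", {
  n <- 20; V <- 40
  set.seed(101)
  cmX <- matrixCohort(matrix(runif(n * V, 0.1, 1), n, V), smoothed = TRUE)
  X <- densityMatrix(cmX)
  expect_equal(scoreSubjects(cmX, rep(0, V)), rep(0, n))
  w <- rep(0, V); w[7] <- 2.5
  expect_equal(scoreSubjects(cmX, w), 2.5 * X[, 7], ignore_attr = TRUE)

  set.seed(102)
  Y <- matrix(runif(n * V, 0.1, 1), n, V)
  sal <- rnorm(V)
  sXY <- scoreSubjects(matrixCohort(2 * X + 3 * Y, smoothed = TRUE), sal)
  expect_equal(sXY, 2 * scoreSubjects(cmX, sal) +
                 3 * scoreSubjects(matrixCohort(Y, smoothed = TRUE), sal),
               tolerance = 1e-10)
  expect_error(scoreSubjects(cmX, rep(1, V + 1)), "mismatch")
})

test_that("cluster extraction honors size, sign, and connectivity rules", {
  d <- c(20, 20, 10)
  a <- array(0, d)
  a[2:7, 2:6, 2:6] <- 4          # 150-voxel positive blob
  a[12:15, 12:15, 2:6] <- 5      # 80-voxel positive blob (dropped)
  cl <- extractClusters(VoxelGrid(a, diag(4)), threshold = 3.3,
                        min_size = 100)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$size_voxels, 150)
  expect_equal(cl$peak_bsr, 4)

  # touching blobs of opposite sign are thresholded separately
  b <- array(0, c(10, 10, 5))
  b[2:4, 2:4, 2:4] <- 4
  b[5:7, 2:4, 2:4] <- -4
  cl2 <- extractClusters(VoxelGrid(b, diag(4)), threshold = 3.3,
                         min_size = 5)
  expect_equal(nrow(cl2), 2)
  expect_setequal(cl2$sign, c("positive", "negative"))

  # peak is reported in mm through the affine
  aff <- affineFromSpacing(2, d)
  one <- array(0, d); one[3:5, 3:5, 3:5] <- 3.5; one[4, 4, 4] <- 6
  cl3 <- extractClusters(VoxelGrid(one, aff), min_size = 10)
  expect_equal(c(cl3$peak_x, cl3$peak_y, cl3$peak_z),
               as.numeric(voxelToMM(aff, c(4, 4, 4))))
})

test_that("cluster extraction matches an igraph flood-fill oracle", {
  skip_if_not_installed("igraph")
  set.seed(103)
  a <- array(rnorm(15^3), c(15, 15, 15))
  a <- gridData(smoothImage(
    new("GMImage", data = array(abs(a), dim(a)), affine = diag(4),
        subjectID = "x", smoothed = FALSE), fwhm_mm = 2)) - 0.25
  for (conn in c(6L, 26L)) {
    mask <- a >= 0.15
    mine <- hippoSCN:::connectedComponents(mask, conn)
    oracle <- igraphComponents(mask, conn)
    key <- function(l) sort(vapply(l, function(v) paste(v, collapse = ","),
                                   character(1)))
    expect_identical(key(mine), key(oracle))
  }
})

test_that("seedPLS bundles a coherent latent variable", {
  co <- generateCohort(smallConfig(n_subjects = 50, rng_seed = 61))
  agg <- aggregateSubfields(co@truth$labels)
  amask <- buildAnalysisMask(co@gmImages, 0.1)
  keep <- gridData(amask) > 0 & gridData(agg$anterior) == 0 &
    gridData(agg$posterior) == 0
  cm <- buildCohortMatrix(co@gmImages, VoxelGrid(keep + 0, gridAffine(amask)))
  seeds <- seedDensities(co@gmImages, agg$anterior, agg$posterior)
  lv <- seedPLS(cm, seeds[, c("ahpc", "phpc")], n_perm = 100, n_boot = 100,
                rng_seed = 12)
  expect_s4_class(lv, "LatentVariable")
  expect_equal(singularValue(lv), sqrt(sum(saliences(lv)^2)),
               tolerance = 1e-10)
  expect_lt(permP(lv), 0.05)
  expect_length(brainScores(lv), 50)
  expect_identical(lv@nPerm, 100L)
})
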