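test_that("identical configurations generate byte-identical cohorts", {
  cfg <- smallConfig(n_subjects = 8, rng_seed = 13)
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(gridData(a@gmImages[[3]]), gridData(b@gmImages[[3]]))
  expect_identical(lapply(a@subjectMasks, gridData),
                   lapply(b@subjectMasks, gridData))
  expect_identical(a@ema, b@ema)
  expect_identical(a@subjects, b@subjects)
  expect_identical(a@truth$f, b@truth$f)
})

test_that("configuration validation rejects degenerate inputs", {
  expect_error(synthConfig(grid_shape = c(7, 18, 12)), "too small")
  expect_error(synthConfig(noise_sd = 0), "noise_sd")
  expect_error(synthConfig(mask_jitter_prob = 1.2), "jitter")
  expect_error(synthConfig(completion_prob = -0.1), "completion")
  expect_error(generateSubjectMasks(VoxelGrid(array(0, c(4, 4, 4))),
                                    jitter = 2, n_subjects = 3), "jitter")
})

test_that("density maps are finite, non-negative, and geometry-consistent", {
  co <- generateCohort(smallConfig(n_subjects = 6, rng_seed = 2))
  for (im in co@gmImages) {
    expect_true(all(is.finite(gridData(im))))
    expect_gte(min(gridData(im)), 0)
  }
  expect_identical(dim(co@gmImages[[1]]), dim(co@subjectMasks[[1]]))
  # posterior sits at more negative y than anterior (MNI-like convention)
  lab <- gridData(co@truth$labels)
  y <- hippoSCN:::axisCoordinateArray(co@truth$labels, 2)
  expect_true(max(y[lab %in% 2:3]) < min(y[lab == 1]))
  expect_true(all(y[lab == 1] >= -21))
  expect_true(all(y[lab %in% 2:3] <= -32))
})

test_that("zero network loading decouples seed and network densities", {
  n <- 400
  co <- generateCohort(smallConfig(n_subjects = n, rng_seed = 31,
                                   latent_loading_network = 0))
  lab <- gridData(co@truth$labels)
  agg <- aggregateSubfields(co@truth$labels)
  seedMean <- vapply(co@gmImages, meanDensity, numeric(1),
                     mask = agg$anterior)
  netVox <- which(gridData(co@truth$networkMask) > 0)[1]
  netDens <- vapply(co@gmImages, function(im) gridData(im)[netVox],
                    numeric(1))
  expect_lt(abs(cor(seedMean, netDens)), 2 / sqrt(n))
})

test_that("planted loadings reproduce the closed-form voxel correlation", {
  # one-factor model: cor(seed voxel, network voxel)
  #   = a*b / sqrt((a^2 + s^2)(b^2 + s^2)) = 0.36/(0.36 + 0.64) = 0.36
  # at a = b = 0.6, s = 0.8; empirical r must fall in the Fisher-z 95% CI.
  n <- 500
  co <- generateCohort(smallConfig(n_subjects = n, rng_seed = 3,
                                   latent_loading_seed = 0.6,
                                   latent_loading_network = 0.6,
                                   noise_sd = 0.8))
  lab <- gridData(co@truth$labels)
  av <- which(lab == 1)[1]
  nv <- which(gridData(co@truth$networkMask) > 0)[1]
  x <- vapply(co@gmImages, function(im) gridData(im)[av], numeric(1))
  y <- vapply(co@gmImages, function(im) gridData(im)[nv], numeric(1))
  r <- cor(x, y)
  ciZ <- atanh(0.36) + c(-1, 1) * 1.96 / sqrt(n - 3)
  expect_gt(r, tanh(ciZ[1]))
  expect_lt(r, tanh(ciZ[2]))
})

test_that("subject masks: zero jitter reproduces truth, full jitter
           randomizes the boundary", {
  co <- generateCohort(smallConfig(n_subjects = 3, rng_seed = 5))
  truth <- co@truth$labels

  exact <- generateSubjectMasks(truth, jitter = 0, n_subjects = 5,
                                rng_seed = 9)
  expect_length(exact, 5)
  for (m in exact) expect_identical(gridData(m), gridData(truth))

  # the small head block is 2 voxels thick along y: every voxel is boundary,
  # so at jitter = 1 each membership is a fair coin and the probabilistic
  # template converges to 0.5 there
  jit <- generateSubjectMasks(truth, jitter = 1, n_subjects = 150,
                              rng_seed = 11)
  heads <- lapply(jit, function(m)
    VoxelGrid((gridData(m) == 1) + 0, gridAffine(m)))
  tm <- buildProbabilisticTemplate(heads, "head")
  boundaryVals <- gridData(tm)[gridData(truth) == 1]
  expect_lt(abs(mean(boundaryVals) - 0.5), 0.03)
})

test_that("interior voxels are never altered by mask jitter", {
  lab <- array(0, c(10, 10, 10))
  lab[3:8, 3:8, 3:8] <- 1
  truth <- VoxelGrid(lab, diag(4))
  masks <- generateSubjectMasks(truth, jitter = 1, n_subjects = 20,
                                rng_seed = 21)
  interior <- array(FALSE, c(10, 10, 10))
  interior[4:7, 4:7, 4:7] <- TRUE
  for (m in masks)
    expect_true(all(gridData(m)[interior] == 1))
})

test_that("planted counts honor the survey schedule and the null case", {
  cfg <- smallConfig(n_subjects = 30, completion_prob = 1, rng_seed = 8)
  set.seed(401); scores <- rnorm(30)
  ema <- plantCounts(scores, cfg, rng_seed = 17)
  fr <- trimFrequency(ema)
  expect_true(all(fr$n_trim_surveys == 42))     # 14 days x 3 TR-IM slots
  expect_true(all(fr$followup_days == 14))
  expect_identical(plantCounts(scores, cfg, rng_seed = 17), ema)

  n <- 400
  cfg0 <- smallConfig(n_subjects = n, completion_prob = 1, beta_brain = 0)
  set.seed(402); s0 <- rnorm(n)
  fr0 <- trimFrequency(plantCounts(s0, cfg0, rng_seed = 19))
  z <- as.numeric(scale(s0))
  tot <- fr0$trim_frequency[match(sprintf("S%03d", 1:n), fr0$subject_id)]
  expect_lt(abs(cor(z, tot)), 2 / sqrt(n))
})

test_that("replicate cohorts recover the planted correlation and IRR", {
  # 50 replicates at n = 200: the mean voxel-pair correlation must sit
  # within 0.03 of the closed-form 0.36, the mean estimated IRR within
  # 0.02 of exp(beta_brain).
  nrep <- 50
  n <- 200
  rs <- numeric(nrep)
  irrs <- numeric(nrep)
  for (r in seq_len(nrep)) {
    cfg <- smallConfig(n_subjects = n, rng_seed = 3000 + r,
                       completion_prob = 1, beta0 = log(1.5))
    co <- generateCohort(cfg)
    lab <- gridData(co@truth$labels)
    av <- which(lab == 1)[5]
    nv <- which(gridData(co@truth$networkMask) > 0)[5]
    x <- vapply(co@gmImages, function(im) gridData(im)[av], numeric(1))
    y <- vapply(co@gmImages, function(im) gridData(im)[nv], numeric(1))
    rs[r] <- cor(x, y)
    d <- merge(data.frame(subject_id = co@subjects$subject_id,
                          score = co@truth$trueScore),
               trimFrequency(co@ema), by = "subject_id")
    irrs[r] <- irrTable(fitTrimPoisson(d, "score"))$irr[2]
  }
  expect_lt(abs(mean(rs) - 0.36), 0.03)
  expect_lt(abs(mean(irrs) - exp(-0.105)), 0.02)
})

test_that("cohorts round-trip through NIfTI and CSV on disk", {
  co <- generateCohort(smallConfig(n_subjects = 3, rng_seed = 23))
  dir <- withr::local_tempdir()
  writeCohort(co, dir)
  expect_true(file.exists(file.path(dir, "gm_S002.nii.gz")))
  back <- readVoxelGrid(file.path(dir, "gm_S002.nii.gz"))
  expect_equal(gridData(back), gridData(co@gmImages[[2]]), tolerance = 1e-6)
  expect_equal(gridAffine(back), gridAffine(co@gmImages[[2]]),
               tolerance = 1e-5)
  subj <- utils::read.csv(file.path(dir, "subjects.csv"))
  expect_identical(subj$subject_id, co@subjects$subject_id)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$f, co@truth$f)
})
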