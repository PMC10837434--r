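#' Configuration for the synthetic cohort generator
#'
#' Defines the study conditions the generator emulates: a cohort of
#' trauma-exposed adults whose modulated gray-matter density maps carry a
#' planted one-factor covariance between an anterior hippocampal seed and a
#' distributed set of "network" voxels, an independent factor driving the
#' posterior seed, per-subject segmentation jitter for template building,
#' and two weeks of EMA surveys whose trauma-related intrusive-memory
#' (TR-IM) counts follow a log-linear Poisson model in the latent brain
#' score with an exposure offset.
#'
#' Defaults mirror the reference cohort: 93 subjects, survey completion
#' 0.835 (so ~58/70 total and ~35/42 TR-IM surveys complete), a baseline
#' daily TR-IM rate of 1.82 (expected two-week frequency ~21), and a planted
#' log incidence-rate-ratio of -0.105 per SD of the latent score. The
#' one-factor loadings (0.6) and noise SD (0.8) give a seed-network voxel
#' correlation of 0.36.
#'
#' @param grid_shape three positive integers, voxels per axis (each >= 8).
#' @param voxel_size_mm isotropic voxel size.
#' @param n_subjects cohort size.
#' @param latent_loading_seed loading of anterior-seed (and posterior-seed)
#'   voxel densities on their latent factor.
#' @param latent_loading_network loading of network voxels on the anterior
#'   factor.
#' @param noise_sd SD of i.i.d. Gaussian voxel noise (> 0).
#' @param mask_jitter_prob probability in `[0, 1]` that a boundary voxel's
#'   region membership is re-randomized (fair coin) in a subject's mask.
#' @param beta0 log baseline TR-IM rate per day.
#' @param beta_brain log IRR per 1 SD of the true latent score.
#' @param completion_prob probability each scheduled survey is completed.
#' @param baseline_density baseline GM density inside the brain; large
#'   relative to the fluctuation scale so truncation at zero is negligible.
#' @param rng_seed integer seed; identical configs generate byte-identical
#'   cohorts.
#' @return A validated list of class `"SynthConfig"`.
#' @seealso [generateCohort()]
#' @export
synthConfig <- function(grid_shape = c(28L, 44L, 28L),
                        voxel_size_mm = 2,
                        n_subjects = 93L,
                        latent_loading_seed = 0.6,
                        latent_loading_network = 0.6,
                        noise_sd = 0.8,
                        mask_jitter_prob = 0.1,
                        beta0 = log(1.82),
                        beta_brain = -0.105,
                        completion_prob = 0.835,
                        baseline_density = 3,
                        rng_seed = 1L) {
  cfg <- list(grid_shape = as.integer(grid_shape),
              voxel_size_mm = voxel_size_mm,
              n_subjects = as.integer(n_subjects),
              latent_loading_seed = latent_loading_seed,
              latent_loading_network = latent_loading_network,
              noise_sd = noise_sd,
              mask_jitter_prob = mask_jitter_prob,
              beta0 = beta0, beta_brain = beta_brain,
              completion_prob = completion_prob,
              baseline_density = baseline_density,
              rng_seed = as.integer(rng_seed))
  if (length(cfg$grid_shape) != 3L || any(cfg$grid_shape < 8L))
    stop("grid_shape must be three integers >= 8 (too small to host ",
         "disjoint anterior/posterior/network regions otherwise)")
  if (!isScalar(cfg$voxel_size_mm) || cfg$voxel_size_mm <= 0)
    stop("voxel_size_mm must be a positive scalar")
  if (cfg$n_subjects < 1L) stop("n_subjects must be positive")
  if (!isScalar(cfg$noise_sd) || cfg$noise_sd <= 0)
    stop("noise_sd must be > 0")
  if (!isProbability(cfg$mask_jitter_prob))
    stop("mask_jitter_prob must lie in [0, 1]")
  if (!isProbability(cfg$completion_prob))
    stop("completion_prob must lie in [0, 1]")
  for (f in c("latent_loading_seed", "latent_loading_network",
              "beta0", "beta_brain", "baseline_density"))
    if (!isScalar(cfg[[f]])) stop(f, " must be a finite scalar")
  class(cfg) <- "SynthConfig"
  cfg
}

#' @export
print.SynthConfig <- function(x, ...) {
  cat("SynthConfig:", x$n_subjects, "subjects,",
      paste(x$grid_shape, collapse = "x"), "voxels at",
      x$voxel_size_mm, "mm, seed", x$rng_seed, "\n")
  invisible(x)
}

# Region layout in index space, anchored in mm so that the anterior
# subregion sits at y >= -21 and the posterior at y <= -32 (hence the
# longitudinal-axis cuts never clip planted voxels), with posterior y more
# negative (MNI-like RAS+ convention). Returns index ranges, the affine,
# the truth label grid, the network mask and the brain mask.
cohortLayout <- function(config) {
  d <- config$grid_shape
  s <- config$voxel_size_mm
  I <- d[1]; J <- d[2]; K <- d[3]

  jAntStart <- round(0.5 * J)
  antSlabs <- max(2L, round(0.11 * J))
  gap2 <- max(3L, round(0.11 * J))
  jAnt <- jAntStart:(jAntStart + antSlabs - 1L)
  netStart <- jAntStart + antSlabs + gap2
  jNetA <- netStart:(netStart + antSlabs - 1L)
  g <- ceiling(11 / s)                 # middle-portion gap: (-32, -21) mm
  jPostEnd <- jAntStart - g
  bodySlabs <- max(2L, round(0.07 * J))
  tailSlabs <- max(1L, round(0.05 * J))
  jBody <- (jPostEnd - bodySlabs + 1L):jPostEnd
  jTail <- (jPostEnd - bodySlabs - tailSlabs + 1L):(jPostEnd - bodySlabs)
  if (max(jNetA) > J - 1L || min(jTail) < 2L)
    stop("grid too small along axis 2 to host the planted regions at ",
         "voxel size ", s, " mm")
  bSlabs <- max(2L, round(0.09 * J))
  jBEnd <- min(jTail) - 4L
  jNetB <- if (jBEnd - bSlabs + 1L >= 2L) (jBEnd - bSlabs + 1L):jBEnd
           else integer(0)

  xl <- max(2L, round(0.14 * I)):round(0.39 * I)
  xr <- sort(I + 1L - xl)
  xlN <- if (length(xl) > 2L) xl[-c(1L, length(xl))] else xl
  xrN <- sort(I + 1L - xlN)
  kWide <- round(0.40 * K):round(0.65 * K)
  kPost <- if (length(kWide) > 2L) kWide[-c(1L, length(kWide))] else kWide
  kB <- round(0.60 * K):min(K - 1L, round(0.80 * K))

  affine <- affineFromSpacing(s, d, yOffset = -21 - s * (jAntStart - 1))

  labels <- array(0, d)
  labels[c(xl, xr), jAnt, kWide] <- 1          # head
  labels[c(xlN, xrN), jBody, kPost] <- 2       # body
  labels[c(xlN, xrN), jTail, kPost] <- 3       # tail
  network <- array(FALSE, d)
  network[c(xl, xr), jNetA, kWide] <- TRUE
  if (length(jNetB)) network[c(xl, xr), jNetB, kB] <- TRUE
  brain <- array(FALSE, d)
  brain[2:(I - 1L), 2:(J - 1L), 2:(K - 1L)] <- TRUE

  list(affine = affine,
       labels = VoxelGrid(labels, affine),
       networkMask = VoxelGrid(network + 0, affine),
       brainMask = VoxelGrid(brain + 0, affine),
       xLeft = xl, xRight = xr, jAnterior = jAnt,
       jBody = jBody, jTail = jTail, jNetworkA = jNetA, jNetworkB = jNetB)
}

#' Generate a synthetic cohort with planted covariance structure
#'
#' Simulates per-subject GM density maps under a one-factor linear-Gaussian
#' model per region: anterior-seed voxels load on a standard-normal factor
#' `f_i` with `latent_loading_seed`, designated network voxels load on the
#' same factor with `latent_loading_network`, posterior-seed voxels load on
#' an independent factor `g_i`, and all other in-brain voxels are baseline
#' plus noise. Densities are clipped at zero (modulated GM density cannot be
#' negative). Subject label masks are jittered copies of the truth labels
#' ([generateSubjectMasks()]), covariates are drawn from cohort-typical
#' marginals, and EMA counts are planted with [plantCounts()] using the
#' standardized `f_i` as the true brain score.
#'
#' @param config a [synthConfig()].
#' @return A [SynthCohort-class].
#' @examples
#' cohort <- generateCohort(synthConfig(grid_shape = c(12, 18, 12),
#'                                      voxel_size_mm = 3, n_subjects = 10))
#' cohort
#' @export
generateCohort <- function(config) {
  stopifnot(inherits(config, "SynthConfig"))
  lay <- cohortLayout(config)
  n <- config$n_subjects
  d <- config$grid_shape
  nv <- prod(d)
  ids <- sprintf("S%03d", seq_len(n))

  antIdx <- which(gridData(lay$labels) == 1)
  postIdx <- which(gridData(lay$labels) %in% c(2, 3))
  netIdx <- which(gridData(lay$networkMask) > 0)
  brainIdx <- which(gridData(lay$brainMask) > 0)

  sim <- withSeed(config$rng_seed, function() {
    f <- rnorm(n)
    g <- rnorm(n)
    imgs <- vector("list", n)
    base <- numeric(nv)
    base[brainIdx] <- config$baseline_density
    for (i in seq_len(n)) {
      v <- base + config$noise_sd * rnorm(nv)
      v[antIdx] <- v[antIdx] + config$latent_loading_seed * f[i]
      v[netIdx] <- v[netIdx] + config$latent_loading_network * f[i]
      v[postIdx] <- v[postIdx] + config$latent_loading_seed * g[i]
      v[v < 0] <- 0
      imgs[[i]] <- new("GMImage", data = array(v, d), affine = lay$affine,
                       subjectID = ids[i], smoothed = FALSE)
    }
    age <- pmin(65, pmax(18, rnorm(n, 32.7, 11.18)))
    sex <- rbinom(n, 1L, 0.806)          # 1 = female
    caps <- pmax(0, round(rnorm(n, 24.37, 9.27)))
    list(f = f, g = g, imgs = imgs, age = age, sex = sex, caps = caps)
  })

  masks <- generateSubjectMasks(lay$labels, config$mask_jitter_prob, n,
                                rng_seed = config$rng_seed + 1L)
  trueScore <- if (n > 1L) as.numeric(scale(sim$f)) else sim$f
  ema <- plantCounts(sim$f, config, subject_ids = ids,
                     rng_seed = config$rng_seed + 2L)

  subjects <- data.frame(subject_id = ids, age = sim$age, sex = sim$sex,
                         caps_composite = sim$caps,
                         stringsAsFactors = FALSE)
  truth <- list(f = sim$f, g = sim$g, trueScore = trueScore,
                labels = lay$labels, networkMask = lay$networkMask,
                brainMask = lay$brainMask, layout = lay)
  new("SynthCohort", gmImages = sim$imgs, subjectMasks = masks,
      truth = truth, subjects = subjects, ema = ema,
      config = unclass(config))
}

setMethod("show", "SynthCohort", function(object) {
  cat(sprintf("SynthCohort: %d subjects, grid %s, seed %d\n",
              nrow(object@subjects),
              paste(dim(object@gmImages[[1]]@data), collapse = "x"),
              object@config$rng_seed))
})

#' Jittered per-subject subregion label masks
#'
#' Each subject's mask equals the truth labels except at region boundaries:
#' a boundary voxel (a labeled voxel with a 6-connected background
#' neighbour, or a background voxel with a 6-connected labeled neighbour)
#' has its membership re-randomized to a fair coin with probability
#' `jitter`. Interior voxels are never altered. At `jitter = 0` every mask
#' equals the truth; at `jitter = 1` boundary membership is fully
#' randomized, so probabilistic template values at the boundary approach
#' 0.5.
#'
#' @param truth_labels label [VoxelGrid-class] with codes 0 (background),
#'   1 (head), 2 (body), 3 (tail).
#' @param jitter re-randomization probability in `[0, 1]`.
#' @param n_subjects number of masks to draw.
#' @param rng_seed integer seed.
#' @return list of `n_subjects` label [VoxelGrid-class] objects.
#' @export
generateSubjectMasks <- function(truth_labels, jitter, n_subjects,
                                 rng_seed = 1L) {
  if (!isProbability(jitter)) stop("jitter must lie in [0, 1]")
  lab <- gridData(truth_labels)
  if (!all(unique(as.vector(lab)) %in% 0:3))
    stop("truth_labels must use codes {0, 1, 2, 3}")
  d <- dim(lab)
  off <- neighborOffsets(6L)

  # boundary detection via shifted copies (6-connectivity)
  inReg <- lab > 0
  hasBgNb <- array(FALSE, d)
  hasRegNb <- array(FALSE, d)
  nbLabel <- array(0, d)        # a labeled neighbour's code, for halo voxels
  for (r in seq_len(nrow(off))) {
    shifted <- shiftArray(lab, off[r, ])
    hasBgNb <- hasBgNb | (shifted == 0)
    hasRegNb <- hasRegNb | (shifted > 0)
    take <- nbLabel == 0 & shifted > 0
    nbLabel[take] <- shifted[take]
  }
  innerIdx <- which(inReg & hasBgNb)
  haloIdx <- which(!inReg & hasRegNb)
  nb <- length(innerIdx) + length(haloIdx)

  withSeed(rng_seed, function() {
    lapply(seq_len(n_subjects), function(i) {
      m <- lab
      hit <- runif(nb) < jitter
      coin <- runif(nb) < 0.5
      dropInner <- hit[seq_along(innerIdx)] & coin[seq_along(innerIdx)]
      m[innerIdx[dropInner]] <- 0
      jh <- seq_along(haloIdx) + length(innerIdx)
      addHalo <- hit[jh] & coin[jh]
      m[haloIdx[addHalo]] <- nbLabel[haloIdx[addHalo]]
      VoxelGrid(m, gridAffine(truth_labels))
    })
  })
}

# Shift an array by one voxel along each axis per `by` (values in -1:1),
# padding with 0: used for neighbourhood queries.
shiftArray <- function(a, by) {
  d <- dim(a)
  out <- array(0, d)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    if (by[ax] == 0) { src[[ax]] <- seq_len(d[ax]); dst[[ax]] <- seq_len(d[ax]) }
    else if (by[ax] == 1) { src[[ax]] <- seq_len(d[ax] - 1L); dst[[ax]] <- 2:d[ax] }
    else { src[[ax]] <- 2:d[ax]; dst[[ax]] <- seq_len(d[ax] - 1L) }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Plant EMA TR-IM counts from true latent scores
#'
#' Simulates the two-week EMA schedule: 14 days x 5 daily surveys, of which
#' slots 2-4 probe TR-IMs (42 TR-IM surveys maximum). Each scheduled survey
#' is completed independently with `completion_prob`. Each completed TR-IM
#' survey's count is Poisson with log rate
#' `beta0 + beta_brain * z(true_score)`, the daily exposure being shared
#' equally across the three TR-IM slots.
#'
#' @param true_scores numeric, one latent score per subject (standardized
#'   internally).
#' @param config a [synthConfig()] supplying `beta0`, `beta_brain`,
#'   `completion_prob`.
#' @param subject_ids optional ids; default `S001`, ...
#' @param rng_seed integer seed.
#' @return long-format data.frame: `subject_id`, `day` (1-14), `slot`
#'   (1-5), `completed` (logical), `trim_count` (integer; `NA` unless the
#'   slot is a completed TR-IM survey).
#' @export
plantCounts <- function(true_scores, config,
                        subject_ids = sprintf("S%03d", seq_along(true_scores)),
                        rng_seed = config$rng_seed) {
  stopifnot(inherits(config, "SynthConfig"))
  n <- length(true_scores)
  if (length(subject_ids) != n) stop("one id per subject required")
  z <- if (n > 1L && sd(true_scores) > 0) as.numeric(scale(true_scores))
       else rep(0, n)
  lambdaDay <- exp(config$beta0 + config$beta_brain * z)

  grid <- expand.grid(slot = 1:5, day = 1:14, subject = seq_len(n))
  nrec <- nrow(grid)
  withSeed(rng_seed, function() {
    completed <- runif(nrec) < config$completion_prob
    isTrim <- grid$slot %in% 2:4
    cnt <- rep(NA_integer_, nrec)
    doCount <- completed & isTrim
    cnt[doCount] <- rpois(sum(doCount), lambdaDay[grid$subject[doCount]] / 3)
    data.frame(subject_id = subject_ids[grid$subject],
               day = grid$day, slot = grid$slot,
               completed = completed, trim_count = cnt,
               stringsAsFactors = FALSE)
  })
}

#' Write a synthetic cohort to disk
#'
#' Writes `gm_<id>.nii.gz` and `mask_<id>.nii.gz` (NIfTI-1, RAS+ affine),
#' `subjects.csv`, `ema.csv` and `truth.json` under `dir`.
#'
#' @param cohort a [SynthCohort-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- cohort@subjects$subject_id
  for (i in seq_along(ids)) {
    writeVoxelGrid(cohort@gmImages[[i]],
                   file.path(dir, sprintf("gm_%s.nii.gz", ids[i])))
    writeVoxelGrid(cohort@subjectMasks[[i]],
                   file.path(dir, sprintf("mask_%s.nii.gz", ids[i])))
  }
  utils::write.csv(cohort@subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort@ema, file.path(dir, "ema.csv"), row.names = FALSE)
  truth <- list(f = cohort@truth$f, g = cohort@truth$g,
                trueScore = cohort@truth$trueScore,
                rng_seed = cohort@config$rng_seed)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
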