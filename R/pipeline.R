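#' Full run configuration
#'
#' Bundles every stage's settings. All stage seeds are derived
#' deterministically from the single `seed`, so a run is a pure function of
#' its configuration.
#'
#' @param synth a [synthConfig()] for the simulated cohort (its `rng_seed`
#'   is overridden by `seed`).
#' @param template a [templateConfig()].
#' @param mask_threshold analysis-mask mean-density cutoff.
#' @param fwhm_mm smoothing kernel FWHM for the brain-score images.
#' @param contrast a priori seed contrast (anterior, posterior).
#' @param n_perm,n_boot resampling sizes.
#' @param bsr_threshold,min_cluster,connectivity cluster-report settings.
#' @param method association method, `"correlation"` or `"covariance"`.
#' @param exclude_seeds drop the seed templates' own voxels from the
#'   voxelwise matrix, so the latent variable relates the seeds to all the
#'   *other* brain voxels (default `TRUE`; keeps the permutation test
#'   calibrated, since a seed mean trivially correlates with its
#'   constituent voxels).
#' @param min_surveys EMA inclusion cutoff.
#' @param seed global integer seed.
#' @return list of class `"RunConfig"`.
#' @export
runConfig <- function(synth = synthConfig(),
                      template = templateConfig(),
                      mask_threshold = 0.1,
                      fwhm_mm = 8,
                      contrast = c(1, -1),
                      n_perm = 1000L,
                      n_boot = 1000L,
                      bsr_threshold = 3.3,
                      min_cluster = 100L,
                      connectivity = 26L,
                      method = "correlation",
                      exclude_seeds = TRUE,
                      min_surveys = 49L,
                      seed = 1L) {
  seed <- as.integer(seed)
  synth$rng_seed <- seed
  structure(list(synth = synth, template = template,
                 mask_threshold = mask_threshold, fwhm_mm = fwhm_mm,
                 contrast = contrast, n_perm = as.integer(n_perm),
                 n_boot = as.integer(n_boot),
                 bsr_threshold = bsr_threshold,
                 min_cluster = as.integer(min_cluster),
                 connectivity = as.integer(connectivity),
                 method = method, exclude_seeds = isTRUE(exclude_seeds),
                 min_surveys = as.integer(min_surveys),
                 seed = seed),
            class = "RunConfig")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the [runConfig()] arguments; `synth` and
#' `template` are nested maps passed to [synthConfig()] and
#' [templateConfig()].
#'
#' @param path YAML file.
#' @param ... overrides applied after reading.
#' @return list of class `"RunConfig"`.
#' @export
readRunConfig <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  args <- raw
  if (!is.null(raw$synth)) args$synth <- do.call(synthConfig, raw$synth)
  if (!is.null(raw$template))
    args$template <- do.call(templateConfig, raw$template)
  over <- list(...)
  args[names(over)] <- over
  do.call(runConfig, args)
}

stageLog <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s (%s)", stage, sprintf(fmt, ...),
                  format(Sys.time(), "%H:%M:%S")))
}

#' Run the full pipeline: simulate, templates, volumes, PLS, regression
#'
#' Executes every stage in order on a simulated cohort and returns a single
#' machine-readable report: template statistics, subregion volumes, the
#' latent-variable summary (singular value, permutation p), the cluster
#' table, brain-score correlations, and the Poisson model table (anterior
#' volume, posterior volume, brain score, and the brain-score model with
#' the CAPS composite added as a sensitivity covariate). Every output is
#' stamped with the configuration hash and seed; identical configurations
#' yield identical reports. Progress is logged to standard error.
#'
#' @param config a [runConfig()].
#' @param out_dir optional directory; when given, NIfTI maps
#'   (salience, BSR), CSV tables (brain scores, volumes, clusters) and the
#'   JSON report are written there.
#' @return the report, an ordinary list.
#' @export
runPipeline <- function(config = runConfig(), out_dir = NULL) {
  stopifnot(inherits(config, "RunConfig"))
  t0 <- Sys.time()

  stageLog("simulate", "generating cohort of %d subjects",
           config$synth$n_subjects)
  cohort <- generateCohort(config$synth)

  stageLog("ema", "compliance and TR-IM accounting")
  comp <- emaCompliance(cohort@ema, config$min_surveys)
  freq <- trimFrequency(cohort@ema)
  keep <- comp$subject_id[comp$include]
  sel <- match(keep, cohort@subjects$subject_id)
  subjects <- cohort@subjects[sel, , drop = FALSE]
  subjects <- merge(subjects, comp, by = "subject_id", sort = FALSE)
  subjects <- merge(subjects, freq, by = "subject_id", sort = FALSE)
  imgs <- cohort@gmImages[sel]
  masks <- cohort@subjectMasks[sel]

  stageLog("templates", "probabilistic templates from %d masks",
           length(masks))
  tmpl <- buildTemplates(masks, config$template)

  stageLog("volumes", "subregion volumes and seed densities")
  vols <- volumeTable(imgs, tmpl$anterior, tmpl$posterior)
  seeds <- seedDensities(imgs, tmpl$anterior, tmpl$posterior)
  subjects <- merge(subjects, vols, by = "subject_id", sort = FALSE)

  stageLog("pls", "analysis mask, cohort matrices, seed PLS (%d perm, %d boot)",
           config$n_perm, config$n_boot)
  amask <- buildAnalysisMask(imgs, config$mask_threshold)
  if (config$exclude_seeds) {
    keepVox <- gridData(amask) > 0 & gridData(tmpl$anterior) == 0 &
      gridData(tmpl$posterior) == 0
    amask <- VoxelGrid(keepVox + 0, gridAffine(amask))
  }
  cmRaw <- buildCohortMatrix(imgs, amask)
  smoothImgs <- lapply(imgs, smoothImage, fwhm_mm = config$fwhm_mm)
  cmSmooth <- buildCohortMatrix(smoothImgs, amask)
  lv <- seedPLS(cmRaw, seeds[, c("ahpc", "phpc")],
                contrast = config$contrast,
                n_perm = config$n_perm, n_boot = config$n_boot,
                rng_seed = config$seed + 1000L, method = config$method,
                smoothed_cohort = cmSmooth)
  subjects$brain_score <- brainScores(lv)
  bsrMap <- statMap(cmRaw, ifelse(is.na(lv@bsr), 0, lv@bsr))
  clusters <- extractClusters(bsrMap, config$bsr_threshold,
                              config$min_cluster, config$connectivity)

  stageLog("regress", "Poisson models")
  covars <- c("age", "sex", "n_trim_surveys")
  mA <- fitTrimPoisson(subjects, c("aHPC_volume", covars),
                       label = "aHPC_volume")
  mP <- fitTrimPoisson(subjects, c("pHPC_volume", covars),
                       label = "pHPC_volume")
  mB <- fitTrimPoisson(subjects, c("brain_score", covars),
                       label = "brain_score")
  mBc <- fitTrimPoisson(subjects,
                        c("brain_score", covars, "caps_composite"),
                        label = "brain_score+caps")
  corA <- pearsonR(subjects$brain_score, subjects$aHPC_volume)
  corP <- pearsonR(subjects$brain_score, subjects$pHPC_volume)

  report <- list(
    schema_version = "1.0",
    seed = config$seed,
    config_hash = configHash(config),
    n_simulated = config$synth$n_subjects,
    n_included = nrow(subjects),
    ema = list(mean_total_surveys = mean(subjects$n_total_surveys),
               mean_trim_surveys = mean(subjects$n_trim_surveys),
               mean_trim_frequency = mean(subjects$trim_frequency),
               sd_trim_frequency = sd(subjects$trim_frequency)),
    templates = tmpl$stats,
    volumes = list(aHPC_mean = mean(subjects$aHPC_volume),
                   pHPC_mean = mean(subjects$pHPC_volume)),
    lv = list(singular_value = singularValue(lv),
              perm_p = permP(lv),
              n_perm = config$n_perm, n_boot = config$n_boot,
              n_reliable_pos = sum(lv@bsr >= config$bsr_threshold,
                                   na.rm = TRUE),
              n_reliable_neg = sum(lv@bsr <= -config$bsr_threshold,
                                   na.rm = TRUE)),
    correlations = list(
      brainscore_ahpc = corA, brainscore_phpc = corP),
    clusters = clusters,
    models = lapply(list(mA, mP, mB, mBc), function(f)
      list(model = f@model, n = f@n, converged = f@converged,
           nagelkerke_r2 = f@nagelkerke, dispersion = f@dispersion,
           coefficients = f@coefficients)))
  stageLog("done", "finished in %.1f s",
           as.numeric(difftime(Sys.time(), t0, units = "secs")))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeVoxelGrid(statMap(cmRaw, lv@saliences),
                   file.path(out_dir, "salience_map.nii.gz"))
    writeVoxelGrid(bsrMap, file.path(out_dir, "bsr_map.nii.gz"))
    utils::write.csv(subjects[, c("subject_id", "brain_score")],
                     file.path(out_dir, "brain_scores.csv"),
                     row.names = FALSE)
    utils::write.csv(vols, file.path(out_dir, "volumes.csv"),
                     row.names = FALSE)
    utils::write.csv(clusters, file.path(out_dir, "clusters.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "pls_report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  report
}

# Build thresholded, axis-cut bilateral anterior/posterior templates from
# per-subject label masks, per hemisphere, and merge hemispheres back into
# bilateral masks for seeding/volumes.
buildTemplates <- function(masks, tcfg = templateConfig()) {
  agg <- lapply(masks, aggregateSubfields)
  pieces <- list()
  for (region in c("anterior", "posterior")) {
    for (hemi in c("left", "right")) {
      hmasks <- lapply(agg, function(a) splitHemispheres(a[[region]])[[hemi]])
      tm <- buildProbabilisticTemplate(hmasks,
                                       paste(region, hemi, sep = "_"))
      pieces[[paste(region, hemi, sep = "_")]] <-
        thresholdTemplate(tm, tcfg$prob_threshold)
    }
  }
  cutL <- applyAxisCuts(pieces$anterior_left, pieces$posterior_left, tcfg)
  cutR <- applyAxisCuts(pieces$anterior_right, pieces$posterior_right, tcfg)
  aff <- gridAffine(pieces$anterior_left)
  bilat <- function(a, b) VoxelGrid((gridData(a) > 0 | gridData(b) > 0) + 0,
                                    aff)
  anterior <- bilat(cutL$anterior, cutR$anterior)
  posterior <- bilat(cutL$posterior, cutR$posterior)
  list(anterior = anterior, posterior = posterior,
       stats = list(
         n_masks = length(masks),
         prob_threshold = tcfg$prob_threshold,
         anterior_voxels = sum(gridData(anterior) > 0),
         posterior_voxels = sum(gridData(posterior) > 0)))
}

# Deterministic fingerprint of a configuration (md5 of its serialized JSON).
configHash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(config, f, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(f))
}
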