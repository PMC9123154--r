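# End-to-end orchestration: (1) pre-processing (registration + subtraction +
# denoising + smoothing), (2) lesion detection (CMF), (3) post-processing
# (morphological refinement).

#' Default pipeline configuration
#'
#' Nested list of every stage's parameters. Notable defaults: rigid
#' volume-shared registration with a 3-level pyramid; log-Gabor bank with 8
#' scales and 6 orientations (min wavelength 3 px, multiplier 2.1, sigmaOnF
#' 0.55, Rayleigh multiplier c = 1); 5 x 5 adaptive Wiener window; bilateral
#' sigmas (2 px, 15 gray levels); CMF with alpha = 1, lambda_tv = 25,
#' threshold 0.5 and a per-slice contrast gate of 10 gray levels (slices
#' whose two-class means separate by less are declared lesion-free); disc
#' radius 5 refinement with 8-connectivity per slice.
#'
#' @return nested configuration list
#' @export
defaultPipelineConfig <- function() {
  list(
    post_frame_index = 1L,
    registration = list(enabled = TRUE, metric = "robust_mse", mode = "rigid",
                        levels = 1L, max_iter = 400L, tol = 1e-6,
                        robust_k = 6, smooth_sigma = 1.5, per_slice = FALSE),
    denoise = list(enabled = TRUE, n_scales = 8L, n_orientations = 6L,
                   min_wavelength = 3, mult = 2.1, sigma_on_f = 0.55, c = 1),
    wiener = list(enabled = TRUE, window = c(5L, 5L), v2 = NULL),
    bilateral = list(enabled = TRUE, sigma_spatial = 2, sigma_range = 15),
    cmf = list(alpha = 1, lambda_tv = 25, edge_adaptive = FALSE, beta = 10,
               step = 0.16, cc = 0.3, max_iter = 300L, tol = 1e-4,
               threshold = 0.5, min_contrast = 10),
    post = list(enabled = TRUE, se_radius = 5L, connectivity = 8L,
                per_slice = TRUE)
  )
}

#' Validate (and complete) a pipeline configuration
#'
#' Unknown keys raise an error; omitted keys inherit the defaults.
#'
#' @param cfg nested list (possibly partial)
#' @return completed configuration list
#' @export
validatePipelineConfig <- function(cfg) {
  def <- defaultPipelineConfig()
  if (is.null(cfg)) return(def)
  bad <- setdiff(names(cfg), names(def))
  if (length(bad))
    stop("unknown config section(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (sec in names(cfg)) {
    if (!is.list(def[[sec]])) { def[[sec]] <- cfg[[sec]]; next }
    badk <- setdiff(names(cfg[[sec]]), names(def[[sec]]))
    if (length(badk))
      stop("unknown config key(s) in ", sec, ": ",
           paste(badk, collapse = ", "), call. = FALSE)
    for (k in names(cfg[[sec]])) def[[sec]][[k]] <- cfg[[sec]][[k]]
  }
  with(def, {
    stopifnot(cmf$alpha > 0, cmf$lambda_tv > 0,
              cmf$threshold >= 0, cmf$threshold <= 1,
              denoise$n_scales >= 1, denoise$n_orientations >= 1,
              post$se_radius >= 0)
  })
  def
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys mirror [defaultPipelineConfig()]
#' @param overrides optional character vector of \code{key.subkey=value}
#'   overrides (values parsed as R literals when possible)
#' @return completed configuration list
#' @export
readPipelineConfig <- function(path = NULL, overrides = character()) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  for (ov in overrides) {
    kv <- strsplit(ov, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("bad --set override: ", ov, call. = FALSE)
    keys <- strsplit(kv[1], ".", fixed = TRUE)[[1]]
    val <- tryCatch(eval(parse(text = kv[2]), envir = baseenv()),
                    error = function(e) kv[2])
    if (length(keys) == 1) cfg[[keys]] <- val
    else cfg[[keys[1]]][[keys[2]]] <- val
  }
  validatePipelineConfig(cfg)
}

.segmentSlice <- function(slice, cmfCfg) {
  means <- tryCatch(.twoClassMeans(slice), error = function(e) NULL)
  if (is.null(means) || diff(means) < cmfCfg$min_contrast)
    return(list(u = matrix(0, nrow(slice), ncol(slice)), gated = TRUE))
  cap <- buildCapacities(slice, fgMean = means[2], bgMean = means[1],
                         alpha = cmfCfg$alpha, lambdaTV = cmfCfg$lambda_tv,
                         edgeAdaptive = cmfCfg$edge_adaptive,
                         beta = cmfCfg$beta)
  res <- solveCmfTwoLabel(cap, step = cmfCfg$step, cc = cmfCfg$cc,
                          maxIter = cmfCfg$max_iter, tol = cmfCfg$tol)
  list(u = res@u, gated = FALSE)
}

#' Segment a DCE-MRI case end to end
#'
#' Runs registration (post onto pre), subtraction (clamped at 0),
#' phase-preserved denoising, adaptive Wiener and bilateral smoothing,
#' per-slice two-label CMF segmentation with a contrast gate, thresholding,
#' and morphological refinement. Deterministic for a fixed configuration.
#'
#' @param pre,post [VolumeImage-class]s of identical shape
#' @param config configuration list (see [defaultPipelineConfig()]); partial
#'   lists are completed
#' @param gt optional ground-truth [BinaryMask-class]; when supplied the
#'   result carries a [MetricsReport-class] (plus ROC AUC from the soft
#'   labels)
#' @param verbose log per-stage progress
#' @return a [CaseResult-class]
#' @export
segmentCase <- function(pre, post, config = defaultPipelineConfig(),
                        gt = NULL, verbose = FALSE) {
  cfg <- validatePipelineConfig(config)
  stopifnot(is(pre, "VolumeImage"), is(post, "VolumeImage"))
  if (!all(dim(pre@data) == dim(post@data)))
    stop("pre and post volumes must have identical shape", call. = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  flags <- character()

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  # (1) registration + subtraction
  if (cfg$registration$enabled) {
    say("registering post onto pre (%s, %d levels)",
        cfg$registration$mode, cfg$registration$levels)
    reg <- stage("registration",
      registerAffine(post, pre, mode = cfg$registration$mode,
                     levels = cfg$registration$levels,
                     maxIter = cfg$registration$max_iter,
                     tol = cfg$registration$tol,
                     robustK = cfg$registration$robust_k,
                     smoothSigma = cfg$registration$smooth_sigma,
                     perSlice = cfg$registration$per_slice))
    transform <- reg$transform
    registered <- stage("registration",
      applyAffineVolume(post, transform, interpolation = "bicubic"))
  } else {
    transform <- composeAffine()
    registered <- post
  }
  subtracted <- stage("subtraction", subtractVolumes(registered, pre))

  # denoising + smoothing
  denoised <- subtracted
  if (cfg$denoise$enabled) {
    say("phase-preserved denoising (%d scales x %d orientations)",
        cfg$denoise$n_scales, cfg$denoise$n_orientations)
    denoised <- stage("denoise",
      denoiseVolume(subtracted, nScales = cfg$denoise$n_scales,
                    nOrientations = cfg$denoise$n_orientations,
                    minWavelength = cfg$denoise$min_wavelength,
                    mult = cfg$denoise$mult,
                    sigmaOnF = cfg$denoise$sigma_on_f, c = cfg$denoise$c))
  }
  smoothed <- denoised@data
  if (cfg$wiener$enabled)
    smoothed <- stage("wiener",
      .mapSlices(smoothed, adaptiveWiener, window = cfg$wiener$window,
                 v2 = cfg$wiener$v2))
  if (cfg$bilateral$enabled)
    smoothed <- stage("bilateral",
      .mapSlices(smoothed, bilateralFilter,
                 sigmaSpatial = cfg$bilateral$sigma_spatial,
                 sigmaRange = cfg$bilateral$sigma_range))
  smoothedVol <- VolumeImage(smoothed, pre@spacing)

  # (2) lesion detection: per-slice two-label CMF
  d <- dim(smoothed)
  u <- array(0, d)
  gated <- logical(d[1])
  for (z in seq_len(d[1])) {
    r <- stage("cmf", .segmentSlice(smoothed[z, , , drop = TRUE], cfg$cmf))
    u[z, , ] <- r$u
    gated[z] <- r$gated
  }
  if (all(gated)) flags <- c(flags, "no lesion detected")
  maskRaw <- BinaryMask(.mapSlices(u, thresholdLabels,
                                   level = cfg$cmf$threshold), pre@spacing)

  # (3) post-processing
  mask <- maskRaw
  if (cfg$post$enabled && sum(maskRaw@data) > 0) {
    say("morphological refinement (disc r=%d)", cfg$post$se_radius)
    mask <- stage("postprocess",
      refineMask(maskRaw, seRadius = cfg$post$se_radius,
                 connectivity = cfg$post$connectivity,
                 perSlice = cfg$post$per_slice))
  }

  metrics <- NULL
  if (!is.null(gt)) {
    metrics <- computeMetrics(confusionCounts(mask, gt))
    auc <- tryCatch(rocAuc(pmin(pmax(u, 0), 1), gt), error = function(e) NA)
    metrics@values <- c(metrics@values, AUC = auc)
  }

  new("CaseResult", mask = mask, maskRaw = maskRaw, u = u,
      transform = if (is.list(transform)) transform[[1]] else transform,
      intermediates = list(registered = registered, subtracted = subtracted,
                           denoised = denoised, smoothed = smoothedVol),
      metrics = metrics,
      provenance = list(package = "cmfseg",
                        version = as.character(utils::packageVersion("cmfseg")),
                        config = cfg, flags = flags))
}

#' Batch segmentation from a manifest
#'
#' The manifest CSV needs columns \code{case_id}, \code{pre_path},
#' \code{post_path} and optionally \code{gt_path}; a metrics table (one row
#' per case) is written to \code{outDir/metrics.csv}.
#'
#' @param manifest CSV path
#' @param outDir output directory (created if needed)
#' @param config pipeline configuration
#' @param saveIntermediate also write intermediate volumes per case
#' @return the metrics data.frame, invisibly
#' @export
segmentBatch <- function(manifest, outDir, config = defaultPipelineConfig(),
                         saveIntermediate = FALSE) {
  man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("case_id", "pre_path", "post_path")
  if (!all(need %in% names(man)))
    stop("manifest must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  reports <- list(); aucs <- numeric()
  for (i in seq_len(nrow(man))) {
    id <- man$case_id[i]
    pre <- readVolume(man$pre_path[i])
    post <- readVolume(man$post_path[i])
    gt <- if (!is.null(man$gt_path) && nzchar(man$gt_path[i]))
      readVolume(man$gt_path[i], mask = TRUE) else NULL
    res <- segmentCase(pre, post, config, gt = gt)
    writeVolume(res@mask, file.path(outDir, paste0(id, "_mask.nii.gz")))
    if (saveIntermediate)
      for (nm in names(res@intermediates))
        writeVolume(res@intermediates[[nm]],
                    file.path(outDir, paste0(id, "_", nm, ".nii.gz")))
    if (!is.null(res@metrics)) {
      reports[[id]] <- res@metrics
      aucs[id] <- res@metrics@values[["AUC"]]
    }
  }
  tab <- if (length(reports)) metricsTable(reports, auc = aucs) else NULL
  if (!is.null(tab))
    utils::write.csv(cbind(case_id = names(reports), tab),
                     file.path(outDir, "metrics.csv"), row.names = FALSE)
  invisible(tab)
}
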