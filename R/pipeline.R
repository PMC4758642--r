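#' Default pipeline configuration
#'
#' The full resolved configuration of a pipeline run as a flat named list.
#' The schema (all keys, with defaults) is exactly what this function
#' returns; \code{\link{readRunConfig}} and \code{\link{writeRunConfig}}
#' round-trip it losslessly through a YAML file of \code{key: value} pairs.
#'
#' Keys: \code{stages} (subset of "simulate", "puncta", "coloc", "unmix",
#' "kymo" in dependency order), \code{seed}, geometry
#' (\code{pixel_size_um}, \code{width_px}, \code{height_px}), puncta
#' simulation (\code{n_puncta}, \code{punctum_sigma_um}, \code{amplitude},
#' \code{background}, \code{noise_sd}), colocalization
#' (\code{coloc_fraction}, \code{offset_um}, \code{tolerance}), thresholds
#' (\code{threshold_method}, \code{percentile}, \code{min_area}), movie
#' (\code{frames}, \code{fps}, \code{move_px}, \code{stationary_frames},
#' \code{region_um}), unmixing (\code{lambda_noise_sd}), and optional input
#' paths (\code{image_path}, \code{movie_path}, \code{stack_path}) that
#' replace the simulated inputs of downstream stages.
#'
#' @return named list of defaults
#' @export
defaultRunConfig <- function() {
  list(
    stages = c("simulate", "puncta", "coloc", "unmix", "kymo"),
    seed = 1L,
    pixel_size_um = 0.16, width_px = 512L, height_px = 64L,
    n_puncta = 12L, punctum_sigma_um = 0.6 / 2.355,
    amplitude = 100, background = 10, noise_sd = 2,
    coloc_fraction = 0.5, offset_um = 0, tolerance = 0.1,
    threshold_method = "otsu", percentile = 0.05, min_area = 4L,
    frames = 100L, fps = 3.1, move_px = 3L, stationary_frames = 3L,
    region_um = 18,
    lambda_noise_sd = 0.01,
    image_path = NULL, movie_path = NULL, stack_path = NULL)
}

#' Read / write a pipeline configuration
#'
#' Configurations are YAML files of flat \code{key: value} pairs following
#' the \code{\link{defaultRunConfig}} schema; unknown keys are rejected and
#' missing keys filled from the defaults, so a round trip through
#' \code{writeRunConfig} then \code{readRunConfig} is lossless.
#'
#' @param path path of the YAML config file
#' @return \code{readRunConfig}: the resolved config list
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- defaultRunConfig()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(user)] <- user
  cfg
}

#' @rdname readRunConfig
#' @param config a config list (missing keys filled from defaults)
#' @export
writeRunConfig <- function(config, path) {
  cfg <- defaultRunConfig()
  cfg[names(config)] <- config
  yaml::write_yaml(cfg[!vapply(cfg, is.null, TRUE)], path)
  invisible(path)
}

#' Run the analysis pipeline end to end
#'
#' Executes the requested stages in dependency order inside a run directory:
#' \code{simulate} writes synthetic inputs (puncta image, two-channel image,
#' lambda stack, movie) as TIFF with ground-truth CSVs; \code{puncta}
#' thresholds and detects puncta and writes the per-punctum CSV plus a
#' density summary; \code{coloc} computes the tolerance-fraction and Pearson
#' statistics and writes the binary colocalization mask; \code{unmix} writes
#' the GFP and autofluorescence abundance images; \code{kymo} builds the
#' kymograph, tracks particles, classifies them and writes per-track and
#' transport summary CSVs. A machine-readable manifest (resolved config,
#' seed, package version, produced files) is written as JSON. A stage whose
#' input is neither configured nor produced by an earlier stage raises a
#' dependency error naming the missing stage.
#'
#' @param config a config list (see \code{\link{defaultRunConfig}}) or the
#'   path of a YAML config file
#' @param outDir run directory (created if needed)
#' @return the run directory, invisibly; side effect: files + manifest.json
#' @export
runPipeline <- function(config = defaultRunConfig(), outDir = tempfile("run")) {
  if (is.character(config) && length(config) == 1L)
    config <- readRunConfig(config)
  cfg <- defaultRunConfig()
  cfg[names(config)] <- config
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  produced <- character(0)
  emit <- function(path) { produced <<- c(produced, path); path }
  p <- function(f) file.path(outDir, f)
  stages <- cfg$stages

  img <- NULL; two <- NULL; stack <- NULL; movie <- NULL

  if ("simulate" %in% stages) {
    ispec <- simImageSpec(cfg$width_px, cfg$height_px, cfg$pixel_size_um,
                          cfg$n_puncta, cfg$punctum_sigma_um, cfg$amplitude,
                          cfg$background, cfg$noise_sd, cfg$seed)
    sim <- makePunctaImage(ispec)
    img <- sim$image
    writeImageTIFF(img, emit(p("puncta_image.tif")))
    utils::write.csv(sim$truth$puncta, emit(p("puncta_truth.csv")),
                     row.names = FALSE)

    two <- makeTwoChannelImage(ispec, cfg$coloc_fraction, cfg$offset_um)
    writeImageTIFF(two$ch1, emit(p("coloc_ch1.tif")))
    writeImageTIFF(two$ch2, emit(p("coloc_ch2.tif")))
    utils::write.csv(two$truth$puncta, emit(p("coloc_truth.csv")),
                     row.names = FALSE)

    ab <- matrix(0.5, 32, 32)
    ab[, 1:16] <- 1
    sl <- makeLambdaStack(ab, ab[, ncol(ab):1], noiseSd = cfg$lambda_noise_sd,
                          seed = cfg$seed, pixelSizeUm = cfg$pixel_size_um)
    stack <- sl$stack
    writeLambdaStackTIFF(stack, emit(p("lambda_stack.tif")))

    mspec <- simMovieSpec(frames = cfg$frames, frameRateHz = cfg$fps,
                          pixelSizeUm = cfg$pixel_size_um,
                          noiseSd = cfg$noise_sd, seed = cfg$seed)
    mv <- makeMovie(mspec)
    movie <- mv$movie
    writeTimeLapseTIFF(movie, emit(p("movie.tif")))
    tt <- data.frame(frame = seq_len(nrow(mv$truth$trajectoriesUm)),
                     mv$truth$trajectoriesUm)
    utils::write.csv(tt, emit(p("movie_truth.csv")), row.names = FALSE)
  }

  if ("puncta" %in% stages) {
    if (is.null(img)) {
      if (is.null(cfg$image_path))
        stop("dependency error: stage 'puncta' needs stage 'simulate' or an image_path")
      img <- readImageTIFF(cfg$image_path, cfg$pixel_size_um)
    }
    th <- autoThreshold(img, cfg$threshold_method, cfg$percentile)
    ps <- detectPuncta(th$mask, img, cfg$min_area, threshold = th$threshold)
    writePunctaCSV(ps, emit(p("puncta.csv")))
    utils::write.csv(data.frame(
      nPuncta = punctaCount(ps), threshold = th$threshold,
      densityPer100Um = punctaDensity(ps),
      integratedDensity = integratedDensity(img, th$mask)),
      emit(p("puncta_summary.csv")), row.names = FALSE)
  }

  if ("coloc" %in% stages) {
    if (is.null(two)) {
      stop("dependency error: stage 'coloc' needs stage 'simulate'")
    }
    m1 <- autoThreshold(two$ch1)$mask
    m2 <- autoThreshold(two$ch2)$mask
    tc <- toleranceColoc(two$ch1, two$ch2, m1, m2, cfg$tolerance)
    pr <- pearsonColoc(two$ch1, two$ch2, m1 & m2)
    writeImageTIFF(FluorImage(tc$mask * 1, pixelSize(two$ch1)),
                   emit(p("coloc_mask.tif")), fullScale = 1)
    utils::write.csv(data.frame(
      toleranceFraction = tc$fraction, nColocPx = tc$nColocPx,
      nCh1Px = tc$nCh1Px, pearsonR = pr$r, nJointPx = pr$nPx),
      emit(p("coloc_summary.csv")), row.names = FALSE)
  }

  if ("unmix" %in% stages) {
    if (is.null(stack)) {
      if (is.null(cfg$stack_path))
        stop("dependency error: stage 'unmix' needs stage 'simulate' or a stack_path")
      stack <- readLambdaStackTIFF(cfg$stack_path,
                                   pixelSizeUm = cfg$pixel_size_um)
    }
    u <- unmix(stack)
    writeImageTIFF(u$gfpAbundance, emit(p("gfp_abundance.tif")),
                   fullScale = max(1, max(intensities(u$gfpAbundance))))
    writeImageTIFF(u$autoAbundance, emit(p("auto_abundance.tif")),
                   fullScale = max(1, max(intensities(u$autoAbundance))))
    writeProfileCSV(gfpEmissionProfile(), emit(p("gfp_profile.csv")))
    writeProfileCSV(autofluorescenceProfile(), emit(p("auto_profile.csv")))
  }

  if ("kymo" %in% stages) {
    if (is.null(movie)) {
      if (is.null(cfg$movie_path))
        stop("dependency error: stage 'kymo' needs stage 'simulate' or a movie_path")
      movie <- readTimeLapseTIFF(cfg$movie_path, cfg$fps, cfg$pixel_size_um)
    }
    ky <- buildKymograph(movie)
    writeImageTIFF(FluorImage(intensities(ky), pixelSize(ky)),
                   emit(p("kymograph.tif")))
    tracks <- lapply(detectAndLink(ky),
                     classifyTrack, movePx = cfg$move_px,
                     stationaryFrames = cfg$stationary_frames)
    writeTracksCSV(tracks, emit(p("tracks.csv")))
    ts <- transportSummary(tracks, cfg$region_um,
                           dim(intensities(movie))[3] / frameRate(movie))
    utils::write.csv(data.frame(
      flux = ts$flux, nMobile = ts$nMobile, nStationary = ts$nStationary,
      nExcluded = ts$nExcluded,
      fractionAnterograde = ts$fractionAnterograde,
      fractionRetrograde = ts$fractionRetrograde,
      meanVelocityAnterograde = ts$velocityAnterograde[["mean"]],
      meanVelocityRetrograde = ts$velocityRetrograde[["mean"]]),
      emit(p("transport_summary.csv")), row.names = FALSE)
  }

  manifest <- list(
    package = "cordQuant",
    version = as.character(utils::packageVersion("cordQuant")),
    seed = cfg$seed,
    config = cfg[!vapply(cfg, is.null, TRUE)],
    files = basename(produced))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(outDir)
}
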