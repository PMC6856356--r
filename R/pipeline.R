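# End-to-end orchestration: YAML run configuration, simulate -> segment ->
# score -> summarize, with deterministic outputs and a self-describing
# manifest.

.configKeys <- list(
  top = c("seed", "pixel_size", "outdir", "scene", "gradient", "walkers",
          "owa", "fin", "glcm", "bins", "time_window", "normalization",
          "segmentation", "clusters"),
  scene = c("image_shape", "cell_radius", "membrane_thickness",
            "vesicle_count", "vesicle_sigma", "vesicle_min_dist",
            "vesicular_fraction", "diffuse_fraction", "dome_amplitude",
            "dome_sigma_frac", "rim_boost", "edge_offset", "edge_width",
            "background_level", "total_flux", "noise_model",
            "noise_sigma_frac"),
  gradient = c("decay_length", "n_cells", "max_distance", "margin_length"),
  walkers = c("n_tracks", "n_frames", "dt", "mean_speed", "speed_sd",
              "persistence", "bias_strength", "bias_range", "dwell_frames",
              "p_reverse", "speed_coupling", "start_distance"),
  glcm = c("n_levels", "offset", "symmetric"),
  bins = c("distance_width", "cos_width", "distance_max"),
  segmentation = c("threshold", "min_area_px"),
  clusters = c("min_area_um2", "wound_center", "half_width_um", "window")
)

.checkKeys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop("config error: unknown key(s) in ", where, ": ",
         paste(bad, collapse = ", "))
}

#' Read and validate a run configuration
#'
#' Loads a YAML configuration for the pipeline commands. Every analysis
#' parameter of the package is representable; unknown keys are rejected
#' with an error naming them, and a seed is mandatory.
#'
#' @param path path to a YAML file, or an already-parsed list.
#' @return validated configuration list (class \code{"RunConfig"}).
#' @export
readRunConfig <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  .checkKeys(cfg, .configKeys$top, "config")
  for (sec in c("scene", "gradient", "walkers", "glcm", "bins",
                "segmentation", "clusters"))
    if (!is.null(cfg[[sec]]))
      .checkKeys(cfg[[sec]], .configKeys[[sec]], sec)
  if (is.null(cfg$seed)) stop("config error: missing mandatory key: seed")
  if (is.null(cfg$pixel_size)) cfg$pixel_size <- 0.5
  if (is.null(cfg$outdir)) cfg$outdir <- "."
  class(cfg) <- c("RunConfig", "list")
  cfg
}

.polyFromConfig <- function(x, what) {
  if (is.null(x)) stop("config error: missing ", what, " polygon")
  if (is.character(x)) {
    if (!file.exists(x))
      stop("config error: ", what, " file not found: ", x)
    v <- utils::read.csv(x)
    owaPolygon(cbind(v$x_um, v$y_um))
  } else {
    owaPolygon(do.call(rbind, lapply(x, unlist)))
  }
}

.writePolygonCsv <- function(poly, name, path) {
  v <- owaVertices(poly)
  utils::write.csv(data.frame(name = name,
                              vertex_index = seq_len(nrow(v)),
                              x_um = v[, 1], y_um = v[, 2]),
                   path, row.names = FALSE)
}

.writeImageTiff <- function(img, path) {
  tiff::writeTIFF(pmin(pmax(img, 0), 65535) / 65535, path,
                  bits.per.sample = 16L, compression = "none")
}

.readImageTiff <- function(path) {
  im <- tiff::readTIFF(path)
  round(im * 65535)
}

.writeManifest <- function(cfg, outdir, files) {
  manifest <- list(config = unclass(cfg),
                   files = files,
                   config_hash = unname(tools::md5sum(
                     {tmp <- tempfile(); writeLines(
                       yaml::as.yaml(unclass(cfg)), tmp); tmp})))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

.sceneParamsFromConfig <- function(cfg) {
  sc <- cfg$scene
  args <- list(pixelSize = cfg$pixel_size, seed = cfg$seed)
  if (!is.null(sc)) {
    map <- c(image_shape = "imageShape", cell_radius = "cellRadius",
             membrane_thickness = "membraneThickness",
             vesicle_count = "vesicleCount", vesicle_sigma = "vesicleSigma",
             vesicle_min_dist = "vesicleMinDist",
             vesicular_fraction = "vesicularFraction",
             diffuse_fraction = "diffuseFraction",
             dome_amplitude = "domeAmplitude",
             dome_sigma_frac = "domeSigmaFrac", rim_boost = "rimBoost",
             edge_offset = "edgeOffset", edge_width = "edgeWidth",
             background_level = "backgroundLevel", total_flux = "totalFlux",
             noise_model = "noiseModel", noise_sigma_frac = "noiseSigmaFrac")
    for (k in names(sc)) args[[map[[k]]]] <- sc[[k]]
  }
  do.call(scenePhantomParams, args)
}

#' Simulate a scene and tracks to disk
#'
#' Renders the wound-gradient scene and simulates labelled walker tracks
#' from the configuration, writing the phantom image (16-bit TIFF), label
#' mask, per-cell ground truth CSV, tracks CSV, polygon CSVs, and a
#' manifest JSON carrying the full configuration and its hash. Outputs are
#' deterministic for a given configuration and seed.
#'
#' @param config a [readRunConfig()] list or YAML path.
#' @return (invisibly) the list of written file paths.
#' @export
runSimulate <- function(config) {
  cfg <- if (inherits(config, "RunConfig")) config else readRunConfig(config)
  outdir <- cfg$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  phantom <- .sceneParamsFromConfig(cfg)
  g <- cfg$gradient
  gp <- gradientSceneParams(
    decayLength = if (is.null(g$decay_length)) 200 else g$decay_length,
    nCells = if (is.null(g$n_cells)) 40L else g$n_cells,
    maxDistance = if (is.null(g$max_distance)) 500 else g$max_distance,
    marginLength = if (is.null(g$margin_length)) 400 else g$margin_length,
    seed = cfg$seed)
  scene <- renderGradientScene(gp, phantom)

  w <- cfg$walkers
  fin <- .polyFromConfig(cfg$fin, "fin")
  owa <- .polyFromConfig(cfg$owa, "owa")
  wp <- walkerParams(
    nTracks = if (is.null(w$n_tracks)) 100L else w$n_tracks,
    nFrames = if (is.null(w$n_frames)) 240L else w$n_frames,
    dt = if (is.null(w$dt)) 30 else w$dt,
    meanSpeed = if (is.null(w$mean_speed)) 8 else w$mean_speed,
    speedSd = if (is.null(w$speed_sd)) 2 else w$speed_sd,
    persistence = if (is.null(w$persistence)) 0.6 else w$persistence,
    biasStrength = if (is.null(w$bias_strength)) 4 else w$bias_strength,
    biasRange = if (is.null(w$bias_range)) 200 else w$bias_range,
    dwellFrames = if (is.null(w$dwell_frames)) 10L else w$dwell_frames,
    pReverse = if (is.null(w$p_reverse)) 0.3 else w$p_reverse,
    speedCoupling = if (is.null(w$speed_coupling)) 0 else w$speed_coupling,
    startDistance = w$start_distance,
    finPolygon = fin, seed = cfg$seed)
  tracks <- simulateTracks(wp, owa)

  files <- c(scene = file.path(outdir, "scene.tif"),
             labels = file.path(outdir, "scene_labels.tif"),
             truth = file.path(outdir, "scene_truth.csv"),
             margin = file.path(outdir, "wound_margin.csv"),
             tracks = file.path(outdir, "tracks.csv"),
             owa = file.path(outdir, "owa.csv"),
             fin = file.path(outdir, "fin.csv"))
  .writeImageTiff(scene$image, files["scene"])
  .writeImageTiff(scene$labels * (65535 / max(1, max(scene$labels))),
                  files["labels"])
  utils::write.csv(scene$cells, files["truth"], row.names = FALSE)
  utils::write.csv(data.frame(vertex_index = seq_len(nrow(scene$woundMargin)),
                              x_um = scene$woundMargin[, 1],
                              y_um = scene$woundMargin[, 2]),
                   files["margin"], row.names = FALSE)
  utils::write.csv(tracks, files["tracks"], row.names = FALSE)
  .writePolygonCsv(owa, "owa", files["owa"])
  .writePolygonCsv(fin, "fin", files["fin"])
  .writeManifest(cfg, outdir, as.list(files))
  invisible(files)
}

#' Score internalization on a simulated or measured scene
#'
#' Threshold-segments the scene image, scores the co-occurrence contrast of
#' every retained component, applies the configured normalization, assigns
#' distances from the wound margin and writes the per-cell table and the
#' binned gradient profile.
#'
#' @param config a [readRunConfig()] list or YAML path; expects
#'   \code{scene.tif} and \code{wound_margin.csv} in the output directory
#'   (as written by [runSimulate()]).
#' @return (invisibly) list with \code{cells} and \code{profile}
#'   data.frames.
#' @export
runInternalization <- function(config) {
  cfg <- if (inherits(config, "RunConfig")) config else readRunConfig(config)
  outdir <- cfg$outdir
  img <- .readImageTiff(file.path(outdir, "scene.tif"))
  margin <- utils::read.csv(file.path(outdir, "wound_margin.csv"))
  seg <- cfg$segmentation
  thr <- if (!is.null(seg$threshold)) seg$threshold else
    stats::median(img) + 3 * stats::mad(img)
  minArea <- if (is.null(seg$min_area_px)) 50L else seg$min_area_px
  masks <- thresholdSegment(img, thr, minAreaPx = minArea,
                            pixelSize = cfg$pixel_size)
  if (length(masks) == 0L) {
    warning("no cells segmented")
    empty <- data.frame()
    utils::write.csv(empty, file.path(outdir, "contrast_cells.csv"),
                     row.names = FALSE)
    return(invisible(list(cells = empty, profile = empty)))
  }
  glcm <- cfg$glcm
  cells <- contrastPerCell(
    img, masks,
    nLevels = if (is.null(glcm$n_levels)) 8L else glcm$n_levels,
    offset = if (is.null(glcm$offset)) c(0L, 1L) else unlist(glcm$offset),
    symmetric = isTRUE(glcm$symmetric))
  mode <- if (is.null(cfg$normalization)) "movie_max" else cfg$normalization
  cells <- normalizeContrast(cells, mode)
  cen <- t(vapply(masks[match(cells$cell_id,
                              vapply(masks, function(m) m@cellId,
                                     character(1)))],
                  maskCentroid, numeric(2)))
  marginXY <- cbind(margin$x_um, margin$y_um)
  cells$x_um <- cen[, 1]; cells$y_um <- cen[, 2]
  cells$distance_um <- distanceToPolyline(cen[, 1], cen[, 2], marginXY)
  bw <- if (is.null(cfg$bins$distance_width)) 25 else cfg$bins$distance_width
  prof <- gradientProfile(cen, cells$normalized_contrast, marginXY,
                          binWidthUm = bw,
                          maxDistanceUm = cfg$bins$distance_max)
  utils::write.csv(cells, file.path(outdir, "contrast_cells.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(unclass(prof))[
    c("bin_lo", "bin_hi", "mean", "sem", "n")],
    file.path(outdir, "contrast_profile.csv"), row.names = FALSE)
  invisible(list(cells = cells, profile = prof))
}

#' Run the trajectory analyses
#'
#' Loads the tracks and owa/fin polygons, classifies every track, computes
#' step records, the speed-distance and speed-cosine profiles,
#' straightness, and the cohort summary (category counts, net reverse
#' traffic, straightness quantiles), writing each as CSV/JSON.
#'
#' @param config a [readRunConfig()] list or YAML path; expects
#'   \code{tracks.csv}, \code{owa.csv} and \code{fin.csv} in the output
#'   directory.
#' @return (invisibly) list with \code{steps}, \code{classifications},
#'   \code{summary}.
#' @export
runTrajectories <- function(config) {
  cfg <- if (inherits(config, "RunConfig")) config else readRunConfig(config)
  outdir <- cfg$outdir
  trackPath <- file.path(outdir, "tracks.csv")
  if (!file.exists(trackPath))
    stop("config error: tracks file not found: ", trackPath)
  owaPath <- file.path(outdir, "owa.csv")
  if (!file.exists(owaPath))
    stop("config error: owa polygon file not found: ", owaPath)
  owa <- .polyFromConfig(owaPath, "owa")
  fin <- .polyFromConfig(file.path(outdir, "fin.csv"), "fin")
  tw <- cfg$time_window
  tracks <- loadTracks(trackPath, finPolygon = fin,
                       timeWindow = if (is.null(tw)) NULL else unlist(tw))
  cl <- classifyTracks(tracks, owa)
  steps <- stepRecords(tracks, owa, cl)
  dw <- if (is.null(cfg$bins$distance_width)) 25 else cfg$bins$distance_width
  dmax <- if (is.null(cfg$bins$distance_max))
    dw * ceiling(max(steps$d_t) / dw) else cfg$bins$distance_max
  cw <- if (is.null(cfg$bins$cos_width)) 0.25 else cfg$bins$cos_width
  profD <- speedVsDistance(steps, cl, binEdges = seq(0, dmax, by = dw))
  profC <- speedVsCosine(steps, binEdges = seq(-1, 1, by = cw))
  straight <- trackStraightness(tracks, owa)
  nrt <- netReverseTraffic(cl)
  sVals <- straight$straightness[!straight$excluded]
  summary <- list(
    n_tracks = length(unique(tracks$track_id)),
    categories = as.list(table(cl$category)),
    net_reverse_traffic = nrt,
    straightness_quantiles = if (length(sVals))
      as.list(stats::quantile(sVals, c(0.25, 0.5, 0.75))) else NULL)
  utils::write.csv(steps, file.path(outdir, "steps.csv"), row.names = FALSE)
  utils::write.csv(cl, file.path(outdir, "classifications.csv"),
                   row.names = FALSE)
  utils::write.csv(profD, file.path(outdir, "speed_vs_distance.csv"),
                   row.names = FALSE)
  utils::write.csv(profC, file.path(outdir, "speed_vs_cosine.csv"),
                   row.names = FALSE)
  utils::write.csv(straight, file.path(outdir, "straightness.csv"),
                   row.names = FALSE)
  jsonlite::write_json(summary, file.path(outdir, "cohort_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(steps = steps, classifications = cl, summary = summary))
}

#' Run the cluster statistics
#'
#' Computes recruitment counts and the filtered mean cluster size from the
#' label image written by [runSimulate()] (one frame in the simulated
#' case).
#'
#' @param config a [readRunConfig()] list or YAML path.
#' @return (invisibly) list with \code{recruitment} and \code{cluster}.
#' @export
runClusters <- function(config) {
  cfg <- if (inherits(config, "RunConfig")) config else readRunConfig(config)
  outdir <- cfg$outdir
  truth <- utils::read.csv(file.path(outdir, "scene_truth.csv"))
  cc <- cfg$clusters
  wc <- if (is.null(cc$wound_center)) c(0, 200) else unlist(cc$wound_center)
  hw <- if (is.null(cc$half_width_um)) 100 else cc$half_width_um
  rec <- recruitmentCount(truth[, c("x_um", "y_um")], wc, hw)
  img <- .readImageTiff(file.path(outdir, "scene.tif"))
  seg <- cfg$segmentation
  thr <- if (!is.null(seg$threshold)) seg$threshold else
    stats::median(img) + 3 * stats::mad(img)
  masks <- thresholdSegment(img, thr, pixelSize = cfg$pixel_size)
  records <- data.frame(
    frame = 1L,
    area_um2 = vapply(masks, areaUm2, numeric(1)))
  cs <- clusterSize(records,
                    minAreaUm2 = if (is.null(cc$min_area_um2)) 60 else
                      cc$min_area_um2)
  out <- list(recruitment = rec, cluster = cs)
  jsonlite::write_json(out, file.path(outdir, "cluster_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out)
}

#' Run the full pipeline
#'
#' \code{simulate -> internalization -> trajectories -> clusters} into one
#' output directory. With a fixed configuration and seed, every data output
#' is byte-identical across runs.
#'
#' @param config a [readRunConfig()] list or YAML path.
#' @return (invisibly) the output directory.
#' @export
runAll <- function(config) {
  cfg <- if (inherits(config, "RunConfig")) config else readRunConfig(config)
  runSimulate(cfg)
  runInternalization(cfg)
  runTrajectories(cfg)
  runClusters(cfg)
  invisible(cfg$outdir)
}
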