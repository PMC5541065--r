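# Full-transect orchestration: one call runs colour rendering, reference
# correction, index maps, topography and classification, and persists every
# artifact with a manifest recording inputs, seeds and checksums.

#' Assemble a transect run configuration
#'
#' @param cube Path to the ENVI header (or binary stem) of the transect cube.
#' @param annotations Path to the annotation JSON (must include a
#'   `"Reference"` region for the board).
#' @param track Path to the sensor-track CSV, or `NULL` to skip topography.
#' @param transect_length Transect length in m (for the topographic profile).
#' @param indices Character vector of index-registry names to map.
#' @param algorithms Classifier algorithms to run.
#' @param modes Feature modes to run (`"hsi"`, `"rgb"`).
#' @param board_albedo Albedo assigned to the reference board.
#' @param seed Run seed (split + perceptron init).
#' @param outdir Output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(cube, annotations, track = NULL, transect_length = NULL,
                       indices = c("chl_670", "coral_rededge_700",
                                   "chromo_580", "phyco_605"),
                       algorithms = c("perceptron", "mahalanobis",
                                      "svm_linear"),
                       modes = c("hsi", "rgb"), board_albedo = 1.0,
                       seed = 0L, outdir = "benthoscan_out") {
  for (p in c(cube, annotations, track))
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  structure(list(cube = cube, annotations = annotations, track = track,
                 transect_length = transect_length, indices = indices,
                 algorithms = algorithms, modes = modes,
                 board_albedo = board_albedo, seed = as.integer(seed),
                 outdir = outdir),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML or JSON file with the fields of `run_config()`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is needed for YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, cfg)
}

#' Run a full transect analysis
#'
#' Stages: read cube -> colour render -> board reflectance correction ->
#' true-colour render -> derivative index maps -> topographic profile and
#' rugosity -> (per algorithm x feature mode) stratified 75/25 split, train,
#' validate, full-image map. Every artifact is listed in `manifest.json`
#' together with input checksums, the run seed and per-stage timings; a
#' failing stage aborts with its name.
#'
#' @param config A `run_config` (or a path accepted by [read_run_config()]).
#' @return Invisibly, the manifest list.
#' @export
run_transect <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    seed = config$seed,
    inputs = lapply(
      Filter(Negate(is.null),
             list(cube = config$cube, annotations = config$annotations,
                  track = config$track)),
      function(p) list(path = p, md5 = unname(tools::md5sum(p)))),
    artifacts = list(), timings = list(), qc = list())
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    manifest$timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  art <- function(name, path) {
    manifest$artifacts[[name]] <<- list(path = path,
                                        md5 = unname(tools::md5sum(path)))
  }
  out <- function(...) file.path(config$outdir, ...)

  cube <- stage("read_cube", read_envi(config$cube))
  ann <- stage("read_annotations", read_annotations(config$annotations))

  stage("render_raw", {
    write_color_png(to_rgb(cube), out("scene_raw.png"))
  })
  art("scene_raw", out("scene_raw.png"))

  rcube <- stage("reflectance", {
    board <- board_spectrum(cube, ann)
    manifest$qc$board_cv_max <- max(board$cv)
    rc <- to_reflectance(cube, board, board_albedo = config$board_albedo)
    manifest$qc$n_out_of_gamut <- rc$qc$n_out_of_gamut
    write_envi(rc, out("reflectance.dat"), data_type = "float32")
    rc
  })
  art("reflectance", out("reflectance.dat.hdr"))
  stage("render_true_color", {
    write_color_png(true_color(rcube), out("scene_true_color.png"))
  })
  art("scene_true_color", out("scene_true_color.png"))

  for (ix in config$indices) {
    stage(paste0("index_", ix), {
      write_index_map(index_map(rcube, ix), out(paste0("index_", ix)))
    })
    art(paste0("index_", ix), out(paste0("index_", ix, ".png")))
  }

  if (!is.null(config$track)) {
    stage("topography", {
      track <- read_sensor_track(config$track)
      len <- if (!is.null(config$transect_length)) config$transect_length
             else nrow(cube$values) * 0.02
      prof <- fuse_bottom_profile(track, len)
      write_topo_summary(prof, out("topo"))
    })
    art("topo", out("topo.json"))
  }

  labels <- stage("rasterize", rasterize_annotations(ann, dim(cube$values)[1:2]))
  for (mode in config$modes) {
    ds <- stage(paste0("extract_", mode),
                extract_dataset(cube, labels, mode = mode))
    sp <- split_dataset(ds, 0.75, seed = config$seed)
    for (alg in config$algorithms) {
      key <- paste(alg, mode, sep = "_")
      stage(paste0("classify_", key), {
        model <- train_classifier(sp$train, alg, seed = config$seed)
        rep <- evaluate(model, sp$validation)
        write_metrics(rep, out(paste0("metrics_", key)))
        map <- predict_map(model, cube)
        write_label_png(map, out(paste0("map_", key, ".png")))
        manifest$qc[[paste0("accuracy_", key)]] <- rep$accuracy
      })
      art(paste0("metrics_", key), out(paste0("metrics_", key, ".json")))
      art(paste0("map_", key), out(paste0("map_", key, ".png")))
    }
  }

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
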