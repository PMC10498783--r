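#' @include AllClasses.R
NULL

#' Load a well image from TIFF
#'
#' Reads an 8-bit TIFF. RGB images become H x W x 3 frames; grayscale images
#' are promoted to three identical channels (so grayscale conversion is a
#' round trip); an alpha channel, if present, is dropped. Images deeper than
#' 8 bits per sample are rejected with an error naming the file.
#'
#' @param path TIFF file path.
#' @param pixelScale calibration in pixels per micrometre attached to the
#'   frame (default 0.3525, the reference whole-well scan scale).
#' @return an [RGBFrame-class].
#' @export
loadFrame <- function(path, pixelScale = 0.3525) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path))
  img <- tryCatch(tiff::readTIFF(path, info = TRUE),
                  error = function(e) {
                    stop(sprintf("cannot read '%s': %s", path, conditionMessage(e)))
                  })
  bits <- attr(img, "bits.per.sample")
  if (!is.null(bits) && any(bits != 8L)) {
    stop(sprintf("unsupported bit depth in '%s': %s bits per sample (need 8)",
                 path, paste(unique(bits), collapse = "/")))
  }
  # values come back rescaled to [0, 1]; map back to 8-bit levels exactly
  img <- round(img * 255)
  d <- dim(img)
  if (length(d) == 2L) {
    img <- array(rep(as.integer(img), 3L), dim = c(d[1], d[2], 3L))
  } else if (d[3] >= 3L) {
    img <- img[, , 1:3, drop = FALSE]
  } else {
    stop(sprintf("unsupported channel count in '%s': %d", path, d[3]))
  }
  rgbFrame(img, pixelScale)
}

#' Write a frame as 24-bit RGB TIFF
#'
#' @param frame an [RGBFrame-class].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeFrame <- function(frame, path) {
  stopifnot(is(frame, "RGBFrame"))
  tiff::writeTIFF(frame@data / 255, path, bits.per.sample = 8L)
  invisible(path)
}

#' Discover a time-lapse series on disk
#'
#' Scans a directory for frames matching a filename pattern with two capture
#' groups, well label and time index (default \code{<well>_t<index>.tif}),
#' and builds a manifest sorted by well and index. Gaps in a well's index
#' sequence are reported as warnings, not errors, so partially acquired
#' series remain analysable.
#'
#' @param directory directory containing the TIFF frames.
#' @param pattern regular expression with capture group 1 = well label and
#'   group 2 = integer time index.
#' @param frameIntervalH hours between consecutive indices (default 3).
#' @return data.frame manifest with columns \code{well_id},
#'   \code{time_index}, \code{time_h}, \code{path}.
#' @export
discoverSeries <- function(directory, pattern = "^(.+)_t(\\d+)\\.tiff?$",
                           frameIntervalH = 3) {
  stopifnot(dir.exists(directory), frameIntervalH > 0)
  files <- list.files(directory)
  hits <- regmatches(files, regexec(pattern, files))
  ok <- vapply(hits, length, integer(1)) == 3L
  if (!any(ok)) {
    stop(sprintf("no files matching '%s' under '%s'", pattern, directory))
  }
  man <- data.frame(
    well_id = vapply(hits[ok], `[`, character(1), 2L),
    time_index = as.integer(vapply(hits[ok], `[`, character(1), 3L)),
    path = file.path(directory, files[ok])
  )
  if (anyDuplicated(man[, c("well_id", "time_index")])) {
    stop("duplicate (well, time index) entries in directory")
  }
  man$time_h <- man$time_index * frameIntervalH
  man <- man[order(man$well_id, man$time_index),
             c("well_id", "time_index", "time_h", "path")]
  rownames(man) <- NULL
  for (w in unique(man$well_id)) {
    idx <- man$time_index[man$well_id == w]
    missing <- setdiff(seq(min(idx), max(idx)), idx)
    if (length(missing)) {
      warning(sprintf("well '%s': missing time indices %s", w,
                      paste(missing, collapse = ", ")))
    }
  }
  man
}

#' Run the segmentation pipeline over a whole manifest
#'
#' Applies [runPipeline()] with one shared parameter set to every manifest
#' entry (universal parameters keep wells comparable). Per-frame warnings are
#' logged with well and time context; a failing frame is recorded in the
#' failure table and the batch continues.
#'
#' @param manifest data.frame from [discoverSeries()] (columns
#'   \code{well_id}, \code{time_h}, \code{path}).
#' @param params a [pipelineParams()] list shared across all frames.
#' @param pixelScale calibration in px/um applied to every frame.
#' @param outCsv optional path; when given, the results table is written
#'   there as UTF-8 CSV with '.' decimal separator.
#' @return list with \code{results} (data.frame: well_id, time_h, area_um2,
#'   area_mm2, n_components, warnings) and \code{failures} (data.frame:
#'   well_id, time_h, path, error).
#' @export
runBatch <- function(manifest, params = pipelineParams(),
                     pixelScale = 0.3525, outCsv = NULL) {
  stopifnot(is.data.frame(manifest),
            all(c("well_id", "time_h", "path") %in% names(manifest)))
  results <- list()
  failures <- list()
  for (i in seq_len(nrow(manifest))) {
    wid <- manifest$well_id[i]
    th <- manifest$time_h[i]
    flags <- character(0)
    res <- tryCatch(
      withCallingHandlers(
        runPipeline(loadFrame(manifest$path[i], pixelScale), params),
        warning = function(w) {
          flags <<- c(flags, conditionMessage(w))
          message(sprintf("[%s t=%gh] warning: %s", wid, th,
                          conditionMessage(w)))
          invokeRestart("muffleWarning")
        }
      ),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      message(sprintf("[%s t=%gh] FAILED: %s", wid, th, conditionMessage(res)))
      failures[[length(failures) + 1L]] <- data.frame(
        well_id = wid, time_h = th, path = manifest$path[i],
        error = conditionMessage(res)
      )
      next
    }
    results[[length(results) + 1L]] <- data.frame(
      well_id = wid, time_h = th,
      area_um2 = areaUm2(res), area_mm2 = areaMm2(res),
      n_components = nComponents(res),
      warnings = paste(unique(c(resultFlags(res), flags)), collapse = "; ")
    )
  }
  results <- if (length(results)) {
    do.call(rbind, c(results, list(make.row.names = FALSE)))
  } else {
    data.frame(well_id = character(), time_h = numeric(),
               area_um2 = numeric(), area_mm2 = numeric(),
               n_components = integer(), warnings = character())
  }
  failures <- if (length(failures)) {
    do.call(rbind, c(failures, list(make.row.names = FALSE)))
  } else {
    data.frame(well_id = character(), time_h = numeric(),
               path = character(), error = character())
  }
  if (!is.null(outCsv)) {
    utils::write.csv(results, outCsv, row.names = FALSE, fileEncoding = "UTF-8")
  }
  list(results = results, failures = failures)
}

#' Read a plate layout mapping wells to treatments
#'
#' YAML file with a top-level \code{wells} mapping (or a bare mapping) of
#' well label to treatment label.
#'
#' @param path YAML file path.
#' @return data.frame with columns \code{well_id}, \code{treatment}.
#' @export
readPlateLayout <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$wells)) y <- y$wells
  if (length(y) == 0L) stop("plate layout is empty")
  data.frame(
    well_id = names(y),
    treatment = vapply(y, as.character, character(1)),
    row.names = NULL
  )
}

#' Read an analysis configuration file
#'
#' YAML key-value file overriding analysis defaults: \code{pixel_scale},
#' \code{crop_fraction}, \code{erode_iterations}, \code{min_um2},
#' \code{max_um2}, \code{frame_interval_h}, \code{adjust}
#' (sidak/bonferroni), \code{alpha}, and an optional \code{geometry} block
#' with the insert dimensions. Missing keys keep their defaults.
#'
#' @param path YAML file path, or NULL for pure defaults.
#' @return named list of configuration values, with \code{geometry} as an
#'   [InsertGeometry-class].
#' @export
readConfig <- function(path = NULL) {
  defaults <- list(
    pixel_scale = 0.3525, crop_fraction = 0.8, erode_iterations = 1L,
    min_um2 = 1e5, max_um2 = 7e8, frame_interval_h = 3,
    adjust = "sidak", alpha = 0.05,
    geometry = insertGeometry()
  )
  if (is.null(path)) return(defaults)
  y <- yaml::read_yaml(path)
  if (!is.null(y$geometry)) {
    g <- y$geometry
    pick <- function(key, def) if (is.null(g[[key]])) def else g[[key]]
    defaults$geometry <- insertGeometry(
      topLengthMm = pick("top_length_mm", 16),
      topHeightMm = pick("top_height_mm", 3),
      midDiameterMm = pick("mid_diameter_mm", 9),
      midHeightMm = pick("mid_height_mm", 10),
      bottomDiameterMm = pick("bottom_diameter_mm", 5),
      bottomHeightMm = pick("bottom_height_mm", 4)
    )
    y$geometry <- NULL
  }
  for (key in names(y)) defaults[[key]] <- y[[key]]
  defaults
}
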