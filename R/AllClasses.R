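#' @include AllGenerics.R
NULL

#' InsertGeometry: parametric model of the three-section migration insert
#'
#' The insert that stamps the exclusion zone has three stacked sections: a
#' plus-sign shaped top (allows pipette access and imaging while in place), a
#' wider middle cylinder (weight and support) and a narrow bottom cylinder
#' whose footprint defines the circular cell-free zone. All dimensions are in
#' millimetres, the unit in which the device is specified; conversion to
#' micrometres happens only at the image boundary.
#'
#' @slot topLengthMm arm span of the plus-sign top section (mm).
#' @slot topHeightMm height of the top section (mm).
#' @slot midDiameterMm diameter of the middle cylinder (mm).
#' @slot midHeightMm height of the middle cylinder (mm).
#' @slot bottomDiameterMm diameter of the bottom foot; this is the diameter
#'   of the cell-free zone it stamps (mm).
#' @slot bottomHeightMm height of the bottom foot (mm).
#'
#' @seealso [insertGeometry()], [totalHeight()], [theoreticalZoneArea()]
#' @export
setClass("InsertGeometry",
  representation(
    topLengthMm = "numeric",
    topHeightMm = "numeric",
    midDiameterMm = "numeric",
    midHeightMm = "numeric",
    bottomDiameterMm = "numeric",
    bottomHeightMm = "numeric"
  )
)

setValidity("InsertGeometry", function(object) {
  dims <- c(
    object@topLengthMm, object@topHeightMm, object@midDiameterMm,
    object@midHeightMm, object@bottomDiameterMm, object@bottomHeightMm
  )
  if (length(dims) != 6L || any(!is.finite(dims))) {
    return("all six dimensions must be finite scalars")
  }
  if (any(dims <= 0)) {
    return("all insert dimensions must be strictly positive")
  }
  if (object@bottomDiameterMm >= object@midDiameterMm) {
    return("bottom (foot) diameter must be smaller than the middle cylinder diameter")
  }
  TRUE
})

#' Construct an InsertGeometry
#'
#' Defaults are the dimensions of the reference insert for 24-well plates:
#' 16 mm plus-sign span, section heights 3 + 10 + 4 = 17 mm, 9 mm middle
#' cylinder, 5 mm foot (the stamped cell-free zone diameter).
#'
#' @param topLengthMm,topHeightMm,midDiameterMm,midHeightMm,bottomDiameterMm,bottomHeightMm
#'   section dimensions in millimetres; see [InsertGeometry-class].
#' @return an [InsertGeometry-class] object.
#' @examples
#' geom <- insertGeometry()
#' totalHeight(geom)                        # 17 mm
#' theoreticalZoneArea(geom@bottomDiameterMm)  # 19.63 mm^2
#' @export
insertGeometry <- function(topLengthMm = 16, topHeightMm = 3,
                           midDiameterMm = 9, midHeightMm = 10,
                           bottomDiameterMm = 5, bottomHeightMm = 4) {
  new("InsertGeometry",
    topLengthMm = topLengthMm, topHeightMm = topHeightMm,
    midDiameterMm = midDiameterMm, midHeightMm = midHeightMm,
    bottomDiameterMm = bottomDiameterMm, bottomHeightMm = bottomHeightMm
  )
}

#' RGBFrame: a single calibrated 8-bit RGB well image
#'
#' Raw pipeline input: one timepoint of one well as a height x width x 3
#' array of integer intensities in 0-255, plus the pixel scale in
#' pixels per micrometre.
#'
#' @slot data integer array, height x width x 3, values in 0-255.
#' @slot pixelScale pixels per micrometre (> 0).
#' @export
setClass("RGBFrame",
  representation(data = "array", pixelScale = "numeric")
)

setValidity("RGBFrame", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L || dim(d)[3] != 3L) {
    return("data must be a height x width x 3 array")
  }
  if (min(d) < 0 || max(d) > 255) {
    return("intensities must lie in [0, 255]")
  }
  if (length(object@pixelScale) != 1L || !is.finite(object@pixelScale) ||
      object@pixelScale <= 0) {
    return("pixelScale must be a single positive number")
  }
  TRUE
})

#' @param data integer array, height x width x 3.
#' @param pixelScale pixels per micrometre.
#' @rdname RGBFrame-class
#' @export
rgbFrame <- function(data, pixelScale) {
  storage.mode(data) <- "integer"
  new("RGBFrame", data = data, pixelScale = pixelScale)
}

#' GrayFrame: a single calibrated 8-bit grayscale image
#'
#' Intermediate of the segmentation chain: integer intensities 0-255 with the
#' pixel scale carried along.
#'
#' @slot intensities integer matrix, values in 0-255.
#' @slot pixelScale pixels per micrometre (> 0).
#' @export
setClass("GrayFrame",
  representation(intensities = "matrix", pixelScale = "numeric")
)

setValidity("GrayFrame", function(object) {
  v <- object@intensities
  if (!is.numeric(v)) return("intensities must be numeric")
  if (min(v) < 0 || max(v) > 255) return("intensities must lie in [0, 255]")
  if (length(object@pixelScale) != 1L || !is.finite(object@pixelScale) ||
      object@pixelScale <= 0) {
    return("pixelScale must be a single positive number")
  }
  TRUE
})

#' @param intensities integer matrix in 0-255.
#' @param pixelScale pixels per micrometre.
#' @rdname GrayFrame-class
#' @export
grayFrame <- function(intensities, pixelScale) {
  storage.mode(intensities) <- "integer"
  new("GrayFrame", intensities = intensities, pixelScale = pixelScale)
}

#' BinaryMask: a calibrated binary image whose foreground is the cell-free
#' region
#'
#' Module-wide polarity contract: \code{TRUE} pixels are the cell-free
#' candidate region (not the cells). Every morphological operation in the
#' package operates on this polarity.
#'
#' @slot foreground logical matrix.
#' @slot pixelScale pixels per micrometre (> 0).
#' @export
setClass("BinaryMask",
  representation(foreground = "matrix", pixelScale = "numeric")
)

setValidity("BinaryMask", function(object) {
  if (!is.logical(object@foreground)) return("foreground must be logical")
  if (length(object@pixelScale) != 1L || !is.finite(object@pixelScale) ||
      object@pixelScale <= 0) {
    return("pixelScale must be a single positive number")
  }
  TRUE
})

#' @param foreground logical matrix (TRUE = cell-free).
#' @param pixelScale pixels per micrometre.
#' @rdname BinaryMask-class
#' @export
binaryMask <- function(foreground, pixelScale) {
  new("BinaryMask", foreground = foreground, pixelScale = pixelScale)
}

#' AreaResult: calibrated cell-free area of one frame
#'
#' Result of particle analysis on a segmented frame: the total calibrated
#' area of foreground components surviving the size filter, in both square
#' micrometres and square millimetres, the number of surviving components,
#' the mask of their union, and any warning flags raised along the way.
#'
#' @slot areaUm2 total surviving area in square micrometres.
#' @slot areaMm2 the same area in square millimetres (areaUm2 / 1e6).
#' @slot nComponents number of components within the size range.
#' @slot componentMask [BinaryMask-class] of the union of surviving components.
#' @slot flags character vector of warning flags (empty when clean).
#' @slot stages named list of intermediate stage objects when the pipeline is
#'   run with \code{keepStages = TRUE} (empty otherwise).
#'
#' @export
setClass("AreaResult",
  representation(
    areaUm2 = "numeric", areaMm2 = "numeric", nComponents = "integer",
    componentMask = "BinaryMask", flags = "character", stages = "list"
  )
)

setValidity("AreaResult", function(object) {
  if (object@areaUm2 < 0) return("area cannot be negative")
  if (abs(object@areaMm2 - object@areaUm2 / 1e6) >
      1e-9 * max(1, object@areaUm2 / 1e6)) {
    return("areaMm2 must equal areaUm2 / 1e6")
  }
  if (object@nComponents < 0L) return("component count cannot be negative")
  TRUE
})

#' SimConfig: parameters of the synthetic exclusion-zone assay
#'
#' Describes one simulated well: geometry and optics (zone diameter, pixel
#' scale, image margin), imaging cadence, front dynamics (signed velocity and
#' a lag phase), and the appearance model of the confluent monolayer
#' (polygonal cell mosaic with bright borders), debris, illumination gradient
#' and sensor noise. All randomness derives from \code{rngSeed}.
#'
#' Front dynamics: the cell-free disc radius follows
#' \code{r(t) = max(0, r0 - v * max(0, t - lag))} in micrometres, so a
#' positive velocity closes the zone and a negative one lets it grow
#' (inhibitor regime, where the relative cell-free area exceeds 100%).
#'
#' @slot zoneDiameterMm nominal stamped zone diameter (mm), default 5.
#' @slot pixelScale pixels per micrometre, default 0.3525.
#' @slot frameIntervalH imaging interval (h), default 3.
#' @slot durationH total imaging duration (h), default 96; must be an integer
#'   multiple of the interval.
#' @slot frontVelocityUmPerH signed front speed (um/h); positive = closure.
#' @slot frontLagH quiescent phase before the front starts moving (h),
#'   default 24.
#' @slot textureCellDiameterUm monolayer cell diameter (um), default 30.
#' @slot textureContrast contrast of the cell mosaic in 0-1, default 0.5.
#' @slot debrisDensityPerMm2 bright speck density inside the zone, default 0.5.
#' @slot illuminationGradient relative lateral illumination slope 0-1,
#'   default 0.1.
#' @slot noiseSd additive Gaussian noise SD in gray levels, default 2.
#' @slot imageMarginMm monolayer margin rendered around the zone (mm),
#'   default 0.75.
#' @slot rngSeed integer seed driving all randomness.
#' @export
setClass("SimConfig",
  representation(
    zoneDiameterMm = "numeric", pixelScale = "numeric",
    frameIntervalH = "numeric", durationH = "numeric",
    frontVelocityUmPerH = "numeric", frontLagH = "numeric",
    textureCellDiameterUm = "numeric", textureContrast = "numeric",
    debrisDensityPerMm2 = "numeric", illuminationGradient = "numeric",
    noiseSd = "numeric", imageMarginMm = "numeric", rngSeed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  if (object@zoneDiameterMm <= 0) return("zone diameter must be positive")
  if (object@pixelScale <= 0) return("pixel scale must be positive")
  if (object@frameIntervalH <= 0 || object@durationH < 0) {
    return("interval must be positive and duration non-negative")
  }
  k <- object@durationH / object@frameIntervalH
  if (abs(k - round(k)) > 1e-9) {
    return("duration must be an integer multiple of the frame interval")
  }
  if (object@frontLagH < 0) return("front lag must be non-negative")
  if (object@textureCellDiameterUm <= 0) return("cell diameter must be positive")
  if (object@textureContrast < 0 || object@textureContrast > 1) {
    return("texture contrast must lie in [0, 1]")
  }
  if (object@debrisDensityPerMm2 < 0) return("debris density must be >= 0")
  if (object@illuminationGradient < 0 || object@illuminationGradient > 1) {
    return("illumination gradient must lie in [0, 1]")
  }
  if (object@noiseSd < 0) return("noise SD must be >= 0")
  if (object@imageMarginMm < 0) {
    return("image must contain the full zone plus a non-negative margin")
  }
  TRUE
})

#' Construct a SimConfig
#'
#' Defaults emulate the reference assay: a 5 mm zone imaged at
#' 0.3525 pixels/um every 3 h for 96 h, a 24 h quiescent phase before the
#' front moves, 30 um monolayer cells at contrast 0.5, sparse debris, a mild
#' lateral illumination gradient and 2 gray levels of sensor noise.
#'
#' @param zoneDiameterMm,pixelScale,frameIntervalH,durationH see
#'   [SimConfig-class].
#' @param frontVelocityUmPerH signed front speed in um/h (positive = closure).
#' @param frontLagH,textureCellDiameterUm,textureContrast see
#'   [SimConfig-class].
#' @param debrisDensityPerMm2,illuminationGradient,noiseSd,imageMarginMm see
#'   [SimConfig-class].
#' @param rngSeed integer seed for all randomness.
#' @return a [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(frontVelocityUmPerH = treatmentPresets()[["egf"]])
#' @export
simConfig <- function(zoneDiameterMm = 5, pixelScale = 0.3525,
                      frameIntervalH = 3, durationH = 96,
                      frontVelocityUmPerH = 2, frontLagH = 24,
                      textureCellDiameterUm = 30, textureContrast = 0.5,
                      debrisDensityPerMm2 = 0.5, illuminationGradient = 0.1,
                      noiseSd = 2, imageMarginMm = 0.75, rngSeed = 1L) {
  new("SimConfig",
    zoneDiameterMm = zoneDiameterMm, pixelScale = pixelScale,
    frameIntervalH = frameIntervalH, durationH = durationH,
    frontVelocityUmPerH = frontVelocityUmPerH, frontLagH = frontLagH,
    textureCellDiameterUm = textureCellDiameterUm,
    textureContrast = textureContrast,
    debrisDensityPerMm2 = debrisDensityPerMm2,
    illuminationGradient = illuminationGradient,
    noiseSd = noiseSd, imageMarginMm = imageMarginMm,
    rngSeed = as.integer(rngSeed)
  )
}

#' WellSeries: a simulated time-lapse of one well
#'
#' @slot wellId well label.
#' @slot timesH acquisition times in hours.
#' @slot frames list of [RGBFrame-class], one per time.
#' @slot config the [SimConfig-class] the series was generated from.
#' @export
setClass("WellSeries",
  representation(
    wellId = "character", timesH = "numeric", frames = "list",
    config = "SimConfig"
  )
)

#' GroundTruth: the known truth behind a simulated series
#'
#' @slot masks list of [BinaryMask-class] truth masks (TRUE = cell-free).
#' @slot table data.frame with columns \code{frame}, \code{time_h},
#'   \code{true_area_mm2}, \code{true_percent}.
#' @slot tracks data.frame of simulated cell tracks
#'   (\code{cell_id, time_h, x_um, y_um}), possibly empty.
#' @export
setClass("GroundTruth",
  representation(masks = "list", table = "data.frame", tracks = "data.frame")
)

## ---- accessors & show methods -------------------------------------------

#' @describeIn RGBFrame-class pixel scale in px/um.
#' @export
setMethod("pixelScale", "RGBFrame", function(x) x@pixelScale)

#' @describeIn GrayFrame-class pixel scale in px/um.
#' @export
setMethod("pixelScale", "GrayFrame", function(x) x@pixelScale)

#' @describeIn BinaryMask-class pixel scale in px/um.
#' @export
setMethod("pixelScale", "BinaryMask", function(x) x@pixelScale)

#' Raw pixel data of a frame
#'
#' @param x an [RGBFrame-class] or [GrayFrame-class].
#' @return the integer array (RGB) or matrix (gray) of intensities.
#' @export
setMethod("frameData", "RGBFrame", function(x) x@data)

#' @rdname frameData
#' @export
setMethod("frameData", "GrayFrame", function(x) x@intensities)

#' Logical foreground grid of a mask
#'
#' @param x a [BinaryMask-class].
#' @return logical matrix, TRUE = cell-free foreground.
#' @export
setMethod("maskData", "BinaryMask", function(x) x@foreground)

#' @describeIn AreaResult-class area in square micrometres.
#' @param x an AreaResult.
#' @export
setMethod("areaUm2", "AreaResult", function(x) x@areaUm2)

#' @describeIn AreaResult-class area in square millimetres.
#' @export
setMethod("areaMm2", "AreaResult", function(x) x@areaMm2)

#' @describeIn AreaResult-class number of components inside the size range.
#' @export
setMethod("nComponents", "AreaResult", function(x) x@nComponents)

#' @describeIn AreaResult-class mask of the union of surviving components.
#' @export
setMethod("componentMask", "AreaResult", function(x) x@componentMask)

#' @describeIn AreaResult-class warning flags accumulated during analysis.
#' @export
setMethod("resultFlags", "AreaResult", function(x) x@flags)

setMethod("show", "InsertGeometry", function(object) {
  cat("InsertGeometry (mm):\n",
    sprintf("  top    %g x %g (plus-sign span x height)\n",
            object@topLengthMm, object@topHeightMm),
    sprintf("  middle d=%g h=%g\n", object@midDiameterMm, object@midHeightMm),
    sprintf("  bottom d=%g h=%g (zone diameter %g mm)\n",
            object@bottomDiameterMm, object@bottomHeightMm,
            object@bottomDiameterMm),
    sprintf("  total height %g mm; theoretical zone area %.2f mm^2\n",
            totalHeight(object),
            theoreticalZoneArea(object@bottomDiameterMm)),
    sep = ""
  )
})

setMethod("show", "RGBFrame", function(object) {
  d <- dim(object@data)
  cat(sprintf("RGBFrame %d x %d x 3, %.4f px/um (%.2f x %.2f mm)\n",
              d[1], d[2], object@pixelScale,
              d[1] / object@pixelScale / 1000,
              d[2] / object@pixelScale / 1000))
})

setMethod("show", "GrayFrame", function(object) {
  d <- dim(object@intensities)
  cat(sprintf("GrayFrame %d x %d, %.4f px/um, intensity range [%d, %d]\n",
              d[1], d[2], object@pixelScale,
              min(object@intensities), max(object@intensities)))
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@foreground)
  cat(sprintf(
    "BinaryMask %d x %d, %.4f px/um, %d foreground px (%.1f%%) [fg = cell-free]\n",
    d[1], d[2], object@pixelScale, sum(object@foreground),
    100 * mean(object@foreground)
  ))
})

setMethod("show", "AreaResult", function(object) {
  cat(sprintf(
    "AreaResult: %.1f um^2 = %.4f mm^2 in %d component(s)%s\n",
    object@areaUm2, object@areaMm2, object@nComponents,
    if (length(object@flags)) paste0(" [", paste(object@flags, collapse = ", "), "]")
    else ""
  ))
})

setMethod("show", "WellSeries", function(object) {
  cat(sprintf(
    "WellSeries '%s': %d frames, t = %g..%g h (every %g h), v = %g um/h\n",
    object@wellId, length(object@frames), min(object@timesH),
    max(object@timesH), object@config@frameIntervalH,
    object@config@frontVelocityUmPerH
  ))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf(
    "GroundTruth: %d frames, area %.3f -> %.3f mm^2 (%.1f%% at end)\n",
    nrow(object@table), object@table$true_area_mm2[1],
    object@table$true_area_mm2[nrow(object@table)],
    object@table$true_percent[nrow(object@table)]
  ))
})
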