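#' @include AllClasses.R
NULL

## Synthetic exclusion-zone assay.
##
## A well is rendered as a confluent monolayer (seeded jittered-grid Voronoi
## mosaic: per-cell shading, bright polygonal borders) surrounding a smooth,
## dark circular cell-free zone. The front at radius
## r(t) = max(0, r0 - v * max(0, t - lag)) advances (v > 0, promoters) or
## retreats (v < 0, inhibitors); a soft contrast ramp of two cell diameters
## just outside the front keeps segmentation honestly imperfect. Debris
## specks (far below the particle-size minimum) and additive Gaussian noise
## exercise the erode and size-filter steps. The truth mask is exactly the
## disc of radius r(t).

.frontRadiusUm <- function(config, timeH) {
  r0 <- config@zoneDiameterMm * 1000 / 2
  max(0, r0 - config@frontVelocityUmPerH * max(0, timeH - config@frontLagH))
}

## Static per-well render context: everything that does not depend on time.
.renderContext <- function(config) {
  s <- config@pixelScale
  sideMm <- config@zoneDiameterMm + 2 * config@imageMarginMm
  n <- as.integer(round(sideMm * 1000 * s))
  if (n < 8L) stop("image too small: increase zone, margin or pixel scale")
  c0 <- (n + 1) / 2
  px <- (seq_len(n) - c0) / s             # um from center, along one axis
  X <- matrix(px, n, n, byrow = TRUE)     # column offset (x)
  Y <- matrix(px, n, n)                   # row offset (y)
  D <- sqrt(X^2 + Y^2)

  ## jittered-grid Voronoi texture (static monolayer)
  g <- config@textureCellDiameterUm
  gi <- floor(Y / g); gj <- floor(X / g)
  giRange <- range(gi); gjRange <- range(gj)
  nGi <- diff(giRange) + 3L; nGj <- diff(gjRange) + 3L  # +1 ring of cells
  set.seed(config@rngSeed)
  JX <- matrix(runif(nGi * nGj, 0.1, 0.9), nGi, nGj)
  JY <- matrix(runif(nGi * nGj, 0.1, 0.9), nGi, nGj)
  SH <- matrix(runif(nGi * nGj), nGi, nGj)
  i0 <- giRange[1] - 1L; j0 <- gjRange[1] - 1L  # grid offset incl. ring

  f1 <- matrix(Inf, n, n); f2 <- matrix(Inf, n, n)
  shade <- matrix(0, n, n)
  for (di in -1:1) {
    for (dj in -1:1) {
      ci <- gi + di; cj <- gj + dj
      idx <- cbind(as.vector(ci - i0 + 1L), as.vector(cj - j0 + 1L))
      sx <- (cj + matrix(JX[idx], n, n)) * g
      sy <- (ci + matrix(JY[idx], n, n)) * g
      d2 <- (X - sx)^2 + (Y - sy)^2
      isMin <- d2 < f1
      f2 <- ifelse(isMin, f1, pmin(f2, d2))
      shade[isMin] <- matrix(SH[idx], n, n)[isMin]
      f1 <- ifelse(isMin, d2, f1)
    }
  }
  f1 <- sqrt(f1); f2 <- sqrt(f2)
  borderWidthUm <- 1.5 / s
  isBorder <- (f2 - f1) < borderWidthUm
  contrast <- config@textureContrast
  bg0 <- 45
  texture <- bg0 + contrast * (90 * (0.6 + 0.4 * shade))
  texture[isBorder] <- bg0 + contrast * 220

  ## illumination gradient: relative lateral slope across the field
  illum <- 1 + config@illuminationGradient * (X / max(abs(px))) / 2

  ## static debris specks inside the initial zone
  r0 <- config@zoneDiameterMm * 1000 / 2
  set.seed(config@rngSeed + 101L)
  nDebris <- stats::rpois(1, config@debrisDensityPerMm2 *
                             theoreticalZoneArea(config@zoneDiameterMm))
  debris <- NULL
  if (nDebris > 0) {
    theta <- runif(nDebris, 0, 2 * pi)
    rad <- r0 * 0.85 * sqrt(runif(nDebris))
    debris <- data.frame(
      x = rad * cos(theta), y = rad * sin(theta),
      r = runif(nDebris, 3, 8)
    )
  }

  rampUm <- 2 * config@textureCellDiameterUm
  list(
    n = n, X = X, Y = Y, D = D, texture = texture, illum = illum,
    debris = debris, rampUm = rampUm, bg0 = bg0, r0 = r0
  )
}

.smoothstep <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x * x * (3 - 2 * x)
}

.composeFrame <- function(config, ctx, timeH, frameIndex) {
  rt <- .frontRadiusUm(config, timeH)
  ## blend weight: 0 inside the zone, 1 in the monolayer. The ramp starts at
  ## the true front radius and develops outward, so the truth disc is exactly
  ## the cell-free region while the leading cells fade in gradually.
  w <- .smoothstep((ctx$D - rt) / ctx$rampUm)
  img <- ctx$bg0 * (1 - w) + ctx$texture * w
  if (!is.null(ctx$debris)) {
    for (k in seq_len(nrow(ctx$debris))) {
      dk <- ctx$debris[k, ]
      ## specks visible only while still inside the cell-free zone
      if (sqrt(dk$x^2 + dk$y^2) + dk$r < rt) {
        hit <- (ctx$X - dk$x)^2 + (ctx$Y - dk$y)^2 < dk$r^2
        img[hit] <- pmax(img[hit], 180)
      }
    }
  }
  img <- img * ctx$illum
  if (config@noiseSd > 0) {
    set.seed((config@rngSeed + 7919L * (frameIndex + 1L)) %% 2147483647L)
    img <- img + stats::rnorm(length(img), 0, config@noiseSd)
  }
  img <- floor(pmin(pmax(img, 0), 255))
  rgb <- array(as.integer(img), dim = c(ctx$n, ctx$n, 3L))
  truth <- binaryMask(ctx$D <= rt, config@pixelScale)
  list(frame = rgbFrame(rgb, config@pixelScale), truth = truth)
}

#' Render one synthetic well frame with its ground-truth mask
#'
#' @param config a [SimConfig-class].
#' @param timeH time in hours, within \code{[0, durationH]}.
#' @return list with elements \code{frame} ([RGBFrame-class]) and
#'   \code{truth} ([BinaryMask-class], TRUE = cell-free disc).
#' @examples
#' cfg <- simConfig(zoneDiameterMm = 0.4, pixelScale = 0.15,
#'                  imageMarginMm = 0.15)
#' fr <- renderFrame(cfg, 0)
#' mean(maskData(fr$truth))  # fraction of the image inside the zone
#' @export
renderFrame <- function(config, timeH) {
  stopifnot(is(config, "SimConfig"))
  if (timeH < 0 || timeH > config@durationH) {
    stop("timeH must lie within [0, durationH]")
  }
  ctx <- .renderContext(config)
  .composeFrame(config, ctx, timeH,
                as.integer(round(timeH / config@frameIntervalH)))
}

#' Simulate a complete time-lapse series with ground truth
#'
#' Frames at t = 0, interval, ..., duration inclusive
#' (\code{duration/interval + 1} frames). The monolayer texture and debris
#' field are static across the series; only the front position and the
#' per-frame noise change. Identical configuration (including seed) gives
#' bit-identical output.
#'
#' The truth table reports per-frame pixel-counted areas
#' (\code{count / scale^2}), consistent with the calibration used by the
#' segmentation chain, and the percent area relative to the first frame
#' (100 at t = 0 by construction).
#'
#' @param config a [SimConfig-class].
#' @param wellId label attached to the series (default "SIM1").
#' @return list with elements \code{series} ([WellSeries-class]) and
#'   \code{truth} ([GroundTruth-class]).
#' @export
simulateTimelapse <- function(config, wellId = "SIM1") {
  stopifnot(is(config, "SimConfig"))
  times <- seq(0, config@durationH, by = config@frameIntervalH)
  ctx <- .renderContext(config)
  frames <- vector("list", length(times))
  masks <- vector("list", length(times))
  areaMm2 <- numeric(length(times))
  for (k in seq_along(times)) {
    out <- .composeFrame(config, ctx, times[k], k - 1L)
    frames[[k]] <- out$frame
    masks[[k]] <- out$truth
    areaMm2[k] <- sum(out$truth@foreground) / config@pixelScale^2 / 1e6
  }
  tab <- data.frame(
    frame = seq_along(times) - 1L,
    time_h = times,
    true_area_mm2 = areaMm2,
    true_percent = 100 * areaMm2 / areaMm2[1]
  )
  list(
    series = new("WellSeries", wellId = wellId, timesH = times,
                 frames = frames, config = config),
    truth = new("GroundTruth", masks = masks, table = tab,
                tracks = data.frame())
  )
}

#' Treatment presets: signed front velocities
#'
#' Velocities (um/h) chosen so that, with the default 5 mm zone, 24 h lag and
#' 96 h duration, the simulated endpoint percent cell-free areas match the
#' characteristic behaviour of the five reference treatments: medium alone
#' (~89%), serum (~78%), serum + EGF (~49%), and the colchicine (~103%) and
#' doxorubicin (~111%) inhibitor regimes where the zone grows slightly.
#'
#' @return named numeric vector of front velocities in um/h.
#' @export
treatmentPresets <- function() {
  r0 <- 2500
  tEff <- 96 - 24
  p96 <- c(dmem = 88.8, fbs = 78.1, egf = 48.9,
           colchicine = 103.3, doxorubicin = 110.7)
  r0 * (1 - sqrt(p96 / 100)) / tEff
}

#' Simulate cell centroid tracks
#'
#' Each cell starts on a coarse grid (well separated), picks a random fixed
#' heading, and advances \code{speed * interval} micrometres per frame;
#' isotropic Gaussian positional jitter of SD \code{jitterSdUm} is added to
#' every sampled position independently. Ground truth for the velocity
#' analysis of the tracking module.
#'
#' @param nCells number of cells (>= 1).
#' @param speedUmPerH generating speed in um/h (>= 0).
#' @param durationH,intervalH sampling duration and interval in hours.
#' @param jitterSdUm positional jitter SD in um per coordinate.
#' @param seed integer seed.
#' @return data.frame with columns \code{cell_id}, \code{time_h},
#'   \code{x_um}, \code{y_um}.
#' @examples
#' tr <- simulateTracks(3, 1, 10, 1, 0, seed = 1)
#' averageVelocity(tr)$meanSpeed  # exactly 1 um/h with zero jitter
#' @export
simulateTracks <- function(nCells, speedUmPerH, durationH, intervalH,
                           jitterSdUm = 0, seed = 1L) {
  stopifnot(nCells >= 1, speedUmPerH >= 0, jitterSdUm >= 0)
  if (intervalH <= 0) stop("intervalH must be positive")
  if (durationH < intervalH) stop("durationH must cover at least one step")
  set.seed(as.integer(seed))
  times <- seq(0, durationH, by = intervalH)
  nT <- length(times)
  side <- ceiling(sqrt(nCells))
  starts <- expand.grid(x = seq_len(side), y = seq_len(side))[seq_len(nCells), ] * 100
  heading <- stats::runif(nCells, 0, 2 * pi)
  out <- vector("list", nCells)
  for (i in seq_len(nCells)) {
    x <- starts$x[i] + cos(heading[i]) * speedUmPerH * times +
      stats::rnorm(nT, 0, jitterSdUm)
    y <- starts$y[i] + sin(heading[i]) * speedUmPerH * times +
      stats::rnorm(nT, 0, jitterSdUm)
    out[[i]] <- data.frame(
      cell_id = sprintf("cell%02d", i), time_h = times, x_um = x, y_um = y
    )
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Write a simulated series to disk
#'
#' Frames are written as 24-bit RGB TIFF named \code{<well>_t<index>.tif}
#' (zero-padded index), the truth table as CSV, and truth masks as 8-bit
#' binary-valued (0/255) TIFF under \code{truth_masks/}.
#'
#' @param sim result of [simulateTimelapse()].
#' @param dir output directory (created if needed).
#' @param writeMasks also write the truth masks (default TRUE).
#' @return invisibly, the data.frame of written frame paths.
#' @export
writeSimulation <- function(sim, dir, writeMasks = TRUE) {
  stopifnot(is(sim$series, "WellSeries"), is(sim$truth, "GroundTruth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  series <- sim$series
  nFrames <- length(series@frames)
  paths <- character(nFrames)
  for (k in seq_len(nFrames)) {
    paths[k] <- file.path(dir, sprintf("%s_t%03d.tif", series@wellId, k - 1L))
    writeFrame(series@frames[[k]], paths[k])
  }
  utils::write.csv(sim$truth@table,
                   file.path(dir, sprintf("%s_truth.csv", series@wellId)),
                   row.names = FALSE)
  if (writeMasks) {
    mdir <- file.path(dir, "truth_masks")
    dir.create(mdir, showWarnings = FALSE)
    for (k in seq_len(nFrames)) {
      m <- sim$truth@masks[[k]]@foreground
      tiff::writeTIFF(matrix(as.numeric(m), nrow(m), ncol(m)),
                      file.path(mdir, sprintf("%s_t%03d_mask.tif",
                                              series@wellId, k - 1L)),
                      bits.per.sample = 8L)
    }
  }
  invisible(data.frame(
    well_id = series@wellId, time_index = seq_len(nFrames) - 1L,
    time_h = series@timesH, path = paths
  ))
}
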