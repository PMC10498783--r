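# Small, fast simulator configuration used across tests: a 0.5 mm zone at a
# reduced pixel scale keeps frames ~100 px wide so whole series render in
# well under a second.
tinyConfig <- function(...) {
  args <- list(...)
  defaults <- list(
    zoneDiameterMm = 0.5, pixelScale = 0.12, imageMarginMm = 0.2,
    frameIntervalH = 3, durationH = 96, frontVelocityUmPerH = 2,
    frontLagH = 24, textureCellDiameterUm = 30, textureContrast = 0.5,
    debrisDensityPerMm2 = 0.5, illuminationGradient = 0.1, noiseSd = 2,
    rngSeed = 1L
  )
  defaults[names(args)] <- args
  do.call(simConfig, defaults)
}

# Flat gray RGB frame with an optional bright rectangle, for pipeline edge
# cases.
flatRgb <- function(n = 32, value = 120, pixelScale = 0.3525) {
  rgbFrame(array(as.integer(value), dim = c(n, n, 3L)), pixelScale)
}

grayFromMatrix <- function(m, scale = 1) grayFrame(m, scale)

maskFromMatrix <- function(m, scale = 1) binaryMask(m > 0, scale)
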