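#' @include AllClasses.R
NULL

## The segmentation chain mirrors the batch image-analysis macro used for
## exclusion-zone assays: 8-bit grayscale -> crop -> Sobel edge enhancement
## -> maximum-entropy threshold (dark background) -> polarity-normalised
## binary mask (foreground = cell-free) -> erode -> fill holes -> calibrated
## particle analysis with a fixed size range.

#' Convert an RGB frame to 8-bit grayscale
#'
#' Unweighted channel mean truncated to integer, the default RGB-to-8-bit
#' conversion of common image-analysis tools when conversion weights are not
#' enabled.
#'
#' @param rgb an [RGBFrame-class].
#' @return a [GrayFrame-class] with the same pixel scale.
#' @examples
#' px <- array(c(30, 60, 90), dim = c(1, 1, 3))
#' frameData(toGrayscale(rgbFrame(px, 0.3525)))  # 60
#' @export
toGrayscale <- function(rgb) {
  stopifnot(is(rgb, "RGBFrame"))
  d <- rgb@data
  g <- (d[, , 1] + d[, , 2] + d[, , 3]) %/% 3L
  dim(g) <- dim(d)[1:2]
  grayFrame(g, rgb@pixelScale)
}

#' Crop a grayscale frame to a rectangular region of interest
#'
#' @param frame a [GrayFrame-class].
#' @param roi integer vector \code{c(row, col, height, width)}, 1-based,
#'   fully inside the frame.
#' @return the cropped [GrayFrame-class]; pixel scale is preserved.
#' @export
cropFrame <- function(frame, roi) {
  stopifnot(is(frame, "GrayFrame"), length(roi) == 4L)
  roi <- as.integer(roi)
  d <- dim(frame@intensities)
  if (roi[1] < 1L || roi[2] < 1L || roi[3] < 1L || roi[4] < 1L ||
      roi[1] + roi[3] - 1L > d[1] || roi[2] + roi[4] - 1L > d[2]) {
    stop("roi exceeds frame bounds")
  }
  grayFrame(
    frame@intensities[roi[1]:(roi[1] + roi[3] - 1L),
                      roi[2]:(roi[2] + roi[4] - 1L), drop = FALSE],
    frame@pixelScale
  )
}

#' Centered fractional crop
#'
#' Crops a centered window whose side is \code{fraction} of each frame
#' dimension, the default way batch analysis focuses on the cell-free zone.
#'
#' @param frame a [GrayFrame-class].
#' @param fraction fractional side in (0, 1]; 1 returns the frame unchanged.
#' @return a [GrayFrame-class].
#' @export
cropCentered <- function(frame, fraction = 0.8) {
  stopifnot(is(frame, "GrayFrame"), fraction > 0, fraction <= 1)
  if (fraction == 1) return(frame)
  d <- dim(frame@intensities)
  h <- max(1L, as.integer(round(d[1] * fraction)))
  w <- max(1L, as.integer(round(d[2] * fraction)))
  r0 <- as.integer(floor((d[1] - h) / 2)) + 1L
  c0 <- as.integer(floor((d[2] - w) / 2)) + 1L
  cropFrame(frame, c(r0, c0, h, w))
}

#' Sobel edge enhancement ("Find Edges")
#'
#' 3x3 Sobel gradient magnitude \eqn{\sqrt{G_x^2 + G_y^2}} with replicated
#' borders, clipped to [0, 255] and truncated to 8 bits. On brightfield
#' monolayers this highlights cell borders, turning texture into signal for
#' the threshold step.
#'
#' @param frame a [GrayFrame-class] of at least 3 x 3 pixels.
#' @return a [GrayFrame-class] of gradient magnitudes.
#' @export
findEdges <- function(frame) {
  stopifnot(is(frame, "GrayFrame"))
  v <- frame@intensities
  if (nrow(v) < 3L || ncol(v) < 3L) stop("frame must be at least 3 x 3")
  storage.mode(v) <- "double"
  # direct (exact) 3x3 convolution on a replicate-padded grid; spatial-domain
  # sums keep integer arithmetic exact where an FFT-based filter would not
  n <- nrow(v); p <- ncol(v)
  pad <- rbind(v[1, , drop = FALSE], v, v[n, , drop = FALSE])
  pad <- cbind(pad[, 1, drop = FALSE], pad, pad[, p, drop = FALSE])
  sh <- function(a, b) pad[(2 + a):(n + 1 + a), (2 + b):(p + 1 + b)]
  gx <- (sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))
  gy <- (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1))
  mag <- floor(pmin(sqrt(gx^2 + gy^2), 255))
  grayFrame(mag, frame@pixelScale)
}

#' 256-bin intensity histogram of a frame
#'
#' @param frame a [GrayFrame-class].
#' @return integer vector of length 256; element \code{i} counts pixels with
#'   intensity \code{i - 1}.
#' @export
frameHistogram <- function(frame) {
  stopifnot(is(frame, "GrayFrame"))
  tabulate(as.integer(frame@intensities) + 1L, nbins = 256L)
}

#' Maximum-entropy (Kapur) threshold
#'
#' Selects the gray level \code{T} maximizing the sum of Shannon entropies of
#' the two histogram classes it induces,
#' \deqn{\psi(T) = H_{\le T} + H_{> T},}
#' where each class entropy is computed over its occupied bins with
#' probabilities renormalized within the class. Candidate thresholds leaving
#' either class empty are skipped; ties are broken by the lowest maximizing
#' level. This is the "MaxEntropy" auto-threshold of common image-analysis
#' tools.
#'
#' @param histogram numeric vector of 256 non-negative bin counts; at least
#'   two bins must be occupied.
#' @return integer threshold in 0-255.
#' @examples
#' h <- numeric(256); h[c(11, 201)] <- 1
#' maxEntropyThreshold(h)  # 10: lowest level separating the two bins
#' @export
maxEntropyThreshold <- function(histogram) {
  if (length(histogram) != 256L || any(histogram < 0) ||
      any(!is.finite(histogram))) {
    stop("histogram must be 256 non-negative counts")
  }
  if (sum(histogram > 0) < 2L) {
    stop("degenerate image: fewer than two occupied gray levels")
  }
  p <- histogram / sum(histogram)
  plogp <- ifelse(p > 0, p * log(p), 0)
  cumP <- cumsum(p)           # P_T for T = 0..255 at index T + 1
  cumPlogp <- cumsum(plogp)
  totPlogp <- cumPlogp[256L]
  psi <- rep(-Inf, 255L)      # candidates T = 0..254
  for (Ti in 1:255) {         # Ti = T + 1
    PT <- cumP[Ti]
    PH <- 1 - PT
    if (PT <= 0 || PH <= 0) next
    hLow <- log(PT) - cumPlogp[Ti] / PT
    hHigh <- log(PH) - (totPlogp - cumPlogp[Ti]) / PH
    psi[Ti] <- hLow + hHigh
  }
  ## lowest maximizer, with ties resolved at numerical precision: a candidate
  ## only displaces the incumbent when its criterion is larger by more than
  ## 1e-12, so algebraically tied plateaus resolve to the lowest level
  best <- -Inf
  bestT <- 0L
  for (Ti in 1:255) {
    if (psi[Ti] > best + 1e-12) {
      best <- psi[Ti]
      bestT <- Ti - 1L
    }
  }
  as.integer(bestT)
}

#' Threshold a frame into a cell-free candidate mask
#'
#' With \code{darkBackground = TRUE} pixels strictly above the threshold are
#' provisional foreground (edge/cell pixels, bright on the Sobel image).
#' The returned mask is polarity-normalized so that mask foreground is the
#' non-edge, cell-free candidate region: the display-level LUT inversion of
#' the original macro is made an explicit complement here, so every
#' downstream morphological step operates on a fixed, documented polarity.
#'
#' @param frame a [GrayFrame-class] (normally the Sobel image).
#' @param threshold integer gray level in 0-255.
#' @param darkBackground logical; if \code{FALSE} pixels strictly below the
#'   threshold are taken as provisional foreground instead.
#' @return a [BinaryMask-class] with foreground = cell-free candidate.
#' @export
binarize <- function(frame, threshold, darkBackground = TRUE) {
  stopifnot(is(frame, "GrayFrame"))
  if (threshold < 0 || threshold > 255) stop("threshold must lie in 0-255")
  edges <- if (darkBackground) frame@intensities > threshold
           else frame@intensities < threshold
  binaryMask(!edges, frame@pixelScale)
}

#' Binary erosion of the cell-free foreground
#'
#' Standard binary erosion with a full 3x3 (8-connected) structuring element,
#' applied \code{iterations} times; pixels beyond the image border count as
#' background, so foreground touching the border is eroded there too. One
#' iteration removes isolated noise pixels and detaches thin bridges.
#'
#' @param mask a [BinaryMask-class].
#' @param iterations non-negative iteration count (default 1).
#' @return the eroded [BinaryMask-class].
#' @export
erodeMask <- function(mask, iterations = 1L) {
  stopifnot(is(mask, "BinaryMask"))
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 0L) {
    stop("iterations must be a non-negative integer")
  }
  fg <- mask@foreground
  if (iterations == 0L || !any(fg)) {
    return(binaryMask(fg, mask@pixelScale))
  }
  d <- dim(fg)
  # zero-pad so the border is treated as background
  pad <- iterations
  buf <- matrix(0, d[1] + 2L * pad, d[2] + 2L * pad)
  buf[(pad + 1L):(pad + d[1]), (pad + 1L):(pad + d[2])] <- fg * 1
  br <- EBImage::makeBrush(3L, shape = "box")
  for (i in seq_len(iterations)) buf <- EBImage::erode(buf, br)
  binaryMask(buf[(pad + 1L):(pad + d[1]), (pad + 1L):(pad + d[2])] > 0.5,
             mask@pixelScale)
}

#' Fill enclosed holes in the cell-free foreground
#'
#' Every background component that is not 4-connected to the image border
#' becomes foreground. Debris specks inside the zone leave edge-pixel rings
#' in the mask; this step absorbs them into the surrounding cell-free region.
#'
#' @param mask a [BinaryMask-class].
#' @return the filled [BinaryMask-class].
#' @export
fillHoles <- function(mask) {
  stopifnot(is(mask, "BinaryMask"))
  fg <- mask@foreground
  bg <- EBImage::bwlabel((!fg) * 1)  # 4-connected background components
  if (max(bg) == 0L) return(binaryMask(fg, mask@pixelScale))
  d <- dim(bg)
  borderLabels <- unique(c(bg[1, ], bg[d[1], ], bg[, 1], bg[, d[2]]))
  borderLabels <- borderLabels[borderLabels > 0]
  hole <- bg > 0 & !(bg %in% borderLabels)
  binaryMask(fg | hole, mask@pixelScale)
}

## 8-connected labelling: EBImage::bwlabel is 4-connected; diagonal contacts
## between distinct 4-labels are merged with a union-find pass.
.label8 <- function(fg) {
  lab <- EBImage::bwlabel(fg * 1)
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)
  d <- dim(lab)
  a1 <- lab[-d[1], -d[2]]; b1 <- lab[-1, -1]          # "\" diagonal
  a2 <- lab[-d[1], -1];    b2 <- lab[-1, -d[2]]       # "/" diagonal
  sel1 <- a1 > 0 & b1 > 0 & a1 != b1
  sel2 <- a2 > 0 & b2 > 0 & a2 != b2
  pairs <- unique(rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2])))
  if (nrow(pairs) == 0L) return(lab)
  parent <- seq_len(nlab)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Calibrated particle analysis of the cell-free mask
#'
#' Labels 8-connected foreground components, converts each pixel count to a
#' calibrated area via \code{count / scale^2} (um^2), discards components
#' outside \code{[minUm2, maxUm2]} and returns the union of the survivors
#' with their total area. The default range 1e5-7e8 um^2 (0.1-700 mm^2)
#' passes the millimetre-scale zone while rejecting sub-cell-scale specks.
#'
#' If no component survives, a zero-area result flagged
#' \code{"no_component_in_range"} is returned with a warning, so batch series
#' keep the frame with area 0 rather than dropping it.
#'
#' @param mask a [BinaryMask-class] (foreground = cell-free).
#' @param minUm2,maxUm2 inclusive calibrated size range in square
#'   micrometres.
#' @return an [AreaResult-class].
#' @export
extractCellFree <- function(mask, minUm2 = 1e5, maxUm2 = 7e8) {
  stopifnot(is(mask, "BinaryMask"), minUm2 >= 0, maxUm2 >= minUm2)
  scale <- mask@pixelScale
  fg <- mask@foreground
  empty <- binaryMask(matrix(FALSE, nrow(fg), ncol(fg)), scale)
  if (!any(fg)) {
    warning("no cell-free component within size range; reporting area 0")
    return(new("AreaResult",
      areaUm2 = 0, areaMm2 = 0, nComponents = 0L,
      componentMask = empty, flags = "no_component_in_range", stages = list()
    ))
  }
  lab <- .label8(fg)
  counts <- tabulate(lab[lab > 0], nbins = max(lab))
  areas <- counts / scale^2
  keep <- which(areas >= minUm2 & areas <= maxUm2)
  if (length(keep) == 0L) {
    warning("no cell-free component within size range; reporting area 0")
    return(new("AreaResult",
      areaUm2 = 0, areaMm2 = 0, nComponents = 0L,
      componentMask = empty, flags = "no_component_in_range", stages = list()
    ))
  }
  survivors <- matrix(lab %in% keep, nrow(fg), ncol(fg))
  total <- sum(areas[keep])
  new("AreaResult",
    areaUm2 = total, areaMm2 = total / 1e6, nComponents = length(keep),
    componentMask = binaryMask(survivors, scale),
    flags = character(0), stages = list()
  )
}

#' Segmentation pipeline parameters
#'
#' One shared parameter set is applied to every frame of a batch so results
#' stay comparable across wells and times.
#'
#' @param cropFraction centered-crop fractional side in (0, 1]; default 0.8.
#' @param erodeIterations erosion iterations after thresholding; default 1.
#' @param minUm2,maxUm2 particle-size range in um^2; default 1e5-7e8.
#' @param darkBackground threshold polarity flag; default TRUE.
#' @param keepStages keep all intermediate stage objects on the result for
#'   debugging; default FALSE.
#' @return a named list of class \code{"PipelineParams"}.
#' @export
pipelineParams <- function(cropFraction = 0.8, erodeIterations = 1L,
                           minUm2 = 1e5, maxUm2 = 7e8,
                           darkBackground = TRUE, keepStages = FALSE) {
  stopifnot(cropFraction > 0, cropFraction <= 1, erodeIterations >= 0,
            minUm2 >= 0, maxUm2 >= minUm2)
  structure(
    list(
      cropFraction = cropFraction,
      erodeIterations = as.integer(erodeIterations),
      minUm2 = minUm2, maxUm2 = maxUm2,
      darkBackground = isTRUE(darkBackground),
      keepStages = isTRUE(keepStages)
    ),
    class = "PipelineParams"
  )
}

#' Run the full segmentation pipeline on one frame
#'
#' Fixed-order composition: grayscale conversion, centered crop, Sobel edge
#' enhancement, maximum-entropy threshold, polarity-normalized binarization,
#' erosion, hole filling, calibrated particle analysis. A degenerate
#' threshold (frame with fewer than two occupied gray levels) is downgraded
#' to a zero-area result flagged \code{"degenerate_threshold"} so batch runs
#' keep going.
#'
#' @param rgb an [RGBFrame-class].
#' @param params a [pipelineParams()] list.
#' @return an [AreaResult-class]; when \code{params$keepStages} is TRUE its
#'   \code{stages} slot holds every intermediate object.
#' @examples
#' cfg <- simConfig(zoneDiameterMm = 0.4, pixelScale = 0.15,
#'                  imageMarginMm = 0.15, debrisDensityPerMm2 = 0)
#' fr <- renderFrame(cfg, 0)
#' res <- runPipeline(fr$frame, pipelineParams(minUm2 = 1e3))
#' areaMm2(res)
#' @export
runPipeline <- function(rgb, params = pipelineParams()) {
  stopifnot(is(rgb, "RGBFrame"), inherits(params, "PipelineParams"))
  gray <- toGrayscale(rgb)
  cropped <- cropCentered(gray, params$cropFraction)
  edges <- findEdges(cropped)
  thr <- tryCatch(maxEntropyThreshold(frameHistogram(edges)),
                  error = function(e) NA_integer_)
  if (is.na(thr)) {
    warning("degenerate threshold (uniform frame); reporting area 0")
    d <- dim(edges@intensities)
    return(new("AreaResult",
      areaUm2 = 0, areaMm2 = 0, nComponents = 0L,
      componentMask = binaryMask(matrix(FALSE, d[1], d[2]), rgb@pixelScale),
      flags = "degenerate_threshold", stages = list()
    ))
  }
  mask <- binarize(edges, thr, params$darkBackground)
  eroded <- erodeMask(mask, params$erodeIterations)
  filled <- fillHoles(eroded)
  res <- withCallingHandlers(
    extractCellFree(filled, params$minUm2, params$maxUm2),
    warning = function(w) invokeRestart("muffleWarning")
  )
  if ("no_component_in_range" %in% res@flags) {
    warning("no cell-free component within size range; reporting area 0")
  }
  if (params$keepStages) {
    res@stages <- list(
      gray = gray, cropped = cropped, edges = edges, threshold = thr,
      binary = mask, eroded = eroded, filled = filled
    )
  }
  res
}

#' Equivalent circular diameter of a measured area
#'
#' Diameter of the circle with the same area, \eqn{2\sqrt{A/\pi}}; used to
#' compare a measured cell-free component against the nominal stamped zone
#' diameter.
#'
#' @param areaMm2 area in square millimetres.
#' @return diameter in millimetres.
#' @export
equivalentDiameterMm <- function(areaMm2) {
  stopifnot(areaMm2 >= 0)
  2 * sqrt(areaMm2 / pi)
}
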