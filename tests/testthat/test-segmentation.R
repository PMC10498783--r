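test_that("grayscale conversion is the truncated unweighted channel mean", {
  px <- array(c(30, 255, 10, 60, 0, 10, 90, 0, 11), dim = c(3, 1, 3))
  # pixels (rows): (30,60,90) -> 60; (255,0,0) -> 85; (10,10,11) -> 10
  g <- toGrayscale(rgbFrame(px, 0.3525))
  expect_identical(as.vector(frameData(g)), c(60L, 85L, 10L))
  expect_equal(pixelScale(g), 0.3525)
  # idempotence on gray pixels
  v <- array(rep(0:255, 3), dim = c(256, 1, 3))
  expect_identical(as.vector(frameData(toGrayscale(rgbFrame(v, 1)))), 0:255)
})

test_that("crop preserves scale and rejects out-of-bounds rois", {
  m <- matrix(sample(0:255, 100 * 100, replace = TRUE), 100, 100)
  fr <- grayFromMatrix(m, 0.3525)
  full <- cropFrame(fr, c(1, 1, 100, 100))
  expect_identical(frameData(full), frameData(fr))
  sub <- cropFrame(fr, c(11, 21, 10, 10))
  expect_identical(frameData(sub), m[11:20, 21:30])
  expect_equal(pixelScale(sub), 0.3525)
  expect_error(cropFrame(fr, c(95, 1, 10, 10)), "bounds")
  expect_error(cropFrame(fr, c(0, 1, 10, 10)), "bounds")
  cc <- cropCentered(fr, 0.5)
  expect_equal(dim(frameData(cc)), c(50, 50))
})

test_that("Sobel magnitude matches a direct hand convolution", {
  # independent oracle: explicit 3x3 convolution with replicated borders
  sobelOracle <- function(m) {
    n <- nrow(m); p <- ncol(m)
    cl <- function(i, lim) min(max(i, 1), lim)
    out <- matrix(0, n, p)
    kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
    ky <- t(kx)
    for (i in 1:n) for (j in 1:p) {
      gx <- 0; gy <- 0
      for (a in -1:1) for (b in -1:1) {
        v <- m[cl(i + a, n), cl(j + b, p)]
        gx <- gx + kx[a + 2, b + 2] * v
        gy <- gy + ky[a + 2, b + 2] * v
      }
      out[i, j] <- floor(min(sqrt(gx^2 + gy^2), 255))
    }
    storage.mode(out) <- "integer"
    out
  }
  set.seed(42)
  m5 <- matrix(sample(0:255, 25, replace = TRUE), 5, 5)
  expect_identical(frameData(findEdges(grayFromMatrix(m5))), sobelOracle(m5))
  m9 <- matrix(sample(0:255, 81, replace = TRUE), 9, 9)
  expect_identical(frameData(findEdges(grayFromMatrix(m9))), sobelOracle(m9))
})

test_that("Sobel responds at a step edge and is zero on constant frames", {
  flat <- grayFromMatrix(matrix(77L, 8, 8))
  expect_true(all(frameData(findEdges(flat)) == 0L))
  step <- matrix(0L, 8, 8); step[, 5:8] <- 255L
  e <- frameData(findEdges(grayFromMatrix(step)))
  expect_true(all(e[, 4:5] == 255L))  # clipped maximal response at the step
  expect_true(all(e[, c(1, 2, 7, 8)] == 0L))
  expect_error(findEdges(grayFromMatrix(matrix(1L, 2, 2))), "3 x 3")
})

test_that("max-entropy threshold equals the brute-force argmax oracle", {
  # independent oracle: literal two-class entropy scan over all 256 levels
  kapurOracle <- function(h) {
    p <- h / sum(h)
    best <- -Inf; bestT <- NA_integer_
    for (T in 0:254) {
      lo <- p[1:(T + 1)]; hi <- p[(T + 2):256]
      Plo <- sum(lo); Phi <- sum(hi)
      if (Plo <= 0 || Phi <= 0) next
      lo <- lo[lo > 0] / Plo; hi <- hi[hi > 0] / Phi
      psi <- -sum(lo * log(lo)) - sum(hi * log(hi))
      if (psi > best + 1e-12) { best <- psi; bestT <- T }
    }
    bestT
  }
  set.seed(7)
  for (k in 1:200) {
    h <- numeric(256)
    occupied <- sample(256, sample(2:60, 1))
    h[occupied] <- rpois(length(occupied), 40) + 1
    expect_identical(maxEntropyThreshold(h), kapurOracle(h))
  }
})

test_that("max-entropy threshold: bimodal plateau resolves to the lowest tie", {
  h <- numeric(256)
  h[1:64] <- 10      # levels 0-63
  h[193:256] <- 10   # levels 192-255
  expect_identical(maxEntropyThreshold(h), 63L)
  h1 <- numeric(256); h1[100] <- 50
  expect_error(maxEntropyThreshold(h1), "degenerate")
  expect_error(maxEntropyThreshold(rep(-1, 256)), "non-negative")
})

test_that("binarize applies the cell-free polarity contract", {
  m <- matrix(as.integer(c(0, 50, 120, 200)), 2, 2)
  fr <- grayFromMatrix(m)
  # threshold 255: nothing exceeds it -> everything is cell-free candidate
  expect_true(all(maskData(binarize(fr, 255))))
  # threshold 0 with all pixels >= 1: everything is edge -> empty candidate
  fr1 <- grayFromMatrix(matrix(as.integer(c(1, 3, 8, 255)), 2, 2))
  expect_false(any(maskData(binarize(fr1, 0))))
  # mid threshold: low pixels cell-free, high pixels edge
  b <- maskData(binarize(fr, 100))
  expect_identical(as.vector(b), c(TRUE, TRUE, FALSE, FALSE))
  expect_error(binarize(fr, 300), "0-255")
})

test_that("erosion uses a full 3x3 element with background borders", {
  # solid 3x3 block -> single centre pixel
  m <- matrix(0, 5, 5); m[2:4, 2:4] <- 1
  e <- maskData(erodeMask(maskFromMatrix(m)))
  expect_equal(sum(e), 1)
  expect_true(e[3, 3])
  # isolated pixel removed
  s <- matrix(0, 5, 5); s[3, 3] <- 1
  expect_false(any(maskData(erodeMask(maskFromMatrix(s)))))
  # empty mask fixed point
  expect_false(any(maskData(erodeMask(maskFromMatrix(matrix(0, 4, 4))))))
  # border counts as background: a full mask loses its 1-px rim
  f <- maskData(erodeMask(maskFromMatrix(matrix(1, 5, 5))))
  expect_equal(sum(f), 9)
  expect_true(all(f[2:4, 2:4]))
  # zero iterations is identity; negative rejected
  m2 <- matrix(runif(64) > 0.5, 8, 8)
  expect_identical(maskData(erodeMask(binaryMask(m2, 1), 0)), m2)
  expect_error(erodeMask(binaryMask(m2, 1), -1), "non-negative")
})

test_that("hole filling matches a flood-fill-from-border oracle", {
  floodOracle <- function(fg) {
    # mark background reachable from the border by 4-connectivity
    n <- nrow(fg); p <- ncol(fg)
    reach <- matrix(FALSE, n, p)
    queue <- which(!fg & (row(fg) %in% c(1, n) | col(fg) %in% c(1, p)))
    reach[queue] <- TRUE
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      r <- (i - 1) %% n + 1; c <- (i - 1) %/% n + 1
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        rr <- r + d[1]; cc <- c + d[2]
        if (rr >= 1 && rr <= n && cc >= 1 && cc <= p &&
            !fg[rr, cc] && !reach[rr, cc]) {
          reach[rr, cc] <- TRUE
          queue <- c(queue, (cc - 1) * n + rr)
        }
      }
    }
    fg | !reach
  }
  # 1-px ring becomes a solid disc
  ring <- matrix(0, 9, 9)
  ring[3, 3:7] <- 1; ring[7, 3:7] <- 1; ring[3:7, 3] <- 1; ring[3:7, 7] <- 1
  filled <- maskData(fillHoles(maskFromMatrix(ring)))
  expect_identical(filled, floodOracle(ring > 0))
  expect_true(all(filled[4:6, 4:6]))
  # nested rings: both enclosed annuli fill
  nest <- matrix(0, 13, 13)
  nest[2, 2:12] <- 1; nest[12, 2:12] <- 1; nest[2:12, 2] <- 1; nest[2:12, 12] <- 1
  nest[5, 5:9] <- 1; nest[9, 5:9] <- 1; nest[5:9, 5] <- 1; nest[5:9, 9] <- 1
  expect_identical(maskData(fillHoles(maskFromMatrix(nest))),
                   floodOracle(nest > 0))
  expect_true(all(maskData(fillHoles(maskFromMatrix(nest)))[3:11, 3:11]))
  # background touching the border everywhere stays unchanged
  open <- matrix(0, 8, 8); open[3:5, 3:5] <- 1
  expect_identical(maskData(fillHoles(maskFromMatrix(open))), open > 0)
  # random-mask property: equality with the oracle, monotonicity
  set.seed(11)
  for (k in 1:20) {
    m <- matrix(runif(144) > 0.6, 12, 12)
    got <- maskData(fillHoles(binaryMask(m, 1)))
    expect_identical(got, floodOracle(m))
    expect_true(all(m <= got))  # never removes foreground
  }
})

test_that("erosion never adds pixels and composes with filling as expected", {
  set.seed(3)
  for (k in 1:20) {
    m <- matrix(runif(400) > 0.5, 20, 20)
    mk <- binaryMask(m, 1)
    er <- maskData(erodeMask(mk))
    expect_true(all(er <= m))
    fl <- fillHoles(mk)
    expect_true(all(maskData(erodeMask(fl)) <= maskData(fl)))
  }
})

test_that("particle analysis filters by calibrated size and unions survivors", {
  scale <- 0.3525
  # one 19.6 mm^2 disc and one ~0.05 mm^2 speck
  n <- 2000
  fg <- matrix(FALSE, n, n)
  cx <- 900; cy <- 900
  rpx <- sqrt(19.6e6 / pi) * scale           # disc radius in px
  d2 <- (row(fg) - cx)^2 + (col(fg) - cy)^2
  fg[d2 <= rpx^2] <- TRUE
  spx <- sqrt(5e4 / pi) * scale              # speck radius: 0.05 mm^2
  s2 <- (row(fg) - 80)^2 + (col(fg) - 1900)^2
  fg[s2 <= spx^2] <- TRUE
  res <- extractCellFree(binaryMask(fg, scale))
  expect_equal(nComponents(res), 1L)
  expect_equal(areaMm2(res), 19.6, tolerance = 0.005)
  expect_equal(areaUm2(res), areaMm2(res) * 1e6)
  # empty mask: zero area, flagged, with warning
  expect_warning(
    r0 <- extractCellFree(binaryMask(matrix(FALSE, 10, 10), scale)),
    "size range"
  )
  expect_equal(areaUm2(r0), 0)
  expect_equal(nComponents(r0), 0L)
  expect_true("no_component_in_range" %in% resultFlags(r0))
  # single pixel: (1/0.3525)^2 ~ 8 um^2, below the 1e5 minimum
  one <- matrix(FALSE, 10, 10); one[5, 5] <- TRUE
  expect_warning(r1 <- extractCellFree(binaryMask(one, scale)), "size range")
  expect_equal(nComponents(r1), 0L)
  # with a permissive range the pixel survives at its calibrated area
  r2 <- extractCellFree(binaryMask(one, scale), minUm2 = 0, maxUm2 = 1e9)
  expect_equal(areaUm2(r2), (1 / scale)^2, tolerance = 1e-12)
})

test_that("particle analysis is 8-connected", {
  # two diagonal pixel chains form one component
  m <- matrix(FALSE, 6, 6)
  m[cbind(1:5, 1:5)] <- TRUE
  m[cbind(1:5, 6:2)] <- TRUE
  res <- extractCellFree(binaryMask(m, 1), minUm2 = 0, maxUm2 = 1e9)
  expect_equal(nComponents(res), 1L)
})

test_that("pipeline handles degenerate and zone-free frames gracefully", {
  # pure flat frame: degenerate threshold downgraded to zero-area result
  expect_warning(res <- runPipeline(flatRgb(48)), "degenerate")
  expect_equal(areaUm2(res), 0)
  expect_true("degenerate_threshold" %in% resultFlags(res))
  # pure monolayer texture, no zone: no surviving cell-free component
  cfg <- tinyConfig(zoneDiameterMm = 0.01, imageMarginMm = 0.4,
                    debrisDensityPerMm2 = 0)
  fr <- renderFrame(cfg, 0)
  expect_warning(r2 <- runPipeline(fr$frame), "size range")
  expect_equal(areaUm2(r2), 0)
})

test_that("pipeline is deterministic and keeps stages on request", {
  cfg <- tinyConfig()
  fr <- renderFrame(cfg, 30)$frame
  p <- pipelineParams(minUm2 = 1e3, keepStages = TRUE)
  a <- runPipeline(fr, p)
  b <- runPipeline(fr, p)
  expect_identical(areaUm2(a), areaUm2(b))
  expect_identical(maskData(componentMask(a)), maskData(componentMask(b)))
  expect_named(a@stages,
               c("gray", "cropped", "edges", "threshold", "binary",
                 "eroded", "filled"))
  expect_true(is(a@stages$edges, "GrayFrame"))
})

test_that("measured disc area is calibration-consistent across diameters", {
  # rendered discs of 1-5 mm measured to within one perimeter-pixel ring
  for (dmm in c(1, 3, 5)) {
    scale <- 0.05  # coarse scale keeps frames small
    n <- as.integer(round((dmm + 0.4) * 1000 * scale))
    c0 <- (n + 1) / 2
    rpx <- dmm * 1000 * scale / 2
    fg <- (row(matrix(0, n, n)) - c0)^2 + (col(matrix(0, n, n)) - c0)^2 <= rpx^2
    res <- extractCellFree(binaryMask(fg, scale), minUm2 = 0, maxUm2 = 1e12)
    ringUm2 <- 2 * pi * rpx / scale^2  # one-pixel perimeter ring
    expect_lt(abs(areaUm2(res) - theoreticalZoneArea(dmm) * 1e6), ringUm2)
  }
})

test_that("equivalent diameter inverts the disc area formula", {
  expect_equal(equivalentDiameterMm(theoreticalZoneArea(5)), 5)
  expect_equal(equivalentDiameterMm(pi), 2)
  expect_equal(equivalentDiameterMm(0), 0)
})
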