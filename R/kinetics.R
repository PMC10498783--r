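#' @include AllClasses.R
NULL

#' Percent cell-free area per well
#'
#' Normalizes each well's area series to its own first frame:
#' \code{percent = 100 * area(t) / area(t0)}. Self-normalization (rather than
#' division by the theoretical zone area) is deliberate: under inhibitor
#' treatments the monolayer retracts slightly and percent values above 100
#' are real and must be representable.
#'
#' @param results data.frame with columns \code{well_id}, \code{time_h},
#'   \code{area_mm2}, and optionally \code{treatment}.
#' @return data.frame with columns \code{well_id}, \code{treatment},
#'   \code{time_h}, \code{area_mm2}, \code{percent_area}, ordered by well
#'   and time.
#' @examples
#' df <- data.frame(well_id = "A1", time_h = c(0, 3), area_mm2 = c(20, 10))
#' percentArea(df)$percent_area  # 100, 50
#' @export
percentArea <- function(results) {
  stopifnot(is.data.frame(results),
            all(c("well_id", "time_h", "area_mm2") %in% names(results)))
  if (!"treatment" %in% names(results)) results$treatment <- NA_character_
  parts <- split(results, results$well_id)
  out <- lapply(parts, function(d) {
    d <- d[order(d$time_h), , drop = FALSE]
    base <- d$area_mm2[1]
    if (!is.finite(base) || base <= 0) {
      stop(sprintf("well '%s' has zero or invalid baseline area; cannot normalize",
                   d$well_id[1]))
    }
    d$percent_area <- 100 * d$area_mm2 / base
    d
  })
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  out[, c("well_id", "treatment", "time_h", "area_mm2", "percent_area")]
}

#' Aggregate kinetics across replicate wells
#'
#' Per (treatment, time): mean percent area, sample SD (n - 1 denominator)
#' and SEM = SD / sqrt(n). A cell with a single replicate gets SD = SEM = 0
#' with a warning.
#'
#' @param records output of [percentArea()] with a \code{treatment} column.
#' @return data.frame with columns \code{treatment}, \code{time_h},
#'   \code{mean_percent}, \code{sd}, \code{sem}, \code{n}.
#' @export
aggregateKinetics <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("treatment", "time_h", "percent_area") %in% names(records)))
  key <- interaction(records$treatment, records$time_h, drop = TRUE)
  parts <- split(records, key)
  singletons <- FALSE
  rows <- lapply(parts, function(d) {
    n <- nrow(d)
    s <- if (n > 1) stats::sd(d$percent_area) else {
      singletons <<- TRUE
      0
    }
    data.frame(
      treatment = d$treatment[1], time_h = d$time_h[1],
      mean_percent = mean(d$percent_area), sd = s, sem = s / sqrt(n), n = n
    )
  })
  if (singletons) {
    warning("single-replicate cells present: SD and SEM reported as 0")
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$treatment, out$time_h), , drop = FALSE]
}

#' Paired t test
#'
#' Two-sided paired t test on the differences \code{x - y}: the statistic is
#' \code{mean(d) / (sd(d) / sqrt(n))} on \code{n - 1} degrees of freedom.
#' Identical vectors (zero variance of differences, zero mean) return
#' \code{t = 0, p = 1} rather than erroring, the natural limit.
#'
#' @param x,y numeric vectors of equal length n >= 2.
#' @return list with \code{statistic}, \code{df}, \code{p.value}.
#' @export
pairedTTest <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("paired t test needs at least two pairs")
  d <- x - y
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      return(list(statistic = 0, df = length(d) - 1L, p.value = 1))
    }
    return(list(statistic = sign(mean(d)) * Inf, df = length(d) - 1L,
                p.value = 0))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value)
}

#' One-way ANOVA
#'
#' Standard fixed-effects one-way analysis of variance across k groups,
#' \code{F = MS_between / MS_within} on (k - 1, N - k) degrees of freedom.
#' When all group means coincide exactly (zero between-group sum of squares)
#' the statistic is 0 and p = 1 even if the within-group variance is also 0.
#'
#' @param groups list of numeric vectors, each of length >= 2, at least two
#'   groups.
#' @return list with \code{statistic} (F), \code{dfBetween}, \code{dfWithin},
#'   \code{p.value}.
#' @export
oneWayAnova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need at least two groups")
  }
  if (any(vapply(groups, length, integer(1)) < 2L)) {
    stop("each group needs at least two values")
  }
  value <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  ssb <- sum(tapply(value, grp, length) *
               (tapply(value, grp, mean) - mean(value))^2)
  dfB <- length(groups) - 1L
  dfW <- length(value) - length(groups)
  if (ssb == 0) {
    return(list(statistic = 0, dfBetween = dfB, dfWithin = dfW, p.value = 1))
  }
  tab <- stats::anova(stats::lm(value ~ grp))
  list(statistic = tab[["F value"]][1], dfBetween = tab$Df[1],
       dfWithin = tab$Df[2], p.value = tab[["Pr(>F)"]][1])
}

.sidak <- function(p, m) 1 - (1 - p)^m
.bonferroni <- function(p, m) pmin(1, p * m)

#' Balanced two-way ANOVA with per-timepoint multiple comparisons
#'
#' Fits the standard balanced two-factor model with interaction
#' (treatment x time) to percent-area data and, at every time level, performs
#' all pairwise treatment comparisons using the pooled residual mean square,
#' with family-wise adjustment (Sidak by default, Bonferroni optionally) at
#' the given alpha. The family is the set of pairwise comparisons within one
#' timepoint. Unbalanced designs are rejected.
#'
#' Degenerate layouts with zero residual variance are guarded: an effect
#' whose mean square is 0 gets F = 0 and p = 1; a non-zero effect over a zero
#' residual gets a capped large F (1e300) and p = 0.
#'
#' @param data data.frame with columns \code{percent_area} (or \code{value}),
#'   \code{treatment} and \code{time_h} (or \code{time}).
#' @param alpha family-wise significance level (default 0.05).
#' @param adjust \code{"sidak"} or \code{"bonferroni"}.
#' @return list with \code{anova} (data.frame: term, df, sumsq, meansq, F, p)
#'   and \code{comparisons} (data.frame: time_h, group1, group2, diff, t, df,
#'   p, p_adj, significant).
#' @export
twoWayAnova <- function(data, alpha = 0.05, adjust = c("sidak", "bonferroni")) {
  adjust <- match.arg(adjust)
  stopifnot(is.data.frame(data))
  vcol <- if ("percent_area" %in% names(data)) "percent_area" else "value"
  tcol <- if ("time_h" %in% names(data)) "time_h" else "time"
  if (!all(c(vcol, "treatment", tcol) %in% names(data))) {
    stop("data must have value/percent_area, treatment and time columns")
  }
  y <- data[[vcol]]
  treatment <- factor(data$treatment)
  time <- factor(data[[tcol]])
  if (nlevels(treatment) < 2L || nlevels(time) < 2L) {
    stop("need at least two levels of each factor")
  }
  cellN <- table(treatment, time)
  if (length(unique(as.vector(cellN))) != 1L || any(cellN == 0)) {
    stop("unbalanced design: every treatment x time cell needs the same number of replicates")
  }
  r <- as.vector(cellN)[1]

  fit <- stats::aov(y ~ treatment * time)
  tab <- summary(fit)[[1]]
  terms <- trimws(rownames(tab))
  dfRes <- tab$Df[terms == "Residuals"]
  ## numerically-zero guard: a sum of squares below machine-level rounding of
  ## the total variation counts as exactly zero
  ssTot <- sum((y - mean(y))^2)
  eps <- 1e-10 * max(ssTot, 1e-10)
  isZero <- function(ss) ss <= eps
  msRes <- if (isZero(tab$`Sum Sq`[terms == "Residuals"])) 0
           else tab$`Mean Sq`[terms == "Residuals"]
  guard <- function(ss, ms, df) {
    if (isZero(ss)) return(c(0, 1))
    if (msRes == 0) return(c(1e300, 0))
    f <- ms / msRes
    c(f, stats::pf(f, df, dfRes, lower.tail = FALSE))
  }
  eff <- terms[terms != "Residuals"]
  fp <- t(vapply(eff, function(e) {
    i <- which(terms == e)
    guard(tab$`Sum Sq`[i], tab$`Mean Sq`[i], tab$Df[i])
  }, numeric(2)))
  anovaTab <- data.frame(
    term = c(eff, "Residuals"),
    df = tab$Df,
    sumsq = tab$`Sum Sq`,
    meansq = tab$`Mean Sq`,
    F = c(fp[, 1], NA),
    p = c(fp[, 2], NA),
    row.names = NULL
  )

  ## per-timepoint pairwise treatment comparisons on cell means, pooled MSE
  lv <- levels(treatment)
  pairs <- utils::combn(lv, 2)
  m <- ncol(pairs)
  comp <- list()
  for (tl in levels(time)) {
    for (k in seq_len(m)) {
      a <- pairs[1, k]; b <- pairs[2, k]
      ma <- mean(y[treatment == a & time == tl])
      mb <- mean(y[treatment == b & time == tl])
      diffab <- ma - mb
      if (msRes == 0) {
        nil <- abs(diffab) <= 1e-8 * max(1, abs(ma), abs(mb))
        tstat <- if (nil) 0 else sign(diffab) * 1e300
        p <- if (nil) 1 else 0
      } else {
        se <- sqrt(msRes * 2 / r)
        tstat <- diffab / se
        p <- 2 * stats::pt(abs(tstat), dfRes, lower.tail = FALSE)
      }
      comp[[length(comp) + 1L]] <- data.frame(
        time_h = tl, group1 = a, group2 = b, diff = diffab,
        t = tstat, df = dfRes, p = p
      )
    }
  }
  comp <- do.call(rbind, comp)
  comp$p_adj <- if (adjust == "sidak") .sidak(comp$p, m)
                else .bonferroni(comp$p, m)
  comp$significant <- comp$p_adj < alpha
  list(anova = anovaTab, comparisons = comp)
}

#' Plot kinetics curves (mean +/- SEM per treatment)
#'
#' Line plot of mean percent cell-free area against time with SEM error
#' bars, one line per treatment. Requires ggplot2 (suggested dependency).
#'
#' @param agg output of [aggregateKinetics()].
#' @return a ggplot object.
#' @export
plotKinetics <- function(agg) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotKinetics requires the ggplot2 package")
  }
  ggplot2::ggplot(
    agg,
    ggplot2::aes(x = time_h, y = mean_percent,
                 colour = treatment, group = treatment)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = mean_percent - sem, ymax = mean_percent + sem),
      width = 1.5
    ) +
    ggplot2::labs(x = "Time (h)", y = "% cell-free area",
                  colour = "Treatment") +
    ggplot2::theme_minimal()
}
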