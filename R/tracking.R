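#' @include AllClasses.R
NULL

#' Link per-frame detections into tracks
#'
#' Greedy nearest-neighbour frame-to-frame assignment: between consecutive
#' frames, candidate (track end, detection) pairs are taken in order of
#' increasing distance; each end and each detection is used at most once, and
#' pairs farther apart than \code{maxDispUm} are never linked (the track ends
#' and the detection starts a new track). A simplified stand-in for dedicated
#' cell-tracking software, adequate when cells are well separated relative to
#' their per-frame motion.
#'
#' @param detections data.frame with columns \code{time_h}, \code{x_um},
#'   \code{y_um} (one row per detected centroid); at least two distinct
#'   times.
#' @param maxDispUm maximum linking displacement in um.
#' @return data.frame of tracks with columns \code{cell_id}, \code{time_h},
#'   \code{x_um}, \code{y_um}.
#' @export
linkTracks <- function(detections, maxDispUm) {
  stopifnot(is.data.frame(detections),
            all(c("time_h", "x_um", "y_um") %in% names(detections)),
            maxDispUm > 0)
  times <- sort(unique(detections$time_h))
  if (length(times) < 2L) stop("need detections at two or more frames")

  nextId <- 0L
  newTrack <- function(t, x, y) {
    nextId <<- nextId + 1L
    list(id = nextId, t = t, x = x, y = y)
  }
  first <- detections[detections$time_h == times[1], , drop = FALSE]
  active <- lapply(seq_len(nrow(first)), function(i) {
    newTrack(times[1], first$x_um[i], first$y_um[i])
  })
  finished <- list()

  for (ti in times[-1]) {
    det <- detections[detections$time_h == ti, , drop = FALSE]
    nA <- length(active); nD <- nrow(det)
    linkedA <- logical(nA); linkedD <- logical(nD)
    if (nA > 0 && nD > 0) {
      ax <- vapply(active, function(tr) tr$x[length(tr$x)], numeric(1))
      ay <- vapply(active, function(tr) tr$y[length(tr$y)], numeric(1))
      dmat <- sqrt(outer(ax, det$x_um, "-")^2 + outer(ay, det$y_um, "-")^2)
      ord <- order(dmat)
      for (o in ord) {
        if (dmat[o] > maxDispUm) break
        i <- (o - 1L) %% nA + 1L
        j <- (o - 1L) %/% nA + 1L
        if (linkedA[i] || linkedD[j]) next
        linkedA[i] <- TRUE; linkedD[j] <- TRUE
        active[[i]]$t <- c(active[[i]]$t, ti)
        active[[i]]$x <- c(active[[i]]$x, det$x_um[j])
        active[[i]]$y <- c(active[[i]]$y, det$y_um[j])
      }
    }
    finished <- c(finished, active[!linkedA])
    active <- active[linkedA]
    for (j in which(!linkedD)) {
      active <- c(active, list(newTrack(ti, det$x_um[j], det$y_um[j])))
    }
  }
  all <- c(finished, active)
  rows <- lapply(all, function(tr) {
    data.frame(cell_id = sprintf("track%03d", tr$id), time_h = tr$t,
               x_um = tr$x, y_um = tr$y)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$cell_id, out$time_h), , drop = FALSE]
}

#' Average cell velocity over tracks
#'
#' Per-track speed is the total path length (sum of successive Euclidean
#' steps in um) divided by elapsed time in hours, the usual definition of
#' average cell velocity in migration tracking; \code{method = "net"} uses
#' the net start-to-end displacement instead. Positional jitter inflates the
#' path-length estimate slightly (extra step length per frame), which is why
#' the path definition over-estimates when localization noise is comparable
#' to the per-frame displacement.
#'
#' Tracks with fewer than two samples are skipped with a warning.
#'
#' @param tracks data.frame with columns \code{cell_id}, \code{time_h},
#'   \code{x_um}, \code{y_um}.
#' @param method \code{"path"} (default) or \code{"net"}.
#' @return list with \code{meanSpeed}, \code{sd} (um/h, sample SD over
#'   tracks) and \code{perTrack} (data.frame: cell_id, speed_um_per_h,
#'   n_samples).
#' @export
averageVelocity <- function(tracks, method = c("path", "net")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(tracks),
            all(c("cell_id", "time_h", "x_um", "y_um") %in% names(tracks)))
  parts <- split(tracks, tracks$cell_id)
  skipped <- 0L
  rows <- lapply(parts, function(d) {
    if (nrow(d) < 2L) {
      skipped <<- skipped + 1L
      return(NULL)
    }
    d <- d[order(d$time_h), , drop = FALSE]
    elapsed <- d$time_h[nrow(d)] - d$time_h[1]
    dist <- if (method == "path") {
      sum(sqrt(diff(d$x_um)^2 + diff(d$y_um)^2))
    } else {
      sqrt((d$x_um[nrow(d)] - d$x_um[1])^2 + (d$y_um[nrow(d)] - d$y_um[1])^2)
    }
    data.frame(cell_id = d$cell_id[1], speed_um_per_h = dist / elapsed,
               n_samples = nrow(d))
  })
  if (skipped > 0L) {
    warning(sprintf("%d track(s) with fewer than two samples skipped", skipped))
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) stop("no track with two or more samples")
  perTrack <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  list(
    meanSpeed = mean(perTrack$speed_um_per_h),
    sd = if (nrow(perTrack) > 1) stats::sd(perTrack$speed_um_per_h) else 0,
    perTrack = perTrack
  )
}
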