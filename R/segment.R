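# droplet segmentation and tracking: connected-component labelling on a
# per-frame threshold (Otsu by default), moment-based shape descriptors,
# greedy nearest-centroid linking with explicit fusion handling

#' Segment droplets in a single frame
#'
#' Thresholds the frame (Otsu on the intensity-normalized copy by default, so
#' the result is invariant to affine intensity rescaling), labels connected
#' components, and reports per-droplet shape descriptors: intensity-weighted
#' sub-pixel centroid (row, col; 1-based pixel centres), equivalent-disk
#' radius \code{sqrt(area/pi) * pixel_size}, and the moment-derived major and
#' minor axes in um.
#'
#' @param frame 2-D numeric matrix of intensities.
#' @param pixel_size um/px.
#' @param min_area minimum component area in px (smaller components dropped).
#' @param threshold_policy "otsu", "quantile", or "relative" (a fixed
#'   fraction of the robust intensity range above the floor; appropriate when
#'   droplets carry strong interior structure that would split an
#'   Otsu/bimodal threshold).
#' @param quantile threshold quantile when \code{threshold_policy="quantile"}.
#' @param relative_frac fraction of the robust range (0.1%-99.9% quantiles)
#'   above the floor for \code{threshold_policy="relative"}.
#' @return object of class \code{droplet_mask}: list with \code{labels}
#'   (integer label matrix) and \code{props} (data frame: label, row, col,
#'   area_px, radius_um, major_um, minor_um, mean_intensity). An all-constant
#'   frame yields zero droplets, not an error.
#' @export
segment_frame <- function(frame, pixel_size = 1, min_area = 9L,
                          threshold_policy = c("otsu", "quantile", "relative"),
                          quantile = 0.99, relative_frac = 0.15) {
  threshold_policy <- match.arg(threshold_policy)
  if (!all(is.finite(frame))) stop_coac("frame contains non-finite values")
  if (min_area < 1L) stop_coac("min_area must be >= 1")
  rng <- range(frame)
  empty <- function() {
    structure(list(labels = matrix(0L, nrow(frame), ncol(frame)),
                   props = data.frame(label = integer(), row = numeric(),
                                      col = numeric(), area_px = numeric(),
                                      radius_um = numeric(), major_um = numeric(),
                                      minor_um = numeric(),
                                      mean_intensity = numeric()),
                   pixel_size = pixel_size),
              class = "droplet_mask")
  }
  if (diff(rng) == 0) return(empty())
  norm <- (frame - rng[1]) / diff(rng)
  thr <- switch(threshold_policy,
    otsu = EBImage::otsu(EBImage::Image(norm), range = c(0, 1)),
    quantile = stats::quantile(norm, quantile, names = FALSE),
    relative = {
      q <- stats::quantile(norm, c(0.001, 0.999), names = FALSE)
      q[1] + relative_frac * (q[2] - q[1])
    })
  bw <- norm > thr
  labels <- EBImage::bwlabel(EBImage::Image(bw))
  lab <- EBImage::imageData(labels)
  if (max(lab) == 0) return(empty())
  areas <- tabulate(lab[lab > 0L])
  keep <- which(areas >= min_area)
  if (length(keep) == 0L) return(empty())
  # drop small components, relabel compactly
  lab[!(lab %in% keep)] <- 0L
  lab <- match(lab, c(0L, keep)) - 1L
  dim(lab) <- dim(frame)
  labimg <- EBImage::Image(lab)
  mom <- EBImage::computeFeatures.moment(labimg, ref = EBImage::Image(norm))
  shp <- EBImage::computeFeatures.shape(labimg)
  mom <- matrix(mom, ncol = 5L,
                dimnames = list(NULL, c("m.cx", "m.cy", "m.majoraxis",
                                        "m.eccentricity", "m.theta")))
  minor <- mom[, "m.majoraxis"] * sqrt(1 - mom[, "m.eccentricity"]^2)
  area <- shp[, "s.area"]
  means <- vapply(seq_len(max(lab)), function(l) mean(frame[lab == l]),
                  numeric(1))
  props <- data.frame(
    label = seq_len(max(lab)),
    row = mom[, "m.cx"], col = mom[, "m.cy"],
    area_px = as.numeric(area),
    radius_um = sqrt(area / pi) * pixel_size,
    major_um = mom[, "m.majoraxis"] * pixel_size,
    minor_um = minor * pixel_size,
    mean_intensity = means
  )
  structure(list(labels = matrix(as.integer(lab), nrow(frame), ncol(frame)),
                 props = props, pixel_size = pixel_size),
            class = "droplet_mask")
}

#' @export
print.droplet_mask <- function(x, ...) {
  cat(sprintf("<droplet_mask> %d droplet(s)\n", nrow(x$props)))
  if (nrow(x$props)) print(x$props, digits = 4)
  invisible(x)
}

#' Link per-frame droplet masks into tracks
#'
#' Greedy nearest-centroid linking: each track head is linked to the nearest
#' unclaimed centroid in the next frame within \code{max_step}; ties are
#' broken by smaller label index so linking is deterministic. A next-frame
#' droplet lying within \code{max_step} of two or more track heads is treated
#' as a fusion: both parent tracks terminate and a new track starts there,
#' flagged with its parents.
#'
#' @param masks list of \code{droplet_mask}, frame-ordered.
#' @param max_step maximum centroid displacement per frame, um.
#' @return list of \code{droplet_track} objects; each is a data frame
#'   (frame, label, row, col, area_px, radius_um, major_um, minor_um) with
#'   attributes \code{track_id} and \code{merged_from} (integer parent ids,
#'   empty if none).
#' @export
track_droplets <- function(masks, max_step = 2) {
  check_pos(max_step, "max_step")
  tracks <- list()   # each: list(rows = data.frame, open = TRUE, merged_from)
  new_track <- function(frame, p, merged_from = integer()) {
    tracks[[length(tracks) + 1L]] <<- list(
      rows = cbind(frame = frame, p), open = TRUE, merged_from = merged_from)
  }
  px <- masks[[1]]$pixel_size
  p1 <- masks[[1]]$props
  for (i in seq_len(nrow(p1))) new_track(1L, p1[i, , drop = FALSE])
  for (f in seq_along(masks)[-1]) {
    props <- masks[[f]]$props
    open_idx <- which(vapply(tracks, `[[`, logical(1), "open"))
    heads <- lapply(tracks[open_idx], function(tr) tr$rows[nrow(tr$rows), ])
    if (nrow(props) == 0L) {
      for (i in open_idx) tracks[[i]]$open <- FALSE
      next
    }
    # distance matrix (um) between open track heads and current centroids
    dmat <- matrix(Inf, length(open_idx), nrow(props))
    for (a in seq_along(open_idx)) {
      h <- heads[[a]]
      dmat[a, ] <- sqrt((props$row - h$row)^2 + (props$col - h$col)^2) * px
    }
    within <- dmat <= max_step
    n_near <- colSums(within)
    fused <- which(n_near >= 2L)
    claimed <- rep(FALSE, nrow(props))
    for (j in fused) {
      parents <- open_idx[within[, j]]
      for (i in parents) tracks[[i]]$open <- FALSE
      new_track(f, props[j, , drop = FALSE], merged_from = parents)
      claimed[j] <- TRUE
      dmat[, j] <- Inf
    }
    # greedy assignment of remaining candidates, global-minimum first;
    # ties broken by smaller label index via column order
    repeat {
      if (all(!is.finite(dmat)) || all(claimed)) break
      best <- which(dmat == min(dmat), arr.ind = TRUE)
      if (!is.finite(min(dmat)) || min(dmat) > max_step) break
      best <- best[order(best[, 2]), , drop = FALSE][1, ]
      a <- best[1]; j <- best[2]
      ti <- open_idx[a]
      tracks[[ti]]$rows <- rbind(tracks[[ti]]$rows,
                                 cbind(frame = f, props[j, , drop = FALSE]))
      claimed[j] <- TRUE
      dmat[a, ] <- Inf
      dmat[, j] <- Inf
    }
    # unmatched heads terminate; unmatched droplets start tracks
    still_open <- which(vapply(tracks, `[[`, logical(1), "open"))
    for (i in still_open) {
      tr <- tracks[[i]]
      if (tr$rows$frame[nrow(tr$rows)] < f) tracks[[i]]$open <- FALSE
    }
    for (j in which(!claimed)) new_track(f, props[j, , drop = FALSE])
  }
  out <- lapply(seq_along(tracks), function(i) {
    rows <- tracks[[i]]$rows
    rows$mean_intensity <- NULL
    rownames(rows) <- NULL
    structure(rows, class = c("droplet_track", "data.frame"),
              track_id = i, merged_from = tracks[[i]]$merged_from)
  })
  out
}

#' @export
print.droplet_track <- function(x, ...) {
  mf <- attr(x, "merged_from")
  cat(sprintf("<droplet_track #%d> frames %d-%d%s\n", attr(x, "track_id"),
              min(x$frame), max(x$frame),
              if (length(mf)) paste0(" (fusion of tracks ",
                                     paste(mf, collapse = "+"), ")") else ""))
  invisible(print.data.frame(x, digits = 4))
}

#' Whole-droplet trace from a two-channel acquisition
#'
#' Segments every frame of the mask channel and reports, per frame, the mean
#' intensity of the measured channel within the union droplet mask. Used for
#' whole-droplet FRAP where one label recovers immediately (the peptide) and
#' provides the mask while the slow channel (RNA) is measured.
#'
#' @param stacks named list of \code{image_stack} objects (one per channel).
#' @param mask_channel,measure_channel channel names within \code{stacks}.
#' @param min_area,threshold_policy passed to \code{\link{segment_frame}}.
#' @return a \code{trace_table} with columns \code{time_s},
#'   \code{measured_mean} (NA where the mask was empty, with a warning).
#' @export
whole_droplet_mask_from_channel <- function(stacks, mask_channel,
                                            measure_channel, min_area = 9L,
                                            threshold_policy = "otsu") {
  for (ch in c(mask_channel, measure_channel)) {
    if (!ch %in% names(stacks)) stop_coac("unknown channel label '%s'", ch)
  }
  sm <- stacks[[mask_channel]]
  sv <- stacks[[measure_channel]]
  if (!identical(dim(sm$frames), dim(sv$frames))) {
    stop_coac("channels must share dimensions and frame count")
  }
  nt <- n_frames(sm)
  vals <- rep(NA_real_, nt)
  n_empty <- 0L
  for (t in seq_len(nt)) {
    dm <- segment_frame(sm$frames[, , t], pixel_size = sm$pixel_size,
                        min_area = min_area,
                        threshold_policy = threshold_policy)
    inside <- dm$labels > 0L
    if (!any(inside)) {
      n_empty <- n_empty + 1L
    } else {
      vals[t] <- mean(sv$frames[, , t][inside])
    }
  }
  if (n_empty > 0L) {
    warning(sprintf("empty droplet mask in %d frame(s); reported as missing",
                    n_empty), call. = FALSE)
  }
  trace_table(time_s = frame_times(sm), measured_mean = vals,
              units = c(measured_mean = "a.u."))
}
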