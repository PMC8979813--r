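# droplet coalescence: aspect-ratio relaxation fits and the inverse capillary
# velocity eta/gamma from tau(r) = a * r with the intercept fixed at 0

#' Aspect-ratio time series of a post-fusion droplet
#'
#' Extracts AR(t) = major/minor axis from a tracked droplet, with time rebased
#' to the fusion start. Frames missing from the track (failed segmentation)
#' appear as NA and are not interpolated.
#'
#' @param track a \code{droplet_track} covering the post-merge droplet.
#' @param fusion_start_frame frame index of the first post-merge frame
#'   (defaults to the first frame of the track).
#' @param frame_interval s per frame.
#' @return object of class \code{ar_series}: data frame (time_s, ar).
#' @export
aspect_ratio_series <- function(track, fusion_start_frame = NULL,
                                frame_interval = 1) {
  if (is.null(fusion_start_frame)) fusion_start_frame <- min(track$frame)
  frames <- seq(min(track$frame), max(track$frame))
  ar <- rep(NA_real_, length(frames))
  i <- match(track$frame, frames)
  ar[i] <- track$major_um / track$minor_um
  out <- data.frame(time_s = (frames - fusion_start_frame) * frame_interval,
                    ar = ar)
  structure(out, class = c("ar_series", "data.frame"))
}

#' Fit the coalescence relaxation exponential
#'
#' Least-squares fit of \code{f(t) = A*exp(-t/tau) + c} to an aspect-ratio
#' series; \code{c} is the offset to a perfect sphere (~1). Initialization:
#' c at 1, A at AR(0) - 1, tau at the time to half relaxation. A fitted
#' \code{|c - 1| >= 0.2} flags likely segmentation problems; a series that
#' does not decrease overall is flagged "no_relaxation".
#'
#' @param ar numeric AR values or an \code{ar_series}.
#' @param time_s times (s) when \code{ar} is a bare vector.
#' @param tol relative convergence tolerance.
#' @return object of class \code{relaxation_fit} with coefficients
#'   (A, tau, c), covariance, fitted curve and \code{flags}.
#' @export
fit_relaxation <- function(ar, time_s = NULL, tol = 1e-8) {
  if (inherits(ar, "ar_series")) {
    time_s <- ar$time_s
    ar <- ar$ar
  }
  keep <- is.finite(ar) & is.finite(time_s)
  y <- ar[keep]; tt <- time_s[keep]
  if (length(y) < 5L) stop_coac("need >= 5 finite points")
  if (any(y < 1 - 1e-6)) stop_coac("aspect ratio must be >= 1")
  flags <- character()
  A0 <- y[1] - 1
  if (A0 < 0.02) {
    return(structure(list(coefficients = c(A = max(A0, 0), tau = NA_real_,
                                           c = mean(y)),
                          vcov = NULL,
                          curve = data.frame(time_s = tt, ar = y,
                                             fitted = rep(mean(y), length(y))),
                          flags = "amplitude_unidentifiable"),
                     class = "relaxation_fit"))
  }
  if (y[length(y)] >= y[1]) flags <- c(flags, "no_relaxation")
  half <- 1 + A0 / 2
  ih <- which(y <= half)[1]
  tau0 <- if (!is.na(ih) && tt[ih] > 0) tt[ih] / log(2) else diff(range(tt)) / 5
  fit <- fit_ls(function(tt, p) p[["A"]] * exp(-tt / p[["tau"]]) + p[["c"]],
                start = c(A = A0, tau = tau0, c = 1),
                x = tt, y = y, lower = c(0, 1e-9, 0.5), upper = c(Inf, Inf, 2),
                ftol = tol, context = "relaxation fit")
  co <- fit$par
  names(co) <- c("A", "tau", "c")
  if (abs(co[["c"]] - 1) >= 0.2) flags <- c(flags, "offset_far_from_sphere")
  structure(list(coefficients = co, vcov = fit$vcov,
                 curve = data.frame(time_s = tt, ar = y, fitted = fit$fitted),
                 flags = flags, deviance = fit$deviance),
            class = "relaxation_fit")
}

#' @export
coef.relaxation_fit <- function(object, ...) object$coefficients

#' @export
print.relaxation_fit <- function(x, ...) {
  co <- x$coefficients
  cat(sprintf("<relaxation_fit> A = %.4g, tau = %.4g s, c = %.4g%s\n",
              co["A"], co["tau"], co["c"],
              if (length(x$flags)) paste0("  [", paste(x$flags, collapse = ", "),
                                          "]") else ""))
  invisible(x)
}

#' @export
predict.relaxation_fit <- function(object, time_s = NULL, ...) {
  if (is.null(time_s)) return(object$curve$fitted)
  co <- object$coefficients
  co[["A"]] * exp(-time_s / co[["tau"]]) + co[["c"]]
}

#' @export
plot.relaxation_fit <- function(x, ...) {
  graphics::plot(x$curve$time_s, x$curve$ar, pch = 16, cex = 0.6,
                 xlab = "time (s)", ylab = "aspect ratio", ...)
  graphics::lines(x$curve$time_s, x$curve$fitted, col = 2, lwd = 2)
  invisible(x)
}

#' Bundle one fusion event
#'
#' @param tau fitted relaxation time constant, s.
#' @param r1,r2 pre-fusion droplet radii, um (taken from the last frame before
#'   the merge).
#' @param fit optional \code{relaxation_fit}.
#' @return object of class \code{fusion_event} with \code{r_geo = sqrt(r1*r2)}.
#' @export
fusion_event <- function(tau, r1, r2, fit = NULL) {
  check_pos(tau, "tau"); check_pos(r1, "r1"); check_pos(r2, "r2")
  structure(list(tau = tau, r1 = r1, r2 = r2, r_geo = sqrt(r1 * r2),
                 fit = fit),
            class = "fusion_event")
}

#' Inverse capillary velocity from fusion events
#'
#' Origin-constrained least squares of the relaxation time constant on the
#' geometric radius, \code{tau(r) = a * r}; the slope a is the inverse
#' capillary velocity eta/gamma (s/um). The closed form of the slope is
#' \code{sum(tau*r) / sum(r^2)}.
#'
#' @param events list of \code{fusion_event}, or data frame with columns
#'   \code{tau} and \code{r_geo}.
#' @return object of class \code{capillary_fit}: slope a (s/um), 95% CI
#'   (undefined with a single event), and the per-event points.
#' @export
capillary_velocity <- function(events) {
  pts <- if (is.data.frame(events)) {
    events[, c("r_geo", "tau")]
  } else {
    data.frame(r_geo = vapply(events, `[[`, numeric(1), "r_geo"),
               tau = vapply(events, `[[`, numeric(1), "tau"))
  }
  if (nrow(pts) < 1L) stop_coac("need at least one fusion event")
  if (nrow(pts) == 1L) {
    a <- pts$tau / pts$r_geo
    return(structure(list(slope = a, lower = NA_real_, upper = NA_real_,
                          points = pts, lm = NULL),
                     class = "capillary_fit"))
  }
  fit <- stats::lm(tau ~ 0 + r_geo, data = pts)
  ci <- if (nrow(pts) > 1L && stats::df.residual(fit) > 0) {
    # summary.lm warns on an essentially perfect fit; the zero-width CI is
    # exactly what we want to report there
    suppressWarnings(stats::confint(fit, level = 0.95))
  } else {
    matrix(NA_real_, 1, 2)
  }
  structure(list(slope = unname(stats::coef(fit)[["r_geo"]]),
                 lower = ci[1, 1], upper = ci[1, 2], points = pts, lm = fit),
            class = "capillary_fit")
}

#' @export
coef.capillary_fit <- function(object, ...) c(a = object$slope)

#' @export
print.capillary_fit <- function(x, ...) {
  cat(sprintf(
    "<capillary_fit> inverse capillary velocity a = %.4g s/um, 95%% CI [%.4g, %.4g], %d event(s)\n",
    x$slope, x$lower, x$upper, nrow(x$points)))
  invisible(x)
}

#' @export
plot.capillary_fit <- function(x, ...) {
  graphics::plot(x$points$r_geo, x$points$tau, pch = 16,
                 xlab = "geometric radius (um)", ylab = "tau (s)", ...)
  graphics::abline(a = 0, b = x$slope, col = 2, lwd = 2)
  invisible(x)
}

#' End-to-end fusion analysis of a movie
#'
#' Segments and tracks droplets, locates the fusion (merge-flagged track),
#' takes the pre-fusion radii from the last frame of the parent tracks,
#' extracts the post-merge aspect-ratio series (window ends when AR drops
#' below \code{ar_stop} or the series ends), and fits the relaxation.
#'
#' @param stack an \code{image_stack} of a coalescing pair.
#' @param max_step tracking step limit, um/frame.
#' @param ar_stop fit-window stop threshold on AR (default 1.05).
#' @param min_area passed to \code{\link{segment_frame}}.
#' @return a \code{fusion_event} (with the fitted relaxation in \code{$fit}).
#' @export
analyze_fusion_movie <- function(stack, max_step = 2, ar_stop = 1.05,
                                 min_area = 9L) {
  nt <- n_frames(stack)
  masks <- lapply(seq_len(nt), function(t) {
    segment_frame(stack$frames[, , t], pixel_size = stack$pixel_size,
                  min_area = min_area)
  })
  tracks <- track_droplets(masks, max_step = max_step)
  merged <- Filter(function(tr) length(attr(tr, "merged_from")) >= 2L, tracks)
  if (length(merged) == 0L) stop_coac("no fusion event found in the movie")
  tr <- merged[[1]]
  parents <- attr(tr, "merged_from")
  radii <- vapply(tracks[parents], function(p) p$radius_um[nrow(p)], numeric(1))
  ars <- aspect_ratio_series(tr, frame_interval = stack$frame_interval)
  stop_i <- which(ars$ar < ar_stop)[1]
  if (!is.na(stop_i) && stop_i >= 5L) ars <- ars[seq_len(stop_i), ]
  fit <- fit_relaxation(ars)
  fusion_event(tau = coef(fit)[["tau"]], r1 = radii[1], r2 = radii[2],
               fit = fit)
}
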