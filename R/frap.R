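# FRAP analysis: four-ROI normalization, exponential recovery fit, apparent
# diffusion coefficient D = 0.88 r^2 / (4 tau ln 2)

#' FRAP ROI traces
#'
#' Per-frame mean intensities of the four regions of interest of a FRAP
#' experiment: bleached region, whole droplet, unbleached reference droplet,
#' and background.
#'
#' @param time_s frame times, s.
#' @param bleach,whole,reference,background numeric traces of equal length.
#' @param bleach_radius_um radius r of the bleaching region, um.
#' @param t_bleach bleach frame index (1-based), or NA for auto-detection.
#' @param pre_bleach_frames number of frames before the bleach used for
#'   normalization (default 20).
#' @return object of class \code{frap_traces}.
#' @export
frap_traces <- function(time_s, bleach, whole, reference, background,
                        bleach_radius_um, t_bleach = NA_integer_,
                        pre_bleach_frames = 20L) {
  n <- length(time_s)
  if (!all(lengths(list(bleach, whole, reference, background)) == n)) {
    stop_coac("all four traces must have the same length as time_s")
  }
  check_pos(bleach_radius_um, "bleach_radius_um")
  if (pre_bleach_frames < 1L) stop_coac("pre_bleach_frames must be >= 1")
  if (!is.na(t_bleach) && t_bleach < pre_bleach_frames) {
    stop_coac("bleach frame %d lies inside the pre-bleach window", t_bleach)
  }
  structure(list(time_s = time_s, bleach = bleach, whole = whole,
                 reference = reference, background = background,
                 bleach_radius_um = bleach_radius_um,
                 t_bleach = as.integer(t_bleach),
                 pre_bleach_frames = as.integer(pre_bleach_frames)),
            class = "frap_traces")
}

#' Normalize FRAP traces to a recovery curve
#'
#' Normalization pipeline, in order: (1) subtract the background trace from
#' the bleach, whole-droplet and reference traces; (2) correct for acquisition
#' photobleaching by dividing bleach and whole by the reference; (3) divide
#' each by its own pre-bleach-window mean; (4) divide the bleach series by the
#' whole-droplet series. Pre-bleach values are ~1 by construction, and the
#' output is invariant to adding a common constant to all four traces and to
#' multiplying all four by a common positive time-varying factor.
#'
#' @param traces a \code{frap_traces}.
#' @return object of class \code{recovery_curve}: data frame (time_s, value)
#'   with attributes \code{t_bleach} (frame index; detected as the argmin of
#'   the curve if not supplied), \code{bleach_radius_um},
#'   \code{pre_bleach_frames}.
#' @export
normalize_frap <- function(traces) {
  stopifnot(inherits(traces, "frap_traces"))
  npre <- traces$pre_bleach_frames
  if (npre >= length(traces$time_s)) {
    stop_coac("pre-bleach window (%d frames) longer than the trace", npre)
  }
  ref <- traces$reference - traces$background
  bad <- which(ref <= 0)
  if (length(bad)) {
    stop_coac("reference minus background is non-positive at frame %d", bad[1])
  }
  b <- (traces$bleach - traces$background) / ref
  w <- (traces$whole - traces$background) / ref
  pre <- seq_len(npre)
  if (mean(b[pre]) <= 0 || mean(w[pre]) <= 0) {
    stop_coac("pre-bleach window mean must be positive")
  }
  b <- b / mean(b[pre])
  w <- w / mean(w[pre])
  value <- b / w
  tb <- traces$t_bleach
  if (is.na(tb)) tb <- which.min(value)
  out <- data.frame(time_s = traces$time_s, value = value)
  structure(out, class = c("recovery_curve", "data.frame"),
            t_bleach = as.integer(tb),
            bleach_radius_um = traces$bleach_radius_um,
            pre_bleach_frames = npre)
}

#' Fit the exponential FRAP recovery model
#'
#' Fits \code{1 - A*exp(-(t - t_bleach)/tau) + C} to the post-bleach part of a
#' normalized recovery curve by least squares (pre-bleach frames are used only
#' for normalization). \code{C} is the offset to complete recovery; set
#' \code{fix_C = TRUE} to pin it at 0, the convention applied when full
#' recovery is not observed.
#'
#' @param curve a \code{recovery_curve}, or numeric vector with \code{time_s}.
#' @param time_s frame times when \code{curve} is a bare numeric vector.
#' @param t_bleach bleach frame index; defaults to the curve attribute or the
#'   argmin of the series.
#' @param fix_C logical; fix C = 0.
#' @param tol relative convergence tolerance.
#' @return object of class \code{frap_fit} with coefficients (A, tau, C), the
#'   parameter covariance, the fitted curve, and a \code{flags} character
#'   vector ("amplitude_unidentifiable" for flat curves, "tau_at_bound" when
#'   the time constant pinned at a box bound).
#' @export
fit_recovery <- function(curve, time_s = NULL, t_bleach = NULL,
                         fix_C = FALSE, tol = 1e-8) {
  if (inherits(curve, "recovery_curve")) {
    time_s <- curve$time_s
    if (is.null(t_bleach)) t_bleach <- attr(curve, "t_bleach")
    y_all <- curve$value
  } else {
    y_all <- as.numeric(curve)
    if (is.null(time_s)) stop_coac("`time_s` required for a bare numeric curve")
  }
  if (!all(is.finite(y_all))) stop_coac("curve contains non-finite values")
  if (is.null(t_bleach) || is.na(t_bleach)) t_bleach <- which.min(y_all)
  idx <- t_bleach:length(y_all)
  if (length(idx) < 5L) stop_coac("need >= 5 post-bleach points")
  tb_time <- time_s[t_bleach]
  tt <- time_s[idx] - tb_time
  y <- y_all[idx]
  flags <- character()

  A0 <- 1 - y[1]
  plateau <- mean(y[max(1L, length(y) - max(5L, length(y) %/% 10)):length(y)])
  if (A0 < 0.02 || stats::sd(y) < 1e-12) {
    # flat curve: amplitude and tau are unidentifiable
    co <- c(A = max(A0, 0), tau = NA_real_, C = 0)
    return(structure(list(coefficients = co, vcov = NULL,
                          curve = data.frame(time_s = time_s[idx], value = y,
                                             fitted = rep(mean(y), length(y))),
                          t_bleach = t_bleach, t_bleach_time = tb_time,
                          fix_C = fix_C,
                          flags = "amplitude_unidentifiable"),
                     class = "frap_fit"))
  }
  # tau init: time to half recovery towards the plateau
  half <- y[1] + (plateau - y[1]) / 2
  ih <- which(y >= half)[1]
  tau0 <- if (!is.na(ih) && tt[ih] > 0) tt[ih] / log(2) else diff(range(tt)) / 5
  fit <- if (fix_C) {
    fit_ls(function(tt, p) 1 - p[["A"]] * exp(-tt / p[["tau"]]),
           start = c(A = min(max(A0, 1e-3), 1.4), tau = tau0),
           x = tt, y = y, lower = c(0, 1e-9), upper = c(1.5, Inf),
           ftol = tol, context = "FRAP recovery fit")
  } else {
    fit_ls(function(tt, p) 1 - p[["A"]] * exp(-tt / p[["tau"]]) + p[["C"]],
           start = c(A = min(max(A0, 1e-3), 1.4), tau = tau0, C = 0),
           x = tt, y = y, lower = c(0, 1e-9, -0.5), upper = c(1.5, Inf, 0.5),
           ftol = tol, context = "FRAP recovery fit")
  }
  co <- if (fix_C) c(fit$par, C = 0) else fit$par
  names(co) <- c("A", "tau", "C")
  if (co[["A"]] >= 1.5 - 1e-9) flags <- c(flags, "A_at_bound")
  if (co[["tau"]] <= 2e-9) flags <- c(flags, "tau_at_bound")
  structure(list(coefficients = co, vcov = fit$vcov,
                 curve = data.frame(time_s = time_s[idx], value = y,
                                    fitted = fit$fitted),
                 t_bleach = t_bleach, t_bleach_time = tb_time,
                 fix_C = fix_C, flags = flags, deviance = fit$deviance),
            class = "frap_fit")
}

#' @export
coef.frap_fit <- function(object, ...) object$coefficients

#' @export
print.frap_fit <- function(x, ...) {
  co <- x$coefficients
  cat(sprintf("<frap_fit> A = %.4g, tau = %.4g s, C = %.4g%s\n",
              co["A"], co["tau"], co["C"],
              if (length(x$flags)) paste0("  [", paste(x$flags, collapse = ", "),
                                          "]") else ""))
  invisible(x)
}

#' @export
predict.frap_fit <- function(object, time_s = NULL, ...) {
  if (is.null(time_s)) return(object$curve$fitted)
  co <- object$coefficients
  tt <- time_s - object$t_bleach_time
  ifelse(tt < 0, 1, 1 - co["A"] * exp(-tt / co["tau"]) + co["C"])
}

#' @export
residuals.frap_fit <- function(object, ...) {
  object$curve$value - object$curve$fitted
}

#' @export
plot.frap_fit <- function(x, ...) {
  graphics::plot(x$curve$time_s, x$curve$value, pch = 16, cex = 0.5,
                 xlab = "time (s)", ylab = "normalized intensity", ...)
  graphics::lines(x$curve$time_s, x$curve$fitted, col = 2, lwd = 2)
  invisible(x)
}

#' Apparent diffusion coefficient from a FRAP time constant
#'
#' \code{D = 0.88 * r^2 / (4 * tau * ln 2)}, where r is the radius of the
#' bleaching region. The 0.88 prefactor is an experimentally calibrated
#' constant of the half-time relation and is used verbatim.
#'
#' @param tau fitted recovery time constant, s.
#' @param r bleach-region radius, um.
#' @return D in um^2/s (vectorized).
#' @export
diffusion_from_fit <- function(tau, r) {
  if (any(tau <= 0) || any(r <= 0)) stop_coac("tau and r must be positive")
  0.88 * r^2 / (4 * tau * log(2))
}

#' Summarize per-droplet diffusion coefficients
#'
#' Arithmetic mean of per-droplet D values with a t-distribution 95%
#' confidence interval.
#'
#' @param estimates numeric vector of per-droplet D, um^2/s.
#' @param level confidence level (default 0.95).
#' @return object of class \code{diffusion_estimate}: list(mean, lower, upper,
#'   n, values). With n < 2 the CI is NA and reported as undefined.
#' @export
summarize_diffusion <- function(estimates, level = 0.95) {
  estimates <- estimates[is.finite(estimates)]
  ci <- t_ci(estimates, level)
  structure(list(mean = ci[["mean"]], lower = ci[["lower"]],
                 upper = ci[["upper"]], n = length(estimates),
                 level = level, values = estimates),
            class = "diffusion_estimate")
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  if (x$n < 2) {
    cat(sprintf("<diffusion_estimate> D = %.4g um^2/s (n = %d; CI undefined)\n",
                x$mean, x$n))
  } else {
    cat(sprintf("<diffusion_estimate> D = %.4g um^2/s, %d%% CI [%.4g, %.4g], n = %d\n",
                x$mean, round(100 * x$level), x$lower, x$upper, x$n))
  }
  invisible(x)
}

# mean ROI traces for a set of pixel masks, vectorized over frames
roi_traces <- function(stack, masks) {
  d <- dim(stack$frames)
  m <- matrix(stack$frames, nrow = d[1] * d[2])
  lapply(masks, function(mask) {
    idx <- which(as.logical(mask))
    if (length(idx) == 0L) stop_coac("empty ROI mask")
    colMeans(m[idx, , drop = FALSE])
  })
}

disk_mask <- function(nrow, ncol, row, col, radius_px) {
  rr <- matrix(seq_len(nrow), nrow, ncol)
  cc <- matrix(seq_len(ncol), nrow, ncol, byrow = TRUE)
  (rr - row)^2 + (cc - col)^2 <= radius_px^2
}

#' End-to-end FRAP analysis of a movie
#'
#' Runs the full pipeline on a single-channel movie containing a bleached
#' droplet and an unbleached reference droplet: segments the first frame,
#' extracts per-droplet raw traces, detects the bleach frame (argmin of the
#' per-droplet trace; the droplet with the largest fractional drop is the
#' bleached one, the one with the smallest is the reference), builds the four
#' ROI traces (bleach disk of radius \code{bleach_radius_um} at the bleached
#' droplet centre, whole bleached droplet, reference droplet, background =
#' unlabelled pixels), normalizes, fits the recovery, and converts tau to D.
#'
#' @param stack an \code{image_stack}.
#' @param bleach_radius_um radius of the bleaching region, um (experimental
#'   setting, not inferred from the data).
#' @param pre_bleach_frames frames before the bleach (default 20).
#' @param t_bleach fixed bleach frame index, or NA for auto-detection.
#' @param fix_C passed to \code{\link{fit_recovery}}.
#' @param min_area passed to \code{\link{segment_frame}}.
#' @return object of class \code{frap_analysis}: list(fit, D, traces, curve,
#'   t_bleach, droplets).
#' @export
analyze_frap_movie <- function(stack, bleach_radius_um,
                               pre_bleach_frames = 20L, t_bleach = NA,
                               fix_C = FALSE, min_area = 9L) {
  dm <- segment_frame(stack$frames[, , 1], pixel_size = stack$pixel_size,
                      min_area = min_area)
  if (nrow(dm$props) < 2L) {
    stop_coac("need a bleached and a reference droplet; found %d droplet(s)",
              nrow(dm$props))
  }
  d <- dim(stack$frames)
  m <- matrix(stack$frames, nrow = d[1] * d[2])
  lab_trace <- function(l) colMeans(m[which(dm$labels == l), , drop = FALSE])
  raw <- vapply(dm$props$label, lab_trace, numeric(d[3]))
  pre <- seq_len(pre_bleach_frames)
  # bleach detection on the sharpest frame-to-frame drop (robust to slow
  # acquisition photobleaching), relative to the pre-bleach level
  step_drop <- apply(raw, 2L, function(tr) -min(diff(tr)) / mean(tr[pre]))
  bl <- which.max(step_drop)
  rf <- which.min(step_drop)
  if (bl == rf) stop_coac("could not distinguish bleached from reference droplet")
  tb <- if (is.na(t_bleach)) {
    which.min(diff(raw[, bl])) + 1L
  } else {
    as.integer(t_bleach)
  }
  r_px <- bleach_radius_um / stack$pixel_size
  masks <- list(
    bleach = disk_mask(d[1], d[2], dm$props$row[bl], dm$props$col[bl], r_px),
    whole = dm$labels == dm$props$label[bl],
    reference = dm$labels == dm$props$label[rf],
    background = dm$labels == 0L
  )
  tr <- roi_traces(stack, masks)
  traces <- frap_traces(frame_times(stack), tr$bleach, tr$whole, tr$reference,
                        tr$background, bleach_radius_um = bleach_radius_um,
                        t_bleach = tb, pre_bleach_frames = pre_bleach_frames)
  curve <- normalize_frap(traces)
  fit <- fit_recovery(curve, fix_C = fix_C)
  D <- if (is.na(coef(fit)[["tau"]])) NA_real_ else {
    diffusion_from_fit(coef(fit)[["tau"]], bleach_radius_um)
  }
  structure(list(fit = fit, D = D, traces = traces, curve = curve,
                 t_bleach = tb, droplets = dm$props),
            class = "frap_analysis")
}

#' @export
print.frap_analysis <- function(x, ...) {
  cat(sprintf("<frap_analysis> bleach frame %d, tau = %.4g s, D = %.4g um^2/s\n",
              x$t_bleach, coef(x$fit)[["tau"]], x$D))
  invisible(x)
}
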