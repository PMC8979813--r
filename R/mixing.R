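# two-colour mixing kinetics: per-droplet Pearson correlation between
# channels over time, aggregated across droplets and fitted with a single
# exponential as a guide

#' Pearson correlation between two channels inside a droplet
#'
#' Sample Pearson correlation computed over the masked pixels only; the
#' background is excluded so the droplet/background contrast cannot inflate
#' the coefficient. Invariant to independent affine intensity rescaling of
#' either channel.
#'
#' @param imgA,imgB 2-D matrices of the same dimensions.
#' @param mask logical (or 0/1) matrix selecting the droplet pixels.
#' @return the correlation coefficient, or NA when a channel is constant
#'   within the mask (undefined).
#' @export
droplet_pearson <- function(imgA, imgB, mask) {
  if (!identical(dim(imgA), dim(imgB))) stop_coac("images must share dimensions")
  if (!identical(dim(imgA), dim(mask))) stop_coac("mask must match image size")
  idx <- which(as.logical(mask))
  if (length(idx) == 0L) stop_coac("mask is empty")
  a <- imgA[idx]; b <- imgB[idx]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Mixing time course across droplets
#'
#' Computes the per-droplet two-channel Pearson coefficient at every
#' timepoint, aggregates across droplets (mean with a t-based 95% CI on
#' Fisher z-transformed coefficients, back-transformed), and fits
#' \code{rho(t) = A*exp(-t/tau) + rho_inf} as a guide to the mixing kinetics.
#'
#' Droplets are segmented on the summed channels at the first timepoint and
#' matched at later timepoints by nearest centroid; a droplet whose match
#' fails at some timepoint is excluded from later timepoints (logged).
#'
#' @param stackA,stackB \code{image_stack} objects (one frame per timepoint).
#' @param masks optional list of label matrices (one per timepoint)
#'   overriding segmentation.
#' @param max_step matching limit for droplet identity across timepoints, um.
#' @param min_area passed to \code{\link{segment_frame}}.
#' @return object of class \code{mixing_series}: \code{table} (time_s,
#'   droplet_id, rho), \code{summary} (time_s, mean, lower, upper, n),
#'   \code{coefficients} (A, tau, rho_inf) and \code{flags}.
#' @export
mixing_timecourse <- function(stackA, stackB, masks = NULL, max_step = 2,
                              min_area = 9L) {
  if (!identical(dim(stackA$frames), dim(stackB$frames))) {
    stop_coac("channels must share dimensions and frame count")
  }
  nt <- n_frames(stackA)
  if (nt < 3L) stop_coac("need >= 3 timepoints")
  times <- frame_times(stackA)
  if (is.null(masks)) {
    # segment the time-averaged summed image: averaging removes the interior
    # domain structure (which would otherwise bias a per-frame threshold),
    # and droplets are near-static on the sampling grid; supply per-timepoint
    # masks explicitly for moving droplets
    seg <- segment_frame(
      apply(stackA$frames + stackB$frames, c(1, 2), mean),
      pixel_size = stackA$pixel_size, min_area = min_area,
      threshold_policy = "relative")
    masks <- rep(list(seg), nt)
    ref <- seg$props
  } else {
    masks <- lapply(masks, function(m) {
      if (inherits(m, "droplet_mask")) return(m)
      props <- data.frame(label = sort(unique(m[m > 0])))
      props$row <- vapply(props$label, function(l) {
        mean(which(m == l, arr.ind = TRUE)[, 1])
      }, numeric(1))
      props$col <- vapply(props$label, function(l) {
        mean(which(m == l, arr.ind = TRUE)[, 2])
      }, numeric(1))
      structure(list(labels = m, props = props,
                     pixel_size = stackA$pixel_size),
                class = "droplet_mask")
    })
    ref <- masks[[1]]$props
  }
  if (nrow(ref) < 2L) stop_coac("need >= 2 droplets")
  rows <- list()
  alive <- rep(TRUE, nrow(ref))
  for (t in seq_len(nt)) {
    props <- masks[[t]]$props
    for (d in seq_len(nrow(ref))) {
      if (!alive[d]) next
      if (nrow(props) == 0L) { alive[d] <- FALSE; next }
      dist <- sqrt((props$row - ref$row[d])^2 + (props$col - ref$col[d])^2) *
        stackA$pixel_size
      j <- which.min(dist)
      if (dist[j] > max_step) {
        coac_log("mixing", sprintf("droplet %d lost at timepoint %d", d, t))
        alive[d] <- FALSE
        next
      }
      msk <- masks[[t]]$labels == props$label[j]
      rho <- droplet_pearson(stackA$frames[, , t], stackB$frames[, , t], msk)
      rows[[length(rows) + 1L]] <- data.frame(time_s = times[t],
                                              droplet_id = d, rho = rho)
    }
  }
  tab <- do.call(rbind, rows)
  agg <- lapply(split(tab, tab$time_s), function(df) {
    r <- df$rho[is.finite(df$rho)]
    z <- atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))
    ci <- t_ci(z, 0.95)
    data.frame(time_s = df$time_s[1], mean = mean(r),
               lower = tanh(ci[["lower"]]), upper = tanh(ci[["upper"]]),
               n = length(r))
  })
  summ <- do.call(rbind, agg)
  rownames(summ) <- NULL
  flags <- character()
  co <- c(A = NA_real_, tau = NA_real_, rho_inf = NA_real_)
  fit <- NULL
  if (nrow(summ) >= 3L && stats::sd(summ$mean) > 1e-10) {
    A0 <- summ$mean[1] - summ$mean[nrow(summ)]
    tau0 <- diff(range(summ$time_s)) / 3
    fit <- tryCatch(
      fit_ls(function(tt, p) p[["A"]] * exp(-tt / p[["tau"]]) + p[["rho_inf"]],
             start = c(A = A0, tau = tau0,
                       rho_inf = summ$mean[nrow(summ)]),
             x = summ$time_s, y = summ$mean,
             lower = c(-2, 1e-9, -1), upper = c(2, Inf, 1),
             context = "mixing decay fit"),
      error = function(e) NULL)
    if (is.null(fit)) {
      flags <- c(flags, "decay_fit_failed")
    } else {
      co <- fit$par
      names(co) <- c("A", "tau", "rho_inf")
    }
  } else {
    flags <- c(flags, "decay_unidentifiable")
  }
  structure(list(table = tab, summary = summ, coefficients = co,
                 fit = fit, flags = flags),
            class = "mixing_series")
}

#' @export
coef.mixing_series <- function(object, ...) object$coefficients

#' @export
print.mixing_series <- function(x, ...) {
  co <- x$coefficients
  cat(sprintf(
    "<mixing_series> %d timepoints, %d droplet(s); rho(t) = %.3g*exp(-t/%.4g) + %.3g%s\n",
    nrow(x$summary), length(unique(x$table$droplet_id)), co["A"], co["tau"],
    co["rho_inf"],
    if (length(x$flags)) paste0("  [", paste(x$flags, collapse = ", "), "]")
    else ""))
  invisible(x)
}

#' @export
plot.mixing_series <- function(x, ...) {
  s <- x$summary
  graphics::plot(s$time_s, s$mean, ylim = range(c(s$lower, s$upper, s$mean),
                                                na.rm = TRUE),
                 pch = 16, xlab = "time (s)", ylab = "Pearson rho", ...)
  graphics::arrows(s$time_s, s$lower, s$time_s, s$upper, angle = 90,
                   code = 3, length = 0.03)
  if (!is.null(x$fit)) {
    tt <- seq(min(s$time_s), max(s$time_s), length.out = 200)
    co <- x$coefficients
    graphics::lines(tt, co["A"] * exp(-tt / co["tau"]) + co["rho_inf"],
                    col = 2, lwd = 2)
  }
  invisible(x)
}
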