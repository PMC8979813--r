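# synthetic-data generator: every pipeline input with serialized ground
# truth. Scenarios emulate the experimental acquisition settings (200 ms
# frames over 3 min with 20 pre-bleach frames for FRAP; 30 min intervals
# over 4 h for mixing; 39 x 1 ul injections for ITC) and encode the
# analysis-level models directly (exponential recovery / relaxation laws)
# rather than simulating photophysics, so recovery of the embedded
# parameters tests the normalization/fitting stack.

disk_px <- function(nrow, ncol, row, col, r_px) {
  rr <- matrix(seq_len(nrow), nrow, ncol)
  cc <- matrix(seq_len(ncol), nrow, ncol, byrow = TRUE)
  (rr - row)^2 + (cc - col)^2 <= r_px^2
}

ellipse_px <- function(nrow, ncol, row, col, a_px, b_px, theta = 0) {
  rr <- matrix(seq_len(nrow), nrow, ncol) - row
  cc <- matrix(seq_len(ncol), nrow, ncol, byrow = TRUE) - col
  u <- rr * cos(theta) + cc * sin(theta)
  v <- -rr * sin(theta) + cc * cos(theta)
  (u / a_px)^2 + (v / b_px)^2 <= 1
}

quantize16 <- function(x) round(pmin(pmax(x, 0), 1) * 65535) / 65535

#' Synthetic FRAP movie with known diffusion coefficient
#'
#' Renders a bleached droplet and an unbleached reference droplet. The bleach
#' disk follows \code{1 - A*exp(-(t - t_b)/tau*)} with
#' \code{tau* = 0.88 r^2 / (4 D* ln 2)} (the diffusion relation inverted), a
#' global photobleaching decay \code{exp(-t/photobleach_t)} multiplies all
#' fluorescent structures, and Gaussian read noise is added. The returned
#' idealized \code{frap_traces} take the small-bleach-ROI limit (whole-droplet
#' trace carrying only the acquisition factors), so their normalized curve is
#' exactly the embedded exponential.
#'
#' @param D_star ground-truth diffusion coefficient, um^2/s.
#' @param bleach_radius_um bleach-region radius r, um.
#' @param bleach_depth amplitude A of the bleach (fraction of signal lost).
#' @param droplet_radius_um,ref_radius_um droplet radii, um.
#' @param pixel_size um/px. @param frame_interval s (default 0.2).
#' @param duration_s total movie time (default 180).
#' @param pre_bleach_frames frames before the bleach (default 20).
#' @param photobleach_t_s time constant of acquisition photobleaching, s
#'   (Inf disables).
#' @param noise_sd Gaussian read-noise sd on the [0, 1] intensity scale.
#' @param dim image size c(rows, cols).
#' @param baseline background level.
#' @param seed integer seed fixing all randomness.
#' @return list(stack, traces, truth): the rendered \code{image_stack}, the
#'   idealized noise-free \code{frap_traces}, and the ground truth (D, tau,
#'   bleach geometry, bleach frame).
#' @export
sim_frap_movie <- function(D_star = 0.1, bleach_radius_um = 1,
                           bleach_depth = 0.6, droplet_radius_um = 2.4,
                           ref_radius_um = 1.6, pixel_size = 0.2,
                           frame_interval = 0.2, duration_s = 180,
                           pre_bleach_frames = 20L, photobleach_t_s = 500,
                           noise_sd = 0.01, dim = c(64L, 64L),
                           baseline = 0.05, seed = 1L) {
  set.seed(seed)
  tau_star <- 0.88 * bleach_radius_um^2 / (4 * D_star * log(2))
  nt <- floor(duration_s / frame_interval) + 1L
  times <- (seq_len(nt) - 1L) * frame_interval
  tb <- pre_bleach_frames + 1L
  amp <- 0.8
  ctr_d <- c(dim[1] / 2, dim[2] * 0.3)
  ctr_r <- c(dim[1] / 2, dim[2] * 0.78)
  m_d <- disk_px(dim[1], dim[2], ctr_d[1], ctr_d[2],
                 droplet_radius_um / pixel_size)
  m_b <- disk_px(dim[1], dim[2], ctr_d[1], ctr_d[2],
                 bleach_radius_um / pixel_size) & m_d
  m_r <- disk_px(dim[1], dim[2], ctr_r[1], ctr_r[2],
                 ref_radius_um / pixel_size)
  pb <- exp(-times / photobleach_t_s)
  rec <- ifelse(times < times[tb], 1,
                1 - bleach_depth * exp(-(times - times[tb]) / tau_star))
  frames <- array(0, c(dim[1], dim[2], nt))
  for (t in seq_len(nt)) {
    img <- baseline + amp * pb[t] * (m_d * 1 + m_b * (rec[t] - 1) + m_r * 1)
    if (noise_sd > 0) img <- img + stats::rnorm(length(img), sd = noise_sd)
    frames[, , t] <- quantize16(img)
  }
  stack <- image_stack(frames, channel = "Cy5", pixel_size = pixel_size,
                       frame_interval = frame_interval)
  traces <- frap_traces(
    time_s = times,
    bleach = baseline + amp * pb * rec,
    whole = baseline + amp * pb,
    reference = baseline + amp * pb,
    background = rep(baseline, nt),
    bleach_radius_um = bleach_radius_um, t_bleach = tb,
    pre_bleach_frames = pre_bleach_frames)
  list(stack = stack, traces = traces,
       truth = list(D = D_star, tau = tau_star, A = bleach_depth,
                    t_bleach = tb, bleach_radius_um = bleach_radius_um,
                    photobleach_t_s = photobleach_t_s, noise_sd = noise_sd,
                    seed = seed))
}

#' Synthetic droplet-fusion movie
#'
#' Two disks of radii r1, r2 sit side by side for a few frames, then merge
#' into an area-conserving ellipse whose aspect ratio relaxes as
#' \code{1 + (AR0 - 1)*exp(-t/tau*)} with
#' \code{tau* = a_star * sqrt(r1*r2)}.
#'
#' @param a_star ground-truth inverse capillary velocity, s/um.
#' @param r1_um,r2_um pre-fusion radii, um.
#' @param AR0 initial post-merge aspect ratio.
#' @param pixel_size um/px. @param frame_interval s.
#' @param n_pre_frames frames before the merge.
#' @param n_post_frames frames after the merge (defaults to ~5 tau*).
#' @param noise_sd read-noise sd. @param dim image size. @param seed seed.
#' @return list(stack, truth); truth carries tau*, r_geo, the merge frame and
#'   a tracking step bound \code{max_step_um} sufficient to link the event.
#' @export
sim_fusion_movie <- function(a_star = 100, r1_um = 2, r2_um = 2, AR0 = 2,
                             pixel_size = 0.2, frame_interval = NULL,
                             n_pre_frames = 3L, n_post_frames = NULL,
                             noise_sd = 0.005, dim = c(72L, 96L), seed = 1L) {
  set.seed(seed)
  r_geo <- sqrt(r1_um * r2_um)
  tau_star <- a_star * r_geo
  if (is.null(frame_interval)) frame_interval <- tau_star / 40
  if (is.null(n_post_frames)) {
    n_post_frames <- ceiling(5 * tau_star / frame_interval)
  }
  r1 <- r1_um / pixel_size
  r2 <- r2_um / pixel_size
  rf <- sqrt(r1^2 + r2^2)
  gap <- 3
  c1 <- c(dim[1] / 2, dim[2] / 2 - r1 - gap / 2)
  c2 <- c(dim[1] / 2, dim[2] / 2 + r2 + gap / 2)
  ctr <- c(dim[1] / 2, dim[2] / 2)
  nt <- n_pre_frames + n_post_frames
  frames <- array(0, c(dim[1], dim[2], nt))
  baseline <- 0.05
  for (t in seq_len(nt)) {
    if (t <= n_pre_frames) {
      m <- disk_px(dim[1], dim[2], c1[1], c1[2], r1) |
        disk_px(dim[1], dim[2], c2[1], c2[2], r2)
    } else {
      tt <- (t - n_pre_frames - 1L) * frame_interval
      ar <- 1 + (AR0 - 1) * exp(-tt / tau_star)
      m <- ellipse_px(dim[1], dim[2], ctr[1], ctr[2],
                      a_px = rf * sqrt(ar), b_px = rf / sqrt(ar),
                      theta = pi / 2)
    }
    img <- baseline + 0.85 * m
    if (noise_sd > 0) img <- img + stats::rnorm(length(img), sd = noise_sd)
    frames[, , t] <- quantize16(img)
  }
  stack <- image_stack(frames, channel = "Cy5", pixel_size = pixel_size,
                       frame_interval = frame_interval)
  max_step_um <- (r1 + gap / 2 + 2) * pixel_size
  list(stack = stack,
       truth = list(a_star = a_star, tau = tau_star, r1 = r1_um, r2 = r2_um,
                    r_geo = r_geo, AR0 = AR0,
                    merge_frame = n_pre_frames + 1L,
                    max_step_um = max_step_um, seed = seed))
}

#' Synthetic aspect-ratio series for a set of fusion events
#'
#' Trace-level counterpart of \code{\link{sim_fusion_movie}}: for each event a
#' radius pair is drawn, the relaxation \code{1 + (AR0-1)*exp(-t/tau_i)} with
#' \code{tau_i = a_star * sqrt(r1 r2)} is sampled over ~5 tau_i, and Gaussian
#' noise is added to the AR values.
#'
#' @param n_events number of events.
#' @param a_star inverse capillary velocity, s/um.
#' @param r_range_um range of droplet radii to draw from, um.
#' @param AR0 initial aspect ratio. @param n_frames points per event.
#' @param noise_sd absolute Gaussian noise on AR. @param seed seed.
#' @return list(events, truth): \code{events} is a list of lists
#'   (time_s, ar, r1, r2, tau_true).
#' @export
sim_fusion_events <- function(n_events = 20L, a_star = 100,
                              r_range_um = c(1, 5), AR0 = 2, n_frames = 200L,
                              noise_sd = 0.02, seed = 1L) {
  set.seed(seed)
  events <- lapply(seq_len(n_events), function(i) {
    r1 <- stats::runif(1, r_range_um[1], r_range_um[2])
    r2 <- stats::runif(1, r_range_um[1], r_range_um[2])
    tau <- a_star * sqrt(r1 * r2)
    tt <- seq(0, 5 * tau, length.out = n_frames)
    ar <- 1 + (AR0 - 1) * exp(-tt / tau) + stats::rnorm(n_frames, sd = noise_sd)
    list(time_s = tt, ar = pmax(ar, 1), r1 = r1, r2 = r2, tau_true = tau)
  })
  list(events = events, truth = list(a_star = a_star, AR0 = AR0,
                                     noise_sd = noise_sd, seed = seed))
}

# orthonormal in-mask patterns: half-domain step and a quadrant pattern
# Gram-Schmidt orthogonalized against it
mixing_patterns <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  ctr <- colMeans(idx)
  std <- function(v) (v - mean(v)) / stats::sd(v)
  p <- std(ifelse(idx[, 2] <= ctr[2], 1, -1))
  q <- std(ifelse(idx[, 1] <= ctr[1], 1, -1))
  q <- q - sum(q * p) / sum(p * p) * p
  q <- std(q)
  list(p = p, q = q, idx = idx)
}

#' Synthetic two-colour mixing scene
#'
#' Droplets carrying anti-correlated half-droplet RNA domains in the two
#' channels. In "liquid" mode the inter-channel correlation relaxes
#' exponentially toward the mixed state,
#' \code{rho(t) = rho_inf + (rho0 - rho_inf)*exp(-t/tau_star)} (the decay of
#' the fundamental diffusive mode of the domain pattern); in "gel" mode the
#' domains are frozen and rho stays at rho0. The target correlation is
#' realized exactly (up to read noise) by mixing orthonormal within-mask
#' patterns with analytic weights.
#'
#' @param mode "liquid" or "gel".
#' @param tau_star_s ground-truth mixing time, s (default 3600 = 60 min).
#' @param rho0,rho_inf initial and asymptotic correlation targets.
#' @param n_timepoints,interval_s sampling (default 9 points every 30 min).
#' @param n_droplets droplets per scene. @param droplet_radius_um radius.
#' @param pixel_size um/px. @param domain_amp domain intensity amplitude.
#' @param noise_sd read-noise sd. @param seed seed.
#' @return list(stacks = list(FAM, Cy5), truth).
#' @export
sim_mixing_scene <- function(mode = c("liquid", "gel"), tau_star_s = 3600,
                             rho0 = -0.5, rho_inf = 0.85,
                             n_timepoints = 9L, interval_s = 1800,
                             n_droplets = 3L, droplet_radius_um = 2.4,
                             pixel_size = 0.2, domain_amp = 0.2,
                             noise_sd = 0.01, seed = 1L) {
  mode <- match.arg(mode)
  set.seed(seed)
  r_px <- droplet_radius_um / pixel_size
  nr <- ceiling(2 * r_px + 16)
  nc <- n_droplets * ceiling(2 * r_px + 16)
  centers <- cbind(nr / 2, (seq_len(n_droplets) - 0.5) * nc / n_droplets)
  times <- (seq_len(n_timepoints) - 1L) * interval_s
  rho_t <- if (mode == "liquid") {
    rho_inf + (rho0 - rho_inf) * exp(-times / tau_star_s)
  } else {
    rep(rho0, n_timepoints)
  }
  baseline <- 0.05
  level <- 0.5
  fa <- array(baseline, c(nr, nc, n_timepoints))
  fb <- array(baseline, c(nr, nc, n_timepoints))
  for (d in seq_len(n_droplets)) {
    mask <- disk_px(nr, nc, centers[d, 1], centers[d, 2], r_px)
    pat <- mixing_patterns(mask)
    for (t in seq_len(n_timepoints)) {
      a <- level + domain_amp * pat$p
      b <- level + domain_amp *
        (rho_t[t] * pat$p + sqrt(1 - rho_t[t]^2) * pat$q)
      fa[, , t][mask] <- a
      fb[, , t][mask] <- b
    }
  }
  if (noise_sd > 0) {
    fa <- fa + array(stats::rnorm(length(fa), sd = noise_sd), dim(fa))
    fb <- fb + array(stats::rnorm(length(fb), sd = noise_sd), dim(fb))
  }
  fa <- array(quantize16(fa), dim(fa))
  fb <- array(quantize16(fb), dim(fb))
  mk <- function(fr, ch) image_stack(fr, channel = ch,
                                     pixel_size = pixel_size,
                                     frame_interval = interval_s)
  list(stacks = list(FAM = mk(fa, "FAM"), Cy5 = mk(fb, "Cy5")),
       truth = list(mode = mode, tau_star = tau_star_s, rho0 = rho0,
                    rho_inf = rho_inf, rho_t = rho_t, times = times,
                    noise_sd = noise_sd, seed = seed))
}

#' Synthetic two-channel whole-droplet FRAP movie
#'
#' Mask channel (peptide) constant; measured channel (RNA) recovering as
#' \code{1 - A*exp(-(t - t_b)/tau_star)} inside the droplet after a bleach at
#' \code{bleach_after_frame}. Default acquisition: every 30 s for 63 min,
#' bleach after the fifth frame.
#'
#' @param tau_star_s recovery time constant, s.
#' @param A bleach depth. @param droplet_radius_um radius, um.
#' @param pixel_size um/px. @param frame_interval s. @param duration_s total.
#' @param bleach_after_frame bleach follows this frame.
#' @param noise_sd read-noise sd. @param dim image size. @param seed seed.
#' @return list(stacks = list(FITC, Cy5), truth).
#' @export
sim_wholedroplet_frap <- function(tau_star_s = 600, A = 0.7,
                                  droplet_radius_um = 3, pixel_size = 0.2,
                                  frame_interval = 30, duration_s = 3780,
                                  bleach_after_frame = 5L, noise_sd = 0.005,
                                  dim = c(64L, 64L), seed = 1L) {
  set.seed(seed)
  nt <- floor(duration_s / frame_interval) + 1L
  times <- (seq_len(nt) - 1L) * frame_interval
  tb <- bleach_after_frame + 1L
  mask <- disk_px(dim[1], dim[2], dim[1] / 2, dim[2] / 2,
                  droplet_radius_um / pixel_size)
  rec <- ifelse(times < times[tb], 1,
                1 - A * exp(-(times - times[tb]) / tau_star_s))
  baseline <- 0.05
  f_mask <- array(baseline, c(dim[1], dim[2], nt))
  f_meas <- array(baseline, c(dim[1], dim[2], nt))
  for (t in seq_len(nt)) {
    fm <- f_mask[, , t]; fv <- f_meas[, , t]
    fm[mask] <- baseline + 0.8
    fv[mask] <- baseline + 0.8 * rec[t]
    f_mask[, , t] <- fm; f_meas[, , t] <- fv
  }
  if (noise_sd > 0) {
    f_mask <- f_mask + array(stats::rnorm(length(f_mask), sd = noise_sd),
                             dim(f_mask))
    f_meas <- f_meas + array(stats::rnorm(length(f_meas), sd = noise_sd),
                             dim(f_meas))
  }
  mk <- function(fr, ch) image_stack(array(quantize16(fr), dim(fr)),
                                     channel = ch, pixel_size = pixel_size,
                                     frame_interval = frame_interval)
  list(stacks = list(FITC = mk(f_mask, "FITC"), Cy5 = mk(f_meas, "Cy5")),
       truth = list(tau = tau_star_s, A = A, t_bleach = tb, seed = seed))
}

#' Synthetic turbidity titration (EMG-shaped)
#'
#' @param A1,sigma,x0,tau EMG ground-truth parameters.
#' @param x titration grid (a.a./nt).
#' @param noise_frac Gaussian noise sd as a fraction of the curve maximum.
#' @param n_replicates replicate measurements per x. @param seed seed.
#' @return list(x, y (matrix x-by-replicate), y_true, truth).
#' @export
sim_titration <- function(A1 = 1, sigma = 0.3, x0 = 1, tau = 5,
                          x = exp(seq(log(0.05), log(60), length.out = 30)),
                          noise_frac = 0.05, n_replicates = 1L, seed = 1L) {
  set.seed(seed)
  y_true <- emg(x, A1, sigma, x0, tau)
  sdv <- noise_frac * max(abs(y_true))
  y <- matrix(rep(y_true, n_replicates), ncol = n_replicates) +
    matrix(stats::rnorm(length(x) * n_replicates, sd = sdv),
           ncol = n_replicates)
  list(x = x, y = y, y_true = y_true,
       truth = list(A1 = A1, sigma = sigma, x0 = x0, tau = tau,
                    noise_frac = noise_frac, seed = seed))
}

#' Synthetic partitioning curve (Hill-shaped)
#'
#' @param F_min,F_max,F_half,n Hill ground-truth parameters.
#' @param x concentration grid. @param noise_frac noise sd as fraction of
#'   F_max. @param n_replicates replicates per x. @param seed seed.
#' @return list(x, y, y_true, truth).
#' @export
sim_partition <- function(F_min = 0, F_max = 1, F_half = 5, n = 2,
                          x = exp(seq(log(0.2), log(100), length.out = 25)),
                          noise_frac = 0.01, n_replicates = 1L, seed = 1L) {
  set.seed(seed)
  y_true <- hill(x, F_min, F_max, F_half, n)
  sdv <- noise_frac * max(abs(y_true))
  y <- matrix(rep(y_true, n_replicates), ncol = n_replicates) +
    matrix(stats::rnorm(length(x) * n_replicates, sd = sdv),
           ncol = n_replicates)
  list(x = x, y = y, y_true = y_true,
       truth = list(F_min = F_min, F_max = F_max, F_half = F_half, n = n,
                    noise_frac = noise_frac, seed = seed))
}

# saturating coverage model shared by the ITC generators: fraction of
# binding completed as a function of molar ratio
itc_coverage <- function(ratio, r_c = 0.25) 1 - exp(-ratio / r_c)

#' Synthetic ITC experiment set with a chosen magnesium-release fraction
#'
#' Emits the three blank-subtracted titrations of the release comparison: Mg
#' binding to RNA (total heat dH_mg), peptide binding to bare RNA (dH_pep),
#' and peptide binding to Mg-preincubated RNA, built so that the enthalpic
#' difference ddH equals \code{release_fraction * dH_mg} by construction.
#' Per-injection heats follow a saturating coverage increment; the default
#' schedule is 39 x 1 ul injections (priming injection already discarded).
#'
#' @param dH_mg total Mg-binding heat, kJ/mol nucleotide (default -2.9).
#' @param dH_pep total peptide-binding heat, kJ/mol nucleotide.
#' @param release_fraction fraction of RNA-bound Mg released by the peptide.
#' @param cell_mM,cell_volume_ul,syringe_mM cell/syringe setup.
#' @param n_injections,injection_ul schedule.
#' @param noise_uJ Gaussian noise per injection heat, uJ.
#' @param dilution_heat_uJ constant dilution heat per injection embedded in
#'   the raw series and in the returned blanks.
#' @param seed seed.
#' @return list(mg, pep_minus, pep_plus (blank-subtracted \code{itc_series}),
#'   raw = list(mg, blank) with the dilution component still present, truth).
#' @export
sim_itc_pair <- function(dH_mg = -2.9, dH_pep = -10, release_fraction = 1,
                         cell_mM = 5, cell_volume_ul = 200, syringe_mM = 20,
                         n_injections = 39L, injection_ul = 1,
                         noise_uJ = 0, dilution_heat_uJ = -0.5, seed = 1L) {
  set.seed(seed)
  vols <- rep(injection_ul, n_injections)
  nmol <- cell_mM * cell_volume_ul
  base <- itc_series(vols, rep(0, n_injections), syringe_mM, cell_mM,
                     cell_volume_ul)
  cov <- itc_coverage(base$molar_ratio)
  dcov <- diff(c(0, cov))
  mk <- function(dH_total) {
    q <- dH_total * nmol * dcov
    if (noise_uJ > 0) q <- q + stats::rnorm(n_injections, sd = noise_uJ)
    itc_series(vols, q, syringe_mM, cell_mM, cell_volume_ul)
  }
  mg <- mk(dH_mg)
  pep_minus <- mk(dH_pep)
  pep_plus <- mk(dH_pep - release_fraction * dH_mg)
  raw_mg <- mg
  raw_mg$heats_uJ <- raw_mg$heats_uJ + dilution_heat_uJ
  blank <- itc_series(vols, rep(dilution_heat_uJ, n_injections), syringe_mM,
                      cell_mM, cell_volume_ul)
  list(mg = mg, pep_minus = pep_minus, pep_plus = pep_plus,
       raw = list(mg = raw_mg, blank = blank),
       truth = list(dH_mg = dH_mg, dH_pep = dH_pep,
                    release_fraction = release_fraction,
                    coverage_final = cov[n_injections],
                    dilution_heat_uJ = dilution_heat_uJ, seed = seed))
}

#' Synthetic gel lane
#'
#' Intensity profile along the migration axis with Gaussian substrate and
#' product bands over a uniform background, realizing a chosen ligated
#' fraction.
#'
#' @param fraction ground-truth ligated fraction I_P/(I_P+I_S1).
#' @param total combined band integral.
#' @param length profile length, px.
#' @param product_pos,substrate_pos band centres (product migrates higher).
#' @param band_sd Gaussian band width, px.
#' @param background uniform background level. @param noise_sd noise sd.
#' @param seed seed.
#' @return list(profile, substrate_window, product_window, truth).
#' @export
sim_gel_lane <- function(fraction = 0.7, total = 100, length = 300L,
                         product_pos = 80, substrate_pos = 200, band_sd = 8,
                         background = 2, noise_sd = 0.02, seed = 1L) {
  set.seed(seed)
  pos <- seq_len(length)
  band <- function(center, mass) {
    mass * stats::dnorm(pos, mean = center, sd = band_sd)
  }
  profile <- background + band(product_pos, fraction * total) +
    band(substrate_pos, (1 - fraction) * total)
  if (noise_sd > 0) profile <- profile + stats::rnorm(length, sd = noise_sd)
  w <- ceiling(4 * band_sd)
  list(profile = profile,
       substrate_window = (substrate_pos - w):(substrate_pos + w),
       product_window = (product_pos - w):(product_pos + w),
       truth = list(fraction = fraction, total = total, seed = seed))
}
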