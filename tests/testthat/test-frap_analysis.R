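make_traces <- function(bleach, whole, reference, background, n = NULL,
                        r = 1, tb = 21L, npre = 20L) {
  if (is.null(n)) n <- length(bleach)
  frap_traces(time_s = (seq_len(n) - 1) * 0.2,
              bleach = rep_len(bleach, n), whole = rep_len(whole, n),
              reference = rep_len(reference, n),
              background = rep_len(background, n),
              bleach_radius_um = r, t_bleach = tb, pre_bleach_frames = npre)
}

test_that("constant traces normalize to an identically-1 curve", {
  cv <- normalize_frap(make_traces(500, 500, 400, 50, n = 100))
  expect_equal(cv$value, rep(1, 100))
})

test_that("a common photobleaching decay cancels exactly", {
  n <- 200
  pb <- exp(-(seq_len(n) - 1) * 0.2 / 50)
  cv <- normalize_frap(make_traces(10 + 300 * pb, 10 + 300 * pb,
                                   10 + 200 * pb, 10, n = n))
  expect_equal(cv$value, rep(1, n), tolerance = 1e-12)
})

test_that("normalization is invariant to common offsets and common gains", {
  s <- sim_frap_movie(D_star = 0.1, noise_sd = 0, seed = 41)
  tr <- s$traces
  base <- normalize_frap(tr)$value
  gain <- exp(-tr$time_s / 37) * runif(length(tr$time_s), 0.8, 1.2)
  tr2 <- tr
  for (f in c("bleach", "whole", "reference", "background")) {
    tr2[[f]] <- (tr[[f]] + 12.5) * gain
  }
  shifted <- normalize_frap(tr2)$value
  expect_equal(shifted, base, tolerance = 1e-10)
})

test_that("normalization reports degenerate inputs by frame", {
  bad <- make_traces(100, 100, c(rep(100, 50), 10), 20, n = 51, tb = 21L)
  expect_error(normalize_frap(bad), "frame 51")
  short <- make_traces(100, 100, 100, 0, n = 10, tb = NA)
  expect_error(normalize_frap(short), "pre-bleach window")
  expect_error(frap_traces(1:10 * 0.2, 1:10, 1:10, 1:10, 1:10, 1,
                           t_bleach = 5L, pre_bleach_frames = 20L),
               "pre-bleach window")
})

test_that("noiseless recovery parameters are recovered to 0.1%", {
  tt <- seq(0, 180, by = 0.2)
  for (pars in list(c(A = 0.6, tau = 20, C = 0),
                    c(A = 0.9, tau = 5, C = 0.05),
                    c(A = 0.3, tau = 60, C = -0.02))) {
    y <- c(rep(1, 20), 1 - pars["A"] * exp(-tt / pars["tau"]) + pars["C"])
    fit <- fit_recovery(y, time_s = seq_along(y) * 0.2, t_bleach = 21L)
    expect_lt(abs(coef(fit)[["A"]] - pars["A"]) / pars["A"], 1e-3)
    expect_lt(abs(coef(fit)[["tau"]] - pars["tau"]) / pars["tau"], 1e-3)
  }
})

test_that("tau is stable under measurement noise (Monte Carlo)", {
  tt <- seq(0, 180, by = 0.2)
  errs <- vapply(1:10, function(sd) {
    set.seed(sd)
    y <- c(rep(1, 20), 1 - 0.6 * exp(-tt / 20)) + rnorm(length(tt) + 20,
                                                        sd = 0.02)
    fit <- fit_recovery(y, time_s = seq_along(y) * 0.2, t_bleach = 21L)
    abs(coef(fit)[["tau"]] - 20) / 20
  }, numeric(1))
  expect_lt(max(errs), 0.05)
})

test_that("a flat curve is flagged, not silently fitted", {
  fit <- fit_recovery(rep(1, 50), time_s = 1:50 * 0.2, t_bleach = 10L)
  expect_true("amplitude_unidentifiable" %in% fit$flags)
  expect_true(is.na(coef(fit)[["tau"]]))
  expect_lt(coef(fit)[["A"]], 0.02)
})

test_that("the diffusion relation and its scaling laws hold exactly", {
  expect_equal(diffusion_from_fit(1, 1), 0.88 / (4 * log(2)))
  expect_equal(diffusion_from_fit(1, 1), 0.31738, tolerance = 1e-4)
  expect_equal(diffusion_from_fit(7, 2), 4 * diffusion_from_fit(7, 1))
  expect_equal(diffusion_from_fit(1e9, 1), 0, tolerance = 1e-8)
  expect_error(diffusion_from_fit(-1, 1), "positive")
  expect_error(diffusion_from_fit(1, 0), "positive")
})

test_that("diffusion summaries report t-based confidence intervals", {
  s <- summarize_diffusion(c(1, 1, 1, 1))
  expect_equal(s$mean, 1)
  expect_equal(s$upper - s$lower, 0)
  expect_equal(summarize_diffusion(c(1, 3))$mean, 2)
  single <- summarize_diffusion(0.5)
  expect_true(is.na(single$lower) && is.na(single$upper))

  # coverage of the 95% CI under repeated sampling
  set.seed(42)
  hits <- vapply(1:300, function(i) {
    s <- summarize_diffusion(rnorm(10, 0.5, 0.05))
    s$lower <= 0.5 && 0.5 <= s$upper
  }, logical(1))
  expect_gt(mean(hits), 0.90)
  expect_lt(mean(hits), 0.99)
})

test_that("whole-droplet FRAP movies recover tau within 5%", {
  wd <- sim_wholedroplet_frap(tau_star_s = 600, seed = 43)
  tr <- whole_droplet_mask_from_channel(wd$stacks, "FITC", "Cy5")
  norm <- tr$measured_mean / mean(tr$measured_mean[1:5])
  fit <- fit_recovery(norm, time_s = tr$time_s, t_bleach = wd$truth$t_bleach)
  expect_lt(abs(coef(fit)[["tau"]] - 600) / 600, 0.05)
})

test_that("the full movie pipeline recovers the embedded diffusion", {
  s <- sim_frap_movie(D_star = 0.1, seed = 44)
  a <- analyze_frap_movie(s$stack, bleach_radius_um = 1)
  expect_equal(a$t_bleach, s$truth$t_bleach)
  expect_lt(abs(a$D - 0.1) / 0.1, 0.25)
  expect_equal(a$D, diffusion_from_fit(coef(a$fit)[["tau"]], 1))
})
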