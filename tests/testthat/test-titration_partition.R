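test_that("absorbance-to-turbidity conversion is exact and well behaved", {
  expect_equal(turbidity_from_absorbance(0), 0)
  expect_equal(turbidity_from_absorbance(1), 90)
  expect_equal(turbidity_from_absorbance(2), 99)
  A <- seq(0, 4, by = 0.05)
  tb <- turbidity_from_absorbance(A)
  expect_true(all(diff(tb) > 0))
  expect_true(all(tb >= 0 & tb < 100))
  expect_equal(tb + 10^(2 - A), rep(100, length(A)))
  expect_error(turbidity_from_absorbance(-0.1), "nonphysical")
})

test_that("noiseless EMG parameters are recovered to 0.5%", {
  truth <- c(A1 = 1, sigma = 0.3, x0 = 1, tau = 5)
  x <- exp(seq(log(0.05), log(60), length.out = 30))
  fit <- fit_emg(x, emg(x, 1, 0.3, 1, 5))
  expect_true(all(abs(coef(fit) - truth) / truth < 0.005))
  expect_lt(fit$deviance, 1e-12)
})

test_that("EMG x0 is stable under 5% noise (Monte Carlo)", {
  x <- exp(seq(log(0.05), log(60), length.out = 30))
  x0s <- vapply(1:10, function(sd) {
    st <- sim_titration(noise_frac = 0.05, seed = 700 + sd)
    coef(fit_emg(st$x, st$y[, 1]))[["x0"]]
  }, numeric(1))
  expect_lt(abs(mean(x0s) - 1), 0.1)
})

test_that("slow decay reduces the EMG to an erf-shaped sigmoid rise", {
  x <- seq(-1, 3, length.out = 200)
  y <- emg(x, 1, 0.4, 1, 1e5)
  y <- y / max(y)
  oracle <- erf_sigmoid(x, 1, 0.4)
  expect_lt(max(abs(y - oracle)), 0.01)
  # the half-rise of the fitted model sits at x0
  xi <- x[which.min(abs(y - 0.5))]
  expect_lt(abs(xi - 1), 0.05)
})

test_that("monotone titration data are flagged as having no peak", {
  x <- 1:10
  fit <- suppressWarnings(fit_emg(x, x * 2 + 1))
  expect_true("no_peak" %in% fit$flags)
})

test_that("partition ratios follow the background-subtracted quotient", {
  expect_equal(partition_ratio(150, 150, 50), 1)
  expect_equal(partition_ratio(50, 150, 50), 0)
  expect_equal(partition_ratio(300, 150, 50), 2.5)
  expect_error(partition_ratio(300, 40, 50), "positive")
})

test_that("the Hill midpoint identity holds for any cooperativity", {
  for (n in c(0.5, 1, 2, 8)) {
    expect_equal(hill(5, 0.2, 1.4, 5, n), (0.2 + 1.4) / 2)
  }
})

test_that("noiseless Hill parameters are recovered to 0.5%", {
  x <- exp(seq(log(0.2), log(100), length.out = 25))
  fit <- fit_hill(x, hill(x, 0.1, 1, 5, 2))
  truth <- c(F_min = 0.1, F_max = 1, F_half = 5, n = 2)
  expect_true(all(abs(coef(fit) - truth) / truth < 0.005))
})

test_that("large cooperativity approaches a step at F_half", {
  co <- c(F_min = 0, F_max = 1, F_half = 5, n = 40)
  expect_lt(hill(4.8, co[1], co[2], co[3], co[4]), 0.2)
  expect_gt(hill(5.2, co[1], co[2], co[3], co[4]), 0.8)
})

test_that("constrained Hill fits with true F_min = 0 are unbiased", {
  est <- vapply(1:20, function(sd) {
    sp <- sim_partition(noise_frac = 0.01, seed = 800 + sd)
    coef(fit_hill(sp$x, sp$y[, 1], fix_Fmin_zero = TRUE))[["F_half"]]
  }, numeric(1))
  # mean over seeds within Monte-Carlo error of the truth
  expect_lt(abs(mean(est) - 5), 3 * sd(est) / sqrt(length(est)) + 0.05)
})

test_that("inverse-sd weighting changes the fit as requested", {
  set.seed(71)
  x <- exp(seq(log(0.2), log(100), length.out = 25))
  y <- hill(x, 0, 1, 5, 2) + rnorm(25, sd = 0.02)
  sdv <- runif(25, 0.01, 0.2)
  fw <- fit_hill(x, y, sd = sdv, weights_policy = "inverse_sd",
                 fix_Fmin_zero = TRUE)
  expect_equal(coef(fw)[["F_min"]], 0)
  expect_error(fit_hill(x, y, weights_policy = "inverse_sd"), "sd")
})

test_that("the standard ligase mix totals 438 uM nucleotide", {
  st <- mixture_stoichiometry(r3c_standard_mix())
  expect_identical(st$nt_uM, 5 * 66 + 6 * 18)
  expect_identical(st$nt_uM, 438)
})

test_that("stoichiometric ratios follow monomer accounting", {
  # K9 peptide against ninefold nucleotide: a.a./nt = 1
  mix <- mixture_spec(c("rna", "K9"), conc_uM = c(9 * 3, 3),
                      length = c(1, 9), charged = c(1, 9),
                      type = c("rna", "peptide"))
  st <- mixture_stoichiometry(mix)
  expect_equal(st$aa_nt_ratio, 1)

  # (RGG)4: 12 residues, 4 charged -> charge ratio is a third of a.a. ratio
  rgg <- mixture_spec(c("E", "RGG4"), conc_uM = c(5, 100),
                      length = c(66, 12), charged = c(66, 4),
                      type = c("rna", "peptide"))
  sr <- mixture_stoichiometry(rgg)
  expect_equal(sr$charge_nt_ratio, sr$aa_nt_ratio / 3)
})

test_that("stoichiometry is additive over concatenated specifications", {
  set.seed(72)
  for (i in 1:5) {
    n1 <- sample(1:3, 1); n2 <- sample(1:3, 1)
    mk <- function(n, type) {
      mixture_spec(paste0(type, seq_len(n)), conc_uM = runif(n, 1, 50),
                   length = sample(5:70, n), charged = sample(1:5, n,
                                                              replace = TRUE),
                   type = rep(type, n))
    }
    a <- rbind(mk(n1, "rna"), mk(n2, "peptide"))
    b <- rbind(mk(n2, "rna"), mk(n1, "peptide"))
    both <- structure(rbind(a, b), class = c("mixture_spec", "data.frame"))
    sa <- mixture_stoichiometry(a); sb <- mixture_stoichiometry(b)
    st <- mixture_stoichiometry(both)
    expect_equal(st$nt_uM, sa$nt_uM + sb$nt_uM)
    expect_equal(st$aa_uM, sa$aa_uM + sb$aa_uM)
  }
  pep_only <- mixture_spec("K9", 10, 9, 9, "peptide")
  expect_error(mixture_stoichiometry(pep_only), "zero nucleotide")
})

test_that("the combinatorial multiplicity is the exact falling factorial", {
  expect_identical(combinatorial_factor(12, 4), 12 * 11 * 10 * 9)
  expect_identical(combinatorial_factor(12, 4), 11880)
  expect_identical(combinatorial_factor(15, 5), 360360)
  expect_identical(combinatorial_factor(20, 0), 1)
  expect_error(combinatorial_factor(4, 5), "k <= n")
})

test_that("Beer-Lambert nucleotide concentrations invert correctly", {
  expect_equal(rna_concentration_from_absorbance(0), 0)
  eps <- 8.9e-3
  expect_equal(rna_concentration_from_absorbance(eps * 1 * 100), 100)
  expect_equal(rna_concentration_from_absorbance(0.89, 1, 8.9e-3), 100)
})

test_that("replicate aggregation reports mean with 68% intervals", {
  set.seed(73)
  x <- rep(c(1, 2, 4), each = 3)
  y <- rnorm(9, mean = rep(c(10, 20, 30), each = 3))
  agg <- aggregate_replicates(x, y)
  expect_equal(agg$x, c(1, 2, 4))
  expect_equal(agg$n, rep(3, 3))
  expect_true(all(agg$lower < agg$mean & agg$mean < agg$upper))
})
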