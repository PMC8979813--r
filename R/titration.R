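# titration and partitioning: turbidity conversion, exponentially modified
# Gaussian phase-boundary fits, Hill partitioning fits, mixture stoichiometry
# and the combinatorial-plausibility factor

#' Convert absorbance at 500 nm to turbidity
#'
#' \code{turbidity = 100 - 10^(2 - absorbance)}; equivalently 100 - %T where
#' %T = 10^(2 - A) is the percentage of transmittance.
#'
#' @param A500 absorbance (>= 0).
#' @return turbidity in percent (vectorized), in [0, 100).
#' @export
turbidity_from_absorbance <- function(A500) {
  if (any(A500 < 0)) stop_coac("absorbance must be >= 0 (nonphysical input)")
  100 - 10^(2 - A500)
}

#' Exponentially modified Gaussian model
#'
#' The four-parameter Gaussian (x) exponential convolution used for turbidity
#' and ICP-MS titration curves:
#' \deqn{f(x) = A_1 \sigma \exp(\sigma^2/(4\tau^2)) \exp(-(x-x_0)/\tau)
#'   (1 + \mathrm{erf}((x-x_0)/\sigma - \sigma/(2\tau)))}
#' with a sigmoidal rise around the inflection point \code{x0} of width
#' \code{sigma} and an exponential decay of constant \code{tau}.
#'
#' @param x titration axis (a.a./nt ratio).
#' @param A1 scale factor. @param sigma Gaussian width (> 0).
#' @param x0 inflection point. @param tau exponential decay constant (> 0).
#' @return model values (vectorized).
#' @export
emg <- function(x, A1, sigma, x0, tau) {
  A1 * sigma * exp(sigma^2 / (4 * tau^2)) * exp(-(x - x0) / tau) *
    (1 + erf((x - x0) / sigma - sigma / (2 * tau)))
}

#' Fit the exponentially modified Gaussian to a titration curve
#'
#' Least-squares fit of \code{\link{emg}}. Initialization: \code{x0} at the x
#' of half-maximal rise, \code{tau} at the x-distance from the peak to half
#' decay, \code{sigma} at a quarter of the rise width. Serves both turbidity
#' and ICP-MS magnesium-content curves. Monotone data (no interior peak) are
#' flagged "no_peak".
#'
#' @param x,y curve data (>= 6 points spanning rise and decay).
#' @param tol relative convergence tolerance.
#' @return object of class \code{emg_fit} with coefficients
#'   (A1, sigma, x0, tau), covariance, fitted values and \code{flags}.
#' @export
fit_emg <- function(x, y, tol = 1e-10) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 6L) stop_coac("need >= 6 points spanning rise and decay")
  o <- order(x); x <- x[o]; y <- y[o]
  flags <- character()
  ipk <- which.max(y)
  if (ipk <= 1L || ipk >= length(y)) flags <- c(flags, "no_peak")
  ymax <- y[ipk]
  # rise half-crossing (left of peak), decay half-crossing (right of peak)
  ir <- which(y[seq_len(ipk)] >= ymax / 2)[1]
  x0_0 <- if (!is.na(ir)) x[ir] else x[max(ipk - 1L, 1L)]
  idec <- which(y >= ymax / 2)
  xdec <- if (length(idec)) x[max(idec)] else x[length(x)]
  tau0 <- max(xdec - x[ipk], diff(range(x)) / 10)
  sigma0 <- max((x[ipk] - x0_0) / 2, diff(range(x)) / 40)
  A1_0 <- ymax / max(emg(x[ipk], 1, sigma0, x0_0, tau0), 1e-12)
  fit <- fit_ls(
    function(x, p) emg(x, p[["A1"]], p[["sigma"]], p[["x0"]], p[["tau"]]),
    start = c(A1 = A1_0, sigma = sigma0, x0 = x0_0, tau = tau0),
    x = x, y = y, lower = c(-Inf, 1e-9, -Inf, 1e-9), ftol = tol,
    context = "EMG fit")
  co <- fit$par
  names(co) <- c("A1", "sigma", "x0", "tau")
  structure(list(coefficients = co, vcov = fit$vcov,
                 curve = data.frame(x = x, y = y, fitted = fit$fitted),
                 flags = flags, deviance = fit$deviance),
            class = "emg_fit")
}

#' @export
coef.emg_fit <- function(object, ...) object$coefficients

#' @export
print.emg_fit <- function(x, ...) {
  co <- x$coefficients
  cat(sprintf("<emg_fit> A1 = %.4g, sigma = %.4g, x0 = %.4g, tau = %.4g%s\n",
              co["A1"], co["sigma"], co["x0"], co["tau"],
              if (length(x$flags)) paste0("  [", paste(x$flags, collapse = ", "),
                                          "]") else ""))
  invisible(x)
}

#' @export
predict.emg_fit <- function(object, x = NULL, ...) {
  if (is.null(x)) return(object$curve$fitted)
  co <- object$coefficients
  emg(x, co[["A1"]], co[["sigma"]], co[["x0"]], co[["tau"]])
}

#' @export
plot.emg_fit <- function(x, ...) {
  graphics::plot(x$curve$x, x$curve$y, pch = 16,
                 xlab = "a.a./nt ratio", ylab = "signal", ...)
  xx <- seq(min(x$curve$x), max(x$curve$x), length.out = 300)
  graphics::lines(xx, predict(x, xx), col = 2, lwd = 2)
  invisible(x)
}

#' Partition ratio from plate-reader fluorescence
#'
#' Background-subtracted coacervate over supernatant intensity:
#' \code{(F_c - F_bg) / (F_s - F_bg)}.
#'
#' @param F_coacervate,F_supernatant,F_background fluorescence intensities.
#' @return partition ratio (vectorized).
#' @export
partition_ratio <- function(F_coacervate, F_supernatant, F_background) {
  den <- F_supernatant - F_background
  if (any(den <= 0)) stop_coac("supernatant minus background must be positive")
  (F_coacervate - F_background) / den
}

#' Hill model
#'
#' \code{f(x) = F_min + (F_max - F_min) / (1 + (F_half/x)^n)}: saturation at
#' \code{F_max}, half point at \code{F_half}, cooperativity \code{n}.
#'
#' @param x concentration axis (> 0). @param F_min,F_max plateau values.
#' @param F_half half-saturation point (> 0). @param n Hill coefficient.
#' @return model values (vectorized).
#' @export
hill <- function(x, F_min, F_max, F_half, n) {
  F_min + (F_max - F_min) / (1 + (F_half / x)^n)
}

#' Fit the Hill equation
#'
#' Weighted least squares of \code{\link{hill}}. With
#' \code{weights_policy = "inverse_sd"} data points are weighted by the
#' reciprocal of their standard deviation (the variant used for sequestration
#' curves); \code{fix_Fmin_zero} constrains F_min to 0.
#'
#' @param x,y curve data (>= 5 points, x > 0).
#' @param sd per-point standard deviations (required for "inverse_sd").
#' @param weights_policy "none" or "inverse_sd".
#' @param fix_Fmin_zero logical.
#' @param tol relative convergence tolerance.
#' @return object of class \code{hill_fit} with coefficients
#'   (F_min, F_max, F_half, n), covariance, fitted values and \code{flags}
#'   ("n_at_bound" when the Hill coefficient pinned at its box bound).
#' @export
fit_hill <- function(x, y, sd = NULL,
                     weights_policy = c("none", "inverse_sd"),
                     fix_Fmin_zero = FALSE, tol = 1e-10) {
  weights_policy <- match.arg(weights_policy)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 5L) stop_coac("need >= 5 points")
  if (any(x <= 0)) stop_coac("x must be positive")
  w <- rep(1, length(x))
  if (weights_policy == "inverse_sd") {
    if (is.null(sd)) stop_coac("`sd` required for inverse_sd weighting")
    sd <- sd[keep]
    w <- 1 / sd
  }
  o <- order(x); x <- x[o]; y <- y[o]; w <- w[o]
  Fmin0 <- if (fix_Fmin_zero) 0 else min(y)
  Fmax0 <- max(y)
  half <- Fmin0 + (Fmax0 - Fmin0) / 2
  ih <- which(y >= half)[1]
  Fh0 <- if (!is.na(ih)) x[ih] else stats::median(x)
  n_hi <- 50
  fit <- if (fix_Fmin_zero) {
    fit_ls(function(x, p) hill(x, 0, p[["F_max"]], p[["F_half"]], p[["n"]]),
           start = c(F_max = Fmax0, F_half = Fh0, n = 2),
           x = x, y = y, w = w, lower = c(-Inf, 1e-9, 0.1),
           upper = c(Inf, Inf, n_hi), ftol = tol, context = "Hill fit")
  } else {
    fit_ls(function(x, p) hill(x, p[["F_min"]], p[["F_max"]], p[["F_half"]],
                               p[["n"]]),
           start = c(F_min = Fmin0, F_max = Fmax0, F_half = Fh0, n = 2),
           x = x, y = y, w = w, lower = c(-Inf, -Inf, 1e-9, 0.1),
           upper = c(Inf, Inf, Inf, n_hi), ftol = tol, context = "Hill fit")
  }
  co <- if (fix_Fmin_zero) c(F_min = 0, fit$par) else fit$par
  names(co) <- c("F_min", "F_max", "F_half", "n")
  flags <- character()
  if (co[["n"]] >= n_hi - 1e-6 || co[["n"]] <= 0.1 + 1e-6) {
    flags <- c(flags, "n_at_bound")
  }
  structure(list(coefficients = co, vcov = fit$vcov,
                 curve = data.frame(x = x, y = y, fitted = fit$fitted),
                 fix_Fmin_zero = fix_Fmin_zero, flags = flags,
                 deviance = fit$deviance),
            class = "hill_fit")
}

#' @export
coef.hill_fit <- function(object, ...) object$coefficients

#' @export
print.hill_fit <- function(x, ...) {
  co <- x$coefficients
  cat(sprintf(
    "<hill_fit> F_min = %.4g, F_max = %.4g, F_half = %.4g, n = %.4g%s\n",
    co["F_min"], co["F_max"], co["F_half"], co["n"],
    if (length(x$flags)) paste0("  [", paste(x$flags, collapse = ", "), "]")
    else ""))
  invisible(x)
}

#' @export
predict.hill_fit <- function(object, x = NULL, ...) {
  if (is.null(x)) return(object$curve$fitted)
  co <- object$coefficients
  hill(x, co[["F_min"]], co[["F_max"]], co[["F_half"]], co[["n"]])
}

#' @export
plot.hill_fit <- function(x, ...) {
  graphics::plot(x$curve$x, x$curve$y, pch = 16, log = "x",
                 xlab = "a.a./nt ratio", ylab = "signal", ...)
  xx <- exp(seq(log(min(x$curve$x)), log(max(x$curve$x)), length.out = 300))
  graphics::lines(xx, predict(x, xx), col = 2, lwd = 2)
  invisible(x)
}

#' Mixture specification and monomer stoichiometry
#'
#' \code{mixture_spec} describes the species in a coacervation mix;
#' \code{mixture_stoichiometry} reduces it to monomer totals and the
#' amino-acid/nucleotide (a.a./nt) ratio that forms the titration axis of the
#' phase diagrams, plus a charge/nt ratio counting only charged monomers.
#'
#' The default ligase mix (5 uM enzyme strand of 66 nt + 6 uM substrate of
#' 18 nt) totals 438 uM nucleotide.
#'
#' @param name species names.
#' @param conc_uM molar chain concentrations, uM.
#' @param length monomers per chain (nt or residues).
#' @param charged charged monomers per chain.
#' @param type "rna" or "peptide" per species.
#' @return \code{mixture_spec}: a classed data frame.
#' @export
mixture_spec <- function(name, conc_uM, length, charged, type) {
  if (any(conc_uM < 0)) stop_coac("concentrations must be >= 0")
  if (any(length < 1)) stop_coac("lengths must be >= 1")
  if (any(charged > length)) stop_coac("charged monomers cannot exceed length")
  if (!all(type %in% c("rna", "peptide"))) {
    stop_coac("type must be 'rna' or 'peptide'")
  }
  structure(data.frame(name = name, conc_uM = conc_uM, length = length,
                       charged = charged, type = type),
            class = c("mixture_spec", "data.frame"))
}

#' @rdname mixture_spec
#' @param spec a \code{mixture_spec}.
#' @return \code{mixture_stoichiometry}: list(nt_uM, aa_uM, aa_nt_ratio,
#'   charge_nt_ratio, charge_uM_rna, charge_uM_peptide). Monomer totals are
#'   sums of conc * length over the species class; the charge ratio uses
#'   charged monomers only.
#' @export
mixture_stoichiometry <- function(spec) {
  stopifnot(inherits(spec, "mixture_spec"))
  rna <- spec[spec$type == "rna", ]
  pep <- spec[spec$type == "peptide", ]
  nt <- sum(rna$conc_uM * rna$length)
  aa <- sum(pep$conc_uM * pep$length)
  if (nt == 0) stop_coac("zero nucleotide total: a.a./nt ratio undefined")
  list(nt_uM = nt, aa_uM = aa, aa_nt_ratio = aa / nt,
       charge_nt_ratio = sum(pep$conc_uM * pep$charged) / nt,
       charge_uM_rna = sum(rna$conc_uM * rna$charged),
       charge_uM_peptide = sum(pep$conc_uM * pep$charged))
}

#' Default R3C ligase coacervation mix
#'
#' 5 uM enzyme strand (66 nt, fully charged backbone) plus 6 uM substrate
#' strand (18 nt): 438 uM total nucleotide.
#'
#' @return a \code{mixture_spec}.
#' @export
r3c_standard_mix <- function() {
  mixture_spec(name = c("E", "S2"), conc_uM = c(5, 6), length = c(66, 18),
               charged = c(66, 18), type = c("rna", "rna"))
}

#' Combinatorial plausibility factor of a heteropeptide
#'
#' Number of distinct arrangements of k cationic residues over an n-mer
#' relative to the single arrangement of an equally long homopeptide: the
#' falling factorial \code{n * (n-1) * ... * (n-k+1)}, exact.
#'
#' @param n peptide length. @param k cationic residue count (0 <= k <= n).
#' @return the multiplicity as a double (exact for the ranges of interest).
#' @export
combinatorial_factor <- function(n, k) {
  if (k > n || k < 0 || n < 0) stop_coac("need 0 <= k <= n")
  if (k == 0) return(1)
  prod(seq(n, n - k + 1))
}

#' RNA nucleotide concentration from absorbance (Beer-Lambert)
#'
#' \code{c = A / (epsilon * l)} with the average per-nucleotide extinction
#' coefficient epsilon = 8.9e-3 1/(uM cm) at 260 nm.
#'
#' @param A260 absorbance. @param path_cm path length, cm.
#' @param epsilon extinction coefficient, 1/(uM cm).
#' @return concentration in uM nucleotide.
#' @export
rna_concentration_from_absorbance <- function(A260, path_cm = 1,
                                              epsilon = 8.9e-3) {
  check_pos(path_cm, "path_cm")
  check_pos(epsilon, "epsilon")
  if (any(A260 < 0)) stop_coac("absorbance must be >= 0")
  A260 / (epsilon * path_cm)
}

#' Aggregate replicate measurements
#'
#' Mean with a t-based 68% confidence interval per x value (the reporting
#' convention for titration and partitioning curves).
#'
#' @param x grouping axis values.
#' @param y measurements (same length).
#' @param level confidence level, default 0.68.
#' @return data frame (x, mean, lower, upper, n), ordered by x.
#' @export
aggregate_replicates <- function(x, y, level = 0.68) {
  out <- lapply(split(y, x), function(v) {
    ci <- t_ci(v, level)
    data.frame(mean = ci[["mean"]], lower = ci[["lower"]],
               upper = ci[["upper"]], n = ci[["n"]])
  })
  df <- do.call(rbind, out)
  df <- cbind(x = as.numeric(names(out)), df)
  rownames(df) <- NULL
  df[order(df$x), ]
}
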