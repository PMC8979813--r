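# small shared utilities: special functions, confidence intervals, hashing,
# stage-level logging

#' Error function
#'
#' \code{erf(z) = 2*pnorm(z*sqrt(2)) - 1}, used by the exponentially modified
#' Gaussian model.
#' @param z numeric vector.
#' @return numeric vector of the same length.
#' @export
erf <- function(z) 2 * stats::pnorm(z * sqrt(2)) - 1

# t-based confidence interval of the mean; level 0.95 for diffusion summaries,
# 0.68 for replicate aggregation (the reporting convention for titrations)
t_ci <- function(x, level = 0.95) {
  x <- x[is.finite(x)]
  n <- length(x)
  m <- mean(x)
  if (n < 2) {
    return(c(mean = m, lower = NA_real_, upper = NA_real_, n = n))
  }
  half <- stats::qt(1 - (1 - level) / 2, df = n - 1) * stats::sd(x) / sqrt(n)
  c(mean = m, lower = m - half, upper = m + half, n = n)
}

# FNV-1a 32-bit hash over a serialized object; used to stamp a run
# configuration into downstream results for provenance
fnv1a32 <- function(x) {
  bytes <- as.integer(serialize(x, connection = NULL, version = 2L))
  h <- 2166136261
  for (b in bytes) {
    # xor with a byte touches only the low 8 bits (bitwXor cannot take
    # values past 2^31, so operate on the low byte explicitly)
    low <- h %% 256
    h <- h - low + bitwXor(low, b)
    # 32-bit modular multiply by the FNV prime 16777619 = 2^24 + 403, split
    # so intermediate products stay below 2^53 (doubles are exact there)
    h <- ((h %% 256) * 16777216 + (h * 403) %% 4294967296) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

coac_log <- function(stage, ..., verbose = getOption("coacdyn.verbose", FALSE)) {
  if (isTRUE(verbose)) {
    message(sprintf("[coacdyn:%s] %s", stage, paste0(..., collapse = "")))
  }
  invisible(NULL)
}

stop_coac <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Levenberg-Marquardt least squares on an arbitrary model function.
# `model(x, p)` takes the predictor and a named parameter vector; optional
# residual weights w multiply the residuals. Returns parameters, fitted
# values, a moment-based covariance sigma^2 (J'J)^-1 (zero for perfect fits),
# and the optimizer diagnostics.
fit_ls <- function(model, start, x, y, w = NULL,
                   lower = rep(-Inf, length(start)),
                   upper = rep(Inf, length(start)),
                   maxiter = 1000L, ftol = 1e-10, context = "fit") {
  fn <- function(p) {
    r <- y - model(x, unlist(p))
    if (!is.null(w)) r <- w * r
    r
  }
  out <- minpack.lm::nls.lm(
    par = as.list(start), fn = fn, lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = maxiter, ftol = ftol,
                                         maxfev = 100000L))
  if (out$info == 0L) {
    stop_coac("%s: improper optimizer input (start: %s)", context,
              paste(sprintf("%s=%.4g", names(start), unlist(start)),
                    collapse = ", "))
  }
  if (out$info == 5L) {
    stop_coac(
      "%s did not converge in %d iterations (start: %s; residual %.4g)",
      context, maxiter,
      paste(sprintf("%s=%.4g", names(start), unlist(start)), collapse = ", "),
      out$deviance)
  }
  p <- unlist(out$par)
  np <- length(p)
  n <- length(y)
  sigma2 <- out$deviance / max(n - np, 1L)
  vc <- tryCatch(sigma2 * solve(out$hessian), error = function(e) NULL)
  if (!is.null(vc)) dimnames(vc) <- list(names(p), names(p))
  list(par = p, fitted = model(x, p), vcov = vc, deviance = out$deviance,
       info = out$info, message = out$message)
}

# shared validator for strictly positive scalars
check_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_coac("`%s` must be a single positive finite number", name)
  }
  invisible(x)
}
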