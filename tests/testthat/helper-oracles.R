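# independent oracles used across tests

# brute-force grid minimizer for the origin-constrained regression slope;
# iterative refinement keeps the oracle purely enumerative while reaching
# high resolution
brute_force_origin_slope <- function(r, tau, lo = NULL, hi = NULL,
                                     n_grid = 2001L, passes = 4L) {
  if (is.null(lo)) lo <- 0.5 * min(tau / r)
  if (is.null(hi)) hi <- 2 * max(tau / r)
  best <- NA_real_
  for (p in seq_len(passes)) {
    grid <- seq(lo, hi, length.out = n_grid)
    sse <- vapply(grid, function(a) sum((tau - a * r)^2), numeric(1))
    i <- which.min(sse)
    best <- grid[i]
    step <- grid[2] - grid[1]
    lo <- best - 2 * step
    hi <- best + 2 * step
  }
  best
}

# error-function sigmoid: the slow-decay limit of the Gaussian (x)
# exponential convolution has a pure erf-shaped rise around x0
erf_sigmoid <- function(x, x0, sigma) {
  (1 + coacdyn::erf((x - x0) / sigma)) / 2
}

# draw a filled ellipse (semi-axes in px, rotation in radians)
render_ellipse <- function(nrow, ncol, row, col, a, b, theta = 0,
                           fg = 0.9, bg = 0.05) {
  rr <- matrix(seq_len(nrow), nrow, ncol) - row
  cc <- matrix(seq_len(ncol), nrow, ncol, byrow = TRUE) - col
  u <- rr * cos(theta) + cc * sin(theta)
  v <- -rr * sin(theta) + cc * cos(theta)
  bg + (fg - bg) * (((u / a)^2 + (v / b)^2) <= 1)
}

render_disk <- function(nrow, ncol, row, col, r, fg = 0.9, bg = 0.05) {
  render_ellipse(nrow, ncol, row, col, r, r, 0, fg, bg)
}
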