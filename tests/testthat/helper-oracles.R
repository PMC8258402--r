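# Independent oracles used across tests: direct quadrature on the analytic
# expressions, never the package's own curve machinery.

# arc length of y = a*sin(2*pi*x/wl) over [0, L] by adaptive quadrature
sine_arc_quadrature <- function(L, a, wl) {
  k <- 2 * pi / wl
  stats::integrate(function(x) sqrt(1 + (a * k * cos(k * x))^2), 0, L,
                   rel.tol = 1e-10)$value
}

# analytic sample of y = sin(x) on [0, 2*pi], arc-length-uniform via a
# dense inversion grid (independent of generate_curve)
sine_unit_samples <- function(n = 400) {
  m <- 200001L
  xg <- seq(0, 2 * pi, length.out = m)
  sp <- sqrt(1 + cos(xg)^2)
  cum <- c(0, cumsum((sp[-1] + sp[-m]) / 2 * diff(xg)))
  s <- seq(0, cum[m], length.out = n)
  xs <- stats::approx(cum, xg, xout = s, ties = "ordered")$y
  cbind(xs, sin(xs))
}

rotate_points <- function(pts, angle, shift = c(0, 0)) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  sweep(pts %*% t(R), 2, -shift)
}

# endpoint count of a skeleton raster via direct neighbor counting
# (independent of the package's internals)
count_endpoints <- function(raster) {
  nr <- nrow(raster); nc <- ncol(raster)
  n <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!raster[r, c]) next
    nb <- raster[max(1, r - 1):min(nr, r + 1), max(1, c - 1):min(nc, c + 1)]
    if (sum(nb) - 1L == 1L) n <- n + 1L
  }
  n
}

# brute-force minimum over slab voxels for minIP checks
min_over_slab <- function(volume, axis, planes) {
  apply(volume, setdiff(1:3, axis), function(v) min(v[planes]))
}
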