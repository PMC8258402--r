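#' Specify an analytic centerline curve
#'
#' Builds a validated specification for one of the analytic curve families
#' used as ground truth for the morphometry pipeline. All curves are laid
#' out in a chord-aligned frame: the endpoints sit at (0, 0) and
#' (`chord_length`, 0), so the chord length is exact by construction.
#'
#' Families and their parameters:
#' \describe{
#'   \item{straight}{no extra parameters.}
#'   \item{circular_arc}{`arc_angle` (rad, in (0, 2*pi)): the subtended
#'     angle; the radius follows from the chord.}
#'   \item{sinusoid}{`amplitude` (mm, >= 0) and `wavelength` (mm, > 0);
#'     y = amplitude * sin(2*pi*x / wavelength) over x in [0, chord].}
#'   \item{spline}{`n_control` (>= 3) interior knot count and `wiggle`
#'     (mm, sd of random knot heights); a natural cubic spline through
#'     seeded random control points with zero-height endpoints.}
#' }
#'
#' @param family One of "straight", "circular_arc", "sinusoid", "spline".
#' @param chord_length Endpoint-to-endpoint distance in mm; must be > 0.
#' @param sample_count Number of points returned along the curve (>= 2).
#' @param seed Integer seed; only consulted by the spline family.
#' @param ... Family-specific parameters, see Details.
#' @return An object of class `curve_spec`.
#' @seealso [generate_curve()]
#' @export
curve_spec <- function(family = c("straight", "circular_arc", "sinusoid", "spline"),
                       chord_length, sample_count = 200L, seed = 1L, ...) {
  family <- match.arg(family)
  if (!is.numeric(chord_length) || length(chord_length) != 1L || chord_length <= 0)
    stop("chord_length must be a single positive number (mm)")
  if (sample_count < 2L) stop("sample_count must be >= 2")
  pars <- list(...)
  if (family == "circular_arc") {
    ang <- pars$arc_angle
    if (is.null(ang) || ang <= 0 || ang >= 2 * pi)
      stop("circular_arc needs arc_angle in (0, 2*pi)")
  }
  if (family == "sinusoid") {
    if (is.null(pars$amplitude) || pars$amplitude < 0)
      stop("sinusoid needs amplitude >= 0")
    if (is.null(pars$wavelength) || pars$wavelength <= 0)
      stop("sinusoid needs wavelength > 0")
  }
  if (family == "spline") {
    if (is.null(pars$n_control)) pars$n_control <- 4L
    if (is.null(pars$wiggle)) pars$wiggle <- chord_length / 10
    if (pars$n_control < 1L) stop("spline needs n_control >= 1")
  }
  structure(list(family = family, chord_length = chord_length,
                 sample_count = as.integer(sample_count),
                 seed = as.integer(seed), parameters = pars),
            class = "curve_spec")
}

# y(x) and y'(x) for the graph-of-a-function families (sinusoid, spline).
.curve_fun <- function(spec) {
  p <- spec$parameters
  switch(spec$family,
    straight = list(f = function(x) rep(0, length(x)),
                    df = function(x) rep(0, length(x))),
    sinusoid = {
      k <- 2 * pi / p$wavelength
      list(f = function(x) p$amplitude * sin(k * x),
           df = function(x) p$amplitude * k * cos(k * x))
    },
    spline = {
      set.seed(spec$seed)
      xs <- seq(0, spec$chord_length, length.out = p$n_control + 2L)
      ys <- c(0, stats::rnorm(p$n_control, 0, p$wiggle), 0)
      sf <- stats::splinefun(xs, ys, method = "natural")
      list(f = function(x) sf(x), df = function(x) sf(x, deriv = 1L))
    },
    stop("unknown family: ", spec$family))
}

#' Generate an analytic curve and its ground truth
#'
#' Samples `sample_count` points uniformly in arc length along the curve
#' described by `spec` (mimicking even pixel-wise delineation density) and
#' computes ground-truth quantities: arc length (closed form where
#' available, otherwise adaptive quadrature), chord, true distance metric,
#' and the true number of critical points (slope sign changes in the
#' chord-aligned frame).
#'
#' @param spec A [curve_spec()].
#' @return A list with components `centerline` (a [centerline] object) and
#'   `ground_truth` (list: `arc_length`, `chord`, `dm_true`,
#'   `n_critical_true`).
#' @examples
#' gc <- generate_curve(curve_spec("circular_arc", chord_length = 2,
#'                                 arc_angle = pi))
#' gc$ground_truth$dm_true   # pi/2 for a semicircle
#' @export
generate_curve <- function(spec) {
  stopifnot(inherits(spec, "curve_spec"))
  L <- spec$chord_length
  n <- spec$sample_count
  if (spec$family == "straight") {
    pts <- cbind(seq(0, L, length.out = n), 0)
    gt <- list(arc_length = L, chord = L, dm_true = 1, n_critical_true = 0L)
    return(list(centerline = centerline(pts), ground_truth = gt))
  }
  if (spec$family == "circular_arc") {
    phi <- spec$parameters$arc_angle
    r <- L / (2 * sin(phi / 2))
    t <- seq(-phi / 2, phi / 2, length.out = n)   # constant speed: arc-uniform
    pts <- cbind(L / 2 + r * sin(t), r * cos(t) - r * cos(phi / 2))
    gt <- list(arc_length = r * phi, chord = L,
               dm_true = phi / (2 * sin(phi / 2)),
               n_critical_true = 1L)   # single apex where dy/dx = 0
    return(list(centerline = centerline(pts), ground_truth = gt))
  }
  fn <- .curve_fun(spec)
  # dense grid (>= 100x the sample density) for quadrature + inversion
  m <- max(100L * n, 10000L)
  xg <- seq(0, L, length.out = m)
  speed <- sqrt(1 + fn$df(xg)^2)
  dx <- L / (m - 1)
  cum <- c(0, cumsum((speed[-1] + speed[-m]) / 2 * dx))
  arc <- cum[m]
  # arc-length-uniform resampling
  s <- seq(0, arc, length.out = n)
  xs <- stats::approx(cum, xg, xout = s, ties = "ordered")$y
  pts <- cbind(xs, fn$f(xs))
  # critical points: strict sign changes of y' on the dense grid
  sgn <- sign(fn$df(xg))
  sgn <- sgn[sgn != 0]
  ncrit <- if (length(sgn) < 2L) 0L else sum(diff(sgn) != 0)
  gt <- list(arc_length = arc, chord = L, dm_true = arc / L,
             n_critical_true = as.integer(ncrit))
  list(centerline = centerline(pts), ground_truth = gt)
}

# 8-connected Bresenham line between two pixels (inclusive)
.bresenham <- function(p0, p1) {
  dr <- p1[1] - p0[1]; dc <- p1[2] - p0[2]
  n <- max(abs(dr), abs(dc))
  if (n == 0L) return(matrix(p0, 1L, 2L))
  t <- seq_len(n) / n
  cbind(p0[1] + round(t * dr), p0[2] + round(t * dc))
}

#' Rasterize a centerline into a binary vessel mask
#'
#' Draws the curve onto a pixel grid at the requested physical spacing,
#' producing an 8-connected stroke, optionally thickened and decorated
#' with short false side branches ("spurs") emulating tracing noise.
#'
#' @param curve A [centerline] (points in mm).
#' @param spacing Pixel spacing in mm/pixel; scalar or `c(row, col)`.
#' @param width Stroke width in pixels (>= 1; odd widths are symmetric).
#' @param spur_n Number of false spurs to attach at random curve pixels.
#' @param spur_len Spur length in pixels.
#' @param margin Canvas margin in pixels around the curve bounding box.
#' @param seed Seed for spur placement.
#' @return A [vessel_mask] whose `origin` places pixel (1,1)'s center at
#'   the bounding-box corner minus the margin.
#' @export
rasterize_curve <- function(curve, spacing, width = 1L, spur_n = 0L,
                            spur_len = 2L, margin = 3L, seed = 1L) {
  pts <- as_centerline_matrix(curve)
  if (any(spacing <= 0)) stop("spacing must be > 0")
  if (width < 1L) stop("width must be >= 1 pixel")
  sp <- if (length(spacing) == 1L) c(spacing, spacing) else spacing[1:2]
  x0 <- min(pts[, 1]) - margin * sp[2]
  y0 <- min(pts[, 2]) - margin * sp[1]
  col <- round((pts[, 1] - x0) / sp[2]) + 1L
  row <- round((pts[, 2] - y0) / sp[1]) + 1L
  px <- cbind(row, col)
  px <- px[c(TRUE, rowSums(abs(diff(px))) > 0), , drop = FALSE]
  # Bresenham-connect successive sample pixels: the stroke stays a thin
  # 8-connected chain (no 4-connected staircase doubling)
  chain <- vector("list", max(1L, nrow(px) - 1L))
  if (nrow(px) == 1L) chain[[1L]] <- px
  for (i in seq_len(nrow(px) - 1L))
    chain[[i]] <- .bresenham(px[i, ], px[i + 1L, ])
  seg <- rbind(px[1L, , drop = FALSE], do.call(rbind, chain))
  seg <- seg[c(TRUE, rowSums(abs(diff(seg))) > 0), , drop = FALSE]
  # collapse L-corners (drop a pixel when its neighbors are mutually
  # 8-adjacent) so the stroke is a minimal 8-connected chain
  repeat {
    n <- nrow(seg)
    if (n < 3L) break
    drop <- rep(FALSE, n)
    i <- 2L
    while (i < n) {
      if (!drop[i - 1L] &&
          max(abs(seg[i - 1L, ] - seg[i + 1L, ])) <= 1L) {
        drop[i] <- TRUE
        i <- i + 2L
      } else i <- i + 1L
    }
    if (!any(drop)) break
    seg <- seg[!drop, , drop = FALSE]
    seg <- seg[c(TRUE, rowSums(abs(diff(seg))) > 0), , drop = FALSE]
  }
  row <- seg[, 1]; col <- seg[, 2]
  nr <- max(row) + margin
  nc <- max(col) + margin
  ras <- matrix(FALSE, nr, nc)
  ras[cbind(row, col)] <- TRUE
  if (width > 1L) {
    r <- (width - 1) / 2
    offs <- expand.grid(dr = -ceiling(r):ceiling(r), dc = -ceiling(r):ceiling(r))
    offs <- offs[offs$dr^2 + offs$dc^2 <= r^2 + 1e-9, , drop = FALSE]
    base <- which(ras, arr.ind = TRUE)
    for (j in seq_len(nrow(offs))) {
      rr <- base[, 1] + offs$dr[j]; cc <- base[, 2] + offs$dc[j]
      ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
      ras[cbind(rr[ok], cc[ok])] <- TRUE
    }
  }
  if (spur_n > 0L) {
    set.seed(seed)
    path_px <- unique(cbind(row, col))
    # avoid the curve's own endpoints so spurs are genuine side branches
    idx <- sample(seq(max(2L, spur_len + 2L), nrow(path_px) - max(1L, spur_len + 1L)),
                  spur_n, replace = spur_n > nrow(path_px))
    dirs <- matrix(c(1, 0, -1, 0, 0, 1, 0, -1, 1, 1, -1, -1, 1, -1, -1, 1),
                   ncol = 2, byrow = TRUE)
    stroke <- ras
    for (i in idx) {
      # pick a direction whose pixels (and their neighborhoods) leave the
      # existing stroke, so the spur is a genuine false side branch that
      # survives thinning with its own endpoint
      for (di in sample.int(8L)) {
        d <- dirs[di, ]
        rr <- path_px[i, 1] + seq_len(spur_len) * d[1]
        cc <- path_px[i, 2] + seq_len(spur_len) * d[2]
        if (any(rr < 2 | rr > nr - 1 | cc < 2 | cc > nc - 1)) next
        clear <- TRUE
        for (k in seq_len(spur_len)) {
          nbhd <- stroke[(rr[k] - 1):(rr[k] + 1), (cc[k] - 1):(cc[k] + 1)]
          # pixel 1 may touch the attachment pixel and its two chain
          # neighbors; deeper spur pixels must be clear of the stroke
          allowed <- if (k == 1L) 3L else 0L
          if (sum(nbhd) > allowed) { clear <- FALSE; break }
        }
        if (clear) {
          ras[cbind(rr, cc)] <- TRUE
          break
        }
      }
    }
  }
  vessel_mask(ras, spacing = sp, origin = c(x0, y0))
}
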