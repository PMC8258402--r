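#' Vessel length (L_A)
#'
#' Actual path length between the origin and the terminal of a vessel:
#' the sum of Euclidean distances between consecutive centerline points.
#'
#' @param c A [centerline].
#' @return Length in mm.
#' @export
vessel_length <- function(c) {
  pts <- as_centerline_matrix(c)
  if (nrow(pts) < 2L) stop("centerline needs >= 2 points")
  sum(sqrt(rowSums(diff(pts)^2)))
}

chord_length <- function(c) {
  pts <- as_centerline_matrix(c)
  sqrt(sum((pts[nrow(pts), ] - pts[1, ])^2))
}

#' Distance metric (DM)
#'
#' Conventional tortuosity: the ratio of vessel length to the Euclidean
#' distance between the two centerline endpoints. Equals 1 for a
#' straight vessel and is >= 1 otherwise.
#'
#' @param c A [centerline].
#' @return Dimensionless ratio >= 1 (up to floating tolerance).
#' @export
distance_metric <- function(c) {
  ch <- chord_length(c)
  if (ch <= .Machine$double.eps^0.5)
    stop("coincident endpoints: DM undefined for closed curves")
  vessel_length(c) / ch
}

# rotate + translate so the endpoint chord lies on the +x axis with the
# start point at the origin
chord_align <- function(pts) {
  pts <- sweep(pts, 2, pts[1, ])
  v <- pts[nrow(pts), ]
  ang <- atan2(v[2], v[1])
  R <- matrix(c(cos(-ang), sin(-ang), -sin(-ang), cos(-ang)), 2, 2)
  pts %*% t(R)
}

# per-point tangent vectors by central differences over +/- window points
# (one-sided at the ends)
.tangents <- function(pts, window) {
  n <- nrow(pts)
  j1 <- pmax(1L, seq_len(n) - window)
  j2 <- pmin(n, seq_len(n) + window)
  cbind(pts[j2, 1] - pts[j1, 1], pts[j2, 2] - pts[j1, 2])
}

#' Tangent angles along a centerline
#'
#' Estimates the angle between the tangent at each centerline point and
#' the x axis. In the default chord-aligned frame the centerline is
#' first rotated so its endpoint chord lies on the x axis, which makes
#' the angles (and everything built on them) rotation-invariant. Angles
#' are unwrapped along the path so consecutive values never jump by more
#' than 180 degrees.
#'
#' @param c A [centerline] with more than `window` points.
#' @param window Half-width, in points, of the central-difference
#'   tangent estimate (>= 1); one-sided at the ends.
#' @param frame "chord" (default) aligns the endpoint chord with the x
#'   axis first; "image" uses the raw coordinate frame.
#' @param unit "degrees" (default) or "radians".
#' @return Numeric vector of unwrapped tangent angles, one per point.
#' @export
tangent_angles <- function(c, window = 3L, frame = c("chord", "image"),
                           unit = c("degrees", "radians")) {
  frame <- match.arg(frame)
  unit <- match.arg(unit)
  pts <- as_centerline_matrix(c)
  if (window < 1L) stop("window must be >= 1")
  if (nrow(pts) <= window) stop("too few points for the tangent window")
  if (frame == "chord") pts <- chord_align(pts)
  tg <- .tangents(pts, window)
  ang <- atan2(tg[, 2], tg[, 1])
  # unwrap: keep successive differences within (-pi, pi]
  d <- diff(ang)
  d <- d - 2 * pi * round(d / (2 * pi))
  ang <- ang[1] + c(0, cumsum(d))
  if (unit == "degrees") ang * 180 / pi else ang
}

#' Standard deviation of tangent angles (SD_theta)
#'
#' Sample standard deviation of the unwrapped tangent angles: the local
#' angle-change component of the vessel tortuosity index.
#'
#' @param angles Vector of angles from [tangent_angles()].
#' @return SD in the unit of the input angles.
#' @export
sd_theta <- function(angles) {
  if (length(angles) < 2L) stop("need >= 2 angles")
  stats::sd(angles)
}

# slope signs along the chord-aligned curve: smoothed dy per point with
# zeros dropped (zero-slope plateaus collapse) and short jitter runs
# shorter than min_run removed. tol must be set from the curve scale so
# that exactly-straight lines (dy at rounding noise) read as all-zero.
.slope_signs <- function(dy, min_run, tol) {
  s <- sign(dy)
  s[abs(dy) <= tol] <- 0
  idx <- which(s != 0)
  if (length(idx) == 0L) return(list(sign = integer(0), index = integer(0)))
  r <- rle(s[idx])
  keep <- r$lengths >= min_run | seq_along(r$lengths) %in%
    c(1L, length(r$lengths))  # never drop the first/last run
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sgn <- r$values[keep]
  loc <- idx[starts[keep]]
  # merge adjacent equal signs left after dropping jitter runs
  if (length(sgn) > 1L) {
    m <- c(TRUE, diff(sgn) != 0)
    sgn <- sgn[m]; loc <- loc[m]
  }
  list(sign = sgn, index = loc)
}

#' Critical points of a centerline (N)
#'
#' Counts the points where the first derivative of the chord-aligned
#' centerline vanishes, detected as strict sign changes of the smoothed
#' slope sequence. Consecutive zero-slope runs collapse to a single
#' candidate, and sign runs shorter than `min_run` points are treated as
#' rasterization jitter and ignored.
#'
#' @inheritParams tangent_angles
#' @param min_run Minimum persistence (points) of a slope sign before it
#'   counts; guards against pixel jitter on rasterized curves.
#' @return List with `n` (integer count) and `index` (point indices just
#'   after each sign change).
#' @export
critical_points <- function(c, window = 3L, frame = c("chord", "image"),
                            min_run = 3L) {
  frame <- match.arg(frame)
  pts <- as_centerline_matrix(c)
  if (frame == "chord") pts <- chord_align(pts)
  tg <- .tangents(pts, min(window, nrow(pts) - 1L))
  ss <- .slope_signs(tg[, 2], min_run, tol = 1e-8 * max(abs(tg)))
  if (length(ss$sign) < 2L) return(list(n = 0L, index = integer(0)))
  chg <- which(diff(ss$sign) != 0)
  list(n = length(chg), index = ss$index[chg + 1L])
}

#' Split a centerline at inflection points
#'
#' Cuts the chord-aligned centerline where the sign of the discrete
#' curvature (the turn direction of successive tangents) changes.
#' Segments cover the whole curve and overlap only at the cut points;
#' endpoints always bound the first and last segment.
#'
#' @inheritParams critical_points
#' @return List of [centerline] segments.
#' @export
inflection_segments <- function(c, window = 3L, frame = c("chord", "image"),
                                min_run = 3L) {
  frame <- match.arg(frame)
  pts0 <- as_centerline_matrix(c)
  pts <- if (match.arg(frame) == "chord") chord_align(pts0) else pts0
  n <- nrow(pts)
  tg <- .tangents(pts, min(window, n - 1L))
  # turn direction: z-component of the cross product of successive tangents
  cross <- tg[-n, 1] * tg[-1, 2] - tg[-n, 2] * tg[-1, 1]
  ss <- .slope_signs(cross, min_run, tol = 1e-8 * max(abs(tg))^2)
  cuts <- integer(0)
  if (length(ss$sign) >= 2L) {
    chg <- which(diff(ss$sign) != 0)
    cuts <- ss$index[chg + 1L]
  }
  cuts <- sort(unique(pmin(pmax(cuts, 2L), n - 1L)))
  bounds <- c(1L, cuts, n)
  lapply(seq_len(length(bounds) - 1L), function(i)
    centerline(pts0[bounds[i]:bounds[i + 1L], , drop = FALSE]))
}

#' Curvature magnitude (M)
#'
#' Arc-to-chord ratio evaluated between consecutive inflection points
#' (centerline endpoints included), averaged over segments. Equals the
#' distance metric when the curve has a single curvature sign.
#'
#' @inheritParams critical_points
#' @return Dimensionless magnitude >= 1.
#' @export
curve_magnitude <- function(c, window = 3L, frame = c("chord", "image"),
                            min_run = 3L) {
  segs <- inflection_segments(c, window = window, frame = frame,
                              min_run = min_run)
  ratios <- vapply(segs, function(s) {
    ch <- chord_length(s)
    if (ch <= .Machine$double.eps^0.5)
      stop("inflection segment with coincident endpoints")
    vessel_length(s) / ch
  }, numeric(1))
  mean(ratios)
}

#' Vessel tortuosity index (VTI)
#'
#' Composite tortuosity score combining local angle variation, critical
#' points, curvature magnitude and the arc/chord ratio:
#'
#'   VTI = 0.1 * SD_theta * N * M * (L_A / L_C)
#'
#' It is exactly zero for a straight centerline (N = 0) and has no upper
#' bound. SD_theta is measured in degrees by default; the choice of unit
#' rescales VTI globally and is recorded with the result.
#'
#' @inheritParams tangent_angles
#' @param min_run Jitter guard for sign-change detection, see
#'   [critical_points()].
#' @return VTI (dimensionless, >= 0).
#' @export
vti <- function(c, window = 3L, frame = c("chord", "image"),
                unit = c("degrees", "radians"), min_run = 3L) {
  m <- tortuosity_metrics(c, window = window, frame = frame, unit = unit,
                          min_run = min_run)
  m$vti
}

#' All per-vessel tortuosity metrics
#'
#' Computes vessel length (L_A), chord (L_C), distance metric, tangent
#' angle SD, critical-point count, curvature magnitude and VTI for one
#' centerline.
#'
#' @inheritParams vti
#' @return A one-row data.frame: `vl_mm`, `chord_mm`, `dm`,
#'   `sd_theta_deg` (or `_rad`), `n_critical`, `magnitude`, `vti`.
#' @export
tortuosity_metrics <- function(c, window = 3L, frame = c("chord", "image"),
                               unit = c("degrees", "radians"), min_run = 3L) {
  frame <- match.arg(frame)
  unit <- match.arg(unit)
  vl <- vessel_length(c)
  ch <- chord_length(c)
  dm <- distance_metric(c)
  ang <- tangent_angles(c, window = window, frame = frame, unit = unit)
  sdt <- sd_theta(ang)
  cp <- critical_points(c, window = window, frame = frame, min_run = min_run)
  v <- if (cp$n == 0L) 0 else {
    m <- curve_magnitude(c, window = window, frame = frame, min_run = min_run)
    0.1 * sdt * cp$n * m * dm
  }
  mg <- if (cp$n == 0L) {
    # still report M (it is defined for any curve); straight lines give 1
    tryCatch(curve_magnitude(c, window = window, frame = frame,
                             min_run = min_run), error = function(e) NA_real_)
  } else curve_magnitude(c, window = window, frame = frame, min_run = min_run)
  out <- data.frame(vl_mm = vl, chord_mm = ch, dm = dm, sd_theta = sdt,
                    n_critical = cp$n, magnitude = mg, vti = v)
  names(out)[4] <- if (unit == "degrees") "sd_theta_deg" else "sd_theta_rad"
  out
}

#' Per-subject morphometry summary
#'
#' Aggregates a subject's per-vessel metrics: the LSA count plus the
#' mean, median and sample SD (n - 1 denominator; a single vessel
#' reports SD 0) of vessel length, distance metric and VTI.
#'
#' @param metrics data.frame of per-vessel metrics as returned by
#'   [tortuosity_metrics()] (one row per vessel); must be non-empty.
#' @return One-row data.frame with `lsa_count` and
#'   `{vl,dm,vti}_{mean,median,sd}` columns.
#' @export
summarize_subject <- function(metrics) {
  if (!is.data.frame(metrics) || nrow(metrics) == 0L)
    stop("metrics must be a non-empty data.frame")
  one <- function(v, stem) {
    s <- if (length(v) < 2L) 0 else stats::sd(v)
    out <- data.frame(mean(v), stats::median(v), s)
    names(out) <- paste0(stem, c("_mean", "_median", "_sd"))
    out
  }
  cbind(data.frame(lsa_count = nrow(metrics)),
        one(metrics$vl_mm, "vl"), one(metrics$dm, "dm"),
        one(metrics$vti, "vti"))
}
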