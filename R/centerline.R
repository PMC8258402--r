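#' Binary vessel mask with physical spacing
#'
#' Container for a 2D binary delineation raster. Rows map to the y axis
#' and columns to the x axis; pixel (1,1)'s center sits at `origin`
#' (x, y in mm) and spacing is anisotropic `c(row_mm, col_mm)`.
#'
#' @param raster Logical (or 0/1) matrix with at least one TRUE pixel.
#' @param spacing Pixel spacing, mm: scalar or `c(row, col)`; both > 0.
#' @param origin Physical (x, y) of the center of pixel (1,1), mm.
#' @return An object of class `vessel_mask`.
#' @export
vessel_mask <- function(raster, spacing, origin = c(0, 0)) {
  if (is.numeric(raster)) raster <- raster != 0
  if (!is.matrix(raster) || !is.logical(raster))
    stop("raster must be a logical matrix")
  if (!any(raster)) stop("mask has no foreground pixels")
  sp <- if (length(spacing) == 1L) c(spacing, spacing) else as.numeric(spacing[1:2])
  if (any(sp <= 0)) stop("spacing components must be > 0")
  structure(list(raster = raster, spacing = sp, origin = as.numeric(origin[1:2])),
            class = "vessel_mask")
}

#' @export
print.vessel_mask <- function(x, ...) {
  cat(sprintf("<vessel_mask> %d x %d px, spacing %.3g x %.3g mm, %d foreground px\n",
              nrow(x$raster), ncol(x$raster), x$spacing[1], x$spacing[2],
              sum(x$raster)))
  invisible(x)
}

#' Ordered vessel centerline in physical coordinates
#'
#' @param points Numeric n x 2 matrix of (x, y) mm, ordered along the
#'   vessel; n >= 2, consecutive points distinct, no repeated points.
#' @param spacing Optional source pixel spacing (mm) kept for provenance.
#' @return An object of class `centerline` (an n x 2 matrix).
#' @export
centerline <- function(points, spacing = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 2L || nrow(points) < 2L)
    stop("centerline needs an n x 2 matrix with n >= 2")
  if (any(rowSums(abs(diff(points))) == 0))
    stop("consecutive centerline points must be distinct")
  dimnames(points) <- list(NULL, c("x", "y"))
  structure(points, class = c("centerline", "matrix"),
            spacing = spacing)
}

as_centerline_matrix <- function(c) {
  m <- unclass(c)
  attr(m, "spacing") <- NULL
  m
}

#' Thin-slab minimum intensity projection
#'
#' Collapses a slab of a 3D intensity volume to a 2D image by taking the
#' voxel-wise minimum along one axis, the standard rendering for dark
#' vessels on black-blood MRI. Slab boundaries are resolved to whole
#' voxel planes, rounding half toward the slab center.
#'
#' @param volume 3D numeric array.
#' @param axis Projection axis (1, 2 or 3).
#' @param slab Slab thickness in mm (> 0).
#' @param slab_center Slab center along `axis`, mm from the first plane.
#' @param spacing Voxel size along `axis`, mm (default 1).
#' @return 2D matrix of minima over the slab.
#' @export
min_intensity_projection <- function(volume, axis = 3L, slab, slab_center,
                                     spacing = 1) {
  if (length(dim(volume)) != 3L) stop("volume must be a 3D array")
  if (!axis %in% 1:3) stop("axis must be 1, 2 or 3")
  if (slab <= 0) stop("slab must be > 0 mm")
  nax <- dim(volume)[axis]
  # plane i sits at (i-1)*spacing; keep planes whose centers fall inside
  # the slab. A slab edge exactly halfway between two plane centers keeps
  # the inner plane only (round half toward slab center).
  pos <- (seq_len(nax) - 1) * spacing
  lo <- slab_center - slab / 2
  hi <- slab_center + slab / 2
  keep <- which(pos >= lo - 1e-9 & pos <= hi + 1e-9)
  if (length(keep) == 0L) {
    if (hi < pos[1] || lo > pos[nax]) stop("slab entirely outside volume")
    keep <- which.min(abs(pos - slab_center))  # thin slab between planes
  }
  apply(volume, setdiff(1:3, axis), function(v) min(v[keep]))
}

# shift a logical matrix by (dr, dc), padding with FALSE
.shift <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

# 8-neighborhoods in Zhang-Suen order P2..P9 (N, NE, E, SE, S, SW, W, NW),
# with rows increasing downward so "N" is row - 1
.zs_offsets <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                    c(1, 0), c(1, -1), c(0, -1), c(-1, -1))

# TRUE if the foreground 8-neighbors of pixel (r, c) remain a single
# 8-connected cluster when the pixel itself is removed (an "8-simple"
# pixel; deleting it cannot disconnect the skeleton locally)
.is_simple <- function(img, r, c) {
  pos <- list()
  for (o in .zs_offsets) {
    rr <- r + o[1]; cc <- c + o[2]
    if (rr >= 1 && rr <= nrow(img) && cc >= 1 && cc <= ncol(img) &&
        img[rr, cc])
      pos[[length(pos) + 1L]] <- o
  }
  k <- length(pos)
  if (k <= 1L) return(TRUE)
  seen <- logical(k)
  seen[1] <- TRUE
  queue <- 1L
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    for (j in which(!seen)) {
      if (max(abs(pos[[i]] - pos[[j]])) <= 1L) {
        seen[j] <- TRUE
        queue <- c(queue, j)
      }
    }
  }
  all(seen)
}

# sequentially delete 8-simple pixels with >= 2 neighbors: removes the
# staircase redundancy that parallel thinning leaves behind, yielding a
# minimal 8-connected skeleton. Endpoints (1 neighbor) are never touched.
.sparsify <- function(img) {
  repeat {
    changed <- FALSE
    nbc <- .neighbor_counts(img)
    cand <- which(img & nbc >= 2L, arr.ind = TRUE)
    for (i in seq_len(nrow(cand))) {
      r <- cand[i, 1]; c <- cand[i, 2]
      if (!img[r, c]) next
      nb <- 0L
      for (o in .zs_offsets) {
        rr <- r + o[1]; cc <- c + o[2]
        if (rr >= 1 && rr <= nrow(img) && cc >= 1 && cc <= ncol(img) &&
            img[rr, cc]) nb <- nb + 1L
      }
      if (nb >= 2L && .is_simple(img, r, c)) {
        img[r, c] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img
}

#' Skeletonize a binary vessel mask
#'
#' Zhang-Suen iterative thinning followed by a sequential simple-point
#' sparsification pass, yielding a minimal one-pixel-wide, 8-connected
#' medial skeleton. The output foreground is always a subset of the
#' input foreground.
#'
#' @param mask A [vessel_mask].
#' @return A [vessel_mask] holding the skeleton.
#' @export
skeletonize <- function(mask) {
  stopifnot(inherits(mask, "vessel_mask"))
  img <- mask$raster
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      nb <- lapply(.zs_offsets, function(o) .shift(img, o[1], o[2]))
      bsum <- Reduce(`+`, nb)
      # A: number of FALSE -> TRUE transitions around the ring P2..P9..P2
      ring <- c(nb, nb[1])
      a <- Reduce(`+`, lapply(1:8, function(i) (!ring[[i]]) & ring[[i + 1]]))
      if (sub == 1) {
        c1 <- !(nb[[1]] & nb[[3]] & nb[[5]])   # P2*P4*P6 == 0
        c2 <- !(nb[[3]] & nb[[5]] & nb[[7]])   # P4*P6*P8 == 0
      } else {
        c1 <- !(nb[[1]] & nb[[3]] & nb[[7]])   # P2*P4*P8 == 0
        c2 <- !(nb[[1]] & nb[[5]] & nb[[7]])   # P2*P6*P8 == 0
      }
      del <- img & bsum >= 2 & bsum <= 6 & a == 1 & c1 & c2
      if (any(del)) {
        img <- img & !del
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img <- .sparsify(img)
  vessel_mask(img, mask$spacing, mask$origin)
}

# count of 8-neighbors for every foreground pixel (matrix over the grid)
.neighbor_counts <- function(img) {
  Reduce(`+`, lapply(.zs_offsets, function(o) .shift(img, o[1], o[2])))
}

# physical step length between two adjacent pixels
.px_step <- function(p, q, sp) {
  sqrt(((p[1] - q[1]) * sp[1])^2 + ((p[2] - q[2]) * sp[2])^2)
}

# walk from an endpoint until hitting a junction, an endpoint, or running out
.trace_branch <- function(img, nbc, start) {
  path <- list(start)
  prev <- NULL
  cur <- start
  repeat {
    nbrs <- list()
    for (o in .zs_offsets) {
      r <- cur[1] + o[1]; c <- cur[2] + o[2]
      if (r >= 1 && r <= nrow(img) && c >= 1 && c <= ncol(img) && img[r, c])
        nbrs[[length(nbrs) + 1L]] <- c(r, c)
    }
    if (!is.null(prev))
      nbrs <- Filter(function(p) !(p[1] == prev[1] && p[2] == prev[2]), nbrs)
    if (length(nbrs) != 1L) break                 # junction or dead end
    nxt <- nbrs[[1]]
    if (nbc[nxt[1], nxt[2]] >= 3L) {              # reached a junction pixel
      path[[length(path) + 1L]] <- nxt
      break
    }
    path[[length(path) + 1L]] <- nxt
    prev <- cur
    cur <- nxt
    if (nbc[cur[1], cur[2]] == 1L) break          # other endpoint
  }
  do.call(rbind, path)
}

#' Prune short terminal spurs from a skeleton
#'
#' Iteratively removes terminal branches whose physical length is below
#' `min_branch`, until stable. Branch length is measured from the
#' endpoint up to (not including) the junction pixel. A skeleton without
#' junctions (a simple path) is never pruned, so the longest path always
#' survives.
#'
#' @param skeleton A skeletonized [vessel_mask].
#' @param min_branch Minimum terminal-branch length to keep, mm
#'   (default 2 mm, below the shortest plausible LSA but above tracing
#'   jitter).
#' @return A pruned [vessel_mask].
#' @export
prune_spurs <- function(skeleton, min_branch = 2) {
  stopifnot(inherits(skeleton, "vessel_mask"))
  img <- skeleton$raster
  sp <- skeleton$spacing
  repeat {
    nbc <- .neighbor_counts(img)
    if (!any(img & nbc >= 3L)) break              # no junctions: simple path
    ends <- which(img & nbc == 1L, arr.ind = TRUE)
    if (nrow(ends) == 0L) break
    removed <- FALSE
    for (i in seq_len(nrow(ends))) {
      ep <- ends[i, ]
      if (!img[ep[1], ep[2]]) next                # already removed this pass
      br <- .trace_branch(img, nbc, c(ep[1], ep[2]))
      last <- br[nrow(br), ]
      ends_at_junction <- nbc[last[1], last[2]] >= 3L
      if (!ends_at_junction) next                 # whole-path branch: keep
      seg <- br[-nrow(br), , drop = FALSE]        # exclude the junction px
      len <- 0
      if (nrow(br) >= 2L)
        for (j in seq_len(nrow(br) - 1L))
          len <- len + .px_step(br[j, ], br[j + 1L, ], sp)
      if (len < min_branch) {
        img[seg] <- FALSE
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  nbc <- .neighbor_counts(img)
  pruned_something <- sum(img) < sum(skeleton$raster)
  if (sum(img) < 2L ||
      (pruned_something && !any(img & nbc == 1L)))
    stop("pruning removed the entire skeleton path; min_branch too large")
  vessel_mask(img, sp, skeleton$origin)
}

# igraph over skeleton pixels, 8-adjacency, edges weighted by physical length
.skeleton_graph <- function(img, sp) {
  px <- which(img, arr.ind = TRUE)
  n <- nrow(px)
  id <- matrix(0L, nrow(img), ncol(img))
  id[px] <- seq_len(n)
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (o in .zs_offsets[c(3, 4, 5, 6)]) {  # E, SE, S, SW: each pair once
    r2 <- px[, 1] + o[1]; c2 <- px[, 2] + o[2]
    ok <- r2 >= 1 & r2 <= nrow(img) & c2 >= 1 & c2 <= ncol(img)
    ok[ok] <- img[cbind(r2[ok], c2[ok])]
    if (!any(ok)) next
    from <- c(from, id[px[ok, , drop = FALSE]])
    to <- c(to, id[cbind(r2[ok], c2[ok])])
    w <- c(w, rep(sqrt((o[1] * sp[1])^2 + (o[2] * sp[2])^2), sum(ok)))
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(from))
    g <- igraph::add_edges(g, rbind(from, to), weight = w)
  list(graph = g, px = px)
}

#' Extract the ordered centerline from a pruned skeleton
#'
#' Finds the pair of skeleton endpoints realizing the longest geodesic
#' (along-skeleton) distance and returns the ordered pixel path between
#' them, converted to physical mm coordinates via pixel centers and the
#' anisotropic spacing. Ties are broken by preferring the path whose
#' start pixel is lexicographically smallest in (row, col).
#'
#' @param skeleton A pruned skeletonized [vessel_mask] with >= 2 pixels.
#' @return A [centerline].
#' @export
extract_path <- function(skeleton) {
  stopifnot(inherits(skeleton, "vessel_mask"))
  img <- skeleton$raster
  sp <- skeleton$spacing
  if (sum(img) < 2L) stop("skeleton has fewer than 2 pixels")
  sg <- .skeleton_graph(img, sp)
  comp <- igraph::components(sg$graph)
  if (comp$no > 1L)
    stop(sprintf("skeleton is disconnected: %d components", comp$no))
  nbc <- .neighbor_counts(img)
  ends <- which(img & nbc == 1L, arr.ind = TRUE)
  if (nrow(ends) < 2L)
    stop("skeleton has fewer than 2 endpoints (closed loop?)")
  key <- paste(sg$px[, 1], sg$px[, 2])
  end_ids <- match(paste(ends[, 1], ends[, 2]), key)
  D <- igraph::distances(sg$graph, v = end_ids, to = end_ids)
  # scan endpoint pairs in lexicographic (row, col) order so ties keep
  # the smallest start pixel
  ord <- order(ends[, 1], ends[, 2])
  best <- NULL; bestd <- -Inf
  for (a in ord) for (b in ord) {
    if (a == b) next
    d <- D[a, b]
    if (is.finite(d) && d > bestd + 1e-9) { bestd <- d; best <- c(a, b) }
  }
  if (is.null(best)) stop("no path between skeleton endpoints")
  vp <- igraph::shortest_paths(sg$graph, from = end_ids[best[1]],
                               to = end_ids[best[2]])$vpath[[1]]
  px <- sg$px[as.integer(vp), , drop = FALSE]
  pts <- cbind(x = skeleton$origin[1] + (px[, 2] - 1) * sp[2],
               y = skeleton$origin[2] + (px[, 1] - 1) * sp[1])
  centerline(pts, spacing = sp)
}

#' Smooth a centerline with a moving average
#'
#' Pixel-path centerlines zig-zag at the raster scale, which biases the
#' measured arc length upward. A short moving average (the window
#' shrinks symmetrically near the ends; the endpoints themselves are
#' kept exactly) removes the staircase jitter without displacing the
#' curve.
#'
#' @param c A [centerline].
#' @param window Half-width of the averaging window in points (0 = no
#'   smoothing).
#' @return A smoothed [centerline].
#' @export
smooth_centerline <- function(c, window = 1L) {
  pts <- as_centerline_matrix(c)
  if (window < 1L) return(centerline(pts, attr(c, "spacing")))
  n <- nrow(pts)
  out <- pts
  for (i in seq_len(n)) {
    w <- min(window, i - 1L, n - i)
    if (w > 0L)
      out[i, ] <- colMeans(pts[(i - w):(i + w), , drop = FALSE])
  }
  keep <- c(TRUE, rowSums(abs(diff(out))) > 0)
  centerline(out[keep, , drop = FALSE], attr(c, "spacing"))
}

#' Resample a centerline uniformly in arc length
#'
#' Linear interpolation along the cumulative chord-length
#' parameterization, returning points spaced approximately `step` mm
#' apart (at least 20 points). Fixing the physical sampling step makes
#' angle-based metrics comparable across rasters of different pixel
#' sizes.
#'
#' @param c A [centerline].
#' @param step Target arc-length spacing, mm.
#' @return A resampled [centerline].
#' @export
resample_centerline <- function(c, step = 0.4) {
  pts <- as_centerline_matrix(c)
  d <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  n <- max(20L, round(d[length(d)] / step) + 1L)
  s <- seq(0, d[length(d)], length.out = n)
  out <- cbind(stats::approx(d, pts[, 1], s, ties = "ordered")$y,
               stats::approx(d, pts[, 2], s, ties = "ordered")$y)
  centerline(out, attr(c, "spacing"))
}

#' Mask-to-centerline convenience chain
#'
#' Runs skeletonization, spur pruning, longest-path extraction,
#' staircase smoothing and arc-length resampling in one call — the
#' standard route from a delineation mask to the single centerline
#' consumed by the tortuosity metrics. Smoothing and resampling are
#' specified in mm so results are comparable across pixel sizes.
#'
#' @param mask A [vessel_mask].
#' @param min_branch Spur-pruning threshold in mm, see [prune_spurs()].
#' @param smooth_mm Physical half-width of the staircase-smoothing
#'   moving average (mm); 0 disables smoothing.
#' @param resample_mm Arc-length step of the final resampling (mm); 0
#'   keeps the (smoothed) pixel path.
#' @return A [centerline].
#' @export
mask_to_centerline <- function(mask, min_branch = 2, smooth_mm = 0.4,
                               resample_mm = 0.4) {
  cl <- extract_path(prune_spurs(skeletonize(mask), min_branch = min_branch))
  if (smooth_mm > 0) {
    w <- max(1L, round(smooth_mm / min(mask$spacing)))
    cl <- smooth_centerline(cl, window = w)
  }
  if (resample_mm > 0) cl <- resample_centerline(cl, step = resample_mm)
  cl
}
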