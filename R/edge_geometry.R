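#' Digitized tip cross-section contour
#'
#' An ordered planar polyline tracing a milled blade-tip cross-section:
#' down one flank, around the tip, up the other flank. Coordinates are in
#' pixels; `scale` converts to metres.
#'
#' @param points two-column matrix or data frame of `(x, y)` pixel
#'   coordinates, ordered along the outline; at least 20 points.
#' @param scale metres per pixel; `> 0`.
#' @param specimen_id label.
#' @param cut_location normalized height of the milled cut on the tooth
#'   (0 = base, 1 = tip); metadata only.
#' @return An object of class `cross_section_contour`.
#' @export
cross_section_contour <- function(points, scale, specimen_id = "",
                                  cut_location = NA_real_) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("'points' must have two columns",
                               call. = FALSE)
  storage.mode(points) <- "double"
  if (nrow(points) < 20L) {
    stop("a contour needs at least 20 points", call. = FALSE)
  }
  if (any(!is.finite(points))) stop("contour points must be finite",
                                    call. = FALSE)
  seg <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                       points[-nrow(points), , drop = FALSE])^2))
  if (any(seg == 0)) {
    stop("contour contains duplicated consecutive points", call. = FALSE)
  }
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) ||
      scale <= 0) {
    stop("'scale' must be a single positive number (m per px)",
         call. = FALSE)
  }
  colnames(points) <- c("x", "y")
  structure(list(points = points, scale = scale,
                 specimen_id = specimen_id, cut_location = cut_location),
            class = "cross_section_contour")
}

#' Read a contour from a CSV of pixel coordinates
#'
#' @param path CSV with columns `x_px,y_px`.
#' @param scale metres per pixel.
#' @param ... passed to [cross_section_contour()].
#' @return A [cross_section_contour()].
#' @export
read_contour <- function(path, scale, ...) {
  df <- utils::read.csv(path)
  if (!all(c("x_px", "y_px") %in% names(df))) {
    stop(sprintf("'%s' must have columns x_px,y_px", path), call. = FALSE)
  }
  cross_section_contour(cbind(df$x_px, df$y_px), scale = scale, ...)
}

# Resample an ordered polyline at n points uniformly spaced in arc length.
.resample_polyline <- function(P, n) {
  seg <- sqrt(rowSums((P[-1L, , drop = FALSE] -
                       P[-nrow(P), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  si <- seq(0, s[length(s)], length.out = n)
  cbind(stats::approx(s, P[, 1L], xout = si)$y,
        stats::approx(s, P[, 2L], xout = si)$y)
}

# Moving-average smoothing of coordinates; ends keep the raw values.
.smooth_coords <- function(P, window = 5L) {
  if (window < 3L) return(P)
  w <- rep(1 / window, window)
  S <- apply(P, 2L, function(v) as.numeric(stats::filter(v, w, sides = 2)))
  S[is.na(S[, 1L]), ] <- P[is.na(S[, 1L]), ]
  S
}

# Absolute turning angle (degrees) at every interior vertex.
.turning_angles <- function(P) {
  n <- nrow(P)
  d <- P[-1L, , drop = FALSE] - P[-n, , drop = FALSE]
  ang <- atan2(d[, 2L], d[, 1L])
  turn <- abs(diff(ang))                      # at vertices 2..n-1
  pmin(turn, 2 * pi - turn) * 180 / pi
}

# Total-least-squares line through a point set: centroid + principal axis.
.tls_line <- function(P) {
  ctr <- colMeans(P)
  Q <- sweep(P, 2L, ctr)
  ev <- eigen(crossprod(Q) / nrow(Q), symmetric = TRUE)
  dir <- ev$vectors[, 1L]
  residual <- sqrt(max(ev$values[2L], 0))
  list(point = ctr, direction = dir / sqrt(sum(dir^2)),
       residual = residual)
}

#' Fit the two flank lines of a tip cross-section
#'
#' The contour is resampled at uniform arc-length spacing (a fixed number
#' of points over the whole outline, making the straightness criterion
#' independent of digitization density and pixel scale), and the two
#' longest low-curvature runs - turning angle below `straightness_deg` per
#' resampled step, after light coordinate smoothing - are fitted by total
#' least squares. The apex is the intersection of the two lines;
#' directions are oriented from the apex toward the open end of the wedge,
#' and the interior bisector is their normalized sum.
#'
#' @param contour a [cross_section_contour()].
#' @param straightness_deg turning-angle threshold in degrees per
#'   resampled step below which the outline counts as straight; default 2.
#' @param n_resample number of uniformly spaced points the outline is
#'   resampled to; default 150.
#' @param window moving-average window (points) applied to the resampled
#'   coordinates before the curvature estimate; default 5.
#' @param min_run minimum resampled run length to count as a flank;
#'   default 10.
#' @param trim points dropped from each end of a run before line fitting
#'   (guards against bleed-in from the tip arc); default 2.
#' @return A list of class `flank_fit`: `lines` (two `point`/`direction`
#'   lists), `apex`, `wedge_angle` (degrees), `bisector` (unit vector,
#'   interior), `fit_residual` (m), `runs` (resampled index ranges).
#' @export
fit_flank_lines <- function(contour, straightness_deg = 2,
                            n_resample = 150L, window = 5L,
                            min_run = 10L, trim = 2L) {
  stopifnot(inherits(contour, "cross_section_contour"))
  Pr <- .resample_polyline(contour$points, n_resample)
  turn <- .turning_angles(.smooth_coords(Pr, window))
  straight <- c(FALSE, turn < straightness_deg, FALSE)  # per vertex
  r <- rle(straight)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= min_run)
  if (length(keep) < 2L) {
    stop("no flanks: fewer than two straight runs detected", call. = FALSE)
  }
  keep <- keep[order(r$lengths[keep], decreasing = TRUE)][1:2]
  keep <- keep[order(starts[keep])]           # contour order
  runs <- lapply(keep, function(i) {
    idx <- seq(starts[i], ends[i])
    if (length(idx) > 2L * trim + 4L) {
      idx <- idx[seq(trim + 1L, length(idx) - trim)]
    }
    idx
  })
  fits <- lapply(runs, function(idx) .tls_line(Pr[idx, , drop = FALSE]))

  d1 <- fits[[1L]]$direction
  d2 <- fits[[2L]]$direction
  cross <- abs(d1[1L] * d2[2L] - d1[2L] * d2[1L])
  if (asin(min(cross, 1)) * 180 / pi < 1) {
    stop("degenerate geometry: flank lines are nearly parallel",
         call. = FALSE)
  }
  # apex: solve p1 + s*d1 = p2 + t*d2
  A <- cbind(d1, -d2)
  st <- solve(A, fits[[2L]]$point - fits[[1L]]$point)
  apex <- fits[[1L]]$point + st[1L] * d1

  orient <- function(fit) {
    v <- fit$point - apex
    if (sum(v * fit$direction) < 0) fit$direction <- -fit$direction
    fit
  }
  fits <- lapply(fits, orient)
  d1 <- fits[[1L]]$direction
  d2 <- fits[[2L]]$direction
  wedge <- acos(pmin(pmax(sum(d1 * d2), -1), 1)) * 180 / pi
  bis <- d1 + d2
  bis <- bis / sqrt(sum(bis^2))

  structure(
    list(lines = fits, apex = apex, wedge_angle = wedge, bisector = bis,
         fit_residual = max(vapply(fits, `[[`, 0, "residual")) *
           contour$scale,
         runs = runs),
    class = "flank_fit"
  )
}

#' Wedge angle of a tip cross-section
#'
#' Interior angle between the two fitted flank lines, in degrees.
#'
#' @inheritParams fit_flank_lines
#' @param ... passed to [fit_flank_lines()].
#' @return Angle in degrees, in (0, 180).
#' @export
wedge_angle <- function(contour, ...) {
  fit_flank_lines(contour, ...)$wedge_angle
}

# Distance from a point to each edge of a polyline/polygon (vectorized).
.point_segment_distances <- function(pt, P, closed = TRUE) {
  A <- P
  B <- if (closed) P[c(2:nrow(P), 1L), , drop = FALSE] else
    P[-1L, , drop = FALSE]
  if (!closed) A <- P[-nrow(P), , drop = FALSE]
  ab <- B - A
  ap <- cbind(pt[1L] - A[, 1L], pt[2L] - A[, 2L])
  len2 <- rowSums(ab^2)
  t <- pmin(pmax(rowSums(ap * ab) / len2, 0), 1)
  dx <- ap[, 1L] - t * ab[, 1L]
  dy <- ap[, 2L] - t * ab[, 2L]
  sqrt(dx^2 + dy^2)
}

# Ray-casting point-in-polygon test.
.point_in_polygon <- function(pt, P) {
  x <- P[, 1L]; y <- P[, 2L]
  xj <- c(x[-1L], x[1L]); yj <- c(y[-1L], y[1L])
  crosses <- ((y > pt[2L]) != (yj > pt[2L])) &
    (pt[1L] < (xj - x) * (pt[2L] - y) / (yj - y) + x)
  sum(crosses) %% 2L == 1L
}

# Is the bitangent circle of radius r (px) fully inside the cross-section?
# `poly` is the contour closed by its bounding cut edge; slack_px absorbs
# the sagitta of chord-discretized arcs (well below the bisection tol).
.circle_contained <- function(r, apex, bisector, half_angle, poly,
                              slack_px = 0.01) {
  ctr <- apex + bisector * (r / sin(half_angle))
  if (!.point_in_polygon(ctr, poly)) return(FALSE)
  min(.point_segment_distances(ctr, poly, closed = TRUE)) >= r - slack_px
}

#' Cutting-edge radius from a tip cross-section
#'
#' The edge radius is defined as the radius of the smallest circle that is
#' tangent to both flank lines (its centre therefore lies on the interior
#' bisector) and still fits entirely within the material cross-section.
#' Containment switches on monotonically with radius for wedge-plus-arc
#' tips, so the smallest contained radius is found by bisection after a
#' coarse geometric scan brackets it.
#'
#' @inheritParams fit_flank_lines
#' @param tol_px bisection tolerance on the radius, in pixels; default 0.05.
#' @param flanks optional precomputed [fit_flank_lines()] result.
#' @param slack_px containment slack in pixels, absorbing digitization
#'   jitter of the outline; default `max(0.01, 2 x flank-fit residual)`.
#' @param containment_window moving-average window (points) applied to
#'   the outline before the containment test; default 7.
#' @param ... passed to [fit_flank_lines()].
#' @return Edge radius in metres.
#' @export
edge_radius <- function(contour, tol_px = 0.05, flanks = NULL,
                        slack_px = NULL, containment_window = 7L, ...) {
  stopifnot(inherits(contour, "cross_section_contour"))
  if (is.null(flanks)) flanks <- fit_flank_lines(contour, ...)
  P <- contour$points
  half_angle <- flanks$wedge_angle / 2 * pi / 180
  # light smoothing keeps point jitter from gating containment; on a
  # noiseless outline it moves the tip arc inward by < 0.01 px
  poly <- .smooth_coords(P, containment_window)
  if (is.null(slack_px)) {
    slack_px <- max(0.01, 2 * flanks$fit_residual / contour$scale)
  }
  r_max <- max(.point_segment_distances(flanks$apex, P, closed = TRUE),
               sqrt(colSums((t(P) - flanks$apex)^2)))

  contained <- function(r) {
    .circle_contained(r, flanks$apex, flanks$bisector, half_angle, poly,
                      slack_px = slack_px)
  }
  # geometric scan for a contained radius to bracket the transition
  grid <- exp(seq(log(max(tol_px, 1e-3)), log(r_max), length.out = 60L))
  hi <- NA_real_
  lo <- 0
  for (r in grid) {
    if (contained(r)) { hi <- r; break }
    lo <- r
  }
  if (is.na(hi)) {
    stop("edge radius estimation failed: no tangent circle up to the ",
         "contour extent is contained", call. = FALSE)
  }
  while (hi - lo > tol_px) {
    mid <- (hi + lo) / 2
    if (contained(mid)) hi <- mid else lo <- mid
  }
  hi * contour$scale
}

#' Full edge-geometry estimate for one contour
#'
#' @inheritParams edge_radius
#' @return A list of class `edge_geometry_estimate`: `edge_radius` (m),
#'   `wedge_angle` (degrees), `flank_lines`, `fit_residual` (m),
#'   `specimen_id`.
#' @export
estimate_edge_geometry <- function(contour, tol_px = 0.05, ...) {
  flanks <- fit_flank_lines(contour, ...)
  structure(
    list(edge_radius = edge_radius(contour, tol_px = tol_px,
                                   flanks = flanks),
         wedge_angle = flanks$wedge_angle,
         flank_lines = flanks$lines,
         fit_residual = flanks$fit_residual,
         specimen_id = contour$specimen_id),
    class = "edge_geometry_estimate"
  )
}

#' @export
print.edge_geometry_estimate <- function(x, ...) {
  cat(sprintf("Edge geometry '%s': R = %.3g nm, wedge angle = %.1f deg\n",
              x$specimen_id, x$edge_radius * 1e9, x$wedge_angle))
  invisible(x)
}

#' Brute-force reference for the edge radius
#'
#' Scans radii on a uniform pixel grid and returns the smallest contained
#' bitangent circle. Slow; intended as an independent check of the
#' bisection in [edge_radius()].
#'
#' @inheritParams edge_radius
#' @param step_px grid step in pixels; default 0.1.
#' @return Edge radius in metres.
#' @export
edge_radius_grid_search <- function(contour, step_px = 0.1,
                                    slack_px = NULL,
                                    containment_window = 7L, ...) {
  stopifnot(inherits(contour, "cross_section_contour"))
  flanks <- fit_flank_lines(contour, ...)
  P <- .smooth_coords(contour$points, containment_window)
  half_angle <- flanks$wedge_angle / 2 * pi / 180
  if (is.null(slack_px)) {
    slack_px <- max(0.01, 2 * flanks$fit_residual / contour$scale)
  }
  r_max <- max(sqrt(colSums((t(P) - flanks$apex)^2)))
  for (r in seq(step_px, r_max, by = step_px)) {
    if (.circle_contained(r, flanks$apex, flanks$bisector, half_angle, P,
                          slack_px = slack_px)) {
      return(r * contour$scale)
    }
  }
  stop("edge radius estimation failed: no contained circle on the grid",
       call. = FALSE)
}
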