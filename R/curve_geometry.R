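#' Smooth a polyline by a moving average
#'
#' Each point is replaced by the arithmetic mean of the points in the window
#' `[i - h_i, i + h_i]`, where the effective half width
#' `h_i = min(half_width, i - 1, n - i)` shrinks symmetrically at the two
#' ends. Symmetric shrinking keeps the endpoints fixed, preserves the point
#' count, and makes the filter an exact identity on collinear equally
#' spaced input. With the default `half_width = 2` this is the five-point
#' moving average of two points before and after each point and the point
#' itself.
#'
#' @param points n x 3 matrix of ordered 3-D points (mm).
#' @param half_width number of points included on each side of the centre.
#' @return n x 3 matrix of smoothed points.
#' @export
smooth_polyline <- function(points, half_width = 2) {
  if (is.null(dim(points))) {
    if (length(points) == 0L) stop("empty polyline")
    points <- matrix(as.numeric(points), 1, 3)
  }
  p <- as.matrix(points)
  if (nrow(p) == 0L) stop("empty polyline")
  n <- nrow(p)
  if (half_width < 0) stop("half_width must be >= 0")
  if (n == 1L || half_width == 0) return(p)
  cs <- apply(p, 2, cumsum)
  cs <- rbind(0, matrix(cs, ncol = 3))
  h <- pmin(half_width, seq_len(n) - 1L, n - seq_len(n))
  lo <- seq_len(n) - h
  hi <- seq_len(n) + h
  out <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1L)
  dimnames(out) <- NULL
  out
}

# cumulative arc length of a polyline, from its first point
polyline_arclen <- function(p) {
  if (nrow(p) < 2L) return(0)
  c(0, cumsum(sqrt(rowSums((p[-1L, , drop = FALSE] -
                            p[-nrow(p), , drop = FALSE])^2))))
}

#' Resample a polyline at equal arc-length steps
#'
#' Points are placed on the input polyline (linear interpolation between
#' vertices) at arc lengths 0, `step`, 2 `step`, .... If the total length is
#' not an exact multiple of `step`, the original final endpoint is appended,
#' so the last inter-point spacing may be shorter than `step`. The default
#' 0.5 mm step resolves shape changes at the pixel-spacing level of CT.
#'
#' @param points n x 3 matrix of ordered 3-D points (mm), n >= 2.
#' @param step arc-length spacing in mm (> 0).
#' @return m x 3 matrix of equidistant points on the polyline.
#' @export
resample_polyline <- function(points, step = 0.5) {
  p <- as.matrix(points)
  if (nrow(p) < 2L) stop("need at least 2 points to resample")
  if (step <= 0) stop("step must be > 0")
  # drop exactly repeated consecutive vertices
  keep <- c(TRUE, rowSums((p[-1L, , drop = FALSE] -
                           p[-nrow(p), , drop = FALSE])^2) > 0)
  p <- p[keep, , drop = FALSE]
  if (nrow(p) < 2L) stop("polyline has zero length")
  s <- polyline_arclen(p)
  total <- s[length(s)]
  targets <- seq(0, total, by = step)
  if (total - targets[length(targets)] > 1e-9) targets <- c(targets, total)
  out <- vapply(1:3, function(k) approx(s, p[, k], xout = targets)$y,
                numeric(length(targets)))
  matrix(out, ncol = 3)
}

#' Tangent vectors with a fixed lookahead distance
#'
#' For an equidistantly resampled polyline, the tangent at each point is the
#' unit chord from the point to the point `lookahead` mm further along the
#' curve (the lookahead suppresses the fine vibration that local segmentation
#' defects leave in a 0.5-mm resampled centerline). Points whose lookahead
#' overruns the end use the chord to the final point, and the final point
#' copies the previous point's tangent.
#'
#' @param points m x 3 matrix of points equidistant at `step` (the final
#'   segment may be shorter).
#' @param step arc-length spacing of `points` in mm.
#' @param lookahead chord length in mm (default 10; must be >= `step`).
#' @return m x 3 matrix of unit tangent vectors.
#' @export
compute_tangents <- function(points, step = 0.5, lookahead = 10) {
  p <- as.matrix(points)
  n <- nrow(p)
  if (n < 2L) stop("need at least 2 points for tangents")
  if (lookahead < step) stop("lookahead must be at least one step")
  k <- max(1L, round(lookahead / step))
  tg <- matrix(0, n, 3)
  for (i in seq_len(n - 1L)) {
    j <- if (i + k <= n) i + k else n
    v <- p[j, ] - p[i, ]
    nv <- sqrt(sum(v^2))
    if (nv == 0) {  # degenerate chord; fall back to the next point
      v <- p[min(i + 1L, n), ] - p[i, ]
      nv <- sqrt(sum(v^2))
    }
    tg[i, ] <- v / nv
  }
  tg[n, ] <- tg[n - 1L, ]
  tg
}

#' Orthonormal frames along a curve (rotation-minimizing)
#'
#' Builds, at every point, an orthonormal frame (tangent, normal, binormal)
#' with the normal and binormal orthogonal to the tangent. The first normal
#' is the projection (onto the plane orthogonal to the first tangent) of the
#' world axis least aligned with that tangent, optionally rotated in-plane
#' by `roll` radians; subsequent normals are propagated with the
#' double-reflection rotation-minimizing scheme, which avoids arbitrary
#' frame flips along the curve. Cross-sectional areas measured downstream
#' are invariant to the in-plane orientation of (normal, binormal).
#'
#' @param points m x 3 matrix of curve points (mm).
#' @param tangents m x 3 matrix of unit tangents, e.g. [compute_tangents()].
#' @param ref_axis optional length-3 reference direction for the first
#'   normal; default picks the world axis least aligned with the first
#'   tangent.
#' @param roll in-plane rotation (radians) applied to the initial
#'   (normal, binormal) pair.
#' @return an object of class `frame_set`: a list with matrices `points`,
#'   `tangents`, `normals`, `binormals` (m x 3) and the arc-length vector
#'   `arc_s` (mm, from the first point).
#' @export
build_frames <- function(points, tangents, ref_axis = NULL, roll = 0) {
  p <- as.matrix(points)
  tg <- as.matrix(tangents)
  n <- nrow(p)
  if (nrow(tg) != n) stop("points and tangents must have equal length")
  nrm <- sqrt(rowSums(tg^2))
  if (any(nrm < 1e-12)) stop("zero tangent vector")
  tg <- tg / nrm

  if (is.null(ref_axis)) {
    ref_axis <- diag(3)[, which.min(abs(tg[1, ]))]
  }
  e <- ref_axis / sqrt(sum(ref_axis^2))
  n0 <- e - sum(e * tg[1, ]) * tg[1, ]
  if (sum(n0^2) < 1e-12) stop("reference axis is parallel to the first tangent")
  n0 <- n0 / sqrt(sum(n0^2))
  if (roll != 0) {
    b0 <- cross3(tg[1, ], n0)
    n0 <- cos(roll) * n0 + sin(roll) * b0
  }

  normals <- matrix(0, n, 3)
  normals[1, ] <- n0
  for (i in seq_len(n - 1L)) {
    v1 <- p[i + 1L, ] - p[i, ]
    c1 <- sum(v1^2)
    if (c1 < 1e-18) {
      nL <- normals[i, ]
      tL <- tg[i, ]
    } else {
      nL <- normals[i, ] - (2 / c1) * sum(v1 * normals[i, ]) * v1
      tL <- tg[i, ] - (2 / c1) * sum(v1 * tg[i, ]) * v1
    }
    v2 <- tg[i + 1L, ] - tL
    c2 <- sum(v2^2)
    ni <- if (c2 < 1e-18) nL else nL - (2 / c2) * sum(v2 * nL) * v2
    # re-orthogonalize against the tangent to stop drift
    ni <- ni - sum(ni * tg[i + 1L, ]) * tg[i + 1L, ]
    normals[i + 1L, ] <- ni / sqrt(sum(ni^2))
  }
  binormals <- t(vapply(seq_len(n), function(i) cross3(tg[i, ], normals[i, ]),
                        numeric(3)))
  structure(list(points = p, tangents = tg, normals = normals,
                 binormals = binormals, arc_s = polyline_arclen(p)),
            class = "frame_set")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @export
print.frame_set <- function(x, ...) {
  cat(sprintf("<frame_set> %d frames, arc length %.2f mm\n",
              nrow(x$points), max(x$arc_s)))
  invisible(x)
}

#' @export
as.data.frame.frame_set <- function(x, ...) {
  data.frame(arc_s = x$arc_s,
             x = x$points[, 1], y = x$points[, 2], z = x$points[, 3],
             tx = x$tangents[, 1], ty = x$tangents[, 2], tz = x$tangents[, 3],
             nx = x$normals[, 1], ny = x$normals[, 2], nz = x$normals[, 3],
             bx = x$binormals[, 1], by = x$binormals[, 2], bz = x$binormals[, 3])
}
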