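#' Interior (medialness) distance field of a mask
#'
#' Per-voxel Euclidean distance in mm (spacing-aware) to the nearest
#' background voxel centre; zero on background. Voxels beyond the volume
#' border count as background, so a mask touching the border still has a
#' finite interior distance. Large values mark the medial axis, which the
#' centerline routing cost rewards.
#'
#' @param mask a [voxel_mask()] with at least one foreground voxel.
#' @return numeric 3-D array of distances (mm), same shape as the mask.
#' @export
compute_interior_distance <- function(mask) {
  stopifnot(inherits(mask, "voxel_mask"))
  v <- mask$values
  if (sum(v) == 0L) stop("empty mask: no foreground voxels")
  d <- dim(v)
  pad <- array(0L, d + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- v
  sq <- .edt3d(as.integer(pad), dim(pad), mask$geometry$spacing)
  sq <- array(sq, dim = d + 2L)
  sqrt(sq[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)])
}

# linear (0-based) <-> triple (0-based) voxel index conversion
lin_to_ijk <- function(lin, dims) {
  cbind(lin %% dims[1],
        (lin %/% dims[1]) %% dims[2],
        lin %/% (as.numeric(dims[1]) * dims[2]))
}
ijk_to_lin <- function(ijk, dims) {
  if (is.null(dim(ijk))) ijk <- matrix(ijk, 1, 3)
  ijk[, 1] + dims[1] * (ijk[, 2] + as.numeric(dims[2]) * ijk[, 3])
}

# largest 26-connected foreground component (ties: first label in scan
# order); warns when satellites are discarded
largest_component <- function(mask) {
  lab <- .components3d(as.integer(mask$values), dim(mask$values))
  if (max(lab) == 0L) stop("empty mask: no foreground voxels")
  if (max(lab) > 1L) {
    sizes <- tabulate(lab[lab > 0L])
    keep <- which.max(sizes)
    warning(sprintf(
      "mask '%s' has %d foreground components; using the largest (%d voxels)",
      mask$label, length(sizes), sizes[keep]))
    v <- array(as.integer(array(lab, dim(mask$values)) == keep),
               dim(mask$values))
    return(voxel_mask(v, geometry = mask$geometry, label = mask$label))
  }
  mask
}

#' Tail and head endpoint voxels of a mask
#'
#' Two-pass geodesic farthest-point search on the 26-connected foreground
#' graph (edge weights are physical step lengths): from an arbitrary
#' foreground voxel, find the geodesically farthest voxel A; from A, find
#' the farthest voxel B. The pair spans the geodesic diameter of the organ.
#' The endpoint with the larger patient-left world coordinate is returned
#' as the tail (anatomically, the pancreatic tail points toward the
#' patient's left). If the mask has several components, the largest is used
#' (with a warning).
#'
#' @param mask a [voxel_mask()].
#' @param distance unused placeholder for a precomputed distance field
#'   (endpoint search uses the uniform metric); kept for pipeline symmetry.
#' @return list with `tail` and `head`, each a 0-based voxel index triple.
#' @export
find_endpoints <- function(mask, distance = NULL) {
  mask <- largest_component(mask)
  v <- mask$values
  dims <- dim(v)
  fg <- which(v != 0L) - 1L  # 0-based linear
  if (length(fg) < 1L) stop("empty mask: no foreground voxels")
  if (length(fg) == 1L) {
    ijk <- drop(lin_to_ijk(fg, dims))
    return(list(tail = ijk, head = ijk))
  }
  zerow <- numeric(length(v))
  pass <- function(src) {
    r <- .dijkstra_grid(as.integer(v), dims, mask$geometry$spacing,
                        zerow, 0, as.integer(src), -1L, 26L)
    d <- r$dist
    d[!is.finite(d)] <- -1
    which.max(d) - 1L  # which.max takes the first (smallest index) on ties
  }
  a <- pass(fg[1])
  b <- pass(a)
  ija <- drop(lin_to_ijk(a, dims))
  ijb <- drop(lin_to_ijk(b, dims))
  wa <- voxel_to_world(ija, mask$geometry)
  wb <- voxel_to_world(ijb, mask$geometry)
  # internal world axis 1 points toward the patient's left
  if (wa[1] >= wb[1]) list(tail = ija, head = ijb) else list(tail = ijb, head = ija)
}

#' Minimum-cost voxel path (Dijkstra routing)
#'
#' Shortest path on the 26-connected foreground voxel graph. The cost of
#' stepping from u into v is `step_mm / (1 + distance[v])^p`: steps into
#' deep-interior voxels are cheap, so the optimal route is drawn onto the
#' medial ridge of the organ. Ties are broken on voxel scan order, making
#' the path bit-reproducible.
#'
#' @param mask a [voxel_mask()].
#' @param distance interior distance field from
#'   [compute_interior_distance()] (mm).
#' @param src,dst 0-based voxel index triples; must be foreground and
#'   connected.
#' @param exponent medialness exponent p (default 2).
#' @param connectivity 6, 18 or 26 (default 26).
#' @return list with `path` (m x 3 matrix of 0-based voxel triples,
#'   `src` first) and `cost` (total path cost).
#' @export
dijkstra_path <- function(mask, distance, src, dst, exponent = 2,
                          connectivity = 26) {
  stopifnot(inherits(mask, "voxel_mask"))
  v <- mask$values
  dims <- dim(v)
  src <- as.numeric(src); dst <- as.numeric(dst)
  if (any(src < 0) || any(src >= dims) || any(dst < 0) || any(dst >= dims))
    stop("source or destination voxel lies outside the volume")
  sl <- ijk_to_lin(src, dims)
  dl <- ijk_to_lin(dst, dims)
  if (v[sl + 1] == 0L)
    stop("source voxel is background")
  if (v[dl + 1] == 0L)
    stop("destination voxel is background")
  if (sl == dl)
    return(list(path = matrix(as.numeric(src), 1, 3), cost = 0))
  r <- .dijkstra_grid(as.integer(v), dims, mask$geometry$spacing,
                      as.numeric(distance), exponent,
                      as.integer(sl), as.integer(dl), as.integer(connectivity))
  if (!is.finite(r$dist[dl + 1]))
    stop("no path: source and destination are not connected in the mask")
  path <- dl
  cur <- dl
  while (cur != sl) {
    cur <- r$pred[cur + 1]
    path <- c(path, cur)
  }
  list(path = lin_to_ijk(rev(path), dims), cost = r$dist[dl + 1])
}

#' Estimate the tail-to-head centerline of a pancreas mask
#'
#' Composition of the centerline stages: interior distance field, two-pass
#' geodesic endpoint detection, and Dijkstra routing with the medialness
#' cost, with the resulting voxel path mapped to world coordinates. The
#' returned polyline is ordered from the pancreatic tail (patient-left end)
#' toward the head, and is raw: smoothing and equidistant resampling are
#' separate steps ([smooth_polyline()], [resample_polyline()]).
#'
#' @param mask a [voxel_mask()] of the pancreas.
#' @param exponent medialness exponent for [dijkstra_path()].
#' @param connectivity voxel-graph connectivity (default 26).
#' @return an object of class `centerline`: list with `points` (m x 3 world
#'   mm, row 1 = tail) and `geometry`.
#' @export
estimate_centerline <- function(mask, exponent = 2, connectivity = 26) {
  stopifnot(inherits(mask, "voxel_mask"))
  main <- largest_component(mask)
  dist <- compute_interior_distance(main)
  ep <- find_endpoints(main)
  if (all(ep$tail == ep$head)) {
    pts <- matrix(voxel_to_world(ep$tail, main$geometry), 1, 3)
  } else {
    pth <- dijkstra_path(main, dist, ep$tail, ep$head,
                         exponent = exponent, connectivity = connectivity)
    pts <- voxel_to_world(pth$path, main$geometry)
  }
  structure(list(points = pts, geometry = main$geometry),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  len <- if (nrow(x$points) > 1) max(polyline_arclen(x$points)) else 0
  cat(sprintf("<centerline> %d points, arc length %.2f mm (tail to head)\n",
              nrow(x$points), len))
  invisible(x)
}

#' @export
as.matrix.centerline <- function(x, ...) x$points

#' Write / read a centerline as delimited text
#'
#' One `x_mm  y_mm  z_mm` row per point, tail first; useful for inspection
#' and for injecting ground-truth curves in tests.
#'
#' @param centerline a `centerline` object or m x 3 matrix.
#' @param path output (input) file path.
#' @return `path` invisibly; `read_centerline` returns an m x 3 matrix.
#' @export
write_centerline <- function(centerline, path) {
  p <- if (inherits(centerline, "centerline")) centerline$points else as.matrix(centerline)
  colnames(p) <- c("x_mm", "y_mm", "z_mm")
  write.table(p, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_centerline
#' @export
read_centerline <- function(path) {
  as.matrix(read.delim(path))
}
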