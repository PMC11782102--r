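#' Volume geometry
#'
#' Physical geometry of a voxel grid: per-axis spacing in mm, the world
#' position of the centre of voxel (0,0,0), and a 3x3 orthonormal direction
#' matrix whose columns give the patient-space direction of each voxel axis.
#' World coordinates follow the package's internal convention in which the
#' first world axis points toward the patient's left (masks read from NIfTI,
#' whose world frame is RAS, are flipped on load; see [read_mask()]).
#'
#' @param spacing numeric length-3, voxel edge lengths in mm (all > 0).
#' @param origin numeric length-3, world coordinates (mm) of voxel (0,0,0).
#' @param direction 3x3 orthonormal matrix mapping voxel axes to world axes.
#' @return an object of class `volume_geometry`.
#' @export
volume_geometry <- function(spacing, origin = c(0, 0, 0), direction = diag(3)) {
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  direction <- matrix(as.numeric(direction), 3, 3)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite values (mm)")
  g <- crossprod(direction)
  if (max(abs(g - diag(3))) > 1e-6)
    stop("direction matrix must be orthonormal (unit, mutually orthogonal columns)")
  structure(list(spacing = spacing, origin = origin, direction = direction),
            class = "volume_geometry")
}

#' @export
print.volume_geometry <- function(x, ...) {
  cat("<volume_geometry>\n")
  cat("  spacing (mm):", paste(signif(x$spacing, 6), collapse = " x "), "\n")
  cat("  origin  (mm):", paste(signif(x$origin, 6), collapse = ", "), "\n")
  axis_aligned <- max(abs(abs(x$direction) - diag(3))) < 1e-9
  cat("  direction   :", if (axis_aligned) "axis-aligned" else "oblique", "\n")
  invisible(x)
}

#' Binary voxel mask
#'
#' A 3-D binary label volume with its physical geometry. Any nonzero input
#' value is binarized to 1.
#'
#' @param values 3-D array; nonzero entries become foreground (1).
#' @param geometry a [volume_geometry()], or `NULL` to build one from
#'   `spacing`/`origin`/`direction`.
#' @param spacing,origin,direction used when `geometry` is `NULL`.
#' @param label free-text label name, e.g. `"pancreas"` or `"mpd"`.
#' @return an object of class `voxel_mask` with elements `values`
#'   (integer 3-D array of 0/1), `geometry` and `label`.
#' @export
voxel_mask <- function(values, geometry = NULL, spacing = c(1, 1, 1),
                       origin = c(0, 0, 0), direction = diag(3),
                       label = "mask") {
  d <- dim(values)
  if (is.null(d) || length(d) != 3L || any(d < 1L))
    stop("values must be a 3-D array with positive dimensions")
  if (is.null(geometry))
    geometry <- volume_geometry(spacing, origin, direction)
  if (!inherits(geometry, "volume_geometry"))
    stop("geometry must be a volume_geometry")
  v <- array(as.integer(values != 0), dim = d)
  structure(list(values = v, geometry = geometry, label = as.character(label)[1]),
            class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_mask '%s'> %d x %d x %d voxels, %d foreground\n",
              x$label, d[1], d[2], d[3], sum(x$values)))
  print(x$geometry)
  invisible(x)
}

#' @export
dim.voxel_mask <- function(x) dim(x$values)

# shared geometry check used before any paired-mask computation
check_same_geometry <- function(a, b, tol = 1e-6) {
  if (!identical(dim(a$values), dim(b$values)))
    stop("masks have different voxel grid shapes (", paste(dim(a$values), collapse = "x"),
         " vs ", paste(dim(b$values), collapse = "x"), ")")
  ga <- a$geometry; gb <- b$geometry
  if (max(abs(ga$spacing - gb$spacing)) > tol ||
      max(abs(ga$origin - gb$origin)) > tol ||
      max(abs(ga$direction - gb$direction)) > tol)
    stop("masks have mismatched geometry (spacing/origin/direction differ beyond ",
         tol, " mm)")
  invisible(TRUE)
}

# RAS <-> internal (patient-left-first) world conversion: flip world axis 1
.flip_lr <- diag(c(-1, 1, 1))

#' Read a binary segmentation mask from NIfTI
#'
#' Reads a 3-D NIfTI volume, binarizes nonzero voxels to 1 and extracts the
#' physical geometry from the file's affine. The world frame is normalized
#' on load so the first world axis points toward the patient's left
#' (anatomically, the pancreatic tail lies toward the patient's left, which
#' downstream code uses to orient the centerline tail-to-head).
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param expected_label label name stored on the returned mask.
#' @return a [voxel_mask()].
#' @export
read_mask <- function(path, expected_label = "mask") {
  if (!file.exists(path))
    stop("mask file does not exist: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img2 <- array(as.array(img), dim = d[1:3])
    aff <- RNifti::xform(img)
    img <- img2
  } else if (length(d) != 3L) {
    stop("expected a 3-D volume, got ", length(d), " dimensions in ", path)
  } else {
    aff <- RNifti::xform(img)
  }
  aff <- unclass(aff)[1:4, 1:4]
  # NIfTI affines map 0-based voxel indices to RAS world; flip to internal
  aff[1, ] <- -aff[1, ]
  lin <- aff[1:3, 1:3]
  spacing <- sqrt(colSums(lin^2))
  if (any(spacing <= 0) || any(!is.finite(spacing)))
    stop("degenerate geometry (zero or non-finite spacing) in ", path)
  direction <- sweep(lin, 2, spacing, "/")
  g <- crossprod(direction)
  if (max(abs(g - diag(3))) > 1e-4)
    stop("non-orthogonal voxel axes in ", path, "; sheared affines are not supported")
  # re-orthonormalize exactly (polar decomposition via SVD)
  sv <- svd(direction)
  direction <- sv$u %*% t(sv$v)
  geom <- volume_geometry(spacing, aff[1:3, 4], direction)
  voxel_mask(as.array(img) != 0, geometry = geom, label = expected_label)
}

#' Write a binary mask to NIfTI
#'
#' Inverse of [read_mask()]: the written file re-reads with identical values
#' and geometry to within 1e-6 mm.
#'
#' @param mask a [voxel_mask()].
#' @param path output path (`.nii` or `.nii.gz`); parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "voxel_mask"))
  if (!dir.exists(dirname(path)))
    stop("directory does not exist: ", dirname(path))
  g <- mask$geometry
  lin <- sweep(g$direction, 2, g$spacing, "*")
  aff <- rbind(cbind(lin, g$origin), c(0, 0, 0, 1))
  aff[1, ] <- -aff[1, ]  # internal -> RAS
  img <- RNifti::asNifti(array(as.integer(mask$values), dim = dim(mask$values)),
                         datatype = "uint8")
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Convert voxel indices to world coordinates
#'
#' Voxel indices are 0-based and refer to voxel centres:
#' `world = origin + direction %*% (spacing * index)`.
#'
#' @param index numeric length-3 index, or an n x 3 matrix of indices
#'   (0-based; fractional and out-of-array indices are allowed).
#' @param geometry a [volume_geometry()].
#' @return a length-3 vector or n x 3 matrix of world points (mm).
#' @export
voxel_to_world <- function(index, geometry) {
  one <- is.null(dim(index))
  idx <- if (one) matrix(as.numeric(index), 1, 3) else as.matrix(index)
  w <- sweep(idx, 2, geometry$spacing, "*") %*% t(geometry$direction)
  w <- sweep(w, 2, geometry$origin, "+")
  if (one) drop(w) else w
}

#' Convert world coordinates to (fractional) voxel indices
#'
#' Exact inverse of [voxel_to_world()] for orthonormal direction matrices.
#'
#' @param world length-3 vector or n x 3 matrix of world points (mm).
#' @param geometry a [volume_geometry()].
#' @return 0-based fractional voxel indices, same shape as the input.
#' @export
world_to_voxel <- function(world, geometry) {
  one <- is.null(dim(world))
  w <- if (one) matrix(as.numeric(world), 1, 3) else as.matrix(world)
  w <- sweep(w, 2, geometry$origin, "-")
  idx <- w %*% geometry$direction  # == t(t(direction)) applied rowwise
  idx <- sweep(idx, 2, geometry$spacing, "/")
  if (one) drop(idx) else idx
}
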