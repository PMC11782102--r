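#' Extract a cross-section of a mask perpendicular to the centerline
#'
#' Samples the mask on a square planar grid spanned by the frame's normal
#' and binormal vectors, centred on the frame point: sample (u, v) lies at
#' world point `point + u * normal + v * binormal` for u, v in
#' `[-half_extent, half_extent]`. Sampling is nearest-neighbour; samples
#' falling outside the volume are background.
#'
#' @param mask a [voxel_mask()].
#' @param frame list with `point`, `normal`, `binormal` (a single frame of
#'   a [build_frames()] `frame_set` works: see [frame_at()]).
#' @param half_extent half the grid width in mm (default 40 mm covers any
#'   pancreas cross-section).
#' @param in_plane_step in-plane sample spacing in mm (default 0.5).
#' @return integer matrix of 0/1 samples, rows indexing u and columns v.
#' @export
extract_cross_section <- function(mask, frame, half_extent = 40,
                                  in_plane_step = 0.5) {
  stopifnot(half_extent > 0, in_plane_step > 0)
  g <- seq(-half_extent, half_extent, by = in_plane_step)
  uv <- cbind(rep(g, times = length(g)), rep(g, each = length(g)))
  sec <- sample_section(mask$values, dim(mask$values), mask$geometry,
                        frame$point, frame$normal, frame$binormal, uv)
  matrix(sec, length(g), length(g))
}

# inner sampling kernel shared with dp_profile (uv built once per profile)
sample_section <- function(values, dims, geometry, center, normal, binormal, uv) {
  w <- cbind(center[1] + uv[, 1] * normal[1] + uv[, 2] * binormal[1],
             center[2] + uv[, 1] * normal[2] + uv[, 2] * binormal[2],
             center[3] + uv[, 1] * normal[3] + uv[, 2] * binormal[3])
  idx <- round(world_to_voxel(w, geometry))
  ok <- idx[, 1] >= 0 & idx[, 1] < dims[1] &
        idx[, 2] >= 0 & idx[, 2] < dims[2] &
        idx[, 3] >= 0 & idx[, 3] < dims[3]
  out <- integer(nrow(uv))
  if (any(ok)) {
    lin <- idx[ok, 1] + dims[1] * (idx[ok, 2] + as.numeric(dims[2]) * idx[ok, 3])
    out[ok] <- values[lin + 1]
  }
  out
}

#' Single frame of a frame set
#'
#' @param frames a [build_frames()] `frame_set`.
#' @param i frame index.
#' @return list with `point`, `tangent`, `normal`, `binormal`, `arc_s`.
#' @export
frame_at <- function(frames, i) {
  list(point = frames$points[i, ], tangent = frames$tangents[i, ],
       normal = frames$normals[i, ], binormal = frames$binormals[i, ],
       arc_s = frames$arc_s[i])
}

# one-pixel 8-connected binary dilation (3x3 neighbourhood max)
dilate1 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  out <- matrix(FALSE, nr, nc)
  for (di in 0:2)
    for (dj in 0:2)
      out <- out | pad[di + seq_len(nr), dj + seq_len(nc)]
  out
}

#' Remove cross-section regions the centerline does not traverse
#'
#' Pancreas regions in a cross-section that the centerline does not pass
#' through (8-connected 2-D components containing no piercing pixel) are
#' removed, which suppresses other organs or satellite segmentation errors
#' captured by the sampling plane. If no component contains a piercing
#' pixel (e.g. the centerline point falls inside the duct lumen of a
#' disjoint-label pancreas mask), the nearest component within
#' `rescue_mm` of a piercing pixel is retained; failing that the section is
#' invalid. Duct components are kept only when, after a one-pixel dilation,
#' they touch the retained pancreas region (duct and parenchyma labels may
#' be disjoint).
#'
#' @param section_pancreas,section_duct same-shape 0/1 matrices from
#'   [extract_cross_section()].
#' @param piercing m x 2 matrix of 1-based grid coordinates of centerline
#'   points lying within half an along-axis step of the section plane.
#' @param pixel_mm in-plane pixel spacing in mm.
#' @param rescue_mm maximum pancreas-to-piercing distance for the fallback
#'   retention (default 2 mm).
#' @return list with filtered `pancreas` and `duct` matrices and a `valid`
#'   flag.
#' @export
filter_traversed_components <- function(section_pancreas, section_duct,
                                        piercing, pixel_mm = 0.5,
                                        rescue_mm = 2) {
  if (!identical(dim(section_pancreas), dim(section_duct)))
    stop("pancreas and duct sections have different shapes")
  empty <- matrix(0L, nrow(section_pancreas), ncol(section_pancreas))
  lab <- .components2d(matrix(as.integer(section_pancreas != 0),
                              nrow(section_pancreas)))
  piercing <- matrix(as.numeric(piercing), ncol = 2)
  inb <- piercing[, 1] >= 1 & piercing[, 1] <= nrow(lab) &
         piercing[, 2] >= 1 & piercing[, 2] <= ncol(lab)
  piercing <- piercing[inb, , drop = FALSE]
  if (max(lab) == 0L || nrow(piercing) == 0L)
    return(list(pancreas = empty, duct = empty, valid = FALSE))

  hit <- unique(lab[piercing])
  hit <- hit[hit > 0L]
  if (length(hit) == 0L) {
    # nearest-component fallback within rescue_mm
    fg <- which(lab > 0L, arr.ind = TRUE)
    d2 <- outer(fg[, 1], piercing[, 1], "-")^2 + outer(fg[, 2], piercing[, 2], "-")^2
    dmin <- pixel_mm * sqrt(apply(d2, 1, min))
    comp_d <- tapply(dmin, lab[fg], min)
    best <- which.min(comp_d)
    if (comp_d[best] <= rescue_mm)
      hit <- as.integer(names(comp_d)[best])
    else
      return(list(pancreas = empty, duct = empty, valid = FALSE))
  }
  retP <- matrix(lab %in% hit, nrow(lab))

  retD <- matrix(FALSE, nrow(lab), ncol(lab))
  if (any(section_duct != 0)) {
    labD <- .components2d(matrix(as.integer(section_duct != 0), nrow(section_duct)))
    dilP <- dilate1(retP)
    keepD <- unique(labD[labD > 0L & dilP])
    retD <- matrix(labD %in% keepD, nrow(labD))
  }
  list(pancreas = matrix(as.integer(retP), nrow(retP)),
       duct = matrix(as.integer(retD), nrow(retD)),
       valid = any(retP))
}

#' DP-ratio profile along a framed centerline
#'
#' For every centerline frame, extracts the pancreas and duct cross-sections
#' perpendicular to the curve, removes non-traversed regions, and computes
#' the duct-to-parenchyma area ratio: `duct_area / parenchyma_area`, where
#' the parenchyma is the retained pancreas area excluding retained duct
#' pixels (the duct is segmented inside the pancreas, so the parenchyma is
#' the non-duct tissue; set
#' `config$denominator_convention = "whole_pancreas"` to divide by the full
#' retained pancreas-plus-duct area instead). Sections with no retained
#' pancreas, or zero parenchyma area, are marked invalid and excluded from
#' the percentile summary. Sections where no duct is detected score 0.
#'
#' @param pancreas,duct [voxel_mask()]s on an identical grid.
#' @param frames a [build_frames()] `frame_set` along the (smoothed,
#'   resampled) centerline.
#' @param config a [dp_config()].
#' @return an object of class `dp_profile`: list with `samples`
#'   (`data.frame(arc_s, pancreas_area, duct_area, dp_ratio, valid,
#'   cx, cy, cz)`, one row per frame, areas in mm^2), `score` (the
#'   `config$percentile_level`-th percentile of valid ratios), `n_valid`,
#'   and the config used.
#' @export
dp_profile <- function(pancreas, duct, frames, config = dp_config()) {
  stopifnot(inherits(pancreas, "voxel_mask"), inherits(duct, "voxel_mask"),
            inherits(frames, "frame_set"))
  check_same_geometry(pancreas, duct)
  n <- nrow(frames$points)
  if (n < 1L) stop("need at least one frame")

  he <- config$section_half_extent_mm
  ps <- config$in_plane_step_mm
  g <- seq(-he, he, by = ps)
  m <- length(g)
  c0 <- (m + 1) / 2  # grid coordinate of u = v = 0
  uv <- cbind(rep(g, times = m), rep(g, each = m))
  pix_area <- ps^2
  steps <- diff(frames$arc_s)
  plane_tol <- if (length(steps)) stats::median(steps) / 2 else ps / 2
  geom <- pancreas$geometry
  dims <- dim(pancreas$values)
  excl <- identical(config$denominator_convention, "parenchyma_excludes_duct")

  rec <- data.frame(arc_s = frames$arc_s, pancreas_area = 0, duct_area = 0,
                    dp_ratio = NA_real_, valid = FALSE,
                    cx = frames$points[, 1], cy = frames$points[, 2],
                    cz = frames$points[, 3])
  for (i in seq_len(n)) {
    ctr <- frames$points[i, ]
    nv <- frames$normals[i, ]
    bv <- frames$binormals[i, ]
    tv <- frames$tangents[i, ]
    secP <- matrix(sample_section(pancreas$values, dims, geom, ctr, nv, bv, uv), m, m)
    secD <- matrix(sample_section(duct$values, dims, geom, ctr, nv, bv, uv), m, m)
    rel <- sweep(frames$points, 2, ctr)
    along <- abs(rel %*% tv)
    sel <- which(along <= plane_tol + 1e-12)
    pu <- rel[sel, , drop = FALSE] %*% nv
    pv <- rel[sel, , drop = FALSE] %*% bv
    pier <- cbind(round(pu / ps) + c0, round(pv / ps) + c0)
    fl <- filter_traversed_components(secP, secD, pier, pixel_mm = ps)
    if (!fl$valid) next
    nP <- sum(fl$pancreas)
    nD <- sum(fl$duct)
    overlap <- sum(fl$pancreas & fl$duct)
    par_area <- (nP - overlap) * pix_area
    duct_area <- nD * pix_area
    denom <- if (excl) par_area else par_area + duct_area
    rec$pancreas_area[i] <- nP * pix_area
    rec$duct_area[i] <- duct_area
    if (denom > 0) {
      rec$dp_ratio[i] <- duct_area / denom
      rec$valid[i] <- TRUE
    }
  }
  if (!any(rec$valid))
    stop("no valid cross-sections: the centerline does not traverse any ",
         "retained pancreas region")
  out <- structure(list(samples = rec,
                        score = NA_real_,
                        score_percentile = config$percentile_level,
                        convention = config$denominator_convention,
                        n_sections = n, n_valid = sum(rec$valid),
                        config = config),
                   class = "dp_profile")
  out$score <- percentile_score(out, config$percentile_level)
  out
}

#' Percentile summary of a DP-ratio profile
#'
#' Linear-interpolation percentile (type-7 quantile) of the valid
#' per-section ratios. The default 90th percentile is high enough to react
#' to a focally elevated ratio (duct dilation or focal atrophy need not
#' span the whole organ) while discounting the few extreme sections that
#' segmentation or centerline defects produce.
#'
#' @param profile a [dp_profile()] object, or a numeric vector of ratios.
#' @param level percentile level in (0, 100].
#' @return the percentile value (dimensionless).
#' @export
percentile_score <- function(profile, level = 90) {
  if (inherits(profile, "dp_profile"))
    x <- profile$samples$dp_ratio[profile$samples$valid]
  else
    x <- as.numeric(profile[!is.na(profile)])
  if (length(x) == 0L) stop("no valid samples to summarise")
  if (level <= 0 || level > 100) stop("level must be in (0, 100]")
  unname(quantile(x, level / 100, type = 7))
}

#' @export
print.dp_profile <- function(x, ...) {
  cat(sprintf("<dp_profile> %d sections (%d valid), arc length %.1f mm\n",
              x$n_sections, x$n_valid, max(x$samples$arc_s)))
  cat(sprintf("  %gth DP ratio: %.4f  (convention: %s)\n",
              x$score_percentile, x$score, x$convention))
  invisible(x)
}

#' @export
summary.dp_profile <- function(object, ...) {
  v <- object$samples$dp_ratio[object$samples$valid]
  cat(sprintf("DP-ratio profile over %d cross-sections (%d valid)\n",
              object$n_sections, object$n_valid))
  print(summary(v))
  cat(sprintf("%gth percentile (score): %.4f\n",
              object$score_percentile, object$score))
  invisible(object)
}

#' @export
as.data.frame.dp_profile <- function(x, ...) x$samples

#' @export
plot.dp_profile <- function(x, ...) {
  s <- x$samples
  plot(s$arc_s, s$dp_ratio, type = "l", xlab = "arc length from tail (mm)",
       ylab = "DP ratio", ...)
  points(s$arc_s[!s$valid], rep(0, sum(!s$valid)), pch = 4, col = "red")
  abline(h = x$score, lty = 2, col = "grey40")
  legend("topleft", bty = "n",
         legend = sprintf("%gth percentile = %.4f", x$score_percentile, x$score))
  invisible(x)
}

#' Export a DP-ratio profile as delimited text
#'
#' @param profile a [dp_profile()].
#' @param path output TSV path.
#' @return `path` invisibly.
#' @export
write_profile <- function(profile, path) {
  write.table(profile$samples[, c("arc_s", "pancreas_area", "duct_area",
                                  "dp_ratio", "valid")],
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-case JSON report
#'
#' @param profile a [dp_profile()].
#' @param case_id case identifier recorded in the report.
#' @param path optional output path; when given the report is written as
#'   JSON.
#' @return the report list, invisibly when written.
#' @export
case_report <- function(profile, case_id = "case", path = NULL) {
  rep <- list(case_id = case_id,
              n_sections = profile$n_sections,
              n_valid = profile$n_valid,
              score_percentile = profile$score_percentile,
              score = profile$score,
              convention = profile$convention,
              config = profile$config[setdiff(names(profile$config), "seed")])
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(rep))
  }
  rep
}
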