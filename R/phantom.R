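#' Synthetic pancreas/duct phantom specification
#'
#' Describes a curved tubular "parenchyma" containing an inner "duct" tube,
#' both with circular cross-sections, voxelized on a configurable grid.
#' Circular sections give the duct-to-parenchyma area ratio a closed form
#' (see [analytic_dp_profile()]), so phantoms provide exact ground truth for
#' the whole measurement pipeline. The defaults emulate a healthy adult
#' pancreas: a 120 mm organ of 10 mm half-thickness with a 1.5 mm-radius
#' main duct, voxelized at 1 mm (typical portal-phase CT resolution).
#'
#' @param curve generating curve: `list(type = "straight")`,
#'   `list(type = "arc", radius = <mm>)` (planar circular arc) or
#'   `list(type = "sinusoid", amplitude = <mm>, period = <mm>)` (planar).
#' @param length total arc length of the generating curve in mm.
#' @param parenchyma_radius outer-tube radius profile R(s) in mm: a scalar,
#'   a `data.frame(s, value)` of breakpoints (linear ramps between them), or
#'   a function of arc length s.
#' @param duct_radius inner-tube radius profile r(s) in mm, same forms.
#' @param duct_offset length-2 in-plane displacement (mm) of the duct centre
#'   from the curve, in (normal, binormal) coordinates.
#' @param voxel_spacing length-3 voxel spacing in mm.
#' @param noise `NULL` (noise-free) or a list with any of
#'   `surface_jitter_mm` (amplitude of a smooth radial perturbation of the
#'   tube surfaces), `n_speckle_components` and `speckle_radius_mm`
#'   (spherical satellite components placed at least 5 mm outside the main
#'   tube, exercising the non-traversed-component filter downstream).
#' @param cap `"round"` (tube ends are hemispherical: every voxel closer
#'   than R to the nearest curve point is foreground) or `"flat"` (the tube
#'   is cut by the planes through the curve endpoints).
#' @param seed integer seed controlling all phantom randomness.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(curve = list(type = "straight"),
                         length = 120,
                         parenchyma_radius = 10,
                         duct_radius = 1.5,
                         duct_offset = c(0, 0),
                         voxel_spacing = c(1, 1, 1),
                         noise = NULL,
                         cap = c("round", "flat"),
                         seed = 1L) {
  cap <- match.arg(cap)
  if (!is.list(curve) || is.null(curve$type) ||
      !curve$type %in% c("straight", "arc", "sinusoid"))
    stop("curve$type must be one of 'straight', 'arc', 'sinusoid'")
  if (!is.numeric(length) || length <= 0) stop("length must be > 0")
  if (identical(curve$type, "arc")) {
    if (is.null(curve$radius) || curve$radius <= 0)
      stop("arc curve needs a positive radius")
  }
  if (identical(curve$type, "sinusoid")) {
    if (is.null(curve$amplitude) || is.null(curve$period) || curve$period <= 0)
      stop("sinusoid curve needs amplitude and a positive period")
  }
  voxel_spacing <- rep_len(as.numeric(voxel_spacing), 3L)
  if (any(voxel_spacing <= 0)) stop("voxel_spacing must be > 0")
  duct_offset <- rep_len(as.numeric(duct_offset), 2L)
  if (!is.null(noise)) {
    noise <- utils::modifyList(
      list(surface_jitter_mm = 0, n_speckle_components = 0L,
           speckle_radius_mm = 2), noise)
  }
  spec <- structure(list(curve = curve, length = length,
                         parenchyma_radius = parenchyma_radius,
                         duct_radius = duct_radius,
                         duct_offset = duct_offset,
                         voxel_spacing = voxel_spacing,
                         noise = noise, cap = cap,
                         seed = as.integer(seed)),
                    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

# normalize a radius specification to a vectorized function of arc length
radius_fun <- function(x, what) {
  if (is.function(x)) return(x)
  if (is.numeric(x) && length(x) == 1L) {
    if (x < 0) stop(what, " must be >= 0")
    force(x)
    return(function(s) rep(x, length(s)))
  }
  if (is.data.frame(x) && all(c("s", "value") %in% names(x))) {
    if (nrow(x) == 1L) {
      v <- x$value[1]
      return(function(s) rep(v, length(s)))
    }
    return(function(s) approx(x$s, x$value, xout = s, rule = 2)$y)
  }
  stop(what, " must be a scalar, a data.frame(s, value) or a function")
}

validate_phantom_spec <- function(spec) {
  s <- seq(0, spec$length, length.out = 512L)
  R <- radius_fun(spec$parenchyma_radius, "parenchyma_radius")(s)
  r <- radius_fun(spec$duct_radius, "duct_radius")(s)
  off <- sqrt(sum(spec$duct_offset^2))
  if (any(!is.finite(R)) || any(R <= 0))
    stop("invalid phantom spec: parenchyma_radius must be positive everywhere")
  if (any(!is.finite(r)) || any(r < 0))
    stop("invalid phantom spec: duct_radius must be >= 0 everywhere")
  if (any(r + off >= R))
    stop("invalid phantom spec: duct (radius + offset) must lie strictly ",
         "inside the parenchyma everywhere")
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  s <- seq(0, x$length, length.out = 256L)
  R <- radius_fun(x$parenchyma_radius, "R")(s)
  r <- radius_fun(x$duct_radius, "r")(s)
  cat(sprintf("<phantom_spec> %s curve, length %.1f mm\n", x$curve$type, x$length))
  cat(sprintf("  parenchyma R: %.2f-%.2f mm, duct r: %.2f-%.2f mm, offset %.2f mm\n",
              min(R), max(R), min(r), max(r), sqrt(sum(x$duct_offset^2))))
  cat(sprintf("  spacing %s mm, caps %s, noise %s, seed %d\n",
              paste(x$voxel_spacing, collapse = "x"), x$cap,
              if (is.null(x$noise)) "off" else "on", x$seed))
  invisible(x)
}

# dense sampling (step <= 0.25 mm) of the generating curve with analytic
# tangents; optionally extended beyond both ends (for flat caps)
phantom_curve <- function(spec, extend = 0) {
  step <- 0.25
  s <- seq(-extend, spec$length + extend, by = step)
  if (spec$length + extend - s[length(s)] > 1e-9)
    s <- c(s, spec$length + extend)
  cv <- spec$curve
  if (cv$type == "straight") {
    p <- cbind(s, 0, 0)
    tg <- cbind(rep(1, length(s)), 0, 0)
  } else if (cv$type == "arc") {
    a <- s / cv$radius
    p <- cbind(cv$radius * sin(a), cv$radius * (1 - cos(a)), 0)
    tg <- cbind(cos(a), sin(a), 0)
  } else {  # sinusoid: y = A sin(2 pi x / P), arc-length parameterized
    A <- cv$amplitude; P <- cv$period
    xx <- seq(-extend - A, spec$length + extend + A, by = 0.02)
    dy <- A * 2 * pi / P * cos(2 * pi * xx / P)
    el <- sqrt(1 + dy^2) * c(0, diff(xx))
    cl <- cumsum(el)
    cl <- cl - cl[which.min(abs(xx))]  # arc length 0 at x = 0
    xs <- approx(cl, xx, xout = s, rule = 2)$y
    p <- cbind(xs, A * sin(2 * pi * xs / P), 0)
    d <- A * 2 * pi / P * cos(2 * pi * xs / P)
    nn <- sqrt(1 + d^2)
    tg <- cbind(1 / nn, d / nn, 0)
  }
  list(s = s, points = p, tangents = tg,
       inside = s >= -1e-9 & s <= spec$length + 1e-9)
}

# smooth multiplicative-free radial jitter field: amplitude * sinusoid in
# arc length, modulated around the tube circumference
jitter_field <- function(amp, length, rng) {
  if (amp <= 0) return(function(s, theta) rep(0, base::length(s)))
  f <- sample(2:6, 1)
  phi <- runif(1, 0, 2 * pi)
  k <- sample(0:2, 1)
  psi <- runif(1, 0, 2 * pi)
  function(s, theta)
    amp * sin(2 * pi * f * s / length + phi) *
      (if (k == 0) 1 else cos(k * theta + psi))
}

#' Generate a synthetic pancreas/duct phantom
#'
#' Voxelizes the tube pair described by a [phantom_spec()]: a voxel belongs
#' to the parenchyma mask when its centre lies closer than R(s*) to the
#' generating curve (s* the arc length of the nearest curve point), and to
#' the duct mask when it lies closer than r(s*) to the duct centre curve
#' (the generating curve displaced in-plane by `duct_offset`). Noise-free
#' phantoms are fully deterministic; with noise enabled, a smooth surface
#' jitter and disconnected speckle satellites are added deterministically
#' from the spec seed.
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `phantom_case`: list with `pancreas` and
#'   `duct` ([voxel_mask()]s on a shared grid), `truth_curve` (dense m x 3
#'   matrix of curve points, arc step <= 0.25 mm), `truth_profile`
#'   (`data.frame(s, R, r, dp)` of the analytic ratio profile), `labels`
#'   (`mpdd`/`ppa` logicals) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  Rf <- radius_fun(spec$parenchyma_radius, "parenchyma_radius")
  rf <- radius_fun(spec$duct_radius, "duct_radius")

  jit_amp <- if (is.null(spec$noise)) 0 else spec$noise$surface_jitter_mm
  n_speck <- if (is.null(spec$noise)) 0L else as.integer(spec$noise$n_speckle_components)
  speck_r <- if (is.null(spec$noise)) 0 else spec$noise$speckle_radius_mm

  Rmax <- max(Rf(seq(0, spec$length, length.out = 512L)))
  extend <- if (spec$cap == "flat") Rmax + jit_amp + 2 else 0
  cur <- phantom_curve(spec, extend = extend)
  frames <- build_frames(cur$points, cur$tangents)
  duct_centres <- cur$points +
    spec$duct_offset[1] * frames$normals + spec$duct_offset[2] * frames$binormals

  Rs <- Rf(pmin(pmax(cur$s, 0), spec$length))
  rs <- rf(pmin(pmax(cur$s, 0), spec$length))

  # deterministic noise parameters from the spec seed
  jp <- jd <- NULL
  speckles <- NULL
  if (jit_amp > 0 || n_speck > 0) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    set.seed(spec$seed)
    jp <- jitter_field(jit_amp, spec$length, NULL)
    jd <- jitter_field(0.5 * jit_amp, spec$length, NULL)
    if (n_speck > 0L) {
      inside <- which(cur$inside)
      sk <- runif(n_speck, 0.1 * spec$length, 0.9 * spec$length)
      th <- runif(n_speck, 0, 2 * pi)
      ki <- vapply(sk, function(v) inside[which.min(abs(cur$s[inside] - v))], 1L)
      centre <- cur$points[ki, , drop = FALSE] +
        (Rf(sk) + jit_amp + 5 + speck_r) *
          (cos(th) * frames$normals[ki, , drop = FALSE] +
           sin(th) * frames$binormals[ki, , drop = FALSE])
      speckles <- data.frame(centre, radius = speck_r,
                             target = rep(c("pancreas", "duct"),
                                          length.out = n_speck))
      names(speckles)[1:3] <- c("x", "y", "z")
    }
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()) else
      rm(".Random.seed", envir = globalenv())
  }

  pts_in <- cur$points[cur$inside, , drop = FALSE]
  margin <- Rmax + jit_amp + 2
  lo <- apply(pts_in, 2, min) - margin
  hi <- apply(pts_in, 2, max) + margin
  if (!is.null(speckles)) {
    lo <- pmin(lo, apply(speckles[, 1:3], 2, min) - speck_r - 1)
    hi <- pmax(hi, apply(speckles[, 1:3], 2, max) + speck_r + 1)
  }
  sp <- spec$voxel_spacing
  # Anchor the grid to the global lattice {k*sp - sp/2}: the half-voxel
  # offset keeps voxel centres off the analytic surfaces when radii are
  # integer multiples of the spacing (a degenerate alignment that biases
  # the strict inside test), and anchoring means enlarging the field of
  # view (e.g. for speckle satellites) never re-samples the tube itself.
  lo <- floor(lo / sp) * sp - sp / 2
  dims <- as.integer(floor((hi - lo) / sp)) + 2L
  geom <- volume_geometry(sp, lo)

  nvox <- prod(dims)
  pan <- integer(nvox)
  duc <- integer(nvox)
  C <- cur$points
  Cd <- duct_centres
  cc <- rowSums(C^2)
  ccd <- rowSums(Cd^2)
  ok_s <- cur$inside  # acceptance window for flat caps
  chunk <- 8192L
  n_off <- dims[1]
  ny <- dims[2]
  for (start in seq(0L, nvox - 1L, by = chunk)) {
    idx <- start:min(start + chunk - 1L, nvox - 1L)
    i0 <- idx %% n_off
    j0 <- (idx %/% n_off) %% ny
    k0 <- idx %/% (n_off * ny)
    V <- cbind(lo[1] + i0 * sp[1], lo[2] + j0 * sp[2], lo[3] + k0 * sp[3])
    vv <- rowSums(V^2)
    D2 <- outer(vv, cc, "+") - 2 * V %*% t(C)
    near <- max.col(-D2, ties.method = "first")
    d2 <- D2[cbind(seq_along(near), near)]
    d <- sqrt(pmax(d2, 0))
    accept <- ok_s[near]
    Rn <- Rs[near]
    if (jit_amp > 0) {
      rel <- V - C[near, , drop = FALSE]
      theta <- atan2(rowSums(rel * frames$binormals[near, , drop = FALSE]),
                     rowSums(rel * frames$normals[near, , drop = FALSE]))
      Rn <- Rn + jp(pmin(pmax(cur$s[near], 0), spec$length), theta)
    }
    fg <- accept & d < Rn
    pan[idx + 1L][fg] <- 1L
    # duct: only voxels near the tube can be duct
    cand <- which(d < Rn + 1)
    if (length(cand)) {
      Vc <- V[cand, , drop = FALSE]
      D2d <- outer(rowSums(Vc^2), ccd, "+") - 2 * Vc %*% t(Cd)
      neard <- max.col(-D2d, ties.method = "first")
      dd <- sqrt(pmax(D2d[cbind(seq_along(neard), neard)], 0))
      rn <- rs[neard]
      if (jit_amp > 0) {
        reld <- Vc - Cd[neard, , drop = FALSE]
        thd <- atan2(rowSums(reld * frames$binormals[neard, , drop = FALSE]),
                     rowSums(reld * frames$normals[neard, , drop = FALSE]))
        rn <- pmax(rn + jd(pmin(pmax(cur$s[neard], 0), spec$length), thd), 0)
      }
      fgd <- ok_s[neard] & dd < rn
      duc[idx + 1L][cand[fgd]] <- 1L
    }
  }
  pan <- array(pan, dim = dims)
  duc <- array(duc, dim = dims)

  if (!is.null(speckles)) {
    for (q in seq_len(nrow(speckles))) {
      ctr <- as.numeric(speckles[q, 1:3])
      rad <- speckles$radius[q]
      i0 <- pmax(floor((ctr - rad - lo) / sp), 0)
      i1 <- pmin(ceiling((ctr + rad - lo) / sp), dims - 1L)
      gi <- seq(i0[1], i1[1]); gj <- seq(i0[2], i1[2]); gk <- seq(i0[3], i1[3])
      G <- as.matrix(expand.grid(i = gi, j = gj, k = gk))
      W <- sweep(sweep(G, 2, sp, "*"), 2, lo, "+")
      inb <- rowSums(sweep(W, 2, ctr, "-")^2) < rad^2
      sel <- G[inb, , drop = FALSE] + 1L
      if (nrow(sel)) {
        if (speckles$target[q] == "pancreas") pan[sel] <- 1L else duc[sel] <- 1L
      }
    }
  }

  truth_s <- cur$s[cur$inside]
  prof <- data.frame(s = truth_s, R = Rf(truth_s), r = rf(truth_s))
  prof$dp <- prof$r^2 / (prof$R^2 - prof$r^2)

  structure(list(
    pancreas = voxel_mask(pan, geometry = geom, label = "pancreas"),
    duct = voxel_mask(duc, geometry = geom, label = "mpd"),
    truth_curve = cur$points[cur$inside, , drop = FALSE],
    truth_profile = prof,
    labels = list(mpdd = FALSE, ppa = FALSE),
    spec = spec), class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> mpdd=%s ppa=%s\n", x$labels$mpdd, x$labels$ppa))
  print(x$pancreas)
  cat(sprintf("  duct foreground: %d voxels\n", sum(x$duct$values)))
  invisible(x)
}

#' Analytic DP-ratio profile of a phantom
#'
#' On circular cross-sections, the duct-to-parenchyma area ratio has the
#' closed form `r(s)^2 / (R(s)^2 - r(s)^2)` when the parenchyma excludes the
#' duct lumen, or `r(s)^2 / R(s)^2` for the whole-pancreas denominator. The
#' in-plane duct offset does not change the areas while the duct stays
#' strictly inside the parenchyma.
#'
#' @param spec a [phantom_spec()].
#' @param level percentile level summarising the profile (default 90).
#' @param convention denominator convention, matching [dp_config()].
#' @return list with `profile` (`data.frame(s, R, r, dp)`, arc step 0.25 mm)
#'   and `score` (the `level`-th percentile of `dp`).
#' @export
analytic_dp_profile <- function(spec, level = 90,
                                convention = c("parenchyma_excludes_duct",
                                               "whole_pancreas")) {
  stopifnot(inherits(spec, "phantom_spec"))
  convention <- match.arg(convention)
  s <- seq(0, spec$length, by = 0.25)
  if (spec$length - s[length(s)] > 1e-9) s <- c(s, spec$length)
  R <- radius_fun(spec$parenchyma_radius, "parenchyma_radius")(s)
  r <- radius_fun(spec$duct_radius, "duct_radius")(s)
  dp <- if (convention == "parenchyma_excludes_duct")
    r^2 / (R^2 - r^2) else r^2 / R^2
  list(profile = data.frame(s = s, R = R, r = r, dp = dp),
       score = unname(quantile(dp, level / 100, type = 7)),
       level = level, convention = convention)
}

# deterministic, order-independent per-case seed stream
case_seed <- function(cohort_seed, index) {
  as.integer((as.numeric(cohort_seed) * 10007 + index * 7919) %% 2147483629)
}

# multiply a radius profile by `factor` over the arc span [s0, s1]
span_scaled <- function(base, factor, s0, s1) {
  f <- radius_fun(base, "radius")
  function(s) f(s) * ifelse(s >= s0 & s <= s1, factor, 1)
}

#' Generate a labeled phantom cohort
#'
#' Negative cases are drawn from `base_spec`; positive cases modify it over
#' a random contiguous arc span: duct dilation (MPDD) multiplies the duct
#' radius by `dilation_factor`, parenchymal atrophy (PPA) multiplies the
#' parenchyma radius by `atrophy_factor` (< 1), and `"both"` applies the two
#' over the same span. Per-case random streams are derived deterministically
#' from `(seed, case index)`, so a cohort is reproducible and independent of
#' generation order.
#'
#' @param n_positive,n_negative case counts (>= 0).
#' @param positive_kind `"mpdd"`, `"ppa"` or `"both"`.
#' @param base_spec the negative-case [phantom_spec()].
#' @param seed cohort seed.
#' @param dilation_factor duct-radius multiplier for MPDD positives.
#' @param atrophy_factor parenchyma-radius multiplier for PPA positives.
#' @param span_frac length-2 range: lesion span as a fraction of the organ
#'   length (span start is uniform over the feasible range).
#' @return list of [generate_phantom()] cases with `labels` set; positives
#'   first.
#' @export
generate_cohort <- function(n_positive, n_negative,
                            positive_kind = c("mpdd", "ppa", "both"),
                            base_spec = phantom_spec(), seed = 1,
                            dilation_factor = 3, atrophy_factor = 0.6,
                            span_frac = c(0.25, 0.5)) {
  positive_kind <- match.arg(positive_kind)
  stopifnot(n_positive >= 0, n_negative >= 0)
  n <- n_positive + n_negative
  out <- vector("list", n)
  for (i in seq_len(n)) {
    cs <- case_seed(seed, i)
    positive <- i <= n_positive
    spec_i <- base_spec
    spec_i$seed <- cs
    if (positive) {
      set.seed(cs)
      frac <- runif(1, span_frac[1], span_frac[2])
      span <- frac * base_spec$length
      s0 <- runif(1, 0, base_spec$length - span)
      s1 <- s0 + span
      if (positive_kind %in% c("mpdd", "both"))
        spec_i$duct_radius <- span_scaled(base_spec$duct_radius,
                                          dilation_factor, s0, s1)
      if (positive_kind %in% c("ppa", "both"))
        spec_i$parenchyma_radius <- span_scaled(base_spec$parenchyma_radius,
                                                atrophy_factor, s0, s1)
      class(spec_i) <- "phantom_spec"
      validate_phantom_spec(spec_i)
    }
    case <- generate_phantom(spec_i)
    case$labels <- list(
      mpdd = positive && positive_kind %in% c("mpdd", "both"),
      ppa = positive && positive_kind %in% c("ppa", "both"))
    case$case_id <- sprintf("case%03d", i)
    out[[i]] <- case
  }
  out
}

#' Write a phantom case to disk
#'
#' Writes the two masks as NIfTI and the ground-truth profile as
#' tab-separated text (`s`, `R`, `r`, `dp`).
#'
#' @param case a [generate_phantom()] result.
#' @param dir output directory (created if missing).
#' @param case_id file-name stem.
#' @return named character vector of the three paths.
#' @export
write_phantom_case <- function(case, dir, case_id = "phantom") {
  stopifnot(inherits(case, "phantom_case"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pp <- file.path(dir, paste0(case_id, "_pancreas.nii.gz"))
  dp <- file.path(dir, paste0(case_id, "_duct.nii.gz"))
  tp <- file.path(dir, paste0(case_id, "_truth.tsv"))
  write_mask(case$pancreas, pp)
  write_mask(case$duct, dp)
  write.table(case$truth_profile, tp, sep = "\t", row.names = FALSE,
              quote = FALSE)
  c(pancreas = pp, duct = dp, truth = tp)
}

#' Align a computed DP profile with a phantom's analytic truth
#'
#' Maps every valid cross-section of a computed profile to the arc length of
#' the nearest point on the phantom's generating curve and attaches the
#' analytic ratio there, enabling pointwise comparison regardless of the
#' direction in which the estimated centerline traversed the organ.
#'
#' @param profile a `dp_profile` (see [dp_profile()]).
#' @param case the [generate_phantom()] case the masks came from.
#' @param convention denominator convention used for the analytic ratio.
#' @return `data.frame(arc_s, s_truth, dp, dp_truth)` over valid sections.
#' @export
align_profile_to_truth <- function(profile, case,
                                   convention = c("parenchyma_excludes_duct",
                                                  "whole_pancreas")) {
  stopifnot(inherits(profile, "dp_profile"), inherits(case, "phantom_case"))
  convention <- match.arg(convention)
  sm <- profile$samples[profile$samples$valid, , drop = FALSE]
  ctr <- as.matrix(sm[, c("cx", "cy", "cz")])
  tc <- case$truth_curve
  d2 <- outer(rowSums(ctr^2), rowSums(tc^2), "+") - 2 * ctr %*% t(tc)
  near <- max.col(-d2, ties.method = "first")
  tp <- case$truth_profile
  dp_truth <- if (convention == "parenchyma_excludes_duct")
    tp$r[near]^2 / (tp$R[near]^2 - tp$r[near]^2) else tp$r[near]^2 / tp$R[near]^2
  data.frame(arc_s = sm$arc_s, s_truth = tp$s[near],
             dp = sm$dp_ratio, dp_truth = dp_truth)
}
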