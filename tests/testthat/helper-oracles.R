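# Independent oracles and small fixture builders shared by the test files.
# Every oracle here is deliberately naive (brute force / direct formula) and
# shares no code with the package internals it checks.

# Brute-force Euclidean distance (mm) from every foreground voxel to the
# nearest background voxel centre, treating everything outside the array as
# background (the nearest exterior voxel always lies in the first padding
# layer, so padding by one suffices).
brute_edt <- function(values, spacing) {
  d <- dim(values)
  idx <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1), k = 0:(d[3] - 1)))
  pd <- d + 2L
  pidx <- as.matrix(expand.grid(i = -1:d[1], j = -1:d[2], k = -1:d[3]))
  pvals <- integer(nrow(pidx))
  ok <- pidx[, 1] >= 0 & pidx[, 1] < d[1] & pidx[, 2] >= 0 & pidx[, 2] < d[2] &
        pidx[, 3] >= 0 & pidx[, 3] < d[3]
  pvals[ok] <- values[pidx[ok, , drop = FALSE] + 1L]
  bg <- pidx[pvals == 0, , drop = FALSE]
  out <- array(0, d)
  for (r in seq_len(nrow(idx))) {
    if (values[idx[r, 1] + 1, idx[r, 2] + 1, idx[r, 3] + 1] == 0) next
    dd <- sweep(bg, 2, idx[r, ], "-")
    dd <- sweep(dd, 2, spacing, "*")
    out[idx[r, 1] + 1, idx[r, 2] + 1, idx[r, 3] + 1] <- sqrt(min(rowSums(dd^2)))
  }
  out
}

# Bellman-Ford shortest-path cost on the 26-connected foreground graph with
# the medialness edge cost step_mm / (1 + weight[v])^p; exact oracle for
# tiny masks.
brute_shortest_cost <- function(values, spacing, weight, p, src, dst) {
  d <- dim(values)
  fg <- which(values != 0)
  pos <- arrayInd(fg, d) - 1L
  id <- stats::setNames(seq_along(fg), fg)
  lin <- function(ijk) ijk[1] + d[1] * (ijk[2] + d[2] * ijk[3]) + 1
  edges <- list()
  for (a in seq_along(fg)) {
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      q <- pos[a, ] + c(dx, dy, dz)
      if (any(q < 0) || any(q >= d)) next
      ql <- lin(q)
      if (values[ql] == 0) next
      step <- sqrt(sum((c(dx, dy, dz) * spacing)^2))
      edges[[length(edges) + 1L]] <- c(a, id[[as.character(ql)]],
                                       step / (1 + weight[ql])^p)
    }
  }
  em <- do.call(rbind, edges)
  n <- length(fg)
  dist <- rep(Inf, n)
  dist[id[[as.character(lin(src))]]] <- 0
  for (iter in seq_len(n)) {
    new <- pmin(dist, Inf)
    for (r in seq_len(nrow(em)))
      new[em[r, 2]] <- min(new[em[r, 2]], dist[em[r, 1]] + em[r, 3])
    if (identical(new, dist)) break
    dist <- new
  }
  dist[id[[as.character(lin(dst))]]]
}

# O(n^2) pairwise-concordance AUROC
brute_auroc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Welch's t-test from first principles
welch_oracle <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# linear-interpolation percentile over the sorted array
pct_oracle <- function(x, level) {
  x <- sort(x)
  h <- (length(x) - 1) * level / 100
  lo <- floor(h)
  x[lo + 1] + (h - lo) * (x[min(lo + 2, length(x))] - x[lo + 1])
}

# Flat-ended straight tube along the patient-left axis, built directly from
# voxel-centre coordinates (independent of the phantom generator): a voxel
# is foreground when its x lies in [0, length_mm] and its in-plane distance
# from the axis is < radius. Centres sit on the lattice k*sp - sp/2.
make_tube_mask <- function(length_mm, radius, spacing = 1, margin = 3) {
  sp <- rep(spacing, 3)
  lo <- floor(c(-margin, -radius - margin, -radius - margin) / sp) * sp - sp / 2
  hi <- c(length_mm + margin, radius + margin, radius + margin)
  dims <- as.integer(floor((hi - lo) / sp)) + 2L
  xs <- lo[1] + (0:(dims[1] - 1)) * sp[1]
  ys <- lo[2] + (0:(dims[2] - 1)) * sp[2]
  zs <- lo[3] + (0:(dims[3] - 1)) * sp[3]
  inx <- xs >= 0 & xs <= length_mm
  r2 <- outer(ys^2, zs^2, "+")
  v <- array(0L, dims)
  v[inx, , ] <- rep(as.integer(r2 < radius^2), each = sum(inx))
  voxel_mask(v, spacing = sp, origin = lo, label = "pancreas")
}

# random small binary mask guaranteed to contain a connected pair of voxels
random_small_mask <- function(dims, p_fg = 0.6) {
  v <- array(as.integer(runif(prod(dims)) < p_fg), dims)
  v
}

# small, fast phantom reused by several dp-ratio tests
small_phantom <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      spec <- phantom_spec(length = 60, parenchyma_radius = 8, duct_radius = 2,
                           voxel_spacing = c(0.5, 0.5, 0.5), seed = 7)
      memo <<- list(spec = spec, case = generate_phantom(spec))
    }
    memo
  }
})
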