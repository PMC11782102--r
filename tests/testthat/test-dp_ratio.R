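straight_frame <- function(x, roll = 0) {
  n <- c(0, cos(roll), sin(roll))
  b <- c(0, -sin(roll), cos(roll))
  list(point = c(x, 0, 0), tangent = c(1, 0, 0), normal = n, binormal = b)
}

test_that("cross-sections of an empty mask or out-of-volume frame are empty", {
  m <- voxel_mask(array(0L, c(10, 10, 10)), spacing = c(1, 1, 1))
  sec <- extract_cross_section(m, straight_frame(5), half_extent = 10,
                               in_plane_step = 1)
  expect_true(all(sec == 0))
  tube <- small_phantom()$case$pancreas
  far <- list(point = c(1e4, 1e4, 1e4), normal = c(0, 1, 0), binormal = c(0, 0, 1))
  expect_true(all(extract_cross_section(tube, far) == 0))
})

test_that("a mid-tube cross-section recovers the analytic disk area", {
  tube <- small_phantom()$case$pancreas  # straight, R = 8 mm
  sec <- extract_cross_section(tube, straight_frame(30), half_extent = 20,
                               in_plane_step = 0.5)
  area <- sum(sec) * 0.25
  expect_lt(abs(area - pi * 64) / (pi * 64), 0.05)
})

test_that("non-traversed pancreas components are removed", {
  pan <- matrix(0L, 20, 20)
  pan[3:8, 3:8] <- 1L      # blob A (contains the piercing pixel)
  pan[14:18, 14:18] <- 1L  # blob B (should be removed)
  duct <- matrix(0L, 20, 20)
  fl <- filter_traversed_components(pan, duct, cbind(5, 5), pixel_mm = 0.5)
  expect_true(fl$valid)
  expect_identical(sum(fl$pancreas[3:8, 3:8]), 36L)
  expect_identical(sum(fl$pancreas[14:18, 14:18]), 0L)
})

test_that("a piercing pixel in background rescues only components within 2 mm", {
  pan <- matrix(0L, 30, 30)
  pan[10:14, 10:14] <- 1L
  # at 0.5 mm pixels, component corner (10,10) is 2 px = 1 mm from (8,8)
  near <- filter_traversed_components(pan, matrix(0L, 30, 30), cbind(8, 8),
                                      pixel_mm = 0.5)
  expect_true(near$valid)
  # 12 px = 6 mm away: beyond the 2 mm rescue bound
  far <- filter_traversed_components(pan, matrix(0L, 30, 30), cbind(26, 26),
                                     pixel_mm = 0.5)
  expect_false(far$valid)
  expect_true(all(far$pancreas == 0))
})

test_that("duct components disconnected from the retained pancreas are removed", {
  pan <- matrix(0L, 40, 40)
  pan[5:20, 5:20] <- 1L
  duct <- matrix(0L, 40, 40)
  duct[10:12, 10:12] <- 1L  # inside the pancreas: kept
  duct[32:34, 32:34] <- 1L  # speckle far outside: removed
  fl <- filter_traversed_components(pan, duct, cbind(12, 12), pixel_mm = 0.5)
  expect_identical(sum(fl$duct[10:12, 10:12]), 9L)
  expect_identical(sum(fl$duct[32:34, 32:34]), 0L)
  # a duct region adjacent to (but disjoint from) the pancreas is kept via
  # the one-pixel dilation
  duct2 <- matrix(0L, 40, 40)
  duct2[21:23, 5:7] <- 1L
  fl2 <- filter_traversed_components(pan, duct2, cbind(12, 12), pixel_mm = 0.5)
  expect_identical(sum(fl2$duct), 9L)
})

test_that("mismatched section shapes raise an error", {
  expect_error(filter_traversed_components(matrix(0L, 3, 3), matrix(0L, 4, 4),
                                           cbind(1, 1)), "shapes")
})

test_that("a zero duct mask yields an all-zero profile and score 0", {
  ph <- small_phantom()$case
  empty <- voxel_mask(array(0L, dim(ph$duct$values)), geometry = ph$duct$geometry)
  prof <- compute_case(ph$pancreas, empty)
  expect_true(all(prof$samples$dp_ratio[prof$samples$valid] == 0))
  expect_identical(prof$score, 0)
})

test_that("the computed profile matches the analytic ratio mid-tube", {
  ph <- small_phantom()  # R = 8, r = 2 concentric: dp = 4 / 60
  prof <- compute_case(ph$case$pancreas, ph$case$duct)
  al <- align_profile_to_truth(prof, ph$case)
  interior <- al[al$s_truth > 6 & al$s_truth < 54, ]
  expect_gt(nrow(interior), 50)
  expect_lt(max(abs(interior$dp - interior$dp_truth) /
                pmax(interior$dp_truth, 0.05)), 0.10)
  expect_lt(abs(prof$score - 4 / 60) / (4 / 60), 0.10)
})

test_that("the score is invariant under a 90-degree in-plane frame rotation", {
  ph <- small_phantom()$case
  cfg <- dp_config()
  cl <- estimate_centerline(ph$pancreas)
  pts <- resample_polyline(smooth_polyline(cl$points), 0.5)
  tg <- compute_tangents(pts, 0.5, 10)
  f0 <- build_frames(pts, tg)
  f90 <- build_frames(pts, tg, roll = pi / 2)
  p0 <- dp_profile(ph$pancreas, ph$duct, f0, cfg)
  p90 <- dp_profile(ph$pancreas, ph$duct, f90, cfg)
  expect_lt(max(abs(p0$samples$dp_ratio - p90$samples$dp_ratio), na.rm = TRUE),
            1e-6)
  expect_lt(abs(p0$score - p90$score), 1e-6)
})

test_that("the two denominator conventions are consistently related", {
  ph <- small_phantom()$case
  pe <- compute_case(ph$pancreas, ph$duct, dp_config())
  pw <- compute_case(ph$pancreas, ph$duct,
                     dp_config(denominator_convention = "whole_pancreas"))
  v <- pe$samples$valid & pw$samples$valid
  a <- pe$samples$dp_ratio[v]
  b <- pw$samples$dp_ratio[v]
  # d/p vs d/(p+d): b = a / (1 + a)
  expect_lt(max(abs(b - a / (1 + a))), 1e-9)
})

test_that("dilating the duct never decreases the score", {
  base <- phantom_spec(length = 40, parenchyma_radius = 8, duct_radius = 1.5,
                       voxel_spacing = c(1, 1, 1))
  big <- phantom_spec(length = 40, parenchyma_radius = 8, duct_radius = 2.5,
                      voxel_spacing = c(1, 1, 1))
  s1 <- compute_case(generate_phantom(base)$pancreas,
                     generate_phantom(base)$duct)$score
  s2 <- compute_case(generate_phantom(big)$pancreas,
                     generate_phantom(big)$duct)$score
  expect_gte(s2, s1)
})

test_that("percentile scoring matches the sorted-interpolation oracle", {
  expect_identical(percentile_score(rep(0.3, 8), 90), 0.3)
  expect_identical(percentile_score(rep(0.3, 8), 10), 0.3)
  expect_equal(percentile_score(seq(0, 1, by = 0.1), 90), 0.9,
               tolerance = 1e-12)
  expect_identical(percentile_score(c(0.2, 0.8, 0.5), 100), 0.8)
  set.seed(9)
  for (rep in 1:20) {
    x <- runif(sample(2:40, 1))
    lv <- runif(1, 1, 100)
    expect_equal(percentile_score(x, lv), pct_oracle(x, lv), tolerance = 1e-12)
  }
  expect_error(percentile_score(numeric(0)), "no valid")
  expect_error(percentile_score(c(0.1), 0), "level")
})

test_that("profiles export as delimited text and JSON case reports", {
  ph <- small_phantom()$case
  prof <- compute_case(ph$pancreas, ph$duct)
  tsv <- tempfile(fileext = ".tsv")
  write_profile(prof, tsv)
  back <- read.delim(tsv)
  expect_named(back, c("arc_s", "pancreas_area", "duct_area", "dp_ratio", "valid"))
  expect_identical(nrow(back), prof$n_sections)
  js <- tempfile(fileext = ".json")
  case_report(prof, "demo", js)
  rep <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_identical(rep$case_id, "demo")
  expect_equal(rep$score, prof$score, tolerance = 1e-12)
})
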