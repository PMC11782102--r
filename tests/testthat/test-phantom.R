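test_that("phantom spec validation enforces the duct-inside-parenchyma rule", {
  expect_error(phantom_spec(parenchyma_radius = 5, duct_radius = 5), "inside")
  expect_error(phantom_spec(parenchyma_radius = 5, duct_radius = 3,
                            duct_offset = c(2.5, 0)), "inside")
  expect_error(phantom_spec(length = -1), "length")
  expect_silent(phantom_spec(parenchyma_radius = 5, duct_radius = 2,
                             duct_offset = c(1, 1)))
})

test_that("a zero-radius duct produces an all-zero duct mask", {
  case <- generate_phantom(phantom_spec(length = 40, parenchyma_radius = 6,
                                        duct_radius = 0))
  expect_identical(sum(case$duct$values), 0L)
  expect_gt(sum(case$pancreas$values), 0L)
})

test_that("noise-free phantoms are independent of the seed and deterministic", {
  s1 <- phantom_spec(length = 40, parenchyma_radius = 6, duct_radius = 1.5, seed = 1)
  s2 <- phantom_spec(length = 40, parenchyma_radius = 6, duct_radius = 1.5, seed = 99)
  c1 <- generate_phantom(s1)
  c2 <- generate_phantom(s2)
  expect_identical(c1$pancreas$values, c2$pancreas$values)
  expect_identical(c1$duct$values, c2$duct$values)
})

test_that("noisy phantoms are reproducible from the spec seed", {
  sp <- phantom_spec(length = 40, parenchyma_radius = 6, duct_radius = 1.5,
                     noise = list(surface_jitter_mm = 0.5,
                                  n_speckle_components = 2), seed = 5)
  c1 <- generate_phantom(sp)
  c2 <- generate_phantom(sp)
  expect_identical(c1$pancreas$values, c2$pancreas$values)
  expect_identical(c1$duct$values, c2$duct$values)
})

test_that("the duct is a voxelwise subset of the parenchyma (noise-free)", {
  for (curve in list(list(type = "straight"),
                     list(type = "arc", radius = 50),
                     list(type = "sinusoid", amplitude = 8, period = 50))) {
    case <- generate_phantom(phantom_spec(curve = curve, length = 50,
                                          parenchyma_radius = 7,
                                          duct_radius = 2, duct_offset = c(2, 0)))
    expect_true(all(case$pancreas$values[case$duct$values == 1] == 1),
                info = curve$type)
  }
})

test_that("voxel-counted duct slice areas approach the analytic circle area", {
  case <- small_phantom()$case  # straight, R = 8, r = 2, 0.5 mm voxels
  v <- case$duct$values
  xs <- case$duct$geometry$origin[1] + (0:(dim(v)[1] - 1)) * 0.5
  interior <- which(xs > 10 & xs < 50)
  per_slice <- apply(v[interior, , ], 1, sum) * 0.5^2
  expect_lt(max(abs(per_slice - pi * 4) / (pi * 4)), 0.05)
})

test_that("areas converge to the analytic values as the voxels shrink", {
  area_err <- function(h) {
    case <- generate_phantom(phantom_spec(length = 30, parenchyma_radius = 8,
                                          duct_radius = 2,
                                          voxel_spacing = rep(h, 3)))
    v <- case$duct$values
    xs <- case$duct$geometry$origin[1] + (0:(dim(v)[1] - 1)) * h
    mid <- which.min(abs(xs - 15))
    abs(sum(v[mid, , ]) * h^2 - pi * 4) / (pi * 4)
  }
  expect_lt(area_err(0.5), area_err(1.0))
})

test_that("the analytic DP profile matches closed-form circle ratios", {
  sp <- phantom_spec(length = 100, parenchyma_radius = 10, duct_radius = 2)
  pr <- analytic_dp_profile(sp)
  expect_equal(unique(pr$profile$dp), 4 / 96, tolerance = 1e-12)
  expect_equal(pr$score, 4 / 96, tolerance = 1e-12)

  pr0 <- analytic_dp_profile(phantom_spec(length = 100, parenchyma_radius = 10,
                                          duct_radius = 0))
  expect_true(all(pr0$profile$dp == 0))

  step <- phantom_spec(length = 100, parenchyma_radius = 10,
                       duct_radius = data.frame(s = c(0, 49.99, 50, 100),
                                                value = c(1, 1, 3, 3)))
  pr2 <- analytic_dp_profile(step)
  expect_equal(pr2$score, 9 / 91, tolerance = 1e-6)
})

test_that("the analytic DP ratio is invariant under uniform scaling", {
  a <- analytic_dp_profile(phantom_spec(parenchyma_radius = 10, duct_radius = 2))
  b <- analytic_dp_profile(phantom_spec(parenchyma_radius = 20, duct_radius = 4))
  expect_equal(a$profile$dp, b$profile$dp, tolerance = 1e-12)
})

test_that("cohorts are labeled, deterministic and order-independent", {
  base <- phantom_spec(length = 30, parenchyma_radius = 6, duct_radius = 1.5)
  neg <- generate_cohort(0, 3, "mpdd", base, seed = 11)
  expect_length(neg, 3)
  expect_true(all(!vapply(neg, function(cs) cs$labels$mpdd, TRUE)))

  c1 <- generate_cohort(2, 2, "mpdd", base, seed = 4)
  c2 <- generate_cohort(2, 2, "mpdd", base, seed = 4)
  for (i in seq_along(c1)) {
    expect_identical(c1[[i]]$pancreas$values, c2[[i]]$pancreas$values)
    expect_identical(c1[[i]]$labels, c2[[i]]$labels)
  }
  expect_true(all(vapply(c1[1:2], function(cs) cs$labels$mpdd, TRUE)))
  expect_false(any(vapply(c1[3:4], function(cs) cs$labels$mpdd, TRUE)))
})

test_that("dilated positives dominate negatives in analytic score", {
  base <- phantom_spec(length = 60, parenchyma_radius = 8, duct_radius = 1.5)
  cohort <- generate_cohort(5, 5, "mpdd", base, seed = 2, dilation_factor = 3)
  scores <- vapply(cohort, function(cs) analytic_dp_profile(cs$spec)$score, 0)
  expect_gt(min(scores[1:5]), max(scores[6:10]))
})

test_that("phantom cases write masks and a readable truth sidecar", {
  case <- generate_phantom(phantom_spec(length = 20, parenchyma_radius = 5,
                                        duct_radius = 1.5))
  dir <- tempfile(); dir.create(dir)
  paths <- write_phantom_case(case, dir, "tiny")
  expect_true(all(file.exists(paths)))
  m <- read_mask(paths[["pancreas"]])
  expect_identical(m$values, case$pancreas$values)
  truth <- read.delim(paths[["truth"]])
  expect_named(truth, c("s", "R", "r", "dp"))
  expect_true(all(truth$dp >= 0))
})
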