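test_that("minIP reproduces brute-force slab minima", {
  vol <- array(100, dim = c(6, 7, 8))
  # constant volume projects to a constant image
  expect_true(all(min_intensity_projection(vol, 3, slab = 3,
                                           slab_center = 3) == 100))
  # single-plane slab is the identity on that plane
  vol2 <- array(rnorm(6 * 7 * 8), dim = c(6, 7, 8))
  expect_equal(min_intensity_projection(vol2, 3, slab = 0.8, slab_center = 4),
               vol2[, , 5])
  # a dark tube crossing the slab survives projection
  vol3 <- array(100, dim = c(6, 7, 8))
  vol3[3, , 4:6] <- 10
  proj <- min_intensity_projection(vol3, 3, slab = 2, slab_center = 4)
  expect_equal(proj, min_over_slab(vol3, 3, 4:6))
  expect_true(all(proj[3, ] == 10))
  expect_error(min_intensity_projection(vol, 3, slab = 2, slab_center = 50),
               "outside")
  expect_error(min_intensity_projection(vol, 5, slab = 2, slab_center = 2),
               "axis")
})

test_that("skeletonization thins bars and leaves thin paths unchanged", {
  # one-pixel path is already a skeleton
  ras <- matrix(FALSE, 5, 20)
  ras[3, 2:19] <- TRUE
  sk <- skeletonize(vessel_mask(ras, 0.5))
  expect_identical(sk$raster, ras)
  # 3-pixel-wide bar thins to a single-pixel path of comparable length
  bar <- matrix(FALSE, 7, 20)
  bar[3:5, 2:19] <- TRUE
  skb <- skeletonize(vessel_mask(bar, 0.5))
  px <- which(skb$raster, arr.ind = TRUE)
  expect_true(all(table(px[, 2]) == 1))          # one pixel per column used
  # thinning erodes bar tips by up to the half-width at each end
  expect_gte(diff(range(px[, 2])), 17 - 4)
  expect_true(all(skb$raster[bar == FALSE] == FALSE))  # subset of input
  # single pixel stays put
  one <- matrix(FALSE, 3, 3); one[2, 2] <- TRUE
  expect_identical(skeletonize(vessel_mask(one, 1))$raster, one)
})

test_that("spur pruning removes short branches, keeps long arms, is idempotent", {
  # main path 40 px with a 2-px side branch
  ras <- matrix(FALSE, 9, 44)
  ras[5, 2:41] <- TRUE
  ras[4, 21] <- TRUE; ras[3, 22] <- TRUE
  m <- vessel_mask(ras, 1)
  pruned <- prune_spurs(m, min_branch = 5)
  expect_identical(count_endpoints(pruned$raster), 2L)
  expect_false(pruned$raster[3, 22])
  # spur-free path unchanged
  clean <- matrix(FALSE, 5, 30); clean[3, 2:29] <- TRUE
  expect_identical(prune_spurs(vessel_mask(clean, 1), 5)$raster, clean)
  # Y with both arms longer than min_branch is not over-pruned
  y <- matrix(FALSE, 15, 15)
  y[8, 2:8] <- TRUE
  for (k in 1:6) { y[8 - k, 8 + k] <- TRUE; y[8 + k, 8 + k] <- TRUE }
  ypr <- prune_spurs(vessel_mask(y, 1), min_branch = 3)
  expect_identical(ypr$raster, y)
  # idempotence
  expect_identical(prune_spurs(pruned, min_branch = 5)$raster, pruned$raster)
  # pruning everything is an error
  star <- matrix(FALSE, 40, 40)
  star[20, 16:24] <- TRUE; star[16:24, 20] <- TRUE
  expect_error(prune_spurs(vessel_mask(star, 1), min_branch = 100), "entire")
})

test_that("extract_path orders pixels along the longest geodesic", {
  ras <- matrix(FALSE, 5, 25)
  ras[3, 2:22] <- TRUE
  cl <- extract_path(vessel_mask(ras, 0.5))
  expect_equal(nrow(cl), 21)
  expect_equal(vessel_length(cl), 10)
  # L-shape traverses the corner without duplicates; the geodesic takes
  # the diagonal shortcut at the corner (16 of the 17 pixels)
  L <- matrix(FALSE, 12, 12)
  L[2:10, 2] <- TRUE; L[10, 3:10] <- TRUE
  clL <- extract_path(vessel_mask(L, 1))
  expect_equal(nrow(clL), 16)
  expect_identical(anyDuplicated(as.matrix(clL)), 0L)
  steps <- diff(as.matrix(clL))
  expect_true(all(abs(steps) <= 1))              # 8-adjacent traversal
  # two components error with the count
  two <- matrix(FALSE, 5, 12)
  two[2, 2:4] <- TRUE; two[4, 8:10] <- TRUE
  expect_error(extract_path(vessel_mask(two, 1)), "2 components")
})

test_that("extract_path is invariant to mask translation", {
  gc <- generate_curve(curve_spec("sinusoid", 15, amplitude = 1.5,
                                  wavelength = 7.5))
  m1 <- rasterize_curve(gc$centerline, spacing = 0.3)
  shifted <- centerline(sweep(as.matrix(gc$centerline), 2, c(-40, 25)))
  m2 <- rasterize_curve(shifted, spacing = 0.3)
  p1 <- as.matrix(extract_path(skeletonize(m1)))
  p2 <- as.matrix(extract_path(skeletonize(m2)))
  expect_equal(sweep(p2, 2, p2[1, ]), sweep(p1, 2, p1[1, ]),
               tolerance = 1e-9)
})

test_that("round trip recovers analytic arc length within 3% at fine spacing", {
  for (spec in list(curve_spec("circular_arc", 20, arc_angle = 2.2),
                    curve_spec("sinusoid", 20, amplitude = 2, wavelength = 10),
                    curve_spec("spline", 20, seed = 4, wiggle = 1.5))) {
    gc <- generate_curve(spec)
    cl <- mask_to_centerline(rasterize_curve(gc$centerline, spacing = 0.35))
    expect_equal(vessel_length(cl), gc$ground_truth$arc_length,
                 tolerance = 0.03)
  }
})

test_that("anisotropic spacing converts pixels to mm per axis", {
  ras <- matrix(FALSE, 5, 11)
  ras[3, 2:10] <- TRUE                  # 8 column steps
  cl <- extract_path(vessel_mask(ras, spacing = c(0.44, 0.66)))
  expect_equal(vessel_length(cl), 8 * 0.66)
  rasv <- matrix(FALSE, 11, 5)
  rasv[2:10, 3] <- TRUE                 # 8 row steps
  clv <- extract_path(vessel_mask(rasv, spacing = c(0.44, 0.66)))
  expect_equal(vessel_length(clv), 8 * 0.44)
})
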