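rect_roi <- function(r0, c0, r1, c1) {
  roi_polygon(rbind(c(r0, c0), c(r1, c1)))
}

test_that("mean_gray computes the arithmetic mean over the ROI", {
  expect_equal(mean_gray(matrix(42, 5, 5), rect_roi(0, 0, 5, 5)), 42)
  img <- matrix(c(10, 20, 30, 40), 2, 2)
  expect_equal(mean_gray(img, rect_roi(0, 0, 2, 2)), 25)
})

test_that("mean_gray and area_fraction match per-pixel loop oracles exactly", {
  for (seed in 1:20) {
    set.seed(seed)
    img <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
    roi <- rect_roi(1, 1, 7, 7)
    mask <- rasterize_roi(roi, c(8, 8))
    expect_equal(mean_gray(img, roi), oracle_mean_gray(img, mask),
                 tolerance = 1e-12)
    expect_equal(area_fraction(img, roi, threshold_fixed(128)),
                 oracle_area_fraction(img, mask, 128))
  }
  # synthetic scene, planted node
  g <- generate_smi_scene(default_smi_spec(0.3, 0.1, speckle_sd = 5,
                                           seed = 7))
  p <- test_polygons()
  mask <- rasterize_roi(p$node, dim(g$image))
  expect_equal(mean_gray(g$image, p$node),
               oracle_mean_gray(g$image, mask), tolerance = 1e-9)
})

test_that("area_fraction covers its threshold edge cases", {
  zero <- matrix(0, 4, 4)
  roi <- rect_roi(0, 0, 4, 4)
  expect_equal(area_fraction(zero, roi, threshold_fixed(1)), 0)
  img <- matrix(c(0, 0, 200, 200), 2, 2)
  expect_equal(area_fraction(img, rect_roi(0, 0, 2, 2),
                             threshold_fixed(100)), 0.5)
  # threshold 0 -> everything positive; 256 -> nothing
  set.seed(3)
  rnd <- matrix(sample(0:255, 100, replace = TRUE), 10, 10)
  r10 <- rect_roi(0, 0, 10, 10)
  expect_equal(area_fraction(rnd, r10, threshold_fixed(0)), 1)
  expect_equal(area_fraction(rnd, r10, threshold_fixed(256)), 0)
  # monotone non-decreasing as the threshold decreases
  af <- vapply(seq(256, 0, by = -32), function(k) {
    area_fraction(rnd, r10, threshold_fixed(k))
  }, numeric(1))
  expect_true(all(diff(af) >= 0))
})

test_that("isodata threshold finds the intermeans fixed point", {
  expect_identical(resolve_threshold(matrix(0, 2, 2), matrix(TRUE, 2, 2),
                                     threshold_fixed(100)), 100L)
  bim <- matrix(rep(c(20, 200), 50), 10, 10)
  expect_identical(resolve_threshold(bim, matrix(TRUE, 10, 10),
                                     threshold_isodata()), 110L)
  for (seed in c(5, 6, 7)) {
    set.seed(seed)
    img <- matrix(sample(0:255, 64 * 64, replace = TRUE), 64, 64)
    t_pkg <- resolve_threshold(img, matrix(TRUE, 64, 64),
                               threshold_isodata())
    expect_lte(abs(t_pkg - oracle_isodata(as.vector(img))), 1)
  }
  expect_warning(
    t_const <- resolve_threshold(matrix(7, 3, 3), matrix(TRUE, 3, 3),
                                 threshold_isodata()),
    "constant")
  expect_identical(t_const, 8L)
})

test_that("quotient handles zero parenchyma as flagged-undefined", {
  expect_equal(quotient(17.3, 17.3), 1)
  expect_equal(quotient(0, 5), 0)
  expect_equal(quotient(26, 13), 2)
  expect_true(is.na(quotient(3, 0)))
  expect_error(quotient(1, -1), class = "vq_domain_error")
})

scene_frames <- function(node_frac, par_frac, seeds, speckle_sd = 0) {
  lapply(seeds, function(s) {
    generate_smi_scene(default_smi_spec(node_frac, par_frac,
                                        speckle_sd = speckle_sd,
                                        seed = s))$image
  })
}

profile_rois <- function() {
  p <- test_polygons()
  list(A_long = p$node, B_long = p$par,
       A_cross = roi_polygon(p$node$vertices, role = "node_A",
                             plane = "cross"),
       B_cross = roi_polygon(p$par$vertices, role = "parenchyma_B",
                             plane = "cross"),
       total_node = roi_polygon(p$node$vertices, role = "total_node"),
       total_parenchyma = roi_polygon(p$par$vertices,
                                      role = "total_parenchyma"))
}

test_that("compute_profile reproduces planted quotients and degenerate cases", {
  rois <- profile_rois()
  # identical planting in node and parenchyma -> all quotients 1
  fr <- scene_frames(0.25, 0.25, 1:5)
  imgs <- list(longitudinal = fr[1:2], cross = fr[3:4], total = fr[[5]])
  prof <- compute_profile(imgs, rois, threshold_fixed(100))
  expect_equal(prof$quotient_longitudinal, 1, tolerance = 0.02)
  expect_equal(prof$quotient_longitudinal_area_fraction, 1,
               tolerance = 1e-12)
  expect_equal(prof$quotient_all_area_fraction, 1, tolerance = 1e-12)

  # planted 0.4 node vs 0.2 parenchyma -> area-fraction quotient 2
  fr <- scene_frames(0.4, 0.2, 11:15)
  imgs <- list(longitudinal = fr[1:2], cross = fr[3:4], total = fr[[5]])
  prof <- compute_profile(imgs, rois, threshold_fixed(100))
  npx <- sum(rasterize_roi(rois$A_long, dim(fr[[1]])))
  expect_equal(prof$quotient_longitudinal_area_fraction, 2,
               tolerance = 2 / (0.2 * npx))
  expect_equal(prof$quotient_cross_area_fraction, 2,
               tolerance = 2 / (0.2 * npx))

  # no flow anywhere -> fractions 0, area-fraction quotients undefined
  fr <- scene_frames(0, 0, 21:25)
  imgs <- list(longitudinal = fr[1:2], cross = fr[3:4], total = fr[[5]])
  prof <- compute_profile(imgs, rois, threshold_fixed(100))
  expect_equal(prof$roi_longitudinal_area_fraction, 0)
  expect_true(is.na(prof$quotient_longitudinal_area_fraction))
  expect_true(is.na(prof$quotient_all_area_fraction))
  # gray-value quotients still defined (background is nonzero)
  expect_false(is.na(prof$quotient_longitudinal))
})

test_that("frame averaging is idempotent on duplicated frames", {
  rois <- profile_rois()
  f <- scene_frames(0.3, 0.15, 31)[[1]]
  imgs <- list(longitudinal = list(f, f), cross = list(f, f), total = f)
  prof2 <- compute_profile(imgs, rois, threshold_fixed(100))
  one_mg <- mean_gray(f, rois$A_long)
  expect_identical(prof2$roi_longitudinal, one_mg)
  expect_identical(prof2$roi_cross, one_mg)
})

test_that("compute_profile validates its inputs", {
  rois <- profile_rois()
  f <- scene_frames(0.2, 0.2, 41)[[1]]
  expect_error(compute_profile(list(longitudinal = list(f), cross = list(f, f),
                                    total = f), rois),
               class = "vq_input_error")
  expect_error(compute_profile(list(longitudinal = list(f, f),
                                    cross = list(f, f), total = f),
                               rois[-1]),
               class = "vq_input_error")
  # mismatched ROI-B size triggers the matching warning
  rois$B_long <- roi_polygon(rbind(c(10, 70), c(30, 90)),
                             role = "parenchyma_B")
  expect_warning(compute_profile(list(longitudinal = list(f, f),
                                      cross = list(f, f), total = f),
                                 rois, threshold_fixed(100)),
                 "ROI-B")
})
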