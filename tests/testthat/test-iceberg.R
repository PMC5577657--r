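test_that("single-voxel shells are Chebyshev balls minus the centre", {
  m <- array(FALSE, dim = c(11, 11, 11))
  m[6, 6, 6] <- TRUE
  expect_equal(sum(ring_shell(m, 1)$mask), 26)
  expect_equal(sum(ring_shell(m, 2)$mask), 5^3 - 1)
  expect_error(ring_shell(m, 0), ">= 1")
})

test_that("shells match brute-force distance thresholding", {
  set.seed(41)
  for (metric in c("chebyshev", "euclidean")) {
    for (i in 1:3) {
      d <- sample(12:18, 3, replace = TRUE)
      seed <- bf_dilate(rand_mask(d, 0.015), 1, 26)
      if (!any(seed)) next
      w <- sample(2:4, 1)
      sh <- suppressWarnings(ring_shell(seed, w, metric))
      expect_identical(sh$mask, bf_shell(seed, w, metric))
    }
  }
  sph <- make_sphere(51, 15)
  sh <- ring_shell(sph, 5, "euclidean")
  expect_identical(sh$mask, bf_shell(sph, 5, "euclidean"))
})

test_that("boundary clipping is measured and warned about", {
  m <- array(FALSE, dim = c(15, 15, 15))
  m[2:4, 7:9, 7:9] <- TRUE                      # near the z boundary
  expect_warning(sh <- ring_shell(m, 5), "clipped")
  expect_gt(sh$clipped_fraction, 0.05)
  centered <- array(FALSE, dim = c(15, 15, 15))
  centered[7:9, 7:9, 7:9] <- TRUE
  expect_equal(ring_shell(centered, 3)$clipped_fraction, 0)
})

test_that("ring composition saturates, vanishes and conserves counts", {
  sph <- make_sphere(41, 10)
  sh <- ring_shell(sph, 5)
  all_soil <- make_labels(sph, !sph, 20)
  expect_equal(ring_composition(sh, all_soil)$volume_effect_pct, 100)
  no_soil <- make_labels(sph, array(FALSE, dim = dim(sph)), 20)
  expect_equal(ring_composition(sh, no_soil)$volume_effect_pct, 0)

  set.seed(42)
  soil <- rand_mask(dim(sph), 0.4) & !sph
  lab <- make_labels(sph, soil, 20)
  comp <- ring_composition(sh, lab)
  vox_mm3 <- (20 / 1000)^3
  expect_equal(comp$soil_volume_mm3 / vox_mm3 + comp$air_volume_mm3 / vox_mm3 +
                 comp$stray_seed_voxels, sum(sh$mask))
})

test_that("half-space soil fills half the shell", {
  n <- 61
  sph <- make_sphere(n, 22)
  below <- array(rep(seq_len(n) >= (n + 1) / 2, n * n), dim = rep(n, 3))
  lab <- make_labels(sph, below & !sph, 20)
  sh <- ring_shell(sph, 5)
  expect_lt(abs(ring_composition(sh, lab)$volume_effect_pct - 50), 2)
})

test_that("surface effect: one face of contact against one soil voxel", {
  d <- c(11, 11, 11)
  seed <- array(FALSE, dim = d)
  seed[5:7, 5:7, 5:7] <- TRUE
  soil <- array(FALSE, dim = d)
  soil[4, 6, 6] <- TRUE                          # face-adjacent to the block
  lab <- make_labels(seed, soil, 20)
  ct <- compute_contact(seed, soil, 20, connectivity = 6)
  expect_equal(ct$contact_face_count, 1)
  sh <- ring_shell(seed, 1)
  se <- ring_surface_effect(sh, lab, ct)
  expect_false(se$undefined)
  expect_equal(se$surface_effect_pct, 100 / 6)

  empty <- make_labels(seed, array(FALSE, dim = d), 20)
  se0 <- ring_surface_effect(sh, empty, ct)
  expect_true(se0$undefined)
  expect_true(is.na(se0$surface_effect_pct))
})

test_that("homogeneous soil gives a change ratio of 100", {
  sph <- make_sphere(65, 12)
  lab <- make_labels(sph, !sph, 20)
  ct <- compute_contact(sph, array(!sph, dim = dim(sph)), 20)
  ib <- compute_iceberg(sph, lab, ct)
  expect_equal(ib$short$volume_effect_pct, 100)
  expect_equal(ib$long$volume_effect_pct, 100)
  expect_equal(ib$change_volume_pct, 100)
  expect_equal(ib$short$width_um, 100)
  expect_equal(ib$long$width_um, 300)
})

test_that("soil confined to short range inflates the change ratio", {
  sph <- make_sphere(61, 12)
  near <- ring_shell(sph, 5)$mask
  lab <- make_labels(sph, near, 20)
  ct <- compute_contact(sph, near, 20)
  ib <- compute_iceberg(sph, lab, ct)
  expect_equal(ib$short$volume_effect_pct, 100)
  expect_lt(ib$long$volume_effect_pct, 100)
  expect_gt(ib$change_volume_pct, 100)
})

test_that("shells nest and the annulus option excludes the short range", {
  sph <- make_sphere(51, 10)
  short <- ring_shell(sph, 5)
  long <- ring_shell(sph, 15)
  expect_true(all(long$mask[short$mask]))
  counts <- vapply(1:6, function(w) sum(ring_shell(sph, w)$mask), numeric(1))
  expect_true(all(diff(counts) > 0))

  lab <- make_labels(sph, !sph & long$mask, 20)
  ct <- compute_contact(sph, array(!sph & long$mask, dim = dim(sph)), 20)
  ib <- compute_iceberg(sph, lab, ct, annulus = TRUE)
  expect_equal(ib$long$shell_voxels, sum(long$mask) - sum(short$mask))
})
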