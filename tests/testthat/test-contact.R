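test_that("single-voxel dilation matches the structuring elements", {
  m <- array(FALSE, dim = c(7, 7, 7))
  m[4, 4, 4] <- TRUE
  expect_equal(sum(dilate_mask(m, 1, 26)), 27)
  expect_equal(sum(dilate_mask(m, 1, 18)), 19)
  expect_equal(sum(dilate_mask(m, 1, 6)), 7)
  expect_error(dilate_mask(m, 0, 26), ">= 1")
  expect_error(dilate_mask(m, 1, 10), "must be one of")
})

test_that("dilation equals the brute-force neighbourhood expansion", {
  set.seed(31)
  for (conn in c(6L, 18L, 26L)) {
    for (i in 1:4) {
      d <- sample(8:18, 3, replace = TRUE)
      m <- rand_mask(d, 0.08)
      if (!any(m)) next
      steps <- sample(1:2, 1)
      expect_identical(dilate_mask(m, steps, conn),
                       bf_dilate(m, steps, conn))
    }
  }
})

test_that("surface face enumeration matches closed forms and brute force", {
  m <- array(FALSE, dim = c(5, 5, 5))
  m[3, 3, 3] <- TRUE
  expect_equal(nrow(surface_faces(m)), 6)
  b <- array(FALSE, dim = c(6, 6, 6))
  b[3:4, 3:4, 3:4] <- TRUE
  expect_equal(nrow(surface_faces(b)), 24)
  set.seed(32)
  for (i in 1:4) {
    m <- rand_mask(c(15, 15, 15), 0.2)
    if (!any(m)) next
    got <- as.matrix(surface_faces(m))
    got <- got[order(got[, 1], got[, 2], got[, 3], got[, 4], got[, 5],
                     got[, 6]), , drop = FALSE]
    dimnames(got) <- NULL
    want <- bf_faces(m)
    dimnames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("surface areas: closed forms, mesh accuracy, face-count bias", {
  m <- array(FALSE, dim = c(5, 5, 5))
  m[3, 3, 3] <- TRUE
  expect_equal(surface_area(m, 20, "face_count"), 6 * 0.02^2)
  b <- array(FALSE, dim = c(6, 6, 6))
  b[3:4, 3:4, 3:4] <- TRUE
  expect_equal(surface_area(b, 20, "face_count"), 24 * 0.02^2)

  sph <- make_sphere(65, 25)
  truth <- 4 * pi * (25 * 0.02)^2
  expect_lt(abs(surface_area(sph, 20, "mesh") - truth) / truth, 0.03)
  ratio <- surface_area(sph, 20, "face_count") / truth
  expect_lt(abs(ratio - 1.5), 1.5 * 0.05)
})

test_that("contact saturates and vanishes where it must", {
  sph <- make_sphere(41, 12)
  soil <- !sph
  full <- compute_contact(sph, soil, 20)
  expect_equal(full$contact_pct, 100)
  expect_equal(full$contact_area_mm2, full$surface_area_mm2)
  none <- compute_contact(sph, array(FALSE, dim = dim(sph)), 20)
  expect_equal(none$contact_pct, 0)
  expect_equal(none$contact_area_mm2, 0)
})

test_that("half-space soil touches half the sphere surface", {
  n <- 61
  sph <- make_sphere(n, 25)
  below <- array(rep(seq_len(n) >= (n + 1) / 2, n * n), dim = rep(n, 3))
  soil <- below & !sph
  res <- compute_contact(sph, soil, 20)
  expect_lt(abs(res$contact_pct - 50), 3)
})

test_that("contact classification equals the brute-force face test", {
  set.seed(33)
  for (i in 1:6) {
    d <- sample(10:20, 3, replace = TRUE)
    seed <- bf_dilate(rand_mask(d, 0.02), 1, 26)  # a few small blobs
    soil <- rand_mask(d, 0.15) & !seed
    if (!any(seed) || !any(soil)) next
    conn <- sample(c(6L, 18L, 26L), 1)
    res <- compute_contact(seed, soil, 20, conn)
    want <- bf_contact_counts(seed, soil, conn)
    expect_equal(res$surface_face_count, unname(want["total"]))
    expect_equal(res$contact_face_count, unname(want["hit"]))
  }
})

test_that("adding soil never decreases contact", {
  set.seed(34)
  seed <- make_sphere(21, 6)
  soil <- rand_mask(dim(seed), 0.05) & !seed
  base <- compute_contact(seed, soil, 20)$contact_pct
  extra <- soil | (rand_mask(dim(seed), 0.05) & !seed)
  expect_gte(compute_contact(seed, extra, 20)$contact_pct, base)
  less <- soil
  less[which(less)[1:5]] <- FALSE
  expect_lte(compute_contact(seed, less, 20)$contact_pct, base)
})

test_that("contact is invariant under joint translation", {
  set.seed(35)
  d <- c(20, 20, 20)
  seed <- array(FALSE, dim = d); seed[8:11, 8:11, 8:11] <- TRUE
  soil <- rand_mask(d, 0.1) & !seed
  soil[1:4, , ] <- FALSE; soil[17:20, , ] <- FALSE
  soil[, 1:4, ] <- FALSE; soil[, 17:20, ] <- FALSE
  soil[, , 1:4] <- FALSE; soil[, , 17:20] <- FALSE
  ref <- compute_contact(seed, soil, 20)
  shift3 <- function(m, s) {
    out <- array(FALSE, dim = d)
    out[(1:16) + s[1], (1:16) + s[2], (1:16) + s[3]] <-
      m[1:16, 1:16, 1:16]
    out
  }
  for (s in list(c(2, 0, 1), c(0, 3, 0), c(1, 1, 1))) {
    moved <- compute_contact(shift3(seed, s), shift3(soil, s), 20)
    expect_equal(moved$contact_pct, ref$contact_pct)
    expect_equal(moved$surface_face_count, ref$surface_face_count)
  }
})

test_that("contact grows with dilation connectivity", {
  set.seed(36)
  for (i in 1:3) {
    seed <- make_sphere(25, 7)
    soil <- rand_mask(dim(seed), 0.07) & !seed
    p6 <- compute_contact(seed, soil, 20, 6)$contact_pct
    p18 <- compute_contact(seed, soil, 20, 18)$contact_pct
    p26 <- compute_contact(seed, soil, 20, 26)$contact_pct
    expect_lte(p6, p18)
    expect_lte(p18, p26)
  }
})

test_that("invalid contact inputs are rejected", {
  sph <- make_sphere(11, 3)
  expect_error(compute_contact(sph, sph, 20), "overlap")
  expect_error(compute_contact(sph, array(FALSE, dim = c(5, 5, 5)), 20),
               "same shape")
})
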