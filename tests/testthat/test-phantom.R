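test_that("cap phantoms carry the analytic contact fraction", {
  s90 <- phantom_spec(voxel_size_um = 100, seed_diameter_um = 3000,
                      soil_model = list(type = "spherical_cap",
                                        theta_deg = 90))
  expect_equal(generate_phantom(s90)$truth$analytic_contact_fraction, 0.5)
  s60 <- phantom_spec(voxel_size_um = 100, seed_diameter_um = 3000,
                      soil_model = list(type = "spherical_cap",
                                        theta_deg = 60))
  expect_equal(generate_phantom(s60)$truth$analytic_contact_fraction, 0.25)
})

test_that("generation is bit-reproducible for a fixed seed", {
  spec <- phantom_spec(voxel_size_um = 100, seed_diameter_um = 3000,
                       soil_model = list(type = "grain_packing",
                                         radii_um = c(250, 500),
                                         target_solid_fraction = 0.3),
                       rng_seed = 99)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth$labels$labels, b$truth$labels$labels)
  spec2 <- spec; spec2$rng_seed <- 100L
  expect_false(identical(generate_phantom(spec2)$volume$data,
                         a$volume$data))
})

test_that("grain packing reaches its target fraction", {
  region <- array(TRUE, dim = c(60, 60, 60))
  g <- pack_grains(region, radii_um = c(100, 500), voxel_size_um = 20,
                   target_solid_fraction = 0.30, rng_seed = 4)
  achieved <- attr(g, "achieved_fraction")
  expect_equal(achieved, sum(g) / length(g))
  expect_gte(achieved, 0.28)
  expect_lte(achieved, 0.32)

  empty <- pack_grains(region, c(100, 500), 20, 0, rng_seed = 4)
  expect_equal(sum(empty), 0)
  expect_error(pack_grains(region, c(100, 600), 20, 0.3),
               "sieve cap")
  expect_error(pack_grains(region, c(100, 500), 20, 0.9),
               "feasible range")
})

test_that("grains respect a rigid obstacle", {
  d <- c(40, 40, 40)
  obstacle <- make_sphere(40, 10, center = c(20, 20, 20))
  g <- pack_grains(!obstacle, radii_um = c(250, 500), voxel_size_um = 50,
                   target_solid_fraction = 0.2, obstacle = obstacle,
                   rng_seed = 5)
  expect_false(any(g & obstacle))
})

test_that("the star seed renders at the requested bounding box", {
  star <- star_seed(c(4000, 3000, 3000), points = 5, voxel_size_um = 20)
  expect_identical(dim(star), c(200L, 150L, 150L))
  # lobes span the cross-section up to tip digitisation (a wedge tip
  # narrower than a voxel carries no voxel centre)
  occ <- which(star, arr.ind = TRUE)
  expect_lte(min(occ[, 2]), 4); expect_gte(max(occ[, 2]), 147)
  expect_lte(min(occ[, 3]), 4); expect_gte(max(occ[, 3]), 147)
  expect_error(star_seed(c(4000, 80, 80), voxel_size_um = 20),
               "too small")
})

test_that("the star is one connected object with excess surface", {
  star <- star_seed(c(2000, 1500, 1500), points = 5, voxel_size_um = 20)
  comp <- seedcontact:::cpp_label(star, dim(star), 26L)
  expect_equal(max(comp), 1)
  # volume-equivalent sphere has strictly less face-count surface
  r_eq <- (3 * sum(star) / (4 * pi))^(1 / 3)
  n <- 2 * ceiling(r_eq) + 9
  sph <- make_sphere(n, r_eq)
  expect_gt(surface_area(star, 20, "face_count"),
            surface_area(sph, 20, "face_count"))
})

test_that("a seed without ring clearance is rejected", {
  expect_error(phantom_spec(grid_shape = c(60, 60, 60), voxel_size_um = 50,
                            seed_diameter_um = 3000,
                            soil_model = list(type = "solid")),
               "does not fit")
})

test_that("phantom grey levels support the full pipeline recovery", {
  spec <- phantom_spec(voxel_size_um = 80, seed_diameter_um = 4000,
                       soil_model = list(type = "spherical_cap",
                                         theta_deg = 90),
                       blur_sigma_voxels = 0.5, rng_seed = 6)
  ph <- generate_phantom(spec)
  lab <- segment_phases(ph$volume)
  seed <- select_seed(lab)
  closed <- close_seed(seed, 2, 80)
  soil <- array(lab$labels == 1L & !closed$closed_mask,
                dim = dim(lab$labels))
  res <- compute_contact(closed$closed_mask, soil, 80)
  expect_lt(abs(res$contact_pct -
                  100 * ph$truth$analytic_contact_fraction), 5)
})

test_that("generation-time shell tallies match the measured shells", {
  spec <- phantom_spec(voxel_size_um = 80, seed_diameter_um = 4000,
                       soil_model = list(type = "grain_packing",
                                         target_solid_fraction = 0.3),
                       rng_seed = 7)
  ph <- generate_phantom(spec)
  lab <- ph$truth$labels
  seed <- array(lab$labels == 2L, dim = dim(lab$labels))
  sh5 <- ring_shell(seed, 5)
  comp <- ring_composition(sh5, lab)
  tallies <- ph$truth$shell_soil_counts[1:5, ]
  expect_equal(comp$soil_volume_mm3 / (0.08^3), sum(tallies$soil))
  expect_equal(comp$air_volume_mm3 / (0.08^3), sum(tallies$air))
})
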