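#' Specify a synthetic seed-in-soil phantom
#'
#' Parametric description of a CT-like scene with known ground truth, used
#' to validate the contact and ring metrics in the absence of deposited scan
#' data. Defaults follow the imaged system: isotropic 20 um voxels, a 4 mm
#' spherical seed (the pelleted-and-coated form) or a 4 x 3 x 3 mm
#' star-shaped prism (the naked seed), granular soil sieved below 1 mm, and
#' greyscale modes air < seed < mineral soil.
#'
#' @param grid_shape Integer triple `(nz, ny, nx)`; when `NULL` a grid is
#'   sized to hold the seed with 20 voxels of clearance on every side.
#' @param voxel_size_um Isotropic voxel size, default 20.
#' @param seed_shape `"sphere"` or `"star"`.
#' @param seed_diameter_um Sphere diameter (default 4000).
#' @param star_dims_um Star prism bounding box `(z, y, x)` in um
#'   (default 4000 x 3000 x 3000).
#' @param star_points Number of star lobes (default 5).
#' @param cavity Optional `list(radius_um, crack_width_um = 0)` carving an
#'   internal spherical air space (a germinating, opening seed) plus an
#'   optional open channel of the given width from the cavity to the
#'   exterior.
#' @param soil_model One of `list(type = "solid")` (all non-seed voxels are
#'   soil), `list(type = "spherical_cap", theta_deg)` /
#'   `list(type = "half_space", theta_deg)` (soil fills the half-space below
#'   the plane cutting the seed sphere at polar angle `theta_deg` from the
#'   contact pole; analytic contact fraction `(1 - cos(theta)) / 2`), or
#'   `list(type = "grain_packing", radii_um = c(250, 500),
#'   target_solid_fraction = 0.35, overlap_tolerance = 0.25)`.
#' @param grey_levels `list(air, seed, soil, sd)`: per-phase greyscale means
#'   and the Gaussian noise standard deviation (8-bit scale; defaults 10,
#'   120, 220, sd 8, giving a clean three-mode histogram).
#' @param blur_sigma_voxels Gaussian blur applied after noise to emulate
#'   partial-volume averaging (default 0).
#' @param seed_center_frac Fractional seed position `(z, y, x)` in the grid,
#'   default centred `c(0.5, 0.5, 0.5)`; off-centre placement emulates field
#'   cores where the seed lies near the column edge.
#' @param rng_seed Integer seed making generation fully deterministic.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = NULL, voxel_size_um = 20,
                         seed_shape = c("sphere", "star"),
                         seed_diameter_um = 4000,
                         star_dims_um = c(4000, 3000, 3000),
                         star_points = 5L,
                         cavity = NULL,
                         soil_model = list(type = "grain_packing",
                                           radii_um = c(250, 500),
                                           target_solid_fraction = 0.35),
                         grey_levels = list(air = 10, seed = 120, soil = 220,
                                            sd = 8),
                         blur_sigma_voxels = 0,
                         seed_center_frac = c(0.5, 0.5, 0.5),
                         rng_seed = 1L) {
  seed_shape <- match.arg(seed_shape)
  voxel_size_um <- check_voxel_size(voxel_size_um)
  vs <- voxel_size_um
  seed_extent <- if (seed_shape == "sphere")
    rep(ceiling(seed_diameter_um / vs), 3) else round(star_dims_um / vs)
  clearance <- 20L
  if (is.null(grid_shape))
    grid_shape <- as.integer(seed_extent + 2L * clearance)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    stop("`grid_shape` must be a positive integer triple", call. = FALSE)
  margin <- pmin(seed_center_frac, 1 - seed_center_frac) * grid_shape -
    seed_extent / 2
  if (any(margin < 15))
    stop(paste0("seed does not fit: long-range ring needs >= 15 voxels of ",
                "clearance to every grid boundary"), call. = FALSE)
  if (identical(soil_model$type, "grain_packing")) {
    radii <- soil_model$radii_um
    if (is.null(radii)) radii <- c(250, 500)
    if (max(radii) * 2 > 1000)
      stop("grain diameter exceeds the 1 mm sieve cap", call. = FALSE)
    soil_model$radii_um <- radii
  }
  if (soil_model$type %in% c("spherical_cap", "half_space") &&
      is.null(soil_model$theta_deg))
    stop("`soil_model$theta_deg` is required for cap/half-space soil",
         call. = FALSE)
  structure(list(grid_shape = grid_shape, voxel_size_um = vs,
                 seed_shape = seed_shape,
                 seed_diameter_um = seed_diameter_um,
                 star_dims_um = star_dims_um,
                 star_points = as.integer(star_points),
                 cavity = cavity, soil_model = soil_model,
                 grey_levels = grey_levels,
                 blur_sigma_voxels = blur_sigma_voxels,
                 seed_center_frac = seed_center_frac,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

# squared distance of every voxel centre to a point (voxel coordinates)
dist_sq_grid <- function(d, center) {
  z2 <- (seq_len(d[1]) - center[1])^2
  y2 <- (seq_len(d[2]) - center[2])^2
  x2 <- (seq_len(d[3]) - center[3])^2
  outer(outer(z2, y2, "+"), x2, "+")
}

sphere_mask <- function(d, center, radius_vox) {
  array(dist_sq_grid(d, center) <= radius_vox^2, dim = d)
}

#' Generate a synthetic CT phantom
#'
#' Renders the scene described by a [phantom_spec()]: digitises the seed
#' (and optional internal cavity plus open crack), lays down the soil model,
#' assigns per-phase greyscale means, adds Gaussian noise and optional blur.
#' The ground truth is recorded before any degradation. Generation is
#' bit-reproducible for a fixed `rng_seed`.
#'
#' @param spec A [phantom_spec()].
#' @return A list with `volume` (a [grey_volume()]) and `truth` (class
#'   `phantom_truth`): `labels` (a [phase_label_map()]),
#'   `analytic_contact_fraction` (for cap/half-space sphere scenes, else
#'   `NA`), `shell_soil_counts` (per-Chebyshev-distance soil/air voxel
#'   tallies out to 15 voxels), `solid_seed_voxels` (cavity-free seed voxel
#'   count) and `achieved_solid_fraction` (grain packing only).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  vs <- spec$voxel_size_um
  center <- spec$seed_center_frac * d + 0.5
  r_vox <- spec$seed_diameter_um / 2 / vs
  if (spec$seed_shape == "sphere") {
    seed_solid <- sphere_mask(d, center, r_vox)
  } else {
    star <- star_seed(spec$star_dims_um, spec$star_points, vs)
    seed_solid <- array(FALSE, dim = d)
    off <- round(center - dim(star) / 2)
    seed_solid[off[1] + seq_len(dim(star)[1]) - 1L,
               off[2] + seq_len(dim(star)[2]) - 1L,
               off[3] + seq_len(dim(star)[3]) - 1L] <- star
  }
  seed <- seed_solid
  if (!is.null(spec$cavity)) {
    cav_r <- spec$cavity$radius_um / vs
    seed <- seed & !sphere_mask(d, center, cav_r)
    cw <- spec$cavity$crack_width_um
    if (!is.null(cw) && cw > 0) {
      half_w <- cw / vs / 2
      zc <- (seq_len(d[1]) - center[1])^2
      yc <- (seq_len(d[2]) - center[2])^2
      tube2 <- outer(zc, yc, "+")  # squared radial distance from the x-axis
      crack <- array(rep(tube2 <= half_w^2, d[3]), dim = d)
      xs <- array(rep(seq_len(d[3]) >= center[3], each = d[1] * d[2]),
                  dim = d)
      seed <- seed & !(crack & xs)
    }
  }
  sm <- spec$soil_model
  soil <- if (sm$type == "solid") {
    !seed
  } else if (sm$type %in% c("spherical_cap", "half_space")) {
    theta <- sm$theta_deg * pi / 180
    zplane <- center[1] + r_vox * cos(theta)
    below <- array(rep(seq_len(d[1]) >= zplane, prod(d[2:3])), dim = d)
    below & !seed
  } else if (sm$type == "grain_packing") {
    tol <- if (is.null(sm$overlap_tolerance)) 0.25 else sm$overlap_tolerance
    pack_grains(!seed, radii_um = sm$radii_um, voxel_size_um = vs,
                target_solid_fraction = sm$target_solid_fraction,
                overlap_tolerance = tol, obstacle = seed,
                rng_seed = spec$rng_seed)
  } else stop("unknown soil model: ", sm$type, call. = FALSE)
  achieved <- attr(soil, "achieved_fraction")
  if (is.null(achieved)) achieved <- NA_real_
  if (sm$type == "grain_packing" &&
      achieved < sm$target_solid_fraction - 0.02)
    stop(sprintf("solid fraction %.2f unachievable within the attempt budget (reached %.3f)",
                 sm$target_solid_fraction, achieved), call. = FALSE)
  labels <- array(PHASE_AIR, dim = d)
  labels[soil] <- PHASE_SOIL
  labels[seed] <- PHASE_SEED
  lmap <- phase_label_map(labels, vs)
  gl <- spec$grey_levels
  means <- c(gl$air, gl$soil, gl$seed)[labels + 1L]
  grey <- with_rng_seed(spec$rng_seed + 1L,
                        means + rnorm(length(means), 0, gl$sd))
  grey <- array(grey, dim = d)
  if (spec$blur_sigma_voxels > 0)
    grey <- array(cpp_gauss_blur(grey, d, spec$blur_sigma_voxels), dim = d)
  frac <- NA_real_
  if (spec$seed_shape == "sphere" &&
      sm$type %in% c("spherical_cap", "half_space"))
    frac <- (1 - cos(sm$theta_deg * pi / 180)) / 2
  if (sm$type == "solid") frac <- 1
  shell_counts <- shell_soil_counts(seed, labels, 15L)
  truth <- structure(list(labels = lmap,
                          analytic_contact_fraction = frac,
                          shell_soil_counts = shell_counts,
                          solid_seed_voxels = sum(seed_solid),
                          achieved_solid_fraction = achieved),
                     class = "phantom_truth")
  list(volume = grey_volume(grey, vs, provenance = "synthetic phantom"),
       truth = truth)
}

# soil/air tallies of the Chebyshev distance-d ring, d = 1..max_d
shell_soil_counts <- function(seed, labels, max_d) {
  d <- dim(seed)
  prev <- seed
  out <- data.frame(distance = seq_len(max_d), soil = NA_integer_,
                    air = NA_integer_, seed = NA_integer_)
  for (k in seq_len(max_d)) {
    cur <- array(cpp_dilate(prev, d, 1L, 26L), dim = d)
    ring <- cur & !prev
    lab <- labels[ring]
    out$soil[k] <- sum(lab == PHASE_SOIL)
    out$air[k] <- sum(lab == PHASE_AIR)
    out$seed[k] <- sum(lab == PHASE_SEED)
    prev <- cur
  }
  out
}

#' Pack spherical grains into a region
#'
#' Random sequential addition of spheres with radii drawn uniformly from
#' `radii_um` until the target solid fraction of the region is reached (or
#' the attempt budget is exhausted, in which case the achieved fraction is
#' returned with a warning). A configurable centre-distance overlap
#' tolerance lets grains interpenetrate slightly, mimicking touching and
#' merged aggregates; grain voxels are clipped to the region. Grain
#' diameters above 1 mm violate the sieve cap and are rejected.
#'
#' @param region 3-D logical array of allowed voxels.
#' @param radii_um Radius range `c(min, max)` in um (a single value gives
#'   monodisperse grains).
#' @param voxel_size_um Isotropic voxel size in um.
#' @param target_solid_fraction Target grain volume fraction of the region,
#'   in `[0, 0.64]`.
#' @param overlap_tolerance Fraction of the radius sum by which two grain
#'   centres may come closer than contact (default 0.25).
#' @param obstacle Optional 3-D logical array of a rigid body (the seed):
#'   grains may touch it but not penetrate it, so narrow concavities that no
#'   grain fits into stay empty, as they do around a real angular seed.
#'   Without an obstacle, grains are simply clipped to `region`.
#' @param max_attempts Placement attempt budget (default 20000).
#' @param rng_seed Optional integer seed; when given, packing runs on a
#'   private RNG stream.
#' @return A 3-D logical grain mask with attribute `achieved_fraction`.
#' @export
pack_grains <- function(region, radii_um, voxel_size_um,
                        target_solid_fraction, overlap_tolerance = 0.25,
                        obstacle = NULL, max_attempts = 20000L,
                        rng_seed = NULL) {
  check_mask(region, "region")
  vs <- check_voxel_size(voxel_size_um)
  if (length(radii_um) == 1L) radii_um <- rep(radii_um, 2)
  if (any(radii_um <= 0)) stop("grain radii must be positive", call. = FALSE)
  if (max(radii_um) * 2 > 1000)
    stop("grain diameter exceeds the 1 mm sieve cap", call. = FALSE)
  if (target_solid_fraction < 0 || target_solid_fraction > 0.64)
    stop("target solid fraction outside the feasible range [0, 0.64]",
         call. = FALSE)
  obs_dist <- NULL
  if (!is.null(obstacle) && any(obstacle))
    obs_dist <- sqrt(array(cpp_edt_sq(obstacle, dim(obstacle)),
                           dim = dim(obstacle)))
  run <- function() rsa_pack(region, radii_um / vs, target_solid_fraction,
                             overlap_tolerance, max_attempts, obs_dist)
  if (is.null(rng_seed)) run() else with_rng_seed(rng_seed, run())
}

rsa_pack <- function(region, radii_vox, target, tol, max_attempts,
                     obs_dist = NULL) {
  d <- dim(region)
  n_region <- sum(region)
  mask <- array(FALSE, dim = d)
  if (target == 0) {
    attr(mask, "achieved_fraction") <- 0
    return(mask)
  }
  env <- new.env()
  env$centers <- matrix(numeric(0), 0, 3)
  env$radii <- numeric(0)
  env$grain_voxels <- 0
  try_place <- function(ctr, r) {
    vox <- round(ctr)
    if (any(vox < 1L) || any(vox > d)) return(FALSE)
    if (!region[vox[1], vox[2], vox[3]]) return(FALSE)
    # rigid-body exclusion: the grain may touch the obstacle (half-voxel
    # slack so flush contact survives digitisation) but not penetrate it
    if (!is.null(obs_dist) && obs_dist[vox[1], vox[2], vox[3]] < r - 0.5)
      return(FALSE)
    if (nrow(env$centers) > 0) {
      dd <- sqrt(colSums((t(env$centers) - ctr)^2))
      if (any(dd < (1 - tol) * (env$radii + r))) return(FALSE)
    }
    env$centers <- rbind(env$centers, ctr)
    env$radii <- c(env$radii, r)
    lo <- pmax(1, floor(ctr - r))
    hi <- pmin(d, ceiling(ctr + r))
    zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
    d2 <- outer(outer((zi - ctr[1])^2, (yi - ctr[2])^2, "+"),
                (xi - ctr[3])^2, "+")
    add <- d2 <= r^2 & region[zi, yi, xi] & !mask[zi, yi, xi]
    mask[zi, yi, xi] <<- mask[zi, yi, xi] | add
    env$grain_voxels <- env$grain_voxels + sum(add)
    TRUE
  }
  # settled-contact phase: around a rigid obstacle, soil poured into the
  # column comes to rest against it, so a jammed layer of tangent grains is
  # laid down first; a grain lands only where it fits, leaving concavities
  # narrower than a grain empty
  if (!is.null(obs_dist)) {
    bins <- seq(radii_vox[1], radii_vox[2], length.out = 8L)
    band_idx <- lapply(bins, function(r)
      which(region & abs(obs_dist - r) <= 0.5))
    n_contact_attempts <- min(4000L, max_attempts %/% 2L)
    for (i in seq_len(n_contact_attempts)) {
      if (env$grain_voxels / n_region >= target) break
      b <- sample.int(length(bins), 1L)
      if (length(band_idx[[b]]) == 0) next
      vox <- arrayInd(sample(band_idx[[b]], 1L), d)
      try_place(as.numeric(vox) + runif(3, -0.5, 0.5), bins[b])
    }
  }
  attempts <- 0L
  while (env$grain_voxels / n_region < target && attempts < max_attempts) {
    attempts <- attempts + 1L
    try_place(runif(3, 1, d), runif(1, radii_vox[1], radii_vox[2]))
  }
  frac <- env$grain_voxels / n_region
  if (frac < target - 0.02)
    warning(sprintf("packing attempts exhausted at solid fraction %.3f (target %.3f)",
                    frac, target), call. = FALSE)
  attr(mask, "achieved_fraction") <- frac
  mask
}

#' Digitise a star-shaped seed
#'
#' A star-polygon prism emulating the naked sugar beet seed: a star
#' cross-section (default 5 lobes, inner/outer radius ratio 0.45) in the
#' `(y, x)` plane, extruded along `z`, rescaled so the voxelised bounding
#' box matches `dims_um` exactly. The spiky outline gives it a strictly
#' larger surface than the volume-equivalent sphere.
#'
#' @param dims_um Bounding box `(z, y, x)` in um (default
#'   4000 x 3000 x 3000).
#' @param points Number of lobes.
#' @param voxel_size_um Isotropic voxel size in um.
#' @param inner_ratio Inner/outer vertex radius ratio of the star polygon.
#' @return A 3-D logical array of dimensions `round(dims_um /
#'   voxel_size_um)`.
#' @export
star_seed <- function(dims_um = c(4000, 3000, 3000), points = 5L,
                      voxel_size_um = 20, inner_ratio = 0.45) {
  vs <- check_voxel_size(voxel_size_um)
  dims <- round(dims_um / vs)
  if (any(dims < 6)) stop("dims too small to render lobes", call. = FALSE)
  p <- as.integer(points)
  if (p < 3L) stop("`points` must be >= 3", call. = FALSE)
  k <- seq_len(2L * p) - 1L
  ang <- k * pi / p - pi / 2
  rad <- ifelse(k %% 2L == 0L, 1, inner_ratio)
  py <- rad * sin(ang)
  px <- rad * cos(ang)
  # rescale the polygon so its bounding box fills the requested cross-section
  fit <- function(v, n) (v - min(v)) / diff(range(v)) * (n - 1) + 1
  py <- fit(py, dims[2]); px <- fit(px, dims[3])
  yy <- matrix(rep(seq_len(dims[2]), dims[3]), dims[2], dims[3])
  xx <- matrix(rep(seq_len(dims[3]), each = dims[2]), dims[2], dims[3])
  inside <- matrix(FALSE, dims[2], dims[3])
  m <- length(py)
  j <- m
  for (i in seq_len(m)) {  # even-odd ray casting
    cross <- ((py[i] > yy) != (py[j] > yy)) &
      (xx < (px[j] - px[i]) * (yy - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, cross)
    j <- i
  }
  array(rep(inside, each = dims[1]), dim = dims)
}
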