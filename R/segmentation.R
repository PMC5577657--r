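#' Segment a CT volume into air, soil and seed phases
#'
#' Splits the greyscale range at two cut points `t1 < t2` into three bands
#' and assigns each band a phase. By default the darkest band is air, the
#' middle band the seed (organic material attenuates between air and mineral
#' soil) and the brightest band soil; `bands` overrides this mapping for
#' scans where, e.g., pellet material is brighter than the soil. When no
#' thresholds are supplied they are estimated by a 3-class Otsu criterion
#' (exhaustive two-cut maximisation of the between-class variance over a
#' 256-bin histogram).
#'
#' @param vol A [grey_volume()].
#' @param thresholds Optional numeric pair `(t1, t2)`, `t1 < t2`. A voxel
#'   with value `v` falls in band 1 if `v < t1`, band 2 if `t1 <= v < t2`,
#'   band 3 if `v >= t2`.
#' @param bands Character vector naming the phases of the three bands in
#'   increasing-intensity order; a permutation of
#'   `c("air", "seed", "soil")`.
#' @return A [phase_label_map()].
#' @export
segment_phases <- function(vol, thresholds = NULL,
                           bands = c("air", "seed", "soil")) {
  stopifnot(inherits(vol, "grey_volume"))
  if (!identical(sort(bands), c("air", "seed", "soil")))
    stop("`bands` must be a permutation of c(\"air\", \"seed\", \"soil\")",
         call. = FALSE)
  if (is.null(thresholds)) {
    thresholds <- otsu3(vol$data)
  } else {
    if (length(thresholds) != 2L || thresholds[1] >= thresholds[2])
      stop("thresholds must satisfy t1 < t2", call. = FALSE)
  }
  code <- c(air = PHASE_AIR, seed = PHASE_SEED, soil = PHASE_SOIL)[bands]
  band <- findInterval(vol$data, thresholds) + 1L  # 1, 2, 3
  labels <- array(code[band], dim = dim(vol$data))
  out <- phase_label_map(labels, vol$voxel_size_um)
  attr(out, "thresholds") <- as.numeric(thresholds)
  out
}

# 3-class Otsu: exhaustive search of two cut points maximising the
# between-class variance of a 256-bin histogram
otsu3 <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) stop("degenerate histogram", call. = FALSE)
  nb <- 256L
  bin <- pmin(nb - 1L, floor((x - rng[1]) / diff(rng) * nb))
  h <- tabulate(as.integer(bin) + 1L, nbins = nb)
  p <- h / sum(h)
  mids <- seq_len(nb) - 0.5
  cw <- cumsum(p)                 # class weight up to bin
  cm <- cumsum(p * mids)          # first moment up to bin
  best <- -Inf; cut <- c(NA, NA)
  for (i in 1:(nb - 2)) {
    w1 <- cw[i]
    if (w1 == 0) next
    m1 <- cm[i] / w1
    for (j in (i + 1):(nb - 1)) {
      w2 <- cw[j] - cw[i]
      w3 <- 1 - cw[j]
      if (w2 == 0 || w3 == 0) next
      m2 <- (cm[j] - cm[i]) / w2
      m3 <- (cm[nb] - cm[j]) / w3
      mg <- cm[nb]
      v <- w1 * (m1 - mg)^2 + w2 * (m2 - mg)^2 + w3 * (m3 - mg)^2
      if (v > best) { best <- v; cut <- c(i, j) }
    }
  }
  rng[1] + cut / nb * diff(rng)
}

#' Select the seed object from a label map
#'
#' Returns one 26-connected component of the seed phase as a boolean mask:
#' the component containing `marker` when given, otherwise the largest one
#' (ties broken by first-encountered component, which is deterministic).
#'
#' @param labels A [phase_label_map()].
#' @param marker Optional integer voxel coordinate `c(z, y, x)` lying on a
#'   seed-phase voxel.
#' @return A 3-D logical array.
#' @export
select_seed <- function(labels, marker = NULL) {
  stopifnot(inherits(labels, "phase_label_map"))
  seed <- labels$labels == PHASE_SEED
  if (!any(seed)) stop("no seed phase present", call. = FALSE)
  comp <- cpp_label(seed, dim(seed), 26L)
  if (!is.null(marker)) {
    marker <- as.integer(marker)
    if (length(marker) != 3L || any(marker < 1L) ||
        any(marker > dim(seed)))
      stop("marker out of bounds", call. = FALSE)
    id <- comp[marker[1], marker[2], marker[3]]
    if (id == 0L) stop("marker not on a seed-phase voxel", call. = FALSE)
  } else {
    id <- which.max(tabulate(comp[comp > 0L]))
  }
  array(comp == id, dim = dim(seed))
}

#' Close the seed mask
#'
#' A germinating seed opens and develops internal air space, so its raw
#' segmentation is not a closed object. This applies a morphological closing
#' with a Euclidean ball of the given radius (sealing narrow openings),
#' then fills every background component not connected to the grid boundary
#' (6-connected background, the standard dual of the 26-connected
#' foreground). The result is the closed surface used as the denominator of
#' the contact percentage.
#'
#' @param raw_mask 3-D logical seed mask.
#' @param closing_radius_voxels Ball radius in voxels; `0` skips the closing
#'   and only fills enclosed cavities.
#' @param voxel_size_um Isotropic voxel size in micrometres.
#' @param surface_method Estimator used for the reported surface change
#'   (see [surface_area()]).
#' @return An object of class `closed_seed_result` with fields `closed_mask`,
#'   `raw_mask`, `volume_increase_pct`, `surface_change_pct` (signed,
#'   negative = decrease), `cavity_filled_voxels`, `closing_added_voxels`
#'   and `voxel_size_um`.
#' @export
close_seed <- function(raw_mask, closing_radius_voxels = 3L, voxel_size_um,
                       surface_method = c("face_count", "mesh")) {
  check_mask(raw_mask, "raw_mask")
  surface_method <- match.arg(surface_method)
  voxel_size_um <- check_voxel_size(voxel_size_um)
  r <- closing_radius_voxels
  if (r < 0) stop("closing radius must be non-negative", call. = FALSE)
  if (2 * r + 1 > min(dim(raw_mask)))
    stop("closing element larger than the grid", call. = FALSE)
  closed <- if (r > 0) ball_closing(raw_mask, r) else raw_mask
  n_closing <- sum(closed) - sum(raw_mask)
  closed <- fill_holes(closed)
  n_fill <- sum(closed) - sum(raw_mask) - n_closing
  a_raw <- surface_area(raw_mask, voxel_size_um, surface_method)
  a_closed <- surface_area(closed, voxel_size_um, surface_method)
  structure(list(
    closed_mask = closed,
    raw_mask = raw_mask,
    volume_increase_pct = 100 * (sum(closed) - sum(raw_mask)) / sum(raw_mask),
    surface_change_pct = 100 * (a_closed - a_raw) / a_raw,
    cavity_filled_voxels = n_fill,
    closing_added_voxels = n_closing,
    voxel_size_um = voxel_size_um,
    surface_method = surface_method
  ), class = "closed_seed_result")
}

#' @export
print.closed_seed_result <- function(x, ...) {
  cat("<closed_seed_result>\n")
  cat(sprintf("  raw %d voxels -> closed %d voxels (+%.2f%% volume)\n",
              sum(x$raw_mask), sum(x$closed_mask), x$volume_increase_pct))
  cat(sprintf("  surface change %+.2f%% (%s); closing added %d, fill added %d voxels\n",
              x$surface_change_pct, x$surface_method,
              x$closing_added_voxels, x$cavity_filled_voxels))
  invisible(x)
}

# exact Euclidean-ball closing via two distance transforms:
# dilation = {d(v, mask) <= r}, erosion = {d(v, complement) > r}
ball_closing <- function(mask, r) {
  d <- dim(mask)
  dil <- array(cpp_edt_sq(mask, d) <= r^2, dim = d)
  comp <- !dil
  if (!any(comp)) return(array(TRUE, dim = d))
  array(cpp_edt_sq(comp, d) > r^2, dim = d)
}

# fill background components not connected to the grid boundary
# (6-connected background)
fill_holes <- function(mask) {
  d <- dim(mask)
  bg <- !mask
  if (!any(bg)) return(mask)
  lab <- cpp_label(bg, d, 6L)
  edge <- unique(c(lab[1, , ], lab[d[1], , ], lab[, 1, ], lab[, d[2], ],
                   lab[, , 1], lab[, , d[3]]))
  enclosed <- lab > 0L & !(lab %in% edge)
  out <- mask | enclosed
  array(out, dim = d)
}
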