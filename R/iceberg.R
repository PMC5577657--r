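#' Ring shell around the closed seed
#'
#' The set of non-seed voxels within `width_voxels` of the seed under the
#' chosen metric. With the default Chebyshev metric the shell is exactly the
#' difference between `width_voxels` iterations of the same 26-connected
#' +1-voxel dilation used for contact and the seed itself, so "5 voxels"
#' means five applications of that dilation; the Euclidean variant
#' thresholds an exact distance transform instead. Shells clipped by the
#' grid boundary are computed on the clipped domain and the lost portion is
#' reported as `clipped_fraction` (a warning is raised above 5%).
#'
#' @param seed_closed 3-D logical closed seed mask.
#' @param width_voxels Shell width in voxels (positive integer).
#' @param metric `"chebyshev"` or `"euclidean"`.
#' @return An object of class `ring_shell` with fields `mask`,
#'   `width_voxels`, `metric` and `clipped_fraction`.
#' @export
ring_shell <- function(seed_closed, width_voxels,
                       metric = c("chebyshev", "euclidean")) {
  check_mask(seed_closed, "seed_closed")
  metric <- match.arg(metric)
  w <- as.integer(width_voxels)
  if (length(w) != 1L || w < 1L) stop("`width_voxels` must be >= 1",
                                      call. = FALSE)
  mask <- shell_mask(seed_closed, w, metric)
  n <- sum(mask)
  clipped <- 0
  d <- dim(seed_closed)
  idx <- which(seed_closed, arr.ind = TRUE)
  margin <- min(idx - 1L, sweep(-idx, 2, d, "+"))
  if (margin < w) {
    pad <- array(FALSE, dim = d + 2L * w)
    pad[w + seq_len(d[1]), w + seq_len(d[2]), w + seq_len(d[3])] <-
      seed_closed
    n_full <- sum(shell_mask(pad, w, metric))
    clipped <- 1 - n / n_full
    if (clipped > 0.05)
      warning(sprintf("ring shell clipped by the grid boundary: %.1f%% lost",
                      100 * clipped), call. = FALSE)
  }
  structure(list(mask = mask, width_voxels = w, metric = metric,
                 clipped_fraction = clipped),
            class = "ring_shell")
}

shell_mask <- function(seed, w, metric) {
  d <- dim(seed)
  if (metric == "chebyshev") {
    array(cpp_dilate(seed, d, w, 26L) & !seed, dim = d)
  } else {
    array(cpp_edt_sq(seed, d) <= w^2 & !seed, dim = d)
  }
}

#' @export
print.ring_shell <- function(x, ...) {
  cat(sprintf("<ring_shell> width %d voxels (%s), %d voxels, %.1f%% clipped\n",
              x$width_voxels, x$metric, sum(x$mask),
              100 * x$clipped_fraction))
  invisible(x)
}

#' Phase composition of a ring shell
#'
#' Counts soil and air voxels inside the shell and converts them to volumes.
#' The volume effect is the soil fraction of the shell pore+soil space,
#' `100 * soil / (soil + air)`: how much of the space around the seed is
#' solid soil able to hold and conduct water. Seed-phase voxels inside the
#' shell (e.g. a neighbouring seed) belong to neither class; they are
#' reported separately and excluded from the ratio.
#'
#' @param shell A [ring_shell()].
#' @param labels A [phase_label_map()] on the same grid.
#' @return A list with `soil_volume_mm3`, `air_volume_mm3`,
#'   `volume_effect_pct`, `stray_seed_voxels`, `shell_voxels`.
#' @export
ring_composition <- function(shell, labels) {
  stopifnot(inherits(shell, "ring_shell"), inherits(labels, "phase_label_map"))
  if (!identical(dim(shell$mask), dim(labels$labels)))
    stop("shell and label map shapes differ", call. = FALSE)
  if (!any(shell$mask)) stop("empty shell", call. = FALSE)
  lab <- labels$labels[shell$mask]
  n_soil <- sum(lab == PHASE_SOIL)
  n_air <- sum(lab == PHASE_AIR)
  n_seed <- sum(lab == PHASE_SEED)
  vox_mm3 <- (labels$voxel_size_um / 1000)^3
  list(soil_volume_mm3 = n_soil * vox_mm3,
       air_volume_mm3 = n_air * vox_mm3,
       volume_effect_pct = 100 * n_soil / (n_soil + n_air),
       stray_seed_voxels = n_seed,
       shell_voxels = length(lab))
}

#' Surface effect within a ring shell
#'
#' The soil surface inside the ring is the boundary-face area (the same
#' 6-face discretisation as the contact measurement) of the soil phase
#' restricted to shell voxels. The surface effect is the seed-soil contact
#' area divided by that soil surface: how much soil surface stands behind
#' each unit of direct contact. A shell with no soil surface yields an
#' undefined (NA) effect with `undefined = TRUE` rather than an error.
#'
#' @param shell A [ring_shell()].
#' @param labels A [phase_label_map()] on the same grid.
#' @param contact A [compute_contact()] result.
#' @return A list with `soil_surface_mm2`, `surface_effect_pct`,
#'   `undefined`.
#' @export
ring_surface_effect <- function(shell, labels, contact) {
  stopifnot(inherits(shell, "ring_shell"),
            inherits(labels, "phase_label_map"),
            inherits(contact, "contact_result"))
  if (!any(shell$mask)) stop("empty shell", call. = FALSE)
  soil_in <- shell$mask & labels$labels == PHASE_SOIL
  vs_mm <- labels$voxel_size_um / 1000
  if (!any(soil_in))
    return(list(soil_surface_mm2 = 0, surface_effect_pct = NA_real_,
                undefined = TRUE))
  soil_surf <- count_faces(soil_in) * vs_mm^2
  list(soil_surface_mm2 = soil_surf,
       surface_effect_pct = 100 * contact$contact_area_mm2 / soil_surf,
       undefined = FALSE)
}

#' Iceberg-effect metrics at short and long range
#'
#' Builds the short- and long-range ring shells (defaults 5 and 15 voxels:
#' 100 and 300 micrometres at 20 micrometre voxels), computes the volume and
#' surface effects in each, and the change-in-soil-mass ratios
#' `100 * short / long` that describe how soil density decays with distance
#' from the seed. By default the long-range shell spans distances 1..long
#' from the seed surface and therefore contains the short shell's region;
#' `annulus = TRUE` restricts it to the annulus beyond the short shell
#' instead.
#'
#' @param seed_closed 3-D logical closed seed mask.
#' @param labels A [phase_label_map()] on the same grid.
#' @param contact A [compute_contact()] result for this seed.
#' @param widths Strictly increasing pair of shell widths in voxels.
#' @param metric `"chebyshev"` or `"euclidean"`.
#' @param annulus Measure the long range on the annulus
#'   `(short, long]` instead of the full shell `[1, long]`.
#' @return An object of class `iceberg_result`: a list with `short` and
#'   `long` components (each carrying `width_voxels`, `width_um`,
#'   `soil_volume_mm3`, `air_volume_mm3`, `volume_effect_pct`,
#'   `soil_surface_mm2`, `surface_effect_pct`, `clipped_fraction`) plus
#'   `change_volume_pct` and `change_surface_pct`.
#' @export
compute_iceberg <- function(seed_closed, labels, contact,
                            widths = c(5L, 15L),
                            metric = c("chebyshev", "euclidean"),
                            annulus = FALSE) {
  stopifnot(inherits(labels, "phase_label_map"),
            inherits(contact, "contact_result"))
  metric <- match.arg(metric)
  if (length(widths) != 2L || widths[1] >= widths[2] || any(widths < 1))
    stop("`widths` must be a strictly increasing pair of positive integers",
         call. = FALSE)
  shells <- list(short = ring_shell(seed_closed, widths[1], metric),
                 long = ring_shell(seed_closed, widths[2], metric))
  if (annulus) {
    shells$long$mask <- shells$long$mask & !shells$short$mask
  }
  per_range <- lapply(names(shells), function(nm) {
    sh <- shells[[nm]]
    comp <- ring_composition(sh, labels)
    surf <- ring_surface_effect(sh, labels, contact)
    c(list(width_voxels = sh$width_voxels,
           width_um = sh$width_voxels * labels$voxel_size_um,
           clipped_fraction = sh$clipped_fraction),
      comp, surf)
  })
  names(per_range) <- names(shells)
  ratio <- function(a, b) if (is.na(a) || is.na(b) || b == 0) NA_real_
                          else 100 * a / b
  structure(c(per_range, list(
    change_volume_pct = ratio(per_range$short$volume_effect_pct,
                              per_range$long$volume_effect_pct),
    change_surface_pct = ratio(per_range$short$surface_effect_pct,
                               per_range$long$surface_effect_pct),
    metric = metric, annulus = annulus
  )), class = "iceberg_result")
}

#' @export
print.iceberg_result <- function(x, ...) {
  cat("<iceberg_result>\n")
  for (nm in c("short", "long")) {
    r <- x[[nm]]
    cat(sprintf("  %-5s range (%d vox = %g um): volume effect %.2f%%, surface effect %s\n",
                nm, r$width_voxels, r$width_um, r$volume_effect_pct,
                if (is.na(r$surface_effect_pct)) "undefined"
                else sprintf("%.2f%%", r$surface_effect_pct)))
  }
  cat(sprintf("  change in soil mass: volume %.2f%%, surface %s\n",
              x$change_volume_pct,
              if (is.na(x$change_surface_pct)) "undefined"
              else sprintf("%.2f%%", x$change_surface_pct)))
  invisible(x)
}

#' @export
as.data.frame.iceberg_result <- function(x, ...) {
  data.frame(volume_effect_short_pct = x$short$volume_effect_pct,
             volume_effect_long_pct = x$long$volume_effect_pct,
             surface_effect_short_pct = x$short$surface_effect_pct,
             surface_effect_long_pct = x$long$surface_effect_pct,
             change_volume_pct = x$change_volume_pct,
             change_surface_pct = x$change_surface_pct)
}
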