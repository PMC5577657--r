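#' Greyscale CT volume
#'
#' Container for a reconstructed 3-D X-ray CT volume. Axis order is fixed as
#' `(z, y, x)` with `z` the scan axis, so `data[k, , ]` is the k-th
#' reconstructed slice. Voxels must be isotropic: all dilation and ring
#' arithmetic in this package converts voxel counts to physical units with a
#' single edge length.
#'
#' @param data 3-D numeric array in `(z, y, x)` order.
#' @param voxel_size_um Isotropic voxel edge length in micrometres. A length-3
#'   vector is accepted only when all entries agree (relative spread below
#'   1e-6); anisotropic spacings are rejected.
#' @param provenance Free-text description of where the volume came from.
#' @return An object of class `grey_volume` with fields `data`,
#'   `voxel_size_um` and `provenance`.
#' @export
grey_volume <- function(data, voxel_size_um, provenance = "") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array", call. = FALSE)
  if (any(dim(data) < 1L)) stop("all dimensions must be >= 1", call. = FALSE)
  voxel_size_um <- check_voxel_size(voxel_size_um)
  structure(list(data = data, voxel_size_um = voxel_size_um,
                 provenance = as.character(provenance)[1]),
            class = "grey_volume")
}

check_voxel_size <- function(voxel_size_um) {
  if (!is.numeric(voxel_size_um) || !length(voxel_size_um) %in% c(1L, 3L) ||
      any(!is.finite(voxel_size_um)) || any(voxel_size_um <= 0))
    stop("`voxel_size_um` must be a positive number", call. = FALSE)
  if (length(voxel_size_um) == 3L) {
    if (diff(range(voxel_size_um)) > 1e-6 * max(voxel_size_um))
      stop("anisotropic voxel sizes are not supported", call. = FALSE)
    voxel_size_um <- voxel_size_um[1]
  }
  as.numeric(voxel_size_um)
}

#' @export
print.grey_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<grey_volume> %d x %d x %d voxels (z,y,x) @ %g um\n",
              d[1], d[2], d[3], x$voxel_size_um))
  cat(sprintf("  greyscale range [%g, %g]", min(x$data), max(x$data)))
  if (nzchar(x$provenance)) cat("  |", x$provenance)
  cat("\n")
  invisible(x)
}

#' Three-phase label map
#'
#' Categorical volume assigning every voxel one of the three phases the
#' contact analysis distinguishes: air (`0`), soil (`1`) and seed (`2`).
#'
#' @param labels 3-D integer array with values in `{0, 1, 2}`.
#' @param voxel_size_um Isotropic voxel edge length in micrometres.
#' @return An object of class `phase_label_map`.
#' @export
phase_label_map <- function(labels, voxel_size_um) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3-D array", call. = FALSE)
  if (anyNA(labels) || !all(labels %in% 0:2))
    stop("labels must all be 0 (air), 1 (soil) or 2 (seed)", call. = FALSE)
  storage.mode(labels) <- "integer"
  structure(list(labels = labels,
                 voxel_size_um = check_voxel_size(voxel_size_um)),
            class = "phase_label_map")
}

#' @export
print.phase_label_map <- function(x, ...) {
  d <- dim(x$labels)
  n <- length(x$labels)
  cat(sprintf("<phase_label_map> %d x %d x %d voxels @ %g um\n",
              d[1], d[2], d[3], x$voxel_size_um))
  cat(sprintf("  air %.1f%% | soil %.1f%% | seed %.1f%%\n",
              100 * sum(x$labels == 0L) / n, 100 * sum(x$labels == 1L) / n,
              100 * sum(x$labels == 2L) / n))
  invisible(x)
}

# phase codes used throughout
PHASE_AIR  <- 0L
PHASE_SOIL <- 1L
PHASE_SEED <- 2L

sidecar_path <- function(path) {
  if (dir.exists(path)) return(file.path(path, "volume.info.yaml"))
  paste0(tools::file_path_sans_ext(path), ".info.yaml")
}

#' Read a 3-D volume
#'
#' Reads a multi-page TIFF, a directory of equally sized single-page TIFF
#' slices (stacked in lexicographic filename order), or a raw-encoded NRRD
#' file. The voxel size is resolved in this order: the explicit
#' `voxel_size_um` argument, then the `.info.yaml` sidecar written by
#' [write_volume()], then the NRRD `spacings` header. TIFF spacing tags are
#' ignored as untrustworthy. When both an argument and stored metadata are
#' present and disagree, the argument wins with a warning.
#'
#' @param path File or directory path.
#' @param voxel_size_um Optional isotropic voxel size in micrometres;
#'   mandatory when the file carries no usable spacing metadata.
#' @return A [grey_volume()], or a [phase_label_map()] when the sidecar marks
#'   the volume as a label map.
#' @export
read_volume <- function(path, voxel_size_um = NULL) {
  if (!file.exists(path)) stop("path does not exist: ", path, call. = FALSE)
  meta <- list()
  sc <- sidecar_path(path)
  if (file.exists(sc)) meta <- yaml::read_yaml(sc)
  if (dir.exists(path)) {
    arr <- read_slice_dir(path)
  } else {
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("tif", "tiff")) {
      arr <- stack_slices(tiff::readTIFF(path, all = TRUE, as.is = TRUE))
    } else if (ext == "nrrd") {
      nr <- read_nrrd(path)
      arr <- nr$data
      if (!is.null(nr$voxel_size_um) && is.null(meta$voxel_size_um))
        meta$voxel_size_um <- nr$voxel_size_um
      if (!is.null(nr$provenance)) meta$provenance <- nr$provenance
    } else stop("unsupported volume format: .", ext, call. = FALSE)
  }
  vs <- resolve_voxel_size(voxel_size_um, meta$voxel_size_um, path)
  prov <- if (!is.null(meta$provenance)) meta$provenance else path
  if (identical(meta$type, "labels"))
    return(phase_label_map(arr, vs))
  grey_volume(arr, vs, provenance = prov)
}

resolve_voxel_size <- function(arg, stored, path) {
  if (!is.null(stored)) stored <- check_voxel_size(stored)
  if (!is.null(arg)) {
    arg <- check_voxel_size(arg)
    if (!is.null(stored) && abs(arg - stored) > 1e-6 * stored)
      warning(sprintf(paste0("voxel size %g um given for %s disagrees with ",
                             "stored value %g um; using the explicit value"),
                      arg, path, stored), call. = FALSE)
    return(arg)
  }
  if (is.null(stored))
    stop("voxel size absent from both header/sidecar and argument",
         call. = FALSE)
  stored
}

read_slice_dir <- function(path) {
  files <- list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                      full.names = TRUE)
  if (length(files) == 0) stop("no TIFF slices in ", path, call. = FALSE)
  files <- files[order(basename(files), method = "radix")]
  slices <- lapply(files, function(f) {
    s <- tiff::readTIFF(f, as.is = TRUE)
    if (length(dim(s)) == 3L) s <- s[, , 1]  # collapse grey-stored-as-RGB
    s
  })
  stack_slices(slices)
}

stack_slices <- function(slices) {
  if (!is.list(slices)) slices <- list(slices)
  dims <- vapply(slices, function(s) dim(s)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("inconsistent slice dimensions", call. = FALSE)
  ny <- dims[1, 1]; nx <- dims[2, 1]; nz <- length(slices)
  arr <- array(0, dim = c(nz, ny, nx))
  for (k in seq_len(nz)) arr[k, , ] <- slices[[k]]
  if (all(arr == round(arr))) storage.mode(arr) <- "integer"
  arr
}

#' Write a 3-D volume
#'
#' Writes a [grey_volume()] or [phase_label_map()] so that [read_volume()]
#' returns it value-exactly. `.tif`/`.tiff` writes a multi-page unsigned
#' 8- or 16-bit TIFF (integer data only); `.nrrd` writes raw little-endian
#' NRRD and holds any numeric data, including doubles, losslessly. The voxel
#' size (and label-map flag) is stored in the NRRD header and in a
#' `.info.yaml` sidecar next to the file.
#'
#' @param vol A [grey_volume()] or [phase_label_map()].
#' @param path Output path ending in `.tif`, `.tiff` or `.nrrd`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  is_labels <- inherits(vol, "phase_label_map")
  if (!is_labels && !inherits(vol, "grey_volume"))
    stop("`vol` must be a grey_volume or phase_label_map", call. = FALSE)
  arr <- if (is_labels) vol$labels else vol$data
  if (any(!is.finite(arr))) stop("non-finite greyscale", call. = FALSE)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    write_tiff_stack(arr, path)
  } else if (ext == "nrrd") {
    write_nrrd(arr, path, vol$voxel_size_um,
               provenance = if (is_labels) "" else vol$provenance)
  } else stop("unsupported volume format: .", ext, call. = FALSE)
  meta <- list(voxel_size_um = vol$voxel_size_um,
               type = if (is_labels) "labels" else "grey")
  if (!is_labels && nzchar(vol$provenance)) meta$provenance <- vol$provenance
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

write_tiff_stack <- function(arr, path) {
  if (any(arr != round(arr)) || min(arr) < 0 || max(arr) > 65535)
    stop(paste0("TIFF output supports unsigned 8/16-bit integer greyscale ",
                "only; write non-integer volumes to .nrrd"), call. = FALSE)
  bits <- if (max(arr) > 255) 16L else 8L
  scale <- 2^bits - 1
  pages <- lapply(seq_len(dim(arr)[1]),
                  function(k) matrix(arr[k, , ] / scale, dim(arr)[2], dim(arr)[3]))
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
}

nrrd_types <- list(uint8 = list(what = "integer", size = 1, signed = FALSE),
                   uint16 = list(what = "integer", size = 2, signed = FALSE),
                   int = list(what = "integer", size = 4, signed = TRUE),
                   int32 = list(what = "integer", size = 4, signed = TRUE),
                   float = list(what = "double", size = 4, signed = TRUE),
                   double = list(what = "double", size = 8, signed = TRUE))

write_nrrd <- function(arr, path, voxel_size_um, provenance = "") {
  type <- if (is.integer(arr) || all(arr == round(arr))) {
    if (min(arr) >= 0 && max(arr) <= 255) "uint8"
    else if (min(arr) >= 0 && max(arr) <= 65535) "uint16"
    else "int32"
  } else "double"
  d <- dim(arr)
  hdr <- c("NRRD0004",
           paste0("type: ", type),
           "dimension: 3",
           paste0("sizes: ", paste(d, collapse = " ")),
           "encoding: raw",
           "endian: little",
           sprintf("spacings: %.9g %.9g %.9g", voxel_size_um, voxel_size_um,
                   voxel_size_um),
           "space units: \"um\" \"um\" \"um\"")
  if (nzchar(provenance)) hdr <- c(hdr, paste0("provenance:=", provenance))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(hdr, ""), con, sep = "\n")
  ti <- nrrd_types[[type]]
  if (ti$what == "integer") {
    writeBin(as.integer(arr), con, size = ti$size, endian = "little")
  } else {
    writeBin(as.numeric(arr), con, size = ti$size, endian = "little")
  }
  invisible(path)
}

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!startsWith(magic, "NRRD"))
    stop("not an NRRD file: ", path, call. = FALSE)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0 || !nzchar(line)) break
    if (startsWith(line, "#")) next
    if (grepl(":=", line, fixed = TRUE)) {
      kv <- strsplit(line, ":=", fixed = TRUE)[[1]]
      fields[[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = ":="))
    } else {
      kv <- strsplit(line, ": ", fixed = TRUE)[[1]]
      fields[[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = ": "))
    }
  }
  type <- fields[["type"]]
  if (is.null(nrrd_types[[type]]))
    stop("unsupported NRRD type: ", type, call. = FALSE)
  if (!identical(fields[["encoding"]], "raw"))
    stop("only raw-encoded NRRD is supported", call. = FALSE)
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  if (length(sizes) != 3) stop("only 3-D NRRD is supported", call. = FALSE)
  ti <- nrrd_types[[type]]
  n <- prod(sizes)
  vals <- readBin(con, what = ti$what, n = n, size = ti$size,
                  signed = ti$signed, endian = "little")
  if (length(vals) != n) stop("truncated NRRD data", call. = FALSE)
  vs <- NULL
  if (!is.null(fields[["spacings"]])) {
    sp <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
    if (diff(range(sp)) > 1e-6 * max(sp))
      stop("anisotropic voxel sizes are not supported", call. = FALSE)
    vs <- sp[1]
  }
  list(data = array(vals, dim = sizes), voxel_size_um = vs,
       provenance = fields[["provenance"]])
}

#' Analysis configuration
#'
#' Bundle of the tunable parameters of the contact and ring analyses, with
#' the defaults used throughout: 26-connectivity for the +1-voxel dilation,
#' ring widths of 5 and 15 voxels (100 and 300 micrometres at 20 micrometre
#' voxels), ball closing radius 3 and face-count surface areas.
#'
#' @param thresholds Optional pair of greyscale cut points `(t1, t2)` with
#'   `t1 < t2`; when `NULL`, thresholds are estimated by 3-class Otsu.
#' @param closing_radius_voxels Ball radius of the morphological closing
#'   applied to the raw seed mask, in voxels (non-negative).
#' @param connectivity Neighbourhood used for dilation: 6, 18 or 26.
#' @param ring_widths_voxels Strictly increasing pair of shell widths in
#'   voxels (short and long range).
#' @param surface_method `"face_count"` or `"mesh"` (see [surface_area()]).
#' @param rng_seed Integer seed for any stochastic step driven by the config.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(thresholds = NULL, closing_radius_voxels = 3L,
                            connectivity = 26L,
                            ring_widths_voxels = c(5L, 15L),
                            surface_method = c("face_count", "mesh"),
                            rng_seed = 1L) {
  if (!is.null(thresholds)) {
    if (length(thresholds) != 2L || !is.numeric(thresholds))
      stop("`thresholds` must be two greyscale cut points", call. = FALSE)
    if (thresholds[1] >= thresholds[2])
      stop("thresholds must satisfy t1 < t2", call. = FALSE)
  }
  if (length(closing_radius_voxels) != 1L || closing_radius_voxels < 0)
    stop("`closing_radius_voxels` must be a non-negative integer",
         call. = FALSE)
  connectivity <- check_connectivity(connectivity)
  if (length(ring_widths_voxels) != 2L || any(ring_widths_voxels < 1) ||
      ring_widths_voxels[1] >= ring_widths_voxels[2])
    stop("ring widths must be a strictly increasing pair of positive integers",
         call. = FALSE)
  surface_method <- match.arg(surface_method)
  structure(list(thresholds = thresholds,
                 closing_radius_voxels = as.integer(closing_radius_voxels),
                 connectivity = connectivity,
                 ring_widths_voxels = as.integer(ring_widths_voxels),
                 surface_method = surface_method,
                 rng_seed = as.integer(rng_seed)),
            class = "analysis_config")
}

#' Load an analysis configuration from a YAML/JSON key-value file
#'
#' Absent keys take the defaults of [analysis_config()]; unknown keys raise
#' an error so typos do not silently fall back to defaults.
#'
#' @param path Path to a YAML (or JSON, a YAML subset) mapping.
#' @return An [analysis_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("thresholds", "closing_radius_voxels", "connectivity",
             "ring_widths_voxels", "surface_method", "rng_seed")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  if (!is.null(raw$thresholds)) raw$thresholds <- unlist(raw$thresholds)
  if (!is.null(raw$ring_widths_voxels))
    raw$ring_widths_voxels <- unlist(raw$ring_widths_voxels)
  do.call(analysis_config, raw)
}
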