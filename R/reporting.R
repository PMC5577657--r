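#' Summarise replicate measurements
#'
#' Mean and standard error of the mean (sample standard deviation with the
#' n-1 denominator, divided by sqrt(n)), as used for the per-treatment
#' replicate summaries. A single replicate yields `sem = 0` with
#' `single_replicate = TRUE` so downstream tables stay well-formed.
#'
#' @param values Numeric vector of replicate values (finite, length >= 1).
#' @return An object of class `replicate_summary` with fields `n`, `mean`,
#'   `sem`, `values`, `single_replicate`.
#' @examples
#' # the three field-core contact percentages
#' summarize_replicates(c(4.79, 31.96, 17.89))  # 18.21 (+/- 7.84)
#' @export
summarize_replicates <- function(values) {
  if (length(values) < 1L) stop("no values to summarise", call. = FALSE)
  if (!is.numeric(values) || any(!is.finite(values)))
    stop("values must all be finite numbers", call. = FALSE)
  n <- length(values)
  s <- if (n == 1L) 0 else sd(values) / sqrt(n)
  structure(list(n = n, mean = mean(values), sem = s,
                 values = as.numeric(values),
                 single_replicate = n == 1L),
            class = "replicate_summary")
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf("%.2f (+/- %.2f), n = %d%s\n", x$mean, x$sem, x$n,
              if (x$single_replicate) "  [single replicate]" else ""))
  invisible(x)
}

#' Length of a polyline
#'
#' Total Euclidean length of an ordered 3-D point chain in voxel
#' coordinates, converted to mm. This is how radicle length is measured:
#' the user traces the root with a few points and the segment lengths are
#' summed.
#'
#' @param points Numeric matrix with one `(z, y, x)` point per row (>= 2
#'   rows; consecutive duplicate points are rejected).
#' @param voxel_size_um Isotropic voxel size in um.
#' @return Length in mm.
#' @export
polyline_length <- function(points, voxel_size_um) {
  points <- as.matrix(points)
  if (nrow(points) < 2L || ncol(points) != 3L)
    stop("a polyline needs at least two 3-D points", call. = FALSE)
  if (any(!is.finite(points))) stop("non-finite coordinates", call. = FALSE)
  seg <- diff(points)
  if (any(rowSums(seg^2) == 0))
    stop("consecutive duplicate points", call. = FALSE)
  vs_mm <- check_voxel_size(voxel_size_um) / 1000
  sum(sqrt(rowSums(seg^2))) * vs_mm
}

#' Run the full contact + iceberg analysis over a batch of volumes
#'
#' For each volume: read, segment into phases, select the largest seed
#' object, close it, compute the contact result against the soil phase and
#' the iceberg metrics at the configured ring widths. A failing volume is
#' recorded as an error row and does not abort the batch; the run fails only
#' when every volume fails. Replicate summaries (mean +/- SEM over the
#' successful volumes) are appended per metric.
#'
#' @param config An [analysis_config()].
#' @param volumes Character vector of volume paths readable by
#'   [read_volume()].
#' @param voxel_size_um Optional voxel size forwarded to [read_volume()]
#'   for files without stored spacing.
#' @return A list with `results` (one row per successful volume),
#'   `summaries` (metric, n, mean, sem) and `errors` (volume, message).
#' @export
run_batch <- function(config, volumes, voxel_size_um = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  if (length(volumes) == 0) stop("empty volume list", call. = FALSE)
  rows <- list()
  errs <- list()
  for (path in volumes) {
    res <- tryCatch({
      vol <- read_volume(path, voxel_size_um)
      labels <- if (inherits(vol, "phase_label_map")) vol
        else segment_phases(vol, config$thresholds)
      raw_seed <- select_seed(labels)
      closed <- close_seed(raw_seed, config$closing_radius_voxels,
                           labels$voxel_size_um, config$surface_method)
      soil <- labels$labels == PHASE_SOIL & !closed$closed_mask
      soil <- array(soil, dim = dim(soil))
      contact <- compute_contact(closed$closed_mask, soil,
                                 labels$voxel_size_um, config$connectivity,
                                 config$surface_method)
      iceberg <- compute_iceberg(closed$closed_mask, labels, contact,
                                 config$ring_widths_voxels)
      cbind(data.frame(volume = path,
                       volume_increase_pct = closed$volume_increase_pct,
                       surface_change_pct = closed$surface_change_pct),
            as.data.frame(contact), as.data.frame(iceberg))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errs[[length(errs) + 1L]] <- data.frame(volume = path,
                                              message = conditionMessage(res))
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  if (length(rows) == 0)
    stop("all volumes failed: ",
         paste(vapply(errs, function(e) e$message, ""), collapse = "; "),
         call. = FALSE)
  results <- do.call(rbind, rows)
  metrics <- setdiff(names(results), "volume")
  summaries <- do.call(rbind, lapply(metrics, function(m) {
    v <- results[[m]]
    v <- v[is.finite(v)]
    if (length(v) == 0)
      return(data.frame(metric = m, n = 0L, mean = NA_real_,
                        sem = NA_real_))
    s <- summarize_replicates(v)
    data.frame(metric = m, n = s$n, mean = s$mean, sem = s$sem)
  }))
  list(results = results, summaries = summaries,
       errors = if (length(errs)) do.call(rbind, errs)
                else data.frame(volume = character(), message = character()))
}
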