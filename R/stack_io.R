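# Voxel-stack and plate-series containers plus TIFF/CSV I/O.
#
# Conventions enforced here and relied on everywhere else:
#   * stacks are indexed (channel, z, y, x); z = 1 is the bottommost plane
#     (coverslip side) and plane k sits at (k - 1) * dz micrometres;
#   * lateral voxel centres are at (i - 1/2) * dx and (j - 1/2) * dy;
#   * intensities are nonnegative finite floats in arbitrary detector units.

#' Physical voxel geometry of a confocal stack
#'
#' @param dx,dy Lateral voxel size in micrometres.
#' @param dz Axial plane spacing in micrometres (typical confocal acquisitions
#'   use 0.3 or 0.6).
#' @return An object of class `voxel_geometry`.
#' @export
voxel_geometry <- function(dx, dy = dx, dz) {
  for (v in list(dx = dx, dy = dy, dz = dz)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("voxel sizes dx, dy, dz must be single positive numbers", call. = FALSE)
    }
  }
  structure(list(dx = dx, dy = dy, dz = dz), class = "voxel_geometry")
}

#' Axial position of a z-plane
#'
#' Plane 1 is the bottommost plane (coverslip side) at z = 0.
#'
#' @param geometry A [voxel_geometry()].
#' @param plane_index 1-based plane index (vectorised).
#' @return Axial position(s) in micrometres.
#' @export
plane_z_um <- function(geometry, plane_index) {
  (plane_index - 1) * geometry$dz
}

#' Multi-channel 3D intensity stack
#'
#' @param data Numeric array indexed `(channel, z, y, x)`; a 3D array is
#'   promoted to a single channel. All values must be finite and >= 0.
#' @param geometry A [voxel_geometry()].
#' @param channel_names Optional character vector of channel labels.
#' @return An object of class `voxel_stack` with elements `data`, `geometry`,
#'   `channel_names`.
#' @export
voxel_stack <- function(data, geometry, channel_names = NULL) {
  if (!inherits(geometry, "voxel_geometry")) {
    stop("`geometry` must be a voxel_geometry", call. = FALSE)
  }
  if (length(dim(data)) == 3L) {
    dim(data) <- c(1L, dim(data))
  }
  if (length(dim(data)) != 4L) {
    stop("`data` must be a (channel, z, y, x) array", call. = FALSE)
  }
  if (any(!is.finite(data)) || any(data < 0)) {
    stop("stack intensities must be finite and nonnegative", call. = FALSE)
  }
  d <- dim(data)
  if (d[1] < 1L || d[2] < 2L) {
    stop("need at least 1 channel and 2 z-planes", call. = FALSE)
  }
  if (is.null(channel_names)) {
    channel_names <- paste0("ch", seq_len(d[1]))
  }
  if (length(channel_names) != d[1]) {
    stop("channel_names length must equal the number of channels", call. = FALSE)
  }
  structure(
    list(data = data, geometry = geometry, channel_names = as.character(channel_names)),
    class = "voxel_stack"
  )
}

#' @export
print.voxel_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "voxel_stack: %d channel(s) [%s], %d z-planes, %d x %d px, dx=%g dy=%g dz=%g um\n",
    d[1], paste(x$channel_names, collapse = ", "), d[2], d[4], d[3],
    x$geometry$dx, x$geometry$dy, x$geometry$dz
  ))
  invisible(x)
}

n_channels <- function(stack) dim(stack$data)[1]
n_planes <- function(stack) dim(stack$data)[2]

#' Resolve a channel name or index to an index
#' @keywords internal
channel_index <- function(stack, channel) {
  if (is.character(channel)) {
    idx <- match(channel, stack$channel_names)
    if (is.na(idx)) {
      stop(sprintf("channel '%s' not found (have: %s)", channel,
                   paste(stack$channel_names, collapse = ", ")), call. = FALSE)
    }
    return(idx)
  }
  idx <- as.integer(channel)
  if (idx < 1L || idx > n_channels(stack)) {
    stop("channel index out of range", call. = FALSE)
  }
  idx
}

#' Extract one channel as a (z, y, x) array
#' @param stack A [voxel_stack()].
#' @param channel Channel name or index.
#' @return 3D numeric array.
#' @export
channel_data <- function(stack, channel) {
  ci <- channel_index(stack, channel)
  arr <- stack$data[ci, , , , drop = FALSE]
  dim(arr) <- dim(stack$data)[2:4]
  arr
}

# On-disk TIFF samples are 32-bit and constrained to [0, 1] by the writer;
# intensities are scaled by this constant, bounding absolute round-trip error
# at ADU_TIFF_SCALE / 2^32 (~2.4e-4 ADU).
ADU_TIFF_SCALE <- 2^20

#' Write a voxel stack as a multi-page TIFF
#'
#' One page per (channel, z) slice. Pages are channel-major: all z-planes of
#' channel 1 (bottom plane first), then channel 2, etc. Geometry is not stored
#' in the file; it is supplied again at read time.
#'
#' @param stack A [voxel_stack()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(stack, path) {
  if (!inherits(stack, "voxel_stack")) stop("`stack` must be a voxel_stack", call. = FALSE)
  if (max(stack$data) > ADU_TIFF_SCALE) {
    stop(sprintf("intensities above %g ADU cannot be stored losslessly", ADU_TIFF_SCALE),
         call. = FALSE)
  }
  d <- dim(stack$data)
  pages <- vector("list", d[1] * d[2])
  p <- 0L
  for (ci in seq_len(d[1])) {
    for (zi in seq_len(d[2])) {
      p <- p + 1L
      pages[[p]] <- matrix(stack$data[ci, zi, , ] / ADU_TIFF_SCALE, d[3], d[4])
    }
  }
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                            reduce = FALSE), silent = TRUE)
  if (inherits(ok, "try-error")) {
    stop(sprintf("cannot write TIFF to '%s'", path), call. = FALSE)
  }
  invisible(path)
}

#' Read a multi-page TIFF into a voxel stack
#'
#' The file layout (number of channels, page order) must be declared by the
#' caller; TIFF metadata dialects are deliberately not parsed. Negative stored
#' values are clamped to zero with a warning.
#'
#' @param path TIFF file path.
#' @param geometry A [voxel_geometry()] for the stack.
#' @param n_channels Number of channels interleaved in the file.
#' @param order `"channel_major"` (all z of channel 1 first, the
#'   [write_tiff_stack()] layout) or `"z_major"` (all channels of plane 1
#'   first).
#' @param channel_names Optional channel labels.
#' @param n_planes Optional expected number of z-planes; mismatch is an error.
#' @return A [voxel_stack()].
#' @export
read_tiff_stack <- function(path, geometry, n_channels = 1L,
                            order = c("channel_major", "z_major"),
                            channel_names = NULL, n_planes = NULL) {
  order <- match.arg(order)
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path), call. = FALSE)
  pages <- try(tiff::readTIFF(path, all = TRUE, as.is = FALSE), silent = TRUE)
  if (inherits(pages, "try-error")) {
    stop(sprintf("'%s' is not a readable TIFF", path), call. = FALSE)
  }
  if (!is.list(pages)) pages <- list(pages)
  np <- length(pages)
  n_channels <- as.integer(n_channels)
  if (np %% n_channels != 0L) {
    stop(sprintf("%d pages are not divisible by %d declared channels", np, n_channels),
         call. = FALSE)
  }
  nz <- np %/% n_channels
  if (!is.null(n_planes) && nz != n_planes) {
    stop(sprintf("file holds %d planes per channel, %d declared", nz, n_planes),
         call. = FALSE)
  }
  if (nz < 2L) stop("stack must hold at least 2 z-planes per channel", call. = FALSE)
  dims <- dim(pages[[1]])[1:2]
  arr <- array(0, c(n_channels, nz, dims[1], dims[2]))
  for (p in seq_len(np)) {
    pg <- pages[[p]]
    if (length(dim(pg)) > 2L) pg <- pg[, , 1]
    if (!identical(dim(pg)[1:2], dims)) {
      stop("pages have inconsistent dimensions", call. = FALSE)
    }
    if (order == "channel_major") {
      ci <- (p - 1L) %/% nz + 1L
      zi <- (p - 1L) %% nz + 1L
    } else {
      zi <- (p - 1L) %/% n_channels + 1L
      ci <- (p - 1L) %% n_channels + 1L
    }
    arr[ci, zi, , ] <- pg * ADU_TIFF_SCALE
  }
  if (any(arr < 0)) {
    warning(sprintf("%d negative stored values clamped to 0", sum(arr < 0)))
    arr[arr < 0] <- 0
  }
  voxel_stack(arr, geometry, channel_names)
}

#' Plate-reader luminescence time series
#'
#' @param times Sampling times in minutes, strictly increasing.
#' @param values Numeric matrix, one row per time point, one column per well;
#'   relative light units, finite and >= 0.
#' @param well_labels Optional well identifiers (default: column names).
#' @param condition_map Optional named character vector mapping well label to
#'   condition label.
#' @return An object of class `plate_series`.
#' @export
plate_series <- function(times, values, well_labels = NULL, condition_map = NULL) {
  times <- as.numeric(times)
  if (any(!is.finite(times)) || any(diff(times) <= 0)) {
    stop("`times` must be finite and strictly increasing", call. = FALSE)
  }
  values <- as.matrix(values)
  if (nrow(values) != length(times)) {
    stop("`values` must have one row per time point", call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("luminescence values must be finite and nonnegative", call. = FALSE)
  }
  if (is.null(well_labels)) {
    well_labels <- colnames(values)
    if (is.null(well_labels)) well_labels <- paste0("W", seq_len(ncol(values)))
  }
  if (length(well_labels) != ncol(values)) {
    stop("one well label per column required", call. = FALSE)
  }
  colnames(values) <- well_labels
  if (!is.null(condition_map)) {
    missing_wells <- setdiff(well_labels, names(condition_map))
    if (length(missing_wells)) {
      stop(sprintf("condition_map lacks wells: %s", paste(missing_wells, collapse = ", ")),
           call. = FALSE)
    }
    condition_map <- condition_map[well_labels]
  }
  structure(
    list(times = times, values = values, well_labels = well_labels,
         condition_map = condition_map),
    class = "plate_series"
  )
}

#' @export
print.plate_series <- function(x, ...) {
  cat(sprintf("plate_series: %d wells x %d time points (%g-%g min)\n",
              ncol(x$values), length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Read a plate-reader series from delimited text
#'
#' Expects a header row, a first column `time_min` (minutes) and one column
#' per well. Comma and tab delimiters are auto-detected from the extension
#' (.csv vs .tsv/.txt).
#'
#' @param path Input file.
#' @param condition_map Optional named character vector well -> condition.
#' @return A [plate_series()].
#' @export
read_plate_series <- function(path, condition_map = NULL) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path), call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("need a time column plus at least one well column", call. = FALSE)
  if (names(df)[1] != "time_min") {
    stop("first column must be named 'time_min'", call. = FALSE)
  }
  num <- suppressWarnings(
    vapply(df, function(col) as.numeric(col), numeric(nrow(df)))
  )
  if (is.null(dim(num))) num <- matrix(num, nrow = nrow(df))
  bad <- which(is.na(num) & !is.na(as.matrix(df)), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric value at row %d, column '%s'",
                 bad[1, 1], names(df)[bad[1, 2]]), call. = FALSE)
  }
  times <- num[, 1]
  if (anyDuplicated(times) || is.unsorted(times, strictly = TRUE)) {
    stop("time_min column must be strictly increasing without duplicates", call. = FALSE)
  }
  plate_series(times, num[, -1, drop = FALSE], well_labels = names(df)[-1],
               condition_map = condition_map)
}

#' Write a plate series as CSV
#'
#' @param series A [plate_series()].
#' @param path Output path (CSV).
#' @return `path`, invisibly.
#' @export
write_plate_series <- function(series, path) {
  df <- data.frame(time_min = series$times, series$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
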