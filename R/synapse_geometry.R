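# Synapse-plane determination from axial intensity gradients.
#
# Rationale: below a cell adhered to the coverslip, out-of-focus light from
# the axial PSF tail makes intensity rise as the focal plane approaches the
# cell, so axial gradients there are consistently positive. The synapse
# (cell/coverslip interface) is taken as the first plane, scanning upward,
# at which the gradients stop being consistently positive.

#' Estimate the camera background of one channel
#'
#' Robust estimator suited to sparse-signal stacks: the offset is the median
#' of the dimmest decile of voxels, its dispersion the MAD of that subset.
#'
#' @param stack A [voxel_stack()].
#' @param channel Channel name or index.
#' @return Object of class `background_model` with `offset`, `method`,
#'   `stats` (MAD of the dim subset, ADU).
#' @export
estimate_background <- function(stack, channel) {
  v <- as.vector(channel_data(stack, channel))
  if (!length(v)) stop("channel holds no voxels", call. = FALSE)
  q10 <- stats::quantile(v, 0.10, names = FALSE)
  dim_subset <- v[v <= q10]
  structure(list(
    offset = stats::median(dim_subset),
    method = "dimmest_decile_median",
    stats = stats::mad(dim_subset)
  ), class = "background_model")
}

#' Subtract a background offset from one channel
#'
#' Values are clamped at zero; other channels are untouched.
#'
#' @param stack A [voxel_stack()].
#' @param model A [estimate_background()] result (or a bare numeric offset).
#' @param channel Channel name or index.
#' @return A new [voxel_stack()].
#' @export
subtract_background <- function(stack, model, channel) {
  offset <- if (inherits(model, "background_model")) model$offset else as.numeric(model)
  if (offset < 0) stop("background offset must be >= 0", call. = FALSE)
  ci <- channel_index(stack, channel)
  out <- stack
  out$data[ci, , , ] <- pmax(stack$data[ci, , , ] - offset, 0)
  out
}

#' Threshold rule for "sufficient intensity"
#'
#' @param type `"percentile"` keeps voxels at or above the p-th percentile of
#'   the nonzero voxels (illumination-invariant); `"sd"` keeps voxels above
#'   `k` times the background dispersion.
#' @param p Percentile in [0, 100] (percentile rule).
#' @param k Multiplier (sd rule).
#' @param background A [estimate_background()] result (sd rule).
#' @return Object of class `threshold_rule`.
#' @export
threshold_rule <- function(type = c("percentile", "sd"), p = 75, k = 3,
                           background = NULL) {
  type <- match.arg(type)
  if (type == "percentile" && (p < 0 || p > 100)) {
    stop("p must be in [0, 100]", call. = FALSE)
  }
  if (type == "sd" && k < 0) stop("k must be >= 0", call. = FALSE)
  structure(list(type = type, p = p, k = k, background = background),
            class = "threshold_rule")
}

#' Voxel mask of sufficient intensity
#'
#' Apply after background subtraction. The percentile rule keeps nonzero
#' voxels at or above the p-th percentile of the nonzero voxels; the sd rule
#' keeps voxels above `k` times the background dispersion.
#'
#' @param stack A background-subtracted [voxel_stack()].
#' @param channel Channel name or index.
#' @param rule A [threshold_rule()].
#' @return Logical (z, y, x) array with attribute `empty` flagging an
#'   all-FALSE mask.
#' @export
sufficient_intensity_mask <- function(stack, channel, rule = threshold_rule()) {
  v <- channel_data(stack, channel)
  if (rule$type == "percentile") {
    nz <- v[v > 0]
    if (!length(nz)) {
      mask <- array(FALSE, dim(v))
      attr(mask, "empty") <- TRUE
      return(mask)
    }
    thr <- stats::quantile(nz, rule$p / 100, names = FALSE)
    mask <- v >= thr & v > 0
  } else {
    if (is.null(rule$background)) {
      stop("sd rule needs a background model in the rule", call. = FALSE)
    }
    mask <- v > rule$k * rule$background$stats
  }
  attr(mask, "empty") <- !any(mask)
  mask
}

#' Per-voxel axial intensity gradients
#'
#' Central differences `(I[z+1] - I[z-1]) / (2 dz)` on interior planes,
#' one-sided differences on the two boundary planes. Units ADU/um.
#'
#' @param stack A [voxel_stack()].
#' @param channel Channel name or index.
#' @return Numeric (z, y, x) array of signed gradients.
#' @export
axial_gradients <- function(stack, channel) {
  v <- channel_data(stack, channel)
  nz <- dim(v)[1]
  if (nz < 3L) stop("need at least 3 z-planes for gradients", call. = FALSE)
  dz <- stack$geometry$dz
  g <- array(0, dim(v))
  g[2:(nz - 1), , ] <- (v[3:nz, , ] - v[1:(nz - 2), , ]) / (2 * dz)
  g[1, , ] <- (v[2, , ] - v[1, , ]) / dz
  g[nz, , ] <- (v[nz, , ] - v[nz - 1, , ]) / dz
  g
}

#' Synapse detection parameters
#'
#' @param rule A [threshold_rule()] selecting the voxels that vote.
#' @param theta Fraction of positive gradients in a plane's masked voxels at
#'   or above which the plane counts as "consistently positive"; in (0, 1].
#' @param min_voxels Planes with fewer masked voxels are uninformative and
#'   skipped.
#' @param channel Channel used for detection; the structural (actin-like)
#'   channel by default.
#' @return Object of class `synapse_detection_params`.
#' @export
synapse_detection_params <- function(rule = threshold_rule(), theta = 0.75,
                                     min_voxels = 20L, channel = "structural") {
  if (theta <= 0 || theta > 1) stop("theta must be in (0, 1]", call. = FALSE)
  if (min_voxels < 1L) stop("min_voxels must be >= 1", call. = FALSE)
  structure(list(rule = rule, theta = theta, min_voxels = as.integer(min_voxels),
                 channel = channel),
            class = "synapse_detection_params")
}

#' Detect the synapse plane
#'
#' Scans planes upward from the coverslip. A plane is "consistently positive"
#' when, among its masked voxels (at least `min_voxels` of them), the
#' fraction with positive axial gradient is at least `theta`. The synapse is
#' the first informative plane failing this test after at least one plane has
#' passed it. The stack must already be background-subtracted in the analysed
#' channel.
#'
#' @param stack A background-subtracted [voxel_stack()].
#' @param params A [synapse_detection_params()].
#' @return Object of class `synapse_result`: `plane_index`, `plane_z_um`,
#'   `per_plane_positive_fraction` (NA where uninformative).
#' @export
detect_synapse_plane <- function(stack, params = synapse_detection_params()) {
  mask <- sufficient_intensity_mask(stack, params$channel, params$rule)
  if (isTRUE(attr(mask, "empty"))) {
    stop_synloc("no_synapse", "no voxels pass the intensity threshold")
  }
  grad <- axial_gradients(stack, params$channel)
  nz <- dim(grad)[1]
  frac <- rep(NA_real_, nz)
  for (k in seq_len(nz)) {
    m <- mask[k, , ]
    if (sum(m) >= params$min_voxels) {
      frac[k] <- mean(grad[k, , ][m] > 0)
    }
  }
  passed <- FALSE
  for (k in seq_len(nz)) {
    if (is.na(frac[k])) next
    if (frac[k] >= params$theta) {
      passed <- TRUE
    } else if (passed) {
      return(structure(list(
        plane_index = k,
        plane_z_um = plane_z_um(stack$geometry, k),
        per_plane_positive_fraction = frac
      ), class = "synapse_result"))
    }
  }
  if (!passed) {
    stop_synloc("no_synapse", "no plane shows consistently positive gradients (no cell signal?)")
  }
  stop_synloc("synapse_above_stack", "gradients stay consistently positive through the top plane")
}

# classed conditions so the pipeline can convert failures into reason codes
stop_synloc <- function(class, msg) {
  stop(structure(class = c(paste0("synloc_", class), "error", "condition"),
                 list(message = msg, call = NULL)))
}
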