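# Per-cell localization metrics: intensity-weighted centre of fluorescence,
# its axial distance to the synapse plane, and the axial dispersion.

# voxel-centre coordinate grids (um) for one channel array, as flat vectors
voxel_positions <- function(dims, geometry) {
  nz <- dims[1]; ny <- dims[2]; nx <- dims[3]
  list(
    z = rep((seq_len(nz) - 1) * geometry$dz, times = ny * nx),
    y = rep(rep((seq_len(ny) - 0.5) * geometry$dy, each = nz), times = nx),
    x = rep((seq_len(nx) - 0.5) * geometry$dx, each = nz * ny)
  )
}

#' Intensity-weighted centre of fluorescence (COF)
#'
#' The analogue of a centre of mass: voxel positions weighted by the masked,
#' background-subtracted reporter intensity. Lateral positions are voxel
#' centres; axial positions are the plane grid points (plane k at
#' (k - 1) dz).
#'
#' @param stack A background-subtracted [voxel_stack()].
#' @param channel Reporter channel name or index.
#' @param mask Logical (z, y, x) array from [sufficient_intensity_mask()].
#' @return Object of class `center_of_fluorescence` with `x`, `y`, `z` (um)
#'   and `total_intensity`.
#' @export
compute_cof <- function(stack, channel, mask) {
  v <- channel_data(stack, channel)
  if (!any(mask)) stop_synloc("no_signal", "empty mask: no voxels to weight")
  w <- as.vector(v) * as.vector(mask)
  tot <- sum(w)
  if (tot <= 0) stop_synloc("no_signal", "masked intensity sums to zero")
  pos <- voxel_positions(dim(v), stack$geometry)
  structure(list(
    x = sum(w * pos$x) / tot,
    y = sum(w * pos$y) / tot,
    z = sum(w * pos$z) / tot,
    total_intensity = tot
  ), class = "center_of_fluorescence")
}

#' Axial distance of the COF to the synapse plane
#'
#' @param cof A [compute_cof()] result.
#' @param synapse A [detect_synapse_plane()] result (or a bare z position
#'   in um).
#' @return Nonnegative distance in um.
#' @export
cof_axial_distance <- function(cof, synapse) {
  z_syn <- if (inherits(synapse, "synapse_result")) synapse$plane_z_um else as.numeric(synapse)
  abs(cof$z - z_syn)
}

#' Axial dispersion of the reporter signal
#'
#' Intensity-weighted mean axial distance of the masked voxels to the COF.
#' Low values mean the signal is tightly confined along z. Voxels below the
#' intensity threshold carry zero weight by construction.
#'
#' @param stack A background-subtracted [voxel_stack()].
#' @param channel Reporter channel name or index.
#' @param mask Logical (z, y, x) array.
#' @param cof A [compute_cof()] result (computed if missing).
#' @return Dispersion in um.
#' @export
axial_dispersion <- function(stack, channel, mask, cof = NULL) {
  if (is.null(cof)) cof <- compute_cof(stack, channel, mask)
  v <- channel_data(stack, channel)
  w <- as.vector(v) * as.vector(mask)
  tot <- sum(w)
  if (tot <= 0) stop_synloc("no_signal", "masked intensity sums to zero")
  z <- voxel_positions(dim(v), stack$geometry)$z
  sum(w * abs(z - cof$z)) / tot
}

#' All localization metrics for one cell
#'
#' @param stack A background-subtracted [voxel_stack()].
#' @param channel Reporter channel.
#' @param mask Logical voxel mask.
#' @param synapse A [detect_synapse_plane()] result.
#' @return Object of class `localization_metrics`: `cof`, `cof_distance_um`,
#'   `axial_dispersion_um`, `n_voxels`.
#' @export
localization_metrics <- function(stack, channel, mask, synapse) {
  cof <- compute_cof(stack, channel, mask)
  structure(list(
    cof = cof,
    cof_distance_um = cof_axial_distance(cof, synapse),
    axial_dispersion_um = axial_dispersion(stack, channel, mask, cof),
    n_voxels = sum(mask)
  ), class = "localization_metrics")
}
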