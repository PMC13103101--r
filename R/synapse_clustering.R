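# Synapse-plane clustering analysis: structural-channel segmentation and the
# masked pair autocorrelation function g(r) with its average g_ave.
#
# The g(r) estimator is the standard intensity-based one for irregular cell
# footprints: the FFT autocorrelation of the masked intensity image,
# normalised by the squared mean masked intensity and by the autocorrelation
# of the mask itself (edge correction). g = 1 for spatially random signal;
# g > 1 at small r indicates clustering.

#' Segmentation parameters for the synapse-plane mask
#'
#' @param gaussian_sigma Smoothing SD, um.
#' @param morph_radius Disk radius in pixels for morphological closing then
#'   opening; 0 disables.
#' @param keep_largest Keep only the largest connected component.
#' @param fill_holes Fill holes in the mask.
#' @return Object of class `segmentation_params`.
#' @export
segmentation_params <- function(gaussian_sigma = 0.3, morph_radius = 2L,
                                keep_largest = TRUE, fill_holes = TRUE) {
  if (gaussian_sigma <= 0) stop("gaussian_sigma must be > 0", call. = FALSE)
  if (morph_radius < 0) stop("morph_radius must be >= 0", call. = FALSE)
  structure(list(gaussian_sigma = gaussian_sigma,
                 morph_radius = as.integer(morph_radius),
                 keep_largest = isTRUE(keep_largest),
                 fill_holes = isTRUE(fill_holes)),
            class = "segmentation_params")
}

# deterministic two-class 1-D k-means: Lloyd iterations from quantile centres
kmeans_two_class <- function(values) {
  ctr <- stats::quantile(values, c(0.25, 0.75), names = FALSE)
  if (diff(ctr) <= 0) {
    stop_synloc("segmentation_degenerate", "image is (near-)constant: two-class split undefined")
  }
  km <- suppressWarnings(
    stats::kmeans(values, centers = matrix(ctr, ncol = 1), iter.max = 100L,
                  algorithm = "Lloyd")
  )
  km$cluster == which.max(km$centers)
}

#' Segment the cell footprint at the synapse plane
#'
#' Pipeline: Gaussian smoothing, log(1 + I) transform, deterministic
#' two-class k-means on pixel values (bright class as initial mask), then
#' morphological closing and opening, optional hole filling and
#' largest-component selection.
#'
#' @param plane_image Nonnegative 2D intensity matrix (y, x) at the synapse
#'   plane (structural channel).
#' @param params A [segmentation_params()].
#' @param pixel_size Lateral pixel size, um.
#' @return Logical matrix mask with attribute `pixel_size`.
#' @export
segment_synapse_mask <- function(plane_image, params = segmentation_params(),
                                 pixel_size) {
  if (any(plane_image < 0)) stop("plane image must be nonnegative", call. = FALSE)
  sigma_px <- params$gaussian_sigma / pixel_size
  sm <- EBImage::gblur(plane_image, sigma = sigma_px)
  lt <- log1p(pmax(sm, 0))
  bright <- kmeans_two_class(as.vector(lt))
  mask <- matrix(bright, nrow(plane_image), ncol(plane_image))
  if (params$morph_radius > 0) {
    brush <- EBImage::makeBrush(2L * params$morph_radius + 1L, shape = "disc")
    mask <- EBImage::closing(mask, brush)
    mask <- EBImage::opening(mask, brush)
  }
  if (params$fill_holes) mask <- EBImage::fillHull(mask)
  mask <- mask > 0
  if (params$keep_largest && any(mask)) {
    lab <- EBImage::bwlabel(mask)
    tab <- tabulate(lab[lab > 0])
    mask <- lab == which.max(tab)
  }
  mask <- matrix(as.logical(mask), nrow(plane_image), ncol(plane_image))
  attr(mask, "pixel_size") <- pixel_size
  mask
}

# 2D autocorrelation via zero-padded FFT; returns array of raw correlation
# sums indexed by integer shifts (dy, dx) in [-(n-1), n-1]
autocorr_fft <- function(img) {
  d <- dim(img)
  P <- array(0, 2 * d)
  P[seq_len(d[1]), seq_len(d[2])] <- img
  FT <- stats::fft(P)
  ac <- Re(stats::fft(FT * Conj(FT), inverse = TRUE)) / length(P)
  ac
}

# shift index grids for the padded autocorrelation array
shift_grids <- function(padded_dim) {
  idx <- function(n) {
    s <- seq_len(n) - 1L
    ifelse(s > n / 2, s - n, s)
  }
  list(dy = idx(padded_dim[1]), dx = idx(padded_dim[2]))
}

#' Masked pair autocorrelation function g(r)
#'
#' @param plane_image Background-subtracted 2D intensity matrix (y, x).
#' @param mask Logical matrix from [segment_synapse_mask()] (same shape).
#' @param bin_width Radial bin width, um; defaults to one pixel pitch.
#' @param pixel_size Lateral pixel size, um (taken from the mask attribute if
#'   absent).
#' @param r_limit Largest radius reported, um; defaults to a quarter of the
#'   shorter image side, where edge-corrected support is still ample.
#' @return Object of class `radial_correlation`: `r_bins` (bin centres, um,
#'   zero-lag bin excluded), `g`, `bin_counts` (mask-pair support per bin).
#' @export
pair_autocorrelation <- function(plane_image, mask, bin_width = NULL,
                                 pixel_size = NULL, r_limit = NULL) {
  if (is.null(pixel_size)) pixel_size <- attr(mask, "pixel_size")
  if (is.null(pixel_size)) stop("pixel_size required", call. = FALSE)
  if (!any(mask)) stop_synloc("insufficient_support", "mask is empty")
  if (is.null(bin_width)) bin_width <- pixel_size
  if (is.null(r_limit)) r_limit <- min(dim(plane_image)) * pixel_size / 4

  M <- mask * 1
  IM <- plane_image * M
  rho <- sum(IM) / sum(M)
  if (rho <= 0) stop_synloc("insufficient_support", "masked intensity is zero")

  ac_im <- autocorr_fft(IM)
  ac_m <- autocorr_fft(M)
  sh <- shift_grids(dim(ac_im))
  r_px <- sqrt(outer(sh$dy^2, sh$dx^2, "+"))
  r_um <- r_px * pixel_size

  keep <- r_um > 0 & r_um <= r_limit & ac_m > 0.5  # exclude zero lag; require pair support
  bin_id <- floor(r_um[keep] / bin_width) + 1L
  num <- tapply(ac_im[keep], bin_id, sum)
  den <- tapply(ac_m[keep], bin_id, sum)
  ids <- as.integer(names(num))

  n_bins <- max(ids)
  g <- rep(NA_real_, n_bins)
  counts <- rep(0, n_bins)
  g[ids] <- (num / den) / rho^2
  counts[ids] <- den
  supported <- counts > 0
  structure(list(
    r_bins = (seq_len(n_bins) - 0.5) * bin_width,
    g = g,
    bin_counts = counts,
    bin_width = bin_width,
    supported = supported
  ), class = "radial_correlation")
}

#' Clustering coefficient g_ave
#'
#' Unweighted mean of g(r) over supported radial bins with centre at or below
#' the cutoff `r_max`.
#'
#' @param corr A [pair_autocorrelation()] result.
#' @param r_max Cutoff radius, um; the conventional choices are 0.25 or 0.5.
#' @return Object of class `clustering_coefficient` with `g_ave`, `r_max`,
#'   `n_bins`.
#' @export
clustering_coefficient <- function(corr, r_max = 0.5) {
  sel <- corr$supported & corr$r_bins <= r_max & !is.na(corr$g)
  if (!any(sel)) {
    stop_synloc("insufficient_support", "no supported radial bins at or below r_max")
  }
  structure(list(g_ave = mean(corr$g[sel]), r_max = r_max, n_bins = sum(sel)),
            class = "clustering_coefficient")
}
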