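# Small, fast simulation configuration shared across tests. The geometry is a
# scaled-down single-cell crop: 6 x 6 um field, 18 planes at 0.3 um, a 2 um
# cell resting on plane 4.
small_sim_config <- function(...) {
  args <- utils::modifyList(
    list(nx = 48L, ny = 48L, nz = 18L,
         geometry = voxel_geometry(0.125, 0.125, 0.3),
         synapse_plane = 4L, cell_radius_xy = 2, cell_height = 3.3),
    list(...))
  do.call(sim_config, args)
}

# uniform random stack for oracle comparisons
random_stack <- function(dims = c(1, 8, 8, 8), seed = 1,
                         geometry = voxel_geometry(0.1, 0.1, 0.3)) {
  set.seed(seed)
  voxel_stack(array(runif(prod(dims), 0, 100), dims), geometry)
}

# naive shift-loop 2D autocorrelation oracle (independent of the FFT path):
# returns sum_{x} f(x) g(x + s) for integer shifts |s| <= max_shift
naive_xcorr <- function(f, g, max_shift) {
  ny <- nrow(f); nx <- ncol(f)
  out <- matrix(0, 2 * max_shift + 1, 2 * max_shift + 1)
  for (sy in -max_shift:max_shift) {
    for (sx in -max_shift:max_shift) {
      y1 <- max(1, 1 - sy):min(ny, ny - sy)
      x1 <- max(1, 1 - sx):min(nx, nx - sx)
      out[sy + max_shift + 1, sx + max_shift + 1] <-
        sum(f[y1, x1] * g[y1 + sy, x1 + sx])
    }
  }
  out
}

# naive g(r) estimator built on naive_xcorr, same binning convention as
# pair_autocorrelation
naive_g_of_r <- function(img, mask, bin_width, pixel_size, r_limit) {
  max_shift <- ceiling(r_limit / pixel_size) + 1L
  M <- mask * 1
  ac_im <- naive_xcorr(img * M, img * M, max_shift)
  ac_m <- naive_xcorr(M, M, max_shift)
  rho <- sum(img * M) / sum(M)
  sh <- -max_shift:max_shift
  r_um <- sqrt(outer(sh^2, sh^2, "+")) * pixel_size
  keep <- r_um > 0 & r_um <= r_limit & ac_m > 0.5
  bin_id <- floor(r_um[keep] / bin_width) + 1L
  num <- tapply(ac_im[keep], bin_id, sum)
  den <- tapply(ac_m[keep], bin_id, sum)
  ids <- as.integer(names(num))
  g <- rep(NA_real_, max(ids))
  g[ids] <- (num / den) / rho^2
  g
}
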