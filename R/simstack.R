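# Synthetic confocal-stack and kinetics generator with exact ground truth.
#
# The simulated cell is a cylinder (footprint disk x height) resting on the
# synapse plane, mimicking a T cell spread on an antigen-coated coverslip.
# The reporter channel renders point fluorophores; the structural channel
# renders the filled cell body. Both are blurred with a separable Gaussian
# PSF whose axial tails create the positive below-cell intensity gradients
# the synapse detector exploits.

#' Simulation configuration
#'
#' Defaults describe a realistic single-cell confocal crop: 9 x 9 um field at
#' 0.125 um lateral pitch, 24 planes at the 0.3 um axial spacing typical of
#' these acquisitions, a 3 um-radius cell of height 4.5 um resting on plane 4,
#' and a diffraction-limited Gaussian PSF (sigma_xy 0.15 um, sigma_z 0.45 um).
#'
#' @param nx,ny,nz Grid size in voxels.
#' @param geometry A [voxel_geometry()].
#' @param synapse_plane 1-based index of the coverslip/cell interface plane.
#' @param cell_radius_xy Cell footprint radius, um.
#' @param cell_height Cell height above the synapse plane, um.
#' @param psf_sigma_xy,psf_sigma_z Gaussian PSF standard deviations, um.
#' @param background Additive camera background, ADU.
#' @param photon_scale Expected photons (ADU) per unit reporter source
#'   amplitude; the default treats one source as a vesicle-scale object.
#' @param struct_density Expected photons per voxel of the structural (actin-
#'   like) cortical shell.
#' @param interface_boost Multiplier on `struct_density` for the synaptic
#'   actin sheet at the interface plane. Values > 1 make the structural
#'   intensity peak at the interface, so axial gradients are positive below
#'   the cell and flip at the synapse plane.
#' @param read_noise_sd Gaussian read noise SD, ADU.
#' @param shot_noise Apply Poisson shot noise to signal + background.
#' @param seed Default RNG seed for rendering noise.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(nx = 72L, ny = 72L, nz = 24L,
                       geometry = voxel_geometry(0.125, 0.125, 0.3),
                       synapse_plane = 4L,
                       cell_radius_xy = 3, cell_height = 4.5,
                       psf_sigma_xy = 0.15, psf_sigma_z = 0.45,
                       background = 100, photon_scale = 1500,
                       struct_density = 150, interface_boost = 4,
                       read_noise_sd = 2,
                       shot_noise = TRUE, seed = 1L) {
  if (synapse_plane < 1L || synapse_plane > nz) {
    stop("synapse_plane must lie within [1, nz]", call. = FALSE)
  }
  if (psf_sigma_xy <= 0 || psf_sigma_z <= 0) {
    stop("PSF sigmas must be positive", call. = FALSE)
  }
  if (cell_radius_xy <= 0 || cell_height <= 0 || photon_scale < 0 ||
      background < 0 || read_noise_sd < 0 || struct_density < 0 ||
      interface_boost < 1) {
    stop("sizes must be positive; background, scales and noise nonnegative; interface_boost >= 1",
         call. = FALSE)
  }
  structure(list(
    nx = as.integer(nx), ny = as.integer(ny), nz = as.integer(nz),
    geometry = geometry, synapse_plane = as.integer(synapse_plane),
    cell_radius_xy = cell_radius_xy, cell_height = cell_height,
    psf_sigma_xy = psf_sigma_xy, psf_sigma_z = psf_sigma_z,
    background = background, photon_scale = photon_scale,
    struct_density = struct_density, interface_boost = interface_boost,
    read_noise_sd = read_noise_sd,
    shot_noise = isTRUE(shot_noise), seed = as.integer(seed)
  ), class = "sim_config")
}

# cell centre (um) in the lateral plane
cell_center_xy <- function(config) {
  c(config$nx * config$geometry$dx / 2, config$ny * config$geometry$dy / 2)
}

# axial position (um) of the synapse interface
synapse_z <- function(config) plane_z_um(config$geometry, config$synapse_plane)

#' Place fluorophores inside the simulated cell
#'
#' Distribution modes:
#' \describe{
#'   \item{uniform}{uniform in the cylindrical cell volume;}
#'   \item{synapse_enriched}{a fraction `f_syn` of points uniform in the slab
#'     within one dz above the synapse plane, the rest uniform in the volume;}
#'   \item{clustered}{cluster centres uniform in the synapse-plane disk,
#'     members laterally Gaussian around their centre with SD
#'     `cluster_radius`, at the synapse plane.}
#' }
#'
#' @param config A [sim_config()].
#' @param mode One of `"uniform"`, `"synapse_enriched"`, `"clustered"`.
#' @param n_points Number of fluorophores.
#' @param mode_params List: `f_syn` (enriched), `n_clusters` and
#'   `cluster_radius` um (clustered).
#' @param seed RNG seed; identical seeds give identical fields.
#' @return Object of class `fluorophore_field`: `points` (n x 3 matrix of
#'   x, y, z in um), `amplitudes`, `mode`, `mode_params`.
#' @export
place_fluorophores <- function(config, mode = c("uniform", "synapse_enriched", "clustered"),
                               n_points, mode_params = list(), seed = config$seed) {
  mode <- match.arg(mode)
  if (n_points < 1L) stop("n_points must be >= 1", call. = FALSE)
  ctr <- cell_center_xy(config)
  zs <- synapse_z(config)
  H <- config$cell_height
  R <- config$cell_radius_xy
  dz <- config$geometry$dz

  set.seed(seed)

  unif_disk <- function(n) {
    r <- R * sqrt(stats::runif(n))
    a <- stats::runif(n, 0, 2 * pi)
    cbind(ctr[1] + r * cos(a), ctr[2] + r * sin(a))
  }
  unif_volume <- function(n) {
    cbind(unif_disk(n), zs + stats::runif(n, 0, H))
  }

  if (mode == "uniform") {
    pts <- unif_volume(n_points)
  } else if (mode == "synapse_enriched") {
    f_syn <- mode_params$f_syn
    if (is.null(f_syn)) f_syn <- 0.8
    if (f_syn < 0 || f_syn > 1) stop("f_syn must be in [0, 1]", call. = FALSE)
    n_syn <- round(f_syn * n_points)
    pts_syn <- if (n_syn > 0) {
      cbind(unif_disk(n_syn), zs + stats::runif(n_syn, 0, min(dz, H)))
    } else NULL
    pts_rest <- if (n_points - n_syn > 0) unif_volume(n_points - n_syn) else NULL
    pts <- rbind(pts_syn, pts_rest)
  } else {
    n_clusters <- mode_params$n_clusters
    if (is.null(n_clusters)) n_clusters <- 5L
    cl_r <- mode_params$cluster_radius
    if (is.null(cl_r)) cl_r <- 0.15
    if (n_clusters < 1L || cl_r <= 0) {
      stop("need n_clusters >= 1 and cluster_radius > 0", call. = FALSE)
    }
    # centres stay cl_r inside the footprint so members rarely need clamping
    r0 <- max(R - 2 * cl_r, R / 2)
    rc <- r0 * sqrt(stats::runif(n_clusters))
    ac <- stats::runif(n_clusters, 0, 2 * pi)
    cx <- ctr[1] + rc * cos(ac)
    cy <- ctr[2] + rc * sin(ac)
    assign_cl <- sample.int(n_clusters, n_points, replace = TRUE)
    px <- cx[assign_cl] + stats::rnorm(n_points, 0, cl_r)
    py <- cy[assign_cl] + stats::rnorm(n_points, 0, cl_r)
    # clamp stragglers back into the footprint disk
    rr <- sqrt((px - ctr[1])^2 + (py - ctr[2])^2)
    over <- rr > R
    if (any(over)) {
      shrink <- (R * 0.999) / rr[over]
      px[over] <- ctr[1] + (px[over] - ctr[1]) * shrink
      py[over] <- ctr[2] + (py[over] - ctr[2]) * shrink
    }
    pts <- cbind(px, py, rep(zs, n_points))
  }
  colnames(pts) <- c("x", "y", "z")
  structure(list(
    points = pts, amplitudes = rep(1, nrow(pts)),
    mode = mode, mode_params = mode_params, seed = seed
  ), class = "fluorophore_field")
}

#' Ground truth of a fluorophore field
#'
#' Computed from the source points before any rendering or noise, so it is
#' independent of the rendering path under test.
#'
#' @param field A [place_fluorophores()] result.
#' @param config The [sim_config()] used.
#' @return Object of class `sim_truth`: `synapse_plane` (index),
#'   `synapse_z_um`, `cof_true` (x, y, z um), `axial_dispersion_true` um,
#'   `cluster_params`, `seed`.
#' @export
sim_truth <- function(field, config) {
  w <- field$amplitudes
  cof <- colSums(field$points * w) / sum(w)
  disp <- sum(w * abs(field$points[, "z"] - cof["z"])) / sum(w)
  structure(list(
    synapse_plane = config$synapse_plane,
    synapse_z_um = synapse_z(config),
    cof_true = cof,
    axial_dispersion_true = disp,
    cluster_params = field$mode_params,
    mode = field$mode,
    seed = field$seed
  ), class = "sim_truth")
}

# 1-D discrete Gaussian convolution matrix with zero padding (n x n).
# Kernel truncated at 4 sigma and normalised to unit sum, so interior mass
# is conserved and boundary mass leaks out (no wrap-around).
conv_matrix_1d <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  half <- max(1L, ceiling(4 * sigma_vox))
  k <- stats::dnorm(seq(-half, half), sd = sigma_vox)
  k <- k / sum(k)
  M <- matrix(0, n, n)
  for (off in seq(-half, half)) {
    idx <- seq_len(n)
    src <- idx + off
    ok <- src >= 1 & src <= n
    M[cbind(idx[ok], src[ok])] <- M[cbind(idx[ok], src[ok])] + k[off + half + 1]
  }
  M
}

# separable 3D Gaussian blur of a (z, y, x) array, zero-padded boundaries
blur_3d <- function(arr, sigma_z_vox, sigma_y_vox, sigma_x_vox) {
  d <- dim(arr)
  Mz <- conv_matrix_1d(d[1], sigma_z_vox)
  My <- conv_matrix_1d(d[2], sigma_y_vox)
  Mx <- conv_matrix_1d(d[3], sigma_x_vox)
  # z axis: fold (z) x (y*x)
  m <- matrix(arr, d[1], d[2] * d[3])
  arr <- array(Mz %*% m, d)
  # y axis
  arr <- aperm(arr, c(2, 1, 3))
  m <- matrix(arr, d[2], d[1] * d[3])
  arr <- array(My %*% m, c(d[2], d[1], d[3]))
  arr <- aperm(arr, c(2, 1, 3))
  # x axis
  arr <- aperm(arr, c(3, 2, 1))
  m <- matrix(arr, d[3], d[2] * d[1])
  arr <- array(Mx %*% m, c(d[3], d[2], d[1]))
  aperm(arr, c(3, 2, 1))
}

# bin point sources (um coordinates) into a (z, y, x) voxel grid
bin_points <- function(points, amplitudes, config) {
  g <- config$geometry
  ix <- pmin(pmax(ceiling(points[, "x"] / g$dx), 1L), config$nx)
  iy <- pmin(pmax(ceiling(points[, "y"] / g$dy), 1L), config$ny)
  # planes sit at (k-1)*dz: nearest plane index
  iz <- pmin(pmax(round(points[, "z"] / g$dz) + 1L, 1L), config$nz)
  arr <- array(0, c(config$nz, config$ny, config$nx))
  for (p in seq_along(amplitudes)) {
    arr[iz[p], iy[p], ix[p]] <- arr[iz[p], iy[p], ix[p]] + amplitudes[p]
  }
  arr
}

# (z, y, x) photon-density grid of the structural (actin-like) channel.
# Cortical actin is membrane-proximal: a bright synaptic sheet fills the
# footprint disk at the interface plane (density struct_density *
# interface_boost) and a thin lateral shell (~0.25 um) outlines the cell body
# above it at struct_density. Within the footprint interior the axial profile
# therefore peaks at the interface and is symmetric about it after blurring,
# so axial gradients are positive below the cell and flip at the synapse
# plane -- the premise the detector relies on.
cell_body_grid <- function(config) {
  g <- config$geometry
  ctr <- cell_center_xy(config)
  xs <- (seq_len(config$nx) - 0.5) * g$dx
  ys <- (seq_len(config$ny) - 0.5) * g$dy
  zs_planes <- plane_z_um(g, seq_len(config$nz))
  r2 <- outer(ys, xs, function(y, x) (x - ctr[1])^2 + (y - ctr[2])^2)
  R <- config$cell_radius_xy
  in_disk <- r2 <= R^2
  shell_thick <- 2 * g$dx
  in_shell <- in_disk & r2 >= (R - shell_thick)^2
  z0 <- synapse_z(config)
  in_z <- zs_planes >= z0 & zs_planes <= z0 + config$cell_height
  arr <- array(0, c(config$nz, config$ny, config$nx))
  for (k in which(in_z)) {
    if (k == config$synapse_plane) {
      arr[k, , ] <- in_disk * config$struct_density * config$interface_boost
    } else {
      arr[k, , ] <- in_shell * config$struct_density
    }
  }
  arr
}

#' Render a fluorophore field into a two-channel stack
#'
#' Reporter channel: point sources binned to voxels, blurred with the
#' separable Gaussian PSF, scaled by `photon_scale`. Structural channel: the
#' synaptic actin sheet plus the cortical shell (see [sim_config()]), blurred
#' the same way. Both then receive the camera model: Poisson shot noise on
#' signal + background (if `shot_noise`) and Gaussian read noise.
#'
#' @param field A [place_fluorophores()] result.
#' @param config A [sim_config()].
#' @param seed RNG seed for the noise draws.
#' @return A [voxel_stack()] with channels `reporter`, `structural`.
#' @export
render_stack <- function(field, config, seed = config$seed) {
  g <- config$geometry
  sz <- config$psf_sigma_z / g$dz
  sy <- config$psf_sigma_xy / g$dy
  sx <- config$psf_sigma_xy / g$dx

  reporter <- blur_3d(bin_points(field$points, field$amplitudes, config), sz, sy, sx) *
    config$photon_scale
  structural <- blur_3d(cell_body_grid(config), sz, sy, sx)

  set.seed(seed)
  apply_noise <- function(signal) {
    expected <- signal + config$background
    out <- if (config$shot_noise) {
      stats::rpois(length(expected), lambda = expected)
    } else {
      expected
    }
    if (config$read_noise_sd > 0) {
      out <- out + stats::rnorm(length(expected), 0, config$read_noise_sd)
    }
    array(pmax(out, 0), dim(signal))
  }
  rep_n <- apply_noise(reporter)
  str_n <- apply_noise(structural)

  arr <- array(0, c(2L, config$nz, config$ny, config$nx))
  arr[1, , , ] <- rep_n
  arr[2, , , ] <- str_n
  voxel_stack(arr, g, c("reporter", "structural"))
}

#' Simulate one cell: fluorophores, rendering, and ground truth
#'
#' @inheritParams place_fluorophores
#' @return List with elements `stack` (a [voxel_stack()]) and `truth`
#'   (a [sim_truth()]).
#' @export
simulate_cell <- function(config, mode = "uniform", mode_params = list(),
                          n_points = 400L, seed = config$seed) {
  field <- place_fluorophores(config, mode, n_points, mode_params, seed = seed)
  truth <- sim_truth(field, config)
  # decouple the noise stream from the placement stream
  stack <- render_stack(field, config, seed = seed + 10000L)
  list(stack = stack, truth = truth)
}

#' Simulate a luminescence time course
#'
#' Double-exponential complementation kinetics
#' \eqn{A (e^{-k_d t} - e^{-k_r t})} sampled at `dt`-minute intervals, with
#' optional Gaussian noise (clamped at zero: the plate reader reports
#' nonnegative light units). The closed-form peak time
#' \eqn{t^* = \log(k_r / k_d) / (k_r - k_d)} is attached as ground truth.
#'
#' @param k_rise,k_decay Rise and decay rates, per minute; `k_rise > k_decay`.
#' @param amplitude Scale, RLU.
#' @param t_max Duration, minutes (default 180, i.e. 3 h at 1-min cadence).
#' @param dt Sampling interval, minutes.
#' @param noise_sd Gaussian noise SD, RLU.
#' @param seed RNG seed.
#' @param n_wells Number of replicate wells.
#' @param condition Condition label applied to all wells.
#' @return A [plate_series()] with attributes `t_peak_true`, `peak_true`.
#' @export
simulate_kinetics <- function(k_rise, k_decay, amplitude = 1000, t_max = 180,
                              dt = 1, noise_sd = 0, seed = 1L, n_wells = 1L,
                              condition = "sim") {
  if (k_rise <= k_decay || k_decay <= 0) {
    stop("need k_rise > k_decay > 0", call. = FALSE)
  }
  times <- seq(0, t_max, by = dt)
  mu <- amplitude * (exp(-k_decay * times) - exp(-k_rise * times))
  set.seed(seed)
  vals <- matrix(rep(mu, n_wells), ncol = n_wells)
  if (noise_sd > 0) {
    vals <- vals + matrix(stats::rnorm(length(vals), 0, noise_sd), ncol = n_wells)
    vals <- pmax(vals, 0)
  }
  labels <- paste0("W", seq_len(n_wells))
  ps <- plate_series(times, vals, labels,
                     condition_map = stats::setNames(rep(condition, n_wells), labels))
  t_star <- log(k_rise / k_decay) / (k_rise - k_decay)
  attr(ps, "t_peak_true") <- t_star
  attr(ps, "peak_true") <- amplitude * (exp(-k_decay * t_star) - exp(-k_rise * t_star))
  ps
}
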