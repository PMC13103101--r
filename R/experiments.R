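# Study-level simulation experiments: the validation studies the analysis
# scripts and the acceptance checks run. Each function generates its own
# cells from a base seed, runs the pipeline, and returns tidy results.

#' Synapse-plane recovery experiment
#'
#' Simulates cells with the interface placed at varying planes and compares
#' the detected plane with ground truth.
#'
#' @param n_cells Number of simulated cells.
#' @param seed Base RNG seed.
#' @param config Base [sim_config()]; the synapse plane is varied per cell.
#' @param planes Candidate interface planes cycled across cells.
#' @return A tibble with `cell`, `mode`, `true_plane`, `detected_plane`,
#'   `abs_error`, plus attribute `rate_within_1` (fraction within one plane).
#' @export
experiment_synapse_recovery <- function(n_cells = 24, seed = 1,
                                        config = sim_config(),
                                        planes = 3:8) {
  acfg <- analysis_config()
  modes <- c("uniform", "synapse_enriched")
  rows <- lapply(seq_len(n_cells), function(i) {
    cfg_i <- config
    cfg_i$synapse_plane <- planes[(i - 1) %% length(planes) + 1]
    mode <- modes[(i - 1) %% 2 + 1]
    mp <- if (mode == "synapse_enriched") list(f_syn = 0.8) else list()
    sim <- simulate_cell(cfg_i, mode, mp, n_points = 300, seed = seed * 1000 + i)
    rep <- analyze_cell(sim$stack, acfg, cell_id = paste0("cell", i))
    tibble::tibble(cell = i, mode = mode,
                   true_plane = sim$truth$synapse_plane,
                   detected_plane = rep$synapse_plane,
                   abs_error = abs(rep$synapse_plane - sim$truth$synapse_plane))
  })
  out <- do.call(rbind, rows)
  attr(out, "rate_within_1") <- mean(!is.na(out$abs_error) & out$abs_error <= 1)
  out
}

#' Noiseless slab-cell distance recovery
#'
#' Slab cells (all sources within a thin layer on the interface) rendered
#' without noise isolate the rendering + COF chain: the recovered
#' COF-to-synapse distance must match the source-level truth to within one
#' plane spacing.
#'
#' @param planes Interface planes to test.
#' @param seed Base RNG seed.
#' @param config Base [sim_config()].
#' @return Tibble with per-cell true and recovered distances and errors.
#' @export
experiment_noiseless_slab <- function(planes = c(4L, 6L, 9L), seed = 1,
                                      config = sim_config()) {
  acfg <- analysis_config()
  rows <- lapply(planes, function(k) {
    cfg <- config
    cfg$synapse_plane <- k
    cfg$cell_height <- 0.25
    cfg$read_noise_sd <- 0
    cfg$shot_noise <- FALSE
    sim <- simulate_cell(cfg, "uniform", n_points = 300, seed = seed * 100 + k)
    rep <- analyze_cell(sim$stack, acfg)
    true_dist <- abs(sim$truth$cof_true[["z"]] - sim$truth$synapse_z_um)
    tibble::tibble(plane = k, detected_plane = rep$synapse_plane,
                   true_distance_um = true_dist,
                   recovered_distance_um = rep$cof_distance_um,
                   abs_error_um = abs(rep$cof_distance_um - true_dist))
  })
  do.call(rbind, rows)
}

#' Axial-dispersion ladder: estimate vs ground truth under noise
#'
#' Simulates cells across a ladder of synapse-enrichment fractions (hence a
#' ladder of true axial dispersions) at the default camera noise and
#' correlates estimated with true dispersion.
#'
#' @param n_cells Number of cells (>= 20 advised for a stable rank test).
#' @param seed Base RNG seed.
#' @param config Base [sim_config()].
#' @return Tibble of true and estimated dispersions with attribute
#'   `spearman_rho`.
#' @export
experiment_dispersion_ladder <- function(n_cells = 20, seed = 1,
                                         config = sim_config()) {
  acfg <- analysis_config()
  f_grid <- seq(0.05, 0.95, length.out = n_cells)
  rows <- lapply(seq_len(n_cells), function(i) {
    sim <- simulate_cell(config, "synapse_enriched", list(f_syn = f_grid[i]),
                         n_points = 300, seed = seed * 1000 + 500 + i)
    rep <- analyze_cell(sim$stack, acfg)
    tibble::tibble(f_syn = f_grid[i],
                   dispersion_true_um = sim$truth$axial_dispersion_true,
                   dispersion_est_um = rep$axial_dispersion_um)
  })
  out <- do.call(rbind, rows)
  attr(out, "spearman_rho") <- stats::cor(out$dispersion_true_um,
                                          out$dispersion_est_um,
                                          method = "spearman")
  out
}

#' Synapse-enriched vs uniform localization contrast
#'
#' The simulation analogue of comparing protease localization between a
#' synapse-recruiting condition and a dispersed condition: n cells per arm,
#' pooled two-tailed t on both per-cell metrics.
#'
#' @param n_per_arm Cells per condition.
#' @param seed Base RNG seed.
#' @param config Base [sim_config()].
#' @param f_syn Enrichment fraction of the enriched arm.
#' @return List with `reports` and `comparisons` (see [run_batch()]).
#' @export
experiment_localization_contrast <- function(n_per_arm = 15, seed = 1,
                                             config = sim_config(),
                                             f_syn = 0.9) {
  cells <- c(
    lapply(seq_len(n_per_arm), function(i) list(
      stack = simulate_cell(config, "synapse_enriched", list(f_syn = f_syn),
                            n_points = 300, seed = seed * 1000 + i)$stack,
      condition = "synapse_enriched", cell_id = paste0("enr", i))),
    lapply(seq_len(n_per_arm), function(i) list(
      stack = simulate_cell(config, "uniform", n_points = 300,
                            seed = seed * 1000 + 200 + i)$stack,
      condition = "uniform", cell_id = paste0("uni", i)))
  )
  run_batch(cells, analysis_config())
}

#' Clustered vs laterally-random g_ave discrimination
#'
#' Paired comparison: for each seed, one cell with laterally clustered
#' synapse-plane fluorophores and one with the same number of fluorophores
#' placed without lateral structure (uniform in the synapse slab, the CSR
#' reference). Both are rendered and analysed identically.
#'
#' @param n_pairs Number of seeded pairs.
#' @param seed Base RNG seed.
#' @param config Base [sim_config()].
#' @param n_clusters,cluster_radius Cluster parameters for the clustered arm.
#' @return Tibble of paired g_ave values with attribute `win_rate` (fraction
#'   of pairs with g_ave(clustered) > g_ave(CSR)).
#' @export
experiment_clustering_discrimination <- function(n_pairs = 40, seed = 1,
                                                 config = sim_config(),
                                                 n_clusters = 6,
                                                 cluster_radius = 0.2) {
  acfg <- analysis_config()
  rows <- lapply(seq_len(n_pairs), function(i) {
    cl <- simulate_cell(config, "clustered",
                        list(n_clusters = n_clusters, cluster_radius = cluster_radius),
                        n_points = 300, seed = seed * 1000 + 3000 + i)
    cs <- simulate_cell(config, "synapse_enriched", list(f_syn = 1),
                        n_points = 300, seed = seed * 1000 + 6000 + i)
    tibble::tibble(pair = i,
                   g_ave_clustered = analyze_cell(cl$stack, acfg)$g_ave,
                   g_ave_csr = analyze_cell(cs$stack, acfg)$g_ave)
  })
  out <- do.call(rbind, rows)
  attr(out, "win_rate") <- mean(out$g_ave_clustered > out$g_ave_csr, na.rm = TRUE)
  out
}

#' g_ave calibration on complete spatial randomness
#'
#' Homogeneous Poisson point images inside a disk mask: the pair
#' autocorrelation of CSR is identically 1, so g_ave must average to 1
#' within Monte-Carlo error.
#'
#' @param n_seeds Number of replicate point images.
#' @param seed Base RNG seed.
#' @param n_points Points per image.
#' @param side Image side, pixels.
#' @param pixel_size Pixel pitch, um.
#' @param r_max g_ave cutoff, um.
#' @return Tibble of per-replicate g_ave with attributes `mean` and `se`.
#' @export
experiment_csr_calibration <- function(n_seeds = 50, seed = 1, n_points = 600,
                                       side = 64L, pixel_size = 0.125,
                                       r_max = 0.5) {
  ctr <- (side + 1) / 2
  mask <- outer(seq_len(side), seq_len(side),
                function(y, x) (x - ctr)^2 + (y - ctr)^2 <= (0.42 * side)^2)
  in_mask <- which(mask)
  vals <- vapply(seq_len(n_seeds), function(i) {
    set.seed(seed * 1000 + i)
    img <- matrix(0, side, side)
    pts <- sample(in_mask, n_points, replace = TRUE)
    for (p in pts) img[p] <- img[p] + 1
    corr <- pair_autocorrelation(img, mask, bin_width = pixel_size,
                                 pixel_size = pixel_size)
    clustering_coefficient(corr, r_max)$g_ave
  }, numeric(1))
  out <- tibble::tibble(replicate = seq_len(n_seeds), g_ave = vals)
  attr(out, "mean") <- mean(vals)
  attr(out, "se") <- stats::sd(vals) / sqrt(n_seeds)
  out
}
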