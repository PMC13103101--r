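# Footprint segmentation and the masked pair autocorrelation g(r) / g_ave.

test_that("segmentation separates two constant regions exactly", {
  img <- matrix(10, 40, 40)
  img[10:30, 12:32] <- 1000
  mask <- segment_synapse_mask(img, segmentation_params(gaussian_sigma = 0.1,
                                                        morph_radius = 0L),
                               pixel_size = 0.1)
  inside <- matrix(FALSE, 40, 40); inside[10:30, 12:32] <- TRUE
  # smoothing blurs only the 1-px boundary ring; interior must be exact
  core <- matrix(FALSE, 40, 40); core[12:28, 14:30] <- TRUE
  expect_true(all(mask[core]))
  outer_ring <- !inside & row(img) %in% c(1:7, 33:40)
  expect_true(!any(mask[outer_ring]))
  expect_error(segment_synapse_mask(matrix(5, 20, 20), pixel_size = 0.1),
               class = "synloc_segmentation_degenerate")
})

test_that("segmentation recovers disk footprints from noisy mixtures and renders", {
  # two-Gaussian intensity mixture on a disk footprint at SNR 5: Dice >= 0.95
  set.seed(41)
  n <- 64
  true_fp <- outer(seq_len(n), seq_len(n),
                   function(y, x) (x - 32)^2 + (y - 32)^2 <= 20^2)
  img <- matrix(rnorm(n * n, 20, 10), n, n)          # background class
  img[true_fp] <- rnorm(sum(true_fp), 70, 10)        # signal class, SNR = 5
  img <- pmax(img, 0)
  mask <- segment_synapse_mask(img, segmentation_params(gaussian_sigma = 0.2),
                               pixel_size = 0.1)
  dice <- 2 * sum(mask & true_fp) / (sum(mask) + sum(true_fp))
  expect_gte(dice, 0.95)

  # rendered simulator footprint: the PSF halo blurs the boundary, so the
  # recovered footprint is close but not pixel-exact
  cfg <- small_sim_config(seed = 41)
  sim <- simulate_cell(cfg, "uniform", n_points = 200, seed = 41)
  stk <- subtract_background(sim$stack, estimate_background(sim$stack, "structural"),
                             "structural")
  plane <- channel_data(stk, "structural")[cfg$synapse_plane, , ]
  maskr <- segment_synapse_mask(plane, segmentation_params(), pixel_size = cfg$geometry$dx)
  ctr <- c(cfg$nx, cfg$ny) * cfg$geometry$dx / 2
  xs <- (seq_len(cfg$nx) - 0.5) * cfg$geometry$dx
  ys <- (seq_len(cfg$ny) - 0.5) * cfg$geometry$dy
  fp <- outer(ys, xs, function(y, x) (x - ctr[1])^2 + (y - ctr[2])^2 <=
                cfg$cell_radius_xy^2)
  dice_r <- 2 * sum(maskr & fp) / (sum(maskr) + sum(fp))
  expect_gte(dice_r, 0.80)
})

test_that("segmentation is deterministic and morphology is ordered", {
  cfg <- small_sim_config(seed = 43)
  sim <- simulate_cell(cfg, "uniform", n_points = 200, seed = 43)
  plane <- channel_data(sim$stack, "structural")[cfg$synapse_plane, , ]
  m1 <- segment_synapse_mask(plane, segmentation_params(), cfg$geometry$dx)
  m2 <- segment_synapse_mask(plane, segmentation_params(), cfg$geometry$dx)
  expect_identical(m1, m2)

  # opening shrinks, closing grows, on random blob images
  brush <- EBImage::makeBrush(5, "disc")
  set.seed(7)
  for (i in 1:20) {
    img <- EBImage::gblur(matrix(runif(30 * 30), 30, 30), 2) > 0.5
    op <- EBImage::opening(img, brush) > 0
    cl <- EBImage::closing(img, brush) > 0
    expect_lte(sum(op), sum(img))
    expect_gte(sum(cl), sum(img))
  }
})

test_that("g(r) is exactly 1 for constant masked intensity and scale-invariant", {
  mask <- matrix(FALSE, 48, 48)
  mask[8:40, 10:38] <- TRUE
  img <- matrix(0, 48, 48)
  img[mask] <- 7.5
  corr <- pair_autocorrelation(img, mask, bin_width = 0.1, pixel_size = 0.1)
  expect_true(all(abs(corr$g[corr$supported] - 1) < 1e-9))

  gave <- clustering_coefficient(corr, r_max = 0.5)
  expect_equal(gave$g_ave, 1, tolerance = 1e-9)

  set.seed(11)
  img2 <- matrix(rexp(48 * 48), 48, 48)
  c1 <- pair_autocorrelation(img2, mask, bin_width = 0.1, pixel_size = 0.1)
  img3 <- img2 * 42
  c2 <- pair_autocorrelation(img3, mask, bin_width = 0.1, pixel_size = 0.1)
  expect_equal(c1$g, c2$g, tolerance = 1e-12)
})

test_that("FFT estimator matches the naive shift-loop oracle", {
  set.seed(13)
  mask <- matrix(FALSE, 32, 32)
  mask[5:28, 4:29] <- TRUE
  # sparse point image, < 200 points
  img <- matrix(0, 32, 32)
  pts <- sample(which(mask), 150)
  img[pts] <- 1
  px <- 0.1
  corr <- pair_autocorrelation(img, mask, bin_width = 0.1, pixel_size = px,
                               r_limit = 0.8)
  g_naive <- naive_g_of_r(img, mask, bin_width = 0.1, pixel_size = px, r_limit = 0.8)
  n <- min(length(corr$g), length(g_naive))
  ok <- corr$supported[1:n] & !is.na(g_naive[1:n])
  expect_equal(corr$g[1:n][ok], g_naive[1:n][ok], tolerance = 1e-9)
})

test_that("CSR intensity fields give g near 1; clustered fields exceed CSR", {
  px <- 0.1
  mask <- matrix(TRUE, 56, 56)
  g_means <- replicate(25, NA_real_)
  set.seed(29)
  for (i in 1:25) {
    img <- matrix(0, 56, 56)
    pts <- sample(length(img), 600, replace = TRUE)  # homogeneous Poisson counts
    for (p in pts) img[p] <- img[p] + 1
    corr <- pair_autocorrelation(img, mask, bin_width = 0.1, pixel_size = px,
                                 r_limit = 0.6)
    sel <- corr$supported & corr$r_bins >= 0.1 & corr$r_bins <= 0.5
    g_means[i] <- mean(corr$g[sel])
  }
  se <- sd(g_means) / sqrt(length(g_means))
  expect_lt(abs(mean(g_means) - 1), 3 * se + 0.02)

  # a single tight cluster: small-r g dwarfs large-r g
  imgc <- matrix(0, 56, 56)
  set.seed(31)
  cx <- round(rnorm(200, 28, 1.2)); cy <- round(rnorm(200, 28, 1.2))
  keep <- cx >= 1 & cx <= 56 & cy >= 1 & cy <= 56
  for (p in seq_len(sum(keep))) {
    imgc[cy[keep][p], cx[keep][p]] <- imgc[cy[keep][p], cx[keep][p]] + 1
  }
  corrc <- pair_autocorrelation(imgc, mask, bin_width = 0.1, pixel_size = px,
                                r_limit = 1.2)
  first_supported <- min(which(corrc$supported))
  last_supported <- max(which(corrc$supported))
  expect_gt(corrc$g[first_supported], 10 * corrc$g[last_supported])
  expect_gt(corrc$g[first_supported], 10)  # strong small-r enrichment
})

test_that("g_ave is the unweighted mean over supported bins below the cutoff", {
  corr <- structure(list(
    r_bins = c(0.1, 0.2, 0.4), g = c(3, 1, 1), bin_counts = c(10, 10, 10),
    bin_width = 0.1, supported = c(TRUE, TRUE, TRUE)
  ), class = "radial_correlation")
  expect_equal(clustering_coefficient(corr, r_max = 0.25)$g_ave, 2)
  expect_equal(clustering_coefficient(corr, r_max = 0.5)$g_ave, 5 / 3)
  corr$supported <- rep(FALSE, 3)
  expect_error(clustering_coefficient(corr, 0.25),
               class = "synloc_insufficient_support")
})

test_that("clustered simulator fields score higher g_ave than matched CSR fields", {
  cfg <- small_sim_config()
  acfg <- analysis_config()
  wins <- 0L
  n_pairs <- 10
  for (s in seq_len(n_pairs)) {
    cl <- simulate_cell(cfg, "clustered", list(n_clusters = 5, cluster_radius = 0.2),
                        n_points = 250, seed = 4000 + s)
    cs <- simulate_cell(cfg, "synapse_enriched", list(f_syn = 1),
                        n_points = 250, seed = 5000 + s)
    g_cl <- analyze_cell(cl$stack, acfg)$g_ave
    g_cs <- analyze_cell(cs$stack, acfg)$g_ave
    if (isTRUE(g_cl > g_cs)) wins <- wins + 1L
  }
  expect_gte(wins, n_pairs - 1L)
})
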