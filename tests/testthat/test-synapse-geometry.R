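# Background estimation, intensity masking, axial gradients, and the
# synapse-plane detection rule.

make_stack <- function(arr, dz = 0.3) {
  voxel_stack(arr, voxel_geometry(0.1, 0.1, dz), "structural")
}

test_that("background estimator recovers constant, zero, and noisy offsets", {
  s <- make_stack(array(37, c(1, 5, 6, 6)))
  expect_equal(estimate_background(s, 1)$offset, 37)
  s0 <- make_stack(array(0, c(1, 5, 6, 6)))
  expect_equal(estimate_background(s0, 1)$offset, 0)

  # known background + sparse bright signal: offset within 3 * sd/sqrt(n_dim)
  set.seed(21)
  n <- c(1, 10, 24, 24)
  arr <- array(pmax(rnorm(prod(n), 50, 4), 0), n)
  arr[1, 5, 1:4, 1:4] <- 5000
  sn <- make_stack(arr)
  bg <- estimate_background(sn, 1)
  # the dimmest-decile median estimates a low quantile of the noise, so it
  # must sit below the true mean but within a few noise SDs of it
  expect_lt(bg$offset, 50)
  expect_gt(bg$offset, 50 - 3 * 4)
})

test_that("background subtraction clamps at zero and leaves other channels alone", {
  g <- voxel_geometry(0.1, 0.1, 0.3)
  arr <- array(20, c(2, 3, 4, 4))
  arr[1, 2, 1, 1] <- 30
  s <- voxel_stack(arr, g, c("a", "b"))
  out <- subtract_background(s, 20, "a")
  expect_equal(out$data[1, 2, 1, 1], 10)
  expect_equal(sum(out$data[1, , , ]), 10)  # every other voxel clamped to 0
  expect_equal(out$data[2, , , ], s$data[2, , , ])
  expect_lte(sum(out$data[1, , , ]), sum(s$data[1, , , ]))
})

test_that("percentile mask honours its boundary cases and target fraction", {
  set.seed(3)
  arr <- array(0, c(1, 4, 10, 10))
  nz_vals <- sample(1:1000, 200)
  arr[sample(length(arr), 200)] <- nz_vals
  s <- make_stack(arr)
  m0 <- sufficient_intensity_mask(s, 1, threshold_rule(p = 0))
  expect_equal(sum(m0), 200)          # all nonzero voxels
  m100 <- sufficient_intensity_mask(s, 1, threshold_rule(p = 100))
  expect_equal(sum(m100), 1)          # only the maximum
  m75 <- sufficient_intensity_mask(s, 1, threshold_rule(p = 75))
  # brute-force check of the percentile definition
  thr <- quantile(nz_vals, 0.75)
  expect_equal(sum(m75), sum(nz_vals >= thr))
  expect_equal(sum(m75) / 200, 0.25, tolerance = 0.02)

  empty <- sufficient_intensity_mask(make_stack(array(0, c(1, 3, 4, 4))), 1,
                                     threshold_rule(p = 50))
  expect_true(attr(empty, "empty"))
})

test_that("axial gradients are exact on linear data and match a naive oracle", {
  dz <- 0.3
  nz <- 6
  arr <- array(rep(5 * (seq_len(nz) - 1), 5 * 5), c(1, nz, 5, 5))  # slope 5 ADU/plane
  s <- make_stack(arr, dz)
  g <- axial_gradients(s, 1)
  expect_true(all(abs(g[2:(nz - 1), , ] - 5 / dz) < 1e-12))
  expect_true(all(abs(g[1, , ] - 5 / dz) < 1e-12))   # one-sided, exact for linear

  expect_true(all(axial_gradients(make_stack(array(7, c(1, 4, 3, 3))), 1) == 0))
  expect_error(axial_gradients(make_stack(array(1, c(1, 2, 3, 3))), 1), "3 z-planes")

  # naive voxel-loop oracle
  rs <- random_stack(c(1, 5, 4, 4), seed = 9)
  g2 <- axial_gradients(rs, 1)
  v <- channel_data(rs, 1)
  dzr <- rs$geometry$dz
  for (k in 1:5) for (j in 1:4) for (i in 1:4) {
    expected <- if (k == 1) (v[2, j, i] - v[1, j, i]) / dzr
    else if (k == 5) (v[5, j, i] - v[4, j, i]) / dzr
    else (v[k + 1, j, i] - v[k - 1, j, i]) / (2 * dzr)
    expect_equal(g2[k, j, i], expected, tolerance = 1e-12)
  }

  # linearity of the gradient operator
  a <- random_stack(c(1, 5, 4, 4), seed = 1)
  b <- random_stack(c(1, 5, 4, 4), seed = 2)
  ab <- a; ab$data <- 2 * a$data + 3 * b$data
  expect_equal(axial_gradients(ab, 1),
               2 * axial_gradients(a, 1) + 3 * axial_gradients(b, 1))
})

test_that("synapse detection finds a noiseless slab interface", {
  # noiseless rendered cell: detected plane within one plane of the interface
  cfg <- small_sim_config(read_noise_sd = 0, shot_noise = FALSE)
  sim <- simulate_cell(cfg, "uniform", n_points = 100, seed = 1)
  stk <- subtract_background(sim$stack, estimate_background(sim$stack, "structural"),
                             "structural")
  res <- detect_synapse_plane(stk, synapse_detection_params())
  expect_lte(abs(res$plane_index - cfg$synapse_plane), 1)
  expect_equal(res$plane_z_um, plane_z_um(cfg$geometry, res$plane_index))
  frs <- res$per_plane_positive_fraction
  expect_true(all(frs[!is.na(frs)] >= 0 & frs[!is.na(frs)] <= 1))
  # planes below the detected interface that vote must be consistently positive
  below <- frs[seq_len(res$plane_index - 1)]
  expect_true(any(below[!is.na(below)] >= 0.75))
})

test_that("degenerate stacks raise the dedicated detection errors", {
  # strictly increasing in z everywhere: gradients never stop being positive
  nz <- 8
  arr <- array(rep((seq_len(nz)) * 10, 12 * 12), c(1, nz, 12, 12))
  s <- make_stack(arr)
  expect_error(
    detect_synapse_plane(s, synapse_detection_params(threshold_rule(p = 0),
                                                     min_voxels = 5)),
    class = "synloc_synapse_above_stack")

  # background-only stack: with every nonzero voxel voting, no plane can
  # reach a 75% positive-gradient fraction by chance
  set.seed(5)
  noise <- array(abs(rnorm(8 * 24 * 24, 0, 1)), c(1, 8, 24, 24))
  expect_error(
    detect_synapse_plane(make_stack(noise),
                         synapse_detection_params(threshold_rule(p = 0))),
    class = "synloc_no_synapse")
})

test_that("detection is invariant to intensity scaling and offset re-estimation", {
  cfg <- small_sim_config(seed = 31)
  sim <- simulate_cell(cfg, "uniform", n_points = 150, seed = 31)
  prep <- function(stack) {
    subtract_background(stack, estimate_background(stack, "structural"), "structural")
  }
  base <- detect_synapse_plane(prep(sim$stack), synapse_detection_params())

  scaled <- sim$stack
  scaled$data <- scaled$data * 3.7
  expect_equal(detect_synapse_plane(prep(scaled), synapse_detection_params())$plane_index,
               base$plane_index)

  shifted <- sim$stack
  shifted$data <- shifted$data + 50
  expect_equal(detect_synapse_plane(prep(shifted), synapse_detection_params())$plane_index,
               base$plane_index)
})
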