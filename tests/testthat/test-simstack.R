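# Synthetic generator: seeded determinism, placement distributions, ground
# truth, PSF rendering, and kinetics curves.

test_that("placement is deterministic and respects each distribution mode", {
  cfg <- small_sim_config()
  f1 <- place_fluorophores(cfg, "uniform", n_points = 200, seed = 11)
  f2 <- place_fluorophores(cfg, "uniform", n_points = 200, seed = 11)
  expect_identical(f1$points, f2$points)

  # fully enriched: every z within one dz of the synapse plane
  fe <- place_fluorophores(cfg, "synapse_enriched", n_points = 300,
                           mode_params = list(f_syn = 1), seed = 2)
  zs <- plane_z_um(cfg$geometry, cfg$synapse_plane)
  expect_true(all(fe$points[, "z"] >= zs & fe$points[, "z"] <= zs + cfg$geometry$dz))
  expect_error(place_fluorophores(cfg, "synapse_enriched", n_points = 10,
                                  mode_params = list(f_syn = 1.5)), "f_syn")

  # clustered: all points at the synapse plane, inside the footprint
  fc <- place_fluorophores(cfg, "clustered", n_points = 200,
                           mode_params = list(n_clusters = 4, cluster_radius = 0.15),
                           seed = 5)
  expect_true(all(fc$points[, "z"] == zs))
  ctr <- c(cfg$nx * cfg$geometry$dx / 2, cfg$ny * cfg$geometry$dy / 2)
  rr <- sqrt((fc$points[, "x"] - ctr[1])^2 + (fc$points[, "y"] - ctr[2])^2)
  expect_true(all(rr <= cfg$cell_radius_xy))
})

test_that("uniform placement matches the moments of the uniform distribution", {
  cfg <- small_sim_config()
  n <- 10000
  f <- place_fluorophores(cfg, "uniform", n_points = n, seed = 99)
  zs <- plane_z_um(cfg$geometry, cfg$synapse_plane)
  H <- cfg$cell_height
  # mean z = zs + H/2 within 3 standard errors (SE of uniform = H/sqrt(12n))
  se_mean <- H / sqrt(12 * n)
  expect_lt(abs(mean(f$points[, "z"]) - (zs + H / 2)), 3 * se_mean)
  # mean |z - mean| = H/4 within 3 SE (SD of |U - H/2| is H/(4 sqrt 3))
  truth <- sim_truth(f, cfg)
  se_mad <- H / (4 * sqrt(3 * n))
  expect_lt(abs(truth$axial_dispersion_true - H / 4), 3 * se_mad)
})

test_that("ground truth reproduces closed-form two-point values", {
  cfg <- small_sim_config()
  f <- place_fluorophores(cfg, "uniform", n_points = 2, seed = 1)
  f$points[, "z"] <- c(1.0, 3.0)
  truth <- sim_truth(f, cfg)
  expect_equal(unname(truth$cof_true["z"]), 2.0)
  expect_equal(truth$axial_dispersion_true, 1.0)

  sim <- simulate_cell(cfg, "synapse_enriched", list(f_syn = 1), n_points = 50, seed = 3)
  expect_lte(sim$truth$axial_dispersion_true, cfg$geometry$dz)
})

test_that("noise-free rendering leaves pure background and conserves mass", {
  cfg <- small_sim_config(background = 55, read_noise_sd = 0, shot_noise = FALSE,
                          photon_scale = 0, struct_density = 0)
  f <- place_fluorophores(cfg, "uniform", n_points = 10, seed = 1)
  stk <- render_stack(f, cfg)
  expect_true(all(stk$data == 55))

  # sources >= 4 sigma from every boundary: total intensity above background
  # equals photon_scale * sum(amplitudes) up to kernel truncation
  cfg2 <- sim_config(nx = 48, ny = 48, nz = 24, synapse_plane = 9,
                     cell_radius_xy = 1.5, cell_height = 2.4,
                     background = 0, read_noise_sd = 0, shot_noise = FALSE,
                     struct_density = 0, photon_scale = 500)
  f2 <- place_fluorophores(cfg2, "uniform", n_points = 40, seed = 2)
  stk2 <- render_stack(f2, cfg2)
  total <- sum(channel_data(stk2, "reporter"))
  expect_equal(total, cfg2$photon_scale * sum(f2$amplitudes), tolerance = 1e-3)
})

test_that("a single on-axis point renders symmetrically with argmax at its plane", {
  cfg <- small_sim_config(background = 0, read_noise_sd = 0, shot_noise = FALSE,
                          struct_density = 0, synapse_plane = 9)
  f <- place_fluorophores(cfg, "uniform", n_points = 1, seed = 1)
  # place exactly at a voxel centre on plane 9
  f$points[1, ] <- c((24 - 0.5) * 0.125, (24 - 0.5) * 0.125, plane_z_um(cfg$geometry, 9))
  stk <- render_stack(f, cfg)
  prof <- apply(channel_data(stk, "reporter"), 1, sum)
  expect_equal(which.max(prof), 9)
  expect_equal(prof[9 - 3], prof[9 + 3], tolerance = 1e-9)
})

test_that("expected reporter intensity peaks at the synapse plane for enriched fields", {
  cfg <- small_sim_config(read_noise_sd = 0, shot_noise = FALSE, struct_density = 0)
  sim <- simulate_cell(cfg, "synapse_enriched", list(f_syn = 1), n_points = 500, seed = 4)
  prof <- apply(channel_data(sim$stack, "reporter") - cfg$background, 1, mean)
  k <- cfg$synapse_plane
  sigma_planes <- ceiling(3 * cfg$psf_sigma_z / cfg$geometry$dz)
  above <- (k + sigma_planes):length(prof)
  expect_true(all(prof[k] > prof[above]))
})

test_that("seeded rendering is reproducible and noise obeys the camera model", {
  cfg <- small_sim_config()
  s1 <- simulate_cell(cfg, "uniform", n_points = 100, seed = 8)
  s2 <- simulate_cell(cfg, "uniform", n_points = 100, seed = 8)
  expect_identical(s1$stack$data, s2$stack$data)
  s3 <- simulate_cell(cfg, "uniform", n_points = 100, seed = 9)
  expect_false(identical(s1$stack$data, s3$stack$data))

  # background-only region: variance approximately Poisson(background) + read noise
  cfg0 <- small_sim_config(photon_scale = 0, struct_density = 0,
                           background = 100, read_noise_sd = 2)
  stk <- render_stack(place_fluorophores(cfg0, "uniform", n_points = 1, seed = 1), cfg0)
  v <- as.vector(channel_data(stk, "reporter"))
  expect_equal(mean(v), 100, tolerance = 0.02)
  expect_equal(stats::var(v), 104, tolerance = 0.05)
})

test_that("kinetics simulation matches the double-exponential closed form", {
  expect_error(simulate_kinetics(0.02, 0.10), "k_rise > k_decay")
  ps <- simulate_kinetics(0.10, 0.02, amplitude = 1000, t_max = 180, dt = 1,
                          noise_sd = 0, seed = 1)
  expect_equal(unname(ps$values[1, 1]), 0)
  t_star <- log(0.10 / 0.02) / (0.10 - 0.02)
  pk <- peak_luminescence(ps, 1)
  expect_lte(abs(pk$t_peak - t_star), 1)
  expect_equal(attr(ps, "t_peak_true"), t_star)
  ps2 <- simulate_kinetics(0.10, 0.02, amplitude = 1000, noise_sd = 20, seed = 5)
  ps3 <- simulate_kinetics(0.10, 0.02, amplitude = 1000, noise_sd = 20, seed = 5)
  expect_identical(ps2$values, ps3$values)
})
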