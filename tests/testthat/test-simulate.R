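test_that("accurate perception integrates the displacement exactly", {
  set.seed(901)
  tr <- cube_random_walk(3000)
  # at kappa = Inf the plane-dependent update reduces to B dx: volumetric
  # and plane-independent trials produce identical activity
  t1 <- simulate_trial(tr, "volumetric", kappa = Inf, tau = 10, seed = 902)
  t2 <- simulate_trial(tr, "plane_independent", seed = 903)
  expect_equal(t1$a_prime, t2$a_prime, tolerance = 1e-9)

  # closed trajectory: activity returns to the start
  loop <- rbind(tr$positions[1:50, ], tr$positions[1, , drop = FALSE])
  tl <- simulate_trial(loop, "plane_independent", seed = 904)
  expect_lt(max(Mod(tl$activity[51, ] - tl$activity[1, ])), 1e-9)
})

test_that("perception noise perturbs the integrated path", {
  set.seed(905)
  tr <- cube_random_walk(3000)
  t_acc <- simulate_trial(tr, "volumetric", kappa = Inf, tau = 10,
                          seed = 906)
  t_noisy <- simulate_trial(tr, "volumetric", kappa = 300, tau = 10,
                            seed = 906)
  expect_gt(max(abs(t_acc$a_prime - t_noisy$a_prime)), 0.05)
})

test_that("sweeps are deterministic and carry the full schema", {
  cfg <- sweep_config(kappas = c(300, Inf), taus = c(50, 500),
                      n_trajectories = 2, n_steps = 3000, n_shuffles = 10,
                      n_bins = 10, seed = 7)
  sw1 <- run_sweep(cfg)
  sw2 <- run_sweep(cfg)
  expect_equal(sw1, sw2)
  # samples per (kappa, tau): n_trajectories x 4 neurons
  counts <- table(sw1$kappa, sw1$tau)
  expect_true(all(counts == 2 * 4))
  expect_true(all(c("trajectory", "kappa", "tau", "neuron", "n_spikes",
                    "si", "z_si", "sparsity", "z_sparsity", "chi_fcc",
                    "chi_hcp", "chi_col", "n_fields", "median_ifd") %in%
                    names(sw1)))
  expect_error(sweep_config(kappas = -1), "kappas")
})

test_that("mode demos report the expected field structure", {
  demo <- run_mode_demo("planar", n_steps = 4e4, seed = 3)
  expect_true(all(demo$summary$hex_2d > 0.5))
  expect_equal(nrow(demo$summary), 3)
})

test_that("virtual walk is independent of the number of sub-updates", {
  arena <- switch_arena()
  consts <- grid_constants()
  c0 <- exp(1i * c(0.3, -1.2, 2.2, 0.5))
  dxp <- c(0.4, -0.3, 0)
  v1 <- virtual_walk(c0, dxp, arena, "flat", consts, n = 1)
  v100 <- virtual_walk(c0, dxp, arena, "flat", consts, n = 100)
  expect_lt(max(Mod(v1 - v100)), 1e-9)
  # zero displacement restores the stored pattern exactly
  expect_equal(virtual_walk(c0, c(0, 0, 0), arena, "slope", consts), c0,
               tolerance = 1e-12)
})

test_that("mode switching shifts the grid unless the phase is restored", {
  ex0 <- run_switch_experiment(restore = FALSE, seed = 11)
  ex1 <- run_switch_experiment(restore = TRUE, seed = 11)
  expect_equal(ex0$visits$region, c("flat", "slope", "flat", "slope"))
  expect_true(all(ex0$visits$end - ex0$visits$start + 1 >= 5000))
  # region membership is a deterministic function of position
  z <- ex0$positions[, 3]
  x <- ex0$positions[, 1]
  expect_true(all(z[x < 0] == 0))
  expect_equal(z[x >= 0], tan(30 * pi / 180) * x[x >= 0], tolerance = 1e-12)

  for (reg in c("flat", "slope")) {
    m0 <- switch_map_correlation(ex0, reg)
    # translated copy: high correlation at a common nonzero offset
    expect_gt(m0$corr_at_peak, 0.4)
    expect_gt(sqrt(sum(m0$offset^2)), 0.05)
    expect_gt(m0$corr_at_peak, m0$corr_at_zero + 0.2)
    expect_true(all(m0$per_neuron > 0.2))
    # restored: second-visit fields overlap the first
    m1 <- switch_map_correlation(ex1, reg)
    expect_gt(m1$corr_at_zero, 0.4)
    d1 <- compare_switch_fields(ex1, reg)
    expect_gt(nrow(d1), 3)
    expect_lt(median(d1$dist), median(d1$radius))
  }
})
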