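test_that("cube walk respects bounds, step size, and corner clipping", {
  set.seed(401)
  tr <- cube_random_walk(5000)
  expect_true(all(abs(tr$positions) <= 1))
  expect_lte(max(abs(diff(tr$positions))), 0.08)

  # starting in the corner, the next step can only move inward
  tc <- cube_random_walk(50, init = c(1, 1, 1))
  expect_true(all(tc$positions[2, ] >= 1 - 0.08))
  expect_true(all(tc$positions[2, ] <= 1))
})

test_that("a long walk covers the whole cube", {
  set.seed(402)
  tr <- cube_random_walk(1e5)
  b <- floor((tr$positions + 1) / 2 * 10)
  b[b == 10] <- 9
  idx <- b[, 1] + 10 * b[, 2] + 100 * b[, 3] + 1
  occupied <- length(unique(idx))
  expect_gte(occupied, 990)  # at least 99% of the 10^3 bins
})

test_that("manifold walks ride the surface with unit normals", {
  flat <- function(x, y) 0 * x
  set.seed(403)
  trf <- manifold_walk(2000, flat)
  expect_true(all(trf$positions[, 3] == 0))
  expect_equal(trf$normals, matrix(c(0, 0, 1), 2000, 3, byrow = TRUE))

  surf <- gaussian_bump_surface()
  set.seed(404)
  tr <- manifold_walk(2000, surf)
  expect_equal(tr$positions[, 3],
               surf(tr$positions[, 1], tr$positions[, 2]))
  expect_equal(unname(sqrt(rowSums(tr$normals^2))), rep(1, 2000),
               tolerance = 1e-12)
  # analytic gradient agrees with finite differences
  g <- attr(surf, "gradient")(0.3, -0.2)
  h <- 1e-6
  gfd <- c((surf(0.3 + h, -0.2) - surf(0.3 - h, -0.2)) / (2 * h),
           (surf(0.3, -0.2 + h) - surf(0.3, -0.2 - h)) / (2 * h))
  expect_equal(unname(drop(g)), gfd, tolerance = 1e-6)
})

test_that("the wandering axis refreshes on schedule with small turns", {
  set.seed(405)
  u <- c(0, 0, 1)
  for (t in 1:9) {
    u2 <- trajectory_axis(t %% 10, u, tau = 10)
    if (t %% 10 != 0) expect_identical(u2, u)
  }
  U <- trajectory_axes(2000, kappa_traj = 200)
  ang <- acos(pmin(1, rowSums(U[-1, ] * U[-2000, ])))
  # expected angle ~ acos(coth(200) - 1/200) ~ 5.7 degrees
  expect_equal(mean(ang), acos(vmf_mean_resultant(200)),
               tolerance = 0.15)
  # tau = T means a single axis for the whole trial
  tr <- cube_random_walk(500)
  trial <- simulate_trial(tr, "volumetric", kappa = 300, tau = 500,
                          seed = 406)
  expect_s3_class(trial, "grid_trial")
})

test_that("trajectory and spike tables round-trip through text files", {
  set.seed(407)
  tr <- cube_random_walk(300)
  f <- tempfile(fileext = ".tsv")
  write_trajectory(tr, f)
  tr2 <- read_trajectory(f)
  expect_equal(tr2$positions, tr$positions, tolerance = 1e-12)

  trial <- simulate_trial(tr, "volumetric", kappa = Inf, tau = 10,
                          seed = 408)
  fs <- tempfile(fileext = ".tsv")
  write_spikes(trial, fs)
  spk <- read_spikes(fs)
  expect_equal(nrow(spk), sum(trial$counts))
  expect_true(all(spk$neuron %in% 1:4))
  unlink(c(f, fs))
})
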