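# positions at the centers of an n^3 grid, one visit per bin, visited in a
# fixed order; lets rate maps be constructed exactly
grid_positions <- function(n) {
  ctrs <- seq(-1 + 1 / n, 1 - 1 / n, length.out = n)
  as.matrix(expand.grid(x = ctrs, y = ctrs, z = ctrs))
}

test_that("rate maps accumulate occupancy and rates exactly", {
  # hand-built 2-bin case: visits 3:1, spikes 6:2 -> rates (2, 2)
  pos <- rbind(matrix(c(-0.5, -0.5, -0.5), 3, 3, byrow = TRUE),
               c(0.5, 0.5, 0.5))
  m <- bin_rate_map(pos, c(2, 2, 2, 2), n_bins = 2)
  expect_equal(sum(m$p), 1)
  v <- m$visits > 0
  expect_equal(sort(m$visits[v]), c(1, 3))
  expect_equal(unname(m$rate[v]), c(2, 2))
  expect_equal(spatial_information(m), 0)
  expect_equal(sparsity_index(m), 1)
  expect_error(bin_rate_map(pos, 1:3), "nrow")
})

test_that("information and sparsity hit their closed forms", {
  X <- grid_positions(2)
  # uniform: SI = 0, sparsity = 1
  mu <- bin_rate_map(X, rep(5, 8), n_bins = 2)
  expect_equal(spatial_information(mu), 0)
  expect_equal(sparsity_index(mu), 1)
  # one active bin of 8: SI = 3 bits, sparsity = 1/8
  m1 <- bin_rate_map(X, c(8, rep(0, 7)), n_bins = 2)
  expect_equal(spatial_information(m1), 3)
  expect_equal(sparsity_index(m1), 1 / 8)
  # p = (1/2, 1/2), lambda = (1, 3)
  pos <- rbind(matrix(c(-0.5, -0.5, -0.5), 2, 3, byrow = TRUE),
               matrix(c(0.5, 0.5, 0.5), 2, 3, byrow = TRUE))
  m2 <- bin_rate_map(pos, c(1, 1, 3, 3), n_bins = 2)
  expect_equal(spatial_information(m2),
               0.5 * 0.5 * log2(0.5) + 0.5 * 1.5 * log2(1.5),
               tolerance = 1e-12)
  expect_equal(sparsity_index(m2), 4 / 5, tolerance = 1e-12)
  expect_error(spatial_information(bin_rate_map(X, rep(0, 8), n_bins = 2)),
               "all-zero")
})

test_that("shuffle Z-scores separate spatial from non-spatial firing", {
  set.seed(701)
  tr <- cube_random_walk(4000)
  # null: position-independent Poisson spikes -> |Z| rarely beyond 2.58
  hits <- 0L
  for (r in 1:20) {
    spk <- rpois(4000, 0.3)
    z <- shuffle_zscore(tr, spk, spatial_information, n_shuffles = 50,
                        n_bins = 10)
    hits <- hits + (abs(z) < 2.58)
  }
  expect_gte(hits, 18L)

  # positive control: rate modulated by position across the whole trial
  # (the walk revisits both halves many times, so the circular shift
  # destroys the alignment)
  spk <- rpois(4000, ifelse(tr$positions[, 1] > 0, 0.8, 0.02))
  z_si <- shuffle_zscore(tr, spk, spatial_information, n_bins = 10)
  expect_gt(z_si, 2.58)
  z_sp <- shuffle_zscore(tr, spk, sparsity_index, n_bins = 10)
  expect_lt(z_sp, -2.58)
})

test_that("3D autocorrelograms are symmetric, unit-centered, calibrated", {
  set.seed(702)
  noise <- array(rnorm(30^3), rep(30, 3))
  ac <- autocorrelogram_3d(noise)
  ctr <- ac$center
  expect_equal(ac$A[ctr[1], ctr[2], ctr[3]], 1)
  # off-center correlations are small where the overlap is substantial
  win <- -10:10
  off <- ac$A[ctr[1] + win, ctr[2] + win, ctr[3] + win]
  off[11, 11, 11] <- NA
  expect_lt(max(abs(off), na.rm = TRUE), 0.1)
  # symmetry under offset negation
  idx <- rbind(c(3, -2, 5), c(1, 1, 1), c(-7, 0, 2))
  for (k in seq_len(nrow(idx))) {
    a1 <- ac$A[ctr[1] + idx[k, 1], ctr[2] + idx[k, 2], ctr[3] + idx[k, 3]]
    a2 <- ac$A[ctr[1] - idx[k, 1], ctr[2] - idx[k, 2], ctr[3] - idx[k, 3]]
    expect_equal(a1, a2, tolerance = 1e-10)
  }
  # periodic map peaks at its period
  p <- 5
  per <- array(0, rep(20, 3))
  per[] <- cos(2 * pi * slice.index(per, 1) / p)
  acp <- autocorrelogram_3d(per)
  cp <- acp$center
  expect_gt(acp$A[cp[1] + p, cp[2], cp[3]], 0.99)
  expect_gt(acp$A[cp[1] - p, cp[2], cp[3]], 0.99)
})

test_that("modified radial autocorrelation uses sqrt-shell normalization", {
  # synthetic autocorrelation array: delta at the center -> zero shells
  deltaA <- array(0, rep(9, 3))
  deltaA[5, 5, 5] <- 1
  ac <- structure(list(A = deltaA, center = c(5, 5, 5)),
                  class = "autocorr3")
  mra <- modified_radial_autocorr(ac)
  expect_equal(length(mra$value), 4)
  expect_true(all(mra$value == 0))

  A2 <- ac
  A2$A <- ac$A * 2
  m1 <- modified_radial_autocorr(ac)
  m2 <- modified_radial_autocorr(A2)
  expect_equal(m2$value, 2 * m1$value, tolerance = 1e-12)

  # shells partition by Euclidean radius: shell 1 holds the 6+12+8 = 26
  # offsets with 0 < r <= 1... i.e. the 6 unit offsets
  expect_equal(m1$n[1], 6)
  # sqrt normalization: a constant-1 array gives sum/sqrt(N) = sqrt(N)
  ones <- ac
  ones$A[] <- 1
  mo <- modified_radial_autocorr(ones)
  expect_equal(mo$value, sqrt(mo$n), tolerance = 1e-12)
})

test_that("MRA reveals lattice periodicity and its absence in RND", {
  set.seed(703)
  fcc <- prototype_cloud("FCC", points_per_vertex = 200)
  acf <- autocorrelogram_3d(fcc$points, n_bins = 20)
  mf <- modified_radial_autocorr(acf)
  d_bins <- default_spacing() / 0.1
  # first non-central peak near the lattice spacing (in bins)
  v <- mf$value
  pk <- which(diff(sign(diff(v))) < 0) + 1
  pk <- pk[pk > 2]
  expect_true(any(abs(pk - d_bins) <= 1.5))
  # and a second repeat farther out
  expect_true(any(pk > d_bins + 2))

  rnd <- prototype_cloud("RND", points_per_vertex = 200)
  mr <- modified_radial_autocorr(autocorrelogram_3d(rnd$points, n_bins = 20))
  vr <- mr$value
  first_peak <- max(vr[1:3])
  later <- vr[6:length(vr)]
  lpk <- which(diff(sign(diff(later))) < 0) + 1
  if (length(lpk))
    expect_lt(max(later[lpk]), 0.5 * first_peak)
})

test_that("slice grid scores identify hexagonal and square symmetry", {
  set.seed(704)
  fcc <- prototype_cloud("FCC", points_per_vertex = 300)
  ac <- autocorrelogram_3d(fcc$points, n_bins = 20)
  # horizontal slice of this FCC construction is a hexagonal layer
  og <- orientation_grid(6)
  vertical <- og[og$el == 90, ][1, ]
  sc <- slice_grid_scores(ac, vertical)
  expect_gt(sc$hex, 0.5)

  # isotropic noise: no orientation shows the structured symmetry level;
  # individual slices are noisy (tiny annuli), so test the average
  noise <- array(rnorm(20^3), rep(20, 3))
  acn <- autocorrelogram_3d(noise)
  scn <- slice_grid_scores(acn, og[og$el %in% c(0, 42, 90), ])
  expect_lt(mean(abs(c(scn$hex, scn$square)), na.rm = TRUE), 0.4)
  expect_lt(mean(scn$hex, na.rm = TRUE), sc$hex / 2)

  # a square lattice in the horizontal plane: square score beats hex
  sq <- array(0, rep(20, 3))
  sq[] <- cos(2 * pi * slice.index(sq, 1) / 6) +
          cos(2 * pi * slice.index(sq, 2) / 6)
  acs <- autocorrelogram_3d(sq)
  scs <- slice_grid_scores(acs, vertical)
  expect_gt(scs$square, scs$hex)
  expect_gt(scs$square, 0.5)
})
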