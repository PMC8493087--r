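test_that("FCC and HCP lattices have 12-fold coordination but differ", {
  vf <- lattice_vertices("FCC")
  vh <- lattice_vertices("HCP")
  d <- default_spacing()
  for (v in list(vf, vh)) {
    D <- as.matrix(dist(v))
    diag(D) <- Inf
    ctr <- which.min(rowSums(v^2))
    expect_equal(min(D), d, tolerance = 1e-9)
    expect_equal(sum(abs(D[ctr, ] - d) < 1e-6), 12)
  }
  # stacking period distinguishes the packings: atoms align vertically
  # every 2 layers in HCP (A-B) but every 3 in FCC (A-B-C); use a finer
  # spacing so several stacking periods fit inside the cube
  min_vertical_gap <- function(v) {
    gaps <- c()
    for (i in seq_len(nrow(v))) {
      same_col <- abs(v[, 1] - v[i, 1]) < 1e-6 &
                  abs(v[, 2] - v[i, 2]) < 1e-6
      dz <- abs(v[same_col, 3] - v[i, 3])
      gaps <- c(gaps, dz[dz > 1e-6])
    }
    min(gaps)
  }
  s <- 0.4
  dz <- s * sqrt(2 / 3)
  expect_equal(min_vertical_gap(lattice_vertices("HCP", s)), 2 * dz,
               tolerance = 1e-6)
  expect_equal(min_vertical_gap(lattice_vertices("FCC", s)), 3 * dz,
               tolerance = 1e-6)

  expect_error(lattice_vertices("FCC", spacing = 2.5), "spacing too large")
})

test_that("columnar vertices stack one hexagonal offset at 1/10 interlayer", {
  v <- columnar_vertices()
  # undo the 8-degree rotation: all layers project to one hexagonal lattice
  v0 <- v %*% rotation_z(8)
  xy <- unique(round(v0[, 1:2], 6))
  expect_lt(nrow(xy), nrow(v) / 5)  # many layers share each column
  zs <- sort(unique(round(v0[, 3], 9)))
  expect_equal(min(diff(zs)), default_spacing() * sqrt(2 / 3) / 10,
               tolerance = 1e-6)
})

test_that("random vertices are uniform in the cube", {
  set.seed(501)
  v <- random_vertices(100)
  expect_true(all(abs(v) <= 1))
  # per-coordinate mean within 3 sigma of 0 (sd = (2/sqrt(12))/sqrt(100))
  expect_true(all(abs(colMeans(v)) < 3 * 0.577 / 10))
  # minimum pairwise distance is typically far below the lattice spacing
  D <- dist(v)
  expect_lt(min(D), default_spacing() / 2)
})

test_that("blurred clouds recover their vertices under mean-shift", {
  set.seed(502)
  v <- lattice_vertices("FCC")
  tight <- blur_vertices(v, sigma = 1e-9, points_per_vertex = 5)
  expect_equal(tight$points[1:5, ], v[rep(1, 5), ], tolerance = 1e-6)

  cloud <- blur_vertices(v, sigma = 0.05, points_per_vertex = 200)
  fs <- detect_fields(cloud$points, bounds = NULL)
  expect_lt(abs(nrow(fs$centers) - nrow(v)) / nrow(v), 0.05)

  # per-cluster covariance ~ sigma^2 I (averaged over clusters to beat
  # the per-cluster sampling noise of the variance estimate)
  covs <- vapply(seq_len(nrow(fs$centers)), function(k) {
    idx <- which(fs$assignment == k)
    if (length(idx) < 100) return(rep(NA_real_, 6))
    S <- cov(cloud$points[idx, ])
    c(diag(S), S[upper.tri(S)])
  }, numeric(6))
  expect_equal(unname(rowMeans(covs[1:3, ], na.rm = TRUE)),
               rep(0.05^2, 3), tolerance = 0.1)
  expect_lt(max(abs(rowMeans(covs[4:6, , drop = FALSE], na.rm = TRUE))),
            0.1 * 0.05^2)
})

test_that("columnar clouds cluster into elongated columns", {
  set.seed(503)
  cloud <- prototype_cloud("COL", points_per_vertex = 30)
  fs <- suppressWarnings(detect_fields(cloud$points, bounds = NULL))
  skip_if(nrow(fs$centers) < 2)
  anis <- vapply(seq_len(min(5, nrow(fs$centers))), function(k) {
    pts <- cloud$points[which(fs$assignment == k), , drop = FALSE]
    if (nrow(pts) < 40) return(NA_real_)
    ev <- eigen(cov(pts), only.values = TRUE)$values
    ev[1] / ev[3]
  }, numeric(1))
  expect_gt(median(anis, na.rm = TRUE), 3)  # elongated, not spherical
})
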