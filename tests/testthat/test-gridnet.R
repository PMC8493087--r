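consts <- grid_constants()

test_that("network constants satisfy the tetrahedral-basis identities", {
  Bn <- consts$B / consts$b0
  expect_equal(unname(rowSums(Bn^2)), rep(1, 4), tolerance = 1e-12)
  G <- tcrossprod(Bn)
  expect_equal(unname(G[upper.tri(G)]), rep(-1 / 3, 6), tolerance = 1e-12)
  expect_equal(unname(colSums(Bn)), rep(0, 3), tolerance = 1e-12)
  expect_lt(max(Mod(consts$U %*% Conj(t(consts$U)) - diag(4))), 1e-14)
  expect_error(grid_constants(b0 = 0), "nonzero")
})

test_that("weight generators are commuting skew-Hermitian matrices", {
  set.seed(301)
  for (i in 1:20) {
    u <- random_unit()
    if (u[3] < -0.999) next
    phi <- runif(1, -pi, pi)
    W <- weight_generators(u, c(cos(phi), sin(phi)), consts)
    expect_lt(max(Mod(W$W_r + Conj(t(W$W_r)))), 1e-12)
    expect_lt(max(Mod(W$W_b + Conj(t(W$W_b)))), 1e-12)
    expect_lt(max(Mod(W$W_r %*% W$W_b - W$W_b %*% W$W_r)), 1e-12)
  }
  # vertical axis: W_b eigenvalues are i * B e_z
  Wz <- weight_generators(c(0, 0, 1), c(1, 0), consts)$W_b
  ev <- sort(Im(eigen(Wz, only.values = TRUE)$values))
  expect_equal(ev, sort(drop(consts$B %*% c(0, 0, 1))), tolerance = 1e-10)
})

test_that("eigenbasis update equals the literal matrix exponential", {
  set.seed(302)
  state <- network_state(consts)
  for (i in 1:10) {
    u <- random_unit()
    if (u[3] < -0.999) next
    rot <- plane_rotation(u)
    cd <- decompose_displacement(rnorm(3, sd = 0.1), rot)
    W <- weight_generators(u, cd$gamma, consts, M = rot$M)
    a_oracle <- drop(expm_complex(W$W_r * cd$r + W$W_b * cd$b) %*% state$a)
    state <- update_activity(state, cd, u, consts, M = rot$M)
    expect_lt(max(Mod(state$a - a_oracle)), 1e-9)
    # eigen-coordinate moduli are conserved
    expect_equal(Mod(state$c), rep(1, 4), tolerance = 1e-12)
  }
})

test_that("null updates and closed loops leave the activity unchanged", {
  st0 <- network_state(consts)
  cd0 <- decompose_displacement(c(0, 0, 0), u = c(0, 0, 1))
  st <- update_activity(st0, cd0, c(0, 0, 1), consts)
  expect_equal(st$a, st0$a, tolerance = 1e-12)

  set.seed(303)
  steps <- matrix(rnorm(60, sd = 0.1), 20, 3)
  steps <- rbind(steps, -colSums(steps))  # closes the loop
  st <- st0
  for (i in seq_len(nrow(steps))) {
    u <- random_unit()
    if (u[3] < -0.999) u <- c(0, 0, 1)
    rot <- plane_rotation(u)
    cd <- decompose_displacement(steps[i, ], rot)
    st <- update_activity(st, cd, u, consts, M = rot$M)
  }
  expect_lt(max(Mod(st$a - st0$a)), 1e-9)
})

test_that("the activity is periodic along lattice translations", {
  # a displacement p with B p = 2 pi (1, -1, 0, 0) exists because the rows
  # of B sum to zero; after moving by p every phase advances by 2 pi k
  m <- 2 * pi * c(1, -1, 0, 0)
  p <- drop(qr.solve(consts$B, m))
  expect_lt(max(abs(consts$B %*% p - m)), 1e-9)
  st0 <- network_state(consts)
  rot <- plane_rotation(c(0, 0, 1))
  cd <- decompose_displacement(p, rot)
  st <- update_activity(st0, cd, c(0, 0, 1), consts, M = rot$M)
  expect_lt(max(Mod(st$a - st0$a)), 1e-9)
})

test_that("activity normalization maps the trial range onto [0, 1]", {
  h <- cbind(seq(-2, 2, length.out = 11), rep(1, 11))
  expect_warning(n <- normalized_activity(h), "constant")
  expect_equal(n[1, 1], 0)
  expect_equal(n[11, 1], 1)
  expect_true(all(n[, 2] == 0.5))

  s <- matrix(sin(seq(0, 20 * pi, length.out = 4001)), ncol = 1)
  expect_equal(mean(normalized_activity(s)), 0.5, tolerance = 1e-3)
})

test_that("logistic rate and Poisson emission match closed forms", {
  expect_equal(spike_rate(0.7), 1 / 2.1, tolerance = 1e-12)
  expect_equal(spike_rate(1e6), 1 / 1.1, tolerance = 1e-9)
  expect_equal(spike_rate(0), 1 / (1.1 + exp(10.5)), tolerance = 1e-12)
  expect_true(all(spike_rate(seq(0, 1, 0.01)) < 1 / 1.1))

  expect_identical(emit_spikes(rep(0, 10)), rep(0L, 10))
  set.seed(304)
  k <- emit_spikes(rep(0.476, 1e5))
  se <- sqrt(0.476 / 1e5)
  expect_lt(abs(mean(k) - 0.476), 3 * se)
  expect_equal(var(k), mean(k), tolerance = 0.05)
})

test_that("planar navigation yields hexagonal firing fields", {
  set.seed(305)
  tr <- cube_random_walk(1e5, dims = 2)
  trial <- simulate_trial(tr, "planar", seed = 306)
  for (j in 1:3) {
    g <- gridness_2d(spike_positions(trial, j)[, 1:2])
    expect_gt(g$hex, 0.5)
  }
})
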