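test_that("backbone selection follows the R3/S9 index rule", {
  t4 <- build_chain_topology(4)
  expect_equal(backbone_selection(t4), c(3L, 9L, 12L, 18L))
  expect_equal(nrow(backbone_vectors(build_initial_coordinates(t4), t4)), 3)
  for (nd in c(1, 5, 50)) {
    top <- build_chain_topology(2 * nd)
    expect_equal(length(backbone_selection(top)), 2 * nd)
    co <- build_initial_coordinates(top)
    expect_equal(nrow(backbone_vectors(co, top)), 2 * nd - 1)
  }
  expect_error(backbone_selection(build_monomer_topology("GlcNAc")), "R3/S9")
})

test_that("autocorrelation handles the exact limiting chains", {
  # straight chain: all vectors parallel
  straight <- matrix(rep(c(0.5, 0, 0), 10), ncol = 3, byrow = TRUE)
  C <- bond_autocorrelation(straight)
  expect_equal(C$C, rep(1, 10), tolerance = 1e-12)
  expect_identical(C$C[1], 1)
  # alternating +-x: C(n) = (-1)^n
  alt <- matrix(rep(c(1, 0, 0, -1, 0, 0), 5), ncol = 3, byrow = TRUE)
  Ca <- bond_autocorrelation(alt)
  expect_equal(Ca$C, (-1)^(0:9), tolerance = 1e-12)
  expect_true(all(abs(Ca$C) <= 1 + 1e-12))
  expect_error(bond_autocorrelation(matrix(c(1, 0, 0), 1, 3)), "2 bond vectors")
})

test_that("C(n) is unchanged by reversing the chain direction", {
  traj <- sample_wlc(n_bonds = 25, d = 0.5, l_p = 3, n_frames = 200, seed = 5)
  C_fwd <- bond_autocorrelation(traj)
  rev_traj <- -traj[, rev(seq_len(dim(traj)[2])), , drop = FALSE]
  C_rev <- bond_autocorrelation(rev_traj)
  expect_equal(C_fwd$C, C_rev$C, tolerance = 1e-12)
})

test_that("exact exponential series invert to the closed-form persistence length", {
  n <- 0:30
  series <- data.frame(n = n, C = exp(-n / 20))
  fit <- fit_persistence_length(series, d = 0.5)
  expect_equal(fit$l_p, 10, tolerance = 1e-6)
  expect_identical(fit$status, "ok")
  fit_log <- fit_persistence_length(series, d = 0.5, method = "log")
  expect_equal(fit_log$l_p, 10, tolerance = 1e-9)
  # non-decaying series: graceful non-fit
  flat <- data.frame(n = 0:10, C = rep(1, 11))
  nf <- fit_persistence_length(flat, d = 0.5)
  expect_true(is.na(nf$l_p))
  expect_identical(nf$status, "exceeds resolvable range")
})

test_that("a noisy synthetic series is recovered within 10 percent", {
  set.seed(914)
  n <- 0:40
  truth <- 8  # l_p / d = 16
  series <- data.frame(n = n, C = exp(-n * 0.5 / truth) + rnorm(41, 0, 0.02))
  series$C[1] <- 1
  fit <- fit_persistence_length(series, d = 0.5)
  expect_lt(abs(fit$l_p - truth) / truth, 0.10)
})

test_that("the full WLC pipeline recovers the target persistence length", {
  d <- 0.5
  l_p <- 5
  traj <- sample_wlc(n_bonds = 40, d = d, l_p = l_p, n_frames = 2000, seed = 77)
  C <- bond_autocorrelation(traj)
  fit <- fit_persistence_length(C, d = d)
  expect_lt(abs(fit$l_p - l_p) / l_p, 0.10)
  # estimator tightens with more frames
  small <- sample_wlc(n_bonds = 40, d = d, l_p = l_p, n_frames = 100, seed = 78)
  big <- sample_wlc(n_bonds = 40, d = d, l_p = l_p, n_frames = 2000, seed = 78)
  err_small <- abs(fit_persistence_length(bond_autocorrelation(small), d)$l_p - l_p)
  err_big <- abs(fit_persistence_length(bond_autocorrelation(big), d)$l_p - l_p)
  expect_lt(err_big, err_small + 0.25)
})

test_that("persistence_length runs end-to-end on chain coordinates", {
  top <- build_chain_topology(20)
  co <- build_initial_coordinates(top)
  traj <- array(0, dim = c(4, nrow(co), 3))
  for (f in 1:4) traj[f, , ] <- co
  fit <- persistence_length(traj, top)
  # a rigid, nearly straight repeat geometry: correlations stay high, so
  # either a large l_p or a declared non-fit is acceptable behavior
  expect_true(is.na(fit$l_p) || fit$l_p > 2)
  expect_gt(fit$d, 0.3)
  expect_lt(fit$d, 1.2)
})

test_that("radius of gyration and end-to-end match closed forms", {
  single <- matrix(c(1, 2, 3), 1, 3)
  g1 <- gyration_and_e2e(single)
  expect_equal(g1$per_frame$rg, 0)
  two <- rbind(c(0, 0, 0), c(1, 0, 0))
  g2 <- gyration_and_e2e(two)
  expect_equal(g2$per_frame$e2e, 1)
  expect_equal(g2$per_frame$rg, 0.5)
  # discrete rod limit: Rg^2 = (n^2 - 1) / 12 * s^2 -> L^2 / 12
  n <- 2000
  rod <- cbind(seq(0, 10, length.out = n), 0, 0)
  gr <- gyration_and_e2e(rod)
  expect_equal(gr$per_frame$rg^2, 10^2 / 12, tolerance = 0.01)
})

test_that("surface areas follow sphere closed forms and converge", {
  one <- matrix(0, 1, 3)
  a1 <- sasa(one, radii = 0.264, probe_radius = 0.14)
  expect_equal(as.numeric(a1), 4 * pi * 0.404^2, tolerance = 1e-6)
  expect_equal(as.numeric(a1), 2.051, tolerance = 1e-3)
  # two distant beads: additive
  two_far <- rbind(c(0, 0, 0), c(5, 0, 0))
  a2 <- sasa(two_far, radii = c(0.264, 0.264), probe_radius = 0.14)
  expect_equal(as.numeric(a2), 2 * as.numeric(a1), tolerance = 1e-9)
  # coincident identical beads: area of one
  two_same <- rbind(c(0, 0, 0), c(0, 0, 0))
  a3 <- sasa(two_same, radii = c(0.264, 0.264), probe_radius = 0.14)
  expect_equal(as.numeric(a3), as.numeric(a1), tolerance = 1e-9)
  # size-class radii come from the topology
  t2 <- build_chain_topology(2)
  co <- build_initial_coordinates(t2)
  a_top <- sasa(co, t2)
  expect_gt(as.numeric(a_top), 0)
  # resolution convergence: doubling the point count moves the area < 0.5%
  a480 <- sasa(co, t2, n_points = 480)
  a960 <- sasa(co, t2, n_points = 960)
  expect_lt(abs(a960 - a480) / a960, 0.005)
})

test_that("aggregate clustering groups molecules by minimum bead distance", {
  t8 <- build_chain_topology(8)
  co <- build_initial_coordinates(t8)
  n <- nrow(co)
  # 25 well-separated copies
  spread <- do.call(rbind, lapply(1:25, function(m) sweep(co, 2, c(10 * m, 0, 0), "+")))
  mol <- rep(1:25, each = n)
  sizes <- cluster_aggregates(spread, mol, cutoff = 0.6)
  expect_equal(as.integer(sizes), rep(1L, 25))
  # all within contact: one aggregate of 25
  tight <- do.call(rbind, lapply(1:25, function(m) sweep(co, 2, c(0.1 * m, 0, 0), "+")))
  expect_equal(as.integer(cluster_aggregates(tight, mol, cutoff = 0.6)), 25L)
  # two planted groups of 13 and 12, separated by 50 nm
  planted <- do.call(rbind, lapply(1:25, function(m) {
    base <- if (m <= 13) c(0.2 * m, 0, 0) else c(50 + 0.2 * m, 0, 0)
    sweep(co, 2, base, "+")
  }))
  expect_equal(as.integer(cluster_aggregates(planted, mol, cutoff = 0.6)),
               c(13L, 12L))
})
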