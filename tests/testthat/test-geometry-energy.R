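test_that("internal-coordinate measurements follow the standard conventions", {
  co <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  expect_equal(measure(co, c(1, 2))$value, 1.0)
  expect_equal(measure(rbind(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 1:3)$value, 90)
  # trans-planar quadruplet: 180 wraps to -180
  trans <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))
  expect_equal(measure(trans, 1:4)$value, -180)
  # cis-planar quadruplet: 0
  cis <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  expect_equal(measure(cis, 1:4)$value, 0)
  # sign convention: a +90 degree screw
  screw <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 0, 1))
  expect_equal(abs(measure(screw, 1:4)$value), 90)
  # exactly collinear triplets are errors; near-collinear warns
  lin <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_error(measure(lin, 1:3), "collinear")
  nearlin <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 1e-5, 0))
  expect_warning(v <- measure(nearlin, 1:3)$value, "near-collinear")
  expect_gt(v, 179.9)
  expect_error(measure(co, c(1, 5)), "out of range")
})

test_that("term energies match their closed forms", {
  nac <- monomer_parameter_set("GlcNAc")
  b14 <- nac$bonds[nac$bonds$i == 1 & nac$bonds$j == 4, ]
  co0 <- matrix(0, 5, 3)
  co0[4, ] <- c(0.270, 0, 0)
  expect_equal(term_energy(b14, co0), 0)
  co1 <- co0
  co1[4, 1] <- 0.280
  expect_equal(term_energy(b14, co1), 0.5 * 10700 * 0.010^2, tolerance = 1e-10)
  expect_equal(term_energy(b14, co1), 0.535, tolerance = 1e-6)

  # G96 cosine angle: zero at theta0, 1/2 k (cos th - cos th0)^2 away from it
  ang <- data.frame(i = 1, j = 2, k = 3, k_theta = 230, theta0 = 81,
                    form = "g96_cosine")
  make_angle <- function(th) rbind(c(1, 0, 0), c(0, 0, 0),
                                   c(cos(th * pi / 180), sin(th * pi / 180), 0))
  expect_equal(term_energy(ang, make_angle(81)), 0, tolerance = 1e-12)
  expect_equal(term_energy(ang, make_angle(100)),
               0.5 * 230 * (cos(100 * pi / 180) - cos(81 * pi / 180))^2,
               tolerance = 1e-10)

  # improper: displacement wrapped and converted to radians (GROMACS type 2)
  imp <- data.frame(i = 1, j = 2, k = 3, l = 4, k_xi = 300, xi0 = 10.5)
  make_dih <- function(phi) rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                                  c(1, cos(phi * pi / 180), sin(phi * pi / 180)))
  expect_equal(measure(make_dih(25), 1:4)$value, 25, tolerance = 1e-9)
  expect_equal(term_energy(imp, make_dih(10.5)), 0, tolerance = 1e-12)
  expect_equal(term_energy(imp, make_dih(25)),
               0.5 * 300 * ((25 - 10.5) * pi / 180)^2, tolerance = 1e-9)

  # proper dihedral: k (1 + cos(m phi - phi0)); zero where the cosine is -1
  dih <- data.frame(i = 1, j = 2, k = 3, l = 4, k_phi = -32, phi0 = -138,
                    mult = 1L)
  expect_equal(term_energy(dih, make_dih(42)), 0, tolerance = 1e-9)  # 42+138 = 180
  expect_equal(term_energy(dih, make_dih(-138)), 2 * (-32), tolerance = 1e-9)
})

test_that("energies are invariant under rigid motions", {
  t2 <- build_chain_topology(2)
  co <- perturbed_geometry(build_initial_coordinates(t2), 0.02, seed = 7)
  e0 <- total_bonded_energy(t2, co)
  for (s in 1:5) {
    moved <- random_rigid_motion(co, seed = 100 + s)
    e1 <- total_bonded_energy(t2, moved)
    expect_equal(e1$total, e0$total, tolerance = 1e-9)
    expect_equal(e1$by_class, e0$by_class, tolerance = 1e-9)
  }
})

test_that("energy is continuous through the dihedral wrap point", {
  imp <- data.frame(i = 1, j = 2, k = 3, l = 4, k_xi = 300, xi0 = -165)
  make_dih <- function(phi) rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                                  c(1, cos(phi * pi / 180), sin(phi * pi / 180)))
  # the two geometries are 0.002 degrees apart; energies must nearly agree
  e_plus <- term_energy(imp, make_dih(179.999))
  e_minus <- term_energy(imp, make_dih(-179.999))
  expect_lt(abs(e_plus - e_minus), 0.01)
  dih <- data.frame(i = 1, j = 2, k = 3, l = 4, k_phi = -60, phi0 = -165,
                    mult = 1L)
  expect_lt(abs(term_energy(dih, make_dih(179.999)) -
                term_energy(dih, make_dih(-179.999))), 0.01)
})

test_that("restricted bending diverges monotonically approaching linearity", {
  ang <- data.frame(i = 1, j = 2, k = 3, k_theta = 345, theta0 = 146,
                    form = "restricted_bending")
  make_angle <- function(th) rbind(c(1, 0, 0), c(0, 0, 0),
                                   c(cos(th * pi / 180), sin(th * pi / 180), 0))
  grid <- c(160, 170, 175, 178, 179, 179.5, 179.9)
  e <- suppressWarnings(
    vapply(grid, function(th) term_energy(ang, make_angle(th)), numeric(1)))
  expect_true(all(diff(e) > 0))
  expect_gt(e[length(e)], 100 * e[1])
})

test_that("breakdown totals are additive and linear in the force constants", {
  t4 <- build_chain_topology(4)
  co <- perturbed_geometry(build_initial_coordinates(t4), 0.03, seed = 11)
  e <- total_bonded_energy(t4, co)
  expect_equal(e$total, sum(unlist(e$per_term)), tolerance = 1e-9)
  expect_equal(e$total, sum(e$by_class), tolerance = 1e-9)
  doubled <- t4
  doubled$bonds$k_b <- 2 * doubled$bonds$k_b
  doubled$angles$k_theta <- 2 * doubled$angles$k_theta
  doubled$impropers$k_xi <- 2 * doubled$impropers$k_xi
  doubled$dihedrals$k_phi <- 2 * doubled$dihedrals$k_phi
  e2 <- total_bonded_energy(doubled, co)
  # dihedral terms carry a k-independent offset: V = k (1 + cos(...))
  expect_equal(e2$by_class[["bonds"]], 2 * e$by_class[["bonds"]], tolerance = 1e-9)
  expect_equal(e2$by_class[["angles"]], 2 * e$by_class[["angles"]], tolerance = 1e-9)
  expect_equal(e2$by_class[["impropers"]], 2 * e$by_class[["impropers"]],
               tolerance = 1e-9)
  expect_equal(e2$by_class[["dihedrals"]], 2 * e$by_class[["dihedrals"]],
               tolerance = 1e-9)
  # harmonic classes are nonnegative at any geometry
  expect_gte(e$by_class[["bonds"]], 0)
  expect_gte(e$by_class[["angles"]], 0)
  expect_gte(e$by_class[["impropers"]], 0)
  # per-frame series over a trajectory
  traj <- array(0, dim = c(2, 18, 3))
  traj[1, , ] <- co
  traj[2, , ] <- co
  series <- total_bonded_energy(t4, traj)
  expect_equal(nrow(series), 2)
  expect_equal(series$total, rep(e$total, 2), tolerance = 1e-9)
  expect_error(total_bonded_energy(t4, co[1:10, ]), "does not match")
})
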