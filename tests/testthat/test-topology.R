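test_that("free monosaccharide topologies match their tables", {
  nac <- build_monomer_topology("GlcNAc")
  expect_equal(nrow(nac$beads), 5)
  expect_equal(nrow(nac$bonds), 6)
  expect_equal(nrow(nac$angles), 3)
  expect_equal(nrow(nac$impropers), 2)
  expect_equal(nrow(nac$dihedrals), 0)
  expect_equal(nac$net_charge, 0)
  # the free sugar carries the anomeric hydroxyl: bead 2 is small
  expect_identical(nac$beads$label[2], "S2")
  expect_identical(nac$beads$mass[2], 54)
  expect_equal(nac$recommended_timestep, 0.03)

  ga <- build_monomer_topology("GlcA")
  expect_equal(nrow(ga$beads), 4)
  expect_equal(ga$net_charge, -1)
  expect_identical(ga$beads$label[2], "S7")
  lab <- ga$beads$label
  bond_labels <- sort(paste(pmin(lab[ga$bonds$i], lab[ga$bonds$j]),
                            pmax(lab[ga$bonds$i], lab[ga$bonds$j]), sep = "-"))
  # the table rows 6-9, 7-8, 7-9, 8-9 with the free sugar's S-sized bead 7
  expect_equal(bond_labels, sort(c("S6-S9", "R8-S7", "S7-S9", "R8-S9")))
  bond_idx <- sort(paste(ga$bonds$i, ga$bonds$j))
  expect_equal(bond_idx, sort(c("1 4", "2 3", "2 4", "3 4")))

  expect_error(build_monomer_topology("Xyl"), "GlcNAc and GlcA")
})

test_that("chain expansion equals the brute-force row-by-row oracle for n = 1..10 dimers", {
  for (nd in 1:10) {
    top <- build_chain_topology(2 * nd)
    expect_equal(nrow(top$beads), 9 * nd)
    for (kind in c("bonds", "angles", "impropers", "dihedrals")) {
      expect_equal(index_key(top[[kind]]), index_key(oracle_expand(nd, kind)),
                   info = paste("n_dimers =", nd, kind))
    }
    # no duplicated (sorted indices, kind) pair
    for (kind in c("bonds", "angles", "impropers", "dihedrals")) {
      df <- top[[kind]]
      cols <- intersect(c("i", "j", "k", "l"), names(df))
      keys <- apply(df[, cols, drop = FALSE], 1,
                    function(v) paste(sort(v), collapse = "-"))
      expect_false(any(duplicated(keys)), info = kind)
    }
  }
})

test_that("term counts grow linearly in the number of repeats", {
  for (nd in c(1, 2, 5, 10)) {
    top <- build_chain_topology(2 * nd)
    expect_equal(nrow(top$bonds), 12 * nd + 4 * (nd - 1))
    expect_equal(nrow(top$angles), 8 * nd + 3 * (nd - 1))
    expect_equal(nrow(top$impropers), 5 * nd + 2 * (nd - 1))
    expect_equal(nrow(top$dihedrals), nd + (nd - 1))
  }
})

test_that("dimer topology has no junction terms", {
  t2 <- build_chain_topology(2)
  expect_equal(nrow(t2$beads), 9)
  expect_equal(nrow(t2$bonds), 12)
  expect_equal(nrow(t2$dihedrals), 1)
  expect_true(all(unlist(t2$bonds[, c("i", "j")]) <= 9))
})

test_that("long chains follow the periodicity rule for beads and charge", {
  t100 <- build_chain_topology(100)
  expect_equal(nrow(t100$beads), 450)
  expect_equal(t100$net_charge, -50)
  expect_equal(t100$recommended_timestep, 0.01)
  # one Q5n per repeat
  expect_equal(sum(t100$beads$martini_type == "Q5n"), 50)
  # reducing end: bead 7 of the last repeat is S, all previous bead 7 are T
  b7 <- t100$beads[seq(7, 450, by = 9), ]
  expect_identical(b7$size, c(rep("T", 49), "S"))
  expect_identical(tail(b7$label, 1), "S7")
  # bead 2 stays tiny throughout the chain
  expect_true(all(t100$beads$size[seq(2, 450, by = 9)] == "T"))
  # every term within range (validated at construction) and indices 1-based
  expect_equal(t100$beads$index, 1:450)
})

test_that("odd or invalid unit counts are rejected with the repeat constraint", {
  expect_error(build_chain_topology(3), "even")
  expect_error(build_chain_topology(0), "even")
  expect_error(build_chain_topology(-4), "even")
  expect_error(build_chain_topology(2.5), "even")
})

test_that("exclusions are exactly the directly bonded pairs", {
  t4 <- build_chain_topology(4)
  expect_equal(t4$nrexcl, 1L)
  expect_equal(nrow(t4$exclusions), nrow(t4$bonds))
  got <- sort(paste(t4$exclusions$i, t4$exclusions$j))
  want <- sort(paste(pmin(t4$bonds$i, t4$bonds$j), pmax(t4$bonds$i, t4$bonds$j)))
  expect_equal(got, want)
})

test_that("initial coordinates are deterministic, compact and low-strain", {
  for (top in list(build_monomer_topology("GlcNAc"),
                   build_monomer_topology("GlcA"),
                   build_chain_topology(2),
                   build_chain_topology(100))) {
    co <- build_initial_coordinates(top)
    expect_equal(nrow(co), nrow(top$beads))
    expect_identical(co, build_initial_coordinates(top))  # bit-exact rerun
    # every bonded pair within 3x its reference length
    for (r in seq_len(nrow(top$bonds))) {
      b <- top$bonds[r, ]
      d <- sqrt(sum((co[b$i, ] - co[b$j, ])^2))
      expect_lt(d, 3 * b$b0)
      expect_true(is.finite(d) && d > 0)
    }
    e <- total_bonded_energy(top, co)
    expect_true(is.finite(e$total))
  }
  # 100-mer stays within a predictable bounding box
  co100 <- build_initial_coordinates(build_chain_topology(100))
  expect_true(all(co100 >= 0))
  expect_lt(max(co100[, 1]), 0.8575 * 50 + 3)
})
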