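# Independent oracles and shared fixtures for the test suite.

# Brute-force expansion oracle for chain topologies: the printed repeat
# rows are instantiated literally, row by row, with index offsets 9r per
# repeat (junction rows only while a next repeat exists). Kept independent
# of the package's own expansion code.
oracle_rows <- list(
  bonds = list(
    intra = list(c(1, 4), c(6, 9), c(2, 3), c(7, 8), c(2, 4), c(7, 9),
                 c(3, 4), c(8, 9), c(3, 5), c(2, 9), c(4, 5), c(4, 7)),
    junction = list(c(7, 12), c(7, 11), c(9, 13), c(2, 12))
  ),
  angles = list(
    intra = list(c(1, 4, 2), c(6, 9, 7), c(1, 4, 3), c(6, 9, 8),
                 c(5, 3, 2), c(3, 2, 9), c(2, 9, 8), c(2, 9, 6)),
    junction = list(c(8, 7, 12), c(7, 12, 11), c(7, 12, 13))
  ),
  impropers = list(
    intra = list(c(4, 3, 2, 1), c(5, 3, 2, 4), c(9, 8, 7, 6),
                 c(2, 3, 9, 4), c(9, 2, 8, 7)),
    junction = list(c(7, 8, 9, 12), c(12, 11, 13, 7))
  ),
  dihedrals = list(
    intra = list(c(1, 3, 8, 6)),
    junction = list(c(8, 7, 12, 11))
  )
)

oracle_expand <- function(n_dimers, kind) {
  rows <- oracle_rows[[kind]]
  out <- list()
  for (r in seq_len(n_dimers) - 1L) {
    for (ix in rows$intra) out[[length(out) + 1L]] <- ix + 9L * r
    if (r < n_dimers - 1L) {
      for (ix in rows$junction) out[[length(out) + 1L]] <- ix + 9L * r
    }
  }
  out
}

# canonical string form of an index set for set comparison
index_key <- function(mat_or_list) {
  rows <- if (is.data.frame(mat_or_list)) {
    cols <- intersect(c("i", "j", "k", "l"), names(mat_or_list))
    lapply(seq_len(nrow(mat_or_list)),
           function(r) unlist(mat_or_list[r, cols]))
  } else {
    mat_or_list
  }
  sort(vapply(rows, function(ix) paste(ix, collapse = "-"), character(1)))
}

# random rigid motion (rotation + translation) with fixed seed control
random_rigid_motion <- function(coords, seed) {
  set.seed(seed)
  axis <- stats::rnorm(3); axis <- axis / sqrt(sum(axis^2))
  th <- stats::runif(1, 0, 2 * pi)
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  shift <- stats::rnorm(3, 0, 5)
  sweep(coords %*% t(R), 2, shift, "+")
}

expect_topology_equal <- function(a, b) {
  expect_equal(a$molecule_name, b$molecule_name)
  expect_equal(a$beads, b$beads)
  expect_equal(a$bonds, b$bonds)
  expect_equal(a$angles, b$angles)
  expect_equal(a$impropers, b$impropers)
  expect_equal(a$dihedrals, b$dihedrals)
  expect_equal(a$net_charge, b$net_charge)
  expect_equal(a$recommended_timestep, b$recommended_timestep)
}
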