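# Bonded-energy evaluation, term by term, in the GROMACS functional
# dialects used by the model:
#   bonds (type 1):      V = 1/2 k_b (b - b0)^2
#   angles (type 2):     V = 1/2 k (cos th - cos th0)^2          (G96 cosine)
#   angles (type 10):    V = 1/2 k (cos th - cos th0)^2 / sin^2 th (restricted)
#   impropers (type 2):  V = 1/2 k (dxi)^2, dxi wrapped to (-180, 180] and
#                        taken in radians; k interpreted per GROMACS in
#                        kJ/mol/rad^2 even though the tables print deg^-2
#   dihedrals (type 1):  V = k (1 + cos(m phi - phi0))

#' Energy of a single bonded term
#'
#' Evaluates one bond, angle, improper or proper dihedral term at the given
#' coordinates. The term is a single-row data.frame in the layout produced
#' by \code{\link{monomer_parameter_set}} / \code{\link{build_chain_topology}}.
#'
#' @param term Single-row data.frame: bonds need \code{i,j,k_b,b0}; angles
#'   \code{i,j,k,k_theta,theta0,form}; impropers \code{i,j,k,l,k_xi,xi0};
#'   dihedrals \code{i,j,k,l,k_phi,phi0,mult}.
#' @param coords Numeric n x 3 coordinate matrix (nm).
#' @param restricted_cap Energy cap (kJ/mol) applied when a restricted
#'   bending angle comes within sin(theta) < 1e-6 of linearity, where the
#'   potential diverges; a warning is raised.
#' @return Energy in kJ/mol.
#' @export
term_energy <- function(term, coords, restricted_cap = 1e6) {
  .stopifnot_coords(coords)
  stopifnot(is.data.frame(term), nrow(term) == 1)
  nm <- names(term)
  if ("k_b" %in% nm) {
    b <- .bond_length(coords, term$i, term$j)
    return(0.5 * term$k_b * (b - term$b0)^2)
  }
  if ("k_theta" %in% nm) {
    th <- .deg2rad(.bond_angle(coords, term$i, term$j, term$k))
    dcos <- cos(th) - cos(.deg2rad(term$theta0))
    if (identical(term$form, "restricted_bending")) {
      s2 <- sin(th)^2
      if (s2 < 1e-12) {
        warning("restricted bending angle within guard band of linearity; ",
                "energy capped at ", restricted_cap, " kJ/mol")
        return(restricted_cap)
      }
      return(min(restricted_cap, 0.5 * term$k_theta * dcos^2 / s2))
    }
    return(0.5 * term$k_theta * dcos^2)
  }
  if ("k_xi" %in% nm) {
    xi <- .dihedral_angle(coords, term$i, term$j, term$k, term$l)
    dxi <- .deg2rad(.wrap_deg_right(xi - term$xi0))
    return(0.5 * term$k_xi * dxi^2)
  }
  if ("k_phi" %in% nm) {
    phi <- .dihedral_angle(coords, term$i, term$j, term$k, term$l)
    return(term$k_phi * (1 + cos(.deg2rad(term$mult * phi - term$phi0))))
  }
  stop("unrecognized term layout: columns ", paste(nm, collapse = ", "))
}

.class_energy <- function(terms, coords, restricted_cap) {
  if (is.null(terms) || nrow(terms) == 0) return(numeric(0))
  vapply(seq_len(nrow(terms)),
         function(r) term_energy(terms[r, , drop = FALSE], coords,
                                 restricted_cap = restricted_cap),
         numeric(1))
}

#' Total bonded energy of a topology at given coordinates
#'
#' Sums all bond, angle, improper and proper-dihedral terms of a topology
#' over one configuration or a trajectory, returning per-term energies,
#' per-class totals and the grand total.
#'
#' @param topology An \code{ha_topology} (see
#'   \code{\link{build_chain_topology}}).
#' @param coords n x 3 coordinate matrix, or a [frame, bead, 3] array for
#'   per-frame series.
#' @param restricted_cap Passed to \code{\link{term_energy}}.
#' @return For a single configuration, an object of class
#'   \code{ha_energy}: list with \code{per_term} (list of numeric vectors
#'   by class), \code{by_class} (named totals), \code{total}. For a
#'   trajectory, a data.frame with one row per frame.
#' @export
total_bonded_energy <- function(topology, coords, restricted_cap = 1e6) {
  stopifnot(inherits(topology, "ha_topology"))
  if (is.array(coords) && length(dim(coords)) == 3) {
    traj <- .as_traj(coords)
    rows <- lapply(seq_len(dim(traj)[1]), function(f) {
      e <- total_bonded_energy(topology, traj[f, , , drop = TRUE],
                               restricted_cap = restricted_cap)
      c(frame = f, e$by_class, total = e$total)
    })
    return(as.data.frame(do.call(rbind, rows)))
  }
  .stopifnot_coords(coords, n = nrow(topology$beads))
  per_term <- list(
    bonds = .class_energy(topology$bonds, coords, restricted_cap),
    angles = .class_energy(topology$angles, coords, restricted_cap),
    impropers = .class_energy(topology$impropers, coords, restricted_cap),
    dihedrals = .class_energy(topology$dihedrals, coords, restricted_cap)
  )
  by_class <- vapply(per_term, sum, numeric(1))
  structure(list(per_term = per_term, by_class = by_class,
                 total = sum(by_class)),
            class = "ha_energy")
}

#' @export
print.ha_energy <- function(x, ...) {
  cat("Bonded energy breakdown (kJ/mol)\n")
  for (cl in names(x$by_class)) {
    cat(sprintf("  %-10s %12.4f  (%d terms)\n", cl, x$by_class[[cl]],
                length(x$per_term[[cl]])))
  }
  cat(sprintf("  %-10s %12.4f\n", "total", x$total))
  invisible(x)
}
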