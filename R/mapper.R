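# Atomistic -> coarse-grained mapping by center of geometry (COG): each
# bead sits at the unweighted mean of its member atoms — all heavy atoms
# of the mapped group plus the hydrogens bonded to carbon ("aliphatic"
# hydrogens). O-H and N-H hydrogens are excluded, and equal weights are
# used regardless of element, following Martini COG practice.

# CHARMM36 carbohydrate atom names per residue and bead. Atoms flagged
# optional may be absent (the anomeric O1/HO1 exists only at a free
# reducing end; the glycosidic bridging oxygen is owned by the bead that
# holds the anomeric carbon of its parent residue and is named O1 there).
.charmm36_tables <- function() {
  g <- function(bead, atoms, hydrogens = character(), optional = character()) {
    data.frame(bead = bead,
               atom = c(atoms, hydrogens, optional),
               heavy = c(rep(TRUE, length(atoms)), rep(FALSE, length(hydrogens)),
                         rep(TRUE, length(optional))),
               optional = c(rep(FALSE, length(atoms)),
                            rep(TRUE, length(hydrogens)),
                            rep(TRUE, length(optional))),
               stringsAsFactors = FALSE)
  }
  list(
    GlcNAc = rbind(
      g(1L, c("C6", "O6"), c("H61", "H62")),
      g(2L, c("C1", "O5"), "H1", optional = "O1"),
      g(3L, c("C2", "C3", "O3", "N"), c("H2", "H3")),
      g(4L, c("C4", "C5", "O4"), c("H4", "H5")),
      g(5L, c("C", "O", "CT"), c("HT1", "HT2", "HT3"))
    ),
    GlcA = rbind(
      g(6L, c("C6", "O61", "O62")),
      g(7L, c("C1", "O5"), "H1", optional = "O1"),
      g(8L, c("C2", "C3", "O2", "O3"), c("H2", "H3")),
      g(9L, c("C4", "C5", "O4"), c("H4", "H5"))
    )
  )
}

#' Default atomistic-to-CG mapping tables
#'
#' Returns, per residue and bead, the atom names contributing to each bead
#' position: the bead's heavy atoms plus its aliphatic (carbon-bound)
#' hydrogens. The default dialect uses CHARMM36 carbohydrate atom naming.
#'
#' @param dialect Atomistic naming scheme; only \code{"charmm36"} is built
#'   in.
#' @return A named list (\code{GlcNAc}, \code{GlcA}) of data.frames with
#'   columns \code{bead}, \code{atom}, \code{heavy}, \code{optional}.
#' @export
default_mapping_tables <- function(dialect = "charmm36") {
  if (!identical(tolower(dialect), "charmm36")) {
    stop("unknown atom-naming dialect '", dialect,
         "': supported dialects: charmm36")
  }
  .charmm36_tables()
}

#' Map an atomistic structure onto CG beads
#'
#' Places one bead per mapped atom group at the unweighted mean (center of
#' geometry) of the group's atoms present in the structure. Residues are
#' processed in order of residue id; within each residue, beads follow the
#' model's numbering, so the output order matches the corresponding
#' topology's bead order.
#'
#' @param structure Atom table from \code{\link{read_aa_structure}} or
#'   \code{\link{toy_aa_fragment}}: columns \code{resid}, \code{resname},
#'   \code{name}, \code{x}, \code{y}, \code{z} (nm).
#' @param tables Mapping tables from \code{\link{default_mapping_tables}}.
#' @return An n x 3 matrix of bead coordinates (nm), with attributes
#'   \code{bead} (dimer bead index) and \code{resid}.
#' @export
map_aa_to_cg <- function(structure, tables = default_mapping_tables()) {
  req <- c("resid", "resname", "name", "x", "y", "z")
  if (!all(req %in% names(structure))) {
    stop("structure must have columns ", paste(req, collapse = ", "))
  }
  out <- list()
  bead_ids <- integer()
  res_ids <- integer()
  for (rid in unique(structure$resid)) {
    res_atoms <- structure[structure$resid == rid, , drop = FALSE]
    res <- .canon_residue(res_atoms$resname[1])
    tab <- tables[[res]]
    for (b in unique(tab$bead)) {
      rows <- tab[tab$bead == b, , drop = FALSE]
      hit <- res_atoms[res_atoms$name %in% rows$atom, , drop = FALSE]
      missing <- setdiff(rows$atom, hit$name)
      hard_missing <- missing[rows$optional[match(missing, rows$atom)] == FALSE &
                              rows$heavy[match(missing, rows$atom)] == TRUE]
      if (length(hard_missing)) {
        stop("cannot map residue ", res, " ", rid, ": heavy atom(s) ",
             paste(hard_missing, collapse = ", "), " not found for bead ", b)
      }
      soft_missing <- setdiff(missing, hard_missing)
      soft_h <- soft_missing[!rows$heavy[match(soft_missing, rows$atom)]]
      if (length(soft_h)) {
        warning("residue ", res, " ", rid, " bead ", b,
                ": aliphatic hydrogen(s) ", paste(soft_h, collapse = ", "),
                " missing; mapping over the atoms present")
      }
      out[[length(out) + 1]] <- colMeans(as.matrix(hit[, c("x", "y", "z")]))
      bead_ids <- c(bead_ids, b)
      res_ids <- c(res_ids, rid)
    }
  }
  coords <- do.call(rbind, out)
  dimnames(coords) <- NULL
  attr(coords, "bead") <- bead_ids
  attr(coords, "resid") <- res_ids
  coords
}
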