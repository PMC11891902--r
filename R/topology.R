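# Topology construction: expands the monomer tables and the disaccharide
# repeat template into complete molecules. Bead indices are 1-based
# throughout (matching GROMACS ITP numbering), both internally and in all
# user-facing output.

.new_topology <- function(molecule_name, beads, bonds, angles, impropers,
                          dihedrals, timestep) {
  beads$index <- seq_len(nrow(beads))
  rownames(beads) <- NULL
  excl <- if (nrow(bonds)) {
    data.frame(i = pmin(bonds$i, bonds$j), j = pmax(bonds$i, bonds$j))
  } else {
    data.frame(i = integer(), j = integer())
  }
  excl <- unique(excl[order(excl$i, excl$j), , drop = FALSE])
  rownames(excl) <- NULL
  top <- list(
    molecule_name = molecule_name,
    beads = beads,
    bonds = bonds,
    angles = angles,
    impropers = impropers,
    dihedrals = dihedrals,
    exclusions = excl,
    nrexcl = 1L,
    net_charge = sum(beads$charge),
    recommended_timestep = timestep
  )
  class(top) <- "ha_topology"
  .validate_topology(top)
  top
}

.validate_topology <- function(top) {
  n <- nrow(top$beads)
  idx_cols <- function(df) unlist(df[, intersect(c("i", "j", "k", "l"), names(df))])
  for (cls in c("bonds", "angles", "impropers", "dihedrals")) {
    ix <- idx_cols(top[[cls]])
    if (length(ix) && (any(ix < 1) || any(ix > n))) {
      stop("topology term in '", cls, "' references a bead outside 1..", n)
    }
  }
  if (n > 1) {
    # bonds must connect the molecule into one component
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
    for (r in seq_len(nrow(top$bonds))) {
      a <- find(top$bonds$i[r]); b <- find(top$bonds$j[r])
      if (a != b) parent[a] <- b
    }
    roots <- vapply(seq_len(n), find, integer(1))
    if (length(unique(roots)) != 1) {
      stop("topology bonds do not connect the molecule into a single component")
    }
  }
  invisible(top)
}

.offset_terms <- function(df, offset) {
  for (col in intersect(c("i", "j", "k", "l"), names(df))) {
    df[[col]] <- df[[col]] + offset
  }
  df
}

.bind_terms <- function(lst) {
  out <- do.call(rbind, lst)
  rownames(out) <- NULL
  out
}

#' Build the topology of a free monosaccharide
#'
#' Free GlcNAc is represented by 5 beads and free GlcA by 4; both carry the
#' anomeric hydroxyl, so the anomeric bead (2 or 7) takes the small (S)
#' size class. Bonded terms are exactly those of the residue's
#' monosaccharide table.
#'
#' @param residue \code{"GlcNAc"} or \code{"GlcA"}.
#' @return An \code{ha_topology}.
#' @export
build_monomer_topology <- function(residue) {
  res <- .canon_residue(residue)
  beads <- bead_catalog("free_monomer", residue = res)
  ps <- monomer_parameter_set(res)
  offset <- if (res == "GlcNAc") 0L else -5L  # GlcA table indices run 6..9
  beads$resid <- 1L
  .new_topology(
    molecule_name = toupper(res),
    beads = beads,
    bonds = .offset_terms(ps$bonds, offset),
    angles = .offset_terms(ps$angles, offset),
    impropers = .offset_terms(ps$impropers, offset),
    dihedrals = ps$dihedrals,
    timestep = ha_params()$timestep_ps$monomer
  )
}

#' Build the topology of an HA chain
#'
#' Expands the disaccharide repeat template into a chain of
#' \code{n_units} monosaccharides (GlcNAc at the non-reducing end, GlcA at
#' the reducing end, so \code{n_units} must be even). For repeat r
#' (1-based) the intra-dimer terms are emitted with index offset 9(r-1);
#' the junction terms, whose template indices 10-18 point into the next
#' repeat, are emitted for r < n_dimers. The terminal GlcA anomeric bead
#' (bead 7 of the last repeat) takes the S size class; every other bead
#' keeps its internal size.
#'
#' @param n_units Even, positive number of monosaccharide units.
#' @param molecule_name Optional molecule name (default \code{HA<n_units>}).
#' @return An \code{ha_topology} with 9 * n_units / 2 beads and net charge
#'   -n_units / 2.
#' @export
build_chain_topology <- function(n_units, molecule_name = NULL) {
  if (length(n_units) != 1 || !is.finite(n_units) || n_units < 2 ||
      n_units != round(n_units) || n_units %% 2 != 0) {
    stop("n_units must be a positive even integer: HA is a strict ",
         "GlcNAc-GlcA repeat and no parameters exist for a GlcNAc reducing end")
  }
  n_units <- as.integer(n_units)
  n_dimers <- n_units %/% 2L
  p <- ha_params()
  tpl <- chain_parameter_template()

  internal <- bead_catalog("internal")
  reducing <- bead_catalog("reducing_end")
  bead_blocks <- lapply(seq_len(n_dimers), function(r) {
    b <- if (r == n_dimers) reducing else internal
    b$resid <- ifelse(b$residue == "GlcNAc", 2L * r - 1L, 2L * r)
    b
  })
  beads <- .bind_terms(bead_blocks)

  gather <- function(kind) {
    blocks <- lapply(seq_len(n_dimers), function(r) {
      off <- 9L * (r - 1L)
      intra <- .offset_terms(tpl$intra[[kind]], off)
      if (r < n_dimers) {
        rbind(intra, .offset_terms(tpl$junction[[kind]], off))
      } else {
        intra
      }
    })
    .bind_terms(blocks)
  }

  .new_topology(
    molecule_name = if (is.null(molecule_name)) paste0("HA", n_units) else molecule_name,
    beads = beads,
    bonds = gather("bonds"),
    angles = gather("angles"),
    impropers = gather("impropers"),
    dihedrals = gather("dihedrals"),
    timestep = p$timestep_ps$chain
  )
}

# full GROMACS atom type name: Martini 3 prefixes S/T for small/tiny sizes
.full_type <- function(size, martini_type) {
  ifelse(size == "R", martini_type, paste0(size, martini_type))
}

#' @export
print.ha_topology <- function(x, ...) {
  cat("HA coarse-grained topology:", x$molecule_name, "\n")
  cat(sprintf("  %d beads, net charge %+d, recommended dt %.3g ps\n",
              nrow(x$beads), x$net_charge, x$recommended_timestep))
  cat(sprintf("  %d bonds, %d angles, %d impropers, %d dihedrals, %d exclusions\n",
              nrow(x$bonds), nrow(x$angles), nrow(x$impropers),
              nrow(x$dihedrals), nrow(x$exclusions)))
  invisible(x)
}
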