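# Parameter store: every bonded constant and bead assignment of the HA
# Martini 3 model lives in one checksummed JSON file under extdata and is
# loaded exactly once per session.

.params_cache <- new.env(parent = emptyenv())

# md5 of the shipped parameter file; guards against silent edits.
.PARAMS_MD5 <- "b9c11978b23c00edcf8fcf1e519096e6"

#' Load the HA Martini 3 parameter tables
#'
#' Reads the packaged parameter file (bead definitions, monosaccharide and
#' chain bonded terms, nonbonded configuration) and caches it for the
#' session. All other functions in the package obtain their numbers through
#' this single source.
#'
#' @return A list with elements \code{beads}, \code{glcnac}, \code{glca},
#'   \code{chain}, \code{nonbonded}, \code{masses}, \code{timestep_ps}.
#' @export
ha_params <- function() {
  if (!is.null(.params_cache$params)) return(.params_cache$params)
  path <- system.file("extdata", "ha_martini3_params.json", package = "hacg",
                      mustWork = TRUE)
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, .PARAMS_MD5)) {
    stop("parameter file checksum mismatch (", md5, "): the packaged table ",
         "data appear to have been modified")
  }
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  raw$beads <- as.data.frame(raw$beads, stringsAsFactors = FALSE)
  .params_cache$params <- raw
  raw
}

.canon_residue <- function(residue) {
  key <- tolower(gsub("[^a-z]", "", tolower(residue)))
  if (key %in% c("glcnac", "glcna", "glcn", "nag", "bglcna")) return("GlcNAc")
  if (key %in% c("glca", "gcu", "bglca")) return("GlcA")
  stop("unknown residue '", residue, "': supported residues are GlcNAc and GlcA")
}

#' Bead catalog for the HA disaccharide repeat
#'
#' Returns the nine coarse-grained bead definitions of the HA dimer (or the
#' subset belonging to one residue), with Martini 3 types, size classes,
#' charges and mapped chemical groups. At the reducing end (and in the free
#' sugars, which carry the anomeric hydroxyl) the anomeric beads 2 and 7
#' grow from tiny (T) to small (S).
#'
#' @param variant One of \code{"internal"}, \code{"reducing_end"},
#'   \code{"free_monomer"}.
#' @param residue For \code{variant = "free_monomer"}: \code{"GlcNAc"} or
#'   \code{"GlcA"}.
#' @return A data.frame with columns \code{index}, \code{label},
#'   \code{martini_type}, \code{size}, \code{charge}, \code{mass},
#'   \code{residue}, \code{group}.
#' @export
bead_catalog <- function(variant = c("internal", "reducing_end", "free_monomer"),
                         residue = NULL) {
  variant <- match.arg(variant)
  p <- ha_params()
  beads <- p$beads
  if (variant %in% c("reducing_end", "free_monomer")) {
    for (idx in names(p$reducing_end_resize)) {
      i <- as.integer(idx)
      beads$size[beads$index == i] <- p$reducing_end_resize[[idx]]
    }
  }
  if (variant == "free_monomer") {
    if (is.null(residue)) {
      stop("variant 'free_monomer' requires a residue (GlcNAc or GlcA)")
    }
    res <- .canon_residue(residue)
    beads <- beads[beads$residue == res, , drop = FALSE]
    # the resize applies only to the residue's own anomeric bead
  }
  if (variant == "reducing_end") {
    # in a chain the reducing end is GlcA: only bead 7 is resized
    beads$size[beads$index == 2] <- p$beads$size[p$beads$index == 2]
  }
  beads$index <- as.integer(beads$index)
  beads$charge <- as.numeric(beads$charge)
  beads$label <- paste0(beads$size, beads$index)
  beads$mass <- as.numeric(unname(unlist(p$masses)[beads$size]))
  rownames(beads) <- NULL
  beads[, c("index", "label", "martini_type", "size", "charge", "mass",
            "residue", "group")]
}

.term_df <- function(x, cols) {
  df <- as.data.frame(x, stringsAsFactors = FALSE)
  for (col in intersect(c("i", "j", "k", "l", "mult"), names(df))) {
    df[[col]] <- as.integer(df[[col]])
  }
  for (col in intersect(c("k_b", "b0", "k_theta", "theta0", "k_xi", "xi0",
                          "k_phi", "phi0"), names(df))) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df[, cols, drop = FALSE]
}

#' Bonded parameter set of a free monosaccharide
#'
#' Returns the bond, angle and improper-dihedral terms of the GlcNAc or
#' GlcA monosaccharide table. Angle rows carry a \code{form} flag
#' distinguishing the cosine-harmonic (GROMACS angle type 2) and the
#' restricted-bending (type 10) potentials.
#'
#' @param residue \code{"GlcNAc"} or \code{"GlcA"}.
#' @return An object of class \code{ha_parameter_set}: a list with
#'   data.frames \code{bonds}, \code{angles}, \code{impropers},
#'   \code{dihedrals} (empty for monomers).
#' @export
monomer_parameter_set <- function(residue) {
  res <- .canon_residue(residue)
  p <- ha_params()
  tab <- if (res == "GlcNAc") p$glcnac else p$glca
  out <- list(
    residue = res,
    bonds = .term_df(tab$bonds, c("i", "j", "k_b", "b0")),
    angles = .term_df(tab$angles, c("i", "j", "k", "k_theta", "theta0", "form")),
    impropers = .term_df(tab$impropers, c("i", "j", "k", "l", "k_xi", "xi0")),
    dihedrals = data.frame(i = integer(), j = integer(), k = integer(),
                           l = integer(), k_phi = numeric(), phi0 = numeric(),
                           mult = integer())
  )
  class(out) <- "ha_parameter_set"
  out
}

#' Chain parameter template for HA oligo- and polysaccharides
#'
#' Returns the disaccharide repeat template: the intra-dimer terms (bead
#' indices 1-9) and the junction terms that bridge into the next dimer
#' (indices 10-18 refer to beads of the following repeat). Periodic images
#' are not stored; chains of any length are produced by offsetting these
#' rows by 9 per repeat (see \code{\link{build_chain_topology}}).
#'
#' @return An object of class \code{ha_dimer_template}: a list with
#'   \code{intra} and \code{junction}, each holding data.frames
#'   \code{bonds}, \code{angles}, \code{impropers}, \code{dihedrals}.
#' @export
chain_parameter_template <- function() {
  p <- ha_params()
  shape <- function(tab) {
    list(
      bonds = .term_df(tab$bonds, c("i", "j", "k_b", "b0")),
      angles = .term_df(tab$angles, c("i", "j", "k", "k_theta", "theta0", "form")),
      impropers = .term_df(tab$impropers, c("i", "j", "k", "l", "k_xi", "xi0")),
      dihedrals = .term_df(tab$dihedrals, c("i", "j", "k", "l", "k_phi", "phi0", "mult"))
    )
  }
  out <- list(intra = shape(p$chain$intra), junction = shape(p$chain$junction))
  class(out) <- "ha_dimer_template"
  out
}

#' Nonbonded configuration of the model
#'
#' The model's nonbonded settings: first covalent neighbors excluded
#' (nrexcl 1), reaction-field electrostatics with relative permittivity 15,
#' 1.1 nm cutoffs, and size-class radii used for surface-area analysis.
#' Pair Lennard-Jones parameters are defined by the Martini 3 distribution
#' files via the bead type names and are not stored here.
#'
#' @return A list with \code{exclusion_depth}, \code{eps_r},
#'   \code{cutoff_nm}, \code{pair_table_source}, \code{radii_nm}.
#' @export
nonbonded_config <- function() {
  nb <- ha_params()$nonbonded
  nb$exclusion_depth <- as.integer(nb$exclusion_depth)
  nb$eps_r <- as.integer(nb$eps_r)
  nb
}

#' @export
print.ha_parameter_set <- function(x, ...) {
  cat("Bonded parameter set:", x$residue, "\n")
  cat("  bonds:", nrow(x$bonds), " angles:", nrow(x$angles),
      " impropers:", nrow(x$impropers), "\n")
  invisible(x)
}

#' @export
print.ha_dimer_template <- function(x, ...) {
  cat("HA disaccharide repeat template\n")
  cat("  intra:    ", nrow(x$intra$bonds), "bonds,", nrow(x$intra$angles),
      "angles,", nrow(x$intra$impropers), "impropers,",
      nrow(x$intra$dihedrals), "dihedral\n")
  cat("  junction: ", nrow(x$junction$bonds), "bonds,",
      nrow(x$junction$angles), "angles,", nrow(x$junction$impropers),
      "impropers,", nrow(x$junction$dihedrals), "dihedral\n")
  invisible(x)
}

#' Dump the parameter tables as human-readable text
#'
#' Writes the full bonded parameter set, grouped by molecule and
#' interaction class, in a fixed-width layout suitable for inspection or
#' diffing against force-field distribution files.
#'
#' @param file Connection or file name; \code{""} prints to stdout.
#' @return Invisibly, the character vector of lines.
#' @export
dump_parameters <- function(file = "") {
  lines <- character()
  add <- function(...) lines <<- c(lines, paste0(...))
  fmt_terms <- function(ps, title) {
    add("== ", title, " ==")
    if (nrow(ps$bonds)) {
      add("[ bonds ]  ; i j k_b(kJ/mol/nm^2) b0(nm)")
      for (r in seq_len(nrow(ps$bonds))) {
        b <- ps$bonds[r, ]
        add(sprintf("  B%d-B%d  %8s  %s", b$i, b$j, .fmt_num(b$k_b), .fmt_num(b$b0)))
      }
    }
    if (nrow(ps$angles)) {
      add("[ angles ]  ; i j k k_theta(kJ/mol) theta0(deg) form")
      for (r in seq_len(nrow(ps$angles))) {
        a <- ps$angles[r, ]
        add(sprintf("  B%d-B%d-B%d  %6s  %5s  %s", a$i, a$j, a$k,
                    .fmt_num(a$k_theta), .fmt_num(a$theta0), a$form))
      }
    }
    if (nrow(ps$impropers)) {
      add("[ improper dihedrals ]  ; i j k l k_xi xi0(deg)")
      for (r in seq_len(nrow(ps$impropers))) {
        d <- ps$impropers[r, ]
        add(sprintf("  B%d-B%d-B%d-B%d  %5s  %5s", d$i, d$j, d$k, d$l,
                    .fmt_num(d$k_xi), .fmt_num(d$xi0)))
      }
    }
    if (nrow(ps$dihedrals)) {
      add("[ dihedrals ]  ; i j k l k_phi(kJ/mol) phi0(deg) mult")
      for (r in seq_len(nrow(ps$dihedrals))) {
        d <- ps$dihedrals[r, ]
        add(sprintf("  B%d-B%d-B%d-B%d  %5s  %5s  %d", d$i, d$j, d$k, d$l,
                    .fmt_num(d$k_phi), .fmt_num(d$phi0), d$mult))
      }
    }
    add("")
  }
  add("Martini 3 hyaluronic acid parameter tables (hacg)")
  add("")
  cat_beads <- bead_catalog("internal")
  add("[ beads ]  ; index label type size charge mass group")
  for (r in seq_len(nrow(cat_beads))) {
    b <- cat_beads[r, ]
    add(sprintf("  %d  %-3s %-5s %s %+d %3d  %s", b$index, b$label,
                b$martini_type, b$size, b$charge, b$mass, b$group))
  }
  add("")
  fmt_terms(monomer_parameter_set("GlcNAc"), "GlcNAc monosaccharide")
  fmt_terms(monomer_parameter_set("GlcA"), "GlcA monosaccharide")
  tpl <- chain_parameter_template()
  fmt_terms(tpl$intra, "HA chain: intra-dimer terms (beads 1-9)")
  fmt_terms(tpl$junction, "HA chain: junction terms (indices 10+ = next repeat)")
  if (!identical(file, "")) writeLines(lines, file) else cat(lines, sep = "\n")
  invisible(lines)
}
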