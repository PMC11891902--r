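# GROMACS topology (ITP) serialization. Function types follow the model's
# interaction list: bonds funct 1; angles funct 2 (G96 cosine) or 10
# (restricted bending); impropers dihedrals funct 2; proper dihedrals
# funct 1. Improper force constants are serialized verbatim as printed in
# the parameter tables (GROMACS reads them as kJ/mol/rad^2).

.res_itp_name <- function(residue) {
  c(GlcNAc = "GLCNAC", GlcA = "GLCA")[residue]
}

.res_from_itp <- function(name) {
  key <- toupper(name)
  if (key == "GLCNAC") return("GlcNAc")
  if (key == "GLCA") return("GlcA")
  stop("unknown residue name in ITP: ", name)
}

#' Write a topology as a GROMACS ITP file
#'
#' Serializes an \code{ha_topology} to the GROMACS include-topology format
#' with sections [moleculetype] (nrexcl 1), [atoms], [bonds], [angles] and
#' two [dihedrals] blocks (impropers funct 2, propers funct 1). Numeric
#' fields reproduce the stored table values exactly; bond lengths are
#' written with three decimals and other constants in their printed form,
#' so the output diffs cleanly against force-field distribution files.
#'
#' @param topology An \code{ha_topology}.
#' @param file File name or connection; \code{NULL} returns the text only.
#' @return Invisibly (or visibly for \code{file = NULL}), the ITP text as a
#'   single string.
#' @export
write_itp <- function(topology, file = NULL) {
  stopifnot(inherits(topology, "ha_topology"))
  t <- topology
  L <- character()
  add <- function(...) L <<- c(L, paste0(...))

  add("; ", t$molecule_name, " - Martini 3 hyaluronic acid model (hacg)")
  add("")
  add("[ moleculetype ]")
  add("; name            nrexcl")
  add(sprintf("%-16s  %d", t$molecule_name, t$nrexcl))
  add("")
  add("[ atoms ]")
  add(";  nr  type   resnr residue atom  cgnr   charge   mass")
  for (r in seq_len(nrow(t$beads))) {
    b <- t$beads[r, ]
    add(sprintf("%5d  %-5s  %5d %-7s %-5s %5d %8s %6s",
                b$index, .full_type(b$size, b$martini_type), b$resid,
                .res_itp_name(b$residue), b$label, b$index,
                .fmt_num(b$charge), .fmt_num(b$mass)))
  }
  if (nrow(t$bonds)) {
    add("")
    add("[ bonds ]")
    add(";   i    j funct   b0       k_b")
    for (r in seq_len(nrow(t$bonds))) {
      b <- t$bonds[r, ]
      add(sprintf("%5d %4d %5d   %.3f  %8s", b$i, b$j, 1L, b$b0, .fmt_num(b$k_b)))
    }
  }
  if (nrow(t$angles)) {
    add("")
    add("[ angles ]")
    add(";   i    j    k funct  theta0   k_theta")
    for (r in seq_len(nrow(t$angles))) {
      a <- t$angles[r, ]
      funct <- if (identical(a$form, "restricted_bending")) 10L else 2L
      add(sprintf("%5d %4d %4d %5d  %6s  %8s", a$i, a$j, a$k, funct,
                  .fmt_num(a$theta0), .fmt_num(a$k_theta)))
    }
  }
  if (nrow(t$impropers)) {
    add("")
    add("[ dihedrals ]")
    add("; improper dihedrals")
    add(";   i    j    k    l funct   xi0      k_xi")
    for (r in seq_len(nrow(t$impropers))) {
      d <- t$impropers[r, ]
      add(sprintf("%5d %4d %4d %4d %5d  %6s  %8s", d$i, d$j, d$k, d$l, 2L,
                  .fmt_num(d$xi0), .fmt_num(d$k_xi)))
    }
  }
  if (nrow(t$dihedrals)) {
    add("")
    add("[ dihedrals ]")
    add("; proper dihedrals")
    add(";   i    j    k    l funct   phi0     k_phi  mult")
    for (r in seq_len(nrow(t$dihedrals))) {
      d <- t$dihedrals[r, ]
      add(sprintf("%5d %4d %4d %4d %5d  %6s  %8s %5d", d$i, d$j, d$k, d$l, 1L,
                  .fmt_num(d$phi0), .fmt_num(d$k_phi), d$mult))
    }
  }
  add("")
  text <- paste0(paste(L, collapse = "\n"), "\n")
  if (!is.null(file)) {
    writeLines(L, file)
    return(invisible(text))
  }
  text
}

.split_fields <- function(line) {
  line <- sub(";.*$", "", line)
  line <- trimws(line)
  if (!nzchar(line)) return(character(0))
  strsplit(line, "[ \t]+")[[1]]
}

#' Parse a GROMACS ITP file into a topology
#'
#' Reads ITP text in the dialect produced by \code{\link{write_itp}}
#' (tolerating arbitrary whitespace, blank lines and \code{;} comments) and
#' reconstructs an equal \code{ha_topology}. Unknown function types and
#' malformed records raise errors.
#'
#' @param text ITP content as a single string, a character vector of lines,
#'   or a file path.
#' @return An \code{ha_topology}.
#' @export
parse_itp <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    lines <- readLines(text)
  } else {
    lines <- unlist(strsplit(text, "\n"))
  }
  section <- NULL
  mol_name <- NULL
  nrexcl <- NULL
  atoms <- list()
  bonds <- list(); angles <- list(); impropers <- list(); dihedrals <- list()
  p <- ha_params()
  groups <- stats::setNames(p$beads$group, p$beads$index)

  for (ln in lines) {
    stripped <- trimws(sub(";.*$", "", ln))
    if (!nzchar(stripped)) next
    sec <- regmatches(stripped, regexec("^\\[\\s*(\\S+)\\s*\\]$", stripped))[[1]]
    if (length(sec) == 2) {
      section <- tolower(sec[2])
      if (!section %in% c("moleculetype", "atoms", "bonds", "angles",
                          "dihedrals", "exclusions")) {
        stop("unsupported ITP section: [", section, "]")
      }
      next
    }
    f <- .split_fields(ln)
    if (is.null(section)) stop("ITP record before any section: ", ln)
    if (section == "moleculetype") {
      if (length(f) != 2) stop("malformed [moleculetype] record: ", ln)
      mol_name <- f[1]
      nrexcl <- as.integer(f[2])
    } else if (section == "atoms") {
      if (length(f) < 8) stop("malformed [atoms] record: ", ln)
      atoms[[length(atoms) + 1]] <- data.frame(
        index = as.integer(f[1]), type = f[2], resid = as.integer(f[3]),
        residue = .res_from_itp(f[4]), label = f[5],
        charge = as.numeric(f[7]), mass = as.numeric(f[8]),
        stringsAsFactors = FALSE)
    } else if (section == "bonds") {
      if (length(f) != 5) stop("malformed [bonds] record: ", ln)
      if (f[3] != "1") stop("unsupported bond function type: ", f[3])
      bonds[[length(bonds) + 1]] <- data.frame(
        i = as.integer(f[1]), j = as.integer(f[2]),
        k_b = as.numeric(f[5]), b0 = as.numeric(f[4]))
    } else if (section == "angles") {
      if (length(f) != 6) stop("malformed [angles] record: ", ln)
      form <- switch(f[4], "2" = "g96_cosine", "10" = "restricted_bending",
                     stop("unsupported angle function type: ", f[4]))
      angles[[length(angles) + 1]] <- data.frame(
        i = as.integer(f[1]), j = as.integer(f[2]), k = as.integer(f[3]),
        k_theta = as.numeric(f[6]), theta0 = as.numeric(f[5]), form = form,
        stringsAsFactors = FALSE)
    } else if (section == "dihedrals") {
      if (!length(f) %in% c(7, 8)) stop("malformed [dihedrals] record: ", ln)
      funct <- f[5]
      if (funct == "2") {
        impropers[[length(impropers) + 1]] <- data.frame(
          i = as.integer(f[1]), j = as.integer(f[2]), k = as.integer(f[3]),
          l = as.integer(f[4]), k_xi = as.numeric(f[7]), xi0 = as.numeric(f[6]))
      } else if (funct == "1") {
        if (length(f) != 8) stop("proper dihedral record lacks multiplicity: ", ln)
        dihedrals[[length(dihedrals) + 1]] <- data.frame(
          i = as.integer(f[1]), j = as.integer(f[2]), k = as.integer(f[3]),
          l = as.integer(f[4]), k_phi = as.numeric(f[7]),
          phi0 = as.numeric(f[6]), mult = as.integer(f[8]))
      } else {
        stop("unsupported dihedral function type: ", funct)
      }
    } else if (section == "exclusions") {
      next  # regenerated from bonds
    }
  }
  if (is.null(mol_name)) stop("ITP lacks a [moleculetype] section")
  if (!identical(nrexcl, 1L)) stop("unsupported nrexcl: ", nrexcl)
  if (!length(atoms)) stop("ITP lacks an [atoms] section")

  beads <- .bind_terms(atoms)
  beads <- beads[order(beads$index), , drop = FALSE]
  beads$size <- substr(beads$label, 1, 1)
  if (!all(beads$size %in% c("T", "S", "R"))) {
    stop("atom labels must encode the size class (T/S/R prefix)")
  }
  beads$martini_type <- ifelse(beads$size == "R", beads$type,
                               substring(beads$type, 2))
  dimer_idx <- suppressWarnings(as.integer(substring(beads$label, 2)))
  beads$group <- unname(groups[as.character(((dimer_idx - 1) %% 9) + 1)])
  beads <- beads[, c("index", "label", "martini_type", "size", "charge",
                     "mass", "residue", "group", "resid")]

  empty <- list(
    bonds = data.frame(i = integer(), j = integer(), k_b = numeric(), b0 = numeric()),
    angles = data.frame(i = integer(), j = integer(), k = integer(),
                        k_theta = numeric(), theta0 = numeric(),
                        form = character(), stringsAsFactors = FALSE),
    impropers = data.frame(i = integer(), j = integer(), k = integer(),
                           l = integer(), k_xi = numeric(), xi0 = numeric()),
    dihedrals = data.frame(i = integer(), j = integer(), k = integer(),
                           l = integer(), k_phi = numeric(), phi0 = numeric(),
                           mult = integer())
  )
  pick <- function(lst, nm) if (length(lst)) .bind_terms(lst) else empty[[nm]]
  is_monomer <- length(unique(beads$resid)) == 1
  .new_topology(
    molecule_name = mol_name,
    beads = beads,
    bonds = pick(bonds, "bonds"),
    angles = pick(angles, "angles"),
    impropers = pick(impropers, "impropers"),
    dihedrals = pick(dihedrals, "dihedrals"),
    timestep = if (is_monomer) ha_params()$timestep_ps$monomer
               else ha_params()$timestep_ps$chain
  )
}

#' Write a minimal GROMACS system topology (.top)
#'
#' Emits a run-ready .top that includes the Martini 3 distribution files
#' (which supply the nonbonded pair parameters for the bead types) and the
#' molecule's own ITP.
#'
#' @param topology An \code{ha_topology}.
#' @param file Output file or connection.
#' @param itp_file Name of the molecule ITP to include.
#' @param martini_include Path of the Martini 3 master include file, as
#'   distributed with the force field.
#' @param nmols Number of copies of the molecule in the system.
#' @return Invisibly, the text.
#' @export
write_top <- function(topology, file = NULL, itp_file = "molecule.itp",
                      martini_include = "martini_v3.0.0.itp", nmols = 1L) {
  stopifnot(inherits(topology, "ha_topology"))
  L <- c(
    "; system topology (hacg) - nonbonded pair parameters come from the",
    "; Martini 3 distribution files referenced below",
    sprintf("#include \"%s\"", martini_include),
    sprintf("#include \"%s\"", itp_file),
    "",
    "[ system ]",
    paste0(topology$molecule_name, " in Martini 3 water"),
    "",
    "[ molecules ]",
    sprintf("%-16s %d", topology$molecule_name, as.integer(nmols))
  )
  text <- paste0(paste(L, collapse = "\n"), "\n")
  if (!is.null(file)) { writeLines(L, file); return(invisible(text)) }
  text
}

#' Write an MDP run-settings template
#'
#' Emits a GROMACS .mdp template with the run settings the model was
#' developed under: leapfrog integration at the recommended timestep,
#' V-rescale thermostat, Parrinello-Rahman barostat, 1.1 nm cutoffs, and
#' reaction-field electrostatics with relative permittivity 15. A
#' convenience template, not a validated protocol.
#'
#' @param topology An \code{ha_topology} (sets the timestep).
#' @param file Output file or connection.
#' @param nsteps Number of MD steps.
#' @param ref_t Reference temperature, K.
#' @return Invisibly, the text.
#' @export
write_mdp <- function(topology, file = NULL, nsteps = 500000L, ref_t = 298) {
  stopifnot(inherits(topology, "ha_topology"))
  nb <- nonbonded_config()
  L <- c(
    "; Martini 3 run-settings template (hacg)",
    "integrator               = md",
    sprintf("dt                       = %.3f", topology$recommended_timestep),
    sprintf("nsteps                   = %d", as.integer(nsteps)),
    "cutoff-scheme            = Verlet",
    "coulombtype              = reaction-field",
    sprintf("rcoulomb                 = %.1f", nb$cutoff_nm),
    sprintf("epsilon_r                = %d", as.integer(nb$eps_r)),
    "vdw-type                 = cutoff",
    "vdw-modifier             = Potential-shift-verlet",
    sprintf("rvdw                     = %.1f", nb$cutoff_nm),
    "tcoupl                   = v-rescale",
    "tc-grps                  = System",
    "tau_t                    = 1.0",
    sprintf("ref_t                    = %g", ref_t),
    "pcoupl                   = parrinello-rahman",
    "pcoupltype               = isotropic",
    "tau_p                    = 40.0",
    "ref_p                    = 1.0",
    "compressibility          = 3e-4",
    "comm-mode                = Linear"
  )
  text <- paste0(paste(L, collapse = "\n"), "\n")
  if (!is.null(file)) { writeLines(L, file); return(invisible(text)) }
  text
}
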