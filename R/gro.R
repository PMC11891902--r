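# Coordinate file I/O. GRO (GROMACS, nm) is read and written natively,
# including multi-frame concatenated GRO as a simple trajectory carrier;
# PDB (Angstrom) goes through bio3d with the nm <-> Angstrom conversion
# applied here.

.bead_names_for <- function(topology, n) {
  if (!is.null(topology)) {
    # GRO/PDB residue-name fields are width-limited; GLCNAC becomes GLCNA
    list(resid = topology$beads$resid,
         resname = substr(.res_itp_name(topology$beads$residue), 1, 5),
         name = topology$beads$label)
  } else {
    list(resid = rep(1L, n), resname = rep("CG", n),
         name = paste0("B", seq_len(n)))
  }
}

#' Write coordinates as a GRO file
#'
#' Writes one configuration (n x 3 matrix) or a trajectory
#' ([frame, bead, 3] array, emitted as concatenated frames) in the GROMACS
#' GRO fixed-column format, coordinates in nm.
#'
#' @param coords n x 3 matrix or [frame, bead, 3] array, nm.
#' @param file Output file or connection.
#' @param topology Optional \code{ha_topology} supplying residue and bead
#'   names.
#' @param box Length-3 box vector lengths in nm; defaults to the bounding
#'   box plus 2 nm margin.
#' @param title Title line.
#' @return Invisibly, the character vector of lines.
#' @export
write_gro <- function(coords, file = NULL, topology = NULL, box = NULL,
                      title = "hacg coordinates") {
  traj <- .as_traj(coords)
  n <- dim(traj)[2]
  if (!is.null(topology) && nrow(topology$beads) != n) {
    stop("topology bead count does not match coordinate count")
  }
  nm <- .bead_names_for(topology, n)
  L <- character()
  for (f in seq_len(dim(traj)[1])) {
    xyz <- traj[f, , , drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    bx <- box
    if (is.null(bx)) {
      span <- apply(xyz, 2, function(c) diff(range(c)))
      bx <- span + 2
    }
    L <- c(L, title, sprintf("%5d", n),
           sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                   nm$resid %% 100000L, nm$resname, nm$name, seq_len(n) %% 100000L,
                   xyz[, 1], xyz[, 2], xyz[, 3]),
           sprintf("%10.5f%10.5f%10.5f", bx[1], bx[2], bx[3]))
  }
  if (!is.null(file)) { writeLines(L, file); return(invisible(L)) }
  L
}

#' Read a GRO file
#'
#' Reads a (possibly multi-frame) GRO file. Velocities, if present, are
#' ignored.
#'
#' @param file Path to a GRO file.
#' @return A list with \code{title}, \code{atoms} (data.frame with
#'   \code{resid}, \code{resname}, \code{name}), \code{coords} (n x 3
#'   matrix for a single frame, [frame, bead, 3] array otherwise),
#'   \code{box} (of the first frame), \code{n_frames}.
#' @export
read_gro <- function(file) {
  lines <- readLines(file)
  frames <- list()
  atoms <- NULL
  title <- NULL
  box <- NULL
  pos <- 1
  while (pos <= length(lines) && nzchar(trimws(lines[pos]))) {
    ttl <- lines[pos]
    natoms <- suppressWarnings(as.integer(trimws(lines[pos + 1])))
    if (is.na(natoms)) stop("malformed GRO: bad atom count at line ", pos + 1)
    rec <- lines[pos + 1 + seq_len(natoms)]
    if (length(rec) < natoms || anyNA(rec)) stop("malformed GRO: truncated frame")
    xyz <- cbind(as.numeric(substr(rec, 21, 28)),
                 as.numeric(substr(rec, 29, 36)),
                 as.numeric(substr(rec, 37, 44)))
    if (anyNA(xyz)) stop("malformed GRO: unreadable coordinates")
    if (is.null(atoms)) {
      title <- ttl
      atoms <- data.frame(
        resid = as.integer(substr(rec, 1, 5)),
        resname = trimws(substr(rec, 6, 10)),
        name = trimws(substr(rec, 11, 15)),
        stringsAsFactors = FALSE)
      box <- as.numeric(strsplit(trimws(lines[pos + 2 + natoms]), "\\s+")[[1]])[1:3]
    }
    frames[[length(frames) + 1]] <- xyz
    pos <- pos + natoms + 3
  }
  if (!length(frames)) stop("empty GRO file: ", file)
  coords <- if (length(frames) == 1) {
    frames[[1]]
  } else {
    arr <- array(0, dim = c(length(frames), nrow(frames[[1]]), 3))
    for (f in seq_along(frames)) arr[f, , ] <- frames[[f]]
    arr
  }
  list(title = title, atoms = atoms, coords = coords, box = box,
       n_frames = length(frames))
}

#' Write coordinates as a PDB file
#'
#' Converts bead coordinates from nm to Angstrom and writes a PDB through
#' bio3d.
#'
#' @param coords n x 3 matrix, nm.
#' @param file Output path.
#' @param topology Optional \code{ha_topology} supplying names.
#' @return Invisibly, \code{file}.
#' @export
write_cg_pdb <- function(coords, file, topology = NULL) {
  .stopifnot_coords(coords)
  nm <- .bead_names_for(topology, nrow(coords))
  # standard PDB ligand codes (3 characters, as the PDB format requires)
  pdb_res <- nm$resname
  pdb_res[startsWith(pdb_res, "GLCN")] <- "NAG"
  pdb_res[pdb_res == "GLCA"] <- "GCU"
  pdb_res <- substr(pdb_res, 1, 3)
  bio3d::write.pdb(file = file, xyz = as.vector(t(coords * 10)),
                   resno = nm$resid, resid = pdb_res,
                   elety = nm$name, chain = rep("A", nrow(coords)))
  invisible(file)
}

#' Read an atomistic structure for mapping
#'
#' Reads a PDB (via bio3d, Angstrom converted to nm) or GRO file into the
#' flat atom table used by \code{\link{map_aa_to_cg}}.
#'
#' @param file Path to a .pdb or .gro file.
#' @return A data.frame with columns \code{resid}, \code{resname},
#'   \code{name}, \code{x}, \code{y}, \code{z} (nm).
#' @export
read_aa_structure <- function(file) {
  if (grepl("\\.gro$", file, ignore.case = TRUE)) {
    g <- read_gro(file)
    co <- if (length(dim(g$coords)) == 3) g$coords[1, , , drop = TRUE] else g$coords
    return(cbind(g$atoms, data.frame(x = co[, 1], y = co[, 2], z = co[, 3])))
  }
  pdb <- bio3d::read.pdb(file)
  a <- pdb$atom
  data.frame(resid = a$resno, resname = a$resid, name = a$elety,
             x = a$x / 10, y = a$y / 10, z = a$z / 10,
             stringsAsFactors = FALSE)
}
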