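# Internal-coordinate measurements on bead coordinates (nm / degrees).
# Dihedral sign follows the IUPAC convention (atan2 formulation); impropers
# are computed as proper dihedrals over their four indices, matching the
# GROMACS harmonic-improper (dihedral type 2) ordering.

.vnorm <- function(v) sqrt(sum(v * v))

.check_vec <- function(v, what) {
  n <- .vnorm(v)
  if (n < 1e-9) stop("degenerate geometry: ", what, " vector shorter than 1e-9 nm")
  n
}

.bond_length <- function(coords, i, j) {
  .vnorm(coords[j, ] - coords[i, ])
}

.bond_angle <- function(coords, i, j, k) {
  u <- coords[i, ] - coords[j, ]
  v <- coords[k, ] - coords[j, ]
  nu <- .check_vec(u, "angle arm")
  nv <- .check_vec(v, "angle arm")
  cosang <- sum(u * v) / (nu * nv)
  cosang <- min(1, max(-1, cosang))
  if (cosang <= -1) {
    stop("collinear triplet: angle is exactly 180 degrees")
  }
  if (cosang >= 1) {
    stop("collinear triplet: angle is exactly 0 degrees")
  }
  ang <- .rad2deg(acos(cosang))
  if (ang > 179.9 || ang < 0.1) {
    warning("near-collinear triplet: angle = ", signif(ang, 6), " degrees")
  }
  ang
}

.dihedral_angle <- function(coords, i, j, k, l) {
  b1 <- coords[j, ] - coords[i, ]
  b2 <- coords[k, ] - coords[j, ]
  b3 <- coords[l, ] - coords[k, ]
  .check_vec(b2, "dihedral axis")
  c1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  c2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  .check_vec(c1, "dihedral plane normal")
  .check_vec(c2, "dihedral plane normal")
  x <- sum(c1 * c2)
  y <- sum(b1 * c2) * .vnorm(b2)
  phi <- .rad2deg(atan2(y, x))
  .wrap_deg(phi)
}

#' Measure an internal coordinate from bead coordinates
#'
#' Computes a bond length (nm), bond angle (degrees), or (improper)
#' dihedral angle (degrees, wrapped to [-180, 180)) from 2, 3 or 4 bead
#' indices. Impropers use the same four-point construction as proper
#' dihedrals.
#'
#' @param coords Numeric n x 3 matrix of bead positions in nm.
#' @param indices Integer vector of 2 (bond), 3 (angle) or 4 (dihedral)
#'   bead indices, or a single-row term data.frame with columns
#'   \code{i,j[,k[,l]]}.
#' @param kind Optional: \code{"bond"}, \code{"angle"}, \code{"dihedral"}
#'   or \code{"improper"}; inferred from the index count when missing.
#' @return An object of class \code{ha_measurement}: list with \code{kind},
#'   \code{indices}, \code{value} (nm or degrees).
#' @export
measure <- function(coords, indices, kind = NULL) {
  .stopifnot_coords(coords)
  if (is.data.frame(indices)) {
    indices <- unlist(indices[1, intersect(c("i", "j", "k", "l"), names(indices))])
  }
  indices <- as.integer(indices)
  if (any(indices < 1) || any(indices > nrow(coords))) {
    stop("bead index out of range 1..", nrow(coords))
  }
  n <- length(indices)
  if (is.null(kind)) {
    kind <- switch(as.character(n), "2" = "bond", "3" = "angle", "4" = "dihedral",
                   stop("indices must have length 2, 3 or 4"))
  }
  value <- switch(kind,
    bond = .bond_length(coords, indices[1], indices[2]),
    angle = .bond_angle(coords, indices[1], indices[2], indices[3]),
    dihedral = ,
    improper = .dihedral_angle(coords, indices[1], indices[2], indices[3],
                               indices[4]),
    stop("unknown measurement kind: ", kind))
  structure(list(kind = kind, indices = indices, value = value),
            class = "ha_measurement")
}

#' @export
print.ha_measurement <- function(x, ...) {
  unit <- if (x$kind == "bond") "nm" else "deg"
  cat(sprintf("%s %s: %.4f %s\n", x$kind,
              paste(x$indices, collapse = "-"), x$value, unit))
  invisible(x)
}
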