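# small shared helpers

# format a numeric exactly as the tables print it: integers without decimals,
# fractional values with the minimal number of digits (pure function of the
# value, so write -> parse -> write is byte-stable)
.fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (v == round(v) && abs(v) < 1e15) {
      sprintf("%d", as.integer(v))
    } else {
      # up to 6 significant decimals, trailing zeros trimmed
      s <- formatC(v, format = "f", digits = 6)
      s <- sub("0+$", "", s)
      sub("\\.$", "", s)
    }
  }, character(1))
}

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

# wrap an angle in degrees to [-180, 180)
.wrap_deg <- function(x) {
  w <- (x + 180) %% 360 - 180
  w[w >= 180] <- w[w >= 180] - 360
  w
}

# wrap to (-180, 180] (GROMACS improper delta convention)
.wrap_deg_right <- function(x) {
  w <- (x - 180) %% 360 - 180
  w[w <= -180] <- w[w <= -180] + 360
  w
}

.stopifnot_coords <- function(coords, n = NULL) {
  if (!is.matrix(coords) || ncol(coords) != 3 || !is.numeric(coords)) {
    stop("coordinates must be a numeric n x 3 matrix (nm)")
  }
  if (!is.null(n) && nrow(coords) != n) {
    stop("coordinate count (", nrow(coords), ") does not match bead count (",
         n, ")")
  }
  invisible(coords)
}

# coerce a trajectory argument to a 3-d array [frame, bead, xyz]
.as_traj <- function(x) {
  if (is.matrix(x)) {
    x <- array(x, dim = c(1, nrow(x), 3))
  }
  if (!(is.array(x) && length(dim(x)) == 3 && dim(x)[3] == 3)) {
    stop("trajectory must be an n x 3 coordinate matrix or a [frame, bead, 3] array")
  }
  x
}
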