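# Synthetic inputs for testing and calibration: worm-like-chain bond-vector
# ensembles with known persistence length, Gaussian geometry perturbations,
# and toy atomistic fragments carrying CHARMM36 atom names.
#
# All generators seed R's Mersenne-Twister generator explicitly and record
# the seed in their output metadata; identical seeds give identical output.

# inverse Langevin: kappa such that coth(k) - 1/k = alpha
.langevin_inverse <- function(alpha) {
  stopifnot(alpha > 0, alpha < 1)
  L <- function(k) 1 / tanh(k) - 1 / k - alpha
  lo <- 1e-6
  hi <- max(10, 2 / (1 - alpha))
  stats::uniroot(L, c(lo, hi), tol = 1e-12)$root
}

# one cosine draw from p(c) ~ exp(kappa c) on [-1, 1] (exact inverse CDF;
# stable for large kappa)
.sample_cos <- function(n, kappa) {
  u <- stats::runif(n)
  1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
}

#' Sample a worm-like-chain bond-vector ensemble
#'
#' Generates frames of consecutive unit bond vectors in which each bending
#' cosine is drawn from the equilibrium distribution p(cos t) proportional
#' to exp(kappa cos t), with kappa chosen so that <cos t> = exp(-d / l_p)
#' exactly. Successive bends are independent with uniform azimuth, so the
#' bond-vector autocorrelation satisfies E[C(n)] = exp(-n d / l_p) in
#' closed form.
#'
#' @param n_bonds Bond vectors per frame.
#' @param d Bond length, nm.
#' @param l_p Target persistence length, nm (\code{Inf} gives a straight
#'   chain).
#' @param n_frames Number of independent frames.
#' @param seed Integer seed (recorded in the output metadata).
#' @return A [n_frames, n_bonds, 3] array of unit vectors with attribute
#'   \code{spec} (list of all arguments and the bending kappa).
#' @export
sample_wlc <- function(n_bonds, d, l_p, n_frames, seed) {
  stopifnot(n_bonds >= 1, d > 0, l_p > 0, n_frames >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  out <- array(0, dim = c(n_frames, n_bonds, 3))
  if (is.infinite(l_p)) {
    out[, , 3] <- 1
    kappa <- Inf
  } else {
    alpha <- exp(-d / l_p)
    kappa <- .langevin_inverse(alpha)
    for (f in seq_len(n_frames)) {
      u <- c(0, 0, 1)
      out[f, 1, ] <- u
      if (n_bonds > 1) {
        cs <- .sample_cos(n_bonds - 1, kappa)
        ph <- stats::runif(n_bonds - 1, 0, 2 * pi)
        for (b in 2:n_bonds) {
          # orthonormal frame around u
          ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
          e1 <- c(u[2] * ref[3] - u[3] * ref[2],
                  u[3] * ref[1] - u[1] * ref[3],
                  u[1] * ref[2] - u[2] * ref[1])
          e1 <- e1 / sqrt(sum(e1^2))
          e2 <- c(u[2] * e1[3] - u[3] * e1[2],
                  u[3] * e1[1] - u[1] * e1[3],
                  u[1] * e1[2] - u[2] * e1[1])
          ct <- cs[b - 1]
          st <- sqrt(max(0, 1 - ct^2))
          u <- ct * u + st * (cos(ph[b - 1]) * e1 + sin(ph[b - 1]) * e2)
          u <- u / sqrt(sum(u^2))
          out[f, b, ] <- u
        }
      }
    }
  }
  attr(out, "spec") <- list(n_bonds = n_bonds, d = d, l_p = l_p,
                            n_frames = n_frames, seed = seed, kappa = kappa,
                            generator = "Mersenne-Twister")
  out
}

#' Gaussian perturbation of a geometry
#'
#' Displaces every bead by an isotropic Gaussian of standard deviation
#' \code{sigma}; used to probe the energy evaluator away from reference
#' geometries.
#'
#' @param coords n x 3 matrix (nm).
#' @param sigma Displacement sd per coordinate, nm.
#' @param seed Integer seed.
#' @return Perturbed n x 3 matrix with attribute \code{seed}.
#' @export
perturbed_geometry <- function(coords, sigma, seed) {
  .stopifnot_coords(coords)
  stopifnot(sigma >= 0)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  out <- coords + matrix(stats::rnorm(length(coords), 0, sigma), nrow(coords), 3)
  attr(out, "seed") <- seed
  out
}

.toy_atoms <- function(residue) {
  # ring on a hexagon (nm), substituents pushed radially/axially outward;
  # the geometry is schematic but respects which atoms sit near which
  ring <- c("C1", "C2", "C3", "C4", "C5", "O5")
  th <- 2 * pi * (seq_along(ring) - 1) / 6
  pos <- list()
  for (k in seq_along(ring)) pos[[ring[k]]] <- c(0.15 * cos(th[k]), 0.15 * sin(th[k]), 0)
  radial <- function(parent, scale, dz) {
    p <- pos[[parent]]
    c(p[1] * scale, p[2] * scale, dz)
  }
  if (residue == "GlcNAc") {
    pos$H1 <- radial("C1", 1.4, 0.08)
    pos$O1 <- radial("C1", 1.9, -0.05)
    pos$HO1 <- radial("C1", 2.3, -0.08)
    pos$N <- radial("C2", 1.9, 0.02)
    pos$HN <- radial("C2", 2.2, 0.10)
    pos$C <- radial("C2", 2.6, -0.04)
    pos$O <- radial("C2", 3.0, 0.05)
    pos$CT <- radial("C2", 3.1, -0.15)
    pos$HT1 <- radial("C2", 3.4, -0.20)
    pos$HT2 <- radial("C2", 3.3, -0.08)
    pos$HT3 <- radial("C2", 2.9, -0.25)
    pos$H2 <- radial("C2", 1.4, -0.08)
    pos$O3 <- radial("C3", 1.9, -0.03)
    pos$HO3 <- radial("C3", 2.3, -0.05)
    pos$H3 <- radial("C3", 1.4, 0.08)
    pos$O4 <- radial("C4", 1.9, 0.04)
    pos$HO4 <- radial("C4", 2.3, 0.07)
    pos$H4 <- radial("C4", 1.4, -0.08)
    pos$C6 <- radial("C5", 1.8, 0.12)
    pos$O6 <- radial("C5", 2.4, 0.18)
    pos$H61 <- radial("C5", 2.0, 0.22)
    pos$H62 <- radial("C5", 1.6, 0.20)
    pos$HO6 <- radial("C5", 2.7, 0.24)
    pos$H5 <- radial("C5", 1.4, -0.08)
    resname <- "GLCNAC"
  } else {
    pos$H1 <- radial("C1", 1.4, 0.08)
    pos$O1 <- radial("C1", 1.9, -0.05)
    pos$HO1 <- radial("C1", 2.3, -0.08)
    pos$O2 <- radial("C2", 1.9, -0.02)
    pos$HO2 <- radial("C2", 2.3, -0.04)
    pos$H2 <- radial("C2", 1.4, 0.08)
    pos$O3 <- radial("C3", 1.9, 0.03)
    pos$HO3 <- radial("C3", 2.3, 0.05)
    pos$H3 <- radial("C3", 1.4, -0.08)
    pos$O4 <- radial("C4", 1.9, -0.04)
    pos$HO4 <- radial("C4", 2.3, -0.06)
    pos$H4 <- radial("C4", 1.4, 0.08)
    pos$C6 <- radial("C5", 1.9, 0.10)
    pos$O61 <- radial("C5", 2.4, 0.16)
    pos$O62 <- radial("C5", 2.4, 0.02)
    pos$H5 <- radial("C5", 1.4, -0.08)
    resname <- "GLCA"
  }
  xyz <- do.call(rbind, pos)
  data.frame(resname = resname, name = names(pos),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

#' Toy atomistic fragment with CHARMM36 atom names
#'
#' Builds a schematic (not chemically accurate) atomistic model of a free
#' GlcNAc or GlcA residue whose atom names follow the default mapping
#' dialect, so the mapper's partition and COG behavior can be tested
#' without external structure files.
#'
#' @param residue \code{"GlcNAc"} or \code{"GlcA"}.
#' @param resid Residue id for the output table.
#' @param origin Translation applied to all atoms (nm).
#' @return A data.frame with columns \code{resid}, \code{resname},
#'   \code{name}, \code{x}, \code{y}, \code{z} (nm), usable with
#'   \code{\link{map_aa_to_cg}}.
#' @export
toy_aa_fragment <- function(residue, resid = 1L, origin = c(0, 0, 0)) {
  res <- .canon_residue(residue)
  at <- .toy_atoms(res)
  at$x <- at$x + origin[1]
  at$y <- at$y + origin[2]
  at$z <- at$z + origin[3]
  cbind(data.frame(resid = as.integer(resid)), at)
}
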