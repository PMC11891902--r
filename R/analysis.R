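# Chain-scale observables: backbone bond-vector autocorrelation and
# persistence length, radius of gyration and end-to-end distance, CG
# surface area with size-class radii, and aggregate clustering.

#' Backbone bead selection of an HA chain
#'
#' The backbone direction of an HA chain is traced through the R3 and S9
#' beads: indices 3, 9, 12, 18, ... (3 + 9r and 9 + 9s per repeat). For a
#' chain of n repeats this yields 2n points and 2n - 1 bond vectors.
#'
#' @param topology An \code{ha_topology} built by
#'   \code{\link{build_chain_topology}}.
#' @return Integer vector of bead indices, strictly increasing.
#' @export
backbone_selection <- function(topology) {
  stopifnot(inherits(topology, "ha_topology"))
  lab <- sub("^[TSR]", "", topology$beads$label)
  sel <- which(lab %in% c("3", "9"))
  if (length(sel) < 2) {
    stop("topology has no R3/S9 backbone pattern: not an HA chain")
  }
  want <- as.vector(t(outer((seq_len(length(sel) / 2) - 1) * 9, c(3, 9), "+")))
  if (!identical(as.integer(sel), as.integer(want))) {
    stop("topology does not follow the 9-bead HA repeat layout")
  }
  sel
}

#' Backbone bond vectors of one frame
#'
#' @param coords n x 3 coordinate matrix (nm).
#' @param topology The chain topology (defines the R3/S9 selection).
#' @return (2n - 1) x 3 matrix of consecutive backbone bond vectors.
#' @export
backbone_vectors <- function(coords, topology) {
  .stopifnot_coords(coords, n = nrow(topology$beads))
  sel <- backbone_selection(topology)
  pts <- coords[sel, , drop = FALSE]
  diff(pts)
}

#' Bond-vector autocorrelation C(n)
#'
#' Computes the average cosine between unit bond vectors separated by n
#' bonds, averaged over all valid index pairs and over frames:
#' C(n) = < a_i . a_{i+n} / (|a_i| |a_{i+n}|) >, with C(0) = 1 by
#' construction. Unit-vector normalization is used (recorded in the
#' result's metadata).
#'
#' @param vectors Bond vectors: a [frame, bond, 3] array, a single m x 3
#'   matrix, or a list of m x 3 matrices (one per frame).
#' @param n_max Largest separation to compute (default: all).
#' @return A data.frame with columns \code{n} (0..n_max) and \code{C};
#'   attribute \code{normalization = "unit_vectors"}.
#' @export
bond_autocorrelation <- function(vectors, n_max = NULL) {
  if (is.list(vectors) && !is.array(vectors)) {
    m <- nrow(vectors[[1]])
    arr <- array(0, dim = c(length(vectors), m, 3))
    for (f in seq_along(vectors)) arr[f, , ] <- vectors[[f]]
    vectors <- arr
  }
  arr <- .as_traj(vectors)
  n_frames <- dim(arr)[1]
  m <- dim(arr)[2]
  if (n_frames < 1 || m < 2) stop("need at least one frame with >= 2 bond vectors")
  # normalize to unit vectors
  norms <- sqrt(arr[, , 1]^2 + arr[, , 2]^2 + arr[, , 3]^2)
  if (any(norms < 1e-12)) stop("zero-length bond vector in input")
  for (d in 1:3) arr[, , d] <- arr[, , d] / norms
  if (is.null(n_max)) n_max <- m - 1
  n_max <- min(n_max, m - 1)
  C <- numeric(n_max + 1)
  C[1] <- 1
  for (n in seq_len(n_max)) {
    i1 <- seq_len(m - n)
    dots <- arr[, i1, 1, drop = FALSE] * arr[, i1 + n, 1, drop = FALSE] +
            arr[, i1, 2, drop = FALSE] * arr[, i1 + n, 2, drop = FALSE] +
            arr[, i1, 3, drop = FALSE] * arr[, i1 + n, 3, drop = FALSE]
    C[n + 1] <- mean(dots)
  }
  out <- data.frame(n = 0:n_max, C = C)
  attr(out, "normalization") <- "unit_vectors"
  out
}

#' Fit the persistence length from a C(n) series
#'
#' Fits C(n) = exp(-n d / l_p) by direct least squares in the single
#' parameter l_p (a log-space linear fit is available as a cross-check).
#' The default fit range is n in [1, n_max] where n_max is the largest n
#' with C(n) above a noise floor of 0.05, capped at half the number of
#' bonds.
#'
#' @param C_series data.frame with columns \code{n}, \code{C} (from
#'   \code{\link{bond_autocorrelation}}).
#' @param d Mean backbone bond length, nm.
#' @param fit_range Optional integer c(n_min, n_max) overriding the default.
#' @param method \code{"nls"} (direct least squares) or \code{"log"}
#'   (linear fit of log C(n) vs n).
#' @param noise_floor C values at or below this are excluded from the
#'   default range.
#' @return An object of class \code{ha_persistence_fit}: list with
#'   \code{C} (the series), \code{d}, \code{l_p} (nm; \code{NA} with
#'   status \code{"exceeds resolvable range"} when the series does not
#'   decay), \code{fit_range}, \code{residual}, \code{method},
#'   \code{status}.
#' @export
fit_persistence_length <- function(C_series, d, fit_range = NULL,
                                   method = c("nls", "log"),
                                   noise_floor = 0.05) {
  method <- match.arg(method)
  stopifnot(is.data.frame(C_series), all(c("n", "C") %in% names(C_series)),
            d > 0)
  if (is.null(fit_range)) {
    usable <- C_series$n[C_series$C > noise_floor & C_series$n >= 1]
    n_hi <- if (length(usable)) max(usable) else 0
    n_hi <- min(n_hi, floor(max(C_series$n) / 2))
    fit_range <- c(1L, max(n_hi, 1L))
  }
  sub <- C_series[C_series$n >= fit_range[1] & C_series$n <= fit_range[2], ]
  if (nrow(sub) < 3) {
    stop("fewer than 3 usable C(n) points in the fit range")
  }
  # a series that never decays below ~1 cannot be inverted for l_p
  if (all(sub$C >= 0.999)) {
    out <- list(C = C_series, d = d, l_p = NA_real_, fit_range = fit_range,
                residual = NA_real_, method = method,
                status = "exceeds resolvable range")
    class(out) <- "ha_persistence_fit"
    return(out)
  }
  if (method == "log") {
    pos <- sub[sub$C > 0, ]
    fit <- stats::lm(log(C) ~ 0 + n, data = pos)
    slope <- stats::coef(fit)[["n"]]
    if (slope >= 0) {
      l_p <- NA_real_
      status <- "exceeds resolvable range"
      resid <- NA_real_
    } else {
      l_p <- -d / slope
      status <- "ok"
      resid <- sum(stats::residuals(fit)^2)
    }
  } else {
    sse <- function(lp) sum((sub$C - exp(-sub$n * d / lp))^2)
    # bracket l_p between a fraction of d and a huge multiple of the
    # contour length represented by the series
    upper <- d * max(sub$n) * 1e4
    opt <- stats::optimize(sse, interval = c(d * 1e-3, upper), tol = 1e-12)
    l_p <- opt$minimum
    resid <- opt$objective
    status <- "ok"
    if (l_p > 0.99 * upper) {
      l_p <- NA_real_
      resid <- NA_real_
      status <- "exceeds resolvable range"
    }
  }
  out <- list(C = C_series, d = d, l_p = l_p, fit_range = fit_range,
              residual = resid, method = method, status = status)
  class(out) <- "ha_persistence_fit"
  out
}

#' @export
print.ha_persistence_fit <- function(x, ...) {
  cat("Persistence-length fit (C(n) = exp(-n d / l_p))\n")
  cat(sprintf("  d = %.4f nm, fit range n in [%d, %d], method %s\n",
              x$d, x$fit_range[1], x$fit_range[2], x$method))
  if (identical(x$status, "ok")) {
    cat(sprintf("  l_p = %.4f nm  (residual SSE %.3g)\n", x$l_p, x$residual))
  } else {
    cat("  l_p:", x$status, "\n")
  }
  invisible(x)
}

#' Persistence length of a chain trajectory
#'
#' The full pipeline: backbone bond vectors per frame, bond-vector
#' autocorrelation, mean bond length d over all selected vectors and
#' frames, and the exponential fit.
#'
#' @param trajectory [frame, bead, 3] array or n x 3 matrix (nm).
#' @param topology Chain topology.
#' @param ... Passed to \code{\link{fit_persistence_length}}.
#' @return An \code{ha_persistence_fit}.
#' @export
persistence_length <- function(trajectory, topology, ...) {
  traj <- .as_traj(trajectory)
  sel <- backbone_selection(topology)
  sub <- traj[, sel, , drop = FALSE]
  n_frames <- dim(sub)[1]
  vecs <- array(0, dim = c(n_frames, length(sel) - 1, 3))
  for (f in seq_len(n_frames)) {
    vecs[f, , ] <- diff(sub[f, , , drop = TRUE])
  }
  d <- mean(sqrt(vecs[, , 1]^2 + vecs[, , 2]^2 + vecs[, , 3]^2))
  C <- bond_autocorrelation(vecs)
  fit_persistence_length(C, d, ...)
}

#' Radius of gyration and end-to-end distance
#'
#' Per-frame radius of gyration (equal bead weights) and distance between
#' the first and last bead, with summary statistics.
#'
#' @param trajectory [frame, bead, 3] array or n x 3 matrix (nm).
#' @return A list with \code{per_frame} (data.frame \code{frame},
#'   \code{rg}, \code{e2e}) and \code{summary} (means and sds).
#' @export
gyration_and_e2e <- function(trajectory) {
  traj <- .as_traj(trajectory)
  n_frames <- dim(traj)[1]
  n <- dim(traj)[2]
  rg <- numeric(n_frames)
  e2e <- numeric(n_frames)
  for (f in seq_len(n_frames)) {
    xyz <- traj[f, , , drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    ctr <- colMeans(xyz)
    rg[f] <- sqrt(mean(rowSums(sweep(xyz, 2, ctr)^2)))
    e2e[f] <- sqrt(sum((xyz[n, ] - xyz[1, ])^2))
  }
  list(per_frame = data.frame(frame = seq_len(n_frames), rg = rg, e2e = e2e),
       summary = c(rg_mean = mean(rg), rg_sd = stats::sd(rg),
                   e2e_mean = mean(e2e), e2e_sd = stats::sd(e2e)))
}

# deterministic, nearly uniform directions on the unit sphere
.fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area of a bead model
#'
#' Shrake-Rupley-style point sampling: each bead is inflated by the probe
#' radius, covered with a deterministic quasi-uniform point set, and the
#' fraction of points outside all other inflated beads contributes to the
#' area. Bead radii follow the model's size classes (T 0.191, S 0.230,
#' R 0.264 nm) unless overridden.
#'
#' @param coords n x 3 matrix (nm).
#' @param topology Optional \code{ha_topology} (supplies size classes);
#'   alternatively pass \code{radii}.
#' @param probe_radius Probe radius in nm (default 0.14).
#' @param radii Optional explicit per-bead radii (nm).
#' @param n_points Surface points per bead (default 480).
#' @return Total SASA in nm^2, with attribute \code{per_bead}.
#' @export
sasa <- function(coords, topology = NULL, probe_radius = 0.14, radii = NULL,
                 n_points = 480) {
  .stopifnot_coords(coords)
  n <- nrow(coords)
  if (is.null(radii)) {
    if (is.null(topology)) stop("supply either a topology or explicit radii")
    class_radii <- unlist(nonbonded_config()$radii_nm)
    radii <- unname(class_radii[topology$beads$size])
  }
  if (length(radii) != n) stop("radii length must match bead count")
  rr <- radii + probe_radius
  pts <- .fibonacci_sphere(n_points)
  per_bead <- numeric(n)
  for (i in seq_len(n)) {
    surf <- sweep(pts * rr[i], 2, coords[i, ], "+")
    exposed <- rep(TRUE, n_points)
    for (j in seq_len(n)) {
      if (j == i) next
      dij <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      if (dij >= rr[i] + rr[j]) next
      if (dij < 1e-9 && abs(rr[i] - rr[j]) < 1e-9) {
        # coincident identical spheres: count the surface once
        if (j < i) exposed[] <- FALSE
        next
      }
      d2 <- (surf[, 1] - coords[j, 1])^2 + (surf[, 2] - coords[j, 2])^2 +
            (surf[, 3] - coords[j, 3])^2
      exposed <- exposed & (d2 > rr[j]^2 * (1 - 1e-12))
    }
    per_bead[i] <- 4 * pi * rr[i]^2 * mean(exposed)
  }
  structure(sum(per_bead), per_bead = per_bead)
}

#' Cluster molecules into aggregates
#'
#' Single-linkage clustering of molecules: two molecules are in contact
#' when their minimum inter-bead distance is below the cutoff, and
#' aggregates are the connected groups under this contact relation
#' (computed with \code{stats::hclust}, single linkage).
#'
#' @param coords n x 3 matrix of all bead positions (nm).
#' @param molecule Integer vector assigning each bead to a molecule.
#' @param cutoff Contact distance, nm (default 0.6, a bead-contact
#'   convention).
#' @return Integer vector of cluster sizes, sorted decreasing, with
#'   attribute \code{membership} (cluster id per molecule).
#' @export
cluster_aggregates <- function(coords, molecule, cutoff = 0.6) {
  .stopifnot_coords(coords)
  stopifnot(length(molecule) == nrow(coords), cutoff > 0)
  mols <- sort(unique(molecule))
  m <- length(mols)
  if (m == 1) {
    return(structure(1L, membership = stats::setNames(1L, mols[1])))
  }
  dmin <- matrix(Inf, m, m)
  for (a in seq_len(m - 1)) {
    xa <- coords[molecule == mols[a], , drop = FALSE]
    for (b in (a + 1):m) {
      xb <- coords[molecule == mols[b], , drop = FALSE]
      d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
      dmin[a, b] <- dmin[b, a] <- sqrt(max(0, min(d2)))
    }
  }
  diag(dmin) <- 0
  hc <- stats::hclust(stats::as.dist(dmin), method = "single")
  member <- stats::cutree(hc, h = cutoff * (1 - 1e-9))  # contact is strict '<'
  sizes <- sort(as.integer(table(member)), decreasing = TRUE)
  structure(sizes, membership = stats::setNames(member, mols))
}
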