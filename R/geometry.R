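#' Anchor insertion depth in one frame
#'
#' Depth = (mean z of neighbouring same-leaflet phosphate P atoms) - (minimum
#' z over the anchor carbons). "Neighbouring" means upper-leaflet P atoms
#' within `neighbor_cutoff` lateral (minimum-image) distance of the anchor's
#' lateral centroid; if fewer than 3 qualify, the whole upper leaflet is used
#' with a warning. Positive = inserted below the phosphate plane; never
#' clamped, so desorption shows up as negative depth.
#'
#' @param frame a `Frame`.
#' @param gg_carbons AtomSet of anchor chain carbons.
#' @param phosphorus AtomSet of phospholipid P atoms.
#' @param neighbor_cutoff lateral neighbour radius in nm (default 1.0).
#' @return depth in nm.
#' @export
anchor_insertion_depth <- function(frame, gg_carbons, phosphorus,
                                   neighbor_cutoff = 1.0) {
  if (length(gg_carbons) == 0L) stop("empty anchor AtomSet")
  lab <- assign_leaflets(frame, phosphorus)
  pz <- frame_coords(frame, phosphorus)
  up <- lab == "upper"
  if (!any(up)) stop("no upper-leaflet P atoms")
  gg <- frame_coords(frame, gg_carbons)
  ac <- colMeans(gg)[1:2]
  dx <- wrap_displacement(pz[up, 1] - ac[1], frame$box[1])
  dy <- wrap_displacement(pz[up, 2] - ac[2], frame$box[2])
  near <- sqrt(dx^2 + dy^2) <= neighbor_cutoff
  if (sum(near) < 3L) {
    warning("fewer than 3 neighbouring P atoms within ", neighbor_cutoff,
            " nm; falling back to the whole-leaflet mean plane")
    near <- rep(TRUE, sum(up))
  }
  mean(pz[up, 3][near]) - min(gg[, 3])
}

#' Per-frame anchor insertion depth series
#' @param traj a `Trajectory`.
#' @inheritParams anchor_insertion_depth
#' @return numeric vector, one depth (nm) per frame.
#' @export
insertion_depth_series <- function(traj, gg_carbons, phosphorus,
                                   neighbor_cutoff = 1.0) {
  vapply(seq_len(n_frames(traj)), function(f)
    anchor_insertion_depth(get_frame(traj, f), gg_carbons, phosphorus,
                           neighbor_cutoff), numeric(1))
}

#' Depth distribution summary with modality detection
#'
#' Histogram, mean +/- sd, and modality: 1- vs 2-component Gaussian mixtures
#' compared by BIC (via `mclust`; equal- and unequal-variance models).
#'
#' @param depths numeric per-frame depth series (nm); at least 100 frames.
#' @param bin_width histogram bin width in nm (default 0.05).
#' @importFrom mclust Mclust mclustBIC
#' @return a `DepthSeries`: list with `depths`, `mean`, `sd`, `histogram`
#'   (`breaks`, `counts`), `modality` (1 or 2), `component_means`,
#'   `component_sds`, `component_weights`.
#' @export
depth_distribution <- function(depths, bin_width = 0.05) {
  depths <- as.numeric(depths)
  if (length(depths) < 100) stop("need at least 100 frames of depths")
  lo <- floor(min(depths) / bin_width) * bin_width
  hi <- ceiling(max(depths) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  h <- graphics::hist(depths, breaks = breaks, plot = FALSE)
  mc <- mclust::Mclust(depths, G = 1:2, modelNames = c("E", "V"),
                       verbose = FALSE)
  structure(list(depths = depths, mean = mean(depths),
                 sd = stats::sd(depths),
                 histogram = list(breaks = h$breaks, counts = h$counts),
                 modality = mc$G,
                 component_means = as.numeric(mc$parameters$mean),
                 component_sds = sqrt(as.numeric(
                   mc$parameters$variance$sigmasq)),
                 component_weights = as.numeric(mc$parameters$pro)),
            class = "DepthSeries")
}

#' @export
print.DepthSeries <- function(x, ...) {
  cat(sprintf("DepthSeries: %d frames, mean %.3f +/- %.3f nm, modality %d (means %s)\n",
              length(x$depths), x$mean, x$sd, x$modality,
              paste(sprintf("%.2f", x$component_means), collapse = "/")))
  invisible(x)
}

#' Per-residue z-distances to the membrane phosphate plane
#'
#' For every frame and protein residue: (mass-weighted residue centre-of-mass
#' z) - (mean z of upper-leaflet P atoms). The proximal (upper) leaflet mean
#' plane is used.
#'
#' @param traj a `Trajectory`.
#' @param protein AtomSet of protein atoms.
#' @param phosphorus AtomSet of phospholipid P atoms.
#' @return a `ResidueDistanceMap`: numeric matrix `n_residues x n_frames`
#'   (nm), rownames = residue numbers, with attribute `time`.
#' @export
residue_membrane_distances <- function(traj, protein, phosphorus) {
  if (length(protein) == 0L) stop("empty protein AtomSet")
  a <- traj$topology$atoms[protein, ]
  resids <- sort(unique(a$resid))
  groups <- split(seq_along(protein), a$resid)
  if (any(vapply(groups, length, 1L) == 0L)) stop("residue with zero atoms")
  m <- a$mass
  nf <- n_frames(traj)
  out <- matrix(NA_real_, length(resids), nf,
                dimnames = list(resids, NULL))
  for (f in seq_len(nf)) {
    fr <- get_frame(traj, f)
    lab <- assign_leaflets(fr, phosphorus)
    plane <- mean(frame_coords(fr, phosphorus)[lab == "upper", 3])
    z <- frame_coords(fr, protein)[, 3]
    comz <- vapply(groups, function(ix) sum(z[ix] * m[ix]) / sum(m[ix]),
                   numeric(1))
    out[, f] <- comz[as.character(resids)] - plane
  }
  attr(out, "time") <- traj$time
  class(out) <- c("ResidueDistanceMap", class(out))
  out
}

#' Mass-weighted radius of gyration
#'
#' `sqrt( sum_i m_i |r_i - r_COM|^2 / sum_i m_i )`.
#'
#' @param frame a `Frame` with a topology (for masses), or supply `masses`.
#' @param atoms AtomSet (>= 2 atoms).
#' @param masses optional masses overriding the topology.
#' @return radius of gyration in nm.
#' @export
radius_of_gyration <- function(frame, atoms, masses = NULL) {
  if (length(atoms) < 2L) stop("need at least 2 atoms")
  xyz <- frame_coords(frame, atoms)
  if (is.null(masses)) {
    if (is.null(frame$topology)) stop("no topology; supply masses")
    masses <- frame$topology$atoms$mass[atoms]
  }
  M <- sum(masses)
  if (M <= 0) stop("zero total mass")
  com <- colSums(xyz * masses) / M
  d2 <- rowSums(sweep(xyz, 2, com)^2)
  sqrt(sum(masses * d2) / M)
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Optimal weighted rigid transform (rotation + translation, reflections
#' excluded by the determinant guard) mapping `mobile` onto `reference`.
#'
#' @param mobile,reference `n x 3` coordinate matrices, `n >= 3`,
#'   non-collinear.
#' @param weights optional per-point weights (e.g. masses).
#' @return list with `rotation` (3x3), `translation` (length 3; transformed
#'   points are `mobile %*% rotation + translation`), `rmsd` (weighted, nm),
#'   and `apply` (function transforming an `n x 3` matrix).
#' @export
superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference) || ncol(mobile) != 3)
    stop("mobile and reference must be equal-size n x 3 matrices")
  if (nrow(mobile) < 3) stop("need at least 3 points")
  w <- if (is.null(weights)) rep(1, nrow(mobile)) else as.numeric(weights)
  w <- w / sum(w)
  cm <- colSums(mobile * w); cr <- colSums(reference * w)
  P <- sweep(mobile, 2, cm); Q <- sweep(reference, 2, cr)
  H <- t(P * w) %*% Q
  sv <- svd(H)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1e-300))
    stop("degenerate (collinear) point set; superposition undefined")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  tr <- cr - as.numeric(cm %*% R)
  moved <- sweep(mobile %*% R, 2, tr, "+")
  rmsd <- sqrt(sum(w * rowSums((moved - reference)^2)))
  list(rotation = R, translation = tr, rmsd = rmsd,
       apply = function(x) sweep(as.matrix(x) %*% R, 2, tr, "+"))
}

#' Root-mean-square fluctuation after superposition
#'
#' Every frame's `fit_atoms` are superposed onto the reference frame; the
#' resulting transform is applied to `ca_atoms`, and per-atom RMSF is
#' computed about the mean structure.
#'
#' @param traj a `Trajectory` (>= 2 frames).
#' @param ca_atoms AtomSet whose fluctuations are reported (e.g. C-alpha).
#' @param fit_atoms AtomSet used for the superposition (e.g. G-domain
#'   C-alpha); defaults to `ca_atoms`.
#' @param ref_frame reference frame index (default 1).
#' @param weights optional fit weights (defaults to fit-atom masses).
#' @return named numeric vector of per-atom RMSF (nm), names = residue
#'   numbers of `ca_atoms`.
#' @export
rmsf <- function(traj, ca_atoms, fit_atoms = ca_atoms, ref_frame = 1,
                 weights = NULL) {
  nf <- n_frames(traj)
  if (nf < 2L) stop("RMSF needs at least 2 frames")
  ref <- get_frame(traj, ref_frame)
  reffit <- frame_coords(ref, fit_atoms)
  if (is.null(weights) && !is.null(traj$topology))
    weights <- traj$topology$atoms$mass[fit_atoms]
  pos <- array(NA_real_, c(nf, length(ca_atoms), 3))
  for (f in seq_len(nf)) {
    fr <- get_frame(traj, f)
    sp <- superpose(frame_coords(fr, fit_atoms), reffit, weights)
    pos[f, , ] <- sp$apply(frame_coords(fr, ca_atoms))
  }
  mean_pos <- apply(pos, c(2, 3), mean)
  d2 <- vapply(seq_along(ca_atoms), function(i)
    mean(rowSums(sweep(pos[, i, , drop = TRUE], 2, mean_pos[i, ])^2)),
    numeric(1))
  out <- sqrt(d2)
  names(out) <- traj$topology$atoms$resid[ca_atoms]
  out
}

#' Dihedral angle of four points, in [0, 360)
#'
#' Standard atan2 convention on the b1/b2/b3 bond vectors; the returned
#' angle is the torsion p1-p2-p3-p4 mapped to `[0, 360)` degrees.
#'
#' @param p1,p2,p3,p4 length-3 coordinate vectors.
#' @return angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- pracma_cross(b1, b2); n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, b2 / sqrt(sum(b2^2)))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  (ang + 360) %% 360
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' G-domain orientation descriptors: pivot angle theta and dihedral omega
#'
#' Geometric construction: `A` = anchor-carbon centroid, `G` = mass-weighted
#' G-domain centre of mass, `S` = switch-regions centre of mass, and
#' `M = A - z_hat` (a probe point displaced into the membrane along -z).
#' Theta is the angle between the G-domain vector `G - A` and the +z bilayer
#' normal, so theta = 90 deg is a G domain lying parallel to the membrane
#' plane. Omega is the torsion M-A-G-S in `[0, 360)`: it measures how the
#' switch regions are rotated about the anchor-to-G-domain axis relative to
#' the membrane normal. Frames are labelled 'exo' when omega is within 45
#' deg of 80 deg (switch regions solvent-exposed), 'endo' within 45 deg of
#' 190 deg (switch regions facing the membrane), else 'intermediate'.
#'
#' This A/G/S/M construction is a documented, self-consistent definition of
#' the orientation descriptors (the constraint set: theta = 90 iff parallel;
#' omega separates endo from exo populations); other tools may use different
#' internal reference atoms.
#'
#' @param frame a `Frame` with topology (for masses).
#' @param g_domain AtomSet of G-domain atoms.
#' @param switch_regions AtomSet of switch-region atoms (switch I + II).
#' @param anchor AtomSet of anchor carbons.
#' @return list with `theta` (deg, `[0, 180]`), `omega` (deg, `[0, 360)`),
#'   `label` ('endo' / 'exo' / 'intermediate').
#' @export
orientation_angles <- function(frame, g_domain, switch_regions, anchor) {
  if (length(g_domain) == 0L || length(switch_regions) == 0L ||
      length(anchor) == 0L)
    stop("g_domain, switch_regions and anchor must be non-empty")
  mass <- function(atoms) frame$topology$atoms$mass[atoms]
  com <- function(atoms) {
    xyz <- frame_coords(frame, atoms); m <- mass(atoms)
    colSums(xyz * m) / sum(m)
  }
  A <- colMeans(frame_coords(frame, anchor))
  G <- com(g_domain); S <- com(switch_regions)
  M <- A - c(0, 0, 1)
  vG <- G - A
  if (sqrt(sum(vG^2)) < 1e-9) stop("coincident anchor and G-domain centres")
  theta <- acos(pmin(1, pmax(-1, vG[3] / sqrt(sum(vG^2))))) * 180 / pi
  omega <- dihedral_angle(M, A, G, S)
  circ_dist <- function(a, b) {
    d <- abs(a - b) %% 360
    pmin(d, 360 - d)
  }
  label <- if (circ_dist(omega, 80) <= 45) "exo"
           else if (circ_dist(omega, 190) <= 45) "endo"
           else "intermediate"
  list(theta = theta, omega = omega, label = label)
}

#' Per-frame orientation series
#'
#' @param traj a `Trajectory`.
#' @inheritParams orientation_angles
#' @return an `OrientationSeries` data frame with columns `time`, `theta`,
#'   `omega`, `label`.
#' @export
orientation_series <- function(traj, g_domain, switch_regions, anchor) {
  rows <- lapply(seq_len(n_frames(traj)), function(f) {
    o <- orientation_angles(get_frame(traj, f), g_domain, switch_regions,
                            anchor)
    data.frame(time = traj$time[f], theta = o$theta, omega = o$omega,
               label = o$label, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("OrientationSeries", class(out))
  out
}
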