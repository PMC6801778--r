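# ---- orientation-distribution calibration ----------------------------------

#' Cone-band half-angle for a target C-H order parameter magnitude
#'
#' The C-H bond orientation model is a uniform "cone band" about the membrane
#' plane: cos(theta) uniform in `[-sin(alpha), +sin(alpha)]` with uniform
#' azimuth, i.e. vectors confined to within `alpha` of the x,y-plane. The
#' half-angle `alpha` is found by bisection such that `|<P2(cos theta)>|`
#' over the band equals `target_s`, with the expectation evaluated by
#' numerical quadrature. `target_s -> 0.5` is the planar limit (all vectors
#' perpendicular to the normal), `target_s -> 0` the isotropy limit.
#'
#' @param target_s target order magnitude, in (0, 0.5].
#' @param tol bisection tolerance on the order value (default 1e-6).
#' @return half-angle alpha in radians.
#' @export
cone_halfangle_for_order <- function(target_s, tol = 1e-6) {
  if (target_s <= 0 || target_s > 0.5)
    stop("unattainable target: |<P2>| for a cone band lies in (0, 0.5]")
  band_mag <- function(alpha) {
    h <- sin(alpha)
    if (h < 1e-12) return(0.5)
    abs(stats::integrate(legendre_p2, -h, h)$value / (2 * h))
  }
  lo <- 1e-9; hi <- pi / 2
  # band_mag is decreasing in alpha: 0.5 at 0, 0 at pi/2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (band_mag(mid) > target_s) lo <- mid else hi <- mid
    if (abs(band_mag(mid) - target_s) < tol) return(mid)
  }
  mid
}

#' Sample unit vectors from the cone-band orientation distribution
#'
#' @param n number of vectors.
#' @param halfangle band half-angle in radians (see
#'   [cone_halfangle_for_order()]).
#' @param seed optional integer seed for reproducibility.
#' @return `n x 3` matrix of unit vectors.
#' @export
sample_cone_vectors <- function(n, halfangle, seed = NULL) {
  draw <- function() {
    h <- sin(halfangle)
    cz <- stats::runif(n, -h, h)
    phi <- stats::runif(n, 0, 2 * pi)
    st <- sqrt(pmax(0, 1 - cz^2))
    cbind(st * cos(phi), st * sin(phi), cz)
  }
  if (is.null(seed)) draw() else with_local_seed(seed, draw())
}

# chain-axis polar cap: cos(beta) uniform in [b, 1]. With the two C-H bonds
# of each methylene perpendicular to the chain axis, <P2(cos theta_CH)> =
# -<P2(cos beta)>/2, so a target |S_CD| = s needs <P2(cos beta)> = 2 s:
# (b + b^2)/2 = 2 s  =>  b = (-1 + sqrt(1 + 16 s)) / 2  (b = 1 exactly at
# s = 0.5: all chains along the normal, the planar C-H limit).
cap_cos_for_order <- function(target_s) {
  if (target_s <= 0 || target_s > 0.5)
    stop("chain-axis calibration needs target order in (0, 0.5]")
  (-1 + sqrt(1 + 16 * target_s)) / 2
}

# ---- bilayer generator ------------------------------------------------------

#' Specification for a synthetic planar bilayer
#'
#' @param n_lipids_per_leaflet lipids per leaflet.
#' @param thickness phosphate-plane separation (nm).
#' @param area_per_lipid nm^2 per lipid (sets the lateral box).
#' @param target_order chain-averaged |S_CD| to plant, in (0, 0.5].
#' @param species named fractions of lipid species (must sum to 1);
#'   recognised names: POPC, PSM, POPE, POPS, PI3P (phospholipids with an
#'   sn-1 chain; PI3P has no headgroup N) and CHOL (no phosphate, hydroxyl
#'   oxygen O3 as leaflet reference).
#' @param jitter_sd sd of the per-frame z jitter of headgroup atoms (nm).
#' @param pn_angle planted P-N tilt angle from +z (degrees).
#' @param n_frames,dt frames and frame interval (ns).
#' @param seed integer seed (generation is bit-reproducible given the spec).
#' @param local_deficit optional `list(x, y, radius, delta)`: lipids whose
#'   lateral grid position lies within `radius` (minimum image) of `(x, y)`
#'   are generated with order `target_order - delta` (a planted disordered
#'   patch, e.g. around an anchor).
#' @return object of class `BilayerSpec` (a validated list).
#' @export
bilayer_spec <- function(n_lipids_per_leaflet = 64, thickness = 3.87,
                         area_per_lipid = 0.662, target_order = 0.176,
                         species = c(POPC = 1), jitter_sd = 0.05,
                         pn_angle = 80, n_frames = 25, dt = 1, seed = 1,
                         local_deficit = NULL) {
  stopifnot(n_lipids_per_leaflet > 0, thickness > 0, area_per_lipid > 0,
            jitter_sd >= 0, n_frames >= 1, dt > 0)
  if (abs(sum(species) - 1) > 1e-9) stop("species fractions must sum to 1")
  known <- c("POPC", "PSM", "POPE", "POPS", "PI3P", "CHOL")
  if (!all(names(species) %in% known))
    stop("unknown species: ", paste(setdiff(names(species), known),
                                    collapse = ", "))
  if (target_order <= 0 || target_order > 0.5)
    stop("target_order must be in (0, 0.5]")
  if (!is.null(local_deficit)) {
    stopifnot(all(c("x", "y", "radius", "delta") %in% names(local_deficit)))
    if (target_order - local_deficit$delta <= 0)
      stop("local_deficit$delta leaves a non-positive local order")
  }
  structure(list(n_lipids_per_leaflet = n_lipids_per_leaflet,
                 thickness = thickness, area_per_lipid = area_per_lipid,
                 target_order = target_order, species = species,
                 jitter_sd = jitter_sd, pn_angle = pn_angle,
                 n_frames = n_frames, dt = dt, seed = seed,
                 local_deficit = local_deficit), class = "BilayerSpec")
}

# geometry constants of the pseudo-lipid chains (nm, degrees)
.cc_bond <- 0.1526
.ccc_angle <- 111
.ch_bond <- 0.1111
.chain_adv <- .cc_bond * cos((180 - .ccc_angle) / 2 * pi / 180)
.chain_off <- .cc_bond * sin((180 - .ccc_angle) / 2 * pi / 180)

# atoms of one pseudo-lipid; returns data.frame(name) in order
lipid_atom_names <- function(species) {
  if (species == "CHOL") return(c("O3", paste0("C", 1:8)))
  nm <- c("P", if (species != "PI3P") "N", "C1")
  for (ci in 2:15) nm <- c(nm, paste0("C", ci), paste0("H", ci, "R"),
                           paste0("H", ci, "S"))
  c(nm, "C16")
}

# one frame of one chain: carbons along a zigzag with axis d (unit), in-plane
# offset direction e (unit, perpendicular to d); returns n_c x 3 matrix
chain_positions <- function(start, d, e, n_c) {
  k <- seq_len(n_c)
  sweep(outer(k - 1, d * .chain_adv) +
        outer((-1)^k * .chain_off / 2, e), 2, start, "+")
}

# unit vector at polar angle beta (from +z or -z) and azimuth phi
polar_unit <- function(cosb, phi, down = FALSE) {
  sb <- sqrt(pmax(0, 1 - cosb^2))
  cbind(sb * cos(phi), sb * sin(phi), if (down) -cosb else cosb)
}

# an arbitrary unit vector perpendicular to d, rotated by psi about d
perp_unit <- function(d, psi) {
  ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- pracma_cross(d, ref); e1 <- e1 / sqrt(sum(e1^2))
  e2 <- pracma_cross(d, e1)
  cos(psi) * e1 + sin(psi) * e2
}

#' Generate a synthetic planar bilayer trajectory with planted ground truth
#'
#' Two leaflets of pseudo-lipids on a lateral grid. Phosphate (or, for
#' cholesterol, hydroxyl-oxygen) planes sit at +/- thickness/2 with per-frame
#' Gaussian z jitter; the lateral box is exactly
#' `sqrt(n * area_per_lipid)` squared; saturated chains (C1..C16 with
#' explicit hydrogens on C2..C15) are all-trans zigzags whose axes are drawn
#' per frame from a polar-cap distribution calibrated so the chain-averaged
#' |S_CD| equals `target_order`; headgroup P-N vectors are planted at
#' `pn_angle`. Deterministic given the spec (including its seed).
#'
#' @param spec a [bilayer_spec()].
#' @return a `Trajectory` with attribute `ground_truth` (list of planted
#'   values: thickness, area_per_lipid, target_order, per-leaflet count,
#'   species counts, pn_angle).
#' @export
make_bilayer <- function(spec) {
  stopifnot(inherits(spec, "BilayerSpec"))
  with_local_seed(spec$seed, make_bilayer_impl(spec))
}

make_bilayer_impl <- function(spec) {
  n <- spec$n_lipids_per_leaflet
  L <- sqrt(n * spec$area_per_lipid)
  Lz <- spec$thickness + 4
  g <- ceiling(sqrt(n))
  cells <- expand.grid(ix = seq_len(g), iy = seq_len(g))[seq_len(n), ]
  gx <- (cells$ix - 0.5) * L / g
  gy <- (cells$iy - 0.5) * L / g
  # species assignment: largest-remainder counts, shuffled across the grid
  counts <- floor(spec$species * n)
  rem <- spec$species * n - counts
  short <- n - sum(counts)
  if (short > 0) {
    add <- order(rem, decreasing = TRUE)[seq_len(short)]
    counts[add] <- counts[add] + 1
  }
  species_by_lipid <- sample(rep(names(counts), counts))
  # per-lipid chain-axis cap parameter (with optional local order deficit)
  target <- rep(spec$target_order, n)
  if (!is.null(spec$local_deficit)) {
    ld <- spec$local_deficit
    dx <- wrap_displacement(gx - ld$x, L); dy <- wrap_displacement(gy - ld$y, L)
    target[sqrt(dx^2 + dy^2) <= ld$radius] <- spec$target_order - ld$delta
  }
  cap_b <- vapply(target, cap_cos_for_order, numeric(1))

  # topology: leaflet 1 (upper, +z) then leaflet 2 (lower), same grid
  name <- character(0); resname <- character(0); resid <- integer(0)
  per_lipid <- vector("list", 2L * n)
  for (side in 1:2) for (i in seq_len(n)) {
    li <- (side - 1L) * n + i
    nm <- lipid_atom_names(species_by_lipid[i])
    per_lipid[[li]] <- nm
    name <- c(name, nm)
    resname <- c(resname, rep(species_by_lipid[i], length(nm)))
    resid <- c(resid, rep(li, length(nm)))
  }
  top <- topology(name = name, resname = resname, resid = resid,
                  segid = "MEMB")
  na <- n_atoms(top)
  nf <- spec$n_frames
  coords <- array(NA_real_, c(nf, na, 3))
  half <- spec$thickness / 2
  for (f in seq_len(nf)) {
    at <- 0L
    for (side in 1:2) {
      sgn <- if (side == 1L) 1 else -1
      for (i in seq_len(n)) {
        sp <- species_by_lipid[i]
        head_z <- sgn * half +
          if (spec$jitter_sd > 0) stats::rnorm(1, 0, spec$jitter_sd) else 0
        head <- c(gx[i], gy[i], head_z)
        n_c <- if (sp == "CHOL") 8L else 16L
        # chain axis from the calibrated polar cap about the inward normal
        cosb <- stats::runif(1, cap_b[i], 1)
        d <- drop(polar_unit(cosb, stats::runif(1, 0, 2 * pi),
                             down = (side == 1L)))
        e <- perp_unit(d, stats::runif(1, 0, 2 * pi))
        cpos <- chain_positions(head + 0.25 * d, d, e, n_c)
        # pin the lateral chain centroid at the lipid's grid site so lateral
        # assignments (local order maps) see the planted per-lipid order
        cpos[, 1] <- cpos[, 1] - mean(cpos[, 1]) + head[1]
        cpos[, 2] <- cpos[, 2] - mean(cpos[, 2]) + head[2]
        if (sp == "CHOL") {
          xyz <- rbind(head, cpos)
        } else {
          hh <- reconstruct_ch_vectors(cpos[1:14, , drop = FALSE],
                                       cpos[2:15, , drop = FALSE],
                                       cpos[3:16, , drop = FALSE])
          xyz <- head
          if (sp != "PI3P") {
            pn <- drop(polar_unit(cos(spec$pn_angle * pi / 180),
                                  stats::runif(1, 0, 2 * pi)))
            xyz <- rbind(xyz, head + 0.1 * pn)
          }
          xyz <- rbind(xyz, cpos[1, ])
          for (ci in 2:15) {
            k <- ci - 1L
            xyz <- rbind(xyz, cpos[ci, ],
                         cpos[ci, ] + .ch_bond * hh$h1[k, ],
                         cpos[ci, ] + .ch_bond * hh$h2[k, ])
          }
          xyz <- rbind(xyz, cpos[16, ])
        }
        coords[f, at + seq_len(nrow(xyz)), ] <- xyz
        at <- at + nrow(xyz)
      }
    }
  }
  traj <- trajectory(top, coords, c(L, L, Lz),
                     time = (seq_len(nf) - 1) * spec$dt)
  attr(traj, "ground_truth") <- list(
    thickness = spec$thickness, area_per_lipid = spec$area_per_lipid,
    target_order = spec$target_order, n_per_leaflet = n,
    species_counts = counts, pn_angle = spec$pn_angle,
    local_deficit = spec$local_deficit)
  traj
}

# ---- Brownian track generator ----------------------------------------------

#' Specification for synthetic 2D Brownian tracks
#'
#' @param populations list of `list(D, fraction)` with `D` in 1e-7 cm^2/s
#'   and fractions summing to 1; an optional `label` per population names
#'   the species (defaults "POP1", "POP2", ...).
#' @param n_particles,n_steps particles and steps (frames = steps + 1).
#' @param dt frame interval (ns).
#' @param box lateral box length (nm).
#' @param seed integer seed.
#' @return object of class `TrackSpec`.
#' @export
track_spec <- function(populations = list(list(D = 1.36, fraction = 1)),
                       n_particles = 100, n_steps = 500, dt = 1,
                       box = 15, seed = 1) {
  fr <- vapply(populations, function(p) p$fraction, numeric(1))
  Ds <- vapply(populations, function(p) p$D, numeric(1))
  if (abs(sum(fr) - 1) > 1e-9) stop("population fractions must sum to 1")
  if (any(Ds < 0)) stop("diffusion coefficients must be >= 0")
  step_sd <- sqrt(2 * e7cm2s_to_nm2ns(max(Ds)) * dt)
  if (step_sd > box / 4)
    stop("step sd ", signif(step_sd, 3), " nm exceeds box/4; unwrapping ",
         "would be ambiguous (reduce D*dt or enlarge the box)")
  labels <- vapply(seq_along(populations), function(i)
    populations[[i]]$label %||% paste0("POP", i), character(1))
  structure(list(populations = populations, labels = labels,
                 n_particles = n_particles, n_steps = n_steps, dt = dt,
                 box = box, seed = seed), class = "TrackSpec")
}

#' Generate wrapped Brownian tracks plus the unwrapped ground truth
#'
#' Each particle performs a 2D random walk with per-axis step variance
#' `2 D dt` (D converted from 1e-7 cm^2/s to nm^2/ns); positions are wrapped
#' into the periodic box for the returned `Trajectory`, and the unwrapped
#' truth is returned as a `TrackSet`. Population membership is assigned
#' deterministically in proportion to the fractions.
#'
#' @param spec a [track_spec()].
#' @return list with `trajectory` (wrapped; one atom per particle),
#'   `tracks` (unwrapped truth `TrackSet` with species labels), and `spec`.
#' @export
make_brownian_tracks <- function(spec) {
  stopifnot(inherits(spec, "TrackSpec"))
  with_local_seed(spec$seed, make_brownian_tracks_impl(spec))
}

make_brownian_tracks_impl <- function(spec) {
  np <- spec$n_particles; nf <- spec$n_steps + 1L
  fr <- vapply(spec$populations, function(p) p$fraction, numeric(1))
  counts <- floor(fr * np)
  short <- np - sum(counts)
  if (short > 0) {
    add <- order(fr * np - counts, decreasing = TRUE)[seq_len(short)]
    counts[add] <- counts[add] + 1
  }
  pop <- rep(seq_along(counts), counts)
  Ds <- vapply(spec$populations, function(p) p$D, numeric(1))
  sds <- sqrt(2 * e7cm2s_to_nm2ns(Ds[pop]) * spec$dt)
  x0 <- stats::runif(np, 0, spec$box); y0 <- stats::runif(np, 0, spec$box)
  dx <- matrix(stats::rnorm(spec$n_steps * np, 0, rep(sds, each = spec$n_steps)),
               spec$n_steps, np)
  dy <- matrix(stats::rnorm(spec$n_steps * np, 0, rep(sds, each = spec$n_steps)),
               spec$n_steps, np)
  x <- rbind(x0, sweep(matrix(apply(dx, 2, cumsum), spec$n_steps), 2, x0, "+"))
  y <- rbind(y0, sweep(matrix(apply(dy, 2, cumsum), spec$n_steps), 2, y0, "+"))
  labels <- spec$labels[pop]
  truth <- track_set(x, y, spec$dt, labels = labels,
                     box = c(spec$box, spec$box))
  top <- topology(name = rep("C1", np), resname = labels,
                  resid = seq_len(np), segid = "TRK")
  coords <- array(NA_real_, c(nf, np, 3))
  coords[, , 1] <- wrap_position(x, spec$box)
  coords[, , 2] <- wrap_position(y, spec$box)
  coords[, , 3] <- 5
  traj <- trajectory(top, coords, c(spec$box, spec$box, 10),
                     time = (seq_len(nf) - 1) * spec$dt)
  list(trajectory = traj, tracks = truth, spec = spec)
}

# ---- anchored-protein generator --------------------------------------------

#' Specification for a synthetic anchored pseudo-protein
#'
#' @param depth_means,depth_sds,depth_weights parameters of the planted
#'   insertion-depth distribution (Gaussian mixture; scalars for unimodal).
#' @param theta,theta_sd planted pivot angle (degrees) and its sd.
#' @param omega,omega_sd planted internal dihedral (degrees) and its sd.
#' @param n_gg number of anchor chains (1 = mono-, 2 = doubly lipidated).
#' @param ag_len anchor-to-G-domain distance (nm).
#' @param s_len G-domain-to-switch-COM offset (nm).
#' @param seed integer seed.
#' @return object of class `AnchorSpec`.
#' @export
anchor_spec <- function(depth_means = 1.74, depth_sds = 0.15,
                        depth_weights = 1, theta = 90, theta_sd = 0,
                        omega = 190, omega_sd = 0, n_gg = 2,
                        ag_len = 2.5, s_len = 0.8, seed = 1) {
  k <- length(depth_means)
  depth_sds <- rep_len(depth_sds, k)
  depth_weights <- rep_len(depth_weights, k)
  if (abs(sum(depth_weights) - 1) > 1e-9)
    stop("depth_weights must sum to 1")
  stopifnot(n_gg %in% 1:2, ag_len > 0, s_len > 0, all(depth_sds >= 0))
  structure(list(depth_means = depth_means, depth_sds = depth_sds,
                 depth_weights = depth_weights, theta = theta,
                 theta_sd = theta_sd, omega = omega, omega_sd = omega_sd,
                 n_gg = n_gg, ag_len = ag_len, s_len = s_len, seed = seed),
            class = "AnchorSpec")
}

# switch-region residue ranges (switch I, switch II) of the 215-residue
# pseudo-protein; G domain spans residues 15-185
.switch_resids <- c(50:60, 75:92)
.gdomain_resids <- 15:185

# rigid CA template of the pseudo-protein in a local frame where the
# G-domain COM is the origin, the switch COM sits at s_len * x_hat, and the
# anchor direction is -z_hat; returns 215 x 3 matrix (rows = residues 1:215)
protein_template <- function(s_len, ag_len) {
  xyz <- matrix(0, 215, 3)
  sw1 <- 50:60; sw2 <- 75:92
  gdom <- .gdomain_resids
  other <- setdiff(gdom, c(sw1, sw2))
  ring <- function(n, radius, plane = c("yz")) {
    ph <- 2 * pi * seq_len(n) / n
    cbind(0, radius * cos(ph), radius * sin(ph))
  }
  # switch I sits 25% farther out than the switch COM, switch II closer,
  # weighted so the joint COM is exactly s_len * x_hat (switch I is the
  # planted "distal" patch in membrane-distance fixtures)
  d1 <- 1.25
  d2 <- 1 - (d1 - 1) * length(sw1) / length(sw2)
  xyz[sw1, ] <- ring(length(sw1), 0.25) +
    matrix(c(d1 * s_len, 0, 0), length(sw1), 3, byrow = TRUE)
  xyz[sw2, ] <- ring(length(sw2), 0.25) +
    matrix(c(d2 * s_len, 0, 0), length(sw2), 3, byrow = TRUE)
  # the rest of the G domain balances the switch offset so the G-domain COM
  # stays at the origin
  bal <- -s_len * length(c(sw1, sw2)) / length(other)
  ph <- 2 * pi * seq_along(other) / length(other)
  xyz[other, ] <- cbind(bal + 0.3 * (-1)^seq_along(other),
                        0.55 * cos(ph), 0.55 * sin(ph))
  # N-terminal tail (1-14) tucked above the G domain
  ph <- 2 * pi * seq_len(14) / 14
  xyz[1:14, ] <- cbind(0.3 * cos(ph), 0.3 * sin(ph), 0.45)
  # HVR (186-215) descends from the G domain toward the anchor at
  # local (0, 0, -ag_len)
  hvr <- 186:215
  t <- (hvr - 185) / length(hvr)
  xyz[hvr, ] <- cbind(0.05 * (-1)^hvr, 0, -t * ag_len)
  xyz
}

# rotate v about unit axis k by angle a (Rodrigues)
rotate_about <- function(v, k, a) {
  v * cos(a) + pracma_cross(k, v) * sin(a) + k * sum(k * v) * (1 - cos(a))
}

#' Generate an anchored pseudo-protein posed in a bilayer
#'
#' Adds a coarse CA-only pseudo-protein (215 residues: G-domain blob with
#' switch-region sub-blobs, N-terminal tail, C-terminal HVR) plus 1 or 2
#' geranylgeranyl-like anchor chains (20 carbons each, resname `GGC`) to an
#' existing synthetic bilayer. Per frame, the anchor's deepest carbon is
#' placed so the insertion depth (relative to the mean z of neighbouring
#' upper-leaflet P atoms, the same rule the measurement uses) follows the
#' planted distribution, and the protein is posed so the pivot angle theta
#' and dihedral omega equal their planted values.
#'
#' @param spec an [anchor_spec()].
#' @param bilayer a `Trajectory` from [make_bilayer()].
#' @return a `Trajectory` (bilayer + protein) with attribute `ground_truth`
#'   carrying the planted per-frame `depths`, `theta`, `omega` and the
#'   AtomSets `gg_carbons`, `phosphorus`, `ca_atoms`.
#' @export
make_anchored_protein <- function(spec, bilayer) {
  stopifnot(inherits(spec, "AnchorSpec"), inherits(bilayer, "Trajectory"))
  gt <- attr(bilayer, "ground_truth")
  if (!is.null(gt) && max(spec$depth_means) > gt$thickness)
    stop("infeasible geometry: planted depth exceeds the bilayer thickness")
  with_local_seed(spec$seed, make_anchored_protein_impl(spec, bilayer))
}

make_anchored_protein_impl <- function(spec, bilayer) {
  nf <- n_frames(bilayer)
  nb <- n_atoms(bilayer)
  box <- bilayer$box[1, ]
  # protein topology: one CA per residue; GG chains carried by resname GGC
  resid <- 1:215
  resname <- rep("ALA", 215)
  gg_res <- if (spec$n_gg == 2) c(212L, 213L) else 212L
  resname[gg_res] <- "GGC"
  name <- rep("CA", 215)
  pn <- data.frame(name = name, resname = resname, resid = resid)
  for (r in gg_res) {
    pn <- rbind(pn, data.frame(name = paste0("C", 1:20, "G"),
                               resname = "GGC", resid = r))
  }
  pn <- pn[order(pn$resid, match(pn$name, c("CA", paste0("C", 1:20, "G")))), ]
  prot_top <- topology(name = pn$name, resname = pn$resname,
                       resid = pn$resid, segid = "PROT")
  np <- n_atoms(prot_top)
  # merged topology
  a_b <- bilayer$topology$atoms; a_p <- prot_top$atoms
  top <- topology(name = c(a_b$name, a_p$name),
                  resname = c(a_b$resname, a_p$resname),
                  resid = c(a_b$resid, a_p$resid),
                  segid = c(a_b$segid, a_p$segid))
  ca_rows <- nb + which(a_p$name == "CA")
  gg_rows <- nb + which(a_p$resname == "GGC" & a_p$name != "CA")
  phos <- which(a_b$name == "P")
  template <- protein_template(spec$s_len, spec$ag_len)

  A_lat <- box[1:2] / 2
  gg_per_chain <- split(gg_rows, rep(seq_along(gg_res), each = 20))
  depths <- theta <- omega <- numeric(nf)
  coords <- array(NA_real_, c(nf, nb + np, 3))
  coords[, seq_len(nb), ] <- bilayer$coords
  for (f in seq_len(nf)) {
    fr <- get_frame(bilayer, f)
    lab <- assign_leaflets(fr, phos)
    pco <- frame_coords(fr, phos)
    up <- lab == "upper"
    dx <- wrap_displacement(pco[up, 1] - A_lat[1], box[1])
    dy <- wrap_displacement(pco[up, 2] - A_lat[2], box[2])
    near <- sqrt(dx^2 + dy^2) <= 1.0
    plane <- if (sum(near) >= 3) mean(pco[up, 3][near])
             else mean(pco[up, 3])
    comp <- sample.int(length(spec$depth_weights), 1,
                       prob = spec$depth_weights)
    d_f <- stats::rnorm(1, spec$depth_means[comp], spec$depth_sds[comp])
    th <- spec$theta + if (spec$theta_sd > 0) stats::rnorm(1, 0, spec$theta_sd) else 0
    om <- spec$omega + if (spec$omega_sd > 0) stats::rnorm(1, 0, spec$omega_sd) else 0
    om <- om %% 360
    depths[f] <- d_f; theta[f] <- th; omega[f] <- om
    # anchor chains: vertical 20-carbon stacks, deepest carbon at plane - d_f
    z_deep <- plane - d_f
    for (j in seq_along(gg_per_chain)) {
      off <- if (length(gg_per_chain) == 2) c(-0.075, 0.075)[j] else 0
      coords[f, gg_per_chain[[j]], 1] <- A_lat[1] + off
      coords[f, gg_per_chain[[j]], 2] <- A_lat[2]
      coords[f, gg_per_chain[[j]], 3] <- z_deep + (0:19) * 0.12
    }
    A <- c(A_lat, z_deep + mean((0:19) * 0.12))
    phi <- stats::runif(1, 0, 2 * pi)
    thr <- th * pi / 180
    axis <- c(sin(thr) * cos(phi), sin(thr) * sin(phi), cos(thr))
    G <- A + spec$ag_len * axis
    # reference direction: membrane probe M = A - z_hat, projected off-axis
    v0 <- c(0, 0, -1) - sum(c(0, 0, -1) * axis) * axis
    if (sqrt(sum(v0^2)) < 1e-9) v0 <- c(1, 0, 0) - axis[1] * axis
    v0 <- v0 / sqrt(sum(v0^2))
    place_S <- function(ang) G + spec$s_len *
      rotate_about(v0, axis, ang * pi / 180)
    # the dihedral sign convention is fixed by measurement: pick the
    # rotation sense that reproduces om
    S <- place_S(om)
    meas <- dihedral_angle(A - c(0, 0, 1), A, G, S)
    if (abs(((meas - om + 180) %% 360) - 180) > 1e-6) S <- place_S(-om)
    vS <- (S - G) / spec$s_len
    w <- pracma_cross(axis, vS)
    Rmat <- cbind(vS, w, axis) # local x,y,z -> world
    ca <- template %*% t(Rmat)
    ca <- sweep(ca, 2, G, "+")
    coords[f, ca_rows, ] <- ca
  }
  traj <- trajectory(top, coords, bilayer$box, time = bilayer$time)
  attr(traj, "ground_truth") <- list(
    depths = depths, theta = theta, omega = omega,
    gg_carbons = gg_rows, phosphorus = phos, ca_atoms = ca_rows,
    bilayer_truth = attr(bilayer, "ground_truth"))
  traj
}
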