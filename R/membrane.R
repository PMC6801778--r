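#' Bilayer phosphate-plane thickness
#'
#' Thickness = (mean z of upper-leaflet reference atoms) - (mean z of
#' lower-leaflet reference atoms), with leaflets from the median-z split.
#'
#' @param frame a `Frame`.
#' @param phosphorus AtomSet of phosphate P atoms (or other per-lipid
#'   reference atoms), one per phospholipid.
#' @return thickness in nm (positive).
#' @export
bilayer_thickness <- function(frame, phosphorus) {
  lab <- assign_leaflets(frame, phosphorus)
  z <- frame_coords(frame, phosphorus)[, 3]
  nu <- sum(lab == "upper"); nl <- sum(lab == "lower")
  if (nu < 2L || nl < 2L)
    stop("one-sided leaflet: need at least 2 reference atoms per leaflet (",
         nu, " upper / ", nl, " lower)")
  mean(z[lab == "upper"]) - mean(z[lab == "lower"])
}

#' Area per lipid
#'
#' Lateral box area divided by the number of lipid molecules per leaflet
#' (cholesterol counted like any other lipid).
#'
#' @param frame a `Frame`.
#' @param lipids_per_leaflet lipid count per leaflet (> 0).
#' @return area per lipid in nm^2.
#' @export
area_per_lipid <- function(frame, lipids_per_leaflet) {
  if (length(lipids_per_leaflet) != 1L || lipids_per_leaflet <= 0)
    stop("lipids_per_leaflet must be a positive count")
  frame$box[1] * frame$box[2] / lipids_per_leaflet
}

#' Order parameter of a set of C-H (or arbitrary) bond vectors
#'
#' S = < P2(cos theta) > with theta the angle between each vector and the
#' +z bilayer normal.
#'
#' @param vectors `n x 3` matrix of bond vectors (any length; normalized
#'   internally).
#' @return scalar S in `[-0.5, 1]`.
#' @export
order_from_vectors <- function(vectors) {
  vectors <- as.matrix(vectors)
  len <- sqrt(rowSums(vectors^2))
  if (any(len == 0)) stop("zero-length bond vector")
  mean(legendre_p2(vectors[, 3] / len))
}

#' Ideal-geometry reconstruction of the two C-H directions of a methylene
#'
#' Given the two carbon neighbours of a chain carbon, the C-H unit vectors
#' are placed symmetrically about the C-C-C plane:
#' `h+- = cos(z) b1 +- sin(z) b2` with `b1` the (negated, normalized) bisector
#' of the two C-C bonds, `b2` the C-C-C plane normal, and `z` half the H-C-H
#' angle. This is the carbon-skeleton route to S_CD for trajectories without
#' explicit hydrogens; with ideal tetrahedral placement it is exact.
#'
#' @param c_prev,c_this,c_next `n x 3` coordinates of carbons i-1, i, i+1.
#' @param hch H-C-H angle in degrees (default ideal tetrahedral 109.471).
#' @return list of two `n x 3` unit-vector matrices `h1`, `h2`.
#' @export
reconstruct_ch_vectors <- function(c_prev, c_this, c_next, hch = 109.4712) {
  u1 <- c_prev - c_this; u2 <- c_next - c_this
  nrm <- function(m) m / sqrt(rowSums(m^2))
  u1 <- nrm(u1); u2 <- nrm(u2)
  bis <- -(u1 + u2)
  nb <- sqrt(rowSums(bis^2))
  crs <- cbind(u1[, 2] * u2[, 3] - u1[, 3] * u2[, 2],
               u1[, 3] * u2[, 1] - u1[, 1] * u2[, 3],
               u1[, 1] * u2[, 2] - u1[, 2] * u2[, 1])
  nc <- sqrt(rowSums(crs^2))
  if (any(nb < 1e-10) || any(nc < 1e-10))
    stop("degenerate (collinear) carbon skeleton; cannot reconstruct C-H")
  b1 <- bis / nb; b2 <- crs / nc
  zeta <- hch / 2 * pi / 180
  list(h1 = cos(zeta) * b1 + sin(zeta) * b2,
       h2 = cos(zeta) * b1 - sin(zeta) * b2)
}

# resolve (lipid residue x carbon) atom indices for sn-1 chain carbons
# returns a list with per-carbon index vectors for C, H's and neighbours
chain_atom_index <- function(topology, lipid_sel, carbons) {
  atoms <- topology$atoms
  lip_idx <- if (is.character(lipid_sel)) select_atoms(topology, lipid_sel)
             else as.integer(lipid_sel)
  if (length(lip_idx) == 0L) stop("lipid selection matched no atoms")
  mols <- sort(unique(atoms$molid[lip_idx]))
  key <- paste(atoms$molid, atoms$name)
  find <- function(nm) {
    i <- match(paste(mols, nm), key)
    i
  }
  out <- list(mols = mols, carbons = carbons)
  for (ci in carbons) {
    out[[paste0("C", ci)]] <- list(
      c = find(paste0("C", ci)),
      cp = find(paste0("C", ci - 1)), cn = find(paste0("C", ci + 1)),
      h1 = find(paste0("H", ci, "R")), h2 = find(paste0("H", ci, "S")))
  }
  out
}

#' Acyl-chain order parameters S_CD
#'
#' Per-carbon deuterium order parameters of the saturated sn-1 palmitoyl
#' chain: `S_CD(Ci) = < P2(cos theta_CH) >` over both C-H vectors, all
#' selected lipids and all frames, with theta_CH the angle to the +z bilayer
#' normal. The chain average is `mean(|S_CD|)` over the carbon range, so the
#' planar limit is reported as a positive 0.5. Atom naming convention:
#' carbons `C2..C15` with hydrogens `H2R/H2S` etc.; carbons `C1`/`C16` serve
#' as skeleton neighbours for the reconstruction route.
#'
#' @param traj a `Trajectory` with explicit hydrogens (or use
#'   `method = "reconstruct"` for H-less systems).
#' @param lipid_sel selection string (or AtomSet) defining the lipids whose
#'   chains are analysed, e.g. `"resname POPC PSM POPE POPS"`.
#' @param carbons integer carbon positions, default `2:15`.
#' @param method `"explicit"` (C-H vectors from hydrogen coordinates) or
#'   `"reconstruct"` (ideal-geometry skeleton reconstruction).
#' @param frames optional frame indices (default all).
#' @param n_blocks number of contiguous time blocks for the uncertainty of
#'   the chain average (default 5).
#' @return an `OrderProfile`: list with `carbons`, `s_cd` (signed, per
#'   carbon), `chain_average` (mean |S_CD|), `uncertainty` (sd of the
#'   chain average over time blocks), `n_lipids`, `method`.
#' @export
acyl_order_parameters <- function(traj, lipid_sel, carbons = 2:15,
                                  method = c("explicit", "reconstruct"),
                                  frames = NULL, n_blocks = 5) {
  method <- match.arg(method)
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  idx <- chain_atom_index(traj$topology, lipid_sel, carbons)
  nb <- min(n_blocks, length(frames))
  blk <- block_ids(length(frames), nb)
  # accumulators: per carbon x block sums of P2 and counts
  s_sum <- matrix(0, length(carbons), nb, dimnames = list(carbons, NULL))
  s_n <- matrix(0L, length(carbons), nb)
  for (fi in seq_along(frames)) {
    co <- traj$coords[frames[fi], , , drop = TRUE]
    b <- blk[fi]
    for (k in seq_along(carbons)) {
      ci <- carbons[k]
      ix <- idx[[paste0("C", ci)]]
      if (anyNA(ix$c))
        stop("carbon C", ci, " missing in some selected lipids")
      if (method == "explicit") {
        if (anyNA(ix$h1) || anyNA(ix$h2))
          stop("missing hydrogens on carbon C", ci,
               " (use method = \"reconstruct\" for H-less systems)")
        v1 <- co[ix$h1, , drop = FALSE] - co[ix$c, , drop = FALSE]
        v2 <- co[ix$h2, , drop = FALSE] - co[ix$c, , drop = FALSE]
      } else {
        if (anyNA(ix$cp) || anyNA(ix$cn))
          stop("missing skeleton neighbours for carbon C", ci)
        h <- reconstruct_ch_vectors(co[ix$cp, , drop = FALSE],
                                    co[ix$c, , drop = FALSE],
                                    co[ix$cn, , drop = FALSE])
        v1 <- h$h1; v2 <- h$h2
      }
      p2 <- c(legendre_p2(v1[, 3] / sqrt(rowSums(v1^2))),
              legendre_p2(v2[, 3] / sqrt(rowSums(v2^2))))
      s_sum[k, b] <- s_sum[k, b] + sum(p2)
      s_n[k, b] <- s_n[k, b] + length(p2)
    }
  }
  s_cd <- rowSums(s_sum) / rowSums(s_n)
  block_avg <- colSums(abs(s_sum / s_n)) / length(carbons)
  structure(list(carbons = carbons, s_cd = unname(s_cd),
                 chain_average = mean(abs(s_cd)),
                 uncertainty = if (nb > 1) stats::sd(block_avg) else NA_real_,
                 block_averages = block_avg,
                 n_lipids = length(idx$mols), method = method),
            class = "OrderProfile")
}

#' @export
print.OrderProfile <- function(x, ...) {
  cat(sprintf("OrderProfile (%s): chain average |S_CD| = %.3f +/- %.3f over C%d..C%d, %d lipids\n",
              x$method, x$chain_average,
              ifelse(is.na(x$uncertainty), 0, x$uncertainty),
              min(x$carbons), max(x$carbons), x$n_lipids))
  invisible(x)
}

# per-lipid, per-frame chain-average order (|mean P2| over all C-H vectors of
# the chain) and lateral chain centroid -- shared by the local order map
lipid_framewise_order <- function(traj, idx, frame, method = "explicit") {
  co <- traj$coords[frame, , , drop = TRUE]
  nmol <- length(idx$mols)
  p2 <- matrix(0, nmol, length(idx$carbons))
  cx <- matrix(0, nmol, 2)
  for (k in seq_along(idx$carbons)) {
    ix <- idx[[paste0("C", idx$carbons[k])]]
    if (method == "explicit") {
      v1 <- co[ix$h1, , drop = FALSE] - co[ix$c, , drop = FALSE]
      v2 <- co[ix$h2, , drop = FALSE] - co[ix$c, , drop = FALSE]
    } else {
      h <- reconstruct_ch_vectors(co[ix$cp, , drop = FALSE],
                                  co[ix$c, , drop = FALSE],
                                  co[ix$cn, , drop = FALSE])
      v1 <- h$h1; v2 <- h$h2
    }
    p2[, k] <- (legendre_p2(v1[, 3] / sqrt(rowSums(v1^2))) +
                legendre_p2(v2[, 3] / sqrt(rowSums(v2^2)))) / 2
    cx <- cx + co[ix$c, 1:2, drop = FALSE]
  }
  list(order = abs(rowMeans(p2)), centroid = cx / length(idx$carbons))
}

#' Local order-deviation map around a membrane anchor
#'
#' Lays a lateral grid over the box; each lipid contributes its per-frame
#' chain-average order (|mean P2| over its C-H vectors) to the cell holding
#' its chain centroid. Cell values are time-averaged and reported as the
#' deviation from the global average order. Additionally reports the scalar
#' mean deviation of lipids whose chain centroid lies within `cutoff` of the
#' anchor's lateral centroid (minimum-image), time-averaged.
#'
#' @param traj a `Trajectory`.
#' @param lipid_sel lipid selection (string or AtomSet) as in
#'   [acyl_order_parameters()].
#' @param anchor AtomSet of anchor carbons (lateral anchor position = their
#'   per-frame centroid); may be `NULL` for a map without the anchor scalar.
#' @param cutoff anchor-proximal radius in nm (default 0.5).
#' @param grid_spacing lateral grid spacing in nm (default 0.2).
#' @param carbons carbon range (default 2:15).
#' @param method as in [acyl_order_parameters()].
#' @return a `LocalOrderMap`: list with cell centre vectors `x`, `y`,
#'   `deviation` matrix (NA where no lipid visited), `counts`,
#'   `global_order`, `anchor_deviation`, `cutoff`, `grid_spacing`.
#' @export
local_order_map <- function(traj, lipid_sel, anchor = NULL, cutoff = 0.5,
                            grid_spacing = 0.2, carbons = 2:15,
                            method = c("explicit", "reconstruct")) {
  method <- match.arg(method)
  idx <- chain_atom_index(traj$topology, lipid_sel, carbons)
  if (!is.null(anchor) && length(anchor) == 0L) stop("anchor AtomSet is empty")
  L <- traj$box[1, 1:2]
  nx <- max(1L, ceiling(L[1] / grid_spacing))
  ny <- max(1L, ceiling(L[2] / grid_spacing))
  cell_sum <- matrix(0, nx, ny); cell_n <- matrix(0L, nx, ny)
  anch_sum <- 0; anch_n <- 0L
  tot_sum <- 0; tot_n <- 0L
  for (f in seq_len(n_frames(traj))) {
    lf <- lipid_framewise_order(traj, idx, f, method)
    gx <- wrap_position(lf$centroid[, 1], L[1])
    gy <- wrap_position(lf$centroid[, 2], L[2])
    i <- pmin(nx, 1L + floor(gx / L[1] * nx))
    j <- pmin(ny, 1L + floor(gy / L[2] * ny))
    for (m in seq_along(i)) {
      cell_sum[i[m], j[m]] <- cell_sum[i[m], j[m]] + lf$order[m]
      cell_n[i[m], j[m]] <- cell_n[i[m], j[m]] + 1L
    }
    tot_sum <- tot_sum + sum(lf$order); tot_n <- tot_n + length(lf$order)
    if (!is.null(anchor)) {
      am <- traj$coords[f, anchor, , drop = FALSE]
      ac <- c(mean(am[1, , 1]), mean(am[1, , 2]))
      dx <- wrap_displacement(lf$centroid[, 1] - ac[1], L[1])
      dy <- wrap_displacement(lf$centroid[, 2] - ac[2], L[2])
      near <- sqrt(dx^2 + dy^2) <= cutoff
      anch_sum <- anch_sum + sum(lf$order[near]); anch_n <- anch_n + sum(near)
    }
  }
  global <- tot_sum / tot_n
  dev <- cell_sum / cell_n - global
  dev[cell_n == 0L] <- NA_real_ # no-data cells flagged, excluded from averages
  structure(list(x = (seq_len(nx) - 0.5) * L[1] / nx,
                 y = (seq_len(ny) - 0.5) * L[2] / ny,
                 deviation = dev, counts = cell_n, global_order = global,
                 anchor_deviation = if (anch_n > 0) anch_sum / anch_n - global
                                    else NA_real_,
                 cutoff = cutoff, grid_spacing = grid_spacing),
            class = "LocalOrderMap")
}

#' Headgroup P-N vector tilt angle
#'
#' Angle in degrees between the +z bilayer normal and the P -> N vector of a
#' lipid headgroup. Vectorized over atom pairs.
#'
#' @param frame a `Frame`.
#' @param p_atom,n_atom atom indices of the phosphorus and nitrogen atoms
#'   (same length).
#' @return angle(s) in `[0, 180]` degrees.
#' @export
headgroup_pn_angle <- function(frame, p_atom, n_atom) {
  v <- frame_coords(frame, n_atom) - frame_coords(frame, p_atom)
  len <- sqrt(rowSums(v^2))
  if (any(len < 1e-12)) stop("coincident P and N atoms")
  acos(pmin(1, pmax(-1, v[, 3] / len))) * 180 / pi
}

#' Global membrane summary: thickness, area per lipid, chain order
#'
#' Per-frame thickness and area per lipid (mean +/- sd over frames) plus the
#' chain-averaged order parameter with its block-averaging uncertainty.
#'
#' @param traj a `Trajectory`.
#' @param phosphorus AtomSet of per-phospholipid reference atoms.
#' @param lipids_per_leaflet lipid count per leaflet.
#' @param lipid_sel chain selection for [acyl_order_parameters()]; `NULL`
#'   skips the order computation.
#' @param carbons,method,n_blocks passed to [acyl_order_parameters()].
#' @return a `MembraneSummary`: list of `thickness`, `thickness_sd`,
#'   `area_per_lipid`, `area_per_lipid_sd`, `order`, `order_sd`, plus
#'   per-frame vectors.
#' @export
membrane_summary <- function(traj, phosphorus, lipids_per_leaflet,
                             lipid_sel = NULL, carbons = 2:15,
                             method = "explicit", n_blocks = 5) {
  nf <- n_frames(traj)
  th <- apl <- numeric(nf)
  for (f in seq_len(nf)) {
    fr <- get_frame(traj, f)
    th[f] <- bilayer_thickness(fr, phosphorus)
    apl[f] <- area_per_lipid(fr, lipids_per_leaflet)
  }
  ord <- if (!is.null(lipid_sel))
    acyl_order_parameters(traj, lipid_sel, carbons = carbons,
                          method = method, n_blocks = n_blocks) else NULL
  structure(list(thickness = mean(th),
                 thickness_sd = if (nf > 1) stats::sd(th) else NA_real_,
                 area_per_lipid = mean(apl),
                 area_per_lipid_sd = if (nf > 1) stats::sd(apl) else NA_real_,
                 order = if (!is.null(ord)) ord$chain_average else NA_real_,
                 order_sd = if (!is.null(ord)) ord$uncertainty else NA_real_,
                 per_frame = data.frame(time = traj$time, thickness = th,
                                        area_per_lipid = apl),
                 order_profile = ord),
            class = "MembraneSummary")
}

#' @export
print.MembraneSummary <- function(x, ...) {
  cat(sprintf("MembraneSummary: thickness %.3f +/- %.3f nm; APL %.3f +/- %.3f nm^2; order %.3f +/- %.3f\n",
              x$thickness, ifelse(is.na(x$thickness_sd), 0, x$thickness_sd),
              x$area_per_lipid,
              ifelse(is.na(x$area_per_lipid_sd), 0, x$area_per_lipid_sd),
              x$order, ifelse(is.na(x$order_sd), 0, x$order_sd)))
  invisible(x)
}
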