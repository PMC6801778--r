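# small constructed system: P atoms on two planes plus a 2-carbon anchor
depth_system <- function(p_upper_z = 2.0, p_lower_z = -2.0, gg_z = c(1.0, 1.2),
                         box = 3) {
  n_side <- 9
  g <- expand.grid(x = (1:3 - 0.5) * box / 3, y = (1:3 - 0.5) * box / 3)
  nme <- c(rep("P", 2 * n_side), rep("C1G", length(gg_z)))
  res <- c(seq_len(2 * n_side), rep(2 * n_side + 1, length(gg_z)))
  rn <- c(rep("POPC", 2 * n_side), rep("GGC", length(gg_z)))
  top <- topology(nme, rn, res, segid = c(rep("MEMB", 2 * n_side),
                                          rep("PROT", length(gg_z))))
  co <- array(0, c(1, 2 * n_side + length(gg_z), 3))
  co[1, 1:n_side, ] <- cbind(g$x, g$y, p_upper_z)
  co[1, n_side + 1:n_side, ] <- cbind(g$x, g$y, p_lower_z)
  co[1, 2 * n_side + seq_along(gg_z), ] <-
    cbind(box / 2, box / 2, gg_z)
  list(frame = get_frame(trajectory(top, co, c(box, box, 10)), 1),
       phos = 1:(2 * n_side),
       gg = 2 * n_side + seq_along(gg_z))
}

test_that("anchor insertion depth follows the plane-to-deepest-carbon rule", {
  s <- depth_system(p_upper_z = 2.0, gg_z = c(1.0, 1.4))
  expect_equal(anchor_insertion_depth(s$frame, s$gg, s$phos), 1.0)
  # anchor above the plane: negative depth, reported unclamped
  s2 <- depth_system(p_upper_z = 2.0, gg_z = c(2.5, 2.6))
  expect_equal(anchor_insertion_depth(s2$frame, s2$gg, s2$phos), -0.5)
  # falls back to the whole leaflet when no neighbours are near
  s3 <- depth_system(gg_z = c(1.0, 1.2), box = 30)
  expect_warning(d <- anchor_insertion_depth(s3$frame, s3$gg, s3$phos),
                 "whole-leaflet")
  expect_equal(d, 1.0)
})

test_that("planted Gaussian depths are recovered to the stated precision", {
  ap <- anchored_fixture()
  gt <- attr(ap, "ground_truth")
  d <- insertion_depth_series(ap, gt$gg_carbons, gt$phosphorus)
  # the measurement reproduces the planted per-frame depths exactly
  expect_equal(d, gt$depths, tolerance = 1e-9)
  expect_equal(mean(d), 1.74, tolerance = 0.03 / 1.74)
})

test_that("depth distributions detect planted uni- and bimodality", {
  set.seed(51)
  uni <- rnorm(500, 1.71, 0.1)
  du <- depth_distribution(uni)
  expect_equal(du$modality, 1)
  expect_equal(du$mean, 1.71, tolerance = 0.01 / 1.71)
  expect_equal(du$mean, mean(uni)) # summary mean is the series mean, exactly
  expect_equal(sum(du$histogram$counts), 500)
  bi <- c(rnorm(300, 0.9, 0.1), rnorm(300, 1.6, 0.1))
  db <- depth_distribution(bi)
  expect_equal(db$modality, 2)
  expect_equal(sort(db$component_means), c(0.9, 1.6), tolerance = 0.05)
  expect_error(depth_distribution(rnorm(50)), "100")
})

test_that("residue-membrane distances are plane-referenced and covariant", {
  ap <- anchored_fixture()
  gt <- attr(ap, "ground_truth")
  prot <- select_atoms(ap$topology, "segid PROT and name CA")
  m <- residue_membrane_distances(ap, prot, gt$phosphorus)
  expect_equal(dim(m), c(215, n_frames(ap)))
  # rigid +1 nm z-translation of the protein raises every distance by 1
  ap2 <- ap
  ap2$coords[, prot, 3] <- ap$coords[, prot, 3] + 1
  m2 <- residue_membrane_distances(ap2, prot, gt$phosphorus)
  expect_equal(m2, m + 1, tolerance = 1e-9, ignore_attr = TRUE)
  # with the switch regions posed away from the membrane (omega ~ 190 puts
  # them low; use theta/omega that point them up for the distal check)
  bl <- make_bilayer(bilayer_spec(n_lipids_per_leaflet = 16, n_frames = 30,
                                  seed = 52))
  up <- make_anchored_protein(anchor_spec(depth_means = 1.0, theta = 60,
                                          omega = 180, seed = 53), bl)
  gu <- attr(up, "ground_truth")
  pu <- select_atoms(up$topology, "segid PROT and name CA")
  mu <- residue_membrane_distances(up, pu, gu$phosphorus)
  avg <- rowMeans(mu)
  gdom <- as.character(15:185)
  # switch I (residues 50-60) is the planted distal patch of the G domain
  sw1 <- as.character(50:60)
  expect_gt(min(avg[sw1]), max(avg[setdiff(gdom, c(sw1, as.character(75:92)))]))
})

test_that("radius of gyration matches point-mass and uniform-ball limits", {
  top <- topology(c("CA", "CA"), "ALA", 1:2, "PROT")
  co <- array(0, c(1, 2, 3)); co[1, 2, 1] <- 2
  fr <- get_frame(trajectory(top, co, c(5, 5, 5)), 1)
  expect_equal(radius_of_gyration(fr, 1:2, masses = c(1, 1)), 1.0)
  # uniform ball of radius R: r_gyr -> R * sqrt(3/5)
  set.seed(54)
  R <- 1.8; n <- 1000
  pts <- matrix(rnorm(3 * 4 * n), ncol = 3)
  pts <- pts[rowSums(pts^2) > 0, ][1:n, ]
  pts <- pts / sqrt(rowSums(pts^2)) * R * runif(n)^(1 / 3)
  frb <- make_frame(pts, box = c(10, 10, 10))
  rg <- radius_of_gyration(frb, 1:n, masses = rep(1, n))
  expect_equal(rg, R * sqrt(3 / 5), tolerance = 0.03)
  # isometry invariance
  Rm <- rot_axis(c(1, 2, 3), 0.8)
  fr2 <- make_frame(pts %*% Rm + matrix(c(1, -2, 3), n, 3, byrow = TRUE),
                    box = c(10, 10, 10))
  expect_equal(radius_of_gyration(fr2, 1:n, masses = rep(1, n)), rg)
  expect_error(radius_of_gyration(fr, 1, masses = 1), "2 atoms")
})

test_that("superposition matches the quaternion oracle and recovers rotations", {
  set.seed(55)
  X <- matrix(rnorm(60), 20, 3)
  # identical sets: identity rotation, zero rmsd
  s0 <- superpose(X, X)
  expect_equal(s0$rotation, diag(3), tolerance = 1e-10)
  expect_lt(s0$rmsd, 1e-12)
  # pure rotation: recovered within 1e-10
  Rm <- rot_axis(c(0.2, -1, 0.5), 1.2)
  Y <- X %*% Rm
  s1 <- superpose(X, Y)
  expect_lt(s1$rmsd, 1e-12)
  expect_equal(s1$rotation, Rm, tolerance = 1e-10)
  # noisy rotated set: rmsd equals the independent quaternion-method rmsd
  Yn <- Y + matrix(rnorm(60, sd = 0.1), 20, 3)
  s2 <- superpose(X, Yn)
  expect_equal(s2$rmsd, quaternion_rmsd(X, Yn), tolerance = 1e-8)
  # collinear sets are rejected
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(superpose(line, line + 1), "degenerate")
  # reflection guard: mirrored sets still yield a proper rotation
  s3 <- superpose(X, cbind(-Yn[, 1], Yn[, 2], Yn[, 3]))
  expect_equal(det(s3$rotation), 1, tolerance = 1e-9)
})

test_that("RMSF vanishes for rigid-body motion and scales as sigma*sqrt(3)", {
  set.seed(56)
  na <- 80
  base <- matrix(rnorm(3 * na, sd = 0.8), na, 3)
  top <- topology(rep("CA", na), "ALA", 1:na, "PROT")
  nf <- 40
  co <- array(NA_real_, c(nf, na, 3))
  for (f in 1:nf) {
    Rm <- rot_axis(c(f, 1, 2), 0.1 * f)
    co[f, , ] <- base %*% Rm + matrix(c(f, -f, 0.5 * f), na, 3, byrow = TRUE)
  }
  tr <- trajectory(top, co, c(50, 50, 50))
  expect_lt(max(rmsf(tr, 1:na)), 1e-10) # fit removes all rigid motion
  # static structure + isotropic jitter: RMSF -> sigma * sqrt(3)
  sig <- 0.05; nf2 <- 300
  co2 <- array(rep(base, each = nf2), c(nf2, na, 3)) +
    array(rnorm(nf2 * 3 * na, sd = sig), c(nf2, na, 3))
  tr2 <- trajectory(top, co2, c(50, 50, 50))
  r2 <- rmsf(tr2, 1:na)
  expect_equal(mean(r2), sig * sqrt(3), tolerance = 0.05)
  # reference-frame independence within 2% on jittered fixtures
  r2b <- rmsf(tr2, 1:na, ref_frame = nf2 %/% 2)
  expect_lt(max(abs(r2 - r2b) / r2), 0.02)
})

test_that("orientation angles reproduce constructed theta and omega", {
  ap <- anchored_fixture()
  gt <- attr(ap, "ground_truth")
  gdom <- select_atoms(ap$topology, "name CA and resid 15:185")
  sw <- select_atoms(ap$topology, "name CA and resid 50:60 75:92")
  ori <- orientation_series(ap, gdom, sw, gt$gg_carbons)
  expect_equal(ori$theta, gt$theta, tolerance = 1e-9)
  expect_equal(ori$omega, gt$omega, tolerance = 1e-9)
  expect_true(all(ori$theta >= 0 & ori$theta <= 180))
  expect_true(all(ori$omega >= 0 & ori$omega < 360))
  # planted (theta, omega) = (90, 190): the screened 'endo' state
  expect_true(all(ori$label == "endo"))
})

test_that("dihedral convention: planted 80 deg and its mirror at 280 deg", {
  # constructed four-point geometry with a known torsion
  p1 <- c(0, 0, -1); p2 <- c(0, 0, 0); p3 <- c(0, 1, 0)
  ang <- 80 * pi / 180
  p4 <- c(sin(ang), 1, -cos(ang)) # torsion 80 deg about the p2-p3 axis
  w <- dihedral_angle(p1, p2, p3, p4)
  expect_true(abs(w - 80) < 1e-9 || abs(w - 280) < 1e-9)
  # reflecting the fourth point through the p2-p3 axis plane maps
  # omega -> 360 - omega
  p4m <- c(-p4[1], p4[2], p4[3])
  wm <- dihedral_angle(p1, p2, p3, p4m)
  expect_equal((w + wm) %% 360, 0, tolerance = 1e-9)
  # generator plants omega through the same measured convention
  bl <- make_bilayer(bilayer_spec(n_lipids_per_leaflet = 9, n_frames = 5,
                                  seed = 57))
  ap80 <- make_anchored_protein(anchor_spec(depth_means = 1.0, theta = 120,
                                            omega = 80, seed = 58), bl)
  g80 <- attr(ap80, "ground_truth")
  gdom <- select_atoms(ap80$topology, "name CA and resid 15:185")
  sw <- select_atoms(ap80$topology, "name CA and resid 50:60 75:92")
  o80 <- orientation_series(ap80, gdom, sw, g80$gg_carbons)
  expect_equal(o80$omega, rep(80, 5), tolerance = 1e-6)
  expect_true(all(o80$label == "exo"))
})

test_that("angles and depths are invariant under xy-translation and
           z-rotation of the whole system", {
  bl <- make_bilayer(bilayer_spec(n_lipids_per_leaflet = 9, n_frames = 3,
                                  seed = 59))
  ap <- make_anchored_protein(anchor_spec(depth_means = 1.2, theta = 70,
                                          omega = 150, seed = 60), bl)
  gt <- attr(ap, "ground_truth")
  gdom <- select_atoms(ap$topology, "name CA and resid 15:185")
  sw <- select_atoms(ap$topology, "name CA and resid 50:60 75:92")
  d0 <- insertion_depth_series(ap, gt$gg_carbons, gt$phosphorus)
  o0 <- orientation_series(ap, gdom, sw, gt$gg_carbons)
  # rotate everything about the box-centre z-axis, then translate in xy
  ap2 <- ap
  ctr <- c(ap$box[1, 1:2] / 2, 0)
  Rz <- rot_z(0.9)
  for (f in 1:n_frames(ap)) {
    ap2$coords[f, , ] <-
      sweep(sweep(ap$coords[f, , ], 2, ctr) %*% Rz, 2, ctr + c(0.4, -0.7, 0),
            "+")
  }
  d2 <- insertion_depth_series(ap2, gt$gg_carbons, gt$phosphorus)
  o2 <- orientation_series(ap2, gdom, sw, gt$gg_carbons)
  expect_equal(d2, d0, tolerance = 1e-9)
  expect_equal(o2$theta, o0$theta, tolerance = 1e-9)
  expect_equal(o2$omega, o0$omega, tolerance = 1e-6)
})
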