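test_that("bilayer thickness equals the planted phosphate-plane separation", {
  # exact planes, no jitter
  b <- make_bilayer(bilayer_spec(n_lipids_per_leaflet = 16, thickness = 3.87,
                                 jitter_sd = 0, n_frames = 1, seed = 1))
  phos <- select_atoms(b, "name P")
  expect_equal(bilayer_thickness(get_frame(b, 1), phos), 3.87,
               tolerance = 1e-12)
  # planes at +/- 1.0
  b2 <- make_bilayer(bilayer_spec(n_lipids_per_leaflet = 16, thickness = 2.0,
                                  jitter_sd = 0, n_frames = 1, seed = 1))
  expect_equal(bilayer_thickness(get_frame(b2, 1),
                                 select_atoms(b2, "name P")), 2.0,
               tolerance = 1e-12)
  # jittered planes: mean of the planted normal draws
  b3 <- make_bilayer(bilayer_spec(n_lipids_per_leaflet = 512,
                                  thickness = 3.88, jitter_sd = 0.05,
                                  n_frames = 1, seed = 2))
  th <- bilayer_thickness(get_frame(b3, 1), select_atoms(b3, "name P"))
  expect_equal(th, 3.88, tolerance = 0.01 / 3.88)
})

test_that("thickness is invariant under rigid xy-translation", {
  b <- make_bilayer(bilayer_spec(n_lipids_per_leaflet = 16, n_frames = 1,
                                 seed = 3))
  phos <- select_atoms(b, "name P")
  fr <- get_frame(b, 1)
  fr2 <- fr; fr2$coords[, 1] <- fr$coords[, 1] + 1.7
  fr2$coords[, 2] <- fr$coords[, 2] - 0.9
  expect_equal(bilayer_thickness(fr2, phos), bilayer_thickness(fr, phos))
})

test_that("area per lipid is the lateral box area over the leaflet count", {
  fr <- make_frame(matrix(0, 2, 3), box = c(10, 10, 8))
  expect_equal(area_per_lipid(fr, 100), 1.0)
  # planted value: box sized to 128 * 0.662 nm^2
  b <- make_bilayer(bilayer_spec(n_lipids_per_leaflet = 128,
                                 area_per_lipid = 0.662, n_frames = 1,
                                 seed = 4))
  expect_equal(area_per_lipid(get_frame(b, 1), 128), 0.662,
               tolerance = 1e-12)
  # exact identity APL * N = lateral area, frame by frame
  for (f in 1:1) {
    fr <- get_frame(b, f)
    expect_identical(area_per_lipid(fr, 128) * 128, fr$box[1] * fr$box[2])
  }
  expect_error(area_per_lipid(fr, 0), "positive")
})

test_that("S_CD hits the planar and isotropic limits", {
  # all vectors in the x,y-plane -> S = -0.5 exactly
  phi <- seq(0, 2 * pi, length.out = 100)
  v <- cbind(cos(phi), sin(phi), 0)
  expect_equal(order_from_vectors(v), -0.5)
  # isotropic vectors -> S = 0 within Monte-Carlo error
  set.seed(5)
  n <- 1e5
  z <- runif(n, -1, 1); ph <- runif(n, 0, 2 * pi)
  iso <- cbind(sqrt(1 - z^2) * cos(ph), sqrt(1 - z^2) * sin(ph), z)
  expect_lt(abs(order_from_vectors(iso)), 0.005)
})

test_that("S_CD bounds hold for arbitrary vector sets", {
  set.seed(6)
  for (i in 1:25) {
    v <- matrix(rnorm(3 * 50), 50, 3)
    s <- order_from_vectors(v)
    expect_gte(s, -0.5); expect_lte(s, 1.0)
  }
})

test_that("cone-band calibration reproduces planted chain-average order", {
  alpha <- cone_halfangle_for_order(0.327)
  v <- sample_cone_vectors(1e5, alpha, seed = 11)
  expect_equal(abs(order_from_vectors(v)), 0.327, tolerance = 0.003 / 0.327)
})

test_that("explicit-H and skeleton-reconstruction order parameters agree", {
  b <- fixture("order_bilayer",
    make_bilayer(bilayer_spec(n_lipids_per_leaflet = 32,
                              target_order = 0.327, n_frames = 20,
                              seed = 12)))
  oe <- acyl_order_parameters(b, "resname POPC", method = "explicit")
  or <- acyl_order_parameters(b, "resname POPC", method = "reconstruct")
  expect_lt(abs(oe$chain_average - or$chain_average), 0.01)
  expect_equal(length(oe$s_cd), 14)
  expect_true(all(oe$s_cd >= -0.5 & oe$s_cd <= 1))
  expect_true(oe$chain_average >= 0 && oe$chain_average <= 1)
  expect_false(is.na(oe$uncertainty))
})

test_that("planted order parameters are recovered from bilayer fixtures", {
  b <- fixture("order_bilayer",
    make_bilayer(bilayer_spec(n_lipids_per_leaflet = 32,
                              target_order = 0.327, n_frames = 20,
                              seed = 12)))
  op <- acyl_order_parameters(b, "resname POPC")
  expect_equal(op$chain_average, 0.327, tolerance = 0.02 / 0.327)
  # ternary-like planting exceeds pure-POPC-like planting (cholesterol
  # ordering emulated through the planted targets 0.327 vs 0.176)
  b_popc <- make_bilayer(bilayer_spec(n_lipids_per_leaflet = 32,
                                      target_order = 0.176, n_frames = 20,
                                      seed = 13))
  op_popc <- acyl_order_parameters(b_popc, "resname POPC")
  expect_equal(op_popc$chain_average, 0.176, tolerance = 0.02 / 0.176)
  expect_gt(op$chain_average, op_popc$chain_average)
})

test_that("missing hydrogens are reported by carbon unless reconstructing", {
  b <- make_bilayer(bilayer_spec(n_lipids_per_leaflet = 4, n_frames = 1,
                                 seed = 14))
  keep <- select_atoms(b$topology, "not name H7R")
  a <- b$topology$atoms[keep, ]
  top2 <- topology(a$name, a$resname, a$resid, a$segid)
  tr2 <- trajectory(top2, b$coords[, keep, , drop = FALSE], b$box[1, ])
  expect_error(acyl_order_parameters(tr2, "resname POPC"), "C7")
  expect_silent(acyl_order_parameters(tr2, "resname POPC",
                                      method = "reconstruct"))
})

test_that("local order map recovers a planted disordered disk", {
  sp <- bilayer_spec(n_lipids_per_leaflet = 64, target_order = 0.327,
                     area_per_lipid = 0.662, n_frames = 150, seed = 8,
                     local_deficit = list(x = 0.407, y = 0.407,
                                          radius = 0.5, delta = 0.06))
  b <- make_bilayer(sp)
  phos <- select_atoms(b, "name P")
  pc <- frame_coords(get_frame(b, 1), phos)
  anch <- phos[which.min((pc[, 1] - 0.407)^2 + (pc[, 2] - 0.407)^2)]
  m <- local_order_map(b, "resname POPC", anchor = anch, cutoff = 0.5)
  # global mean includes the deficit lipids, so the expected deviation is
  # -delta * (1 - n_deficit / n_total); 2 of 128 lipids sit in the disk
  expected <- -0.06 * (1 - 2 / 128)
  expect_equal(m$anchor_deviation, expected, tolerance = 0.01 / abs(expected))
  # area-weighted mean deviation over the whole membrane is zero
  expect_lt(abs(sum(m$deviation * m$counts, na.rm = TRUE) / sum(m$counts)),
            1e-12)
  # relative deficit of ~18% of the global order, the Fig 3-style readout
  expect_lt(m$anchor_deviation / m$global_order, -0.1)
})

test_that("local order map of a homogeneous bilayer shows no anchor signal", {
  b <- fixture("order_bilayer150",
    make_bilayer(bilayer_spec(n_lipids_per_leaflet = 36,
                              target_order = 0.305, n_frames = 150,
                              seed = 9)))
  phos <- select_atoms(b, "name P")
  m <- local_order_map(b, "resname POPC", anchor = phos[1], cutoff = 1.0)
  expect_lt(abs(m$anchor_deviation), 0.01)
  # global selection reproduces the global order within block error
  op <- acyl_order_parameters(b, "resname POPC")
  expect_lt(abs(m$global_order - op$chain_average),
            3 * op$uncertainty + 0.005)
})

test_that("headgroup P-N angle matches constructed geometries", {
  top <- topology(name = c("P", "N"), resname = "POPC", resid = 1)
  geom <- function(p, n) {
    co <- array(0, c(1, 2, 3)); co[1, 1, ] <- p; co[1, 2, ] <- n
    get_frame(trajectory(top, co, c(5, 5, 5)), 1)
  }
  expect_equal(headgroup_pn_angle(geom(c(0, 0, 0), c(0, 0, 1)), 1, 2), 0)
  expect_equal(headgroup_pn_angle(geom(c(0, 0, 0), c(1, 0, 0)), 1, 2), 90)
  expect_equal(headgroup_pn_angle(geom(c(0, 0, 0), c(1, 0, 1)), 1, 2), 45)
  expect_error(headgroup_pn_angle(geom(c(0, 0, 0), c(0, 0, 0)), 1, 2),
               "coincident")
  # invariant under rotation about z
  fr <- geom(c(0.3, 0.2, 0), c(1.1, 0.7, 0.4))
  a0 <- headgroup_pn_angle(fr, 1, 2)
  R <- rot_z(1.1)
  fr2 <- fr; fr2$coords <- fr$coords %*% R
  expect_equal(headgroup_pn_angle(fr2, 1, 2), a0)
})

test_that("membrane summary aggregates per-frame observables", {
  b <- make_bilayer(bilayer_spec(n_lipids_per_leaflet = 16, thickness = 4.6,
                                 area_per_lipid = 0.437,
                                 target_order = 0.327, n_frames = 10,
                                 seed = 15))
  ms <- membrane_summary(b, select_atoms(b, "name P"), 16,
                         lipid_sel = "resname POPC")
  expect_equal(ms$thickness, 4.6, tolerance = 0.01)
  expect_equal(ms$area_per_lipid, 0.437, tolerance = 1e-12)
  expect_equal(ms$order, 0.327, tolerance = 0.1)
  expect_equal(nrow(ms$per_frame), 10)
})
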