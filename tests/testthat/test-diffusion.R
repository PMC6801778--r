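test_that("unwrapping removes boundary crossings and round-trips exactly", {
  # particle crossing the +x boundary: wrapped 9.9 -> 0.1 is a +0.2 step
  top <- topology(name = "C1", resname = "TRK", resid = 1, segid = "TRK")
  co <- array(0, c(2, 1, 3))
  co[1, 1, ] <- c(9.9, 5, 5); co[2, 1, ] <- c(0.1, 5, 5)
  tr <- trajectory(top, co, c(10, 10, 10))
  tk <- unwrap_tracks(tr, 1)
  expect_equal(tk$x[2, 1] - tk$x[1, 1], 0.2)
  # stationary particle: zero displacement
  co2 <- array(rep(c(3, 4, 5), each = 4), c(4, 1, 3))
  tk2 <- unwrap_tracks(trajectory(top, co2, c(10, 10, 10)), 1)
  expect_equal(diff(tk2$x[, 1]), rep(0, 3))
  # generator round trip: unwrap(wrapped) == truth, rewrap == input
  bt <- make_brownian_tracks(track_spec(list(list(D = 1.0, fraction = 1)),
                                        n_particles = 40, n_steps = 300,
                                        seed = 31))
  tk3 <- unwrap_tracks(bt$trajectory, seq_len(40))
  expect_equal(tk3$x, bt$tracks$x, tolerance = 1e-12)
  expect_equal(tk3$y, bt$tracks$y, tolerance = 1e-12)
  rw <- rewrap_tracks(tk3)
  expect_equal(rw$x, matrix(bt$trajectory$coords[, , 1], nrow = 301),
               tolerance = 1e-12)
})

test_that("jump distances pool overlapping origins with the right counts", {
  # deterministic mover: +0.3 nm in x per frame
  x <- matrix(seq(0, by = 0.3, length.out = 11), ncol = 1)
  tk <- track_set(x, 0 * x, dt = 1)
  expect_equal(as.numeric(jump_distances(tk, 1)), rep(0.3, 10))
  expect_equal(as.numeric(jump_distances(tk, 2)), rep(0.6, 9))
  # combinatorial count: n_particles * (n_frames - lag)
  bt <- make_brownian_tracks(track_spec(list(list(D = 0.8, fraction = 1)),
                                        n_particles = 7, n_steps = 50,
                                        seed = 32))
  tk2 <- unwrap_tracks(bt$trajectory, 1:7)
  for (lagf in c(1, 3, 10))
    expect_length(jump_distances(tk2, lagf), 7 * (51 - lagf))
  expect_error(jump_distances(tk2, 51), "duration")
  expect_error(jump_distances(tk2, 0.5), "integer multiple")
})

test_that("single-population ML fit recovers D from exact inverse-CDF draws", {
  set.seed(33)
  # D = 1 in reported units = 0.01 nm^2/ns; lag 1 ns
  r <- sample_jumps_exact(1e4, e7cm2s_to_nm2ns(1), 1)
  fit <- fit_jda(structure(r, lag = 1), n_components = 1)
  expect_equal(fit$components$D, 1.00, tolerance = 0.02)
  # histogram-free CDF cross-check agrees
  expect_equal(fit_jda_cdf(structure(r, lag = 1)), fit$components$D,
               tolerance = 0.02)
  # all-zero jumps -> D = 0
  z <- fit_jda(structure(rep(0, 200), lag = 1))
  expect_equal(z$components$D, 0)
})

test_that("two-component mixtures are recovered within stated tolerances", {
  sp <- track_spec(list(list(D = 0.5, fraction = 0.5, label = "slow"),
                        list(D = 2.0, fraction = 0.5, label = "fast")),
                   n_particles = 200, n_steps = 1000, dt = 1, box = 20,
                   seed = 34)
  bt <- make_brownian_tracks(sp)
  tk <- unwrap_tracks(bt$trajectory, 1:200)
  fit <- fit_jda(jump_distances(tk, 1), n_components = 2)
  D <- sort(fit$components$D)
  f <- fit$components$fraction[order(fit$components$D)]
  expect_lt(abs(D[1] - 0.5) / 0.5, 0.15)
  expect_lt(abs(D[2] - 2.0) / 2.0, 0.15)
  expect_lt(max(abs(f - 0.5)), 0.1)
  expect_equal(sum(fit$components$fraction), 1)
  # model selection prefers 2 components here, 1 for a single population
  expect_equal(nrow(fit_jda(jump_distances(tk, 1),
                            n_components = "auto")$components), 2)
})

test_that("estimates are invariant under particle relabeling", {
  bt <- make_brownian_tracks(track_spec(list(list(D = 1.2, fraction = 1)),
                                        n_particles = 50, n_steps = 400,
                                        seed = 35))
  tk <- unwrap_tracks(bt$trajectory, 1:50)
  perm <- sample(50)
  tkp <- track_set(tk$x[, perm], tk$y[, perm], tk$dt, box = tk$box)
  f1 <- fit_jda(jump_distances(tk, 1))
  f2 <- fit_jda(jump_distances(tkp, 1))
  expect_equal(f1$components$D, f2$components$D, tolerance = 1e-9)
})

test_that("JDA and MSD agree on single-population Brownian data", {
  bt <- fixture("tracks_big",
    make_brownian_tracks(track_spec(list(list(D = 1.36, fraction = 1)),
                                    n_particles = 200, n_steps = 2000,
                                    dt = 1, box = 20, seed = 36)))
  tk <- unwrap_tracks(bt$trajectory, 1:200)
  jda <- fit_jda(jump_distances(tk, 1))$components$D
  msd <- msd_diffusion(tk)$D
  expect_lt(abs(jda - msd) / msd, 0.10)
  # both recover the planted D
  expect_equal(jda, 1.36, tolerance = 0.05)
  expect_equal(msd, 1.36, tolerance = 0.10)
})

test_that("MSD has the exact zero-lag and stationary limits", {
  x <- matrix(rep(c(1, 2, 3, 4), 5), 4, 5) * 0 + 3 # constant positions
  tk <- track_set(x, x, dt = 1)
  m <- msd_diffusion(tk, fit_window = c(1, 3))
  expect_equal(m$D, 0)
  expect_equal(m$msd$msd[m$msd$t == 0], 0)
  bt <- make_brownian_tracks(track_spec(list(list(D = 0, fraction = 1)),
                                        n_particles = 10, n_steps = 50,
                                        seed = 37))
  tk0 <- unwrap_tracks(bt$trajectory, 1:10)
  expect_equal(msd_diffusion(tk0, c(1, 10))$D, 0)
})

test_that("diffusion ratios reproduce the printed two-figure table values", {
  expect_equal(diffusion_ratio(1.49, 0.43), 3.5)
  expect_equal(diffusion_ratio(1.59, 0.93), 1.7)
  expect_equal(diffusion_ratio(0.62, 0.62), 1.0)
  expect_error(diffusion_ratio(1, 0), "> 0")
})

test_that("six-component planted fixture keeps the species ordering", {
  # planted per-species D from the six-component double-GG row:
  # POPC fastest, cholesterol slowest
  sp <- track_spec(list(list(D = 0.74, fraction = 0.5, label = "POPC"),
                        list(D = 0.58, fraction = 0.5, label = "CHOL")),
                   n_particles = 120, n_steps = 800, dt = 1, box = 18,
                   seed = 38)
  bt <- make_brownian_tracks(sp)
  tk <- unwrap_tracks(bt$trajectory, 1:120)
  d_popc <- fit_jda(jump_distances(subset_tracks(tk, "POPC"), 1))$components$D
  d_chol <- fit_jda(jump_distances(subset_tracks(tk, "CHOL"), 1))$components$D
  expect_gt(d_popc, d_chol)
  expect_equal(d_popc, 0.74, tolerance = 0.05)
  expect_equal(d_chol, 0.58, tolerance = 0.05)
})

test_that("segment-wise uncertainties accompany track-derived fits", {
  bt <- make_brownian_tracks(track_spec(list(list(D = 1.0, fraction = 1)),
                                        n_particles = 80, n_steps = 600,
                                        seed = 39))
  tk <- unwrap_tracks(bt$trajectory, 1:80)
  fit <- fit_jda(jump_distances(tk, 1))
  expect_false(is.na(fit$components$D_sd))
  expect_lt(fit$components$D_sd, 0.2)
})
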