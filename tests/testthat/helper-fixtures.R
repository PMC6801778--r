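# shared fixtures and independent oracles for the test suite

# cache: expensive fixtures built once per test run
.fx <- new.env(parent = emptyenv())
fixture <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- force(build)
  .fx[[name]]
}

# rotation matrix about z / arbitrary axis (test-side, independent of the
# package's internals)
rot_z <- function(a) matrix(c(cos(a), sin(a), 0,
                              -sin(a), cos(a), 0,
                              0, 0, 1), 3, 3)
rot_axis <- function(axis, a) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * K %*% K
}

# independent quaternion-method (Horn/Kearsley) superposition RMSD oracle
quaternion_rmsd <- function(mobile, reference) {
  X <- sweep(mobile, 2, colMeans(mobile))
  Y <- sweep(reference, 2, colMeans(reference))
  B <- t(X) %*% Y
  Sxx <- B[1, 1]; Sxy <- B[1, 2]; Sxz <- B[1, 3]
  Syx <- B[2, 1]; Syy <- B[2, 2]; Syz <- B[2, 3]
  Szx <- B[3, 1]; Szy <- B[3, 2]; Szz <- B[3, 3]
  N <- rbind(
    c(Sxx + Syy + Szz, Syz - Szy, Szx - Sxz, Sxy - Syx),
    c(Syz - Szy, Sxx - Syy - Szz, Sxy + Syx, Szx + Sxz),
    c(Szx - Sxz, Sxy + Syx, -Sxx + Syy - Szz, Syz + Szy),
    c(Sxy - Syx, Szx + Sxz, Syz + Szy, -Sxx - Syy + Szz))
  lmax <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(X^2) + sum(Y^2) - 2 * lmax) / nrow(X)
  sqrt(max(0, msd))
}

# inverse-CDF sampler of the single-population 2D jump-distance density:
# CDF(r) = 1 - exp(-r^2 / (4 D t))  =>  r = sqrt(-4 D t log(1 - u))
sample_jumps_exact <- function(n, D_nm2ns, lag) {
  u <- stats::runif(n)
  sqrt(-4 * D_nm2ns * lag * log(u))
}

# small analysis-ready anchored-protein system shared across geometry tests
anchored_fixture <- function() {
  fixture("anchored", {
    bl <- make_bilayer(bilayer_spec(n_lipids_per_leaflet = 16,
                                    thickness = 4.54, area_per_lipid = 0.466,
                                    target_order = 0.305, n_frames = 150,
                                    seed = 41))
    make_anchored_protein(anchor_spec(depth_means = 1.74, depth_sds = 0.15,
                                      theta = 90, omega = 190, seed = 42), bl)
  })
}
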