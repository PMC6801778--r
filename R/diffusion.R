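#' Build a TrackSet of unwrapped lateral positions
#'
#' Removes periodic-boundary jumps from per-atom (x, y) tracks: every
#' consecutive displacement is replaced by its minimum image (using the box
#' of the later frame) before cumulative summation. The first frame keeps the
#' wrapped coordinates. Steps whose minimum-image magnitude exceeds a quarter
#' box length are counted as suspect (possible temporal undersampling) and
#' trigger a warning.
#'
#' @param traj a `Trajectory`.
#' @param atoms AtomSet of tracked particles (one atom per particle).
#' @param labels optional per-particle labels (lipid species, "GG anchor");
#'   defaults to the molecule species of each atom.
#' @return a `TrackSet`: list with matrices `x`, `y` (`n_frames x
#'   n_particles`, nm, unwrapped), `dt` (frame interval, ns), `time`,
#'   `labels`, `box`.
#' @export
unwrap_tracks <- function(traj, atoms, labels = NULL) {
  nf <- n_frames(traj)
  if (is.null(labels)) {
    mol <- traj$topology$atoms$molid[atoms]
    labels <- traj$topology$molecules$species[
      match(mol, traj$topology$molecules$molid)]
  }
  x <- matrix(traj$coords[, atoms, 1], nrow = nf)
  y <- matrix(traj$coords[, atoms, 2], nrow = nf)
  suspect <- 0L
  if (nf > 1L) {
    dx <- x[-1, , drop = FALSE] - x[-nf, , drop = FALSE]
    dy <- y[-1, , drop = FALSE] - y[-nf, , drop = FALSE]
    Lx <- traj$box[-1, 1]; Ly <- traj$box[-1, 2]
    dx <- wrap_displacement(dx, Lx); dy <- wrap_displacement(dy, Ly)
    suspect <- sum(abs(dx) > Lx / 4) + sum(abs(dy) > Ly / 4)
    csx <- matrix(apply(dx, 2, cumsum), nrow = nf - 1L)
    csy <- matrix(apply(dy, 2, cumsum), nrow = nf - 1L)
    x <- rbind(x[1, ], sweep(csx, 2, x[1, ], "+"))
    y <- rbind(y[1, ], sweep(csy, 2, y[1, ], "+"))
  }
  if (suspect > 0L)
    warning(suspect, " jump(s) exceed a quarter box length per frame; ",
            "the track may be temporally undersampled")
  dt <- if (nf > 1L) traj$time[2] - traj$time[1] else NA_real_
  structure(list(x = x, y = y, dt = dt, time = traj$time,
                 labels = labels, box = traj$box[1, 1:2]),
            class = "TrackSet")
}

#' Construct a TrackSet from raw position matrices
#' @param x,y `n_frames x n_particles` matrices of unwrapped positions (nm).
#' @param dt frame interval (ns).
#' @param labels optional per-particle labels.
#' @param box optional lateral box lengths (nm).
#' @return a `TrackSet`.
#' @export
track_set <- function(x, y, dt, labels = NULL, box = NULL) {
  x <- as.matrix(x); y <- as.matrix(y)
  dimnames(x) <- NULL; dimnames(y) <- NULL
  stopifnot(all(dim(x) == dim(y)), dt > 0)
  structure(list(x = x, y = y, dt = dt,
                 time = (seq_len(nrow(x)) - 1) * dt,
                 labels = labels %||% rep("track", ncol(x)), box = box),
            class = "TrackSet")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rewrap a TrackSet into the periodic box
#' @param tracks a `TrackSet` with a `box` entry.
#' @return list of wrapped `x`, `y` matrices.
#' @export
rewrap_tracks <- function(tracks) {
  if (is.null(tracks$box)) stop("TrackSet carries no box")
  list(x = wrap_position(tracks$x, tracks$box[1]),
       y = wrap_position(tracks$y, tracks$box[2]))
}

#' Subset a TrackSet by particle
#' @param tracks a `TrackSet`.
#' @param which integer or logical particle index, or a label value.
#' @return a `TrackSet`.
#' @export
subset_tracks <- function(tracks, which) {
  if (is.character(which)) which <- tracks$labels %in% which
  structure(list(x = tracks$x[, which, drop = FALSE],
                 y = tracks$y[, which, drop = FALSE],
                 dt = tracks$dt, time = tracks$time,
                 labels = tracks$labels[which], box = tracks$box),
            class = "TrackSet")
}

#' Pooled jump distances at a fixed lag
#'
#' All lateral Euclidean displacements `|r(t + lag) - r(t)|` pooled over
#' particles and overlapping time origins.
#'
#' @param tracks a `TrackSet` (unwrapped).
#' @param lag lag time in ns; must be an integer multiple of the frame
#'   interval and shorter than the track duration.
#' @return numeric vector of jump distances (nm) with attributes `lag` (ns)
#'   and `origin` (frame index of each jump's time origin, used for
#'   segment-wise uncertainties).
#' @export
jump_distances <- function(tracks, lag) {
  k <- lag / tracks$dt
  if (abs(k - round(k)) > 1e-9)
    stop("lag must be an integer multiple of the frame interval ",
         tracks$dt, " ns")
  k <- as.integer(round(k))
  nf <- nrow(tracks$x)
  if (k < 1L || k >= nf) stop("lag must be positive and less than the track duration")
  i0 <- seq_len(nf - k)
  dx <- tracks$x[i0 + k, , drop = FALSE] - tracks$x[i0, , drop = FALSE]
  dy <- tracks$y[i0 + k, , drop = FALSE] - tracks$y[i0, , drop = FALSE]
  r <- sqrt(dx^2 + dy^2)
  structure(as.vector(r), lag = lag, origin = rep(i0, ncol(r)))
}

# negative log-likelihood of a 2D Brownian jump-distance mixture
# p(r) = sum_i f_i * r/(2 s_i) * exp(-r^2/(4 s_i)), s_i = D_i * lag (nm^2)
jda_nll <- function(r, s, f) {
  dens <- vapply(seq_along(s), function(i)
    f[i] * r / (2 * s[i]) * exp(-r^2 / (4 * s[i])), numeric(length(r)))
  d <- if (is.matrix(dens)) rowSums(dens) else sum(dens)
  -sum(log(pmax(d, 1e-300)))
}

# EM on raw jumps for the Rayleigh-type mixture; deterministic given inits
jda_em <- function(r, lag, s0, f0, max_iter = 500, tol = 1e-10) {
  s <- s0; f <- f0; k <- length(s0)
  nll_old <- Inf
  for (it in seq_len(max_iter)) {
    comp <- vapply(seq_len(k), function(i)
      f[i] * r / (2 * s[i]) * exp(-r^2 / (4 * s[i])), numeric(length(r)))
    tot <- rowSums(comp)
    if (any(!is.finite(tot)) || any(tot <= 0)) return(NULL)
    g <- comp / tot
    f <- colMeans(g)
    s <- colSums(g * r^2) / (4 * colSums(g))
    if (any(!is.finite(s)) || any(s <= 0)) return(NULL)
    nll <- jda_nll(r, s, f)
    if (abs(nll_old - nll) < tol * (1 + abs(nll))) {
      return(list(s = s, f = f, nll = nll, iter = it, converged = TRUE))
    }
    nll_old <- nll
  }
  list(s = s, f = f, nll = nll_old, iter = max_iter, converged = FALSE)
}

#' Fit the jump-distance distribution of 2D Brownian subpopulations
#'
#' Maximum-likelihood fit (EM on the raw jumps, no histogram binning) of
#' `p(r) = sum_i f_i * r/(2 D_i t) * exp(-r^2 / (4 D_i t))`.
#' With `n_components = "auto"`, 1- and 2-component fits are compared by BIC
#' and the 2-component model is kept only if it improves BIC by more than 10.
#' Degenerate components (fraction < 0.01) are pruned with a warning.
#' Uncertainty (sd of D) comes from refitting on 5 contiguous trajectory
#' segments when the jumps carry their time origins.
#'
#' @param jumps numeric vector from [jump_distances()] (nm); at least 100.
#' @param lag lag time in ns (defaults to the `lag` attribute of `jumps`).
#' @param n_components integer >= 1, or `"auto"`.
#' @param n_segments segments for the uncertainty estimate (default 5).
#' @param bic_margin BIC improvement needed to accept the 2-component model
#'   in `"auto"` mode (default 10).
#' @return a `JdaFit`: list with `lag`, `components` data frame
#'   (`D` in 1e-7 cm^2/s, `fraction`, `D_sd`), `loglik`, `bic`, `n_jumps`,
#'   `converged`.
#' @export
fit_jda <- function(jumps, lag = attr(jumps, "lag"), n_components = 1,
                    n_segments = 5, bic_margin = 10) {
  r <- as.numeric(jumps)
  if (length(r) < 100) stop("need at least 100 jumps")
  if (is.null(lag) || lag <= 0) stop("a positive lag (ns) is required")
  if (identical(n_components, "auto")) {
    f1 <- fit_jda(jumps, lag, 1L, n_segments)
    f2 <- tryCatch(fit_jda(jumps, lag, 2L, n_segments),
                   error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(f2) && nrow(f2$components) == 2L &&
        f1$bic - f2$bic > bic_margin) return(f2)
    return(f1)
  }
  k <- as.integer(n_components)
  if (k < 1L) stop("n_components must be >= 1")
  if (all(r == 0)) { # degenerate: immobile population
    comps <- data.frame(D = 0, fraction = 1, D_sd = NA_real_)
    return(structure(list(lag = lag, components = comps, loglik = NA_real_,
                          bic = NA_real_, n_jumps = length(r),
                          converged = TRUE), class = "JdaFit"))
  }
  fit <- jda_fit_core(r, lag, k)
  if (is.null(fit)) stop("JDA mixture fit did not converge (k = ", k, ")")
  if (!fit$converged)
    stop("JDA mixture fit did not converge after ", fit$iter, " iterations")
  keep <- fit$f >= 0.01
  if (!all(keep)) {
    warning("pruned ", sum(!keep), " degenerate JDA component(s) with fraction < 0.01")
    if (sum(keep) >= 1L) {
      fit <- jda_fit_core(r, lag, sum(keep))
    }
  }
  ord <- order(fit$s, decreasing = TRUE)
  s <- fit$s[ord]; f <- fit$f[ord] / sum(fit$f[ord])
  D <- nm2ns_to_1e7cm2s(s / lag)
  D_sd <- rep(NA_real_, length(D))
  origin <- attr(jumps, "origin")
  if (!is.null(origin) && n_segments > 1L) {
    seg <- ceiling(origin / max(origin) * n_segments)
    ests <- matrix(NA_real_, n_segments, length(D))
    for (sg in seq_len(n_segments)) {
      rs <- r[seg == sg]
      if (length(rs) >= 50) {
        fs <- jda_fit_core(rs, lag, length(D))
        if (!is.null(fs))
          ests[sg, ] <- nm2ns_to_1e7cm2s(sort(fs$s, decreasing = TRUE) / lag)
      }
    }
    D_sd <- apply(ests, 2, stats::sd, na.rm = TRUE)
  }
  k <- length(D)
  npar <- 2 * k - 1
  structure(list(lag = lag,
                 components = data.frame(D = D, fraction = f, D_sd = D_sd),
                 loglik = -fit$nll,
                 bic = 2 * fit$nll + npar * log(length(r)),
                 n_jumps = length(r), converged = fit$converged),
            class = "JdaFit")
}

# deterministic multi-start EM: quantile-split initializations
jda_fit_core <- function(r, lag, k) {
  s_hat <- sum(r^2) / (4 * length(r)) # 1-component MLE of s = D * lag
  if (k == 1L)
    return(list(s = s_hat, f = 1, nll = jda_nll(r, s_hat, 1),
                iter = 0L, converged = TRUE))
  starts <- list()
  qs <- stats::quantile(r^2 / 4, probs = seq(0, 1, length.out = k + 1))
  s0 <- vapply(seq_len(k), function(i) {
    lo <- qs[i]; hi <- qs[i + 1]
    mean(r[r^2 / 4 >= lo & r^2 / 4 <= hi]^2) / 4
  }, numeric(1))
  starts[[1]] <- list(s = pmax(s0, 1e-12), f = rep(1 / k, k))
  starts[[2]] <- list(s = s_hat * seq(0.25, 2.5, length.out = k),
                      f = rep(1 / k, k))
  starts[[3]] <- list(s = s_hat * 2^seq(-2, 2, length.out = k),
                      f = rep(1 / k, k))
  best <- NULL
  for (st in starts) {
    fit <- jda_em(r, lag, st$s, st$f)
    if (!is.null(fit) && (is.null(best) || fit$nll < best$nll)) best <- fit
  }
  best
}

#' @export
print.JdaFit <- function(x, ...) {
  cat(sprintf("JdaFit: lag %g ns, %d jumps, %d component(s)\n",
              x$lag, x$n_jumps, nrow(x$components)))
  for (i in seq_len(nrow(x$components)))
    cat(sprintf("  D = %.3f%s x 1e-7 cm^2/s (fraction %.2f)\n",
                x$components$D[i],
                ifelse(is.na(x$components$D_sd[i]), "",
                       sprintf(" +/- %.3f", x$components$D_sd[i])),
                x$components$fraction[i]))
  invisible(x)
}

#' Histogram-CDF least-squares cross-check for single-population JDA
#'
#' Fits the analytic jump-distance CDF `1 - exp(-r^2 / (4 D t))` to the
#' empirical CDF by least squares. Kept as an independent route to the ML
#' fit; insensitive to bin width by construction.
#'
#' @param jumps numeric vector of jump distances (nm).
#' @param lag lag in ns.
#' @return D in 1e-7 cm^2/s.
#' @export
fit_jda_cdf <- function(jumps, lag = attr(jumps, "lag")) {
  if (is.null(lag) || lag <= 0) stop("a positive lag (ns) is required")
  r <- sort(as.numeric(jumps))
  p <- stats::ppoints(length(r))
  # linearize: -log(1 - CDF) = r^2 / (4 s); regress r^2/4 on y through origin
  y <- -log(1 - p)
  s <- sum((r^2 / 4) * y) / sum(y^2)
  nm2ns_to_1e7cm2s(s / lag)
}

#' Mean-square-displacement diffusion coefficient
#'
#' Ensemble- and time-origin-averaged lateral MSD, fitted linearly over the
#' window; `D = slope / 4` (2D diffusion), reported in 1e-7 cm^2/s.
#'
#' @param tracks a `TrackSet` (unwrapped).
#' @param fit_window `c(t_min, t_max)` in ns; defaults to 2--20% of the
#'   track duration, where overlapping time origins still give good
#'   statistics.
#' @return list with `D` (1e-7 cm^2/s), `slope` (nm^2/ns), `intercept`,
#'   `msd` data frame (`t`, `msd`), and `negative_slope` flag.
#' @export
msd_diffusion <- function(tracks, fit_window = NULL) {
  nf <- nrow(tracks$x)
  dur <- (nf - 1) * tracks$dt
  if (is.null(fit_window)) fit_window <- c(0.02, 0.2) * dur
  if (fit_window[2] > dur || fit_window[1] < 0)
    stop("fit_window must lie within the track duration (0..", dur, " ns)")
  lags <- seq_len(max(1L, min(nf - 1L, ceiling(fit_window[2] / tracks$dt))))
  msd <- vapply(lags, function(k) {
    i0 <- seq_len(nf - k)
    dx <- tracks$x[i0 + k, , drop = FALSE] - tracks$x[i0, , drop = FALSE]
    dy <- tracks$y[i0 + k, , drop = FALSE] - tracks$y[i0, , drop = FALSE]
    mean(dx^2 + dy^2)
  }, numeric(1))
  t <- lags * tracks$dt
  df <- data.frame(t = c(0, t), msd = c(0, msd))
  sel <- df$t >= fit_window[1] & df$t <= fit_window[2] & df$t > 0
  if (sum(sel) < 2) stop("fit_window contains fewer than 2 MSD points")
  fit <- stats::lm(msd ~ t, data = df[sel, ])
  slope <- unname(stats::coef(fit)[2])
  neg <- slope < 0
  if (neg) warning("negative MSD slope; D reported as fitted")
  list(D = nm2ns_to_1e7cm2s(slope / 4), slope = slope,
       intercept = unname(stats::coef(fit)[1]), msd = df,
       negative_slope = neg, fit_window = fit_window)
}

#' Ratio of two diffusion coefficients, 2 significant figures
#' @param d_a,d_b diffusion coefficients (same units); `d_b > 0`.
#' @return dimensionless ratio rounded to 2 significant figures.
#' @export
diffusion_ratio <- function(d_a, d_b) {
  if (any(d_b <= 0)) stop("denominator diffusion coefficient must be > 0")
  signif(d_a / d_b, 2)
}
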