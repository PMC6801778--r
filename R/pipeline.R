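#' Default analysis parameters
#'
#' All thresholds used by the composed analyses, overridable per run:
#' JDA lag (ns), component selection, local-order cutoff (nm), insertion
#' neighbour cutoff (nm), depth histogram bin width (nm), block count for
#' uncertainties, chain carbon range, and the residue ranges of the G domain
#' and the switch regions.
#'
#' @return named list of defaults.
#' @export
default_params <- function() {
  list(lag = 1, n_components = "auto", local_cutoff = 0.5,
       neighbor_cutoff = 1.0, bin_width = 0.05, n_blocks = 5,
       carbons = 2:15, g_domain = "name CA and resid 15:185",
       switch_regions = "name CA and resid 50:60 75:92",
       gg_anchor = "resname GGC and not name CA",
       phosphorus = "name P",
       order_lipids = "resname POPC PSM POPE POPS")
}

#' Run the composed trajectory analysis over one or many systems
#'
#' Each system is either generated from synthetic specs (`bilayer`,
#' optional `protein` and `tracks` entries holding the arguments of
#' [bilayer_spec()], [anchor_spec()], [track_spec()]) or loaded from files
#' (`input` with `topology`, `trajectory`, `dt`). Stages run in dependency
#' order: membrane summary, lateral diffusion (JDA + MSD per species),
#' anchored-protein geometry (depths, orientation, radius of gyration).
#' Outputs are deterministic given identical config + seed: per-system CSV
#' tables under `<outdir>/tables/` and a `report.json`.
#'
#' @param config a named list, or a path to a YAML file with the same
#'   structure: `seed`, `outdir` (optional), `params` (overrides of
#'   [default_params()]), `systems` (named list).
#' @return a `Report` (list), invisibly written to `outdir` when given.
#' @export
run_analysis <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$systems) || length(config$systems) == 0)
    stop("config needs at least one system")
  seed <- config$seed %||% 1L
  params <- utils::modifyList(default_params(), config$params %||% list())
  if (is.character(params$carbons))
    params$carbons <- eval(parse(text = params$carbons))
  outdir <- config$outdir
  if (!is.null(outdir)) {
    dir.create(file.path(outdir, "tables"), recursive = TRUE,
               showWarnings = FALSE)
  }
  sys_names <- names(config$systems) %||%
    paste0("system", seq_along(config$systems))
  systems <- list()
  for (i in seq_along(config$systems)) {
    nm <- sys_names[i]
    message("[memanchor] stage: system '", nm, "'")
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(
      run_system(config$systems[[i]], params, seed + 1000L * i, nm, outdir),
      error = function(e) {
        # remove partial outputs for this system before aborting
        if (!is.null(outdir)) {
          part <- list.files(file.path(outdir, "tables"),
                             pattern = paste0("^", nm, "_"),
                             full.names = TRUE)
          unlink(part)
        }
        stop("stage '", nm, "' failed: ", conditionMessage(e),
             call. = FALSE)
      })
    message(sprintf("[memanchor] stage '%s' done in %.1f s", nm,
                    proc.time()[["elapsed"]] - t0))
    systems[[nm]] <- res
  }
  report <- structure(list(
    package = "memanchor",
    version = as.character(utils::packageVersion("memanchor")),
    seed = seed,
    config_hash = rlang::hash(config[setdiff(names(config), "outdir")]),
    params = params[c("lag", "local_cutoff", "neighbor_cutoff", "bin_width",
                      "n_blocks")],
    systems = systems), class = "Report")
  validate_report(report)
  if (!is.null(outdir)) {
    jsonlite::write_json(unclass(report), file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

run_system <- function(sys, params, seed, name, outdir) {
  out <- list()
  tab <- function(df, what) {
    if (!is.null(outdir))
      utils::write.csv(df, file.path(outdir, "tables",
                                     paste0(name, "_", what, ".csv")),
                       row.names = FALSE)
  }
  traj <- NULL
  if (!is.null(sys$input)) {
    traj <- load_trajectory(sys$input$topology, sys$input$trajectory,
                            dt = sys$input$dt %||% 1)
  } else if (!is.null(sys$bilayer)) {
    bargs <- sys$bilayer
    if (is.null(bargs$seed)) bargs$seed <- seed
    bl <- make_bilayer(do.call(bilayer_spec, bargs))
    traj <- bl
    if (!is.null(sys$protein)) {
      pargs <- sys$protein
      if (is.null(pargs$seed)) pargs$seed <- seed + 1L
      traj <- make_anchored_protein(do.call(anchor_spec, pargs), bl)
    }
  }
  if (!is.null(traj)) {
    phos <- select_atoms(traj, params$phosphorus)
    # all lipid molecules (cholesterol included) count in the APL denominator
    npl <- sum(traj$topology$molecules$species != "protein") / 2
    has_chains <- length(select_atoms(traj$topology,
                                      params$order_lipids)) > 0
    ms <- membrane_summary(traj, phos, lipids_per_leaflet = npl,
                           lipid_sel = if (has_chains) params$order_lipids,
                           carbons = params$carbons,
                           n_blocks = params$n_blocks)
    out$membrane <- list(thickness = ms$thickness,
                         thickness_sd = ms$thickness_sd,
                         area_per_lipid = ms$area_per_lipid,
                         area_per_lipid_sd = ms$area_per_lipid_sd,
                         order = ms$order, order_sd = ms$order_sd,
                         units = list(thickness = "nm",
                                      area_per_lipid = "nm^2",
                                      order = "dimensionless"))
    tab(ms$per_frame, "membrane_per_frame")
    if (!is.null(ms$order_profile))
      tab(data.frame(carbon = ms$order_profile$carbons,
                     s_cd = ms$order_profile$s_cd), "order_profile")
    gg <- select_atoms(traj$topology, params$gg_anchor)
    if (length(gg) > 0) {
      depths <- insertion_depth_series(traj, gg, phos,
                                       params$neighbor_cutoff)
      dd <- if (length(depths) >= 100)
        depth_distribution(depths, params$bin_width) else NULL
      ca <- select_atoms(traj$topology, "name CA and segid PROT")
      gdom <- select_atoms(traj$topology, params$g_domain)
      sw <- select_atoms(traj$topology, params$switch_regions)
      ori <- orientation_series(traj, gdom, sw, gg)
      rg <- vapply(seq_len(n_frames(traj)), function(f)
        radius_of_gyration(get_frame(traj, f), ca), numeric(1))
      out$geometry <- list(
        depth_mean = mean(depths), depth_sd = stats::sd(depths),
        depth_modality = if (!is.null(dd)) dd$modality else NA_integer_,
        depth_component_means = if (!is.null(dd)) dd$component_means,
        theta_mean = mean(ori$theta), omega_mean = mean(ori$omega),
        label_fractions = as.list(table(ori$label) / nrow(ori)),
        rgyr_mean = mean(rg), rgyr_sd = stats::sd(rg),
        units = list(depth = "nm", theta = "degrees", omega = "degrees",
                     rgyr = "nm"))
      tab(data.frame(time = traj$time, depth = depths), "depth_series")
      tab(cbind(ori, rgyr = rg), "orientation_series")
    }
  }
  if (!is.null(sys$tracks)) {
    targs <- sys$tracks
    if (is.null(targs$seed)) targs$seed <- seed + 2L
    bt <- make_brownian_tracks(do.call(track_spec, targs))
    tk <- unwrap_tracks(bt$trajectory,
                        seq_len(n_atoms(bt$trajectory)))
    rows <- list()
    for (sp in unique(tk$labels)) {
      sub <- subset_tracks(tk, sp)
      jumps <- jump_distances(sub, params$lag)
      fit <- fit_jda(jumps, n_components = params$n_components,
                     n_segments = params$n_blocks)
      msd <- msd_diffusion(sub)
      rows[[sp]] <- data.frame(
        species = sp, n_particles = ncol(sub$x),
        D_jda = fit$components$D[1], D_jda_sd = fit$components$D_sd[1],
        n_components = nrow(fit$components),
        D_msd = msd$D, units = "1e-7 cm^2/s",
        lag_ns = params$lag, overlapping_origins = TRUE)
    }
    diff_tab <- do.call(rbind, rows)
    rownames(diff_tab) <- NULL
    out$diffusion <- list(table = diff_tab)
    tab(diff_tab, "diffusion")
  }
  if (length(out) == 0) stop("system defines no analysable inputs")
  out
}

#' Compare diffusion coefficients across systems
#'
#' Per species and system pair: ratio of JDA diffusion coefficients to 2
#' significant figures with first-order uncertainty propagation
#' (`sd(a/b) = |a/b| sqrt((sa/a)^2 + (sb/b)^2)`). Species missing from a
#' system yield `NA` cells.
#'
#' @param reports list of >= 2 `Report` objects (or a single multi-system
#'   `Report`).
#' @param which_systems optional character vector restricting/ordering the
#'   systems compared.
#' @return data frame with columns `species`, `system_a`, `system_b`,
#'   `D_a`, `D_b`, `ratio`, `ratio_sd`.
#' @export
compare_systems <- function(reports, which_systems = NULL) {
  if (inherits(reports, "Report")) reports <- list(reports)
  systems <- list()
  for (rp in reports) {
    for (nm in names(rp$systems)) {
      d <- rp$systems[[nm]]$diffusion$table
      if (!is.null(d)) systems[[nm]] <- d
    }
  }
  if (!is.null(which_systems)) systems <- systems[which_systems]
  if (length(systems) < 2) stop("need at least 2 systems with diffusion tables")
  nms <- names(systems)
  rows <- list()
  for (i in seq_along(nms)) for (j in seq_along(nms)) {
    if (i == j) next
    a <- systems[[i]]; b <- systems[[j]]
    for (sp in unique(a$species)) {
      da <- a[a$species == sp, , drop = FALSE]
      db <- b[b$species == sp, , drop = FALSE]
      if (nrow(db) == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          species = sp, system_a = nms[i], system_b = nms[j],
          D_a = da$D_jda[1], D_b = NA_real_, ratio = NA_real_,
          ratio_sd = NA_real_)
        next
      }
      rows[[length(rows) + 1]] <- ratio_row(sp, nms[i], nms[j],
                                            da$D_jda[1], da$D_jda_sd[1],
                                            db$D_jda[1], db$D_jda_sd[1])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

ratio_row <- function(sp, na_, nb_, a, sa, b, sb) {
  r <- diffusion_ratio(a, b)
  rsd <- if (is.na(sa) || is.na(sb)) NA_real_
         else abs(a / b) * sqrt((sa / a)^2 + (sb / b)^2)
  data.frame(species = sp, system_a = na_, system_b = nb_,
             D_a = a, D_b = b, ratio = r, ratio_sd = rsd)
}

#' Propagated ratio of two uncertain values
#'
#' First-order (delta-method) uncertainty of `a/b` given independent sds.
#'
#' @param a,b values (`b > 0`).
#' @param sa,sb standard deviations.
#' @return list with `ratio` (2 significant figures) and `sd`.
#' @export
ratio_with_uncertainty <- function(a, sa, b, sb) {
  list(ratio = diffusion_ratio(a, b),
       sd = abs(a / b) * sqrt((sa / a)^2 + (sb / b)^2))
}

#' Validate a Report against the shipped schema
#'
#' Structural validation of the report produced by [run_analysis()]:
#' required top-level fields, field types, and per-system blocks. The JSON
#' Schema document describing the same structure ships at
#' `system.file("schema", "report.schema.json", package = "memanchor")`.
#'
#' @param report a `Report` (or a list parsed from `report.json`).
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validate_report <- function(report) {
  need <- c("package", "version", "seed", "config_hash", "params", "systems")
  missing <- setdiff(need, names(report))
  if (length(missing) > 0)
    stop("report is missing field(s): ", paste(missing, collapse = ", "))
  if (!identical(report$package, "memanchor")) stop("report$package mismatch")
  if (!is.character(report$config_hash)) stop("config_hash must be a string")
  if (length(report$systems) < 1) stop("report has no systems")
  for (nm in names(report$systems)) {
    s <- report$systems[[nm]]
    if (!is.list(s) || length(s) == 0) stop("system '", nm, "' is empty")
    if (!is.null(s$membrane)) {
      for (f in c("thickness", "area_per_lipid"))
        if (!is.numeric(s$membrane[[f]]) || s$membrane[[f]] <= 0)
          stop("system '", nm, "': membrane$", f, " must be positive")
      if (is.null(s$membrane$units))
        stop("system '", nm, "': membrane block lacks units")
    }
    if (!is.null(s$diffusion)) {
      d <- s$diffusion$table
      if (is.null(d$species) || is.null(d$D_jda))
        stop("system '", nm, "': diffusion table lacks species/D_jda")
    }
  }
  invisible(TRUE)
}
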