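#!/usr/bin/env Rscript
# Anchor insertion depth distributions and protein-membrane distances.
#
# Doubly lipidated protein in the six-component-like bilayer: depths planted
# as a narrow normal around 1.74 nm (GDP) and 1.71 nm (GTP) -> unimodal
# recovery. Mono-lipidated protein: a broad bimodal plant -> modality 2.
# Also writes the per-residue membrane-distance map of an exo-posed frame
# set, where the switch-I patch (residues 50-60) sits most distal.
# Writes results/depth_*.csv and results/residue_distances.csv.

suppressMessages(library(memanchor))
dir.create("results", showWarnings = FALSE)

bl <- make_bilayer(bilayer_spec(
  n_lipids_per_leaflet = 16, thickness = 4.54, area_per_lipid = 0.466,
  target_order = 0.305, n_frames = 600, seed = 401))

cases <- list(
  double_gg_gdp = anchor_spec(depth_means = 1.74, depth_sds = 0.15,
                              n_gg = 2, theta = 90, omega = 190, seed = 402),
  double_gg_gtp = anchor_spec(depth_means = 1.71, depth_sds = 0.15,
                              n_gg = 2, theta = 90, omega = 80, seed = 403),
  mono_gg = anchor_spec(depth_means = c(0.9, 1.6), depth_sds = 0.18,
                        depth_weights = c(0.5, 0.5), n_gg = 1,
                        theta = 120, omega = 80, seed = 404))

hist_rows <- list()
for (nm in names(cases)) {
  ap <- make_anchored_protein(cases[[nm]], bl)
  gt <- attr(ap, "ground_truth")
  d <- insertion_depth_series(ap, gt$gg_carbons, gt$phosphorus)
  dd <- depth_distribution(d, bin_width = 0.05)
  cat(sprintf("%-14s mean depth %.2f +/- %.2f nm, modality %d (means %s)\n",
              nm, dd$mean, dd$sd, dd$modality,
              paste(sprintf("%.2f", sort(dd$component_means)),
                    collapse = " / ")))
  mids <- head(dd$histogram$breaks, -1) + 0.025
  hist_rows[[nm]] <- data.frame(system = nm, depth = mids,
                                count = dd$histogram$counts)
}
write.csv(do.call(rbind, hist_rows), "results/depth_distributions.csv",
          row.names = FALSE)

# residue-membrane distance map (exo pose, switch regions pointing away)
bl30 <- make_bilayer(bilayer_spec(n_lipids_per_leaflet = 16, n_frames = 40,
                                  thickness = 4.54, area_per_lipid = 0.466,
                                  seed = 405))
ap <- make_anchored_protein(anchor_spec(depth_means = 1.0, theta = 60,
                                        omega = 180, seed = 406), bl30)
gt <- attr(ap, "ground_truth")
prot <- select_atoms(ap$topology, "segid PROT and name CA")
m <- residue_membrane_distances(ap, prot, gt$phosphorus)
long <- data.frame(residue = rep(as.integer(rownames(m)), ncol(m)),
                   frame = rep(seq_len(ncol(m)), each = nrow(m)),
                   distance = as.vector(m))
write.csv(long, "results/residue_distances.csv", row.names = FALSE)
avg <- rowMeans(m)
top5 <- names(sort(avg[as.character(15:185)], decreasing = TRUE))[1:5]
cat(sprintf("most distal G-domain residues (planted: switch I, 50-60): %s\n",
            paste(top5, collapse = ", ")))
cat("wrote results/depth_distributions.csv, results/residue_distances.csv\n")
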