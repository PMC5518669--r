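#!/usr/bin/env Rscript
# Step 4: the two oxidation-specific analyses.
#
# (a) Marker depth: the polar aldehyde groups of an 11.1% OX3 bilayer start
#     halfway the bilayer (where oxidation happens) and end up bent toward
#     the phosphate planes; the aldehyde-marker density profile shows the
#     migration.
# (b) Pore characterisation: the fully oxidised OX3 system develops a
#     water channel; single-linkage clustering of core waters yields the
#     spanning verdict, onset frame and the slab-wise diameter profile.

suppressPackageStartupMessages(library(oxbilayer))
dir.create("results", showWarnings = FALSE)

base <- function(bend) {
  synthetic_spec(n_lipids = 72, ox_fraction = 8 / 72, ox_species = "OX3",
                 polar_bend = bend, tilt = 25, seed = 211)
}

profs <- list()
for (mode in c("straight", "bent")) {
  r <- gen_bent_tail_frame(base(mode == "bent"))
  m <- density_profile(r$trajectory, marker_selection, equil_time = -1)
  p <- density_profile(r$trajectory, phosphate_selection, equil_time = -1)
  w <- density_profile(r$trajectory, water_selection, equil_time = -1)
  profs[[mode]] <- data.frame(mode = mode, z = m$bin_center,
                              marker = m$density, phosphate = p$density,
                              water = w$density)
  up <- m$bin_center > 0
  cat(sprintf("%-8s mode: upper marker peak at %+.2f nm, P peak at %+.2f nm\n",
              mode, m$bin_center[up][which.max(m$density[up])],
              p$bin_center[up][which.max(p$density[up])]))
}
out <- do.call(rbind, profs)
con <- file("results/marker_profiles.tsv", "w")
writeLines(c("# aldehyde-marker / phosphate / water density profiles",
             "# z: nm from bilayer midplane; densities: kg m^-3"), con)
write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
close(con)
cat("wrote results/marker_profiles.tsv\n\n")

# fully oxidised system with a ~15 Angstrom pore
r <- gen_bilayer_trajectory(
  synthetic_spec(n_lipids = 72, ox_fraction = 1, ox_species = "OX3",
                 polar_bend = TRUE, pore_radius = 7.5, n_frames = 24,
                 seed = 212))
pore <- detect_pore(r$trajectory)
print(pore)
cat(sprintf("constructed pore diameter: %.1f A; recovered maximum: %.1f A\n",
            r$truth$pore_diameter, pore$diameter_max))
core <- water_density_center(r$trajectory)
cat(sprintf("core water density: %.1f kg m^-3 (geometric prediction %.1f)\n",
            core, r$truth$core_water_density))
writeLines(c("# pore report (fully oxidised OX3 system)",
             sprintf("spanning\t%s", pore$spanning),
             sprintf("diameter_max\t%.2f\tAngstrom", pore$diameter_max),
             sprintf("diameter_min\t%.2f\tAngstrom", pore$diameter_min),
             sprintf("onset\t%g\tps", pore$frame_of_onset),
             sprintf("core_water_density\t%.2f\tkg m^-3", core)),
           "results/pore_report.tsv")
cat("wrote results/pore_report.tsv\n")
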