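#!/usr/bin/env Rscript
# Stage 1: generate the default synthetic world and its lidar footprints.
#
# The default landscape is a 100 x 100 km plane with 20 protected areas
# grown preferentially over the covariate index that also drives biomass
# (confounded placement), a true protection effect of +10 Mg/ha AGBD, and
# forest-loss rates of 1% inside vs 5% outside PAs. Ground truth is
# written to its own file (truth.csv) and is not read by later stages.

library(pacarbon)

out_dir <- "scratch/landscape"
cfg <- landscape_config(seed = 1)
ls <- generate_landscape(cfg)
fp <- sample_footprints(ls)
write_landscape(ls, out_dir, footprints = fp)

cat(sprintf("landscape: %d cells, %d PAs covering %d km2\n",
            nrow(ls$cells), nrow(ls$pas), sum(ls$cells$is_protected)))
cat(sprintf("footprints: %d shots on %d tracks\n",
            nrow(fp), length(unique(fp$track_id))))
cat("written to", out_dir, "\n")
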