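#!/usr/bin/env Rscript
# Generate the synthetic study inputs: coccosphere geometry, per-sample
# loose-coccolith lengths, assemblage counts, the parameter registry and the
# age-model tie points, all with recorded ground truth. Later steps re-read
# these files, so the whole workflow runs off delimited text.

suppressPackageStartupMessages(library(coccotraits))

seed <- 1
dir <- "results/synthetic_inputs"
bundle <- gen_ground_truth_bundle("U1553-like", seed = seed, dir = dir)

write.csv(bundle$true_values, file.path(dir, "true_community_values.csv"),
          row.names = FALSE)

cat("Synthetic study written to", dir, "\n")
cat(sprintf("  %d coccospheres across %d placolith morphogroups\n",
            nrow(bundle$coccospheres),
            length(unique(bundle$coccospheres$morphogroup))))
cat(sprintf("  %d coccolith length measurements (%d samples x %d morphogroups x 50)\n",
            nrow(bundle$lith_sizes), bundle$truth$n_samples,
            length(bundle$truth$morphogroups)))
cat(sprintf("  %d assemblage counts of 300 coccoliths each\n",
            bundle$truth$n_samples))
cat(sprintf("  true community PIC:POC spans %.2f-%.2f, mean size %.1f-%.1f um\n",
            min(bundle$true_values$community_pic_poc),
            max(bundle$true_values$community_pic_poc),
            min(bundle$true_values$mean_community_size),
            max(bundle$true_values$mean_community_size)))
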