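#!/usr/bin/env Rscript
# Step 1: generate the study-design-scale synthetic data set.
#
# Emulates the 33-array substrate x growth-phase design (11 conditions x 3
# biological replicates) on a 2322-gene array with 20 negative-control
# probes: 13 planted co-expression modules totalling 614 genes (largest
# 138), one hub per module, 5% SNR dropout. Writes the expression, SNR,
# design, annotation and ground-truth tables that the later steps consume.

library(glyconet)

seed <- 1L
out_dir <- file.path("results", "data")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

spec <- paper_preset_spec(seed = seed)
sim <- simulate_expression(spec)

write_expression(sim$expr,
                 matrix_path = file.path(out_dir, "expression.tsv"),
                 design_path = file.path(out_dir, "design.tsv"),
                 snr_path = file.path(out_dir, "snr.tsv"))
write_annotation(sim$annotation, file.path(out_dir, "annotation.tsv"))
truth <- data.frame(gene_id = names(sim$truth$module),
                    module_id = unname(sim$truth$module))
write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE, na = "NA")

sizes <- vapply(spec$modules, `[[`, 0L, "size")
writeLines(c(
  sprintf("seed: %d", seed),
  sprintf("genes: %d (negative controls: %d)", spec$n_genes,
          spec$n_negative_controls),
  sprintf("samples: %d (%d conditions x 3 replicates)", nrow(spec$design),
          nrow(unique(spec$design[, c("substrate", "phase")]))),
  sprintf("planted modules: %d, members: %d, sizes: %s", length(sizes),
          sum(sizes), paste(sizes, collapse = ", ")),
  sprintf("noise_sd: %g, snr_dropout_rate: %g", spec$noise_sd,
          spec$snr_dropout_rate)
), file.path(out_dir, "spec_log.txt"))

cat(sprintf("simulated %d genes x %d samples; %d module genes in %d modules\n",
            spec$n_genes, nrow(spec$design), sum(sizes), length(sizes)))
cat("wrote", file.path(out_dir, c("expression.tsv", "snr.tsv", "design.tsv",
                                  "annotation.tsv", "truth.tsv")), "\n")
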