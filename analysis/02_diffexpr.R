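#!/usr/bin/env Rscript
# Step 2: differential expression and growth-phase dynamics.
#
# Applies the |log2R| >= 1, |Z| >= 2 replicate filter to every condition
# (counting up/down calls per condition), and classifies each gene's peak
# expression phase along the glucose, xylose and glucose+xylose time
# courses with SNR < 2 spots masked.

library(glyconet)

data_dir <- file.path("results", "data")
out_dir <- "results"
x <- read_expression(file.path(data_dir, "expression.tsv"),
                     file.path(data_dir, "design.tsv"),
                     snr_path = file.path(data_dir, "snr.tsv"))

conds <- unique(x$design[, c("substrate", "phase")])
counts <- do.call(rbind, lapply(seq_len(nrow(conds)), function(i) {
  calls <- summarize_contrast(x, c(conds$substrate[i], conds$phase[i]))
  n <- count_significant(calls)
  data.frame(substrate = conds$substrate[i], phase = conds$phase[i],
             n_up = n[["n_up"]], n_down = n[["n_down"]])
}))
write.table(counts, file.path(out_dir, "de_counts.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("significant calls per condition (|log2R| >= 1, |Z| >= 2):\n")
print(counts, row.names = FALSE)

# full call table for the View II contrast: xylose vs glucose at mid phase
xg <- summarize_contrast(x, c("xylose", "mid"), vs = c("glucose", "mid"))
write.table(xg, file.path(out_dir, "de_xylose_vs_glucose_mid.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
cat(sprintf("xylose vs glucose (mid): %d up, %d down\n",
            count_significant(xg)[["n_up"]], count_significant(xg)[["n_down"]]))

# peak-phase choreography along the three time courses
for (sub in c("glucose", "xylose", "glucose_xylose")) {
  pp <- peak_phase(x, sub)
  write.table(pp, file.path(out_dir, sprintf("peak_phase_%s.tsv", sub)),
              sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  cat(sprintf("%s time course peak phases: %s\n", sub,
              paste(sprintf("%s=%d", names(table(pp$peak_phase)),
                            as.integer(table(pp$peak_phase))),
                    collapse = ", ")))
}
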