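#!/usr/bin/env Rscript
# Step 5: assemble the machine-readable run report and text summary.

library(glyconet)

out_dir <- "results"
data_dir <- file.path("results", "data")

x <- read_expression(file.path(data_dir, "expression.tsv"),
                     file.path(data_dir, "design.tsv"),
                     snr_path = file.path(data_dir, "snr.tsv"))
ann <- read_annotation(file.path(data_dir, "annotation.tsv"))
tau <- as.numeric(readLines(file.path(out_dir, "selected_tau.txt")))
edges <- read.delim(file.path(out_dir, "network_edges.tsv"))
net <- coexpression_network(edges, tau = tau)
part <- fast_greedy_modules(net, min_module_size = 5)

report <- run_report(expr = x, net = net, partition = part,
                     annotation = ann, seed = 1L,
                     config = list(tau = tau, min_module_size = 5))
write_report(report, file.path(out_dir, "run_report.json"),
             file.path(out_dir, "run_report.txt"))
cat(readLines(file.path(out_dir, "run_report.txt")), sep = "\n")
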