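#!/usr/bin/env Rscript
# Step 4: fast greedy modularity modules, recovery against ground truth,
# hubs and inter-module structure.

library(glyconet)

out_dir <- "results"
data_dir <- file.path("results", "data")
tau <- as.numeric(readLines(file.path(out_dir, "selected_tau.txt")))
edges <- read.delim(file.path(out_dir, "network_edges.tsv"))
net <- coexpression_network(edges, tau = tau)

part <- fast_greedy_modules(net, min_module_size = 5)
print(part)

truth_tab <- read.delim(file.path(data_dir, "truth.tsv"),
                        colClasses = "character")
truth <- list(module = setNames(ifelse(truth_tab$module_id == "NA",
                                       NA_character_, truth_tab$module_id),
                                truth_tab$gene_id))
qual <- partition_quality(part, truth)
cat(sprintf("recovery vs planted modules: ARI = %.3f, recovered = %.1f%%\n",
            qual$ari, 100 * qual$recovered_fraction))

ann <- read_annotation(file.path(data_dir, "annotation.tsv"))
summary_tab <- do.call(rbind, lapply(names(part$modules), function(id) {
  members <- part$modules[[id]]
  comp <- cog_composition(members, ann, top_k = 3)
  intra <- sum(net$edges$gene_a %in% members & net$edges$gene_b %in% members)
  data.frame(module_id = id, size = length(members), intra_edges = intra,
             major_cogs = paste(comp$major_categories, collapse = ""),
             major_cog_pct = comp$major_cog_fraction)
}))
iml <- inter_module_links(net, part)
summary_tab$n_partner_modules <-
  attr(iml, "interaction_degree")[summary_tab$module_id]
summary_tab$standalone <- attr(iml, "standalone")[summary_tab$module_id]
write.table(summary_tab, file.path(out_dir, "module_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(as.data.frame(iml), file.path(out_dir, "inter_module_links.tsv"),
            sep = "\t", quote = FALSE)
cat(sprintf("%d of %d modules are standalone\n",
            sum(attr(iml, "standalone")), length(part$modules)))

hubs <- hub_ranking(net, n_top = 23)
write.table(hubs, file.path(out_dir, "hub_table.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("top 5 hubs:", paste(sprintf("%s(%d)", hubs$gene_id[1:5],
                                 hubs$degree[1:5]), collapse = ", "), "\n")

nodes <- data.frame(gene_id = net$nodes,
                    module_id = unname(part$module_of[net$nodes]),
                    degree = unname(network_degree(net)[net$nodes]),
                    cog = ann$cog[match(net$nodes, ann$gene_id)])
write.table(nodes, file.path(out_dir, "node_modules.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE, na = "NA")
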