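#' Round half away from zero
#'
#' Percentage display rounding: values are first reported to 1 decimal,
#' and the integer display style rounds that 1-decimal value half away
#' from zero (so 36.2% displays as 36%).
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_away <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' COG composition of a module
#'
#' Counts members per COG functional category and the percentage of the
#' module covered by the `top_k` most frequent categories. Members without
#' a COG assignment count toward the module size but not toward any
#' category.
#'
#' @param members character vector of member gene ids.
#' @param annotation gene annotation data.frame (see [read_annotation()]).
#' @param top_k number of major categories (default 3).
#' @return list: `cog_counts` (named, decreasing; ties by letter),
#'   `major_categories`, `major_cog_fraction` (percent, 1 decimal),
#'   `major_cog_display` (integer-style string, e.g. "36%").
#' @export
cog_composition <- function(members, annotation, top_k = 3L) {
  annotation <- validate_annotation(annotation)
  size <- length(members)
  cogs <- annotation$cog[match(members, annotation$gene_id)]
  cogs <- cogs[!is.na(cogs)]
  if (length(cogs) == 0L) {
    return(list(cog_counts = integer(0), major_categories = character(0),
                major_cog_fraction = 0, major_cog_display = "0%"))
  }
  tab <- table(cogs)
  counts <- sort(stats::setNames(as.integer(tab), names(tab)),
                 decreasing = TRUE)
  major <- names(counts)[seq_len(min(top_k, length(counts)))]
  frac <- round_half_away(100 * sum(counts[major]) / size, 1L)
  list(cog_counts = counts, major_categories = major,
       major_cog_fraction = frac,
       major_cog_display = sprintf("%d%%", round_half_away(frac, 0L)))
}

#' Rank genes by number of network connections
#'
#' @param net a `coexpr_network`.
#' @param n_top how many hubs to report (default 23).
#' @return data.frame `gene_id`, `degree`, sorted by degree descending,
#'   ties by gene id ascending.
#' @export
hub_ranking <- function(net, n_top = 23L) {
  stopifnot(inherits(net, "coexpr_network"))
  if (length(net$nodes) == 0L) stop("empty network")
  deg <- network_degree(net)
  o <- order(-deg, names(deg))
  out <- data.frame(gene_id = names(deg)[o], degree = as.integer(deg[o]),
                    stringsAsFactors = FALSE, row.names = NULL)
  utils::head(out, n_top)
}

#' Edge counts between reported modules
#'
#' Symmetric matrix counting edges whose endpoints lie in two different
#' reported modules. A module's interaction degree is its number of
#' distinct partner modules; a module with none is "standalone".
#'
#' @param net a `coexpr_network`.
#' @param p a `module_partition` covering the network's nodes.
#' @return integer matrix with attributes `interaction_degree` and
#'   `standalone` (named logical).
#' @export
inter_module_links <- function(net, p) {
  stopifnot(inherits(net, "coexpr_network"), inherits(p, "module_partition"))
  ids <- names(p$modules)
  mat <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  ma <- p$module_of[net$edges$gene_a]
  mb <- p$module_of[net$edges$gene_b]
  cross <- !is.na(ma) & !is.na(mb) & ma != mb
  if (any(cross)) {
    for (e in which(cross)) {
      mat[ma[e], mb[e]] <- mat[ma[e], mb[e]] + 1L
      mat[mb[e], ma[e]] <- mat[mb[e], ma[e]] + 1L
    }
  }
  idg <- rowSums(mat > 0L)
  attr(mat, "interaction_degree") <- idg
  attr(mat, "standalone") <- idg == 0L
  mat
}

#' First-neighbour subnetwork of seed genes
#'
#' Induced subgraph on the seeds plus every gene directly connected to a
#' seed. Seeds absent from the network are skipped with a warning.
#'
#' @param net a `coexpr_network`.
#' @param seeds character vector of seed gene ids.
#' @return a `coexpr_network`.
#' @export
first_neighbors <- function(net, seeds) {
  stopifnot(inherits(net, "coexpr_network"))
  unknown <- setdiff(seeds, net$nodes)
  if (length(unknown) > 0L) {
    warning("seed(s) not in network, skipped: ",
            paste(unknown, collapse = ", "))
  }
  seeds <- intersect(seeds, net$nodes)
  if (length(seeds) == 0L) stop("no seed gene is present in the network")
  touch <- net$edges$gene_a %in% seeds | net$edges$gene_b %in% seeds
  keep_nodes <- union(seeds, unique(c(net$edges$gene_a[touch],
                                      net$edges$gene_b[touch])))
  sub <- net$edges[net$edges$gene_a %in% keep_nodes &
                     net$edges$gene_b %in% keep_nodes, , drop = FALSE]
  rownames(sub) <- NULL
  structure(list(nodes = sort(unique(c(sub$gene_a, sub$gene_b, seeds))),
                 edges = sub, tau = net$tau, mode = net$mode),
            class = "coexpr_network")
}

#' Assemble the run report
#'
#' Collects the headline quantities of a full run: array content, network
#' size and genome percentage, selected cutoff, modules and their sizes,
#' modularity, hubs and standalone modules; plus version, seed and a hash
#' of the configuration for reproducibility. Stages not supplied are
#' reported as nulls.
#'
#' @param expr an `expr_matrix` (or NULL).
#' @param scan a `threshold_scan` (or NULL).
#' @param net a `coexpr_network` (or NULL).
#' @param partition a `module_partition` (or NULL).
#' @param annotation annotation data.frame (or NULL).
#' @param seed the run's seed.
#' @param config any serializable object describing the run configuration.
#' @param genome_size denominator for the percent-of-genome figure
#'   (default: number of non-control genes on the array).
#' @param n_top_hubs hub table length (default 23).
#' @return list of class `run_report`.
#' @export
run_report <- function(expr = NULL, scan = NULL, net = NULL,
                       partition = NULL, annotation = NULL, seed = NA,
                       config = NULL, genome_size = NULL, n_top_hubs = 23L) {
  n_array <- if (is.null(expr)) NULL else length(expr$genes)
  n_controls <- if (is.null(annotation)) NULL else
    sum(annotation$is_negative_control)
  if (is.null(genome_size) && !is.null(n_array)) {
    genome_size <- n_array - if (is.null(n_controls)) 0L else n_controls
  }
  n_net <- if (is.null(net)) NULL else length(net$nodes)
  report <- list(
    tool = "glyconet",
    version = as.character(utils::packageVersion("glyconet")),
    seed = seed,
    config_hash = config_hash(config),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    genes_on_array = n_array,
    negative_controls = n_controls,
    genome_size = genome_size,
    selected_tau = if (is.null(scan)) NULL else scan$selected_tau,
    tau_warning = if (is.null(scan)) NULL else scan$warning_flag,
    genes_in_network = n_net,
    pct_of_genome = if (is.null(n_net) || is.null(genome_size)) NULL else
      round_half_away(100 * n_net / genome_size, 1L),
    n_edges = if (is.null(net)) NULL else nrow(net$edges),
    n_modules = if (is.null(partition)) NULL else length(partition$modules),
    module_sizes = if (is.null(partition)) NULL else
      as.list(lengths(partition$modules)),
    modularity_q = if (is.null(partition)) NULL else partition$modularity_q,
    n_unassigned = if (is.null(partition)) NULL else
      length(partition$unassigned),
    standalone_modules = if (is.null(partition) || is.null(net) ||
                             length(net$nodes) == 0L) NULL else
      names(which(attr(inter_module_links(net, partition), "standalone"))),
    hub_table = if (is.null(net) || length(net$nodes) == 0L) NULL else
      hub_ranking(net, n_top_hubs)
  )
  if (!is.null(n_net) && n_net == 0L) {
    report$warnings <- "network is empty"
  }
  class(report) <- "run_report"
  report
}

config_hash <- function(config) {
  if (is.null(config)) return(NA_character_)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(utils::capture.output(utils::str(config, digits.d = 15)), f)
  unname(tools::md5sum(f))
}

#' Write a run report as JSON plus a plain-text summary
#'
#' Two runs with the same seed and configuration produce byte-identical
#' files except for the timestamp line.
#'
#' @param report a `run_report`.
#' @param json_path output path for the machine-readable report.
#' @param txt_path optional output path for the human-readable summary.
#' @export
write_report <- function(report, json_path, txt_path = NULL) {
  stopifnot(inherits(report, "run_report"))
  jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  if (!is.null(txt_path)) {
    fmt <- function(x) if (is.null(x)) "NA" else paste(x, collapse = ", ")
    lines <- c(
      sprintf("glyconet run report (version %s)", report$version),
      sprintf("timestamp: %s", report$timestamp),
      sprintf("seed: %s  config: %s", fmt(report$seed),
              fmt(report$config_hash)),
      sprintf("genes on array: %s (%s negative controls)",
              fmt(report$genes_on_array), fmt(report$negative_controls)),
      sprintf("selected cutoff tau: %s%s", fmt(report$selected_tau),
              if (isTRUE(report$tau_warning)) " [unstable]" else ""),
      sprintf("network: %s genes (%s%% of genome), %s edges",
              fmt(report$genes_in_network), fmt(report$pct_of_genome),
              fmt(report$n_edges)),
      sprintf("modules: %s (Q = %s); sizes: %s", fmt(report$n_modules),
              fmt(report$modularity_q),
              fmt(unlist(report$module_sizes))),
      sprintf("standalone modules: %s", fmt(report$standalone_modules))
    )
    if (!is.null(report$hub_table)) {
      lines <- c(lines, "top hubs (gene, degree):",
                 sprintf("  %s %d", report$hub_table$gene_id,
                         report$hub_table$degree))
    }
    writeLines(lines, txt_path)
  }
  invisible(NULL)
}

net_to_igraph <- function(net, partition = NULL, annotation = NULL) {
  g <- igraph::graph_from_data_frame(net$edges[, c("gene_a", "gene_b")],
                                     directed = FALSE,
                                     vertices = data.frame(name = net$nodes))
  igraph::E(g)$r <- net$edges$r
  igraph::E(g)$sign <- net$edges$sign
  if (!is.null(partition)) {
    mod <- partition$module_of[net$nodes]
    igraph::V(g)$module <- ifelse(is.na(mod), "", mod)
  }
  if (!is.null(annotation)) {
    cog <- annotation$cog[match(net$nodes, annotation$gene_id)]
    igraph::V(g)$cog <- ifelse(is.na(cog), "", cog)
  }
  g
}

#' Export network and node tables for external viewers
#'
#' Writes the edge list TSV (`gene_a`, `gene_b`, `r`, `sign`), a
#' node-attribute TSV (`gene_id`, `module_id`, `degree`, `cog`), a simple
#' interaction format (SIF) file and a GML graph file.
#'
#' @param net a `coexpr_network`.
#' @param prefix output path prefix; files get suffixes `_edges.tsv`,
#'   `_nodes.tsv`, `.sif`, `.gml`.
#' @param partition optional `module_partition` for node attributes.
#' @param annotation optional annotation for node attributes.
#' @return invisibly, the vector of files written.
#' @export
export_network <- function(net, prefix, partition = NULL,
                           annotation = NULL) {
  stopifnot(inherits(net, "coexpr_network"))
  edges_path <- paste0(prefix, "_edges.tsv")
  utils::write.table(net$edges, edges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  deg <- network_degree(net)
  nodes <- data.frame(
    gene_id = net$nodes,
    module_id = if (is.null(partition)) NA_character_ else
      unname(partition$module_of[net$nodes]),
    degree = as.integer(deg[net$nodes]),
    cog = if (is.null(annotation)) NA_character_ else
      annotation$cog[match(net$nodes, annotation$gene_id)],
    stringsAsFactors = FALSE)
  nodes_path <- paste0(prefix, "_nodes.tsv")
  utils::write.table(nodes, nodes_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  sif_path <- paste0(prefix, ".sif")
  writeLines(sprintf("%s cor %s", net$edges$gene_a, net$edges$gene_b),
             sif_path)
  gml_path <- paste0(prefix, ".gml")
  igraph::write_graph(net_to_igraph(net, partition, annotation), gml_path,
                      format = "gml")
  invisible(c(edges_path, nodes_path, sif_path, gml_path))
}
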