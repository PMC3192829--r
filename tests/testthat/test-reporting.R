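module138 <- function() {
  # 138 members: top-3 COG categories hold 19 + 19 + 12 = 50 genes, 54
  # genes sit in other categories, 34 are unannotated
  genes <- sprintf("m%03d", 1:138)
  cog <- c(rep("G", 19), rep("C", 19), rep("E", 12),
           rep(c("J", "K", "L", "M", "O", "P"), each = 9),
           rep(NA, 34))
  list(genes = genes,
       ann = data.frame(gene_id = genes, cog = cog,
                        is_negative_control = FALSE))
}

test_that("module COG composition reproduces the printed percentage styles", {
  fx <- module138()
  comp <- cog_composition(fx$genes, fx$ann, top_k = 3)
  expect_equal(unname(comp$cog_counts[comp$major_categories]),
               c(19L, 19L, 12L))
  expect_equal(comp$major_cog_fraction, 36.2)
  expect_identical(comp$major_cog_display, "36%")
  other <- sum(comp$cog_counts) - sum(comp$cog_counts[comp$major_categories])
  expect_equal(other, 54L)
  expect_equal(round_half_away(100 * other / 138, 1), 39.1)
})

test_that("category percentages sum to 100 within rounding slack", {
  fx <- module138()
  comp <- cog_composition(fx$genes, fx$ann)
  pct <- round_half_away(100 * comp$cog_counts / 138, 1)
  unann <- round_half_away(100 * (138 - sum(comp$cog_counts)) / 138, 1)
  n_cat <- length(pct) + 1L
  expect_lte(abs(sum(pct) + unann - 100), 0.1 * n_cat)
})

test_that("a module with no annotated members reports empty composition", {
  ann <- data.frame(gene_id = c("x1", "x2"), cog = NA_character_,
                    is_negative_control = FALSE)
  comp <- cog_composition(c("x1", "x2"), ann)
  expect_length(comp$cog_counts, 0L)
  expect_equal(comp$major_cog_fraction, 0)
})

test_that("hub ranking orders by degree then gene id", {
  leaves <- sprintf("l%02d", 1:6)
  star <- make_net(rep("c0", 6), leaves)
  top <- hub_ranking(star, 3)
  expect_identical(top$gene_id[1], "c0")
  expect_equal(top$degree[1], 6L)

  tied <- make_net(c("a1", "a1", "a2", "a2", "a1", "a2", "b1", "b2"),
                   c("b1", "b2", "b3", "b4", "z1", "z2", "b9", "b9"))
  tt <- hub_ranking(tied, 2)
  expect_identical(tt$gene_id, c("a1", "a2"))
  expect_equal(tt$degree, c(3L, 3L))
})

test_that("planted hubs out-connect their module peers near the cutoff shoulder", {
  run <- preset_run(1)
  net <- build_network(run$cm, 0.97)
  deg <- network_degree(net)
  hubs <- run$sim$truth$hubs
  hits <- 0L
  for (m in names(hubs)) {
    members <- intersect(names(which(run$sim$truth$module == m)), names(deg))
    hits <- hits + (members[which.max(deg[members])] %in% hubs[[m]])
  }
  expect_gte(hits / length(hubs), 0.8)
})

test_that("inter-module link counts are symmetric and flag standalones", {
  edges <- rbind(clique_edges(paste0("a", 1:5)),
                 clique_edges(paste0("b", 1:5)))
  net <- make_net(edges$gene_a, edges$gene_b)
  p <- fast_greedy_modules(net)
  iml <- inter_module_links(net, p)
  expect_true(all(iml == 0L))
  expect_true(all(attr(iml, "standalone")))

  bridged <- rbind(edges, data.frame(gene_a = "a1", gene_b = "b1",
                                     r = 0.95, sign = "+"))
  net2 <- make_net(bridged$gene_a, bridged$gene_b)
  p2 <- fast_greedy_modules(net2)
  iml2 <- inter_module_links(net2, p2)
  expect_identical(iml2, t(iml2))
  expect_equal(sum(iml2), 2L)
  expect_equal(unname(attr(iml2, "interaction_degree")), c(1L, 1L))
  expect_true(all(diag(iml2) == 0L))
})

test_that("planted cross-module correlation makes exactly those modules interact", {
  spec <- synthetic_spec(
    n_genes = 80,
    modules = list(planted_module("A", 20, mean_shift = 0),
                   planted_module("B", 20, mean_shift = 0),
                   planted_module("C", 15, mean_shift = 0)),
    cross_links = data.frame(module_a = "A", module_b = "B", weight = 0.85),
    seed = 6)
  sim <- simulate_expression(spec)
  cm <- pearson_matrix(sim$expr)
  net <- build_network(cm, 0.85)
  mod <- sim$truth$module
  truth_part <- structure(list(
    assignment = setNames(match(mod[net$nodes], c("A", "B", "C")),
                          net$nodes),
    modularity_q = NA_real_,
    modules = lapply(split(net$nodes, mod[net$nodes]), sort),
    module_of = setNames(mod[net$nodes], net$nodes),
    unassigned = character(0), min_module_size = 5L),
    class = "module_partition")
  iml <- inter_module_links(net, truth_part)
  standalone <- attr(iml, "standalone")
  expect_true(standalone[["C"]])
  expect_false(standalone[["A"]])
  expect_false(standalone[["B"]])
  expect_gt(iml["A", "B"], 0L)
  expect_equal(iml["A", "C"] + iml["B", "C"], 0L)
})

test_that("first neighbors induce the subgraph of seeds plus direct contacts", {
  net <- make_net(c("n1", "n2", "n2", "o1", "s1", "s1"),
                  c("s1", "s1", "o1", "p1", "z9", "z8"))
  fn <- first_neighbors(net, "s1")
  expect_setequal(fn$nodes, c("s1", "n1", "n2", "z8", "z9"))
  expect_equal(nrow(fn$edges), 4L)  # o1-p1 and n2-o1 dropped with o1
  # an edge between two non-seed neighbors is retained
  net2 <- make_net(c("a1", "a1", "b1"), c("b1", "b2", "b2"))
  fn2 <- first_neighbors(net2, "a1")
  expect_true(any(fn2$edges$gene_a == "b1" & fn2$edges$gene_b == "b2"))
  # idempotence when re-seeded with its own node set
  again <- first_neighbors(fn, fn$nodes)
  expect_identical(again$edges, fn$edges)
  expect_warning(first_neighbors(net, c("s1", "ghost")), "ghost")
  expect_error(suppressWarnings(first_neighbors(net, "ghost")), "no seed")
})

test_that("run reports are reproducible apart from the timestamp", {
  run_once <- function() {
    spec <- synthetic_spec(
      n_genes = 120,
      modules = list(planted_module("A", 25), planted_module("B", 15)),
      n_negative_controls = 4, seed = 3)
    sim <- simulate_expression(spec)
    cm <- pearson_matrix(sim$expr)
    net <- build_network(cm, 0.9)
    p <- fast_greedy_modules(net)
    run_report(expr = sim$expr, net = net, partition = p,
               annotation = sim$annotation, seed = 3, config = spec)
  }
  r1 <- run_once(); r2 <- run_once()
  td <- withr::local_tempdir()
  f1 <- file.path(td, "r1.json"); f2 <- file.path(td, "r2.json")
  write_report(r1, f1, file.path(td, "r1.txt"))
  write_report(r2, f2, file.path(td, "r2.txt"))
  strip <- function(f) grep("timestamp", readLines(f), value = TRUE,
                            invert = TRUE)
  expect_identical(strip(f1), strip(f2))
  expect_identical(strip(file.path(td, "r1.txt")),
                   strip(file.path(td, "r2.txt")))
  expect_equal(r1$genes_on_array, 120L)
  expect_equal(r1$negative_controls, 4L)
  expect_equal(r1$n_modules, 2L)
})

test_that("an empty network yields a null-module report with a warning note", {
  spec <- synthetic_spec(n_genes = 30, modules = list(), seed = 1)
  sim <- simulate_expression(spec)
  cm <- pearson_matrix(sim$expr)
  net <- build_network(cm, 0.999)
  rep0 <- run_report(expr = sim$expr, net = net, seed = 1)
  expect_equal(rep0$genes_in_network, 0L)
  expect_null(rep0$n_modules)
  expect_match(rep0$warnings, "empty")
})

test_that("network exports write edge, node, SIF and GML files", {
  edges <- clique_edges(paste0("g", 1:4))
  net <- make_net(edges$gene_a, edges$gene_b)
  p <- fast_greedy_modules(net, min_module_size = 3)
  ann <- data.frame(gene_id = paste0("g", 1:4), cog = "G",
                    is_negative_control = FALSE)
  td <- withr::local_tempdir()
  files <- export_network(net, file.path(td, "net"), partition = p,
                          annotation = ann)
  expect_true(all(file.exists(files)))
  ed <- read.delim(files[1])
  expect_equal(nrow(ed), 6L)
  nd <- read.delim(files[2])
  expect_setequal(nd$gene_id, paste0("g", 1:4))
  expect_true(all(nd$degree == 3L))
  g <- igraph::read_graph(files[4], format = "gml")
  expect_equal(igraph::vcount(g), 4L)
  expect_equal(igraph::ecount(g), 6L)
})
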