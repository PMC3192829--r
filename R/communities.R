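#' Newman modularity of a partition, recomputed from scratch
#'
#' `Q = sum_c [ l_c / m - (d_c / 2m)^2 ]` with `l_c` the number of
#' intra-community edges, `d_c` the total degree of community `c` and `m`
#' the number of edges; edges are unweighted and undirected.
#'
#' @param assignment named vector mapping node id to community label.
#' @param edges data.frame with columns `gene_a`, `gene_b`.
#' @return modularity Q in \[-0.5, 1\].
#' @export
modularity_q <- function(assignment, edges) {
  m <- nrow(edges)
  if (m == 0L) stop("no edges")
  ca <- assignment[edges$gene_a]
  cb <- assignment[edges$gene_b]
  if (anyNA(ca) || anyNA(cb)) stop("assignment does not cover all endpoints")
  comms <- unique(assignment)
  l_c <- table(factor(ca[ca == cb], levels = comms))
  d_c <- table(factor(c(ca, cb), levels = comms))
  sum(as.numeric(l_c) / m - (as.numeric(d_c) / (2 * m))^2)
}

#' Fast greedy modularity optimization
#'
#' Agglomerative community detection: every node starts as a singleton
#' community; at each step the pair of connected communities whose merge
#' yields the largest modularity gain `dQ = l_ij/m - d_i d_j / (2 m^2)` is
#' merged, until no merge increases Q. Ties in dQ (within 1e-12) are broken
#' by merging the pair whose canonical labels (smallest member gene id of
#' each community) sort lexicographically lowest, making the result
#' deterministic. Edges are treated as unweighted and undirected.
#'
#' @param net a [build_network()] result with at least one edge.
#' @param min_module_size communities below this size are reported as
#'   unassigned rather than as modules (default 5: a module is a group of
#'   more than four genes).
#' @return object of class `module_partition`: `assignment` (node ->
#'   community integer), `modularity_q`, `modules` (module id -> member
#'   genes, numbered by decreasing size), `module_of`, `unassigned`,
#'   `min_module_size`.
#' @export
fast_greedy_modules <- function(net, min_module_size = 5L) {
  stopifnot(inherits(net, "coexpr_network"))
  nodes <- net$nodes
  n <- length(nodes)
  m <- nrow(net$edges)
  if (n == 0L || m == 0L) stop("empty network")
  ia <- match(net$edges$gene_a, nodes)
  ib <- match(net$edges$gene_b, nodes)

  # community-pair edge counts (diagonal = intra), community degrees
  L <- matrix(0, n, n)
  for (e in seq_len(m)) {
    L[ia[e], ib[e]] <- L[ia[e], ib[e]] + 1
    L[ib[e], ia[e]] <- L[ib[e], ia[e]] + 1
  }
  d <- rowSums(L)
  alive <- rep(TRUE, n)
  label <- nodes  # canonical label: smallest member gene id
  comm <- seq_len(n)
  q <- sum(-(d / (2 * m))^2)  # all-singleton partition (l_c = 0)

  dq <- L / m - outer(d, d) / (2 * m^2)
  diag(dq) <- -Inf

  repeat {
    best <- max(dq)
    if (!is.finite(best) || best <= 0) break
    cand <- which(dq >= best - 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    lo <- pmin(label[cand[, 1L]], label[cand[, 2L]])
    hi <- pmax(label[cand[, 1L]], label[cand[, 2L]])
    pick <- order(lo, hi)[1L]
    i <- cand[pick, 1L]; j <- cand[pick, 2L]
    q <- q + dq[i, j]
    # merge j into i
    L[i, i] <- L[i, i] + L[j, j] + L[i, j]
    ks <- setdiff(which(alive), c(i, j))
    L[i, ks] <- L[i, ks] + L[j, ks]
    L[ks, i] <- L[i, ks]
    d[i] <- d[i] + d[j]
    label[i] <- min(label[i], label[j])
    alive[j] <- FALSE
    comm[comm == j] <- i
    L[j, ] <- 0; L[, j] <- 0
    dq[j, ] <- -Inf; dq[, j] <- -Inf
    dq[i, ks] <- L[i, ks] / m - d[i] * d[ks] / (2 * m^2)
    dq[ks, i] <- dq[i, ks]
    dq[i, i] <- -Inf
    if (sum(alive) == 1L) break
  }

  assignment <- stats::setNames(comm, nodes)
  structure(
    c(list(assignment = assignment, modularity_q = q),
      partition_tables(assignment, min_module_size)),
    class = "module_partition")
}

partition_tables <- function(assignment, min_module_size) {
  by_comm <- split(names(assignment), assignment)
  by_comm <- lapply(by_comm, sort)
  sizes <- lengths(by_comm)
  keep <- sizes >= min_module_size
  # number by decreasing size, ties by smallest member gene id
  kept <- by_comm[keep]
  if (length(kept) > 0L) {
    first_gene <- vapply(kept, `[[`, "", 1L)
    kept <- kept[order(-lengths(kept), first_gene)]
    names(kept) <- sprintf("M%02d", seq_along(kept))
  } else {
    kept <- stats::setNames(list(), character())
  }
  module_of <- stats::setNames(rep(NA_character_, length(assignment)),
                               names(assignment))
  for (id in names(kept)) module_of[kept[[id]]] <- id
  list(modules = kept, module_of = module_of,
       unassigned = sort(unlist(by_comm[!keep], use.names = FALSE)),
       min_module_size = as.integer(min_module_size))
}

#' Re-filter a partition at a different minimum module size
#'
#' Communities below `min_module_size` are moved to `unassigned`; surviving
#' modules are renumbered by decreasing size (ties by smallest member gene
#' id).
#'
#' @param p a `module_partition`.
#' @param min_module_size new minimum size.
#' @return a `module_partition`.
#' @export
filter_modules <- function(p, min_module_size) {
  stopifnot(inherits(p, "module_partition"))
  structure(
    c(list(assignment = p$assignment, modularity_q = p$modularity_q),
      partition_tables(p$assignment, min_module_size)),
    class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("module_partition: Q = %.4f, %d modules (>= %d genes), %d unassigned\n",
              x$modularity_q, length(x$modules), x$min_module_size,
              length(x$unassigned)))
  if (length(x$modules) > 0L) {
    cat("  sizes:", paste(lengths(x$modules), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Compare a partition against planted ground truth
#'
#' Adjusted Rand index between the detected community assignment and the
#' planted module labels, restricted to planted-module members present in
#' the network, plus the fraction of all planted members that ended up in
#' some reported module.
#'
#' @param p a `module_partition`.
#' @param truth the `truth` element of [simulate_expression()].
#' @return list with `ari` and `recovered_fraction`.
#' @export
partition_quality <- function(p, truth) {
  stopifnot(inherits(p, "module_partition"))
  planted <- names(truth$module)[!is.na(truth$module)]
  present <- intersect(planted, names(p$assignment))
  if (length(present) == 0L) {
    stop("no planted-module gene appears in the partition")
  }
  ari <- mclust::adjustedRandIndex(p$assignment[present],
                                   truth$module[present])
  in_module <- planted %in% unlist(p$modules, use.names = FALSE)
  list(ari = ari, recovered_fraction = mean(in_module))
}
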