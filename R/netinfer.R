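#' Pairwise-complete Pearson correlation matrix
#'
#' Computes the sample Pearson correlation for every gene pair over the
#' samples where both genes are quantifiable (mask true). Pairs with fewer
#' than `min_pairs` shared samples, or involving a gene with zero variance
#' over its usable samples, are flagged unusable and never become edges.
#'
#' @param x an [expression_matrix()] with at least 3 samples.
#' @param min_pairs minimum shared quantifiable samples per pair
#'   (default 9, about a quarter of the 33-array design; below this the
#'   high-cutoff correlations are dominated by small-sample noise).
#' @return object of class `corr_matrix`: `genes`, `r` (NA where unusable),
#'   `n_pairs`, `usable`, `min_pairs`.
#' @export
pearson_matrix <- function(x, min_pairs = 9L) {
  stopifnot(inherits(x, "expr_matrix"))
  if (nrow(x$design) < 3L) stop("need at least 3 samples")
  v <- x$values
  v[!x$mask] <- NA_real_
  r <- suppressWarnings(stats::cor(t(v), use = "pairwise.complete.obs"))
  n_pairs <- tcrossprod(x$mask * 1L)
  usable <- n_pairs >= min_pairs & !is.na(r)
  diag(usable) <- TRUE
  r[!usable] <- NA_real_
  diag(r) <- 1
  storage.mode(n_pairs) <- "integer"
  structure(list(genes = x$genes, r = r, n_pairs = n_pairs, usable = usable,
                 min_pairs = as.integer(min_pairs)),
            class = "corr_matrix")
}

#' Nearest-neighbour spacing statistics of an eigenvalue spectrum
#'
#' Implements the random-matrix-theory diagnostic: eigenvalues are sorted,
#' near-degenerate values (gap < `dedup_tol`) collapsed, and the spectrum
#' unfolded through a monotone cubic spline fitted to the empirical
#' cumulative spectral distribution (about one knot per 20 eigenvalues), so
#' that the mean nearest-neighbour spacing is 1. The unfolded spacings are
#' then binned on \[0, 3\] and tested by chi-square against the Poisson law
#' `P(s) = exp(-s)` (independent spectra, modular structure) and the Wigner
#' surmise `P(s) = (pi s / 2) exp(-pi s^2 / 4)` (GOE, one mixed system).
#'
#' @param eigenvalues numeric vector.
#' @param min_eigs minimum spectrum size after degeneracy removal
#'   (default 100).
#' @param n_bins number of equal bins on \[0, 3\] (default 20); bins with
#'   expected count below 5 are merged from the right.
#' @param dedup_tol near-degeneracy tolerance (default 1e-8).
#' @return list: `unfolded_spacings`, `chi2_poisson`, `chi2_goe`,
#'   `p_poisson`, `p_goe`, `n_spacings`, `n_eigs`.
#' @export
nnsd_statistics <- function(eigenvalues, min_eigs = 100L, n_bins = 20L,
                            dedup_tol = 1e-8) {
  e <- sort(eigenvalues[is.finite(eigenvalues)])
  if (length(e) > 1L) e <- e[c(TRUE, diff(e) >= dedup_tol)]
  n <- length(e)
  if (n < min_eigs) {
    stop(sprintf(paste0("only %d distinct eigenvalues (< %d); use a denser ",
                        "matrix or a lower threshold"), n, min_eigs))
  }
  # monotone cubic spline through every ~20th point of the empirical CDF
  k <- max(6L, ceiling(n / 20))
  idx <- unique(round(seq(1L, n, length.out = k)))
  fhat <- stats::splinefun(e[idx], idx / n, method = "hyman")
  unfolded <- n * pmin(pmax(fhat(e), 0), 1)
  s <- diff(unfolded)
  chi2_for <- function(cdf) {
    breaks <- seq(0, 3, length.out = n_bins + 1L)
    obs <- as.vector(table(cut(s[s >= 0 & s <= 3], breaks,
                               include.lowest = TRUE)))
    p_bin <- diff(cdf(breaks))
    p_bin <- p_bin / sum(p_bin)  # condition on s in [0, 3]
    expd <- sum(obs) * p_bin
    while (length(obs) > 2L && expd[length(expd)] < 5) {
      m <- length(obs)
      obs[m - 1L] <- obs[m - 1L] + obs[m]
      expd[m - 1L] <- expd[m - 1L] + expd[m]
      obs <- obs[-m]; expd <- expd[-m]
    }
    chi2 <- sum((obs - expd)^2 / expd)
    list(chi2 = chi2,
         p = stats::pchisq(chi2, df = length(obs) - 1L, lower.tail = FALSE))
  }
  pois <- chi2_for(function(q) 1 - exp(-q))
  goe <- chi2_for(function(q) 1 - exp(-pi * q^2 / 4))
  list(unfolded_spacings = s, chi2_poisson = pois$chi2, chi2_goe = goe$chi2,
       p_poisson = pois$p, p_goe = goe$p, n_spacings = length(s), n_eigs = n)
}

threshold_adjacency <- function(cm, tau, mode, binary = FALSE) {
  strength <- if (mode == "abs") abs(cm$r) else cm$r
  keep <- !is.na(strength) & strength >= tau & cm$usable
  diag(keep) <- FALSE
  a <- if (binary) keep * 1 else ifelse(keep, cm$r, 0)
  a[is.na(a)] <- 0
  a
}

#' Scan correlation cutoffs for the Poisson transition of the spectrum
#'
#' For each candidate cutoff tau, builds the thresholded (weighted)
#' adjacency matrix, takes the eigenvalues of its non-isolated part, and
#' computes [nnsd_statistics()]. The selected cutoff is the smallest tau
#' whose spacing distribution is accepted as Poisson (`p_poisson >
#' p_accept`) and that stays accepted over the next `stability_window`
#' evaluable candidates, so that an isolated false acceptance cannot be
#' selected and an isolated false rejection high in the grid (where the
#' spectrum is smallest and the chi-square test noisiest) cannot veto a
#' uniform acceptance plateau; if no tau qualifies, the largest grid value
#' is returned with `warning_flag = TRUE`. Candidates whose spectrum
#' shrinks below `min_eigs` distinct eigenvalues are recorded but not
#' evaluated.
#'
#' @param cm a [pearson_matrix()] result.
#' @param tau_grid ascending cutoffs in (0, 1); default 0.70-0.99 by 0.01.
#' @param mode `"abs"` thresholds on |r| (default; spectral statistics
#'   concern magnitude structure), `"positive"` on signed r.
#' @param p_accept Poisson acceptance level (default 0.001).
#' @param min_eigs,n_bins passed to [nnsd_statistics()].
#' @param stability_window how many consecutive evaluable candidates after
#'   a cutoff must also be accepted (default 5).
#' @param binary use the 0/1 adjacency instead of the r-weighted one.
#' @return object of class `threshold_scan`: `candidates` data.frame (tau,
#'   n_nodes, n_edges, n_eigs, chi2_poisson, chi2_goe, p_poisson, p_goe,
#'   accepted), `spacings` (list per candidate), `selected_tau`,
#'   `warning_flag`, `p_accept`, `mode`.
#' @export
rmt_threshold_scan <- function(cm, tau_grid = seq(0.70, 0.99, by = 0.01),
                               mode = c("abs", "positive"), p_accept = 0.001,
                               min_eigs = 100L, n_bins = 20L,
                               stability_window = 5L, binary = FALSE) {
  stopifnot(inherits(cm, "corr_matrix"))
  mode <- match.arg(mode)
  if (length(tau_grid) == 0L) stop("empty tau grid")
  if (is.unsorted(tau_grid, strictly = TRUE) ||
      any(tau_grid <= 0 | tau_grid >= 1)) {
    stop("tau_grid must be strictly ascending within (0, 1)")
  }
  rows <- vector("list", length(tau_grid))
  spacings <- vector("list", length(tau_grid))
  for (i in seq_along(tau_grid)) {
    a <- threshold_adjacency(cm, tau_grid[i], mode, binary)
    deg <- rowSums(a != 0)
    keep <- deg > 0
    n_edges <- sum(a != 0) / 2
    stats_i <- list(chi2_poisson = NA_real_, chi2_goe = NA_real_,
                    p_poisson = NA_real_, p_goe = NA_real_, n_eigs = NA_integer_)
    if (sum(keep) >= 2L) {
      # isolated nodes only add exact-zero eigenvalues, which degeneracy
      # removal collapses; the non-isolated submatrix is spectrally exact
      ev <- eigen(a[keep, keep, drop = FALSE], symmetric = TRUE,
                  only.values = TRUE)$values
      res <- tryCatch(nnsd_statistics(ev, min_eigs = min_eigs,
                                      n_bins = n_bins),
                      error = function(e) NULL)
      if (!is.null(res)) {
        stats_i <- res
        spacings[[i]] <- res$unfolded_spacings
      }
    }
    rows[[i]] <- data.frame(
      tau = tau_grid[i], n_nodes = sum(keep), n_edges = n_edges,
      n_eigs = stats_i$n_eigs, chi2_poisson = stats_i$chi2_poisson,
      chi2_goe = stats_i$chi2_goe, p_poisson = stats_i$p_poisson,
      p_goe = stats_i$p_goe,
      accepted = if (is.na(stats_i$p_poisson)) NA else
        stats_i$p_poisson > p_accept)
  }
  cand <- do.call(rbind, rows)
  evaluable <- which(!is.na(cand$accepted))
  selected <- NA_real_
  for (k in seq_along(evaluable)) {
    window <- evaluable[k:min(k + stability_window, length(evaluable))]
    if (all(cand$accepted[window])) {
      selected <- cand$tau[evaluable[k]]
      break
    }
  }
  warning_flag <- is.na(selected)
  if (warning_flag) {
    selected <- max(tau_grid)
    warning("no cutoff reached a stable Poisson acceptance; ",
            "returning the largest grid value")
  }
  structure(list(candidates = cand, spacings = spacings,
                 selected_tau = selected, warning_flag = warning_flag,
                 p_accept = p_accept, mode = mode),
            class = "threshold_scan")
}

#' @export
print.threshold_scan <- function(x, ...) {
  cat(sprintf("threshold_scan (%s mode): %d candidates, selected tau = %.2f%s\n",
              x$mode, nrow(x$candidates), x$selected_tau,
              if (x$warning_flag) " [no stable acceptance]" else ""))
  invisible(x)
}

#' Build the co-expression network at a correlation cutoff
#'
#' Connects every usable gene pair whose correlation passes the cutoff
#' (`r >= tau` in positive mode, the reported-network convention;
#' `|r| >= tau` in abs mode). Isolated genes are not nodes.
#'
#' @param cm a [pearson_matrix()] result.
#' @param tau cutoff in (0, 1).
#' @param mode `"positive"` (default) or `"abs"`.
#' @return object of class `coexpr_network`: `nodes`, `edges` data.frame
#'   (`gene_a` < `gene_b`, `r`, `sign`), `tau`, `mode`.
#' @export
build_network <- function(cm, tau, mode = c("positive", "abs")) {
  stopifnot(inherits(cm, "corr_matrix"), tau > 0, tau < 1)
  mode <- match.arg(mode)
  a <- threshold_adjacency(cm, tau, mode)
  idx <- which(upper.tri(a) & a != 0, arr.ind = TRUE)
  # canonical order: gene_a is the lexicographically smaller id
  ga <- cm$genes[idx[, 1L]]
  gb <- cm$genes[idx[, 2L]]
  swap <- ga > gb
  tmp <- ga[swap]; ga[swap] <- gb[swap]; gb[swap] <- tmp
  r <- a[idx]
  o <- order(ga, gb)
  edges <- data.frame(gene_a = ga[o], gene_b = gb[o], r = r[o],
                      sign = ifelse(r[o] >= 0, "+", "-"),
                      stringsAsFactors = FALSE)
  structure(list(nodes = sort(unique(c(edges$gene_a, edges$gene_b))),
                 edges = edges, tau = tau, mode = mode),
            class = "coexpr_network")
}

#' Construct a co-expression network from an edge table
#'
#' Validates and canonicalizes an edge list (for example one re-read from
#' an exported edge TSV): no self edges, endpoints in `gene_a < gene_b`
#' order, no duplicate pairs, signs consistent with `r`.
#'
#' @param edges data.frame with columns `gene_a`, `gene_b`, `r`.
#' @param tau the cutoff the edges came from.
#' @param mode `"positive"` or `"abs"`.
#' @return a `coexpr_network`.
#' @export
coexpression_network <- function(edges, tau, mode = "positive") {
  stopifnot(all(c("gene_a", "gene_b", "r") %in% names(edges)))
  if (any(edges$gene_a == edges$gene_b)) stop("self edges are not allowed")
  ga <- pmin(edges$gene_a, edges$gene_b)
  gb <- pmax(edges$gene_a, edges$gene_b)
  if (anyDuplicated(paste(ga, gb))) stop("duplicate edges")
  o <- order(ga, gb)
  edges <- data.frame(gene_a = ga[o], gene_b = gb[o], r = edges$r[o],
                      sign = ifelse(edges$r[o] >= 0, "+", "-"),
                      stringsAsFactors = FALSE)
  structure(list(nodes = sort(unique(c(ga, gb))), edges = edges,
                 tau = tau, mode = mode),
            class = "coexpr_network")
}

#' @export
print.coexpr_network <- function(x, ...) {
  cat(sprintf("coexpr_network: %d nodes, %d edges (tau = %.2f, %s mode)\n",
              length(x$nodes), nrow(x$edges), x$tau, x$mode))
  invisible(x)
}

#' Node degrees of a co-expression network
#' @param net a `coexpr_network`.
#' @return named integer vector over the network's nodes.
#' @export
network_degree <- function(net) {
  stopifnot(inherits(net, "coexpr_network"))
  tab <- table(factor(c(net$edges$gene_a, net$edges$gene_b),
                      levels = net$nodes))
  stats::setNames(as.integer(tab), names(tab))
}
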