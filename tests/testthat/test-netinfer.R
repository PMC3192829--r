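corr_of <- function(rows, min_pairs = 3L) {
  v <- do.call(rbind, rows)
  dimnames(v) <- list(names(rows), paste0("s", seq_len(ncol(v))))
  pearson_matrix(make_expr(v), min_pairs = min_pairs)
}

test_that("pearson correlations match closed forms and a naive oracle", {
  cm <- corr_of(list(x = c(1, 2, 3), y = c(2, 4, 6), z = c(3, 2, 1),
                     w = c(1, 3, 2)))
  expect_equal(cm$r["x", "y"], 1.0, tolerance = 1e-12)
  expect_equal(cm$r["x", "z"], -1.0, tolerance = 1e-12)
  expect_equal(cm$r["x", "w"], 0.5, tolerance = 1e-12)

  set.seed(42)
  v <- matrix(rnorm(8 * 12), 8, dimnames = list(paste0("g", 1:8),
                                                paste0("s", 1:12)))
  mask <- matrix(runif(96) > 0.15, 8, 12)
  snr <- matrix(10, 8, 12, dimnames = dimnames(v)); snr[!mask] <- 1
  cm2 <- pearson_matrix(make_expr(v, snr = snr), min_pairs = 3)
  for (i in 1:7) for (j in (i + 1):8) {
    vi <- v[i, ]; vi[!mask[i, ]] <- NA
    vj <- v[j, ]; vj[!mask[j, ]] <- NA
    expect_equal(cm2$r[i, j], naive_pearson(vi, vj), tolerance = 1e-12)
    expect_equal(cm2$n_pairs[i, j], sum(mask[i, ] & mask[j, ]))
  }
})

test_that("thin pairs and zero-variance genes are unusable, not NaN edges", {
  v <- rbind(a = c(1, 2, 3, 4, 5, 6), b = c(2, 1, 3, 5, 4, 6),
             flat = c(1, 1, 1, 1, 1, 1))
  colnames(v) <- paste0("s", 1:6)
  snr <- matrix(10, 3, 6, dimnames = dimnames(v))
  snr["b", 4:6] <- 1  # only 3 shared samples with a
  cm <- pearson_matrix(make_expr(v, snr = snr), min_pairs = 4)
  expect_false(cm$usable["a", "b"])
  expect_true(is.na(cm$r["a", "b"]))
  expect_false(cm$usable["a", "flat"])
  net <- build_network(cm, 0.9)
  expect_equal(nrow(net$edges), 0L)
})

test_that("unfolded spacings have mean 1 and the chi-square calls the law", {
  set.seed(7)
  ev <- cumsum(rexp(2000))
  s <- nnsd_statistics(ev)
  expect_lt(abs(mean(s$unfolded_spacings) - 1), 0.05)
  expect_gt(s$p_poisson, 0.05)
  expect_lt(s$p_goe, 1e-6)

  goe <- matrix(rnorm(500^2), 500)
  goe <- (goe + t(goe)) / sqrt(2)
  sg <- nnsd_statistics(eigen(goe, symmetric = TRUE, only.values = TRUE)$values)
  expect_lt(abs(mean(sg$unfolded_spacings) - 1), 0.05)
  expect_gt(sg$p_goe, 0.001)
  expect_lt(sg$p_poisson, 0.001)

  bm <- matrix(0, 400, 400)
  for (b in 0:9) {
    idx <- b * 40 + 1:40
    x <- matrix(rnorm(1600), 40)
    bm[idx, idx] <- (x + t(x)) / sqrt(2)
  }
  sb <- nnsd_statistics(eigen(bm, symmetric = TRUE, only.values = TRUE)$values)
  expect_gt(sb$p_poisson, 0.001)
  expect_lt(sb$p_goe, 1e-6)

  expect_error(nnsd_statistics(rnorm(50)), "denser matrix|lower")
})

test_that("near-degenerate eigenvalues are collapsed before unfolding", {
  ev <- c(rep(0, 300), cumsum(rexp(600)) + 1)
  s <- nnsd_statistics(ev)
  expect_equal(s$n_eigs, 601L)
})

test_that("edges are monotone in the cutoff and the grid scan reflects it", {
  spec <- synthetic_spec(
    n_genes = 80,
    modules = list(planted_module("A", 25, mean_shift = 0,
                                  within_correlation = 0.9)),
    seed = 13)
  cm <- pearson_matrix(simulate_expression(spec)$expr)
  taus <- c(0.3, 0.5, 0.7, 0.9)
  edge_sets <- lapply(taus, function(t) {
    e <- build_network(cm, t, mode = "abs")$edges
    paste(e$gene_a, e$gene_b)
  })
  for (k in 2:length(taus)) {
    expect_true(all(edge_sets[[k]] %in% edge_sets[[k - 1]]))
  }
})

test_that("thresholding a toy triangle at 0.94 keeps the two strong edges", {
  v <- diag(3)
  r <- matrix(c(1, 0.95, 0.93, 0.95, 1, 0.96, 0.93, 0.96, 1), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  cm <- structure(list(genes = c("a", "b", "c"), r = r,
                       n_pairs = matrix(33L, 3, 3), usable = r > -2,
                       min_pairs = 9L),
                  class = "corr_matrix")
  net <- build_network(cm, 0.94)
  expect_equal(nrow(net$edges), 2L)
  expect_length(net$nodes, 3L)
  none <- build_network(cm, 0.99)
  expect_equal(nrow(none$edges), 0L)
  expect_length(none$nodes, 0L)
})

test_that("a pure-noise matrix yields no stable modular structure", {
  spec <- synthetic_spec(n_genes = 300, modules = list(), seed = 2)
  cm <- pearson_matrix(simulate_expression(spec)$expr)
  scan <- suppressWarnings(
    rmt_threshold_scan(cm, tau_grid = seq(0.70, 0.90, 0.05)))
  n_pairs_total <- choose(300, 2)
  sel <- scan$candidates[scan$candidates$tau == scan$selected_tau, ]
  expect_true(scan$warning_flag || sel$n_edges <= 0.01 * n_pairs_total)
})

test_that("the scan recovers a planted GOE-to-Poisson transition", {
  # two regimes glued block-diagonally: 12 independent 30-gene modules
  # whose spectra superpose to Poisson once inter-block noise is cut
  spec <- synthetic_spec(
    n_genes = 450,
    modules = lapply(1:12, function(k)
      planted_module(sprintf("B%02d", k), 30, mean_shift = 0,
                     within_correlation = 0.9)),
    seed = 5)
  sim <- simulate_expression(spec)
  cm <- pearson_matrix(sim$expr)
  scan <- rmt_threshold_scan(cm, tau_grid = seq(0.30, 0.85, 0.05))
  expect_false(scan$warning_flag)
  expect_true(scan$selected_tau %in% scan$candidates$tau)
  cand <- scan$candidates
  expect_true(all(diff(cand$n_edges) <= 0))
  # below the selected cutoff the spacing law must have been non-Poisson
  below <- cand[cand$tau < scan$selected_tau & !is.na(cand$accepted), ]
  if (nrow(below) > 0) expect_false(all(below$accepted))
})
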