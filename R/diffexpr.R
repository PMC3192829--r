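cond_columns <- function(x, substrate, phase) {
  which(x$design$substrate == substrate & x$design$phase == phase)
}

row_stats <- function(vals, mask) {
  n <- rowSums(mask)
  v <- vals
  v[!mask] <- NA_real_
  m <- rowMeans(v, na.rm = TRUE)
  m[n == 0L] <- NA_real_
  s <- apply(v, 1L, stats::sd, na.rm = TRUE)  # n-1 denominator
  s[n < 2L] <- NA_real_
  list(n = n, mean = m, sd = s)
}

#' Replicate summary and significance calls for one condition
#'
#' Summarizes the biological replicates of a (substrate, phase) condition
#' per gene: mean log2 ratio, sample standard deviation (n-1 denominator)
#' and the replicate Z score `z = mean / (sd / sqrt(n))`. A gene is called
#' significant when `|mean| >= r_min` and `|z| >= z_min` with at least two
#' quantifiable replicates; the direction is the sign of the mean. With
#' `vs`, the call is made on the difference of two condition means, with a
#' Welch-form standard error `sqrt(s1^2/n1 + s2^2/n2)`.
#'
#' @param x an [expression_matrix()].
#' @param condition length-2 character vector `c(substrate, phase)`.
#' @param vs optional second condition to contrast against.
#' @param r_min minimum absolute mean log2 ratio (default 1.0).
#' @param z_min minimum absolute Z score (default 2.0).
#' @return data.frame (one row per gene): `gene_id`, `mean_log2R`,
#'   `sd_log2R`, `z`, `n_used`, `significant`, `direction`.
#' @export
summarize_contrast <- function(x, condition, vs = NULL, r_min = 1.0,
                               z_min = 2.0) {
  stopifnot(inherits(x, "expr_matrix"), length(condition) == 2L)
  cols <- cond_columns(x, condition[1L], condition[2L])
  if (length(cols) == 0L) {
    stop("condition not in design: ", condition_key(condition[1L], condition[2L]))
  }
  if (length(cols) < 2L) stop("condition has fewer than 2 replicates")
  a <- row_stats(x$values[, cols, drop = FALSE], x$mask[, cols, drop = FALSE])
  if (is.null(vs)) {
    mean_l <- a$mean
    sd_l <- a$sd
    n_used <- a$n
    z <- mean_l / (sd_l / sqrt(n_used))
  } else {
    stopifnot(length(vs) == 2L)
    cols2 <- cond_columns(x, vs[1L], vs[2L])
    if (length(cols2) < 2L) stop("reference condition absent or unreplicated")
    b <- row_stats(x$values[, cols2, drop = FALSE],
                   x$mask[, cols2, drop = FALSE])
    mean_l <- a$mean - b$mean
    sd_l <- sqrt(a$sd^2 + b$sd^2)
    n_used <- pmin(a$n, b$n)
    z <- mean_l / sqrt(a$sd^2 / a$n + b$sd^2 / b$n)
  }
  ok <- n_used >= 2L & !is.na(sd_l)
  z[!ok] <- NA_real_
  sig <- ok & !is.na(mean_l) & abs(mean_l) >= r_min & !is.na(z) &
    abs(z) >= z_min
  sig[is.na(sig)] <- FALSE
  direction <- ifelse(!sig, "none", ifelse(mean_l > 0, "up", "down"))
  if (all(n_used == 0L)) {
    warning("all replicates masked for every gene; empty call set")
  }
  data.frame(gene_id = x$genes, mean_log2R = mean_l, sd_log2R = sd_l, z = z,
             n_used = as.integer(n_used), significant = sig,
             direction = direction, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Count up- and downregulated genes in a call set
#'
#' @param calls output of [summarize_contrast()].
#' @return named integer vector `c(n_up, n_down)`.
#' @export
count_significant <- function(calls) {
  stopifnot(all(c("significant", "direction") %in% names(calls)))
  c(n_up = sum(calls$direction == "up"),
    n_down = sum(calls$direction == "down"))
}

#' Growth-phase expression profile and peak phase
#'
#' For one substrate's early/mid/late series, computes per gene the
#' replicate-mean log2 ratio at each phase (masked replicates excluded) and
#' the phase at which expression peaks. The peak is `undetermined` when
#' fewer than two phases are quantifiable or when the top two phase means
#' are within `tie_eps` of each other.
#'
#' @param x an [expression_matrix()].
#' @param substrate substrate whose time course to profile.
#' @param genes optional subset of gene ids (default all).
#' @param tie_eps tie tolerance on phase means (default 1e-9; only exact
#'   ties are ties on continuous data).
#' @return data.frame: `gene_id`, `early`, `mid`, `late`, `peak_phase`.
#' @export
peak_phase <- function(x, substrate, genes = NULL, tie_eps = 1e-9) {
  stopifnot(inherits(x, "expr_matrix"))
  phases <- intersect(PHASES, x$design$phase[x$design$substrate == substrate])
  if (length(phases) < 2L) {
    stop("substrate ", substrate, " has fewer than 2 phases in the design")
  }
  if (is.null(genes)) genes <- x$genes
  unknown <- setdiff(genes, x$genes)
  if (length(unknown) > 0L) {
    stop("unknown gene(s): ", paste(unknown, collapse = ", "))
  }
  rows <- match(genes, x$genes)
  phase_means <- sapply(PHASES, function(ph) {
    if (!ph %in% phases) return(rep(NA_real_, length(rows)))
    cols <- cond_columns(x, substrate, ph)
    st <- row_stats(x$values[rows, cols, drop = FALSE],
                    x$mask[rows, cols, drop = FALSE])
    st$mean
  })
  if (length(rows) == 1L) phase_means <- matrix(phase_means, nrow = 1L,
                                                dimnames = list(NULL, PHASES))
  peak <- apply(phase_means, 1L, function(v) {
    ok <- which(!is.na(v))
    if (length(ok) < 2L) return("undetermined")
    o <- ok[order(v[ok], decreasing = TRUE)]
    if (length(o) >= 2L && v[o[1L]] - v[o[2L]] <= tie_eps) return("undetermined")
    PHASES[o[1L]]
  })
  data.frame(gene_id = genes, early = phase_means[, "early"],
             mid = phase_means[, "mid"], late = phase_means[, "late"],
             peak_phase = peak, stringsAsFactors = FALSE, row.names = NULL)
}
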