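#' The 33-array substrate-by-phase study design
#'
#' Eleven (substrate, growth phase) conditions with three biological
#' replicates each: glucose, xylose, fructose and cellobiose at mid
#' exponential phase; the equimolar glucose+xylose condition at mid phase;
#' and early/mid/late exponential time courses for glucose, xylose and
#' glucose+xylose. Mid-phase conditions shared between the substrate view
#' and the time-course view are counted once, giving 33 arrays.
#'
#' @return A validated design data.frame with 33 rows.
#' @export
default_design <- function() {
  abbrev <- c(glucose = "G", xylose = "X", fructose = "F",
              cellobiose = "C", glucose_xylose = "GX")
  conds <- rbind(
    expand.grid(substrate = c("glucose", "xylose", "glucose_xylose"),
                phase = c("early", "mid", "late"),
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE),
    data.frame(substrate = c("fructose", "cellobiose"),
               phase = "mid", stringsAsFactors = FALSE)
  )
  conds <- conds[order(match(conds$substrate, SUBSTRATES),
                       match(conds$phase, PHASES)), ]
  design <- do.call(rbind, lapply(seq_len(nrow(conds)), function(i) {
    data.frame(
      sample_id = sprintf("%s_%s_%d", abbrev[[conds$substrate[i]]],
                          conds$phase[i], 1:3),
      substrate = conds$substrate[i], phase = conds$phase[i],
      replicate = 1:3, stringsAsFactors = FALSE)
  }))
  validate_design(design)
}

condition_key <- function(substrate, phase) paste(substrate, phase, sep = ":")

#' Describe one planted co-expression module
#'
#' @param module_id unique module label.
#' @param size number of member genes (>= 5).
#' @param responsive data.frame with columns `substrate`, `phase`: the
#'   conditions in which members are shifted by `mean_shift` log2 units
#'   (NULL = not condition-responsive).
#' @param mean_shift expected log2 ratio of members under responsive
#'   conditions (0 elsewhere).
#' @param within_correlation target pairwise Pearson correlation among
#'   members across the full sample axis, in \[0, 1).
#' @param n_hubs number of members given reduced unique noise so that they
#'   out-correlate, and hence out-connect, their peers.
#' @return A list describing the module.
#' @export
planted_module <- function(module_id, size, responsive = NULL,
                           mean_shift = 2.0, within_correlation = 0.95,
                           n_hubs = 0L) {
  stopifnot(size >= 5, within_correlation >= 0, within_correlation < 1,
            n_hubs >= 0, n_hubs <= size)
  if (!is.null(responsive)) {
    stopifnot(all(c("substrate", "phase") %in% names(responsive)))
    responsive$substrate <- as.character(responsive$substrate)
    responsive$phase <- as.character(responsive$phase)
  }
  list(module_id = as.character(module_id), size = as.integer(size),
       responsive = responsive, mean_shift = mean_shift,
       within_correlation = within_correlation, n_hubs = as.integer(n_hubs))
}

#' Specify a synthetic expression data set
#'
#' @param n_genes total gene rows, negative controls included
#'   (default 2322, the number of annotated genes covered by the array).
#' @param design sample design (default [default_design()], 33 arrays).
#' @param modules list of [planted_module()] descriptions.
#' @param n_negative_controls pure-noise control probes (default 20).
#' @param noise_sd total per-gene stochastic standard deviation on the log2
#'   scale (latent factor + unique noise; default 0.25).
#' @param snr_dropout_rate fraction of cells given SNR < 2 (unquantifiable).
#' @param cross_links optional data.frame (`module_a`, `module_b`, `weight`)
#'   planting shared latent variance between two modules; `weight` in (0,1)
#'   is the fraction of factor variance shared.
#' @param hub_noise_scale multiplier (< 1) on the unique-noise SD of hub
#'   genes.
#' @param seed RNG seed; the whole data set is a pure function of the spec.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes, design = default_design(),
                           modules = list(), n_negative_controls = 0L,
                           noise_sd = 0.25, snr_dropout_rate = 0,
                           cross_links = NULL, hub_noise_scale = 0.3,
                           seed = 1L) {
  design <- validate_design(design)
  ids <- vapply(modules, `[[`, "", "module_id")
  if (anyDuplicated(ids)) stop("module ids must be unique")
  sizes <- vapply(modules, `[[`, 0L, "size")
  if (sum(sizes) + n_negative_controls > n_genes) {
    stop("module sizes plus negative controls exceed n_genes")
  }
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (snr_dropout_rate < 0 || snr_dropout_rate >= 1) {
    stop("snr_dropout_rate must be in [0, 1)")
  }
  if (!is.null(cross_links)) {
    stopifnot(all(c("module_a", "module_b", "weight") %in% names(cross_links)))
    linked <- c(cross_links$module_a, cross_links$module_b)
    if (anyDuplicated(linked)) {
      stop("a module may appear in at most one cross link")
    }
    if (!all(linked %in% ids)) stop("cross link names an unknown module")
    if (any(cross_links$weight <= 0 | cross_links$weight >= 1)) {
      stop("cross link weights must lie in (0, 1)")
    }
  }
  structure(
    list(n_genes = as.integer(n_genes), design = design, modules = modules,
         n_negative_controls = as.integer(n_negative_controls),
         noise_sd = noise_sd, snr_dropout_rate = snr_dropout_rate,
         cross_links = cross_links, hub_noise_scale = hub_noise_scale,
         seed = as.integer(seed)),
    class = "synthetic_spec")
}

#' The paper-scale preset: 2322 genes, 13 modules, 614 module members
#'
#' Thirteen planted modules whose sizes (138 down to 15) sum to 614 genes,
#' echoing the scale of the reconstructed glycobiome network (614 genes,
#' thirteen modules, largest module 138 nodes) without claiming to
#' reproduce the real partition. Modules 1-11 each respond to one of the
#' eleven design conditions; modules 12-13 are constitutively co-expressed
#' (no condition shift). Each module carries one planted hub. The remaining
#' 1688 genes are independent background noise and 20 rows are
#' negative-control probes.
#'
#' @param seed RNG seed for the generated data set.
#' @param noise_sd,snr_dropout_rate see [synthetic_spec()].
#' @return A `synthetic_spec`.
#' @export
paper_preset_spec <- function(seed = 1L, noise_sd = 0.25,
                              snr_dropout_rate = 0.05) {
  sizes <- c(138, 80, 65, 55, 50, 45, 40, 35, 30, 25, 20, 16, 15)
  design <- default_design()
  conds <- unique(design[, c("substrate", "phase")])
  modules <- lapply(seq_along(sizes), function(k) {
    responsive <- if (k <= nrow(conds)) conds[k, , drop = FALSE] else NULL
    planted_module(sprintf("M%02d", k), sizes[k], responsive = responsive,
                   mean_shift = if (is.null(responsive)) 0 else 2.0,
                   within_correlation = 0.95, n_hubs = 1L)
  })
  synthetic_spec(n_genes = 2322L, design = design, modules = modules,
                 n_negative_controls = 20L, noise_sd = noise_sd,
                 snr_dropout_rate = snr_dropout_rate, seed = seed)
}

# Variance of the condition mean-shift profile across the sample axis and
# the factor loading needed so TOTAL pairwise correlation (deterministic
# profile + shared latent factor over unique noise) hits the target.
module_loading <- function(mod, design, noise_sd) {
  shift <- rep(0, nrow(design))
  if (!is.null(mod$responsive) && mod$mean_shift != 0) {
    resp <- condition_key(mod$responsive$substrate, mod$responsive$phase)
    shift[condition_key(design$substrate, design$phase) %in% resp] <-
      mod$mean_shift
  }
  n <- length(shift)
  vp <- stats::var(shift) * (n - 1) / n  # population variance over the design
  s2 <- noise_sd^2
  a2 <- mod$within_correlation * (vp + s2) - vp
  if (a2 < 0) {
    stop(sprintf(paste0("module %s: infeasible correlation/noise ",
                        "combination (mean-shift profile alone induces ",
                        "correlation %.3f > target %.3f)"),
                 mod$module_id, vp / (vp + s2), mod$within_correlation))
  }
  list(shift = shift, loading = sqrt(a2), unique_sd = sqrt(s2 - a2))
}

#' Generate a synthetic expression data set with ground truth
#'
#' Members of a planted module share, per sample, a latent factor; a gene's
#' value is `mean_shift(condition) + loading * factor + unique noise`. The
#' loading is calibrated so that the expected pairwise Pearson correlation
#' among members across the whole sample axis equals the module's
#' `within_correlation` (an error is raised when the mean-shift profile
#' alone already exceeds that target). Background genes and negative
#' controls are independent Gaussian noise with mean 0 and SD `noise_sd`.
#' An SNR table is generated with `snr_dropout_rate` of cells below the
#' quantifiability cutoff of 2.
#'
#' @param spec a [synthetic_spec()].
#' @return list with elements `expr` (an [expression_matrix()]),
#'   `annotation` (gene annotation data.frame) and `truth` (list:
#'   `module` named gene->module_id vector, NA for background;
#'   `true_means` gene x condition matrix; `planted_r` per module;
#'   `hubs` per module; `seed`).
#' @export
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  design <- spec$design
  n_s <- nrow(design)
  sizes <- vapply(spec$modules, `[[`, 0L, "size")
  n_mod_genes <- sum(sizes)
  n_bg <- spec$n_genes - n_mod_genes - spec$n_negative_controls
  mod_ids <- vapply(spec$modules, `[[`, "", "module_id")

  genes <- c(sprintf("g%04d", seq_len(spec$n_genes - spec$n_negative_controls)),
             if (spec$n_negative_controls > 0)
               sprintf("neg%02d", seq_len(spec$n_negative_controls)))
  values <- matrix(stats::rnorm(spec$n_genes * n_s, sd = spec$noise_sd),
                   nrow = spec$n_genes,
                   dimnames = list(genes, design$sample_id))
  conds <- unique(condition_key(design$substrate, design$phase))
  true_means <- matrix(0, spec$n_genes, length(conds),
                       dimnames = list(genes, conds))
  module_of <- stats::setNames(rep(NA_character_, spec$n_genes), genes)
  hubs <- stats::setNames(vector("list", length(spec$modules)), mod_ids)

  # shared factor streams for cross-linked module pairs
  pair_factor <- list()
  if (!is.null(spec$cross_links)) {
    for (i in seq_len(nrow(spec$cross_links))) {
      key <- paste(spec$cross_links$module_a[i], spec$cross_links$module_b[i],
                   sep = "|")
      pair_factor[[key]] <- stats::rnorm(n_s)
    }
  }
  cross_weight <- function(id) {
    if (is.null(spec$cross_links)) return(NULL)
    i <- which(spec$cross_links$module_a == id | spec$cross_links$module_b == id)
    if (length(i) == 0L) return(NULL)
    key <- paste(spec$cross_links$module_a[i], spec$cross_links$module_b[i],
                 sep = "|")
    list(weight = spec$cross_links$weight[i], stream = pair_factor[[key]])
  }

  offset <- 0L
  for (k in seq_along(spec$modules)) {
    mod <- spec$modules[[k]]
    rows <- offset + seq_len(mod$size)
    offset <- offset + mod$size
    cal <- module_loading(mod, design, spec$noise_sd)
    own <- stats::rnorm(n_s)
    cw <- cross_weight(mod$module_id)
    factor_t <- if (is.null(cw)) own else
      sqrt(1 - cw$weight) * own + sqrt(cw$weight) * cw$stream
    unique_sd <- rep(cal$unique_sd, mod$size)
    if (mod$n_hubs > 0) {
      unique_sd[seq_len(mod$n_hubs)] <- cal$unique_sd * spec$hub_noise_scale
      hubs[[mod$module_id]] <- genes[rows[seq_len(mod$n_hubs)]]
    }
    noise <- matrix(stats::rnorm(mod$size * n_s), mod$size, n_s) * unique_sd
    values[rows, ] <- rep(cal$shift + cal$loading * factor_t,
                          each = mod$size) + noise
    module_of[rows] <- mod$module_id
    shift_by_cond <- cal$shift[match(conds,
                                     condition_key(design$substrate,
                                                   design$phase))]
    true_means[rows, ] <- rep(shift_by_cond, each = mod$size)
  }

  snr <- matrix(stats::runif(spec$n_genes * n_s, 2.5, 60), spec$n_genes, n_s,
                dimnames = dimnames(values))
  if (spec$snr_dropout_rate > 0) {
    drop <- matrix(stats::runif(spec$n_genes * n_s) < spec$snr_dropout_rate,
                   spec$n_genes, n_s)
    snr[drop] <- stats::runif(sum(drop), 0.1, 1.9)
  }

  is_neg <- grepl("^neg", genes)
  major_cog <- sample(COG_LETTERS, length(spec$modules), replace = TRUE)
  cog <- sample(COG_LETTERS, spec$n_genes, replace = TRUE)
  cog[stats::runif(spec$n_genes) < 0.2] <- NA_character_
  for (k in seq_along(spec$modules)) {
    m_rows <- which(module_of == mod_ids[k])
    take <- stats::runif(length(m_rows)) < 0.5
    cog[m_rows[take]] <- major_cog[k]
  }
  cog[is_neg] <- NA_character_
  annotation <- data.frame(gene_id = genes, cog = cog,
                           operon_id = NA_character_,
                           is_negative_control = is_neg,
                           stringsAsFactors = FALSE)

  expr <- expression_matrix(values, design, snr = snr, snr_min = 2)
  truth <- list(module = module_of, true_means = true_means,
                planted_r = stats::setNames(
                  vapply(spec$modules, `[[`, 0, "within_correlation"),
                  mod_ids),
                hubs = hubs, seed = spec$seed)
  list(expr = expr, annotation = annotation, truth = truth)
}
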