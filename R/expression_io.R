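#' @keywords internal
"_PACKAGE"

SUBSTRATES <- c("glucose", "xylose", "fructose", "cellobiose", "glucose_xylose")
PHASES <- c("early", "mid", "late")
COG_LETTERS <- strsplit("JAKLBDYVTMNZWUOCGEFHIPQRS", "")[[1]]

#' Validate a sample design table
#'
#' A sample design describes the arrays of a substrate-by-growth-phase
#' experiment: one row per hybridized sample, with its carbon substrate,
#' growth phase (early/mid/late exponential) and biological replicate index.
#'
#' @param design data.frame with columns `sample_id`, `substrate`, `phase`,
#'   `replicate`.
#' @return The design, with `substrate` and `phase` checked against the
#'   allowed levels and `replicate` coerced to integer.
#' @export
validate_design <- function(design) {
  req <- c("sample_id", "substrate", "phase", "replicate")
  missing_cols <- setdiff(req, names(design))
  if (length(missing_cols) > 0L) {
    stop("design is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  design$sample_id <- as.character(design$sample_id)
  dup <- design$sample_id[duplicated(design$sample_id)]
  if (length(dup) > 0L) {
    stop("duplicate sample id(s) in design: ", paste(unique(dup), collapse = ", "))
  }
  bad_sub <- setdiff(unique(design$substrate), SUBSTRATES)
  if (length(bad_sub) > 0L) {
    stop("unknown substrate(s): ", paste(bad_sub, collapse = ", "),
         " (allowed: ", paste(SUBSTRATES, collapse = ", "), ")")
  }
  bad_phase <- setdiff(unique(design$phase), PHASES)
  if (length(bad_phase) > 0L) {
    stop("unknown phase(s): ", paste(bad_phase, collapse = ", "))
  }
  design$replicate <- as.integer(design$replicate)
  if (anyNA(design$replicate) || any(design$replicate < 1L)) {
    stop("replicate indices must be positive integers")
  }
  design[, req]
}

#' Construct an expression matrix object
#'
#' Container for normalized two-color log2 ratios (log2 of the Cy5 sample
#' over Cy3 common-reference intensity), one row per gene and one column per
#' sample, together with the sample design, an optional signal-to-noise
#' (SNR) matrix and the quantifiability mask derived from it. Spots with
#' SNR below `snr_min` (default 2) are considered not quantifiable and are
#' masked from all downstream summaries.
#'
#' @param values numeric gene x sample matrix of log2 ratios; rownames are
#'   gene ids, colnames are sample ids.
#' @param design sample design table (see [validate_design()]).
#' @param snr optional nonnegative matrix of the same shape as `values`.
#' @param snr_min SNR threshold below which a cell is masked.
#' @return An object of class `expr_matrix` with elements `genes`, `design`,
#'   `values`, `snr`, `mask`, `snr_min`.
#' @export
expression_matrix <- function(values, design, snr = NULL, snr_min = 2) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (is.null(rownames(values))) stop("values must have gene ids as rownames")
  if (is.null(colnames(values))) stop("values must have sample ids as colnames")
  design <- validate_design(design)
  genes <- rownames(values)
  dupg <- genes[duplicated(genes)]
  if (length(dupg) > 0L) {
    stop("duplicate gene id(s): ", paste(unique(dupg), collapse = ", "))
  }
  if (nrow(values) == 0L) stop("expression matrix has no genes")
  extra_mat <- setdiff(colnames(values), design$sample_id)
  extra_des <- setdiff(design$sample_id, colnames(values))
  if (length(extra_mat) > 0L || length(extra_des) > 0L) {
    stop("matrix/design sample mismatch; only in matrix: [",
         paste(extra_mat, collapse = ", "), "]; only in design: [",
         paste(extra_des, collapse = ", "), "]")
  }
  # design column order is authoritative for nothing; matrix column order wins
  design <- design[match(colnames(values), design$sample_id), , drop = FALSE]
  rownames(design) <- NULL
  if (!is.null(snr)) {
    snr <- as.matrix(snr)
    if (!all(dim(snr) == dim(values))) {
      stop("snr matrix dimensions differ from the expression matrix")
    }
    if (any(snr < 0, na.rm = TRUE)) stop("snr values must be nonnegative")
    dimnames(snr) <- dimnames(values)
    mask <- !is.na(snr) & snr >= snr_min
  } else {
    mask <- !is.na(values)
  }
  if (any(!is.finite(values[mask]))) {
    bad <- which(!is.finite(values) & mask, arr.ind = TRUE)[1L, ]
    stop("non-finite expression value at unmasked cell gene=",
         genes[bad[1L]], ", sample=", colnames(values)[bad[2L]])
  }
  structure(
    list(genes = genes, design = design, values = values, snr = snr,
         mask = mask, snr_min = snr_min),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (%d conditions)\n",
              length(x$genes), nrow(x$design),
              nrow(unique(x$design[, c("substrate", "phase")]))))
  cat(sprintf("  masked cells: %d (%.1f%%); SNR table: %s\n",
              sum(!x$mask), 100 * mean(!x$mask),
              if (is.null(x$snr)) "absent" else
                sprintf("present (snr_min = %g)", x$snr_min)))
  invisible(x)
}

read_tsv_matrix <- function(path, what) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = NULL,
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL)
  if (names(raw)[1L] != "gene_id") {
    stop(what, " file must have 'gene_id' as its first header cell: ", path)
  }
  ids <- raw[[1L]]
  m <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(m), dim = dim(m)))
  bad <- which(is.na(num) & !(m %in% c("NA", "")), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric cell in %s file at gene=%s, sample=%s: '%s'",
                 what, ids[bad[1L, 1L]], colnames(m)[bad[1L, 2L]],
                 m[bad[1L, 1L], bad[1L, 2L]]))
  }
  dimnames(num) <- list(ids, colnames(m))
  num
}

#' Read an expression data set from TSV files
#'
#' The expression matrix is a tab-separated table whose first column
#' (`gene_id`) holds gene ids and whose remaining columns are samples; the
#' optional SNR table has the identical layout. Masked / missing cells are
#' written as `NA`.
#'
#' @param matrix_path path to the log2-ratio TSV.
#' @param design_path path to the design TSV
#'   (columns sample_id, substrate, phase, replicate).
#' @param snr_path optional path to an SNR TSV of the same shape.
#' @param snr_min SNR quantifiability cutoff (default 2).
#' @return An [expression_matrix()] object.
#' @export
read_expression <- function(matrix_path, design_path, snr_path = NULL,
                            snr_min = 2) {
  values <- read_tsv_matrix(matrix_path, "expression")
  design <- utils::read.delim(design_path, sep = "\t",
                              colClasses = "character", check.names = FALSE)
  snr <- NULL
  if (!is.null(snr_path)) {
    snr <- read_tsv_matrix(snr_path, "SNR")
    if (!identical(dimnames(snr), dimnames(values))) {
      stop("SNR table gene/sample ids do not match the expression matrix")
    }
  }
  expression_matrix(values, design, snr = snr, snr_min = snr_min)
}

write_tsv_matrix <- function(m, path) {
  df <- data.frame(gene_id = rownames(m),
                   format(m, digits = 15, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
}

#' Write an expression data set to TSV files
#'
#' Serializes to the same tab-separated dialect that [read_expression()]
#' accepts; masked cells are written as `NA`. Values round-trip as decimal
#' text at 15 significant digits.
#'
#' @param x an `expr_matrix`.
#' @param matrix_path output path for the log2-ratio TSV.
#' @param design_path optional output path for the design TSV.
#' @param snr_path optional output path for the SNR TSV.
#' @export
write_expression <- function(x, matrix_path, design_path = NULL,
                             snr_path = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  if (length(x$genes) == 0L) stop("nothing to write: empty gene list")
  vals <- x$values
  vals[!x$mask] <- NA_real_
  write_tsv_matrix(vals, matrix_path)
  if (!is.null(design_path)) {
    utils::write.table(x$design, design_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(snr_path)) {
    if (is.null(x$snr)) stop("no SNR table to write")
    write_tsv_matrix(x$snr, snr_path)
  }
  invisible(NULL)
}

#' Read a gene annotation table
#'
#' Tab-separated with columns `gene_id`, `cog` (single COG category letter or
#' NA), `operon_id` (optional), `is_negative_control` (TRUE/FALSE).
#'
#' @param path annotation TSV path.
#' @return data.frame with validated columns.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.delim(path, sep = "\t", colClasses = "character",
                           check.names = FALSE)
  validate_annotation(ann)
}

#' Validate a gene annotation table
#' @param ann data.frame with at least a `gene_id` column.
#' @return normalized annotation data.frame.
#' @export
validate_annotation <- function(ann) {
  if (!"gene_id" %in% names(ann)) stop("annotation needs a gene_id column")
  ann$gene_id <- as.character(ann$gene_id)
  dup <- ann$gene_id[duplicated(ann$gene_id)]
  if (length(dup) > 0L) {
    stop("duplicate gene id(s) in annotation: ",
         paste(unique(dup), collapse = ", "))
  }
  if (!"cog" %in% names(ann)) ann$cog <- NA_character_
  ann$cog[ann$cog %in% c("", "NA")] <- NA_character_
  bad <- setdiff(stats::na.omit(unique(ann$cog)), COG_LETTERS)
  if (length(bad) > 0L) {
    stop("invalid COG letter(s): ", paste(bad, collapse = ", "))
  }
  if (!"operon_id" %in% names(ann)) ann$operon_id <- NA_character_
  ann$operon_id[ann$operon_id %in% c("", "NA")] <- NA_character_
  if (!"is_negative_control" %in% names(ann)) ann$is_negative_control <- FALSE
  ann$is_negative_control <- as.logical(ann$is_negative_control)
  ann$is_negative_control[is.na(ann$is_negative_control)] <- FALSE
  ann[, c("gene_id", "cog", "operon_id", "is_negative_control")]
}

#' Write a gene annotation table
#' @param ann annotation data.frame.
#' @param path output TSV path.
#' @export
write_annotation <- function(ann, path) {
  utils::write.table(validate_annotation(ann), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(NULL)
}
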