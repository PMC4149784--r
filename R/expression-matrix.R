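#' Gene-by-sample expression matrix with a sample sheet
#'
#' Light container pairing a non-negative abundance matrix (raw counts or
#' RPKM) with a sample sheet describing genotype, condition and replicate
#' index for every column. Raw-count matrices may additionally carry gene
#' lengths and per-sample total mapped reads so they can be converted to
#' RPKM with [compute_rpkm()].
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids). All values must be
#'   non-negative and finite.
#' @param samples data frame with columns `sample`, `genotype`,
#'   `condition`, `replicate`; one row per matrix column.
#' @param unit `"rpkm"` or `"counts"`.
#' @param gene_lengths optional named numeric vector of transcript lengths
#'   in nucleotides (required by [compute_rpkm()]).
#' @param total_reads optional named numeric vector of total mapped reads
#'   per sample (required by [compute_rpkm()]).
#' @return An object of class `expr_matrix`.
#' @export
expression_matrix <- function(values, samples,
                              unit = c("rpkm", "counts"),
                              gene_lengths = NULL, total_reads = NULL) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have gene rownames and sample colnames")
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("abundance values must be finite and >= 0")
  }
  required <- c("sample", "genotype", "condition", "replicate")
  if (!all(required %in% names(samples))) {
    stop("sample sheet needs columns: ", paste(required, collapse = ", "))
  }
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (!setequal(samples$sample, colnames(values)) ||
      anyDuplicated(samples$sample)) {
    stop("sample sheet rows must match matrix columns one-to-one")
  }
  samples <- samples[match(colnames(values), samples$sample), , drop = FALSE]
  rownames(samples) <- NULL
  if (!is.null(gene_lengths)) {
    if (!all(rownames(values) %in% names(gene_lengths))) {
      stop("gene_lengths missing for some genes")
    }
    gene_lengths <- gene_lengths[rownames(values)]
    if (any(gene_lengths <= 0)) stop("gene lengths must be > 0")
  }
  if (!is.null(total_reads)) {
    if (!all(colnames(values) %in% names(total_reads))) {
      stop("total_reads missing for some samples")
    }
    total_reads <- total_reads[colnames(values)]
  }
  structure(
    list(values = values, samples = samples, unit = unit,
         gene_lengths = gene_lengths, total_reads = total_reads),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$unit))
  grp <- table(paste(x$samples$genotype, x$samples$condition, sep = "/"))
  cat("groups:", paste(sprintf("%s (n=%d)", names(grp), grp), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

# Sample ids belonging to one (genotype, condition) group.
group_samples <- function(x, genotype, condition) {
  sel <- x$samples$genotype == genotype & x$samples$condition == condition
  x$samples$sample[sel]
}

#' Convert raw counts to RPKM
#'
#' Reads per kilobase of transcript per million mapped reads:
#' `rpkm = count * 1e9 / (length_nt * total_mapped_reads)`. Length and
#' sequencing-depth normalisation make replicate libraries of different
#' depth comparable on a common abundance scale.
#'
#' @param counts an [expression_matrix()] with `unit = "counts"` carrying
#'   `gene_lengths` and `total_reads`.
#' @return An `expr_matrix` with `unit = "rpkm"`.
#' @export
compute_rpkm <- function(counts) {
  stopifnot(inherits(counts, "expr_matrix"))
  if (counts$unit != "counts") stop("input is not a count matrix")
  if (is.null(counts$gene_lengths) || is.null(counts$total_reads)) {
    stop("compute_rpkm() needs gene_lengths and total_reads")
  }
  if (any(counts$total_reads <= 0)) stop("total mapped reads must be > 0")
  rpkm <- counts$values * 1e9 /
    outer(counts$gene_lengths, counts$total_reads)
  expression_matrix(rpkm, counts$samples, unit = "rpkm",
                    gene_lengths = counts$gene_lengths)
}
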