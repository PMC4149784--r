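# Build an expr_matrix with one reference and one test group from
# per-gene replicate value matrices.
make_two_group_matrix <- function(ref, tst, genes = NULL) {
  ref <- rbind(ref); tst <- rbind(tst)
  if (is.null(genes)) genes <- paste0("G", seq_len(nrow(ref)))
  values <- cbind(ref, tst)
  rownames(values) <- genes
  colnames(values) <- c(paste0("ref_", seq_len(ncol(ref))),
                        paste0("tst_", seq_len(ncol(tst))))
  samples <- data.frame(
    sample = colnames(values),
    genotype = "wt",
    condition = rep(c("untreated", "cu_bpq"), c(ncol(ref), ncol(tst))),
    replicate = c(seq_len(ncol(ref)), seq_len(ncol(tst)))
  )
  expression_matrix(values, samples, unit = "rpkm")
}

two_group_fc <- function(ref, tst, genes = NULL, floor = 0.1) {
  fold_changes(make_two_group_matrix(ref, tst, genes),
               c("wt", "untreated"), c("wt", "cu_bpq"), floor = floor)
}

# Hand-built fold_change_table for threshold / fingerprint fixtures.
fc_fixture <- function(gene, fold, sd = 0, direction = "up",
                       significant = TRUE) {
  n <- length(gene)
  fold <- rep_len(fold, n); sd <- rep_len(sd, n)
  direction <- rep_len(direction, n)
  significant <- rep_len(significant, n)
  fold[direction == "none"] <- 1
  mean_fc <- fold
  mean_fc[direction == "down"] <- 1 / fold[direction == "down"]
  signed <- fold
  signed[direction == "down"] <- -fold[direction == "down"]
  out <- data.frame(
    gene = gene, mean_fc = mean_fc, sd_fc = sd,
    direction = direction, fold = fold, sd_fold = sd,
    signed_fold = signed,
    significant = significant, flags = character(n),
    stringsAsFactors = FALSE
  )
  class(out) <- c("fold_change_table", "data.frame")
  out
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
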