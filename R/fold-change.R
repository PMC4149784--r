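#' Replicate fold changes of a test group against a reference group
#'
#' For each gene the reference mean is the average of the reference
#' replicates, floored at `floor` (RPKM) so that genes with negligible
#' basal expression do not produce unbounded ratios. Each test replicate
#' is divided by that reference mean (the cultures are independent, so
#' replicates are not paired), giving per-replicate fold changes whose
#' mean and sample standard deviation are reported.
#'
#' Down-regulated genes (`mean_fc < 1`) are additionally summarised on the
#' fold-decrease scale: the per-replicate ratios are inverted before
#' taking mean and SD, so a gene at one fifth of its reference level is
#' reported as a 5-fold decrease. `signed_fold` is `+fold` for
#' up-regulation and `-fold` for down-regulation, a plotting convention
#' that leaves no values strictly inside (-1, 1).
#'
#' @param x an [expression_matrix()].
#' @param reference,test length-2 character vectors `c(genotype,
#'   condition)` naming the two groups.
#' @param floor reference-mean floor on the abundance scale (default 0.1
#'   RPKM). Genes whose reference mean (or any test replicate used on the
#'   reciprocal scale) is floored are flagged.
#' @return A `fold_change_table` data frame with columns `gene`,
#'   `mean_fc`, `sd_fc`, `direction` (`up`/`down`/`none`), `fold`
#'   (direction-scale fold, >= 1), `sd_fold` (direction-scale SD),
#'   `signed_fold`, `significant` (NA until [apply_significance()]), and
#'   `flags`.
#' @export
fold_changes <- function(x, reference, test, floor = 0.1) {
  stopifnot(inherits(x, "expr_matrix"))
  if (floor <= 0) stop("`floor` must be > 0")
  ref_ids <- group_samples(x, reference[1], reference[2])
  test_ids <- group_samples(x, test[1], test[2])
  if (length(ref_ids) == 0 || length(test_ids) == 0) {
    stop("reference or test group has zero samples")
  }
  ref <- x$values[, ref_ids, drop = FALSE]
  tst <- x$values[, test_ids, drop = FALSE]

  ref_mean_raw <- rowMeans(ref)
  low_ref <- ref_mean_raw < floor
  ref_mean <- pmax(ref_mean_raw, floor)

  fc <- tst / ref_mean
  mean_fc <- rowMeans(fc)
  sd_fc <- apply(fc, 1, sd)

  direction <- ifelse(abs(mean_fc - 1) < 1e-12, "none",
                      ifelse(mean_fc > 1, "up", "down"))

  # Fold-decrease scale uses reciprocals of per-replicate ratios; test
  # replicates are floored too so all-zero genes stay finite.
  low_test <- rowSums(tst < floor) > 0
  inv <- ref_mean / pmax(tst, floor)
  inv_mean <- rowMeans(inv)
  inv_sd <- apply(inv, 1, sd)

  down <- direction == "down"
  fold <- ifelse(down, inv_mean, mean_fc)
  sd_fold <- ifelse(down, inv_sd, sd_fc)
  signed_fold <- ifelse(direction == "up", fold,
                        ifelse(down, -fold, 1))

  flags <- character(nrow(tst))
  flags[low_ref] <- "low-reference"
  flags[down & low_test] <- trimws(paste(flags[down & low_test], "low-test"))

  out <- data.frame(
    gene = rownames(x$values), mean_fc = mean_fc, sd_fc = sd_fc,
    direction = direction, fold = fold, sd_fold = sd_fold,
    signed_fold = signed_fold, significant = NA,
    flags = flags, stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "reference") <- reference
  attr(out, "test") <- test
  attr(out, "floor") <- floor
  class(out) <- c("fold_change_table", "data.frame")
  out
}

#' Flag significant fold changes with the one-SD rule
#'
#' A change is called significant when the direction-scale fold change
#' minus one replicate standard deviation still exceeds the threshold:
#' `fold - sd_fold > threshold`. This is the strict reading of requiring
#' a greater-than-threshold change to hold within one SD of the replicate
#' spread; genes with no direction are never significant.
#'
#' @param table a `fold_change_table` from [fold_changes()].
#' @param threshold fold threshold (> 1); default 2.
#' @return The table with the `significant` column filled.
#' @export
apply_significance <- function(table, threshold = 2) {
  stopifnot(inherits(table, "fold_change_table"))
  if (threshold <= 1) stop("`threshold` must be > 1")
  sig <- table$direction != "none" &
    !is.na(table$sd_fold) &
    (table$fold - table$sd_fold) > threshold
  sig[is.na(table$sd_fold)] <- FALSE
  table$significant <- sig
  table$flags[is.na(table$sd_fold)] <-
    trimws(paste(table$flags[is.na(table$sd_fold)], "single-replicate"))
  attr(table, "significance_threshold") <- threshold
  table
}

#' Genes beyond a fold cutoff in one direction
#'
#' Selects significant genes of the requested direction whose
#' direction-scale fold change is at least `cutoff`, sorted by descending
#' fold — the format of a "more than 4.5-fold changed" table.
#'
#' @param table a `fold_change_table` with significance applied.
#' @param cutoff direction-scale fold cutoff (>= 1); default 4.5.
#' @param direction `"up"` or `"down"`.
#' @return Subset of `table`, ordered by decreasing `fold`.
#' @export
threshold_table <- function(table, cutoff = 4.5,
                            direction = c("up", "down")) {
  stopifnot(inherits(table, "fold_change_table"))
  direction <- match.arg(direction)
  if (cutoff < 1) stop("`cutoff` must be >= 1")
  if (nrow(table) > 0 && all(is.na(table$significant))) {
    stop("apply_significance() first")
  }
  keep <- table$direction == direction & table$significant %in% TRUE &
    table$fold >= cutoff
  out <- table[keep, , drop = FALSE]
  out[order(-out$fold), , drop = FALSE]
}

#' Fra2-dependent fraction of each gene's response
#'
#' Partitions a gene's total response to treatment into a Fra2-dependent
#' and a Fra2-independent part. With both fold-change tables computed in
#' a *fra2* deletion background against the same wild-type untreated
#' reference, the de-repression already present without treatment,
#' relative to the full treated response, is
#' `f_dep = (S_untreated - 1) / (S_treated - 1)` on the linear fold scale
#' (`S = mean_fc`). A gene fully de-repressed by loss of Fra2 alone gives
#' 1; a gene whose induction needs the treatment regardless of Fra2 gives
#' 0. Genes whose treated response is within `tol` of no change cannot be
#' partitioned and are flagged instead of divided.
#'
#' @param fc_fra2_untreated,fc_fra2_treated `fold_change_table`s for the
#'   mutant untreated and mutant treated groups, both against the same
#'   reference.
#' @param tol minimum `|mean_fc - 1|` of the treated table for the ratio
#'   to be formed (default 0.05).
#' @return A `fra2_partition` data frame: `gene`, `f_dep`, `f_indep`,
#'   `out_of_range` (f outside [0,1]), `flags`.
#' @export
fra2_fraction <- function(fc_fra2_untreated, fc_fra2_treated, tol = 0.05) {
  stopifnot(inherits(fc_fra2_untreated, "fold_change_table"),
            inherits(fc_fra2_treated, "fold_change_table"))
  if (!identical(fc_fra2_untreated$gene, fc_fra2_treated$gene)) {
    stop("gene sets of the two tables do not match")
  }
  s_u <- fc_fra2_untreated$mean_fc
  s_t <- fc_fra2_treated$mean_fc
  near_unity <- abs(s_t - 1) < tol
  f <- ifelse(near_unity, NA_real_, (s_u - 1) / (s_t - 1))
  out <- data.frame(
    gene = fc_fra2_untreated$gene,
    f_dep = f, f_indep = 1 - f,
    out_of_range = !is.na(f) & (f < 0 | f > 1),
    flags = ifelse(near_unity, "near-unity-denominator", ""),
    stringsAsFactors = FALSE
  )
  class(out) <- c("fra2_partition", "data.frame")
  out
}
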