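#' Packaged regulon annotation for the named yeast genes
#'
#' Regulon assignments of the characterised genes appearing in the
#' study's threshold tables and Yap5 panel, following the established
#' regulon literature (Aft1/2 iron uptake, Ace1 copper detoxification,
#' Mac1 copper uptake, Cth2 iron sparing, Yap5 iron surplus). The
#' late-annotated ORFs are carried as `unknown`.
#'
#' @return Data frame `gene`, `class` with classes in
#'   `c("aft", "cth2", "ace1", "mac1", "yap5", "unknown")`.
#' @export
regulon_annotation_default <- function() {
  data.frame(
    gene = c("FIT1", "ARN2", "FIT2", "FIT3", "HMX1", "CTH2", "ARN1",
             "FTR1", "SIT1", "CCC2", "BIO5", "FET3",
             "CUP1-1", "CUP1-2", "CRS5",
             "CTR1", "FRE7", "REE1", "IRC7",
             "LEU1",
             "GRX4", "CCC1", "TYW1",
             "YJR005C-A", "YBR200W-A", "YDR210W-B"),
    class = c(rep("aft", 12), rep("ace1", 3), rep("mac1", 4), "cth2",
              rep("yap5", 3), rep("unknown", 3)),
    stringsAsFactors = FALSE
  )
}

#' Assemble the two-condition transcriptional fingerprint
#'
#' One point per gene responding to the ionophore treatment: x is the
#' signed fold change under copper + ionophore, y the signed fold change
#' under copper alone, both against the same untreated reference. Genes
#' enter the fingerprint only if their ionophore response is significant
#' and at least `min_fold` on the direction scale. Regulon classes come
#' from the annotation; unannotated genes are `unknown`.
#'
#' @param fc_cu_bpq,fc_cu_only `fold_change_table`s (significance
#'   applied) for the two treatments against the untreated reference.
#' @param annotation data frame `gene`, `class`; default
#'   [regulon_annotation_default()].
#' @param min_fold inclusion threshold on the ionophore fold change.
#' @return A `fingerprint_points` data frame: `gene`, `x`, `y`, `class`.
#' @export
assemble_fingerprint <- function(fc_cu_bpq, fc_cu_only,
                                 annotation = regulon_annotation_default(),
                                 min_fold = 2) {
  stopifnot(inherits(fc_cu_bpq, "fold_change_table"),
            inherits(fc_cu_only, "fold_change_table"))
  if (!setequal(fc_cu_bpq$gene, fc_cu_only$gene)) {
    stop("gene universes of the two tables do not match")
  }
  if (all(is.na(fc_cu_bpq$significant))) stop("apply_significance() first")
  fc_cu_only <- fc_cu_only[match(fc_cu_bpq$gene, fc_cu_only$gene), ]
  keep <- fc_cu_bpq$significant %in% TRUE & fc_cu_bpq$fold >= min_fold
  cls <- annotation$class[match(fc_cu_bpq$gene[keep], annotation$gene)]
  cls[is.na(cls)] <- "unknown"
  out <- data.frame(
    gene = fc_cu_bpq$gene[keep],
    x = fc_cu_bpq$signed_fold[keep],
    y = fc_cu_only$signed_fold[keep],
    class = cls,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "min_fold") <- min_fold
  class(out) <- c("fingerprint_points", "data.frame")
  out
}

#' Best-fit lines through the iron- and copper-regulated fingerprints
#'
#' Ordinary least squares of y on x on the signed-fold axes, fitted
#' separately through the iron-responsive classes (respond to the
#' ionophore only, so the line is near horizontal) and the
#' copper-responsive classes (respond equally to copper with or without
#' ionophore, so the line is near the diagonal). Iron-surplus (`yap5`)
#' and unknown genes are excluded from both lines.
#'
#' @param points a `fingerprint_points` data frame.
#' @param iron_classes,copper_classes class labels entering each line.
#' @return A `group_lines` data frame: `group`, `slope`, `intercept`,
#'   `n`, `residual_sd`.
#' @export
fit_group_lines <- function(points,
                            iron_classes = c("aft", "cth2"),
                            copper_classes = c("ace1", "mac1")) {
  stopifnot(inherits(points, "fingerprint_points"))
  fit_one <- function(group, classes) {
    p <- points[points$class %in% classes, , drop = FALSE]
    if (nrow(p) < 2) stop("fewer than 2 points in ", group, " group")
    if (sd(p$x) == 0) stop("degenerate x variance in ", group, " group")
    m <- lm(y ~ x, data = p)
    data.frame(group = group,
               slope = unname(coef(m)[2]),
               intercept = unname(coef(m)[1]),
               n = nrow(p),
               residual_sd = sqrt(sum(m$residuals^2) /
                                    max(1, nrow(p) - 2)),
               stringsAsFactors = FALSE)
  }
  out <- rbind(fit_one("iron", iron_classes),
               fit_one("copper", copper_classes))
  class(out) <- c("group_lines", "data.frame")
  out
}

#' Nominate candidate regulon targets from expression and motif evidence
#'
#' Candidate iron-sparing (Cth2) targets are genes down-regulated by at
#' least `min_fold` whose metalloregulation is unknown and whose 3' UTR
#' carries an AU-rich element; candidate iron-uptake (Aft) targets are
#' unknown genes up-regulated by at least `min_fold` with a consensus
#' Aft1 site in the promoter. Every candidate cites its supporting
#' motif matches.
#'
#' @param points a `fingerprint_points` data frame (already filtered to
#'   significant >= `min_fold` responders).
#' @param matches a `motif_match` data frame covering the same gene
#'   universe (ARE matches in utr3, Aft1 matches in promoters).
#' @param min_fold candidate fold threshold (default 2).
#' @return A `candidate_report` list: `cth2_candidates`,
#'   `aft_candidates` (data frames `gene`, `x`, `y`, `n_matches`), and
#'   `matches` (the supporting subset).
#' @export
nominate_candidates <- function(points, matches, min_fold = 2) {
  stopifnot(inherits(points, "fingerprint_points"))
  pick <- function(sign_ok, consensus, region) {
    m <- matches[matches$consensus == consensus &
                   matches$region == region, , drop = FALSE]
    p <- points[sign_ok & points$class == "unknown" &
                  points$gene %in% m$gene, , drop = FALSE]
    n_m <- vapply(p$gene, function(g) sum(m$gene == g), 0L)
    list(
      candidates = data.frame(gene = p$gene, x = p$x, y = p$y,
                              n_matches = as.integer(n_m),
                              stringsAsFactors = FALSE),
      matches = m[m$gene %in% p$gene, , drop = FALSE]
    )
  }
  cth2 <- pick(points$x <= -min_fold, "ARE", "utr3")
  aft <- pick(points$x >= min_fold, "Aft1", "promoter")
  support <- rbind(cth2$matches, aft$matches)
  rownames(support) <- NULL
  structure(
    list(cth2_candidates = cth2$candidates,
         aft_candidates = aft$candidates,
         matches = support),
    class = "candidate_report"
  )
}

#' @export
print.candidate_report <- function(x, ...) {
  cat(sprintf(
    "candidate report: %d Cth2-like (ARE in 3'UTR), %d Aft-like (promoter site)\n",
    nrow(x$cth2_candidates), nrow(x$aft_candidates)))
  if (nrow(x$cth2_candidates)) {
    cat("  Cth2 candidates:",
        paste(x$cth2_candidates$gene, collapse = ", "), "\n")
  }
  if (nrow(x$aft_candidates)) {
    cat("  Aft candidates:",
        paste(x$aft_candidates$gene, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Scatter plot of the two-condition fingerprint
#'
#' Signed fold change under copper + ionophore (x) against copper alone
#' (y), coloured by regulon group, with the fitted group lines overlaid.
#'
#' @param points a `fingerprint_points` data frame.
#' @param lines optional `group_lines` from [fit_group_lines()].
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, `points`.
#' @export
plot_fingerprint <- function(points, lines = NULL, ...) {
  cols <- c(aft = "red3", cth2 = "red3", ace1 = "blue3", mac1 = "blue3",
            yap5 = "orange3", unknown = "grey50")
  col <- cols[points$class]
  col[is.na(col)] <- "grey50"
  graphics::plot(points$x, points$y, col = col, pch = 19,
                 xlab = "signed fold change, Cu + ionophore",
                 ylab = "signed fold change, Cu alone", ...)
  graphics::abline(h = 0, v = 0, col = "grey80")
  if (!is.null(lines)) {
    for (i in seq_len(nrow(lines))) {
      graphics::abline(lines$intercept[i], lines$slope[i],
                       col = if (lines$group[i] == "iron") "red3"
                             else "blue3")
    }
  }
  invisible(points)
}
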