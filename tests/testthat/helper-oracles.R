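# Independent oracles, deliberately built on different machinery than the
# implementation (base-R regex / grid search vs Biostrings / bisection).

oracle_revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(x, ""), function(ch) paste(rev(ch), collapse = ""),
                ""))
}

# All start positions of word `w` in `s`, overlap-aware (zero-width
# lookahead, so self-overlapping words are fully enumerated).
oracle_find <- function(s, w) {
  p <- gregexpr(paste0("(?=", w, ")"), s, perl = TRUE)[[1]]
  p[p > 0]
}

# All matches of concrete `words` in a character vector of sequences.
# Minus-strand positions are located in the reverse-complemented string
# and mapped back to the stored sequence, a different route than the
# scanner's reverse-complemented-pattern search.
oracle_scan <- function(ids, seqs, words, both_strands) {
  out <- list()
  for (i in seq_along(seqs)) {
    L <- nchar(seqs[i])
    for (w in words) {
      nw <- nchar(w)
      for (q in oracle_find(seqs[i], w)) {
        out[[length(out) + 1]] <-
          data.frame(id = ids[i], strand = "+", start = q, word = w,
                     stringsAsFactors = FALSE)
      }
      if (both_strands) {
        rc <- oracle_revcomp(seqs[i])
        for (q in oracle_find(rc, w)) {
          out[[length(out) + 1]] <-
            data.frame(id = ids[i], strand = "-",
                       start = L - (q + nw - 1) + 1, word = w,
                       stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(id = character(), strand = character(),
                      start = integer(), word = character(),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  df[order(df$id, df$strand, df$start, df$word), , drop = FALSE]
}

# Brute-force mass-balance solution by two-stage grid search on free
# ligand (about 1e6 evaluations per point); returns complex in uM.
oracle_mass_balance <- function(M_total_uM, L_total_uM, beta, n = 2) {
  Lt <- L_total_uM * 1e-6
  vapply(M_total_uM * 1e-6, function(Mt) {
    obj <- function(L) {
      ml <- (Lt - L) / n
      abs(beta * (Mt - ml) * L^n - ml)
    }
    grid <- seq(0, Lt, length.out = 1e3 + 1)
    i <- which.min(obj(grid))
    lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
    for (stage in 1:2) {
      grid <- seq(lo, hi, length.out = 1e3 + 1)
      i <- which.min(obj(grid))
      lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
    }
    (Lt - grid[i]) / n * 1e6
  }, 0)
}

sorted_matches <- function(df) {
  df <- df[order(df$id, df$strand, df$start, df$word), , drop = FALSE]
  rownames(df) <- NULL
  df
}
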