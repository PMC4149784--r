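# Base-R reverse complement used by the generator; the scanner uses
# Biostrings, keeping the two code paths independent.
revcomp_chr <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(x, function(s) {
           paste(rev(strsplit(s, "")[[1]]), collapse = "")
         }, "", USE.NAMES = FALSE))
}

# All start positions of fixed word `w` in `s` (base-R fixed matching).
find_word <- function(s, w) {
  p <- gregexpr(w, s, fixed = TRUE)[[1]]
  p[p > 0]
}

# Does `s` contain any word (on the strands requested) outside the
# allowed interval [lo, hi]? Used to keep planted hits unique.
has_stray_hit <- function(s, words, both_strands, lo = 0, hi = -1) {
  all_words <- words
  if (both_strands) all_words <- unique(c(words, revcomp_chr(words)))
  for (w in all_words) {
    for (p in find_word(s, w)) {
      if (p < lo || (p + nchar(w) - 1) > hi) return(TRUE)
    }
  }
  FALSE
}

# Uniform random sequence of length n.
random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Draw a background sequence free of the given words, then embed one
# concrete instance; redraw until the planted instance is the only hit.
embed_word <- function(len, word, words, both_strands, max_tries = 1000) {
  w <- nchar(word)
  if (len < w) stop("region shorter than motif")
  for (try in seq_len(max_tries)) {
    s <- random_seq(len)
    start <- sample.int(len - w + 1, 1)
    s <- paste0(substr(s, 1, start - 1), word, substr(s, start + w, len))
    if (!has_stray_hit(s, words, both_strands, start, start + w - 1)) {
      return(list(seq = s, start = start))
    }
  }
  stop("could not embed motif without stray background hits")
}

#' Generate promoter and 3'-UTR sequences with planted motifs
#'
#' Every gene in the ground truth receives a uniform-random promoter and
#' 3' UTR. Genes of the iron-uptake classes (`aft`, `cand_aft`) carry one
#' concrete Aft1-site expansion in the promoter, on a random strand;
#' genes of the iron-sparing classes (`cth2`, `cand_cth2`) carry the
#' AU-rich nonamer in the 3' UTR on the sense strand. Each embedding
#' happens with probability `embed_rate`, at a uniform random position,
#' and the background is re-drawn until the planted instance is the only
#' occurrence of the designated consensus in that sequence, so truth
#' positions are the unique planted hits.
#'
#' @param config a [sim_config()].
#' @param truth the `sim_truth` from [gen_expression()].
#' @return `list(sequences = sequence_set, embedded = data frame of
#'   planted sites: gene, region, consensus, strand, start, word)`.
#' @export
gen_regions <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  aft_words <- expand_degenerate(consensus_aft1())
  are_word <- expand_degenerate(consensus_are()) # single nonamer
  are_words <- consensus_words(consensus_are())  # nonamer + octamers
  if (config$promoter_len < max(nchar(aft_words)) ||
      config$utr3_len < max(nchar(are_words))) {
    stop("region shorter than motif")
  }
  withr::with_seed(config$seed + 1L, {
    seqs <- list(); planted <- list()
    for (i in seq_len(nrow(truth))) {
      cls <- truth$class[i]; g <- truth$gene[i]
      # promoter
      if (cls %in% c("aft", "cand_aft") && runif(1) < config$embed_rate) {
        word <- sample(aft_words, 1)
        strand <- sample(c("+", "-"), 1)
        ins <- if (strand == "+") word else revcomp_chr(word)
        e <- embed_word(config$promoter_len, ins, aft_words, TRUE)
        prom <- e$seq
        planted[[length(planted) + 1]] <- data.frame(
          gene = g, region = "promoter", consensus = "Aft1",
          strand = strand, start = e$start, word = word,
          stringsAsFactors = FALSE
        )
      } else {
        prom <- random_seq(config$promoter_len)
      }
      # 3' UTR
      if (cls %in% c("cth2", "cand_cth2") && runif(1) < config$embed_rate) {
        e <- embed_word(config$utr3_len, are_word, are_words, FALSE)
        utr <- e$seq
        planted[[length(planted) + 1]] <- data.frame(
          gene = g, region = "utr3", consensus = "ARE",
          strand = "+", start = e$start, word = are_word,
          stringsAsFactors = FALSE
        )
      } else {
        utr <- random_seq(config$utr3_len)
      }
      seqs[[length(seqs) + 1]] <- data.frame(
        gene = g, region = c("promoter", "utr3"), seq = c(prom, utr),
        stringsAsFactors = FALSE
      )
    }
    all <- do.call(rbind, seqs)
    embedded <- if (length(planted)) do.call(rbind, planted) else
      data.frame(gene = character(), region = character(),
                 consensus = character(), strand = character(),
                 start = integer(), word = character(),
                 stringsAsFactors = FALSE)
    list(sequences = sequence_set(all$gene, all$region, all$seq),
         embedded = embedded)
  })
}
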