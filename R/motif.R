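#' Degenerate consensus motif
#'
#' A consensus over the alphabet {A, C, G, T, U}, the multi-character
#' pyrimidine/purine tokens `Py` (C/T) and `Pu` (A/G), and single-letter
#' IUPAC ambiguity codes. `U` is canonicalised to `T` internally, so RNA
#' elements can be given in RNA spelling.
#'
#' @param pattern consensus string, e.g. `"PyPuCACCCPu"` or
#'   `"UUAUUUAUU"`.
#' @param name short motif name used in match reports.
#' @param region_target region type the motif is biologically expected
#'   in (`"promoter"`, `"utr3"`, or `NA` for no restriction).
#' @param strand_policy `"both"` for DNA-binding sites, `"sense"` for
#'   RNA elements that exist only in the transcript.
#' @param derivatives `"none"`, or `"octamer"` to also scan the
#'   contiguous 8-mers of each 9-mer expansion (the classic AU-rich
#'   element definition admits the nonamer or an octamer derivative).
#' @return A `degenerate_consensus` object.
#' @export
degenerate_consensus <- function(pattern, name = pattern,
                                 region_target = NA_character_,
                                 strand_policy = c("both", "sense"),
                                 derivatives = c("none", "octamer")) {
  strand_policy <- match.arg(strand_policy)
  derivatives <- match.arg(derivatives)
  tokens <- parse_consensus_tokens(pattern)
  if (length(tokens) < 4) stop("consensus must have length >= 4")
  structure(
    list(pattern = pattern, name = name, tokens = tokens,
         region_target = region_target, strand_policy = strand_policy,
         derivatives = derivatives),
    class = "degenerate_consensus"
  )
}

# Tokenise a consensus string into per-position alternative sets.
parse_consensus_tokens <- function(pattern) {
  iupac <- Biostrings::IUPAC_CODE_MAP
  tokens <- list()
  i <- 1
  while (i <= nchar(pattern)) {
    two <- substr(pattern, i, i + 1)
    one <- toupper(substr(pattern, i, i))
    if (two == "Py") {
      tokens[[length(tokens) + 1]] <- c("C", "T"); i <- i + 2
    } else if (two == "Pu") {
      tokens[[length(tokens) + 1]] <- c("A", "G"); i <- i + 2
    } else if (one == "U") {
      tokens[[length(tokens) + 1]] <- "T"; i <- i + 1
    } else if (one %in% names(iupac)) {
      tokens[[length(tokens) + 1]] <- strsplit(iupac[[one]], "")[[1]]
      i <- i + 1
    } else {
      stop("unknown consensus token at position ", i, ": '", one, "'")
    }
  }
  tokens
}

#' Expand a degenerate consensus into concrete words
#'
#' Cartesian expansion over the per-position alternatives; the number of
#' words equals the product of alternative counts.
#'
#' @param consensus a [degenerate_consensus()] (or a pattern string).
#' @return Character vector of concrete DNA words.
#' @export
expand_degenerate <- function(consensus) {
  if (is.character(consensus)) consensus <- degenerate_consensus(consensus)
  stopifnot(inherits(consensus, "degenerate_consensus"))
  grid <- do.call(expand.grid,
                  c(rev(consensus$tokens),
                    list(stringsAsFactors = FALSE)))
  words <- do.call(paste0, rev(grid))
  unique(words)
}

#' Contiguous octamer derivatives of a nonamer
#'
#' The AU-rich element literature admits the nonamer or an octamer formed
#' by dropping one terminal base; these are the two contiguous 8-mer
#' windows of the 9-mer (duplicates collapse).
#'
#' @param nonamer a concrete word of length 9 (U accepted, canonicalised
#'   to T).
#' @return Character vector of one or two 8-mers.
#' @export
octamer_derivatives <- function(nonamer) {
  nonamer <- chartr("Uu", "Tt", toupper(nonamer))
  if (nchar(nonamer) != 9) stop("input must have length 9")
  unique(c(substr(nonamer, 1, 8), substr(nonamer, 2, 9)))
}

#' The Aft1/2 promoter consensus (PyPuCACCCPu)
#'
#' DNA site bound by the iron-responsive activators; scanned on both
#' strands of promoters.
#' @return A [degenerate_consensus()].
#' @export
consensus_aft1 <- function() {
  degenerate_consensus("PyPuCACCCPu", name = "Aft1",
                       region_target = "promoter",
                       strand_policy = "both")
}

#' The Cth2 AU-rich element consensus (UUAUUUAUU or octamer derivative)
#'
#' RNA destabilising element in 3' UTRs; scanned on the sense strand
#' only, including the two octamer derivatives.
#' @return A [degenerate_consensus()].
#' @export
consensus_are <- function() {
  degenerate_consensus("UUAUUUAUU", name = "ARE",
                       region_target = "utr3",
                       strand_policy = "sense",
                       derivatives = "octamer")
}

# Full concrete word set of a consensus, including derivatives.
consensus_words <- function(consensus) {
  words <- expand_degenerate(consensus)
  if (consensus$derivatives == "octamer") {
    words <- unique(c(words, unlist(lapply(words, octamer_derivatives))))
  }
  words
}

#' Build a sequence set
#'
#' @param gene,region,seq parallel vectors: gene id, region type
#'   (`"promoter"`/`"utr3"`), and sequence over {A,C,G,T,N}.
#' @param strand strand of the gene on its chromosome (informational).
#' @param truncated logical, region shortened at a chromosome edge.
#' @return A `sequence_set` data frame keyed uniquely by (gene, region).
#' @export
sequence_set <- function(gene, region, seq, strand = "+",
                         truncated = FALSE) {
  out <- data.frame(gene = gene, region = region, strand = strand,
                    seq = toupper(seq), truncated = truncated,
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out[, c("gene", "region")])) {
    stop("duplicate (gene, region) keys")
  }
  if (any(nchar(out$seq) == 0)) stop("empty sequence")
  class(out) <- c("sequence_set", "data.frame")
  out
}

# DNAStringSet view of a sequence_set, named "GENE|region".
as_dna_stringset <- function(seqs) {
  dss <- Biostrings::DNAStringSet(seqs$seq)
  names(dss) <- paste(seqs$gene, seqs$region, sep = "|")
  dss
}

#' Scan sequences for a degenerate consensus
#'
#' Every occurrence of every concrete expansion (plus octamer derivatives
#' when the consensus defines them) is located with exact string matching
#' (`Biostrings::vmatchPattern`, ambiguity-free so `N` never matches).
#' Under `strand_policy = "both"` the minus strand is scanned by matching
#' the reverse complement of each word; a minus-strand hit is reported at
#' the position of that reverse-complement instance on the stored
#' sequence. Overlapping hits of words of different length at the same
#' start are collapsed to the longest word by default.
#'
#' @param seqs a [sequence_set()].
#' @param consensus a [degenerate_consensus()].
#' @param dedupe `"collapse"` (longest word per (gene, region, strand,
#'   start)) or `"all"`.
#' @param restrict_region scan only records whose region matches the
#'   consensus `region_target` (default TRUE when the target is set).
#' @return A `motif_match` data frame: `gene`, `region`, `strand`,
#'   `start` (1-based on the stored sequence), `word`, `consensus`.
#' @export
scan_motifs <- function(seqs, consensus,
                        dedupe = c("collapse", "all"),
                        restrict_region = TRUE) {
  stopifnot(inherits(seqs, "sequence_set"),
            inherits(consensus, "degenerate_consensus"))
  dedupe <- match.arg(dedupe)
  if (restrict_region && !is.na(consensus$region_target)) {
    seqs <- seqs[seqs$region == consensus$region_target, , drop = FALSE]
  }
  empty <- data.frame(gene = character(), region = character(),
                      strand = character(), start = integer(),
                      word = character(), consensus = character(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("motif_match", "data.frame")
  if (nrow(seqs) == 0) return(empty)

  dss <- as_dna_stringset(seqs)
  words <- consensus_words(consensus)
  hits <- list()
  collect <- function(word, pattern, strand) {
    m <- Biostrings::vmatchPattern(pattern, dss, fixed = TRUE)
    starts <- Biostrings::startIndex(m)
    idx <- which(lengths(starts) > 0)
    if (length(idx) == 0) return(NULL)
    data.frame(
      gene = rep(seqs$gene[idx], lengths(starts)[idx]),
      region = rep(seqs$region[idx], lengths(starts)[idx]),
      strand = strand,
      start = unlist(starts[idx], use.names = FALSE),
      word = word, consensus = consensus$name,
      stringsAsFactors = FALSE
    )
  }
  for (w in words) {
    hits[[length(hits) + 1]] <- collect(w, w, "+")
    if (consensus$strand_policy == "both") {
      rc <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(w)))
      hits[[length(hits) + 1]] <- collect(w, rc, "-")
    }
  }
  out <- do.call(rbind, hits)
  if (is.null(out) || nrow(out) == 0) return(empty)
  out <- out[order(out$gene, out$region, out$strand, out$start,
                   -nchar(out$word), out$word), , drop = FALSE]
  if (dedupe == "collapse") {
    key <- paste(out$gene, out$region, out$strand, out$start, sep = "\r")
    out <- out[!duplicated(key), , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("motif_match", "data.frame")
  out
}

#' Extract promoter and 3'-UTR regions from a genome
#'
#' Promoters are the `promoter_len` nucleotides immediately upstream of
#' the annotated 5' gene end on the gene's strand (reverse-complemented
#' for minus-strand genes). The 3' UTR is the annotated UTR when
#' `utr3_start`/`utr3_end` columns are present, otherwise the `utr3_len`
#' nucleotides immediately downstream, reported on the sense strand of
#' the transcript. Regions running off a chromosome edge are truncated
#' and flagged. Annotation coordinates are 1-based inclusive; reported
#' match positions elsewhere in the package are 1-based on the stored
#' (strand-oriented) region sequence.
#'
#' @param genome a named `DNAStringSet` or path to a FASTA file.
#' @param annotation data frame with columns `gene`, `chrom`, `start`,
#'   `end`, `strand` (+/-), optionally `utr3_start`, `utr3_end`.
#' @param promoter_len,utr3_len window lengths in nucleotides.
#' @return A [sequence_set()] with one promoter and one utr3 record per
#'   gene.
#' @export
extract_regions <- function(genome, annotation,
                            promoter_len = 600, utr3_len = 200) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  # FASTA headers may carry descriptions; key on the first word.
  names(genome) <- sub("\\s.*$", "", names(genome))
  need <- c("gene", "chrom", "start", "end", "strand")
  if (!all(need %in% names(annotation))) {
    stop("annotation needs columns: ", paste(need, collapse = ", "))
  }
  recs <- list()
  for (i in seq_len(nrow(annotation))) {
    a <- annotation[i, ]
    if (!a$chrom %in% names(genome)) stop("unknown chromosome: ", a$chrom)
    clen <- Biostrings::nchar(genome[[a$chrom]])
    if (is.na(a$start) || is.na(a$end) || a$start < 1 || a$end > clen ||
        a$start > a$end) {
      stop("malformed coordinates for gene ", a$gene)
    }
    minus <- a$strand == "-"
    take <- function(from, to, revcomp) {
      trunc <- from < 1 || to > clen
      from <- max(from, 1); to <- min(to, clen)
      if (from > to) stop("region of gene ", a$gene,
                          " lies entirely outside the chromosome")
      s <- Biostrings::subseq(genome[[a$chrom]], from, to)
      if (revcomp) s <- Biostrings::reverseComplement(s)
      list(seq = as.character(s), truncated = trunc)
    }
    prom <- if (minus) take(a$end + 1, a$end + promoter_len, TRUE)
            else take(a$start - promoter_len, a$start - 1, FALSE)
    utr <- if (!is.null(annotation$utr3_start) && !is.na(a$utr3_start)) {
      take(a$utr3_start, a$utr3_end, minus)
    } else if (minus) {
      take(a$start - utr3_len, a$start - 1, TRUE)
    } else {
      take(a$end + 1, a$end + utr3_len, FALSE)
    }
    recs[[length(recs) + 1]] <- data.frame(
      gene = a$gene, region = c("promoter", "utr3"),
      strand = a$strand,
      seq = c(prom$seq, utr$seq),
      truncated = c(prom$truncated, utr$truncated),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, recs)
  sequence_set(out$gene, out$region, out$seq, out$strand, out$truncated)
}

#' Write a sequence set to FASTA
#'
#' Records are named `GENE|region`.
#' @param seqs a [sequence_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_region_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(as_dna_stringset(seqs), path)
  invisible(path)
}

#' Read a sequence set written by [write_region_fasta()]
#' @param path FASTA file with `GENE|region` record ids.
#' @return A [sequence_set()].
#' @export
read_region_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(dss), "|", fixed = TRUE)
  sequence_set(vapply(parts, `[`, "", 1), vapply(parts, `[`, "", 2),
               as.character(dss))
}
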