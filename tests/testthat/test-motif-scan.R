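test_that("degenerate expansion enumerates the Cartesian alternatives", {
  words <- expand_degenerate("PyPuCACCCPu")
  expect_length(words, 8) # 2 x 2 x 2
  expect_true(all(c("CACACCCA", "TGCACCCG") %in% words))
  expect_identical(expand_degenerate("ACGT"), "ACGT")
  expect_identical(expand_degenerate("UUAUUUAUU"), "TTATTTATT")
  expect_error(expand_degenerate("AC?T"), "unknown consensus token")
  expect_error(expand_degenerate("ACG"), "length")

  # cardinality equals the product of per-position alternative counts
  alt <- c(A = 1, C = 1, G = 1, T = 1, R = 2, Y = 2, S = 2, W = 2,
           K = 2, M = 2, B = 3, D = 3, H = 3, V = 3, N = 4)
  set.seed(8)
  for (i in 1:5) {
    pat <- paste(sample(names(alt), 6, replace = TRUE), collapse = "")
    expect_length(expand_degenerate(pat), prod(alt[strsplit(pat, "")[[1]]]))
  }
})

test_that("octamer derivatives are the two contiguous windows", {
  expect_setequal(octamer_derivatives("TTATTTATT"),
                  c("TTATTTAT", "TATTTATT"))
  expect_identical(octamer_derivatives("AAAAAAAAA"), "AAAAAAAA")
  expect_setequal(octamer_derivatives("UUAUUUAUU"),
                  c("TTATTTAT", "TATTTATT"))
  expect_error(octamer_derivatives("TTATTTAT"), "length 9")
})

test_that("ARE scanning finds the nonamer and collapses embedded octamers", {
  seqs <- sequence_set("g1", "utr3", "GGTTATTTATTGG")
  all_hits <- scan_motifs(seqs, consensus_are(), dedupe = "all")
  expect_true(any(all_hits$start == 3 & all_hits$word == "TTATTTATT"))
  expect_gt(nrow(all_hits), 1) # embedded octamer hits reported too
  collapsed <- scan_motifs(seqs, consensus_are())
  at3 <- collapsed[collapsed$start == 3, ]
  expect_identical(at3$word, "TTATTTATT") # longest word per position
  expect_true(all(collapsed$strand == "+")) # RNA element: sense only
})

test_that("minus-strand promoter sites are reported at the stored position", {
  # TGGGTGTG is the reverse complement of CACACCCA
  seq <- paste0("AAAA", "TGGGTGTG", "CCCC")
  seqs <- sequence_set("g1", "promoter", seq)
  hits <- scan_motifs(seqs, consensus_aft1(), dedupe = "all")
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$strand, "-")
  expect_identical(hits$start, 5L)
  expect_identical(hits$word, "CACACCCA")
  # N never matches
  seqs_n <- sequence_set("g1", "utr3", "GGTTATNTATTGG")
  expect_identical(nrow(scan_motifs(seqs_n, consensus_are(),
                                    dedupe = "all")), 0L)
})

test_that("the scanner agrees with a regex oracle on random sequences", {
  set.seed(99)
  n <- 200
  seqs <- vapply(seq_len(n), function(i) random_dna(2000), "")
  ids <- sprintf("g%03d", seq_len(n))

  for (cons in list(consensus_are(), consensus_aft1())) {
    region <- cons$region_target
    ss <- sequence_set(ids, region, seqs)
    got <- scan_motifs(ss, cons, dedupe = "all")
    got <- sorted_matches(data.frame(id = got$gene, strand = got$strand,
                                     start = got$start, word = got$word,
                                     stringsAsFactors = FALSE))
    words <- unique(c(expand_degenerate(cons),
                      if (cons$derivatives == "octamer") {
                        unlist(lapply(expand_degenerate(cons),
                                      octamer_derivatives))
                      }))
    want <- sorted_matches(oracle_scan(ids, seqs, words,
                                       cons$strand_policy == "both"))
    expect_equal(got, want)
  }
})

test_that("double-strand match multisets are strand symmetric", {
  set.seed(7)
  n <- 100
  seqs <- vapply(seq_len(n), function(i) random_dna(1500), "")
  ids <- sprintf("g%03d", seq_len(n))
  ss <- sequence_set(ids, "promoter", seqs)
  fwd <- scan_motifs(ss, consensus_aft1(), dedupe = "all")

  rc <- sequence_set(ids, "promoter", oracle_revcomp(seqs))
  rev <- scan_motifs(rc, consensus_aft1(), dedupe = "all")
  # map matches on the reverse-complemented set back: strand flips and
  # start reflects through the sequence
  L <- 1500
  rev$strand <- ifelse(rev$strand == "+", "-", "+")
  rev$start <- L - (rev$start + nchar(rev$word) - 1) + 1L
  key <- function(df) sort(paste(df$gene, df$strand, df$start, df$word))
  expect_identical(key(fwd), key(rev))
})

test_that("regions are extracted with correct windows, strands and edges", {
  set.seed(12)
  chr <- random_dna(3000)
  genome <- Biostrings::DNAStringSet(c(chr1 = chr))
  anno <- data.frame(
    gene = c("P", "M", "E"),
    chrom = "chr1",
    start = c(1001, 1001, 50),
    end = c(2000, 2000, 700),
    strand = c("+", "-", "+")
  )
  regs <- extract_regions(genome, anno, promoter_len = 600,
                          utr3_len = 200)
  get <- function(g, r) regs[regs$gene == g & regs$region == r, ]
  expect_identical(get("P", "promoter")$seq, substr(chr, 401, 1000))
  expect_identical(get("P", "utr3")$seq, substr(chr, 2001, 2200))
  expect_identical(get("M", "promoter")$seq,
                   oracle_revcomp(substr(chr, 2001, 2600)))
  expect_identical(get("M", "utr3")$seq,
                   oracle_revcomp(substr(chr, 801, 1000)))
  # promoter truncated at the chromosome start
  ep <- get("E", "promoter")
  expect_identical(nchar(ep$seq), 49L)
  expect_true(ep$truncated)
  expect_false(get("P", "promoter")$truncated)

  expect_error(extract_regions(genome,
                               transform(anno, chrom = "chrX")),
               "unknown chromosome")
  bad <- anno; bad$end[1] <- 9000
  expect_error(extract_regions(genome, bad), "malformed")

  # annotated 3' UTR overrides the downstream window
  anno2 <- data.frame(gene = "P", chrom = "chr1", start = 1001,
                      end = 2000, strand = "+",
                      utr3_start = 2001, utr3_end = 2100)
  regs2 <- extract_regions(genome, anno2)
  expect_identical(regs2$seq[regs2$region == "utr3"],
                   substr(chr, 2001, 2100))
})

test_that("region FASTA round-trips through GENE|region records", {
  ss <- sequence_set(c("A", "B"), c("promoter", "utr3"),
                     c("ACGTACGTAC", "TTATTTATTA"))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_region_fasta(ss, path)
  back <- read_region_fasta(path)
  expect_identical(back$gene, ss$gene)
  expect_identical(back$region, ss$region)
  expect_identical(back$seq, ss$seq)
})
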