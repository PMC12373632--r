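# Shared fixtures, built in code and memoised per test run.

ref_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_toy_reference(toy_fixture_spec(),
                                                     seed = 42L)
    cache
  }
})

toybam_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_toy_bam(ref_fixture(), seed = 42L,
                             dir = file.path(tempdir(), "splicesim-toybam"))
    }
    cache
  }
})

chars_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_default_characteristics()
    cache
  }
})

# SAM scaffolding for hand-built alignment cases -------------------------

sam_header <- function(targets) {
  c("@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", names(targets), unname(targets)))
}

# one proper pair; pos are 1-based SAM coordinates; qual defaults to Q30
sam_pair <- function(name, contig, pos1, cigar1, seq1, pos2, cigar2, seq2,
                     bc = "AAACCC", ub = NULL, qual1 = NULL, qual2 = NULL,
                     flag1 = 99L, flag2 = 147L) {
  if (is.null(qual1)) qual1 <- strrep("?", nchar(seq1))
  if (is.null(qual2)) qual2 <- strrep("?", nchar(seq2))
  tags <- character(0)
  if (!is.null(bc)) tags <- c(tags, sprintf("BC:Z:%s", bc))
  if (!is.null(ub)) tags <- c(tags, sprintf("UB:Z:%s", ub))
  tagf <- if (length(tags)) paste0("\t", paste(tags, collapse = "\t")) else ""
  c(sprintf("%s\t%d\t%s\t%d\t60\t%s\t=\t%d\t0\t%s\t%s%s",
            name, flag1, contig, pos1, cigar1, pos2, seq1, qual1, tagf),
    sprintf("%s\t%d\t%s\t%d\t60\t%s\t=\t%d\t0\t%s\t%s%s",
            name, flag2, contig, pos2, cigar2, pos1, seq2, qual2, tagf))
}

write_test_bam <- function(lines, targets, dir = tempfile("sam")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sam <- file.path(dir, "test.sam")
  writeLines(c(sam_header(targets), lines), sam)
  bam0 <- Rsamtools::asBam(sam, file.path(dir, "unsorted"),
                           overwrite = TRUE, indexDestination = FALSE)
  bam <- Rsamtools::sortBam(bam0, file.path(dir, "test"))
  Rsamtools::indexBam(bam)
  bam
}

# annotation with one single-transcript single-exon gene spanning
# [0, len) on chr1: the simplest possible estimation gene
single_exon_annotation <- function(len = 1000L, contig = "chr1",
                                   gene = "g1", strand = "+") {
  gene_annotation(data.frame(contig = contig, start = 0L, end = len,
                             strand = strand, gene_id = gene,
                             transcript_id = paste0(gene, ".t1"),
                             stringsAsFactors = FALSE))
}

# a minimal hand-made ground truth for simulator unit tests
manual_truth <- function(seqs, counts, population = NULL) {
  species <- data.frame(species_id = names(seqs),
                        gene_id = sub("\\..*$", "", names(seqs)),
                        type = "spliced", novelty = "annotated",
                        transcript_id = names(seqs),
                        sequence = unname(seqs), stringsAsFactors = FALSE)
  if (is.null(population)) population <- rep(1L, ncol(counts))
  rownames(counts) <- names(seqs)
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("cell%03d", seq_len(ncol(counts)))
  }
  list(transcripts = species, counts = counts, population = population)
}
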