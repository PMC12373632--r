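# The eight-step read simulator.

test_that("cell barcodes are distinct, sized and seed-stable", {
  bc <- assign_barcodes(200L, 16L, seed = 8L)
  expect_length(unique(bc), 200L)
  expect_true(all(nchar(bc) == 16L))
  expect_identical(bc, assign_barcodes(200L, 16L, seed = 8L))
  expect_error(assign_barcodes(5L, 1L), "barcode space")
})

test_that("UMI assignment expands counts with per-(cell,gene) uniqueness", {
  counts <- matrix(c(3L, 0L, 2L, 1L), nrow = 2L,
                   dimnames = list(c("tA", "tB"), c("c1", "c2")))
  species <- data.frame(species_id = c("tA", "tB"), gene_id = c("g1", "g1"))
  mols <- assign_umis(counts, species, umi_len = 4L, seed = 3L)
  expect_equal(nrow(mols), sum(counts))
  expect_equal(as.vector(table(mols$cell)), unname(colSums(counts)))
  for (cell in unique(mols$cell)) {
    expect_false(anyDuplicated(mols$umi[mols$cell == cell]) > 0)
  }
  expect_equal(nrow(assign_umis(counts * 0L, species, 4L)), 0L)
})

test_that("tagging prepends tag + UMI + GGG exactly", {
  expect_equal(tag_molecule("CCCCCCCC", "AAAA"),
               "ATTGCGCAATGCCCCCCCCGGGAAAA")
  expect_equal(nchar(tag_molecule("CCCCCCCC", "AAAA")), 11L + 8L + 3L + 4L)
  expect_equal(tag_molecule("CCCCCCCC", ""), "ATTGCGCAATGCCCCCCCCGGG")
})

test_that("PCR amplification inflates by PAF and records targets", {
  d2 <- empirical_distribution(2)
  amp <- pcr_amplify(10L, d2, paf = 3, seed = 1L)
  expect_true(all(amp$copies == 6L) && all(amp$target == 2L))
  amp1 <- pcr_amplify(10L, chars_fixture()$reads_per_umi, paf = 1, seed = 1L)
  expect_equal(amp1$copies, amp1$target)
  # mean copies tracks paf * mean(reads_per_umi) over many molecules
  rpu <- chars_fixture()$reads_per_umi
  amp_big <- pcr_amplify(10000L, rpu, paf = 5, seed = 2L)
  se <- sqrt(distribution_var(rpu) / 10000) * 5
  expect_lt(abs(mean(amp_big$copies) - 5 * distribution_mean(rpu)),
            3 * se + 0.5)  # 0.5 allows for round() granularity
})

test_that("UMI fragments are clamped 5' prefixes bearing the tag", {
  tagged <- tag_molecule("AAAAAAAA", strrep("ACGT", 250))  # 1022 nt
  f <- extract_umi_fragment(tagged, empirical_distribution(300), seed = 1L)
  expect_equal(f$frag_len, 300L)
  expect_equal(f$fragment, substr(tagged, 1, 300))
  expect_equal(f$remainder, substr(tagged, 301, nchar(tagged)))
  expect_true(startsWith(f$fragment, SMARTSEQ3_TAG))
  fbig <- extract_umi_fragment(tagged, empirical_distribution(5000))
  expect_equal(fbig$fragment, tagged)
  expect_equal(fbig$remainder, "")
})

test_that("internal fragments are remainder substrings in ratio counts", {
  remainder <- strrep("ACGTTGCA", 100)  # 800 nt
  fr <- extract_internal_fragments(remainder, 3L,
                                   empirical_distribution(2),
                                   empirical_distribution(120), seed = 2L)
  expect_equal(nrow(fr), 6L)  # ratio 2 x 3 UMI fragments
  for (i in seq_len(nrow(fr))) {
    expect_equal(fr$fragment[i],
                 substr(remainder, fr$offset[i] + 1L,
                        fr$offset[i] + fr$frag_len[i]))
    expect_true(grepl(fr$fragment[i], remainder, fixed = TRUE))
  }
  empty <- extract_internal_fragments("", 5L, empirical_distribution(2),
                                      empirical_distribution(120))
  expect_equal(nrow(empty), 0L)
})

test_that("internal orientation flips half the fragments and involutes", {
  set.seed(5)
  frags <- vapply(1:10000, function(i)
    paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = ""),
    character(1))
  out <- orient_internal(frags, seed = 6L)
  anti <- mean(out$orientation == "antisense")
  expect_lt(abs(anti - 0.5), 3 * sqrt(0.25 / 10000))
  flipped <- out$orientation == "antisense"
  expect_equal(revcomp(out$fragment[flipped]), frags[flipped])
  expect_equal(out$fragment[!flipped], frags[!flipped])
  expect_error(orient_internal("ACGT", role = "umi"), "internal")
})

test_that("read pairs take the fragment's two ends in FR geometry", {
  frag <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  pr <- make_read_pair(frag, 150L)
  expect_equal(pr$read1, substr(frag, 1, 150))
  expect_equal(pr$read2, revcomp(substr(frag, 251, 400)))
  short <- make_read_pair(substr(frag, 1, 100), 150L)
  expect_equal(nchar(short$read1), 100L)
  expect_equal(short$read2, revcomp(short$read1))
})

test_that("error injection is Bernoulli per base over the alphabet", {
  seqs <- rep(strrep("ACGT", 50), 100)
  expect_identical(inject_errors(seqs, 0), seqs)
  all_err <- inject_errors(seqs, 1, seed = 3L)
  expect_true(all(nchar(all_err) == nchar(seqs)))
  a <- strsplit(paste(seqs, collapse = ""), "")[[1L]]
  b <- strsplit(paste(all_err, collapse = ""), "")[[1L]]
  expect_true(all(a != b))
  expect_true(all(b %in% c("A", "C", "G", "T")))
  mid <- inject_errors(seqs, 0.01, seed = 4L)
  rate <- mean(a != strsplit(paste(mid, collapse = ""), "")[[1L]])
  n <- sum(nchar(seqs))
  expect_lt(abs(rate - 0.01), 3 * sqrt(0.01 * 0.99 / n))
})

test_that("subsampling restores per-molecule targets and the balance", {
  mol <- rep(1:3, c(6L, 6L, 3L))
  targets <- c(2L, 6L, 1L)
  sub <- subsample_reads(mol, targets, n_internal = 100L, seed = 5L)
  kept <- tapply(sub$keep_umi, mol, sum)
  expect_equal(as.vector(kept, mode = "integer"), c(2L, 6L, 1L))
  expect_equal(sum(sub$keep_internal), round(sub$retention * 100))
  # paf = 1 means copies == targets: everything is retained
  sub1 <- subsample_reads(rep(1:4, 2:5), 2:5, n_internal = 10L, seed = 1L)
  expect_true(all(sub1$keep_umi))
  expect_true(all(sub1$keep_internal))
})

test_that("quality strings follow the positional profile", {
  q30 <- list(empirical_distribution(30))
  expect_equal(assign_quality(c(4L, 2L), q30), c("????", "??"))
  # extension rule: positions beyond the profile reuse the last position
  prof <- list(empirical_distribution(40), empirical_distribution(10))
  q <- assign_quality(6L, prof)
  expect_equal(phred_scores(q), c(40L, rep(10L, 5L)))
  # sampled means track profile means
  chars <- chars_fixture()
  qs <- assign_quality(rep(150L, 3000L), chars$quality_by_position_read,
                       seed = 2L)
  mat <- vapply(qs, phred_scores, integer(150))
  for (pos in c(1L, 75L, 150L)) {
    d <- chars$quality_by_position_read[[pos]]
    se <- sqrt(distribution_var(d) / 3000)
    expect_lt(abs(mean(mat[pos, ]) - distribution_mean(d)), 4 * se)
  }
})

test_that("a one-molecule simulation is reconstructible by hand", {
  txseq <- strrep("ACGGTTCA", 125)  # 1000 nt
  truth <- manual_truth(c(gX.t1 = txseq),
                        matrix(1L, 1L, 1L))
  chars <- chars_fixture()
  cfg <- simulation_config(error_rate = 0, paf = 1)
  sim <- simulate_reads(truth, chars, cfg, seed = 21L)
  led <- sim$ledger
  expect_true(all(led$species_id == "gX.t1"))
  umi_reads <- sim$reads[led$role == "umi", ]
  umi <- led$umi[led$role == "umi"][1L]
  tagged <- tag_molecule(umi, txseq)
  for (i in seq_len(nrow(umi_reads))) {
    row <- led[led$role == "umi", ][i, ]
    frag <- substr(tagged, row$frag_start + 1L, row$frag_end)
    expect_equal(umi_reads$read1[i], substr(frag, 1, 150))
    expect_true(startsWith(umi_reads$read1[i],
                           paste0(SMARTSEQ3_TAG, umi, "GGG")))
  }
  # with P = 0 the ledger reconstruction matches every read exactly
  er <- measure_error_rate(sim, truth)
  expect_equal(er$mismatches, 0L)
})

test_that("an empty count matrix yields valid empty outputs", {
  truth <- manual_truth(c(gX.t1 = strrep("ACGT", 100)),
                        matrix(0L, 1L, 2L))
  prefix <- tempfile("empty")
  sim <- simulate_reads(truth, chars_fixture(), seed = 1L,
                        out_prefix = prefix)
  expect_equal(nrow(sim$reads), 0L)
  expect_equal(nrow(read_fastq(paste0(prefix, "_R1.fastq"))), 0L)
})

test_that("identical seeds give byte-identical FASTQ output", {
  ref <- ref_fixture()
  chars <- chars_fixture()
  truth <- build_ground_truth(ref$annotation, ref$genome, chars,
                              population_design(1L, 2L), k = 2L, seed = 13L)
  run <- function(prefix) {
    simulate_reads(truth, chars, simulation_config(paf = 2), seed = 31L,
                   out_prefix = prefix)
    tools::md5sum(paste0(prefix, c("_R1.fastq", "_R2.fastq", "_truth.tsv")))
  }
  m1 <- run(tempfile("detA"))
  m2 <- run(tempfile("detB"))
  expect_equal(unname(m1), unname(m2))
})

test_that("UMI-containing reads keep sense and trace their truth entries", {
  ref <- ref_fixture()
  chars <- chars_fixture()
  truth <- build_ground_truth(ref$annotation, ref$genome, chars,
                              population_design(2L, 3L), k = 3L, seed = 7L)
  sim <- simulate_reads(truth, chars, simulation_config(paf = 2,
                                                        error_rate = 0),
                        seed = 9L)
  led <- sim$ledger
  expect_true(all(led$orientation[led$role == "umi"] == "sense"))
  expect_true(all(startsWith(
    sim$reads$read1[led$role == "umi"],
    paste0(SMARTSEQ3_TAG, led$umi[led$role == "umi"], "GGG"))))
  # read ids parse back to the ledger fields
  parts <- strsplit(sim$reads$id, ":")
  expect_true(all(vapply(parts, length, integer(1)) == 5L))
  expect_equal(vapply(parts, `[[`, character(1), 1L), led$barcode)
  expect_equal(vapply(parts, `[[`, character(1), 5L), led$species_id)
  # distinct (cell, species, UMI) triples equal the count-matrix total
  umi_led <- led[led$role == "umi", ]
  expect_equal(length(unique(paste(umi_led$cell, umi_led$species_id,
                                   umi_led$umi))),
               sum(truth$counts))
})
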