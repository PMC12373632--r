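# Ground-truth construction: transcript selection, novel splice events,
# and the gene-UMI x PSI x unspliced matrix cascade.

three_tx_ann <- function() {
  # genes with 1, 2 and 3 transcripts
  rows <- list()
  add <- function(g, t, s, e) data.frame(contig = "chr1", start = s, end = e,
                                         strand = "+", gene_id = g,
                                         transcript_id = t,
                                         stringsAsFactors = FALSE)
  gene_annotation(rbind(
    add("g1", "g1.t1", 0L, 100L),
    add("g2", "g2.t1", 200L, 300L), add("g2", "g2.t2", 200L, 250L),
    add("g3", "g3.t1", 400L, 500L), add("g3", "g3.t2", 400L, 450L),
    add("g3", "g3.t3", 450L, 500L)))
}

test_that("transcript selection honours eligibility and forced choices", {
  ann <- three_tx_ann()
  sel <- get_transcripts(ann, k = 2L, n = 2L, seed = 3L)
  expect_setequal(unique(sel$gene_id), c("g2", "g3"))
  expect_equal(as.vector(table(sel$gene_id)), c(2L, 2L))
  sel2 <- get_transcripts(ann, gene_list = c("g1", "g2"), n = 2L, seed = 3L)
  expect_equal(unique(sel2$gene_id), "g2")
  expect_setequal(sel2$transcript_id, c("g2.t1", "g2.t2"))
  expect_error(get_transcripts(ann, k = 3L, n = 2L), "2 gene")
})

test_that("novel junctions join exon pairs no annotated transcript uses", {
  # exons A [0,100), B [200,300), C [400,500); chains A-B and B-C
  ann <- gene_annotation(data.frame(
    contig = "chr1",
    start = c(0L, 200L, 200L, 400L), end = c(100L, 300L, 300L, 500L),
    strand = "+", gene_id = "g",
    transcript_id = c("tAB", "tAB", "tBC", "tBC"), stringsAsFactors = FALSE))
  # enumeration oracle: ordered non-overlapping exon pairs minus annotated
  # junctions leaves exactly A-C
  for (seed in 1:5) {
    nj <- add_new_junction(ann, "g", seed = seed)
    expect_equal(nj$junction, c(100L, 400L))
    expect_true(any(nj$exons$end == 100L) && any(nj$exons$start == 400L))
  }
  single <- gene_annotation(data.frame(contig = "chr1", start = 0L,
                                       end = 100L, strand = "+",
                                       gene_id = "s", transcript_id = "s.t"))
  expect_error(add_new_junction(single, "s"), "no novel junction")
})

test_that("novel-junction chains differ from every annotated chain", {
  ann <- ref_fixture()$annotation
  for (g in c("gB1", "gC1", "gD2")) {
    nj <- add_new_junction(ann, g, seed = 17L)
    chains <- vapply(annotation_transcripts(ann, g), function(tx) {
      ex <- transcript_exons(ann, tx)
      paste(ex$start, ex$end, collapse = ";")
    }, character(1))
    novel_chain <- paste(nj$exons$start, nj$exons$end, collapse = ";")
    expect_false(novel_chain %in% chains)
    aug <- add_transcripts(ann, nj)
    expect_true(nj$transcript_id %in% annotation_transcripts(aug, g))
  }
})

test_that("novel exons land on planted canonical sites, both strands", {
  # plus strand: intron [100,300) with a single AG...GT slot for a 6 nt
  # exon at [150,156)
  intron <- strrep("C", 200)
  substr(intron, 49, 50) <- "AG"   # genomic [148,150)
  substr(intron, 57, 58) <- "GT"   # genomic [156,158)
  contig <- paste0(strrep("T", 100), intron, strrep("T", 100))
  genome_p <- Biostrings::DNAStringSet(c(chr1 = contig))
  ann_p <- gene_annotation(data.frame(
    contig = "chr1", start = c(0L, 300L), end = c(100L, 400L), strand = "+",
    gene_id = "g", transcript_id = "g.t1", stringsAsFactors = FALSE))
  ne <- add_new_exon(ann_p, genome_p, "g", exon_length_range = c(4L, 8L))
  expect_equal(unname(ne$novel_exon), c(150L, 156L))
  expect_true(verify_canonical_exon(genome_p, "chr1", "+", 150L, 156L))
  expect_equal(nrow(ne$exons), 3L)

  # minus strand: same placement demands genomic AC before and CT after,
  # built by hand-reverse-complementing the plus-strand reasoning
  intron_m <- strrep("C", 200)
  substr(intron_m, 49, 50) <- "AC"
  substr(intron_m, 57, 58) <- "CT"
  genome_m <- Biostrings::DNAStringSet(
    c(chr1 = paste0(strrep("T", 100), intron_m, strrep("T", 100))))
  ann_m <- ann_p
  ann_m$exons$strand <- "-"
  ne_m <- add_new_exon(ann_m, genome_m, "g", exon_length_range = c(4L, 8L))
  expect_equal(unname(ne_m$novel_exon), c(150L, 156L))
  expect_true(verify_canonical_exon(genome_m, "chr1", "-", 150L, 156L))

  # motif removed: canonical search fails, non-canonical succeeds
  genome_x <- Biostrings::DNAStringSet(
    c(chr1 = paste0(strrep("T", 100), strrep("C", 200), strrep("T", 100))))
  expect_error(add_new_exon(ann_p, genome_x, "g",
                            exon_length_range = c(4L, 8L)),
               "introns searched")
  ne_nc <- add_new_exon(ann_p, genome_x, "g", canonical = FALSE,
                        exon_length_range = c(4L, 8L), seed = 2L)
  expect_gte(ne_nc$novel_exon[1L], 101L)
  expect_lte(ne_nc$novel_exon[2L], 299L)
})

test_that("gene UMI matrices respect minimum counts and size factors", {
  chars <- chars_fixture()
  gene_table <- data.frame(gene_id = rep(c("gA", "gB"), each = 2L),
                           transcript_id = paste0("t", 1:4))
  design <- population_design(2L, 50L)
  gm <- generate_gene_umi_matrix(chars, design, gene_table, seed = 5L)
  expect_true(all(gm$counts >= 2L))            # n_min = transcripts per gene
  expect_true(all(gm$size_factors >= 0.25 & gm$size_factors <= 4))
  # counts follow round-half-even scaling of the population base counts
  for (j in seq_len(ncol(gm$counts))) {
    expected <- pmax(gm$n_min,
                     as.integer(round(gm$base[, gm$population[j]] *
                                        gm$size_factors[j])))
    expect_equal(unname(gm$counts[, j]), unname(expected))
  }
  # distribution support too small for the minimum: hard error
  tiny <- chars
  tiny$umis_per_gene <- empirical_distribution(1)
  gt4 <- data.frame(gene_id = "gA", transcript_id = paste0("t", 1:4))
  expect_error(generate_gene_umi_matrix(tiny, design, gt4), "minimum")
})

test_that("PSI matrices are simplex draws shared or split by population", {
  design <- population_design(3L, 2L, n_diff_splicing = 1L)
  gene_table <- data.frame(
    gene_id = c("g1", rep("g2", 2L), rep("g3", 3L)),
    transcript_id = paste0("t", 1:6))
  psi <- generate_psi_matrix(gene_table, design, seed = 11L)
  expect_equal(unname(psi["t1", ]), rep(100, 3L))  # single-transcript gene
  for (g in unique(gene_table$gene_id)) {
    rows <- gene_table$gene_id == g
    expect_equal(unname(colSums(psi[rows, , drop = FALSE])), rep(100, 3L),
                 tolerance = 1e-12)
  }
  diff_genes <- attr(psi, "differential")
  expect_length(diff_genes, 1L)
  for (g in setdiff(unique(gene_table$gene_id), diff_genes)) {
    rows <- gene_table$gene_id == g
    expect_equal(psi[rows, 1L], psi[rows, 2L])
    expect_equal(psi[rows, 1L], psi[rows, 3L])
  }
  if (sum(gene_table$gene_id == diff_genes) > 1L) {
    rows <- gene_table$gene_id == diff_genes
    expect_false(isTRUE(all.equal(psi[rows, 1L], psi[rows, 2L])))
  }
})

test_that("unspliced matrices pass custom values through and sample fixed", {
  chars <- chars_fixture()
  design <- population_design(2L, 3L, n_diff_unspliced = 1L)
  genes <- c("g1", "g2", "g3")
  m <- generate_unspliced_matrix(chars, genes, design, seed = 4L)
  expect_true(all(m >= 0 & m <= 1))
  fixed <- setdiff(genes, attr(m, "differential"))
  for (g in fixed) expect_equal(m[g, 1L], m[g, 2L])
  # single-nuclei style custom matrix passes through verbatim
  custom <- matrix(0.9, nrow = 3L, ncol = 2L)
  out <- generate_unspliced_matrix(chars, genes, design,
                                   custom_matrix = custom)
  expect_equal(unname(out), unname(custom))
  bad <- custom; bad[1L] <- 1.2
  expect_error(generate_unspliced_matrix(chars, genes, design,
                                         custom_matrix = bad), "\\[0,1\\]")
  # a distribution concentrated at zero yields an all-zero matrix
  zero <- chars
  zero$unspliced_fraction <- empirical_distribution(0)
  z <- generate_unspliced_matrix(zero, genes, design, seed = 1L)
  expect_true(all(z == 0))
})

test_that("combine_truth apportions counts by the stated arithmetic", {
  gene_table <- data.frame(gene_id = "g", transcript_id = c("tA", "tB"))
  mk <- function(G, unspl_frac, psi_vec) {
    gm <- structure(list(counts = matrix(G, 1L, 1L,
                                         dimnames = list("g", "cell001")),
                         population = 1L), class = "gene_umi_matrix")
    psi <- matrix(psi_vec, ncol = 1L,
                  dimnames = list(gene_table$transcript_id, NULL))
    un <- matrix(unspl_frac, 1L, 1L, dimnames = list("g", NULL))
    combine_truth(gm, psi, un, gene_table)
  }
  out <- mk(100L, 0, c(60, 40))
  expect_equal(unname(out$counts[, 1L]), c(60L, 40L, 0L))
  out2 <- mk(10L, 0.2, c(50, 50))
  expect_equal(unname(out2$counts["g.unspliced", 1L]), 2L)
  expect_equal(unname(out2$counts[c("tA", "tB"), 1L]), c(4L, 4L))
})

test_that("combine_truth conserves per-gene per-cell totals exactly", {
  set.seed(77)
  for (rep in 1:200) {
    n_genes <- sample(1:4, 1L)
    ntx <- sample(1:4, n_genes, replace = TRUE)
    genes <- sprintf("g%d", seq_len(n_genes))
    gene_table <- data.frame(
      gene_id = rep(genes, ntx),
      transcript_id = sprintf("g%d.t%d", rep(seq_len(n_genes), ntx),
                              unlist(lapply(ntx, seq_len))))
    p <- sample(1:3, 1L); n_cells <- sample(1:4, 1L)
    counts <- matrix(sample(0:50, n_genes * n_cells, replace = TRUE),
                     n_genes, dimnames = list(genes, NULL))
    colnames(counts) <- sprintf("c%d", seq_len(n_cells))
    gm <- structure(list(counts = counts,
                         population = sample(seq_len(p), n_cells,
                                             replace = TRUE)),
                    class = "gene_umi_matrix")
    psi <- matrix(0, nrow(gene_table), p,
                  dimnames = list(gene_table$transcript_id, NULL))
    for (g in genes) {
      rows <- gene_table$gene_id == g
      for (q in seq_len(p)) {
        v <- stats::rexp(sum(rows))
        psi[rows, q] <- 100 * v / sum(v)
      }
    }
    un <- matrix(stats::runif(n_genes * p), n_genes, p,
                 dimnames = list(genes, NULL))
    out <- combine_truth(gm, psi, un, gene_table)
    for (g in genes) {
      rows <- out$species$gene_id == g
      expect_equal(unname(colSums(out$counts[rows, , drop = FALSE])),
                   unname(counts[g, ]))
    }
    expect_true(all(out$counts >= 0L))
  }
})

test_that("ground truths are seed-deterministic and write/read cleanly", {
  ref <- ref_fixture()
  chars <- chars_fixture()
  design <- population_design(2L, 3L, n_diff_splicing = 1L,
                              n_diff_unspliced = 1L)
  build <- function() build_ground_truth(ref$annotation, ref$genome, chars,
                                         design, k = 3L,
                                         transcripts_per_gene = 2L,
                                         novel_junctions = 1L,
                                         novel_exons = 1L, seed = 99L)
  t1 <- build(); t2 <- build()
  expect_identical(t1$counts, t2$counts)
  expect_identical(t1$psi, t2$psi)
  expect_identical(t1$transcripts$sequence, t2$transcripts$sequence)
  expect_setequal(unique(t1$transcripts$novelty),
                  c("annotated", "novel-junction", "novel-exon", "pre-mRNA"))
  # sequence length equals the exon-length sum for every spliced species
  sp <- t1$transcripts[t1$transcripts$type == "spliced", ]
  for (i in seq_len(nrow(sp))) {
    ex <- transcript_exons(t1$annotation, sp$transcript_id[i])
    expect_equal(nchar(sp$sequence[i]), sum(ex$end - ex$start))
  }
  dir <- tempfile("truth")
  write_ground_truth(t1, dir)
  back <- read_ground_truth(dir)
  expect_equal(back$counts, t1$counts)
  expect_equal(back$transcripts$sequence[
    match(t1$transcripts$species_id, back$transcripts$species_id)],
    t1$transcripts$sequence)
  expect_equal(back$population, t1$population)
})
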