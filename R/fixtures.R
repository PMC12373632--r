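# Synthetic fixtures: a toy genome and annotation with planted splice
# structures, a toy tagged BAM with full bookkeeping, and parametric
# default characteristics. Everything the package needs to run and test
# end to end is generated here, from a seed, with no downloads.
#
# The fixture laws are simple parametric stand-ins chosen at Smart-seq3
# scale: discretised log-normal fragment lengths, geometric reads per
# UMI, mostly-spliced unspliced fractions. They are not copies of any
# real dataset's statistics.

#' Describe a synthetic fixture set
#'
#' Bundles the layout of the toy reference (contigs, planted exon/intron
#' lengths) and the sampling laws of the toy BAM. Every planted structure
#' (estimation genes, canonical splice-site positions) is re-derivable
#' from the returned spec.
#'
#' @param n_contigs Number of contigs `chr1..chrN`; each contig carries
#'   one single-transcript estimation gene and three multi-transcript
#'   genes with planted canonical-site introns.
#' @param bam_read_len Read length of toy BAM records.
#' @param bam_cells Number of cell barcodes in the toy BAM.
#' @param bam_frag_meanlog,bam_frag_sdlog Log-normal law of toy-BAM
#'   exonic fragment lengths (nt).
#' @param bam_frag_range Clipping range of those lengths.
#' @param bam_reads_per_umi_p Geometric success probability: reads per
#'   UMI is `1 + Geom(p)`, truncated at 8.
#' @param bam_umis_per_gene_lambda Poisson intensity of UMIs per
#'   (estimation gene, cell); 5 is added so every gene-cell has data.
#' @return Object of class `fixture_spec`.
#' @export
toy_fixture_spec <- function(n_contigs = 2L, bam_read_len = 100L,
                             bam_cells = 4L,
                             bam_frag_meanlog = log(400),
                             bam_frag_sdlog = 0.25,
                             bam_frag_range = c(150L, 1200L),
                             bam_reads_per_umi_p = 0.5,
                             bam_umis_per_gene_lambda = 15) {
  stopifnot(n_contigs >= 1L)
  structure(list(n_contigs = as.integer(n_contigs),
                 bam_read_len = as.integer(bam_read_len),
                 bam_cells = as.integer(bam_cells),
                 bam_frag_meanlog = bam_frag_meanlog,
                 bam_frag_sdlog = bam_frag_sdlog,
                 bam_frag_range = as.integer(bam_frag_range),
                 bam_reads_per_umi_p = bam_reads_per_umi_p,
                 bam_umis_per_gene_lambda = bam_umis_per_gene_lambda),
            class = "fixture_spec")
}

# one contig's gene layout: exon lengths, intron lengths, transcript
# chains (exon index lists), strand, planted novel-exon slot (intron
# index, offset, length) or NULL
contig_layout <- function(ci) {
  list(
    list(gene = sprintf("gE%d", ci), strand = "+",
         exons = c(500L, 400L, 500L), introns = c(300L, 300L),
         chains = list(t1 = 1:3), planted = NULL),
    list(gene = sprintf("gB%d", ci), strand = "+",
         exons = c(400L, 350L, 300L, 450L), introns = c(250L, 350L, 250L),
         chains = list(t1 = 1:4, t2 = c(1L, 3L, 4L)),
         planted = list(intron = 3L, offset = 60L, len = 80L)),
    list(gene = sprintf("gC%d", ci), strand = "-",
         exons = c(350L, 300L, 400L), introns = c(300L, 300L),
         chains = list(t1 = 1:3, t2 = c(2L, 3L)),
         planted = list(intron = 1L, offset = 80L, len = 60L)),
    list(gene = sprintf("gD%d", ci), strand = "+",
         exons = c(300L, 250L, 300L, 250L), introns = c(200L, 200L, 200L),
         chains = list(t1 = 1:4, t2 = c(1L, 2L, 4L), t3 = c(1L, 3L, 4L)),
         planted = NULL))
}

#' Build the toy reference genome and annotation
#'
#' Lays out non-overlapping genes along contigs `chr1..chrN`: per contig
#' one single-transcript gene (so fragment-length estimation has a clean
#' target) and three multi-transcript genes, one of them on the minus
#' strand. Selected introns carry planted canonical splice motifs (AG
#' acceptor / GT donor on the sense strand) at recorded positions so
#' novel-exon injection has known ground truth.
#'
#' @param spec A `fixture_spec`.
#' @param seed Integer seed.
#' @param dir Optional directory; writes `genome.fa` and
#'   `annotation.gtf` there.
#' @return List with `genome` (named `DNAStringSet`), `annotation`
#'   (`gene_annotation`), `planted` (data.frame of planted novel-exon
#'   sites: gene, contig, strand, intron bounds and exon coordinates,
#'   0-based half-open), and the file paths when `dir` is given.
#' @export
make_toy_reference <- function(spec = toy_fixture_spec(), seed = 1L,
                               dir = NULL) {
  set.seed(seed)
  contigs <- character(spec$n_contigs)
  names(contigs) <- sprintf("chr%d", seq_len(spec$n_contigs))
  exon_rows <- list()
  planted <- list()
  for (ci in seq_len(spec$n_contigs)) {
    cursor <- 100L
    pieces <- list(random_dna(1L, 100L))
    for (g in contig_layout(ci)) {
      n_ex <- length(g$exons)
      starts <- integer(n_ex); ends <- integer(n_ex)
      gene_seq_parts <- list()
      for (i in seq_len(n_ex)) {
        starts[i] <- cursor
        ends[i] <- cursor + g$exons[i]
        gene_seq_parts[[length(gene_seq_parts) + 1L]] <-
          random_dna(1L, g$exons[i])
        cursor <- ends[i]
        if (i < n_ex) {
          intron <- random_dna(1L, g$introns[i])
          if (!is.null(g$planted) && g$planted$intron == i) {
            # plant a canonical novel-exon site at a recorded position
            s <- g$planted$offset            # exon start within intron
            e <- s + g$planted$len           # exon end within intron
            stopifnot(s >= 2L, e + 2L <= g$introns[i])
            if (g$strand == "+") {
              substr(intron, s - 1L, s) <- "AG"
              substr(intron, e + 1L, e + 2L) <- "GT"
            } else {
              substr(intron, s - 1L, s) <- "AC"  # sense-strand GT donor
              substr(intron, e + 1L, e + 2L) <- "CT"  # sense-strand AG acceptor
            }
            planted[[length(planted) + 1L]] <- data.frame(
              gene_id = g$gene, contig = names(contigs)[ci],
              strand = g$strand,
              intron_start = cursor, intron_end = cursor + g$introns[i],
              exon_start = cursor + s, exon_end = cursor + e,
              stringsAsFactors = FALSE)
          }
          gene_seq_parts[[length(gene_seq_parts) + 1L]] <- intron
          cursor <- cursor + g$introns[i]
        }
      }
      pieces[[length(pieces) + 1L]] <- paste(unlist(gene_seq_parts),
                                             collapse = "")
      for (tx in names(g$chains)) {
        idx <- g$chains[[tx]]
        exon_rows[[length(exon_rows) + 1L]] <- data.frame(
          contig = names(contigs)[ci], start = starts[idx], end = ends[idx],
          strand = g$strand, gene_id = g$gene,
          transcript_id = sprintf("%s.%s", g$gene, tx),
          stringsAsFactors = FALSE)
      }
      pieces[[length(pieces) + 1L]] <- random_dna(1L, 500L)
      cursor <- cursor + 500L
    }
    contigs[ci] <- paste(unlist(pieces), collapse = "")
  }
  genome <- Biostrings::DNAStringSet(contigs)
  ann <- gene_annotation(do.call(rbind, exon_rows))
  out <- list(genome = genome, annotation = ann,
              planted = do.call(rbind, planted), spec = spec)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    out$genome_path <- file.path(dir, "genome.fa")
    out$gtf_path <- file.path(dir, "annotation.gtf")
    write_genome(genome, out$genome_path)
    write_annotation(ann, out$gtf_path)
  }
  out
}

# map a transcript-coordinate interval [fs, fe) to genomic blocks over a
# plus-strand exon chain; returns data.frame(start, end) 0-based half-open
transcript_interval_blocks <- function(exons, fs, fe) {
  widths <- exons$end - exons$start
  offs <- cumsum(c(0L, widths))
  blocks <- list()
  for (i in seq_len(nrow(exons))) {
    a <- max(fs, offs[i]); b <- min(fe, offs[i + 1L])
    if (a < b) {
      blocks[[length(blocks) + 1L]] <-
        data.frame(start = exons$start[i] + (a - offs[i]),
                   end = exons$start[i] + (b - offs[i]))
    }
  }
  do.call(rbind, blocks)
}

blocks_to_cigar <- function(blocks) {
  parts <- sprintf("%dM", blocks$end - blocks$start)
  if (nrow(blocks) > 1L) {
    gaps <- sprintf("%dN", blocks$start[-1L] - blocks$end[-nrow(blocks)])
    paste0(paste0(parts[-length(parts)], gaps, collapse = ""),
           parts[length(parts)])
  } else {
    parts
  }
}

#' Build a toy tagged BAM with known bookkeeping
#'
#' Emits coordinate-sorted, indexed BAM alignments over the toy
#' reference's estimation genes, with cell barcodes in the BC tag and
#' UMIs in the UB tag. Fragment exonic lengths, reads-per-UMI
#' multiplicities, internal-to-UMI ratios and intronic (unspliced)
#' coverage are drawn from the fixture-spec laws and recorded in a truth
#' ledger, so [characterize_data()] output can be compared to known
#' inputs. Also plants one secondary alignment and one pair without a BC
#' tag to exercise the skip rules.
#'
#' @param reference Result of [make_toy_reference()].
#' @param spec A `fixture_spec` (defaults to the reference's).
#' @param seed Integer seed.
#' @param dir Directory for the BAM (created if needed).
#' @return List with `bam_path` and `ledger` (one row per intended pair:
#'   qname, gene, barcode, umi (`NA` for internal), role, exonic length,
#'   intronic flag).
#' @export
make_toy_bam <- function(reference, spec = reference$spec, seed = 1L,
                         dir = tempfile("toybam")) {
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- reference$annotation
  genome <- reference$genome
  est <- select_estimation_genes(ann)
  stopifnot(length(est) >= 1L)
  cells <- random_dna(spec$bam_cells, 12L)
  rl <- spec$bam_read_len
  draw_len <- function(n, max_len) {
    pmin(pmax(as.integer(round(stats::rlnorm(n, spec$bam_frag_meanlog,
                                             spec$bam_frag_sdlog))),
              spec$bam_frag_range[1L]),
         min(spec$bam_frag_range[2L], max_len))
  }
  sam <- character(0)
  ledger <- list()
  qn <- 0L
  qual_str <- function() {
    phred_string(c(rep(37L, min(50L, rl)), rep(33L, max(0L, rl - 50L))))
  }
  emit_pair <- function(gene, tx_exons, contig, fs, fe, bc, ub) {
    qn <<- qn + 1L
    name <- sprintf("pair%05d", qn)
    L <- fe - fs
    k <- min(rl, L)
    b1 <- transcript_interval_blocks(tx_exons, fs, fs + k)
    b2 <- transcript_interval_blocks(tx_exons, fe - k, fe)
    fetch <- function(b) {
      paste(vapply(seq_len(nrow(b)), function(i) {
        as.character(Biostrings::subseq(genome[[contig]], b$start[i] + 1L,
                                        b$end[i]))
      }, character(1)), collapse = "")
    }
    tags <- if (is.na(bc)) character(0) else sprintf("BC:Z:%s", bc)
    if (!is.na(ub)) tags <- c(tags, sprintf("UB:Z:%s", ub))
    tagf <- if (length(tags)) paste0("\t", paste(tags, collapse = "\t")) else ""
    r1 <- sprintf("%s\t99\t%s\t%d\t60\t%s\t=\t%d\t%d\t%s\t%s%s",
                  name, contig, b1$start[1L] + 1L, blocks_to_cigar(b1),
                  b2$start[1L] + 1L, fe - fs, fetch(b1), qual_str(), tagf)
    r2 <- sprintf("%s\t147\t%s\t%d\t60\t%s\t=\t%d\t%d\t%s\t%s%s",
                  name, contig, b2$start[1L] + 1L, blocks_to_cigar(b2),
                  b1$start[1L] + 1L, -(fe - fs), fetch(b2), qual_str(), tagf)
    sam <<- c(sam, r1, r2)
    name
  }
  for (g in est) {
    tx <- annotation_transcripts(ann, g)[1L]
    ex <- transcript_exons(ann, tx)
    contig <- ex$contig[1L]
    tx_len <- sum(ex$end - ex$start)
    for (bc in cells) {
      n_umi <- stats::rpois(1L, spec$bam_umis_per_gene_lambda) + 5L
      umis <- random_dna(n_umi, 8L)
      n_umi_pairs <- 0L
      for (u in umis) {
        r <- min(1L + stats::rgeom(1L, spec$bam_reads_per_umi_p), 8L)
        for (d in seq_len(r)) {
          L <- draw_len(1L, tx_len)
          fs <- sample.int(tx_len - L + 1L, 1L) - 1L
          name <- emit_pair(g, ex, contig, fs, fs + L, bc, u)
          ledger[[length(ledger) + 1L]] <- data.frame(
            qname = name, gene_id = g, barcode = bc, umi = u, role = "umi",
            exonic_length = L, intronic = FALSE, stringsAsFactors = FALSE)
          n_umi_pairs <- n_umi_pairs + 1L
        }
      }
      # internal pairs: per-gene-cell ratio from a small discrete law
      ratio <- sample(c(0.5, 1, 1.5, 2), 1L)
      n_int <- as.integer(round(ratio * n_umi_pairs))
      for (i in seq_len(n_int)) {
        L <- draw_len(1L, tx_len)
        fs <- sample.int(tx_len - L + 1L, 1L) - 1L
        name <- emit_pair(g, ex, contig, fs, fs + L, bc, NA_character_)
        ledger[[length(ledger) + 1L]] <- data.frame(
          qname = name, gene_id = g, barcode = bc, umi = NA_character_,
          role = "internal", exonic_length = L, intronic = FALSE,
          stringsAsFactors = FALSE)
      }
      # intronic pairs (unspliced pre-mRNA coverage): single block in
      # the first intron, zero exonic overlap
      n_intron <- stats::rbinom(1L, 3L, 0.4)
      intron_start <- ex$end[1L]; intron_end <- ex$start[2L]
      iw <- intron_end - intron_start
      for (i in seq_len(n_intron)) {
        flen <- min(160L, iw)
        fs <- intron_start + sample.int(iw - flen + 1L, 1L) - 1L
        qn <- qn + 1L
        name <- sprintf("pair%05d", qn)
        k <- min(rl, flen)
        seq1 <- as.character(Biostrings::subseq(genome[[contig]], fs + 1L,
                                                fs + k))
        seq2 <- as.character(Biostrings::subseq(genome[[contig]],
                                                fs + flen - k + 1L,
                                                fs + flen))
        sam <- c(sam,
          sprintf("%s\t99\t%s\t%d\t60\t%dM\t=\t%d\t%d\t%s\t%s\tBC:Z:%s",
                  name, contig, fs + 1L, k, fs + flen - k + 1L, flen,
                  seq1, qual_str(), bc),
          sprintf("%s\t147\t%s\t%d\t60\t%dM\t=\t%d\t%d\t%s\t%s\tBC:Z:%s",
                  name, contig, fs + flen - k + 1L, k, fs + 1L, -flen,
                  seq2, qual_str(), bc))
        ledger[[length(ledger) + 1L]] <- data.frame(
          qname = name, gene_id = g, barcode = bc, umi = NA_character_,
          role = "internal", exonic_length = 0L, intronic = TRUE,
          stringsAsFactors = FALSE)
      }
    }
  }
  # one pair without a BC tag (must be skipped, counted)
  g <- est[1L]
  tx <- annotation_transcripts(ann, g)[1L]
  ex <- transcript_exons(ann, tx)
  emit_pair(g, ex, ex$contig[1L], 0L, 300L, NA_character_, NA_character_)
  # one secondary alignment record (flag 256; must be excluded)
  sec <- sub("^(\\S+)\t99", "\\1\t355", sam[1L])
  sam <- c(sam, sec)

  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(genome),
                      Biostrings::width(genome)))
  sam_path <- file.path(dir, "toy.sam")
  writeLines(c(header, sam), sam_path)
  bam0 <- Rsamtools::asBam(sam_path, file.path(dir, "toy_unsorted"),
                           overwrite = TRUE, indexDestination = FALSE)
  bam <- Rsamtools::sortBam(bam0, file.path(dir, "toy"))
  Rsamtools::indexBam(bam)
  ledger <- do.call(rbind, ledger)
  rownames(ledger) <- NULL
  list(bam_path = bam, ledger = ledger)
}

#' Parametric default data characteristics
#'
#' A fully parametric characteristics bundle for simulation without any
#' characterised dataset: discretised log-normal fragment lengths (UMI
#' fragments around 350 nt, internal around 200 nt), geometric reads per
#' UMI (mean 2), a gamma-shaped internal-to-UMI ratio with extra mass at
#' zero, a mostly-zero unspliced fraction, negative-binomial UMIs per
#' gene, and a positional quality profile that decays gently from Q37
#' over 150 positions. All weights are closed-form; no randomness.
#'
#' @param read_len Length of the positional quality profile.
#' @return A validated `data_characteristics`.
#' @export
make_default_characteristics <- function(read_len = 150L) {
  lnorm_dist <- function(meanlog, sdlog, from, to, by) {
    v <- seq(from, to, by)
    empirical_distribution(v, stats::dlnorm(v, meanlog, sdlog))
  }
  umi_len_d <- lnorm_dist(log(350), 0.30, 50, 1200, 10)
  int_len_d <- lnorm_dist(log(200), 0.30, 50, 800, 10)
  k <- 1:10
  rpu <- empirical_distribution(k, 0.5^k)
  rv <- seq(0, 6, 0.25)
  ratio_w <- stats::dgamma(rv, shape = 2, scale = 0.75)
  ratio_w[1L] <- ratio_w[1L] + 0.5 * sum(ratio_w)  # genes with few internals
  ratio <- empirical_distribution(rv, ratio_w)
  uv <- c(0, seq(0.02, 0.6, 0.02))
  uw <- c(0.8, 0.2 * stats::dbeta(seq(0.02, 0.6, 0.02), 1, 8) /
            sum(stats::dbeta(seq(0.02, 0.6, 0.02), 1, 8)))
  unspl <- empirical_distribution(uv, uw)
  gv <- 0:80
  upg <- empirical_distribution(gv, stats::dnbinom(gv, mu = 12, size = 2))
  scores <- c(2L, 12L, 22L, 27L, 32L, 37L)
  qprof <- lapply(seq_len(read_len), function(i) {
    decay <- (i - 1) / max(1L, read_len - 1L)   # 0 at 5' end, 1 at 3' end
    w <- c(0.001, 0.004, 0.01, 0.03, 0.10, 0.855) *
      (1 - 0.25 * decay * c(-8, -6, -4, -2, 0, 0.35))
    empirical_distribution(scores, pmax(w, 1e-6))
  })
  data_characteristics(
    umi_fragment_length = umi_len_d,
    internal_fragment_length = int_len_d,
    reads_per_umi = rpu,
    internal_to_umi_ratio = ratio,
    unspliced_fraction = unspl,
    umis_per_gene = upg,
    quality_by_position_read = qprof,
    quality_by_position_barcode = list(),
    metadata = list(source = "parametric defaults", read_length = read_len))
}

#' Load the packaged default characteristics
#'
#' Reads the default bundle shipped under `inst/extdata`; identical to
#' [make_default_characteristics()] output.
#'
#' @return A validated `data_characteristics`.
#' @export
default_characteristics <- function() {
  path <- system.file("extdata", "default_characteristics.json",
                      package = "splicesim", mustWork = TRUE)
  load_characteristics(path)
}
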