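# Learning protocol characteristics from a tagged BAM.
#
# Fragment lengths are estimated only on a conservative subset of genes
# (standard chromosomes, non-overlapping span, single annotated
# transcript) so that alternative splicing and multi-gene ambiguity cannot
# distort the protocol-driven length distributions. All other per-gene
# quantities use every gene a pair can be assigned to unambiguously.

STANDARD_CHROMOSOMES <- c(as.character(1:22), "X", "Y")

#' Select genes suitable for fragment-length estimation
#'
#' Returns the genes that (1) lie on chromosomes 1-22 or X/Y (with or
#' without a "chr" prefix), (2) do not overlap any other gene on their
#' genomic span (strand-agnostic), and (3) have exactly one annotated
#' transcript.
#'
#' @param ann A `gene_annotation`.
#' @return Character vector of gene ids (possibly empty).
#' @export
select_estimation_genes <- function(ann) {
  if (nrow(ann$exons) == 0L) return(character(0))
  sp <- gene_spans(ann)
  contig_plain <- sub("^chr", "", sp$contig)
  on_std <- contig_plain %in% STANDARD_CHROMOSOMES
  ntx <- vapply(split(ann$exons$transcript_id, ann$exons$gene_id),
                function(t) length(unique(t)), integer(1))
  single_tx <- ntx[sp$gene_id] == 1L
  gr <- GenomicRanges::GRanges(sp$contig,
                               IRanges::IRanges(sp$start + 1L, sp$end))
  hits <- GenomicRanges::countOverlaps(gr, gr, ignore.strand = TRUE)
  non_overlapping <- hits == 1L  # only self-hit
  sp$gene_id[on_std & single_tx & non_overlapping]
}

#' Exonic fragment length of an aligned pair
#'
#' The fragment spans the outermost aligned genomic positions of the pair;
#' its exonic length is the number of positions in that span that fall in
#' an exon of the given transcript (0-based half-open arithmetic).
#'
#' @param frag_start,frag_end Outermost aligned positions of the pair,
#'   0-based half-open.
#' @param exons Exon table of the transcript (columns `start`, `end`),
#'   e.g. from [transcript_exons()].
#' @return Integer count of exonic positions; 0 means the pair should be
#'   discarded from the length distribution.
#' @export
exonic_fragment_length <- function(frag_start, frag_end, exons) {
  stopifnot(frag_start < frag_end)
  sum(pmax(0L, pmin(frag_end, exons$end) - pmax(frag_start, exons$start)))
}

# union of exon intervals of a gene as an IRanges (0-based stored as 1-based)
gene_exon_union <- function(ann, gene_id) {
  ex <- ann$exons[ann$exons$gene_id == gene_id, ]
  IRanges::reduce(IRanges::IRanges(ex$start + 1L, ex$end))
}

#' Unspliced RNA fraction per gene per cell
#'
#' For each (gene, cell barcode) with at least one covered base, computes
#' the fraction of covered positions that are intronic: covered positions
#' are the union of aligned block positions of all the cell's pairs,
#' clipped to the gene span; introns are the gene span minus the union of
#' the gene's annotated exons.
#'
#' @param aln An `alignment_pairs` with a `gene_id` column in `$pairs`
#'   (see [assign_pairs_to_genes()]).
#' @param ann A `gene_annotation`.
#' @return data.frame with `gene_id`, `barcode`, `fraction` (in \[0,1\]).
#' @export
unspliced_fraction_per_gene_cell <- function(aln, ann) {
  p <- aln$pairs
  stopifnot("gene_id" %in% names(p))
  keep <- !is.na(p$gene_id)
  if (!any(keep)) {
    return(data.frame(gene_id = character(0), barcode = character(0),
                      fraction = numeric(0), stringsAsFactors = FALSE))
  }
  sp <- gene_spans(ann)
  idx <- split(which(keep), paste(p$gene_id[keep], p$barcode[keep], sep = "\r"))
  res <- lapply(idx, function(i) {
    g <- p$gene_id[i[1L]]
    span <- IRanges::IRanges(sp$start[sp$gene_id == g] + 1L,
                             sp$end[sp$gene_id == g])
    blocks <- c(unlist(aln$r1_blocks[i]), unlist(aln$r2_blocks[i]))
    covered <- IRanges::reduce(IRanges::intersect(
      IRanges::ranges(blocks), span))
    total <- sum(IRanges::width(covered))
    if (total == 0L) return(NULL)
    exonic <- sum(IRanges::width(
      IRanges::intersect(covered, gene_exon_union(ann, g))))
    data.frame(gene_id = g, barcode = p$barcode[i[1L]],
               fraction = (total - exonic) / total, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), barcode = character(0),
                      fraction = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Assign aligned pairs to genes
#'
#' Adds a `gene_id` column to `aln$pairs`: the single gene whose span
#' overlaps the pair's fragment span. Pairs overlapping zero or multiple
#' gene spans get `NA` (ambiguous assignments would distort per-gene
#' statistics).
#'
#' @param aln An `alignment_pairs`.
#' @param ann A `gene_annotation`.
#' @return The `alignment_pairs` with `$pairs$gene_id` filled in.
#' @export
assign_pairs_to_genes <- function(aln, ann) {
  sp <- gene_spans(ann)
  ggr <- GenomicRanges::GRanges(sp$contig,
                                IRanges::IRanges(sp$start + 1L, sp$end))
  p <- aln$pairs
  pgr <- GenomicRanges::GRanges(p$contig, IRanges::IRanges(p$start + 1L, p$end))
  hits <- GenomicRanges::findOverlaps(pgr, ggr, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits)
  gene <- rep(NA_character_, nrow(p))
  once <- qh[!(duplicated(qh) | duplicated(qh, fromLast = TRUE))]
  gene[once] <- sp$gene_id[S4Vectors::subjectHits(hits)[match(once, qh)]]
  aln$pairs$gene_id <- gene
  aln
}

# per-position Phred profiles pooled over quality strings; profile length
# is the modal string length, shorter strings contribute their positions
quality_profile <- function(quals) {
  quals <- quals[nzchar(quals)]
  if (length(quals) == 0L) return(list())
  lens <- nchar(quals)
  modal <- as.integer(names(which.max(table(lens))))
  mat <- matrix(NA_integer_, nrow = length(quals), ncol = modal)
  for (i in seq_along(quals)) {
    s <- phred_scores(quals[i])
    k <- min(length(s), modal)
    mat[i, seq_len(k)] <- s[seq_len(k)]
  }
  lapply(seq_len(modal), function(j) {
    v <- mat[, j]
    empirical_distribution(v[!is.na(v)])
  })
}

#' Extract data characteristics from tagged BAM files
#'
#' Computes the six empirical distributions and the positional quality
#' profiles that drive simulation:
#' \itemize{
#'   \item UMI-containing and internal fragment lengths, measured as
#'     exonic positions spanned by each pair, on estimation genes only
#'     (see [select_estimation_genes()]); zero-overlap pairs are dropped.
#'   \item reads per UMI: multiplicity of each (barcode, gene, UMI) triple.
#'   \item internal-to-UMI read ratio per gene; genes with zero
#'     UMI-containing pairs are omitted (ratio undefined).
#'   \item unspliced fraction per gene per cell
#'     (see [unspliced_fraction_per_gene_cell()]).
#'   \item UMIs per gene: distinct UMIs per (gene, cell), pooled over
#'     cells.
#'   \item per-position Phred profiles pooled over all primary reads.
#' }
#'
#' @param bams Character vector of BAM paths.
#' @param ann A `gene_annotation`.
#' @param region Optional region restriction (see
#'   [read_alignment_pairs()]).
#' @return A validated `data_characteristics`.
#' @export
characterize_data <- function(bams, ann, region = NULL) {
  aln <- read_alignment_pairs(bams, region)
  aln <- assign_pairs_to_genes(aln, ann)
  p <- aln$pairs
  est <- select_estimation_genes(ann)

  # fragment lengths on estimation genes
  on_est <- !is.na(p$gene_id) & p$gene_id %in% est
  frag_len <- rep(NA_integer_, nrow(p))
  for (i in which(on_est)) {
    tx <- annotation_transcripts(ann, p$gene_id[i])[1L]
    frag_len[i] <- exonic_fragment_length(p$start[i], p$end[i],
                                          transcript_exons(ann, tx))
  }
  n_zero <- sum(!is.na(frag_len) & frag_len == 0L)
  if (n_zero > 0L) {
    ss_log("characterize_data: discarded %d pair(s) with zero exonic overlap",
           n_zero)
  }
  umi_len <- frag_len[on_est & frag_len > 0L & p$role == "umi"]
  int_len <- frag_len[on_est & frag_len > 0L & p$role == "internal"]
  if (length(umi_len) == 0L || length(int_len) == 0L) {
    stop("no estimation genes with both UMI-containing and internal data; ",
         "supply the packaged default characteristics ",
         "(make_default_characteristics) instead")
  }

  assigned <- !is.na(p$gene_id)
  # reads per UMI: multiplicity of (barcode, gene, UMI)
  is_umi <- assigned & p$role == "umi"
  rpu <- as.integer(table(paste(p$barcode[is_umi], p$gene_id[is_umi],
                                p$umi[is_umi], sep = "\r")))

  # internal:UMI ratio per gene (genes with zero UMI pairs omitted)
  genes_seen <- unique(p$gene_id[assigned])
  n_umi_g <- table(factor(p$gene_id[is_umi], levels = genes_seen))
  n_int_g <- table(factor(p$gene_id[assigned & p$role == "internal"],
                          levels = genes_seen))
  has_umi <- n_umi_g > 0
  if (any(!has_umi)) {
    ss_log("characterize_data: %d gene(s) without UMI-containing reads %s",
           sum(!has_umi), "omitted from the internal:UMI ratio")
  }
  ratios <- as.numeric(n_int_g[has_umi]) / as.numeric(n_umi_g[has_umi])

  # distinct UMIs per gene per cell, pooled over cells
  tri <- unique(data.frame(bc = p$barcode[is_umi], gene = p$gene_id[is_umi],
                           umi = p$umi[is_umi]))
  upg <- as.integer(table(paste(tri$bc, tri$gene, sep = "\r")))

  unspl <- unspliced_fraction_per_gene_cell(aln, ann)

  data_characteristics(
    umi_fragment_length = empirical_distribution(umi_len),
    internal_fragment_length = empirical_distribution(int_len),
    reads_per_umi = empirical_distribution(rpu),
    internal_to_umi_ratio = empirical_distribution(ratios),
    unspliced_fraction = empirical_distribution(unspl$fraction),
    umis_per_gene = empirical_distribution(upg),
    quality_by_position_read = quality_profile(c(aln$r1_qual, aln$r2_qual)),
    quality_by_position_barcode = list(),
    metadata = list(source = paste(bams, collapse = ","),
                    n_pairs = nrow(p),
                    n_estimation_genes = length(est),
                    skipped = as.list(aln$skipped)))
}
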