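# Genome and annotation I/O.
#
# Internal coordinate convention: 0-based half-open [start, end) for every
# exon interval, converted at the GTF boundary (GTF is 1-based inclusive).
# A gene_annotation is a validated exon table; genes and transcripts are
# implicit groupings of that table, mirroring how GTF itself encodes them.

#' Read a reference genome FASTA
#'
#' Loads a genome FASTA into a named [Biostrings::DNAStringSet]; contig
#' names are truncated at the first whitespace (the FASTA identifier),
#' matching samtools faidx conventions.
#'
#' @param path Path to a FASTA file.
#' @return A `DNAStringSet` keyed by contig name.
#' @export
read_genome <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Write a genome FASTA
#' @param genome Named `DNAStringSet` (or named character vector).
#' @param path Output FASTA path.
#' @export
write_genome <- function(genome, path) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Construct a gene annotation from an exon table
#'
#' @param exons A data.frame with columns `contig`, `start`, `end`
#'   (0-based half-open), `strand` ("+" or "-"), `gene_id`,
#'   `transcript_id`.
#' @return A validated object of class `gene_annotation`.
#' @export
gene_annotation <- function(exons) {
  required <- c("contig", "start", "end", "strand", "gene_id", "transcript_id")
  missing <- setdiff(required, names(exons))
  if (length(missing)) {
    stop("exon table missing columns: ", paste(missing, collapse = ", "))
  }
  exons <- as.data.frame(exons)[required]
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (any(exons$start >= exons$end)) {
    stop("every exon must satisfy start < end (0-based half-open)")
  }
  if (!all(exons$strand %in% c("+", "-"))) {
    stop("exon strand must be '+' or '-'")
  }
  # one gene per transcript
  tx_gene <- unique(exons[, c("transcript_id", "gene_id")])
  dup <- duplicated(tx_gene$transcript_id)
  if (any(dup)) {
    stop("transcript assigned to multiple genes: ",
         paste(unique(tx_gene$transcript_id[dup]), collapse = ", "))
  }
  # sort exons by transcript then genomic coordinate, check non-overlap
  exons <- exons[order(exons$transcript_id, exons$start, exons$end), ]
  rownames(exons) <- NULL
  by_tx <- split(seq_len(nrow(exons)), exons$transcript_id)
  for (idx in by_tx) {
    s <- exons$start[idx]; e <- exons$end[idx]
    if (length(idx) > 1L && any(s[-1L] < e[-length(e)])) {
      stop("overlapping exons within transcript ",
           exons$transcript_id[idx[1L]])
    }
  }
  structure(list(exons = exons), class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("gene_annotation: %d genes, %d transcripts, %d exons\n",
              length(unique(x$exons$gene_id)),
              length(unique(x$exons$transcript_id)),
              nrow(x$exons)))
  invisible(x)
}

#' List gene identifiers in an annotation
#' @param ann A `gene_annotation`.
#' @return Character vector of gene ids.
#' @export
annotation_genes <- function(ann) unique(ann$exons$gene_id)

#' List transcript identifiers, optionally for one gene
#' @param ann A `gene_annotation`.
#' @param gene_id Optional gene id to restrict to.
#' @return Character vector of transcript ids.
#' @export
annotation_transcripts <- function(ann, gene_id = NULL) {
  ex <- ann$exons
  if (!is.null(gene_id)) ex <- ex[ex$gene_id %in% gene_id, ]
  unique(ex$transcript_id)
}

#' Exon table of one transcript
#' @param ann A `gene_annotation`.
#' @param transcript_id Transcript id.
#' @return Exon rows sorted by genomic coordinate.
#' @export
transcript_exons <- function(ann, transcript_id) {
  ex <- ann$exons[ann$exons$transcript_id == transcript_id, ]
  if (nrow(ex) == 0L) stop("unknown transcript id: ", transcript_id)
  ex[order(ex$start), ]
}

#' Per-gene genomic spans
#' @param ann A `gene_annotation`.
#' @return data.frame with gene_id, contig, strand, start, end (span over
#'   all exons of all transcripts, 0-based half-open).
#' @export
gene_spans <- function(ann) {
  ex <- ann$exons
  sp <- do.call(rbind, lapply(split(ex, ex$gene_id), function(g) {
    data.frame(gene_id = g$gene_id[1L], contig = g$contig[1L],
               strand = g$strand[1L], start = min(g$start), end = max(g$end),
               stringsAsFactors = FALSE)
  }))
  rownames(sp) <- NULL
  sp
}

#' Read a GTF annotation
#'
#' Imports an Ensembl-dialect GTF (attributes `gene_id`, `transcript_id`)
#' through [rtracklayer::import()] and converts exon coordinates from
#' 1-based inclusive to the internal 0-based half-open convention.
#'
#' @param path Path to a GTF file.
#' @return A `gene_annotation`.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  gr <- tryCatch(
    rtracklayer::import(path, format = "gtf"),
    error = function(e) stop("failed to parse GTF ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  md <- S4Vectors::mcols(gr)
  if (!all(c("gene_id", "transcript_id") %in% names(md))) {
    stop("GTF ", path, " lacks gene_id/transcript_id attributes")
  }
  is_exon <- md$type == "exon"
  # a transcript feature with no exon rows is malformed
  if ("transcript" %in% md$type) {
    declared <- unique(md$transcript_id[md$type == "transcript"])
    with_exons <- unique(md$transcript_id[is_exon])
    orphans <- setdiff(declared, with_exons)
    if (length(orphans)) {
      stop("transcript(s) with zero exons in ", path, ": ",
           paste(orphans, collapse = ", "))
    }
  }
  gr <- gr[is_exon]
  if (length(gr) == 0L) stop("no exon features in ", path)
  gene_annotation(data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = as.character(S4Vectors::mcols(gr)$gene_id),
    transcript_id = as.character(S4Vectors::mcols(gr)$transcript_id),
    stringsAsFactors = FALSE))
}

#' Write a gene annotation to GTF
#'
#' Exports exon features with `gene_id`/`transcript_id` attributes,
#' converting back to GTF 1-based inclusive coordinates; the round trip
#' `read_annotation(write_annotation(ann))` preserves every interval.
#'
#' @param ann A `gene_annotation`.
#' @param path Output GTF path.
#' @export
write_annotation <- function(ann, path) {
  ex <- ann$exons
  gr <- GenomicRanges::GRanges(
    seqnames = ex$contig,
    ranges = IRanges::IRanges(start = ex$start + 1L, end = ex$end),
    strand = ex$strand)
  S4Vectors::mcols(gr)$source <- "splicesim"
  S4Vectors::mcols(gr)$type <- "exon"
  S4Vectors::mcols(gr)$gene_id <- ex$gene_id
  S4Vectors::mcols(gr)$transcript_id <- ex$transcript_id
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Fetch the sequence of a transcript
#'
#' Assembles the transcript sequence from the genome: with `spliced = TRUE`
#' the exon sequences are concatenated in transcript order; with
#' `spliced = FALSE` the full genomic span from the first exon start to the
#' last exon end is returned (the intron-retaining pre-mRNA). Minus-strand
#' transcripts are reverse-complemented so the result is always the
#' 5'-to-3' mRNA sense sequence.
#'
#' @param ann A `gene_annotation`.
#' @param genome Named `DNAStringSet` from [read_genome()].
#' @param transcript_id Transcript id.
#' @param spliced Logical; mature mRNA (default) or pre-mRNA.
#' @return A single character string over A/C/G/T/N.
#' @export
fetch_transcript_sequence <- function(ann, genome, transcript_id,
                                      spliced = TRUE) {
  ex <- transcript_exons(ann, transcript_id)
  contig <- ex$contig[1L]
  if (!contig %in% names(genome)) {
    stop("contig not in genome: ", contig)
  }
  clen <- length(genome[[contig]])
  if (max(ex$end) > clen) {
    stop("exon beyond contig end for transcript ", transcript_id,
         " (contig ", contig, " length ", clen, ")")
  }
  if (spliced) {
    parts <- Biostrings::extractAt(
      genome[[contig]],
      IRanges::IRanges(start = ex$start + 1L, end = ex$end))
    seq <- unlist(parts)
  } else {
    seq <- Biostrings::subseq(genome[[contig]],
                              start = min(ex$start) + 1L, end = max(ex$end))
  }
  if (ex$strand[1L] == "-") seq <- Biostrings::reverseComplement(seq)
  as.character(seq)
}
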