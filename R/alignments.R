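# Reading aligned read pairs from tagged BAM files.
#
# Expects the zUMIs tag convention: cell barcode in the "BC" tag, UMI in
# the "UB" tag. Only mated primary alignments are surfaced; secondary,
# supplementary and unmapped records are skipped, as are pairs lacking a
# BC tag (counted, not fatal: real demultiplexed output contains
# unassigned reads).

#' Read mated alignment pairs from tagged BAM files
#'
#' @param paths Character vector of one or more BAM file paths.
#' @param region Optional region string (`"chr1"` or `"chr1:1-1000"`);
#'   requires the BAMs to be indexed.
#' @return An object of class `alignment_pairs`: a list with
#'   \describe{
#'     \item{pairs}{data.frame with `qname`, `contig`, `barcode`, `umi`
#'       (`NA` when absent), `role` ("umi" or "internal"), `start`, `end`
#'       (outermost aligned genomic positions of the pair, 0-based
#'       half-open).}
#'     \item{r1_blocks, r2_blocks}{`GRangesList` of aligned blocks per
#'       mate, parallel to `pairs`.}
#'     \item{r1_qual, r2_qual}{Phred+33 quality strings per mate.}
#'     \item{skipped}{named integer vector of skip counts
#'       (`missing_bc`, `unpaired`).}
#'   }
#' @export
read_alignment_pairs <- function(paths, region = NULL) {
  stopifnot(length(paths) >= 1L, all(file.exists(paths)))
  which <- NULL
  if (!is.null(region)) {
    m <- regmatches(region, regexec("^([^:]+)(?::(\\d+)-(\\d+))?$", region))[[1]]
    if (length(m) == 0L) stop("malformed region: ", region)
    if (m[3] == "") {
      # whole-contig query: look up the contig length from the header
      hdr <- Rsamtools::scanBamHeader(paths[1])[[1]]$targets
      if (!m[2] %in% names(hdr)) stop("region contig not in BAM header: ", m[2])
      which <- GenomicRanges::GRanges(m[2], IRanges::IRanges(1L, hdr[[m[2]]]))
    } else {
      which <- GenomicRanges::GRanges(m[2], IRanges::IRanges(as.integer(m[3]),
                                                             as.integer(m[4])))
    }
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param_args <- list(what = c("qname", "flag", "qual"),
                     tag = c("BC", "UB"), flag = flag)
  if (!is.null(which)) param_args$which <- which
  param <- do.call(Rsamtools::ScanBamParam, param_args)

  galns <- lapply(paths, function(p) {
    GenomicAlignments::readGAlignments(p, param = param, use.names = FALSE)
  })
  galn <- do.call(c, galns)
  md <- S4Vectors::mcols(galn)
  n <- length(galn)
  skipped <- c(missing_bc = 0L, unpaired = 0L)
  empty <- function() {
    eg <- GenomicRanges::GRangesList()
    structure(list(pairs = data.frame(qname = character(0),
                                      contig = character(0),
                                      barcode = character(0),
                                      umi = character(0),
                                      role = character(0),
                                      start = integer(0), end = integer(0),
                                      stringsAsFactors = FALSE),
                   r1_blocks = eg, r2_blocks = eg,
                   r1_qual = character(0), r2_qual = character(0),
                   skipped = skipped),
              class = "alignment_pairs")
  }
  if (n == 0L) return(empty())

  is_r1 <- bitwAnd(md$flag, 64L) > 0L
  is_r2 <- bitwAnd(md$flag, 128L) > 0L
  key <- paste(md$qname, as.character(GenomicAlignments::seqnames(galn)))
  i1 <- which(is_r1); i2 <- which(is_r2)
  m12 <- match(key[i1], key[i2])
  ok <- !is.na(m12) & !duplicated(key[i1])
  skipped["unpaired"] <- sum(!is_r1 & !is_r2) + sum(!ok) +
    (length(i2) - length(unique(m12[ok])))
  i1 <- i1[ok]; i2 <- i2[m12[ok]]
  if (length(i1) == 0L) return(empty())

  bc <- md$BC[i1]
  has_bc <- !is.na(bc) & nzchar(bc)
  skipped["missing_bc"] <- sum(!has_bc)
  if (skipped["missing_bc"] > 0L) {
    ss_log("read_alignment_pairs: skipped %d pair(s) without BC tag",
           skipped["missing_bc"])
  }
  i1 <- i1[has_bc]; i2 <- i2[has_bc]

  umi <- md$UB[i1]
  umi[!is.na(umi) & !nzchar(umi)] <- NA_character_
  blocks1 <- GenomicAlignments::grglist(galn[i1])
  blocks2 <- GenomicAlignments::grglist(galn[i2])
  start0 <- pmin(GenomicAlignments::start(galn[i1]),
                 GenomicAlignments::start(galn[i2])) - 1L
  end0 <- pmax(GenomicAlignments::end(galn[i1]),
               GenomicAlignments::end(galn[i2]))
  pairs <- data.frame(
    qname = md$qname[i1],
    contig = as.character(GenomicAlignments::seqnames(galn[i1])),
    barcode = md$BC[i1],
    umi = umi,
    role = ifelse(is.na(umi), "internal", "umi"),
    start = start0, end = end0,
    stringsAsFactors = FALSE)
  structure(list(pairs = pairs, r1_blocks = blocks1, r2_blocks = blocks2,
                 r1_qual = as.character(md$qual[i1]),
                 r2_qual = as.character(md$qual[i2]),
                 skipped = skipped),
            class = "alignment_pairs")
}

#' @export
print.alignment_pairs <- function(x, ...) {
  cat(sprintf(
    "alignment_pairs: %d pairs (%d UMI-containing, %d internal), %d skipped\n",
    nrow(x$pairs), sum(x$pairs$role == "umi"),
    sum(x$pairs$role == "internal"), sum(x$skipped)))
  invisible(x)
}

#' Classify a read pair as UMI-containing or internal
#'
#' A pair is UMI-containing iff its UB tag is present and non-empty;
#' everything else (absent tag, empty string) is an internal read.
#'
#' @param umi UMI tag value(s); `NA` or `""` mean absent.
#' @return Character vector, `"umi"` or `"internal"`.
#' @export
classify_pair <- function(umi) {
  ifelse(!is.na(umi) & nzchar(umi), "umi", "internal")
}
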