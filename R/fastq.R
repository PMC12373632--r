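# Paired FASTQ output.
#
# Read identifiers encode the ground truth
# (barcode:molecule:duplicate:role:transcript) so alignments of simulated
# reads can be scored without auxiliary files.

#' Encode numeric Phred scores as a Phred+33 string
#' @param scores Integer vector of Phred scores (0..93).
#' @return A single character string.
#' @export
phred_string <- function(scores) {
  stopifnot(all(scores >= 0 & scores <= 93))
  rawToChar(as.raw(scores + 33L))
}

#' Decode a Phred+33 string to numeric scores
#' @param qual A quality string.
#' @return Integer vector of Phred scores.
#' @export
phred_scores <- function(qual) {
  as.integer(charToRaw(qual)) - 33L
}

#' Write simulated read pairs to paired FASTQ files
#'
#' @param reads data.frame with columns `id`, `read1`, `qual1`, `read2`,
#'   `qual2`; qualities are Phred+33 strings of the same length as their
#'   read.
#' @param r1_path,r2_path Output paths for mate 1 and mate 2.
#' @param gzip Compress output with gzip.
#' @return Invisibly, `c(r1_path, r2_path)` (with `.gz` appended when
#'   `gzip = TRUE` and the paths do not already end in it).
#' @export
write_fastq_pairs <- function(reads, r1_path, r2_path, gzip = FALSE) {
  required <- c("id", "read1", "qual1", "read2", "qual2")
  stopifnot(all(required %in% names(reads)))
  if (nrow(reads) > 0L) {
    if (any(nchar(reads$read1) != nchar(reads$qual1)) ||
        any(nchar(reads$read2) != nchar(reads$qual2))) {
      stop("sequence/quality length mismatch")
    }
  }
  if (gzip) {
    if (!grepl("\\.gz$", r1_path)) r1_path <- paste0(r1_path, ".gz")
    if (!grepl("\\.gz$", r2_path)) r2_path <- paste0(r2_path, ".gz")
  }
  write_one <- function(seqs, quals, ids, path) {
    if (length(seqs) == 0L) {
      con <- if (gzip) gzfile(path, "wb") else file(path, "wb")
      close(con)
      return(invisible(NULL))
    }
    x <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(seqs),
      Biostrings::PhredQuality(quals))
    names(x) <- ids
    Biostrings::writeQualityScaledXStringSet(x, path, compress = gzip)
  }
  write_one(reads$read1, reads$qual1, reads$id, r1_path)
  write_one(reads$read2, reads$qual2, reads$id, r2_path)
  invisible(c(r1_path, r2_path))
}

#' Read a FASTQ file into sequences and qualities
#'
#' Convenience reader used by the round-trip checks.
#'
#' @param path FASTQ path (optionally gzipped).
#' @return data.frame with `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) {
    return(data.frame(id = character(0), seq = character(0),
                      qual = character(0), stringsAsFactors = FALSE))
  }
  # QualityScaledDNAStringSet() warns about dropping the (empty) mcols of
  # freshly parsed FASTQ input; nothing is lost
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  data.frame(id = names(x),
             seq = as.character(x),
             qual = as.character(Biostrings::quality(x)),
             stringsAsFactors = FALSE)
}

#' Compose a ground-truth-traceable read identifier
#'
#' Fields joined by `:` — cell barcode, molecule id, duplicate index,
#' fragment role, source transcript id.
#'
#' @param barcode,molecule,duplicate,role,transcript Identifier fields.
#' @return Character vector of read ids.
#' @export
make_read_id <- function(barcode, molecule, duplicate, role, transcript) {
  paste(barcode, molecule, duplicate, role, transcript, sep = ":")
}
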