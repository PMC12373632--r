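# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement nucleotide strings
#'
#' Vectorised reverse complement over character strings restricted to the
#' A/C/G/T/N alphabet. Thin wrapper around [Biostrings::reverseComplement()]
#' so every module uses one implementation.
#'
#' @param x Character vector of nucleotide strings.
#' @return Character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Derive a stage-specific child seed from a global seed
#'
#' Each pipeline stage draws its randomness from a child seed obtained by a
#' fixed splitting rule, `(seed * 7919 + stage_index) mod (2^31 - 1)`, so a
#' stage is reproducible independently of which other stages ran before it.
#'
#' @param seed Global integer seed.
#' @param stage Integer stage index (>= 1).
#' @return An integer seed.
#' @export
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(stage))
  as.integer((as.double(seed) * 7919 + as.double(stage)) %% (2^31 - 1))
}

#' Generate random DNA sequences
#' @param n Number of sequences.
#' @param len Length of each sequence (scalar or vector of length n).
#' @return Character vector of n sequences over A/C/G/T.
#' @keywords internal
random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  len <- rep_len(len, n)
  total <- sum(len)
  bases <- sample(DNA_BASES, total, replace = TRUE)
  ends <- cumsum(len)
  starts <- ends - len + 1L
  vapply(seq_len(n), function(i) paste(bases[starts[i]:ends[i]], collapse = ""),
         character(1))
}

# round-half-even (banker's rounding); base::round already implements it but
# we name the rule explicitly where conservation depends on it
round_half_even <- function(x) round(x)

# simple condition-count logger: messages suppressed unless option set
ss_log <- function(fmt, ...) {
  if (isTRUE(getOption("splicesim.verbose", FALSE))) {
    message(sprintf(fmt, ...))
  }
  invisible(NULL)
}
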