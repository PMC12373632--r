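# Smart-seq3 read simulation.
#
# Eight steps per cell, mimicking the library preparation protocol:
# (1) barcode/UMI assignment and tagmentation-style tagging
#     (tag + UMI + GGG prepended to each molecule),
# (2) PCR amplification inflated by the PCR amplification factor (PAF),
# (3) UMI-containing fragment extraction from the 5' end,
# (4) internal fragment extraction from the remainder,
# (5) paired-end read generation (first/last read_len bases, FR geometry;
#     internal fragments lose strand information),
# (6) per-base substitution errors,
# (7) subsampling back to the reads-per-UMI targets,
# (8) empirical positional quality assignment.
# All randomness flows through a single seeded RNG stream, so a fixed
# seed yields byte-identical FASTQ output.

#' Smart-seq3 5' tag sequence prepended to every tagged molecule
#' @export
SMARTSEQ3_TAG <- "ATTGCGCAATG"

#' Simulation configuration
#'
#' @param read_len Read length in nt (default 150).
#' @param error_rate Per-base substitution probability P (default 0.005).
#' @param paf PCR amplification factor, >= 1 (default 5): temporary
#'   inflation of duplicate counts, corrected by subsampling.
#' @param umi_len UMI length in nt (default 8).
#' @param barcode_len Cell barcode length in nt (default 16).
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(read_len = 150L, error_rate = 0.005,
                              paf = 5, umi_len = 8L, barcode_len = 16L) {
  stopifnot(read_len >= 1L, error_rate >= 0, error_rate <= 1, paf >= 1,
            umi_len >= 1L, barcode_len >= 1L)
  structure(list(read_len = as.integer(read_len),
                 error_rate = error_rate, paf = paf,
                 umi_len = as.integer(umi_len),
                 barcode_len = as.integer(barcode_len)),
            class = "simulation_config")
}

#' Assign distinct random cell barcodes
#'
#' @param n_cells Number of cells.
#' @param barcode_len Barcode length; `4^barcode_len` must be >=
#'   `n_cells`.
#' @param seed Integer seed.
#' @return Character vector of `n_cells` distinct barcodes.
#' @export
assign_barcodes <- function(n_cells, barcode_len, seed = 1L) {
  if (4^barcode_len < n_cells) {
    stop("barcode space too small: 4^", barcode_len, " < ", n_cells)
  }
  set.seed(seed)
  bc <- random_dna(n_cells, barcode_len)
  while (anyDuplicated(bc)) {
    dup <- duplicated(bc)
    bc[dup] <- random_dna(sum(dup), barcode_len)
  }
  bc
}

#' Expand a transcript UMI count matrix into tagged molecules
#'
#' Each matrix entry of count m yields m molecules, each with an
#' independent random UMI; UMIs are kept unique within (cell, gene) so
#' ground-truth molecule counts stay identifiable after UMI collapsing.
#'
#' @param counts Species x cells integer matrix.
#' @param species data.frame with `species_id`, `gene_id` matching the
#'   matrix rows.
#' @param umi_len UMI length.
#' @param seed Integer seed.
#' @return data.frame: `molecule` (global id), `cell` (column index),
#'   `species` (row index), `umi`.
#' @export
assign_umis <- function(counts, species, umi_len, seed = 1L) {
  stopifnot(nrow(counts) == nrow(species), all(counts >= 0))
  set.seed(seed)
  idx <- which(counts > 0, arr.ind = TRUE)
  if (length(idx) == 0L) {
    return(data.frame(molecule = integer(0), cell = integer(0),
                      species = integer(0), umi = character(0),
                      stringsAsFactors = FALSE))
  }
  reps <- counts[idx]
  mol_species <- rep(idx[, "row"], reps)
  mol_cell <- rep(idx[, "col"], reps)
  n <- length(mol_species)
  umi <- random_dna(n, umi_len)
  group <- paste(mol_cell, species$gene_id[mol_species], sep = "\r")
  repeat {
    dup <- duplicated(paste(group, umi, sep = "\r"))
    if (!any(dup)) break
    umi[dup] <- random_dna(sum(dup), umi_len)
  }
  data.frame(molecule = seq_len(n), cell = mol_cell, species = mol_species,
             umi = umi, stringsAsFactors = FALSE)
}

#' Tag a molecule for Smart-seq3 simulation
#'
#' Prepends the Smart-seq3 tag, the molecule's UMI and GGG to the
#' transcript sequence, mimicking the tagged 5' end produced by the
#' protocol.
#'
#' @param umi UMI sequence(s).
#' @param transcript_seq Transcript sequence(s).
#' @return Character vector `TAG + UMI + GGG + transcript`.
#' @export
tag_molecule <- function(umi, transcript_seq) {
  paste0(SMARTSEQ3_TAG, umi, "GGG", transcript_seq)
}

#' Draw PCR duplicate counts
#'
#' For each molecule, the target read count r is drawn from the empirical
#' reads-per-UMI distribution; the amplified copy count is
#' `max(1, round(r * paf))`. Subsampling later restores the target.
#'
#' @param n Number of molecules.
#' @param reads_per_umi `empirical_distribution` of reads per UMI.
#' @param paf PCR amplification factor (>= 1).
#' @param seed Integer seed (`NULL` to use the current RNG stream).
#' @return data.frame with `target` and `copies`.
#' @export
pcr_amplify <- function(n, reads_per_umi, paf, seed = NULL) {
  stopifnot(paf >= 1)
  if (!is.null(seed)) set.seed(seed)
  r <- sample_distribution(reads_per_umi, n)
  data.frame(target = as.integer(r),
             copies = pmax(1L, as.integer(round(r * paf))))
}

#' Extract the UMI-containing fragment of a tagged molecule
#'
#' The fragment is the 5' prefix of the tagged sequence with length drawn
#' from the UMI fragment-length distribution (clamped to the molecule
#' length); the remainder is everything after it.
#'
#' @param tagged Tagged sequence(s).
#' @param umi_fragment_length `empirical_distribution` of lengths.
#' @param seed Integer seed (`NULL` to use the current RNG stream).
#' @return data.frame with `fragment`, `remainder`, `frag_len`.
#' @export
extract_umi_fragment <- function(tagged, umi_fragment_length, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(tagged)
  len <- nchar(tagged)
  L <- pmin(as.integer(sample_distribution(umi_fragment_length, n)), len)
  data.frame(fragment = substr(tagged, 1L, L),
             remainder = substr(tagged, L + 1L, len),
             frag_len = L, stringsAsFactors = FALSE)
}

#' Extract internal fragments from a molecule remainder
#'
#' The number of internal fragments is `round(ratio * n_umi_frags)` with
#' the ratio drawn from the per-gene internal-to-UMI distribution; each
#' fragment is a uniformly positioned subsequence of the remainder with
#' length drawn from the internal fragment-length distribution (clamped).
#' An empty remainder yields zero fragments.
#'
#' @param remainder Remainder sequence (single string).
#' @param n_umi_frags Number of UMI-containing fragments of the
#'   transcript.
#' @param internal_to_umi_ratio,internal_fragment_length
#'   `empirical_distribution`s.
#' @param seed Integer seed (`NULL` to use the current RNG stream).
#' @return data.frame with `fragment`, `offset` (0-based within the
#'   remainder), `frag_len`.
#' @export
extract_internal_fragments <- function(remainder, n_umi_frags,
                                       internal_to_umi_ratio,
                                       internal_fragment_length,
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ratio <- sample_distribution(internal_to_umi_ratio, 1L)
  n <- as.integer(round(ratio * n_umi_frags))
  rem_len <- nchar(remainder)
  if (n <= 0L || rem_len == 0L) {
    return(data.frame(fragment = character(0), offset = integer(0),
                      frag_len = integer(0), stringsAsFactors = FALSE))
  }
  L <- pmin(as.integer(sample_distribution(internal_fragment_length, n)),
            rem_len)
  offset <- as.integer(floor(stats::runif(n) * (rem_len - L + 1L)))
  data.frame(fragment = substr(rep(remainder, n), offset + 1L, offset + L),
             offset = offset, frag_len = L, stringsAsFactors = FALSE)
}

#' Randomly reorient internal fragments
#'
#' Internal reads carry no strand information: each internal fragment is
#' reverse-complemented with probability 0.5. Calling this on
#' UMI-containing fragments is a contract violation (they always keep the
#' transcript sense).
#'
#' @param fragments Character vector of fragment sequences.
#' @param role Fragment role(s); must all be `"internal"`.
#' @param seed Integer seed (`NULL` to use the current RNG stream).
#' @return data.frame with `fragment` (possibly reverse-complemented) and
#'   `orientation` ("sense"/"antisense").
#' @export
orient_internal <- function(fragments, role = "internal", seed = NULL) {
  if (any(role != "internal")) {
    stop("orient_internal applies only to internal fragments")
  }
  if (!is.null(seed)) set.seed(seed)
  flip <- stats::runif(length(fragments)) < 0.5
  out <- fragments
  if (any(flip)) out[flip] <- revcomp(fragments[flip])
  data.frame(fragment = out,
             orientation = ifelse(flip, "antisense", "sense"),
             stringsAsFactors = FALSE)
}

#' Generate a paired-end read from a fragment
#'
#' Standard FR geometry: read 1 is the first `min(read_len, L)` bases of
#' the fragment, read 2 the reverse complement of the last
#' `min(read_len, L)` bases. For UMI-containing fragments read 1 thus
#' begins with tag + UMI + GGG.
#'
#' @param fragments Character vector of fragment sequences.
#' @param read_len Read length.
#' @return data.frame with `read1`, `read2`.
#' @export
make_read_pair <- function(fragments, read_len) {
  len <- nchar(fragments)
  k <- pmin(read_len, len)
  data.frame(read1 = substr(fragments, 1L, k),
             read2 = revcomp(substr(fragments, len - k + 1L, len)),
             stringsAsFactors = FALSE)
}

#' Inject per-base substitution errors
#'
#' Independent Bernoulli(P) substitution at every base; an erroneous base
#' is replaced by one of the other three nucleotides with equal
#' probability. Length-preserving; no indels.
#'
#' @param seqs Character vector of sequences.
#' @param p Substitution probability in \[0, 1\].
#' @param seed Integer seed (`NULL` to use the current RNG stream).
#' @return Character vector of mutated sequences.
#' @export
inject_errors <- function(seqs, p, seed = NULL) {
  stopifnot(p >= 0, p <= 1)
  if (length(seqs) == 0L || p == 0) return(seqs)
  if (!is.null(seed)) set.seed(seed)
  lens <- nchar(seqs)
  big <- charToRaw(paste(seqs, collapse = ""))
  hit <- which(stats::runif(length(big)) < p)
  if (length(hit)) {
    cur <- rawToChar(big[hit], multiple = TRUE)
    # pick uniformly among the three alternative bases
    alt <- matrix(c("C","G","T", "A","G","T", "A","C","T", "A","C","G"),
                  nrow = 3L,
                  dimnames = list(NULL, c("A", "C", "G", "T")))
    choice <- sample.int(3L, length(hit), replace = TRUE)
    known <- cur %in% colnames(alt)
    repl <- cur
    repl[known] <- alt[cbind(choice[known], match(cur[known],
                                                  colnames(alt)))]
    big[hit] <- charToRaw(paste(repl, collapse = ""))
  }
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  substring(rawToChar(big), starts, ends)
}

#' Subsample amplified read pairs back to their targets
#'
#' For each molecule, `min(target, available)` UMI-containing pairs are
#' retained uniformly without replacement, undoing the PAF inflation.
#' Internal pairs are subsampled by the same global retention fraction so
#' the internal-to-UMI balance established during fragment extraction is
#' preserved.
#'
#' @param umi_molecule Molecule id per amplified UMI pair.
#' @param targets Named/indexed integer vector: target read count per
#'   molecule id.
#' @param n_internal Number of internal pairs.
#' @param seed Integer seed (`NULL` to use the current RNG stream).
#' @return List with `keep_umi` (logical per UMI pair), `keep_internal`
#'   (logical per internal pair), `retention` (global fraction applied to
#'   internal pairs).
#' @export
subsample_reads <- function(umi_molecule, targets, n_internal = 0L,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(umi_molecule)
  keep_umi <- logical(n)
  if (n > 0L) {
    ord <- order(umi_molecule, stats::runif(n))
    pos <- stats::ave(seq_len(n), umi_molecule[ord], FUN = seq_along)
    keep_umi[ord] <- pos <= targets[umi_molecule[ord]]
  }
  retention <- if (n > 0L) sum(keep_umi) / n else 1
  keep_internal <- logical(n_internal)
  if (n_internal > 0L) {
    k <- as.integer(round(retention * n_internal))
    keep_internal[sample.int(n_internal, min(k, n_internal))] <- TRUE
  }
  list(keep_umi = keep_umi, keep_internal = keep_internal,
       retention = retention)
}

#' Assign positional quality strings
#'
#' Position i of each read receives a Phred score drawn from the
#' empirical profile at position i; reads longer than the profile reuse
#' the final position's distribution.
#'
#' @param lengths Integer vector of read lengths.
#' @param profile List of per-position `empirical_distribution`s.
#' @param seed Integer seed (`NULL` to use the current RNG stream).
#' @return Character vector of Phred+33 quality strings.
#' @export
assign_quality <- function(lengths, profile, seed = NULL) {
  stopifnot(length(profile) >= 1L)
  if (!is.null(seed)) set.seed(seed)
  n <- length(lengths)
  if (n == 0L) return(character(0))
  maxlen <- max(lengths)
  lp <- length(profile)
  scores <- matrix(0L, nrow = n, ncol = maxlen)
  for (i in seq_len(maxlen)) {
    scores[, i] <- as.integer(
      sample_distribution(profile[[min(i, lp)]], n))
  }
  big <- rawToChar(as.raw(t(scores) + 33L))
  starts <- (seq_len(n) - 1L) * maxlen + 1L
  substring(big, starts, starts + lengths - 1L)
}

#' Simulate Smart-seq3 reads from a ground truth
#'
#' Runs the full eight-step protocol over every cell of the truth's
#' transcript UMI count matrix and returns (and optionally writes) paired
#' FASTQ reads plus a ground-truth ledger that maps every read id back to
#' its barcode, UMI, source species and fragment coordinates within the
#' tagged molecule — sufficient to reconstruct the error-free read
#' sequences without alignment.
#'
#' @param truth A `ground_truth` (or any list with `transcripts`
#'   including `sequence`, `counts`, `population`).
#' @param chars A `data_characteristics`.
#' @param config A `simulation_config`.
#' @param seed Integer seed; the run is byte-reproducible under it.
#' @param out_prefix Optional path prefix; writes `<prefix>_R1.fastq[.gz]`,
#'   `<prefix>_R2.fastq[.gz]`, `<prefix>_truth.tsv`,
#'   `<prefix>_barcodes.tsv`.
#' @param gzip Compress the FASTQ output.
#' @return List of class `simulated_reads`: `reads` (data.frame `id`,
#'   `read1`, `qual1`, `read2`, `qual2`), `ledger` (per-read truth
#'   table), `barcodes` (cell/barcode/population), `stats` (per-stage
#'   counts).
#' @export
simulate_reads <- function(truth, chars, config = simulation_config(),
                           seed = 1L, out_prefix = NULL, gzip = FALSE) {
  validate_characteristics(chars)
  species <- truth$transcripts
  counts <- truth$counts
  stopifnot(nrow(species) == nrow(counts))
  n_cells <- ncol(counts)
  population <- if (!is.null(truth$population)) truth$population else
    rep(1L, n_cells)
  set.seed(child_seed(seed, 1L))

  # step 1: barcodes, UMIs, tagging
  barcodes <- assign_barcodes(n_cells, config$barcode_len,
                              seed = child_seed(seed, 2L))
  mols <- assign_umis(counts, species, config$umi_len,
                      seed = child_seed(seed, 3L))
  bc_table <- data.frame(cell = colnames(counts), barcode = barcodes,
                         population = population, stringsAsFactors = FALSE)
  empty_reads <- data.frame(id = character(0), read1 = character(0),
                            qual1 = character(0), read2 = character(0),
                            qual2 = character(0), stringsAsFactors = FALSE)
  finish <- function(reads, ledger, stats) {
    out <- structure(list(reads = reads, ledger = ledger,
                          barcodes = bc_table, stats = stats),
                     class = "simulated_reads")
    if (!is.null(out_prefix)) {
      write_fastq_pairs(reads, paste0(out_prefix, "_R1.fastq"),
                        paste0(out_prefix, "_R2.fastq"), gzip = gzip)
      utils::write.table(ledger, paste0(out_prefix, "_truth.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(bc_table, paste0(out_prefix, "_barcodes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    out
  }
  if (nrow(mols) == 0L) {
    ledger <- data.frame(read_id = character(0), cell = character(0),
                         barcode = character(0), population = integer(0),
                         species_id = character(0), gene_id = character(0),
                         role = character(0), umi = character(0),
                         molecule = integer(0), duplicate = integer(0),
                         frag_start = integer(0), frag_end = integer(0),
                         orientation = character(0),
                         stringsAsFactors = FALSE)
    return(finish(empty_reads, ledger, list(n_molecules = 0L)))
  }

  set.seed(child_seed(seed, 4L))
  n_mol <- nrow(mols)
  tagged <- tag_molecule(mols$umi, species$sequence[mols$species])
  tagged_len <- nchar(tagged)

  # step 2: PCR amplification with PAF inflation
  amp <- pcr_amplify(n_mol, chars$reads_per_umi, config$paf)
  copy_mol <- rep.int(seq_len(n_mol), amp$copies)
  n_copies <- length(copy_mol)

  # step 3: UMI-containing fragments from the 5' end of each copy
  L <- pmin(as.integer(sample_distribution(chars$umi_fragment_length,
                                           n_copies)),
            tagged_len[copy_mol])

  # step 4: internal fragments from the remainders
  ratio <- sample_distribution(chars$internal_to_umi_ratio, n_mol)
  n_int_mol <- as.integer(round(ratio * amp$copies))
  int_mol <- rep.int(seq_len(n_mol), n_int_mol)
  copy_offset <- cumsum(c(0L, amp$copies))[seq_len(n_mol)]
  int_copy <- copy_offset[int_mol] +
    as.integer(floor(stats::runif(length(int_mol)) *
                       amp$copies[int_mol])) + 1L
  rem_len <- tagged_len[copy_mol][int_copy] - L[int_copy]
  nonempty <- rem_len > 0L
  int_copy <- int_copy[nonempty]; int_mol <- int_mol[nonempty]
  rem_len <- rem_len[nonempty]
  Li <- pmin(as.integer(sample_distribution(chars$internal_fragment_length,
                                            length(int_mol))), rem_len)
  int_off <- as.integer(floor(stats::runif(length(int_mol)) *
                                (rem_len - Li + 1L)))
  int_start <- L[int_copy] + int_off
  int_end <- int_start + Li
  int_frag <- substr(tagged[int_mol], int_start + 1L, int_end)

  # step 5: orientation and paired-end read generation
  oriented <- orient_internal(int_frag)
  umi_frag <- substr(tagged[copy_mol], 1L, L)
  pairs_umi <- make_read_pair(umi_frag, config$read_len)
  pairs_int <- make_read_pair(oriented$fragment, config$read_len)

  # step 6: substitution errors
  all_r1 <- inject_errors(c(pairs_umi$read1, pairs_int$read1),
                          config$error_rate)
  all_r2 <- inject_errors(c(pairs_umi$read2, pairs_int$read2),
                          config$error_rate)

  # step 7: subsample back to the reads-per-UMI targets
  sub <- subsample_reads(copy_mol, amp$target, n_internal = length(int_mol))
  keep <- c(sub$keep_umi, sub$keep_internal)

  role <- rep(c("umi", "internal"), c(n_copies, length(int_mol)))
  mol_of <- c(copy_mol, int_mol)
  frag_start <- c(rep(0L, n_copies), int_start)
  frag_end <- c(L, int_end)
  orientation <- c(rep("sense", n_copies), oriented$orientation)
  r1 <- all_r1[keep]; r2 <- all_r2[keep]
  role <- role[keep]; mol_of <- mol_of[keep]
  frag_start <- frag_start[keep]; frag_end <- frag_end[keep]
  orientation <- orientation[keep]

  # step 8: positional qualities
  qual1 <- assign_quality(nchar(r1), chars$quality_by_position_read)
  qual2 <- assign_quality(nchar(r2), chars$quality_by_position_read)

  dup <- stats::ave(seq_along(mol_of), paste(mol_of, role), FUN = seq_along)
  cell_of <- mols$cell[mol_of]
  ids <- make_read_id(barcodes[cell_of], mol_of, dup, role,
                      species$species_id[mols$species[mol_of]])
  reads <- data.frame(id = ids, read1 = r1, qual1 = qual1,
                      read2 = r2, qual2 = qual2, stringsAsFactors = FALSE)
  ledger <- data.frame(
    read_id = ids,
    cell = colnames(counts)[cell_of],
    barcode = barcodes[cell_of],
    population = population[cell_of],
    species_id = species$species_id[mols$species[mol_of]],
    gene_id = species$gene_id[mols$species[mol_of]],
    role = role,
    umi = mols$umi[mol_of],
    molecule = mol_of,
    duplicate = dup,
    frag_start = frag_start,
    frag_end = frag_end,
    orientation = orientation,
    stringsAsFactors = FALSE)
  stats <- list(n_molecules = n_mol, n_amplified_umi = n_copies,
                n_internal_extracted = length(int_mol),
                n_reads = nrow(reads),
                n_umi_reads = sum(role == "umi"),
                n_internal_reads = sum(role == "internal"),
                retention = sub$retention)
  ss_log("simulate_reads: %d molecules -> %d read pairs (%d UMI, %d internal)",
         n_mol, stats$n_reads, stats$n_umi_reads, stats$n_internal_reads)
  finish(reads, ledger, stats)
}

#' @export
print.simulated_reads <- function(x, ...) {
  cat(sprintf("simulated_reads: %d pairs (%d UMI-containing, %d internal), %d cells\n",
              nrow(x$reads), sum(x$ledger$role == "umi"),
              sum(x$ledger$role == "internal"), nrow(x$barcodes)))
  invisible(x)
}

#' Reconstruct the error-free read sequences from the truth ledger
#'
#' Rebuilds each tagged molecule (tag + UMI + GGG + species sequence),
#' cuts the ledger-recorded fragment, applies the recorded orientation
#' and regenerates both mates — the error-free reads a perfect sequencer
#' would have produced. Used to measure the realised substitution rate
#' without any aligner.
#'
#' @param ledger Ledger from [simulate_reads()].
#' @param truth The `ground_truth` the reads were simulated from.
#' @param read_len Read length used in the simulation.
#' @return data.frame with `read_id`, `read1`, `read2` (expected
#'   sequences).
#' @export
expected_read_sequences <- function(ledger, truth, read_len = 150L) {
  seqs <- truth$transcripts$sequence[
    match(ledger$species_id, truth$transcripts$species_id)]
  tagged <- tag_molecule(ledger$umi, seqs)
  frag <- substr(tagged, ledger$frag_start + 1L, ledger$frag_end)
  anti <- ledger$orientation == "antisense"
  frag[anti] <- revcomp(frag[anti])
  pr <- make_read_pair(frag, read_len)
  data.frame(read_id = ledger$read_id, read1 = pr$read1, read2 = pr$read2,
             stringsAsFactors = FALSE)
}

#' Measure the realised per-base substitution rate
#'
#' Compares simulated reads against the ledger-reconstructed error-free
#' sequences, base by base.
#'
#' @param sim A `simulated_reads` result.
#' @param truth The `ground_truth` it was simulated from.
#' @param read_len Read length used in the simulation.
#' @return List with `mismatches`, `bases`, `rate`.
#' @export
measure_error_rate <- function(sim, truth, read_len = 150L) {
  exp <- expected_read_sequences(sim$ledger, truth, read_len)
  stopifnot(identical(exp$read_id, sim$reads$id))
  count_mm <- function(a, b) {
    ra <- charToRaw(paste(a, collapse = ""))
    rb <- charToRaw(paste(b, collapse = ""))
    stopifnot(length(ra) == length(rb))
    sum(ra != rb)
  }
  mm <- count_mm(sim$reads$read1, exp$read1) +
    count_mm(sim$reads$read2, exp$read2)
  bases <- sum(nchar(sim$reads$read1)) + sum(nchar(sim$reads$read2))
  list(mismatches = mm, bases = bases, rate = mm / bases)
}
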