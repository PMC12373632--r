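# Building the simulation ground truth.
#
# The truth is assembled in a cascade: a gene-level UMI count matrix
# (empirical counts, cell size factors), a per-population PSI matrix
# (flat-Dirichlet split of 100% across each gene's isoforms), and a
# per-population unspliced-fraction matrix. Combining the three yields the
# transcript-level UMI count matrix over spliced isoforms plus one
# intron-retaining pre-mRNA species per gene.

#' Describe the cell-population design of a simulated experiment
#'
#' @param n_populations Number of cell populations (>= 1).
#' @param cells_per_population Cells per population (>= 1).
#' @param n_diff_splicing Number of genes with population-specific PSI;
#'   the remaining genes keep one PSI vector across populations.
#' @param n_diff_unspliced Number of genes with population-specific
#'   unspliced fraction.
#' @return Object of class `population_design`.
#' @export
population_design <- function(n_populations, cells_per_population,
                              n_diff_splicing = 0L, n_diff_unspliced = 0L) {
  stopifnot(n_populations >= 1L, cells_per_population >= 1L,
            n_diff_splicing >= 0L, n_diff_unspliced >= 0L)
  structure(list(n_populations = as.integer(n_populations),
                 cells_per_population = as.integer(cells_per_population),
                 n_diff_splicing = as.integer(n_diff_splicing),
                 n_diff_unspliced = as.integer(n_diff_unspliced)),
            class = "population_design")
}

#' Select genes and annotated transcripts to simulate
#'
#' Either selects `k` random genes that have at least `n` annotated
#' transcripts, or filters a user-supplied `gene_list` (ineligible genes,
#' i.e. those with fewer than `n` transcripts, are dropped with a log
#' message). For each selected gene, `n` distinct transcripts are chosen
#' uniformly at random.
#'
#' @param ann A `gene_annotation`.
#' @param k Number of genes to select (mutually exclusive with
#'   `gene_list`).
#' @param gene_list Character vector of candidate gene ids.
#' @param n Transcripts per gene.
#' @param seed Integer seed.
#' @return data.frame with `gene_id`, `transcript_id`, `novelty`
#'   (`"annotated"`).
#' @export
get_transcripts <- function(ann, k = NULL, gene_list = NULL, n = 2L,
                            seed = 1L) {
  stopifnot(xor(is.null(k), is.null(gene_list)), n >= 1L)
  tx_by_gene <- lapply(split(ann$exons$transcript_id, ann$exons$gene_id),
                       unique)
  eligible <- names(tx_by_gene)[vapply(tx_by_gene, length, integer(1)) >= n]
  set.seed(seed)
  if (!is.null(k)) {
    if (length(eligible) < k) {
      stop("only ", length(eligible), " gene(s) with >= ", n,
           " transcripts; ", k, " requested")
    }
    genes <- sort(eligible)[sample.int(length(eligible), k)]
  } else {
    genes <- intersect(gene_list, eligible)
    dropped <- setdiff(gene_list, genes)
    if (length(dropped)) {
      ss_log("get_transcripts: dropped %d ineligible gene(s): %s",
             length(dropped), paste(dropped, collapse = ", "))
    }
    if (length(genes) == 0L) stop("no eligible genes in gene_list")
  }
  out <- do.call(rbind, lapply(genes, function(g) {
    tx <- sort(tx_by_gene[[g]])
    data.frame(gene_id = g,
               transcript_id = tx[sample.int(length(tx), n)],
               novelty = "annotated", stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# unique exon intervals of a gene, sorted; and the set of junctions
# (end_i, start_j) used by consecutive exons of any annotated transcript
gene_exon_catalog <- function(ann, gene_id) {
  ex <- ann$exons[ann$exons$gene_id == gene_id, ]
  if (nrow(ex) == 0L) stop("unknown gene id: ", gene_id)
  uniq <- unique(ex[, c("start", "end")])
  uniq <- uniq[order(uniq$start, uniq$end), ]
  rownames(uniq) <- NULL
  junctions <- character(0)
  for (tx in unique(ex$transcript_id)) {
    e <- ex[ex$transcript_id == tx, ]
    e <- e[order(e$start), ]
    if (nrow(e) > 1L) {
      junctions <- c(junctions,
                     paste(e$end[-nrow(e)], e$start[-1L], sep = "-"))
    }
  }
  list(exons = uniq, junctions = unique(junctions),
       contig = ex$contig[1L], strand = ex$strand[1L],
       transcripts = unique(ex$transcript_id))
}

# exon chain of a transcript as "start-end,start-end,..." for identity tests
chain_key <- function(exons) {
  exons <- exons[order(exons$start), ]
  paste(paste(exons$start, exons$end, sep = "-"), collapse = ",")
}

new_transcript_id <- function(ann, gene_id, tag) {
  existing <- annotation_transcripts(ann)
  i <- 1L
  repeat {
    id <- sprintf("%s-%s%d", gene_id, tag, i)
    if (!id %in% existing) return(id)
    i <- i + 1L
  }
}

#' Add a transcript with a novel splice junction
#'
#' Creates a novel isoform of `gene_id` by joining two existing exons of
#' the gene across a splice junction that no annotated transcript of the
#' gene uses. The host chain is built on a randomly chosen annotated
#' backbone: exons upstream of the first joined exon and downstream of
#' the second are retained.
#'
#' @param ann A `gene_annotation`.
#' @param gene_id Gene to modify.
#' @param seed Integer seed.
#' @return List with `transcript_id`, `gene_id`, `exons` (full exon table
#'   of the novel transcript), `novelty = "novel-junction"`, and
#'   `junction` (`c(donor_end, acceptor_start)`, 0-based).
#' @export
add_new_junction <- function(ann, gene_id, seed = 1L) {
  cat0 <- gene_exon_catalog(ann, gene_id)
  ex <- cat0$exons
  n <- nrow(ex)
  cand <- list()
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        if (ex$end[i] < ex$start[j]) {  # ordered, non-overlapping, intron > 0
          key <- paste(ex$end[i], ex$start[j], sep = "-")
          if (!key %in% cat0$junctions) cand[[length(cand) + 1L]] <- c(i, j)
        }
      }
    }
  }
  if (length(cand) == 0L) {
    stop("no novel junction possible for gene ", gene_id,
         ": every admissible exon pair is already joined by an annotated ",
         "transcript")
  }
  set.seed(seed)
  pick <- cand[[sample.int(length(cand), 1L)]]
  a <- ex[pick[1L], ]; b <- ex[pick[2L], ]
  backbone <- sample(cat0$transcripts, 1L)
  bex <- transcript_exons(ann, backbone)
  chain <- rbind(bex[bex$end <= a$start, c("start", "end")],
                 a, b,
                 bex[bex$start >= b$end, c("start", "end")])
  chain <- unique(chain[order(chain$start), ])
  annotated_chains <- vapply(cat0$transcripts, function(tx) {
    chain_key(transcript_exons(ann, tx))
  }, character(1))
  stopifnot(!chain_key(chain) %in% annotated_chains)
  id <- new_transcript_id(ann, gene_id, "nj")
  list(transcript_id = id, gene_id = gene_id,
       exons = data.frame(contig = cat0$contig, start = chain$start,
                          end = chain$end, strand = cat0$strand,
                          gene_id = gene_id, transcript_id = id,
                          stringsAsFactors = FALSE),
       novelty = "novel-junction",
       junction = c(a$end, b$start))
}

# admissible novel-exon placements inside one intron [is, ie) (0-based)
# on `strand`, honouring the canonical AG acceptor / GT donor rule on the
# transcript's sense strand; returns data.frame(start, end)
scan_intron_placements <- function(genome, contig, intron_start, intron_end,
                                   strand, canonical, len_range) {
  width <- intron_end - intron_start
  if (width < 5L) return(data.frame(start = integer(0), end = integer(0)))
  if (!canonical) {
    # any strictly interior placement
    smin <- intron_start + 1L
    emax <- intron_end - 1L
    lens <- seq.int(max(1L, len_range[1L]), len_range[2L])
    out <- do.call(rbind, lapply(lens, function(L) {
      s <- seq.int(smin, emax - L)
      if (length(s) == 0L || s[1L] > emax - L) {
        return(NULL)
      }
      data.frame(start = s, end = s + L)
    }))
    if (is.null(out)) out <- data.frame(start = integer(0), end = integer(0))
    return(out)
  }
  iseq <- as.character(Biostrings::subseq(genome[[contig]],
                                          intron_start + 1L, intron_end))
  find_motif <- function(m) {
    hits <- gregexpr(m, iseq, fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) integer(0) else as.integer(hits) - 1L  # 0-based
  }
  if (strand == "+") {
    # acceptor AG immediately before exon, donor GT immediately after
    starts <- find_motif("AG") + 2L + intron_start   # exon start candidates
    ends <- find_motif("GT") + intron_start          # exon end candidates
  } else {
    # sense strand is the reverse complement: genomic CT after the exon is
    # the AG acceptor, genomic AC before it is the GT donor
    starts <- find_motif("AC") + 2L + intron_start
    ends <- find_motif("CT") + intron_start
  }
  starts <- starts[starts >= intron_start + 2L]
  ends <- ends[ends <= intron_end - 2L]
  grid <- expand.grid(start = starts, end = ends)
  grid <- grid[grid$end > grid$start &
                 (grid$end - grid$start) >= len_range[1L] &
                 (grid$end - grid$start) <= len_range[2L], , drop = FALSE]
  rownames(grid) <- NULL
  grid
}

#' Add a transcript with a novel exon
#'
#' Inserts a new exon strictly inside an intron of the gene, creating two
#' novel splice junctions. With `canonical = TRUE` the placement is
#' restricted so both new junctions carry canonical splice motifs on the
#' transcript's sense strand: the 2 nt immediately preceding the novel
#' exon read AG (acceptor of the upstream new intron) and the 2 nt
#' immediately following it read GT (donor of the downstream new intron).
#' Pre-existing flanking splice sites are untouched.
#'
#' @param ann A `gene_annotation`.
#' @param genome Named `DNAStringSet`.
#' @param gene_id Gene to modify.
#' @param canonical Require AG/GT motifs (default TRUE).
#' @param exon_length_range Length bounds (nt) of the novel exon.
#' @param seed Integer seed.
#' @return List with `transcript_id`, `gene_id`, `exons`,
#'   `novelty = "novel-exon"`, `novel_exon` (`c(start, end)`, 0-based
#'   half-open), and `backbone` (host transcript id).
#' @export
add_new_exon <- function(ann, genome, gene_id, canonical = TRUE,
                         exon_length_range = c(20L, 200L), seed = 1L) {
  cat0 <- gene_exon_catalog(ann, gene_id)
  set.seed(seed)
  # introns of every transcript of the gene: gaps between consecutive exons
  searched <- character(0)
  placements <- list()
  for (tx in cat0$transcripts) {
    ex <- transcript_exons(ann, tx)
    if (nrow(ex) < 2L) next
    for (i in seq_len(nrow(ex) - 1L)) {
      is0 <- ex$end[i]; ie0 <- ex$start[i + 1L]
      if (ie0 - is0 < 5L) next
      searched <- c(searched, sprintf("%s:%d-%d", tx, is0, ie0))
      pl <- scan_intron_placements(genome, cat0$contig, is0, ie0,
                                   cat0$strand, canonical, exon_length_range)
      if (nrow(pl)) {
        pl$backbone <- tx
        pl$after_exon <- i
        placements[[length(placements) + 1L]] <- pl
      }
    }
  }
  if (length(placements) == 0L) {
    stop("no admissible novel-exon placement in gene ", gene_id,
         if (canonical) " under the canonical AG/GT rule" else "",
         "; introns searched: ",
         if (length(searched)) paste(searched, collapse = ", ") else "none")
  }
  all_pl <- do.call(rbind, placements)
  pick <- all_pl[sample.int(nrow(all_pl), 1L), ]
  bex <- transcript_exons(ann, pick$backbone)
  chain <- rbind(bex[, c("start", "end")],
                 data.frame(start = pick$start, end = pick$end))
  chain <- chain[order(chain$start), ]
  id <- new_transcript_id(ann, gene_id, "ne")
  list(transcript_id = id, gene_id = gene_id,
       exons = data.frame(contig = cat0$contig, start = chain$start,
                          end = chain$end, strand = cat0$strand,
                          gene_id = gene_id, transcript_id = id,
                          stringsAsFactors = FALSE),
       novelty = "novel-exon",
       novel_exon = c(pick$start, pick$end),
       backbone = pick$backbone)
}

#' Verify canonical splice motifs at a novel exon's junctions
#'
#' Independent check used by the test suite: reads the genome directly at
#' the two junctions created by a novel exon and reports whether the
#' sense-strand acceptor (AG) and donor (GT) motifs are present.
#'
#' @param genome Named `DNAStringSet`.
#' @param contig Contig name.
#' @param strand `"+"` or `"-"`.
#' @param exon_start,exon_end Novel exon coordinates, 0-based half-open.
#' @return Logical scalar.
#' @export
verify_canonical_exon <- function(genome, contig, strand,
                                  exon_start, exon_end) {
  before <- as.character(Biostrings::subseq(genome[[contig]],
                                            exon_start - 1L, exon_start))
  after <- as.character(Biostrings::subseq(genome[[contig]],
                                           exon_end + 1L, exon_end + 2L))
  if (strand == "+") {
    before == "AG" && after == "GT"
  } else {
    revcomp(after) == "AG" && revcomp(before) == "GT"
  }
}

#' Merge novel transcripts into an annotation
#' @param ann A `gene_annotation`.
#' @param novel List of results from [add_new_junction()] /
#'   [add_new_exon()], or a single such result.
#' @return The augmented `gene_annotation`.
#' @export
add_transcripts <- function(ann, novel) {
  if (!is.null(novel$exons)) novel <- list(novel)
  gene_annotation(rbind(ann$exons,
                        do.call(rbind, lapply(novel, `[[`, "exons"))))
}

#' Generate the gene-level UMI count matrix
#'
#' Step one of the truth cascade. For each population, a base expression
#' level per gene is drawn from the empirical UMIs-per-gene distribution,
#' redrawing until the count reaches the gene's minimum `n_min` (by
#' default the number of transcripts simulated for the gene, so every
#' isoform can receive a UMI). Per cell, a size factor `s` is drawn
#' log2-uniformly from \[2^-2, 2^2\] and the cell's counts are
#' `round(base * s)` (round-half-even), floored at `n_min`.
#'
#' @param chars A `data_characteristics`.
#' @param design A `population_design`.
#' @param gene_table data.frame with `gene_id`, `transcript_id` (one row
#'   per simulated transcript) as returned by [get_transcripts()].
#' @param n_min Minimum UMI count per gene; `NULL` (default) uses each
#'   gene's transcript count.
#' @param seed Integer seed.
#' @return List of class `gene_umi_matrix`: `counts` (genes x cells),
#'   `base` (genes x populations), `size_factors` (per cell),
#'   `population` (population index per cell).
#' @export
generate_gene_umi_matrix <- function(chars, design, gene_table, n_min = NULL,
                                     seed = 1L) {
  genes <- unique(gene_table$gene_id)
  ntx <- vapply(genes, function(g) sum(gene_table$gene_id == g), integer(1))
  nmin <- if (is.null(n_min)) ntx else rep_len(as.integer(n_min), length(genes))
  names(nmin) <- genes
  dmax <- max(chars$umis_per_gene$values)
  if (any(dmax < nmin)) {
    stop("UMIs-per-gene distribution maximum (", dmax,
         ") below the required minimum count for gene(s): ",
         paste(genes[dmax < nmin], collapse = ", "))
  }
  set.seed(seed)
  p <- design$n_populations; cc <- design$cells_per_population
  base <- matrix(0L, nrow = length(genes), ncol = p,
                 dimnames = list(genes, NULL))
  for (q in seq_len(p)) {
    for (g in seq_along(genes)) {
      repeat {
        v <- sample_distribution(chars$umis_per_gene, 1L)
        if (v >= nmin[g]) break
      }
      base[g, q] <- as.integer(v)
    }
  }
  n_cells <- p * cc
  population <- rep(seq_len(p), each = cc)
  s <- 2^stats::runif(n_cells, -2, 2)
  counts <- matrix(0L, nrow = length(genes), ncol = n_cells,
                   dimnames = list(genes,
                                   sprintf("cell%03d", seq_len(n_cells))))
  for (j in seq_len(n_cells)) {
    counts[, j] <- pmax(nmin,
                        as.integer(round_half_even(base[, population[j]] *
                                                     s[j])))
  }
  structure(list(counts = counts, base = base, size_factors = s,
                 population = population, n_min = nmin),
            class = "gene_umi_matrix")
}

#' Generate the transcript PSI matrix
#'
#' Step two of the truth cascade. For each gene and population, 100% is
#' distributed across the gene's transcripts by a flat Dirichlet draw
#' (uniform on the simplex). Fixed-splicing genes reuse one draw across
#' all populations; the `n_diff_splicing` differentially spliced genes
#' (chosen at random) draw independently per population.
#'
#' @param gene_table data.frame with `gene_id`, `transcript_id`.
#' @param design A `population_design`.
#' @param seed Integer seed.
#' @return Matrix (transcripts x populations) of PSI percentages with a
#'   `differential` attribute naming the differentially spliced genes.
#'   Within each gene and population the values sum to 100.
#' @export
generate_psi_matrix <- function(gene_table, design, seed = 1L) {
  genes <- unique(gene_table$gene_id)
  stopifnot(design$n_diff_splicing <= length(genes))
  set.seed(seed)
  diff_genes <- if (design$n_diff_splicing > 0L) {
    sort(genes)[sample.int(length(genes), design$n_diff_splicing)]
  } else character(0)
  p <- design$n_populations
  psi <- matrix(0, nrow = nrow(gene_table), ncol = p,
                dimnames = list(gene_table$transcript_id, NULL))
  rdirichlet_flat <- function(n) {
    g <- stats::rexp(n)
    g / sum(g)
  }
  for (g in genes) {
    rows <- which(gene_table$gene_id == g)
    if (g %in% diff_genes) {
      for (q in seq_len(p)) psi[rows, q] <- 100 * rdirichlet_flat(length(rows))
    } else {
      v <- 100 * rdirichlet_flat(length(rows))
      psi[rows, ] <- matrix(v, nrow = length(rows), ncol = p)
    }
  }
  attr(psi, "differential") <- diff_genes
  psi
}

#' Generate the unspliced-fraction matrix
#'
#' Step three of the truth cascade. Per gene and population, the fraction
#' of the gene's molecules that remain unspliced (intron-retaining
#' pre-mRNA). Fixed genes sample one value from the empirical
#' unspliced-fraction distribution and reuse it across populations; the
#' `n_diff_unspliced` genes sample independently per population. A
#' user-supplied `custom_matrix` (genes x populations, values in \[0,1\])
#' is validated and returned verbatim — e.g. a high-fraction matrix to
#' emulate single-nuclei data.
#'
#' @param chars A `data_characteristics` (ignored when `custom_matrix`
#'   is given).
#' @param gene_ids Character vector of gene ids (row order).
#' @param design A `population_design`.
#' @param custom_matrix Optional genes x populations matrix.
#' @param seed Integer seed.
#' @return Matrix (genes x populations) of fractions in \[0,1\] with a
#'   `differential` attribute.
#' @export
generate_unspliced_matrix <- function(chars, gene_ids, design,
                                      custom_matrix = NULL, seed = 1L) {
  p <- design$n_populations
  if (!is.null(custom_matrix)) {
    custom_matrix <- as.matrix(custom_matrix)
    if (nrow(custom_matrix) != length(gene_ids) || ncol(custom_matrix) != p) {
      stop("custom unspliced matrix must be ", length(gene_ids), " x ", p)
    }
    if (any(custom_matrix < 0 | custom_matrix > 1)) {
      stop("custom unspliced matrix values must lie in [0,1]")
    }
    rownames(custom_matrix) <- gene_ids
    return(custom_matrix)
  }
  stopifnot(design$n_diff_unspliced <= length(gene_ids))
  set.seed(seed)
  diff_genes <- if (design$n_diff_unspliced > 0L) {
    sort(gene_ids)[sample.int(length(gene_ids), design$n_diff_unspliced)]
  } else character(0)
  m <- matrix(0, nrow = length(gene_ids), ncol = p,
              dimnames = list(gene_ids, NULL))
  for (g in gene_ids) {
    if (g %in% diff_genes) {
      m[g, ] <- sample_distribution(chars$unspliced_fraction, p)
    } else {
      m[g, ] <- rep(sample_distribution(chars$unspliced_fraction, 1L), p)
    }
  }
  attr(m, "differential") <- diff_genes
  m
}

# largest-remainder apportionment of `total` over weights w (>= 0, sum > 0)
largest_remainder <- function(total, w) {
  if (total == 0L) return(rep(0L, length(w)))
  quota <- total * w / sum(w)
  base <- floor(quota)
  rem <- total - sum(base)
  if (rem > 0L) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

#' Combine the truth matrices into transcript-level UMI counts
#'
#' For gene `g` in cell `j` of population `q` with gene count `G`: the
#' unspliced pre-mRNA species receives `round(G * unspliced[g,q])` UMIs
#' (round-half-even) and the remaining spliced UMIs are apportioned over
#' the gene's transcripts by largest-remainder rounding of their PSI
#' shares, so per-gene per-cell totals are conserved exactly.
#'
#' @param gene_umi A `gene_umi_matrix`.
#' @param psi PSI matrix from [generate_psi_matrix()].
#' @param unspliced Matrix from [generate_unspliced_matrix()].
#' @param gene_table data.frame with `gene_id`, `transcript_id` matching
#'   the PSI rows.
#' @return List of class `transcript_umi_matrix`: `counts` (species x
#'   cells, spliced transcript rows followed by per-gene `.unspliced`
#'   pre-mRNA rows), `species` (data.frame: `species_id`, `gene_id`,
#'   `type`, `transcript_id`), `population`.
#' @export
combine_truth <- function(gene_umi, psi, unspliced, gene_table) {
  genes <- rownames(gene_umi$counts)
  stopifnot(identical(rownames(psi), gene_table$transcript_id),
            all(gene_table$gene_id %in% genes),
            identical(rownames(unspliced), genes))
  n_cells <- ncol(gene_umi$counts)
  species <- rbind(
    data.frame(species_id = gene_table$transcript_id,
               gene_id = gene_table$gene_id, type = "spliced",
               transcript_id = gene_table$transcript_id,
               stringsAsFactors = FALSE),
    data.frame(species_id = paste0(genes, ".unspliced"),
               gene_id = genes, type = "unspliced",
               transcript_id = NA_character_, stringsAsFactors = FALSE))
  counts <- matrix(0L, nrow = nrow(species), ncol = n_cells,
                   dimnames = list(species$species_id,
                                   colnames(gene_umi$counts)))
  for (j in seq_len(n_cells)) {
    q <- gene_umi$population[j]
    for (g in genes) {
      G <- gene_umi$counts[g, j]
      u <- as.integer(round_half_even(G * unspliced[g, q]))
      if (u < 0L || u > G) stop("internal error: unspliced count ", u,
                                " outside [0, ", G, "]")
      rows <- which(gene_table$gene_id == g)
      spliced <- largest_remainder(G - u, psi[rows, q])
      counts[gene_table$transcript_id[rows], j] <- spliced
      counts[paste0(g, ".unspliced"), j] <- u
    }
  }
  structure(list(counts = counts, species = species,
                 population = gene_umi$population),
            class = "transcript_umi_matrix")
}

#' Build a complete simulation ground truth
#'
#' Convenience orchestrator: selects genes and transcripts, injects the
#' requested novel junctions and exons (each into a distinct randomly
#' chosen selected gene), runs the three-step matrix cascade, and fetches
#' every species' sequence (spliced transcript sequences; one
#' intron-retaining pre-mRNA per gene spanning the gene's full exon
#' span). Stage seeds are derived from `seed` by [child_seed()].
#'
#' @param ann A `gene_annotation`.
#' @param genome Named `DNAStringSet`.
#' @param design A `population_design`.
#' @param k Number of genes (or use `gene_list`).
#' @param gene_list Optional explicit gene ids.
#' @param transcripts_per_gene Annotated transcripts per gene.
#' @param novel_junctions,novel_exons Number of novel-junction /
#'   novel-exon transcripts to inject.
#' @param canonical Restrict novel exons to canonical AG/GT junctions.
#' @param exon_length_range Novel-exon length bounds (nt).
#' @param n_min Minimum gene UMI count (default: per-gene transcript
#'   count).
#' @param custom_unspliced Optional custom unspliced-fraction matrix.
#' @param chars A `data_characteristics`.
#' @param seed Integer seed.
#' @return Object of class `ground_truth`: `transcripts` (species table
#'   with sequences and novelty flags), `counts`, `psi`, `unspliced`,
#'   `gene_umi`, `population`, `design`, `annotation` (augmented with the
#'   novel transcripts), `gene_table`.
#' @export
build_ground_truth <- function(ann, genome, chars, design,
                               k = NULL, gene_list = NULL,
                               transcripts_per_gene = 2L,
                               novel_junctions = 0L, novel_exons = 0L,
                               canonical = TRUE,
                               exon_length_range = c(20L, 200L),
                               n_min = NULL, custom_unspliced = NULL,
                               seed = 1L) {
  sel <- get_transcripts(ann, k = k, gene_list = gene_list,
                         n = transcripts_per_gene, seed = child_seed(seed, 1L))
  genes <- unique(sel$gene_id)
  n_novel <- novel_junctions + novel_exons
  if (n_novel > length(genes)) {
    stop("more novel events requested (", n_novel, ") than selected genes (",
         length(genes), ")")
  }
  aug <- ann
  if (n_novel > 0L) {
    set.seed(child_seed(seed, 2L))
    hosts <- sort(genes)[sample.int(length(genes), n_novel)]
    novel <- list()
    for (i in seq_len(novel_junctions)) {
      novel[[length(novel) + 1L]] <-
        add_new_junction(aug, hosts[i], seed = child_seed(seed, 100L + i))
      aug <- add_transcripts(aug, novel[[length(novel)]])
    }
    for (i in seq_len(novel_exons)) {
      novel[[length(novel) + 1L]] <-
        add_new_exon(aug, genome, hosts[novel_junctions + i],
                     canonical = canonical,
                     exon_length_range = exon_length_range,
                     seed = child_seed(seed, 200L + i))
      aug <- add_transcripts(aug, novel[[length(novel)]])
    }
    sel <- rbind(sel, do.call(rbind, lapply(novel, function(nv) {
      data.frame(gene_id = nv$gene_id, transcript_id = nv$transcript_id,
                 novelty = nv$novelty, stringsAsFactors = FALSE)
    })))
    sel <- sel[order(match(sel$gene_id, genes)), ]
    rownames(sel) <- NULL
  }
  gene_umi <- generate_gene_umi_matrix(chars, design, sel, n_min = n_min,
                                       seed = child_seed(seed, 3L))
  psi <- generate_psi_matrix(sel, design, seed = child_seed(seed, 4L))
  unspl <- generate_unspliced_matrix(chars, unique(sel$gene_id), design,
                                     custom_matrix = custom_unspliced,
                                     seed = child_seed(seed, 5L))
  tum <- combine_truth(gene_umi, psi, unspl, sel)

  # species sequences: spliced isoforms + per-gene pre-mRNA
  seqs <- character(nrow(tum$species))
  sp <- gene_spans(aug)
  for (i in seq_len(nrow(tum$species))) {
    if (tum$species$type[i] == "spliced") {
      seqs[i] <- fetch_transcript_sequence(aug, genome,
                                           tum$species$transcript_id[i],
                                           spliced = TRUE)
    } else {
      g <- tum$species$gene_id[i]
      row <- sp[sp$gene_id == g, ]
      s <- Biostrings::subseq(genome[[row$contig]], row$start + 1L, row$end)
      if (row$strand == "-") s <- Biostrings::reverseComplement(s)
      seqs[i] <- as.character(s)
    }
  }
  transcripts <- cbind(tum$species,
                       novelty = ifelse(
                         tum$species$type == "unspliced", "pre-mRNA",
                         sel$novelty[match(tum$species$transcript_id,
                                           sel$transcript_id)]),
                       sequence = seqs, stringsAsFactors = FALSE)
  structure(list(transcripts = transcripts, counts = tum$counts,
                 psi = psi, unspliced = unspl, gene_umi = gene_umi,
                 population = gene_umi$population, design = design,
                 annotation = aug, gene_table = sel),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(paste0("ground_truth: %d genes, %d species (%d spliced, ",
                     "%d pre-mRNA), %d cells in %d population(s)\n"),
              length(unique(x$transcripts$gene_id)), nrow(x$transcripts),
              sum(x$transcripts$type == "spliced"),
              sum(x$transcripts$type == "unspliced"),
              ncol(x$counts), x$design$n_populations))
  invisible(x)
}

#' Write a ground truth to a directory
#'
#' Emits plain-text artefacts: `transcripts.fa` (species sequences),
#' `species.tsv` (species table with novelty flags), `counts.tsv`
#' (species x cells), `psi.tsv`, `unspliced.tsv`, `cells.tsv`
#' (cell/population map) and `annotation.gtf` (annotation augmented with
#' novel transcripts).
#'
#' @param truth A `ground_truth`.
#' @param dir Output directory (created if needed).
#' @export
write_ground_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- Biostrings::DNAStringSet(truth$transcripts$sequence)
  names(fa) <- truth$transcripts$species_id
  Biostrings::writeXStringSet(fa, file.path(dir, "transcripts.fa"))
  write_tsv <- function(x, f) {
    utils::write.table(x, file.path(dir, f), sep = "\t", quote = FALSE,
                       col.names = NA)
  }
  utils::write.table(truth$transcripts[, setdiff(names(truth$transcripts),
                                                 "sequence")],
                     file.path(dir, "species.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_tsv(truth$counts, "counts.tsv")
  write_tsv(truth$psi, "psi.tsv")
  write_tsv(truth$unspliced, "unspliced.tsv")
  utils::write.table(data.frame(cell = colnames(truth$counts),
                                population = truth$population),
                     file.path(dir, "cells.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_annotation(truth$annotation, file.path(dir, "annotation.gtf"))
  invisible(dir)
}

#' Read a ground truth directory for simulation
#'
#' Restores the parts of a [write_ground_truth()] directory that the read
#' simulator needs: species sequences, the transcript UMI count matrix
#' and the species/cell tables.
#'
#' @param dir Directory written by [write_ground_truth()].
#' @return A list with `transcripts`, `counts`, `population`, usable as
#'   the `truth` argument of [simulate_reads()].
#' @export
read_ground_truth <- function(dir) {
  fa <- Biostrings::readDNAStringSet(file.path(dir, "transcripts.fa"))
  species <- utils::read.table(file.path(dir, "species.tsv"), sep = "\t",
                               header = TRUE, stringsAsFactors = FALSE)
  counts <- as.matrix(utils::read.table(file.path(dir, "counts.tsv"),
                                        sep = "\t", header = TRUE,
                                        row.names = 1L, check.names = FALSE))
  cells <- utils::read.table(file.path(dir, "cells.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  species$sequence <- as.character(fa)[species$species_id]
  storage.mode(counts) <- "integer"
  list(transcripts = species, counts = counts, population = cells$population)
}
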