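# The data-characteristics bundle: six empirical distributions plus
# per-position quality profiles, learned from a tagged BAM (or supplied as
# parametric defaults), and serialised as a self-describing JSON document
# with a schema version so bundles are portable across implementations.

CHARACTERISTICS_SCHEMA_VERSION <- 1L

DISTRIBUTION_FIELDS <- c("umi_fragment_length", "internal_fragment_length",
                         "reads_per_umi", "internal_to_umi_ratio",
                         "unspliced_fraction", "umis_per_gene")

#' Construct a data-characteristics bundle
#'
#' Bundles the empirical distributions that drive simulation: fragment
#' lengths of UMI-containing and internal reads (nt), reads per UMI
#' (counts >= 1), per-gene internal-to-UMI read ratio (>= 0), per
#' gene-cell unspliced RNA fraction (in \[0,1\]), UMIs per gene per cell
#' (counts >= 0), and positional Phred-score profiles for the read and the
#' barcode/UMI segment.
#'
#' @param umi_fragment_length,internal_fragment_length,reads_per_umi,internal_to_umi_ratio,unspliced_fraction,umis_per_gene
#'   `empirical_distribution` objects.
#' @param quality_by_position_read List of `empirical_distribution`, one
#'   per read position 1..L.
#' @param quality_by_position_barcode List of `empirical_distribution` for
#'   the barcode/UMI segment positions (may be length 0).
#' @param metadata Named list (free-form provenance: source, read length,
#'   pair counts).
#' @return Object of class `data_characteristics`.
#' @export
data_characteristics <- function(umi_fragment_length,
                                 internal_fragment_length,
                                 reads_per_umi,
                                 internal_to_umi_ratio,
                                 unspliced_fraction,
                                 umis_per_gene,
                                 quality_by_position_read,
                                 quality_by_position_barcode = list(),
                                 metadata = list()) {
  x <- structure(list(
    umi_fragment_length = umi_fragment_length,
    internal_fragment_length = internal_fragment_length,
    reads_per_umi = reads_per_umi,
    internal_to_umi_ratio = internal_to_umi_ratio,
    unspliced_fraction = unspliced_fraction,
    umis_per_gene = umis_per_gene,
    quality_by_position_read = quality_by_position_read,
    quality_by_position_barcode = quality_by_position_barcode,
    metadata = metadata), class = "data_characteristics")
  validate_characteristics(x)
  x
}

#' Validate a data-characteristics bundle
#'
#' Checks presence of every distribution and the domain invariants:
#' fragment lengths >= 1, reads per UMI >= 1, ratios >= 0, unspliced
#' fractions in \[0,1\], UMI counts >= 0, and a non-empty per-position
#' read quality profile.
#'
#' @param x A `data_characteristics`.
#' @return Invisibly `x`; stops with the offending field named otherwise.
#' @export
validate_characteristics <- function(x) {
  stopifnot(inherits(x, "data_characteristics"))
  for (f in DISTRIBUTION_FIELDS) {
    if (is.null(x[[f]]) || !is_empirical_distribution(x[[f]])) {
      stop("characteristics bundle missing distribution: ", f)
    }
  }
  chk <- function(field, test, what) {
    if (!all(test(x[[field]]$values))) {
      stop("invalid ", field, ": ", what)
    }
  }
  chk("umi_fragment_length", function(v) v >= 1, "fragment lengths must be >= 1")
  chk("internal_fragment_length", function(v) v >= 1,
      "fragment lengths must be >= 1")
  chk("reads_per_umi", function(v) v >= 1, "reads per UMI must be >= 1")
  chk("internal_to_umi_ratio", function(v) v >= 0, "ratios must be >= 0")
  chk("unspliced_fraction", function(v) v >= 0 & v <= 1,
      "unspliced fractions must lie in [0,1]")
  chk("umis_per_gene", function(v) v >= 0, "UMI counts must be >= 0")
  if (length(x$quality_by_position_read) == 0L) {
    stop("characteristics bundle missing distribution: quality_by_position_read")
  }
  for (d in x$quality_by_position_read) {
    if (!is_empirical_distribution(d)) {
      stop("quality_by_position_read entries must be empirical distributions")
    }
  }
  invisible(x)
}

#' @export
print.data_characteristics <- function(x, ...) {
  cat("data_characteristics bundle\n")
  for (f in DISTRIBUTION_FIELDS) {
    cat(sprintf("  %-25s mean %8.3f (%d support points)\n", f,
                distribution_mean(x[[f]]), length(x[[f]]$values)))
  }
  cat(sprintf("  read quality profile over %d positions\n",
              length(x$quality_by_position_read)))
  invisible(x)
}

dist_to_list <- function(d) list(values = d$values, weights = d$weights)
dist_from_list <- function(l) {
  empirical_distribution(as.numeric(l$values), as.numeric(l$weights))
}

#' Save a characteristics bundle to disk
#'
#' Writes a self-describing JSON document (values + weights per
#' distribution, schema-version field) that [load_characteristics()]
#' restores losslessly.
#'
#' @param chars A `data_characteristics`.
#' @param path Output path (conventionally `.json`).
#' @export
save_characteristics <- function(chars, path) {
  validate_characteristics(chars)
  doc <- list(schema_version = CHARACTERISTICS_SCHEMA_VERSION,
              metadata = chars$metadata)
  for (f in DISTRIBUTION_FIELDS) doc[[f]] <- dist_to_list(chars[[f]])
  doc$quality_by_position_read <-
    lapply(chars$quality_by_position_read, dist_to_list)
  doc$quality_by_position_barcode <-
    lapply(chars$quality_by_position_barcode, dist_to_list)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a characteristics bundle from disk
#'
#' @param path Path written by [save_characteristics()].
#' @return A validated `data_characteristics`.
#' @export
load_characteristics <- function(path) {
  if (!file.exists(path)) stop("characteristics file not found: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  ver <- doc$schema_version
  if (is.null(ver) || ver != CHARACTERISTICS_SCHEMA_VERSION) {
    stop("characteristics schema version mismatch: file has ",
         if (is.null(ver)) "none" else ver, ", expected ",
         CHARACTERISTICS_SCHEMA_VERSION)
  }
  for (f in DISTRIBUTION_FIELDS) {
    if (is.null(doc[[f]])) {
      stop("characteristics bundle missing distribution: ", f)
    }
  }
  data_characteristics(
    umi_fragment_length = dist_from_list(doc$umi_fragment_length),
    internal_fragment_length = dist_from_list(doc$internal_fragment_length),
    reads_per_umi = dist_from_list(doc$reads_per_umi),
    internal_to_umi_ratio = dist_from_list(doc$internal_to_umi_ratio),
    unspliced_fraction = dist_from_list(doc$unspliced_fraction),
    umis_per_gene = dist_from_list(doc$umis_per_gene),
    quality_by_position_read =
      lapply(doc$quality_by_position_read, dist_from_list),
    quality_by_position_barcode =
      lapply(doc$quality_by_position_barcode, dist_from_list),
    metadata = if (is.null(doc$metadata)) list() else doc$metadata)
}
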