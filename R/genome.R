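#' Read a chromosome-sizes table
#'
#' Reads a three-column tab-separated table describing the genome layout:
#' chromosome name, length in base pairs, and subgenome label (for hexaploid
#' wheat: `A`, `B`, or `D`). Every interval handled by the package is validated
#' against this layout. Gzipped files are read transparently.
#'
#' @param path Path to a `chrom<TAB>length<TAB>subgenome` file (no header).
#' @return A tibble with columns `chrom`, `length`, `subgenome`.
#' @export
read_chrom_sizes <- function(path) {
  layout <- readr::read_tsv(path,
    col_names = c("chrom", "length", "subgenome"),
    col_types = readr::cols(
      chrom = readr::col_character(),
      length = readr::col_double(),
      subgenome = readr::col_character()
    ),
    comment = "#", progress = FALSE
  )
  validate_layout(layout)
  layout
}

validate_layout <- function(layout) {
  stopifnot(all(c("chrom", "length") %in% names(layout)))
  if (anyDuplicated(layout$chrom)) {
    abort("chromosome names in the genome layout must be unique")
  }
  if (any(layout$length <= 0)) {
    abort("chromosome lengths must be positive")
  }
  invisible(layout)
}

#' Validate intervals against a genome layout
#'
#' Checks the package-wide coordinate invariant: zero-based half-open
#' intervals with `0 <= start < end <= chrom_length`, on declared chromosomes.
#'
#' @param x A tibble with `chrom`, `start`, `end` columns.
#' @param layout Genome layout tibble (see [read_chrom_sizes()]); optional.
#' @param what Label used in error messages.
#' @return `x`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_intervals <- function(x, layout = NULL, what = "intervals") {
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad)) {
    abort(sprintf(
      "%s: %d record(s) violate 0 <= start < end (first at row %d: [%s, %s))",
      what, length(bad), bad[1], x$start[bad[1]], x$end[bad[1]]
    ))
  }
  if (!is.null(layout)) {
    unknown <- setdiff(unique(x$chrom), layout$chrom)
    if (length(unknown)) {
      abort(sprintf("%s: undeclared chromosome(s): %s", what,
                    paste(unknown, collapse = ", ")))
    }
    len <- layout$length[match(x$chrom, layout$chrom)]
    over <- which(x$end > len)
    if (length(over)) {
      abort(sprintf("%s: %d record(s) extend past the chromosome end (first at row %d)",
                    what, length(over), over[1]))
    }
  }
  invisible(x)
}

# Tibble (0-based half-open) -> GRanges (1-based closed). Strand column "." or
# absent maps to "*". Internal plumbing for all overlap/nearest queries.
as_gr <- function(x, layout = NULL, use_strand = TRUE) {
  strand <- if (use_strand && "strand" %in% names(x)) {
    ifelse(x$strand %in% c("+", "-"), x$strand, "*")
  } else {
    "*"
  }
  sl <- if (!is.null(layout)) setNames(layout$length, layout$chrom) else NULL
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand,
    seqlengths = sl
  )
}

# Single-base positions (0-based) -> GRanges points.
points_gr <- function(chrom, pos, strand = NULL) {
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = pos + 1L, width = 1L),
    strand = strand %||% "*"
  )
}

#' Distance from intervals to the nearest gene
#'
#' Minimal edge-to-edge gap (bp) between each interval and any gene body on
#' the same chromosome, ignoring strand; 0 for overlapping or book-ended
#' features, `Inf` on chromosomes without genes. Both high- and low-confidence
#' genes count, so distal-element filters exclude anything near an annotated
#' gene of either class.
#'
#' @param x Tibble of intervals (`chrom`, `start`, `end`).
#' @param genes Gene-model tibble (see [read_gff3()]); only `chrom`, `start`,
#'   `end` are used.
#' @return `x` with a `distance_to_gene` column appended.
#' @export
nearest_gene_distance <- function(x, genes) {
  if (nrow(x) == 0) {
    return(mutate(x, distance_to_gene = double()))
  }
  d <- rep(Inf, nrow(x))
  if (nrow(genes) > 0) {
    q <- as_gr(x, use_strand = FALSE)
    s <- as_gr(genes[, c("chrom", "start", "end")], use_strand = FALSE)
    sl <- base::union(GenomeInfoDb::seqlevels(q), GenomeInfoDb::seqlevels(s))
    GenomeInfoDb::seqlevels(q) <- sl
    GenomeInfoDb::seqlevels(s) <- sl
    hits <- GenomicRanges::distanceToNearest(q, s, ignore.strand = TRUE)
    d[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  }
  mutate(x, distance_to_gene = d)
}

# Edge-to-edge gap between interval pairs given as parallel vectors
# (same chromosome assumed); 0 when overlapping.
interval_gap <- function(start1, end1, start2, end2) {
  pmax(0, pmax(start2 - end1, start1 - end2))
}

# Complement of a set of intervals within a layout, per chromosome.
interval_complement <- function(x, layout) {
  gr <- GenomicRanges::reduce(as_gr(x, layout, use_strand = FALSE))
  gaps <- GenomicRanges::gaps(gr)
  gaps <- gaps[BiocGenerics::strand(gaps) == "*"]
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gaps)),
    start = BiocGenerics::start(gaps) - 1,
    end = BiocGenerics::end(gaps)
  )
}
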