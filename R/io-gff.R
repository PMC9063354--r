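#' Read gene models from a GFF3 file
#'
#' Parses `gene`/`mRNA`/`exon` features (via rtracklayer) into a tidy
#' gene-model table. GFF3 1-based closed coordinates are converted to the
#' package-wide 0-based half-open convention on read. Exons may be attached to
#' an mRNA (with `Parent` resolving through it) or directly to the gene.
#'
#' @param path Path to a GFF3 file (gz transparent).
#' @param confidence_attr Name of the GFF3 attribute carrying the annotation
#'   confidence class (values `high`/`low`, as for IWGSC HC/LC gene sets). If
#'   absent, `default_confidence` is used.
#' @param default_confidence Confidence assigned when the attribute is missing.
#' @param layout Optional genome layout for coordinate validation.
#' @return A tibble with one row per gene: `gene_id`, `chrom`, `strand`,
#'   `start`, `end`, `confidence`, and `exons` (a list-column of
#'   `start`/`end` tibbles, sorted, 0-based half-open).
#' @export
read_gff3 <- function(path, confidence_attr = "confidence",
                      default_confidence = "high", layout = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  meta <- S4Vectors::mcols(gr)
  feats <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1,
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    type = as.character(meta$type),
    id = as.character(meta$ID),
    parent = vapply(meta$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
                    character(1))
  )
  if (confidence_attr %in% names(meta)) {
    feats$confidence <- as.character(meta[[confidence_attr]])
  } else {
    feats$confidence <- NA_character_
  }

  genes <- filter(feats, .data$type == "gene")
  if (nrow(genes) == 0) abort("no gene features found in GFF3 file")
  if (!all(genes$strand %in% c("+", "-"))) {
    abort("gene strand must be '+' or '-'")
  }
  mrna <- filter(feats, .data$type == "mRNA")
  exons <- filter(feats, .data$type == "exon")
  # Resolve exon parents through mRNA where needed.
  exons$gene_id <- ifelse(exons$parent %in% genes$id, exons$parent,
                          mrna$parent[match(exons$parent, mrna$id)])
  orphan <- is.na(exons$gene_id)
  if (any(orphan)) {
    abort(sprintf("%d exon(s) with unresolvable Parent in %s", sum(orphan), path))
  }

  exon_tbl <- exons |>
    select("gene_id", "start", "end") |>
    arrange(.data$gene_id, .data$start) |>
    tidyr::nest(exons = c("start", "end"))

  out <- genes |>
    transmute(
      gene_id = .data$id, chrom = .data$chrom, strand = .data$strand,
      start = .data$start, end = .data$end,
      confidence = ifelse(is.na(.data$confidence), default_confidence,
                          .data$confidence)
    ) |>
    left_join(exon_tbl, by = "gene_id")
  no_ex <- vapply(out$exons, is.null, logical(1))
  out$exons[no_ex] <- purrr::map2(out$start[no_ex], out$end[no_ex],
                                  ~ tibble(start = .x, end = .y))
  validate_gene_models(out, layout)
  out
}

validate_gene_models <- function(genes, layout = NULL) {
  validate_intervals(genes, layout, what = "gene models")
  purrr::pwalk(list(genes$gene_id, genes$start, genes$end, genes$exons),
    function(id, s, e, ex) {
      ex <- arrange(ex, .data$start)
      if (any(ex$start < s | ex$end > e)) {
        abort(sprintf("gene %s: exon outside gene span", id))
      }
      if (nrow(ex) > 1 && any(ex$start[-1] < ex$end[-nrow(ex)])) {
        abort(sprintf("gene %s: overlapping exons", id))
      }
    })
  invisible(genes)
}

#' Write gene models to GFF3
#'
#' Inverse of [read_gff3()]: emits `gene`, `mRNA` and `exon` features with the
#' confidence class as a `confidence` attribute, converting back to 1-based
#' closed coordinates. A read/write/read round trip is value-identical.
#'
#' @param genes Gene-model tibble as returned by [read_gff3()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  rows <- purrr::pmap(genes, function(gene_id, chrom, strand, start, end,
                                      confidence, exons, ...) {
    g <- sprintf("%s\ternascape\tgene\t%d\t%d\t.\t%s\t.\tID=%s;confidence=%s",
                 chrom, start + 1, end, strand, gene_id, confidence)
    m <- sprintf("%s\ternascape\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.1;Parent=%s",
                 chrom, start + 1, end, strand, gene_id, gene_id)
    ex <- sprintf("%s\ternascape\texon\t%d\t%d\t.\t%s\t.\tParent=%s.1",
                  chrom, exons$start + 1, exons$end, strand, gene_id)
    c(g, m, ex)
  })
  writeLines(c("##gff-version 3", unlist(rows)), path)
  invisible(path)
}

#' Read a homoeolog-group mapping
#'
#' Tab-separated table with header `group_id  gene_A  gene_B  gene_D` listing,
#' per 1:1:1 triad, the corresponding gene on each subgenome.
#'
#' @param path Path to the TSV.
#' @return A tibble with one row per triad.
#' @export
read_homoeolog_map <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE)
}

#' Read a gene expression table
#'
#' Two-column TSV (`gene_id`, `level`) of normalized expression values.
#'
#' @param path Path to the TSV (with header).
#' @return A tibble with columns `gene_id` and `level`.
#' @export
read_expression <- function(path) {
  x <- readr::read_tsv(path, col_types = "cd", progress = FALSE)
  names(x) <- c("gene_id", "level")
  if (any(x$level < 0)) abort("expression levels must be >= 0")
  x
}
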