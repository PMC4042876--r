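#' Read gene annotations from BED6 or GFF3
#'
#' Returns a gene table with the internal 0-based half-open convention:
#' BED intervals are kept as-is, GFF3 1-based closed intervals are converted.
#' On the plus strand the TSS is `start` and the TES `end - 1`; on the minus
#' strand the reverse. Strand is mandatory: every downstream window is
#' oriented.
#'
#' The gene category (used by the category exclusion filter) is read from
#' the GFF3 attribute named by `category_attr`; BED6 files carry no category
#' column and default to `"coding"`.
#'
#' @param path BED6 or GFF3 file.
#' @param format `"auto"` (by extension), `"bed"` or `"gff3"`.
#' @param category_attr GFF3 attribute holding the gene category.
#' @return Data frame with columns `gene_id`, `chrom`, `strand`, `start`,
#'   `end`, `category`.
#' @export
read_annotation <- function(path, format = "auto", category_attr = "category") {
  stopifnot(file.exists(path))
  if (format == "auto") {
    format <- if (grepl("\\.(gff3?|gff)$", tolower(path))) "gff3" else "bed"
  }
  gr <- rtracklayer::import(path, format = format)
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*")) {
    stop("annotation contains strandless features; strand is required")
  }
  mc <- S4Vectors::mcols(gr)
  ids <- if (format == "bed") {
    as.character(mc$name)
  } else if (!is.null(mc$ID)) as.character(mc$ID) else as.character(mc$Name)
  if (is.null(ids) || anyNA(ids)) stop("every feature needs an identifier")
  category <- rep("coding", length(gr))
  if (format == "gff3" && !is.null(mc[[category_attr]])) {
    cat_col <- as.character(mc[[category_attr]])
    category[!is.na(cat_col)] <- cat_col[!is.na(cat_col)]
  }
  data.frame(gene_id = ids,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             strand = strand,
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             category = category,
             stringsAsFactors = FALSE)
}

#' Write gene annotations as BED6
#'
#' The category is stored in the BED name field as `gene_id|category` when
#' `keep_category = TRUE`, so a round trip through [read_annotation()] with
#' `split_category = TRUE` recovers it.
#'
#' @param genes Gene table as returned by [read_annotation()].
#' @param path Output path.
#' @param keep_category Append the category to the name field.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(genes, path, keep_category = FALSE) {
  name <- if (keep_category) paste(genes$gene_id, genes$category, sep = "|")
          else genes$gene_id
  df <- data.frame(genes$chrom, as.integer(genes$start),
                   as.integer(genes$end), name, 0L, genes$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' TSS and TES boundary coordinates
#'
#' Boundary convention: the TSS boundary of a plus-strand gene is its
#' `start`, of a minus-strand gene its `end`; windows built from these
#' boundaries are half-open and strand-oriented (see [gene_window()]).
#'
#' @param genes Gene table.
#' @return Integer vector of boundary coordinates.
#' @export
tss_position <- function(genes) {
  ifelse(genes$strand == "+", genes$start, genes$end)
}

#' @rdname tss_position
#' @export
tes_position <- function(genes) {
  ifelse(genes$strand == "+", genes$end, genes$start)
}

oriented_coord <- function(genes, anchor = c("tss", "tes"), offset) {
  anchor <- match.arg(anchor)
  base <- if (anchor == "tss") tss_position(genes) else tes_position(genes)
  ifelse(genes$strand == "+", base + offset, base - offset)
}

#' Strand-oriented genomic windows around gene anchors
#'
#' Offsets are in oriented bp: positive is downstream (3'-ward along the
#' gene), negative upstream. The window runs from `(from_anchor, from)` to
#' `(to_anchor, to)` and is returned in genomic coordinates (0-based
#' half-open), so e.g. `gene_window(g, "tss", -500, "tss", 0)` is the
#' antisense promoter window and `gene_window(g, "tss", -1000, "tes", 2000)`
#' the extended whole-gene window.
#'
#' @param genes Gene table.
#' @param from_anchor,to_anchor `"tss"` or `"tes"`.
#' @param from,to Oriented offsets in bp.
#' @return Data frame `chrom`, `start`, `end`, `gene_id`, `strand`.
#' @export
gene_window <- function(genes, from_anchor, from, to_anchor, to) {
  a <- oriented_coord(genes, from_anchor, from)
  b <- oriented_coord(genes, to_anchor, to)
  data.frame(chrom = genes$chrom,
             start = pmin(a, b),
             end = pmax(a, b),
             gene_id = genes$gene_id,
             strand = genes$strand,
             stringsAsFactors = FALSE)
}

#' Named standard analysis windows
#'
#' Shorthand for the windows the pipeline uses throughout:
#' \describe{
#'   \item{gene}{whole gene, TSS-1000 to TES+2000 (gene-level selection)}
#'   \item{tss}{TSS +/- 500 (promoter-level selection)}
#'   \item{body}{TSS+1000 to TES-500}
#'   \item{tes3}{TES-500 to TES+1000}
#'   \item{corr}{TSS-1000 to TES+1000 (replicate correlation)}
#'   \item{promoter}{TSS-2000 to TSS+1000 (promoter-region test)}
#'   \item{as}{antisense window, TSS-500 to TSS}
#'   \item{s}{sense window, TSS to TSS+500}
#' }
#'
#' @param genes Gene table.
#' @param which One of the window names above.
#' @return As [gene_window()].
#' @export
standard_window <- function(genes,
                            which = c("gene", "tss", "body", "tes3", "corr",
                                      "promoter", "as", "s")) {
  which <- match.arg(which)
  switch(which,
         gene = gene_window(genes, "tss", -1000, "tes", 2000),
         tss = gene_window(genes, "tss", -500, "tss", 500),
         body = gene_window(genes, "tss", 1000, "tes", -500),
         tes3 = gene_window(genes, "tes", -500, "tes", 1000),
         corr = gene_window(genes, "tss", -1000, "tes", 1000),
         promoter = gene_window(genes, "tss", -2000, "tss", 1000),
         as = gene_window(genes, "tss", -500, "tss", 0),
         s = gene_window(genes, "tss", 0, "tss", 500))
}
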