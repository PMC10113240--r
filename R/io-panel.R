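#' Gene coordinate panel
#'
#' A data.frame with columns `gene`, `chrom`, `start`, `end` (1-based
#' inclusive), used to project segment-level copy numbers onto genes
#' ([project_to_genes()]) and to lay out the synthetic genome. Gene names
#' must be unique and `start <= end`.
#'
#' @param panel A data.frame with the four columns above.
#' @return The validated panel with class `gene_panel`.
#' @export
gene_panel <- function(panel) {
  req <- c("gene", "chrom", "start", "end")
  miss <- setdiff(req, names(panel))
  if (length(miss) > 0)
    stop("gene panel is missing column(s): ", paste(miss, collapse = ", "))
  panel <- as.data.frame(panel)[req]
  panel$gene <- as.character(panel$gene)
  panel$chrom <- as.character(panel$chrom)
  if (anyDuplicated(panel$gene))
    stop("gene panel has duplicated gene name(s): ",
         paste(unique(panel$gene[duplicated(panel$gene)]), collapse = ", "))
  if (any(panel$start > panel$end)) stop("gene panel has start > end")
  rownames(panel) <- NULL
  class(panel) <- c("gene_panel", "data.frame")
  panel
}

#' Read a gene panel from a BED file
#'
#' BED is 0-based half-open on disk with the gene symbol in the name
#' (fourth) column; coordinates are converted to the panel's 1-based
#' inclusive convention.
#'
#' @param path Path to the BED file.
#' @return A [gene_panel()].
#' @export
read_gene_panel <- function(path) {
  gr <- as.data.frame(rtracklayer::import(path, format = "BED"))
  if (is.null(gr$name) || anyNA(gr$name))
    stop("BED gene panel requires a name column with gene symbols")
  # GRanges coordinates are already 1-based inclusive after import
  gene_panel(data.frame(
    gene = gr$name, chrom = as.character(gr$seqnames),
    start = gr$start, end = gr$end, stringsAsFactors = FALSE))
}

#' Write a gene panel to a BED file
#'
#' @param panel A [gene_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_panel <- function(panel, path) {
  panel <- gene_panel(panel)
  bed <- data.frame(chrom = panel$chrom, start = panel$start - 1L,
                    end = panel$end, name = panel$gene)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
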