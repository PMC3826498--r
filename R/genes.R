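#' Construct a gene-model collection
#'
#' Holds a gene table and an exon table in 0-based half-open coordinates.
#' The TSS is derived from the strand: span start for \code{+} genes, span
#' end minus one for \code{-} genes, unless given explicitly.
#'
#' @param genes data frame with columns \code{gene_id}, \code{chrom},
#'   \code{strand} (\code{+}/\code{-}), \code{start}, \code{end}; optional
#'   \code{symbol}, \code{gene_type} (default \code{protein_coding}),
#'   \code{tss}, \code{tags} (list column of character tags among
#'   \code{TF}, \code{developmental}, \code{diff_expressed}) and
#'   \code{description}.
#' @param exons data frame with columns \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end} and logical \code{is_coding}.
#' @return an object of class \code{gene_models}.
#' @export
gene_models <- function(genes, exons = NULL) {
  stopifnot(all(c("gene_id", "chrom", "strand", "start", "end") %in%
                  names(genes)))
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be + or -")
  if (is.null(genes$symbol)) genes$symbol <- genes$gene_id
  if (is.null(genes$gene_type))
    genes$gene_type <- rep("protein_coding", nrow(genes))
  if (is.null(genes$tss))
    genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  if (any(genes$tss < genes$start | genes$tss >= genes$end))
    stop("tss outside gene span")
  if (is.null(genes$tags))
    genes$tags <- replicate(nrow(genes), character(), simplify = FALSE)
  if (is.null(exons))
    exons <- data.frame(gene_id = character(), chrom = character(),
                        start = integer(), end = integer(),
                        is_coding = logical())
  stopifnot(all(c("gene_id", "chrom", "start", "end", "is_coding") %in%
                  names(exons)))
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d gene(s), %d exon(s) (%d coding)\n",
              nrow(x$genes), nrow(x$exons), sum(x$exons$is_coding)))
  invisible(x)
}

#' Read gene models from GTF/GFF
#'
#' Uses \pkg{rtracklayer} for parsing; 1-based GTF coordinates are
#' converted to the package's 0-based half-open convention.  An exon is
#' flagged coding when a CDS record of the same transcript overlaps it.
#' Gene type comes from the \code{gene_type} (or \code{gene_biotype})
#' attribute.
#'
#' @param path GTF/GFF file.
#' @return a \code{gene_models} object.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path)
  mc <- GenomicRanges::mcols(gr)
  gtype <- if ("gene_type" %in% names(mc)) mc$gene_type
           else if ("gene_biotype" %in% names(mc)) mc$gene_biotype
           else rep("protein_coding", length(gr))
  typ <- as.character(mc$type)
  gi <- typ == "gene"
  genes <- data.frame(
    gene_id = as.character(mc$gene_id[gi]),
    symbol = if ("gene_name" %in% names(mc))
      as.character(mc$gene_name[gi]) else as.character(mc$gene_id[gi]),
    chrom = as.character(GenomicRanges::seqnames(gr)[gi]),
    strand = as.character(GenomicRanges::strand(gr)[gi]),
    start = GenomicRanges::start(gr)[gi] - 1L,
    end = GenomicRanges::end(gr)[gi],
    gene_type = as.character(gtype[gi]),
    stringsAsFactors = FALSE)
  genes$symbol[is.na(genes$symbol)] <- genes$gene_id[is.na(genes$symbol)]
  ei <- typ == "exon"
  exons <- data.frame(
    gene_id = as.character(mc$gene_id[ei]),
    chrom = as.character(GenomicRanges::seqnames(gr)[ei]),
    start = GenomicRanges::start(gr)[ei] - 1L,
    end = GenomicRanges::end(gr)[ei],
    stringsAsFactors = FALSE)
  cds <- which(typ == "CDS")
  if (length(cds) && any(ei)) {
    ov <- GenomicRanges::findOverlaps(gr[ei], gr[cds])
    same_gene <- mc$gene_id[ei][S4Vectors::queryHits(ov)] ==
      mc$gene_id[cds][S4Vectors::subjectHits(ov)]
    exons$is_coding <- seq_len(nrow(exons)) %in%
      unique(S4Vectors::queryHits(ov)[same_gene])
  } else {
    exons$is_coding <- rep(FALSE, nrow(exons))
  }
  gene_models(genes, exons)
}

#' TSS index of a gene-model collection
#'
#' @param genes a \code{gene_models} object.
#' @return data frame with columns \code{chrom}, \code{pos} (0-based) and
#'   \code{gene_id}, suitable for \code{\link{tss_distance}}.
#' @export
tss_index <- function(genes) {
  data.frame(chrom = genes$genes$chrom, pos = genes$genes$tss,
             gene_id = genes$genes$gene_id, stringsAsFactors = FALSE)
}

#' Tag genes whose description matches a keyword list
#'
#' Emulates keyword mining of gene descriptions (e.g. for embryonic and
#' fetal development terms) to produce a tag column used by proximity
#' counts and candidate scoring.
#'
#' @param genes a \code{gene_models} object with a \code{description}
#'   column in its gene table.
#' @param keywords character vector of (case-insensitive) keywords.
#' @param tag tag to add, one of \code{"TF"}, \code{"developmental"},
#'   \code{"diff_expressed"}.
#' @return the updated \code{gene_models}.
#' @export
tag_genes_by_keywords <- function(genes, keywords,
                                  tag = c("developmental", "TF",
                                          "diff_expressed")) {
  tag <- match.arg(tag)
  desc <- genes$genes$description
  if (is.null(desc)) stop("gene table has no description column")
  pat <- paste(keywords, collapse = "|")
  hit <- grepl(pat, desc, ignore.case = TRUE)
  genes$genes$tags[hit] <- lapply(genes$genes$tags[hit],
                                  function(t) unique(c(t, tag)))
  genes
}

#' Tag genes from an id list
#'
#' @param genes a \code{gene_models} object.
#' @param gene_ids ids to tag.
#' @param tag tag label.
#' @return the updated \code{gene_models}.
#' @export
tag_genes <- function(genes, gene_ids, tag) {
  hit <- genes$genes$gene_id %in% gene_ids
  genes$genes$tags[hit] <- lapply(genes$genes$tags[hit],
                                  function(t) unique(c(t, tag)))
  genes
}

has_tag <- function(genes, tag) {
  vapply(genes$genes$tags, function(t) tag %in% t, TRUE)
}
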