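# GRanges for monomer loci; contacts coordinates are 0-based half-open
loci_granges <- function(ann) {
  GRanges(ann$chrom, IRanges(ann$start + 1, ann$end))
}

flanked_granges <- function(ann) {
  GRanges(ann$chrom, IRanges(ann$flank_start + 1, ann$flank_end))
}

#' Annotate multi-way contact loci with multi-omic evidence
#'
#' Each monomer locus is extended by `flank` bp on both sides (clipped to
#' the chromosome when sizes are supplied) and queried for overlap
#' (>= 1 bp, strand-ignorant) with accessibility and RNA Pol II peak sets,
#' for overlapping gene bodies, and optionally for further peak sets
#' (CTCF, cohesin subunits, enhancers). A gene is "expressed" when its
#' expression value is at or above `expr_threshold`; genes absent from the
#' expression table are treated as unexpressed (reported once).
#'
#' @param contacts A `contacts` data frame ([read_contacts()]).
#' @param atac Accessibility peak `GRanges` (ATAC/DNase).
#' @param polii RNA Pol II peak `GRanges`.
#' @param genes Gene annotation `GRanges` with `gene_id` metadata column.
#' @param expression Named numeric vector gene id -> expression value.
#' @param flank Flanking distance in bp (default 5000).
#' @param expr_threshold Expression call threshold (default 1, TPM scale).
#' @param chrom_sizes Optional named chromosome lengths for clipping.
#' @param extra_peaks Named list of additional peak `GRanges`; each
#'   contributes a logical overlap column named after the list element.
#' @return An `annotated_contacts` data frame, one row per monomer, with
#'   flags `accessible` and `polii`, list-columns `genes` and
#'   `expressed_genes`, and one flag column per extra peak set.
#' @export
annotate_loci <- function(contacts, atac, polii, genes, expression,
                          flank = 5000, expr_threshold = 1,
                          chrom_sizes = NULL, extra_peaks = list()) {
  stopifnot(flank >= 0)
  ann <- as.data.frame(contacts)
  ann$flank_start <- pmax(0, ann$start - flank)
  ann$flank_end <- ann$end + flank
  if (!is.null(chrom_sizes)) {
    maxlen <- chrom_sizes[ann$chrom]
    ann$flank_end <- pmin(ann$flank_end, ifelse(is.na(maxlen), ann$flank_end,
                                                maxlen))
  }
  fl <- flanked_granges(ann)
  ann$accessible <- IRanges::overlapsAny(fl, atac, ignore.strand = TRUE)
  ann$polii <- IRanges::overlapsAny(fl, polii, ignore.strand = TRUE)
  hits <- findOverlaps(fl, genes, ignore.strand = TRUE)
  gene_ids <- mcols(genes)$gene_id
  per_locus <- rep(list(character(0)), nrow(ann))
  if (length(hits) > 0) {
    sp <- split(gene_ids[subjectHits(hits)], queryHits(hits))
    per_locus[as.integer(names(sp))] <- lapply(sp, unique)
  }
  missing <- setdiff(unique(unlist(per_locus)), names(expression))
  if (length(missing) > 0)
    message(length(missing),
            " gene(s) absent from the expression table, treated as unexpressed")
  expressed <- names(expression)[expression >= expr_threshold]
  ann$genes <- I(per_locus)
  ann$expressed_genes <- I(lapply(per_locus, intersect, y = expressed))
  for (nm in names(extra_peaks))
    ann[[nm]] <- IRanges::overlapsAny(fl, extra_peaks[[nm]],
                                      ignore.strand = TRUE)
  attr(ann, "flank") <- flank
  attr(ann, "expr_threshold") <- expr_threshold
  attr(ann, "extra_peaks") <- names(extra_peaks)
  class(ann) <- c("annotated_contacts", "data.frame")
  ann
}

# one row per read: order (distinct loci), accessibility/Pol II flags and
# gene unions across the read's loci
read_table <- function(ann) {
  f <- factor(ann$read_id, levels = unique(ann$read_id))
  locus_key <- paste(ann$chrom, ann$start, ann$end)
  order_ <- as.integer(tapply(locus_key, f, function(x) length(unique(x))))
  out <- data.frame(read_id = levels(f),
                    order = order_,
                    all_accessible = as.logical(tapply(ann$accessible, f, all)),
                    any_polii = as.logical(tapply(ann$polii, f, any)),
                    stringsAsFactors = FALSE)
  flat <- function(g) {
    u <- unique(unlist(g))
    if (is.null(u)) character(0) else u
  }
  out$genes <- I(lapply(split(ann$genes, f), flat))
  out$expressed_genes <- I(lapply(split(ann$expressed_genes, f), flat))
  for (nm in attr(ann, "extra_peaks"))
    out[[nm]] <- as.logical(tapply(ann[[nm]], f, any))
  rownames(out) <- NULL
  out
}
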