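#' Read a multi-way contact table
#'
#' Reads the tab-separated interchange format for aligned Pore-C monomers:
#' one row per aligned fragment with columns `read_id`, `chrom`, `start`,
#' `end` (0-based half-open). Rows belonging to one read need not be
#' adjacent; they are grouped by `read_id` with the original within-read
#' order preserved. Reads with a single monomer (order 1) are kept.
#'
#' @param path Path to the contact TSV (with header).
#' @return A `contacts` data frame with columns `read_id`, `chrom`,
#'   `start`, `end`, ordered by first appearance of each read.
#' @export
read_contacts <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t",
                   colClasses = "character", comment.char = "#",
                   check.names = FALSE)
  required <- c("read_id", "chrom", "start", "end")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("contact table is missing column(s): ",
         paste(missing, collapse = ", "))
  start <- suppressWarnings(as.numeric(df$start))
  end <- suppressWarnings(as.numeric(df$end))
  # +1 for the header when reporting line numbers
  bad <- which(is.na(start) | is.na(end) |
                 start != floor(start) | end != floor(end))
  if (length(bad) > 0)
    stop("non-integer coordinates at line ", bad[1] + 1L, " of ", path)
  bad <- which(start < 0 | start >= end)
  if (length(bad) > 0)
    stop("invalid interval (need 0 <= start < end) at line ", bad[1] + 1L,
         " of ", path)
  out <- data.frame(read_id = df$read_id, chrom = df$chrom,
                    start = start, end = end, stringsAsFactors = FALSE)
  as_contacts(out)
}

#' @rdname read_contacts
#' @param x A data frame with columns `read_id`, `chrom`, `start`, `end`.
#' @export
as_contacts <- function(x) {
  stopifnot(all(c("read_id", "chrom", "start", "end") %in% names(x)))
  # group rows by read, preserving first-appearance order of reads and
  # input order within a read
  ord <- order(match(x$read_id, unique(x$read_id)))
  x <- x[ord, c("read_id", "chrom", "start", "end"), drop = FALSE]
  rownames(x) <- NULL
  class(x) <- c("contacts", "data.frame")
  x
}

#' @rdname read_contacts
#' @param contacts A `contacts` data frame.
#' @export
write_contacts <- function(contacts, path) {
  write.table(contacts, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Number of monomers per read
#'
#' @param contacts A `contacts` data frame.
#' @return Named integer vector: read id -> number of monomer rows.
#' @export
contact_orders <- function(contacts) {
  tab <- table(factor(contacts$read_id, levels = unique(contacts$read_id)))
  setNames(as.integer(tab), names(tab))
}

#' Read a BED interval file
#'
#' Accepts BED3 and BED6 (name/score/strand retained when present);
#' `track` and `#` comment lines are ignored. BED coordinates are 0-based
#' half-open; the returned `GRanges` uses the Bioconductor 1-based closed
#' convention (start + 1).
#'
#' @param path Path to a BED file.
#' @return A `GRanges`; empty input yields an empty `GRanges`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) == 0) return(GRanges())
  fields <- strsplit(lines, "\t")
  nf <- lengths(fields)
  if (any(nf < 3)) stop("BED line with fewer than 3 fields in ", path)
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- as.numeric(vapply(fields, `[[`, "", 2L))
  end <- as.numeric(vapply(fields, `[[`, "", 3L))
  if (any(is.na(start) | is.na(end))) stop("non-numeric BED coordinates in ", path)
  if (any(start < 0)) stop("negative BED coordinates in ", path)
  if (any(start >= end)) stop("BED interval with start >= end in ", path)
  name <- ifelse(nf >= 4, vapply(fields, function(f) f[min(4L, length(f))], ""), NA)
  score <- ifelse(nf >= 5, vapply(fields, function(f) f[min(5L, length(f))], ""), NA)
  strand <- ifelse(nf >= 6, vapply(fields, function(f) f[min(6L, length(f))], ""), "*")
  strand[!strand %in% c("+", "-", "*")] <- "*"
  gr <- GRanges(chrom, IRanges(start + 1, end), strand = strand)
  mcols(gr)$name <- as.character(name)
  mcols(gr)$score <- suppressWarnings(as.numeric(score))
  gr
}

#' @rdname read_bed
#' @param gr A `GRanges` to serialize (BED6 when name/strand present).
#' @export
write_bed <- function(gr, path) {
  if (length(gr) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  name <- if (!is.null(mcols(gr)$name)) mcols(gr)$name else rep(".", length(gr))
  name[is.na(name)] <- "."
  score <- if (!is.null(mcols(gr)$score)) mcols(gr)$score else rep(0, length(gr))
  score[is.na(score)] <- 0
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1, end = end(gr),
                   name = name, score = score,
                   strand = as.character(strand(gr)))
  df$strand[df$strand == "*"] <- "."
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene annotation (BED6 with name = gene id)
#'
#' The TSS is derivable from strand: interval start on `+`, end on `-`.
#'
#' @param path Path to a BED6 file whose name column holds gene ids.
#' @return `GRanges` with a `gene_id` metadata column.
#' @export
read_gene_annotation <- function(path) {
  gr <- read_bed(path)
  if (length(gr) > 0 && (is.null(mcols(gr)$name) || anyNA(mcols(gr)$name)))
    stop("gene annotation requires a name column carrying gene ids")
  mcols(gr)$gene_id <- mcols(gr)$name
  if (anyDuplicated(mcols(gr)$gene_id))
    stop("duplicate gene ids in ", path)
  gr
}

#' Read chromosome sizes
#'
#' @param path Two-column TSV (chrom, length in bp), no header.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- read.delim(path, header = FALSE, sep = "\t", comment.char = "#")
  sizes <- as.numeric(df[[2]])
  if (any(is.na(sizes) | sizes <= 0)) stop("invalid chromosome length in ", path)
  setNames(sizes, as.character(df[[1]]))
}

#' @rdname read_chrom_sizes
#' @param sizes Named numeric vector of chromosome lengths.
#' @export
write_chrom_sizes <- function(sizes, path) {
  write.table(data.frame(names(sizes), format(sizes, scientific = FALSE, trim = TRUE)),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read an expression table
#'
#' @param path Two-column TSV with header (`gene_id`, `value`); values are
#'   non-negative on an arbitrary scale (e.g. TPM).
#' @return Named numeric vector gene id -> expression value.
#' @export
read_expression <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#")
  if (ncol(df) < 2) stop("expression table needs two columns")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate gene ids in expression table ", path)
  vals <- as.numeric(df[[2]])
  if (any(is.na(vals) | vals < 0)) stop("expression values must be >= 0")
  setNames(vals, ids)
}

#' @rdname read_expression
#' @param expression Named numeric vector.
#' @export
write_expression <- function(expression, path) {
  write.table(data.frame(gene_id = names(expression), value = expression),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a transcription-factor motif count table
#'
#' Rows are genes, columns are TFs, entries are counts of binding sites
#' for that TF within the promoter-proximal window of the gene (as emitted
#' by an external motif scanner). Absent pairs count as 0.
#'
#' @param path TSV with header; first column gene ids, remaining columns TFs.
#' @return Integer matrix with gene rownames and TF colnames.
#' @export
read_motif_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   check.names = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate gene rows in motif table ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (any(is.na(m) | m < 0 | m != floor(m)))
    stop("motif counts must be non-negative integers")
  rownames(m) <- ids
  m
}

#' @rdname read_motif_table
#' @param motif Motif count matrix (genes x TFs).
#' @export
write_motif_table <- function(motif, path) {
  df <- data.frame(gene_id = rownames(motif), motif, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Motif count lookup with absent-pair = 0 semantics
#'
#' @param motif Motif count matrix from [read_motif_table()].
#' @param gene,tf Character vectors (recycled) of gene and TF ids.
#' @return Numeric vector of counts, 0 for pairs absent from the table.
#' @export
motif_count <- function(motif, gene, tf) {
  n <- max(length(gene), length(tf))
  gene <- rep_len(gene, n); tf <- rep_len(tf, n)
  ri <- match(gene, rownames(motif)); ci <- match(tf, colnames(motif))
  out <- numeric(n)
  ok <- !is.na(ri) & !is.na(ci)
  out[ok] <- motif[cbind(ri[ok], ci[ok])]
  out
}

#' Read / write the TF -> encoding-gene sidecar map
#'
#' @param path Two-column TSV with header (`tf`, `gene_id`). A TF may be
#'   absent from the map (its encoding gene is unknown).
#' @return Named character vector TF -> gene id.
#' @export
read_tf_gene_map <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#")
  if (ncol(df) < 2) stop("TF-gene map needs two columns")
  setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' @rdname read_tf_gene_map
#' @param map Named character vector TF -> gene id.
#' @export
write_tf_gene_map <- function(map, path) {
  write.table(data.frame(tf = names(map), gene_id = map),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a hypergraph incidence structure
#'
#' The incidence is serialized as three TSVs sharing a path prefix:
#' `<prefix>.triplets.tsv` (node_id, hyperedge_id, 1),
#' `<prefix>.nodes.tsv` (node dictionary: node_id, chrom, bin_index) and
#' `<prefix>.edges.tsv` (hyperedge dictionary: hyperedge_id, weight).
#' The round trip is lossless for the hypergraph structure.
#'
#' @param hg A [hypergraph] object.
#' @param prefix Path prefix for the three files.
#' @export
write_incidence <- function(hg, prefix) {
  stopifnot(inherits(hg, "hypergraph"))
  nodes <- data.frame(node_id = seq_len(nrow(hg$nodes)) - 1L,
                      chrom = hg$nodes$chrom, bin_index = hg$nodes$bin_index)
  edges <- data.frame(hyperedge_id = seq_along(hg$edges) - 1L,
                      weight = hg$weights)
  trip <- if (length(hg$edges) > 0) {
    data.frame(node_id = unlist(hg$edges) - 1L,
               hyperedge_id = rep(seq_along(hg$edges) - 1L, lengths(hg$edges)),
               value = 1L)
  } else data.frame(node_id = integer(0), hyperedge_id = integer(0),
                    value = integer(0))
  hdr <- sprintf("# resolution=%s", as.character(hg$resolution))
  for (x in list(list(trip, ".triplets.tsv"), list(nodes, ".nodes.tsv"),
                 list(edges, ".edges.tsv"))) {
    p <- paste0(prefix, x[[2]])
    writeLines(hdr, p)
    suppressWarnings(write.table(x[[1]], p, sep = "\t", quote = FALSE,
                                 row.names = FALSE, append = TRUE))
  }
  if (!is.null(hg$chrom_sizes))
    write_chrom_sizes(hg$chrom_sizes, paste0(prefix, ".chrom_sizes.tsv"))
  invisible(prefix)
}

#' @rdname write_incidence
#' @export
read_incidence <- function(prefix) {
  res_line <- readLines(paste0(prefix, ".nodes.tsv"), n = 1)
  resolution <- sub("^# resolution=", "", res_line)
  if (resolution != "read") resolution <- as.numeric(resolution)
  nodes <- read.delim(paste0(prefix, ".nodes.tsv"), comment.char = "#")
  edges_df <- read.delim(paste0(prefix, ".edges.tsv"), comment.char = "#")
  trip <- read.delim(paste0(prefix, ".triplets.tsv"), comment.char = "#")
  edges <- rep(list(integer(0)), nrow(edges_df))
  if (nrow(trip) > 0) {
    sp <- split(trip$node_id + 1L, factor(trip$hyperedge_id,
                                          levels = edges_df$hyperedge_id))
    edges[] <- lapply(sp, function(v) sort(as.integer(v)))
  }
  sizes_path <- paste0(prefix, ".chrom_sizes.tsv")
  sizes <- if (file.exists(sizes_path)) read_chrom_sizes(sizes_path) else NULL
  new_hypergraph(data.frame(chrom = as.character(nodes$chrom),
                            bin_index = nodes$bin_index),
                 edges, as.numeric(edges_df$weight), resolution, sizes)
}

#' Write / read a labelled dense matrix as TSV
#'
#' @param m Matrix with row and column names.
#' @param path Output path.
#' @export
write_matrix <- function(m, path) {
  m <- as.matrix(m)
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, comment.char = "#")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  m
}
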