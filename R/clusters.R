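# TFs binding (>= min_sites) a strict majority of `genes` (both, when
# exactly two genes are present)
common_tfs_for_genes <- function(genes, motif, min_sites = 3) {
  n <- length(genes)
  if (n < 2) return(character(0))
  binds <- vapply(colnames(motif), function(tf)
    sum(motif_count(motif, genes, tf) >= min_sites), 0)
  need <- if (n == 2) 2 else n / 2       # strict majority when n >= 3
  tfs <- if (n == 2) names(binds)[binds >= 2] else names(binds)[binds > need]
  sort(tfs)
}

#' Master regulators of a motif table
#'
#' A TF is a master regulator (MR) when its binding motif occurs at least
#' `min_sites` times at its own encoding gene. TFs without a mapped
#' encoding gene cannot be MRs.
#'
#' @param motif Motif count matrix (genes x TFs).
#' @param tf_gene_map Named character vector TF -> encoding gene id.
#' @param min_sites Binding-site count threshold (default 3).
#' @return Character vector of MR TF names.
#' @export
master_regulators <- function(motif, tf_gene_map, min_sites = 3) {
  tfs <- intersect(colnames(motif), names(tf_gene_map))
  tfs[motif_count(motif, tf_gene_map[tfs], tfs) >= min_sites]
}

#' Identify potential transcription clusters
#'
#' A multi-way contact is a potential transcription cluster when every one
#' of its (flanked) loci is accessible and at least one locus binds RNA
#' Pol II; only contacts of order >= 2 qualify.
#'
#' @param ann An `annotated_contacts` data frame ([annotate_loci()]).
#' @return A cluster table (one row per retained read) with
#'   `status = "potential"`, order, and gene list-columns.
#' @export
find_potential_clusters <- function(ann) {
  tbl <- read_table(ann)
  tbl <- tbl[tbl$order >= 2 & tbl$all_accessible & tbl$any_polii, ,
             drop = FALSE]
  tbl$status <- rep("potential", nrow(tbl))
  rownames(tbl) <- NULL
  tbl
}

#' Promote potential clusters to transcription clusters
#'
#' A potential cluster becomes a transcription cluster when it contains at
#' least two expressed genes and those genes share transcription factors:
#' with exactly two expressed genes a common TF must bind both; with three
#' or more it must bind a strict majority. "Binds" means >= `min_sites`
#' motif occurrences at the gene.
#'
#' @param potential Cluster table from [find_potential_clusters()].
#' @param motif Motif count matrix (genes x TFs).
#' @param min_sites Binding-site threshold (default 3).
#' @return The qualifying subset with `status = "cluster"` and a
#'   `common_tfs` list-column.
#' @export
find_clusters <- function(potential, motif, min_sites = 3) {
  ctf <- lapply(potential$expressed_genes, common_tfs_for_genes,
                motif = motif, min_sites = min_sites)
  keep <- lengths(potential$expressed_genes) >= 2 & lengths(ctf) >= 1
  out <- potential[keep, , drop = FALSE]
  out$common_tfs <- I(ctf[keep])
  out$status <- rep("cluster", nrow(out))
  rownames(out) <- NULL
  out
}

#' Specialized transcription clusters
#'
#' A transcription cluster is specialized when at least one of its common
#' TFs is a master regulator (binds its own encoding gene).
#'
#' @param clusters Cluster table from [find_clusters()].
#' @inheritParams master_regulators
#' @return The qualifying subset with `status = "specialized"` and a
#'   `common_mrs` list-column.
#' @export
find_specialized <- function(clusters, motif, tf_gene_map, min_sites = 3) {
  mrs <- master_regulators(motif, tf_gene_map, min_sites)
  unmapped <- setdiff(unique(unlist(clusters$common_tfs)), names(tf_gene_map))
  if (length(unmapped) > 0)
    message(length(unmapped),
            " common TF(s) without a mapped encoding gene cannot be master regulators")
  cm <- lapply(clusters$common_tfs, intersect, y = mrs)
  keep <- lengths(cm) >= 1
  out <- clusters[keep, , drop = FALSE]
  out$common_mrs <- I(cm[keep])
  out$status <- rep("specialized", nrow(out))
  rownames(out) <- NULL
  out
}

#' Self-sustaining and core transcription clusters
#'
#' A cluster is self-sustaining when it contains an expressed TF-encoding
#' gene whose TF also has a binding motif (>= `min_sites` sites) at a gene
#' of the same cluster — the cluster transcribes a factor that can act at
#' the cluster itself. It is additionally "core" when such a TF is a
#' master regulator. Two side classes are reported as attributes:
#' `analog_independent` lists (tf, expressed_in, binds_in) triples where a
#' TF-encoding gene is expressed in one cluster while its motif occurs
#' only at other clusters, and `unclustered_tf_genes` tallies expressed
#' TF-encoding genes found in no cluster (requires `expression`).
#'
#' @param clusters Cluster table (from [find_clusters()] or later tiers).
#' @inheritParams master_regulators
#' @param expression Optional named expression vector for the genome-wide
#'   tally of expressed TF genes outside clusters.
#' @param expr_threshold Expression call threshold (default 1).
#' @return `clusters` with logical columns `self_sustaining`, `core` and a
#'   `self_tfs` list-column, plus the attributes described above.
#' @export
find_self_sustaining <- function(clusters, motif, tf_gene_map,
                                 min_sites = 3, expression = NULL,
                                 expr_threshold = 1) {
  mrs <- master_regulators(motif, tf_gene_map, min_sites)
  gene_of <- tf_gene_map
  self_tfs <- vector("list", nrow(clusters))
  expressed_tfs <- vector("list", nrow(clusters))
  binds_in_cluster <- function(tf, genes)
    any(motif_count(motif, genes, tf) >= min_sites)
  for (i in seq_len(nrow(clusters))) {
    eg <- clusters$expressed_genes[[i]]
    tfs_here <- names(gene_of)[gene_of %in% eg]
    expressed_tfs[[i]] <- tfs_here
    self_tfs[[i]] <- Filter(function(tf)
      binds_in_cluster(tf, clusters$genes[[i]]), tfs_here)
  }
  clusters$self_tfs <- I(self_tfs)
  clusters$self_sustaining <- lengths(self_tfs) > 0
  clusters$core <- vapply(self_tfs, function(x) any(x %in% mrs), TRUE)
  # class (c): TF-gene expressed in one cluster, motif only at others
  pairs <- list()
  for (i in seq_len(nrow(clusters))) {
    away <- setdiff(expressed_tfs[[i]], self_tfs[[i]])
    for (tf in away) {
      elsewhere <- which(vapply(seq_len(nrow(clusters)), function(j)
        j != i && binds_in_cluster(tf, clusters$genes[[j]]), TRUE))
      for (j in elsewhere)
        pairs[[length(pairs) + 1]] <- data.frame(
          tf = tf, expressed_in = clusters$read_id[i],
          binds_in = clusters$read_id[j])
    }
  }
  attr(clusters, "analog_independent") <-
    if (length(pairs) > 0) do.call(rbind, pairs)
    else data.frame(tf = character(0), expressed_in = character(0),
                    binds_in = character(0))
  if (!is.null(expression)) {
    expr_genes <- names(expression)[expression >= expr_threshold]
    tf_genes_expr <- intersect(unname(gene_of), expr_genes)
    in_clusters <- unique(unlist(clusters$expressed_genes))
    attr(clusters, "unclustered_tf_genes") <-
      setdiff(tf_genes_expr, in_clusters)
  }
  clusters
}

#' Rank transcription factors by binding frequency across clusters
#'
#' For each TF, the fraction of clusters in which it binds (>= `min_sites`
#' motif sites) at least one of the cluster's expressed genes; sorted
#' descending with ties broken by TF name.
#'
#' @param clusters Cluster table with an `expressed_genes` list-column.
#' @param motif Motif count matrix.
#' @param min_sites Binding-site threshold (default 3).
#' @return Data frame with columns `tf`, `frequency`.
#' @export
rank_tfs <- function(clusters, motif, min_sites = 3) {
  stopifnot(nrow(clusters) >= 1)
  freq <- vapply(colnames(motif), function(tf)
    mean(vapply(clusters$expressed_genes, function(g)
      length(g) > 0 && any(motif_count(motif, g, tf) >= min_sites), TRUE)),
    0)
  out <- data.frame(tf = colnames(motif), frequency = as.numeric(freq))
  out <- out[order(-out$frequency, out$tf), ]
  rownames(out) <- NULL
  out
}

#' Top-k overlap between two TF rankings
#'
#' @param rank_a,rank_b Outputs of [rank_tfs()].
#' @param k Ranking depth (default 10).
#' @return Fraction in [0, 1] of shared TFs among the top k.
#' @export
tf_overlap <- function(rank_a, rank_b, k = 10) {
  length(intersect(head(rank_a$tf, k), head(rank_b$tf, k))) / k
}
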