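#' Peak-binding enrichment of transcription clusters
#'
#' Compares the fraction of clusters with at least one flanked locus
#' overlapping a peak set (e.g. CTCF, RAD21, SMC3, enhancers) against the
#' same statistic on size-matched random samples of multi-way contacts,
#' drawn `N` times from all contacts. The one-sided p-value is the
#' proportion of background fractions at or above the observed fraction.
#'
#' @param clusters Cluster table (rows identify reads via `read_id`).
#' @param ann `annotated_contacts` for the full contact set.
#' @param peaks Peak `GRanges` for the factor being tested.
#' @param N Number of background samples (default 1000).
#' @param seed Optional integer seed.
#' @param factor_name Label carried into the result.
#' @return An `enrichment_result`: list with `factor`, `observed`,
#'   `background_mean`, `p_value`, `N`.
#' @export
binding_enrichment <- function(clusters, ann, peaks, N = 1000, seed = NULL,
                               factor_name = "factor") {
  if (nrow(clusters) == 0) stop("no clusters to test")
  fl <- flanked_granges(ann)
  hit <- IRanges::overlapsAny(fl, peaks, ignore.strand = TRUE)
  f <- factor(ann$read_id, levels = unique(ann$read_id))
  read_hit <- as.logical(tapply(hit, f, any))
  names(read_hit) <- levels(f)
  observed <- mean(read_hit[clusters$read_id])
  n <- nrow(clusters)
  all_ids <- names(read_hit)
  with_seed(seed, {
    background <- vapply(seq_len(N), function(i)
      mean(read_hit[sample(all_ids, n, replace = n > length(all_ids))]), 0)
    structure(list(factor = factor_name, observed = observed,
                   background_mean = mean(background),
                   p_value = mean(background >= observed), N = N),
              class = "enrichment_result")
  })
}

#' @exportS3Method base::print
print.enrichment_result <- function(x, ...) {
  cat(sprintf("%s: %.1f%% of clusters vs %.1f%% of random contacts (p = %g, N = %d)\n",
              x$factor, 100 * x$observed, 100 * x$background_mean,
              x$p_value, x$N))
  invisible(x)
}

# per-read cluster criteria over the full contact set: >= 1 expressed
# gene, >= 2 expressed genes, common TFs, common MRs
read_criteria <- function(ann, motif, tf_gene_map = NULL, min_sites = 3) {
  tbl <- read_table(ann)
  ctf <- lapply(tbl$expressed_genes, common_tfs_for_genes,
                motif = motif, min_sites = min_sites)
  mrs <- if (!is.null(tf_gene_map))
    master_regulators(motif, tf_gene_map, min_sites) else character(0)
  data.frame(read_id = tbl$read_id, order = tbl$order,
             ge1_gene = lengths(tbl$expressed_genes) >= 1,
             ge2_genes = lengths(tbl$expressed_genes) >= 2,
             common_tf = lengths(ctf) >= 1,
             common_mr = vapply(ctf, function(x) any(x %in% mrs), TRUE),
             stringsAsFactors = FALSE)
}

order_class <- function(k) {
  ifelse(k >= 6, "6+", as.character(k))
}

#' Permutation significance of transcription-cluster criteria
#'
#' Tests whether the identified candidate clusters satisfy the downstream
#' criteria (>= 1 expressed gene, >= 2 expressed genes, common TFs, common
#' MRs) more often than randomly drawn multi-way contacts. Contacts are
#' partitioned by order (3, 4, 5, 6-or-more; plus a pooled "all" class
#' over orders >= 2); in each trial, as many contacts as there are
#' candidates of that class are drawn at random and scored against the
#' criteria; the one-sided p-value per criterion is the proportion of
#' trials whose background count reaches the observed count. If a class
#' holds fewer contacts than candidates, sampling falls back to with
#' replacement (reported).
#'
#' @param ann `annotated_contacts` for the full contact set.
#' @param candidates Candidate cluster table (e.g. from
#'   [find_potential_clusters()]).
#' @param motif Motif count matrix.
#' @param tf_gene_map Named TF -> gene map (for the MR criterion).
#' @param N Number of trials (default 1000).
#' @param min_sites Binding-site threshold (default 3).
#' @param seed Optional integer seed.
#' @return Data frame with `order_class`, `criterion`, `observed`,
#'   `n_candidates`, `p_value`.
#' @export
permutation_test_clusters <- function(ann, candidates, motif,
                                      tf_gene_map = NULL, N = 1000,
                                      min_sites = 3, seed = NULL) {
  stopifnot(N >= 1)
  crit <- read_criteria(ann, motif, tf_gene_map, min_sites)
  crit_cols <- c("ge1_gene", "ge2_genes", "common_tf", "common_mr")
  cand <- crit[crit$read_id %in% candidates$read_id, , drop = FALSE]
  classes <- list(all = crit$order >= 2)
  for (oc in c("3", "4", "5", "6+"))
    classes[[oc]] <- order_class(crit$order) == oc
  rows <- list()
  with_seed(seed, {
    for (cl in names(classes)) {
      pool <- which(classes[[cl]])
      in_class <- if (cl == "all") cand$order >= 2
        else order_class(cand$order) == cl
      n_cand <- sum(in_class)
      if (n_cand == 0 || length(pool) == 0) next
      replace <- n_cand > length(pool)
      if (replace)
        message("order class ", cl,
                ": fewer contacts than candidates; sampling with replacement")
      observed <- colSums(cand[in_class, crit_cols, drop = FALSE])
      bg <- matrix(0, N, length(crit_cols))
      for (t in seq_len(N)) {
        draw <- sample(pool, n_cand, replace = replace)
        bg[t, ] <- colSums(crit[draw, crit_cols, drop = FALSE])
      }
      for (k in seq_along(crit_cols))
        rows[[length(rows) + 1]] <- data.frame(
          order_class = cl, criterion = crit_cols[k],
          observed = observed[[k]], n_candidates = n_cand,
          p_value = mean(bg[, k] >= observed[[k]]))
    }
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
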