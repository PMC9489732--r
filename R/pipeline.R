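#' Run the transcription-cluster pipeline on a simulated (or loaded) study
#'
#' Convenience wrapper chaining [annotate_loci()],
#' [find_potential_clusters()], [find_clusters()], [find_specialized()]
#' and [find_self_sustaining()].
#'
#' @param study A list with `contacts`, `atac`, `polii`, `genes`,
#'   `expression`, `motif`, `tf_gene_map` (e.g. from [simulate_study()]),
#'   and optionally `ctcf`/`enhancers` and `config$chrom_sizes`.
#' @param flank,expr_threshold,min_sites Pipeline parameters (defaults
#'   5000 bp, 1, 3).
#' @return List with `ann`, `potential`, `clusters`, `specialized`,
#'   `classified` (clusters with self-sustaining/core flags).
#' @export
run_cluster_pipeline <- function(study, flank = 5000, expr_threshold = 1,
                                 min_sites = 3) {
  extra <- list()
  for (nm in c("ctcf", "enhancers"))
    if (!is.null(study[[nm]])) extra[[nm]] <- study[[nm]]
  sizes <- if (!is.null(study$config)) study$config$chrom_sizes
    else study$chrom_sizes
  ann <- annotate_loci(study$contacts, study$atac, study$polii,
                       study$genes, study$expression, flank = flank,
                       expr_threshold = expr_threshold,
                       chrom_sizes = sizes, extra_peaks = extra)
  potential <- find_potential_clusters(ann)
  clusters <- find_clusters(potential, study$motif, min_sites)
  specialized <- find_specialized(clusters, study$motif, study$tf_gene_map,
                                  min_sites)
  classified <- find_self_sustaining(clusters, study$motif,
                                     study$tf_gene_map, min_sites,
                                     expression = study$expression,
                                     expr_threshold = expr_threshold)
  list(ann = ann, potential = potential, clusters = clusters,
       specialized = specialized, classified = classified)
}

#' Precision and recall of planted-cluster recovery
#'
#' Scores a pipeline run against the read-level ground truth of a
#' simulated study, per classification tier.
#'
#' @param study Output of [simulate_study()].
#' @param pipeline Optional output of [run_cluster_pipeline()]; computed
#'   with default parameters when missing.
#' @return Data frame with `tier`, `tp`, `fp`, `fn`, `precision`,
#'   `recall` for the five tiers.
#' @export
planted_recovery <- function(study, pipeline = NULL) {
  if (is.null(pipeline)) pipeline <- run_cluster_pipeline(study)
  flags <- tier_flags(study$truth$tier)
  truth_ids <- list(
    potential = study$truth$read_id[flags$is_potential],
    cluster = study$truth$read_id[flags$is_cluster],
    specialized = study$truth$read_id[flags$is_specialized],
    self_sustaining = study$truth$read_id[flags$is_self_sustaining],
    core = study$truth$read_id[flags$is_core])
  pred_ids <- list(
    potential = pipeline$potential$read_id,
    cluster = pipeline$clusters$read_id,
    specialized = pipeline$specialized$read_id,
    self_sustaining =
      pipeline$classified$read_id[pipeline$classified$self_sustaining],
    core = pipeline$classified$read_id[pipeline$classified$core])
  rows <- lapply(names(truth_ids), function(tier) {
    tp <- length(intersect(truth_ids[[tier]], pred_ids[[tier]]))
    fp <- length(setdiff(pred_ids[[tier]], truth_ids[[tier]]))
    fn <- length(setdiff(truth_ids[[tier]], pred_ids[[tier]]))
    data.frame(tier = tier, tp = tp, fp = fp, fn = fn,
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
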