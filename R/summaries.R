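#' Contact-order frequencies
#'
#' Tabulates hyperedges by order (1 = self-contact, 2 = pairwise,
#' 3+ = higher order), weighted by multiplicity.
#'
#' @param hg A [hypergraph].
#' @return Data frame with columns `order`, `weight`.
#' @export
order_frequencies <- function(hg) {
  if (length(hg$edges) == 0)
    return(data.frame(order = integer(0), weight = numeric(0)))
  k <- edge_orders(hg)
  agg <- tapply(hg$weights, k, sum)
  data.frame(order = as.integer(names(agg)), weight = as.numeric(agg),
             row.names = NULL)
}

# chromosomes touched by each hyperedge, as a list of character vectors
edge_chroms <- function(hg) {
  lapply(hg$edges, function(e) unique(hg$nodes$chrom[e]))
}

# deterministic ordering of edge indices: weight descending, then
# lexicographic node-index order
order_edges_by_weight <- function(hg, idx) {
  key <- vapply(hg$edges[idx], function(e)
    paste(formatC(e, width = 9, flag = "0"), collapse = ","), "")
  idx[order(-hg$weights[idx], key)]
}

#' Most frequent multi-way contacts per chromosome
#'
#' For each chromosome, selects the highest-weight distinct
#' intra-chromosomal and inter-chromosomal hyperedges (order >= 2). When a
#' chromosome has fewer than `per_chrom_intra` distinct intra-chromosomal
#' contacts, the shortfall is supplemented with additional
#' inter-chromosomal ones. A hyperedge already selected for an earlier
#' chromosome is never repeated. Ties are broken by lexicographic
#' node-index order.
#'
#' @param hg A weighted [hypergraph] with chromosome-labelled nodes.
#' @param per_chrom_intra,per_chrom_inter Number of contacts of each kind
#'   per chromosome (default 5 and 5).
#' @return Data frame with columns `chrom`, `type` ("intra"/"inter"),
#'   `edge`, `nodes`, `weight`.
#' @export
top_contacts <- function(hg, per_chrom_intra = 5, per_chrom_inter = 5) {
  chroms <- unique(hg$nodes$chrom)
  ec <- edge_chroms(hg)
  multi <- which(lengths(hg$edges) >= 2)
  selected <- logical(length(hg$edges))
  out <- list()
  for (ch in chroms) {
    touches <- vapply(ec, function(x) ch %in% x, TRUE)
    intra_idx <- multi[vapply(multi, function(e)
      touches[e] && length(ec[[e]]) == 1, TRUE)]
    inter_idx <- multi[vapply(multi, function(e)
      touches[e] && length(ec[[e]]) > 1, TRUE)]
    intra_idx <- order_edges_by_weight(hg, intra_idx[!selected[intra_idx]])
    inter_idx <- order_edges_by_weight(hg, inter_idx[!selected[inter_idx]])
    take_intra <- head(intra_idx, per_chrom_intra)
    deficit <- per_chrom_intra - length(take_intra)
    take_inter <- head(inter_idx, per_chrom_inter + deficit)
    sel <- c(take_intra, take_inter)
    selected[sel] <- TRUE
    if (length(sel) > 0)
      out[[ch]] <- data.frame(
        chrom = ch,
        type = rep(c("intra", "inter"),
                   c(length(take_intra), length(take_inter))),
        edge = sel,
        nodes = vapply(hg$edges[sel], function(e)
          paste(node_labels(hg)[e], collapse = ";"), ""),
        weight = hg$weights[sel])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Chromosome-combination frequencies
#'
#' Maps each hyperedge to its set of distinct chromosomes (multiple loci
#' on one chromosome collapse to a single instance), accumulates weights
#' per combination of 2..`max_order` chromosomes, and normalizes each
#' count by the summed bp length of the member chromosomes so that
#' combinations of short chromosomes are comparable to long ones.
#'
#' @param hg A weighted [hypergraph] (typically coarse, e.g. 25 Mb bins).
#' @param chrom_sizes Named numeric vector of chromosome lengths; defaults
#'   to the sizes stored in the hypergraph.
#' @param max_order Largest combination size reported (default 5).
#' @return Data frame with `combination`, `order`, `count`,
#'   `normalized` (count / summed length), sorted by normalized frequency.
#' @export
chrom_combination_frequencies <- function(hg, chrom_sizes = hg$chrom_sizes,
                                          max_order = 5) {
  if (is.null(chrom_sizes)) stop("chromosome sizes required")
  ec <- edge_chroms(hg)
  sz <- vapply(ec, length, 0L)
  keep <- sz >= 2 & sz <= max_order
  if (!any(keep))
    return(data.frame(combination = character(0), order = integer(0),
                      count = numeric(0), normalized = numeric(0)))
  combos <- vapply(ec[keep], function(x) paste(sort(x), collapse = "+"), "")
  cnt <- tapply(hg$weights[keep], combos, sum)
  combo <- names(cnt)
  totlen <- vapply(strsplit(combo, "+", fixed = TRUE),
                   function(ch) sum(chrom_sizes[ch]), 0)
  res <- data.frame(combination = combo,
                    order = lengths(strsplit(combo, "+", fixed = TRUE)),
                    count = as.numeric(cnt),
                    normalized = as.numeric(cnt) / totlen)
  res <- res[order(-res$normalized, res$combination), ]
  rownames(res) <- NULL
  res
}

#' Per-chromosome top combination at each order
#'
#' @param combos Output of [chrom_combination_frequencies()].
#' @return Data frame with `chrom`, `order`, `combination`, `normalized`:
#'   for each chromosome, its highest normalized-frequency combination at
#'   each combination order.
#' @export
top_chrom_combinations <- function(combos) {
  if (nrow(combos) == 0) return(combos)
  members <- strsplit(combos$combination, "+", fixed = TRUE)
  rows <- list()
  for (ch in sort(unique(unlist(members)))) {
    has <- vapply(members, function(x) ch %in% x, TRUE)
    for (k in sort(unique(combos$order[has]))) {
      sub <- combos[has & combos$order == k, ]
      rows[[length(rows) + 1]] <- data.frame(
        chrom = ch, order = k, combination = sub$combination[1],
        normalized = sub$normalized[1])
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Node degrees
#'
#' Degree of a node = weighted number of hyperedges containing it. With
#' `normalized = TRUE` degrees are divided by the maximum degree so the
#' most connected locus scores 1.
#'
#' @param hg A [hypergraph].
#' @param normalized Divide by the maximum degree (default `FALSE`).
#' @return Named numeric vector over all nodes (label "chrom:bin").
#' @export
node_degrees <- function(hg, normalized = FALSE) {
  deg <- numeric(n_nodes(hg))
  for (e in seq_along(hg$edges))
    deg[hg$edges[[e]]] <- deg[hg$edges[[e]]] + hg$weights[e]
  if (normalized && max(deg) > 0) deg <- deg / max(deg)
  setNames(deg, node_labels(hg))
}
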