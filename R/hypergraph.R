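#' Genomic hypergraph
#'
#' A hypergraph G = (V, E) over genomic bins. `nodes` is an ordered data
#' frame (chromosome order then bin index) defining the row order of any
#' derived incidence matrix; `edges` is a list of sorted node-index
#' vectors; `weights` holds the multiplicity of each distinct hyperedge.
#' Identical hyperedges are always stored merged; whether multiplicities
#' are expanded into repeated incidence columns is decided at
#' [build_incidence()] time.
#'
#' @param nodes Data frame with columns `chrom`, `bin_index`.
#' @param edges List of integer vectors (1-based node indices).
#' @param weights Numeric multiplicities, one per edge, all >= 1.
#' @param resolution Bin width in bp, or `"read"` for read-level nodes.
#' @param chrom_sizes Optional named vector of chromosome lengths.
#' @return An object of class `hypergraph`.
#' @export
new_hypergraph <- function(nodes, edges, weights, resolution,
                           chrom_sizes = NULL) {
  stopifnot(is.data.frame(nodes), all(c("chrom", "bin_index") %in% names(nodes)))
  n <- nrow(nodes)
  edges <- lapply(edges, function(e) sort(unique(as.integer(e))))
  if (length(edges) > 0) {
    rng <- range(c(1L, unlist(edges)))
    if (rng[1] < 1L || rng[2] > n) stop("hyperedge refers to unknown node")
    if (any(lengths(edges) < 1L)) stop("empty hyperedge")
  }
  weights <- as.numeric(weights)
  if (length(weights) != length(edges) || any(weights < 1))
    stop("need one weight >= 1 per hyperedge")
  hg <- structure(list(nodes = nodes, edges = edges, weights = weights,
                       resolution = resolution, chrom_sizes = chrom_sizes),
                  class = "hypergraph")
  merge_edges(hg)
}

# collapse identical hyperedge sets, summing weights; edge order follows
# first appearance
merge_edges <- function(hg) {
  if (length(hg$edges) < 2) return(hg)
  key <- vapply(hg$edges, paste, "", collapse = ",")
  first <- !duplicated(key)
  w <- vapply(split(hg$weights, factor(key, levels = key[first])), sum, 0)
  hg$edges <- hg$edges[first]
  hg$weights <- as.numeric(w)
  hg
}

#' @exportS3Method base::print
print.hypergraph <- function(x, ...) {
  cat(sprintf("hypergraph: %d nodes, %d distinct hyperedges (total weight %g), resolution %s\n",
              nrow(x$nodes), length(x$edges), sum(x$weights),
              as.character(x$resolution)))
  invisible(x)
}

#' Number of nodes / hyperedges
#' @param hg A hypergraph.
#' @export
n_nodes <- function(hg) nrow(hg$nodes)

#' @rdname n_nodes
#' @param weighted Count multiplicities if `TRUE`.
#' @export
n_edges <- function(hg, weighted = FALSE)
  if (weighted) sum(hg$weights) else length(hg$edges)

#' Hyperedge orders (number of distinct nodes per hyperedge)
#' @param hg A hypergraph.
#' @export
edge_orders <- function(hg) lengths(hg$edges)

# bin universe for a chromosome-sizes vector: all bins of every chromosome,
# in the order the sizes are given, so hypergraphs from different samples
# share a row order
bin_universe <- function(chrom_sizes, resolution) {
  nb <- pmax(1L, as.integer(ceiling(chrom_sizes / resolution)))
  data.frame(chrom = rep(names(chrom_sizes), nb),
             bin_index = unlist(lapply(nb, function(k) seq_len(k) - 1L)),
             stringsAsFactors = FALSE)
}

#' Bin multi-way reads into a genomic hypergraph
#'
#' Each monomer is assigned to the bin containing its midpoint
#' (`floor(midpoint / resolution)`). Bins repeated within one read collapse
#' to a single node, so the hyperedge order can shrink; reads collapsing to
#' one bin are retained as order-1 self-contacts. Identical hyperedges are
#' merged with weight equal to their multiplicity. When `chrom_sizes` is
#' supplied the node universe is every bin of every listed chromosome
#' (shared row order across samples); otherwise only observed bins are
#' nodes. With `resolution = "read"` every distinct monomer interval is its
#' own node.
#'
#' @param contacts A `contacts` data frame (see [read_contacts()]).
#' @param resolution Bin size in bp (> 0) or `"read"`.
#' @param chrom_sizes Optional named numeric vector of chromosome lengths.
#' @return A [hypergraph].
#' @export
bin_reads <- function(contacts, resolution, chrom_sizes = NULL) {
  stopifnot(nrow(contacts) > 0)
  if (!identical(resolution, "read")) {
    resolution <- as.numeric(resolution)
    if (is.na(resolution) || resolution <= 0)
      stop("resolution must be a positive bin size or \"read\"")
  }
  if (!is.null(chrom_sizes)) {
    unknown <- setdiff(unique(contacts$chrom), names(chrom_sizes))
    if (length(unknown) > 0)
      stop("chromosome(s) absent from sizes table: ",
           paste(unknown, collapse = ", "))
  }
  if (identical(resolution, "read")) {
    key <- paste(contacts$chrom, contacts$start, contacts$end, sep = ":")
    ukey <- unique(key[order(match(contacts$chrom, unique(contacts$chrom)),
                             contacts$start, contacts$end)])
    nodes <- data.frame(chrom = sub(":.*", "", ukey),
                        bin_index = seq_along(ukey) - 1L,
                        key = ukey, stringsAsFactors = FALSE)
    idx <- match(key, ukey)
  } else {
    mid <- (contacts$start + contacts$end) / 2
    bin <- floor(mid / resolution)
    if (is.null(chrom_sizes)) {
      key <- paste(contacts$chrom, bin, sep = ":")
      obs <- !duplicated(key)
      ord <- order(match(contacts$chrom[obs], unique(contacts$chrom)),
                   bin[obs])
      nodes <- data.frame(chrom = contacts$chrom[obs][ord],
                          bin_index = as.integer(bin[obs][ord]),
                          stringsAsFactors = FALSE)
      idx <- match(key, paste(nodes$chrom, nodes$bin_index, sep = ":"))
    } else {
      nodes <- bin_universe(chrom_sizes, resolution)
      idx <- match(paste(contacts$chrom, bin, sep = ":"),
                   paste(nodes$chrom, nodes$bin_index, sep = ":"))
      if (anyNA(idx))
        stop("monomer midpoint beyond chromosome length")
    }
  }
  nodes$key <- NULL
  by_read <- split(idx, factor(contacts$read_id,
                               levels = unique(contacts$read_id)))
  edges <- lapply(by_read, function(v) sort(unique(v)))
  new_hypergraph(nodes, edges, rep(1, length(edges)), resolution, chrom_sizes)
}

#' Default weighting convention for a resolution
#'
#' Weighted incidence (one column per distinct hyperedge) at coarse
#' resolutions (>= 1 Mb) where repeated contacts are common; unweighted
#' (one column per read) at read level and fine resolutions.
#'
#' @param hg A hypergraph.
#' @export
is_weighted_default <- function(hg) {
  !identical(hg$resolution, "read") && hg$resolution >= 1e6
}

#' Build the incidence matrix of a hypergraph
#'
#' Rows are genomic bins (nodes), columns are hyperedges, entries are 0/1.
#' With `weighted = FALSE` every read occurrence gets its own column (a
#' hyperedge of weight w contributes w identical columns); with
#' `weighted = TRUE` each distinct hyperedge is one column and weights are
#' carried in the `"weights"` attribute. Column sums equal hyperedge
#' orders; row sums equal node degrees.
#'
#' @param hg A [hypergraph].
#' @param weighted Column-per-distinct-edge if `TRUE` (default depends on
#'   resolution, see [is_weighted_default()]).
#' @return A sparse 0/1 `Matrix` with node labels as rownames.
#' @export
build_incidence <- function(hg, weighted = is_weighted_default(hg)) {
  n <- n_nodes(hg)
  edges <- hg$edges
  w <- hg$weights
  if (!weighted && length(edges) > 0) {
    rep_idx <- rep(seq_along(edges), times = w)
    edges <- edges[rep_idx]
    w <- rep(1, length(edges))
  }
  m <- length(edges)
  H <- sparseMatrix(i = if (m > 0) unlist(edges) else integer(0),
                    j = if (m > 0) rep(seq_len(m), lengths(edges)) else integer(0),
                    x = 1, dims = c(n, m))
  rownames(H) <- node_labels(hg)
  attr(H, "weights") <- w
  H
}

#' Node labels ("chrom:bin_index")
#' @param hg A hypergraph.
#' @export
node_labels <- function(hg) paste(hg$nodes$chrom, hg$nodes$bin_index, sep = ":")

#' Decompose a hypergraph into a pairwise contact matrix
#'
#' Every order-k hyperedge (k >= 2) of weight w contributes w to each of
#' its choose(k, 2) unordered node pairs; order-1 self-contacts contribute
#' w to the diagonal. The result is interchangeable with a Hi-C style
#' contact matrix at the same resolution.
#'
#' @param hg A [hypergraph].
#' @return Symmetric sparse `Matrix` of non-negative counts.
#' @export
decompose_pairwise <- function(hg) {
  n <- n_nodes(hg)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (e in seq_along(hg$edges)) {
    nodes <- hg$edges[[e]]; w <- hg$weights[e]
    if (length(nodes) == 1) {
      ii <- c(ii, nodes); jj <- c(jj, nodes); xx <- c(xx, w)
    } else {
      pr <- combn(nodes, 2)
      ii <- c(ii, pr[1, ], pr[2, ])
      jj <- c(jj, pr[2, ], pr[1, ])
      xx <- c(xx, rep(w, 2 * ncol(pr)))
    }
  }
  M <- sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  rownames(M) <- colnames(M) <- node_labels(hg)
  M
}

# distinct off-diagonal pair counts from the pairwise decomposition,
# as a data.frame(i, j, count) with i < j
pair_counts <- function(hg) {
  M <- decompose_pairwise(hg)
  T3 <- as(Matrix::triu(M, k = 1), "TsparseMatrix")
  data.frame(i = T3@i + 1L, j = T3@j + 1L, count = T3@x)
}

# nearest-rank percentile: smallest value with at least p% of the
# distribution at or below it
nearest_rank <- function(x, p) {
  stopifnot(p > 0, p <= 100)
  s <- sort(x)
  s[ceiling(p / 100 * length(s))]
}

#' Filter a hypergraph by pairwise contact frequency
#'
#' Spurious multi-way contacts are pruned using the frequency of their
#' pairwise components: the hypergraph is decomposed to distinct locus-pair
#' counts, a threshold t is set at the nearest-rank `percentile` of that
#' count distribution, and a pair is "supported" iff its count >= t.
#' Within each hyperedge, the node incident to the most unsupported
#' internal pairs is removed iteratively (ties broken towards the lower
#' node index) until all remaining internal pairs are supported; hyperedges
#' left with fewer than 2 nodes are dropped and identical survivors are
#' re-merged. Because trimming changes the pair-count distribution (and
#' with it the threshold), the pass is repeated until the hyperedge set is
#' a fixed point, making the operation idempotent; each pass strictly
#' removes incidence mass, so the loop terminates. Order-1 self-contacts
#' take no part in the pair statistics and are dropped from the filtered
#' hypergraph.
#'
#' @param hg A [hypergraph].
#' @param percentile Percentile in (0, 100] for the support threshold
#'   (default 85).
#' @return The filtered [hypergraph] (same node universe).
#' @export
filter_hypergraph <- function(hg, percentile = 85) {
  stopifnot(percentile > 0, percentile <= 100)
  repeat {
    out <- filter_pass(hg, percentile)
    if (identical(out$edges, hg$edges) &&
        identical(out$weights, hg$weights)) return(out)
    hg <- out
  }
}

filter_pass <- function(hg, percentile) {
  multi <- lengths(hg$edges) >= 2
  if (!any(multi))
    return(new_hypergraph(hg$nodes, list(), numeric(0), hg$resolution,
                          hg$chrom_sizes))
  sub <- hg
  sub$edges <- hg$edges[multi]; sub$weights <- hg$weights[multi]
  pc <- pair_counts(sub)
  t <- nearest_rank(pc$count, percentile)
  supported <- new.env(hash = TRUE)
  for (k in which(pc$count >= t))
    assign(paste(pc$i[k], pc$j[k]), TRUE, envir = supported)
  is_supported <- function(a, b)
    exists(paste(min(a, b), max(a, b)), envir = supported)
  trim <- function(nodes) {
    while (length(nodes) >= 2) {
      bad <- matrix(FALSE, length(nodes), length(nodes))
      pr <- combn(seq_along(nodes), 2)
      for (k in seq_len(ncol(pr))) {
        a <- pr[1, k]; b <- pr[2, k]
        if (!is_supported(nodes[a], nodes[b])) bad[a, b] <- bad[b, a] <- TRUE
      }
      nbad <- rowSums(bad)
      if (all(nbad == 0)) break
      # remove the node with most unsupported pairs; tie -> lower node index
      worst <- which(nbad == max(nbad))
      drop <- worst[which.min(nodes[worst])]
      nodes <- nodes[-drop]
    }
    nodes
  }
  trimmed <- lapply(sub$edges, trim)
  keep <- lengths(trimmed) >= 2
  new_hypergraph(hg$nodes, trimmed[keep], sub$weights[keep], hg$resolution,
                 hg$chrom_sizes)
}
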