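# shared fixtures built in code

# the two-hyperedge textbook hypergraph {v1,v2,v3}, {v3,v4}
worked_example_hypergraph <- function() {
  new_hypergraph(data.frame(chrom = "chr1", bin_index = 0:3),
                 list(c(1, 2, 3), c(3, 4)), c(1, 1), 1e6)
}

worked_example_incidence <- function() {
  matrix(c(1, 1, 1, 0,
           0, 0, 1, 1), nrow = 4, ncol = 2)
}

# independent dense-arithmetic oracle for the hypergraph adjacency
# A = H E^-1 H^T: accumulate w/k over all ordered node pairs of each edge
oracle_adjacency <- function(edges, n, weights = rep(1, length(edges))) {
  A <- matrix(0, n, n)
  for (e in seq_along(edges)) {
    k <- length(edges[[e]])
    for (a in edges[[e]]) for (b in edges[[e]])
      A[a, b] <- A[a, b] + weights[e] / k
  }
  A
}

oracle_laplacian <- function(edges, n, weights = rep(1, length(edges))) {
  deg <- numeric(n)
  for (e in seq_along(edges)) deg[edges[[e]]] <- deg[edges[[e]]] + weights[e]
  diag(deg, n) - oracle_adjacency(edges, n, weights)
}

# random small hypergraph for property tests; edges confined to the first
# `active` nodes so relocation moves mass onto untouched nodes
random_toy_hypergraph <- function(n = 12, m = 10, max_order = 4,
                                  active = n, seed = NULL) {
  draw <- function() {
    edges <- lapply(seq_len(m), function(i)
      sample(seq_len(active), sample(2:max_order, 1)))
    new_hypergraph(data.frame(chrom = "chr1", bin_index = seq_len(n) - 1L),
                   edges, rep(1, m), 1e6)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# minimal annotation scenario built by hand: loci as contact rows plus
# peak/gene/motif objects, for unit tests of the cluster tier logic
toy_gr <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
}
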