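new_distance_result <- function(measure, value, p_value = NA_real_,
                                n_perm = NA_integer_) {
  structure(list(measure = measure, value = value, p_value = p_value,
                 n_perm = n_perm),
            class = "distance_result")
}

#' @exportS3Method base::print
print.distance_result <- function(x, ...) {
  cat(sprintf("%s distance: %g", x$measure, x$value))
  if (!is.na(x$p_value))
    cat(sprintf("  (permutation p = %g, N = %d)", x$p_value, x$n_perm))
  cat("\n")
  invisible(x)
}

check_same_n <- function(b1, b2) {
  if (b1$n != b2$n)
    stop("hypergraphs must share a node universe (n mismatch: ",
         b1$n, " vs ", b2$n, ")")
}

#' Hamming distance between hypergraphs
#'
#' Local similarity: mean absolute difference of the two adjacency
#' matrices, \eqn{D_H = (1/n^2) \sum_{jk} |A_{1,jk} - A_{2,jk}|}.
#'
#' @param x1,x2 [hypergraph]s, incidence matrices, or `comparison_bundle`s
#'   over the same node universe.
#' @param epsilon Affinity constant forwarded to [comparison_bundle()].
#' @return A `distance_result`.
#' @export
hamming_distance <- function(x1, x2, epsilon = 1e-3) {
  b1 <- comparison_bundle(x1, epsilon); b2 <- comparison_bundle(x2, epsilon)
  check_same_n(b1, b2)
  new_distance_result("hamming", sum(abs(b1$A - b2$A)) / b1$n^2)
}

#' Spectral distance between hypergraphs
#'
#' Global similarity: p-norm of the difference between the ascending
#' eigenvalue sequences of the two normalized Laplacians,
#' \eqn{D_\lambda = (1/n) (\sum_j |\lambda_{1,j} - \lambda_{2,j}|^p)^{1/p}}.
#'
#' @inheritParams hamming_distance
#' @param p Norm exponent, >= 1 (default 2).
#' @return A `distance_result`.
#' @export
spectral_distance <- function(x1, x2, p = 2, epsilon = 1e-3) {
  if (p < 1) stop("p must be >= 1")
  b1 <- comparison_bundle(x1, epsilon); b2 <- comparison_bundle(x2, epsilon)
  check_same_n(b1, b2)
  l1 <- rev(eigen(b1$Ltilde, symmetric = TRUE, only.values = TRUE)$values)
  l2 <- rev(eigen(b2$Ltilde, symmetric = TRUE, only.values = TRUE)$values)
  new_distance_result("spectral", sum(abs(l1 - l2)^p)^(1 / p) / b1$n)
}

#' DeltaCon distance between hypergraphs
#'
#' Local and global similarity: the Matusita difference between the two
#' fast-belief-propagation affinity matrices
#' \eqn{S_i = (I + \epsilon^2 D^a_i - \epsilon A_i)^{-1}},
#' \eqn{D_\Delta = (1/n^2) (\sum_{jk} (S_{1,jk}^{1/2} - S_{2,jk}^{1/2})^2)^{1/2}}.
#' Results are insensitive to `epsilon` over several orders of magnitude;
#' at large `epsilon` the affinity matrix can develop negative entries, in
#' which case an error advises a smaller value.
#'
#' @inheritParams hamming_distance
#' @return A `distance_result`.
#' @export
deltacon_distance <- function(x1, x2, epsilon = 1e-3) {
  b1 <- comparison_bundle(x1, epsilon); b2 <- comparison_bundle(x2, epsilon)
  check_same_n(b1, b2)
  if (min(b1$S) < 0 || min(b2$S) < 0)
    stop("negative affinity entries; use a smaller epsilon")
  d <- sqrt(sum((sqrt(b1$S) - sqrt(b2$S))^2)) / b1$n^2
  new_distance_result("deltacon", d)
}

measure_fun <- function(measure) {
  switch(match.arg(measure, c("hamming", "spectral", "deltacon")),
         hamming = hamming_distance,
         spectral = spectral_distance,
         deltacon = deltacon_distance)
}

#' Random hypergraph similar to a template
#'
#' Draws a hypergraph with the same node universe, the same hyperedge
#' order multiset and weights, and approximately the same node-degree
#' distribution: each hyperedge's members are re-drawn without replacement
#' with probability proportional to the template's (weighted) node
#' degrees, a bipartite configuration-style null.
#'
#' @param template A [hypergraph] with at least one hyperedge.
#' @param seed Optional integer; the draw is deterministic given it.
#' @return A [hypergraph].
#' @export
random_similar_hypergraph <- function(template, seed = NULL) {
  stopifnot(length(template$edges) >= 1)
  deg <- node_degrees(template)
  pool <- which(deg > 0)
  with_seed(seed, {
    edges <- lapply(template$edges, function(e) {
      k <- length(e)
      if (k > n_nodes(template)) stop("hyperedge order exceeds node count")
      if (k >= length(pool)) return(sort(pool[seq_len(min(k, length(pool)))]))
      sort(sample(pool, k, prob = deg[pool]))
    })
    new_hypergraph(template$nodes, edges, template$weights,
                   template$resolution, template$chrom_sizes)
  })
}

#' Permutation significance of a hypergraph distance
#'
#' Builds a null distribution of distances between `g1` and `N` random
#' hypergraphs similar to `g1` (see [random_similar_hypergraph()]); the
#' p-value is the proportion of null distances greater than or equal to
#' the observed distance d(g1, g2). A reported 0 means no null draw
#' reached the observed distance.
#'
#' @param g1,g2 [hypergraph]s over the same node universe.
#' @param measure One of "hamming", "spectral", "deltacon".
#' @param N Number of null draws (default 1000).
#' @param epsilon,p Forwarded to the distance measure.
#' @param seed Optional integer seed for reproducibility.
#' @return A `distance_result` with `p_value` and `n_perm` filled in.
#' @export
permutation_test_distance <- function(g1, g2, measure = "hamming",
                                      N = 1000, epsilon = 1e-3, p = 2,
                                      seed = NULL) {
  stopifnot(N >= 1)
  f <- measure_fun(measure)
  dfun <- if (identical(f, spectral_distance))
    function(a, b) f(a, b, p = p, epsilon = epsilon)$value
  else function(a, b) f(a, b, epsilon = epsilon)$value
  b1 <- comparison_bundle(g1, epsilon)
  d_obs <- dfun(b1, comparison_bundle(g2, epsilon))
  with_seed(seed, {
    background <- vapply(seq_len(N), function(i) {
      r <- random_similar_hypergraph(g1)
      dfun(b1, comparison_bundle(r, epsilon))
    }, 0)
    new_distance_result(measure, d_obs,
                        p_value = mean(background >= d_obs), n_perm = N)
  })
}
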