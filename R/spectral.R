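# coerce hypergraph -> dense incidence with one column per occurrence
# (weight w becomes w identical columns, keeping D and E counting
# semantics); matrices pass through
as_incidence <- function(x) {
  if (inherits(x, "hypergraph")) x <- build_incidence(x, weighted = FALSE)
  as.matrix(x)
}

#' Hypergraph Laplacian and spectrum
#'
#' For an n x m incidence matrix H, the hypergraph Laplacian is
#' \deqn{L = D - H E^{-1} H^T}
#' where D is the diagonal matrix of node degrees (row sums of H) and E
#' the diagonal matrix of hyperedge orders (column sums). Unlike the
#' clique-expansion graph Laplacian, each hyperedge's contribution is
#' scaled by its order, so L is symmetric positive semidefinite with zero
#' row sums. Eigenvalues are returned ascending, clipped at zero, together
#' with their trace-normalized counterparts.
#'
#' @param x A [hypergraph] or an incidence matrix (0/1, nodes x edges).
#' @return A `spectral_bundle`: list with `L` (dense matrix), `degrees`,
#'   `orders`, `values` (ascending eigenvalues) and `values_norm`
#'   (eigenvalues scaled to sum to 1; zero vector if the spectrum is null).
#' @export
hypergraph_laplacian <- function(x) {
  H <- as_incidence(x)
  if (nrow(H) < 1 || ncol(H) < 1) stop("need at least one node and one hyperedge")
  orders <- colSums(H)
  if (any(orders == 0)) stop("hyperedge column with order zero")
  degrees <- rowSums(H)
  A <- H %*% (t(H) / orders)
  L <- diag(degrees, nrow(H)) - A
  L <- (L + t(L)) / 2
  values <- rev(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  values <- pmax(values, 0)
  total <- sum(values)
  structure(list(L = L, degrees = degrees, orders = orders,
                 values = values,
                 values_norm = if (total > 0) values / total else values),
            class = "spectral_bundle")
}

#' @exportS3Method base::print
print.spectral_bundle <- function(x, ...) {
  cat(sprintf("spectral_bundle: n = %d, trace = %g\n",
              length(x$degrees), sum(x$values)))
  invisible(x)
}

#' Hypergraph entropy
#'
#' Shannon entropy of the trace-normalized hypergraph Laplacian spectrum
#' (a von Neumann style network entropy):
#' \deqn{S = -\sum_i \bar\lambda_i \ln \bar\lambda_i,}
#' with the convention 0 ln 0 = 0. Larger, more uniformly spread spectra
#' (less organized folding) give higher entropy.
#'
#' @param x A [hypergraph], incidence matrix, or `spectral_bundle`.
#' @return Non-negative scalar entropy (natural log units).
#' @export
hypergraph_entropy <- function(x) {
  b <- if (inherits(x, "spectral_bundle")) x else hypergraph_laplacian(x)
  if (sum(b$values) <= 1e-12)
    stop("all-zero Laplacian spectrum: entropy undefined")
  l <- b$values_norm[b$values_norm > 0]
  -sum(l * log(l))
}

#' Comparison bundle: adjacency, normalized Laplacian, affinity
#'
#' Precomputes the matrices the hypergraph distance measures operate on,
#' from the incidence matrix H of each hypergraph over a shared node
#' universe:
#' \deqn{A = H E^{-1} H^T, \quad \tilde L = I - D^{-1/2} A D^{-1/2},}
#' and the fast-belief-propagation node affinity matrix
#' \deqn{S = (I + \epsilon^2 D^a - \epsilon A)^{-1}}
#' with \eqn{D^a} the diagonal of row sums of A. Rows/columns of
#' \eqn{D^{-1/2}} for zero-degree nodes are set to zero (their normalized
#' Laplacian row is entirely zero), so samples can share a node universe
#' that includes bins untouched in one of them.
#'
#' @param x A [hypergraph] or incidence matrix.
#' @param epsilon Neighbor-influence constant in (0, 1) for the affinity
#'   matrix (default 1e-3).
#' @return A `comparison_bundle`: list with `A`, `Ltilde`, `S`, `Da`,
#'   `epsilon`, `n`.
#' @export
comparison_bundle <- function(x, epsilon = 1e-3) {
  if (inherits(x, "comparison_bundle")) return(x)
  if (!(epsilon > 0 && epsilon < 1)) stop("epsilon must lie in (0, 1)")
  H <- as_incidence(x)
  orders <- colSums(H)
  if (ncol(H) > 0 && any(orders == 0)) stop("hyperedge column with order zero")
  n <- nrow(H)
  A <- if (ncol(H) > 0) H %*% (t(H) / orders) else matrix(0, n, n)
  A <- (A + t(A)) / 2
  deg <- rowSums(H)
  dinv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  Ltilde <- diag(as.numeric(deg > 0), n) - (dinv * A) %*% diag(dinv, n)
  Ltilde <- (Ltilde + t(Ltilde)) / 2
  Da <- rowSums(A)
  M <- diag(1 + epsilon^2 * Da, n) - epsilon * A
  S <- tryCatch(solve(M), error = function(e)
    stop("singular affinity system (I + eps^2 D^a - eps A); try smaller epsilon"))
  S <- (S + t(S)) / 2
  structure(list(A = A, Ltilde = Ltilde, S = S, Da = Da,
                 epsilon = epsilon, n = n),
            class = "comparison_bundle")
}

#' @exportS3Method base::print
print.comparison_bundle <- function(x, ...) {
  cat(sprintf("comparison_bundle: n = %d, epsilon = %g\n", x$n, x$epsilon))
  invisible(x)
}
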