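# the worked-example pair used across the distance tests: the textbook
# hypergraph vs the same plus an extra pairwise hyperedge {v1,v4}
distance_pair <- function() {
  g1 <- worked_example_hypergraph()
  g2 <- new_hypergraph(g1$nodes, c(g1$edges, list(c(1, 4))),
                       c(g1$weights, 1), 1e6)
  list(g1 = g1, g2 = g2)
}

test_that("comparison bundle reproduces hand-computed adjacency entries", {
  b <- comparison_bundle(worked_example_hypergraph())
  A <- unname(b$A)
  expect_equal(A[3, 3], 5 / 6)   # 1/3 from the triple + 1/2 from the pair
  expect_equal(A[1, 2], 1 / 3)
  expect_equal(A[3, 4], 1 / 2)
  expect_equal(A, oracle_adjacency(list(c(1, 2, 3), c(3, 4)), 4))
})

test_that("zero-degree nodes produce zero normalized-Laplacian rows", {
  # add an isolated node v5 to the worked example
  H <- rbind(worked_example_incidence(), 0)
  b <- comparison_bundle(H)
  expect_false(anyNA(b$Ltilde))
  expect_equal(b$Ltilde[5, ], rep(0, 5))
  expect_equal(b$Ltilde[, 5], rep(0, 5))
  expect_error(comparison_bundle(H, epsilon = 0), "epsilon")
})

test_that("all three distances vanish on identical hypergraphs", {
  g <- worked_example_hypergraph()
  expect_equal(hamming_distance(g, g)$value, 0)
  expect_equal(spectral_distance(g, g)$value, 0)
  expect_equal(deltacon_distance(g, g)$value, 0)
})

test_that("Hamming distance matches hand matrix arithmetic on the pair", {
  p <- distance_pair()
  # the extra {v1,v4} edge changes A by 1/2 at (1,1),(4,4),(1,4),(4,1)
  expect_equal(hamming_distance(p$g1, p$g2)$value, 2 / 16)
  A1 <- oracle_adjacency(p$g1$edges, 4)
  A2 <- oracle_adjacency(p$g2$edges, 4)
  expect_equal(hamming_distance(p$g1, p$g2)$value, sum(abs(A1 - A2)) / 16)
})

test_that("spectral distance is invariant to node relabelling", {
  withr::with_seed(11, {
    g <- random_toy_hypergraph(n = 9, m = 7)
    perm <- sample(9)
    g_perm <- new_hypergraph(g$nodes, lapply(g$edges, function(e) perm[e]),
                             g$weights, g$resolution)
  })
  expect_equal(spectral_distance(g, g_perm)$value, 0, tolerance = 1e-9)
})

test_that("spectral and DeltaCon match dense oracles on the worked pair", {
  p <- distance_pair()
  A1 <- oracle_adjacency(p$g1$edges, 4)
  A2 <- oracle_adjacency(p$g2$edges, 4)
  # normalized Laplacian oracle from first principles
  norm_lap <- function(edges, A) {
    deg <- numeric(4)
    for (e in edges) deg[e] <- deg[e] + 1
    Dm <- diag(1 / sqrt(deg))
    diag(4) - Dm %*% A %*% Dm
  }
  sp_oracle <- {
    l1 <- sort(eigen(norm_lap(p$g1$edges, A1), symmetric = TRUE)$values)
    l2 <- sort(eigen(norm_lap(p$g2$edges, A2), symmetric = TRUE)$values)
    sqrt(sum((l1 - l2)^2)) / 4
  }
  expect_equal(spectral_distance(p$g1, p$g2)$value, sp_oracle,
               tolerance = 1e-12)
  dc_oracle <- {
    eps <- 1e-3
    S1 <- solve(diag(4) + eps^2 * diag(rowSums(A1)) - eps * A1)
    S2 <- solve(diag(4) + eps^2 * diag(rowSums(A2)) - eps * A2)
    sqrt(sum((sqrt(S1) - sqrt(S2))^2)) / 16
  }
  expect_equal(deltacon_distance(p$g1, p$g2)$value, dc_oracle,
               tolerance = 1e-12)
})

test_that("distance axioms hold and DeltaCon is epsilon-insensitive", {
  for (seed in 1:20) {
    g1 <- random_toy_hypergraph(n = 10, m = 8, seed = seed)
    g2 <- random_toy_hypergraph(n = 10, m = 8, seed = seed + 1000)
    for (f in list(hamming_distance, spectral_distance, deltacon_distance)) {
      d12 <- f(g1, g2)$value
      d21 <- f(g2, g1)$value
      expect_gte(d12, 0)
      expect_equal(d12, d21, tolerance = 1e-12)
      expect_equal(f(g1, g1)$value, 0, tolerance = 1e-12)
    }
    # epsilon-insensitivity concerns comparative results: the raw value
    # scales as sqrt(epsilon), but ratios between pairs are stable
    g3 <- random_toy_hypergraph(n = 10, m = 8, seed = seed + 2000)
    ratio <- vapply(c(1e-2, 1e-3, 1e-4), function(eps)
      deltacon_distance(g1, g2, epsilon = eps)$value /
        deltacon_distance(g1, g3, epsilon = eps)$value, 0)
    expect_lt(max(ratio) / min(ratio) - 1, 0.10)
  }
})

test_that("distance computations demand a shared node universe", {
  g1 <- worked_example_hypergraph()
  g3 <- new_hypergraph(data.frame(chrom = "chr1", bin_index = 0:4),
                       list(c(1, 2)), 1, 1e6)
  expect_error(hamming_distance(g1, g3), "node universe")
})

test_that("similar random hypergraphs preserve orders and degree profile", {
  # forced case: one hyperedge spanning every node reproduces the template
  all_nodes <- new_hypergraph(data.frame(chrom = "chr1", bin_index = 0:5),
                              list(1:6), 1, 1e6)
  r <- random_similar_hypergraph(all_nodes, seed = 1)
  expect_equal(r$edges, all_nodes$edges)

  tpl <- random_toy_hypergraph(n = 12, m = 10, seed = 3)
  for (s in 1:25) {
    r <- random_similar_hypergraph(tpl, seed = s)
    expect_equal(sort(rep(edge_orders(r), r$weights)),
                 sort(rep(edge_orders(tpl), tpl$weights)))
  }
  # Monte-Carlo degree calibration: mean degree per node across draws
  # tracks the template's degrees
  withr::with_seed(99, {
    acc <- numeric(n_nodes(tpl))
    reps <- 500
    for (i in seq_len(reps))
      acc <- acc + node_degrees(random_similar_hypergraph(tpl))
    mean_deg <- acc / reps
  })
  tpl_deg <- node_degrees(tpl)
  on_nodes <- tpl_deg > 0
  expect_lt(max(abs(mean_deg[on_nodes] - tpl_deg[on_nodes]) /
                  tpl_deg[on_nodes]), 0.35)
  expect_equal(sum(mean_deg), sum(tpl_deg), tolerance = 1e-9)
})

test_that("distance permutation test is reproducible and calibrated", {
  tpl <- random_toy_hypergraph(n = 16, m = 12, active = 8, seed = 5)
  moved <- perturb_hypergraph(tpl, "relocate", 0.5, seed = 6)
  r1 <- permutation_test_distance(tpl, moved, "hamming", N = 100, seed = 42)
  r2 <- permutation_test_distance(tpl, moved, "hamming", N = 100, seed = 42)
  expect_equal(r1$p_value, r2$p_value)
  expect_gte(r1$p_value, 0)
  expect_lte(r1$p_value, 1)
  expect_lte(r1$p_value, 0.05)   # gross planted difference is significant
  # a null draw from the generator itself should not look significant
  null_g2 <- random_similar_hypergraph(tpl, seed = 7)
  r0 <- permutation_test_distance(tpl, null_g2, "hamming", N = 100,
                                  seed = 42)
  expect_gte(r0$p_value, 0.05)
})
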