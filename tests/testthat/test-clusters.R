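# hand-built annotation scenario: two 3-way contacts on a 1 Mb chromosome
# r1: loci at 10k, 200k, 400k (all in ATAC peaks, Pol II at the first)
# r2: like r1 but its third locus lies outside any ATAC peak
toy_contacts <- function() {
  as_contacts(data.frame(
    read_id = rep(c("r1", "r2"), each = 3),
    chrom = "chr1",
    start = c(10000, 200000, 400000, 12000, 202000, 600000),
    end = c(11000, 201000, 401000, 13000, 203000, 601000)))
}

toy_annotation <- function(expr = c(g1 = 10, g2 = 5, g3 = 0)) {
  atac <- toy_gr("chr1", c(9000, 199000, 399000, 11500, 201500),
                 c(14000, 204000, 402000, 13500, 203500))
  polii <- toy_gr("chr1", 9500, 11500)
  genes <- toy_gr("chr1", c(10200, 200200, 404500), c(10800, 200800, 405500))
  S4Vectors::mcols(genes)$gene_id <- c("g1", "g2", "g3")
  list(atac = atac, polii = polii, genes = genes, expr = expr)
}

toy_ann <- function(expr = c(g1 = 10, g2 = 5, g3 = 0)) {
  t <- toy_annotation(expr)
  annotate_loci(toy_contacts(), t$atac, t$polii, t$genes, t$expr,
                flank = 5000, expr_threshold = 1,
                chrom_sizes = c(chr1 = 1e6))
}

test_that("locus annotation applies flanks, peaks and gene overlap", {
  ann <- toy_ann()
  expect_true(ann$accessible[1])            # locus inside an ATAC peak
  expect_false(ann$accessible[6])           # r2's third locus is bare
  expect_true(ann$polii[1])
  expect_false(ann$polii[2])
  # gene g3 starts 3.5 kb downstream of locus 3's end: inside the 5 kb flank
  expect_true("g3" %in% ann$genes[[3]])
  expect_false("g3" %in% ann$expressed_genes[[3]])  # expression 0
  # flank clipped at the chromosome start
  expect_equal(ann$flank_start[1], 5000)
  ct0 <- as_contacts(data.frame(read_id = "r0", chrom = "chr1",
                                start = 1000, end = 2000))
  t <- toy_annotation()
  ann0 <- annotate_loci(ct0, t$atac, t$polii, t$genes, t$expr, flank = 5000)
  expect_equal(ann0$flank_start[1], 0)
})

test_that("genes absent from the expression table are unexpressed, once", {
  t <- toy_annotation(expr = c(g1 = 10))
  expect_message(
    ann <- annotate_loci(toy_contacts(), t$atac, t$polii, t$genes, t$expr),
    "absent from the expression table")
  expect_false("g2" %in% unlist(ann$expressed_genes))
})

test_that("potential clusters need full accessibility and some Pol II", {
  ann <- toy_ann()
  pot <- find_potential_clusters(ann)
  expect_equal(pot$read_id, "r1")           # r2 has an inaccessible locus
  expect_equal(pot$status, "potential")
  # remove Pol II -> nothing qualifies
  t <- toy_annotation()
  ann_nopol <- annotate_loci(toy_contacts(), t$atac,
                             toy_gr("chr1", 900000, 900100),
                             t$genes, t$expr, chrom_sizes = c(chr1 = 1e6))
  expect_equal(nrow(find_potential_clusters(ann_nopol)), 0)
})

test_that("common-TF rule: both of two genes, strict majority of three", {
  motif <- matrix(c(5, 3,    # TF_A binds g1 and g2
                    5, 2,    # TF_B misses g2 (2 < 3 sites)
                    0, 0),
                  nrow = 2, ncol = 3,
                  dimnames = list(c("g1", "g2"), c("TF_A", "TF_B", "TF_C")))
  expect_equal(common_tfs_for_genes(c("g1", "g2"), motif), "TF_A")
  # three genes: binding two of three is a strict majority, one is not
  motif3 <- matrix(c(4, 4, 0,
                     4, 0, 0),
                   nrow = 3, ncol = 2,
                   dimnames = list(c("g1", "g2", "g3"), c("TF_A", "TF_B")))
  expect_equal(common_tfs_for_genes(c("g1", "g2", "g3"), motif3), "TF_A")

  ann <- toy_ann()
  pot <- find_potential_clusters(ann)
  cl <- find_clusters(pot, motif)
  expect_equal(cl$read_id, "r1")
  expect_equal(cl$common_tfs[[1]], "TF_A")
  expect_equal(cl$status, "cluster")
  # raising min_sites beyond the counts removes the cluster
  expect_equal(nrow(find_clusters(pot, motif, min_sites = 6)), 0)
})

test_that("specialized clusters require a self-binding common TF", {
  motif <- matrix(c(5, 3, 4,    # TF_A binds g1, g2 and its own gene gA
                    5, 3, 0),
                  nrow = 3, ncol = 2,
                  dimnames = list(c("g1", "g2", "gA"), c("TF_A", "TF_B")))
  map <- c(TF_A = "gA", TF_B = "gB_unknown")
  expect_equal(master_regulators(motif, map), "TF_A")
  cl <- find_clusters(find_potential_clusters(toy_ann()), motif)
  sp <- find_specialized(cl, motif, map)
  expect_equal(sp$common_mrs[[1]], "TF_A")
  # TF without self-binding is no MR; with no mapped gene it never can be
  expect_equal(nrow(find_specialized(cl, motif, c(TF_A = "g3"))), 0)
})

test_that("self-sustaining and core flags follow the TF-gene placement", {
  # cluster r1 holds expressed genes g1 (encoding TF_X) and g2
  motif <- matrix(c(0, 4,     # TF_X binds g2 but not its own gene g1
                    4, 4),    # TF_Y binds both (the common TF)
                  nrow = 2, ncol = 2,
                  dimnames = list(c("g1", "g2"), c("TF_X", "TF_Y")))
  map <- c(TF_X = "g1", TF_Y = "g_elsewhere")
  cl <- find_clusters(find_potential_clusters(toy_ann()), motif)
  ss <- find_self_sustaining(cl, motif, map)
  expect_true(ss$self_sustaining[1])
  expect_false(ss$core[1])              # TF_X lacks self-binding
  # give TF_X self-binding: it becomes an MR and the cluster core
  motif2 <- motif; motif2["g1", "TF_X"] <- 4
  ss2 <- find_self_sustaining(cl, motif2, map)
  expect_true(ss2$core[1])
})

test_that("a TF expressed in one cluster but binding only another is reported", {
  # two separated 2-way contacts, each with two expressed genes
  ct <- as_contacts(data.frame(
    read_id = rep(c("x", "y"), each = 2), chrom = "chr1",
    start = c(10000, 200000, 500000, 700000),
    end = c(11000, 201000, 501000, 701000)))
  atac <- toy_gr("chr1", c(9000, 199000, 499000, 699000),
                 c(12000, 202000, 502000, 702000))
  polii <- toy_gr("chr1", c(9500, 499500), c(11500, 501500))
  genes <- toy_gr("chr1", c(10100, 200100, 500100, 700100),
                  c(10900, 200900, 500900, 700900))
  S4Vectors::mcols(genes)$gene_id <- c("gA", "gB", "gC", "gD")
  expr <- c(gA = 10, gB = 10, gC = 10, gD = 10)
  motif <- matrix(c(0, 0, 4, 4,     # TF_1 (encoded by gA) binds only in y
                    4, 4, 0, 0,     # TF_2 makes x a cluster
                    0, 0, 4, 4),    # TF_3 makes y a cluster
                  nrow = 4, ncol = 3,
                  dimnames = list(c("gA", "gB", "gC", "gD"),
                                  c("TF_1", "TF_2", "TF_3")))
  map <- c(TF_1 = "gA", TF_2 = "g_far1", TF_3 = "g_far2")
  ann <- annotate_loci(ct, atac, polii, genes, expr,
                       chrom_sizes = c(chr1 = 1e6))
  cl <- find_clusters(find_potential_clusters(ann), motif)
  expect_equal(sort(cl$read_id), c("x", "y"))
  ss <- find_self_sustaining(cl, motif, map)
  expect_false(any(ss$self_sustaining))
  ai <- attr(ss, "analog_independent")
  expect_equal(ai$tf, "TF_1")
  expect_equal(ai$expressed_in, "x")
  expect_equal(ai$binds_in, "y")
})

test_that("TF ranking frequencies and top-k overlap", {
  clusters <- data.frame(read_id = c("a", "b", "c", "d"))
  clusters$expressed_genes <- I(list("g1", "g2", "g1", "g3"))
  motif <- matrix(c(4, 0, 0,
                    4, 4, 4),
                  nrow = 3, ncol = 2,
                  dimnames = list(c("g1", "g2", "g3"), c("TF_A", "TF_B")))
  rk <- rank_tfs(clusters, motif)
  expect_equal(rk$frequency[rk$tf == "TF_A"], 0.5)   # binds in 2 of 4
  expect_equal(rk$tf[1], "TF_B")
  expect_equal(tf_overlap(rk, rk, k = 2), 1)
  rk2 <- data.frame(tf = c("TF_X", "TF_Y"), frequency = c(1, 1))
  expect_equal(tf_overlap(rk, rk2, k = 2), 0)
})

test_that("tier containment and threshold monotonicity hold on noisy data", {
  cfg <- sim_config(seed = 21, n_reads = 300, n_clusters = 6,
                    background_peak_density = 10,
                    background_gene_density = 20,
                    background_motif_rate = 0.2)
  study <- simulate_study(cfg)
  pipe <- run_cluster_pipeline(study)
  expect_true(all(pipe$clusters$read_id %in% pipe$potential$read_id))
  expect_true(all(pipe$specialized$read_id %in% pipe$clusters$read_id))
  cl <- pipe$classified
  expect_true(all(cl$read_id[cl$core] %in% cl$read_id[cl$self_sustaining]))
  # stricter thresholds can only shrink each tier
  stricter <- run_cluster_pipeline(study, expr_threshold = 20, min_sites = 5)
  expect_lte(nrow(stricter$potential), nrow(pipe$potential))
  expect_lte(nrow(stricter$clusters), nrow(pipe$clusters))
  expect_lte(nrow(stricter$specialized), nrow(pipe$specialized))
})

test_that("binding enrichment flags planted peak placement", {
  cfg <- sim_config(seed = 31, n_reads = 200, n_clusters = 6)
  study <- simulate_study(cfg)
  pipe <- run_cluster_pipeline(study)
  enr <- binding_enrichment(pipe$potential, pipe$ann, study$ctcf,
                            N = 200, seed = 1, factor_name = "ctcf")
  expect_equal(enr$observed, 1)            # CTCF placed at planted loci only
  expect_lte(enr$p_value, 0.01)
  # peaks covering the whole genome: both fractions 1, p = 1
  genome <- toy_gr(names(cfg$chrom_sizes), rep(0, 3), cfg$chrom_sizes)
  enr2 <- binding_enrichment(pipe$potential, pipe$ann, genome,
                             N = 50, seed = 1)
  expect_equal(enr2$observed, 1)
  expect_equal(enr2$background_mean, 1)
  expect_equal(enr2$p_value, 1)
  # no peaks at all: both fractions zero
  enr3 <- binding_enrichment(pipe$potential, pipe$ann, GenomicRanges::GRanges(),
                             N = 50, seed = 1)
  expect_equal(enr3$observed, 0)
  expect_equal(enr3$background_mean, 0)
})

test_that("cluster permutation test separates planted from random contacts", {
  cfg <- sim_config(seed = 41, n_reads = 400, n_clusters = 8)
  study <- simulate_study(cfg)
  pipe <- run_cluster_pipeline(study)
  perm <- permutation_test_clusters(pipe$ann, pipe$potential, study$motif,
                                    study$tf_gene_map, N = 200, seed = 2)
  expect_true(all(perm$p_value >= 0 & perm$p_value <= 1))
  pooled <- perm[perm$order_class == "all", ]
  expect_equal(nrow(pooled), 4)
  expect_true(all(pooled$p_value <= 0.01))
  # reproducibility under a fixed seed
  perm2 <- permutation_test_clusters(pipe$ann, pipe$potential, study$motif,
                                     study$tf_gene_map, N = 200, seed = 2)
  expect_identical(perm, perm2)
})
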