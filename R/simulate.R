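#' Simulation configuration
#'
#' Defines the synthetic study conditions: a small multi-chromosome
#' genome, a contact-order distribution that decays from pairwise to
#' 6-way (qualitatively matching observed Pore-C order frequencies), a
#' majority of intra-chromosomal contacts, and a set of planted
#' transcription clusters whose annotations are constructed to satisfy a
#' chosen classification tier exactly. Background annotation noise
#' (peaks, genes, expressed genes, motif entries) is controlled by rate
#' parameters; at rate 0 background contacts satisfy no cluster
#' criterion, by construction.
#'
#' @param seed Integer seed; every downstream draw is deterministic in it.
#' @param chrom_sizes Named chromosome lengths (default three 2 Mb
#'   chromosomes).
#' @param n_reads Number of background reads (default 1000).
#' @param order_probs Named probabilities for monomer counts 2..6
#'   (must sum to 1).
#' @param intra_prob Probability a background read is intra-chromosomal
#'   (default 0.7).
#' @param n_clusters Number of planted transcription clusters (default 8).
#' @param cluster_order_range Range of planted contact orders
#'   (default c(3, 5)).
#' @param reads_per_cluster Reads emitted per planted cluster (default 3).
#' @param genes_per_cluster Expressed genes per planted (non-"potential")
#'   cluster, >= 2 (default 2).
#' @param tfs_per_cluster Shared TFs per planted cluster (default 1).
#' @param cluster_tiers Tier labels recycled over clusters; each in
#'   `c("potential", "cluster", "specialized", "self_sustaining", "core")`.
#' @param monomer_length Aligned fragment length in bp (default 1000).
#' @param expr_level Expression value assigned to planted genes
#'   (default 10, TPM scale).
#' @param background_peak_density Background peaks per Mb for each peak
#'   set (default 0).
#' @param background_gene_density Background genes per Mb (default 0).
#' @param background_expressed_fraction Fraction of background genes
#'   expressed (default 0.5).
#' @param background_motif_rate Probability a background gene x TF entry
#'   meets the binding threshold (default 0.05).
#' @param n_background_tfs Number of background TF columns (default 5).
#' @param flank Flank used to size exclusion zones so background reads
#'   cannot borrow planted signal (default 5000, matching the annotation
#'   default).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       chrom_sizes = c(chr1 = 2e6, chr2 = 2e6, chr3 = 2e6),
                       n_reads = 1000,
                       order_probs = c("2" = 0.45, "3" = 0.25, "4" = 0.15,
                                       "5" = 0.10, "6" = 0.05),
                       intra_prob = 0.7,
                       n_clusters = 8,
                       cluster_order_range = c(3, 5),
                       reads_per_cluster = 3,
                       genes_per_cluster = 2,
                       tfs_per_cluster = 1,
                       cluster_tiers = c("cluster", "specialized",
                                         "self_sustaining", "core",
                                         "potential"),
                       monomer_length = 1000,
                       expr_level = 10,
                       background_peak_density = 0,
                       background_gene_density = 0,
                       background_expressed_fraction = 0.5,
                       background_motif_rate = 0.05,
                       n_background_tfs = 5,
                       flank = 5000) {
  stopifnot(abs(sum(order_probs) - 1) < 1e-8,
            all(order_probs >= 0),
            n_reads >= 0, n_clusters >= 0, reads_per_cluster >= 1,
            genes_per_cluster >= 2, tfs_per_cluster >= 1,
            cluster_order_range[1] >= 2,
            cluster_order_range[1] <= cluster_order_range[2],
            genes_per_cluster <= cluster_order_range[1],
            all(cluster_tiers %in% c("potential", "cluster", "specialized",
                                     "self_sustaining", "core")))
  structure(as.list(environment()), class = "sim_config")
}

# bp reserved at each chromosome start for the distant TF-encoding genes
# of "cluster"/"specialized" tiers; planted loci and background monomers
# are kept out of it so those genes can never pick up cluster signal
.reserved_bp <- function(config) {
  3000 * (config$n_clusters * config$tfs_per_cluster + 2) + 1000
}

# does interval [s, e) on chrom hit any exclusion zone?
.in_zone <- function(zones, chrom, s, e) {
  if (is.null(zones) || nrow(zones) == 0) return(FALSE)
  z <- zones[zones$chrom == chrom, , drop = FALSE]
  any(s < z$end & e > z$start)
}

# uniform monomer on a chromosome avoiding exclusion zones
.draw_monomer <- function(chrom, len, L, zones, max_tries = 200) {
  for (i in seq_len(max_tries)) {
    s <- floor(runif(1, 0, len - L))
    if (!.in_zone(zones, chrom, s - 0, s + L)) return(c(s, s + L))
  }
  stop("could not place a background monomer outside planted zones; ",
       "genome too crowded")
}

#' Simulate multi-way contacts with planted clusters
#'
#' Plants `n_clusters` multi-way contacts (each a fixed set of loci, one
#' tier label per cluster recycled from `cluster_tiers`) and draws
#' `n_reads` background reads with the configured order distribution and
#' intra/inter-chromosomal mix. Background monomers are rejected from the
#' flanked neighbourhoods of planted loci, so background reads can pick
#' up planted annotation signal only through the explicit background
#' noise rates.
#'
#' @param config A [sim_config()].
#' @return List with `contacts` (a `contacts` data frame), `truth`
#'   (read_id, cluster_id, tier for planted reads), `cluster_loci`
#'   (cluster_id, tier, locus_index, chrom, start, end) and `config`.
#' @export
simulate_contacts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cs <- config$chrom_sizes
  L <- config$monomer_length
  with_seed(config$seed, {
    tiers <- rep_len(config$cluster_tiers, max(config$n_clusters, 1))
    # plant cluster loci first; keep them mutually separated and out of
    # the reserved region that hosts distant TF-encoding genes
    zones <- data.frame(chrom = names(cs), start = 0,
                        end = .reserved_bp(config))
    cluster_loci <- list()
    order_choices <- seq(config$cluster_order_range[1],
                         config$cluster_order_range[2])
    for (c in seq_len(config$n_clusters)) {
      k <- order_choices[sample.int(length(order_choices), 1)]
      chroms <- sample(names(cs), k, replace = TRUE)
      for (j in seq_len(k)) {
        pos <- .draw_monomer(chroms[j], cs[[chroms[j]]], L, zones)
        zones <- rbind(zones, data.frame(
          chrom = chroms[j], start = pos[1] - config$flank - L,
          end = pos[2] + config$flank + L))
        cluster_loci[[length(cluster_loci) + 1]] <- data.frame(
          cluster_id = c, tier = tiers[c], locus_index = j,
          chrom = chroms[j], start = pos[1], end = pos[2])
      }
    }
    cluster_loci <- if (length(cluster_loci) > 0) do.call(rbind, cluster_loci)
      else data.frame(cluster_id = integer(0), tier = character(0),
                      locus_index = integer(0), chrom = character(0),
                      start = numeric(0), end = numeric(0))
    # background reads
    orders <- as.integer(sample(names(config$order_probs), config$n_reads,
                                replace = TRUE, prob = config$order_probs))
    rows <- vector("list", config$n_reads)
    for (i in seq_len(config$n_reads)) {
      k <- orders[i]
      intra <- runif(1) < config$intra_prob
      chroms <- if (intra)
        rep(sample(names(cs), 1, prob = cs / sum(cs)), k)
      else sample(names(cs), k, replace = TRUE, prob = cs / sum(cs))
      mono <- t(vapply(chroms, function(ch)
        .draw_monomer(ch, cs[[ch]], L, zones), c(0, 0)))
      rows[[i]] <- data.frame(read_id = sprintf("read_%05d", i),
                              chrom = chroms, start = mono[, 1],
                              end = mono[, 2])
    }
    # planted reads hit the planted loci exactly
    truth <- list()
    for (c in seq_len(config$n_clusters)) {
      loci <- cluster_loci[cluster_loci$cluster_id == c, , drop = FALSE]
      for (r in seq_len(config$reads_per_cluster)) {
        id <- sprintf("planted_c%02d_r%02d", c, r)
        rows[[length(rows) + 1]] <- data.frame(
          read_id = id, chrom = loci$chrom, start = loci$start,
          end = loci$end)
        truth[[length(truth) + 1]] <- data.frame(
          read_id = id, cluster_id = c, tier = tiers[c])
      }
    }
    contacts <- as_contacts(do.call(rbind, rows))
    truth <- if (length(truth) > 0) do.call(rbind, truth)
      else data.frame(read_id = character(0), cluster_id = integer(0),
                      tier = character(0))
    rownames(contacts) <- rownames(truth) <- NULL
    list(contacts = contacts, truth = truth, cluster_loci = cluster_loci,
         config = config)
  })
}

# expected classification flags implied by a tier label
tier_flags <- function(tier) {
  data.frame(
    tier = tier,
    is_potential = TRUE,
    is_cluster = tier %in% c("cluster", "specialized", "self_sustaining",
                             "core"),
    is_specialized = tier %in% c("specialized", "core"),
    is_self_sustaining = tier %in% c("self_sustaining", "core"),
    is_core = tier == "core")
}

#' Simulate annotation inputs for a contact simulation
#'
#' Constructs every annotation input the transcription-cluster pipeline
#' consumes so that each planted cluster satisfies exactly the criteria
#' of its tier: accessibility peaks at every planted locus, an RNA Pol II
#' peak at each cluster's first locus, expressed genes at planted loci,
#' shared TFs with four motif sites at the relevant genes, self-binding
#' (master-regulator) sites for "specialized"/"core" tiers, and
#' TF-encoding genes placed inside the cluster for
#' "self_sustaining"/"core" tiers. CTCF and enhancer peaks are placed at
#' planted loci (for enrichment testing). Background peaks, genes,
#' expression and motif entries are added at the configured noise rates.
#'
#' @param sim Output of [simulate_contacts()].
#' @return List with `atac`, `polii`, `ctcf`, `enhancers` (GRanges),
#'   `genes` (GRanges with `gene_id`), `expression` (named numeric),
#'   `motif` (matrix), `tf_gene_map` (named character), `cluster_truth`
#'   (expected flags per planted cluster).
#' @export
simulate_annotations <- function(sim) {
  config <- sim$config
  cs <- config$chrom_sizes
  with_seed(config$seed + 1L, {
    cl <- sim$cluster_loci
    clusters <- unique(cl$cluster_id)
    peaks <- list(atac = list(), polii = list(), ctcf = list(),
                  enhancers = list())
    gene_rows <- list()
    expression <- numeric(0)
    motif_entries <- list()   # (gene, tf, count)
    tf_gene_map <- character(0)
    truth_rows <- list()
    add_peak <- function(set, chrom, s, e)
      peaks[[set]][[length(peaks[[set]]) + 1]] <<-
        data.frame(chrom = chrom, start = s, end = e)
    add_gene <- function(id, chrom, s, e, expr) {
      gene_rows[[length(gene_rows) + 1]] <<-
        data.frame(gene_id = id, chrom = chrom, start = s, end = e)
      expression[id] <<- expr
    }
    add_motif <- function(gene, tf, count)
      motif_entries[[length(motif_entries) + 1]] <<-
        data.frame(gene = gene, tf = tf, count = count)
    for (c in clusters) {
      loci <- cl[cl$cluster_id == c, , drop = FALSE]
      tier <- loci$tier[1]
      truth_rows[[length(truth_rows) + 1]] <- cbind(
        data.frame(cluster_id = c), tier_flags(tier))
      for (j in seq_len(nrow(loci)))
        add_peak("atac", loci$chrom[j], loci$start[j], loci$end[j])
      add_peak("polii", loci$chrom[1], loci$start[1], loci$end[1])
      for (j in seq_len(nrow(loci))) {
        add_peak("ctcf", loci$chrom[j], loci$start[j], loci$end[j])
        add_peak("enhancers", loci$chrom[j], loci$start[j], loci$end[j])
      }
      if (tier == "potential") {
        # a single expressed gene: accessible + Pol II but never >= 2 genes
        add_gene(sprintf("g_c%02d_1", c), loci$chrom[1], loci$start[1],
                 loci$end[1], config$expr_level)
        next
      }
      g_ids <- sprintf("g_c%02d_%d", c, seq_len(config$genes_per_cluster))
      for (j in seq_along(g_ids))
        add_gene(g_ids[j], loci$chrom[j], loci$start[j], loci$end[j],
                 config$expr_level)
      for (t in seq_len(config$tfs_per_cluster)) {
        tf <- sprintf("TF_c%02d_%d", c, t)
        if (tier %in% c("cluster", "specialized")) {
          # shared TF binds every cluster gene; its own gene sits far away
          for (g in g_ids) add_motif(g, tf, 4)
          own <- sprintf("g_tf_c%02d_%d", c, t)
          slot <- (c * config$tfs_per_cluster + t) %% length(cs) + 1
          pos <- 1000 + 3000 * (c * config$tfs_per_cluster + t)
          add_gene(own, names(cs)[slot], pos, pos + 2000, 0)
          tf_gene_map[tf] <- own
          if (tier == "specialized") add_motif(own, tf, 5)  # MR: self-binding
        } else {
          # self_sustaining / core: the TF's encoding gene is cluster gene 1
          tf_gene_map[tf] <- g_ids[1]
          if (tier == "core") {
            for (g in g_ids) add_motif(g, tf, 4)  # incl. self -> MR, common
          } else {
            for (g in g_ids[-1]) add_motif(g, tf, 4)  # binds in-cluster, no self
            # a second, non-MR TF carries the common-TF requirement
            tf2 <- sprintf("TF_c%02d_%d_aux", c, t)
            for (g in g_ids) add_motif(g, tf2, 4)
            own2 <- sprintf("g_tf_c%02d_%d_aux", c, t)
            pos <- 500 + 3000 * (c * config$tfs_per_cluster + t)
            slot <- (c * config$tfs_per_cluster + t + 1) %% length(cs) + 1
            add_gene(own2, names(cs)[slot], pos, pos + 1500, 0)
            tf_gene_map[tf2] <- own2
          }
        }
      }
    }
    # background noise
    for (set in names(peaks)) {
      if (config$background_peak_density > 0) {
        for (ch in names(cs)) {
          npk <- rpois(1, config$background_peak_density * cs[[ch]] / 1e6)
          if (npk > 0) {
            s <- floor(runif(npk, 0, cs[[ch]] - 1000))
            for (x in s) add_peak(set, ch, x, x + 1000)
          }
        }
      }
    }
    bg_genes <- character(0)
    if (config$background_gene_density > 0) {
      for (ch in names(cs)) {
        ng <- rpois(1, config$background_gene_density * cs[[ch]] / 1e6)
        if (ng > 0) {
          s <- floor(runif(ng, 0, cs[[ch]] - 2000))
          for (x in s) {
            id <- sprintf("g_bg_%04d", length(bg_genes) + 1)
            bg_genes <- c(bg_genes, id)
            expr <- if (runif(1) < config$background_expressed_fraction)
              config$expr_level / 2 else 0
            add_gene(id, ch, x, x + 2000, expr)
          }
        }
      }
    }
    bg_tfs <- if (config$n_background_tfs > 0)
      sprintf("TF_bg_%02d", seq_len(config$n_background_tfs)) else character(0)
    if (length(bg_tfs) > 0 && length(bg_genes) > 0 &&
        config$background_motif_rate > 0) {
      for (g in bg_genes) for (tf in bg_tfs)
        if (runif(1) < config$background_motif_rate) add_motif(g, tf, 3)
    }
    genes_df <- if (length(gene_rows) > 0) do.call(rbind, gene_rows)
      else data.frame(gene_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0))
    genes <- GRanges(genes_df$chrom,
                     IRanges(genes_df$start + 1, genes_df$end),
                     strand = "+")
    mcols(genes)$name <- mcols(genes)$gene_id <- genes_df$gene_id
    mcols(genes)$score <- 0
    to_gr <- function(lst) {
      if (length(lst) == 0) return(GRanges())
      df <- do.call(rbind, lst)
      gr <- GRanges(df$chrom, IRanges(df$start + 1, df$end))
      mcols(gr)$name <- sprintf("peak_%d", seq_along(gr))
      mcols(gr)$score <- 0
      gr
    }
    all_tfs <- unique(c(names(tf_gene_map), bg_tfs))
    motif <- matrix(0, nrow = length(genes_df$gene_id),
                    ncol = length(all_tfs),
                    dimnames = list(genes_df$gene_id, all_tfs))
    for (en in motif_entries) motif[en$gene, en$tf] <- en$count
    truth <- if (length(truth_rows) > 0) do.call(rbind, truth_rows)
      else cbind(data.frame(cluster_id = integer(0)),
                 tier_flags(character(0)))
    rownames(truth) <- NULL
    list(atac = to_gr(peaks$atac), polii = to_gr(peaks$polii),
         ctcf = to_gr(peaks$ctcf), enhancers = to_gr(peaks$enhancers),
         genes = genes, expression = expression, motif = motif,
         tf_gene_map = tf_gene_map, cluster_truth = truth)
  })
}

#' One-call simulation of a full synthetic study
#'
#' @param config A [sim_config()].
#' @return The union of [simulate_contacts()] and
#'   [simulate_annotations()] outputs.
#' @export
simulate_study <- function(config) {
  sim <- simulate_contacts(config)
  c(sim, simulate_annotations(sim))
}

#' Write a simulated study to disk in the interchange dialects
#'
#' @param study Output of [simulate_study()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly. Files: contacts.tsv, truth.tsv,
#'   chrom_sizes.tsv, atac.bed, polii.bed, ctcf.bed, enhancers.bed,
#'   genes.bed, expression.tsv, motifs.tsv, tf_gene_map.tsv,
#'   cluster_truth.tsv.
#' @export
write_simulation <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_contacts(study$contacts, p("contacts.tsv"))
  write.table(study$truth, p("truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(study$cluster_truth, p("cluster_truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_chrom_sizes(study$config$chrom_sizes, p("chrom_sizes.tsv"))
  write_bed(study$atac, p("atac.bed"))
  write_bed(study$polii, p("polii.bed"))
  write_bed(study$ctcf, p("ctcf.bed"))
  write_bed(study$enhancers, p("enhancers.bed"))
  write_bed(study$genes, p("genes.bed"))
  write_expression(study$expression, p("expression.tsv"))
  write_motif_table(study$motif, p("motifs.tsv"))
  write_tf_gene_map(study$tf_gene_map, p("tf_gene_map.tsv"))
  invisible(dir)
}

#' Perturb a hypergraph for distance calibration
#'
#' Two perturbation modes producing hypergraph pairs with a known degree
#' of structural difference: `"relocate"` moves a fraction `strength` of
#' hyperedges to a disjoint node block (indices shifted by half the node
#' count, modulo n); `"rewire"` replaces each node membership with a
#' uniformly random other node with probability `strength`. Strength 0 is
#' the identity in both modes.
#'
#' @param g A [hypergraph].
#' @param mode `"relocate"` or `"rewire"`.
#' @param strength Fraction in [0, 1].
#' @param seed Optional integer seed.
#' @return A perturbed [hypergraph] over the same node universe.
#' @export
perturb_hypergraph <- function(g, mode = c("relocate", "rewire"),
                               strength, seed = NULL) {
  mode <- match.arg(mode)
  if (!(strength >= 0 && strength <= 1))
    stop("strength must lie in [0, 1]")
  if (strength == 0) return(g)
  n <- n_nodes(g)
  with_seed(seed, {
    edges <- g$edges
    if (mode == "relocate") {
      m <- length(edges)
      k <- round(strength * m)
      move <- if (k > 0) sample(seq_len(m), k) else integer(0)
      shift <- floor(n / 2)
      edges[move] <- lapply(edges[move], function(e)
        sort(unique((e - 1L + shift) %% n + 1L)))
    } else {
      edges <- lapply(edges, function(e) {
        flip <- runif(length(e)) < strength
        for (i in which(flip)) {
          cand <- setdiff(seq_len(n), e)
          if (length(cand) > 0) e[i] <- sample(cand, 1)
        }
        sort(unique(e))
      })
    }
    new_hypergraph(g$nodes, edges, g$weights, g$resolution, g$chrom_sizes)
  })
}
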