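# Composite cluster distance, family building, cutoff sweep, dereplication.

make_profiled_pair <- function(sim, i, j) {
  clusters <- clusters_from_truth(sim)
  list(A = cluster_domain_profile(clusters[i, ],
                                  sim$genomes[[clusters$genome_id[i]]],
                                  sim$hits[sim$hits$genome_id == clusters$genome_id[i], ]),
       B = cluster_domain_profile(clusters[j, ],
                                  sim$genomes[[clusters$genome_id[j]]],
                                  sim$hits[sim$hits$genome_id == clusters$genome_id[j], ]))
}

test_that("distance components behave at the extremes and satisfy the weight identity", {
  cfg <- sim_config(n_species = 2, genes_per_genome = 100, n_busco_like = 5,
                    templates = default_templates(2), mu = 0.05, seed = 17)
  sim <- simulate_dataset(cfg)
  pp <- make_profiled_pair(sim, 1, 1)
  self <- cluster_distance(pp$A, pp$B)
  expect_equal(self$J, 1)
  expect_equal(self$DSS, 1)
  expect_equal(self$AI, 1)
  expect_equal(self$d, 0)

  w <- distance_weights()
  pp2 <- make_profiled_pair(sim, 1, 2)  # different templates, same genome
  rec <- cluster_distance(pp2$A, pp2$B, w)
  expect_equal(rec$d, 1 - (w$wJ * rec$J + w$wD * rec$DSS + w$wA * rec$AI))
  expect_true(rec$d >= 0 && rec$d <= 1)

  # disjoint domain-type sets give the maximal distance
  g <- toy_genome(4, genome_id = "dg")
  mk <- function(id, genes, accs) {
    cl <- data.frame(genome_id = "dg", cluster_id = id, contig_id = "c1",
                     anchor_gene = genes[1],
                     start_ordinal = min(match(genes, g$genes$gene_id)) - 1,
                     end_ordinal = max(match(genes, g$genes$gene_id)) - 1,
                     stringsAsFactors = FALSE)
    hits <- do.call(rbind, Map(hit_row, genes, accs))
    cluster_domain_profile(cl, g, hits)
  }
  a <- mk("dg.a", c("dg_g1", "dg_g2"), c("PF00001", "PF00002"))
  b <- mk("dg.b", c("dg_g3", "dg_g4"), c("PF00003", "PF00004"))
  expect_equal(cluster_distance(a, b)$d, 1)
})

test_that("DSS divides greedily paired copy identities by the larger copy number", {
  g <- toy_genome(3, genome_id = "cp",
                  proteins = c(cp_g1 = strrep("MKLV", 20),
                               cp_g2 = strrep("MKLV", 20),
                               cp_g3 = strrep("MKLV", 20)))
  mk <- function(id, genes, accs) {
    cl <- data.frame(genome_id = "cp", cluster_id = id, contig_id = "c1",
                     anchor_gene = genes[1],
                     start_ordinal = min(match(genes, g$genes$gene_id)) - 1,
                     end_ordinal = max(match(genes, g$genes$gene_id)) - 1,
                     stringsAsFactors = FALSE)
    hits <- do.call(rbind, Map(hit_row, genes, accs,
                               MoreArgs = list(env_start = 1, env_end = 80)))
    cluster_domain_profile(cl, g, hits)
  }
  # type X: 2 identical copies in A, 1 in B -> best pair identity 1, s = 1/2
  A <- mk("cp.a", c("cp_g1", "cp_g2"), c("PFX", "PFX"))
  B <- mk("cp.b", "cp_g3", "PFX")
  rec <- cluster_distance(A, B, distance_weights(anchor_domains = character()))
  expect_equal(rec$DSS, 0.5)
})

test_that("family building matches the hand transitive closure and sweeps are nested", {
  clusters <- data.frame(cluster_id = c("c1", "c2", "c3"),
                         genome_id = "g", species = c("s1", "s2", "s3"),
                         stringsAsFactors = FALSE)
  distances <- data.frame(a = c("c1", "c2", "c1"), b = c("c2", "c3", "c3"),
                          J = 0, DSS = 0, AI = 0, d = c(0.1, 0.25, 0.6),
                          stringsAsFactors = FALSE)
  fam3 <- build_families(clusters, distances, 0.3)
  expect_equal(length(fam3$families), 1)
  expect_setequal(fam3$families[[1]], c("c1", "c2", "c3"))

  fam2 <- build_families(clusters, distances, 0.2)
  expect_equal(sort(lengths(fam2$families), decreasing = TRUE), c(2, 1),
               ignore_attr = TRUE)
  expect_setequal(fam2$families[["GCF_001"]], c("c1", "c2"))

  fam0 <- build_families(clusters, distances, 0.05)
  expect_equal(length(fam0$families), 3)  # no edges -> all singletons

  sw <- sweep_cutoffs(clusters, distances)
  expect_equal(nrow(sw$curve), 13)
  expect_true(all(diff(sw$curve$n_families) <= 0))
  expect_equal(sw$curve$n_families[sw$curve$cutoff >= 0.6], c(1, 1, 1, 1, 1))
  # merge events recorded where counts drop
  expect_true(any(sw$merges$cutoff_to == 0.25))
})

test_that("species representatives follow the contig / length / id tie-break", {
  mk <- function(id, sp, n_contigs, clen) {
    contigs <- stats::setNames(
      vapply(seq_len(n_contigs), function(i) strrep("ACGT", clen), character(1)),
      paste0(id, "_c", seq_len(n_contigs)))
    genes <- data.frame(gene_id = paste0(id, "_g1"),
                        contig_id = names(contigs)[1],
                        start = 0, end = 10, strand = "+",
                        stringsAsFactors = FALSE)
    genome_record(id, contigs, genes, species = sp)
  }
  genomes <- list(a = mk("a", "sp1", 50, 100), b = mk("b", "sp1", 10, 100),
                  c = mk("c", "sp2", 5, 100), d = mk("d", "sp2", 5, 200),
                  e = mk("e", "sp3", 2, 100), f = mk("f", "sp3", 2, 100))
  reps <- dereplicate_species(genomes)
  expect_equal(unname(reps["sp1"]), "b")  # fewest contigs
  expect_equal(unname(reps["sp2"]), "d")  # larger assembly
  expect_equal(unname(reps["sp3"]), "e")  # lexicographic
})
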