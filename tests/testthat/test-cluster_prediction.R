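# Promoter extraction, motif background, binomial enrichment and cluster
# border prediction.

test_that("promoter extraction truncates at neighbours, contig ends and gene length", {
  # genes 400 bp apart (gap = 400), default L_up = 1000, L_down = 50
  g <- toy_genome(3, gap = 400, gene_len = 600)
  pr <- extract_promoters(g)
  # first gene: 400 bp upstream available (contig starts at 0 with gap bp)
  expect_equal(pr["g1_g1", "end"] - pr["g1_g1", "start"], 400 + 50)
  # interior gene: truncated at the upstream neighbour boundary
  expect_equal(pr["g1_g2", "end"] - pr["g1_g2", "start"], 400 + 50)

  # isolated first gene with > L_up upstream: capped at L_up + L_down
  g2 <- toy_genome(2, gap = 2000)
  pr2 <- extract_promoters(g2)
  expect_equal(pr2["g1_g1", "end"] - pr2["g1_g1", "start"], 1000 + 50,
               ignore_attr = TRUE)
})

test_that("divergent pairs share the full intergenic region", {
  g <- toy_genome(2, gap = 400, strands = c("-", "+"))
  pr <- extract_promoters(g)
  expect_equal(pr["g1_g1", "shared"], "g1_g2", ignore_attr = TRUE)
  expect_equal(pr["g1_g2", "shared"], "g1_g1", ignore_attr = TRUE)
  gap_start <- g$genes["g1_g1", "end"]
  gap_end <- g$genes["g1_g2", "start"]
  gap_seq <- substr(g$contigs[["c1"]], gap_start + 1, gap_end)
  # plus-strand promoter contains the gap verbatim; minus-strand promoter
  # contains its reverse complement
  expect_true(grepl(gap_seq, pr["g1_g2", "seq"], fixed = TRUE))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(gap_seq)))
  expect_true(grepl(rc, pr["g1_g1", "seq"], fixed = TRUE))
})

test_that("motif background counts canonical k-mers per promoter", {
  promoters <- data.frame(
    gene_id = paste0("p", 1:4), contig_id = "c", start = 0, end = 10,
    strand = "+", shared = NA,
    seq = c("AAAACGTTTTTT",            # contains AAAACGTT
            "AAAACGTTTTTT",
            "AAACGTTTTCCC",            # contains the revcomp -> still counts
            "GGGGGGGGGGGG"),
    stringsAsFactors = FALSE)
  bg <- compute_motif_background(promoters, predictor_config(k = 8))
  m <- canonical_motif("AAAACGTT")
  expect_equal(unname(bg[m]), 3 / 4)
  expect_true(all(bg > 0 & bg <= 1))
})

test_that("score_candidate is the exact binomial upper tail", {
  expect_equal(score_candidate(5, 5, 0.1), 1e-5)
  expect_equal(score_candidate(4, 0, 0.3), 1.0)
  # frozen value from direct pmf summation: sum_{x=3}^{6} C(6,x) .2^x .8^(6-x)
  expect_equal(score_candidate(6, 3, 0.2), 0.09888, tolerance = 1e-4)
  expect_error(score_candidate(5, 2, 0), "p0")
  expect_error(score_candidate(5, 2, 1), "p0")
  # non-increasing in m, equal to 1 at m = 0
  for (p0 in c(0.02, 0.3)) {
    p <- score_candidate(rep(10, 11), 0:10, p0)
    expect_equal(p[1], 1)
    expect_true(all(diff(p) <= 1e-15))
  }
})

test_that("predict_cluster recovers planted spans and rejects random anchors", {
  cfg <- sim_config(n_species = 1, genes_per_genome = 200, n_busco_like = 10,
                    templates = default_templates(3), mu = 0.02, seed = 7)
  sim <- simulate_dataset(cfg)
  g <- sim$genomes[[1]]
  anchors <- find_ics_anchors(g, sim$hits)
  cl <- predict_all_clusters(g, anchors)
  tr <- sim$truth$clusters
  for (i in seq_len(nrow(tr))) {
    p <- cl[cl$anchor_gene == tr$anchor_gene[i], ]
    expect_true(p$is_bgc)
    expect_equal(p$start_ordinal, tr$start_ordinal[i])
    expect_equal(p$end_ordinal, tr$end_ordinal[i])
    expect_equal(p$motif, canonical_motif(tr$motif[i]))
  }
  # ranges always contain the anchor
  expect_true(all(cl$start_ordinal <= cl$anchor_ordinal &
                    cl$anchor_ordinal <= cl$end_ordinal))

  # random non-cluster gene as pseudo-anchor: no enriched motif
  members <- unlist(strsplit(tr$gene_ids, ","))
  pr <- extract_promoters(g)
  bg <- compute_motif_background(pr)
  set.seed(42)
  neg <- sample(setdiff(g$genes$gene_id, members), 8)
  calls <- vapply(neg, function(id)
    predict_cluster(g, id, promoters = pr, background = bg)$is_bgc, logical(1))
  expect_lt(mean(calls), 0.5)
})

test_that("prediction is deterministic for fixed input", {
  cfg <- sim_config(n_species = 1, genes_per_genome = 120, n_busco_like = 5,
                    templates = default_templates(2), mu = 0.02, seed = 13)
  sim <- simulate_dataset(cfg)
  g <- sim$genomes[[1]]
  anchors <- find_ics_anchors(g, sim$hits)
  expect_identical(predict_all_clusters(g, anchors),
                   predict_all_clusters(g, anchors))
})
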