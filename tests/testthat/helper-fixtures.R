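# Shared fixture builders for the test suite. All randomness is seeded inside
# the generator configs; helpers themselves are deterministic.

canonical_motif <- function(m) {
  pmin(m, as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(m))))
}

# cluster-table rows built from the generator's truth table (used to feed the
# GCF / LD / core modules independently of the border predictor)
clusters_from_truth <- function(sim) {
  tr <- sim$truth$clusters
  ords <- vapply(seq_len(nrow(tr)), function(i) {
    sim$genomes[[tr$genome_id[i]]]$genes[tr$anchor_gene[i], "ordinal"]
  }, numeric(1))
  data.frame(genome_id = tr$genome_id,
             cluster_id = paste0(tr$genome_id, ".", tr$anchor_gene),
             contig_id = tr$contig_id, anchor_gene = tr$anchor_gene,
             anchor_ordinal = ords,
             start_ordinal = tr$start_ordinal, end_ordinal = tr$end_ordinal,
             n_genes = tr$n_genes, species = tr$species, is_bgc = TRUE,
             stringsAsFactors = FALSE)
}

og_from_truth <- function(sim) {
  structure(list(og = sim$truth$orthogroups, provenance = "ingested"),
            class = "orthogroup_map")
}

template_partition <- function(sim) {
  tr <- sim$truth$clusters
  stats::setNames(tr$template_id, paste0(tr$genome_id, ".", tr$anchor_gene))
}

# deterministic toy genome: equally spaced genes on one contig
toy_genome <- function(n_genes = 6, genome_id = "g1", species = genome_id,
                       strands = rep("+", n_genes), gene_len = 600,
                       gap = 400, proteins = NULL, dna_seed = 1) {
  starts <- seq(gap, by = gene_len + gap, length.out = n_genes)
  genes <- data.frame(gene_id = sprintf("%s_g%d", genome_id, seq_len(n_genes)),
                      contig_id = "c1", start = starts, end = starts + gene_len,
                      strand = strands, stringsAsFactors = FALSE)
  contig_len <- max(genes$end) + gap
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(dna_seed)
  contig <- paste(sample(c("A", "C", "G", "T"), contig_len, replace = TRUE),
                  collapse = "")
  if (is.null(proteins)) {
    proteins <- stats::setNames(
      vapply(seq_len(n_genes), function(i)
        paste(c("M", sample(c("A","G","L","S","T","V","K","R","E","D"), 40,
                            replace = TRUE)), collapse = ""), character(1)),
      genes$gene_id)
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  genome_record(genome_id, c(c1 = contig), genes, proteins = proteins,
                species = species)
}

# one domain-hit row
hit_row <- function(protein_id, accession, i_evalue = 1e-20,
                    env_start = 5, env_end = 40, name = accession,
                    bit_score = 150) {
  data.frame(protein_id = protein_id, domain_accession = accession,
             domain_name = name, env_start = env_start, env_end = env_end,
             i_evalue = i_evalue, bit_score = bit_score,
             stringsAsFactors = FALSE)
}

# exhaustive-bipartition oracle: a label subset S is a split of an unrooted
# tree iff, after rooting at the reference tip, S (never containing that tip)
# is the exact tip set below some internal node (checked via MRCA descendants)
oracle_splits <- function(tree) {
  labs <- sort(tree$tip.label)
  n <- length(labs)
  tree <- ape::root(tree, outgroup = labs[1], resolve.root = TRUE)
  found <- character()
  for (size in 2:(n - 2)) {
    for (idx in utils::combn(2:n, size, simplify = FALSE)) {
      side <- labs[idx]
      mrca <- ape::getMRCA(tree, side)
      below <- ape::extract.clade(tree, mrca)$tip.label
      if (setequal(below, side)) found <- c(found, paste(sort(side), collapse = ","))
    }
  }
  unique(found)
}

# adjusted Rand index between two labelings (named vectors over same ids)
adjusted_rand <- function(a, b) {
  ids <- names(a)
  b <- b[ids]
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- si * sj / n2
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}
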