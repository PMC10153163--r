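# Genome / domain-table / BUSCO-table I-O and coordinate conventions.

write_tiny_genome_files <- function(dir, gff_lines, contigs, proteins) {
  gff <- file.path(dir, "g.gff3")
  writeLines(c("##gff-version 3", gff_lines), gff)
  fna <- file.path(dir, "g.fna")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(contigs), fna)
  faa <- file.path(dir, "g.faa")
  Biostrings::writeXStringSet(Biostrings::AAStringSet(proteins), faa)
  list(gff = gff, fna = fna, faa = faa)
}

test_that("read_genome converts GFF 1-based coordinates and assigns per-contig ordinals", {
  td <- withr::local_tempdir()
  contigs <- c(c1 = strrep("ACGT", 300), c2 = strrep("GATTACA", 100))
  f <- write_tiny_genome_files(td, c(
    "c1\ttest\tgene\t101\t200\t.\t+\t.\tID=gA",
    "c1\ttest\tgene\t301\t400\t.\t-\t.\tID=gB",
    "c2\ttest\tgene\t51\t150\t.\t+\t.\tID=gC"),
    contigs, c(gA = "MAAA", gB = "MCCC", gC = "MGGG"))
  g <- read_genome(f$gff, f$fna, f$faa, genome_id = "tiny")
  expect_s3_class(g, "GenomeRecord")
  expect_equal(g$genes["gA", "start"], 100)
  expect_equal(g$genes["gA", "end"], 200)
  expect_equal(g$genes$ordinal, c(0L, 1L, 0L))
  expect_equal(g$proteins[["gB"]], "MCCC")
})

test_that("read_genome flags unknown contigs, out-of-bounds genes and missing proteins", {
  td <- withr::local_tempdir()
  contigs <- c(c1 = strrep("ACGT", 100))
  f <- write_tiny_genome_files(td,
    "cX\ttest\tgene\t1\t50\t.\t+\t.\tID=gA",
    contigs, c(gA = "MA"))
  expect_error(read_genome(f$gff, f$fna, f$faa), "unknown|absent")

  f2 <- write_tiny_genome_files(td,
    "c1\ttest\tgene\t1\t9999\t.\t+\t.\tID=gA",
    contigs, c(gA = "MA"))
  expect_error(read_genome(f2$gff, f2$fna, f2$faa), "bounds")

  f3 <- write_tiny_genome_files(td, c(
    "c1\ttest\tgene\t1\t60\t.\t+\t.\tID=gA",
    "c1\ttest\tgene\t101\t160\t.\t+\t.\tID=gB"),
    contigs, c(gA = "MA"))
  expect_warning(g <- read_genome(f3$gff, f3$fna, f3$faa), "gB")
  expect_equal(nrow(g$genes), 2)  # gene kept without protein
})

test_that("read_domain_table parses the domtblout dialect and normalizes accessions", {
  td <- withr::local_tempdir()
  p <- file.path(td, "hits.domtbl")
  row <- function(tn, acc, qn, iev) {
    paste(tn, acc, 200, qn, "-", 400, iev, 100, 0, 1, 1, iev, iev, 100, 0,
          1, 200, 10, 190, 8, 195, 0.9, "some description here")
  }
  writeLines(c("# comment", row("DIT1_PvcA", "PF05141.1", "prot1", "1e-30"),
               row("p450", "PF00067.22", "prot1", "2e-10"),
               row("TauD", "PF02668.13", "prot2", "5e-8")), p)
  h <- read_domain_table(p)
  expect_equal(nrow(h), 3)
  expect_equal(h$domain_accession, c("PF05141", "PF00067", "PF02668"))
  expect_equal(h$protein_id, c("prot1", "prot1", "prot2"))
  expect_equal(h$i_evalue[1], 1e-30)
  expect_equal(h$env_start[1], 8)
  expect_equal(h$env_end[1], 195)

  writeLines("# only comments", p)
  expect_equal(nrow(read_domain_table(p)), 0)

  writeLines(c(row("A", "PF1.1", "p", "1e-5"),
               row("B", "PF2.1", "p", "not_a_number")), p)
  expect_error(read_domain_table(p), "line 2")
})

test_that("read_busco_table validates rows against the genomes", {
  td <- withr::local_tempdir()
  g1 <- toy_genome(3, genome_id = "G1")
  g2 <- toy_genome(3, genome_id = "G2")
  genomes <- list(G1 = g1, G2 = g2)
  p <- file.path(td, "busco.tsv")
  rows <- expand.grid(b = c("B1", "B2"), g = c("G1", "G2"),
                      stringsAsFactors = FALSE)
  writeLines(sprintf("%s\t%s\t%s_g1", rows$b, rows$g, rows$g), p)
  tab <- read_busco_table(p, genomes)
  expect_equal(nrow(tab), 4)  # all busco x genome pairs resolve

  writeLines(c("B1\tG1\tG1_g1", "B1\tG2\tnope"), p)
  expect_warning(tab <- read_busco_table(p, genomes), "dropped")
  expect_equal(nrow(tab), 1)

  writeLines(c("B1\tG1\tG1_g1", "B1\tG1\tG1_g2"), p)
  expect_error(suppressWarnings(read_busco_table(p, genomes)), "duplicated")
})

test_that("export_cluster writes region FASTA/GFF/GenBank that round-trip exactly", {
  td <- withr::local_tempdir()
  cfg <- sim_config(n_species = 1, genes_per_genome = 80, n_busco_like = 5,
                    templates = default_templates(1), mu = 0, seed = 21)
  sim <- simulate_dataset(cfg)
  g <- sim$genomes[[1]]
  cl <- clusters_from_truth(sim)[1, ]
  flags <- cl$anchor_gene
  fl <- export_cluster(cl, g, td, biosynthetic = flags)
  genes <- cluster_genes(cl, g)

  fna <- as.character(Biostrings::readDNAStringSet(fl$fna))[[1]]
  expect_identical(fna, substr(g$contigs[[cl$contig_id]],
                               min(genes$start) + 1, max(genes$end)))

  gr <- rtracklayer::import(fl$gff)
  expect_equal(length(gr), nrow(genes))
  expect_equal(as.character(GenomicRanges::strand(gr)), genes$strand)
  expect_equal(GenomicRanges::start(gr), genes$start - min(genes$start) + 1)
  expect_equal(GenomicRanges::end(gr), genes$end - min(genes$start))

  gb <- readLines(fl$gbk)
  expect_true(any(grepl("/gene_kind=\"biosynthetic\"", gb)))
  expect_true(any(grepl(paste0("/locus_tag=\"", cl$anchor_gene, "\""), gb)))
})

test_that("gene ordinals form a 0..n-1 sequence per contig", {
  cfg <- sim_config(n_species = 2, genes_per_genome = 60, n_busco_like = 5,
                    templates = default_templates(1), mu = 0.02, seed = 3)
  sim <- simulate_dataset(cfg)
  for (g in sim$genomes) {
    for (cid in names(g$contigs)) {
      ords <- sort(g$genes$ordinal[g$genes$contig_id == cid])
      expect_equal(ords, seq_along(ords) - 1L)
    }
  }
})
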