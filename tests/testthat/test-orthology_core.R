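# Orthogroup construction, biosynthetic cores, superfamilies, dit status.

test_that("RBH orthogroups link mutual best hits and leave the rest as singletons", {
  mkg <- function(id, prots) {
    genes <- data.frame(gene_id = names(prots), contig_id = "c1",
                        start = seq(0, by = 100, length.out = length(prots)),
                        end = seq(50, by = 100, length.out = length(prots)),
                        strand = "+", stringsAsFactors = FALSE)
    genome_record(id, c(c1 = strrep("A", 2000)), genes, proteins = prots)
  }
  base1 <- strrep("MKLVANDEQR", 6)
  base2 <- strrep("MGGSTTPWYC", 6)
  ga <- mkg("ga", c(ga_p1 = base1, ga_p2 = base2,
                    ga_p3 = paste(rep("MW", 30), collapse = "")))
  gb <- mkg("gb", c(gb_p1 = sub("ANDE", "ANDA", base1), gb_p2 = base2))
  gc_ <- mkg("gc", c(gc_p1 = sub("MKLV", "MRLV", base1)))
  og <- build_orthogroups(mode = "rbh", genomes = list(ga = ga, gb = gb, gc = gc_))
  # chain ga_p1 - gb_p1 - gc_p1 collapses into one orthogroup
  expect_equal(length(unique(orthogroup_of(og, c("ga_p1", "gb_p1", "gc_p1")))), 1)
  expect_equal(orthogroup_of(og, "ga_p2"), orthogroup_of(og, "gb_p2"))
  expect_false(orthogroup_of(og, "ga_p2") == orthogroup_of(og, "ga_p1"))
  # unmatched protein becomes a singleton; assignment is a partition
  all_genes <- c(names(ga$proteins), names(gb$proteins), names(gc_$proteins))
  expect_setequal(names(og$og), all_genes)
  expect_false(orthogroup_of(og, "ga_p3") %in%
                 orthogroup_of(og, setdiff(all_genes, "ga_p3")))
})

test_that("ingest mode parses orthogroup tables and drops unknown entries", {
  td <- withr::local_tempdir()
  g <- toy_genome(4, genome_id = "ig")
  p <- file.path(td, "og.tsv")
  writeLines(c("OG1\tig_g1\tig_g2", "OG2\tig_g3\tnot_a_gene"), p)
  expect_warning(og <- build_orthogroups("ingest", path = p,
                                         genomes = list(ig = g)), "unknown")
  expect_equal(unname(og$og[c("ig_g1", "ig_g2", "ig_g3")]),
               c("OG1", "OG1", "OG2"))
  # unlisted gene completes the partition as a singleton
  expect_true("ig_g4" %in% names(og$og))
})

test_that("core conservation fractions honour the tau threshold and always keep the anchor", {
  # 5 species; orthogroup OGx present in 4/5 clusters (c = 0.8 -> core),
  # OGy in 3/5 (accessory); anchor orthogroup always core
  mkg <- function(i, with_x, with_y) {
    id <- paste0("sp", i)
    ogs <- c("OGanchor", "OGcommon", if (with_x) "OGx", if (with_y) "OGy")
    prots <- stats::setNames(rep(strrep("MA", 20), length(ogs)),
                             paste0(id, "_g", seq_along(ogs)))
    genes <- data.frame(gene_id = names(prots), contig_id = "c1",
                        start = seq(0, by = 100, length.out = length(ogs)),
                        end = seq(50, by = 100, length.out = length(ogs)),
                        strand = "+", stringsAsFactors = FALSE)
    list(genome = genome_record(id, c(c1 = strrep("A", 2000)), genes,
                                proteins = prots, species = paste0("S", i)),
         og = stats::setNames(ogs, names(prots)))
  }
  specs <- list(mkg(1, TRUE, TRUE), mkg(2, TRUE, TRUE), mkg(3, TRUE, TRUE),
                mkg(4, TRUE, FALSE), mkg(5, FALSE, FALSE))
  genomes <- stats::setNames(lapply(specs, `[[`, "genome"),
                             paste0("sp", 1:5))
  og <- structure(list(og = unlist(lapply(specs, `[[`, "og")),
                       provenance = "ingested"), class = "orthogroup_map")
  names(og$og) <- sub("^.*\\.", "", names(og$og))
  clusters <- do.call(rbind, lapply(1:5, function(i) {
    g <- genomes[[i]]
    data.frame(genome_id = g$genome_id,
               cluster_id = paste0(g$genome_id, ".cl"),
               contig_id = "c1", anchor_gene = g$genes$gene_id[1],
               anchor_ordinal = 0, start_ordinal = 0,
               end_ordinal = max(g$genes$ordinal), species = g$species,
               stringsAsFactors = FALSE)
  }))
  reps <- dereplicate_species(genomes)
  core <- compute_core("F1", clusters$cluster_id, clusters, genomes, og, reps)
  expect_equal(core$anchor_og, "OGanchor")
  expect_true("OGanchor" %in% core$core)
  expect_true("OGx" %in% core$core)        # 4/5 = 0.8 >= tau
  expect_false("OGy" %in% core$core)       # 3/5 < tau
  expect_false(core$low_confidence)
  expect_true(all(core$conservation$c >= 0 & core$conservation$c <= 1))
})

test_that("superfamilies collapse only identical cores", {
  mkcore <- function(id, core) {
    structure(list(gcf_id = id, core = core, anchor_og = core[1],
                   conservation = NULL, n_species = 6, low_confidence = FALSE,
                   tau = 0.8), class = "core_gene_set")
  }
  cores <- list(mkcore("GCF_A", c("ICS_OG", "p450_OG")),
                mkcore("GCF_B", c("p450_OG", "ICS_OG")),
                mkcore("GCF_C", c("ICS_OG", "mfs_OG")))
  sf <- collapse_superfamilies(cores)
  is_sf <- vapply(sf, `[[`, logical(1), "is_superfamily")
  expect_equal(sum(is_sf), 1)
  expect_setequal(sf[[which(is_sf)]]$clans, c("GCF_A", "GCF_B"))
  expect_equal(length(sf), 2)

  sf2 <- collapse_superfamilies(list(mkcore("X", "a"), mkcore("Y", "b")))
  expect_false(any(vapply(sf2, `[[`, logical(1), "is_superfamily")))
})

test_that("dit status distinguishes colocalized, fragmented and absent genomes", {
  cfgd <- list(dit1_og = "OG_dit1", dit2_og = "OG_dit2", D = 3)
  mkg <- function(id, layout) {
    # layout: data.frame gene_id, contig_id, start, strand, og
    genes <- data.frame(gene_id = layout$gene_id, contig_id = layout$contig_id,
                        start = layout$start, end = layout$start + 300,
                        strand = layout$strand, stringsAsFactors = FALSE)
    contigs <- stats::setNames(rep(strrep("ACGT", 5000), 2), c("c1", "c2"))
    prots <- stats::setNames(rep(strrep("MA", 30), nrow(genes)), genes$gene_id)
    list(genome = genome_record(id, contigs, genes, proteins = prots),
         og = stats::setNames(layout$og, layout$gene_id))
  }
  lay_col <- data.frame(gene_id = paste0("a_g", 1:3), contig_id = "c1",
                        start = c(100, 1000, 2000),
                        strand = c("+", "-", "+"),
                        og = c("OGf", "OG_dit2", "OG_dit1"),
                        stringsAsFactors = FALSE)
  lay_frag <- data.frame(gene_id = paste0("b_g", 1:2),
                         contig_id = c("c1", "c2"), start = c(100, 100),
                         strand = c("+", "-"),
                         og = c("OG_dit1", "OG_dit2"), stringsAsFactors = FALSE)
  lay_abs <- data.frame(gene_id = "c_g1", contig_id = "c1", start = 100,
                        strand = "+", og = "OG_dit1", stringsAsFactors = FALSE)
  for (case in list(list(lay_col, "COLOCALIZED"),
                    list(lay_frag, "FRAGMENTED"),
                    list(lay_abs, "ABSENT"))) {
    spec <- mkg("g", case[[1]])
    og <- structure(list(og = spec$og, provenance = "ingested"),
                    class = "orthogroup_map")
    anchors <- data.frame(genome_id = "g",
                          gene_id = names(spec$og)[spec$og == "OG_dit1"],
                          stringsAsFactors = FALSE)
    st <- classify_dit_status(spec$genome, anchors, og, cfgd)
    expect_equal(st$status, case[[2]])
  }

  # same-strand pair is not divergent: both present but never co-localized
  lay_same <- lay_col
  lay_same$strand <- c("+", "+", "+")
  spec <- mkg("g", lay_same)
  og <- structure(list(og = spec$og, provenance = "ingested"),
                  class = "orthogroup_map")
  anchors <- data.frame(genome_id = "g", gene_id = "a_g3",
                        stringsAsFactors = FALSE)
  st <- classify_dit_status(spec$genome, anchors, og, cfgd)
  expect_equal(st$status, "FRAGMENTED")
  expect_error(classify_dit_status(spec$genome, anchors, og, list()), "seed")
})
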