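# Deterministic synthetic pangenome generator with planted truth.
#
# Emulates the statistical structure the mining pipeline assumes: contiguous
# co-regulated clusters sharing an anchor-linked promoter motif, universal
# single-copy (BUSCO-like) genes, orthologous protein families derived from
# master sequences by point mutation, and planted dit1/dit2 loci. Domain
# annotations are simulated as table rows tied to the planted genes, so tests
# need no profile database. Everything is reproducible from (config, seed).

.AA20 <- c("A","C","D","E","F","G","H","I","K","L",
           "M","N","P","Q","R","S","T","V","W","Y")
.DNA4 <- c("A", "C", "G", "T")

.rand_dna <- function(n, gc = 0.5) {
  paste(sample(.DNA4, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

.rand_protein <- function(len) {
  paste(c("M", sample(.AA20, len - 1, replace = TRUE)), collapse = "")
}

#' Mutate a sequence by per-site substitution
#'
#' Each site is independently substituted with probability `mu`, uniformly
#' over the other symbols of the alphabet. Length is preserved.
#'
#' @param seq Input sequence string.
#' @param mu Per-site substitution probability in \[0, 0.5\].
#' @param alphabet `"AA"` or `"DNA"`.
#' @return Mutated sequence string.
#' @export
mutate_sequence <- function(seq, mu, alphabet = c("AA", "DNA")) {
  stopifnot(mu >= 0, mu <= 0.5)
  alphabet <- match.arg(alphabet)
  if (mu == 0 || !nzchar(seq)) return(seq)
  letters <- if (alphabet == "AA") .AA20 else .DNA4
  chars <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(chars)) < mu)
  for (i in hit) {
    chars[i] <- sample(setdiff(letters, chars[i]), 1)
  }
  paste(chars, collapse = "")
}

#' Define a planted cluster template
#'
#' A template describes one gene cluster family to plant: its size, backbone
#' variant, the shared promoter motif, the tailoring-domain complement, the
#' orthogroups of its genes (sharable across templates to build common cores)
#' and per-gene presence probabilities (accessory genes).
#'
#' @param template_id Identifier.
#' @param size Number of genes (>= 2).
#' @param motif Planted promoter k-mer (nucleotides).
#' @param variant Backbone variant: `"MONO"`, `"ICS_TAUD"` or
#'   `"ICS_NRPS_LIKE"`.
#' @param species Integer indices of the species carrying the template
#'   (`NULL` = all).
#' @param domains Domain accession per non-anchor gene (recycled from a
#'   default tailoring pool when `NULL`); entry at the anchor position is
#'   ignored.
#' @param og_ids Orthogroup id per gene (default `OG_<template>_<i>`); reuse
#'   ids across templates to share master proteins (identical cores).
#' @param presence Per-gene presence probability (default 1; the anchor is
#'   always present).
#' @param anchor_pos Position of the ICS anchor within the cluster (default
#'   middle).
#' @return A list of class `cluster_template`.
#' @export
cluster_template <- function(template_id, size, motif, variant = "MONO",
                             species = NULL, domains = NULL, og_ids = NULL,
                             presence = NULL,
                             anchor_pos = ceiling(size / 2)) {
  stopifnot(size >= 2, anchor_pos >= 1, anchor_pos <= size,
            variant %in% c("MONO", "ICS_TAUD", "ICS_NRPS_LIKE"))
  pool <- c("PF07690", "PF00067", "PF01965", "PF00172", "PF08242",
            "PF00106", "PF00561")
  if (is.null(domains)) domains <- rep_len(pool, size)
  if (is.null(og_ids)) og_ids <- sprintf("OG_%s_%d", template_id, seq_len(size))
  if (is.null(presence)) presence <- rep(1, size)
  stopifnot(length(domains) == size, length(og_ids) == size,
            length(presence) == size)
  presence[anchor_pos] <- 1
  structure(list(template_id = template_id, size = size, motif = toupper(motif),
                 variant = variant, species = species, domains = domains,
                 og_ids = og_ids, presence = presence,
                 anchor_pos = anchor_pos),
            class = "cluster_template")
}

#' Default planted templates
#'
#' Five templates of sizes 5-8 with distinct motifs, distinct orthogroups,
#' varied backbone variants and partially overlapping tailoring-domain
#' complements, carried by all species.
#'
#' @param n Number of templates (up to 6).
#' @return List of `cluster_template` objects.
#' @export
default_templates <- function(n = 5) {
  specs <- list(
    list(id = "T1", size = 6L, motif = "ATGCATCC", variant = "MONO",
         domains = c("PF07690", "PF00067", "PF01965", "PF00172", "PF08242", "PF00106")),
    list(id = "T2", size = 8L, motif = "GGATCCAA", variant = "ICS_TAUD",
         domains = c("PF07690", "PF00067", "PF00561", "PF00083", "PF01073",
                     "PF00891", "PF00005", "PF00096")),
    list(id = "T3", size = 5L, motif = "CTTAGACG", variant = "ICS_NRPS_LIKE",
         domains = c("PF07690", "PF01965", "PF05834", "PF00394", "PF00583")),
    list(id = "T4", size = 7L, motif = "TCGGTAAC", variant = "MONO",
         domains = c("PF00067", "PF00172", "PF01494", "PF00732", "PF00248",
                     "PF01593", "PF07690")),
    list(id = "T5", size = 6L, motif = "GACCTTGA", variant = "ICS_TAUD",
         domains = c("PF01965", "PF00106", "PF08240", "PF00107", "PF04082", "PF00664")),
    list(id = "T6", size = 5L, motif = "ATCCGGTT", variant = "MONO",
         domains = c("PF07690", "PF00067", "PF00561", "PF08242", "PF00172")))
  lapply(specs[seq_len(n)], function(s) {
    cluster_template(s$id, s$size, s$motif, s$variant, domains = s$domains)
  })
}

#' Simulation configuration
#'
#' @param n_species Number of species (one genome each).
#' @param genes_per_genome Total genes per genome.
#' @param n_busco_like Number of universal single-copy (BUSCO-like) genes.
#' @param templates List of [cluster_template()] objects.
#' @param mu Per-site protein substitution rate applied to each species' copy
#'   of a master sequence (0-0.5).
#' @param intergenic_range Min/max intergenic length, bp.
#' @param gc Background GC content of intergenic and gene-body DNA.
#' @param protein_length_range Min/max master protein length, aa.
#' @param n_contigs Contigs per genome (>= 2 when fragmented dit loci are
#'   requested).
#' @param dit Named counts `c(colocalized=, fragmented=, absent=)` assigning
#'   the first species to each dit status in that order; remaining species get
#'   no dit locus and are counted `absent`.
#' @param filler_og_pool Size of the shared filler orthogroup pool (default
#'   `2 * genes_per_genome`).
#' @param filler_domain_prob Probability that a filler orthogroup carries a
#'   (non-ICS) domain annotation.
#' @param seed Mandatory integer seed.
#' @return A list of class `SimConfig`.
#' @export
sim_config <- function(n_species = 10L, genes_per_genome = 200L,
                       n_busco_like = 50L, templates = default_templates(),
                       mu = 0.05, intergenic_range = c(200L, 800L), gc = 0.5,
                       protein_length_range = c(120L, 300L), n_contigs = 2L,
                       dit = c(colocalized = 0L, fragmented = 0L, absent = 0L),
                       filler_og_pool = NULL, filler_domain_prob = 0.6,
                       seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  stopifnot(mu >= 0, mu <= 0.5, n_species >= 1, genes_per_genome >= 1,
            all(vapply(templates, inherits, logical(1), "cluster_template")))
  dit <- c(colocalized = 0L, fragmented = 0L, absent = 0L)[] + {
    d <- c(colocalized = 0L, fragmented = 0L, absent = 0L)
    d[names(dit)] <- as.integer(dit)
    d
  }
  if (sum(dit) > n_species) stop("dit plantings exceed n_species")
  if (dit[["fragmented"]] > 0 && n_contigs < 2) {
    stop("fragmented dit loci require n_contigs >= 2")
  }
  motifs <- vapply(templates, `[[`, character(1), "motif")
  canon <- pmin(motifs, .revcomp(motifs))
  if (anyDuplicated(canon)) stop("planted motifs must be canonically distinct")
  if (is.null(filler_og_pool)) filler_og_pool <- 2L * genes_per_genome
  structure(list(n_species = as.integer(n_species),
                 genes_per_genome = as.integer(genes_per_genome),
                 n_busco_like = as.integer(n_busco_like),
                 templates = templates, mu = mu,
                 intergenic_range = as.integer(intergenic_range), gc = gc,
                 protein_length_range = as.integer(protein_length_range),
                 n_contigs = as.integer(n_contigs), dit = dit,
                 filler_og_pool = as.integer(filler_og_pool),
                 filler_domain_prob = filler_domain_prob,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

# deterministic domain layout on a master protein: k consecutive segments
.domain_spans <- function(plen, k) {
  bounds <- round(seq(1, plen, length.out = k + 1))
  data.frame(env_start = pmax(bounds[-(k + 1)], 1L) + c(0L, rep(2L, k - 1)),
             env_end = pmin(bounds[-1] - c(rep(2L, k - 1), 0L), plen))
}

#' Simulate a multi-species pangenome with planted truth
#'
#' Generates one genome per species containing the planted cluster templates
#' (contiguous genes, planted promoter motif inserted once per cluster-gene
#' promoter), BUSCO-like universal single-copy genes in randomized
#' neighbourhoods, optional dit1/dit2 loci and filler genes drawing
#' orthogroups from a shared pool. Proteins are per-site mutations of master
#' sequences at rate `mu`. Planted motifs are made exclusive to their cluster
#' promoters: chance occurrences elsewhere on a contig are resampled away so
#' the planted span is unambiguous. Fully deterministic given the seed.
#'
#' @param cfg A `SimConfig`.
#' @param out_dir Optional directory; when given, per-genome GFF3/FASTA/
#'   protein-FASTA/domain tables plus BUSCO, orthogroup and truth tables are
#'   written there.
#' @return List: `genomes` (named list of `GenomeRecord`), `hits` (combined
#'   domain-hit `data.frame` with a `genome_id` column), `truth` (list:
#'   `clusters`, `orthogroups` named vector, `busco`, `dit`, `motifs`),
#'   `cfg`, and `files` (paths, when `out_dir` was given).
#' @export
simulate_dataset <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "SimConfig"))
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(cfg$seed)

  plen_range <- cfg$protein_length_range
  masters <- new.env(parent = emptyenv())
  master_of <- function(og, n_domains = 1L) {
    if (!exists(og, envir = masters)) {
      plen <- sample(plen_range[1]:plen_range[2], 1)
      assign(og, list(protein = .rand_protein(plen),
                      spans = .domain_spans(plen, max(n_domains, 1L))),
             envir = masters)
    }
    get(og, envir = masters)
  }

  # per-template gene plans
  plans <- lapply(cfg$templates, function(tp) {
    doms <- vector("list", tp$size)
    for (i in seq_len(tp$size)) {
      doms[[i]] <- if (i == tp$anchor_pos) {
        switch(tp$variant,
               MONO = "PF05141",
               ICS_TAUD = c("PF05141", "PF02668"),
               ICS_NRPS_LIKE = c("PF05141", "PF00501", "PF00550"))
      } else tp$domains[i]
      master_of(tp$og_ids[i], length(doms[[i]]))
    }
    list(tp = tp, doms = doms)
  })

  busco_ogs <- sprintf("OG_busco_%03d", seq_len(cfg$n_busco_like))
  for (og in busco_ogs) master_of(og)
  filler_ogs <- sprintf("OG_fill_%04d", seq_len(cfg$filler_og_pool))
  filler_domain_pool <- c("PF00076", "PF00071", "PF00271", "PF00400",
                          "PF00069", "PF03144", "PF07690", "PF00067",
                          "PF00172", "PF00664")
  filler_dom <- stats::setNames(
    ifelse(stats::runif(cfg$filler_og_pool) < cfg$filler_domain_prob,
           sample(filler_domain_pool, cfg$filler_og_pool, replace = TRUE),
           NA_character_),
    filler_ogs)
  for (og in filler_ogs) master_of(og)
  master_of("OG_dit1")
  master_of("OG_dit2")

  dit_status_planned <- rep("ABSENT", cfg$n_species)
  if (cfg$dit[["colocalized"]] > 0) {
    dit_status_planned[seq_len(cfg$dit[["colocalized"]])] <- "COLOCALIZED"
  }
  if (cfg$dit[["fragmented"]] > 0) {
    dit_status_planned[cfg$dit[["colocalized"]] + seq_len(cfg$dit[["fragmented"]])] <-
      "FRAGMENTED"
  }

  genomes <- list()
  hits_all <- list()
  truth_clusters <- list()
  truth_busco <- list()
  truth_og <- character()

  for (s in seq_len(cfg$n_species)) {
    gid <- sprintf("sp%02d", s)
    species <- sprintf("Species_%02d", s)

    # units: lists of gene specs (og, domains, strand, template/busco role)
    units <- list()
    add_unit <- function(genes, contig_pref = NA_integer_, role = NA_character_,
                         role_id = NA_character_) {
      units[[length(units) + 1L]] <<- list(genes = genes,
                                           contig_pref = contig_pref,
                                           role = role, role_id = role_id)
    }
    gene_spec <- function(og, domains, strand, is_anchor = FALSE,
                          motif = NA_character_) {
      list(og = og, domains = domains, strand = strand, is_anchor = is_anchor,
           motif = motif)
    }

    for (pl in plans) {
      tp <- pl$tp
      if (!is.null(tp$species) && !(s %in% tp$species)) next
      keep <- stats::runif(tp$size) < tp$presence
      keep[tp$anchor_pos] <- TRUE
      genes <- lapply(which(keep), function(i) {
        gene_spec(tp$og_ids[i], pl$doms[[i]], strand = "+",
                  is_anchor = i == tp$anchor_pos, motif = tp$motif)
      })
      add_unit(genes, role = "cluster", role_id = tp$template_id)
    }
    if (dit_status_planned[s] == "COLOCALIZED") {
      add_unit(list(gene_spec("OG_dit2", "PF00067", "-"),
                    gene_spec("OG_dit1", "PF05141", "+")), role = "dit_pair")
    } else if (dit_status_planned[s] == "FRAGMENTED") {
      add_unit(list(gene_spec("OG_dit1", "PF05141", "+")),
               contig_pref = 1L, role = "dit1")
      add_unit(list(gene_spec("OG_dit2", "PF00067", "-")),
               contig_pref = 2L, role = "dit2")
    }
    for (b in seq_len(cfg$n_busco_like)) {
      add_unit(list(gene_spec(busco_ogs[b], NA_character_,
                              sample(c("+", "-"), 1))),
               role = "busco", role_id = busco_ogs[b])
    }
    n_planted <- sum(vapply(units, function(u) length(u$genes), integer(1)))
    n_fill <- cfg$genes_per_genome - n_planted
    if (n_fill < 0) stop("planted genes exceed genes_per_genome")
    for (f in seq_len(n_fill)) {
      og <- sample(filler_ogs, 1)
      add_unit(list(gene_spec(og, filler_dom[[og]], sample(c("+", "-"), 1))),
               role = "filler")
    }

    # shuffle units, honour contig preferences, distribute across contigs
    units <- units[sample(length(units))]
    contig_of <- vapply(units, function(u) {
      if (!is.na(u$contig_pref)) u$contig_pref
      else sample(cfg$n_contigs, 1)
    }, integer(1))

    gene_rows <- list()
    contigs <- character(cfg$n_contigs)
    names(contigs) <- sprintf("%s_c%d", gid, seq_len(cfg$n_contigs))
    proteins <- character()
    hits_g <- list()
    motif_sites <- list()  # per contig: matrix of (pos, len) inserted motifs
    counter <- 0L

    for (ci in seq_len(cfg$n_contigs)) {
      seq_parts <- character()
      pos <- 0L
      cid <- names(contigs)[ci]
      for (u in units[contig_of == ci]) {
        for (gs in u$genes) {
          counter <- counter + 1L
          gene_id <- sprintf("%s_g%04d", gid, counter)
          gap <- sample(cfg$intergenic_range[1]:cfg$intergenic_range[2], 1)
          gap_seq <- .rand_dna(gap, cfg$gc)
          master <- master_of(gs$og)
          prot <- mutate_sequence(master$protein, cfg$mu, "AA")
          glen <- 3L * nchar(prot) + 3L
          body_seq <- .rand_dna(glen, cfg$gc)
          if (!is.na(gs$motif) && gs$strand == "+") {
            # plant the motif just inside the gene start, within the L_down
            # promoter stretch; unlike the shared intergenic, this region
            # belongs to this gene's promoter alone
            k <- nchar(gs$motif)
            at <- sample(4:(42 - k), 1)  # 1-based within the gene body
            substr(body_seq, at, at + k - 1L) <- gs$motif
            motif_sites[[cid]] <- rbind(motif_sites[[cid]],
                                        c(pos + gap + at, k))
          }
          gstart <- pos + gap
          gene_rows[[length(gene_rows) + 1L]] <- data.frame(
            gene_id = gene_id, contig_id = cid, start = gstart,
            end = gstart + glen, strand = gs$strand,
            og = gs$og, role = u$role,
            role_id = if (is.null(u$role_id)) NA_character_ else u$role_id,
            is_anchor = isTRUE(gs$is_anchor), motif = gs$motif,
            stringsAsFactors = FALSE)
          proteins[gene_id] <- prot
          doms <- gs$domains[!is.na(gs$domains)]
          if (length(doms)) {
            spans <- master$spans
            if (nrow(spans) < length(doms)) {
              spans <- .domain_spans(nchar(prot), length(doms))
            }
            for (di in seq_along(doms)) {
              hits_g[[length(hits_g) + 1L]] <- data.frame(
                protein_id = gene_id, domain_accession = doms[di],
                domain_name = doms[di],
                env_start = spans$env_start[di], env_end = spans$env_end[di],
                i_evalue = 10^-stats::runif(1, 8, 40),
                bit_score = round(stats::runif(1, 80, 400), 1),
                stringsAsFactors = FALSE)
            }
          }
          seq_parts <- c(seq_parts, gap_seq, body_seq)
          pos <- gstart + glen
        }
      }
      seq_parts <- c(seq_parts, .rand_dna(
        sample(cfg$intergenic_range[1]:cfg$intergenic_range[2], 1), cfg$gc))
      contigs[ci] <- paste(seq_parts, collapse = "")
    }

    # make planted motifs exclusive to their planted sites
    all_motifs <- unique(stats::na.omit(
      vapply(cfg$templates, `[[`, character(1), "motif")))
    if (length(all_motifs)) {
      for (ci in seq_along(contigs)) {
        cid <- names(contigs)[ci]
        keep_sites <- motif_sites[[cid]]
        contigs[ci] <- .scrub_motifs(contigs[[ci]], all_motifs, keep_sites,
                                     cfg$gc)
      }
    }

    genes <- do.call(rbind, gene_rows)
    rec <- genome_record(gid, contigs,
                         genes[, c("gene_id", "contig_id", "start", "end", "strand")],
                         proteins = proteins, species = species)
    genomes[[gid]] <- rec
    truth_og[genes$gene_id] <- genes$og

    hits_df <- if (length(hits_g)) do.call(rbind, hits_g) else
      data.frame(protein_id = character(), domain_accession = character(),
                 domain_name = character(), env_start = integer(),
                 env_end = integer(), i_evalue = numeric(),
                 bit_score = numeric(), stringsAsFactors = FALSE)
    hits_df$genome_id <- gid
    hits_all[[gid]] <- hits_df

    # planted-cluster truth (ordinals from the constructed record)
    gm <- rec$genes
    for (tpid in unique(genes$role_id[genes$role == "cluster"])) {
      sel <- genes$gene_id[genes$role == "cluster" &
                             !is.na(genes$role_id) & genes$role_id == tpid]
      ords <- gm[sel, "ordinal"]
      truth_clusters[[length(truth_clusters) + 1L]] <- data.frame(
        template_id = tpid, genome_id = gid, species = species,
        contig_id = gm[sel[1], "contig_id"],
        anchor_gene = genes$gene_id[genes$role == "cluster" & genes$is_anchor &
                                      genes$role_id == tpid],
        start_ordinal = min(ords), end_ordinal = max(ords),
        n_genes = length(sel),
        motif = genes$motif[genes$gene_id == sel[1]],
        gene_ids = paste(sel, collapse = ","), stringsAsFactors = FALSE)
    }
    bsel <- genes[genes$role == "busco", , drop = FALSE]
    if (nrow(bsel)) {
      truth_busco[[length(truth_busco) + 1L]] <- data.frame(
        busco_id = bsel$role_id, genome_id = gid, gene_id = bsel$gene_id,
        stringsAsFactors = FALSE)
    }
  }

  hits <- do.call(rbind, hits_all)
  rownames(hits) <- NULL
  truth <- list(
    clusters = {
      tc <- do.call(rbind, truth_clusters)
      rownames(tc) <- NULL
      tc
    },
    orthogroups = truth_og,
    busco = {
      tb <- do.call(rbind, truth_busco)
      if (!is.null(tb)) rownames(tb) <- NULL
      tb
    },
    dit = data.frame(genome_id = sprintf("sp%02d", seq_len(cfg$n_species)),
                     status = dit_status_planned, stringsAsFactors = FALSE),
    motifs = data.frame(
      template_id = vapply(cfg$templates, `[[`, character(1), "template_id"),
      motif = vapply(cfg$templates, `[[`, character(1), "motif"),
      stringsAsFactors = FALSE))

  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- list()
    for (gid in names(genomes)) {
      files[[gid]] <- write_genome(genomes[[gid]], out_dir)
      files[[gid]]$domtbl <- file.path(out_dir, paste0(gid, ".domtbl"))
      write_domain_table(hits[hits$genome_id == gid, , drop = FALSE],
                         files[[gid]]$domtbl)
    }
    if (!is.null(truth$busco)) {
      utils::write.table(truth$busco, file.path(out_dir, "busco_anchors.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
    }
    og_split <- split(names(truth_og), truth_og)
    og_lines <- vapply(names(og_split), function(og) {
      paste(c(og, sort(og_split[[og]])), collapse = "\t")
    }, character(1))
    writeLines(og_lines[order(names(og_split))],
               file.path(out_dir, "orthogroups.tsv"))
    utils::write.table(truth$clusters, file.path(out_dir, "truth_clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(truth$dit, file.path(out_dir, "truth_dit.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(truth$motifs, file.path(out_dir, "truth_motifs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  list(genomes = genomes, hits = hits, truth = truth, cfg = cfg, files = files)
}

# resample chance occurrences of planted motifs, preserving recorded sites
.scrub_motifs <- function(contig, motifs, keep_sites, gc) {
  pats <- unique(c(motifs, .revcomp(motifs)))
  keep_start <- if (is.null(keep_sites)) integer() else keep_sites[, 1]
  for (pass in 1:10) {
    found <- FALSE
    for (p in pats) {
      mpos <- gregexpr(p, contig, fixed = TRUE)[[1]]
      mpos <- mpos[mpos > 0]
      if (length(keep_start)) {
        # skip chance occurrences overlapping a planted site
        mpos <- mpos[vapply(mpos, function(a)
          all(abs(a - keep_start) >= nchar(p)), logical(1))]
      }
      for (at in mpos) {
        found <- TRUE
        substr(contig, at, at + nchar(p) - 1L) <- .rand_dna(nchar(p), gc)
      }
    }
    if (!found) break
  }
  contig
}
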