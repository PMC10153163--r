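# Orthogroups, GCF biosynthetic cores, superfamily collapsing and dit1/dit2
# locus classification.

#' Build or ingest an orthogroup map
#'
#' In `ingest` mode a tab-separated orthogroup table (first column orthogroup
#' id, remaining columns gene ids) is parsed verbatim; entries referencing
#' unknown genes are dropped with a warning when `genomes` are supplied. In
#' `rbh` mode orthogroups are the connected components of the inter-genome
#' reciprocal-best-hit graph under unit-cost global alignment (hits below the
#' identity floor are discarded); intended for fixture-scale data. In both
#' modes every unassigned gene becomes a singleton orthogroup.
#'
#' @param mode `"ingest"` or `"rbh"`.
#' @param path Orthogroup table path (ingest mode).
#' @param genomes Named list of `GenomeRecord` objects (required for rbh mode
#'   and for singleton completion / validation in ingest mode).
#' @param min_identity RBH identity floor (default 0.3).
#' @return Object of class `orthogroup_map`: list with `og` (named character
#'   vector gene_id -> orthogroup_id) and `provenance`.
#' @export
build_orthogroups <- function(mode = c("ingest", "rbh"), path = NULL,
                              genomes = NULL, min_identity = 0.3) {
  mode <- match.arg(mode)
  all_genes <- if (!is.null(genomes)) {
    unlist(lapply(genomes, function(g) g$genes$gene_id), use.names = FALSE)
  } else NULL
  if (mode == "ingest") {
    stopifnot(!is.null(path))
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    og <- character()
    dropped <- 0L
    for (ln in lines) {
      f <- strsplit(ln, "\t")[[1]]
      ids <- f[-1][nzchar(f[-1])]
      if (!is.null(all_genes)) {
        unknown <- !(ids %in% all_genes)
        dropped <- dropped + sum(unknown)
        ids <- ids[!unknown]
      }
      if (length(ids)) og[ids] <- f[1]
    }
    if (dropped > 0) warning(dropped, " orthogroup entr(ies) reference unknown genes; dropped")
    prov <- "ingested"
  } else {
    stopifnot(!is.null(genomes), length(genomes) >= 2)
    edges <- list()
    gids <- names(genomes)
    for (i in seq_along(gids)[-length(gids)]) {
      for (j in (i + 1):length(gids)) {
        pa <- genomes[[i]]$proteins; pb <- genomes[[j]]$proteins
        if (!length(pa) || !length(pb)) next
        idm <- matrix(0, length(pa), length(pb),
                      dimnames = list(names(pa), names(pb)))
        for (bi in seq_along(pb)) {
          for (ai in seq_along(pa)) {
            idm[ai, bi] <- alignment_identity(pa[[ai]], pb[[bi]])
          }
        }
        best_ab <- apply(idm, 1, which.max)
        best_ba <- apply(idm, 2, which.max)
        for (ai in seq_along(pa)) {
          bi <- best_ab[ai]
          if (best_ba[bi] == ai && idm[ai, bi] >= min_identity) {
            edges[[length(edges) + 1L]] <- c(names(pa)[ai], names(pb)[bi])
          }
        }
      }
    }
    og <- character()
    if (length(edges)) {
      e <- do.call(rbind, edges)
      gr <- igraph::graph_from_data_frame(as.data.frame(e), directed = FALSE)
      comp <- igraph::components(gr)
      og <- stats::setNames(sprintf("OG%04d", comp$membership),
                            names(comp$membership))
    }
    prov <- "built_in_RBH"
  }
  if (!is.null(all_genes)) {
    missing <- setdiff(all_genes, names(og))
    if (length(missing)) {
      og[missing] <- paste0("OGS_", missing)
    }
  }
  structure(list(og = og, provenance = prov), class = "orthogroup_map")
}

#' Orthogroup of one or more genes
#'
#' @param orthogroups An `orthogroup_map`.
#' @param gene_ids Gene ids.
#' @return Character vector of orthogroup ids (`NA` for unknown genes).
#' @export
orthogroup_of <- function(orthogroups, gene_ids) {
  unname(orthogroups$og[gene_ids])
}

# one representative cluster per species: representative genomes only,
# then smallest anchor ordinal, then cluster id
.representative_clusters <- function(members, clusters, representatives) {
  cl <- clusters[clusters$cluster_id %in% members, , drop = FALSE]
  cl <- cl[cl$genome_id %in% representatives, , drop = FALSE]
  sp <- names(representatives)[match(cl$genome_id, representatives)]
  cl$.species <- sp
  cl <- cl[order(cl$.species, cl$anchor_ordinal, cl$cluster_id), , drop = FALSE]
  cl[!duplicated(cl$.species), , drop = FALSE]
}

#' Compute the biosynthetic core of a GCF
#'
#' After restricting the family to one representative cluster per species, the
#' conservation fraction `c(O)` of an orthogroup is the fraction of species
#' whose cluster contains at least one gene of `O`. The core is every
#' orthogroup with `c(O) >= tau`, plus the anchor orthogroup (always core).
#' Families spanning fewer than five species are flagged low-confidence, not
#' refused.
#'
#' @param gcf_id Family id (metadata only).
#' @param members Member cluster ids.
#' @param clusters Cluster table.
#' @param genomes Named list of `GenomeRecord` objects.
#' @param orthogroups An `orthogroup_map`.
#' @param representatives Species -> genome id map from [dereplicate_species()].
#' @param tau Core-membership threshold (default 0.8).
#' @return List of class `core_gene_set`: `gcf_id`, `conservation`
#'   (`data.frame` orthogroup, c), `core` (character vector of core
#'   orthogroups), `anchor_og`, `n_species`, `low_confidence`, `tau`.
#' @export
compute_core <- function(gcf_id, members, clusters, genomes, orthogroups,
                         representatives, tau = 0.8) {
  reps <- .representative_clusters(members, clusters, representatives)
  if (!nrow(reps)) stop("no representative clusters for ", gcf_id)
  og_sets <- lapply(seq_len(nrow(reps)), function(i) {
    genes <- cluster_genes(reps[i, ], genomes[[reps$genome_id[i]]])$gene_id
    unique(stats::na.omit(orthogroup_of(orthogroups, genes)))
  })
  anchor_ogs <- orthogroup_of(orthogroups, reps$anchor_gene)
  anchor_og <- names(sort(table(anchor_ogs), decreasing = TRUE))[1]
  n_sp <- nrow(reps)
  tab <- table(unlist(og_sets, use.names = FALSE))
  cons <- data.frame(orthogroup = names(tab), c = as.numeric(tab) / n_sp,
                     stringsAsFactors = FALSE)
  cons <- cons[order(-cons$c, cons$orthogroup), , drop = FALSE]
  rownames(cons) <- NULL
  core <- union(cons$orthogroup[cons$c >= tau], anchor_og)
  structure(list(gcf_id = gcf_id, conservation = cons, core = sort(core),
                 anchor_og = anchor_og, n_species = n_sp,
                 low_confidence = n_sp < 5, tau = tau),
            class = "core_gene_set")
}

#' Collapse GCFs sharing an identical core into superfamilies
#'
#' GCFs whose core orthogroup signatures are exactly equal are grouped; groups
#' of two or more become a superfamily whose member GCFs are its clans
#' (distinguished by their accessory genes). GCFs with unique cores pass
#' through unchanged.
#'
#' @param cores List of `core_gene_set` objects computed with the same
#'   orthogroup map.
#' @return List of superfamily records: `superfamily_id`, `signature`
#'   (character vector), `clans` (member gcf ids), `is_superfamily` (`TRUE`
#'   when >= 2 clans).
#' @export
collapse_superfamilies <- function(cores) {
  sigs <- vapply(cores, function(cs) paste(sort(cs$core), collapse = ";"),
                 character(1))
  ids <- vapply(cores, `[[`, character(1), "gcf_id")
  groups <- split(ids, sigs)
  groups <- groups[order(-lengths(groups), vapply(groups, min, character(1)))]
  out <- vector("list", length(groups))
  sf <- 0L
  for (i in seq_along(groups)) {
    members <- sort(groups[[i]])
    is_sf <- length(members) >= 2
    id <- if (is_sf) {
      sf <- sf + 1L
      sprintf("SF_%02d", sf)
    } else members
    out[[i]] <- list(superfamily_id = id,
                     signature = strsplit(names(groups)[i], ";")[[1]],
                     clans = members, is_superfamily = is_sf)
  }
  out
}

#' Classify the dit1/dit2 locus status of a genome
#'
#' `COLOCALIZED`: an ICS gene of the dit1 orthogroup and a p450 gene of the
#' dit2 orthogroup lie within `D` gene ordinals on one contig with the expected
#' relative orientation (default divergent, head-to-head, matching the yeast
#' DIT2/DIT1 arrangement). `FRAGMENTED`: both orthogroups occur in the genome
#' but never as such a pair. `ABSENT`: otherwise. Copy counts are reported; no
#' correction is attempted for assembly-driven fragmentation.
#'
#' @param genome A `GenomeRecord`.
#' @param anchors Anchor table from [find_ics_anchors()] for this genome.
#' @param orthogroups An `orthogroup_map` that includes the reference dit1/dit2
#'   seed orthogroups.
#' @param dit_cfg List with `dit1_og`, `dit2_og`, optional `D` (max ordinal
#'   separation, default 3) and `orientation` (`"divergent"`, `"convergent"`
#'   or `"same"`, default `"divergent"`).
#' @return List of class `dit_status`: `genome_id`, `status`, `pairs`
#'   (`data.frame` of co-localized pairs), `n_dit1`, `n_dit2`, `copy_count`.
#' @export
classify_dit_status <- function(genome, anchors, orthogroups, dit_cfg) {
  if (is.null(dit_cfg$dit1_og) || is.null(dit_cfg$dit2_og)) {
    stop("dit_cfg must provide dit1_og and dit2_og seed orthogroups")
  }
  D <- if (is.null(dit_cfg$D)) 3L else dit_cfg$D
  orientation <- if (is.null(dit_cfg$orientation)) "divergent" else dit_cfg$orientation
  g <- genome$genes
  dit1 <- anchors$gene_id[orthogroup_of(orthogroups, anchors$gene_id) %in% dit_cfg$dit1_og]
  ogs <- orthogroup_of(orthogroups, g$gene_id)
  dit2 <- g$gene_id[!is.na(ogs) & ogs %in% dit_cfg$dit2_og]
  pairs <- list()
  for (a in dit1) {
    for (b in dit2) {
      ra <- g[a, ]; rb <- g[b, ]
      if (ra$contig_id != rb$contig_id) next
      if (abs(ra$ordinal - rb$ordinal) > D) next
      left <- if (ra$start <= rb$start) ra else rb
      right <- if (ra$start <= rb$start) rb else ra
      rel <- if (left$strand == right$strand) "same"
      else if (left$strand == "-" && right$strand == "+") "divergent"
      else "convergent"
      if (rel == orientation) {
        pairs[[length(pairs) + 1L]] <- data.frame(
          dit1_gene = a, dit2_gene = b, contig_id = ra$contig_id,
          separation = abs(ra$ordinal - rb$ordinal), stringsAsFactors = FALSE)
      }
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(dit1_gene = character(), dit2_gene = character(),
               contig_id = character(), separation = integer())
  status <- if (nrow(pairs)) "COLOCALIZED"
  else if (length(dit1) && length(dit2)) "FRAGMENTED"
  else "ABSENT"
  structure(list(genome_id = genome$genome_id, status = status, pairs = pairs,
                 n_dit1 = length(dit1), n_dit2 = length(dit2),
                 copy_count = max(nrow(pairs), min(length(dit1), length(dit2)))),
            class = "dit_status")
}
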