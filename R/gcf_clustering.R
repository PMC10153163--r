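# Gene cluster family (GCF) construction: anchor-weighted composite distance
# over domain content (Jaccard), domain sequence similarity (DSS) and domain
# adjacency (AI); families = connected components at a distance cutoff.

#' Composite distance weights
#'
#' @param wJ,wD,wA Non-negative weights of the domain-content Jaccard index,
#'   the domain sequence similarity and the adjacency index; must sum to 1.
#' @param anchor_boost Multiplicative weight (>= 1) applied to anchor domains
#'   inside the DSS term, so that backbone similarity dominates.
#' @param anchor_domains Accessions treated as anchor (backbone-resident)
#'   domains: the ICS domain plus co-resident backbone domains.
#' @return A list of class `DistanceWeights`.
#' @export
distance_weights <- function(wJ = 0.2, wD = 0.75, wA = 0.05, anchor_boost = 4,
                             anchor_domains = c("PF05141", "PF02668",
                                                "PF00501", "PF00550", "PF00668")) {
  stopifnot(wJ >= 0, wD >= 0, wA >= 0, abs(wJ + wD + wA - 1) < 1e-9,
            anchor_boost >= 1)
  structure(list(wJ = wJ, wD = wD, wA = wA, anchor_boost = anchor_boost,
                 anchor_domains = anchor_domains),
            class = "DistanceWeights")
}

# unit-cost global alignment identity: matches / alignment columns
.aa_unit_matrix <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      al <- c(LETTERS, "*")
      mm <- matrix(-1, length(al), length(al), dimnames = list(al, al))
      diag(mm) <- 1
      m <<- mm
    }
    m
  }
})

#' Global-alignment identity between two sequences
#'
#' Needleman-Wunsch with unit match/mismatch/gap costs; identity is the number
#' of matched columns divided by the total number of alignment columns. The
#' two sequences are ordered canonically before aligning so the result is
#' exactly symmetric (traceback ties would otherwise depend on argument
#' order).
#'
#' @param a,b Sequences (amino-acid strings).
#' @return Identity in \[0, 1\].
#' @export
alignment_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) return(0)
  if (a > b) { tmp <- a; a <- b; b <- tmp }
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       substitutionMatrix = .aa_unit_matrix(),
                                       gapOpening = 0, gapExtension = 1)
  Biostrings::nmatch(aln) / nchar(as.character(Biostrings::alignedPattern(aln)))
}

#' Domain profile of a cluster
#'
#' Collects the thresholded domain hits on a cluster's genes, ordered along the
#' cluster (gene ordinal, then position on the protein), with the protein
#' subsequence spanned by each hit. This is the unit compared by
#' [cluster_distance()].
#'
#' @param cluster One cluster-table row.
#' @param genome The matching `GenomeRecord`.
#' @param hits Domain-hit `data.frame` for this genome.
#' @param evalue_max Per-domain i-Evalue ceiling.
#' @return List of class `cluster_profile` with elements `cluster_id`, `types`
#'   (unique accessions) and `occ` (ordered occurrence `data.frame` with the
#'   spanned subsequences). A domain-free cluster is an error.
#' @export
cluster_domain_profile <- function(cluster, genome, hits, evalue_max = 1e-4) {
  genes <- cluster_genes(cluster, genome)
  h <- hits[hits$protein_id %in% genes$gene_id & hits$i_evalue <= evalue_max, ,
            drop = FALSE]
  if (!nrow(h)) stop("cluster ", cluster$cluster_id, " has no domain-bearing gene")
  h$ordinal <- genes$ordinal[match(h$protein_id, genes$gene_id)]
  h <- h[order(h$ordinal, h$env_start), , drop = FALSE]
  h$subseq <- vapply(seq_len(nrow(h)), function(i) {
    aa <- genome$proteins[[h$protein_id[i]]]
    if (is.null(aa) || is.na(aa)) "" else substr(aa, h$env_start[i], h$env_end[i])
  }, character(1))
  h$occ_id <- paste0(cluster$cluster_id, "#", seq_len(nrow(h)))
  structure(list(cluster_id = cluster$cluster_id,
                 types = unique(h$domain_accession),
                 occ = h[, c("domain_accession", "protein_id", "ordinal",
                             "env_start", "subseq", "occ_id")]),
            class = "cluster_profile")
}

.jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

# unordered adjacent domain-type pairs along the cluster's domain string
.adjacent_pairs <- function(types_in_order) {
  n <- length(types_in_order)
  if (n < 2) return(character())
  a <- types_in_order[-n]; b <- types_in_order[-1]
  unique(paste(pmin(a, b), pmax(a, b), sep = "|"))
}

# greedy copy pairing for one shared domain type, given the identity matrix
.dss_greedy <- function(idm) {
  na <- nrow(idm); nb <- ncol(idm)
  total <- 0
  while (nrow(idm) && ncol(idm)) {
    best <- which(idm == max(idm), arr.ind = TRUE)[1, , drop = TRUE]
    total <- total + idm[best[1], best[2]]
    idm <- idm[-best[1], -best[2], drop = FALSE]
  }
  total / max(na, nb)
}

.dss_type <- function(seqs_a, seqs_b) {
  idm <- matrix(0, length(seqs_a), length(seqs_b))
  for (i in seq_along(seqs_a)) {
    for (j in seq_along(seqs_b)) idm[i, j] <- alignment_identity(seqs_a[i], seqs_b[j])
  }
  .dss_greedy(idm)
}

# all-vs-all unit-cost identities, batched one subject at a time; sequences
# are processed in sorted order so that the pattern is always the
# lexicographically smaller one, matching alignment_identity() exactly
.batch_identity <- function(seqs) {
  n <- length(seqs)
  m <- matrix(1, n, n)
  if (n < 2) return(m)
  sub <- .aa_unit_matrix()
  ord <- order(seqs)
  s <- seqs[ord]
  ms <- matrix(1, n, n)
  for (j in 2:n) {
    pats <- s[seq_len(j - 1)]
    ok <- nzchar(pats) & nzchar(s[j])
    if (any(ok)) {
      aln <- Biostrings::pairwiseAlignment(pats[ok], s[j], type = "global",
                                           substitutionMatrix = sub,
                                           gapOpening = 0, gapExtension = 1)
      ident <- Biostrings::nmatch(aln) /
        nchar(as.character(Biostrings::alignedPattern(aln)))
      ms[which(ok), j] <- ident
    }
    bad <- which(!ok)
    if (length(bad)) ms[bad, j] <- 0
    ms[j, seq_len(j - 1)] <- ms[seq_len(j - 1), j]
  }
  m[ord, ord] <- ms
  m
}

#' Anchor-weighted composite distance between two clusters
#'
#' `d = 1 - (wJ * J + wD * DSS + wA * AI)` where `J` is the Jaccard index of
#' domain-type sets, `AI` the Jaccard index of unordered adjacent domain-type
#' pairs along each cluster's gene-order domain string (0 when either cluster
#' has fewer than two domain positions) and `DSS` a per-type sequence
#' similarity: copies of a shared type are paired greedily by unit-cost
#' global-alignment identity, the summed identities divided by the larger copy
#' number, types unshared between the clusters scoring 0; each type's
#' contribution is weighted by `anchor_boost` for anchor domains and 1
#' otherwise.
#'
#' @param A,B `cluster_profile` objects (see [cluster_domain_profile()]).
#' @param w A `DistanceWeights`.
#' @param id_cache Optional precomputed identity cache (internal, used by
#'   [cluster_distance_matrix()]).
#' @return One-row `data.frame`: `a`, `b`, `J`, `DSS`, `AI`, `d`.
#' @export
cluster_distance <- function(A, B, w = distance_weights(), id_cache = NULL) {
  J <- .jaccard(A$types, B$types)
  AI <- if (nrow(A$occ) < 2 || nrow(B$occ) < 2) 0 else
    .jaccard(.adjacent_pairs(A$occ$domain_accession),
             .adjacent_pairs(B$occ$domain_accession))
  types <- union(A$types, B$types)
  shared <- intersect(A$types, B$types)
  u <- ifelse(types %in% w$anchor_domains, w$anchor_boost, 1)
  s <- stats::setNames(numeric(length(types)), types)
  for (t in shared) {
    sel_a <- A$occ$domain_accession == t
    sel_b <- B$occ$domain_accession == t
    s[t] <- if (!is.null(id_cache) && t %in% names(id_cache)) {
      .dss_greedy(id_cache[[t]][A$occ$occ_id[sel_a], B$occ$occ_id[sel_b],
                                drop = FALSE])
    } else {
      .dss_type(A$occ$subseq[sel_a], B$occ$subseq[sel_b])
    }
  }
  DSS <- sum(u * s) / sum(u)
  d <- 1 - (w$wJ * J + w$wD * DSS + w$wA * AI)
  data.frame(a = A$cluster_id, b = B$cluster_id, J = J, DSS = DSS, AI = AI,
             d = min(max(d, 0), 1), stringsAsFactors = FALSE)
}

#' All pairwise cluster distances
#'
#' @param clusters Cluster table (rows from [predict_all_clusters()]).
#' @param genomes Named list of `GenomeRecord` objects.
#' @param hits Combined domain-hit `data.frame`; a `genome_id` column, when
#'   present, is used to subset per genome.
#' @param w A `DistanceWeights`.
#' @param evalue_max Per-domain i-Evalue ceiling for profiles.
#' @return `data.frame` of distance records for every unordered pair.
#' @export
cluster_distance_matrix <- function(clusters, genomes, hits,
                                    w = distance_weights(), evalue_max = 1e-4) {
  profs <- lapply(seq_len(nrow(clusters)), function(i) {
    cl <- clusters[i, ]
    h <- if ("genome_id" %in% names(hits)) {
      hits[hits$genome_id == cl$genome_id, , drop = FALSE]
    } else hits
    cluster_domain_profile(cl, genomes[[cl$genome_id]], h, evalue_max)
  })
  # identity cache per domain type, shared across all pairs
  occ_all <- do.call(rbind, lapply(profs, `[[`, "occ"))
  id_cache <- lapply(split(occ_all, occ_all$domain_accession), function(o) {
    m <- .batch_identity(o$subseq)
    dimnames(m) <- list(o$occ_id, o$occ_id)
    m
  })
  n <- length(profs)
  out <- vector("list", n * (n - 1) / 2)
  k <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      k <- k + 1L
      out[[k]] <- cluster_distance(profs[[i]], profs[[j]], w, id_cache)
    }
  }
  do.call(rbind, out)
}

#' Build gene cluster families at a distance cutoff
#'
#' Families are the connected components of the graph whose vertices are the
#' clusters and whose edges are pairs with `d <= cutoff`. Singletons are
#' allowed.
#'
#' @param clusters Cluster table (must contain `cluster_id`; `species` is used
#'   for the multi-species flag when present).
#' @param distances Distance records from [cluster_distance_matrix()].
#' @param cutoff Distance cutoff in \[0, 1\].
#' @return List of class `gcf_families`: `families` (named list of member
#'   cluster-id vectors), `table` (`data.frame` gcf_id, cluster_id), `summary`
#'   (`data.frame` gcf_id, n_members, n_species, multi_species) and `cutoff`.
#' @export
build_families <- function(clusters, distances, cutoff) {
  ids <- clusters$cluster_id
  edges <- distances[distances$d <= cutoff, c("a", "b"), drop = FALSE]
  gr <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                      vertices = data.frame(name = ids))
  comp <- igraph::components(gr)
  memb <- comp$membership[ids]
  fams <- split(ids, memb)
  ord <- order(-lengths(fams), vapply(fams, min, character(1)))
  fams <- fams[ord]
  names(fams) <- sprintf("GCF_%03d", seq_along(fams))
  tab <- data.frame(gcf_id = rep(names(fams), lengths(fams)),
                    cluster_id = unlist(fams, use.names = FALSE),
                    stringsAsFactors = FALSE)
  sp <- if ("species" %in% names(clusters)) {
    stats::setNames(clusters$species, clusters$cluster_id)
  } else stats::setNames(rep(NA_character_, length(ids)), ids)
  summ <- data.frame(gcf_id = names(fams),
                     n_members = lengths(fams),
                     n_species = vapply(fams, function(m)
                       length(unique(stats::na.omit(sp[m]))), integer(1)),
                     stringsAsFactors = FALSE)
  summ$multi_species <- summ$n_species > 1
  rownames(summ) <- NULL
  structure(list(families = fams, table = tab, summary = summ, cutoff = cutoff),
            class = "gcf_families")
}

#' Sweep family cutoffs
#'
#' Rebuilds families along an ascending cutoff grid and records the family
#' count curve and the merge events between consecutive cutoffs (families at
#' one cutoff coalescing at the next; components are nested, so the count is
#' non-increasing).
#'
#' @param clusters,distances As for [build_families()].
#' @param grid Ascending numeric cutoffs (default 0.2 to 0.8 in steps of 0.05,
#'   13 values).
#' @return List: `curve` (`data.frame` cutoff, n_families), `families` (list of
#'   `gcf_families` per cutoff), `merges` (`data.frame` cutoff_from, cutoff_to,
#'   merged_families, into).
#' @export
sweep_cutoffs <- function(clusters, distances, grid = seq(0.2, 0.8, by = 0.05)) {
  stopifnot(!is.unsorted(grid))
  fams <- lapply(grid, function(ct) build_families(clusters, distances, ct))
  curve <- data.frame(cutoff = grid,
                      n_families = vapply(fams, function(f)
                        length(f$families), integer(1)))
  merges <- list()
  for (i in seq_along(grid)[-1]) {
    prev <- fams[[i - 1]]$table; cur <- fams[[i]]$table
    map <- unique(data.frame(
      from = prev$gcf_id,
      to = cur$gcf_id[match(prev$cluster_id, cur$cluster_id)],
      stringsAsFactors = FALSE))
    tab <- table(map$to)
    for (target in names(tab)[tab > 1]) {
      merges[[length(merges) + 1L]] <- data.frame(
        cutoff_from = grid[i - 1], cutoff_to = grid[i],
        merged_families = paste(sort(map$from[map$to == target]), collapse = ","),
        into = target, stringsAsFactors = FALSE)
    }
  }
  merges <- if (length(merges)) do.call(rbind, merges) else
    data.frame(cutoff_from = numeric(), cutoff_to = numeric(),
               merged_families = character(), into = character())
  list(curve = curve, families = fams, merges = merges)
}

#' Select one representative genome per species
#'
#' Representative = fewest contigs, then largest total assembly length, then
#' lexicographically smallest genome id.
#'
#' @param genomes Named list of `GenomeRecord` objects.
#' @return Named character vector mapping species to genome id.
#' @export
dereplicate_species <- function(genomes) {
  df <- data.frame(genome_id = vapply(genomes, `[[`, character(1), "genome_id"),
                   species = vapply(genomes, `[[`, character(1), "species"),
                   n_contigs = vapply(genomes, function(g)
                     length(g$contigs), integer(1)),
                   bp = vapply(genomes, function(g)
                     sum(nchar(g$contigs)), numeric(1)),
                   stringsAsFactors = FALSE)
  df <- df[order(df$species, df$n_contigs, -df$bp, df$genome_id), , drop = FALSE]
  df <- df[!duplicated(df$species), , drop = FALSE]
  stats::setNames(df$genome_id, df$species)
}
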