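# Cluster border prediction from shared promoter motifs.
#
# Principle: genes of a co-regulated cluster share an anchor-linked promoter
# motif. Candidate motifs are the k-mers of the anchor promoter; each is scored
# by an upper-tail binomial test of how many neighbour promoters in a candidate
# gene range contain it, against the genome-wide promoter background frequency.

#' Border-predictor configuration
#'
#' @param k Motif length in bp (>= 4).
#' @param L_up Maximum promoter extent upstream of the gene start, bp.
#' @param L_down Promoter extent into the gene, bp.
#' @param K Maximum number of genes considered on each side of the anchor.
#' @param q_max Background-frequency ceiling for candidate motifs (0 < q < 1);
#'   motifs present in more than this fraction of promoters are ignored as
#'   ubiquitous.
#' @param alpha Family-wise significance level after Bonferroni correction over
#'   the candidate motifs tested.
#' @param seed Unused by default (prediction is deterministic); reserved for
#'   tie-broken randomness.
#' @return A list of class `PredictorConfig`.
#' @export
predictor_config <- function(k = 8L, L_up = 1000L, L_down = 50L, K = 10L,
                             q_max = 0.10, alpha = 0.05, seed = NULL) {
  stopifnot(k >= 4, K >= 1, q_max > 0, q_max < 1, alpha > 0, alpha < 1,
            L_up >= 0, L_down >= 0)
  structure(list(k = as.integer(k), L_up = as.integer(L_up),
                 L_down = as.integer(L_down), K = as.integer(K),
                 q_max = q_max, alpha = alpha, seed = seed),
            class = "PredictorConfig")
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Canonical k-mers of a sequence
#'
#' Every k-mer is represented by the lexicographic minimum of itself and its
#' reverse complement, so that a motif and its complement count as one.
#' K-mers containing non-ACGT symbols are dropped.
#'
#' @param seq Nucleotide string.
#' @param k K-mer length.
#' @return Character vector of unique canonical k-mers (possibly empty).
#' @export
canonical_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character())
  seq <- toupper(seq)
  km <- unique(substring(seq, 1:(n - k + 1L), k:n))
  km <- km[!grepl("[^ACGT]", km)]
  if (!length(km)) return(character())
  unique(pmin(km, .revcomp(km)))
}

#' Extract promoter regions for every gene of a genome
#'
#' The promoter of a gene is up to `L_up` bp upstream of its transcription
#' start (strand-aware), truncated at the neighbouring gene boundary and at the
#' contig edge, plus `L_down` bp into the gene. Divergently transcribed
#' adjacent pairs share their intergenic region; the partner gene id is
#' recorded in `shared`. Sequences of minus-strand genes are
#' reverse-complemented.
#'
#' @param genome A `GenomeRecord`.
#' @param cfg A `PredictorConfig`.
#' @return `data.frame` with columns `gene_id`, `contig_id`, `start`, `end`
#'   (0-based half-open span on the contig), `strand`, `shared`, `seq`.
#' @export
extract_promoters <- function(genome, cfg = predictor_config()) {
  out <- vector("list", length(genome$contigs))
  for (ci in seq_along(genome$contigs)) {
    cid <- names(genome$contigs)[ci]
    contig <- genome$contigs[[ci]]
    clen <- nchar(contig)
    g <- genome$genes[genome$genes$contig_id == cid, , drop = FALSE]
    if (!nrow(g)) next
    n <- nrow(g)
    prev_end <- c(0L, g$end[-n])
    next_start <- c(g$start[-1], clen)
    up0 <- integer(n); up1 <- integer(n); shared <- rep(NA_character_, n)
    for (i in seq_len(n)) {
      if (g$strand[i] == "+") {
        s <- max(min(prev_end[i], g$start[i]), g$start[i] - cfg$L_up, 0L)
        e <- min(g$start[i] + cfg$L_down, g$end[i])
        if (i > 1 && g$strand[i - 1] == "-") shared[i] <- g$gene_id[i - 1]
      } else {
        s <- max(g$end[i] - cfg$L_down, g$start[i])
        e <- min(max(next_start[i], g$end[i]), g$end[i] + cfg$L_up, clen)
        if (i < n && g$strand[i + 1] == "+") shared[i] <- g$gene_id[i + 1]
      }
      up0[i] <- s; up1[i] <- e
    }
    seqs <- substring(contig, up0 + 1L, up1)
    neg <- g$strand == "-" & nzchar(seqs)
    if (any(neg)) seqs[neg] <- .revcomp(seqs[neg])
    out[[ci]] <- data.frame(gene_id = g$gene_id, contig_id = cid,
                            start = up0, end = up1, strand = g$strand,
                            shared = shared, seq = seqs,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- res$gene_id
  res
}

#' Genome-wide promoter background frequency of canonical k-mers
#'
#' @param promoters Promoter table from [extract_promoters()].
#' @param cfg A `PredictorConfig`.
#' @return Named numeric vector: for each canonical k-mer observed in any
#'   promoter, the fraction of promoters containing it (on either strand).
#' @export
compute_motif_background <- function(promoters, cfg = predictor_config()) {
  if (!nrow(promoters)) stop("no promoters")
  per <- lapply(promoters$seq, canonical_kmers, k = cfg$k)
  counts <- table(unlist(per, use.names = FALSE))
  stats::setNames(as.numeric(counts) / nrow(promoters), names(counts))
}

#' Upper-tail binomial motif enrichment probability
#'
#' Probability of observing at least `m` motif-containing promoters among `n`
#' when each contains the motif independently with background probability `p0`.
#'
#' @param n Number of promoters considered (>= 0).
#' @param m Number containing the motif (0 <= m <= n).
#' @param p0 Background containment probability, strictly inside (0, 1).
#' @return `P(X >= m | n, p0)`; equals 1 at `m = 0`.
#' @export
score_candidate <- function(n, m, p0) {
  if (any(p0 <= 0) || any(p0 >= 1)) stop("p0 must lie strictly in (0, 1)")
  stopifnot(all(m >= 0), all(m <= n))
  stats::pbinom(m - 1, n, p0, lower.tail = FALSE)
}

#' Predict a cluster around an ICS anchor from shared promoter motifs
#'
#' Candidate motifs are the canonical k-mers of the anchor promoter whose
#' genome-wide background frequency does not exceed `q_max`. Candidate ranges
#' are all contiguous ordinal intervals containing the anchor within `K` genes
#' on each side (truncated at contig ends). Each (motif, range) pair is scored
#' with [score_candidate()] applied to the anchor's *neighbours* in the range
#' (the anchor promoter contains every candidate motif by construction, so it
#' is not counted as evidence). Neighbours are counted as promoter-region
#' units: a divergently transcribed pair shares one intergenic region and
#' contributes a single observation, and the anchor's own divergent partner is
#' excluded from the evidence. The pair minimising the raw probability is
#' selected; ties prefer the smaller range, then the lexicographically smaller
#' motif. The reported `p_adjusted` is Bonferroni-corrected over the number of
#' candidate motifs, and `is_bgc` is `TRUE` iff the selected range contains at
#' least one neighbour and `p_adjusted <= alpha`.
#'
#' @param genome A `GenomeRecord`.
#' @param anchor Anchor gene id, or one row of [find_ics_anchors()] output.
#' @param cfg A `PredictorConfig`.
#' @param promoters,background Optional precomputed promoter table and
#'   background (recomputed from `genome` when `NULL`).
#' @return One-row `data.frame`: `genome_id`, `cluster_id`, `contig_id`,
#'   `anchor_gene`, `anchor_ordinal`, `start_ordinal`, `end_ordinal`,
#'   `n_genes`, `start_bp`, `end_bp`, `motif` (`NA` for a standalone ICS),
#'   `p_raw`, `p_adjusted`, `n_motifs_tested`, `is_bgc`.
#' @export
predict_cluster <- function(genome, anchor, cfg = predictor_config(),
                            promoters = NULL, background = NULL) {
  anchor_id <- if (is.character(anchor)) anchor else anchor$gene_id
  if (!anchor_id %in% genome$genes$gene_id) stop("unknown anchor gene: ", anchor_id)
  if (is.null(promoters)) promoters <- extract_promoters(genome, cfg)
  if (is.null(background)) background <- compute_motif_background(promoters, cfg)
  arow <- genome$genes[anchor_id, ]
  a_ord <- arow$ordinal
  g <- genome$genes[genome$genes$contig_id == arow$contig_id, , drop = FALSE]
  win <- g[g$ordinal >= a_ord - cfg$K & g$ordinal <= a_ord + cfg$K, , drop = FALSE]
  win <- win[order(win$ordinal), , drop = FALSE]
  a_idx <- which(win$gene_id == anchor_id)

  standalone <- function() {
    data.frame(genome_id = genome$genome_id,
               cluster_id = paste0(genome$genome_id, ".", anchor_id),
               contig_id = arow$contig_id, anchor_gene = anchor_id,
               anchor_ordinal = a_ord, start_ordinal = a_ord,
               end_ordinal = a_ord, n_genes = 1L,
               start_bp = arow$start, end_bp = arow$end,
               motif = NA_character_, p_raw = 1, p_adjusted = 1,
               n_motifs_tested = 0L, is_bgc = FALSE, stringsAsFactors = FALSE)
  }

  aseq <- promoters[anchor_id, "seq"]
  if (is.na(aseq) || !nzchar(aseq)) return(standalone())
  cand <- canonical_kmers(aseq, cfg$k)
  p0 <- background[cand]
  p0[is.na(p0)] <- 0
  keep <- p0 > 0 & p0 <= cfg$q_max & p0 < 1
  cand <- cand[keep]; p0 <- unname(p0[keep])
  if (!length(cand)) return(standalone())

  # motif-in-promoter membership, motifs x window genes
  sets <- lapply(win$gene_id, function(id) {
    s <- promoters[id, "seq"]
    if (is.na(s)) character() else canonical_kmers(s, cfg$k)
  })
  M <- vapply(sets, function(s) cand %in% s, logical(length(cand)))
  M <- matrix(M, nrow = length(cand))

  # Promoter-region units: a divergently transcribed pair shares one
  # intergenic region, so two such genes inside the evidence set are one
  # observation (success = motif in either promoter); the anchor's own
  # divergent partner shares the anchor promoter and is excluded entirely.
  partner_idx <- match(promoters[win$gene_id, "shared"], win$gene_id)
  best <- NULL
  for (i in seq_len(a_idx)) {
    for (j in a_idx:nrow(win)) {
      idx <- setdiff(i:j, a_idx)
      pa <- partner_idx[a_idx]
      if (!is.na(pa)) idx <- setdiff(idx, pa)
      succ <- NULL
      used <- logical(nrow(win))
      for (gidx in idx) {
        if (used[gidx]) next
        used[gidx] <- TRUE
        col <- M[, gidx]
        pg <- partner_idx[gidx]
        if (!is.na(pg) && pg %in% idx && !used[pg]) {
          used[pg] <- TRUE
          col <- col | M[, pg]
        }
        succ <- cbind(succ, col)
      }
      n_nb <- if (is.null(succ)) 0L else ncol(succ)
      m_nb <- if (is.null(succ)) rep(0L, length(cand)) else rowSums(succ)
      p <- stats::pbinom(m_nb - 1L, n_nb, p0, lower.tail = FALSE)
      o <- order(p, cand)[1]
      cur <- list(p = p[o], motif = cand[o], i = i, j = j, size = j - i)
      if (is.null(best) ||
          cur$p < best$p ||
          (cur$p == best$p && (cur$size < best$size ||
                               (cur$size == best$size && cur$motif < best$motif)))) {
        best <- cur
      }
    }
  }
  range_genes <- win[best$i:best$j, , drop = FALSE]
  p_adj <- min(1, best$p * length(cand))
  data.frame(genome_id = genome$genome_id,
             cluster_id = paste0(genome$genome_id, ".", anchor_id),
             contig_id = arow$contig_id, anchor_gene = anchor_id,
             anchor_ordinal = a_ord,
             start_ordinal = range_genes$ordinal[1],
             end_ordinal = range_genes$ordinal[nrow(range_genes)],
             n_genes = nrow(range_genes),
             start_bp = min(range_genes$start), end_bp = max(range_genes$end),
             motif = best$motif, p_raw = best$p, p_adjusted = p_adj,
             n_motifs_tested = length(cand),
             is_bgc = (best$j > best$i) && p_adj <= cfg$alpha,
             stringsAsFactors = FALSE)
}

#' Predict clusters for every ICS anchor of a genome
#'
#' Convenience wrapper computing promoters and background once.
#'
#' @param genome A `GenomeRecord`.
#' @param anchors Anchor table from [find_ics_anchors()] (rows for this genome).
#' @param cfg A `PredictorConfig`.
#' @return Cluster table with one row per anchor (see [predict_cluster()]),
#'   plus a `species` column.
#' @export
predict_all_clusters <- function(genome, anchors, cfg = predictor_config()) {
  if (!nrow(anchors)) {
    out <- predict_cluster(genome, genome$genes$gene_id[1], cfg)[0, ]
    out$species <- character()
    return(out)
  }
  promoters <- extract_promoters(genome, cfg)
  background <- compute_motif_background(promoters, cfg)
  rows <- lapply(anchors$gene_id, function(id) {
    predict_cluster(genome, id, cfg, promoters, background)
  })
  out <- do.call(rbind, rows)
  out$species <- genome$species
  rownames(out) <- NULL
  out
}
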