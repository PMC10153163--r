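# Microsynteny-conservation ("linkage disequilibrium") validation of GCFs.
#
# "LD" here is cross-species conservation of the gene neighbourhood around an
# anchor, compared against the neighbourhoods of universal single-copy genes
# (BUSCOs), which stand in for genome-wide background conservation. It is a
# selection signal, not population-genetic r^2.

#' LD-test configuration
#'
#' @param w Window half-width around the anchor, in genes (>= 1).
#' @param p_sig Empirical-p threshold for a `SIGNIFICANT` verdict.
#' @param p_strong Threshold for a `STRONG` verdict (`p_sig <= p_strong < 1`).
#' @return A list of class `LDConfig`.
#' @export
ld_config <- function(w = 5L, p_sig = 0.05, p_strong = 0.07) {
  stopifnot(w >= 1, p_sig > 0, p_sig <= p_strong, p_strong < 1)
  structure(list(w = as.integer(w), p_sig = p_sig, p_strong = p_strong),
            class = "LDConfig")
}

#' Orthogroups in the gene window around an anchor
#'
#' Collects the orthogroups of the genes whose ordinal lies within `w` of the
#' anchor on its contig (truncated at contig ends). The anchor's own
#' orthogroup is excluded so that the score measures neighbourhood, not
#' anchor, conservation.
#'
#' @param genome A `GenomeRecord`.
#' @param anchor_gene Gene id of the anchor.
#' @param orthogroups An `orthogroup_map`.
#' @param w Window half-width in genes.
#' @return Character vector of orthogroup ids.
#' @export
window_orthogroups <- function(genome, anchor_gene, orthogroups, w = 5L) {
  g <- genome$genes
  if (!anchor_gene %in% g$gene_id) stop("unknown gene: ", anchor_gene)
  a <- g[anchor_gene, ]
  win <- g[g$contig_id == a$contig_id &
             abs(g$ordinal - a$ordinal) <= w &
             g$gene_id != anchor_gene, , drop = FALSE]
  ogs <- unique(stats::na.omit(orthogroup_of(orthogroups, win$gene_id)))
  setdiff(ogs, orthogroup_of(orthogroups, anchor_gene))
}

#' Mean pairwise conservation of orthogroup windows
#'
#' Mean Jaccard index over all unordered pairs of species windows; a pair in
#' which either window is empty contributes 0. Permutation-invariant over
#' species.
#'
#' @param windows Named list (one element per species) of orthogroup-id
#'   vectors.
#' @return Score in \[0, 1\].
#' @export
conservation_score <- function(windows) {
  if (length(windows) < 2) stop("need windows from at least two species")
  n <- length(windows)
  total <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- windows[[i]]; b <- windows[[j]]
      total <- total + if (!length(a) || !length(b)) 0 else .jaccard(a, b)
    }
  }
  total / (n * (n - 1) / 2)
}

#' Empirical upper-tail p-value with pseudocount
#'
#' `p = (1 + #\{null >= observed\}) / (1 + n_null)`; never exactly zero.
#'
#' @param observed Observed statistic.
#' @param null Numeric vector of null statistics.
#' @return Empirical p in (0, 1\].
#' @export
empirical_pvalue <- function(observed, null) {
  (1 + sum(null >= observed)) / (1 + length(null))
}

#' Microsynteny-conservation (LD) test of one GCF against a BUSCO null
#'
#' The observed statistic is the conservation score of the windows around each
#' member species' ICS anchor (one representative genome per species; a
#' species with several member clusters contributes the one whose anchor has
#' the smallest gene ordinal). The null distribution is the same score
#' computed around every BUSCO anchor present in all of those genomes. High
#' conservation relative to the null indicates selection maintaining the
#' cluster; significance is the upper-tail empirical percentile rank.
#'
#' @param gcf_id Family id (metadata only).
#' @param members Member cluster ids.
#' @param clusters Cluster table.
#' @param genomes Named list of `GenomeRecord` objects.
#' @param buscos BUSCO anchor table from [read_busco_table()].
#' @param orthogroups An `orthogroup_map`.
#' @param representatives Species -> genome id map.
#' @param cfg An `LDConfig`.
#' @return List of class `ld_result`: `gcf_id`, `observed`, `null`, `n_null`,
#'   `p`, `verdict` (`SIGNIFICANT` / `STRONG` / `NOT_SIGNIFICANT`),
#'   `n_species`.
#' @export
ld_test <- function(gcf_id, members, clusters, genomes, buscos, orthogroups,
                    representatives, cfg = ld_config()) {
  reps <- .representative_clusters(members, clusters, representatives)
  if (nrow(reps) < 2) stop("fewer than two usable species in ", gcf_id)
  obs_windows <- lapply(seq_len(nrow(reps)), function(i) {
    window_orthogroups(genomes[[reps$genome_id[i]]], reps$anchor_gene[i],
                       orthogroups, cfg$w)
  })
  names(obs_windows) <- reps$.species
  observed <- conservation_score(obs_windows)

  gset <- reps$genome_id
  b <- buscos[buscos$genome_id %in% gset, , drop = FALSE]
  tab <- table(b$busco_id)
  usable <- names(tab)[tab == length(gset)]
  if (length(usable) < 20) {
    stop("only ", length(usable), " BUSCO anchors usable in all ",
         length(gset), " genomes; need >= 20")
  }
  null <- vapply(usable, function(bid) {
    rows <- b[b$busco_id == bid, , drop = FALSE]
    wins <- lapply(seq_len(nrow(rows)), function(i) {
      window_orthogroups(genomes[[rows$genome_id[i]]], rows$gene_id[i],
                         orthogroups, cfg$w)
    })
    conservation_score(wins)
  }, numeric(1))
  p <- empirical_pvalue(observed, null)
  verdict <- if (p < cfg$p_sig) "SIGNIFICANT"
  else if (p < cfg$p_strong) "STRONG"
  else "NOT_SIGNIFICANT"
  structure(list(gcf_id = gcf_id, observed = observed, null = unname(null),
                 n_null = length(null), p = p, verdict = verdict,
                 n_species = nrow(reps)),
            class = "ld_result")
}
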