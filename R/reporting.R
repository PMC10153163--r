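# Headline descriptive summaries: per-genome counts, backbone-variant
# proportions, cluster sizes, domain frequencies, correlations and
# class-size comparisons.

#' Summarize genomes, anchors and cluster predictions
#'
#' @param genomes Named list of `GenomeRecord` objects.
#' @param anchors Combined anchor table ([find_ics_anchors()] rows, all
#'   genomes).
#' @param clusters Combined cluster table.
#' @param representatives Optional species -> genome id map; when supplied the
#'   global aggregates are computed on the dereplicated representatives only.
#' @return List: `per_genome` (`data.frame` with genome_id, species, n_genes,
#'   n_contigs, assembly_bp, n_ics_genes, n_ics_bgcs, bgc_fraction) and
#'   `global` (variant_proportions, mean_cluster_bp, mean_genes_per_cluster,
#'   in_cluster_ics_fraction, n_ics_genes, n_ics_bgcs).
#' @export
summarize_genomes <- function(genomes, anchors, clusters,
                              representatives = NULL) {
  per <- do.call(rbind, lapply(genomes, function(g) {
    na <- sum(anchors$genome_id == g$genome_id)
    nb <- sum(clusters$genome_id == g$genome_id & clusters$is_bgc)
    data.frame(genome_id = g$genome_id, species = g$species,
               n_genes = nrow(g$genes), n_contigs = length(g$contigs),
               assembly_bp = sum(nchar(g$contigs)),
               n_ics_genes = na, n_ics_bgcs = nb,
               bgc_fraction = if (na > 0) nb / na else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  keep <- if (!is.null(representatives)) unname(representatives) else names(genomes)
  a <- anchors[anchors$genome_id %in% keep, , drop = FALSE]
  cl <- clusters[clusters$genome_id %in% keep, , drop = FALSE]
  bgc <- cl[cl$is_bgc, , drop = FALSE]
  vp <- if (nrow(a)) table(a$variant) / nrow(a) else table(character())
  global <- list(
    variant_proportions = stats::setNames(as.numeric(vp), names(vp)),
    mean_cluster_bp = if (nrow(bgc)) mean(bgc$end_bp - bgc$start_bp) else NA_real_,
    mean_genes_per_cluster = if (nrow(bgc)) mean(bgc$n_genes) else NA_real_,
    in_cluster_ics_fraction = if (nrow(a)) nrow(bgc) / nrow(a) else NA_real_,
    n_ics_genes = nrow(a), n_ics_bgcs = nrow(bgc))
  list(per_genome = per, global = global)
}

#' Fraction of clusters containing each domain type
#'
#' For every domain accession, the fraction of clusters with at least one gene
#' carrying it. By default, domains resident on backbone (anchor) proteins are
#' excluded from the table — they track the backbone variant rather than
#' cluster content — except the ICS domain itself, which is present in every
#' cluster by construction.
#'
#' @param clusters Cluster table.
#' @param genomes Named list of `GenomeRecord` objects.
#' @param hits Combined domain-hit `data.frame`.
#' @param cfg A `DetectionConfig`.
#' @param include_backbone_domains Keep backbone-resident domains.
#' @return `data.frame` with `domain_accession`, `n_clusters`, `fraction`,
#'   sorted by decreasing fraction.
#' @export
domain_frequency_table <- function(clusters, genomes, hits,
                                   cfg = detection_config(),
                                   include_backbone_domains = FALSE) {
  hits <- hits[hits$i_evalue <= cfg$evalue_max, , drop = FALSE]
  by_gene <- split(hits$domain_accession, hits$protein_id)
  sets <- lapply(seq_len(nrow(clusters)), function(i) {
    cl <- clusters[i, ]
    genes <- cluster_genes(cl, genomes[[cl$genome_id]])$gene_id
    unique(unlist(by_gene[genes], use.names = FALSE))
  })
  if (!include_backbone_domains) {
    backbone <- setdiff(
      unique(unlist(by_gene[clusters$anchor_gene], use.names = FALSE)),
      cfg$ics_domain)
    sets <- lapply(sets, setdiff, y = backbone)
  }
  tab <- table(unlist(sets, use.names = FALSE))
  out <- data.frame(domain_accession = names(tab),
                    n_clusters = as.integer(tab),
                    fraction = as.numeric(tab) / nrow(clusters),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$fraction, out$domain_accession), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pearson correlation with two-sided p
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`, both non-constant.
#' @param labels Optional variable names recorded in the output.
#' @return `data.frame` with `var_x`, `var_y`, `n`, `r`, `p`.
#' @export
correlate <- function(x, y, labels = c("x", "y")) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant vector")
  ct <- stats::cor.test(x, y, method = "pearson")
  data.frame(var_x = labels[1], var_y = labels[2], n = length(x),
             r = unname(ct$estimate), p = ct$p.value, stringsAsFactors = FALSE)
}

#' Welch comparisons of BGC class sizes against the ICS class
#'
#' @param class_lengths Named list mapping BGC class to a numeric vector of
#'   cluster lengths (bp); must contain `ref_class`.
#' @param ref_class Reference class compared against (default `"ICS"`).
#' @param alpha Flagging level on the BH-adjusted p.
#' @return `data.frame`: `class`, `n`, `mean_bp`, `t`, `p`, `p_adj`,
#'   `flagged`. Classes with fewer than two observations are skipped with a
#'   warning.
#' @export
compare_sizes <- function(class_lengths, ref_class = "ICS", alpha = 0.05) {
  if (!ref_class %in% names(class_lengths)) {
    stop("reference class '", ref_class, "' absent")
  }
  ref <- class_lengths[[ref_class]]
  if (length(ref) < 2) stop("reference class needs >= 2 observations")
  others <- setdiff(names(class_lengths), ref_class)
  small <- others[vapply(class_lengths[others], length, integer(1)) < 2]
  if (length(small)) {
    warning("class(es) with < 2 observations skipped: ",
            paste(small, collapse = ", "))
  }
  others <- setdiff(others, small)
  rows <- lapply(others, function(cls) {
    tt <- stats::t.test(class_lengths[[cls]], ref, var.equal = FALSE)
    data.frame(class = cls, n = length(class_lengths[[cls]]),
               mean_bp = mean(class_lengths[[cls]]),
               t = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(class = character(), n = integer(), mean_bp = numeric(),
                      t = numeric(), p = numeric(), p_adj = numeric(),
                      flagged = logical()))
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$flagged <- out$p_adj <= alpha
  rownames(out) <- NULL
  out
}
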