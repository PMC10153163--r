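# ICS backbone detection and domain-based gene classification.

#' Curated specialized-metabolism domain list
#'
#' Reads the editable curated list of Pfam domains associated with specialized
#' metabolite (SM) biosynthesis and with transport/regulation that ships with
#' the package. The defaults follow the condensed antiSMASH-style domain
#' families commonly used to flag biosynthetic genes (cytochrome p450s,
#' oxidoreductases, transferases, isocyanide hydratase, backbone domains, ...).
#'
#' @param path Optional path to a replacement TSV with columns
#'   `accession`, `name`, `category` (`biosynthetic` or `transport_regulation`).
#' @return `data.frame` with the three columns.
#' @export
curated_sm_domains <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "sm_biosynthetic_domains.tsv",
                        package = "icsmine", mustWork = TRUE)
  }
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Detection configuration
#'
#' Parameters governing ICS anchor detection and domain-based classification.
#' The ICS backbone is identified by the DIT1_PvcA Pfam domain (PF05141) with a
#' per-domain i-Evalue at or below `evalue_max` (default 1e-4). The remaining
#' accession sets drive backbone-variant classification and hybrid-cluster
#' censusing.
#'
#' @param ics_domain ICS domain accession.
#' @param evalue_max Per-domain i-Evalue ceiling (> 0).
#' @param tauD_domains Taurine-dioxygenase domain accessions (ICS-TauD variant).
#' @param nrps_domains NRPS-associated accessions (adenylation/AMP-binding,
#'   phosphopantetheine loading, condensation).
#' @param pks_domains PKS-associated accessions (ketosynthase, acyltransferase).
#' @param terpene_domains Terpene-synthase/cyclase accessions.
#' @param sm_domains Curated SM domain table, see [curated_sm_domains()].
#' @return A list of class `DetectionConfig`.
#' @export
detection_config <- function(ics_domain = "PF05141",
                             evalue_max = 1e-4,
                             tauD_domains = c("PF02668"),
                             nrps_domains = c("PF00501", "PF00550", "PF00668"),
                             pks_domains = c("PF00109", "PF02801", "PF00698"),
                             terpene_domains = c("PF01397", "PF03936", "PF19086"),
                             sm_domains = curated_sm_domains()) {
  stopifnot(nzchar(ics_domain), evalue_max > 0)
  structure(list(ics_domain = ics_domain, evalue_max = evalue_max,
                 tauD_domains = tauD_domains, nrps_domains = nrps_domains,
                 pks_domains = pks_domains, terpene_domains = terpene_domains,
                 sm_domains = sm_domains),
            class = "DetectionConfig")
}

# hits for one protein, thresholded
.hits_for <- function(hits, protein_id, evalue_max) {
  hits[hits$protein_id == protein_id & hits$i_evalue <= evalue_max, , drop = FALSE]
}

#' Classify an ICS backbone variant from its domain hits
#'
#' ICS proteins fall into three architectures: monodomain ICS (`MONO`),
#' ICS-dioxygenase (`ICS_TAUD`) and the multidomain ICS-NRPS-like variant
#' (`ICS_NRPS_LIKE`, carrying AMP-binding/PP-loading domains). NRPS-domain
#' co-occurrence takes precedence over TauD when both are present.
#'
#' @param hits_on_protein Domain hits of one protein (already thresholded or
#'   not; the qualifying ICS hit must pass `cfg$evalue_max`).
#' @param cfg A `DetectionConfig`.
#' @return One of `"MONO"`, `"ICS_TAUD"`, `"ICS_NRPS_LIKE"`.
#' @export
classify_backbone_variant <- function(hits_on_protein, cfg = detection_config()) {
  ok <- hits_on_protein$domain_accession == cfg$ics_domain &
    hits_on_protein$i_evalue <= cfg$evalue_max
  if (!any(ok)) stop("no qualifying ICS domain hit on this protein")
  accs <- unique(hits_on_protein$domain_accession[hits_on_protein$i_evalue <= cfg$evalue_max])
  if (any(accs %in% cfg$nrps_domains)) return("ICS_NRPS_LIKE")
  if (any(accs %in% cfg$tauD_domains)) return("ICS_TAUD")
  "MONO"
}

#' Find ICS anchor genes in a genome
#'
#' An anchor is any gene whose protein carries at least one ICS-domain hit with
#' i-Evalue at or below the configured ceiling. The result is invariant to the
#' order of the input hits.
#'
#' @param genome A `GenomeRecord`.
#' @param hits Domain-hit `data.frame` for this genome's proteins.
#' @param cfg A `DetectionConfig`.
#' @return `data.frame` with one row per anchor: `genome_id`, `gene_id`,
#'   `contig_id`, `ordinal`, `variant`, sorted by contig and ordinal.
#' @export
find_ics_anchors <- function(genome, hits, cfg = detection_config()) {
  ics <- hits[hits$domain_accession == cfg$ics_domain &
                hits$i_evalue <= cfg$evalue_max, , drop = FALSE]
  ids <- intersect(genome$genes$gene_id, unique(ics$protein_id))
  empty <- data.frame(genome_id = character(), gene_id = character(),
                      contig_id = character(), ordinal = integer(),
                      variant = character(), stringsAsFactors = FALSE)
  if (!length(ids)) return(empty)
  g <- genome$genes[ids, , drop = FALSE]
  variant <- vapply(ids, function(id) {
    classify_backbone_variant(hits[hits$protein_id == id, , drop = FALSE], cfg)
  }, character(1))
  out <- data.frame(genome_id = genome$genome_id, gene_id = g$gene_id,
                    contig_id = g$contig_id, ordinal = g$ordinal,
                    variant = unname(variant), stringsAsFactors = FALSE)
  out <- out[order(match(out$contig_id, names(genome$contigs)), out$ordinal), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag genes by specialized-metabolism domain content
#'
#' Labels every gene of a genome as `BIOSYNTHETIC` (carries a curated
#' SM-biosynthesis domain), `TRANSPORT_REGULATION` (carries a curated
#' transporter/regulator domain but no biosynthetic one), `OTHER` (has domain
#' hits outside the curated lists) or `NO_DOMAIN` (no hit at or below the
#' e-value ceiling). Deterministic.
#'
#' @inheritParams find_ics_anchors
#' @return Named character vector keyed by gene id.
#' @export
flag_biosynthetic_genes <- function(genome, hits, cfg = detection_config()) {
  hits <- hits[hits$i_evalue <= cfg$evalue_max, , drop = FALSE]
  bio <- cfg$sm_domains$accession[cfg$sm_domains$category == "biosynthetic"]
  tr <- cfg$sm_domains$accession[cfg$sm_domains$category == "transport_regulation"]
  by_gene <- split(hits$domain_accession, hits$protein_id)
  out <- vapply(genome$genes$gene_id, function(id) {
    accs <- by_gene[[id]]
    if (is.null(accs) || !length(accs)) return("NO_DOMAIN")
    if (any(accs %in% bio)) return("BIOSYNTHETIC")
    if (any(accs %in% tr)) return("TRANSPORT_REGULATION")
    "OTHER"
  }, character(1))
  stats::setNames(out, genome$genes$gene_id)
}

#' Census hybrid backbone content of predicted clusters
#'
#' Labels each cluster with the subset of NRPS / PKS / terpene domain classes
#' present on any of its genes (backbone included: ICS-NRPS-like backbones
#' count toward NRPS). Aggregate counts are returned alongside.
#'
#' @param clusters Cluster table (rows as returned by [predict_cluster()]).
#' @param genomes Named list of `GenomeRecord` objects.
#' @param hits Combined domain-hit `data.frame` (all genomes).
#' @param cfg A `DetectionConfig`.
#' @return List with `labels` (per-cluster `data.frame` with logical columns
#'   `nrps`, `pks`, `terpene` and a combined `label` string) and `counts`
#'   (named integer vector: n_nrps, n_pks, n_terpene, n_hybrid, n_plain).
#' @export
hybrid_census <- function(clusters, genomes, hits, cfg = detection_config()) {
  if (!nrow(clusters)) {
    return(list(labels = data.frame(cluster_id = character(), nrps = logical(),
                                    pks = logical(), terpene = logical(),
                                    label = character(), stringsAsFactors = FALSE),
                counts = c(n_nrps = 0L, n_pks = 0L, n_terpene = 0L,
                           n_hybrid = 0L, n_plain = 0L)))
  }
  hits <- hits[hits$i_evalue <= cfg$evalue_max, , drop = FALSE]
  by_gene <- split(hits$domain_accession, hits$protein_id)
  lab <- lapply(seq_len(nrow(clusters)), function(i) {
    cl <- clusters[i, ]
    genes <- cluster_genes(cl, genomes[[cl$genome_id]])$gene_id
    accs <- unique(unlist(by_gene[genes], use.names = FALSE))
    c(nrps = any(accs %in% cfg$nrps_domains),
      pks = any(accs %in% cfg$pks_domains),
      terpene = any(accs %in% cfg$terpene_domains))
  })
  m <- do.call(rbind, lab)
  labels <- data.frame(cluster_id = clusters$cluster_id,
                       nrps = m[, "nrps"], pks = m[, "pks"],
                       terpene = m[, "terpene"], stringsAsFactors = FALSE)
  labels$label <- apply(m, 1, function(r) {
    paste(c("NRPS", "PKS", "TERPENE")[r], collapse = "+")
  })
  counts <- c(n_nrps = sum(labels$nrps), n_pks = sum(labels$pks),
              n_terpene = sum(labels$terpene),
              n_hybrid = sum(rowSums(m) > 0),
              n_plain = sum(rowSums(m) == 0))
  list(labels = labels, counts = counts)
}
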