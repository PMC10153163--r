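# Internal coordinate convention: 0-based half-open [start, end) on the contig.
# GFF3 and GenBank I/O use the standard 1-based inclusive convention.

#' Construct a genome record
#'
#' A `GenomeRecord` bundles one annotated assembly: its contig sequences, an
#' ordered gene table and the protein sequence of each gene. It is the
#' per-genome unit of analysis for all downstream operations.
#'
#' @param genome_id Unique identifier of the assembly.
#' @param contigs Named character vector (or `DNAStringSet`) of contig
#'   nucleotide sequences.
#' @param genes `data.frame` with columns `gene_id`, `contig_id`, `start`,
#'   `end` (0-based half-open), `strand` (`"+"`/`"-"`). Ordinals are (re)assigned
#'   here: genes are sorted by start within each contig and numbered from 0.
#' @param proteins Named character vector (or `AAStringSet`) of amino-acid
#'   sequences keyed by `gene_id`. Genes without a protein are kept.
#' @param species Species label (defaults to `genome_id`).
#' @param taxonomy Optional ordered character vector of rank labels
#'   (phylum ... species).
#' @return An object of class `GenomeRecord`.
#' @export
genome_record <- function(genome_id, contigs, genes, proteins = character(),
                          species = genome_id, taxonomy = character()) {
  if (methods::is(contigs, "XStringSet")) contigs <- stats::setNames(as.character(contigs), names(contigs))
  if (methods::is(proteins, "XStringSet")) proteins <- stats::setNames(as.character(proteins), names(proteins))
  stopifnot(is.character(contigs), !is.null(names(contigs)))
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  req <- c("gene_id", "contig_id", "start", "end", "strand")
  if (!all(req %in% names(genes))) {
    stop("gene table must have columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_id in genome '", genome_id, "'")
  }
  if (!all(genes$contig_id %in% names(contigs))) {
    bad <- setdiff(unique(genes$contig_id), names(contigs))
    stop("gene references unknown contig(s): ", paste(bad, collapse = ", "))
  }
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(genes$start >= genes$end)) stop("gene with start >= end")
  clen <- nchar(contigs)[genes$contig_id]
  if (any(genes$start < 0L) || any(genes$end > clen)) {
    stop("gene coordinates outside contig bounds")
  }
  genes <- genes[order(match(genes$contig_id, names(contigs)), genes$start), , drop = FALSE]
  genes$ordinal <- stats::ave(genes$start, genes$contig_id,
                              FUN = function(x) seq_along(x) - 1L)
  genes$ordinal <- as.integer(genes$ordinal)
  rownames(genes) <- genes$gene_id
  structure(list(genome_id = genome_id, species = species, taxonomy = taxonomy,
                 contigs = contigs,
                 genes = genes[, c("gene_id", "contig_id", "start", "end", "strand", "ordinal")],
                 proteins = proteins),
            class = "GenomeRecord")
}

#' @export
print.GenomeRecord <- function(x, ...) {
  cat(sprintf("GenomeRecord '%s' (%s): %d contig(s), %d gene(s), %d protein(s)\n",
              x$genome_id, x$species, length(x$contigs), nrow(x$genes),
              length(x$proteins)))
  invisible(x)
}

#' Read an annotated genome from GFF3 + FASTA
#'
#' Parses gene models from a GFF3 file, contig sequences from a nucleotide
#' FASTA and protein sequences from an amino-acid FASTA keyed by gene id.
#' GFF 1-based inclusive coordinates are converted to the internal 0-based
#' half-open convention.
#'
#' @param gff_path Path to a GFF3 file; features of type `gene` are used.
#' @param nucl_fasta Path to the contig FASTA.
#' @param prot_fasta Path to the protein FASTA (ids must match gene ids).
#' @param genome_id,species,taxonomy Metadata passed to [genome_record()];
#'   `genome_id` defaults to the GFF file name without extension.
#' @return A `GenomeRecord`. A warning is raised for every gene lacking a
#'   protein sequence (the gene is kept); a gene referencing an unknown contig
#'   or extending past its contig end is a fatal error.
#' @export
read_genome <- function(gff_path, nucl_fasta, prot_fasta,
                        genome_id = sub("\\.[^.]+$", "", basename(gff_path)),
                        species = genome_id, taxonomy = character()) {
  contigs <- Biostrings::readDNAStringSet(nucl_fasta)
  names(contigs) <- sub("\\s.*$", "", names(contigs))
  gr <- rtracklayer::import(gff_path)
  if ("type" %in% names(S4Vectors::mcols(gr))) {
    sel <- as.character(gr$type) %in% c("gene")
    if (!any(sel)) sel <- as.character(gr$type) %in% c("CDS", "mRNA")
    gr <- gr[sel]
  }
  ids <- gr$ID
  if (is.null(ids)) ids <- gr$Name
  if (is.null(ids) || anyNA(ids)) stop("GFF gene features must carry an ID attribute")
  genes <- data.frame(gene_id = as.character(ids),
                      contig_id = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr) - 1L,
                      end = GenomicRanges::end(gr),
                      strand = as.character(GenomicRanges::strand(gr)),
                      stringsAsFactors = FALSE)
  if (!all(genes$contig_id %in% names(contigs))) {
    bad <- setdiff(unique(genes$contig_id), names(contigs))
    stop("GFF references contig(s) absent from the FASTA: ",
         paste(bad, collapse = ", "))
  }
  prot <- Biostrings::readAAStringSet(prot_fasta)
  names(prot) <- sub("\\s.*$", "", names(prot))
  missing <- setdiff(genes$gene_id, names(prot))
  if (length(missing)) {
    warning("gene(s) without protein sequence: ", paste(missing, collapse = ", "))
  }
  genome_record(genome_id, contigs, genes,
                proteins = stats::setNames(as.character(prot), names(prot)),
                species = species, taxonomy = taxonomy)
}

#' Read a HMMER-style per-domain table
#'
#' Reads a whitespace-delimited per-domain tabular file (domtblout dialect,
#' hmmscan orientation: target = domain model, query = protein). Comment lines
#' starting with `#` are skipped. No e-value filtering is applied at read time.
#' Pfam accession version suffixes (e.g. `PF05141.1` -> `PF05141`) are stripped.
#'
#' @param path Path to the table.
#' @return `data.frame` with columns `protein_id`, `domain_accession`,
#'   `domain_name`, `env_start`, `env_end` (1-based inclusive on the protein),
#'   `i_evalue`, `bit_score`, in file order.
#' @export
read_domain_table <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  empty <- data.frame(protein_id = character(), domain_accession = character(),
                      domain_name = character(), env_start = integer(),
                      env_end = integer(), i_evalue = numeric(),
                      bit_score = numeric(), stringsAsFactors = FALSE)
  if (!any(keep)) return(empty)
  lineno <- which(keep)
  rows <- strsplit(trimws(lines[keep]), "\\s+")
  out <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    f <- rows[[i]]
    if (length(f) < 21) {
      stop("line ", lineno[i], ": expected >= 21 whitespace-delimited fields, got ",
           length(f))
    }
    num <- suppressWarnings(as.numeric(f[c(13, 14, 20, 21)]))
    if (anyNA(num)) {
      stop("line ", lineno[i], ": non-numeric score/coordinate field")
    }
    acc <- if (f[2] == "-") f[1] else f[2]
    out[[i]] <- data.frame(protein_id = f[4],
                           domain_accession = sub("\\.\\d+$", "", acc),
                           domain_name = f[1],
                           env_start = as.integer(num[3]),
                           env_end = as.integer(num[4]),
                           i_evalue = num[1], bit_score = num[2],
                           stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, out)
  if (any(hits$env_start > hits$env_end)) stop("domain hit with env_start > env_end")
  if (any(hits$i_evalue < 0)) stop("negative i-evalue")
  hits
}

#' Read a BUSCO anchor table
#'
#' Tab-separated table with columns `busco_id`, `genome_id`, `gene_id`. Rows
#' whose gene does not resolve against the supplied genomes are dropped with a
#' warning; a duplicated (busco_id, genome_id) pair is a fatal error.
#'
#' @param path Path to the table (a header line is optional).
#' @param genomes Named list of `GenomeRecord` objects, keyed by genome id.
#' @return `data.frame` with the retained rows.
#' @export
read_busco_table <- function(path, genomes) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("busco_id", "genome_id", "gene_id"))
  if (nrow(tab) && identical(tolower(unlist(tab[1, ])),
                             c("busco_id", "genome_id", "gene_id"))) {
    tab <- tab[-1, , drop = FALSE]
  }
  resolved <- vapply(seq_len(nrow(tab)), function(i) {
    g <- genomes[[tab$genome_id[i]]]
    !is.null(g) && tab$gene_id[i] %in% g$genes$gene_id
  }, logical(1))
  if (any(!resolved)) {
    warning(sum(!resolved), " BUSCO row(s) dropped: gene does not resolve")
    tab <- tab[resolved, , drop = FALSE]
  }
  key <- paste(tab$busco_id, tab$genome_id)
  if (anyDuplicated(key)) {
    stop("duplicated (busco_id, genome_id) pair: ", key[duplicated(key)][1])
  }
  rownames(tab) <- NULL
  tab
}

#' Genes of a cluster prediction
#'
#' @param cluster One row of a cluster table (see [predict_cluster()]).
#' @param genome The matching `GenomeRecord`.
#' @return The gene-table rows inside the cluster's ordinal range.
#' @export
cluster_genes <- function(cluster, genome) {
  g <- genome$genes
  g[g$contig_id == cluster$contig_id &
      g$ordinal >= cluster$start_ordinal &
      g$ordinal <= cluster$end_ordinal, , drop = FALSE]
}

#' Export a cluster prediction to standard file formats
#'
#' Writes the cluster region as (i) a nucleotide FASTA holding the exact contig
#' substring from the first gene start to the last gene end, (ii) a GFF3 file
#' with coordinates re-based to the region (1-based), and (iii) a GenBank flat
#' file with one CDS feature per gene carrying its translation. Genes flagged
#' biosynthetic receive a `/gene_kind="biosynthetic"` qualifier.
#'
#' @param cluster One row of a cluster table.
#' @param genome The matching `GenomeRecord`.
#' @param out_dir Output directory (created if needed).
#' @param biosynthetic Character vector of gene ids to flag as biosynthetic
#'   (e.g. the `BIOSYNTHETIC` genes from [flag_biosynthetic_genes()]).
#' @param prefix File name stem; defaults to the cluster id.
#' @return Invisibly, a named list of the three file paths.
#' @export
export_cluster <- function(cluster, genome, out_dir,
                           biosynthetic = character(),
                           prefix = cluster$cluster_id) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genes <- cluster_genes(cluster, genome)
  if (!nrow(genes)) stop("cluster contains no genes")
  if (length(unique(genes$contig_id)) != 1L) stop("cluster spans contig boundary")
  contig <- genome$contigs[[genes$contig_id[1]]]
  r0 <- min(genes$start); r1 <- max(genes$end)
  region <- substr(contig, r0 + 1L, r1)
  region_id <- paste0(genome$genome_id, "|", prefix)

  fna <- file.path(out_dir, paste0(prefix, ".fna"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(region, region_id)), fna)

  # region-based 1-based coordinates
  rel_start <- genes$start - r0 + 1L
  rel_end <- genes$end - r0
  gff <- file.path(out_dir, paste0(prefix, ".gff3"))
  gr <- GenomicRanges::GRanges(seqnames = region_id,
                               ranges = IRanges::IRanges(rel_start, rel_end),
                               strand = genes$strand)
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  if (length(biosynthetic)) {
    gr$gene_kind <- ifelse(genes$gene_id %in% biosynthetic, "biosynthetic", NA)
  }
  rtracklayer::export(gr, gff, format = "gff3")

  gbk <- file.path(out_dir, paste0(prefix, ".gbk"))
  write_genbank(gbk, region_id, region, genes, rel_start, rel_end,
                proteins = genome$proteins, biosynthetic = biosynthetic)
  invisible(list(fna = fna, gff = gff, gbk = gbk))
}

# Minimal GenBank flat-file writer (CDS features + translations).
write_genbank <- function(path, locus, seq, genes, rel_start, rel_end,
                          proteins, biosynthetic) {
  wrap_qual <- function(text) {
    # GenBank qualifier continuation lines are indented to column 22
    out <- character()
    while (nchar(text) > 58) {
      out <- c(out, substr(text, 1, 58))
      text <- substr(text, 59, nchar(text))
    }
    c(out, text)
  }
  con <- file(path, "w")
  on.exit(close(con))
  locus_name <- gsub("[^A-Za-z0-9_.|-]", "_", locus)
  writeLines(sprintf("LOCUS       %-16s %d bp    DNA     linear   UNA",
                     substr(locus_name, 1, 16), nchar(seq)), con)
  writeLines(sprintf("DEFINITION  %s ICS cluster region.", locus), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", nchar(seq)), con)
  for (i in seq_len(nrow(genes))) {
    loc <- sprintf("%d..%d", rel_start[i], rel_end[i])
    if (genes$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
    writeLines(sprintf("     CDS             %s", loc), con)
    writeLines(sprintf("                     /locus_tag=\"%s\"", genes$gene_id[i]), con)
    if (genes$gene_id[i] %in% biosynthetic) {
      writeLines("                     /gene_kind=\"biosynthetic\"", con)
    }
    aa <- proteins[[genes$gene_id[i]]]
    if (!is.null(aa) && !is.na(aa)) {
      q <- wrap_qual(sprintf("/translation=\"%s\"", aa))
      writeLines(paste0("                     ", q), con)
    }
  }
  writeLines("ORIGIN", con)
  pos <- seq(1, nchar(seq), by = 60)
  for (p in pos) {
    chunk <- substr(seq, p, min(p + 59, nchar(seq)))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", p, paste(tolower(tens), collapse = " ")), con)
  }
  writeLines("//", con)
}

#' Write a genome as GFF3 + nucleotide FASTA + protein FASTA
#'
#' Inverse of [read_genome()]; used by the synthetic-data generator and for
#' persisting ingested genomes.
#'
#' @param genome A `GenomeRecord`.
#' @param dir Output directory.
#' @return Invisibly, a named list of the three paths.
#' @export
write_genome <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- genome$genome_id
  fna <- file.path(dir, paste0(id, ".fna"))
  faa <- file.path(dir, paste0(id, ".faa"))
  gff <- file.path(dir, paste0(id, ".gff3"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome$contigs), fna)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(genome$proteins), faa)
  g <- genome$genes
  gr <- GenomicRanges::GRanges(seqnames = g$contig_id,
                               ranges = IRanges::IRanges(g$start + 1L, g$end),
                               strand = g$strand)
  gr$type <- "gene"
  gr$ID <- g$gene_id
  rtracklayer::export(gr, gff, format = "gff3")
  invisible(list(gff = gff, fna = fna, faa = faa))
}

#' Write a per-domain table in domtblout dialect
#'
#' @param hits Domain-hit `data.frame` (see [read_domain_table()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_domain_table <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target", con)
  for (i in seq_len(nrow(hits))) {
    writeLines(paste(hits$domain_name[i],
                     paste0(hits$domain_accession[i], ".1"),
                     200L, hits$protein_id[i], "-", 400L,
                     format(hits$i_evalue[i], digits = 3),
                     format(hits$bit_score[i], digits = 4), "0.0",
                     1L, 1L,
                     format(hits$i_evalue[i], digits = 3),
                     format(hits$i_evalue[i], digits = 3),
                     format(hits$bit_score[i], digits = 4), "0.0",
                     1L, 200L,
                     hits$env_start[i], hits$env_end[i],
                     hits$env_start[i], hits$env_end[i],
                     "0.98", "-"), con)
  }
  invisible(path)
}
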