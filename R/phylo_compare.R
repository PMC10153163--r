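# Newick I/O, Robinson-Foulds comparison, alignment concatenation and the
# sister-lineage expansion scan. Trees are `ape` phylo objects; ML inference,
# alignment and trimming are upstream tools whose outputs are consumed here.

#' Parse a newick tree
#'
#' @param text Newick string, or a file path when `file = TRUE`.
#' @param file Read `text` as a path.
#' @return An `ape` `phylo` object. Malformed newick or duplicated leaf labels
#'   are errors.
#' @export
parse_newick <- function(text, file = FALSE) {
  tr <- tryCatch(
    if (file) ape::read.tree(text) else ape::read.tree(text = text),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr)) stop("malformed newick")
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate leaf label: ", tr$tip.label[duplicated(tr$tip.label)][1])
  }
  tr
}

#' Write a tree as newick
#'
#' @param tree A `phylo` object.
#' @return Newick string (branch lengths and node supports preserved).
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree)
}

# non-trivial unrooted splits as canonical sorted label strings
.tree_splits <- function(tree) {
  tree <- ape::unroot(tree)
  labs <- tree$tip.label
  ref <- sort(labs)[1]
  pp <- ape::prop.part(tree)
  out <- character()
  for (cl in pp) {
    side <- labs[cl]
    if (length(side) < 2 || length(side) > length(labs) - 2) next
    if (ref %in% side) side <- setdiff(labs, side)
    out <- c(out, paste(sort(side), collapse = ","))
  }
  unique(out)
}

#' Robinson-Foulds distance between two trees
#'
#' Trees are compared as sets of non-trivial unrooted bipartitions; the
#' distance is the size of their symmetric difference and is normalized by its
#' maximum (the total number of non-trivial splits in both trees).
#'
#' @param t1,t2 `phylo` objects.
#' @param prune_to_common Prune both trees to their shared leaves first; when
#'   `FALSE` the leaf sets must already be identical.
#' @return List of class `rf_result`: `rf` (even, non-negative), `max_rf`,
#'   `normalized` (0 when both trees are stars), `shared` and `conflicting`
#'   bipartition label-sets. Fewer than four common leaves is an error.
#' @export
rf_distance <- function(t1, t2, prune_to_common = TRUE) {
  common <- intersect(t1$tip.label, t2$tip.label)
  if (prune_to_common) {
    if (length(common) < 4) stop("fewer than 4 shared leaves")
    t1 <- ape::keep.tip(t1, common)
    t2 <- ape::keep.tip(t2, common)
  } else if (!setequal(t1$tip.label, t2$tip.label)) {
    stop("leaf sets differ; set prune_to_common = TRUE")
  }
  b1 <- .tree_splits(t1)
  b2 <- .tree_splits(t2)
  shared <- intersect(b1, b2)
  conflicting <- c(setdiff(b1, b2), setdiff(b2, b1))
  rf <- length(conflicting)
  max_rf <- length(b1) + length(b2)
  structure(list(rf = rf, max_rf = max_rf,
                 normalized = if (max_rf > 0) rf / max_rf else 0,
                 shared = shared, conflicting = conflicting),
            class = "rf_result")
}

#' Concatenate alignments into a supermatrix
#'
#' Taxa are united by label across alignments; a taxon missing from an
#' alignment is filled with gap characters over that partition. Within each
#' alignment all sequences must have equal length (ragged input is an error),
#' and a duplicated taxon within one alignment is an error.
#'
#' @param alignments List of aligned sequence sets, each a named character
#'   vector or `XStringSet`. List names become partition sources.
#' @param gap Gap character used for fill (default `"-"`).
#' @return List: `alignment` (named character vector) and `partitions`
#'   (`data.frame` name, start, end, source; 1-based inclusive columns).
#' @export
concatenate_alignments <- function(alignments, gap = "-") {
  alignments <- lapply(alignments, function(a) {
    if (methods::is(a, "XStringSet")) stats::setNames(as.character(a), names(a)) else a
  })
  if (is.null(names(alignments)) || any(!nzchar(names(alignments)))) {
    names(alignments) <- paste0("partition", seq_along(alignments))
  }
  lens <- integer(length(alignments))
  for (i in seq_along(alignments)) {
    a <- alignments[[i]]
    if (!length(a)) stop("empty alignment: ", names(alignments)[i])
    if (anyDuplicated(names(a))) {
      stop("duplicate taxon in alignment ", names(alignments)[i])
    }
    if (length(unique(nchar(a))) != 1) {
      stop("ragged alignment: ", names(alignments)[i])
    }
    lens[i] <- nchar(a[[1]])
  }
  taxa <- unique(unlist(lapply(alignments, names), use.names = FALSE))
  parts <- data.frame(name = names(alignments),
                      start = cumsum(c(1L, lens[-length(lens)])),
                      end = cumsum(lens),
                      source = names(alignments), stringsAsFactors = FALSE)
  rows <- vapply(taxa, function(tx) {
    paste(vapply(seq_along(alignments), function(i) {
      s <- alignments[[i]][tx]
      if (is.na(s)) strrep(gap, lens[i]) else unname(s)
    }, character(1)), collapse = "")
  }, character(1))
  list(alignment = stats::setNames(rows, taxa), partitions = parts)
}

# exact two-sided rank-sum p by full enumeration of rank assignments
# (midranks for ties); falls back to the normal approximation when the
# assignment space is too large
.ranksum_p <- function(x, y, max_enum = 2e5) {
  nx <- length(x); ny <- length(y)
  if (choose(nx + ny, nx) <= max_enum) {
    r <- rank(c(x, y))
    W <- sum(r[seq_len(nx)])
    mu <- nx * (nx + ny + 1) / 2
    combs <- utils::combn(nx + ny, nx)
    Wall <- colSums(matrix(r[combs], nrow = nx))
    mean(abs(Wall - mu) >= abs(W - mu) - 1e-9)
  } else {
    suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$p.value)
  }
}

#' Scan a species tree for sister-lineage differences in cluster counts
#'
#' For each internal node whose two child clades both contain at least
#' `min_clade` leaves, the leaf BGC-count distributions of the clades are
#' compared with an exact two-sided rank-sum test (full enumeration of rank
#' assignments, midranks for ties; normal approximation for large clades).
#' P-values are Benjamini-Hochberg corrected across the tested nodes, and
#' branches with adjusted p at or below `alpha` are flagged.
#'
#' @param species_tree A rooted `phylo` object.
#' @param counts Named numeric vector of per-species cluster counts covering
#'   all tree leaves.
#' @param min_clade Minimum leaves per child clade (default 4).
#' @param alpha Adjusted-p flagging level (default 0.05).
#' @return `data.frame` with one row per tested node: `node`, `n_left`,
#'   `n_right`, `mean_left`, `mean_right`, `p`, `p_adj`, `flagged`, plus
#'   comma-collapsed `left_tips` / `right_tips`.
#' @export
expansion_scan <- function(species_tree, counts, min_clade = 4L, alpha = 0.05) {
  labs <- species_tree$tip.label
  if (!all(labs %in% names(counts))) {
    stop("counts missing for: ",
         paste(utils::head(setdiff(labs, names(counts))), collapse = ", "))
  }
  ntip <- length(labs)
  # tip sets of every node
  desc <- vector("list", ntip + species_tree$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- labs[i]
  edge <- species_tree$edge
  po <- ape::reorder.phylo(species_tree, "postorder")$edge
  for (k in seq_len(nrow(po))) {
    desc[[po[k, 1]]] <- c(desc[[po[k, 1]]], desc[[po[k, 2]]])
  }
  rows <- list()
  for (nd in sort(unique(edge[, 1]))) {
    kids <- edge[edge[, 1] == nd, 2]
    if (length(kids) != 2) next
    left <- desc[[kids[1]]]; right <- desc[[kids[2]]]
    if (length(left) < min_clade || length(right) < min_clade) next
    x <- counts[left]; y <- counts[right]
    rows[[length(rows) + 1L]] <- data.frame(
      node = nd, n_left = length(left), n_right = length(right),
      mean_left = mean(x), mean_right = mean(y),
      p = .ranksum_p(x, y),
      left_tips = paste(left, collapse = ","),
      right_tips = paste(right, collapse = ","),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(node = integer(), n_left = integer(), n_right = integer(),
                      mean_left = numeric(), mean_right = numeric(),
                      p = numeric(), p_adj = numeric(), flagged = logical(),
                      left_tips = character(), right_tips = character()))
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$flagged <- out$p_adj <= alpha
  out[, c("node", "n_left", "n_right", "mean_left", "mean_right",
          "p", "p_adj", "flagged", "left_tips", "right_tips")]
}
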