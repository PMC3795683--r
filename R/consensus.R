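#' Minimum-expression gene filter
#'
#' Retains genes whose normalized expression exceeds `threshold` in at least
#' `min_samples` samples — the "expressed" universe used before unsupervised
#' clustering (default: level > 1 in at least one sample).
#'
#' @param m An [expression_matrix()] of normalized values.
#' @param threshold Expression level a sample must exceed (strictly).
#' @param min_samples Minimum number of samples exceeding the threshold.
#' @return Integer vector of retained gene ids.
#' @export
expression_filter <- function(m, threshold = 1, min_samples = 1) {
  stopifnot(inherits(m, "expr_matrix"))
  min_samples <- as.integer(min_samples)
  if (min_samples < 1) stop("min_samples must be >= 1")
  if (min_samples > ncol(m$values)) {
    stop("min_samples (", min_samples, ") exceeds the number of samples (",
         ncol(m$values), ")")
  }
  keep <- rowSums(m$values > threshold) >= min_samples
  m$gene_ids[keep]
}

#' Per-channel fold-change ranks over a common gene universe
#'
#' Intersects the gene universes of the four channel results, assigns each
#' gene a direction by the majority sign of its per-channel log2 fold
#' changes, and ranks genes within each direction separately for every
#' channel: 1..n by descending |log2fc|, ties broken by ascending p, then
#' ascending gene id. Genes with a 2-2 sign split (no majority) are excluded
#' from both directional lists; their ids are recorded, as are ids dropped
#' at the intersection step.
#'
#' @param results List of four `channel_result` objects from [run_channel()].
#' @return A list of class `fc_ranks`:
#'   * `gene_id`, `direction` (`"pop1"` for majority-positive log2fc,
#'     `"pop2"` for majority-negative);
#'   * `log2fc`, `q`, `rank`: genes x channels matrices;
#'   * `dropped_intersection`, `dropped_tied_sign`: excluded gene ids.
#' @export
fold_change_ranks <- function(results) {
  if (length(results) != 4) stop("exactly four channel results are required")
  names(results) <- vapply(seq_along(results), function(i) {
    attr(results[[i]], "channel") %||% LETTERS[i]
  }, character(1))
  ids <- lapply(results, function(r) r$gene_id)
  common <- Reduce(intersect, ids)
  if (!length(common)) stop("empty gene-id intersection across channels")
  union_ids <- Reduce(union, ids)
  dropped <- sort(setdiff(union_ids, common))
  common <- sort(common)

  get_col <- function(col) {
    vapply(results, function(r) {
      r[[col]][match(common, r$gene_id)]
    }, numeric(length(common)))
  }
  fc <- get_col("log2fc")
  p <- get_col("p")
  q <- get_col("q")
  rownames(fc) <- rownames(p) <- rownames(q) <- as.character(common)

  sgn <- sign(fc)
  n_pos <- rowSums(sgn > 0)
  n_neg <- rowSums(sgn < 0)
  direction <- unname(ifelse(n_pos > n_neg, "pop1",
                             ifelse(n_neg > n_pos, "pop2", NA_character_)))
  tied <- is.na(direction)
  keep <- which(!tied)
  if (!length(keep)) stop("no gene has a majority fold-change direction")

  gene_id <- common[keep]
  direction <- direction[keep]
  fc <- fc[keep, , drop = FALSE]
  p <- p[keep, , drop = FALSE]
  q <- q[keep, , drop = FALSE]

  # within-direction, per-channel ranks on the intersected universe
  rank_mat <- matrix(NA_integer_, length(gene_id), ncol(fc),
                     dimnames = dimnames(fc))
  for (dir in unique(direction)) {
    sel <- which(direction == dir)
    for (ch in seq_len(ncol(fc))) {
      ord <- order(-abs(fc[sel, ch]), p[sel, ch], gene_id[sel])
      rank_mat[sel[ord], ch] <- seq_along(sel)
    }
  }

  structure(list(gene_id = gene_id, direction = direction,
                 log2fc = fc, q = q, rank = rank_mat,
                 dropped_intersection = dropped,
                 dropped_tied_sign = sort(common[tied])),
            class = "fc_ranks")
}

#' Aggregate channel ranks into a consensus marker table
#'
#' Computes each gene's mean fold-change rank across the four channels and
#' counts the channels calling it significant (`q < fdr`). A gene passes the
#' consensus when at least `min_methods` channels call it significant. The
#' table is sorted by direction, then ascending mean rank.
#'
#' @param fcr An `fc_ranks` object from [fold_change_ranks()].
#' @param fdr Per-channel significance threshold on q (default 0.05).
#' @param min_methods Channels required for a consensus pass (default 3 of 4).
#' @return A data frame of class `consensus_table` with columns `entrez_id`,
#'   `direction`, `fc_<ch>`, `q_<ch>`, `rank_<ch>` per channel,
#'   `mean_fc_rank`, `n_significant`, `pass`.
#' @export
mean_rank_aggregate <- function(fcr, fdr = 0.05, min_methods = 3) {
  stopifnot(inherits(fcr, "fc_ranks"))
  if (anyNA(fcr$rank)) stop("gene missing from a channel after intersection")
  chn <- colnames(fcr$rank)
  out <- data.frame(entrez_id = fcr$gene_id, direction = fcr$direction,
                    stringsAsFactors = FALSE)
  for (ch in chn) out[[paste0("fc_", ch)]] <- fcr$log2fc[, ch]
  for (ch in chn) out[[paste0("q_", ch)]] <- fcr$q[, ch]
  for (ch in chn) out[[paste0("rank_", ch)]] <- fcr$rank[, ch]
  out$mean_fc_rank <- rowMeans(fcr$rank)
  out$n_significant <- as.integer(rowSums(fcr$q < fdr))
  out$pass <- out$n_significant >= min_methods
  out <- out[order(out$direction, out$mean_fc_rank, out$entrez_id), ]
  rownames(out) <- NULL
  attr(out, "fdr") <- fdr
  attr(out, "min_methods") <- min_methods
  class(out) <- c("consensus_table", "data.frame")
  out
}

#' @export
print.consensus_table <- function(x, ...) {
  cat("consensus_table: ", nrow(x), " genes, ",
      sum(x$pass), " pass (>= ", attr(x, "min_methods"), " of 4 channels q < ",
      attr(x, "fdr"), ")\n", sep = "")
  print.data.frame(head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat("... (", nrow(x) - 10, " more rows)\n", sep = "")
  invisible(x)
}

# Leaf sets of every internal node of an hclust tree.
.clade_leaf_sets <- function(hc) {
  n <- nrow(hc$merge)
  sets <- vector("list", n)
  for (i in seq_len(n)) {
    mem <- unlist(lapply(hc$merge[i, ], function(j) {
      if (j < 0) -j else sets[[j]]
    }))
    sets[[i]] <- sort(mem)
  }
  sets
}

#' Unsupervised clustering separation check
#'
#' Average-linkage hierarchical clustering of samples on the correlation
#' distance (1 - Pearson correlation of per-sample profiles) over a filtered
#' gene set. The separation flag is true iff every group's samples form one
#' exclusive subtree of the dendrogram.
#'
#' @param m An [expression_matrix()] with group labels and >= 2 samples per
#'   group.
#' @param genes Optional gene ids restricting the profiles (default: all).
#' @return A list with `hclust` (the tree), `separation` (logical), and
#'   `distance` (the dist object).
#' @export
cluster_separation <- function(m, genes = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  if (is.null(m$group_labels)) stop("group labels are required")
  if (any(table(m$group_labels) < 2)) {
    stop("each group needs at least 2 samples")
  }
  v <- m$values
  if (!is.null(genes)) {
    sel <- match(as.integer(genes), m$gene_ids)
    if (anyNA(sel)) stop("unknown gene id(s) in filter set")
    v <- v[sel, , drop = FALSE]
  }
  if (nrow(v) < 2) stop("need at least 2 genes for sample correlation")
  sds <- apply(v, 2, sd)
  if (any(sds == 0)) {
    stop("constant profile in sample(s) ",
         paste(colnames(v)[sds == 0], collapse = ", "),
         "; correlation undefined - consider a stricter expression filter")
  }
  d <- as.dist(1 - cor(v))
  hc <- hclust(d, method = "average")
  sets <- .clade_leaf_sets(hc)
  groups <- split(seq_along(m$sample_ids), m$group_labels)
  separation <- all(vapply(groups, function(g) {
    g <- sort(g)
    length(g) == 1 || any(vapply(sets, identical, logical(1), y = g))
  }, logical(1)))
  list(hclust = hc, separation = separation, distance = d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
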