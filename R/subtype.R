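#' Labeled reference profiles for subtype classification
#'
#' @param profiles Numeric genes x reference-samples matrix with gene-id
#'   rownames (integer, Entrez-style) and sample colnames.
#' @param labels Character vector of subtype labels, named by reference
#'   sample id (or in column order).
#' @return An object of class `subtype_reference` with elements `profiles`,
#'   `labels`, `gene_ids`.
#' @export
subtype_reference <- function(profiles, labels) {
  profiles <- as.matrix(profiles)
  if (is.null(rownames(profiles))) stop("profiles need gene-id rownames")
  if (is.null(colnames(profiles))) {
    colnames(profiles) <- paste0("ref_", seq_len(ncol(profiles)))
  }
  gene_ids <- suppressWarnings(as.integer(rownames(profiles)))
  if (anyNA(gene_ids)) stop("reference gene ids must be integer")
  labels <- as.character(labels)
  if (!is.null(names(labels))) {
    miss <- setdiff(colnames(profiles), names(labels))
    if (length(miss)) {
      stop("unlabeled reference sample(s): ", paste(miss, collapse = ", "))
    }
    labels <- labels[colnames(profiles)]
  } else if (length(labels) == ncol(profiles)) {
    names(labels) <- colnames(profiles)
  } else {
    stop("labels must be named by reference sample or match column count")
  }
  structure(list(profiles = profiles, labels = labels, gene_ids = gene_ids),
            class = "subtype_reference")
}

# Per-gene (row) z-scoring; constant rows map to 0 rather than NaN so an
# uninformative gene contributes nothing to distances.
.row_zscore <- function(x) {
  mu <- rowMeans(x)
  s <- apply(x, 1, sd)
  s[s == 0] <- 1
  (x - mu) / s
}

#' Match cohort and reference on shared signature genes
#'
#' Restricts both matrices to the intersection of their gene ids (identical
#' row order) and z-scores each gene within each dataset, the normalization
#' that makes Euclidean distances comparable across platforms.
#'
#' @param cohort An [expression_matrix()] (or numeric matrix with integer
#'   gene-id rownames) of tumor samples.
#' @param ref A [subtype_reference()].
#' @return A list with `cohort` and `reference` (z-scored matrices over the
#'   matched genes), `labels`, `n_matched`, `n_dropped_cohort`,
#'   `n_dropped_ref`.
#' @export
match_signature_genes <- function(cohort, ref) {
  stopifnot(inherits(ref, "subtype_reference"))
  if (inherits(cohort, "expr_matrix")) {
    cmat <- cohort$values
    cids <- cohort$gene_ids
  } else {
    cmat <- as.matrix(cohort)
    cids <- suppressWarnings(as.integer(rownames(cmat)))
    if (anyNA(cids)) stop("cohort gene ids must be integer")
  }
  common <- sort(intersect(cids, ref$gene_ids))
  if (!length(common)) stop("no shared gene ids between cohort and reference")
  ci <- match(common, cids)
  ri <- match(common, ref$gene_ids)
  list(cohort = .row_zscore(cmat[ci, , drop = FALSE]),
       reference = .row_zscore(ref$profiles[ri, , drop = FALSE]),
       labels = ref$labels,
       n_matched = length(common),
       n_dropped_cohort = length(cids) - length(common),
       n_dropped_ref = length(ref$gene_ids) - length(common))
}

#' k-nearest-neighbor subtype assignment
#'
#' For each cohort sample, Euclidean distances to all reference samples over
#' the matched (z-scored) genes are computed; the assigned subtype is the
#' majority label among the `k` nearest references. Label ties are broken by
#' the smallest summed distance among the tied labels' neighbors, then
#' lexicographically.
#'
#' @param cohort Numeric genes x samples matrix (matched and z-scored, as
#'   from [match_signature_genes()]).
#' @param reference Numeric genes x reference-samples matrix, same rows.
#' @param labels Character subtype labels named by reference sample.
#' @param k Number of neighbors (default 10); must not exceed the number of
#'   reference samples.
#' @return A data frame `sample`, `subtype`, `distance_margin` (mean distance
#'   of non-winning neighbors minus mean distance of winning-label neighbors
#'   within the k; `NA` when the vote is unanimous).
#' @export
knn_assign <- function(cohort, reference, labels, k = 10) {
  cohort <- as.matrix(cohort)
  reference <- as.matrix(reference)
  if (nrow(cohort) != nrow(reference)) {
    stop("cohort and reference must share the same (matched) genes")
  }
  k <- as.integer(k)
  if (k < 1 || k > ncol(reference)) {
    stop("k must be between 1 and the number of reference samples (",
         ncol(reference), ")")
  }
  bad <- colnames(cohort)[colSums(!is.finite(cohort)) > 0]
  if (length(bad)) {
    stop("non-finite profile values in sample(s): ",
         paste(bad, collapse = ", "))
  }
  if (any(!is.finite(reference))) {
    stop("non-finite values in reference profiles")
  }
  labels <- as.character(labels)

  # squared Euclidean distances, cohort x reference
  d2 <- outer(colSums(cohort^2), colSums(reference^2), "+") -
    2 * crossprod(cohort, reference)
  d2[d2 < 0] <- 0
  d <- sqrt(d2)

  n <- ncol(cohort)
  subtype <- character(n)
  margin <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    ord <- order(d[i, ], seq_len(ncol(reference)))[seq_len(k)]
    nn_lab <- labels[ord]
    nn_d <- d[i, ord]
    votes <- table(nn_lab)
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1) {
      sums <- vapply(top, function(l) sum(nn_d[nn_lab == l]), numeric(1))
      top <- top[sums == min(sums)]
      top <- sort(top)[1]
    }
    subtype[i] <- top
    other <- nn_lab != top
    if (any(other)) {
      margin[i] <- mean(nn_d[other]) - mean(nn_d[!other])
    }
  }
  data.frame(sample = colnames(cohort) %||% paste0("sample_", seq_len(n)),
             subtype = subtype, distance_margin = margin,
             stringsAsFactors = FALSE)
}

#' Match, normalize, and assign subtypes in one step
#'
#' Convenience wrapper chaining [match_signature_genes()] and [knn_assign()].
#'
#' @inheritParams match_signature_genes
#' @inheritParams knn_assign
#' @return The [knn_assign()] data frame, with matching counts attached as
#'   attributes `n_matched`, `n_dropped_cohort`, `n_dropped_ref`.
#' @export
assign_subtypes <- function(cohort, ref, k = 10) {
  mt <- match_signature_genes(cohort, ref)
  out <- knn_assign(mt$cohort, mt$reference, mt$labels, k = k)
  attr(out, "n_matched") <- mt$n_matched
  attr(out, "n_dropped_cohort") <- mt$n_dropped_cohort
  attr(out, "n_dropped_ref") <- mt$n_dropped_ref
  out
}

#' Per-subtype expression summary with pairwise tests
#'
#' Median and interquartile range of a gene's expression per subtype, with
#' two-sided Wilcoxon rank-sum p-values for every subtype pair. Subtypes
#' with fewer than 2 samples are summarized but excluded from the pairwise
#' tests (their labels are returned in `excluded`).
#'
#' @param values Numeric expression vector, one entry per sample.
#' @param subtype Character/factor subtype per sample (same order).
#' @return A list with `summary` (data frame `subtype`, `n`, `median`, `q1`,
#'   `q3`), `tests` (data frame `subtype1`, `subtype2`, `p`), `excluded`.
#' @export
subtype_expression_summary <- function(values, subtype) {
  if (length(values) != length(subtype)) {
    stop("values and subtype must have the same length")
  }
  subtype <- as.character(subtype)
  groups <- split(as.numeric(values), subtype)
  summ <- data.frame(
    subtype = names(groups),
    n = vapply(groups, length, integer(1)),
    median = vapply(groups, median, numeric(1)),
    q1 = vapply(groups, function(x) unname(quantile(x, 0.25)), numeric(1)),
    q3 = vapply(groups, function(x) unname(quantile(x, 0.75)), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  testable <- names(groups)[vapply(groups, length, integer(1)) >= 2]
  excluded <- setdiff(names(groups), testable)
  tests <- NULL
  if (length(testable) >= 2) {
    pairs <- combn(sort(testable), 2)
    tests <- data.frame(
      subtype1 = pairs[1, ], subtype2 = pairs[2, ],
      p = apply(pairs, 2, function(pr) {
        suppressWarnings(
          wilcox.test(groups[[pr[1]]], groups[[pr[2]]])$p.value)
      }),
      stringsAsFactors = FALSE
    )
  } else {
    tests <- data.frame(subtype1 = character(0), subtype2 = character(0),
                        p = numeric(0), stringsAsFactors = FALSE)
  }
  list(summary = summ, tests = tests, excluded = excluded)
}
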