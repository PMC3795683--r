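#' Gene-by-sample expression matrix
#'
#' The substrate of every pipeline stage: a numeric genes x samples matrix
#' tagged with its measurement platform and per-sample group labels. Gene
#' identifiers are integer (Entrez-style) and must be unique; count-platform
#' values must be nonnegative.
#'
#' @param values Numeric matrix, genes in rows, samples in columns.
#' @param gene_ids Integer vector of gene identifiers (defaults to numeric
#'   rownames of `values`).
#' @param sample_ids Character vector of sample identifiers (defaults to
#'   colnames of `values`).
#' @param platform `"count"` (raw counts or FPKM/CPM-like nonnegative values)
#'   or `"intensity"` (log2-scale array intensities).
#' @param group_labels Optional character vector mapping samples to groups;
#'   either named by sample id or in column order.
#'
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   (dimnamed matrix), `gene_ids`, `sample_ids`, `platform`, `group_labels`.
#' @export
#' @examples
#' m <- expression_matrix(matrix(rpois(12, 10), 4,
#'                               dimnames = list(1:4, paste0("s", 1:3))),
#'                        platform = "count",
#'                        group_labels = c("a", "a", "b"))
#' m
expression_matrix <- function(values, gene_ids = NULL, sample_ids = NULL,
                              platform = c("count", "intensity"),
                              group_labels = NULL) {
  platform <- match.arg(platform)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids)) gene_ids <- rownames(values)
  if (is.null(sample_ids)) sample_ids <- colnames(values)
  if (is.null(gene_ids)) stop("gene ids are required (argument or rownames)")
  if (is.null(sample_ids)) {
    sample_ids <- paste0("sample_", seq_len(ncol(values)))
  }
  gene_ids <- suppressWarnings(as.integer(gene_ids))
  if (anyNA(gene_ids)) {
    stop("gene ids must be integer (Entrez-style)")
  }
  if (length(gene_ids) != nrow(values)) {
    stop("length of gene_ids (", length(gene_ids),
         ") does not match number of rows (", nrow(values), ")")
  }
  if (length(sample_ids) != ncol(values)) {
    stop("length of sample_ids (", length(sample_ids),
         ") does not match number of columns (", ncol(values), ")")
  }
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup)) {
    stop("duplicate gene ids: ", paste(unique(dup), collapse = ", "))
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("expression values must be finite and non-missing")
  }
  if (platform == "count" && any(values < 0)) {
    stop("count-platform values must be nonnegative")
  }
  if (!is.null(group_labels)) {
    group_labels <- as.character(group_labels)
    if (!is.null(names(group_labels))) {
      missing_s <- setdiff(sample_ids, names(group_labels))
      if (length(missing_s)) {
        stop("no group label for sample(s): ", paste(missing_s, collapse = ", "))
      }
      group_labels <- group_labels[sample_ids]
    } else if (length(group_labels) == ncol(values)) {
      names(group_labels) <- sample_ids
    } else {
      stop("group_labels must be named by sample or match the column count")
    }
  }
  dimnames(values) <- list(as.character(gene_ids), sample_ids)
  structure(
    list(values = values, gene_ids = gene_ids, sample_ids = sample_ids,
         platform = platform, group_labels = group_labels),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("expr_matrix: ", nrow(x$values), " genes x ", ncol(x$values),
      " samples [", x$platform, " platform]\n", sep = "")
  if (!is.null(x$group_labels)) {
    tab <- table(x$group_labels)
    cat("groups: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

# The two group labels in a deterministic order (sorted), with sample index
# lists. Errors if the matrix does not carry exactly two groups.
.two_groups <- function(m, group1 = NULL, group2 = NULL) {
  if (is.null(m$group_labels)) stop("expression matrix has no group labels")
  labs <- sort(unique(m$group_labels))
  if (is.null(group1) && is.null(group2)) {
    if (length(labs) != 2) {
      stop("expected exactly 2 groups, found: ", paste(labs, collapse = ", "))
    }
    group1 <- labs[1]
    group2 <- labs[2]
  }
  i1 <- which(m$group_labels == group1)
  i2 <- which(m$group_labels == group2)
  if (!length(i1)) stop("group not present: ", group1)
  if (!length(i2)) stop("group not present: ", group2)
  list(group1 = group1, group2 = group2, idx1 = i1, idx2 = i2)
}

# Row-wise means and unbiased variances for a column subset.
.row_mean_var <- function(x, idx) {
  n <- length(idx)
  xs <- x[, idx, drop = FALSE]
  m <- rowMeans(xs)
  v <- rowSums((xs - m)^2) / (n - 1)
  list(mean = m, var = v, n = n)
}
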