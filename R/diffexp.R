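#' Depth- (and length-) normalize a count matrix
#'
#' Scales count-platform values to counts per million mapped reads (CPM), or
#' to reads per kilobase per million (FPKM-like) when gene lengths are
#' supplied, so that an expression threshold such as "> 1 in at least one
#' sample" is meaningful across libraries.
#'
#' @param m A count-platform [expression_matrix()].
#' @param gene_lengths Optional numeric vector of gene lengths in base pairs,
#'   named by gene id (or in row order).
#' @return An [expression_matrix()] with normalized values (platform stays
#'   `"count"`: values are nonnegative expression levels).
#' @export
#' @examples
#' m <- expression_matrix(matrix(c(9e5, 1e5), 2,
#'                               dimnames = list(1:2, "s1")),
#'                        platform = "count")
#' normalize_counts(m)$values  # library is already one million reads
normalize_counts <- function(m, gene_lengths = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$platform != "count") stop("normalize_counts requires a count platform")
  lib <- colSums(m$values)
  if (any(lib <= 0)) {
    stop("zero library size in sample(s): ",
         paste(m$sample_ids[lib <= 0], collapse = ", "))
  }
  x <- sweep(m$values, 2, lib / 1e6, "/")
  if (!is.null(gene_lengths)) {
    if (!is.null(names(gene_lengths))) {
      miss <- setdiff(as.character(m$gene_ids), names(gene_lengths))
      if (length(miss)) {
        stop("missing gene length for id(s): ",
             paste(head(miss, 5), collapse = ", "))
      }
      gene_lengths <- gene_lengths[as.character(m$gene_ids)]
    } else if (length(gene_lengths) != nrow(m$values)) {
      stop("gene_lengths must be named by gene id or match the row count")
    }
    if (any(gene_lengths <= 0)) stop("gene lengths must be positive")
    x <- x / (as.numeric(gene_lengths) / 1000)
  }
  expression_matrix(x, gene_ids = m$gene_ids, sample_ids = m$sample_ids,
                    platform = "count", group_labels = m$group_labels)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment: the q-value of the i-th smallest
#' p-value is `min_{j >= i} p_(j) * n / j`, capped at 1. Computed with
#' [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same order as `p`.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
bh_fdr <- function(p) {
  if (!length(p)) return(numeric(0))
  if (anyNA(p) || any(!is.finite(p))) stop("p-values must be finite")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

# Row-wise Welch t test (two-sided). Degenerate-variance rule: when both
# group variances vanish, p = 1 if the means are equal, otherwise the
# variances are floored at 1e-8 so the statistic is finite and extreme.
.row_welch <- function(x, idx1, idx2, var_floor = 1e-8) {
  g1 <- .row_mean_var(x, idx1)
  g2 <- .row_mean_var(x, idx2)
  v1 <- pmax(g1$var, var_floor)
  v2 <- pmax(g2$var, var_floor)
  se2 <- v1 / g1$n + v2 / g2$n
  tstat <- (g1$mean - g2$mean) / sqrt(se2)
  df <- se2^2 / ((v1 / g1$n)^2 / (g1$n - 1) + (v2 / g2$n)^2 / (g2$n - 1))
  p <- 2 * pt(abs(tstat), df = df, lower.tail = FALSE)
  zero_flat <- g1$var <= 0 & g2$var <= 0 & g1$mean == g2$mean
  p[zero_flat] <- 1
  tstat[zero_flat] <- 0
  list(t = tstat, df = df, p = p, mean1 = g1$mean, mean2 = g2$mean)
}

# Row-wise pooled-variance t with per-gene variance shrunk 50/50 toward the
# across-gene mean pooled variance; p on t with doubled residual df (the
# shrinkage target contributes the same effective df as the gene itself).
.row_shrunk_t <- function(x, idx1, idx2, var_floor = 1e-8) {
  g1 <- .row_mean_var(x, idx1)
  g2 <- .row_mean_var(x, idx2)
  df_res <- g1$n + g2$n - 2
  s2 <- ((g1$n - 1) * g1$var + (g2$n - 1) * g2$var) / df_res
  s2_post <- pmax(0.5 * s2 + 0.5 * mean(s2), var_floor)
  tstat <- (g1$mean - g2$mean) / sqrt(s2_post * (1 / g1$n + 1 / g2$n))
  df <- 2 * df_res
  p <- 2 * pt(abs(tstat), df = df, lower.tail = FALSE)
  zero_flat <- s2 <= 0 & mean(s2) <= 0 & g1$mean == g2$mean
  p[zero_flat] <- 1
  tstat[zero_flat] <- 0
  list(t = tstat, df = rep(df, length(tstat)), p = p,
       mean1 = g1$mean, mean2 = g2$mean)
}

# Exact two-sided permutation test (mid-p) on the difference of row means,
# enumerating all assignments of idx-sized subsets to group 1.
.row_exact_perm <- function(x, idx1, idx2) {
  cols <- c(idx1, idx2)
  x <- x[, cols, drop = FALSE]
  n1 <- length(idx1)
  n2 <- length(idx2)
  n <- n1 + n2
  n_split <- choose(n, n1)
  if (n_split > 2e5) {
    stop("exact permutation channel is limited to choose(n, n1) <= 2e5 ",
         "splits; got ", n_split)
  }
  splits <- combn(n, n1)
  # stat for split s: mean over split - mean over complement
  ind <- matrix(0, n, ncol(splits))
  ind[cbind(as.vector(splits),
            rep(seq_len(ncol(splits)), each = n1))] <- 1
  tot <- rowSums(x)
  s1 <- x %*% ind                      # genes x splits group-1 sums
  stat <- s1 / n1 - (tot - s1) / n2
  obs_col <- which(colSums(ind[seq_len(n1), , drop = FALSE]) == n1)
  obs <- stat[, obs_col]
  a <- abs(stat)
  ao <- abs(obs)
  eps <- 1e-9 * pmax(ao, 1)
  greater <- rowSums(a > ao + eps)
  equal <- rowSums(abs(a - ao) <= eps)
  p <- (greater + 0.5 * equal) / n_split
  # degenerate zero-variance rule: constant genes carry no evidence
  constant <- apply(x, 1, function(r) all(r == r[1]))
  p[constant] <- 1
  list(stat = obs, p = p,
       mean1 = rowMeans(x[, seq_len(n1), drop = FALSE]),
       mean2 = rowMeans(x[, n1 + seq_len(n2), drop = FALSE]))
}

# Within-direction fold-change ranks: genes with positive log2fc and genes
# with negative log2fc are ranked separately, 1..n by descending |log2fc|,
# ties by ascending p, then ascending gene id. Zero log2fc -> NA rank.
.direction_ranks <- function(gene_id, log2fc, p) {
  rank_out <- rep(NA_integer_, length(log2fc))
  for (s in c(1, -1)) {
    sel <- which(sign(log2fc) == s)
    if (!length(sel)) next
    ord <- order(-abs(log2fc[sel]), p[sel], gene_id[sel])
    rank_out[sel[ord]] <- seq_along(sel)
  }
  rank_out
}

#' Run one stand-in differential-expression channel
#'
#' Four channels mirror a two-sequencing, two-array analysis design with
#' genuinely different statistics so a 3-of-4 consensus is non-degenerate:
#'
#' * `A` (count): Welch t test on `log2(CPM + 0.5)`.
#' * `B` (count): exact permutation test on the difference of group means of
#'   `log2(CPM + 1)`, enumerating all group-size splits, mid-p.
#' * `C` (intensity): pooled-variance t with the per-gene variance shrunk
#'   50/50 toward the across-gene mean variance (p on doubled residual df).
#' * `D` (intensity): Welch t on quantile-normalized log2 intensities.
#'
#' Count channels are CPM-normalized internally and report
#' `log2fc = log2((mean1 + 0.5) / (mean2 + 0.5))` on normalized means
#' (pseudocount 0.5); intensity channels report the difference of group mean
#' log2 values. Genes with zero counts in every sample are excluded from
#' count channels (the count is recorded in the `n_dropped` attribute).
#' q-values are Benjamini-Hochberg over the channel's tested genes.
#'
#' @param m An [expression_matrix()] with two group labels; channels A and B
#'   require the count platform, C and D the intensity platform. Each group
#'   needs at least 2 samples.
#' @param channel `"A"`, `"B"`, `"C"`, or `"D"`.
#' @param group1,group2 Group labels defining the fold-change direction
#'   (`group1` over `group2`); default: the two labels in sorted order.
#' @param min_expr,min_expr_samples Minimum-expression guard for count
#'   channels: only genes with normalized expression `> min_expr` in at
#'   least `min_expr_samples` samples are tested (default CPM > 1 in at
#'   least one sample, the "expressed genes" universe; all-zero genes are
#'   always excluded). Intensity channels test every gene.
#' @return A data frame of class `channel_result` with columns `gene_id`,
#'   `log2fc`, `p`, `q`, `fc_rank` (within-direction fold-change rank),
#'   attributes `channel`, `group1`, `group2`, `n_dropped`.
#' @export
run_channel <- function(m, channel = c("A", "B", "C", "D"),
                        group1 = NULL, group2 = NULL,
                        min_expr = 1, min_expr_samples = 1) {
  stopifnot(inherits(m, "expr_matrix"))
  channel <- match.arg(channel)
  grp <- .two_groups(m, group1, group2)
  if (length(grp$idx1) < 2 || length(grp$idx2) < 2) {
    stop("each group needs at least 2 samples")
  }
  need_platform <- if (channel %in% c("A", "B")) "count" else "intensity"
  if (m$platform != need_platform) {
    stop("channel ", channel, " requires the ", need_platform, " platform")
  }

  keep <- rep(TRUE, nrow(m$values))
  n_dropped <- 0L
  if (need_platform == "count") {
    norm <- normalize_counts(m)
    keep <- rowSums(m$values) > 0 &
      rowSums(norm$values > min_expr) >= min_expr_samples
    n_dropped <- sum(!keep)
    v <- norm$values[keep, , drop = FALSE]
  } else {
    v <- m$values
  }
  gene_id <- m$gene_ids[keep]

  if (channel == "A") {
    res <- .row_welch(log2(v + 0.5), grp$idx1, grp$idx2)
    log2fc <- log2((rowMeans(v[, grp$idx1, drop = FALSE]) + 0.5) /
                   (rowMeans(v[, grp$idx2, drop = FALSE]) + 0.5))
    p <- res$p
  } else if (channel == "B") {
    res <- .row_exact_perm(log2(v + 1), grp$idx1, grp$idx2)
    log2fc <- log2((rowMeans(v[, grp$idx1, drop = FALSE]) + 0.5) /
                   (rowMeans(v[, grp$idx2, drop = FALSE]) + 0.5))
    p <- res$p
  } else if (channel == "C") {
    res <- .row_shrunk_t(v, grp$idx1, grp$idx2)
    log2fc <- res$mean1 - res$mean2
    p <- res$p
  } else {
    qn <- limma::normalizeQuantiles(v)
    res <- .row_welch(qn, grp$idx1, grp$idx2)
    log2fc <- res$mean1 - res$mean2
    p <- res$p
  }

  out <- data.frame(gene_id = gene_id, log2fc = as.numeric(log2fc),
                    p = as.numeric(p), q = bh_fdr(as.numeric(p)),
                    stringsAsFactors = FALSE)
  out$fc_rank <- .direction_ranks(out$gene_id, out$log2fc, out$p)
  attr(out, "channel") <- channel
  attr(out, "group1") <- grp$group1
  attr(out, "group2") <- grp$group2
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("channel_result", "data.frame")
  out
}

#' Write a channel result to a tab-separated file
#'
#' @param res A `channel_result` from [run_channel()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_channel_result <- function(res, path) {
  df <- as.data.frame(res)[, c("gene_id", "log2fc", "p", "q", "fc_rank")]
  names(df)[1] <- "entrez_id"
  .write_tsv(df, path)
  invisible(path)
}
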