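#' Relative qPCR quantification (delta-delta-CT)
#'
#' Per sample, `dCT = target_ct - reference_ct`; then
#' `ddCT = mean dCT(treatment) - mean dCT(control)` and the fold change of
#' the treatment condition relative to control is `2^(-ddCT)`.
#'
#' @param records Data frame with columns `sample`, `target_ct`,
#'   `reference_ct`, `condition` (values `"control"` / `"treatment"`).
#' @return List with `fold_change`, `ddct`, and `dct` (per-sample table).
#' @export
#' @examples
#' rec <- data.frame(sample = 1:4,
#'                   target_ct = c(25, 25, 23, 23),
#'                   reference_ct = 18,
#'                   condition = rep(c("control", "treatment"), each = 2))
#' ddct_fold_change(rec)$fold_change  # 2^2 = 4
ddct_fold_change <- function(records) {
  need <- c("sample", "target_ct", "reference_ct", "condition")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (anyNA(records$reference_ct)) stop("missing reference CT value(s)")
  if (anyNA(records$target_ct)) stop("missing target CT value(s)")
  cond <- as.character(records$condition)
  if (!all(cond %in% c("control", "treatment"))) {
    stop("condition must be 'control' or 'treatment'")
  }
  if (!all(c("control", "treatment") %in% cond)) {
    stop("need at least one record per condition")
  }
  ct <- c(records$target_ct, records$reference_ct)
  if (any(ct < 10 | ct > 40)) {
    warning("CT values outside the typical 10-40 cycle range")
  }
  dct <- records$target_ct - records$reference_ct
  ddct <- mean(dct[cond == "treatment"]) - mean(dct[cond == "control"])
  list(fold_change = 2^(-ddct), ddct = ddct,
       dct = data.frame(sample = records$sample, condition = cond,
                        dct = dct, stringsAsFactors = FALSE))
}

#' Welch two-sample t test
#'
#' Unequal-variance two-sided t test with Satterthwaite degrees of freedom
#' (via [stats::t.test()]). Two constant groups with equal means return
#' `t = 0, p = 1` instead of an error.
#'
#' @param x,y Numeric vectors, each with at least 2 values.
#' @return List with `t`, `df`, `p`.
#' @export
welch_t <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) < 2 || length(y) < 2) stop("each group needs >= 2 values")
  if (var(x) == 0 && var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(list(t = 0, df = length(x) + length(y) - 2, p = 1))
    }
    # variance floor keeps the statistic finite and extreme
    se <- sqrt(1e-8 / length(x) + 1e-8 / length(y))
    tstat <- (mean(x) - mean(y)) / se
    df <- length(x) + length(y) - 2
    return(list(t = tstat, df = df,
                p = 2 * pt(abs(tstat), df, lower.tail = FALSE)))
  }
  ht <- t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Kruskal-Wallis test with Dunn's post-hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H (via [stats::kruskal.test()]) followed by
#' Dunn's pairwise z tests on mean ranks with the tie correction
#' `sigma^2 = (N(N+1)/12 - sum(t^3 - t) / (12(N-1))) (1/n_i + 1/n_j)` and
#' Bonferroni adjustment across the `g(g-1)/2` pairs.
#'
#' @param groups Named list of >= 3 numeric vectors, each with >= 2 values.
#' @param alpha Significance level recorded alongside the results.
#' @return List with `H`, `df`, `p`, and `pairwise` (data frame `group1`,
#'   `group2`, `z`, `p`, `p_adjusted`, `significant`).
#' @export
kruskal_dunn <- function(groups, alpha = 0.05) {
  if (length(groups) < 3) {
    stop("need >= 3 groups; use welch_t() or a rank-sum test for 2")
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  if (any(vapply(groups, length, integer(1)) < 2)) {
    stop("each group needs >= 2 values")
  }
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, integer(1))),
              levels = names(groups))
  kt <- suppressWarnings(kruskal.test(x, g))
  h <- unname(kt$statistic)
  p_global <- kt$p.value
  if (is.nan(h)) {  # all values identical: no variation in ranks
    h <- 0
    p_global <- 1
  }

  n_tot <- length(x)
  r <- rank(x)
  mean_ranks <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (n_tot - 1))
  base_var <- n_tot * (n_tot + 1) / 12 - tie_term

  pairs <- combn(names(groups), 2)
  n_pairs <- ncol(pairs)
  z <- p_raw <- numeric(n_pairs)
  for (j in seq_len(n_pairs)) {
    a <- pairs[1, j]
    b <- pairs[2, j]
    se <- sqrt(base_var * (1 / ns[[a]] + 1 / ns[[b]]))
    if (se == 0) {
      z[j] <- 0
      p_raw[j] <- 1
    } else {
      z[j] <- (mean_ranks[[a]] - mean_ranks[[b]]) / se
      p_raw[j] <- 2 * pnorm(abs(z[j]), lower.tail = FALSE)
    }
  }
  p_adj <- pmin(p_raw * n_pairs, 1)
  pairwise <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                         z = z, p = p_raw, p_adjusted = p_adj,
                         significant = p_adj < alpha,
                         stringsAsFactors = FALSE)
  list(H = h, df = length(groups) - 1L, p = p_global, pairwise = pairwise,
       alpha = alpha)
}

#' Grubbs outlier exclusion
#'
#' Two-sided Grubbs test: `G = max |x_i - mean| / sd` is compared with the
#' t-based critical value at level `alpha`; the most extreme value is
#' excluded if G exceeds it. At most one value is excluded per pass; with
#' `iterative = TRUE` (default) passes repeat until no further rejection.
#' Zero-variance input excludes nothing.
#'
#' @param x Numeric vector with at least 3 values.
#' @param alpha Significance level of each pass (default 0.05).
#' @param iterative Repeat single-exclusion passes until no rejection.
#' @return List with `retained`, `excluded` (values in exclusion order), and
#'   `n_passes`.
#' @export
#' @examples
#' grubbs_filter(c(1, 1.1, 0.9, 50))$excluded  # 50
grubbs_filter <- function(x, alpha = 0.05, iterative = TRUE) {
  x <- as.numeric(x)
  if (anyNA(x)) stop("missing values are not allowed")
  if (length(x) < 3) stop("Grubbs test needs at least 3 values")
  excluded <- numeric(0)
  n_passes <- 0L
  repeat {
    n <- length(x)
    if (n < 3 || sd(x) == 0) break
    g_all <- abs(x - mean(x)) / sd(x)
    i_max <- which.max(g_all)
    g <- g_all[i_max]
    tcrit <- qt(1 - alpha / (2 * n), df = n - 2)
    gcrit <- ((n - 1) / sqrt(n)) * sqrt(tcrit^2 / (n - 2 + tcrit^2))
    n_passes <- n_passes + 1L
    if (g > gcrit) {
      excluded <- c(excluded, x[i_max])
      x <- x[-i_max]
      if (!iterative) break
    } else {
      break
    }
  }
  list(retained = x, excluded = excluded, n_passes = n_passes)
}
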