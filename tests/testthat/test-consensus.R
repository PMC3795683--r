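intensity_matrix <- function(values, groups) {
  expression_matrix(values, platform = "intensity", group_labels = groups)
}

test_that("expression filter implements '> threshold in >= min_samples'", {
  v <- rbind(`1` = c(0.5, 0.5, 0.5, 0.5, 0.5, 1.2),  # boundary: one of six
             `2` = rep(0, 6),
             `3` = c(5, 4, 3, 2, 1, 0.5))
  colnames(v) <- paste0("s", 1:6)
  m <- expression_matrix(v, platform = "count")
  kept <- expression_filter(m, threshold = 1, min_samples = 1)
  expect_true(1 %in% kept)
  expect_false(2 %in% kept)
  expect_true(3 %in% kept)
  # threshold 0 retains every strictly positive gene
  pos <- expression_matrix(v[c(1, 3), ] + 0.1, platform = "count")
  expect_identical(expression_filter(pos, threshold = 0), c(1L, 3L))
  expect_error(expression_filter(m, min_samples = 7), "exceeds")
})

fake_channel <- function(gene_id, log2fc, p, channel) {
  df <- data.frame(gene_id = gene_id, log2fc = log2fc, p = p,
                   q = bh_fdr(p), stringsAsFactors = FALSE)
  attr(df, "channel") <- channel
  class(df) <- c("channel_result", "data.frame")
  df
}

test_that("within-direction ranks order by |log2fc| with p then id tiebreaks", {
  chans <- lapply(c("A", "B", "C", "D"), function(ch) {
    fake_channel(gene_id = 1:5,
                 log2fc = c(10, 3, 1, 3, -2),
                 p = c(1e-5, 0.04, 0.2, 0.01, 0.5),
                 channel = ch)
  })
  fcr <- fold_change_ranks(chans)
  r <- fcr$rank[, "A"]
  names(r) <- fcr$gene_id
  expect_identical(r[["1"]], 1L)       # largest magnitude
  expect_identical(r[["4"]], 2L)       # tied |fc| with gene 2, smaller p
  expect_identical(r[["2"]], 3L)
  expect_identical(r[["3"]], 4L)
  expect_identical(r[["5"]], 1L)       # sole pop2-direction gene
  expect_identical(fcr$direction[fcr$gene_id == 5], "pop2")
})

test_that("gene universes are intersected and sign ties are excluded", {
  a <- fake_channel(1:4, c(2, 1, -1, 1), c(0.01, 0.2, 0.3, 0.2), "A")
  b <- fake_channel(1:4, c(2, 1, -1, -1), c(0.01, 0.2, 0.3, 0.2), "B")
  c_ <- fake_channel(1:5, c(2, 1, -1, 1, 9), c(0.01, 0.2, 0.3, 0.2, 0.1),
                     "C")
  d <- fake_channel(1:4, c(2, 1, -1, -1), c(0.01, 0.2, 0.3, 0.2), "D")
  fcr <- fold_change_ranks(list(a, b, c_, d))
  expect_identical(fcr$dropped_intersection, 5L)   # absent from A, B, D
  expect_identical(fcr$dropped_tied_sign, 4L)      # 2-2 sign split
  expect_setequal(fcr$gene_id, 1:3)

  empty <- fake_channel(100:101, c(1, 2), c(0.1, 0.2), "B")
  expect_error(fold_change_ranks(list(a, empty, c_, d)),
               "empty gene-id intersection")
})

test_that("mean rank aggregation reproduces hand values and the pass rule", {
  # gene 1 ranked 1 by all four channels; gene 2 ranks (2,3,4,5) -> mean 3.5
  fcs <- list(c(10, 5, 4, 3, 2, 1), c(10, 4, 5, 3, 2, 1),
              c(10, 3, 4, 5, 2, 1), c(10, 2, 4, 3, 5, 1))
  chans <- lapply(seq_along(fcs), function(i) {
    fake_channel(1:6, fcs[[i]],
                 p = c(1e-6, 1e-4, 0.2, 0.3, 0.4, 0.5),
                 channel = LETTERS[i])
  })
  tab <- mean_rank_aggregate(fold_change_ranks(chans))
  expect_identical(tab$entrez_id[1], 1L)
  expect_equal(tab$mean_fc_rank[tab$entrez_id == 1], 1)
  expect_equal(tab$mean_fc_rank[tab$entrez_id == 2], mean(c(2, 3, 4, 5)))
  expect_true(all(diff(tab$mean_fc_rank[tab$direction == "pop1"]) >= 0))
})

test_that("consensus pass set equals the brute-force >=3-of-4 rule", {
  set.seed(77)
  sim <- simulate_two_population_expression(
    two_pop_sim_config(n_genes = 100, n_marker_per_direction = 10,
                       seed = 31))
  res <- lapply(c("A", "B", "C", "D"),
                function(ch) run_channel(sim$channels[[ch]], ch))
  fcr <- fold_change_ranks(res)
  tab <- mean_rank_aggregate(fcr, fdr = 0.05, min_methods = 3)

  # brute force, from the raw per-channel q values
  qmat <- vapply(res, function(r) r$q[match(fcr$gene_id, r$gene_id)],
                 numeric(length(fcr$gene_id)))
  brute <- fcr$gene_id[rowSums(qmat < 0.05) >= 3]
  expect_setequal(tab$entrez_id[tab$pass], brute)

  # pass set between the intersection and union of channel calls
  sig_sets <- lapply(res, function(r) r$gene_id[r$q < 0.05])
  expect_true(all(tab$entrez_id[tab$pass] %in% Reduce(union, sig_sets)))
  inter <- intersect(Reduce(intersect, sig_sets), fcr$gene_id)
  expect_true(all(inter %in% tab$entrez_id[tab$pass]))
})

test_that("mean rank is invariant to channel order", {
  sim <- small_two_pop(seed = 19)
  res <- lapply(c("A", "B", "C", "D"),
                function(ch) run_channel(sim$channels[[ch]], ch))
  t1 <- mean_rank_aggregate(fold_change_ranks(res))
  t2 <- mean_rank_aggregate(fold_change_ranks(res[c(3, 1, 4, 2)]))
  t2 <- t2[match(t1$entrez_id, t2$entrez_id), ]
  expect_equal(t1$mean_fc_rank, t2$mean_fc_rank)
  expect_identical(t1$pass, t2$pass)
})

test_that("duplicated identical profiles cluster into their groups", {
  base <- matrix(rnorm(50 * 2), 50, 2)
  v <- cbind(base[, 1], base[, 1], base[, 1], base[, 2], base[, 2],
             base[, 2] + rnorm(50, sd = 1e-6))
  dimnames(v) <- list(1:50, paste0("s", 1:6))
  m <- intensity_matrix(v, rep(c("g1", "g2"), each = 3))
  expect_true(cluster_separation(m)$separation)
})

test_that("separation collapses under label shuffles of separated data", {
  set.seed(23)
  n_rep <- 8
  base <- rnorm(60)
  effect <- sample(c(-4, 4), 60, replace = TRUE)
  in_g2 <- rep(c(0, 1), each = n_rep)
  v <- outer(base, rep(1, 2 * n_rep)) + outer(effect, in_g2) +
    matrix(rnorm(60 * 2 * n_rep, sd = 0.3), 60)
  dimnames(v) <- list(1:60, paste0("s", seq_len(2 * n_rep)))
  true_groups <- rep(c("g1", "g2"), each = n_rep)
  expect_true(cluster_separation(intensity_matrix(v, true_groups))$separation)
  flags <- vapply(1:30, function(i) {
    shuffled <- sample(true_groups)
    if (identical(shuffled, true_groups) ||
        identical(shuffled, rev(true_groups))) {
      return(FALSE)
    }
    cluster_separation(intensity_matrix(v, shuffled))$separation
  }, logical(1))
  expect_lte(sum(flags), 1)
})

test_that("synthetic default fixture separates the two populations", {
  sim <- small_two_pop(seed = 3)
  norm <- normalize_counts(sim$channels$A)
  kept <- expression_filter(norm, threshold = 1, min_samples = 1)
  expect_true(cluster_separation(norm, kept)$separation)
})

test_that("constant sample profiles are rejected with a filter hint", {
  v <- matrix(1, 10, 4, dimnames = list(1:10, paste0("s", 1:4)))
  v[, 1:2] <- rnorm(20)
  m <- intensity_matrix(v, rep(c("g1", "g2"), each = 2))
  expect_error(cluster_separation(m), "expression filter")
})
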