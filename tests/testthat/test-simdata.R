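test_that("two-population generator is deterministic given its seed", {
  cfg <- two_pop_sim_config(n_genes = 200, n_marker_per_direction = 10,
                            seed = 42)
  a <- simulate_two_population_expression(cfg)
  b <- simulate_two_population_expression(cfg)
  expect_identical(a, b)
  c2 <- simulate_two_population_expression(
    two_pop_sim_config(n_genes = 200, n_marker_per_direction = 10,
                       seed = 43))
  expect_false(identical(a$channels$A$values, c2$channels$A$values))
})

test_that("null configuration yields a truth table with no markers", {
  sim <- simulate_two_population_expression(
    two_pop_sim_config(n_genes = 150, n_marker_per_direction = 0, seed = 1))
  expect_true(all(sim$truth$direction == "null"))
  expect_true(all(sim$truth$log2fc == 0))
  # group means differ only by noise: no gene shows a large separation
  g <- sim$channels$C$group_labels
  diff <- rowMeans(sim$channels$C$values[, g == "pop1"]) -
    rowMeans(sim$channels$C$values[, g == "pop2"])
  expect_lt(max(abs(diff)), 2)
})

test_that("channel structure: shared ids, platforms, nonnegative integer counts", {
  sim <- small_two_pop()
  ids <- lapply(sim$channels, function(m) m$gene_ids)
  expect_true(all(vapply(ids, identical, logical(1), y = ids[[1]])))
  expect_identical(sim$channels$A$platform, "count")
  expect_identical(sim$channels$B$platform, "count")
  expect_identical(sim$channels$C$platform, "intensity")
  expect_identical(sim$channels$D$platform, "intensity")
  for (ch in c("A", "B")) {
    v <- sim$channels[[ch]]$values
    expect_true(all(v >= 0))
    expect_true(all(v == round(v)))
  }
})

test_that("noise-free large-replicate run recovers the programmed fold change", {
  # law-of-large-numbers check: fc pinned at 10, noise terms switched off
  # a single baseline level keeps the two groups' library composition
  # identical, so depth normalization cannot bias the count-scale ratio
  cfg <- two_pop_sim_config(n_genes = 500, n_marker_per_direction = 20,
                            log2fc_range = c(10, 10),
                            replicates_per_group = 50,
                            base_log2_range = c(8, 8),
                            count_dispersion = 0, intensity_sd = 0,
                            replicate_sd = 0, seed = 9)
  sim <- simulate_two_population_expression(cfg)
  truth <- sim$truth
  markers <- truth$direction != "null"
  g <- sim$channels$A$group_labels
  norm <- normalize_counts(sim$channels$A)
  emp_counts <- log2(rowMeans(norm$values[, g == "pop1"]) /
                     rowMeans(norm$values[, g == "pop2"]))
  expect_true(all(abs(emp_counts[markers] -
                      truth$log2fc[markers]) < 0.2))
  emp_int <- rowMeans(sim$channels$C$values[, g == "pop1"]) -
    rowMeans(sim$channels$C$values[, g == "pop2"])
  expect_true(all(abs(emp_int[markers] - truth$log2fc[markers]) < 0.2))
})

test_that("truth directions match realized mean differences for strong effects", {
  hits <- total <- 0
  for (seed in 1:5) {
    sim <- simulate_two_population_expression(
      two_pop_sim_config(n_genes = 400, n_marker_per_direction = 40,
                         log2fc_range = c(4, 12), seed = seed))
    g <- sim$channels$C$group_labels
    diff <- rowMeans(sim$channels$C$values[, g == "pop1"]) -
      rowMeans(sim$channels$C$values[, g == "pop2"])
    truth <- sim$truth
    sel <- truth$direction != "null"
    hits <- hits + sum(sign(diff[sel]) == sign(truth$log2fc[sel]))
    total <- total + sum(sel)
  }
  expect_gte(hits / total, 0.99)
})

test_that("invalid two-population configurations are rejected", {
  expect_error(two_pop_sim_config(log2fc_range = c(5, 2)), "degenerate")
  expect_error(two_pop_sim_config(log2fc_range = c(0, 4)), "lower bound")
  expect_error(two_pop_sim_config(n_genes = 10, n_marker_per_direction = 6),
               "n_marker_per_direction")
  expect_error(two_pop_sim_config(replicates_per_group = 1), ">= 2")
  expect_error(two_pop_sim_config(library_size_range = c(2e7, 1e7)),
               "degenerate")
})

test_that("cohort generator respects censoring, labels, and determinism", {
  a <- simulate_survival_cohort(cohort_sim_config(seed = 12))
  b <- simulate_survival_cohort(cohort_sim_config(seed = 12))
  expect_identical(a, b)
  expect_true(all(a$clinical$event %in% c(0, 1)))
  expect_true(all(a$clinical$time > 0))

  no_cens <- simulate_survival_cohort(
    cohort_sim_config(censoring_rate = 0, seed = 4))
  expect_true(all(no_cens$clinical$event == 1))

  expect_error(
    cohort_sim_config(subtype_log_hrs = c(Sporadic = 0.5)),
    "unknown subtype label")
  expect_error(cohort_sim_config(n_samples = 10), ">= 20")
  expect_error(
    cohort_sim_config(subtype_proportions = c(0.3, 0.3, 0.3, 0.3)),
    "sum to 1")
})

test_that("global-null cohorts give calibrated downstream log-rank tests", {
  cfg0 <- function(seed) {
    cohort_sim_config(marker_log_hr = 0,
                      subtype_log_hrs = c(Classical = 0, Mesenchymal = 0,
                                          Neural = 0, Proneural = 0),
                      seed = seed)
  }
  rej <- vapply(1:500, function(s) {
    coh <- simulate_survival_cohort(cfg0(s))
    grp <- median_dichotomize(coh$truth$marker_value)
    logrank_test(coh$clinical$time, coh$clinical$event, grp)$p < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("fixture writer round-trips, is checksum-stable, and logs truth", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  tp <- two_pop_sim_config(n_genes = 120, n_marker_per_direction = 8,
                           seed = 21)
  cc <- cohort_sim_config(n_samples = 40, n_ref_per_subtype = 3, seed = 22)
  files1 <- write_fixtures(dir1, tp, cc)
  files2 <- write_fixtures(dir2, tp, cc)

  md1 <- tools::md5sum(files1[names(files1) != "manifest"])
  md2 <- tools::md5sum(files2[names(files2) != "manifest"])
  expect_identical(unname(md1), unname(md2))

  m <- read_expression(files1[["channel_A"]], platform = "count")
  sim <- simulate_two_population_expression(tp)
  expect_equal(m$values, sim$channels$A$values)
  expect_identical(m$gene_ids, sim$channels$A$gene_ids)

  clin <- read_clinical(files1[["clinical"]])
  expect_identical(nrow(clin), cc$n_samples)

  manifest <- jsonlite::read_json(files1[["manifest"]],
                                  simplifyVector = TRUE)
  expect_identical(as.integer(manifest$two_pop$n_genes), tp$n_genes)
  truth <- read.delim(files1[["two_pop_truth"]])
  expect_identical(nrow(truth), tp$n_genes)

  blocker <- withr::local_tempfile(lines = "x")
  expect_error(write_fixtures(file.path(blocker, "sub")), "cannot create")
})
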