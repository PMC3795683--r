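#' Pipeline configuration
#'
#' Bundles every stage parameter with the defaults of the published
#' analysis: per-channel FDR 0.05 with a 3-of-4 consensus rule, expression
#' filter "> 1 in >= 1 sample", 10-nearest-neighbor subtype assignment,
#' median dichotomization, Mesenchymal reference subtype.
#'
#' @param work_dir Directory holding all pipeline artifacts.
#' @param seed Master seed for the simulate stage.
#' @param fdr Per-channel q-value threshold.
#' @param min_methods Channels required for a consensus pass.
#' @param knn_k Neighbors for subtype assignment.
#' @param expr_threshold,expr_min_samples Expression-filter parameters.
#' @param reference_subtype Reference level of the subtype contrasts.
#' @param two_pop_cfg,cohort_cfg Simulation configurations used by the
#'   `simulate` stage (seeded from `seed` unless supplied explicitly).
#' @param verbose Emit progress messages.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(work_dir = tempfile("crossmark_"),
                            seed = 1L,
                            fdr = 0.05,
                            min_methods = 3L,
                            knn_k = 10L,
                            expr_threshold = 1,
                            expr_min_samples = 1L,
                            reference_subtype = "Mesenchymal",
                            two_pop_cfg = NULL,
                            cohort_cfg = NULL,
                            verbose = FALSE) {
  if (is.null(two_pop_cfg)) two_pop_cfg <- two_pop_sim_config(seed = seed)
  if (is.null(cohort_cfg)) cohort_cfg <- cohort_sim_config(seed = seed + 1L)
  structure(list(work_dir = work_dir, seed = as.integer(seed), fdr = fdr,
                 min_methods = as.integer(min_methods),
                 knn_k = as.integer(knn_k),
                 expr_threshold = expr_threshold,
                 expr_min_samples = as.integer(expr_min_samples),
                 reference_subtype = reference_subtype,
                 two_pop_cfg = two_pop_cfg, cohort_cfg = cohort_cfg,
                 verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

.pipe_msg <- function(cfg, ...) {
  if (cfg$verbose) message(...)
}

.require_artifact <- function(path, produced_by) {
  if (!file.exists(path)) {
    stop("missing upstream artifact '", basename(path),
         "': run the '", produced_by, "' stage first")
  }
  path
}

.artifact <- function(cfg, name) file.path(cfg$work_dir, name)

#' Run a pipeline stage
#'
#' Executes one named stage against the artifact directory `cfg$work_dir`.
#' Stages consume the files earlier stages wrote and fail with an actionable
#' message when an upstream artifact is missing. All stages are
#' deterministic given `cfg$seed`. Counts of everything filtered or dropped
#' are accumulated in `log.json`.
#'
#' Stages: `simulate` (write all synthetic inputs), `de` (four channels),
#' `consensus` (rank merge + expression filter + clustering separation),
#' `subtype` (kNN assignment), `survival` (univariate + subtype-adjusted
#' marker analysis), `stats` (qPCR fold change), `report` (single JSON
#' summary of the consensus top genes and the survival block).
#'
#' @param cfg A [pipeline_config()].
#' @param command Stage name.
#' @return The stage's primary result, invisibly; artifacts are written
#'   under `cfg$work_dir`.
#' @export
run_pipeline <- function(cfg,
                         command = c("simulate", "de", "consensus",
                                     "subtype", "survival", "stats",
                                     "report")) {
  stopifnot(inherits(cfg, "pipeline_config"))
  command <- match.arg(command)
  if (!dir.exists(cfg$work_dir)) {
    dir.create(cfg$work_dir, recursive = TRUE)
  }
  log_path <- .artifact(cfg, "log.json")
  plog <- if (file.exists(log_path)) {
    jsonlite::read_json(log_path, simplifyVector = TRUE)
  } else {
    list()
  }
  save_log <- function() {
    jsonlite::write_json(plog, log_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }

  if (command == "simulate") {
    .pipe_msg(cfg, "simulate: writing fixtures to ", cfg$work_dir)
    files <- write_fixtures(cfg$work_dir, cfg$two_pop_cfg, cfg$cohort_cfg)
    plog$simulate <- list(n_genes = cfg$two_pop_cfg$n_genes,
                          n_cohort = cfg$cohort_cfg$n_samples)
    save_log()
    return(invisible(files))
  }

  if (command == "de") {
    groups_df <- .read_tsv(.require_artifact(.artifact(cfg, "groups.tsv"),
                                             "simulate"))
    groups <- setNames(groups_df$group, groups_df$sample)
    results <- list()
    dropped <- list()
    for (ch in c("A", "B", "C", "D")) {
      platform <- if (ch %in% c("A", "B")) "count" else "intensity"
      fname <- sprintf("channel_%s_%s.tsv", ch,
                       if (platform == "count") "counts" else "intensity")
      m <- read_expression(.require_artifact(.artifact(cfg, fname),
                                             "simulate"),
                           platform = platform, group_labels = groups)
      res <- run_channel(m, ch)
      write_channel_result(res, .artifact(cfg,
                                          sprintf("channel_%s_results.tsv",
                                                  ch)))
      dropped[[ch]] <- attr(res, "n_dropped")
      results[[ch]] <- res
      .pipe_msg(cfg, "de: channel ", ch, " tested ", nrow(res), " genes (",
                attr(res, "n_dropped"), " dropped)")
    }
    plog$de <- list(genes_dropped = dropped)
    save_log()
    return(invisible(results))
  }

  if (command == "consensus") {
    results <- lapply(c("A", "B", "C", "D"), function(ch) {
      path <- .require_artifact(
        .artifact(cfg, sprintf("channel_%s_results.tsv", ch)), "de")
      df <- .read_tsv(path)
      names(df)[names(df) == "entrez_id"] <- "gene_id"
      attr(df, "channel") <- ch
      class(df) <- c("channel_result", "data.frame")
      df
    })
    fcr <- fold_change_ranks(results)
    tab <- mean_rank_aggregate(fcr, fdr = cfg$fdr,
                               min_methods = cfg$min_methods)
    write_consensus(tab, .artifact(cfg, "consensus.tsv"))

    # clustering separation on the expressed universe of channel A
    groups_df <- .read_tsv(.require_artifact(.artifact(cfg, "groups.tsv"),
                                             "simulate"))
    m <- read_expression(.artifact(cfg, "channel_A_counts.tsv"),
                         platform = "count",
                         group_labels = setNames(groups_df$group,
                                                 groups_df$sample))
    norm <- normalize_counts(m)
    expressed <- expression_filter(norm, threshold = cfg$expr_threshold,
                                   min_samples = cfg$expr_min_samples)
    cl <- cluster_separation(norm, expressed)
    plog$consensus <- list(
      n_tested = nrow(tab), n_pass = sum(tab$pass),
      dropped_intersection = length(fcr$dropped_intersection),
      dropped_tied_sign = length(fcr$dropped_tied_sign),
      n_expressed = length(expressed),
      n_below_expression_filter = nrow(norm$values) - length(expressed),
      cluster_separation = cl$separation)
    save_log()
    .pipe_msg(cfg, "consensus: ", sum(tab$pass), " pass genes; separation ",
              cl$separation)
    return(invisible(list(table = tab, separation = cl$separation)))
  }

  if (command == "subtype") {
    cohort <- read_expression(
      .require_artifact(.artifact(cfg, "cohort_expression.tsv"), "simulate"),
      platform = "intensity")
    refmat <- .read_tsv(.require_artifact(
      .artifact(cfg, "reference_matrix.tsv"), "simulate"))
    labs <- .read_tsv(.require_artifact(
      .artifact(cfg, "reference_labels.tsv"), "simulate"))
    profiles <- as.matrix(refmat[, -1, drop = FALSE])
    rownames(profiles) <- refmat$entrez_id
    ref <- subtype_reference(profiles, setNames(labs$subtype, labs$sample))
    assign <- assign_subtypes(cohort, ref, k = cfg$knn_k)
    .write_tsv(assign, .artifact(cfg, "subtype_assignments.tsv"))
    plog$subtype <- list(n_matched = attr(assign, "n_matched"),
                         n_dropped_cohort = attr(assign, "n_dropped_cohort"),
                         n_dropped_ref = attr(assign, "n_dropped_ref"),
                         assignments = as.list(table(assign$subtype)))
    save_log()
    return(invisible(assign))
  }

  if (command == "survival") {
    clin <- read_clinical(.require_artifact(.artifact(cfg, "clinical.tsv"),
                                            "simulate"))
    assign <- .read_tsv(.require_artifact(
      .artifact(cfg, "subtype_assignments.tsv"), "subtype"))
    cohort <- read_expression(
      .require_artifact(.artifact(cfg, "cohort_expression.tsv"), "simulate"),
      platform = "intensity")
    marker_id <- cfg$cohort_cfg$marker_gene_id
    row <- match(marker_id, cohort$gene_ids)
    if (is.na(row)) stop("marker gene ", marker_id, " absent from cohort")
    marker <- cohort$values[row, clin$sample]
    subtype <- assign$subtype[match(clin$sample, assign$sample)]
    if (anyNA(subtype)) stop("unassigned sample(s) in clinical table")

    uni <- univariate_marker_analysis(clin$time, clin$event, marker)
    adj_d <- subtype_adjusted_analysis(clin$time, clin$event, marker,
                                       subtype, mode = "dichotomized",
                                       reference = cfg$reference_subtype)
    adj_c <- subtype_adjusted_analysis(clin$time, clin$event, marker,
                                       subtype, mode = "continuous",
                                       reference = cfg$reference_subtype)
    report <- list(
      n = length(marker), n_events = sum(clin$event),
      univariate = list(
        logrank_p = uni$logrank$p,
        hr_dichotomized = unname(uni$cox_dichotomized$hr[1]),
        hr_continuous = unname(uni$cox_continuous$hr[1])),
      adjusted_dichotomized = adj_d$table,
      adjusted_continuous = adj_c$table)
    jsonlite::write_json(report, .artifact(cfg, "survival_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    .write_tsv(adj_d$table, .artifact(cfg, "survival_adjusted_dichot.tsv"))
    .write_tsv(adj_c$table, .artifact(cfg, "survival_adjusted_cont.tsv"))
    .write_tsv(uni$km, .artifact(cfg, "km_curves.tsv"))
    plog$survival <- list(n = length(marker), n_events = sum(clin$event))
    save_log()
    return(invisible(list(univariate = uni, adjusted_dichotomized = adj_d,
                          adjusted_continuous = adj_c)))
  }

  if (command == "stats") {
    qpcr <- .read_tsv(.require_artifact(.artifact(cfg, "qpcr.tsv"),
                                        "simulate"))
    dd <- ddct_fold_change(qpcr)
    wt <- welch_t(dd$dct$dct[dd$dct$condition == "control"],
                  dd$dct$dct[dd$dct$condition == "treatment"])
    res <- list(fold_change = dd$fold_change, ddct = dd$ddct,
                welch = wt)
    jsonlite::write_json(res, .artifact(cfg, "stats_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    plog$stats <- list(fold_change = dd$fold_change)
    save_log()
    return(invisible(res))
  }

  # report: single JSON joining consensus top genes and the survival block
  cons_path <- .require_artifact(.artifact(cfg, "consensus.tsv"), "consensus")
  surv_path <- .require_artifact(.artifact(cfg, "survival_report.json"),
                                 "survival")
  cons <- .read_tsv(cons_path)
  surv <- jsonlite::read_json(surv_path, simplifyVector = TRUE)
  top_n <- 25L
  top <- lapply(split(cons, cons$direction), function(d) {
    head(d[order(d$mean_fc_rank), ], top_n)
  })
  report <- list(consensus = list(n_tested = nrow(cons),
                                  n_pass = sum(cons$pass),
                                  top = top),
                 survival = surv,
                 log = plog)
  jsonlite::write_json(report, .artifact(cfg, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
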