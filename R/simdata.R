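#' Configuration for the two-population marker simulation
#'
#' Describes a synthetic experiment in the image of a FACS-purified
#' two-population comparison: two cell populations (`pop1`, `pop2`),
#' `replicates_per_group` biological replicates each, measured on a
#' sequencing platform (overdispersed counts; channels A and B) and an array
#' platform (Gaussian log2 intensities; channels C and D). A chosen number of
#' marker genes per direction carries a true log2 fold change drawn uniformly
#' from `log2fc_range`; all other genes are null.
#'
#' Channel pairs share the same latent per-sample expression and differ only
#' by channel-specific measurement noise, so cross-channel rank agreement is
#' informative rather than automatic.
#'
#' @param n_genes Total number of genes.
#' @param n_marker_per_direction True markers enriched in each population;
#'   `2 * n_marker_per_direction` must not exceed `n_genes`.
#' @param log2fc_range Interval (log2 units) from which true marker fold
#'   changes are drawn; lower bound must be positive.
#' @param replicates_per_group Biological replicates per population (>= 2);
#'   default 3 as in a three-versus-three sorted-cell design.
#' @param count_dispersion Negative-binomial dispersion of the count
#'   channels (variance `mu + dispersion * mu^2`); 0 gives Poisson counts.
#'   Default 0.01, i.e. a biological coefficient of variation of 0.1, the
#'   conventional magnitude for replicates of inbred-animal sorted cells.
#' @param intensity_sd Gaussian measurement noise (log2 units) of the
#'   intensity channels; 0 disables channel noise.
#' @param library_size_range Interval of per-sample sequencing depths (reads).
#' @param replicate_sd Between-replicate biological standard deviation (log2
#'   units) of the shared latent expression.
#' @param base_log2_range Interval of baseline (unenriched) log2 expression
#'   levels.
#' @param seed Integer seed; every draw is deterministic given it.
#'
#' @return A validated list of class `two_pop_sim_config`.
#' @seealso [simulate_two_population_expression()]
#' @export
two_pop_sim_config <- function(n_genes = 10000,
                               n_marker_per_direction = 150,
                               log2fc_range = c(2, 12),
                               replicates_per_group = 3,
                               count_dispersion = 0.01,
                               intensity_sd = 0.2,
                               library_size_range = c(1.5e7, 2.2e7),
                               replicate_sd = 0.1,
                               base_log2_range = c(4, 12),
                               seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_marker_per_direction = as.integer(n_marker_per_direction),
              log2fc_range = as.numeric(log2fc_range),
              replicates_per_group = as.integer(replicates_per_group),
              count_dispersion = as.numeric(count_dispersion),
              intensity_sd = as.numeric(intensity_sd),
              library_size_range = as.numeric(library_size_range),
              replicate_sd = as.numeric(replicate_sd),
              base_log2_range = as.numeric(base_log2_range),
              seed = as.integer(seed))
  .check_interval <- function(x, name, allow_equal = TRUE) {
    if (length(x) != 2 || anyNA(x) || (!allow_equal && x[1] >= x[2]) ||
        x[1] > x[2]) {
      stop("degenerate interval for ", name, ": [",
           paste(x, collapse = ", "), "]")
    }
  }
  .check_interval(cfg$log2fc_range, "log2fc_range")
  .check_interval(cfg$library_size_range, "library_size_range")
  .check_interval(cfg$base_log2_range, "base_log2_range")
  if (cfg$n_genes < 1) stop("n_genes must be positive")
  if (cfg$n_marker_per_direction < 0 ||
      2L * cfg$n_marker_per_direction > cfg$n_genes) {
    stop("need n_marker_per_direction * 2 <= n_genes")
  }
  if (cfg$log2fc_range[1] <= 0 && cfg$n_marker_per_direction > 0) {
    stop("log2fc_range lower bound must be > 0")
  }
  if (cfg$replicates_per_group < 2) stop("replicates_per_group must be >= 2")
  if (cfg$count_dispersion < 0) stop("count_dispersion must be >= 0")
  if (cfg$intensity_sd < 0) stop("intensity_sd must be >= 0")
  if (cfg$replicate_sd < 0) stop("replicate_sd must be >= 0")
  if (any(cfg$library_size_range <= 0)) stop("library sizes must be positive")
  class(cfg) <- "two_pop_sim_config"
  cfg
}

# Draw one platform's latent log2 expression (genes x samples): group means
# plus between-replicate biological noise.
.latent_log2 <- function(mu1, mu2, n_rep, replicate_sd) {
  n_genes <- length(mu1)
  latent <- cbind(matrix(rep(mu1, n_rep), n_genes, n_rep),
                  matrix(rep(mu2, n_rep), n_genes, n_rep))
  latent + matrix(rnorm(n_genes * 2 * n_rep, sd = replicate_sd),
                  n_genes, 2 * n_rep)
}

# NB (or Poisson when dispersion == 0) counts around per-gene x sample means.
.draw_counts <- function(mu, dispersion) {
  n <- length(mu)
  counts <- if (dispersion > 0) {
    rnbinom(n, mu = mu, size = 1 / dispersion)
  } else {
    rpois(n, lambda = mu)
  }
  matrix(counts, nrow = nrow(mu), ncol = ncol(mu))
}

#' Simulate a two-population, two-platform marker experiment
#'
#' Generates four paired expression matrices -- channel A and B counts
#' (sequencing platform) and channel C and D log2 intensities (array
#' platform) -- over a shared gene universe, plus a truth table recording
#' each gene's direction (`pop1`-enriched, `pop2`-enriched, or `null`) and
#' true log2 fold change (`pop1` over `pop2`).
#'
#' Marker genes have their enriched group's latent mean raised by the drawn
#' log2 fold change above the gene's baseline. The two count channels share
#' one latent per-sample expression matrix; the two intensity channels share
#' another (independently drawn replicate noise, emulating platform-specific
#' biological sample sets). Count channel means are scaled per sample so
#' column totals match the drawn library sizes.
#'
#' @param cfg A [two_pop_sim_config()].
#' @return A list with `channels` (named list `A`,`B`,`C`,`D` of
#'   [expression_matrix()] objects sharing gene ids and group labels) and
#'   `truth` (data frame `gene_id`, `direction`, `log2fc`).
#' @export
#' @examples
#' sim <- simulate_two_population_expression(
#'   two_pop_sim_config(n_genes = 200, n_marker_per_direction = 10, seed = 7))
#' table(sim$truth$direction)
simulate_two_population_expression <- function(cfg) {
  stopifnot(inherits(cfg, "two_pop_sim_config"))
  set.seed(cfg$seed)
  n_rep <- cfg$replicates_per_group
  n_samp <- 2L * n_rep
  gene_ids <- seq_len(cfg$n_genes) + 100000L  # Entrez-style integer ids
  sample_ids <- c(paste0("pop1_", seq_len(n_rep)),
                  paste0("pop2_", seq_len(n_rep)))
  groups <- setNames(rep(c("pop1", "pop2"), each = n_rep), sample_ids)

  n_mark <- cfg$n_marker_per_direction
  direction <- rep("null", cfg$n_genes)
  if (n_mark > 0) {
    direction[seq_len(n_mark)] <- "pop1"
    direction[n_mark + seq_len(n_mark)] <- "pop2"
  }
  base <- runif(cfg$n_genes, cfg$base_log2_range[1], cfg$base_log2_range[2])
  fc <- numeric(cfg$n_genes)
  if (n_mark > 0) {
    mag <- runif(2 * n_mark, cfg$log2fc_range[1], cfg$log2fc_range[2])
    fc[direction == "pop1"] <- mag[seq_len(n_mark)]
    fc[direction == "pop2"] <- -mag[n_mark + seq_len(n_mark)]
  }
  mu1 <- base + pmax(fc, 0)   # enriched group sits above baseline
  mu2 <- base + pmax(-fc, 0)

  # sequencing platform: shared latent, per-sample library scaling
  latent_seq <- .latent_log2(mu1, mu2, n_rep, cfg$replicate_sd)
  lib <- runif(n_samp, cfg$library_size_range[1], cfg$library_size_range[2])
  rel <- 2^latent_seq
  rel <- sweep(rel, 2, colSums(rel), "/")
  mu_counts <- sweep(rel, 2, lib, "*")
  mat_a <- .draw_counts(mu_counts, cfg$count_dispersion)
  mat_b <- .draw_counts(mu_counts, cfg$count_dispersion)

  # array platform: its own latent, Gaussian channel noise
  latent_arr <- .latent_log2(mu1, mu2, n_rep, cfg$replicate_sd)
  noise <- function() matrix(rnorm(cfg$n_genes * n_samp, sd = cfg$intensity_sd),
                             cfg$n_genes, n_samp)
  mat_c <- latent_arr + noise()
  mat_d <- latent_arr + noise()

  em <- function(v, platform) {
    expression_matrix(v, gene_ids = gene_ids, sample_ids = sample_ids,
                      platform = platform, group_labels = groups)
  }
  list(
    channels = list(A = em(mat_a, "count"), B = em(mat_b, "count"),
                    C = em(mat_c, "intensity"), D = em(mat_d, "intensity")),
    truth = data.frame(gene_id = gene_ids, direction = direction,
                       log2fc = fc, stringsAsFactors = FALSE)
  )
}

#' Configuration for the survival-cohort simulation
#'
#' Describes a synthetic tumor cohort: samples drawn from molecular subtypes
#' with given proportions, subtype centroids separated on blocks of signature
#' genes, one candidate marker gene, and censored survival times from a
#' proportional-hazards model. Defaults mirror a 159-sample glioblastoma
#' cohort stratified into four transcriptional subtypes (33 Classical, 58
#' Mesenchymal, 19 Neural, 49 Proneural) with a dichotomized-marker hazard
#' ratio of 1.57 and subtype hazard ratios 0.89/1.13/0.60 versus Mesenchymal.
#'
#' @param n_samples Cohort size (>= 20).
#' @param subtype_labels Subtype names.
#' @param subtype_proportions Sampling weights (must sum to 1).
#' @param n_signature_genes Number of subtype signature genes; divided into
#'   one elevated block per subtype.
#' @param centroid_separation Elevation (log2 units) of a subtype's own
#'   signature block above baseline.
#' @param noise_sd Per-gene Gaussian noise of cohort profiles around their
#'   centroid; default `0.25 * centroid_separation`.
#' @param marker_gene_id Integer id of the marker gene (default 50848, the
#'   Entrez id of human F11R, the motivating marker).
#' @param marker_log_hr Log hazard ratio of the High-vs-Low marker indicator
#'   (dichotomized at the realized cohort median).
#' @param baseline_hazard Baseline event rate (events per unitless time).
#' @param censoring_rate Rate of the independent exponential censoring
#'   process; 0 disables censoring.
#' @param subtype_log_hrs Named log hazard ratios per subtype (reference has
#'   0); names must be a subset of `subtype_labels`.
#' @param n_ref_per_subtype Labeled reference samples drawn per subtype for
#'   nearest-neighbor assignment.
#' @param ref_noise_sd Noise of reference profiles; defaults to `noise_sd`.
#' @param seed Integer seed.
#'
#' @return A validated list of class `cohort_sim_config`.
#' @seealso [simulate_survival_cohort()]
#' @export
cohort_sim_config <- function(n_samples = 159,
                              subtype_labels = c("Classical", "Mesenchymal",
                                                 "Neural", "Proneural"),
                              subtype_proportions = c(33, 58, 19, 49) / 159,
                              n_signature_genes = 40,
                              centroid_separation = 2,
                              noise_sd = NULL,
                              marker_gene_id = 50848L,
                              marker_log_hr = log(1.57),
                              baseline_hazard = 1,
                              censoring_rate = 0.2,
                              subtype_log_hrs = c(Classical = log(0.89),
                                                  Mesenchymal = 0,
                                                  Neural = log(1.13),
                                                  Proneural = log(0.60)),
                              n_ref_per_subtype = 12,
                              ref_noise_sd = NULL,
                              seed = 1L) {
  if (is.null(noise_sd)) noise_sd <- 0.25 * centroid_separation
  if (is.null(ref_noise_sd)) ref_noise_sd <- noise_sd
  cfg <- list(n_samples = as.integer(n_samples),
              subtype_labels = as.character(subtype_labels),
              subtype_proportions = as.numeric(subtype_proportions),
              n_signature_genes = as.integer(n_signature_genes),
              centroid_separation = as.numeric(centroid_separation),
              noise_sd = as.numeric(noise_sd),
              marker_gene_id = as.integer(marker_gene_id),
              marker_log_hr = as.numeric(marker_log_hr),
              baseline_hazard = as.numeric(baseline_hazard),
              censoring_rate = as.numeric(censoring_rate),
              subtype_log_hrs = subtype_log_hrs,
              n_ref_per_subtype = as.integer(n_ref_per_subtype),
              ref_noise_sd = as.numeric(ref_noise_sd),
              seed = as.integer(seed))
  if (cfg$n_samples < 20) stop("n_samples must be >= 20")
  if (length(cfg$subtype_proportions) != length(cfg$subtype_labels)) {
    stop("subtype_proportions must match subtype_labels in length")
  }
  if (abs(sum(cfg$subtype_proportions) - 1) > 1e-12) {
    stop("subtype_proportions must sum to 1")
  }
  if (any(cfg$subtype_proportions < 0)) stop("proportions must be nonnegative")
  unknown <- setdiff(names(cfg$subtype_log_hrs), cfg$subtype_labels)
  if (length(unknown)) {
    stop("unknown subtype label in subtype_log_hrs: ",
         paste(unknown, collapse = ", "))
  }
  if (cfg$censoring_rate < 0) stop("censoring_rate must be >= 0")
  if (cfg$baseline_hazard <= 0) stop("baseline_hazard must be positive")
  if (cfg$n_signature_genes < length(cfg$subtype_labels)) {
    stop("need at least one signature gene per subtype")
  }
  if (cfg$noise_sd < 0 || cfg$ref_noise_sd < 0) stop("noise sds must be >= 0")
  if (cfg$n_ref_per_subtype < 1) stop("n_ref_per_subtype must be >= 1")
  class(cfg) <- "cohort_sim_config"
  cfg
}

# Subtype centroids over signature genes: baseline 6, own block raised by
# centroid_separation. Rows = genes, cols = subtypes.
.subtype_centroids <- function(cfg) {
  g <- cfg$n_signature_genes
  k <- length(cfg$subtype_labels)
  block <- rep(seq_len(k), length.out = g)
  centroids <- matrix(6, g, k, dimnames = list(NULL, cfg$subtype_labels))
  for (j in seq_len(k)) {
    centroids[block == j, j] <- 6 + cfg$centroid_separation
  }
  centroids
}

#' Simulate a tumor cohort with subtype structure and censored survival
#'
#' Draws cohort expression profiles around subtype centroids over signature
#' genes, adds one marker gene, and generates exponential survival times
#' whose hazard is multiplied by `exp(marker_log_hr)` for samples whose
#' marker expression exceeds the cohort median, and by the subtype-specific
#' hazard ratios. Censoring is independent exponential. A labeled reference
#' set drawn around the same centroids supports nearest-neighbor subtype
#' assignment.
#'
#' @param cfg A [cohort_sim_config()].
#' @return A list with
#'   * `expression`: [expression_matrix()] (signature genes + marker gene,
#'     intensity platform) for the cohort;
#'   * `clinical`: data frame `sample`, `time`, `event`, `subtype` (true
#'     generating subtype);
#'   * `reference`: a [subtype_reference()] over the signature genes;
#'   * `truth`: the generating parameters, per-sample true subtype, marker
#'     High/Low status, and signature gene ids.
#' @export
simulate_survival_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_samples
  k <- length(cfg$subtype_labels)
  subtype <- sample(cfg$subtype_labels, n, replace = TRUE,
                    prob = cfg$subtype_proportions)
  sig_ids <- seq_len(cfg$n_signature_genes) + 500000L
  if (cfg$marker_gene_id %in% sig_ids) {
    stop("marker_gene_id collides with signature gene ids")
  }
  centroids <- .subtype_centroids(cfg)
  sample_ids <- sprintf("tumor_%03d", seq_len(n))

  expr_sig <- centroids[, subtype, drop = FALSE] +
    matrix(rnorm(cfg$n_signature_genes * n, sd = cfg$noise_sd),
           cfg$n_signature_genes, n)
  marker <- rnorm(n, mean = 8, sd = 1)
  values <- rbind(expr_sig, marker)
  expr <- expression_matrix(values, gene_ids = c(sig_ids, cfg$marker_gene_id),
                            sample_ids = sample_ids, platform = "intensity")

  high <- marker > median(marker)
  log_hr_sub <- setNames(numeric(k), cfg$subtype_labels)
  log_hr_sub[names(cfg$subtype_log_hrs)] <- as.numeric(cfg$subtype_log_hrs)
  rate <- cfg$baseline_hazard *
    exp(cfg$marker_log_hr * high + log_hr_sub[subtype])
  t_event <- rexp(n, rate = rate)
  if (cfg$censoring_rate > 0) {
    t_cens <- rexp(n, rate = cfg$censoring_rate)
  } else {
    t_cens <- rep(Inf, n)
  }
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)

  n_ref <- cfg$n_ref_per_subtype * k
  ref_subtype <- rep(cfg$subtype_labels, each = cfg$n_ref_per_subtype)
  ref_vals <- centroids[, ref_subtype, drop = FALSE] +
    matrix(rnorm(cfg$n_signature_genes * n_ref, sd = cfg$ref_noise_sd),
           cfg$n_signature_genes, n_ref)
  ref_ids <- sprintf("ref_%03d", seq_len(n_ref))
  colnames(ref_vals) <- ref_ids
  rownames(ref_vals) <- as.character(sig_ids)
  reference <- subtype_reference(ref_vals, setNames(ref_subtype, ref_ids))

  list(
    expression = expr,
    clinical = data.frame(sample = sample_ids, time = time, event = event,
                          subtype = subtype, stringsAsFactors = FALSE),
    reference = reference,
    truth = list(config = cfg, subtype = setNames(subtype, sample_ids),
                 marker_high = setNames(high, sample_ids),
                 marker_value = setNames(marker, sample_ids),
                 signature_gene_ids = sig_ids,
                 centroids = centroids)
  )
}

#' Write a complete set of pipeline input fixtures
#'
#' Materializes the outputs of both simulators as the tab-separated files the
#' pipeline consumes, together with a JSON manifest recording seeds,
#' configurations, gene counts, and file checksums. A small qPCR CT table
#' with a known delta-delta-CT fold change is included for the group
#' statistics stage.
#'
#' @param outdir Output directory (created if needed).
#' @param two_pop_cfg A [two_pop_sim_config()].
#' @param cohort_cfg A [cohort_sim_config()].
#' @return Invisibly, a named character vector of the written file paths.
#' @export
write_fixtures <- function(outdir,
                           two_pop_cfg = two_pop_sim_config(),
                           cohort_cfg = cohort_sim_config()) {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", outdir)
  }
  probe <- file.path(outdir, ".write_probe")
  ok <- tryCatch({ file.create(probe, showWarnings = FALSE) },
                 error = function(e) FALSE)
  if (!isTRUE(ok)) stop("output directory not writable: ", outdir)
  unlink(probe)

  sim <- simulate_two_population_expression(two_pop_cfg)
  coh <- simulate_survival_cohort(cohort_cfg)

  files <- c(
    channel_A = file.path(outdir, "channel_A_counts.tsv"),
    channel_B = file.path(outdir, "channel_B_counts.tsv"),
    channel_C = file.path(outdir, "channel_C_intensity.tsv"),
    channel_D = file.path(outdir, "channel_D_intensity.tsv"),
    groups = file.path(outdir, "groups.tsv"),
    two_pop_truth = file.path(outdir, "two_pop_truth.tsv"),
    cohort_expression = file.path(outdir, "cohort_expression.tsv"),
    clinical = file.path(outdir, "clinical.tsv"),
    reference_matrix = file.path(outdir, "reference_matrix.tsv"),
    reference_labels = file.path(outdir, "reference_labels.tsv"),
    qpcr = file.path(outdir, "qpcr.tsv"),
    manifest = file.path(outdir, "manifest.json")
  )

  for (ch in names(sim$channels)) {
    write_expression(sim$channels[[ch]], files[[paste0("channel_", ch)]])
  }
  .write_tsv(data.frame(sample = names(sim$channels$A$group_labels),
                        group = unname(sim$channels$A$group_labels)),
             files[["groups"]])
  .write_tsv(sim$truth, files[["two_pop_truth"]])
  write_expression(coh$expression, files[["cohort_expression"]])
  .write_tsv(coh$clinical, files[["clinical"]])
  ref <- coh$reference
  refdf <- data.frame(entrez_id = rownames(ref$profiles), ref$profiles,
                      check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(refdf, files[["reference_matrix"]])
  .write_tsv(data.frame(sample = names(ref$labels),
                        subtype = unname(ref$labels)),
             files[["reference_labels"]])

  # qPCR fixture: treatment delta-CT 2 cycles below control -> fold change 4
  set.seed(two_pop_cfg$seed + 17L)
  qpcr <- data.frame(
    sample = sprintf("q%02d", 1:6),
    condition = rep(c("control", "treatment"), each = 3),
    target_ct = c(26.1, 25.9, 26.0, 24.1, 23.9, 24.0),
    reference_ct = rep(18.0, 6),
    stringsAsFactors = FALSE
  )
  .write_tsv(qpcr, files[["qpcr"]])

  data_files <- files[names(files) != "manifest"]
  manifest <- list(
    generator = "crossmark::write_fixtures",
    two_pop = list(seed = two_pop_cfg$seed, n_genes = two_pop_cfg$n_genes,
                   n_marker_per_direction = two_pop_cfg$n_marker_per_direction,
                   log2fc_range = two_pop_cfg$log2fc_range,
                   replicates_per_group = two_pop_cfg$replicates_per_group),
    cohort = list(seed = cohort_cfg$seed, n_samples = cohort_cfg$n_samples,
                  subtype_labels = cohort_cfg$subtype_labels,
                  marker_gene_id = cohort_cfg$marker_gene_id,
                  marker_log_hr = cohort_cfg$marker_log_hr),
    files = as.list(setNames(basename(data_files), names(data_files))),
    md5 = as.list(setNames(unname(tools::md5sum(data_files)),
                           names(data_files)))
  )
  jsonlite::write_json(manifest, files[["manifest"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(files)
}
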