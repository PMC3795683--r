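# Shared TSV conventions: tab-delimited, UTF-8, '.' decimal, "NA" missing.
.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA", fileEncoding = "UTF-8")
}

.read_tsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' Write an expression matrix to TSV
#'
#' First column `entrez_id`, remaining columns one per sample.
#'
#' @param m An [expression_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(m, path) {
  stopifnot(inherits(m, "expr_matrix"))
  df <- data.frame(entrez_id = m$gene_ids, m$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_tsv(df, path)
  invisible(path)
}

# Is this file a GEO series-matrix export? (metadata lines begin with "!")
.is_series_matrix <- function(lines) {
  any(startsWith(lines, "!series_matrix_table_begin"))
}

.parse_series_matrix <- function(lines, platform, group_labels) {
  begin <- which(startsWith(lines, "!series_matrix_table_begin"))
  end <- which(startsWith(lines, "!series_matrix_table_end"))
  if (length(begin) != 1 || length(end) != 1 || end <= begin + 1) {
    stop("malformed series matrix: missing or empty table block")
  }
  tab <- read.delim(text = lines[(begin + 1):(end - 1)], sep = "\t",
                    header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  meta_lines <- lines[startsWith(lines, "!Sample_")]
  meta <- NULL
  if (length(meta_lines)) {
    parts <- strsplit(meta_lines, "\t")
    keys <- sub("^!", "", vapply(parts, `[`, character(1), 1))
    vals <- lapply(parts, function(p) gsub('^"|"$', "", p[-1]))
    keep <- lengths(vals) == ncol(tab) - 1
    meta <- as.data.frame(do.call(rbind, vals[keep]),
                          stringsAsFactors = FALSE)
    rownames(meta) <- make.unique(keys[keep])
    colnames(meta) <- colnames(tab)[-1]
  }
  m <- .frame_to_expr(tab, platform, group_labels,
                      what = "series matrix table")
  attr(m, "geo_meta") <- meta
  m
}

.frame_to_expr <- function(df, platform, group_labels, what = "file") {
  if (ncol(df) < 2) stop(what, " needs a gene-id column plus >= 1 sample")
  ids_raw <- df[[1]]
  ids <- suppressWarnings(as.integer(ids_raw))
  if (anyNA(ids)) {
    bad <- which(is.na(ids))[1]
    stop("non-integer gene id '", ids_raw[bad], "' at data row ", bad,
         " of ", what, " (integer Entrez-style ids are required)")
  }
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicated gene id(s) in ", what, ": ",
         paste(unique(dup), collapse = ", "))
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    for (j in seq_len(ncol(df) - 1)) {
      col <- df[[j + 1]]
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad)) {
        stop("non-numeric value '", col[bad[1]], "' at data row ", bad[1],
             ", column '", colnames(df)[j + 1], "' of ", what)
      }
    }
    storage.mode(vals) <- "double"
  }
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop("missing value at data row ", idx[1], ", column '",
         colnames(vals)[idx[2]], "' of ", what)
  }
  expression_matrix(vals, gene_ids = ids, sample_ids = colnames(df)[-1],
                    platform = platform, group_labels = group_labels)
}

#' Read an expression matrix from TSV or GEO series-matrix format
#'
#' Plain TSV files need a gene-id first column and a sample-id header row.
#' GEO series-matrix exports (metadata lines starting with `!`, expression
#' block between `!series_matrix_table_begin/end`) are detected
#' automatically; their `!Sample_*` metadata rows are preserved in the
#' `geo_meta` attribute.
#'
#' @param path File path.
#' @param platform `"count"` or `"intensity"`.
#' @param group_labels Optional group labels (named by sample id).
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, platform = c("count", "intensity"),
                            group_labels = NULL) {
  platform <- match.arg(platform)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty file: ", path)
  if (.is_series_matrix(lines)) {
    return(.parse_series_matrix(lines, platform, group_labels))
  }
  .frame_to_expr(.read_tsv(path), platform, group_labels, what = path)
}

#' Read a clinical table
#'
#' Expects a TSV with columns `sample`, `time`, `event`, and optionally
#' `subtype`. Event values other than 0/1 can be recoded through
#' `event_map`. Validation errors cite the offending file line (header is
#' line 1).
#'
#' @param path File path.
#' @param event_map Optional named vector mapping raw event strings to 0/1,
#'   e.g. `c(dead = 1, alive = 0)`.
#' @return Data frame `sample`, `time`, `event`, and `subtype` if present.
#' @export
read_clinical <- function(path, event_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- .read_tsv(path)
  need <- c("sample", "time", "event")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  line_of <- function(i) i + 1  # header occupies line 1

  time <- suppressWarnings(as.numeric(df$time))
  bad <- which(is.na(time))
  if (length(bad)) {
    stop("missing or non-numeric time at line ", line_of(bad[1]))
  }
  bad <- which(time <= 0)
  if (length(bad)) {
    stop("nonpositive survival time at line ", line_of(bad[1]))
  }

  ev_raw <- df$event
  if (!is.null(event_map)) {
    mapped <- event_map[as.character(ev_raw)]
    bad <- which(is.na(mapped))
    if (length(bad)) {
      stop("event value '", ev_raw[bad[1]], "' at line ", line_of(bad[1]),
           " not covered by event_map")
    }
    event <- as.numeric(mapped)
  } else {
    event <- suppressWarnings(as.numeric(ev_raw))
  }
  bad <- which(is.na(event) | !event %in% c(0, 1))
  if (length(bad)) {
    stop("event value '", ev_raw[bad[1]], "' at line ", line_of(bad[1]),
         " is not 0/1 (supply event_map to recode)")
  }

  out <- data.frame(sample = as.character(df$sample), time = time,
                    event = as.integer(event), stringsAsFactors = FALSE)
  if ("subtype" %in% names(df)) out$subtype <- as.character(df$subtype)
  out
}

#' Write a consensus table to TSV
#'
#' @param tab A `consensus_table` from [mean_rank_aggregate()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_consensus <- function(tab, path) {
  .write_tsv(as.data.frame(tab), path)
  invisible(path)
}
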