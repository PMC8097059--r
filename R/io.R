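# Readers and writers for the plain-text tabular formats the pipeline touches.
# All tables are TSV with a header row, decimal point, missing values encoded
# as empty cells (or "NA") on read and written as empty cells.

#' Read a sample-design table
#'
#' Expected columns: `sample_id`, `condition`, `replicate` and optionally
#' `group_role` (one of `case`, `control`, `other`; defaults to `other`).
#'
#' @param path Path to a TSV file.
#' @return A data.frame with one row per sample.
#' @export
read_sample_design <- function(path) {
  df <- read_tsv_plain(path, colClasses = "character")
  df <- check_design(df)
  df$replicate <- as.integer(df$replicate)
  df
}

#' @rdname read_sample_design
#' @param design A sample-design data.frame.
#' @export
write_sample_design <- function(design, path) {
  design <- check_design(design)
  write_tsv_plain(design, path)
}

#' Read a log2 quantification matrix
#'
#' The file must carry the feature identifier in its first column and one
#' column per sample. Cells that are empty or `NA` become missing values.
#'
#' @param path Path to a TSV file.
#' @param design Optional sample design; when given, columns are restricted
#'   (in design order) to the design's samples, and a design sample missing
#'   from the file is an error naming the sample.
#' @param values_are_log2 If `FALSE` the (strictly positive) raw intensities
#'   are log2-transformed on read; non-positive cells become missing with a
#'   warning.
#' @param feature_kind `"protein"` or `"phosphosite"`, recorded as an
#'   attribute on the returned matrix.
#' @return A numeric matrix, rows = features, columns = samples.
#' @export
read_quant_matrix <- function(path, design = NULL, values_are_log2 = TRUE,
                              feature_kind = c("protein", "phosphosite")) {
  feature_kind <- match.arg(feature_kind)
  df <- read_tsv_plain(path)
  if (ncol(df) < 2) stop2("quantification matrix needs a feature column and >=1 sample")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop2("duplicate feature id(s): ",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  if (any(is.infinite(mat))) stop2("matrix entries must be finite or missing")
  if (!is.null(design)) {
    design <- check_design(design)
    absent <- setdiff(design$sample_id, colnames(mat))
    if (length(absent) > 0) {
      stop2("sample(s) in design absent from file: ", paste(absent, collapse = ", "))
    }
    mat <- mat[, design$sample_id, drop = FALSE]
  }
  if (!values_are_log2) {
    nonpos <- !is.na(mat) & mat <= 0
    if (any(nonpos)) {
      warning("non-positive raw intensities set to missing before log2",
              call. = FALSE)
      mat[nonpos] <- NA_real_
    }
    mat <- log2(mat)
  }
  attr(mat, "feature_kind") <- feature_kind
  mat
}

#' @rdname read_quant_matrix
#' @param mat A numeric matrix with feature row names and sample column names.
#' @export
write_quant_matrix <- function(mat, path) {
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop2("matrix must have feature row names and sample column names")
  }
  df <- data.frame(feature_id = rownames(mat), stringsAsFactors = FALSE)
  for (s in colnames(mat)) df[[s]] <- unname(mat[, s])
  write_tsv_plain(df, path)
}

#' Read a kinase-substrate edge table
#'
#' Columns: `kinase`, `site`, `source` (`curated` or `predicted`) and
#' `score` (required for predicted edges, ignored for curated ones, which
#' are taken at face value). When the same (kinase, site) pair occurs as
#' both curated and predicted, a single edge marked `curated` is kept;
#' re-reading the written output is a no-op.
#'
#' @param path Path to a TSV file.
#' @return A data.frame of deduplicated edges.
#' @export
read_ks_db <- function(path) {
  df <- read_tsv_plain(path)
  req <- c("kinase", "site", "source")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) stop2("K-S table lacks column(s): ", paste(miss, collapse = ", "))
  if (is.null(df$score)) df$score <- NA_real_
  df$score <- as.numeric(df$score)
  bad <- setdiff(unique(df$source), c("curated", "predicted"))
  if (length(bad) > 0) stop2("invalid edge source: ", paste(bad, collapse = ", "))
  if (any(df$source == "predicted" & is.na(df$score))) {
    stop2("predicted edge(s) without a score")
  }
  if (any(!is.na(df$score) & df$score < 0)) stop2("edge scores must be non-negative")
  parse_site_key(unique(df$site))  # validates the site dialect
  ks_dedup(df[, c("kinase", "site", "source", "score")])
}

# Keep one edge per (kinase, site); curated wins over predicted, and curated
# edges carry no score.
ks_dedup <- function(edges) {
  edges$score[edges$source == "curated"] <- NA_real_
  key <- paste(edges$kinase, edges$site, sep = "\r")
  ord <- order(key, edges$source != "curated")  # curated first within a pair
  edges <- edges[ord, , drop = FALSE]
  edges <- edges[!duplicated(key[ord]), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' @rdname read_ks_db
#' @param edges A kinase-substrate edge data.frame.
#' @export
write_ks_db <- function(edges, path) {
  write_tsv_plain(ks_dedup(edges), path)
}

#' Read per-site functional scores
#'
#' Columns: `site`, `score`; scores must lie in `[0, 1]`.
#'
#' @param path Path to a TSV file.
#' @return Named numeric vector, names = site keys.
#' @export
read_functional_scores <- function(path) {
  df <- read_tsv_plain(path)
  if (!all(c("site", "score") %in% names(df))) {
    stop2("functional-score table needs columns site, score")
  }
  score <- as.numeric(df$score)
  if (any(is.na(score)) || any(score < 0 | score > 1)) {
    stop2("functional scores must lie in [0, 1]")
  }
  stats::setNames(score, df$site)
}

#' @rdname read_functional_scores
#' @param scores Named numeric vector of scores.
#' @export
write_functional_scores <- function(scores, path) {
  write_tsv_plain(data.frame(site = names(scores), score = unname(scores),
                             stringsAsFactors = FALSE), path)
}

#' Read gene sets in GMT format
#'
#' Each line: set name, description, then members (tab separated).
#' Duplicate members within a line are stored once; a line without members
#' is skipped with a warning. An empty file yields an empty collection.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors; descriptions kept as an
#'   attribute.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  desc <- character()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    name <- parts[1]
    if (!nzchar(name)) stop2("gene set with empty name")
    members <- unique(parts[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0) {
      warning("gene set '", name, "' has no members; skipped", call. = FALSE)
      next
    }
    sets[[name]] <- members
    desc[name] <- if (length(parts) >= 2) parts[2] else ""
  }
  attr(sets, "description") <- desc
  sets
}

#' @rdname read_gene_sets
#' @param sets Named list of character vectors.
#' @export
write_gene_sets <- function(sets, path) {
  desc <- attr(sets, "description") %||% stats::setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[nm] %||% "", unique(sets[[nm]])), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a dose-response plate table
#'
#' Columns: `dose` (concentration in uM, strictly positive), `response`
#' (surviving fraction relative to vehicle, non-negative), `replicate`,
#' and optionally `agent`.
#'
#' @param path Path to a TSV file.
#' @return A data.frame.
#' @export
read_dose_response <- function(path) {
  df <- read_tsv_plain(path)
  req <- c("dose", "response", "replicate")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) stop2("dose-response table lacks column(s): ",
                              paste(miss, collapse = ", "))
  df$dose <- as.numeric(df$dose)
  df$response <- as.numeric(df$response)
  if (any(is.na(df$dose)) || any(df$dose <= 0)) stop2("doses must be positive")
  if (any(df$response < 0, na.rm = TRUE)) stop2("responses must be non-negative")
  df
}

#' @rdname read_dose_response
#' @param df A dose-response data.frame.
#' @export
write_dose_response <- function(df, path) {
  write_tsv_plain(df, path)
}
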