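# Normalization, filtering, ratio construction and descriptive projections
# applied before significance testing. Conventions follow common practice
# for log2 intensity matrices: per-sample median centering for
# normalization, row z-scaling for display only, sample SD with the n-1
# denominator throughout.

#' Median-center each sample
#'
#' Shifts every sample column by its own median over observed entries so
#' that each sample's post-normalization median is zero.
#'
#' @param mat Log2 quantification matrix (features x samples).
#' @return List with `matrix` (centered) and `report`, a data.frame of
#'   per-sample medians before/after and the method tag.
#' @export
normalize_median_center <- function(mat) {
  if (is.null(colnames(mat))) stop2("matrix must have sample column names")
  n_obs <- colSums(!is.na(mat))
  if (any(n_obs == 0)) {
    stop2("sample(s) with zero observed values: ",
          paste(colnames(mat)[n_obs == 0], collapse = ", "))
  }
  med <- apply(mat, 2, stats::median, na.rm = TRUE)
  out <- sweep(mat, 2, med, "-")
  med_after <- apply(out, 2, stats::median, na.rm = TRUE)
  report <- data.frame(sample_id = colnames(mat),
                       median_before = unname(med),
                       median_after = unname(med_after),
                       method = "median_center",
                       stringsAsFactors = FALSE)
  list(matrix = out, report = report)
}

#' Filter features by per-group completeness
#'
#' Keeps a feature only when every tested group has at least
#' `min_per_group` observed values (e.g. "quantified in at least three
#' replicates per group").
#'
#' @param mat Quantification matrix.
#' @param design Sample design.
#' @param min_per_group Minimum observed values required in each group.
#' @param groups Conditions to test; default all conditions in the design.
#' @return The row-subset matrix (possibly empty, with a warning).
#' @export
filter_by_completeness <- function(mat, design, min_per_group = 3, groups = NULL) {
  design <- check_design(design)
  check_matrix_design(mat, design)
  if (min_per_group < 1) stop2("min_per_group must be >= 1")
  groups <- groups %||% unique(design$condition)
  keep <- rep(TRUE, nrow(mat))
  for (g in groups) {
    cols <- design_samples(design, g)
    keep <- keep & rowSums(!is.na(mat[, cols, drop = FALSE])) >= min_per_group
  }
  if (!any(keep)) warning("completeness filter removed every feature", call. = FALSE)
  mat[keep, , drop = FALSE]
}

#' Log2 ratios against a reference group's row median
#'
#' Each non-reference sample value minus the row-wise median of the
#' reference group (e.g. fold-changes of treated animals over the control
#' arm's median). Rows with an all-missing reference become all-missing.
#'
#' @param mat Quantification matrix.
#' @param design Sample design.
#' @param reference_condition Condition whose row medians are subtracted.
#' @return Matrix of ratios for the non-reference samples.
#' @export
make_log2_ratios_vs_reference <- function(mat, design, reference_condition) {
  design <- check_design(design)
  check_matrix_design(mat, design)
  ref_cols <- design_samples(design, reference_condition)
  if (length(ref_cols) == 0) stop2("unknown reference condition: ", reference_condition)
  case_cols <- setdiff(intersect(colnames(mat), design$sample_id), ref_cols)
  ref_med <- apply(mat[, ref_cols, drop = FALSE], 1, function(r) {
    if (all(is.na(r))) NA_real_ else stats::median(r, na.rm = TRUE)
  })
  mat[, case_cols, drop = FALSE] - ref_med
}

#' Row z-scaling for display
#'
#' Scales each row to mean 0, SD 1 over observed entries. Rows with fewer
#' than two observed values or zero SD are dropped with a warning. This is
#' a display transform (heatmaps); tests run on centered values.
#'
#' @param mat Quantification matrix.
#' @return The row-scaled matrix.
#' @export
scale_rows_z <- function(mat) {
  st <- row_stats(mat, seq_len(ncol(mat)))
  bad <- st$n < 2 | is.na(st$var) | st$var == 0
  if (any(bad)) {
    warning(sum(bad), " constant or under-observed row(s) dropped in z-scaling",
            call. = FALSE)
  }
  out <- (mat[!bad, , drop = FALSE] - st$mean[!bad]) / sqrt(st$var[!bad])
  out
}

#' Principal component analysis of samples
#'
#' Rows with any missing value are excluded (complete-case PCA) and the
#' exclusion reported. Components are ordered by decreasing variance and
#' the sign of each component is fixed so its largest-magnitude loading is
#' positive.
#'
#' @param mat Quantification matrix (features x samples).
#' @return List with `scores` (samples x components), `loadings`
#'   (features x components), `explained_variance` (per component) and
#'   `n_dropped` incomplete features.
#' @export
run_pca <- function(mat) {
  if (ncol(mat) < 2) stop2("PCA needs at least 2 samples")
  complete <- stats::complete.cases(mat)
  n_dropped <- sum(!complete)
  x <- mat[complete, , drop = FALSE]
  if (nrow(x) < 1) stop2("no complete features for PCA")
  if (n_dropped > 0) {
    message(n_dropped, " feature(s) with missing values excluded from PCA")
  }
  pc <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  for (k in seq_len(ncol(pc$rotation))) {
    j <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[j, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  list(scores = pc$x, loadings = pc$rotation,
       explained_variance = pc$sdev^2, n_dropped = n_dropped)
}

#' Two-way hierarchical clustering of a heatmap matrix
#'
#' Rows are clustered with the Canberra distance, columns with the Pearson
#' correlation distance (1 - r), both with average linkage by default. The
#' clustered submatrix must be complete.
#'
#' @param mat Complete numeric matrix.
#' @param row_metric Distance for rows (any [stats::dist()] method).
#' @param col_metric `"pearson"` (1 - correlation) or a [stats::dist()]
#'   method applied to columns.
#' @param linkage Agglomeration method for [stats::hclust()].
#' @return List with `row_order`, `col_order` (id vectors) and the two
#'   `hclust` dendrograms.
#' @export
hierarchical_cluster <- function(mat, row_metric = "canberra",
                                 col_metric = "pearson", linkage = "average") {
  if (any(is.na(mat))) stop2("clustered matrix must have no missing values")
  if (col_metric == "pearson") {
    v <- apply(mat, 2, stats::var)
    if (any(v == 0)) {
      stop2("zero-variance column(s) under the Pearson metric: ",
            paste(colnames(mat)[v == 0], collapse = ", "))
    }
    dcol <- stats::as.dist(1 - stats::cor(mat))
  } else {
    dcol <- stats::dist(t(mat), method = col_metric)
  }
  drow <- stats::dist(mat, method = row_metric)
  hr <- stats::hclust(drow, method = linkage)
  hc <- stats::hclust(dcol, method = linkage)
  list(row_order = rownames(mat)[hr$order],
       col_order = colnames(mat)[hc$order],
       row_hclust = hr, col_hclust = hc)
}
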