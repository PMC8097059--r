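# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop2 <- function(...) stop(..., call. = FALSE)

# Format doubles with 17 significant digits so that write -> read round-trips
# bit-identical values (IEEE-754 doubles are uniquely determined by 17 digits).
fmt_num <- function(x) {
  out <- rep("", length(x))
  ok <- !is.na(x)
  out[ok] <- formatC(x[ok], digits = 17, format = "g")
  out
}

# Write a data.frame as plain TSV: header, tab separated, no quoting,
# missing values as empty cells.
write_tsv_plain <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- fmt_num(df[[j]])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
  invisible(path)
}

read_tsv_plain <- function(path, colClasses = NA) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = c("", "NA"),
                    colClasses = colClasses, comment.char = "")
}

# Row-wise count/mean/variance over observed entries of selected columns.
row_stats <- function(mat, cols) {
  x <- mat[, cols, drop = FALSE]
  obs <- !is.na(x)
  n <- rowSums(obs)
  x0 <- x
  x0[!obs] <- 0
  s <- rowSums(x0)
  mean <- ifelse(n > 0, s / n, NA_real_)
  ss <- rowSums(x0^2)
  var <- ifelse(n > 1, (ss - n * mean^2) / (n - 1), NA_real_)
  var[!is.na(var) & var < 0] <- 0  # guard against tiny negative round-off
  list(n = n, mean = mean, var = var)
}

# Sample-design accessors -----------------------------------------------------

design_samples <- function(design, condition) {
  design$sample_id[design$condition %in% condition]
}

check_design <- function(design) {
  req <- c("sample_id", "condition", "replicate")
  missing_cols <- setdiff(req, names(design))
  if (length(missing_cols) > 0) {
    stop2("sample design lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(design$sample_id)) stop2("duplicate sample_id in design")
  rep_num <- suppressWarnings(as.numeric(design$replicate))
  if (any(is.na(rep_num)) || any(rep_num < 1)) {
    stop2("replicate must be a positive integer")
  }
  if (is.null(design$group_role)) design$group_role <- "other"
  bad <- setdiff(unique(design$group_role), c("case", "control", "other"))
  if (length(bad) > 0) stop2("invalid group_role: ", paste(bad, collapse = ", "))
  design
}

check_matrix_design <- function(mat, design) {
  absent <- setdiff(design$sample_id, colnames(mat))
  if (length(absent) > 0) {
    stop2("sample(s) in design absent from matrix: ", paste(absent, collapse = ", "))
  }
  invisible(TRUE)
}
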