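# Gene-set and signature scoring: ranked top-N query construction,
# Fisher-exact over-representation analysis, z-normalized enrichment
# heatmaps, and a local Kolmogorov-Smirnov connectivity score for
# up/down signature queries.

#' Rank features and select the top N
#'
#' Deterministic ranking of a differential result by fold-change or by
#' the test statistic, with ties broken id-lexicographically. The `up`
#' list takes the `n` largest values, the `down` list the `n` smallest.
#' Typical uses: top-100 per cluster for transcription-factor target
#' enrichment; top-150 per side for connectivity queries.
#'
#' @param result A differential-result data.frame.
#' @param rank_by `"log2FC"` or `"statistic"`.
#' @param n Number of features per side.
#' @param side `"up"`, `"down"` or `"both"`.
#' @return For `side = "both"` a list with `up` and `down` character
#'   vectors; otherwise a single character vector. If fewer than `n`
#'   ranked features are available, all are returned with a warning.
#' @export
rank_and_select_top <- function(result, rank_by = c("log2FC", "statistic"),
                                n, side = c("both", "up", "down")) {
  rank_by <- match.arg(rank_by)
  side <- match.arg(side)
  if (n <= 0) stop2("n must be positive")
  key <- result[[rank_by]]
  if (is.null(key)) stop2("rank key absent: ", rank_by)
  ok <- !is.na(key)
  feats <- result$feature[ok]
  key <- key[ok]
  if (length(feats) < n) {
    warning("only ", length(feats), " ranked features available (requested ",
            n, ")", call. = FALSE)
  }
  up <- feats[order(-key, feats)][seq_len(min(n, length(feats)))]
  down <- feats[order(key, feats)][seq_len(min(n, length(feats)))]
  switch(side, both = list(up = up, down = down), up = up, down = down)
}

#' Fisher-exact over-representation analysis
#'
#' One-sided (enrichment) hypergeometric tail p value for the overlap of
#' a foreground list with each gene set, sets intersected with the
#' background before testing, BH correction across tested sets. All
#' quantified features are the intended background.
#'
#' @param foreground Character vector, must be a subset of `background`.
#' @param sets Named list of character vectors (see [read_gene_sets()]).
#' @param background Character vector of all quantified features.
#' @return Data.frame with columns `set`, `overlap`, `foreground_size`,
#'   `set_size`, `background_size`, `enrichment_factor`, `p`, `q`,
#'   ordered by increasing p.
#' @export
ora_fisher <- function(foreground, sets, background) {
  foreground <- unique(foreground)
  background <- unique(background)
  if (length(foreground) == 0) stop2("empty foreground")
  if (length(background) == 0) stop2("empty background")
  outside <- setdiff(foreground, background)
  if (length(outside) > 0) {
    stop2("foreground not contained in background: ",
          paste(utils::head(outside, 5), collapse = ", "))
  }
  bg_n <- length(background)
  fg_n <- length(foreground)
  rows <- lapply(names(sets), function(nm) {
    set <- intersect(unique(sets[[nm]]), background)
    a <- length(intersect(foreground, set))
    set_n <- length(set)
    p <- stats::phyper(a - 1, set_n, bg_n - set_n, fg_n, lower.tail = FALSE)
    factor <- if (set_n == 0) NA_real_ else (a / fg_n) / (set_n / bg_n)
    data.frame(set = nm, overlap = a, foreground_size = fg_n,
               set_size = set_n, background_size = bg_n,
               enrichment_factor = factor, p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- bh_adjust(res$p)
  res <- res[order(res$p, res$set), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Z-normalize an FDR matrix for heatmap display
#'
#' Transforms a sets x conditions matrix of BH-corrected p values (FDR,
#' in `(0, 1]`) to `-log10` scale, then z-scales each row (mean 0, SD 1
#' across conditions). Zero-SD rows become rows of zeros and are flagged.
#' An FDR of exactly 0 is a domain error; floor such values at the
#' smallest representable FDR before calling.
#'
#' @param fdr_mat Numeric matrix of FDR values in `(0, 1]`.
#' @return Z-normalized matrix; attribute `constant_rows` lists zero-SD
#'   rows.
#' @export
zscore_enrichment_heatmap <- function(fdr_mat) {
  if (any(is.na(fdr_mat)) || any(fdr_mat <= 0) || any(fdr_mat > 1)) {
    stop2("FDR values must lie in (0, 1]")
  }
  L <- -log10(fdr_mat)
  mu <- rowMeans(L)
  s <- apply(L, 1, stats::sd)
  constant <- s == 0
  s[constant] <- 1
  out <- (L - mu) / s
  out[constant, ] <- 0
  attr(out, "constant_rows") <- rownames(fdr_mat)[constant]
  out
}

# Unweighted KS enrichment score of a gene list against a ranking:
# signed maximum deviation of the running sum that steps up by 1/n at
# hits and down by 1/(N - n) elsewhere.
ks_enrichment <- function(genes, reference) {
  N <- length(reference)
  hit <- reference %in% genes
  n <- sum(hit)
  if (n == 0 || n == N) stop2("query must hit a strict subset of the reference")
  steps <- ifelse(hit, 1 / n, -1 / (N - n))
  cs <- cumsum(steps)
  cs[which.max(abs(cs))]
}

#' Connectivity score of an up/down query against a ranked profile
#'
#' Unweighted two-sided Kolmogorov-Smirnov statistics: for each list, the
#' enrichment score is the signed maximum deviation of the KS running sum
#' over the reference ranking (most-upregulated gene first). The combined
#' score is `(ES_up - ES_down) / 2` when the two enrichment scores have
#' opposite signs, and 0 otherwise. A positive score means the query's up
#' list sits high and its down list sits low in the reference, i.e. the
#' reference profile is similar to the query signature.
#'
#' @param up,down Character vectors of query gene ids; genes absent from
#'   the reference are dropped with a warning.
#' @param reference Character vector: the full reference profile ranked
#'   from most up- to most downregulated.
#' @return List with `ES_up`, `ES_down`, `score`, `n_up`, `n_down`.
#' @export
connectivity_score <- function(up, down, reference) {
  if (anyDuplicated(reference)) stop2("reference ranking has duplicate genes")
  up2 <- intersect(unique(up), reference)
  down2 <- intersect(unique(down), reference)
  dropped <- length(unique(up)) - length(up2) + length(unique(down)) - length(down2)
  if (dropped > 0) {
    warning(dropped, " query gene(s) absent from the reference dropped",
            call. = FALSE)
  }
  if (length(up2) == 0 && length(down2) == 0) {
    stop2("both query lists are empty after intersection with the reference")
  }
  es_up <- if (length(up2) > 0) ks_enrichment(up2, reference) else NA_real_
  es_down <- if (length(down2) > 0) ks_enrichment(down2, reference) else NA_real_
  score <- if (!is.na(es_up) && !is.na(es_down) && sign(es_up) != sign(es_down)) {
    (es_up - es_down) / 2
  } else {
    0
  }
  list(ES_up = es_up, ES_down = es_down, score = score,
       n_up = length(up2), n_down = length(down2))
}
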