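# Kinase-substrate enrichment analysis (KSEA) with substrate-network
# expansion, the cross-comparison kinase signature and its k-means
# clustering.

#' Expand a kinase-substrate network with predicted edges
#'
#' Curated edges are always kept; predicted edges are kept iff their
#' prediction score is at least `networkin_min` (inclusive). Setting the
#' threshold to `Inf` yields the curated-only network.
#'
#' @param edges Kinase-substrate edge data.frame (see [read_ks_db()]).
#' @param networkin_min Minimum prediction score for retaining a predicted
#'   edge.
#' @return The filtered, deduplicated edge data.frame.
#' @export
expand_ks_db <- function(edges, networkin_min = 3) {
  edges <- ks_dedup(edges)
  keep <- edges$source == "curated" |
    (edges$source == "predicted" & !is.na(edges$score) &
       edges$score >= networkin_min)
  out <- edges[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' KSEA kinase-activity scores
#'
#' Scores each kinase by the mean log2 fold-change of its matched
#' substrate sites relative to all quantified sites:
#' `z = (mean_s - mean_p) * sqrt(m) / delta`, where `mean_s` is the mean
#' fold-change of the kinase's `m` matched substrates, and `mean_p` and
#' `delta` are the mean and SD of the fold-changes of all quantified
#' sites in the comparison. Two-sided p values come from the standard
#' normal tail, with BH correction across scored kinases. Kinases with
#' fewer than `min_substrates` matched sites receive no score. Sites
#' annotated to several kinases contribute to every matching kinase.
#'
#' @param site_log2fc Named numeric vector of per-site log2 fold-changes
#'   for one comparison (names = site keys); missing values are dropped
#'   with a warning.
#' @param edges Expanded kinase-substrate edge data.frame
#'   (see [expand_ks_db()]).
#' @param min_substrates Minimum matched substrate count `m` for a kinase
#'   to be scored.
#' @return Data.frame with columns `kinase`, `m`, `mean_s`, `mean_p`,
#'   `delta`, `z`, `p`, `q`, one row per scored kinase, ordered by
#'   decreasing `z`. Excluded kinases (too few substrates) are recorded
#'   in the `"excluded"` attribute.
#' @export
ksea_scores <- function(site_log2fc, edges, min_substrates = 4) {
  if (is.null(names(site_log2fc))) stop2("site_log2fc must be named by site key")
  if (anyNA(site_log2fc)) {
    warning(sum(is.na(site_log2fc)), " missing fold-change(s) dropped",
            call. = FALSE)
    site_log2fc <- site_log2fc[!is.na(site_log2fc)]
  }
  if (any(!is.finite(site_log2fc))) stop2("fold-changes must be finite")
  mean_p <- mean(site_log2fc)
  delta <- stats::sd(site_log2fc)
  if (is.na(delta) || delta == 0) stop2("degenerate fold-change distribution")
  edges <- edges[edges$site %in% names(site_log2fc), , drop = FALSE]
  by_kin <- split(edges$site, edges$kinase)
  m <- vapply(by_kin, function(s) length(unique(s)), 1L)
  excluded <- names(by_kin)[m < min_substrates]
  by_kin <- by_kin[m >= min_substrates]
  if (length(by_kin) == 0) {
    res <- data.frame(kinase = character(), m = integer(), mean_s = numeric(),
                      mean_p = numeric(), delta = numeric(), z = numeric(),
                      p = numeric(), q = numeric(), stringsAsFactors = FALSE)
    attr(res, "excluded") <- excluded
    return(res)
  }
  mean_s <- vapply(by_kin, function(s) mean(site_log2fc[unique(s)]), 1)
  m <- m[m >= min_substrates]
  z <- (mean_s - mean_p) * sqrt(m) / delta
  p <- 2 * stats::pnorm(-abs(z))
  res <- data.frame(kinase = names(by_kin), m = unname(m),
                    mean_s = unname(mean_s), mean_p = mean_p, delta = delta,
                    z = unname(z), p = unname(p), q = bh_adjust(unname(p)),
                    stringsAsFactors = FALSE, row.names = NULL)
  res <- res[order(-res$z, res$kinase), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "excluded") <- excluded
  res
}

#' Cross-comparison kinase signature
#'
#' Aggregates per-comparison KSEA scores into a kinases x comparisons z
#' matrix and retains the kinases significantly regulated
#' (`q < q_cut`) in at least `min_significant` comparisons. Cells where a
#' kinase was not scored are missing and count as non-significant, so a
#' kinase scored in fewer comparisons than `min_significant` can never be
#' retained; such kinases are reported in the provenance table rather
#' than silently dropped.
#'
#' @param score_list Named list of [ksea_scores()] results, one per
#'   comparison (names are the comparison labels and must be unique).
#' @param min_significant Minimum number of significant comparisons.
#' @param q_cut Per-cell significance threshold on the BH q value.
#' @return List with `z` (retained kinases x comparisons), `significant`
#'   (logical matrix, same shape), `retained` (kinase ids), and
#'   `provenance` (per-kinase counts of scored / significant comparisons
#'   for all kinases).
#' @export
cross_comparison_signature <- function(score_list, min_significant = 3,
                                       q_cut = 0.05) {
  if (is.null(names(score_list)) || any(!nzchar(names(score_list)))) {
    stop2("comparisons must be named")
  }
  if (anyDuplicated(names(score_list))) stop2("duplicate comparison labels")
  if (length(score_list) < 2) stop2("need >= 2 comparisons")
  kinases <- sort(unique(unlist(lapply(score_list, `[[`, "kinase"))))
  comps <- names(score_list)
  z <- matrix(NA_real_, length(kinases), length(comps),
              dimnames = list(kinases, comps))
  sig <- matrix(FALSE, length(kinases), length(comps),
                dimnames = list(kinases, comps))
  for (cmp in comps) {
    sc <- score_list[[cmp]]
    z[sc$kinase, cmp] <- sc$z
    sig[sc$kinase, cmp] <- !is.na(sc$q) & sc$q < q_cut
  }
  n_scored <- rowSums(!is.na(z))
  n_sig <- rowSums(sig)
  retained <- kinases[n_sig >= min_significant]
  provenance <- data.frame(kinase = kinases, n_scored = n_scored,
                           n_significant = n_sig,
                           retained = kinases %in% retained,
                           stringsAsFactors = FALSE, row.names = NULL)
  list(z = z[retained, , drop = FALSE],
       significant = sig[retained, , drop = FALSE],
       retained = retained, provenance = provenance)
}

#' k-means clustering of signature rows
#'
#' Clusters the retained kinases on their z profiles with seeded
#' multi-start k-means (Euclidean distance; best of `n_init` runs by
#' within-cluster sum of squares). Missing z values are imputed as 0
#' before clustering and flagged. Cluster labels are canonicalized by
#' descending cluster mean z so label 1 is the most-activated cluster.
#'
#' @param signature A [cross_comparison_signature()] result (or a plain z
#'   matrix).
#' @param k Number of clusters.
#' @param seed Seed for the multi-start.
#' @param n_init Number of random starts.
#' @return Named integer vector of cluster labels (1..k) for each
#'   retained kinase; the imputed cell positions are kept in the
#'   `"imputed"` attribute.
#' @export
kmeans_rows <- function(signature, k = 3, seed = 1L, n_init = 10) {
  x <- if (is.list(signature) && !is.null(signature$z)) signature$z else signature
  if (!is.matrix(x)) stop2("signature must contain a z matrix")
  if (nrow(x) < k) stop2("fewer rows than clusters (", nrow(x), " < ", k, ")")
  imputed <- which(is.na(x), arr.ind = TRUE)
  x[is.na(x)] <- 0
  fit <- withr::with_seed(as.integer(seed),
                          stats::kmeans(x, centers = k, nstart = n_init))
  # canonical label order: descending cluster mean z
  means <- vapply(seq_len(k), function(cl) mean(x[fit$cluster == cl, , drop = FALSE]), 1)
  relabel <- match(seq_len(k), order(-means))
  labels <- stats::setNames(relabel[fit$cluster], rownames(x))
  attr(labels, "imputed") <- imputed
  attr(labels, "tot_withinss") <- fit$tot.withinss
  labels
}

#' Long-format export of a kinase signature
#'
#' Heatmap-ready long table (kinase, comparison, z, significant, cluster).
#'
#' @param signature A [cross_comparison_signature()] result.
#' @param clusters Optional [kmeans_rows()] labels.
#' @return A data.frame in long format.
#' @export
signature_long <- function(signature, clusters = NULL) {
  z <- signature$z
  if (nrow(z) == 0) {
    return(data.frame(kinase = character(), comparison = character(),
                      z = numeric(), significant = logical(),
                      cluster = integer(), stringsAsFactors = FALSE))
  }
  out <- data.frame(kinase = rep(rownames(z), times = ncol(z)),
                    comparison = rep(colnames(z), each = nrow(z)),
                    z = as.vector(z),
                    significant = as.vector(signature$significant),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$cluster <- if (is.null(clusters)) NA_integer_ else
    as.integer(clusters[out$kinase])
  out
}
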