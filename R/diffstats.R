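# Significance procedures for differential (phospho)proteomics:
# SAM-style moderated two-class test with additive fudge factor s0 and
# permutation-based FDR, one-way ANOVA with BH correction, one-sample
# moderated t on log2 ratios, and the volcano prioritization with
# asymmetric 3xSD fold-change thresholds, proteome-level correction and
# functional-score filtering.
#
# Conventions used throughout: SD with the n-1 denominator; strict
# inequalities at all thresholds; ties in |d| broken by feature id.

#' SAM parameters
#'
#' @param s0 Fudge factor added to the standard-error denominator of the
#'   moderated statistic (log2-intensity units).
#' @param n_permutations Number of group-label permutations `B`; when the
#'   design admits at most `B` distinct relabelings they are enumerated
#'   exhaustively (making the result seed-independent).
#' @param fdr_target Target permutation FDR `q*` for the significant set.
#' @param seed Seed for permutation sampling.
#' @return A list of validated parameters.
#' @export
sam_params <- function(s0 = 0.1, n_permutations = 250, fdr_target = 0.05,
                       seed = 1L) {
  if (s0 < 0) stop2("s0 must be >= 0")
  if (n_permutations < 25) stop2("need at least 25 permutations")
  if (fdr_target <= 0 || fdr_target >= 1) stop2("fdr_target must lie in (0,1)")
  list(s0 = s0, n_permutations = as.integer(n_permutations),
       fdr_target = fdr_target, seed = as.integer(seed))
}

# Moderated two-class d statistic for given case/control column sets.
# Returns log2FC, d and the group sizes; features with <2 observed values
# in either group are unscored (NA).
two_class_d <- function(mat, case_cols, control_cols, s0) {
  a <- row_stats(mat, case_cols)
  b <- row_stats(mat, control_cols)
  ok <- a$n >= 2 & b$n >= 2
  fc <- ifelse(a$n >= 1 & b$n >= 1, a$mean - b$mean, NA_real_)
  pooled_var <- (pmax(a$n - 1, 0) * a$var + pmax(b$n - 1, 0) * b$var) /
    (a$n + b$n - 2)
  se <- sqrt(pooled_var * (1 / a$n + 1 / b$n))
  d <- ifelse(ok, fc / (se + s0), NA_real_)
  list(log2FC = ifelse(ok, fc, fc), d = d, n_case = a$n, n_control = b$n,
       tested = ok)
}

#' Moderated two-class statistic (SAM-style)
#'
#' Computes, per feature, the log2 fold-change (case - control) and the
#' moderated statistic `d = (mean_case - mean_control) / (se + s0)` with
#' `se` the pooled-variance two-sample standard error. With `s0 = 0` this
#' is the Student t statistic. Features with fewer than two observed
#' values in either group are returned unscored.
#'
#' @param mat Log2 quantification matrix.
#' @param design Sample design.
#' @param case,control Condition labels of the two groups.
#' @param s0 Fudge factor.
#' @return Data.frame with columns `feature`, `log2FC`, `statistic`,
#'   `n_case`, `n_control`, `tested`.
#' @export
moderated_t_two_class <- function(mat, design, case, control, s0 = 0.1) {
  design <- check_design(design)
  check_matrix_design(mat, design)
  case_cols <- design_samples(design, case)
  control_cols <- design_samples(design, control)
  if (length(case_cols) == 0) stop2("condition absent from design: ", case)
  if (length(control_cols) == 0) stop2("condition absent from design: ", control)
  st <- two_class_d(mat, case_cols, control_cols, s0)
  data.frame(feature = rownames(mat), log2FC = st$log2FC, statistic = st$d,
             n_case = st$n_case, n_control = st$n_control, tested = st$tested,
             stringsAsFactors = FALSE, row.names = NULL)
}

# All distinct assignments of the case labels to the pooled samples.
# Returns a list of index vectors into `samples` naming the case set,
# or NULL when there are more than `max_n` of them.
enumerate_label_splits <- function(n_total, n_case, max_n) {
  n_splits <- choose(n_total, n_case)
  if (n_splits > max_n) return(NULL)
  asplit(utils::combn(n_total, n_case), 2)
}

#' Permutation-based FDR for the moderated two-class statistic
#'
#' For a cutoff `c` on `|d|`, `FDR(c)` is the mean over label
#' permutations of the number of permuted statistics at least `c`, divided
#' by the number of observed statistics at least `c` (capped at 1; the
#' null-abundance factor pi0 is fixed at 1, which is conservative). A
#' feature's q value is the minimum `FDR(c)` over all cutoffs that admit
#' it; the significant set is the largest set with `FDR < q*`. When the
#' design admits at most `B` distinct relabelings, all of them are used;
#' otherwise `B` are sampled with the given seed.
#'
#' @inheritParams moderated_t_two_class
#' @param params A [sam_params()] list.
#' @return Data.frame with `feature`, `statistic`, `q`, `significant`;
#'   attributes `n_permutations` and `exhaustive`.
#' @export
permutation_fdr <- function(mat, design, case, control, params = sam_params()) {
  design <- check_design(design)
  check_matrix_design(mat, design)
  case_cols <- design_samples(design, case)
  control_cols <- design_samples(design, control)
  if (length(case_cols) < 2 || length(control_cols) < 2) {
    stop2("degenerate design: both groups need >= 2 samples")
  }
  pooled <- c(case_cols, control_cols)
  n1 <- length(case_cols)
  obs <- two_class_d(mat, case_cols, control_cols, params$s0)
  absd <- abs(obs$d)

  splits <- enumerate_label_splits(length(pooled), n1, params$n_permutations)
  exhaustive <- !is.null(splits)
  if (!exhaustive) {
    splits <- withr::with_seed(params$seed, replicate(
      params$n_permutations, sample(length(pooled), n1), simplify = FALSE))
  }

  cutoffs <- sort(unique(absd[is.finite(absd)]))
  feature <- rownames(mat)
  if (length(cutoffs) == 0) {
    q <- rep(NA_real_, nrow(mat))
    res <- data.frame(feature = feature, statistic = obs$d, q = q,
                      significant = FALSE, stringsAsFactors = FALSE)
    attr(res, "n_permutations") <- length(splits)
    attr(res, "exhaustive") <- exhaustive
    return(res)
  }
  # observed exceedance counts per cutoff
  sorted_obs <- sort(absd[is.finite(absd)])
  n_obs_ge <- length(sorted_obs) -
    findInterval(cutoffs, sorted_obs, left.open = TRUE)
  # permuted exceedance counts: B x n_cutoffs
  perm_counts <- vapply(splits, function(idx) {
    pd <- two_class_d(mat, pooled[idx], pooled[-idx], params$s0)$d
    s <- sort(abs(pd[is.finite(pd)]))
    length(s) - findInterval(cutoffs, s, left.open = TRUE)
  }, numeric(length(cutoffs)))
  perm_counts <- matrix(perm_counts, nrow = length(cutoffs))
  mean_false <- rowMeans(perm_counts)
  fdr_at <- pmin(mean_false / n_obs_ge, 1)
  # q at cutoff c_k = min FDR over cutoffs <= c_k (monotone in |d|)
  q_at <- cummin(fdr_at)
  q <- rep(NA_real_, length(absd))
  fin <- is.finite(absd)
  q[fin] <- q_at[match(absd[fin], cutoffs)]
  significant <- !is.na(q) & q < params$fdr_target
  res <- data.frame(feature = feature, statistic = obs$d, q = q,
                    significant = significant, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(res, "n_permutations") <- length(splits)
  attr(res, "exhaustive") <- exhaustive
  res
}

#' SAM two-class test
#'
#' Composition of [moderated_t_two_class()] and [permutation_fdr()]:
#' moderated statistics with additive `s0`, permutation-estimated q values
#' and a significant set at the target FDR, with direction from the sign
#' of the log2 fold-change.
#'
#' @inheritParams permutation_fdr
#' @return A differential-result data.frame with columns `feature`,
#'   `log2FC`, `statistic`, `p` (NA; the procedure is permutation-based),
#'   `q`, `significant`, `direction`.
#' @export
sam_test <- function(mat, design, case, control, params = sam_params()) {
  mt <- moderated_t_two_class(mat, design, case, control, params$s0)
  pf <- permutation_fdr(mat, design, case, control, params)
  direction <- ifelse(!pf$significant | is.na(mt$log2FC), "none",
                      ifelse(mt$log2FC > 0, "up", "down"))
  res <- data.frame(feature = mt$feature, log2FC = mt$log2FC,
                    statistic = mt$statistic, p = NA_real_, q = pf$q,
                    significant = pf$significant, direction = direction,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "n_permutations") <- attr(pf, "n_permutations")
  attr(res, "exhaustive") <- attr(pf, "exhaustive")
  attr(res, "comparison") <- paste0(case, "/", control)
  res
}

#' Two-class moderated t test with BH correction
#'
#' The parametric companion of [sam_test()] for designs too small for
#' permutation-based FDR (e.g. three replicates per condition, where the
#' 20 distinct relabelings cannot resolve an FDR below 0.1): the same
#' moderated statistic `d = (mean_case - mean_control) / (se + s0)`, a
#' two-sided p value from the t distribution with `n1 + n2 - 2` degrees
#' of freedom evaluated at `d` (exact for `s0 = 0`), and BH correction.
#'
#' @inheritParams moderated_t_two_class
#' @param fdr BH FDR threshold for the significance call.
#' @return A differential-result data.frame.
#' @export
two_class_t_bh <- function(mat, design, case, control, s0 = 0.1, fdr = 0.01) {
  mt <- moderated_t_two_class(mat, design, case, control, s0)
  df <- mt$n_case + mt$n_control - 2
  p <- ifelse(mt$tested, 2 * stats::pt(-abs(mt$statistic), df), NA_real_)
  q <- bh_adjust(p)
  significant <- !is.na(q) & q < fdr
  direction <- ifelse(!significant | is.na(mt$log2FC), "none",
                      ifelse(mt$log2FC > 0, "up", "down"))
  res <- data.frame(feature = mt$feature, log2FC = mt$log2FC,
                    statistic = mt$statistic, p = p, q = q,
                    significant = significant, direction = direction,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "comparison") <- paste0(case, "/", control)
  res
}

#' One-way ANOVA across conditions
#'
#' Standard per-feature F statistic over the design's conditions with BH
#' correction. A feature needs at least two groups with two or more
#' observed values; all-constant features get a missing p and are excluded
#' from the BH family.
#'
#' @param mat Log2 quantification matrix.
#' @param design Sample design.
#' @param groups Conditions to compare; default all in the design.
#' @param fdr BH FDR threshold for the significance call.
#' @return A differential-result data.frame (`log2FC` is `NA`: the test is
#'   omnibus across >2 groups).
#' @export
anova_oneway <- function(mat, design, groups = NULL, fdr = 0.01) {
  design <- check_design(design)
  check_matrix_design(mat, design)
  groups <- groups %||% unique(design$condition)
  if (length(groups) < 2) stop2("ANOVA needs >= 2 groups")
  stats_g <- lapply(groups, function(g) row_stats(mat, design_samples(design, g)))
  n_mat <- vapply(stats_g, `[[`, numeric(nrow(mat)), "n")
  m_mat <- vapply(stats_g, `[[`, numeric(nrow(mat)), "mean")
  v_mat <- vapply(stats_g, `[[`, numeric(nrow(mat)), "var")
  n_mat <- matrix(n_mat, nrow = nrow(mat)); m_mat <- matrix(m_mat, nrow = nrow(mat))
  v_mat <- matrix(v_mat, nrow = nrow(mat))
  usable <- n_mat >= 2
  k <- rowSums(usable)
  n_use <- n_mat * usable
  N <- rowSums(n_use)
  gm <- rowSums(n_use * ifelse(usable, m_mat, 0)) / N
  ssb <- rowSums(n_use * (ifelse(usable, m_mat, 0) - gm)^2 * usable)
  ssw <- rowSums((n_use - usable) * ifelse(usable, v_mat, 0))
  testable <- k >= 2 & (N - k) >= 1
  F <- ifelse(testable & ssw > 0, (ssb / (k - 1)) / (ssw / (N - k)), NA_real_)
  p <- ifelse(is.na(F), NA_real_, stats::pf(F, k - 1, N - k, lower.tail = FALSE))
  q <- bh_adjust(p)
  significant <- !is.na(q) & q < fdr
  data.frame(feature = rownames(mat), log2FC = NA_real_, statistic = F,
             p = p, q = q, significant = significant,
             direction = "none", stringsAsFactors = FALSE, row.names = NULL)
}

#' One-sample moderated t test on log2 ratios
#'
#' Per feature, `d = mean / (sd/sqrt(n) + s0)`; the two-sided p value is
#' taken from the t distribution with `n - 1` degrees of freedom evaluated
#' at the moderated statistic (with `s0 = 0` this is the classical
#' one-sample t), then BH-corrected. Features with fewer than two observed
#' ratios are unscored.
#'
#' @param ratio_mat Matrix of log2 ratios (e.g. treated over the control
#'   arm's median, from [make_log2_ratios_vs_reference()]).
#' @param s0 Fudge factor; regularizes zero-variance features.
#' @param fdr BH FDR threshold for the significance call.
#' @return A differential-result data.frame.
#' @export
one_sample_t <- function(ratio_mat, s0 = 0.1, fdr = 0.01) {
  st <- row_stats(ratio_mat, seq_len(ncol(ratio_mat)))
  ok <- st$n >= 2
  se <- sqrt(st$var) / sqrt(st$n)
  d <- ifelse(ok, st$mean / (se + s0), NA_real_)
  p <- ifelse(ok, 2 * stats::pt(-abs(d), df = st$n - 1), NA_real_)
  q <- bh_adjust(p)
  significant <- !is.na(q) & q < fdr
  direction <- ifelse(!significant, "none", ifelse(st$mean > 0, "up", "down"))
  data.frame(feature = rownames(ratio_mat), log2FC = ifelse(ok, st$mean, NA_real_),
             statistic = d, p = p, q = q, significant = significant,
             direction = direction, stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p values, monotone and capped at 1. Missing p values
#' are allowed and excluded from the family size.
#'
#' @param p Numeric vector of p values in `[0, 1]` (NA allowed).
#' @return Vector of q values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop2("p values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Volcano selection with asymmetric 3xSD fold-change thresholds
#'
#' The up threshold is three times the SD of all positive log2
#' fold-changes; the down threshold three times the SD of all negative
#' ones (computed on all scored features, before FDR filtering). A feature
#' is selected iff its q value is below `fdr` and its fold-change strictly
#' exceeds its side's threshold. A side with fewer than two fold-changes
#' has no defined threshold and makes no calls (with a warning).
#'
#' @param result A differential-result data.frame with `feature`, `log2FC`
#'   and `q`.
#' @param fdr FDR threshold.
#' @return Data.frame with per-feature `selected` flag and `side`;
#'   attributes `up_threshold`, `down_threshold`, `fdr`.
#' @export
volcano_select <- function(result, fdr = 0.01) {
  fc <- result$log2FC
  pos <- fc[!is.na(fc) & fc > 0]
  neg <- fc[!is.na(fc) & fc < 0]
  up_thr <- if (length(pos) >= 2) 3 * stats::sd(pos) else NA_real_
  down_thr <- if (length(neg) >= 2) 3 * stats::sd(neg) else NA_real_
  if (is.na(up_thr)) warning("fewer than 2 positive fold-changes; no up calls",
                             call. = FALSE)
  if (is.na(down_thr)) warning("fewer than 2 negative fold-changes; no down calls",
                               call. = FALSE)
  pass_q <- !is.na(result$q) & result$q < fdr
  up_sel <- pass_q & !is.na(fc) & !is.na(up_thr) & fc > up_thr
  down_sel <- pass_q & !is.na(fc) & !is.na(down_thr) & fc < -down_thr
  out <- data.frame(feature = result$feature, log2FC = fc, q = result$q,
                    selected = up_sel | down_sel,
                    side = ifelse(up_sel, "up", ifelse(down_sel, "down", "none")),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "up_threshold") <- up_thr
  attr(out, "down_threshold") <- down_thr
  attr(out, "fdr") <- fdr
  out
}

#' Flag phosphosites whose parent protein is itself regulated
#'
#' A selected site is flagged `proteome_regulated` iff its parent protein
#' was selected in the same direction by the same volcano rule applied to
#' the proteome's own fold-change distribution. Sites whose protein was
#' not quantified/testable get `FALSE` with provenance
#' `"protein not testable"`.
#'
#' @param site_selection A [volcano_select()] result on phosphosites.
#' @param site_to_protein Named character vector mapping site id to
#'   protein id; by default derived by parsing the site keys.
#' @param protein_selection A [volcano_select()] result on the proteome,
#'   computed with the same FDR and 3xSD rule.
#' @return `site_selection` with `proteome_regulated` and `provenance`
#'   columns added.
#' @export
proteome_correction_flags <- function(site_selection, protein_selection,
                                      site_to_protein = NULL) {
  if (is.null(site_to_protein)) {
    parsed <- parse_site_key(site_selection$feature)
    site_to_protein <- stats::setNames(parsed$protein_id, parsed$site)
  }
  prot <- site_to_protein[site_selection$feature]
  idx <- match(prot, protein_selection$feature)
  testable <- !is.na(idx)
  prot_sel <- rep(FALSE, nrow(site_selection))
  prot_side <- rep(NA_character_, nrow(site_selection))
  prot_sel[testable] <- protein_selection$selected[idx[testable]]
  prot_side[testable] <- protein_selection$side[idx[testable]]
  flagged <- site_selection$selected & prot_sel &
    !is.na(prot_side) & prot_side == site_selection$side
  site_selection$proteome_regulated <- flagged
  site_selection$provenance <- ifelse(testable, "protein testable",
                                      "protein not testable")
  site_selection
}

#' Prioritize selected sites by functional score
#'
#' Keeps selected sites with a functional score strictly above `min_score`
#' (high-scoring sites are the ones most likely to be functionally
#' relevant). Sites without a score are excluded with provenance
#' `"unscored"`.
#'
#' @param selection A [volcano_select()] (optionally proteome-corrected)
#'   result.
#' @param scores Named numeric vector of per-site functional scores in
#'   `[0, 1]`.
#' @param min_score Strict lower bound for prioritization.
#' @return `selection` with `functional_score`, `prioritized` and
#'   `functional_provenance` columns.
#' @export
prioritize_functional <- function(selection, scores, min_score = 0.5) {
  if (length(scores) > 0 && any(scores < 0 | scores > 1, na.rm = TRUE)) {
    stop2("functional scores must lie in [0, 1]")
  }
  sc <- unname(scores[selection$feature])
  scored <- !is.na(sc)
  selection$functional_score <- sc
  selection$prioritized <- selection$selected & scored & sc > min_score
  selection$functional_provenance <- ifelse(scored, "scored", "unscored")
  selection
}
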