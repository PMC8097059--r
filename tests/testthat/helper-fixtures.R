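# Shared fixture builders; everything is generated in code at test time.

toy_design <- function(n_case = 3, n_control = 3,
                       case = "case", control = "control") {
  data.frame(
    sample_id = c(paste0(case, "_", seq_len(n_case)),
                  paste0(control, "_", seq_len(n_control))),
    condition = c(rep(case, n_case), rep(control, n_control)),
    replicate = c(seq_len(n_case), seq_len(n_control)),
    group_role = c(rep("case", n_case), rep("control", n_control)),
    stringsAsFactors = FALSE)
}

toy_matrix <- function(n_features, design, seed = 1, sd = 1, mean = 0) {
  withr::with_seed(seed, {
    m <- matrix(stats::rnorm(n_features * nrow(design), mean, sd),
                n_features, nrow(design))
    dimnames(m) <- list(sprintf("F%03d", seq_len(n_features)),
                        design$sample_id)
    m
  })
}

# Independent step-up BH oracle: sort, scale by m/i, running minimum from
# the largest p value down.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  scaled <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  out <- numeric(m)
  out[ord] <- pmin(adj, 1)
  out
}

# Independent permutation-FDR oracle: explicit loops over every
# assignment of case labels, plain per-feature statistics, mean false
# counts over permutations, minimum FDR over admissible cutoffs.
perm_fdr_oracle <- function(mat, case_cols, control_cols, s0, q_target = 0.05) {
  d_stat <- function(x, ci, bi) {
    a <- x[ci]; b <- x[bi]
    sp <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
      (length(a) + length(b) - 2)
    se <- sqrt(sp * (1 / length(a) + 1 / length(b)))
    (mean(a) - mean(b)) / (se + s0)
  }
  pooled <- c(case_cols, control_cols)
  n1 <- length(case_cols)
  obs <- apply(mat[, pooled, drop = FALSE], 1, d_stat,
               ci = seq_len(n1), bi = (n1 + 1):length(pooled))
  splits <- utils::combn(length(pooled), n1)
  perm_d <- matrix(NA_real_, nrow(mat), ncol(splits))
  for (b in seq_len(ncol(splits))) {
    ci <- splits[, b]
    perm_d[, b] <- apply(mat[, pooled, drop = FALSE], 1, d_stat,
                         ci = ci, bi = setdiff(seq_along(pooled), ci))
  }
  q <- numeric(nrow(mat))
  for (i in seq_len(nrow(mat))) {
    cuts <- sort(unique(abs(obs)))
    cuts <- cuts[cuts <= abs(obs[i])]
    fdrs <- vapply(cuts, function(cc) {
      false_counts <- vapply(seq_len(ncol(splits)),
                             function(b) sum(abs(perm_d[, b]) >= cc), 1)
      min(mean(false_counts) / sum(abs(obs) >= cc), 1)
    }, 1)
    q[i] <- min(fdrs)
  }
  list(statistic = obs, q = q, significant = q < q_target)
}
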