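# Significance procedures: moderated statistics, permutation FDR, ANOVA,
# one-sample test, BH, volcano prioritization.

test_that("moderated two-class statistic follows the pooled-t-with-s0 form", {
  design <- toy_design(3, 3)
  m <- matrix(c(2, 3, 4, 0, 1, 2), nrow = 1,
              dimnames = list("F1", design$sample_id))
  res <- moderated_t_two_class(m, design, "case", "control", s0 = 0.1)
  expect_equal(res$log2FC, 2)
  expect_equal(res$statistic, 2 / (sqrt(2 / 3) + 0.1), tolerance = 1e-12)
  # identical group means give d = 0
  m0 <- matrix(c(1, 2, 3, 3, 2, 1), nrow = 1,
               dimnames = list("F1", design$sample_id))
  expect_equal(moderated_t_two_class(m0, design, "case", "control")$statistic, 0)
  # s0 = 0 reduces to the Student t statistic
  m1 <- toy_matrix(10, design, seed = 5)
  res0 <- moderated_t_two_class(m1, design, "case", "control", s0 = 0)
  tref <- apply(m1, 1, function(x) {
    stats::t.test(x[1:3], x[4:6], var.equal = TRUE)$statistic
  })
  expect_equal(res0$statistic, unname(tref), tolerance = 1e-10)
  expect_error(moderated_t_two_class(m1, design, "case", "missing"), "absent")
})

test_that("permutation FDR agrees with the exhaustive-enumeration oracle", {
  design <- toy_design(3, 3)
  m <- toy_matrix(20, design, seed = 9)
  m[1:4, 1:3] <- m[1:4, 1:3] + 2.5   # a few strong effects
  res <- permutation_fdr(m, design, "case", "control",
                         sam_params(s0 = 0.1, fdr_target = 0.05, seed = 1))
  expect_true(attr(res, "exhaustive"))
  oracle <- perm_fdr_oracle(m, design$sample_id[1:3], design$sample_id[4:6],
                            s0 = 0.1)
  expect_equal(res$statistic, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(res$q, unname(oracle$q), tolerance = 1e-12)
  expect_identical(res$significant, unname(oracle$significant))
  # q is non-increasing in |d|
  ord <- order(abs(res$statistic))
  expect_true(all(diff(res$q[ord]) <= 1e-12))
})

test_that("constant features yield q = 1 and an empty significant set", {
  design <- toy_design(3, 3)
  m <- matrix(5, nrow = 8, ncol = 6,
              dimnames = list(paste0("F", 1:8), design$sample_id))
  res <- permutation_fdr(m, design, "case", "control", sam_params())
  expect_true(all(res$q == 1))
  expect_false(any(res$significant))
})

test_that("a single extreme feature is detected among many nulls", {
  design <- toy_design(4, 4)
  m <- toy_matrix(999, design, seed = 21, sd = 0.3)
  extreme <- matrix(c(rep(10, 4), rep(0, 4)), nrow = 1,
                    dimnames = list("HIT", design$sample_id)) +
    toy_matrix(1, design, seed = 22, sd = 0.05)
  m <- rbind(m, extreme)
  res <- sam_test(m, design, "case", "control", sam_params(seed = 3))
  expect_true(res$significant[res$feature == "HIT"])
  expect_equal(res$direction[res$feature == "HIT"], "up")
})

test_that("exhaustive SAM is seed-independent and row-order invariant", {
  design <- toy_design(3, 3)
  m <- toy_matrix(15, design, seed = 2)
  m[1:3, 1:3] <- m[1:3, 1:3] + 3
  r1 <- sam_test(m, design, "case", "control", sam_params(seed = 1))
  r2 <- sam_test(m, design, "case", "control", sam_params(seed = 999))
  expect_equal(r1$q, r2$q)
  perm <- withr::with_seed(4, sample(nrow(m)))
  r3 <- sam_test(m[perm, ], design, "case", "control", sam_params(seed = 1))
  expect_equal(r3$q[match(r1$feature, r3$feature)], r1$q)
  expect_setequal(r3$feature[r3$significant], r1$feature[r1$significant])
})

test_that("one-way ANOVA matches t^2 for two groups and a hand oracle for three", {
  design <- toy_design(3, 3)
  m <- toy_matrix(12, design, seed = 6)
  a <- anova_oneway(m, design, fdr = 0.05)
  t2 <- moderated_t_two_class(m, design, "case", "control", s0 = 0)$statistic^2
  expect_equal(a$statistic, t2, tolerance = 1e-10)
  pref <- apply(m, 1, function(x) {
    stats::oneway.test(v ~ g, data.frame(v = x, g = design$condition),
                       var.equal = TRUE)$p.value
  })
  expect_equal(a$p, unname(pref), tolerance = 1e-10)

  # 3 groups, means 0/0/3, hand-computed sums of squares
  d3 <- data.frame(sample_id = paste0("s", 1:9),
                   condition = rep(c("g1", "g2", "g3"), each = 3),
                   replicate = rep(1:3, 3), group_role = "other",
                   stringsAsFactors = FALSE)
  vals <- c(-1, 0, 1, -1, 0, 1, 2, 3, 4)
  m3 <- matrix(vals, nrow = 1, dimnames = list("F1", d3$sample_id))
  # group means 0,0,3; grand mean 1; SSB = 3*(1+1+4) = 18; SSW = 6
  expect_equal(anova_oneway(m3, d3)$statistic, (18 / 2) / (6 / 6),
               tolerance = 1e-12)
  # all-constant feature is excluded from the BH family
  mc <- rbind(m3, CONST = rep(2, 9))
  ac <- anova_oneway(mc, d3)
  expect_true(is.na(ac$p[ac$feature == "CONST"]))
  expect_equal(ac$q[ac$feature == "F1"], ac$p[ac$feature == "F1"])  # m = 1
})

test_that("ANOVA p values are roughly uniform under the null", {
  d3 <- data.frame(sample_id = paste0("s", 1:9),
                   condition = rep(c("g1", "g2", "g3"), each = 3),
                   replicate = rep(1:3, 3), group_role = "other",
                   stringsAsFactors = FALSE)
  m <- withr::with_seed(8, matrix(stats::rnorm(500 * 9), 500, 9,
                                  dimnames = list(sprintf("F%03d", 1:500),
                                                  d3$sample_id)))
  p <- anova_oneway(m, d3)$p
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("one-sample moderated t handles zero variance through s0", {
  r <- rbind(zero = c(0, 0, 0, 0), ones = c(1, 1, 1, 1),
             mostlyNA = c(0.5, NA, NA, NA))
  colnames(r) <- paste0("s", 1:4)
  res <- one_sample_t(r, s0 = 0.1)
  expect_equal(res$statistic[res$feature == "zero"], 0)
  expect_equal(res$statistic[res$feature == "ones"], 10)  # se = 0, d = 1/0.1
  expect_true(is.na(res$statistic[res$feature == "mostlyNA"]))  # n < 2
  # s0 = 0 equals the classical one-sample t
  rr <- withr::with_seed(3, matrix(stats::rnorm(40), 8, 5,
                                   dimnames = list(paste0("F", 1:8),
                                                   paste0("s", 1:5))))
  res0 <- one_sample_t(rr, s0 = 0)
  ref <- apply(rr, 1, function(x) stats::t.test(x)$p.value)
  expect_equal(res0$p, unname(ref), tolerance = 1e-10)
})

test_that("BH adjustment matches the step-up oracle exactly", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  withr::with_seed(10, {
    for (i in 1:20) {
      p <- stats::runif(sample(1:50, 1))
      expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
      expect_true(all(bh_adjust(p) >= p))
    }
  })
  p <- c(0.5, NA, 0.01)
  q <- bh_adjust(p)
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], bh_oracle(p[c(1, 3)]))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("volcano selection applies asymmetric 3xSD thresholds strictly", {
  res <- data.frame(feature = sprintf("S%02d", 1:8),
                    log2FC = c(0.1, 0.2, 0.3, 3.0, -0.1, -0.2, -0.3, -3.0),
                    q = rep(0.001, 8), stringsAsFactors = FALSE)
  sel <- volcano_select(res, fdr = 0.01)
  expect_equal(attr(sel, "up_threshold"), 3 * stats::sd(c(0.1, 0.2, 0.3, 3)),
               tolerance = 1e-12)   # ~4.207: nothing passes
  expect_false(any(sel$selected))
  # symmetric distribution: equal thresholds
  expect_equal(attr(sel, "up_threshold"), attr(sel, "down_threshold"),
               tolerance = 1e-12)
  # degenerate SD: equal positive FCs select every up site passing q
  res2 <- data.frame(feature = c("a", "b", "c"), log2FC = c(1, 1, -0.5),
                     q = c(0.001, 0.5, 0.001), stringsAsFactors = FALSE)
  expect_warning(sel2 <- volcano_select(res2, fdr = 0.01), "down")
  expect_identical(sel2$selected, c(TRUE, FALSE, FALSE))
  # feature-id relabeling leaves selection flags unchanged
  res3 <- res
  res3$feature <- rev(res3$feature)
  expect_identical(volcano_select(res3, 0.01)$selected, sel$selected)
})

test_that("proteome correction flags match an independent rule application", {
  withr::with_seed(14, {
    sites <- sprintf("P%d_S%d", rep(1:4, c(3, 3, 2, 2)), 1:10 * 7)
    site_res <- data.frame(feature = sites,
                           log2FC = stats::rnorm(10, 0, 2),
                           q = stats::runif(10, 0, 0.02),
                           stringsAsFactors = FALSE)
    prot_res <- data.frame(feature = c("P1", "P2", "P3", "P9"),
                           log2FC = c(3, -3, 0.1, -0.2),
                           q = c(0.001, 0.001, 0.5, 0.4),
                           stringsAsFactors = FALSE)
    ssel <- volcano_select(site_res, fdr = 0.05)
    psel <- volcano_select(prot_res, fdr = 0.05)
    out <- proteome_correction_flags(ssel, psel)
    # oracle: independent application of both rule sets
    for (i in seq_len(nrow(out))) {
      prot <- sub("_S[0-9]+$", "", out$feature[i])
      j <- match(prot, psel$feature)
      expected <- !is.na(j) && ssel$selected[i] && psel$selected[j] &&
        ssel$side[i] == psel$side[j]
      expect_identical(out$proteome_regulated[i], expected)
    }
    expect_true(all(out$provenance[!out$feature %in% paste0("P", 1:3, "_")] %in%
                      c("protein testable", "protein not testable")))
    expect_equal(out$provenance[grepl("^P4_", out$feature)],
                 rep("protein not testable", 2))
  })
})

test_that("functional prioritization uses a strict 0.5 cutoff", {
  sel <- data.frame(feature = c("A_S1", "B_S2", "C_S3"),
                    log2FC = c(2, 2, 2), q = c(0.001, 0.001, 0.001),
                    selected = c(TRUE, TRUE, TRUE),
                    side = "up", stringsAsFactors = FALSE)
  out <- prioritize_functional(sel, c(A_S1 = 0.51, B_S2 = 0.50))
  expect_identical(out$prioritized, c(TRUE, FALSE, FALSE))
  expect_identical(out$functional_provenance, c("scored", "scored", "unscored"))
  empty <- prioritize_functional(sel, stats::setNames(numeric(), character()))
  expect_false(any(empty$prioritized))
  expect_true(all(empty$functional_provenance == "unscored"))
  all1 <- prioritize_functional(sel, c(A_S1 = 1, B_S2 = 1, C_S3 = 1))
  expect_identical(all1$prioritized, all1$selected)
})
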