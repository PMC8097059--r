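# Kinase-substrate network expansion, KSEA scoring, cross-comparison
# signature and k-means clustering.

make_edges <- function(kinase, sites, source = "curated", score = NA_real_) {
  data.frame(kinase = kinase, site = sites, source = source, score = score,
             stringsAsFactors = FALSE)
}

test_that("network expansion keeps curated edges and thresholds predicted ones", {
  edges <- rbind(
    make_edges("K1", "A_S1"),
    make_edges("K2", "A_S2", "predicted", 3.0),
    make_edges("K3", "A_S3", "predicted", 2.9))
  kept <- expand_ks_db(edges, networkin_min = 3)
  expect_setequal(kept$kinase, c("K1", "K2"))
  only_curated <- expand_ks_db(edges, networkin_min = Inf)
  expect_identical(only_curated$kinase, "K1")
})

test_that("KSEA z follows the closed form and excludes sparse kinases", {
  withr::with_seed(31, {
    fc <- stats::setNames(stats::rnorm(300), sprintf("P%03d_S%d", 1:300, 1:300))
    edges <- rbind(
      make_edges("BIG", names(fc)[1:9]),
      make_edges("SMALL", names(fc)[10:12]),
      make_edges("FOUR", names(fc)[20:23]))
    fc[1:9] <- fc[1:9] + 3
    res <- ksea_scores(fc, edges, min_substrates = 4)
    expect_false("SMALL" %in% res$kinase)        # m = 3: no score emitted
    expect_true(all(c("BIG", "FOUR") %in% res$kinase))
    expect_true("SMALL" %in% attr(res, "excluded"))
    # one-line independent recomputation of z, p from the stored fields
    expect_equal(res$z,
                 (res$mean_s - res$mean_p) * sqrt(res$m) / res$delta,
                 tolerance = 1e-10)
    expect_equal(res$p, 2 * (1 - stats::pnorm(abs(res$z))), tolerance = 1e-12)
    expect_equal(res$mean_p, rep(mean(fc), nrow(res)))
    expect_equal(res$delta, rep(stats::sd(fc), nrow(res)))
    # substrates at the global mean score exactly zero
    fc0 <- stats::setNames(c(rep(1, 4), 0, 2, 0, 2), paste0("Q", 1:8, "_S1"))
    r0 <- ksea_scores(fc0, make_edges("KZ", names(fc0)[1:4]))
    expect_equal(r0$z, 0)
    expect_equal(r0$p, 1)
  })
})

test_that("KSEA z has the normal tail p and location/scale invariance", {
  withr::with_seed(32, {
    fc <- stats::setNames(stats::rnorm(200), sprintf("P%03d_S1", 1:200))
    edges <- make_edges("K", names(fc)[1:9])
    base <- ksea_scores(fc, edges)
    shifted <- ksea_scores(fc + 5, edges)
    scaled <- ksea_scores(fc * 3, edges)
    expect_equal(shifted$z, base$z, tolerance = 1e-10)
    expect_equal(scaled$z, base$z, tolerance = 1e-10)
  })
  # z = 3 example: m = 9 substrates with mean 1 over a null background
  fc <- stats::setNames(c(rep(1, 9), rep(0, 191)), sprintf("P%03d_S1", 1:200))
  # center/scale so mean_p = 0 and delta = 1 exactly
  fc <- (fc - mean(fc)) / stats::sd(fc)
  edges <- make_edges("K", names(fc)[1:9])
  res <- ksea_scores(fc, edges)
  z_expected <- (mean(fc[1:9]) - 0) * 3 / 1
  expect_equal(res$z, z_expected, tolerance = 1e-12)
  expect_equal(res$p, 2 * (1 - stats::pnorm(z_expected)), tolerance = 1e-12)
  expect_error(ksea_scores(stats::setNames(rep(1, 10), paste0("P", 1:10, "_S1")),
                           edges), "degenerate")
})

test_that("signature retains kinases significant in enough comparisons", {
  withr::with_seed(33, {
    # toy flag table: 8 kinases x 5 comparisons with known significance
    kinases <- paste0("K", 1:8)
    n_sig <- c(5, 4, 3, 2, 1, 0, 3, 2)
    score_list <- lapply(1:5, function(cmp) {
      sig <- n_sig >= cmp
      data.frame(kinase = kinases, m = 5, mean_s = 0, mean_p = 0, delta = 1,
                 z = stats::rnorm(8),
                 p = ifelse(sig, 0.001, 0.5), q = ifelse(sig, 0.01, 0.9),
                 stringsAsFactors = FALSE)
    })
    names(score_list) <- paste0("cmp", 1:5)
    sig <- cross_comparison_signature(score_list, min_significant = 3)
    oracle <- kinases[n_sig >= 3]
    expect_setequal(sig$retained, oracle)
    expect_equal(dim(sig$z), c(length(oracle), 5))
    # 2-of-5 dropped, 5-of-5 retained
    expect_false("K4" %in% sig$retained)
    expect_true("K1" %in% sig$retained)
    # unscored comparisons count as non-significant
    score_list2 <- score_list
    score_list2[[1]] <- score_list2[[1]][-(1:2), ]   # K1, K2 unscored in cmp1
    sig2 <- cross_comparison_signature(score_list2, min_significant = 3)
    expect_true(is.na(sig2$z["K1", "cmp1"]))
    expect_equal(sig2$provenance$n_significant[sig2$provenance$kinase == "K1"], 4)
    names(score_list)[2] <- "cmp1"
    expect_error(cross_comparison_signature(score_list), "duplicate")
  })
})

test_that("k-means recovers planted row groups and matches a brute-force optimum", {
  withr::with_seed(34, {
    z <- rbind(matrix(stats::rnorm(10, 8, 0.2), 5, 2),
               matrix(stats::rnorm(10, 0, 0.2), 5, 2),
               matrix(stats::rnorm(10, -8, 0.2), 5, 2))
    rownames(z) <- paste0("K", 1:15)
    colnames(z) <- c("c1", "c2")
    labels <- kmeans_rows(z, k = 3, seed = 1)
    expect_identical(as.integer(labels), rep(1:3, each = 5))  # canonical: high z first
    expect_identical(as.integer(kmeans_rows(z, k = 1, seed = 1)), rep(1L, 15))
    expect_error(kmeans_rows(z[1:2, ], k = 3), "fewer rows")

    # 6x2 toy versus exhaustive assignment oracle minimizing within-SS
    z6 <- matrix(stats::rnorm(12), 6, 2, dimnames = list(paste0("R", 1:6), NULL))
    labels6 <- kmeans_rows(z6, k = 3, seed = 2, n_init = 50)
    withinss <- function(assign) {
      sum(vapply(unique(assign), function(cl) {
        x <- z6[assign == cl, , drop = FALSE]
        sum(sweep(x, 2, colMeans(x))^2)
      }, 1))
    }
    grid <- expand.grid(rep(list(1:3), 6))
    valid <- grid[apply(grid, 1, function(a) length(unique(a)) == 3), ]
    best <- min(apply(valid, 1, withinss))
    expect_equal(attr(labels6, "tot_withinss"), best, tolerance = 1e-9)
  })
})

test_that("missing signature cells are zero-imputed and flagged for clustering", {
  z <- matrix(c(5, 5, NA, -5, -5, -5), 3, 2,
              dimnames = list(paste0("K", 1:3), c("a", "b")))
  labels <- kmeans_rows(z, k = 2, seed = 1)
  expect_equal(nrow(attr(labels, "imputed")), 1)
  expect_equal(unname(labels[c("K1", "K3")]), c(1L, 2L))
})
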