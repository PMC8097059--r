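# Ground-truth generator: determinism, null behavior, planted effects,
# dose-response surfaces.

test_that("identical config and seed give bit-identical datasets", {
  cfg <- synth_config(n_proteins = 60, n_sites = 100, n_kinases = 8, seed = 5)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$proteome, d2$proteome)
  expect_identical(d1$phospho, d2$phospho)
  expect_identical(d1$ks_db, d2$ks_db)
  expect_identical(d1$truth, d2$truth)
  d3 <- generate_dataset(cfg, seed = 6)
  expect_false(identical(d1$proteome, d3$proteome))
})

test_that("null configuration produces approximately uniform t p-values", {
  cfg <- synth_config(n_proteins = 400, n_sites = 10, frac_diff_proteins = 0,
                      planted_kinases = NULL, missing_rate = 0, seed = 2)
  d <- generate_dataset(cfg)
  p <- apply(d$proteome, 1, function(x) {
    stats::t.test(x[d$design$condition == "case"],
                  x[d$design$condition == "control"], var.equal = TRUE)$p.value
  })
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("planted kinase shifts yield the expected KSEA z magnitude", {
  # delta = 1, m = 16, replicate noise chosen so the fold-change SD over
  # null sites is ~1: expected z ~ delta * sqrt(m) / delta_all = 4
  cfg <- synth_config(n_proteins = 150, n_sites = 600,
                      noise_sd = sqrt(3 / 2),  # FC SD = sigma * sqrt(2/3) = 1
                      frac_diff_proteins = 0, frac_protein_driven = 0,
                      missing_rate = 0,
                      planted_kinases = data.frame(kinase = "KIN_A", delta = 1,
                                                   m = 16))
  z <- vapply(1:30, function(s) {
    d <- generate_dataset(cfg, seed = s)
    case <- d$design$sample_id[d$design$condition == "case"]
    ctrl <- d$design$sample_id[d$design$condition == "control"]
    fc <- rowMeans(d$phospho[, case]) - rowMeans(d$phospho[, ctrl])
    sc <- ksea_scores(fc, expand_ks_db(d$ks_db))
    sc$z[sc$kinase == "KIN_A"]
  }, 1)
  expect_gt(mean(z), 3)
  expect_lt(mean(z), 5)
})

test_that("oversized substrate requests and invalid rates are rejected", {
  expect_error(synth_config(n_sites = 10,
                            planted_kinases = data.frame(kinase = "K",
                                                         delta = 1, m = 11)),
               "exceed")
  expect_error(synth_config(missing_rate = 1.5), "rates")
  expect_error(synth_config(noise_sd = 0), "noise_sd")
})

test_that("generated artifacts survive a write/read cycle unchanged", {
  d <- generate_dataset(synth_config(n_proteins = 40, n_sites = 80,
                                     n_kinases = 6, seed = 9))
  dir <- withr::local_tempdir()
  write_quant_matrix(d$phospho, file.path(dir, "ph.tsv"))
  write_ks_db(d$ks_db, file.path(dir, "ks.tsv"))
  write_sample_design(d$design, file.path(dir, "design.tsv"))
  write_functional_scores(d$functional_scores, file.path(dir, "fs.tsv"))
  write_gene_sets(d$gene_sets, file.path(dir, "gs.gmt"))
  ph <- read_quant_matrix(file.path(dir, "ph.tsv"), d$design,
                          feature_kind = "phosphosite")
  expect_identical(unname(ph[, ]), unname(d$phospho[, ]))
  expect_identical(read_ks_db(file.path(dir, "ks.tsv")), d$ks_db)
  expect_identical(read_sample_design(file.path(dir, "design.tsv")), d$design)
  expect_identical(read_functional_scores(file.path(dir, "fs.tsv")),
                   d$functional_scores)
  gs <- read_gene_sets(file.path(dir, "gs.gmt"))
  expect_identical(gs[names(d$gene_sets)], d$gene_sets[names(d$gene_sets)])
})

test_that("protein-driven sites are the ones caught by proteome correction", {
  cfg <- synth_config(n_proteins = 300, n_sites = 600, noise_sd = 0.25,
                      frac_diff_proteins = 0.1, diff_fc_range = c(2, 3),
                      frac_protein_driven = 0.15, missing_rate = 0,
                      n_per_condition = 4,
                      planted_kinases = data.frame(kinase = "KIN_A", delta = 2.5,
                                                   m = 20), seed = 12)
  d <- generate_dataset(cfg)
  phos_res <- one_sample_t(make_log2_ratios_vs_reference(
    d$phospho, d$design, "control"), s0 = 0.05, fdr = 0.05)
  prot_res <- one_sample_t(make_log2_ratios_vs_reference(
    d$proteome, d$design, "control"), s0 = 0.05, fdr = 0.05)
  ssel <- volcano_select(phos_res, fdr = 0.05)
  psel <- volcano_select(prot_res, fdr = 0.05)
  out <- proteome_correction_flags(ssel, psel,
                                   site_to_protein = d$truth$site_parent)
  pd <- out$feature %in% d$truth$protein_driven_sites
  kd <- out$feature %in% unlist(d$truth$kinase_substrates)
  # kinase-driven selected sites are phospho-specific: rarely flagged
  expect_lt(mean(out$proteome_regulated[kd & out$selected]), 0.1)
  # flagged sites are overwhelmingly the protein-driven ones
  flagged <- out$feature[out$proteome_regulated]
  expect_gt(mean(flagged %in% d$truth$protein_driven_sites), 0.9)
})

test_that("dose-response generator encodes the requested interaction exactly", {
  # additive, noiseless: Bliss index identically 0 on the dose grid
  cfg <- dose_response_config(noise_sd = 0, epsilon = 0, n_replicates = 1)
  dr <- generate_dose_response(cfg, seed = 1)
  a <- dr$single[dr$single$agent == "A", ]
  b <- dr$single[dr$single$agent == "B", ]
  sa <- a$response[match(dr$combo$dose_a, a$dose)]
  sb <- b$response[match(dr$combo$dose_b, b$dose)]
  idx <- bliss_index(sa, sb, dr$combo$response)$index
  expect_true(all(idx == 0))
  # epsilon = 0.1, noiseless: index 0.1 everywhere (doses kept low enough
  # that the expected surviving product stays above epsilon)
  cfg2 <- dose_response_config(doses = c(0.05, 0.1, 0.3, 0.6, 1),
                               noise_sd = 0, epsilon = 0.1, n_replicates = 1)
  dr2 <- generate_dose_response(cfg2, seed = 1)
  a2 <- dr2$single[dr2$single$agent == "A", ]
  b2 <- dr2$single[dr2$single$agent == "B", ]
  idx2 <- bliss_index(a2$response[match(dr2$combo$dose_a, a2$dose)],
                      b2$response[match(dr2$combo$dose_b, b2$dose)],
                      dr2$combo$response)$index
  expect_equal(idx2, rep(0.1, nrow(dr2$combo)), tolerance = 1e-12)
  expect_error(dose_response_config(doses = c(-1, 1, 2, 3)), "positive")
})
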