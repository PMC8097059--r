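# Config-driven orchestration of the full analysis graph on synthetic or
# user data: normalize -> completeness filter -> per-comparison tests ->
# volcano + proteome correction + functional filter -> KSEA per
# comparison -> cross-comparison signature + k-means -> ORA ->
# connectivity query lists -> optional synergy analysis.

#' Default run configuration over synthetic data
#'
#' Encodes the canonical five-comparison design over one synthetic
#' dataset with a planted kinase active in every case condition:
#' resistant vs sensitive cell-line groups (SAM, nine samples per group),
#' persister vs parental and persister vs short-term-treated (two-class
#' moderated t with BH at three replicates, where permutation FDR cannot
#' resolve below 0.1), and two PDX-style treated-vs-control comparisons
#' (one-sample moderated t on ratios against the control arm's median,
#' five animals per arm).
#'
#' @param seed Global seed.
#' @return A run-config list accepted by [run_pipeline()].
#' @export
example_run_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    generator = list(
      n_proteins = 1000, n_sites = 1600, n_kinases = 40,
      conditions = c("SENS", "RES", "PAR", "GSI", "PERS",
                     "RTX11", "AN111", "RTX19", "AN119"),
      n_per_condition = c(9, 9, 3, 3, 3, 5, 5, 5, 5),
      case_conditions = c("RES", "PERS", "AN111", "AN119"),
      control_condition = "SENS",
      planted_kinases = data.frame(kinase = "KIN_A", delta = 1.2, m = 16,
                                   stringsAsFactors = FALSE)),
    completeness = list(min_per_group = 2),
    comparisons = list(
      list(name = "RES_vs_SENS", test = "sam", case = "RES", control = "SENS",
           fdr = 0.05, s0 = 0.1),
      list(name = "PERS_vs_PAR", test = "t_bh", case = "PERS", control = "PAR",
           fdr = 0.01, s0 = 0.1),
      list(name = "PERS_vs_GSI", test = "t_bh", case = "PERS", control = "GSI",
           fdr = 0.05, s0 = 0.1),
      list(name = "AN1_vs_RTX_11", test = "one_sample", case = "AN111",
           control = "RTX11", fdr = 0.01, s0 = 0.1),
      list(name = "AN1_vs_RTX_19", test = "one_sample", case = "AN119",
           control = "RTX19", fdr = 0.01, s0 = 0.1)),
    sam = list(n_permutations = 250),
    volcano = list(fdr = 0.05, functional_min = 0.5),
    ksea = list(networkin_min = 3, min_substrates = 4, q_cut = 0.05,
                min_significant = 3, k = 3),
    enrichment = list(top_n = 100),
    connectivity = list(top_n = 150),
    synergy = NULL)
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with the fields of [example_run_config()].
#' @return The configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$generator$planted_kinases)) {
    cfg$generator$planted_kinases <-
      as.data.frame(cfg$generator$planted_kinases, stringsAsFactors = FALSE)
  }
  cfg
}

#' Validate a run configuration
#'
#' Checks that referenced files exist, comparison conditions resolve and
#' numeric ranges are valid. Violations are returned, not raised.
#'
#' @param config A run-config list.
#' @return Character vector of violations; empty when the config is ok.
#' @export
validate_config <- function(config) {
  v <- character()
  if (is.null(config$seed) || !is.finite(suppressWarnings(as.numeric(config$seed)))) {
    v <- c(v, "seed is mandatory and must be numeric")
  }
  if (is.null(config$generator) && is.null(config$data)) {
    v <- c(v, "either a generator block or data paths are required")
  }
  conditions <- NULL
  if (!is.null(config$data)) {
    for (f in unlist(config$data)) {
      if (!file.exists(f)) v <- c(v, paste0("missing input file: ", f))
    }
    if (!is.null(config$data$design) && file.exists(config$data$design)) {
      conditions <- unique(read_sample_design(config$data$design)$condition)
    }
  } else if (!is.null(config$generator)) {
    gen <- tryCatch(do.call(synth_config, config$generator),
                    error = function(e) {
                      v <<- c(v, paste0("generator: ", conditionMessage(e)))
                      NULL
                    })
    if (!is.null(gen)) conditions <- gen$conditions
  }
  if (length(config$comparisons) == 0) v <- c(v, "no comparisons defined")
  for (cmp in config$comparisons) {
    nm <- cmp$name %||% "<unnamed>"
    if (!cmp$test %in% c("sam", "t_bh", "anova", "one_sample")) {
      v <- c(v, paste0(nm, ": unknown test '", cmp$test, "'"))
    }
    if (!is.null(cmp$fdr) && (cmp$fdr <= 0 || cmp$fdr >= 1)) {
      v <- c(v, paste0(nm, ": fdr must lie in (0,1)"))
    }
    if (!is.null(cmp$s0) && cmp$s0 < 0) v <- c(v, paste0(nm, ": s0 must be >= 0"))
    if (!is.null(conditions)) {
      for (cond in c(cmp$case, cmp$control)) {
        if (!cond %in% conditions) {
          v <- c(v, paste0(nm, ": unknown condition '", cond, "'"))
        }
      }
    }
  }
  ks <- config$ksea %||% list()
  if (!is.null(ks$q_cut) && (ks$q_cut <= 0 || ks$q_cut >= 1)) {
    v <- c(v, "ksea: q_cut must lie in (0,1)")
  }
  if (!is.null(ks$min_substrates) && ks$min_substrates < 1) {
    v <- c(v, "ksea: min_substrates must be >= 1")
  }
  v
}

# Deterministic polynomial rolling hash of an R object (config provenance
# tag); exact in double arithmetic since intermediate values stay < 2^40.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 257 + b) %% 2147483647
  sprintf("%08x", h)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop2("pipeline stage '", name, "' failed: ", conditionMessage(e))
  })
}

#' Run the full analysis pipeline
#'
#' Executes every stage of the analysis graph on generated or user data
#' and writes all intermediate and final artifacts as TSV under
#' `output_dir`, together with a `manifest.yaml` recording the config
#' hash, seed and file list, and a run report with per-stage feature
#' counts. Reruns with the same config and seed are bit-identical.
#'
#' @param config A run-config list (see [example_run_config()]) or a path
#'   to a YAML file.
#' @param output_dir Output directory; defaults to `config$output_dir`.
#' @return Invisibly, a list with the run `report` and the in-memory
#'   results (`diff`, `volcano`, `ksea`, `signature`, `clusters`, `ora`,
#'   `queries`, `synergy`).
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  violations <- validate_config(config)
  if (length(violations) > 0) {
    stop2("invalid configuration:\n  ", paste(violations, collapse = "\n  "))
  }
  outdir <- output_dir %||% config$output_dir %||% stop2("no output directory")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  hash <- config_hash(config)
  files <- character()
  save_tsv <- function(df, name) {
    path <- file.path(outdir, name)
    write_tsv_plain(df, path)
    files <<- c(files, name)
    path
  }

  # --- data ------------------------------------------------------------
  data <- stage("load", {
    if (!is.null(config$data)) {
      design <- read_sample_design(config$data$design)
      list(proteome = read_quant_matrix(config$data$proteome, design,
                                        feature_kind = "protein"),
           phospho = read_quant_matrix(config$data$phospho, design,
                                       feature_kind = "phosphosite"),
           ks_db = read_ks_db(config$data$ks_db),
           functional_scores = if (is.null(config$data$functional_scores))
             numeric() else read_functional_scores(config$data$functional_scores),
           gene_sets = if (is.null(config$data$gene_sets)) list() else
             read_gene_sets(config$data$gene_sets),
           design = design, truth = NULL)
    } else {
      gen <- do.call(synth_config, config$generator)
      generate_dataset(gen, seed = seed)
    }
  })
  design <- data$design

  # --- preprocess -------------------------------------------------------
  min_pg <- config$completeness$min_per_group %||% 2
  norm <- stage("normalize", {
    list(proteome = normalize_median_center(data$proteome),
         phospho = normalize_median_center(data$phospho))
  })
  prot <- norm$proteome$matrix
  phos <- norm$phospho$matrix
  filt <- stage("filter", {
    conds <- unique(unlist(lapply(config$comparisons,
                                  function(cmp) c(cmp$case, cmp$control))))
    list(proteome = filter_by_completeness(prot, design, min_pg, groups = conds),
         phospho = filter_by_completeness(phos, design, min_pg, groups = conds))
  })
  prot <- filt$proteome
  phos <- filt$phospho

  # --- per-comparison tests --------------------------------------------
  diff_prot <- list()
  diff_phos <- list()
  volcano <- list()
  ksea_list <- list()
  expanded <- stage("expand_network", {
    expand_ks_db(data$ks_db, config$ksea$networkin_min %||% 3)
  })
  run_test <- function(mat, cmp) {
    if (cmp$test == "sam") {
      params <- sam_params(s0 = cmp$s0 %||% 0.1,
                           n_permutations = config$sam$n_permutations %||% 250,
                           fdr_target = cmp$fdr %||% 0.05, seed = seed)
      sam_test(mat, design, cmp$case, cmp$control, params)
    } else if (cmp$test == "t_bh") {
      two_class_t_bh(mat, design, cmp$case, cmp$control,
                     s0 = cmp$s0 %||% 0.1, fdr = cmp$fdr %||% 0.01)
    } else if (cmp$test == "one_sample") {
      sub <- design[design$condition %in% c(cmp$case, cmp$control), , drop = FALSE]
      ratios <- make_log2_ratios_vs_reference(mat[, sub$sample_id, drop = FALSE],
                                              sub, cmp$control)
      one_sample_t(ratios, s0 = cmp$s0 %||% 0.1, fdr = cmp$fdr %||% 0.01)
    } else {
      anova_oneway(mat, design, groups = cmp$groups %||% c(cmp$case, cmp$control),
                   fdr = cmp$fdr %||% 0.01)
    }
  }
  for (cmp in config$comparisons) {
    nm <- cmp$name
    diff_prot[[nm]] <- stage(paste0("test_proteome:", nm), run_test(prot, cmp))
    diff_phos[[nm]] <- stage(paste0("test_phospho:", nm), run_test(phos, cmp))
    save_tsv(diff_prot[[nm]], paste0("diff_proteome_", nm, ".tsv"))
    save_tsv(diff_phos[[nm]], paste0("diff_phospho_", nm, ".tsv"))

    volcano[[nm]] <- stage(paste0("volcano:", nm), {
      vol_fdr <- config$volcano$fdr %||% 0.01
      sel_site <- volcano_select(diff_phos[[nm]], fdr = vol_fdr)
      sel_prot <- volcano_select(diff_prot[[nm]], fdr = vol_fdr)
      sel <- proteome_correction_flags(sel_site, sel_prot)
      prioritize_functional(sel, data$functional_scores,
                            config$volcano$functional_min %||% 0.5)
    })
    save_tsv(volcano[[nm]], paste0("volcano_", nm, ".tsv"))

    ksea_list[[nm]] <- stage(paste0("ksea:", nm), {
      fc <- diff_phos[[nm]]$log2FC
      names(fc) <- diff_phos[[nm]]$feature
      fc <- fc[!is.na(fc)]
      if (length(fc) < 2) NULL else {
        ksea_scores(fc, expanded,
                    min_substrates = config$ksea$min_substrates %||% 4)
      }
    })
    if (!is.null(ksea_list[[nm]])) {
      save_tsv(ksea_list[[nm]], paste0("ksea_", nm, ".tsv"))
    }
  }

  # --- signature + clustering ------------------------------------------
  ksea_ok <- Filter(Negate(is.null), ksea_list)
  signature <- NULL
  clusters <- NULL
  if (length(ksea_ok) >= 2) {
    signature <- stage("signature", {
      cross_comparison_signature(ksea_ok,
                                 min_significant = config$ksea$min_significant %||% 3,
                                 q_cut = config$ksea$q_cut %||% 0.05)
    })
    k <- config$ksea$k %||% 3
    if (length(signature$retained) >= k) {
      clusters <- stage("kmeans", kmeans_rows(signature, k = k, seed = seed))
    }
    save_tsv(signature_long(signature, clusters), "kinase_signature.tsv")
    save_tsv(signature$provenance, "kinase_signature_provenance.tsv")
  }

  # --- enrichment + connectivity queries -------------------------------
  ora <- list()
  queries <- list()
  for (nm in names(diff_prot)) {
    res <- diff_prot[[nm]]
    if (length(data$gene_sets) > 0) {
      fg <- res$feature[res$significant]
      if (length(fg) > 0) {
        ora[[nm]] <- stage(paste0("ora:", nm),
                           ora_fisher(fg, data$gene_sets, res$feature))
        save_tsv(ora[[nm]], paste0("ora_", nm, ".tsv"))
      }
    }
    if (all(is.na(res$statistic))) next
    queries[[nm]] <- stage(paste0("query:", nm), {
      suppressWarnings(rank_and_select_top(res, "statistic",
                                           config$connectivity$top_n %||% 150,
                                           side = "both"))
    })
    for (s in c("up", "down")) {
      path <- file.path(outdir, paste0("query_", nm, "_", s, ".txt"))
      writeLines(queries[[nm]][[s]], path)
      files <- c(files, basename(path))
    }
  }

  # --- synergy ----------------------------------------------------------
  synergy <- NULL
  if (!is.null(config$synergy)) {
    synergy <- stage("synergy", {
      dr <- generate_dose_response(do.call(dose_response_config, config$synergy),
                                   seed = seed)
      fits <- lapply(split(dr$single, dr$single$agent), fit_4pl)
      agents <- names(fits)
      mean_resp <- function(df, key) {
        stats::aggregate(response ~ ., data = df[c(key, "response")], FUN = mean)
      }
      sa <- mean_resp(dr$single[dr$single$agent == agents[1], ], "dose")
      sb <- mean_resp(dr$single[dr$single$agent == agents[2], ], "dose")
      co <- mean_resp(dr$combo, c("dose_a", "dose_b"))
      co$S_A <- sa$response[match(co$dose_a, sa$dose)]
      co$S_B <- sb$response[match(co$dose_b, sb$dose)]
      bl <- bliss_index(pmax(co$S_A, 0), pmax(co$S_B, 0),
                        pmax(co$response, 0))
      bl$dose_a <- co$dose_a
      bl$dose_b <- co$dose_b
      list(fits = fits, bliss = bl, mean_index = mean(bl$index))
    })
    save_tsv(synergy$bliss, "bliss_surface.tsv")
  }

  # --- report -----------------------------------------------------------
  report <- list(
    config_hash = hash,
    seed = seed,
    n_proteins = nrow(data$proteome), n_sites = nrow(data$phospho),
    n_proteins_after_filter = nrow(prot), n_sites_after_filter = nrow(phos),
    n_significant_proteome = vapply(diff_prot, function(r) sum(r$significant), 1L),
    n_significant_phospho = vapply(diff_phos, function(r) sum(r$significant), 1L),
    n_volcano_selected = vapply(volcano, function(v) sum(v$selected), 1L),
    n_kinases_scored = vapply(ksea_list, function(k) if (is.null(k)) 0L else nrow(k), 1L),
    signature_kinases = if (is.null(signature)) character() else signature$retained,
    mean_bliss_index = if (is.null(synergy)) NA_real_ else synergy$mean_index)
  yaml::write_yaml(report, file.path(outdir, "report.yaml"))
  yaml::write_yaml(list(config_hash = hash, seed = seed,
                        files = sort(unique(c(files, "report.yaml")))),
                   file.path(outdir, "manifest.yaml"))
  invisible(list(report = report, diff_proteome = diff_prot,
                 diff_phospho = diff_phos, volcano = volcano,
                 ksea = ksea_list, signature = signature, clusters = clusters,
                 ora = ora, queries = queries, synergy = synergy,
                 truth = data$truth))
}
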