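# Synthetic proteome/phosphoproteome generator with known ground truth.
# Emulates the statistical structure the downstream analysis assumes:
# multi-condition replicate designs on the log2-intensity scale,
# log-normal (Gaussian-on-log2) replicate noise, planted differential
# proteins, planted kinase-activity shifts propagated through a
# kinase-substrate network, protein-driven phosphosite changes, missing
# values, predicted-edge scores, per-site functional scores and planted
# enriched gene sets.
#
# All stochastic draws derive from one global seed: `set.seed(seed)` is
# applied once and draws happen in a fixed, documented order (proteins,
# planted effects, sites, network, matrices, missingness, functional
# scores, gene sets), so identical (config, seed) pairs give bit-identical
# outputs.

#' Synthetic-dataset generator configuration
#'
#' Defaults emulate a TMT-style design of replicated conditions: three
#' biological replicates per condition, Gaussian replicate noise on the
#' log2 scale, a small fraction of differential proteins with |log2 FC|
#' between 0.5 and 2, one planted active kinase, missing-at-random
#' values, and predicted network edges with scores uniform on [0, 10] so
#' a score-3 expansion threshold separates retained from dropped edges.
#'
#' @param n_proteins,n_sites Numbers of proteins and phosphosites.
#' @param conditions Condition labels.
#' @param n_per_condition Replicates per condition (recycled).
#' @param case_conditions Conditions in which planted effects are active.
#' @param control_condition Condition marked `control` in the design.
#' @param baseline_mean,baseline_sd Log2-intensity baseline distribution.
#' @param site_offset_sd SD of the per-site offset from its protein's
#'   baseline.
#' @param noise_sd Replicate noise SD (log2 units).
#' @param frac_diff_proteins Fraction of proteins with a planted
#'   differential effect.
#' @param diff_fc_range Range of |log2 FC| for planted differential
#'   proteins (sign random).
#' @param planted_kinases Data.frame with columns `kinase`, `delta`
#'   (activity shift in log2 units) and `m` (substrate count), or `NULL`.
#' @param n_kinases Total number of kinases (including planted ones).
#' @param substrates_per_kinase Mean substrate count of background
#'   kinases.
#' @param frac_curated Probability that a background edge is curated
#'   (planted-kinase edges are always curated so the planted signal
#'   survives network expansion).
#' @param predicted_score_range Range of predicted-edge scores.
#' @param frac_protein_driven Fraction of sites whose fold-change mirrors
#'   a planted differential protein's fold-change.
#' @param missing_rate Missing-at-random rate.
#' @param functional_coverage Fraction of sites carrying a functional
#'   score (uniform on [0, 1]).
#' @param n_gene_sets,gene_set_size Gene-set collection shape.
#' @param n_planted_sets Number of sets enriched for planted upregulated
#'   proteins.
#' @param planted_set_frac Fraction of a planted set drawn from the
#'   planted upregulated proteins.
#' @param seed Global generator seed.
#' @return A validated configuration list.
#' @export
synth_config <- function(n_proteins = 1200,
                         n_sites = 2000,
                         conditions = c("control", "case"),
                         n_per_condition = 3,
                         case_conditions = "case",
                         control_condition = conditions[1],
                         baseline_mean = 25,
                         baseline_sd = 2,
                         site_offset_sd = 1,
                         noise_sd = 0.3,
                         frac_diff_proteins = 0.05,
                         diff_fc_range = c(0.5, 2),
                         planted_kinases = data.frame(
                           kinase = "KIN_A", delta = 1, m = 16,
                           stringsAsFactors = FALSE),
                         n_kinases = 30,
                         substrates_per_kinase = 8,
                         frac_curated = 0.5,
                         predicted_score_range = c(0, 10),
                         frac_protein_driven = 0.1,
                         missing_rate = 0.05,
                         functional_coverage = 0.8,
                         n_gene_sets = 10,
                         gene_set_size = 25,
                         n_planted_sets = 1,
                         planted_set_frac = 0.7,
                         seed = 1L) {
  cfg <- as.list(environment())
  rates <- c(cfg$frac_diff_proteins, cfg$frac_curated, cfg$frac_protein_driven,
             cfg$missing_rate, cfg$functional_coverage, cfg$planted_set_frac)
  if (any(rates < 0 | rates > 1)) stop2("all rates must lie in [0, 1]")
  if (cfg$noise_sd <= 0) stop2("noise_sd must be > 0")
  if (!is.null(cfg$planted_kinases) && nrow(cfg$planted_kinases) > 0) {
    if (any(cfg$planted_kinases$m < 1)) stop2("substrate counts m must be >= 1")
    if (sum(cfg$planted_kinases$m) > cfg$n_sites) {
      stop2("requested substrate counts exceed n_sites")
    }
  }
  if (!all(cfg$case_conditions %in% cfg$conditions)) {
    stop2("case_conditions must be among conditions")
  }
  cfg
}

#' Generate a synthetic (phospho)proteomics dataset with known truth
#'
#' Protein log2 intensities are a per-protein baseline plus the planted
#' differential effect (case conditions only) plus replicate noise.
#' Phosphosite intensities are the parent protein's baseline plus a fixed
#' per-site offset, plus the planted kinase shift `delta_k` when the site
#' is a substrate of a planted kinase (case conditions only), plus the
#' parent protein's planted fold-change for protein-driven sites, plus
#' noise; missingness is applied last.
#'
#' @param config A [synth_config()] list.
#' @param seed Overrides `config$seed` when given.
#' @return List with `proteome` and `phospho` matrices, `ks_db` edge
#'   table, `functional_scores`, `gene_sets`, `design` and `truth` (the
#'   planted differential proteins, protein-driven sites, kinase shifts
#'   and substrate memberships, enriched sets and the seed).
#' @export
generate_dataset <- function(config = synth_config(), seed = NULL) {
  seed <- as.integer(seed %||% config$seed)
  withr::with_seed(seed, generate_dataset_impl(config, seed))
}

generate_dataset_impl <- function(cfg, seed) {
  pad <- function(prefix, n) sprintf("%s%0*d", prefix, nchar(n), seq_len(n))
  proteins <- pad("P", cfg$n_proteins)
  baseline <- stats::rnorm(cfg$n_proteins, cfg$baseline_mean, cfg$baseline_sd)
  names(baseline) <- proteins

  # planted differential proteins
  n_diff <- round(cfg$frac_diff_proteins * cfg$n_proteins)
  diff_proteins <- if (n_diff > 0) sample(proteins, n_diff) else character()
  diff_fc <- stats::setNames(
    sample(c(-1, 1), n_diff, replace = TRUE) *
      stats::runif(n_diff, cfg$diff_fc_range[1], cfg$diff_fc_range[2]),
    diff_proteins)

  # sites: protein-driven sites are attached to differential proteins
  n_pd <- if (n_diff > 0) round(cfg$frac_protein_driven * cfg$n_sites) else 0L
  parent <- character(cfg$n_sites)
  if (n_pd > 0) parent[seq_len(n_pd)] <- sample(diff_proteins, n_pd, replace = TRUE)
  if (n_pd < cfg$n_sites) {
    parent[(n_pd + 1):cfg$n_sites] <-
      sample(proteins, cfg$n_sites - n_pd, replace = TRUE)
  }
  residue <- sample(c("S", "T", "Y"), cfg$n_sites, replace = TRUE,
                    prob = c(0.75, 0.2, 0.05))
  # unique positions within each protein
  position <- integer(cfg$n_sites)
  for (p in unique(parent)) {
    idx <- which(parent == p)
    position[idx] <- sort(sample.int(5000, length(idx)))
  }
  sites <- format_site_key(parent, residue, position)
  protein_driven_sites <- sites[seq_len(n_pd)]

  # kinase-substrate network
  planted <- cfg$planted_kinases
  if (is.null(planted)) {
    planted <- data.frame(kinase = character(), delta = numeric(), m = integer(),
                          stringsAsFactors = FALSE)
  }
  edges <- list()
  substrates <- list()
  free_sites <- setdiff(sites, protein_driven_sites)
  for (i in seq_len(nrow(planted))) {
    m_k <- planted$m[i]
    if (m_k > length(free_sites)) stop2("requested substrate counts exceed n_sites")
    subs <- sample(free_sites, m_k)
    free_sites <- setdiff(free_sites, subs)
    substrates[[planted$kinase[i]]] <- subs
    edges[[length(edges) + 1]] <- data.frame(
      kinase = planted$kinase[i], site = subs, source = "curated",
      score = NA_real_, stringsAsFactors = FALSE)
  }
  n_bg <- max(0L, cfg$n_kinases - nrow(planted))
  bg_kinases <- pad("KIN_B", n_bg)
  for (k in bg_kinases) {
    m_k <- 1L + stats::rpois(1, max(cfg$substrates_per_kinase - 1, 0))
    subs <- sample(sites, min(m_k, length(sites)))
    src <- ifelse(stats::runif(length(subs)) < cfg$frac_curated,
                  "curated", "predicted")
    score <- ifelse(src == "predicted",
                    stats::runif(length(subs), cfg$predicted_score_range[1],
                                 cfg$predicted_score_range[2]),
                    NA_real_)
    substrates[[k]] <- subs
    edges[[length(edges) + 1]] <- data.frame(
      kinase = k, site = subs, source = src, score = score,
      stringsAsFactors = FALSE)
  }
  ks_db <- ks_dedup(do.call(rbind, edges))

  # design
  n_rep <- rep_len(cfg$n_per_condition, length(cfg$conditions))
  design <- do.call(rbind, lapply(seq_along(cfg$conditions), function(i) {
    data.frame(sample_id = paste0(cfg$conditions[i], "_", seq_len(n_rep[i])),
               condition = cfg$conditions[i], replicate = seq_len(n_rep[i]),
               group_role = if (cfg$conditions[i] %in% cfg$case_conditions) {
                 "case"
               } else if (identical(cfg$conditions[i], cfg$control_condition)) {
                 "control"
               } else "other",
               stringsAsFactors = FALSE)
  }))
  rownames(design) <- NULL
  is_case_sample <- design$condition %in% cfg$case_conditions

  # proteome matrix
  prot_effect <- stats::setNames(numeric(cfg$n_proteins), proteins)
  prot_effect[diff_proteins] <- diff_fc
  n_samp <- nrow(design)
  proteome <- matrix(baseline, cfg$n_proteins, n_samp) +
    outer(prot_effect, as.numeric(is_case_sample)) +
    matrix(stats::rnorm(cfg$n_proteins * n_samp, 0, cfg$noise_sd),
           cfg$n_proteins, n_samp)
  dimnames(proteome) <- list(proteins, design$sample_id)

  # phosphoproteome matrix
  site_offset <- stats::rnorm(cfg$n_sites, 0, cfg$site_offset_sd)
  kin_shift <- stats::setNames(numeric(cfg$n_sites), sites)
  for (i in seq_len(nrow(planted))) {
    kin_shift[substrates[[planted$kinase[i]]]] <- kin_shift[substrates[[planted$kinase[i]]]] +
      planted$delta[i]
  }
  pd_effect <- stats::setNames(numeric(cfg$n_sites), sites)
  if (n_pd > 0) pd_effect[protein_driven_sites] <- prot_effect[parent[seq_len(n_pd)]]
  site_case_effect <- kin_shift + pd_effect
  phospho <- matrix(baseline[parent] + site_offset, cfg$n_sites, n_samp) +
    outer(unname(site_case_effect), as.numeric(is_case_sample)) +
    matrix(stats::rnorm(cfg$n_sites * n_samp, 0, cfg$noise_sd),
           cfg$n_sites, n_samp)
  dimnames(phospho) <- list(sites, design$sample_id)

  # missingness (MCAR), applied last
  if (cfg$missing_rate > 0) {
    proteome[stats::runif(length(proteome)) < cfg$missing_rate] <- NA_real_
    phospho[stats::runif(length(phospho)) < cfg$missing_rate] <- NA_real_
  }

  # functional scores
  n_scored <- round(cfg$functional_coverage * cfg$n_sites)
  scored_sites <- if (n_scored > 0) sample(sites, n_scored) else character()
  functional_scores <- stats::setNames(stats::runif(n_scored), scored_sites)

  # gene sets; planted sets are enriched for planted upregulated proteins
  up_proteins <- names(diff_fc)[diff_fc > 0]
  gene_sets <- list()
  n_planted_sets <- min(cfg$n_planted_sets, cfg$n_gene_sets)
  for (i in seq_len(cfg$n_gene_sets)) {
    nm <- sprintf("SET_%02d", i)
    if (i <= n_planted_sets && length(up_proteins) > 0) {
      n_from_up <- min(round(cfg$planted_set_frac * cfg$gene_set_size),
                       length(up_proteins))
      members <- c(sample(up_proteins, n_from_up),
                   sample(setdiff(proteins, up_proteins),
                          cfg$gene_set_size - n_from_up))
    } else {
      members <- sample(proteins, cfg$gene_set_size)
    }
    gene_sets[[nm]] <- unique(members)
  }
  attr(gene_sets, "description") <- stats::setNames(
    c(rep("planted", n_planted_sets),
      rep("background", cfg$n_gene_sets - n_planted_sets)),
    names(gene_sets))

  truth <- list(
    diff_proteins = data.frame(protein = names(diff_fc),
                               log2FC = unname(diff_fc),
                               stringsAsFactors = FALSE),
    protein_driven_sites = protein_driven_sites,
    site_parent = stats::setNames(parent, sites),
    kinases = planted,
    kinase_substrates = substrates[planted$kinase],
    enriched_sets = utils::head(names(gene_sets), n_planted_sets),
    seed = seed)

  attr(proteome, "feature_kind") <- "protein"
  attr(phospho, "feature_kind") <- "phosphosite"
  list(proteome = proteome, phospho = phospho, ks_db = ks_db,
       functional_scores = functional_scores, gene_sets = gene_sets,
       design = design, truth = truth)
}

#' Dose-response generator configuration
#'
#' @param doses Dose grid in uM (strictly positive).
#' @param agents Named list of true 4PL parameter lists
#'   (`bottom`, `top`, `ic50`, `hill`) for the two single agents.
#' @param epsilon Bliss interaction: combination surviving fraction is
#'   `S_A * S_B - epsilon` (positive = synergy, negative = antagonism,
#'   0 = Bliss-additive).
#' @param noise_sd Gaussian response noise SD.
#' @param n_replicates Replicate plates.
#' @param seed Generator seed.
#' @return A validated configuration list.
#' @export
dose_response_config <- function(doses = 10^seq(-2, 1.5, length.out = 8),
                                 agents = list(
                                   A = list(bottom = 0, top = 1, ic50 = 1, hill = 1),
                                   B = list(bottom = 0, top = 1, ic50 = 2, hill = 1.2)),
                                 epsilon = 0,
                                 noise_sd = 0.05,
                                 n_replicates = 3,
                                 seed = 1L) {
  if (any(doses <= 0)) stop2("doses must be positive")
  if (length(agents) != 2) stop2("exactly two agents are required")
  as.list(environment())
}

four_pl <- function(dose, p) {
  p$bottom + (p$top - p$bottom) / (1 + (dose / p$ic50)^p$hill)
}

#' Generate synthetic dose-response plates with known interaction
#'
#' Single-agent plates follow the configured true 4PL curves; combination
#' plates over the full dose grid follow
#' `S_AB = S_A * S_B - epsilon + noise`. Responses are not clamped, so the
#' noiseless interaction is recovered exactly; with noise (or a large
#' `epsilon` at high doses) responses may dip slightly below zero, as raw
#' viability readings do.
#'
#' @param config A [dose_response_config()] list.
#' @param seed Overrides `config$seed` when given.
#' @return List with `single` (agent, dose, response, replicate), `combo`
#'   (dose_a, dose_b, response, replicate) and `truth` (agent parameters
#'   and `epsilon`).
#' @export
generate_dose_response <- function(config = dose_response_config(), seed = NULL) {
  seed <- as.integer(seed %||% config$seed)
  withr::with_seed(seed, {
    cfg <- config
    agents <- names(cfg$agents)
    single <- do.call(rbind, lapply(agents, function(a) {
      do.call(rbind, lapply(seq_len(cfg$n_replicates), function(r) {
        resp <- four_pl(cfg$doses, cfg$agents[[a]]) +
          stats::rnorm(length(cfg$doses), 0, cfg$noise_sd)
        data.frame(agent = a, dose = cfg$doses, response = resp,
                   replicate = r, stringsAsFactors = FALSE)
      }))
    }))
    grid <- expand.grid(dose_a = cfg$doses, dose_b = cfg$doses)
    combo <- do.call(rbind, lapply(seq_len(cfg$n_replicates), function(r) {
      s_ab <- four_pl(grid$dose_a, cfg$agents[[1]]) *
        four_pl(grid$dose_b, cfg$agents[[2]]) - cfg$epsilon +
        stats::rnorm(nrow(grid), 0, cfg$noise_sd)
      data.frame(dose_a = grid$dose_a, dose_b = grid$dose_b,
                 response = s_ab, replicate = r,
                 stringsAsFactors = FALSE)
    }))
    list(single = single, combo = combo,
         truth = list(agents = cfg$agents, epsilon = cfg$epsilon, seed = seed))
  })
}
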