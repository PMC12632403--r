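#' Configuration for the synthetic-data generators
#'
#' Bundles the sizes and effect parameters every generator reads. The
#' defaults are the package's reference study conditions: desk-scale analogs
#' of a multi-dataset ubiquitinome compilation, chosen once so that each
#' planted effect is detectable by its intended analysis without being
#' trivial (rationale in the methods vignette).
#'
#' @param seed integer; fully determines every generator's output.
#' @param n_sites planted target ubi-sites in the PSM generator.
#' @param n_proteins proteins the sites are spread over.
#' @param n_datasets independent datasets in the PSM generator.
#' @param false_localization_rate expected fraction of reported target-site
#'   records that are mislocalized; the decoy-alanine channel emits counts at
#'   this same rate so decoy competition estimates it.
#' @param n_ortholog_groups orthologue groups in the conservation generator.
#' @param n_domains,n_instances,domain_width domain alignment sizes.
#' @param lysine_density per-column lysine probability outside planted
#'   regions.
#' @param background_mark_rate probability a lysine carries a background ubi
#'   mark.
#' @param hotspot_enrichment multiplier on the mark rate inside the planted
#'   5-column region (1 = pure null, no region planted).
#' @param n_conditions,n_fc_sites fold-change matrix sizes.
#' @param regulated_fraction fraction of sites planted as regulated per
#'   perturbation group.
#' @param noise_sd residual sd around the shared group response.
#' @param n_feature_sites,n_feature_proteins feature-table sizes.
#' @param class_imbalance negatives per positive in the feature table.
#' @param planted_weights named 16-vector of true model weights on the
#'   preprocessed feature scale (`NULL` for the reference vector).
#' @param n_samples tumour samples in the activity generator.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_sites = 2000L, n_proteins = 300L, n_datasets = 3L,
                       false_localization_rate = 0.10,
                       n_ortholog_groups = 30L,
                       n_domains = 1L, n_instances = 30L, domain_width = 60L,
                       lysine_density = 0.25, background_mark_rate = 0.06,
                       hotspot_enrichment = 8,
                       n_conditions = 12L, n_fc_sites = 1200L,
                       regulated_fraction = 0.05, noise_sd = 0.5,
                       n_feature_sites = 5000L, n_feature_proteins = 300L,
                       class_imbalance = 50, planted_weights = NULL,
                       n_samples = 100L) {
  if (is.null(planted_weights)) {
    planted_weights <- c(
      conservation_level = 1.0, in_hotspot = 0.8, gold_confidence = 0.5,
      n_regulations = 0.7, n_quantifications = 0.6, in_domain = 0.3,
      in_region = 0.2, disorder = -0.6, helix_prob = 0.1, coil_prob = 0.0,
      rsa = 0.5, protein_length = -0.4, at_interface = 0.6,
      site_other_ptms = 0.7, n_nearby_ptms = 0.8, pathogenicity = 1.0)
  }
  stopifnot(false_localization_rate >= 0, false_localization_rate <= 1,
            hotspot_enrichment >= 1, class_imbalance >= 1,
            setequal(names(planted_weights), functional_score_features()))
  structure(as.list(environment()), class = "sim_config")
}

amino_acids <- c("A", "C", "D", "E", "F", "G", "H", "I", "L", "M", "N", "P",
                 "Q", "R", "S", "T", "V", "W", "Y")  # K handled explicitly

#' Generate a synthetic PSM table with planted false localizations
#'
#' Emits PSM-level records for `n_sites` target ubi-sites across
#' `n_datasets` datasets. A fraction `false_localization_rate` of target
#' site records per dataset is planted as mislocalized (ground truth in the
#' sidecar table), and a matching decoy-alanine channel emits decoy site
#' records at the same expected rate and spectral quality, so decoy
#' competition estimates the planted rate. A few peptide C-terminal lysine
#' records are included to exercise the tryptic filter.
#'
#' @param config a [sim_config()].
#' @return list with `psms` (the PSM data.frame) and `truth` (per-record
#'   `true_localization`).
#' @export
gen_psm_table <- function(config) {
  rng <- local_rng(config$seed)
  on.exit(rng(), add = TRUE)
  n <- config$n_sites
  f <- config$false_localization_rate
  protein <- sprintf("P%05d", sample.int(config$n_proteins, n, replace = TRUE))
  position <- stats::ave(seq_len(n), protein, FUN = seq_along) * 7L +
    sample.int(3L, n, replace = TRUE)
  rows <- list()
  for (d in seq_len(config$n_datasets)) {
    detected <- sort(sample.int(n, size = round(0.8 * n)))
    is_false <- stats::rbinom(length(detected), 1L, f) == 1L
    n_psm <- 1L + stats::rpois(length(detected), 1)
    for (i in seq_along(detected)) {
      s <- detected[i]
      # mislocalized placements score lower than correct ones
      loc <- if (is_false[i]) stats::runif(n_psm[i], 0.55, 0.95)
             else stats::runif(n_psm[i], 0.90, 1.0)
      rows[[length(rows) + 1L]] <- data.frame(
        dataset_id = sprintf("DS%02d", d),
        peptidoform_id = sprintf("pf_%s_%d_%d_%d", protein[s], position[s], d,
                                 seq_len(n_psm[i])),
        protein_ac = protein[s],
        site_position = position[s],
        residue = "K",
        localization_prob = loc,
        psm_prob = stats::runif(n_psm[i], 0.95, 1.0),
        is_decoy_residue = FALSE,
        is_peptide_cterm = FALSE,
        true_localization = !is_false[i])
    }
    # decoy-alanine channel at the mislocalized channel's rate and quality
    n_decoy <- stats::rbinom(1L, length(detected), f)
    if (n_decoy > 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        dataset_id = sprintf("DS%02d", d),
        peptidoform_id = sprintf("pf_decoy_%d_%d", d, seq_len(n_decoy)),
        protein_ac = sprintf("P%05d",
                             sample.int(config$n_proteins, n_decoy,
                                        replace = TRUE)),
        site_position = 100000L + seq_len(n_decoy),
        residue = "A",
        localization_prob = stats::runif(n_decoy, 0.55, 0.95),
        psm_prob = stats::runif(n_decoy, 0.95, 1.0),
        is_decoy_residue = TRUE,
        is_peptide_cterm = FALSE,
        true_localization = FALSE)
    }
  }
  # tryptic artefacts: modified Lys at peptide C-termini, to be filtered
  n_ct <- 20L
  rows[[length(rows) + 1L]] <- data.frame(
    dataset_id = "DS01",
    peptidoform_id = sprintf("pf_cterm_%d", seq_len(n_ct)),
    protein_ac = sprintf("P%05d", sample.int(config$n_proteins, n_ct,
                                             replace = TRUE)),
    site_position = 200000L + seq_len(n_ct),
    residue = "K",
    localization_prob = stats::runif(n_ct, 0.90, 1.0),
    psm_prob = stats::runif(n_ct, 0.95, 1.0),
    is_decoy_residue = FALSE,
    is_peptide_cterm = TRUE,
    true_localization = FALSE)
  psms <- do.call(rbind, rows)
  rownames(psms) <- NULL
  truth <- psms[, c("dataset_id", "protein_ac", "site_position",
                    "is_decoy_residue", "true_localization")]
  psms$true_localization <- NULL
  list(psms = psms, truth = truth)
}

#' Generate orthologue groups with planted conservation levels
#'
#' Builds `n_ortholog_groups` ten-species alignments (human, mouse, rat,
#' horse, chicken, frog, zebrafish, fly, worm, yeast) with random indels to
#' exercise column mapping. Each group plants five human ubi-sites, one per
#' conservation level: the non-human lysine fraction at the site's column
#' and the cross-species detection pattern are constructed to satisfy
#' exactly one level rule.
#'
#' @param config a [sim_config()].
#' @return list with `groups` (list of [ortholog_group()]), `human_sites`,
#'   `species_sites` and `truth` (planted level per human site).
#' @export
gen_ortholog_groups <- function(config) {
  rng <- local_rng(config$seed + 1L)
  on.exit(rng(), add = TRUE)
  species <- c("hsapiens", "mmusculus", "rnorvegicus", "ecaballus",
               "ggallus", "xtropicalis", "drerio", "dmelanogaster",
               "celegans", "scerevisiae")
  n_sp <- length(species)
  width <- 120L
  groups <- list()
  human_sites <- list()
  species_sites <- list()
  truth <- list()
  for (g in seq_len(config$n_ortholog_groups)) {
    gid <- sprintf("OG%04d", g)
    acs <- sprintf("%s_%s", toupper(substr(species, 1, 4)), gid)
    mat <- matrix("", nrow = n_sp, ncol = width)
    for (j in seq_len(width)) {
      consensus <- sample(c(amino_acids, "K"), 1L)
      res <- ifelse(stats::runif(n_sp) < 0.7, consensus,
                    sample(c(amino_acids, "K"), n_sp, replace = TRUE))
      mat[, j] <- res
    }
    # random indels: each member gapped at ~8 private columns
    for (i in seq_len(n_sp)) {
      mat[i, sample.int(width, 8L)] <- "-"
    }
    # plant one site per level on non-overlapping columns; fix all residue
    # content first, then derive coordinates (planting un-gaps its column,
    # so positions are only valid once every column is final)
    cols <- sample(seq.int(5L, width - 5L), 5L)
    detect_plan <- list()
    for (lev in 1:5) {
      col <- cols[lev]
      mat[, col] <- "K"                       # start fully conserved, ungapped
      nonhuman <- 2:n_sp
      n_k <- switch(lev, 0L, 3L, 8L, 4L, 9L)  # of 9 non-human members
      not_k <- sample(nonhuman, length(nonhuman) - n_k)
      if (lev == 4L) not_k <- setdiff(not_k, 2L)        # keep mouse K
      if (lev == 5L) not_k <- setdiff(not_k, c(2L, 8L)) # keep mouse + fly K
      mat[not_k, col] <- "R"
      detect_plan[[lev]] <- switch(lev, integer(0), integer(0), integer(0),
                                   2L, c(2L, 8L))
    }
    for (lev in 1:5) {
      col <- cols[lev]
      for (i in detect_plan[[lev]]) {
        pos <- sum(mat[i, seq_len(col)] != "-")
        species_sites[[length(species_sites) + 1L]] <- data.frame(
          species_id = species[i], protein_ac = acs[i], site_position = pos)
      }
      hpos <- sum(mat[1L, seq_len(col)] != "-")
      human_sites[[length(human_sites) + 1L]] <- data.frame(
        protein_ac = acs[1L], site_position = hpos)
      truth[[length(truth) + 1L]] <- data.frame(
        group_id = gid, protein_ac = acs[1L], site_position = hpos,
        column = col, level = lev)
    }
    groups[[g]] <- ortholog_group(
      gid, species_id = species, protein_ac = acs,
      aligned = apply(mat, 1L, paste, collapse = ""))
  }
  list(groups = groups,
       human_sites = do.call(rbind, human_sites),
       species_sites = do.call(rbind, species_sites),
       truth = do.call(rbind, truth))
}

#' Generate domain alignments with an optional planted hotspot
#'
#' Builds `n_domains` alignment sets of `n_instances` instances. Lysines are
#' scattered at `lysine_density`; each lysine carries a background ubi mark
#' with probability `background_mark_rate`. When `hotspot_enrichment > 1` a
#' 5-column region (all-lysine so the signal has somewhere to land) receives
#' marks at `hotspot_enrichment` times the background rate (capped at 0.95);
#' `hotspot_enrichment = 1` produces a pure-null set and no planted region.
#'
#' @param config a [sim_config()].
#' @return list with `sets` (list of [domain_alignment_set()]) and `truth`
#'   (planted region per domain; `NA` bounds under the null).
#' @export
gen_domain_alignments <- function(config) {
  rng <- local_rng(config$seed + 2L)
  on.exit(rng(), add = TRUE)
  W <- config$domain_width
  n_inst <- config$n_instances
  sets <- list()
  truth <- list()
  for (d in seq_len(config$n_domains)) {
    did <- sprintf("DOM%03d", d)
    planted <- config$hotspot_enrichment > 1
    region <- if (planted) {
      start <- sample(seq.int(10L, W - 14L), 1L)
      c(start, start + 4L)
    } else {
      c(NA_integer_, NA_integer_)
    }
    mat <- matrix(sample(amino_acids, n_inst * W, replace = TRUE),
                  nrow = n_inst)
    is_k <- matrix(stats::runif(n_inst * W) < config$lysine_density,
                   nrow = n_inst)
    mat[is_k] <- "K"
    if (planted) mat[, region[1L]:region[2L]] <- "K"
    p_mark <- matrix(config$background_mark_rate, nrow = n_inst, ncol = W)
    if (planted) {
      p_mark[, region[1L]:region[2L]] <-
        min(0.95, config$background_mark_rate * config$hotspot_enrichment)
    }
    marked <- mat == "K" & matrix(stats::runif(n_inst * W), nrow = n_inst) <
      p_mark
    idx <- which(marked, arr.ind = TRUE)
    marks <- data.frame(instance = as.integer(idx[, 1L]),
                        column = as.integer(idx[, 2L]))
    sets[[d]] <- domain_alignment_set(
      did, instance_id = sprintf("%s_inst%03d", did, seq_len(n_inst)),
      aligned = apply(mat, 1L, paste, collapse = ""),
      marks = marks)
    truth[[d]] <- data.frame(domain_id = did, start_col = region[1L],
                             end_col = region[2L])
  }
  list(sets = sets, truth = do.call(rbind, truth))
}

#' Generate a long-format fold-change table with planted group structure
#'
#' Conditions come in four perturbation groups (proteasome inhibition, DNA
#' damage, translation inhibition, infection) sharing a latent per-group
#' response vector, so within-group correlations exceed between-group ones.
#' Each non-proteasome group carries a planted regulated site set shifted by
#' +2 log2 units; proteasome conditions add a broad positive shift to the
#' low-conservation site stratum. Two peptides x two replicates per
#' (site, condition) exercise aggregation; per-condition random blocks of
#' sites are missing, and one extra sparse condition (400 quantified sites)
#' is emitted to exercise the coverage filter.
#'
#' @param config a [sim_config()].
#' @return list with `fc` (long-format data.frame), `conditions` (metadata:
#'   `condition_id`, `study_id`, `perturbation_group`, `compound`), `sites`
#'   (site metadata with conservation stratum) and `truth` (planted
#'   regulated set per group).
#' @export
gen_foldchange_matrix <- function(config) {
  rng <- local_rng(config$seed + 3L)
  on.exit(rng(), add = TRUE)
  n_sites <- config$n_fc_sites
  site_id <- sprintf("site%05d", seq_len(n_sites))
  stratum <- sample(c("low", "high"), n_sites, replace = TRUE,
                    prob = c(0.6, 0.4))
  groups <- c("proteasome_inhibition", "dna_damage",
              "translation_inhibition", "infection")
  compounds <- list(proteasome_inhibition = c("MG-132", "bortezomib",
                                              "epoxomicin"),
                    dna_damage = "etoposide",
                    translation_inhibition = "cycloheximide",
                    infection = "salmonella")
  per_group <- max(1L, config$n_conditions %/% length(groups))
  latent <- lapply(groups, function(g) stats::rnorm(n_sites))
  names(latent) <- groups
  regulated <- lapply(groups[-1L], function(g) {
    sample(site_id, round(config$regulated_fraction * n_sites))
  })
  names(regulated) <- groups[-1L]
  fc_rows <- list()
  cond_rows <- list()
  cond_i <- 0L
  for (g in groups) {
    for (j in seq_len(per_group)) {
      cond_i <- cond_i + 1L
      cid <- sprintf("cond%02d", cond_i)
      compound <- compounds[[g]][1L + (j - 1L) %% length(compounds[[g]])]
      cond_rows[[cond_i]] <- data.frame(
        condition_id = cid, study_id = sprintf("study%02d", 1L + cond_i %/% 3L),
        perturbation_group = g, compound = compound)
      mu <- latent[[g]] + stats::rnorm(n_sites, sd = config$noise_sd)
      if (g == "proteasome_inhibition") {
        mu <- mu + ifelse(stratum == "low", 1.0, 0.0)
      } else {
        mu <- mu + ifelse(site_id %in% regulated[[g]], 2.0, 0)
      }
      missing_block <- sample.int(n_sites, round(0.2 * n_sites))
      present <- setdiff(seq_len(n_sites), missing_block)
      for (pep in 1:2) {
        for (repl in 1:2) {
          fc_rows[[length(fc_rows) + 1L]] <- data.frame(
            site_id = site_id[present], condition_id = cid,
            replicate = sprintf("r%d", repl),
            peptide_id = sprintf("%s_pep%d", site_id[present], pep),
            log2fc = mu[present] + stats::rnorm(length(present), sd = 0.1))
        }
      }
    }
  }
  # sparse condition: under the 500-site coverage threshold
  cond_i <- cond_i + 1L
  cid <- "cond_sparse"
  cond_rows[[cond_i]] <- data.frame(
    condition_id = cid, study_id = "study99",
    perturbation_group = "dna_damage", compound = "etoposide")
  n_sparse <- min(400L, n_sites)
  present <- sample.int(n_sites, n_sparse)
  fc_rows[[length(fc_rows) + 1L]] <- data.frame(
    site_id = site_id[present], condition_id = cid, replicate = "r1",
    peptide_id = sprintf("%s_pep1", site_id[present]),
    log2fc = stats::rnorm(n_sparse))
  truth <- do.call(rbind, lapply(names(regulated), function(g) {
    data.frame(group = g, site_id = regulated[[g]])
  }))
  list(fc = do.call(rbind, fc_rows),
       conditions = do.call(rbind, cond_rows),
       sites = data.frame(site_id = site_id, conservation_stratum = stratum),
       truth = truth)
}

#' Generate a site feature table from a planted logistic model
#'
#' Draws 16 features with realistic types (counts, bounded probabilities,
#' one-hot indicators, log-scale protein lengths; protein-level features are
#' constant within protein, inducing within-protein correlation), applies
#' the pipeline's preprocessing transform internally, and draws labels from
#' `Bernoulli(plogis(b0 + Z w*))` where `Z` is the preprocessed design,
#' `w*` the planted weights and `b0` solved so the expected positive rate is
#' `1 / (1 + class_imbalance)`. A small fraction of `rsa` and
#' `conservation_level` values is blanked to exercise the missingness rules.
#'
#' @param config a [sim_config()].
#' @return list with `table` (features + `site_id`, `protein_ac`, `label`)
#'   and `truth` (`weights`, `intercept`, per-site `bayes_prob`).
#' @export
gen_feature_table <- function(config) {
  rng <- local_rng(config$seed + 4L)
  on.exit(rng(), add = TRUE)
  n <- config$n_feature_sites
  n_prot <- config$n_feature_proteins
  protein <- sprintf("P%05d", sample.int(n_prot, n, replace = TRUE))
  prot_len <- stats::setNames(round(exp(stats::rnorm(n_prot, log(500), 0.6))),
                              sprintf("P%05d", seq_len(n_prot)))
  x <- data.frame(
    site_id = sprintf("fs%05d", seq_len(n)),
    protein_ac = protein,
    conservation_level = sample(1:5, n, replace = TRUE),
    in_hotspot = stats::rbinom(n, 1L, 0.05),
    gold_confidence = stats::rbinom(n, 1L, 0.4),
    n_regulations = stats::rpois(n, 1.2),
    n_quantifications = stats::rpois(n, 8),
    in_domain = stats::rbinom(n, 1L, 0.4),
    in_region = stats::rbinom(n, 1L, 0.2),
    disorder = stats::rbeta(n, 2, 3),
    helix_prob = stats::rbeta(n, 2, 2),
    coil_prob = stats::rbeta(n, 2, 2),
    rsa = stats::rbeta(n, 2, 2),
    protein_length = unname(prot_len[protein]),
    at_interface = stats::rbinom(n, 1L, 0.15),
    site_other_ptms = stats::rbinom(n, 1L, 0.25),
    n_nearby_ptms = stats::rpois(n, 2),
    pathogenicity = stats::rbeta(n, 2, 5),
    stringsAsFactors = FALSE)
  # preprocessed design on complete data, used to define the planted model
  complete <- x
  z <- preprocess_features(complete)
  feats <- functional_score_features()
  Z <- as.matrix(z[, feats])
  w <- config$planted_weights[feats]
  eta <- drop(Z %*% w)
  target_rate <- 1 / (1 + config$class_imbalance)
  b0 <- stats::uniroot(function(b) mean(stats::plogis(b + eta)) - target_rate,
                       interval = c(-30, 10))$root
  bayes_prob <- stats::plogis(b0 + eta)
  x$label <- stats::rbinom(n, 1L, bayes_prob)
  # exercise the missingness rules on a small fraction of rows
  x$rsa[sample.int(n, round(0.02 * n))] <- NA_real_
  x$conservation_level[sample.int(n, round(0.10 * n))] <- NA_integer_
  list(table = x,
       truth = list(weights = w, intercept = b0,
                    bayes_prob = stats::setNames(bayes_prob, x$site_id)))
}

#' Generate an activity/abundance/ubi table with planted association classes
#'
#' Plants four site classes across tumour samples: truly activity-coupled
#' sites (ubi tracks activity, protein abundance independent),
#' abundance-confounded sites (activity and ubi both track abundance),
#' degradation-driven sites (ubi tracks activity but accumulates under
#' proteasome inhibition) and null sites (no association). Each class's fate
#' under the three-step association filter is known by construction.
#'
#' @param config a [sim_config()].
#' @param n_per_class sites planted per class (default 4).
#' @return list with `ubi`, `activity`, `abundance` matrices,
#'   `site2protein`, `proteasome_fc` and `truth` (class per site).
#' @export
gen_activity_table <- function(config, n_per_class = 4L) {
  rng <- local_rng(config$seed + 5L)
  on.exit(rng(), add = TRUE)
  n_s <- config$n_samples
  classes <- c("coupled", "confounded", "degradation", "null")
  n_sites <- n_per_class * length(classes)
  site_id <- sprintf("as%03d", seq_len(n_sites))
  prot_ac <- sprintf("AP%03d", seq_len(n_sites))
  cls <- rep(classes, each = n_per_class)
  ubi <- matrix(NA_real_, n_s, n_sites,
                dimnames = list(sprintf("sample%03d", seq_len(n_s)), site_id))
  activity <- matrix(NA_real_, n_s, n_sites,
                     dimnames = list(rownames(ubi), prot_ac))
  abundance <- matrix(NA_real_, n_s, n_sites,
                      dimnames = list(rownames(ubi), prot_ac))
  proteasome_fc <- stats::setNames(numeric(n_sites), site_id)
  for (i in seq_len(n_sites)) {
    noise <- function() stats::rnorm(n_s, sd = 0.5)
    if (cls[i] == "coupled") {
      act <- stats::rnorm(n_s)
      ub <- act + noise()
      ab <- stats::rnorm(n_s)
      proteasome_fc[i] <- -0.3
    } else if (cls[i] == "confounded") {
      ab <- stats::rnorm(n_s)
      act <- ab + noise()
      ub <- ab + noise()
      proteasome_fc[i] <- -0.3
    } else if (cls[i] == "degradation") {
      act <- stats::rnorm(n_s)
      ub <- act + noise()
      ab <- stats::rnorm(n_s)
      proteasome_fc[i] <- 0.5
    } else {
      act <- stats::rnorm(n_s)
      ub <- stats::rnorm(n_s)
      ab <- stats::rnorm(n_s)
      proteasome_fc[i] <- -0.1
    }
    ubi[, i] <- ub
    activity[, i] <- act
    abundance[, i] <- ab
  }
  list(ubi = ubi, activity = activity, abundance = abundance,
       site2protein = stats::setNames(prot_ac, site_id),
       proteasome_fc = proteasome_fc,
       truth = data.frame(site_id = site_id, class = cls))
}

#' Run the full synthetic pipeline and write every output to disk
#'
#' Generates all synthetic inputs for one seed, runs each analysis stage
#' (site catalog, conservation levels, hotspot detection, fold-change
#' aggregation/clustering/regulation, set tests, activity filter, functional
#' score) and writes the inputs and results as plain-text TSV/FASTA files
#' under `out_dir`. Byte-identical across runs with the same config.
#'
#' @param out_dir output directory (created if needed).
#' @param config a [sim_config()].
#' @return invisibly, the list of result objects.
#' @export
run_synthetic_pipeline <- function(out_dir, config = sim_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(out_dir, ...)

  psm <- gen_psm_table(config)
  write_tsv(psm$psms, fp("psms.tsv"))
  write_tsv(psm$truth, fp("psms_truth.tsv"))
  catalog <- build_site_catalog(psm$psms)
  write_tsv(catalog, fp("site_catalog.tsv"))

  orth <- gen_ortholog_groups(config)
  for (g in orth$groups) {
    write_ortholog_fasta(g, fp(paste0("alignment_", g$group_id, ".fasta")))
  }
  cons <- conservation_table(orth$groups, orth$human_sites,
                             orth$species_sites)
  write_tsv(cons, fp("conservation.tsv"))
  write_tsv(orth$truth, fp("conservation_truth.tsv"))

  dom <- gen_domain_alignments(config)
  hs <- detect_hotspots(dom$sets, seed = config$seed + 10L)
  write_tsv(as.data.frame(hs$regions), fp("hotspot_regions.tsv"))
  write_tsv(dom$truth, fp("hotspot_truth.tsv"))

  fcg <- gen_foldchange_matrix(config)
  m <- aggregate_fold_changes(fcg$fc)
  m <- filter_conditions(m, min_sites = 500L)
  groups_map <- stats::setNames(fcg$conditions$perturbation_group,
                                fcg$conditions$condition_id)
  reg <- flag_regulated(m, groups_map)
  write_tsv(reg, fp("regulation_features.tsv"))
  r <- condition_correlations(m, min_overlap = 50L)
  cl <- cluster_conditions(r, k = 4L)
  write_tsv(data.frame(condition_id = names(cl), cluster = unname(cl)),
            fp("condition_clusters.tsv"))
  sets <- split(fcg$truth$site_id, fcg$truth$group)
  st <- set_regulation_tests(m, sets, groups_map)
  write_tsv(st$tests, fp("set_tests.tsv"))
  write_tsv(fcg$truth, fp("regulated_truth.tsv"))

  act <- gen_activity_table(config)
  assoc <- activity_association_filter(act$ubi, act$activity, act$abundance,
                                       act$site2protein, act$proteasome_fc)
  write_tsv(assoc, fp("activity_associations.tsv"))
  write_tsv(act$truth, fp("activity_truth.tsv"))

  feat <- gen_feature_table(config)
  fit <- train_functional_score(feat$table, seed = config$seed + 20L)
  write_tsv(fit$scores, fp("functional_scores.tsv"))
  write_tsv(fit$weights, fp("feature_weights.tsv"))
  write_tsv(data.frame(feature = names(feat$truth$weights),
                       planted_weight = unname(feat$truth$weights)),
            fp("feature_weights_truth.tsv"))

  invisible(list(catalog = catalog, conservation = cons, hotspots = hs,
                 regulation = reg, clusters = cl, set_tests = st,
                 associations = assoc, score = fit))
}
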