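#' Collapse PSM-level localization evidence to a site probability
#'
#' Peptide-spectrum matches (PSMs) covering one ubiquitination site in one
#' dataset are collapsed in two steps. Each PSM carries a joint score
#' `s = localization_prob * psm_prob`; a PSM that covers the position but is
#' unmodified there contributes `s = 0` (encode it with `localization_prob = 0`).
#' Evidence is first reduced to the peptidoform level by taking the maximum
#' joint score within each peptidoform, then the site probability is the mean
#' of the peptidoform scores: the fraction of ubiquitination evidence over the
#' total covering evidence.
#'
#' @param psms data.frame with columns `peptidoform_id`, `localization_prob`,
#'   `psm_prob`, and optionally `protein_ac`, `site_position`, `dataset_id`
#'   (which must then be constant).
#' @return site probability in `[0, 1]`.
#' @examples
#' collapse_psms_to_site(data.frame(
#'   peptidoform_id = c("a", "b"),
#'   localization_prob = c(1, 0), psm_prob = c(1, 1)))  # 0.5
#' @export
collapse_psms_to_site <- function(psms) {
  if (is.null(psms) || nrow(psms) == 0L) {
    stop("no evidence: empty PSM set")
  }
  for (key in c("protein_ac", "site_position", "dataset_id")) {
    if (key %in% names(psms) && length(unique(psms[[key]])) > 1L) {
      stop("mixed keys: PSMs span more than one ", key)
    }
  }
  p <- psms$localization_prob
  q <- psms$psm_prob
  if (any(p < 0 | p > 1 | q < 0 | q > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  s <- p * q
  per_pf <- tapply(s, psms$peptidoform_id, max)
  mean(per_pf)
}

#' Estimate the false localization rate at a probability threshold
#'
#' Decoy amino-acid FLR: decoy (alanine) site placements that survive the
#' probability threshold estimate the number of false localizations among the
#' surviving target sites. The decoy count is scaled by `residue_ratio`, the
#' ratio of target-residue (Lys) to decoy-residue (Ala) frequency in the
#' searched database, and the ratio of scaled decoys to targets is clipped to
#' `[0, 1]`. With no surviving targets the FLR is 0 by convention.
#'
#' @param probabilities numeric site probabilities (targets and decoys mixed).
#' @param is_decoy logical, same length: decoy-alanine placements.
#' @param threshold probability threshold in `[0, 1]`; sites with probability
#'   `>= threshold` are counted.
#' @param residue_ratio positive scaling of the decoy count (default 1).
#' @return estimated FLR in `[0, 1]`.
#' @seealso [flr_curve()] for the monotonized per-site FLR assignment.
#' @export
estimate_flr <- function(probabilities, is_decoy, threshold,
                         residue_ratio = 1.0) {
  stopifnot(length(probabilities) == length(is_decoy))
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  if (residue_ratio <= 0) stop("residue_ratio must be > 0")
  keep <- probabilities >= threshold
  n_decoy <- sum(keep & is_decoy)
  n_target <- sum(keep & !is_decoy)
  if (n_target == 0L) return(0)
  min(1, max(0, n_decoy * residue_ratio / n_target))
}

#' Monotone FLR curve over probability thresholds
#'
#' Evaluates [estimate_flr()] at each threshold and enforces monotonicity
#' (q-value style): the FLR reported at a threshold is the minimum raw FLR at
#' that or any lower threshold, so the curve is non-increasing as the
#' threshold rises. Used to assign each target site the FLR at its own
#' probability.
#'
#' @inheritParams estimate_flr
#' @param thresholds numeric vector of thresholds (need not be sorted).
#' @return numeric vector of monotone FLRs, aligned with `thresholds`.
#' @export
flr_curve <- function(probabilities, is_decoy, thresholds,
                      residue_ratio = 1.0) {
  ord <- order(thresholds)
  raw <- vapply(thresholds[ord], function(t) {
    estimate_flr(probabilities, is_decoy, t, residue_ratio)
  }, numeric(1))
  # running minimum as the threshold increases: flr(t) = min_{t' <= t} raw(t')
  mono <- cummin(raw)
  out <- numeric(length(thresholds))
  out[ord] <- mono
  out
}

#' Assign a cross-dataset confidence tier from per-dataset FLRs
#'
#' Gold: at least two datasets below 1% FLR. Silver: exactly one dataset below
#' 1%. Bronze: none below 1% but at least one below 5%. Everything else
#' (including no evidence) is Unclassified.
#'
#' @param flrs numeric vector of per-dataset FLR values in `[0, 1]` for one
#'   site (one entry per dataset in which the site passed PSM FDR control).
#' @return one of `"Gold"`, `"Silver"`, `"Bronze"`, `"Unclassified"`.
#' @export
assign_tier <- function(flrs) {
  if (length(flrs) == 0L) return("Unclassified")
  if (any(flrs < 0 | flrs > 1)) stop("FLR values must lie in [0, 1]")
  n1 <- sum(flrs < 0.01)
  if (n1 >= 2L) return("Gold")
  if (n1 == 1L) return("Silver")
  if (any(flrs < 0.05)) return("Bronze")
  "Unclassified"
}

#' Remove peptide C-terminal ubiquitinated lysines
#'
#' Trypsin cannot cleave after a ubiquitinated lysine, so a diGly-modified Lys
#' reported at a peptide C-terminus is an artefact and is dropped. Row order
#' of the surviving records is preserved.
#'
#' @param psms data.frame with columns `residue` and `is_peptide_cterm`.
#' @return the filtered data.frame.
#' @export
filter_cterm_sites <- function(psms) {
  if (nrow(psms) == 0L) return(psms)
  drop <- psms$is_peptide_cterm & psms$residue == "K"
  psms[!drop, , drop = FALSE]
}

#' Resolve a shared peptide to a single protein accession
#'
#' A peptide mapping to several proteins is assigned to the first accession in
#' alphabetical order, under case-sensitive byte (C-locale) ordering for
#' reproducibility across platforms.
#'
#' @param protein_candidates character vector of candidate accessions.
#' @return single accession.
#' @export
resolve_shared_peptide <- function(protein_candidates) {
  if (length(protein_candidates) == 0L) stop("empty candidate set")
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(Sys.setlocale("LC_COLLATE", old), add = TRUE)
  Sys.setlocale("LC_COLLATE", "C")
  sort(unique(protein_candidates))[1L]
}

#' Collapse a PSM table to per-(site, dataset) evidence
#'
#' Applies [collapse_psms_to_site()] within every
#' (dataset, protein, position, decoy-status) group of a PSM table.
#'
#' @inheritParams build_site_catalog
#' @return data.frame with `dataset_id`, `protein_ac`, `site_position`,
#'   `residue`, `is_decoy`, `site_probability`.
#' @export
collapse_psm_table <- function(psms) {
  key <- interaction(psms$dataset_id, psms$protein_ac, psms$site_position,
                     psms$is_decoy_residue, drop = TRUE)
  idx <- split(seq_len(nrow(psms)), key)
  ev <- do.call(rbind, lapply(idx, function(i) {
    block <- psms[i, , drop = FALSE]
    data.frame(dataset_id = block$dataset_id[1L],
               protein_ac = block$protein_ac[1L],
               site_position = block$site_position[1L],
               residue = block$residue[1L],
               is_decoy = block$is_decoy_residue[1L],
               site_probability = collapse_psms_to_site(block))
  }))
  rownames(ev) <- NULL
  ev
}

#' Build the site catalog from a PSM table
#'
#' Runs the post-processing chain on a PSM-level table covering one or more
#' datasets: drops peptide C-terminal Lys records, resolves shared peptides to
#' one accession, collapses PSMs to per-(site, dataset) probabilities,
#' assigns each target site a per-dataset FLR from the decoy-alanine
#' competition (monotone in the site probability), and classifies every site
#' into Gold/Silver/Bronze/Unclassified tiers across datasets.
#'
#' @param psms data.frame with columns `dataset_id`, `peptidoform_id`,
#'   `protein_ac` (possibly `;`-separated for shared peptides),
#'   `site_position`, `residue`, `localization_prob`, `psm_prob`,
#'   `is_decoy_residue`, `is_peptide_cterm`.
#' @param residue_ratio decoy scaling passed to [flr_curve()].
#' @param flr_max sites whose best per-dataset FLR exceeds this are dropped
#'   from the catalog (default 0.05, the Bronze bound).
#' @return data.frame with one row per retained site: `protein_ac`,
#'   `site_position`, `residue`, `tier`, `n_datasets`, `best_flr`.
#' @export
build_site_catalog <- function(psms, residue_ratio = 1.0, flr_max = 0.05) {
  stopifnot(is.data.frame(psms))
  psms <- filter_cterm_sites(psms)
  if (nrow(psms) == 0L) {
    return(data.frame(protein_ac = character(), site_position = integer(),
                      residue = character(), tier = character(),
                      n_datasets = integer(), best_flr = numeric()))
  }
  psms$protein_ac <- vapply(strsplit(psms$protein_ac, ";", fixed = TRUE),
                            resolve_shared_peptide, character(1))

  ev <- collapse_psm_table(psms)

  # per-dataset decoy competition -> per-site FLR at the site's own probability
  ev_split <- split(ev, ev$dataset_id)
  ev <- do.call(rbind, lapply(ev_split, function(d) {
    d$flr <- flr_curve(d$site_probability, d$is_decoy,
                       thresholds = d$site_probability,
                       residue_ratio = residue_ratio)
    d
  }))
  targets <- ev[!ev$is_decoy, , drop = FALSE]

  site_key <- interaction(targets$protein_ac, targets$site_position,
                          drop = TRUE)
  out <- do.call(rbind, lapply(split(targets, site_key), function(s) {
    data.frame(protein_ac = s$protein_ac[1L],
               site_position = s$site_position[1L],
               residue = s$residue[1L],
               tier = assign_tier(s$flr),
               n_datasets = nrow(s),
               best_flr = min(s$flr))
  }))
  rownames(out) <- NULL
  out <- out[out$best_flr <= flr_max, , drop = FALSE]
  out[order(out$protein_ac, out$site_position), , drop = FALSE]
}
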