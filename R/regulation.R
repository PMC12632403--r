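#' Aggregate peptide-level fold-changes into a site x condition matrix
#'
#' Log2 fold-changes are averaged first across peptides mapping to the same
#' site within a replicate, then across technical/biological replicates of
#' the condition. Missing values are ignored at every averaging step.
#'
#' @param fc long-format data.frame with columns `site_id`, `condition_id`,
#'   `replicate`, `peptide_id`, `log2fc`.
#' @return numeric matrix, sites (rows, named) x conditions (columns, named),
#'   `NA` where a site was never quantified in a condition.
#' @export
aggregate_fold_changes <- function(fc) {
  need <- c("site_id", "condition_id", "replicate", "peptide_id", "log2fc")
  stopifnot(all(need %in% names(fc)))
  fc <- fc[!is.na(fc$log2fc), , drop = FALSE]
  # peptides -> (site, condition, replicate)
  rep_means <- stats::aggregate(
    log2fc ~ site_id + condition_id + replicate, data = fc, FUN = mean)
  # replicates -> (site, condition)
  site_means <- stats::aggregate(
    log2fc ~ site_id + condition_id, data = rep_means, FUN = mean)
  sites <- sort(unique(site_means$site_id))
  conds <- sort(unique(site_means$condition_id))
  m <- matrix(NA_real_, nrow = length(sites), ncol = length(conds),
              dimnames = list(sites, conds))
  m[cbind(match(site_means$site_id, sites),
          match(site_means$condition_id, conds))] <- site_means$log2fc
  m
}

#' Drop sparsely quantified conditions
#'
#' Removes every condition column with fewer than `min_sites` non-missing
#' values ("fewer than" is strict: a column with exactly `min_sites` values
#' is kept).
#'
#' @param m site x condition matrix.
#' @param min_sites minimum quantified sites per condition (default 500).
#' @return the filtered matrix; warns when every condition is dropped.
#' @export
filter_conditions <- function(m, min_sites = 500L) {
  if (ncol(m) == 0L) return(m)
  keep <- colSums(!is.na(m)) >= min_sites
  if (!any(keep)) warning("all conditions dropped by the quantification filter")
  m[, keep, drop = FALSE]
}

#' Pairwise Pearson correlations between conditions
#'
#' Correlations are computed on pairwise-complete site sets; pairs whose
#' overlap falls below `min_overlap` quantified sites are reported as `NA`,
#' as are pairs involving a constant column.
#'
#' @param m site x condition matrix.
#' @param min_overlap minimum shared non-missing sites per pair (default 100).
#' @return condition x condition correlation matrix (unit diagonal).
#' @export
condition_correlations <- function(m, min_overlap = 100L) {
  stopifnot(min_overlap >= 3L)
  suppressWarnings(r <- stats::cor(m, use = "pairwise.complete.obs",
                                   method = "pearson"))
  overlap <- crossprod(!is.na(m))
  r[overlap < min_overlap] <- NA_real_
  diag(r) <- 1
  r
}

#' Cluster conditions on correlation distance
#'
#' Hierarchical clustering (complete linkage) on the distance `1 - r`, with
#' the dendrogram cut into exactly `k` clusters.
#'
#' @param r condition correlation matrix (no `NA`s).
#' @param k number of clusters (default 4).
#' @return named integer vector of cluster labels.
#' @export
cluster_conditions <- function(r, k = 4L) {
  if (any(is.na(r))) stop("correlation matrix contains NA; increase overlap")
  if (ncol(r) < k) stop("fewer conditions than clusters")
  hc <- stats::hclust(stats::as.dist(1 - r), method = "complete")
  stats::cutree(hc, k = k)
}

#' Combine replicate conditions by median/IQR normalization
#'
#' Each column is centred on its median and scaled by its interquartile range
#' (quantiles by linear interpolation between order statistics), then mapped
#' back to a common scale: multiplied by the median of the column IQRs and
#' shifted by the median of the column medians. The normalized columns are
#' averaged element-wise, ignoring missing values. Columns with zero IQR are
#' excluded with a warning. A single column is returned unchanged (the two
#' affine maps cancel exactly).
#'
#' @param m sites x conditions matrix (>= 1 column).
#' @return numeric vector, one combined value per site (`NA` where no column
#'   had a value).
#' @export
combine_conditions <- function(m) {
  if (is.null(dim(m))) m <- matrix(m, ncol = 1L)
  if (ncol(m) == 0L) stop("need at least one column")
  if (ncol(m) == 1L) return(m[, 1L])
  meds <- apply(m, 2L, stats::median, na.rm = TRUE)
  iqrs <- apply(m, 2L, stats::IQR, na.rm = TRUE, type = 7)
  keep <- iqrs > 0
  if (!all(keep)) {
    warning(sum(!keep), " zero-IQR column(s) excluded from combination")
    if (!any(keep)) stop("no column with positive IQR")
    m <- m[, keep, drop = FALSE]
    meds <- meds[keep]
    iqrs <- iqrs[keep]
    if (ncol(m) == 1L) return(m[, 1L])
  }
  scale_to <- stats::median(iqrs)
  shift_to <- stats::median(meds)
  norm <- sweep(sweep(m, 2L, meds, "-"), 2L, iqrs, "/") * scale_to + shift_to
  rowMeans(norm, na.rm = TRUE)
}

#' Flag regulated sites and count regulations/quantifications
#'
#' Within each condition a site is regulated when its log2 fold-change lies
#' in the top or bottom `tail` fraction of that condition's non-missing
#' values (non-strict comparison against the linear-interpolation quantiles;
#' strict when the two quantiles coincide, so an all-equal column flags
#' nothing). Per site, `n_regulations` counts regulated conditions outside
#' `exclude_groups` (typically proteasome inhibition) and `n_quantifications`
#' counts all quantified conditions including them.
#'
#' @param m site x condition matrix.
#' @param condition_groups named character vector mapping condition ->
#'   perturbation group (names must cover `colnames(m)`); may be `NULL` when
#'   `exclude_groups` is empty.
#' @param tail tail fraction (default 0.05), in `(0, 0.5)`.
#' @param exclude_groups perturbation groups excluded from the regulation
#'   count (default `"proteasome_inhibition"`).
#' @return data.frame `site_id`, `n_regulations`, `n_quantifications`, plus
#'   the logical site x condition matrix as attribute `"flags"`.
#' @export
flag_regulated <- function(m, condition_groups = NULL, tail = 0.05,
                           exclude_groups = "proteasome_inhibition") {
  stopifnot(tail > 0, tail < 0.5)
  if (length(exclude_groups) > 0L && !is.null(condition_groups)) {
    stopifnot(all(colnames(m) %in% names(condition_groups)))
  }
  flags <- matrix(FALSE, nrow = nrow(m), ncol = ncol(m),
                  dimnames = dimnames(m))
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    ok <- !is.na(x)
    if (!any(ok)) next
    qlo <- stats::quantile(x[ok], tail, type = 7, names = FALSE)
    qhi <- stats::quantile(x[ok], 1 - tail, type = 7, names = FALSE)
    flags[, j] <- if (qhi > qlo) {
      ok & (x <= qlo | x >= qhi)
    } else {
      ok & (x < qlo | x > qhi)
    }
  }
  excluded <- if (is.null(condition_groups)) {
    rep(FALSE, ncol(m))
  } else {
    condition_groups[colnames(m)] %in% exclude_groups
  }
  out <- data.frame(
    site_id = if (is.null(rownames(m))) as.character(seq_len(nrow(m)))
              else rownames(m),
    n_regulations = rowSums(flags[, !excluded, drop = FALSE]),
    n_quantifications = rowSums(!is.na(m)))
  rownames(out) <- NULL
  attr(out, "flags") <- flags
  out
}

#' Competitive set-regulation test for one condition
#'
#' Tests whether a defined set of sites has systematically larger or smaller
#' log2 fold-changes than the remaining quantified sites of the same
#' condition, with a two-sided Wilcoxon rank-sum test (exact for small
#' untied samples, normal approximation with continuity correction
#' otherwise). The direction is the sign of the difference between the set's
#' mean rank and the overall mean rank.
#'
#' @param x named numeric vector of a condition's log2 fold-changes.
#' @param site_set character vector of set member names.
#' @param min_overlap minimum quantified set members (default 3).
#' @return list `p`, `direction` (+1/-1), `n_in`, `n_out`, or `NULL` when the
#'   quantified overlap is below `min_overlap` or no non-members remain.
#' @export
set_regulation_test <- function(x, site_set, min_overlap = 3L) {
  x <- x[!is.na(x)]
  inset <- names(x) %in% site_set
  n_in <- sum(inset)
  n_out <- sum(!inset)
  if (n_in < min_overlap || n_out == 0L) return(NULL)
  wt <- suppressWarnings(stats::wilcox.test(x[inset], x[!inset],
                                            alternative = "two.sided"))
  rk <- rank(x)
  direction <- if (mean(rk[inset]) >= mean(rk)) 1 else -1
  list(p = wt$p.value, direction = direction, n_in = n_in, n_out = n_out)
}

#' Set-regulation tests across conditions with BH and group averaging
#'
#' Runs [set_regulation_test()] for every (condition, set) pair, adjusts all
#' p-values jointly with Benjamini-Hochberg, and averages the signed
#' `-log10(p_adj)` within each perturbation group.
#'
#' @param m site x condition matrix.
#' @param sets named list of site-id vectors.
#' @param condition_groups named character vector condition -> group.
#' @param min_overlap passed to [set_regulation_test()].
#' @return list with `tests` (data.frame `condition`, `set`, `group`,
#'   `direction`, `p_raw`, `p_adj`, `signed_score`) and `group_scores`
#'   (data.frame `group`, `set`, `mean_signed_score`).
#' @export
set_regulation_tests <- function(m, sets, condition_groups,
                                 min_overlap = 3L) {
  stopifnot(all(colnames(m) %in% names(condition_groups)))
  rows <- list()
  for (cond in colnames(m)) {
    for (s in names(sets)) {
      res <- set_regulation_test(stats::setNames(m[, cond], rownames(m)),
                                 sets[[s]], min_overlap)
      if (is.null(res)) next
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, set = s,
        group = unname(condition_groups[cond]),
        direction = res$direction, p_raw = res$p)
    }
  }
  tests <- do.call(rbind, rows)
  if (is.null(tests)) {
    return(list(tests = data.frame(), group_scores = data.frame()))
  }
  tests$p_adj <- stats::p.adjust(tests$p_raw, "BH")
  tests$signed_score <- tests$direction * -log10(tests$p_adj)
  gs <- stats::aggregate(signed_score ~ group + set, data = tests, FUN = mean)
  names(gs)[names(gs) == "signed_score"] <- "mean_signed_score"
  list(tests = tests, group_scores = gs)
}

#' Activity-association filter for ubi-sites
#'
#' Retains ubi-sites whose abundance tracks the activity of their parent
#' protein while excluding degradation-driven and abundance-confounded
#' associations, in three steps: (1) keep sites whose Pearson correlation
#' with parent-protein activity has a Benjamini-Hochberg adjusted p < 0.05;
#' (2) remove sites whose mean log2 fold-change under proteasome inhibition
#' is positive (degradation signature); (3) for the positively correlated
#' survivors, regress parent-protein abundance out of both the site
#' abundance and the activity by ordinary least squares, re-correlate the
#' residuals, and remove sites whose unadjusted p >= 0.05. Associations with
#' fewer than `min_samples` complete sample pairs are skipped.
#'
#' @param ubi samples x sites matrix of ubi-site abundances.
#' @param activity samples x proteins matrix of activity estimates.
#' @param abundance samples x proteins matrix of protein abundances.
#' @param site2protein named character vector site -> parent protein.
#' @param proteasome_fc named numeric vector: per-site mean log2 fold-change
#'   under proteasome inhibition (`NA` treated as not up-regulated).
#' @param min_samples minimum complete pairs (default 3).
#' @return data.frame with one row per tested association: `site_id`,
#'   `protein_ac`, `r`, `p_raw`, `p_adj`, `step1_pass`, `step2_pass`,
#'   `step3_p`, `retained`.
#' @export
activity_association_filter <- function(ubi, activity, abundance,
                                        site2protein, proteasome_fc,
                                        min_samples = 3L) {
  stopifnot(identical(rownames(ubi), rownames(activity)),
            identical(rownames(ubi), rownames(abundance)))
  sites <- colnames(ubi)
  sites <- sites[sites %in% names(site2protein)]
  rows <- list()
  for (s in sites) {
    prot <- site2protein[[s]]
    if (!(prot %in% colnames(activity))) next
    u <- ubi[, s]
    a <- activity[, prot]
    ok <- !is.na(u) & !is.na(a)
    if (sum(ok) < min_samples) next
    ct <- stats::cor.test(u[ok], a[ok], method = "pearson")
    rows[[length(rows) + 1L]] <- data.frame(
      site_id = s, protein_ac = prot, r = unname(ct$estimate),
      p_raw = ct$p.value)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  out$p_adj <- stats::p.adjust(out$p_raw, "BH")
  out$step1_pass <- out$p_adj < 0.05
  fc <- proteasome_fc[out$site_id]
  out$step2_pass <- out$step1_pass & !(!is.na(fc) & fc > 0)
  out$step3_p <- NA_real_
  out$retained <- out$step2_pass
  for (i in which(out$step2_pass & out$r > 0)) {
    s <- out$site_id[i]
    prot <- out$protein_ac[i]
    u <- ubi[, s]
    a <- activity[, prot]
    b <- abundance[, prot]
    ok <- !is.na(u) & !is.na(a) & !is.na(b)
    if (sum(ok) < min_samples) next
    ru <- stats::resid(stats::lm(u[ok] ~ b[ok]))
    ra <- stats::resid(stats::lm(a[ok] ~ b[ok]))
    ct <- stats::cor.test(ru, ra, method = "pearson")
    out$step3_p[i] <- ct$p.value
    out$retained[i] <- ct$p.value < 0.05
  }
  rownames(out) <- NULL
  out
}
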