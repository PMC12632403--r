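test_that("PSM collapse averages peptidoform evidence over total coverage", {
  psm <- function(pf, loc, q = 1) {
    data.frame(peptidoform_id = pf, localization_prob = loc, psm_prob = q)
  }
  # certain evidence
  expect_equal(collapse_psms_to_site(
    psm(c("a", "b", "c"), c(1, 1, 1))), 1.0)
  # one modified, one covering-unmodified peptidoform
  expect_equal(collapse_psms_to_site(psm(c("a", "b"), c(1, 0))), 0.5)
  # two modified peptidoforms, mean of joint scores
  expect_equal(collapse_psms_to_site(psm(c("a", "b"), c(0.9, 0.5))), 0.7)
  # redundant PSMs of one peptidoform collapse by max before averaging
  expect_equal(collapse_psms_to_site(
    psm(c("a", "a", "b"), c(0.9, 0.6, 0.5))), 0.7)
  # joint score multiplies in the PSM probability
  expect_equal(collapse_psms_to_site(psm("a", 0.8, 0.5)), 0.4)
  expect_error(collapse_psms_to_site(
    data.frame(peptidoform_id = character(0),
               localization_prob = numeric(0), psm_prob = numeric(0))),
    "no evidence")
  bad <- data.frame(peptidoform_id = c("a", "b"), localization_prob = 1,
                    psm_prob = 1, dataset_id = c("d1", "d2"))
  expect_error(collapse_psms_to_site(bad), "mixed keys")
})

test_that("decoy-alanine FLR follows the scaled count ratio", {
  probs <- c(rep(0.99, 100), rep(0.99, 2))
  decoy <- c(rep(FALSE, 100), rep(TRUE, 2))
  expect_equal(estimate_flr(probs, decoy, 0.5), 0.02)
  expect_equal(estimate_flr(probs, decoy, 0.5, residue_ratio = 2), 0.04)
  # no decoys above threshold
  expect_equal(estimate_flr(c(0.9, 0.95), c(FALSE, FALSE), 0.5), 0)
  # no targets above threshold: 0 by convention
  expect_equal(estimate_flr(c(0.9, 0.3), c(TRUE, FALSE), 0.5), 0)
  # clipped at 1
  expect_equal(estimate_flr(c(0.9, 0.9, 0.9), c(TRUE, TRUE, FALSE), 0.5), 1)
  expect_error(estimate_flr(probs, decoy, 1.5), "threshold")
  expect_error(estimate_flr(probs, decoy, 0.5, residue_ratio = 0),
               "residue_ratio")
})

test_that("flr_curve is monotone non-increasing in the threshold", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 500
    probs <- c(runif(n, 0.5, 1), runif(n / 10, 0.5, 0.95))
    decoy <- c(rep(FALSE, n), rep(TRUE, n / 10))
    th <- sort(runif(50))
    flr <- flr_curve(probs, decoy, th)
    expect_true(all(diff(flr) <= 1e-12))
    # never exceeds the raw estimate at the same threshold
    raw <- vapply(th, function(t) estimate_flr(probs, decoy, t), numeric(1))
    expect_true(all(flr <= raw + 1e-12))
  }
})

test_that("tier assignment matches the rules and handles edge cases", {
  expect_equal(assign_tier(c(0.005, 0.008)), "Gold")
  expect_equal(assign_tier(c(0.005, 0.03)), "Silver")
  expect_equal(assign_tier(c(0.03, 0.045)), "Bronze")
  expect_equal(assign_tier(0.2), "Unclassified")
  expect_equal(assign_tier(numeric(0)), "Unclassified")
  expect_error(assign_tier(c(0.5, 1.2)), "FLR")
})

test_that("peptide C-terminal ubiquitinated lysines are removed", {
  psms <- data.frame(residue = c("K", "K", "R"),
                     is_peptide_cterm = c(TRUE, FALSE, TRUE),
                     id = 1:3)
  out <- filter_cterm_sites(psms)
  expect_equal(out$id, c(2L, 3L))  # internal K and C-term R kept, in order
  empty <- psms[0, ]
  expect_identical(nrow(filter_cterm_sites(empty)), 0L)
})

test_that("shared peptides resolve to the byte-wise first accession", {
  expect_equal(resolve_shared_peptide(c("Q9Y2X3", "P04637")), "P04637")
  expect_equal(resolve_shared_peptide("P1"), "P1")
  expect_equal(resolve_shared_peptide(c("P10", "P2")), "P10")
  expect_error(resolve_shared_peptide(character(0)), "empty")
})

test_that("site catalog integrates collapse, FLR and tiering", {
  mk <- function(ds, prot, pos, loc, decoy = FALSE) {
    data.frame(dataset_id = ds, peptidoform_id = paste0(prot, pos, ds),
               protein_ac = prot, site_position = pos, residue = if (decoy) "A" else "K",
               localization_prob = loc, psm_prob = 1,
               is_decoy_residue = decoy, is_peptide_cterm = FALSE)
  }
  # two datasets, clean high-probability site + many clean fillers, no decoys
  psms <- rbind(
    mk("d1", "P1", 10, 0.99), mk("d2", "P1", 10, 0.99),
    do.call(rbind, lapply(1:20, function(i) mk("d1", "P2", i * 3, 0.98))),
    do.call(rbind, lapply(1:20, function(i) mk("d2", "P2", i * 3, 0.98))))
  out <- build_site_catalog(psms)
  expect_true(all(out$tier == "Gold"))
  expect_equal(out$n_datasets[out$protein_ac == "P1"], 2L)
  # shared peptide resolves alphabetically
  shared <- mk("d1", "B1;A2", 5, 0.99)
  out2 <- build_site_catalog(rbind(psms, shared))
  expect_true("A2" %in% out2$protein_ac)
  expect_false(any(grepl(";", out2$protein_ac)))
})

test_that("enrichment test matches the hypergeometric tail and skip rules", {
  bg <- sprintf("g%04d", 1:500)
  fg <- bg[1:50]
  # equal fractions: fold 1, no enrichment signal
  term <- c(fg[1:5], bg[51:95])  # 5/50 in fg, 50/500 in bg
  res <- enrichment_test(fg, bg, term)
  expect_equal(res$fold_enrichment, 1.0)
  expect_gte(res$p, 0.5)
  # p equals the exact tail for a handful of tables
  set.seed(42)
  for (i in 1:20) {
    term_i <- sample(bg, sample(20:200, 1))
    res_i <- enrichment_test(fg, bg, term_i, min_term_size = 0L)
    if (is.null(res_i)) next
    k <- sum(term_i %in% fg)
    expect_equal(res_i$p, oracle_hyper_tail(k, length(term_i), 500, 50),
                 tolerance = 1e-12)
  }
  # below min_term_size: skipped
  expect_null(enrichment_test(fg, bg, c(fg[1:2], bg[300:320])))
  # no background members: skipped
  expect_null(enrichment_test(fg, bg, "not_a_gene"))
  expect_error(enrichment_test(c(fg, "zz"), bg, term), "subset")
})

test_that("BH over terms preserves order and never shrinks p-values", {
  set.seed(7)
  bg <- sprintf("g%04d", 1:400)
  fg <- sample(bg, 60)
  terms <- lapply(1:30, function(i) sample(bg, sample(30:150, 1)))
  names(terms) <- sprintf("T%02d", 1:30)
  ns <- rep(c("BP", "MF"), length.out = 30)
  tab <- enrichment_table(fg, bg, terms, namespaces = ns, min_term_size = 1L)
  expect_true(all(tab$p_adj >= tab$p - 1e-15))
  for (s in split(tab, tab$namespace)) {
    o <- order(s$p)
    expect_true(all(diff(s$p_adj[o]) >= -1e-15))
  }
})
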