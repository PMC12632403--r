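test_that("fold-change aggregation averages peptides then replicates", {
  fc <- data.frame(site_id = "s1", condition_id = "c1", replicate = "r1",
                   peptide_id = "p1", log2fc = 1.5)
  expect_equal(unname(aggregate_fold_changes(fc)["s1", "c1"]), 1.5)
  fc2 <- data.frame(site_id = "s1", condition_id = "c1", replicate = "r1",
                    peptide_id = c("p1", "p2"), log2fc = c(1, 3))
  expect_equal(unname(aggregate_fold_changes(fc2)["s1", "c1"]), 2.0)
  # missing replicate values are ignored, not propagated
  fc3 <- data.frame(site_id = "s1", condition_id = "c1",
                    replicate = c("r1", "r2"), peptide_id = "p1",
                    log2fc = c(2, NA))
  expect_equal(unname(aggregate_fold_changes(fc3)["s1", "c1"]), 2.0)
  # replicate means weight equally even with unequal peptide counts
  fc4 <- data.frame(site_id = "s1", condition_id = "c1",
                    replicate = c("r1", "r1", "r2"),
                    peptide_id = c("p1", "p2", "p1"), log2fc = c(1, 3, 4))
  expect_equal(unname(aggregate_fold_changes(fc4)["s1", "c1"]), 3.0)
})

test_that("condition filter drops columns under 500 quantified sites", {
  m <- matrix(NA_real_, 600, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  m[1:499, 1] <- 0
  m[1:500, 2] <- 0
  m[1:600, 3] <- 0
  out <- filter_conditions(m)
  expect_identical(colnames(out), c("b", "c"))  # 499 dropped, 500 kept
  expect_warning(filter_conditions(m[, 1, drop = FALSE]), "dropped")
  expect_identical(ncol(filter_conditions(m[, 0])), 0L)
})

test_that("condition correlations respect overlap and sign", {
  set.seed(2)
  x <- rnorm(200)
  m <- cbind(a = x, b = -x, c = rnorm(200))
  r <- condition_correlations(m, min_overlap = 10)
  expect_equal(r["a", "a"], 1)
  expect_equal(r["a", "b"], -1)
  # insufficient overlap is masked
  m2 <- m
  m2[1:195, "c"] <- NA
  r2 <- condition_correlations(m2, min_overlap = 10)
  expect_true(is.na(r2["a", "c"]))
  # independent columns rarely exceed |r| = 0.1 at n = 1000
  set.seed(3)
  hits <- replicate(100, {
    abs(cor(rnorm(1000), rnorm(1000))) < 0.1
  })
  expect_gte(mean(hits), 0.95)
})

test_that("clustering on correlation distance yields k non-empty clusters", {
  sim <- gen_foldchange_matrix(sim_config(seed = 4))
  m <- filter_conditions(aggregate_fold_changes(sim$fc))
  r <- condition_correlations(m, min_overlap = 50)
  cl <- cluster_conditions(r, k = 4)
  expect_equal(length(unique(cl)), 4L)
  # conditions of one perturbation group co-cluster (shared latent response)
  grp <- setNames(sim$conditions$perturbation_group,
                  sim$conditions$condition_id)
  expect_true(all(tapply(cl, grp[names(cl)],
                         function(z) length(unique(z))) == 1L))
  expect_error(cluster_conditions(r[1:3, 1:3], k = 4), "fewer conditions")
})

test_that("combine_conditions is exact on one column and affine-invariant", {
  set.seed(5)
  x <- rnorm(100)
  expect_identical(combine_conditions(matrix(x, ncol = 1)), x)  # bit-level
  two <- cbind(x, x)
  expect_equal(unname(combine_conditions(two)), x)
  # a positive affine transform of a column changes nothing after scaling
  aff <- cbind(a = x, b = 2 * x + 5)
  direct <- combine_conditions(aff)
  med <- median(x); iqr <- IQR(x)
  meds <- c(med, 2 * med + 5); iqrs <- c(iqr, 2 * iqr)
  manual <- ((x - med) / iqr) * median(iqrs) + median(meds)
  expect_equal(unname(direct), manual)
  # zero-IQR columns are excluded with a warning
  expect_warning(out <- combine_conditions(cbind(x, rep(1, 100))), "zero-IQR")
  expect_equal(unname(out), x)
})

test_that("regulation flags follow the 5% tails and exclusion bookkeeping", {
  m <- matrix(1:100, ncol = 1, dimnames = list(sprintf("s%03d", 1:100), "c1"))
  out <- flag_regulated(m, c(c1 = "dna_damage"))
  flags <- attr(out, "flags")
  expect_equal(sum(flags), 10L)
  expect_true(all(flags[c(1:5, 96:100), 1]))
  # degenerate all-equal column flags nothing
  m0 <- matrix(rep(2, 50), ncol = 1, dimnames = list(NULL, "c1"))
  expect_equal(sum(attr(flag_regulated(m0, c(c1 = "x")), "flags")), 0L)
  # counts: quantified in 7 conditions, flagged in 3, one excluded
  set.seed(6)
  m7 <- matrix(rnorm(100 * 7), 100, 7,
               dimnames = list(sprintf("s%03d", 1:100), paste0("c", 1:7)))
  m7["s001", ] <- c(99, 99, 99, 0, 0, 0, 0)  # flagged high in c1-c3
  groups <- setNames(c("proteasome_inhibition", rep("dna_damage", 6)),
                     paste0("c", 1:7))
  out7 <- flag_regulated(m7, groups)
  row1 <- out7[out7$site_id == "s001", ]
  expect_equal(row1$n_quantifications, 7)
  expect_equal(row1$n_regulations, 2)  # c1 flagged but excluded
})

test_that("tie-free complete data flags exactly ceiling(tail*n) per side", {
  set.seed(8)
  for (n in c(40L, 100L, 1003L)) {
    m <- matrix(sample(rnorm(n)), ncol = 1, dimnames = list(NULL, "c"))
    out <- flag_regulated(m, c(c = "x"))
    expect_equal(sum(attr(out, "flags")), 2L * ceiling(0.05 * n))
  }
})

test_that("set test matches exact rank-sum enumeration and tie behavior", {
  # identical distributions in an exact tie configuration
  x <- setNames(c(1, 2, 3, 1, 2, 3), paste0("s", 1:6))
  res <- set_regulation_test(x, paste0("s", 1:3))
  expect_equal(res$p, 1.0)
  # top-3 of 10: exact tail from exhaustive enumeration
  set.seed(9)
  vals <- setNames(sample(rnorm(10)), paste0("s", 1:10))
  top3 <- names(sort(vals, decreasing = TRUE))[1:3]
  res2 <- set_regulation_test(vals, top3)
  expect_equal(res2$p, oracle_ranksum_p(vals[top3], vals[setdiff(names(vals),
                                                                 top3)]))
  expect_equal(res2$direction, 1)
  # random untied sets agree with the enumeration oracle at n <= 12
  for (i in 1:25) {
    n <- sample(6:12, 1)
    k <- sample(3:(n - 2), 1)
    v <- setNames(sample(rnorm(n)), paste0("g", seq_len(n)))
    inset <- sample(names(v), k)
    got <- set_regulation_test(v, inset)
    expect_equal(got$p,
                 oracle_ranksum_p(v[inset], v[setdiff(names(v), inset)]),
                 tolerance = 1e-12)
  }
  # too few quantified members: skipped
  expect_null(set_regulation_test(x, paste0("s", 1:2)))
})

test_that("set tests aggregate into BH-adjusted signed group scores", {
  sim <- gen_foldchange_matrix(sim_config(seed = 10))
  m <- filter_conditions(aggregate_fold_changes(sim$fc))
  grp <- setNames(sim$conditions$perturbation_group,
                  sim$conditions$condition_id)
  sets <- split(sim$truth$site_id, sim$truth$group)
  res <- set_regulation_tests(m, sets, grp)
  expect_true(all(res$tests$p_adj >= res$tests$p_raw - 1e-15))
  # group score is the arithmetic mean of the member signed scores
  one <- res$tests[res$tests$group == "dna_damage" &
                     res$tests$set == "dna_damage", ]
  got <- res$group_scores[res$group_scores$group == "dna_damage" &
                            res$group_scores$set == "dna_damage",
                          "mean_signed_score"]
  expect_equal(got, mean(one$signed_score))
  # each planted set is up-regulated in its own group
  own <- res$tests[res$tests$group == res$tests$set, ]
  expect_true(all(own$direction == 1))
  expect_true(all(own$p_adj < 0.05))
})

test_that("activity filter applies its three steps as designed", {
  sim <- gen_activity_table(sim_config(seed = 12))
  res <- activity_association_filter(sim$ubi, sim$activity, sim$abundance,
                                     sim$site2protein, sim$proteasome_fc)
  res <- merge(res, sim$truth, by = "site_id")
  # null sites never pass step 1; degradation sites die at step 2
  expect_true(all(!res$step1_pass[res$class == "null"]))
  expect_true(all(res$step1_pass[res$class == "degradation"]))
  expect_true(all(!res$step2_pass[res$class == "degradation"]))
  # truly coupled sites survive everything
  expect_true(all(res$retained[res$class == "coupled"]))
  # insufficient samples are skipped entirely
  tiny <- activity_association_filter(sim$ubi[1:2, , drop = FALSE],
                                      sim$activity[1:2, , drop = FALSE],
                                      sim$abundance[1:2, , drop = FALSE],
                                      sim$site2protein, sim$proteasome_fc)
  expect_equal(nrow(tiny), 0L)
})

test_that("step-3 residualization is inert when abundance is independent", {
  agree <- 0L
  n_runs <- 50L
  for (seed in seq_len(n_runs)) {
    set.seed(seed + 300)
    n <- 60
    act <- rnorm(n)
    ubi <- act * 0.8 + rnorm(n)
    abund <- rnorm(n)  # independent of both
    with_step3 <- {
      ru <- resid(lm(ubi ~ abund)); ra <- resid(lm(act ~ abund))
      cor.test(ru, ra)$p.value < 0.05
    }
    without <- cor.test(ubi, act)$p.value < 0.05
    if (with_step3 == without) agree <- agree + 1L
  }
  expect_gte(agree / n_runs, 0.95)
})
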