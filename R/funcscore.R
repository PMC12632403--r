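#' Canonical feature set of the functional score
#'
#' The 16 site-level features integrated by the model: evolutionary
#' (conservation_level, in_hotspot), identification (gold_confidence),
#' regulation (n_regulations, n_quantifications), sequence context
#' (in_domain, in_region, protein_length), structure (disorder, helix_prob,
#' coil_prob, rsa), interaction (at_interface), PTM crosstalk
#' (site_other_ptms, n_nearby_ptms) and variant pathogenicity
#' (pathogenicity).
#'
#' @return character vector of the 16 feature names.
#' @export
functional_score_features <- function() {
  c("conservation_level", "in_hotspot", "gold_confidence", "n_regulations",
    "n_quantifications", "in_domain", "in_region", "disorder", "helix_prob",
    "coil_prob", "rsa", "protein_length", "at_interface", "site_other_ptms",
    "n_nearby_ptms", "pathogenicity")
}

# features log-transformed towards gaussian shape before scaling
log_features <- c("pathogenicity", "n_nearby_ptms", "n_regulations",
                  "n_quantifications", "protein_length")

#' Preprocess the site feature table
#'
#' Heavy-tailed features (pathogenicity, n_nearby_ptms, n_regulations,
#' n_quantifications, protein_length) are log-transformed; among them, a
#' feature containing any zero uses `log1p`, the others the natural log.
#' Missing conservation levels are imputed with the overall mean (computed on
#' the full table before any row is dropped, and cached for prediction-time
#' reuse); rows missing any other feature are removed. All features are then
#' centred to mean 0 and scaled to sd 1. The fitted transform parameters
#' travel as the `"ubifunc_prep"` attribute; a table already carrying it is
#' returned unchanged, and passing `params` applies a previously fitted
#' transform to new data.
#'
#' @param x data.frame containing the 16 feature columns plus any metadata
#'   (`site_id`, `protein_ac`, `label`, ...).
#' @param features feature column names (default
#'   [functional_score_features()]).
#' @param params optional fitted transform (the `"ubifunc_prep"` attribute of
#'   an earlier result) to apply instead of fitting.
#' @return the processed data.frame, metadata preserved, with attribute
#'   `"ubifunc_prep"`.
#' @export
preprocess_features <- function(x, features = functional_score_features(),
                                params = NULL) {
  if (!is.null(attr(x, "ubifunc_prep"))) return(x)
  stopifnot(all(features %in% names(x)))
  fit <- is.null(params)
  if (fit) {
    params <- list(features = features)
    params$impute_conservation <- mean(x$conservation_level, na.rm = TRUE)
    params$log_fun <- vapply(intersect(log_features, features), function(f) {
      if (any(x[[f]] == 0, na.rm = TRUE)) "log1p" else "log"
    }, character(1))
  }
  x$conservation_level[is.na(x$conservation_level)] <-
    params$impute_conservation
  other <- setdiff(params$features, "conservation_level")
  keep <- stats::complete.cases(x[, other, drop = FALSE])
  x <- x[keep, , drop = FALSE]
  for (f in names(params$log_fun)) {
    x[[f]] <- if (params$log_fun[[f]] == "log1p") log1p(x[[f]])
              else log(x[[f]])
  }
  if (fit) {
    params$center <- vapply(params$features, function(f) mean(x[[f]]),
                            numeric(1))
    params$scale <- vapply(params$features,
                           function(f) stats::sd(x[[f]]), numeric(1))
    zero_var <- params$scale == 0 | is.na(params$scale)
    if (any(zero_var)) {
      stop("zero-variance feature(s) after filtering: ",
           paste(params$features[zero_var], collapse = ", "))
    }
  }
  for (f in params$features) {
    x[[f]] <- (x[[f]] - params$center[[f]]) / params$scale[[f]]
  }
  attr(x, "ubifunc_prep") <- params
  x
}

#' Remove a protein's sites from training data
#'
#' Used to drop XRCC5 (UniProt P13010), whose 19 jointly-mutated annotated
#' sites would dominate the small positive class; its sites still receive
#' predicted scores.
#'
#' @param x feature data.frame with `protein_ac`.
#' @param protein_ac accession to exclude (default `"P13010"`).
#' @return the table without that protein's rows.
#' @export
exclude_training_protein <- function(x, protein_ac = "P13010") {
  x[x$protein_ac != protein_ac, , drop = FALSE]
}

#' Protein-grouped, positive-stratified cross-validation plan
#'
#' Builds `repeats` independent partitions of the rows into `k` folds such
#' that all sites of one protein land in the same fold (no protein-level
#' leakage) and fold positive counts stay as balanced as the grouping
#' allows: proteins are sorted by positive-site count (descending) and
#' greedily assigned to the fold currently lightest in positives, ties
#' broken by a seeded shuffle; zero-positive proteins then fill the fold
#' currently lightest in rows.
#'
#' @param x data.frame with `protein_ac` and logical/0-1 `label`.
#' @param k folds per repeat (default 5).
#' @param repeats independent repeats (default 5).
#' @param seed integer seed.
#' @return integer matrix, rows of `x` x `repeats`, entries in `1..k`.
#' @export
build_fold_plan <- function(x, k = 5L, repeats = 5L, seed = 1L) {
  lab <- as.logical(x$label)
  pos_per_prot <- tapply(lab, x$protein_ac, sum)
  if (sum(pos_per_prot > 0) < k) {
    stop("fewer positive-bearing proteins than folds")
  }
  rows_per_prot <- table(x$protein_ac)
  prots <- names(pos_per_prot)
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  plan <- matrix(NA_integer_, nrow = nrow(x), ncol = repeats)
  for (r in seq_len(repeats)) {
    shuffled <- sample(prots)
    ord <- shuffled[order(pos_per_prot[shuffled], decreasing = TRUE)]
    fold_pos <- numeric(k)
    fold_rows <- numeric(k)
    assign_fold <- integer(length(ord))
    names(assign_fold) <- ord
    for (p in ord) {
      f <- if (pos_per_prot[[p]] > 0) which.min(fold_pos)
           else which.min(fold_rows)
      assign_fold[[p]] <- f
      fold_pos[f] <- fold_pos[f] + pos_per_prot[[p]]
      fold_rows[f] <- fold_rows[f] + rows_per_prot[[p]]
    }
    plan[, r] <- assign_fold[x$protein_ac]
  }
  plan
}

#' Class-weighted logistic regression via Newton/IRLS
#'
#' Maximizes the class-weighted log-likelihood of the logistic model, each
#' row weighted `N / (2 * N_class)` so both classes contribute equally. A
#' small ridge penalty on the non-intercept coefficients keeps the optimum
#' finite under complete separation. Convergence when the gradient max-norm
#' falls below `tol`.
#'
#' @param X numeric design matrix (no intercept column).
#' @param y logical/0-1 response; both classes must be present.
#' @param lambda ridge penalty (default 1e-6; set 0 for the plain fit).
#' @param max_iter Newton iteration cap (default 200).
#' @param tol gradient max-norm tolerance (default 1e-8).
#' @return list with `coef` (named, including `(Intercept)`), `converged`,
#'   `iterations`, class `"ubifunc_logit"`.
#' @export
fit_weighted_logistic <- function(X, y, lambda = 1e-6, max_iter = 200L,
                                  tol = 1e-8) {
  X <- as.matrix(X)
  y <- as.numeric(as.logical(y))
  if (length(unique(y)) < 2L) stop("both classes must be present")
  n <- length(y)
  w <- ifelse(y == 1, n / (2 * sum(y == 1)), n / (2 * sum(y == 0)))
  Xi <- cbind(`(Intercept)` = 1, X)
  p_ <- ncol(Xi)
  pen <- c(0, rep(lambda, p_ - 1L))  # intercept unpenalized
  beta <- numeric(p_)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(Xi %*% beta)
    mu <- stats::plogis(eta)
    grad <- drop(crossprod(Xi, w * (y - mu))) - pen * beta
    if (max(abs(grad)) < tol) {
      converged <- TRUE
      break
    }
    wirls <- w * mu * (1 - mu)
    H <- crossprod(Xi, Xi * wirls) + diag(pen, p_)
    step <- solve(H, grad)
    # halve the step until the penalized objective does not decrease
    obj <- function(b) {
      e <- drop(Xi %*% b)
      sum(w * (y * e - log1p(exp(e)))) - sum(pen * b^2) / 2
    }
    f0 <- obj(beta)
    sc <- 1
    repeat {
      cand <- beta + sc * step
      if (obj(cand) >= f0 || sc < 1e-8) break
      sc <- sc / 2
    }
    beta <- beta + sc * step
  }
  structure(list(coef = stats::setNames(beta, colnames(Xi)),
                 converged = converged, iterations = iter,
                 lambda = lambda),
            class = "ubifunc_logit")
}

#' @export
predict.ubifunc_logit <- function(object, newdata, ...) {
  Xi <- cbind(1, as.matrix(newdata))
  stats::plogis(drop(Xi %*% object$coef))
}

#' Median-aggregate an ensemble of logistic models into functional scores
#'
#' Every model scores every site; the functional score is the per-site
#' median of the ensemble probabilities, and per-feature weight means and
#' standard deviations summarize the ensemble's coefficients.
#'
#' @param models list of [fit_weighted_logistic()] fits (25 by default).
#' @param X design matrix of all sites to score.
#' @param n_models required ensemble size (default 25; set `NA` to accept
#'   any).
#' @return list with `scores` (per-site median), `per_model` (sites x models
#'   probability matrix) and `weights` (data.frame `feature`, `mean`, `sd`).
#' @export
score_ensemble <- function(models, X, n_models = 25L) {
  if (!is.na(n_models) && length(models) != n_models) {
    stop("expected ", n_models, " models, got ", length(models))
  }
  per_model <- vapply(models, function(mod) predict(mod, X),
                      numeric(nrow(X)))
  coefs <- vapply(models, function(mod) mod$coef,
                  numeric(length(models[[1L]]$coef)))
  if (is.null(rownames(coefs))) {
    rownames(coefs) <- c("(Intercept)", paste0("w", seq_len(nrow(coefs) - 1L)))
  }
  weights <- data.frame(feature = rownames(coefs),
                        mean = rowMeans(coefs),
                        sd = apply(coefs, 1L, stats::sd))
  rownames(weights) <- NULL
  list(scores = apply(per_model, 1L, stats::median),
       per_model = per_model, weights = weights)
}

#' Train the functional-score ensemble and score all sites
#'
#' Preprocesses the feature table, removes the excluded protein from
#' training, builds the protein-grouped fold plan (`repeats x k` splits),
#' fits one class-weighted logistic model per training set, and
#' median-aggregates all models' probabilities into per-site functional
#' scores.
#'
#' @param x raw feature data.frame with `site_id`, `protein_ac`, `label` and
#'   the 16 features.
#' @param k,repeats,seed passed to [build_fold_plan()].
#' @param lambda passed to [fit_weighted_logistic()].
#' @param exclude_protein training exclusion (default `"P13010"`; `NULL` to
#'   keep all).
#' @return list with `scores` (data.frame `site_id`, `protein_ac`, `label`,
#'   `functional_score`), `weights`, `models`, `fold_plan`, `prepared`.
#' @export
train_functional_score <- function(x, k = 5L, repeats = 5L, seed = 1L,
                                   lambda = 1e-6,
                                   exclude_protein = "P13010") {
  prep <- preprocess_features(x)
  train_tab <- prep
  if (!is.null(exclude_protein)) {
    train_tab <- exclude_training_protein(train_tab, exclude_protein)
  }
  features <- attr(prep, "ubifunc_prep")$features
  plan <- build_fold_plan(train_tab, k = k, repeats = repeats, seed = seed)
  models <- list()
  for (r in seq_len(repeats)) {
    for (f in seq_len(k)) {
      tr <- plan[, r] != f
      models[[length(models) + 1L]] <- fit_weighted_logistic(
        as.matrix(train_tab[tr, features, drop = FALSE]),
        train_tab$label[tr], lambda = lambda)
    }
  }
  ens <- score_ensemble(models, as.matrix(prep[, features, drop = FALSE]),
                        n_models = k * repeats)
  scores <- data.frame(site_id = prep$site_id, protein_ac = prep$protein_ac,
                       label = prep$label, functional_score = ens$scores)
  list(scores = scores, weights = ens$weights, models = models,
       fold_plan = plan, prepared = prep)
}

#' Rank-based ROC AUC
#'
#' Probability that a random positive outranks a random negative, with tied
#' pairs credited 0.5 (the Wilcoxon/Mann-Whitney estimator).
#'
#' @param scores numeric predictions.
#' @param labels logical/0-1 truth.
#' @return AUC in `[0, 1]`; `NA` if either class is absent.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Estimate generalization AUC of the architecture by negative subsampling
#'
#' One grouped train-test split plan of `k` folds; within each split,
#' `n_subsamples` random negative subsamples are drawn at `subsample_ratio`
#' times the positive count (all training positives kept), a model is fitted
#' on each subsample and evaluated by ROC AUC on the untouched held-out
#' fold, yielding `k * n_subsamples` AUC values. Held-out folds lacking a
#' class yield `NA` AUCs, excluded from the mean with a warning.
#'
#' @inheritParams train_functional_score
#' @param subsample_ratio negatives per positive in each subsample
#'   (default 10).
#' @param n_subsamples subsamples per split (default 5).
#' @return list with `auc` (data.frame `split`, `subsample`, `auc`) and
#'   `mean_auc`.
#' @export
evaluate_architecture <- function(x, subsample_ratio = 10L, n_subsamples = 5L,
                                  k = 5L, seed = 1L, lambda = 1e-6,
                                  exclude_protein = "P13010") {
  prep <- preprocess_features(x)
  if (!is.null(exclude_protein)) {
    prep <- exclude_training_protein(prep, exclude_protein)
  }
  features <- attr(prep, "ubifunc_prep")$features
  plan <- build_fold_plan(prep, k = k, repeats = 1L, seed = seed)[, 1L]
  rng <- local_rng(seed + 1L)
  on.exit(rng(), add = TRUE)
  lab <- as.logical(prep$label)
  out <- list()
  for (f in seq_len(k)) {
    tr_idx <- which(plan != f)
    te_idx <- which(plan == f)
    pos <- tr_idx[lab[tr_idx]]
    neg <- tr_idx[!lab[tr_idx]]
    n_draw <- min(length(neg), subsample_ratio * length(pos))
    for (s in seq_len(n_subsamples)) {
      sub <- c(pos, sample(neg, n_draw))
      fit <- fit_weighted_logistic(
        as.matrix(prep[sub, features, drop = FALSE]), lab[sub],
        lambda = lambda)
      pred <- predict(fit, as.matrix(prep[te_idx, features, drop = FALSE]))
      out[[length(out) + 1L]] <- data.frame(
        split = f, subsample = s, auc = roc_auc(pred, lab[te_idx]))
    }
  }
  auc <- do.call(rbind, out)
  if (any(is.na(auc$auc))) {
    warning("held-out fold(s) with a single class: ",
            sum(is.na(auc$auc)), " AUC value(s) undefined and excluded")
  }
  list(auc = auc, mean_auc = mean(auc$auc, na.rm = TRUE))
}
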