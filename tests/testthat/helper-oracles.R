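# Independent oracles used by unit and acceptance tests. Each is written as
# a direct transcription or brute-force enumeration, deliberately sharing no
# code with the implementation it checks.

# literal transcription of the tier rules
oracle_tier <- function(flrs) {
  below1 <- 0
  below5 <- 0
  for (v in flrs) {
    if (v < 0.01) below1 <- below1 + 1
    if (v < 0.05) below5 <- below5 + 1
  }
  if (below1 >= 2) "Gold"
  else if (below1 == 1) "Silver"
  else if (below5 >= 1) "Bronze"
  else "Unclassified"
}

# literal transcription of the conservation-level rules (scalar)
oracle_level <- function(cons, rodent, distant) {
  if (rodent && distant) return(5L)
  if (rodent) return(4L)
  if (is.na(cons)) return(NA_integer_)
  if (cons < 0.10) 1L
  else if (cons <= 0.50) 2L
  else 3L
}

# hypergeometric upper-tail P(X >= k) by direct log-choose summation
oracle_hyper_tail <- function(k, n_term_bg, n_bg, n_fg) {
  hi <- min(n_term_bg, n_fg)
  if (k > hi) return(0)
  i <- k:hi
  sum(exp(lchoose(n_term_bg, i) + lchoose(n_bg - n_term_bg, n_fg - i) -
            lchoose(n_bg, n_fg)))
}

# exact two-sided rank-sum p by exhaustive enumeration of set assignments
oracle_ranksum_p <- function(x_in, x_out) {
  x <- c(x_in, x_out)
  n <- length(x)
  m <- length(x_in)
  rk <- rank(x)
  w_obs <- sum(rk[seq_len(m)])
  combos <- utils::combn(n, m)
  w_all <- apply(combos, 2L, function(idx) sum(rk[idx]))
  p_lo <- mean(w_all <= w_obs)
  p_hi <- mean(w_all >= w_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# brute-force window recount straight from the definition
oracle_window_counts <- function(set, window = 5L) {
  half <- (window - 1L) %/% 2L
  vapply(seq_len(set$width), function(i) {
    lo <- max(1L, i - half)
    hi <- min(set$width, i + half)
    sum(set$marks$column >= lo & set$marks$column <= hi) / (hi - lo + 1L)
  }, numeric(1))
}

# brute-force AUC by concordant-pair counting with 0.5 tie credit
oracle_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  if (length(pos) == 0L || length(neg) == 0L) return(NA_real_)
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# independent maximizer of the class-weighted ridge-penalized log-likelihood
oracle_logistic <- function(X, y, lambda = 1e-6) {
  X <- cbind(1, as.matrix(X))
  y <- as.numeric(y)
  n <- length(y)
  w <- ifelse(y == 1, n / (2 * sum(y == 1)), n / (2 * sum(y == 0)))
  pen <- c(0, rep(lambda, ncol(X) - 1L))
  negll <- function(b) {
    eta <- drop(X %*% b)
    -sum(w * (y * eta - log1p(exp(eta)))) + sum(pen * b^2) / 2
  }
  grad <- function(b) {
    mu <- stats::plogis(drop(X %*% b))
    -drop(crossprod(X, w * (y - mu))) + pen * b
  }
  stats::optim(numeric(ncol(X)), negll, grad, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))$par
}
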