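#' One-sided annotation enrichment test
#'
#' Tests over-representation of an annotation term in a foreground set
#' relative to a background set with a one-sided Fisher's exact test
#' (hypergeometric upper tail). The fold enrichment is the ratio of the
#' term's foreground fraction to its background fraction. Terms with fewer
#' than `min_term_size` foreground members are skipped, as are terms with no
#' background members (fold undefined).
#'
#' @param foreground character vector, subset of `background`.
#' @param background character vector (the tested universe).
#' @param term_members character vector of the term's members.
#' @param min_term_size minimum foreground overlap required to test the term
#'   (default 3).
#' @return list with `fold_enrichment`, `p`, and the 2x2 counts, or `NULL`
#'   when the term is skipped.
#' @export
enrichment_test <- function(foreground, background, term_members,
                            min_term_size = 3L) {
  foreground <- unique(foreground)
  background <- unique(background)
  term_members <- unique(term_members)
  if (!all(foreground %in% background)) {
    stop("foreground must be a subset of background")
  }
  k_fg <- sum(term_members %in% foreground)
  k_bg <- sum(term_members %in% background)
  if (k_bg == 0L || k_fg < min_term_size) return(NULL)
  n_fg <- length(foreground)
  n_bg <- length(background)
  fold <- (k_fg / n_fg) / (k_bg / n_bg)
  # hypergeometric upper tail: P(X >= k_fg) drawing n_fg from n_bg with
  # k_bg term members in the urn
  p <- stats::phyper(k_fg - 1L, k_bg, n_bg - k_bg, n_fg, lower.tail = FALSE)
  list(fold_enrichment = fold, p = p,
       counts = c(term_fg = k_fg, fg = n_fg, term_bg = k_bg, bg = n_bg))
}

#' Enrichment over a collection of terms with BH adjustment per namespace
#'
#' Applies [enrichment_test()] to every term and adjusts p-values with the
#' Benjamini-Hochberg procedure separately within each ontology namespace
#' (e.g. GO BP/MF/CC), mirroring standard ontology-enrichment practice.
#'
#' @inheritParams enrichment_test
#' @param terms named list of term member vectors.
#' @param namespaces optional character vector (same length as `terms`)
#'   giving each term's ontology namespace; default puts all terms in one.
#' @return data.frame with `term`, `namespace`, `fold_enrichment`, `p`,
#'   `p_adj`, sorted by `p_adj`; skipped terms are absent.
#' @export
enrichment_table <- function(foreground, background, terms,
                             namespaces = NULL, min_term_size = 3L) {
  stopifnot(is.list(terms), !is.null(names(terms)))
  if (is.null(namespaces)) namespaces <- rep("all", length(terms))
  stopifnot(length(namespaces) == length(terms))
  rows <- lapply(seq_along(terms), function(i) {
    res <- enrichment_test(foreground, background, terms[[i]], min_term_size)
    if (is.null(res)) return(NULL)
    data.frame(term = names(terms)[i], namespace = namespaces[i],
               fold_enrichment = res$fold_enrichment, p = res$p)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(term = character(), namespace = character(),
                      fold_enrichment = numeric(), p = numeric(),
                      p_adj = numeric()))
  }
  out$p_adj <- stats::ave(out$p, out$namespace,
                          FUN = function(p) stats::p.adjust(p, "BH"))
  out[order(out$p_adj, out$p), , drop = FALSE]
}
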