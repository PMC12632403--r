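#' Construct a domain alignment set
#'
#' Aligned instances of one protein domain with per-instance ubiquitination
#' marks given in alignment coordinates. Every mark must sit on a lysine of
#' its instance.
#'
#' @param domain_id identifier.
#' @param instance_id character vector of instance identifiers.
#' @param aligned character vector of aligned sequences (gaps `-`), equal
#'   lengths.
#' @param marks data.frame with columns `instance` (index or id) and `column`
#'   (1-based alignment column) of observed ubi-sites.
#' @param representative_index instance used for residue-coordinate reporting
#'   (default 1).
#' @return object of class `domain_alignment_set`.
#' @export
domain_alignment_set <- function(domain_id, instance_id, aligned, marks,
                                 representative_index = 1L) {
  stopifnot(length(instance_id) == length(aligned))
  widths <- nchar(aligned)
  if (length(unique(widths)) != 1L) {
    stop("aligned sequences must all have equal length")
  }
  L <- widths[1L]
  if (is.character(marks$instance)) {
    marks$instance <- match(marks$instance, instance_id)
  }
  marks$instance <- as.integer(marks$instance)
  marks$column <- as.integer(marks$column)
  if (nrow(marks) > 0L) {
    if (any(is.na(marks$instance)) || any(marks$instance < 1L) ||
        any(marks$instance > length(instance_id))) {
      stop("mark instance out of range")
    }
    if (any(marks$column < 1L) || any(marks$column > L)) {
      stop("mark column out of range")
    }
    res <- substring(aligned[marks$instance], marks$column, marks$column)
    if (any(res != "K")) stop("every ubi mark must sit on a lysine")
  }
  stopifnot(representative_index >= 1L,
            representative_index <= length(instance_id))
  structure(list(domain_id = domain_id, instance_id = instance_id,
                 aligned = aligned, marks = marks, width = L,
                 representative_index = as.integer(representative_index)),
            class = "domain_alignment_set")
}

#' @export
print.domain_alignment_set <- function(x, ...) {
  cat("domain_alignment_set", x$domain_id, ":", length(x$instance_id),
      "instances, width", x$width, ",", nrow(x$marks), "ubi marks\n")
  invisible(x)
}

#' Is a domain eligible for hotspot analysis?
#'
#' Requires at least 15 aligned instances and at least 50 ubi marks in total.
#'
#' @param set a [domain_alignment_set()].
#' @param min_instances,min_marks eligibility thresholds.
#' @return logical.
#' @export
check_domain_eligibility <- function(set, min_instances = 15L,
                                     min_marks = 50L) {
  length(set$instance_id) >= min_instances && nrow(set$marks) >= min_marks
}

#' Rolling-window average of ubi marks per alignment column
#'
#' For each column the marks falling in a centered window (size 5 by default,
#' truncated at the alignment ends) are counted and divided by the number of
#' columns actually inside the window, giving an average number of ubi-sites
#' per position.
#'
#' @param set a [domain_alignment_set()].
#' @param window odd window size (default 5).
#' @return numeric vector of length `width`.
#' @export
window_counts <- function(set, window = 5L) {
  if (window < 1L || window %% 2L == 0L) stop("window must be odd and >= 1")
  L <- set$width
  if (window > L) stop("window larger than alignment")
  per_col <- tabulate(set$marks$column, nbins = L)
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, per_col))
  i <- seq_len(L)
  lo <- pmax(1L, i - half)
  hi <- pmin(L, i + half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Lysine-constrained permutation null for the window profile
#'
#' Each permutation reassigns every instance's marks uniformly without
#' replacement among that instance's lysine columns, preserving the
#' per-instance mark count and the alignment's lysine landscape, then the
#' rolling-window profile is recomputed. Per column the median and standard
#' deviation over permutations are returned. Set `global = TRUE` to instead
#' pool all marks and sample among all lysine positions of the alignment.
#'
#' @param set a [domain_alignment_set()].
#' @param n_perm number of permutations (default 100).
#' @param seed integer seed for the permutation stream.
#' @param window passed to [window_counts()].
#' @param global sample lysines globally rather than per instance.
#' @return list with numeric vectors `null_median` and `null_sd` (length
#'   `width`) and the `n_perm` x `width` matrix `profiles`.
#' @export
permutation_null <- function(set, n_perm = 100L, seed = 1L, window = 5L,
                             global = FALSE) {
  if (n_perm < 2L) stop("n_perm must be >= 2")
  lys_cols <- lapply(set$aligned, function(s) {
    which(strsplit(s, "", fixed = TRUE)[[1L]] == "K")
  })
  mark_counts <- tabulate(set$marks$instance, nbins = length(set$instance_id))
  for (i in seq_along(mark_counts)) {
    if (mark_counts[i] > length(lys_cols[[i]])) {
      stop("instance ", set$instance_id[i],
           " has more marks than lysines; cannot permute")
    }
  }
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  profiles <- matrix(0, nrow = n_perm, ncol = set$width)
  for (p in seq_len(n_perm)) {
    if (global) {
      pool <- do.call(rbind, lapply(seq_along(lys_cols), function(i) {
        if (length(lys_cols[[i]]) == 0L) return(NULL)
        cbind(i, lys_cols[[i]])
      }))
      pick <- sample.int(nrow(pool), sum(mark_counts))
      perm_marks <- data.frame(instance = pool[pick, 1L],
                               column = pool[pick, 2L])
    } else {
      perm_marks <- do.call(rbind, lapply(seq_along(mark_counts), function(i) {
        m <- mark_counts[i]
        if (m == 0L) return(NULL)
        ks <- lys_cols[[i]]
        data.frame(instance = i,
                   column = ks[sample.int(length(ks), m)])
      }))
    }
    # permutation invariants: mark count preserved, every mark on a lysine
    stopifnot(nrow(perm_marks) == sum(mark_counts),
              all(mapply(function(i, j) j %in% lys_cols[[i]],
                         perm_marks$instance, perm_marks$column)))
    perm_set <- set
    perm_set$marks <- perm_marks
    profiles[p, ] <- window_counts(perm_set, window)
  }
  list(null_median = apply(profiles, 2L, stats::median),
       null_sd = apply(profiles, 2L, stats::sd),
       profiles = profiles)
}

#' Per-column z-scores and one-sided p-values against the permutation null
#'
#' `z = (observed - null_median) / null_sd`; p-values come from the standard
#' normal survival function, so only enrichment over the null is considered.
#' Degenerate columns (`null_sd == 0`) get `z = 0` when the observation
#' equals the null median, `+Inf` (p = 0) when it exceeds it and `-Inf`
#' (p = 1) when below.
#'
#' @param observed_avg observed window profile ([window_counts()]).
#' @param null_median,null_sd permutation summaries ([permutation_null()]).
#' @return data.frame with columns `z`, `p`.
#' @export
column_pvalues <- function(observed_avg, null_median, null_sd) {
  stopifnot(length(observed_avg) == length(null_median),
            length(observed_avg) == length(null_sd))
  z <- (observed_avg - null_median) / null_sd
  deg <- null_sd == 0
  z[deg] <- sign(observed_avg[deg] - null_median[deg]) * Inf
  z[deg & observed_avg == null_median] <- 0
  data.frame(z = z, p = stats::pnorm(z, lower.tail = FALSE))
}

#' Call hotspot regions from per-column p-values
#'
#' A column is significant when its p-value passes a global Bonferroni bound
#' (`p < alpha / n_tests`) and its observed window average exceeds the effect
#' cutoff (strictly `> effect_min`). Maximal runs of contiguous significant
#' columns are merged into regions, each region is extended by `extend`
#' columns on both sides (clipped to the alignment), and overlapping
#' extended regions are merged.
#'
#' @param p per-column p-values.
#' @param observed_avg per-column window averages.
#' @param alpha family-wise error target (default 0.01).
#' @param effect_min minimum window average (default 2 ubi-sites/position).
#' @param extend columns added on each side (default 2).
#' @param n_tests total number of columns tested across all eligible domains
#'   in the run (global Bonferroni denominator); defaults to `length(p)`.
#' @return data.frame `start_col`, `end_col` (inclusive, 1-based), possibly
#'   empty.
#' @export
call_hotspots <- function(p, observed_avg, alpha = 0.01, effect_min = 2.0,
                          extend = 2L, n_tests = length(p)) {
  stopifnot(length(p) == length(observed_avg), n_tests >= 1L)
  L <- length(p)
  sig <- p < alpha / n_tests & observed_avg > effect_min
  if (!any(sig)) {
    return(data.frame(start_col = integer(), end_col = integer()))
  }
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start_col = starts[r$values], end_col = ends[r$values])
  runs$start_col <- pmax(1L, runs$start_col - extend)
  runs$end_col <- pmin(L, runs$end_col + extend)
  merged <- runs[1L, , drop = FALSE]
  for (i in seq_len(nrow(runs))[-1L]) {
    last <- nrow(merged)
    if (runs$start_col[i] <= merged$end_col[last] + 0L) {
      merged$end_col[last] <- max(merged$end_col[last], runs$end_col[i])
    } else {
      merged <- rbind(merged, runs[i, ])
    }
  }
  rownames(merged) <- NULL
  merged
}

#' Map a hotspot region onto the representative instance's residues
#'
#' Alignment columns are converted to ungapped residue positions of the
#' representative instance. A boundary column gapped in the representative
#' contracts inward to the nearest flanking residue; a region entirely gapped
#' in the representative yields an empty interval with a warning.
#'
#' @param set a [domain_alignment_set()].
#' @param start_col,end_col region bounds in alignment columns.
#' @return list `rep_start`, `rep_end` (1-based residue positions), or both
#'   `NA` for an empty interval.
#' @export
map_region_to_representative <- function(set, start_col, end_col) {
  stopifnot(start_col >= 1L, end_col <= set$width, start_col <= end_col)
  rep_seq <- strsplit(set$aligned[set$representative_index], "",
                      fixed = TRUE)[[1L]]
  is_res <- rep_seq != "-"
  res_index <- cumsum(is_res)            # residue number at/before column
  cols_in <- seq.int(start_col, end_col)
  if (!any(is_res[cols_in])) {
    warning("region entirely gapped in representative; empty interval")
    return(list(rep_start = NA_integer_, rep_end = NA_integer_))
  }
  first_res_col <- cols_in[which(is_res[cols_in])[1L]]
  last_res_col <- cols_in[rev(which(is_res[cols_in]))[1L]]
  list(rep_start = res_index[first_res_col], rep_end = res_index[last_res_col])
}

#' Hotspot detection across a collection of domain alignment sets
#'
#' Filters domains for eligibility, computes observed window profiles and
#' lysine-constrained permutation nulls, converts to p-values, applies the
#' global Bonferroni correction over all columns of all eligible domains, and
#' calls, merges and extends hotspot regions, mapping each onto the domain's
#' representative instance.
#'
#' @param sets list of [domain_alignment_set()] objects.
#' @param n_perm,seed,window passed to [permutation_null()].
#' @param alpha,effect_min,extend passed to [call_hotspots()].
#' @param min_instances,min_marks passed to [check_domain_eligibility()].
#' @return list with `regions` (data.frame `domain_id`, `start_col`,
#'   `end_col`, `rep_start`, `rep_end`, `min_p_bonf`, `max_observed_avg`),
#'   `profiles` (per-domain data.frames of column statistics) and `n_tests`.
#' @export
detect_hotspots <- function(sets, n_perm = 100L, seed = 1L, window = 5L,
                            alpha = 0.01, effect_min = 2.0, extend = 2L,
                            min_instances = 15L, min_marks = 50L) {
  eligible <- Filter(function(s) {
    check_domain_eligibility(s, min_instances, min_marks)
  }, sets)
  if (length(eligible) == 0L) {
    return(list(regions = data.frame(), profiles = list(), n_tests = 0L))
  }
  n_tests <- sum(vapply(eligible, function(s) s$width, numeric(1)))
  profiles <- list()
  regions <- list()
  for (k in seq_along(eligible)) {
    set <- eligible[[k]]
    obs <- window_counts(set, window)
    null <- permutation_null(set, n_perm = n_perm, seed = seed + k - 1L,
                             window = window)
    pv <- column_pvalues(obs, null$null_median, null$null_sd)
    prof <- data.frame(domain_id = set$domain_id,
                       column = seq_len(set$width),
                       observed_avg = obs,
                       null_median = null$null_median,
                       null_sd = null$null_sd,
                       z = pv$z, p = pv$p,
                       p_bonferroni = pmin(1, pv$p * n_tests))
    profiles[[set$domain_id]] <- prof
    reg <- call_hotspots(pv$p, obs, alpha = alpha, effect_min = effect_min,
                         extend = extend, n_tests = n_tests)
    if (nrow(reg) > 0L) {
      reg$domain_id <- set$domain_id
      rep_pos <- lapply(seq_len(nrow(reg)), function(i) {
        map_region_to_representative(set, reg$start_col[i], reg$end_col[i])
      })
      reg$rep_start <- vapply(rep_pos, function(x) x$rep_start, integer(1))
      reg$rep_end <- vapply(rep_pos, function(x) x$rep_end, integer(1))
      reg$min_p_bonf <- vapply(seq_len(nrow(reg)), function(i) {
        min(prof$p_bonferroni[reg$start_col[i]:reg$end_col[i]])
      }, numeric(1))
      reg$max_observed_avg <- vapply(seq_len(nrow(reg)), function(i) {
        max(prof$observed_avg[reg$start_col[i]:reg$end_col[i]])
      }, numeric(1))
      regions[[length(regions) + 1L]] <- reg
    }
  }
  regions <- if (length(regions)) do.call(rbind, regions) else data.frame()
  if (nrow(regions) > 0L) {
    regions <- regions[, c("domain_id", "start_col", "end_col", "rep_start",
                           "rep_end", "min_p_bonf", "max_observed_avg")]
    rownames(regions) <- NULL
  }
  list(regions = regions, profiles = profiles, n_tests = n_tests)
}
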