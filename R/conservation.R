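#' Construct an orthologue alignment group
#'
#' Bundles one orthologue group's aligned sequences (with `-` gaps) and
#' identifies the single human member. All sequences must have the same
#' aligned length.
#'
#' @param group_id identifier.
#' @param species_id character vector of species identifiers.
#' @param protein_ac character vector of accessions, same length.
#' @param aligned character vector of aligned sequences (gaps as `-`).
#' @param human_species identifier of the human species (default
#'   `"hsapiens"`); exactly one member must carry it.
#' @return object of class `ortholog_group`.
#' @export
ortholog_group <- function(group_id, species_id, protein_ac, aligned,
                           human_species = "hsapiens") {
  stopifnot(length(species_id) == length(protein_ac),
            length(species_id) == length(aligned))
  widths <- nchar(aligned)
  if (length(unique(widths)) != 1L) {
    stop("aligned sequences must all have equal length")
  }
  hi <- which(species_id == human_species)
  if (length(hi) != 1L) stop("group must contain exactly one human member")
  structure(list(group_id = group_id, species_id = species_id,
                 protein_ac = protein_ac, aligned = aligned,
                 human_index = hi, width = widths[1L]),
            class = "ortholog_group")
}

#' @export
print.ortholog_group <- function(x, ...) {
  cat("ortholog_group", x$group_id, ":", length(x$species_id),
      "members, alignment width", x$width, "\n")
  invisible(x)
}

#' Map an ungapped protein position to its alignment column
#'
#' @param group an [ortholog_group()].
#' @param species_id member species.
#' @param protein_position 1-based position in the ungapped sequence.
#' @return 1-based alignment column index.
#' @export
map_site_to_column <- function(group, species_id, protein_position) {
  i <- match(species_id, group$species_id)
  if (is.na(i)) stop("species not in group: ", species_id)
  chars <- strsplit(group$aligned[i], "", fixed = TRUE)[[1L]]
  residue_cols <- which(chars != "-")
  if (protein_position < 1L || protein_position > length(residue_cols)) {
    stop("position ", protein_position, " beyond ungapped length ",
         length(residue_cols))
  }
  residue_cols[protein_position]
}

#' Map an alignment column back to an ungapped protein position
#'
#' Inverse of [map_site_to_column()]; errors if the member is gapped at the
#' column.
#'
#' @inheritParams map_site_to_column
#' @param column 1-based alignment column.
#' @return 1-based ungapped position.
#' @export
column_to_position <- function(group, species_id, column) {
  i <- match(species_id, group$species_id)
  if (is.na(i)) stop("species not in group: ", species_id)
  if (column < 1L || column > group$width) stop("column out of range")
  chars <- strsplit(group$aligned[i], "", fixed = TRUE)[[1L]]
  if (chars[column] == "-") stop("member is gapped at column ", column)
  sum(chars[seq_len(column)] != "-")
}

#' Lysine conservation at an alignment column
#'
#' Fraction of non-human members carrying lysine at the column. Gaps are not
#' residues: members gapped at the column are excluded from the denominator,
#' and the value is `NA` when every non-human member is gapped. Set
#' `count_gaps = TRUE` to treat gaps as non-lysine residues instead.
#'
#' @param group an [ortholog_group()].
#' @param column 1-based alignment column.
#' @param count_gaps include gapped members in the denominator (default
#'   `FALSE`).
#' @return fraction in `[0, 1]`, or `NA` if no non-human member has a residue
#'   at the column.
#' @export
lysine_conservation <- function(group, column, count_gaps = FALSE) {
  if (column < 1L || column > group$width) stop("column out of range")
  res <- vapply(group$aligned[-group$human_index],
                function(s) substr(s, column, column), character(1))
  if (!count_gaps) res <- res[res != "-"]
  if (length(res) == 0L) return(NA_real_)
  mean(res == "K")
}

#' Assign an evolutionary conservation level (1-5) to a human ubi-site
#'
#' Detection evidence dominates: level 5 when ubiquitination of the
#' orthologous position is detected both in a rodent (mouse/rat) and in a
#' distant species (chicken, fly, worm or yeast); level 4 when detected in a
#' rodent only. Without rodent detection the level follows the lysine
#' conservation fraction `c`: level 1 if `c < 0.10`, level 2 if
#' `0.10 <= c <= 0.50`, level 3 if `c > 0.50`. Sites with undefined `c`
#' (fully gapped column) and no rodent detection are unassigned (`NA`).
#' Detection only in a distant species without rodent support is not covered
#' by the rules; such sites fall back to the conservation-based levels 1-3
#' and are flagged via the `fallback` attribute (with a warning).
#'
#' @param lys_conservation numeric `c` in `[0, 1]` or `NA`; vectorized.
#' @param group2_detected logical: detected in mouse or rat.
#' @param group3_detected logical: detected in chicken, fly, worm or yeast.
#' @param warn warn on the uncovered distant-only case (default `TRUE`).
#' @return integer vector of levels 1-5 (`NA` where unassigned), with a
#'   logical `fallback` attribute marking distant-only sites.
#' @export
assign_level <- function(lys_conservation, group2_detected, group3_detected,
                         warn = TRUE) {
  n <- length(lys_conservation)
  stopifnot(length(group2_detected) == n, length(group3_detected) == n)
  level <- rep(NA_integer_, n)
  level[group2_detected & group3_detected] <- 5L
  level[group2_detected & !group3_detected] <- 4L
  open <- !group2_detected
  c_ <- lys_conservation
  level[open & !is.na(c_) & c_ < 0.10] <- 1L
  level[open & !is.na(c_) & c_ >= 0.10 & c_ <= 0.50] <- 2L
  level[open & !is.na(c_) & c_ > 0.50] <- 3L
  fallback <- open & group3_detected
  if (warn && any(fallback)) {
    warning(sum(fallback), " site(s) detected in a distant species without ",
            "rodent support; levelled by lysine conservation (fallback)")
  }
  attr(level, "fallback") <- fallback
  level
}

#' Species groups used by the conservation rules
#'
#' Group 2 are the rodents; group 3 are the distant species with usable
#' ubiquitin proteomics evidence. Horse, frog and zebrafish contribute to the
#' alignments only.
#' @return named list of species-id vectors.
#' @export
conservation_species_groups <- function() {
  list(group2 = c("mmusculus", "rnorvegicus"),
       group3 = c("ggallus", "dmelanogaster", "celegans", "scerevisiae"))
}

#' Score conservation levels for human ubi-sites across orthologue groups
#'
#' For each human site: maps the position to its alignment column, computes
#' the lysine conservation among non-human members, looks up cross-species
#' ubiquitination detections at the same column, and assigns the level with
#' [assign_level()]. A non-human detection counts when that species has a
#' reported ubi-site whose mapped column equals the human site's column.
#'
#' @param groups list of [ortholog_group()] objects.
#' @param human_sites data.frame `protein_ac`, `site_position` of human
#'   ubi-sites.
#' @param species_sites data.frame `species_id`, `protein_ac`,
#'   `site_position` of non-human ubi-site detections.
#' @return data.frame `protein_ac`, `site_position`, `column`,
#'   `lysine_conservation`, `group2_detected`, `group3_detected`, `level`,
#'   `fallback`. Human sites on proteins absent from every group are omitted.
#' @export
conservation_table <- function(groups, human_sites, species_sites) {
  grp_defs <- conservation_species_groups()
  by_protein <- list()
  for (g in groups) {
    hp <- g$protein_ac[g$human_index]
    by_protein[[hp]] <- g
  }
  rows <- lapply(seq_len(nrow(human_sites)), function(i) {
    ac <- human_sites$protein_ac[i]
    pos <- human_sites$site_position[i]
    g <- by_protein[[ac]]
    if (is.null(g)) return(NULL)
    human_sp <- g$species_id[g$human_index]
    col <- map_site_to_column(g, human_sp, pos)
    cons <- lysine_conservation(g, col)
    detected_species <- character(0)
    for (j in seq_along(g$species_id)) {
      if (j == g$human_index) next
      sp <- g$species_id[j]
      hits <- species_sites[species_sites$species_id == sp &
                              species_sites$protein_ac == g$protein_ac[j], ,
                            drop = FALSE]
      if (nrow(hits) == 0L) next
      cols <- vapply(hits$site_position, function(p) {
        map_site_to_column(g, sp, p)
      }, numeric(1))
      if (col %in% cols) detected_species <- c(detected_species, sp)
    }
    data.frame(protein_ac = ac, site_position = pos, column = col,
               lysine_conservation = cons,
               group2_detected = any(detected_species %in% grp_defs$group2),
               group3_detected = any(detected_species %in% grp_defs$group3))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(protein_ac = character(), site_position = integer(),
                      column = integer(), lysine_conservation = numeric(),
                      group2_detected = logical(), group3_detected = logical(),
                      level = integer(), fallback = logical()))
  }
  lev <- assign_level(out$lysine_conservation, out$group2_detected,
                      out$group3_detected)
  out$level <- as.integer(lev)
  out$fallback <- attr(lev, "fallback")
  rownames(out) <- NULL
  out
}

#' Read an aligned FASTA file into an ortholog_group
#'
#' Headers must follow `>species_id|protein_ac`.
#'
#' @param path aligned FASTA file.
#' @param group_id identifier (default the file name without extension).
#' @inheritParams ortholog_group
#' @return an [ortholog_group()].
#' @export
read_ortholog_fasta <- function(path, group_id = NULL,
                                human_species = "hsapiens") {
  seqs <- Biostrings::readAAStringSet(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  if (is.null(group_id)) {
    group_id <- sub("\\.[^.]*$", "", basename(path))
  }
  ortholog_group(group_id,
                 species_id = vapply(parts, `[`, character(1), 1L),
                 protein_ac = vapply(parts, `[`, character(1), 2L),
                 aligned = unname(as.character(seqs)),
                 human_species = human_species)
}

#' Write an ortholog_group as aligned FASTA
#'
#' @param group an [ortholog_group()].
#' @param path output file.
#' @export
write_ortholog_fasta <- function(group, path) {
  seqs <- Biostrings::AAStringSet(group$aligned)
  names(seqs) <- paste(group$species_id, group$protein_ac, sep = "|")
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}
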