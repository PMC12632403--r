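#' Scoped RNG seeding
#'
#' Seeds the generator for a reproducible block without disturbing the
#' caller's RNG state. Returns a restore function to be called (typically via
#' `on.exit`) when the block ends.
#'
#' @param seed integer seed.
#' @return zero-argument restore function.
#' @keywords internal
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
    invisible(NULL)
  }
}

#' Write a data.frame as TSV
#'
#' Plain tab-separated output with a header, no quoting and no row names;
#' the on-disk format used by every pipeline stage.
#'
#' @param x data.frame.
#' @param path output file.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path input file.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}
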