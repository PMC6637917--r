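#' Run code with a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `expr` and restores the previous
#' RNG state afterwards, so library internals never perturb a user's stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single non-missing number")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-stage seed from a global seed
#'
#' Each pipeline stage draws from its own substream so that regenerating one
#' stage alone reproduces its output. Kept below 2^31 - 1.
#'
#' @param seed global integer seed.
#' @param stage small non-negative integer identifying the stage.
#' @keywords internal
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 1000 + stage) %% .Machine$integer.max)
}

#' Reverse complement of a DNA string
#'
#' @param x character scalar over A/C/G/T/N (case-insensitive).
#' @return reverse-complemented uppercase string.
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Write a data frame as TSV with a reproducible metadata header
#'
#' Header lines start with `#` and carry package version, seed and
#' parameters but never timestamps, so identical runs are byte-identical.
#'
#' @param df data frame.
#' @param path output path.
#' @param meta named list of scalar metadata values.
#' @keywords internal
write_tsv_meta <- function(df, path, meta = list()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# topoclust %s",
                     as.character(utils::packageVersion("topoclust"))), con)
  for (k in names(meta)) {
    writeLines(sprintf("# %s: %s", k, paste(meta[[k]], collapse = ",")), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_meta()]
#' @param path file path.
#' @keywords internal
read_tsv_meta <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
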