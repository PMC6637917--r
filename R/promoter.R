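#' Extract the 960-bp promoter window of a gene
#'
#' The window spans 750 bases upstream of the translation start codon and
#' 210 bases downstream, read 5'->3' on the coding strand, so the start
#' codon always begins at position 751. Minus-strand genes return the
#' reverse complement of the corresponding genomic slice.
#'
#' @param genome a [genome_seq()].
#' @param gene one-row annotation data frame (or list) with `start`,
#'   `end`, `strand`.
#' @param upstream,downstream window geometry in bases (study values
#'   750 and 210).
#' @return a character string of length `upstream + downstream`, or `NULL`
#'   (with a warning) if the gene lacks sufficient flanking sequence.
#' @export
extract_promoter_window <- function(genome, gene, upstream = 750L,
                                    downstream = 210L) {
  stopifnot(inherits(genome, "genome_seq"))
  if (gene$strand == "+") {
    lo <- gene$start - upstream
    hi <- gene$start + downstream - 1L
    if (lo < 1L || hi > genome$length) {
      warning("gene ", gene$locus_tag %||% "?",
              " skipped: insufficient flanking sequence")
      return(NULL)
    }
    substr(genome$sequence, lo, hi)
  } else {
    lo <- gene$end - downstream + 1L
    hi <- gene$end + upstream
    if (lo < 1L || hi > genome$length) {
      warning("gene ", gene$locus_tag %||% "?",
              " skipped: insufficient flanking sequence")
      return(NULL)
    }
    revcomp(substr(genome$sequence, lo, hi))
  }
}

#' Promoter windows for a set of genes
#'
#' @param genome a [genome_seq()].
#' @param genes annotation data frame.
#' @param locus_tags genes to extract (default: all).
#' @inheritParams extract_promoter_window
#' @return named character vector of windows; genes with insufficient
#'   flank are dropped with one consolidated warning.
#' @export
promoter_windows <- function(genome, genes, locus_tags = genes$locus_tag,
                             upstream = 750L, downstream = 210L) {
  idx <- match(locus_tags, genes$locus_tag)
  if (anyNA(idx)) {
    stop("genes absent from annotation: ",
         paste(locus_tags[is.na(idx)], collapse = ", "))
  }
  out <- withCallingHandlers(
    lapply(idx, function(i) {
      extract_promoter_window(genome, genes[i, ], upstream, downstream)
    }),
    warning = function(w) invokeRestart("muffleWarning"))
  names(out) <- locus_tags
  dropped <- vapply(out, is.null, logical(1))
  if (any(dropped)) {
    warning(sum(dropped), " gene(s) skipped for insufficient flank: ",
            paste(utils::head(locus_tags[dropped], 5), collapse = ", "))
  }
  unlist(out[!dropped])
}

#' Sliding-window AT-content profile of a sequence set
#'
#' For every sequence, window i (covering bases i..i+window-1, 1-based)
#' gets `AT% = 100 * (#A + #T) / window`; the profile value at i is the
#' mean across sequences, plotted against the window's first base. N bases
#' count as non-AT so every window keeps an exact denominator. For 960-bp
#' inputs and 100-bp windows the profile has 861 positions.
#'
#' @param sequences character vector of equal-length sequences.
#' @param set_label label carried on the profile.
#' @param window window width in bases.
#' @param step step in bases (the study used 1).
#' @return object of class `at_profile`: list with `set_label`,
#'   `n_sequences`, `positions`, `mean` (per-position mean AT%) and
#'   `per_seq` (sequences x positions matrix, retained for testing).
#' @export
at_profile <- function(sequences, set_label = "set", window = 100L,
                       step = 1L) {
  if (!length(sequences)) stop("empty sequence set")
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    bad <- names(sequences)[which(lens != lens[1])[1]] %||%
      which(lens != lens[1])[1]
    stop("sequences must share one length; offender: ", bad)
  }
  L <- lens[1]
  if (L < window) stop("sequences shorter than one window")
  positions <- seq(1L, L - window + 1L, by = step)
  per_seq <- matrix(unlist(lapply(sequences, function(s) {
    at <- as.integer(strsplit(s, "", fixed = TRUE)[[1]] %in% c("A", "T"))
    cs <- c(0L, cumsum(at))
    100 * (cs[positions + window] - cs[positions]) / window
  })), nrow = length(sequences), byrow = TRUE,
  dimnames = list(names(sequences), positions))
  structure(list(set_label = set_label, n_sequences = length(sequences),
                 window = window, step = step, positions = positions,
                 mean = colMeans(per_seq), per_seq = per_seq),
            class = "at_profile")
}

#' @export
print.at_profile <- function(x, ...) {
  cat(sprintf("<at_profile> '%s': %d sequences, %d positions, grand mean %.1f%% AT\n",
              x$set_label, x$n_sequences, length(x$positions), mean(x$mean)))
  invisible(x)
}

#' Sample random control promoters
#'
#' Uniform sample, without replacement, of genes whose full promoter
#' window is extractable; the study used 66 random promoter regions as one
#' of its two control sets.
#'
#' @param genes annotation data frame.
#' @param genome a [genome_seq()].
#' @param n number of promoters.
#' @param seed integer seed.
#' @inheritParams extract_promoter_window
#' @return named character vector of `n` promoter windows.
#' @export
sample_random_promoters <- function(genes, genome, n = 66L, seed = 1L,
                                    upstream = 750L, downstream = 210L) {
  ok <- ifelse(genes$strand == "+",
               genes$start - upstream >= 1L &
                 genes$start + downstream - 1L <= genome$length,
               genes$end - downstream + 1L >= 1L &
                 genes$end + upstream <= genome$length)
  eligible <- genes$locus_tag[ok]
  if (length(eligible) < n) {
    stop("fewer than ", n, " genes with sufficient flank (found ",
         length(eligible), ")")
  }
  pick <- if (length(eligible) == n) {
    eligible
  } else {
    with_seed(derive_seed(seed, 8L), sample(eligible, n))
  }
  promoter_windows(genome, genes, pick, upstream, downstream)
}

#' Sample random genomic sequences
#'
#' `n` windows of `length` bases at uniform start positions on either
#' strand; the study's second control set used 66 random 960-bp genomic
#' sequences.
#'
#' @param genome a [genome_seq()].
#' @param n number of sequences.
#' @param length sequence length in bases.
#' @param seed integer seed.
#' @return character vector of `n` sequences.
#' @export
sample_random_genomic <- function(genome, n = 66L, length = 960L, seed = 1L) {
  if (genome$length < length) {
    stop("requested length exceeds the genome (", genome$length, " bp)")
  }
  with_seed(derive_seed(seed, 9L), {
    starts <- sample.int(genome$length - length + 1L, n, replace = TRUE)
    minus <- sample(c(TRUE, FALSE), n, replace = TRUE)
    vapply(seq_len(n), function(i) {
      s <- substr(genome$sequence, starts[i], starts[i] + length - 1L)
      if (minus[i]) revcomp(s) else s
    }, character(1))
  })
}

#' Compare two AT profiles at named window positions
#'
#' At each position, the per-sequence window AT% values of the two sets
#' are tested for normality (Shapiro-Wilk per set) and compared with a
#' two-sided two-sample t-test (Welch by default). When either set fails
#' normality at 0.05 a Mann-Whitney p-value is reported alongside; the
#' t-test is always reported, as in the study. The study tested window
#' start positions 340 and 660 of the 960-bp promoter window.
#'
#' @param profile_a,profile_b [at_profile()] objects retaining per-sequence
#'   values.
#' @param positions window-start positions to test.
#' @param equal_var use the pooled-variance Student t instead of Welch.
#' @return data frame: `position`, `set_a`, `set_b`, `mean_a`, `mean_b`,
#'   `normality_p_a`, `normality_p_b`, `t_p`, `mann_whitney_p`.
#' @export
compare_positions <- function(profile_a, profile_b, positions = c(340, 660),
                              equal_var = FALSE) {
  stopifnot(inherits(profile_a, "at_profile"), inherits(profile_b, "at_profile"))
  do.call(rbind, lapply(positions, function(p) {
    ia <- match(p, profile_a$positions); ib <- match(p, profile_b$positions)
    if (is.na(ia) || is.na(ib)) {
      stop("position ", p, " not present in both profiles")
    }
    x <- profile_a$per_seq[, ia]; y <- profile_b$per_seq[, ib]
    sw <- function(v) {
      if (length(v) < 3L || length(unique(v)) == 1L) return(NA_real_)
      stats::shapiro.test(v)$p.value
    }
    pa <- sw(x); pb <- sw(y)
    t_p <- if (length(x) >= 2L && length(y) >= 2L) {
      if (stats::var(x) == 0 && stats::var(y) == 0) {
        if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
      } else {
        stats::t.test(x, y, var.equal = equal_var)$p.value
      }
    } else {
      NA_real_
    }
    mw <- if ((!is.na(pa) && pa < 0.05) || (!is.na(pb) && pb < 0.05)) {
      suppressWarnings(stats::wilcox.test(x, y)$p.value)
    } else {
      NA_real_
    }
    data.frame(position = p, set_a = profile_a$set_label,
               set_b = profile_b$set_label, mean_a = mean(x),
               mean_b = mean(y), normality_p_a = pa, normality_p_b = pb,
               t_p = t_p, mann_whitney_p = mw, stringsAsFactors = FALSE)
  }))
}
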