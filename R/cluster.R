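#' Map affected genes to transcription-unit start positions
#'
#' Each transcription unit contributes one chromosomal position: the start
#' of its first transcribed gene (plus strand) or the end of its first
#' transcribed gene (minus strand). A unit is affected in a direction if
#' any member gene carries that SSG class; two affected members of one
#' unit yield a single deduplicated position.
#'
#' @param diff a `diff_result` (or data frame with `locus_tag`,
#'   `ssg_class`).
#' @param genes annotation data frame.
#' @param operons optional operon membership table; genes without a TU
#'   assignment are singleton units.
#' @return list with `tu` (one row per TU: `tu_id`, `tss_position`,
#'   `strand`, `direction` - `"up"`, `"down"` or `"none"`) and `affected`
#'   (the affected subset).
#' @export
map_tss <- function(diff, genes, operons = NULL) {
  aff <- diff[diff$ssg_class %in% c("up", "down"), c("locus_tag", "ssg_class")]
  missing <- setdiff(aff$locus_tag, genes$locus_tag)
  if (length(missing)) {
    stop("affected genes absent from annotation: ",
         paste(missing, collapse = ", "))
  }
  tus <- transcription_units(genes, operons)
  tus$ssg_class <- aff$ssg_class[match(tus$locus_tag, aff$locus_tag)]
  sp <- split(tus, tus$tu_id)
  tu <- do.call(rbind, lapply(sp, function(d) {
    cls <- unique(stats::na.omit(d$ssg_class))
    dir <- if (length(cls) == 0L) "none" else if (length(cls) == 1L) cls else "both"
    data.frame(tu_id = d$tu_id[1], tss_position = d$tss_position[1],
               strand = d$strand[1], direction = dir,
               members = paste(d$locus_tag[order(d$order)], collapse = ","),
               stringsAsFactors = FALSE)
  }))
  tu <- tu[order(tu$tss_position), ]
  rownames(tu) <- NULL
  list(tu = tu, affected = tu[tu$direction != "none", , drop = FALSE])
}

#' Sliding-window density of affected transcription units
#'
#' Windows of `window_size` bases start at 1, 1 + step, 1 + 2 step, ...
#' and are clipped at the chromosome end. Every window counts the
#' transcription-unit start positions it contains (`n_total`) and the
#' affected ones (`n_affected`); the percentage is undefined (NA) where
#' `n_total` is 0. The plotting coordinate is the window midpoint.
#'
#' @param affected_positions chromosomal positions of affected TUs.
#' @param all_positions positions of all TUs (the percentage denominator).
#' @param genome_length chromosome length in bases.
#' @param window_size window width in bases (study value: 250,000).
#' @param step window step in bases (study value: 125,000).
#' @return object of class `window_scan`: data frame `window_start`,
#'   `window_end`, `midpoint`, `n_total`, `n_affected`, `percent`.
#' @export
window_scan <- function(affected_positions, all_positions, genome_length,
                        window_size = 250000, step = 125000) {
  if (!(window_size >= step && step > 0)) {
    stop("window_size must be >= step and step > 0")
  }
  if (genome_length < window_size) {
    warning("genome shorter than one window; single clipped window")
  }
  starts <- seq(1, genome_length, by = step)
  ends <- pmin(starts + window_size - 1, genome_length)
  n_total <- vapply(seq_along(starts), function(i) {
    sum(all_positions >= starts[i] & all_positions <= ends[i])
  }, numeric(1))
  n_aff <- vapply(seq_along(starts), function(i) {
    sum(affected_positions >= starts[i] & affected_positions <= ends[i])
  }, numeric(1))
  pct <- ifelse(n_total > 0, 100 * n_aff / n_total, NA_real_)
  structure(
    data.frame(window_start = starts, window_end = ends,
               midpoint = (starts + ends) / 2, n_total = n_total,
               n_affected = n_aff, percent = pct),
    class = c("window_scan", "data.frame"),
    window_size = window_size, step = step, genome_length = genome_length)
}

#' Call supercoiling-sensitive clusters from a window scan
#'
#' Windows whose affected percentage strictly exceeds the threshold
#' qualify; qualifying windows whose spans overlap or abut are merged into
#' one cluster covering their union. Each cluster reports its peak window
#' percentage and the affected transcription units inside its span.
#'
#' @param scan a [window_scan()] computed for one direction.
#' @param affected_positions positions of the affected TUs (same direction
#'   as the scan).
#' @param all_positions positions of all TUs.
#' @param threshold_percent qualifying threshold (strict; study value 5).
#' @param direction `"up"` or `"down"`, recorded on the calls.
#' @param chrom_id chromosome identifier for the calls.
#' @param affected_ids optional names for `affected_positions` (e.g. TU
#'   ids) listed as cluster members.
#' @return data frame of class `cluster_calls`: `chrom_id`, `start`, `end`,
#'   `direction`, `peak_window_percent`, `n_affected`, `n_total`,
#'   `members`.
#' @export
call_clusters <- function(scan, affected_positions, all_positions,
                          threshold_percent = 5, direction = "up",
                          chrom_id = "chr", affected_ids = NULL) {
  stopifnot(inherits(scan, "window_scan"))
  qual <- which(!is.na(scan$percent) & scan$percent > threshold_percent)
  empty <- data.frame(chrom_id = character(), start = numeric(),
                      end = numeric(), direction = character(),
                      peak_window_percent = numeric(), n_affected = integer(),
                      n_total = integer(), members = character(),
                      stringsAsFactors = FALSE)
  if (!length(qual)) {
    return(structure(empty, class = c("cluster_calls", "data.frame")))
  }
  if (is.null(affected_ids)) {
    affected_ids <- as.character(round(affected_positions))
  }
  # merge qualifying windows whose spans overlap or abut
  qs <- scan$window_start[qual]; qe <- scan$window_end[qual]
  groups <- cumsum(c(1, as.integer(qs[-1] > cummax(qe[-length(qe)]) + 1)))
  out <- do.call(rbind, lapply(split(seq_along(qual), groups), function(ii) {
    s <- min(qs[ii]); e <- max(qe[ii])
    inside <- affected_positions >= s & affected_positions <= e
    data.frame(chrom_id = chrom_id, start = s, end = e,
               direction = direction,
               peak_window_percent = max(scan$percent[qual[ii]]),
               n_affected = sum(inside),
               n_total = sum(all_positions >= s & all_positions <= e),
               members = paste(affected_ids[inside], collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  structure(out, class = c("cluster_calls", "data.frame"))
}

#' Locate the densest affected region (hypersensitive cluster search)
#'
#' Slides a fixed-width interval anchored at gene start positions and
#' returns the interval containing the most affected genes (genes are
#' assigned by start position). Ties are broken by the larger affected
#' fraction, then by the leftmost start.
#'
#' @param genes annotation data frame.
#' @param affected_tags locus tags of affected genes.
#' @param width interval width in bases (study value 30,000).
#' @return list `start`, `end`, `n_affected`, `n_total`, `members` (the
#'   affected locus tags inside the interval).
#' @export
densest_region <- function(genes, affected_tags, width = 30000) {
  if (!length(affected_tags)) stop("need at least one affected gene")
  missing <- setdiff(affected_tags, genes$locus_tag)
  if (length(missing)) {
    stop("affected genes absent from annotation: ",
         paste(missing, collapse = ", "))
  }
  ord <- order(genes$start)
  starts <- genes$start[ord]
  tags <- genes$locus_tag[ord]
  is_aff <- tags %in% affected_tags
  best <- NULL
  # anchors visited left to right, strict improvement => leftmost wins ties
  for (i in seq_along(starts)) {
    hi <- starts[i] + width - 1
    in_iv <- starts >= starts[i] & starts <= hi
    na <- sum(is_aff & in_iv); nt <- sum(in_iv)
    if (is.null(best) || na > best$n_affected ||
        (na == best$n_affected && na / nt > best$n_affected / best$n_total)) {
      best <- list(start = starts[i], end = hi, n_affected = na,
                   n_total = nt, members = tags[is_aff & in_iv])
    }
  }
  list(start = best$start, end = best$end, n_affected = best$n_affected,
       n_total = best$n_total, members = best$members)
}
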