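#' Comparative ddCt relative quantification
#'
#' Technical replicate Cts are averaged within each sample; then, per
#' condition, `dCt = mean Ct(target) - mean Ct(reference)` across that
#' condition's samples, `ddCt = dCt(condition) - dCt(calibrator)` and the
#' relative level is `2^-ddCt` (amplification efficiency fixed at 2). The
#' calibrator condition's own level is exactly 1. The study used hrdB as
#' the endogenous control and the wild type as calibrator.
#'
#' @param records Ct data frame (`sample`, `condition`, `gene`,
#'   `replicate`, `ct`), e.g. from [read_ct_table()].
#' @param target target gene name.
#' @param reference_gene endogenous control gene (default `"hrdB"`).
#' @param calibrator_condition condition whose level is set to 1.
#' @return data frame of class `relative_levels`: `target_gene`,
#'   `condition`, `calibrator_condition`, `delta_ct`, `delta_delta_ct`,
#'   `relative_level`, `n_replicates`, `level_sd` (biological-replicate
#'   standard deviation of per-replicate levels; NA with < 2 replicates).
#' @export
ddct <- function(records, target, reference_gene = "hrdB",
                 calibrator_condition) {
  need <- c("sample", "condition", "gene", "ct")
  stopifnot(all(need %in% names(records)))
  if (!calibrator_condition %in% records$condition) {
    stop("calibrator condition '", calibrator_condition,
         "' absent from the Ct table")
  }
  conds <- unique(records$condition)
  # average technical replicates at the Ct level within each sample
  tech <- stats::aggregate(ct ~ sample + condition + gene, data = records,
                           FUN = mean)
  for (cn in conds) {
    sub <- tech[tech$condition == cn, ]
    if (!reference_gene %in% sub$gene) {
      stop("reference gene '", reference_gene,
           "' missing in condition '", cn, "'")
    }
  }
  dct <- vapply(conds, function(cn) {
    sub <- tech[tech$condition == cn, ]
    t_ct <- sub$ct[sub$gene == target]
    if (!length(t_ct)) {
      stop("target '", target, "' has no Ct in condition '", cn, "'")
    }
    mean(t_ct) - mean(sub$ct[sub$gene == reference_gene])
  }, numeric(1))
  ddct_v <- dct - dct[[calibrator_condition]]
  out <- data.frame(
    target_gene = target, condition = conds,
    calibrator_condition = calibrator_condition,
    delta_ct = unname(dct), delta_delta_ct = unname(ddct_v),
    relative_level = 2^(-unname(ddct_v)),
    n_replicates = vapply(conds, function(cn) {
      length(unique(tech$sample[tech$condition == cn & tech$gene == target]))
    }, integer(1)),
    stringsAsFactors = FALSE)
  out$level_sd <- vapply(conds, function(cn) {
    replicate_dispersion(records, target, cn, reference_gene,
                         calibrator_condition)
  }, numeric(1))
  rownames(out) <- NULL
  structure(out, class = c("relative_levels", "data.frame"))
}

#' @export
print.relative_levels <- function(x, ...) {
  cat(sprintf("<relative_levels> %s vs %s (reference-normalized)\n",
              x$target_gene[1], x$calibrator_condition[1]))
  print.data.frame(x[, c("condition", "delta_delta_ct", "relative_level",
                         "level_sd")], row.names = FALSE)
  invisible(x)
}

#' Biological-replicate dispersion of relative levels
#'
#' Per-replicate relative levels use the replicate-matched reference Ct:
#' for each sample, `dCt = Ct(target) - Ct(reference)` within that sample,
#' `ddCt` against the calibrator's mean dCt, level `2^-ddCt`; the standard
#' deviation over the condition's samples is returned (NA with fewer than
#' two).
#'
#' @inheritParams ddct
#' @param condition condition whose dispersion is wanted.
#' @param reference_gene endogenous control gene.
#' @return standard deviation of per-replicate relative levels, or NA.
#' @export
replicate_dispersion <- function(records, target, condition,
                                 reference_gene = "hrdB",
                                 calibrator_condition) {
  tech <- stats::aggregate(ct ~ sample + condition + gene, data = records,
                           FUN = mean)
  per_sample_dct <- function(cn) {
    sub <- tech[tech$condition == cn, ]
    samples <- unique(sub$sample)
    vapply(samples, function(s) {
      t_ct <- sub$ct[sub$sample == s & sub$gene == target]
      r_ct <- sub$ct[sub$sample == s & sub$gene == reference_gene]
      if (!length(t_ct) || !length(r_ct)) return(NA_real_)
      mean(t_ct) - mean(r_ct)
    }, numeric(1))
  }
  dct_cal <- mean(per_sample_dct(calibrator_condition), na.rm = TRUE)
  dct_s <- per_sample_dct(condition)
  dct_s <- dct_s[!is.na(dct_s)]
  if (length(dct_s) < 2L) return(NA_real_)
  stats::sd(2^(-(dct_s - dct_cal)))
}
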