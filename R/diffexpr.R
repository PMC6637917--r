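#' Upper quartile of the nonzero counts of one sample
#'
#' No-interpolation order statistic: the smallest nonzero count whose
#' empirical CDF strictly exceeds 0.75, i.e. `sorted[floor(0.75 n) + 1]`
#' (capped at the maximum). For `[10, 20, 30, 40]` this is 40.
#'
#' @param x numeric vector of counts.
#' @return the upper-quartile scaling factor.
#' @export
upper_quartile <- function(x) {
  nz <- sort(x[x > 0])
  n <- length(nz)
  if (n == 0L) stop("no nonzero counts")
  nz[min(floor(0.75 * n) + 1L, n)]
}

#' Upper-quartile normalization of a count matrix
#'
#' Each sample is divided by the upper quartile of its nonzero counts and
#' rescaled to a common reference so values stay in a count-like range.
#' After normalization, the upper quartile of every sample's nonzero values
#' equals the reference scale; zero counts stay zero.
#'
#' @param cm a [count_matrix()].
#' @param reference_scale a positive number, or `"median-of-uqs"` (default)
#'   to use the median upper quartile across samples.
#' @return object of class `expression_matrix`: list with numeric matrix
#'   `values`, data frame `samples`, and the `uq` and `reference_scale`
#'   used.
#' @export
normalize_upper_quartile <- function(cm, reference_scale = "median-of-uqs") {
  stopifnot(inherits(cm, "count_matrix"))
  all_zero <- colSums(cm$counts) == 0
  if (any(all_zero)) {
    stop("sample(s) with all-zero counts: ",
         paste(colnames(cm$counts)[all_zero], collapse = ", "))
  }
  uq <- apply(cm$counts, 2, upper_quartile)
  s <- if (identical(reference_scale, "median-of-uqs")) {
    stats::median(uq)
  } else {
    stopifnot(is.numeric(reference_scale), reference_scale > 0)
    reference_scale
  }
  values <- sweep(cm$counts, 2, uq, "/") * s
  structure(list(values = values, samples = cm$samples, uq = uq,
                 reference_scale = s),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples, UQ scale %.3g\n",
              nrow(x$values), ncol(x$values), x$reference_scale))
  invisible(x)
}

#' @keywords internal
contrast_columns <- function(expr, contrast) {
  stopifnot(length(contrast) == 2L)
  tcols <- expr$samples$condition == contrast[1]
  ccols <- expr$samples$condition == contrast[2]
  if (sum(tcols) < 2L || sum(ccols) < 2L) {
    stop("both conditions of the contrast need >= 2 replicates (",
         contrast[1], ": ", sum(tcols), ", ", contrast[2], ": ",
         sum(ccols), ")")
  }
  list(treatment = which(tcols), control = which(ccols))
}

#' Per-gene log2 fold changes for a contrast
#'
#' `log2((mean treatment + pc) / (mean control + pc))`; induction under
#' treatment is positive. By default the pseudocount is 0 for genes
#' expressed in both conditions; genes with a zero mean in exactly one
#' condition fall back to pseudocount 1 and are flagged; genes with both
#' means zero get `NA`.
#'
#' @param expr an `expression_matrix`.
#' @param contrast character vector `c(treatment, control)` of condition
#'   names.
#' @param pseudocount a fixed non-negative pseudocount, or `NULL` for the
#'   adaptive default above.
#' @return data frame `locus_tag`, `mean_control`, `mean_treatment`,
#'   `log2fc`, `pseudocount_flag`.
#' @export
log2_fold_change <- function(expr, contrast, pseudocount = NULL) {
  cc <- contrast_columns(expr, contrast)
  mt <- rowMeans(expr$values[, cc$treatment, drop = FALSE])
  mc <- rowMeans(expr$values[, cc$control, drop = FALSE])
  if (is.null(pseudocount)) {
    # pseudocount 1 only when exactly one mean is zero; both-zero genes
    # are undefined and reported missing
    pc <- ifelse(mt > 0 & mc > 0, 0, ifelse(mt == 0 & mc == 0, 0, 1))
    flag <- xor(mt == 0, mc == 0)
  } else {
    stopifnot(pseudocount >= 0)
    pc <- rep(pseudocount, length(mt))
    flag <- rep(FALSE, length(mt))
  }
  l2fc <- ifelse(mt + pc > 0 & mc + pc > 0,
                 log2((mt + pc) / (mc + pc)), NA_real_)
  data.frame(locus_tag = rownames(expr$values), mean_control = mc,
             mean_treatment = mt, log2fc = l2fc, pseudocount_flag = flag,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Welch t-test on two replicate vectors of log2 expression
#'
#' Degenerate cases: both groups constant and equal -> p = 1; both
#' constant and different -> p = 0.
#'
#' @keywords internal
welch_p <- function(x, y) {
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  }
  stats::t.test(x, y, var.equal = FALSE)$p.value
}

#' Per-gene significance for a contrast
#'
#' Two-sided Welch t-test on `log2(normalized value + 1)` across
#' replicates, with Benjamini-Hochberg q-values over all tested genes.
#' The test is a replicate-honest stand-in declared in the output; the
#' classification downstream uses the raw p-value.
#'
#' @param expr an `expression_matrix`.
#' @param contrast `c(treatment, control)` condition names.
#' @return data frame `locus_tag`, `p_value`, `q_value`.
#' @export
test_significance <- function(expr, contrast) {
  cc <- contrast_columns(expr, contrast)
  lt <- log2(expr$values[, cc$treatment, drop = FALSE] + 1)
  lc <- log2(expr$values[, cc$control, drop = FALSE] + 1)
  p <- vapply(seq_len(nrow(lt)), function(i) welch_p(lt[i, ], lc[i, ]),
              numeric(1))
  data.frame(locus_tag = rownames(expr$values), p_value = p,
             q_value = stats::p.adjust(p, method = "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify supercoiling-sensitive genes
#'
#' A gene is `up` if log2FC > `log2fc_threshold` and p < `p_threshold`,
#' `down` symmetrically. Genes on the exemption list (nucleoid-associated
#' proteins and topoisomerases in the study system) are classified on the
#' p-value alone, with direction taken from the sign of the log2FC;
#' everything else is `not_significant`.
#'
#' @param diff data frame with at least `locus_tag`, `log2fc`, `p_value`.
#' @param exemption_list locus tags exempt from the fold-change threshold.
#' @param log2fc_threshold elimination band half-width (default 1.5, i.e.
#'   at least a 2.83-fold change).
#' @param p_threshold significance level (default 0.05).
#' @return `diff` with an added `ssg_class` column.
#' @export
classify_ssg <- function(diff, exemption_list = character(),
                         log2fc_threshold = 1.5, p_threshold = 0.05) {
  stopifnot(all(c("locus_tag", "log2fc", "p_value") %in% names(diff)))
  sig <- !is.na(diff$p_value) & diff$p_value < p_threshold
  l2 <- diff$log2fc
  exempt <- diff$locus_tag %in% exemption_list
  cls <- rep("not_significant", nrow(diff))
  cls[sig & !is.na(l2) & l2 > log2fc_threshold] <- "up"
  cls[sig & !is.na(l2) & l2 < -log2fc_threshold] <- "down"
  cls[exempt & sig & !is.na(l2) & l2 > 0] <- "up"
  cls[exempt & sig & !is.na(l2) & l2 < 0] <- "down"
  diff$ssg_class <- cls
  diff
}

#' Run differential expression for one contrast
#'
#' Upper-quartile normalization (if given raw counts), log2 fold change,
#' Welch significance, and SSG classification in one call.
#'
#' @param x a [count_matrix()] or `expression_matrix`.
#' @param treatment treatment condition name.
#' @param control control condition name.
#' @param exemption_list see [classify_ssg()].
#' @param log2fc_threshold,p_threshold see [classify_ssg()].
#' @param pseudocount see [log2_fold_change()].
#' @return object of class `diff_result`: a data frame with columns
#'   `locus_tag`, `mean_control`, `mean_treatment`, `log2fc`,
#'   `pseudocount_flag`, `p_value`, `q_value`, `ssg_class`, carrying the
#'   contrast and test description as attributes.
#' @export
run_diffexpr <- function(x, treatment, control,
                         exemption_list = character(),
                         log2fc_threshold = 1.5, p_threshold = 0.05,
                         pseudocount = NULL) {
  expr <- if (inherits(x, "count_matrix")) normalize_upper_quartile(x) else x
  stopifnot(inherits(expr, "expression_matrix"))
  contrast <- c(treatment, control)
  fc <- log2_fold_change(expr, contrast, pseudocount)
  sig <- test_significance(expr, contrast)
  diff <- merge(fc, sig, by = "locus_tag", sort = FALSE)
  diff <- classify_ssg(diff, exemption_list, log2fc_threshold, p_threshold)
  structure(diff, class = c("diff_result", "data.frame"),
            contrast = contrast,
            test = "Welch t on log2(UQ-normalized + 1)",
            thresholds = c(log2fc = log2fc_threshold, p = p_threshold))
}

#' @export
print.diff_result <- function(x, ...) {
  ct <- attr(x, "contrast")
  cat(sprintf("<diff_result> %s vs %s: %d genes (%d up, %d down)\n",
              ct[1], ct[2], nrow(x), sum(x$ssg_class == "up"),
              sum(x$ssg_class == "down")))
  invisible(x)
}

#' Summarize affected genes across contrasts
#'
#' Counts up/down/total supercoiling-sensitive genes per contrast, their
#' percentage of the annotated gene complement, and for each pair of
#' contrasts the condition-specific fractions (genes affected in one
#' contrast but not the other).
#'
#' @param diff_list named list of `diff_result` objects (name = contrast
#'   label).
#' @param n_total_genes total annotated genes (denominator for genome
#'   percentages); must be > 0.
#' @param digits rounding for percentages.
#' @return list with data frames `per_contrast` and `overlaps`.
#' @export
summarize_affected <- function(diff_list, n_total_genes, digits = 1) {
  if (n_total_genes <= 0) stop("n_total_genes must be > 0")
  affected <- lapply(diff_list, function(d) {
    d$locus_tag[d$ssg_class %in% c("up", "down")]
  })
  per <- do.call(rbind, lapply(names(diff_list), function(nm) {
    d <- diff_list[[nm]]
    n_up <- sum(d$ssg_class == "up"); n_dn <- sum(d$ssg_class == "down")
    data.frame(contrast = nm, n_up = n_up, n_down = n_dn,
               n_affected = n_up + n_dn,
               pct_of_genome = round(100 * (n_up + n_dn) / n_total_genes,
                                     digits),
               stringsAsFactors = FALSE)
  }))
  ov <- NULL
  nms <- names(diff_list)
  if (length(nms) >= 2L) {
    pairs <- utils::combn(nms, 2)
    ov <- do.call(rbind, apply(pairs, 2, function(pr) {
      a <- affected[[pr[1]]]; b <- affected[[pr[2]]]
      shared <- length(intersect(a, b))
      data.frame(contrast_a = pr[1], contrast_b = pr[2],
                 n_a = length(a), n_b = length(b), n_shared = shared,
                 n_a_specific = length(a) - shared,
                 n_b_specific = length(b) - shared,
                 pct_a_specific = round(100 * (length(a) - shared) /
                                          max(length(a), 1), digits),
                 pct_b_specific = round(100 * (length(b) - shared) /
                                          max(length(b), 1), digits),
                 stringsAsFactors = FALSE)
    }))
  }
  list(per_contrast = per, overlaps = ov)
}
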