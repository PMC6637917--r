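#' Default planted cluster layout for the desk-scale design
#'
#' Six up-regulated and two down-regulated 40-kbp clusters on a 1-Mbp
#' chromosome, planted for the long-term supercoiling-imbalance contrast.
#' Gaps between same-direction clusters exceed the demo window geometry so
#' that calls stay separable.
#'
#' @keywords internal
default_planted_clusters <- function() {
  up_starts <- c(60001, 210001, 360001, 510001, 660001, 810001)
  dn_starts <- c(135001, 910001)
  w <- 40000L
  rbind(
    data.frame(condition = "topA_down", start = up_starts,
               end = up_starts + w - 1L, direction = "up",
               log2_effect = 3, fraction = 0.5, stringsAsFactors = FALSE),
    data.frame(condition = "topA_down", start = dn_starts,
               end = dn_starts + w - 1L, direction = "down",
               log2_effect = 3, fraction = 0.5, stringsAsFactors = FALSE)
  )
}

#' Describe a synthetic study design
#'
#' Captures everything the generators need: chromosome geometry and GC
#' content, gene/operon layout, the condition/replicate structure of the
#' expression experiment, the negative-binomial noise model, spatially
#' planted log2 effects, and the promoter composition architecture planted
#' upstream of "induced" genes.
#'
#' Defaults are the desk-scale emulation of the study system: a 1-Mbp
#' linear chromosome at 72% GC carrying 900 genes partly grouped in
#' operons; a control plus three supercoiling-perturbation conditions with
#' 2-4 biological replicates each; baseline negative-binomial counts; six
#' planted up- and two down-regulated clusters; and 66 induced promoters
#' with a +3-point AT boost just upstream of the start codon and a GC-rich
#' block 100-200 bp further upstream.
#'
#' @param seed global integer seed; every generator derives its own
#'   substream from it.
#' @param genome_length chromosome length in bases.
#' @param gc_fraction genome G+C fraction in `[0,1]`.
#' @param n_genes number of genes to tile.
#' @param operon_fraction fraction of transcription units that are operons.
#' @param operon_size number of genes per operon TU (>= 2).
#' @param clear_fraction fraction of TUs given >= 960 bp of upstream
#'   intergenic clearance so their promoter windows are extractable.
#' @param conditions named integer vector: replicates per condition; the
#'   first name is the control.
#' @param baseline_mean expected count of an unaffected gene.
#' @param nb_dispersion negative-binomial dispersion shared across genes;
#'   0 degenerates to Poisson.
#' @param planted_clusters data frame with columns `condition`, `start`,
#'   `end`, `direction` (up/down), `log2_effect` (positive magnitude),
#'   `fraction` (fraction of member genes affected).
#' @param n_induced_promoters number of induced transcription units that
#'   receive both a planted expression effect (condition
#'   `induced_condition`) and the promoter composition architecture.
#' @param induced_condition condition whose contrast defines the induced
#'   gene set (the rapid-relaxation arm).
#' @param induced_log2_effect planted log2 effect of induced genes.
#' @param promoter_at_interval positions (on the 960-bp promoter window,
#'   1 = 750 bp upstream of the start codon, 751 = start codon) whose AT
#'   content is boosted for induced promoters.
#' @param promoter_at_boost AT boost in percentage points.
#' @param promoter_gc_interval positions of the GC-rich block.
#' @param promoter_gc_boost GC boost in percentage points (AT reduced).
#' @return object of class `synthetic_design` (a validated list).
#' @export
synthetic_design <- function(seed = 1L,
                             genome_length = 1e6,
                             gc_fraction = 0.72,
                             n_genes = 900L,
                             operon_fraction = 0.4,
                             operon_size = 3L,
                             clear_fraction = 0.35,
                             conditions = c(control = 4L, novobiocin = 3L,
                                            topA_down = 4L, topA_up = 3L),
                             baseline_mean = 200,
                             nb_dispersion = 0.05,
                             planted_clusters = default_planted_clusters(),
                             n_induced_promoters = 66L,
                             induced_condition = "novobiocin",
                             induced_log2_effect = 3,
                             promoter_at_interval = c(600L, 760L),
                             promoter_at_boost = 3,
                             promoter_gc_interval = c(340L, 460L),
                             promoter_gc_boost = 3) {
  d <- list(seed = as.integer(seed), genome_length = as.integer(genome_length),
            gc_fraction = gc_fraction, n_genes = as.integer(n_genes),
            operon_fraction = operon_fraction,
            operon_size = as.integer(operon_size),
            clear_fraction = clear_fraction, conditions = conditions,
            baseline_mean = baseline_mean, nb_dispersion = nb_dispersion,
            planted_clusters = planted_clusters,
            n_induced_promoters = as.integer(n_induced_promoters),
            induced_condition = induced_condition,
            induced_log2_effect = induced_log2_effect,
            promoter_at_interval = as.integer(promoter_at_interval),
            promoter_at_boost = promoter_at_boost,
            promoter_gc_interval = as.integer(promoter_gc_interval),
            promoter_gc_boost = promoter_gc_boost)
  validate_design(d)
  structure(d, class = "synthetic_design")
}

#' @keywords internal
validate_design <- function(d) {
  if (d$gc_fraction < 0 || d$gc_fraction > 1) {
    stop("parameter error: gc_fraction must lie in [0,1]")
  }
  if (d$genome_length < 1) stop("parameter error: genome_length must be >= 1")
  if (is.null(names(d$conditions)) || any(names(d$conditions) == "")) {
    stop("parameter error: conditions must be a named vector")
  }
  if (any(d$conditions < 2)) {
    stop("parameter error: every condition needs >= 2 replicates")
  }
  if (d$baseline_mean < 0) {
    stop("parameter error: baseline_mean must be non-negative")
  }
  if (d$nb_dispersion < 0) {
    stop("parameter error: nb_dispersion must be non-negative")
  }
  pc <- d$planted_clusters
  if (!is.null(pc) && nrow(pc)) {
    if (any(pc$start < 1 | pc$end > d$genome_length | pc$start > pc$end)) {
      stop("parameter error: planted cluster intervals must lie within the genome")
    }
    if (any(!pc$direction %in% c("up", "down"))) {
      stop("parameter error: planted cluster direction must be up/down")
    }
    if (any(pc$fraction < 0 | pc$fraction > 1)) {
      stop("parameter error: planted cluster fraction must lie in [0,1]")
    }
  }
  for (iv in list(d$promoter_at_interval, d$promoter_gc_interval)) {
    if (length(iv) != 2L || iv[1] > iv[2] || iv[1] < 1L || iv[2] > 960L) {
      stop("parameter error: promoter intervals must lie within the 960-bp window")
    }
  }
  invisible(d)
}

#' @export
print.synthetic_design <- function(x, ...) {
  cat(sprintf(paste0(
    "<synthetic_design> %s bp @ %.0f%% GC, %d genes, seed %d\n",
    "  conditions: %s\n  planted clusters: %d (%s)\n"),
    format(x$genome_length, big.mark = ","), 100 * x$gc_fraction, x$n_genes,
    x$seed,
    paste(sprintf("%s x%d", names(x$conditions), x$conditions), collapse = ", "),
    nrow(x$planted_clusters),
    paste(table(x$planted_clusters$direction), collapse = " up/down ")))
  invisible(x)
}
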