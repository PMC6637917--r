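#' Simulate a GC-rich genome sequence
#'
#' Bases are drawn i.i.d. with P(G) + P(C) equal to the design's GC
#' fraction, split equally between G and C, and P(A) = P(T). The realized
#' composition converges on the target as the chromosome grows (within
#' 0.2 percentage points at 1 Mbp).
#'
#' @param design a [synthetic_design()].
#' @return a [genome_seq()] named `"chr"`.
#' @export
simulate_genome <- function(design) {
  validate_design(design)
  gc <- design$gc_fraction
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  bases <- with_seed(derive_seed(design$seed, 1L), {
    sample(names(p), design$genome_length, replace = TRUE, prob = p)
  })
  genome_seq("chr", paste(bases, collapse = ""))
}

#' Simulate a gene annotation with operon structure
#'
#' Tiles non-overlapping genes left to right across the chromosome.
#' Transcription units are runs of adjacent same-strand genes: a fraction
#' `operon_fraction` of TUs are operons of exactly `operon_size` genes, the
#' rest are singletons. A fraction `clear_fraction` of TUs receives at
#' least 960 bp of intergenic clearance on the 5' side of its first gene so
#' that full promoter windows are extractable and plantable.
#'
#' @param design a [synthetic_design()].
#' @return list with `genes` (annotation data frame as from [read_gff3()])
#'   and `operons` (membership table for multi-gene TUs, as from
#'   [read_operons()]).
#' @export
simulate_annotation <- function(design) {
  validate_design(design)
  with_seed(derive_seed(design$seed, 2L), {
    n <- design$n_genes
    # TU sizes in genomic order
    sizes <- integer(0)
    left <- n
    while (left > 0L) {
      s <- if (stats::runif(1) < design$operon_fraction) design$operon_size else 1L
      s <- min(s, left)
      sizes <- c(sizes, s)
      left <- left - s
    }
    n_tu <- length(sizes)
    tu_strand <- sample(c("+", "-"), n_tu, replace = TRUE)
    tu_clear <- stats::runif(n_tu) < design$clear_fraction
    gene_len <- round(stats::runif(n, 400, 800))
    intra_gap <- round(stats::runif(n, 30, 150))   # used within TUs only
    # inter-TU gap before TU t: >= 960 bp when the promoter side of this TU
    # (plus strand) or of the previous TU (minus strand) must stay clear
    clear_before <- tu_clear & tu_strand == "+"
    clear_after <- tu_clear & tu_strand == "-"
    gap_before <- round(ifelse(clear_before, stats::runif(n_tu, 960, 1100),
                               stats::runif(n_tu, 30, 150)))
    pending <- c(0, ifelse(clear_after, round(stats::runif(n_tu, 960, 1100)),
                           0)[-n_tu])
    gap_before <- pmax(gap_before, pending)
    lead_in <- 1000L       # upstream room before the first gene
    tail_margin <- 1000L   # room after the last gene
    is_first <- unlist(lapply(sizes, function(s) c(TRUE, rep(FALSE, s - 1L))))
    used <- lead_in + tail_margin + sum(gene_len) + sum(gap_before) +
      sum(intra_gap[!is_first])
    slack <- design$genome_length - used
    if (slack < 0) {
      stop("parameter error: genome too short for the requested genes ",
           "(need >= ", used, " bp)")
    }
    # spread the leftover across inter-TU gaps so genes span the chromosome
    gap_before <- gap_before + floor(slack / n_tu)

    start <- integer(n); end <- integer(n)
    strand <- character(n); tu_of <- integer(n)
    cursor <- lead_in
    gi <- 1L
    for (t in seq_len(n_tu)) {
      cursor <- cursor + gap_before[t]
      for (k in seq_len(sizes[t])) {
        if (k > 1L) cursor <- cursor + intra_gap[gi]
        start[gi] <- cursor
        end[gi] <- cursor + gene_len[gi] - 1L
        strand[gi] <- tu_strand[t]
        tu_of[gi] <- t
        cursor <- end[gi] + 1L
        gi <- gi + 1L
      }
    }
    locus <- sprintf("sg%04d", seq_len(n))
    genes <- data.frame(locus_tag = locus, chrom_id = "chr",
                        start = start, end = end, strand = strand,
                        product = sprintf("synthetic protein %d", seq_len(n)),
                        stringsAsFactors = FALSE)
    # operon membership (multi-gene TUs only; singletons are implicit)
    op <- do.call(rbind, lapply(which(sizes > 1L), function(t) {
      members <- locus[tu_of == t]
      if (tu_strand[t] == "-") members <- rev(members)  # transcription order
      data.frame(tu_id = sprintf("tu%04d", t), locus_tag = members,
                 order = seq_along(members), stringsAsFactors = FALSE)
    }))
    if (is.null(op)) {
      op <- data.frame(tu_id = character(), locus_tag = character(),
                       order = integer(), stringsAsFactors = FALSE)
    }
    list(genes = genes, operons = op)
  })
}

#' Assemble the planted-effect truth table for a design
#'
#' Samples, per planted cluster, the configured fraction of member genes
#' and assigns them the signed log2 effect; optionally appends extra
#' per-gene effects (used for the induced-promoter gene set).
#'
#' @param design a [synthetic_design()].
#' @param genes annotation data frame.
#' @param extra_effects optional data frame with columns `locus_tag`,
#'   `condition`, `direction`, `log2_effect` (signed), `cluster_id`.
#' @return truth data frame: `locus_tag`, `condition`, `direction`,
#'   `log2_effect` (signed), `cluster_id`.
#' @export
planted_truth <- function(design, genes, extra_effects = NULL) {
  validate_design(design)
  pc <- design$planted_clusters
  rows <- list()
  if (!is.null(pc) && nrow(pc)) {
    rows <- with_seed(derive_seed(design$seed, 3L), {
      lapply(seq_len(nrow(pc)), function(i) {
        members <- genes$locus_tag[genes$start >= pc$start[i] &
                                     genes$start <= pc$end[i]]
        k <- round(pc$fraction[i] * length(members))
        hit <- if (k > 0L) sample(members, k) else character(0)
        if (!length(hit)) return(NULL)
        data.frame(locus_tag = hit, condition = pc$condition[i],
                   direction = pc$direction[i],
                   log2_effect = ifelse(pc$direction[i] == "up", 1, -1) *
                     pc$log2_effect[i],
                   cluster_id = sprintf("planted%02d", i),
                   stringsAsFactors = FALSE)
      })
    })
  }
  truth <- do.call(rbind, c(rows, list(extra_effects)))
  if (is.null(truth)) {
    truth <- data.frame(locus_tag = character(), condition = character(),
                        direction = character(), log2_effect = numeric(),
                        cluster_id = character(), stringsAsFactors = FALSE)
  }
  # one effect per (gene, condition): keep the first listed
  truth[!duplicated(truth[, c("locus_tag", "condition")]), , drop = FALSE]
}

#' Simulate a replicate count matrix with planted effects
#'
#' Counts are negative-binomial with mean
#' `baseline_mean * 2^log2_effect` for genes carrying a planted effect in a
#' condition (and `baseline_mean` otherwise) and a gene-shared dispersion;
#' dispersion 0 degenerates to Poisson. The truth table of planted effects
#' is returned alongside so recovery can be scored.
#'
#' @param design a [synthetic_design()].
#' @param genes annotation data frame.
#' @param extra_effects optional extra per-gene effects (see
#'   [planted_truth()]).
#' @return list with `counts` (a [count_matrix()]) and `truth`.
#' @export
simulate_counts <- function(design, genes, extra_effects = NULL) {
  validate_design(design)
  truth <- planted_truth(design, genes, extra_effects)
  conds <- design$conditions
  sample_ids <- unlist(lapply(names(conds), function(cn) {
    sprintf("%s_r%d", cn, seq_len(conds[[cn]]))
  }))
  sample_cond <- rep(names(conds), times = conds)
  n_g <- nrow(genes)
  mu <- matrix(design$baseline_mean, nrow = n_g, ncol = length(sample_ids),
               dimnames = list(genes$locus_tag, sample_ids))
  if (nrow(truth)) {
    for (i in seq_len(nrow(truth))) {
      g <- truth$locus_tag[i]
      cols <- sample_cond == truth$condition[i]
      mu[g, cols] <- design$baseline_mean * 2^truth$log2_effect[i]
    }
  }
  m <- with_seed(derive_seed(design$seed, 4L), {
    if (design$nb_dispersion == 0) {
      matrix(stats::rpois(length(mu), lambda = mu), nrow = n_g)
    } else {
      matrix(stats::rnbinom(length(mu), mu = mu,
                            size = 1 / design$nb_dispersion), nrow = n_g)
    }
  })
  dimnames(m) <- dimnames(mu)
  storage.mode(m) <- "integer"
  samples <- data.frame(sample = sample_ids, condition = sample_cond,
                        replicate = unlist(lapply(conds, seq_len)),
                        stringsAsFactors = FALSE)
  list(counts = count_matrix(m, samples), truth = truth)
}

#' Choose induced transcription units with clear promoters
#'
#' Samples `n_induced_promoters` TUs whose first gene has at least 750 bp
#' of intergenic sequence upstream on its own strand (so the full 960-bp
#' promoter window is extractable and can be rewritten without touching a
#' neighbouring gene).
#'
#' @param design a [synthetic_design()].
#' @param genes annotation data frame.
#' @param operons operon membership table.
#' @return data frame `tu_id`, `locus_tag` (first transcribed gene),
#'   `strand`, `tss_position`.
#' @export
choose_induced_tus <- function(design, genes, operons = NULL) {
  validate_design(design)
  tus <- transcription_units(genes, operons)
  firsts <- tus[tus$order == 1L, ]
  idx <- match(firsts$locus_tag, genes$locus_tag)
  g <- genes[idx, ]
  ord <- order(genes$start)
  starts_sorted <- genes$start[ord]; ends_sorted <- genes$end[ord]
  up_gap <- vapply(seq_len(nrow(g)), function(i) {
    if (g$strand[i] == "+") {
      prev_end <- ends_sorted[ends_sorted < g$start[i]]
      lo <- if (length(prev_end)) max(prev_end) else 0L
      g$start[i] - lo - 1L
    } else {
      nxt <- starts_sorted[starts_sorted > g$end[i]]
      hi <- if (length(nxt)) min(nxt) else design$genome_length + 1L
      hi - g$end[i] - 1L
    }
  }, numeric(1))
  in_bounds <- ifelse(g$strand == "+",
                      g$start - 750L >= 1L,
                      g$end + 750L <= design$genome_length)
  eligible <- which(up_gap >= 750 & in_bounds)
  if (length(eligible) < design$n_induced_promoters) {
    stop("fewer than ", design$n_induced_promoters,
         " transcription units with clear promoters (found ",
         length(eligible), ")")
  }
  pick <- with_seed(derive_seed(design$seed, 5L),
                    sort(sample(eligible, design$n_induced_promoters)))
  data.frame(tu_id = firsts$tu_id[pick], locus_tag = firsts$locus_tag[pick],
             strand = g$strand[pick], tss_position = firsts$tss_position[pick],
             stringsAsFactors = FALSE)
}

#' Plant promoter composition architecture upstream of induced genes
#'
#' Rewrites, on the coding strand, two sub-intervals of the 960-bp promoter
#' window (1 = 750 bp upstream of the start codon) of each induced gene:
#' bases in `promoter_at_interval` are resampled with the background AT
#' probability raised by `promoter_at_boost` percentage points, and bases
#' in `promoter_gc_interval` with it lowered by `promoter_gc_boost` points.
#' A boost of 0 leaves the corresponding interval untouched; promoters of
#' non-induced genes are never modified.
#'
#' @param genome a [genome_seq()].
#' @param genes annotation data frame.
#' @param design a [synthetic_design()].
#' @param induced_locus_tags genes whose promoters receive the architecture.
#' @return a new [genome_seq()] with rewritten promoter intervals.
#' @export
plant_promoter_architecture <- function(genome, genes, design,
                                        induced_locus_tags) {
  validate_design(design)
  stopifnot(inherits(genome, "genome_seq"))
  missing <- setdiff(induced_locus_tags, genes$locus_tag)
  if (length(missing)) {
    stop("induced genes absent from annotation: ",
         paste(missing, collapse = ", "))
  }
  base_at <- 1 - design$gc_fraction
  plan <- list()
  if (design$promoter_at_boost != 0) {
    plan <- c(plan, list(list(iv = design$promoter_at_interval,
                              p_at = min(max(base_at + design$promoter_at_boost / 100, 0), 1))))
  }
  if (design$promoter_gc_boost != 0) {
    plan <- c(plan, list(list(iv = design$promoter_gc_interval,
                              p_at = min(max(base_at - design$promoter_gc_boost / 100, 0), 1))))
  }
  if (!length(plan)) return(genome)

  chars <- strsplit(genome$sequence, "", fixed = TRUE)[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  with_seed(derive_seed(design$seed, 6L), {
    for (tag in induced_locus_tags) {
      gi <- match(tag, genes$locus_tag)
      plus <- genes$strand[gi] == "+"
      if (plus && genes$start[gi] - 750L < 1L) {
        stop("induced gene ", tag, " lacks 750 bp of upstream sequence")
      }
      if (!plus && genes$end[gi] + 750L > genome$length) {
        stop("induced gene ", tag, " lacks 750 bp of upstream sequence")
      }
      for (pl in plan) {
        pos <- pl$iv[1]:pl$iv[2]
        n_b <- length(pos)
        is_at <- stats::runif(n_b) < pl$p_at
        half <- stats::runif(n_b) < 0.5
        new_codes <- ifelse(is_at, ifelse(half, "A", "T"),
                            ifelse(half, "G", "C"))
        gpos <- if (plus) genes$start[gi] - 751L + pos else genes$end[gi] + 751L - pos
        chars[gpos] <- if (plus) new_codes else unname(comp[new_codes])
      }
    }
  })
  genome_seq(genome$chrom_id, paste(chars, collapse = ""),
             topology = genome$topology)
}

#' Simulate a qPCR Ct table
#'
#' The reference gene's Ct is constant within every sample; the target
#' gene's Ct is `reference Ct - log2(true level) + Gaussian noise`, so the
#' comparative ddCt analysis recovers the planted relative levels exactly
#' at zero noise.
#'
#' @param levels data frame with columns `gene`, `condition`, `level`
#'   (true expression relative to the calibrator condition; must be > 0).
#' @param n_replicates biological replicates per condition.
#' @param noise_sd Gaussian Ct noise, in cycles.
#' @param reference_gene endogenous control gene name.
#' @param reference_ct the reference gene's Ct value.
#' @param seed integer seed.
#' @return Ct data frame: `sample`, `condition`, `gene`, `replicate`, `ct`.
#' @export
simulate_ct_table <- function(levels, n_replicates = 3L, noise_sd = 0.1,
                              reference_gene = "hrdB", reference_ct = 20,
                              seed = 1L) {
  if (any(!is.finite(levels$level)) || any(levels$level <= 0)) {
    stop("parameter error: true levels must be positive")
  }
  conds <- unique(levels$condition)
  rows <- list()
  with_seed(derive_seed(seed, 7L), {
    for (cn in conds) {
      for (r in seq_len(n_replicates)) {
        sid <- sprintf("%s_s%d", cn, r)
        rows[[length(rows) + 1L]] <- data.frame(
          sample = sid, condition = cn, gene = reference_gene,
          replicate = 1L, ct = reference_ct, stringsAsFactors = FALSE)
        sub <- levels[levels$condition == cn, , drop = FALSE]
        for (j in seq_len(nrow(sub))) {
          ct <- reference_ct - log2(sub$level[j]) +
            if (noise_sd > 0) stats::rnorm(1, sd = noise_sd) else 0
          rows[[length(rows) + 1L]] <- data.frame(
            sample = sid, condition = cn, gene = sub$gene[j],
            replicate = 1L, ct = ct, stringsAsFactors = FALSE)
        }
      }
    }
  })
  do.call(rbind, rows)
}
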