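#' Assemble (or read) a pipeline configuration
#'
#' The configuration is one declarative list covering input paths,
#' contrasts, thresholds, window geometry, promoter geometry, tested
#' positions and the seed, so a run is fully reproducible from the file.
#'
#' @param x a YAML file path or a named list.
#' @return validated configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(x) {
  cfg <- if (is.character(x) && length(x) == 1L) yaml::read_yaml(x) else x
  defaults <- list(
    thresholds = list(log2fc = 1.5, p = 0.05, cluster_percent = 5),
    window = list(size = 250000, step = 125000),
    densest_width = 30000,
    promoter = list(upstream = 750, downstream = 210, window = 100,
                    step = 1, positions = c(340, 660), n_controls = 66),
    seed = 1L
  )
  for (k in names(defaults)) {
    if (is.null(cfg[[k]])) {
      cfg[[k]] <- defaults[[k]]
    } else if (is.list(defaults[[k]])) {
      for (kk in names(defaults[[k]])) {
        if (is.null(cfg[[k]][[kk]])) cfg[[k]][[kk]] <- defaults[[k]][[kk]]
      }
    }
  }
  if (cfg$window$size < cfg$window$step || cfg$window$step <= 0) {
    stop("config error: window size must be >= step and step > 0")
  }
  if (cfg$thresholds$log2fc <= 0 || cfg$thresholds$p <= 0 ||
      cfg$thresholds$cluster_percent <= 0) {
    stop("config error: thresholds must be positive")
  }
  if (is.null(cfg$paths) || is.null(cfg$contrasts)) {
    stop("config error: 'paths' and 'contrasts' are required")
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

#' @keywords internal
stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes, in dependency order: input parsing, upper-quartile
#' normalization and SSG classification per contrast, TSS mapping and
#' sliding-window cluster calling per direction, densest-region search,
#' promoter AT-profiling of the induced gene set against random promoter
#' and random genomic controls with positional tests, optional ddCt qPCR
#' quantification, and a cross-contrast summary. Every output TSV carries
#' a metadata header (package version, seed, parameters - never
#' timestamps), so identical configurations yield byte-identical outputs.
#'
#' @param config a [pipeline_config()], list, or YAML path.
#' @param outdir output directory (created if absent).
#' @return invisible named list of output file paths.
#' @export
run_all <- function(config, outdir) {
  cfg <- pipeline_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  log_lines <- character()
  logit <- function(...) log_lines <<- c(log_lines, sprintf(...))
  meta_base <- list(seed = cfg$seed)

  inputs <- stage("io", {
    genome <- read_fasta(cfg$paths$genome)[[1]]
    genes <- read_gff3(cfg$paths$gff)
    cm <- read_counts(cfg$paths$counts, cfg$paths$samples)
    operons <- if (!is.null(cfg$paths$operons)) read_operons(cfg$paths$operons)
    exempt <- if (!is.null(cfg$paths$exempt)) readLines(cfg$paths$exempt)
    for (p in c(cfg$paths$genome, cfg$paths$gff, cfg$paths$counts)) {
      logit("input %s md5 %s", basename(p), unname(tools::md5sum(p)))
    }
    logit("io: %d genes, %d x %d counts", nrow(genes), nrow(cm$counts),
          ncol(cm$counts))
    list(genome = genome, genes = genes, cm = cm, operons = operons,
         exempt = exempt %||% character())
  })

  diffs <- stage("diffexpr", {
    res <- list()
    for (ct in cfg$contrasts) {
      d <- run_diffexpr(inputs$cm, ct$treatment, ct$control,
                        exemption_list = inputs$exempt,
                        log2fc_threshold = cfg$thresholds$log2fc,
                        p_threshold = cfg$thresholds$p)
      nm <- sprintf("%s_vs_%s", ct$treatment, ct$control)
      f <- file.path(outdir, sprintf("diff_%s.tsv", nm))
      write_tsv_meta(as.data.frame(d), f, c(meta_base, list(
        contrast = nm, test = attr(d, "test"),
        log2fc_threshold = cfg$thresholds$log2fc,
        p_threshold = cfg$thresholds$p)))
      out[[paste0("diff_", nm)]] <- f
      logit("diffexpr %s: %d up, %d down", nm, sum(d$ssg_class == "up"),
            sum(d$ssg_class == "down"))
      res[[nm]] <- d
    }
    res
  })

  stage("cluster_scan", {
    scan_rows <- list(); call_rows <- list(); dense_rows <- list()
    for (nm in names(diffs)) {
      mt <- map_tss(diffs[[nm]], inputs$genes, inputs$operons)
      for (dir in c("up", "down")) {
        aff <- mt$affected[mt$affected$direction %in% c(dir, "both"), ]
        sc <- window_scan(aff$tss_position, mt$tu$tss_position,
                          inputs$genome$length, cfg$window$size,
                          cfg$window$step)
        scan_rows[[paste(nm, dir)]] <- cbind(contrast = nm, direction = dir,
                                             as.data.frame(sc))
        cl <- call_clusters(sc, aff$tss_position, mt$tu$tss_position,
                            cfg$thresholds$cluster_percent, dir,
                            inputs$genome$chrom_id, aff$tu_id)
        if (nrow(cl)) {
          call_rows[[paste(nm, dir)]] <- cbind(contrast = nm,
                                               as.data.frame(cl))
        }
      }
      aff_tags <- diffs[[nm]]$locus_tag[diffs[[nm]]$ssg_class %in%
                                          c("up", "down")]
      if (length(aff_tags)) {
        dr <- densest_region(inputs$genes, aff_tags, cfg$densest_width)
        dense_rows[[nm]] <- data.frame(
          contrast = nm, start = dr$start, end = dr$end,
          n_affected = dr$n_affected, n_total = dr$n_total,
          members = paste(dr$members, collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
    wmeta <- c(meta_base, list(window_size = cfg$window$size,
                               step = cfg$window$step,
                               threshold_percent = cfg$thresholds$cluster_percent))
    out$windows <- write_tsv_meta(do.call(rbind, scan_rows),
                                   file.path(outdir, "windows.tsv"), wmeta)
    calls <- if (length(call_rows)) do.call(rbind, call_rows) else
      data.frame(contrast = character(), chrom_id = character(),
                 start = numeric(), end = numeric(), direction = character(),
                 peak_window_percent = numeric(), n_affected = integer(),
                 n_total = integer(), members = character())
    out$clusters <- write_tsv_meta(calls, file.path(outdir, "clusters.tsv"),
                                    wmeta)
    out$densest <- write_tsv_meta(do.call(rbind, dense_rows),
                                   file.path(outdir, "densest_region.tsv"),
                                   c(meta_base,
                                     list(width = cfg$densest_width)))
    logit("cluster_scan: %d cluster call(s)", nrow(calls))
  })

  stage("promoter_composition", {
    pcn <- cfg$promoter_contrast %||% names(diffs)[1]
    d <- diffs[[pcn]]
    if (is.null(d)) stop("promoter_contrast '", pcn, "' not among contrasts")
    mt <- map_tss(d, inputs$genes, inputs$operons)
    up_tu <- mt$affected[mt$affected$direction %in% c("up", "both"), ]
    induced <- vapply(strsplit(up_tu$members, ","), `[[`, "", 1L)
    if (length(induced) < 3L) {
      logit("promoter_composition: skipped (%d induced gene(s))",
            length(induced))
    } else {
      pw <- suppressWarnings(
        promoter_windows(inputs$genome, inputs$genes, induced,
                         cfg$promoter$upstream, cfg$promoter$downstream))
      n_ctl <- cfg$promoter$n_controls
      rp <- sample_random_promoters(inputs$genes, inputs$genome, n_ctl,
                                    cfg$seed, cfg$promoter$upstream,
                                    cfg$promoter$downstream)
      rg <- sample_random_genomic(inputs$genome, n_ctl,
                                  cfg$promoter$upstream +
                                    cfg$promoter$downstream, cfg$seed)
      prof_i <- at_profile(pw, "induced", cfg$promoter$window,
                           cfg$promoter$step)
      prof_p <- at_profile(rp, "random_promoters", cfg$promoter$window,
                           cfg$promoter$step)
      prof_g <- at_profile(rg, "random_genomic", cfg$promoter$window,
                           cfg$promoter$step)
      prof_df <- data.frame(position = prof_i$positions,
                            induced = prof_i$mean,
                            random_promoters = prof_p$mean,
                            random_genomic = prof_g$mean)
      pmeta <- c(meta_base, list(
        contrast = pcn, n_induced = length(pw), n_controls = n_ctl,
        geometry = sprintf("%d+%d/%d/%d", cfg$promoter$upstream,
                           cfg$promoter$downstream, cfg$promoter$window,
                           cfg$promoter$step)))
      out$at_profile <- write_tsv_meta(prof_df,
                                        file.path(outdir, "at_profile.tsv"),
                                        pmeta)
      tests <- rbind(
        compare_positions(prof_i, prof_p, cfg$promoter$positions),
        compare_positions(prof_i, prof_g, cfg$promoter$positions))
      out$at_tests <- write_tsv_meta(tests,
                                      file.path(outdir, "at_tests.tsv"),
                                      pmeta)
      logit("promoter_composition: %d induced windows vs %d controls",
            length(pw), n_ctl)
    }
  })

  if (!is.null(cfg$paths$ct)) {
    stage("qpcr", {
      ct <- read_ct_table(cfg$paths$ct)
      q <- cfg$qpcr
      lv <- ddct(ct, q$target, q$reference %||% "hrdB", q$calibrator)
      out$qpcr <- write_tsv_meta(as.data.frame(lv),
                                  file.path(outdir, "qpcr_levels.tsv"),
                                  c(meta_base, list(
                                    target = q$target,
                                    reference = q$reference %||% "hrdB",
                                    calibrator = q$calibrator)))
      logit("qpcr: %d condition(s) quantified", nrow(lv))
    })
  }

  stage("summary", {
    sm <- summarize_affected(diffs, nrow(inputs$genes))
    out$summary <- write_tsv_meta(sm$per_contrast,
                                   file.path(outdir, "summary.tsv"),
                                   meta_base)
    if (!is.null(sm$overlaps)) {
      out$overlaps <- write_tsv_meta(sm$overlaps,
                                      file.path(outdir, "overlaps.tsv"),
                                      meta_base)
    }
  })

  out$log <- file.path(outdir, "run_log.txt")
  writeLines(c(sprintf("topoclust %s run log",
                       as.character(utils::packageVersion("topoclust"))),
               sprintf("seed: %s", cfg$seed), log_lines), out$log)
  invisible(out)
}

#' Generate the packaged synthetic demonstration dataset
#'
#' Writes, under `outdir`, every input the pipeline needs - genome FASTA
#' (with planted promoter architecture), GFF3 annotation, operon table,
#' counts and sample sheet, exemption list, Ct table - plus the truth
#' tables of planted effects, and a ready-to-run `config.yaml`. The
#' default design is the desk-scale study emulation: 1 Mbp at 72% GC,
#' 900 genes, six planted up- and two down-regulated clusters for the
#' long-term contrast, and 66 induced promoters for the rapid-relaxation
#' contrast. The demo configuration scales the window geometry to
#' 50 kbp / 25 kbp to keep cluster calls separable on the 1-Mbp
#' chromosome.
#'
#' @param seed integer seed (also used in the written config).
#' @param outdir directory to create the dataset in.
#' @param design a [synthetic_design()]; defaults to
#'   `synthetic_design(seed = seed)`.
#' @return invisible list with `paths` (named file paths, including
#'   `config`), `design`, `truth`, and `induced`.
#' @export
make_demo <- function(seed = 1L, outdir, design = synthetic_design(seed = seed)) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  genome <- simulate_genome(design)
  ann <- simulate_annotation(design)
  induced <- choose_induced_tus(design, ann$genes, ann$operons)
  extra <- data.frame(locus_tag = induced$locus_tag,
                      condition = design$induced_condition,
                      direction = "up",
                      log2_effect = design$induced_log2_effect,
                      cluster_id = "induced_promoter",
                      stringsAsFactors = FALSE)
  sim <- simulate_counts(design, ann$genes, extra)
  genome <- plant_promoter_architecture(genome, ann$genes, design,
                                        induced$locus_tag)
  ctrl <- names(design$conditions)[1]
  treatments <- setdiff(names(design$conditions), ctrl)
  # qPCR arm: one synthetic target with known relative levels
  lv <- data.frame(gene = "tgtA",
                   condition = c(ctrl, treatments),
                   level = c(1, 2, 4, 1.5)[seq_len(1 + length(treatments))],
                   stringsAsFactors = FALSE)
  ct <- simulate_ct_table(lv, n_replicates = 3L, noise_sd = 0.1,
                          seed = design$seed)
  exempt <- utils::head(setdiff(ann$genes$locus_tag, induced$locus_tag), 4L)

  p <- list(
    genome = file.path(outdir, "genome.fa"),
    gff = file.path(outdir, "genes.gff3"),
    operons = file.path(outdir, "operons.tsv"),
    counts = file.path(outdir, "counts.tsv"),
    samples = file.path(outdir, "samples.tsv"),
    exempt = file.path(outdir, "exempt_genes.txt"),
    ct = file.path(outdir, "ct.tsv"),
    truth_effects = file.path(outdir, "truth_effects.tsv"),
    truth_clusters = file.path(outdir, "truth_clusters.tsv"),
    truth_promoters = file.path(outdir, "truth_promoters.tsv"),
    truth_ct = file.path(outdir, "truth_ct_levels.tsv"),
    config = file.path(outdir, "config.yaml"))
  write_fasta(genome, p$genome)
  write_gff3(ann$genes, p$gff)
  write_operons(ann$operons, p$operons)
  write_counts(sim$counts, p$counts, p$samples)
  writeLines(exempt, p$exempt)
  write_ct_table(ct, p$ct)
  utils::write.table(sim$truth, p$truth_effects, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(design$planted_clusters, p$truth_clusters, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(induced, p$truth_promoters, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(lv, p$truth_ct, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cfg <- list(
    paths = lapply(p[c("genome", "gff", "operons", "counts", "samples",
                       "exempt", "ct")], normalizePath),
    contrasts = lapply(treatments, function(tr) {
      list(treatment = tr, control = ctrl)
    }),
    promoter_contrast = sprintf("%s_vs_%s", design$induced_condition, ctrl),
    thresholds = list(log2fc = 1.5, p = 0.05, cluster_percent = 5),
    window = list(size = 50000L, step = 25000L),
    densest_width = 30000L,
    promoter = list(upstream = 750L, downstream = 210L, window = 100L,
                    step = 1L, positions = c(340L, 660L), n_controls = 66L),
    qpcr = list(target = "tgtA", reference = "hrdB", calibrator = ctrl),
    seed = design$seed)
  yaml::write_yaml(cfg, p$config)
  invisible(list(paths = p, design = design, truth = sim$truth,
                 induced = induced))
}
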