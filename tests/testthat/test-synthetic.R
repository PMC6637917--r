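test_that("simulated genome composition matches the design", {
  d <- synthetic_design(seed = 3, genome_length = 1e6, n_genes = 10,
                        planted_clusters = NULL)
  g <- simulate_genome(d)
  at_pct <- 100 * mean(strsplit(g$sequence, "")[[1]] %in% c("A", "T"))
  expect_lt(abs(at_pct - 28), 0.2)
  # boundary: pure-GC genome
  d2 <- synthetic_design(seed = 3, genome_length = 5e3, gc_fraction = 1,
                         n_genes = 2, planted_clusters = NULL)
  expect_false(grepl("[AT]", simulate_genome(d2)$sequence))
  # determinism
  expect_identical(simulate_genome(d)$sequence, simulate_genome(d)$sequence)
  expect_error(synthetic_design(gc_fraction = 1.2), "gc_fraction")
})

test_that("simulated annotations tile disjoint genes and honor operon structure", {
  d <- synthetic_design(seed = 9, genome_length = 2e5, n_genes = 100,
                        operon_fraction = 0.5, planted_clusters = NULL)
  ann <- simulate_annotation(d)
  expect_equal(nrow(ann$genes), 100L)
  # pairwise disjoint: sorted intervals never overlap
  g <- ann$genes[order(ann$genes$start), ]
  expect_true(all(g$start[-1] > g$end[-nrow(g)]))
  expect_true(max(g$end) <= d$genome_length)

  # operon_fraction 0 -> all singletons
  d0 <- synthetic_design(seed = 9, genome_length = 5e4, n_genes = 10,
                         operon_fraction = 0, planted_clusters = NULL)
  ann0 <- simulate_annotation(d0)
  expect_equal(nrow(ann0$operons), 0L)
  expect_equal(length(unique(transcription_units(ann0$genes)$tu_id)), 10L)

  # operon_fraction 1, size 2, 10 genes -> exactly 5 TUs of 2
  d1 <- synthetic_design(seed = 9, genome_length = 5e4, n_genes = 10,
                         operon_fraction = 1, operon_size = 2,
                         planted_clusters = NULL)
  tu <- transcription_units(simulate_annotation(d1)$genes,
                            simulate_annotation(d1)$operons)
  expect_equal(length(unique(tu$tu_id)), 5L)
  expect_true(all(table(tu$tu_id) == 2L))

  expect_error(
    simulate_annotation(synthetic_design(seed = 1, genome_length = 5e3,
                                         n_genes = 100,
                                         planted_clusters = NULL)),
    "too short")
})

test_that("simulated counts follow the planted negative-binomial model", {
  # null model at Poisson limit: per-gene sample mean near baseline
  d <- synthetic_design(seed = 21, genome_length = 1e5, n_genes = 40,
                        conditions = c(control = 10, trt = 10),
                        baseline_mean = 1000, nb_dispersion = 0,
                        planted_clusters = NULL)
  ann <- simulate_annotation(d)
  sim <- simulate_counts(d, ann$genes)
  means <- rowMeans(sim$counts$counts)
  se <- sqrt(1000 / ncol(sim$counts$counts))
  expect_true(all(abs(means - 1000) < 3 * se * 1.5))
  expect_equal(nrow(sim$truth), 0L)

  # planted log2 effect of 2 -> condition mean ratio near 4 at n = 50
  d2 <- synthetic_design(seed = 22, genome_length = 1e5, n_genes = 40,
                         conditions = c(control = 50, trt = 50),
                         baseline_mean = 500, nb_dispersion = 0.05,
                         planted_clusters = data.frame(
                           condition = "trt", start = 1, end = 1e5,
                           direction = "up", log2_effect = 2, fraction = 1))
  ann2 <- simulate_annotation(d2)
  sim2 <- simulate_counts(d2, ann2$genes)
  expect_setequal(sim2$truth$locus_tag, ann2$genes$locus_tag)
  cm <- sim2$counts
  trt_mean <- rowMeans(cm$counts[, cm$samples$condition == "trt"])
  ctl_mean <- rowMeans(cm$counts[, cm$samples$condition == "control"])
  ratio <- mean(trt_mean) / mean(ctl_mean)
  expect_lt(abs(ratio - 4), 0.3)

  # determinism: identical TSVs from identical designs
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  s1 <- withr::local_tempfile(); s2 <- withr::local_tempfile()
  write_counts(simulate_counts(d2, ann2$genes)$counts, f1, s1)
  write_counts(simulate_counts(d2, ann2$genes)$counts, f2, s2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("promoter architecture planting is local and boosts AT as designed", {
  d <- synthetic_design(seed = 31, genome_length = 3e5, n_genes = 120,
                        n_induced_promoters = 30, planted_clusters = NULL,
                        promoter_at_boost = 3, promoter_gc_boost = 3)
  g0 <- simulate_genome(d)
  ann <- simulate_annotation(d)
  induced <- choose_induced_tus(d, ann$genes, ann$operons)
  g1 <- plant_promoter_architecture(g0, ann$genes, d, induced$locus_tag)

  # zero boosts leave the genome untouched
  d0 <- d; d0$promoter_at_boost <- 0; d0$promoter_gc_boost <- 0
  expect_identical(
    plant_promoter_architecture(g0, ann$genes, d0, induced$locus_tag)$sequence,
    g0$sequence)

  # locality: every base outside the planted intervals is unchanged
  mask <- rep(FALSE, g0$length)
  for (tag in induced$locus_tag) {
    gi <- match(tag, ann$genes$locus_tag)
    for (iv in list(d$promoter_at_interval, d$promoter_gc_interval)) {
      pos <- iv[1]:iv[2]
      gpos <- if (ann$genes$strand[gi] == "+") {
        ann$genes$start[gi] - 751L + pos
      } else {
        ann$genes$end[gi] + 751L - pos
      }
      mask[gpos] <- TRUE
    }
  }
  c0 <- strsplit(g0$sequence, "")[[1]]
  c1 <- strsplit(g1$sequence, "")[[1]]
  expect_identical(c1[!mask], c0[!mask])
  expect_false(identical(c1[mask], c0[mask]))

  # planted +3-point AT boost is recovered from the profiles near the boost
  pi0 <- at_profile(promoter_windows(g0, ann$genes, induced$locus_tag), "pre")
  pi1 <- at_profile(promoter_windows(g1, ann$genes, induced$locus_tag), "post")
  boost_region <- 620:660  # windows fully inside the boosted interval
  at_gain <- mean(pi1$mean[boost_region] - pi0$mean[boost_region])
  expect_lt(abs(at_gain - 3), 1.5)
  gc_region <- 350:360    # windows fully inside the GC block
  gc_loss <- mean(pi1$mean[gc_region] - pi0$mean[gc_region])
  expect_lt(abs(gc_loss + 3), 1.5)
})

test_that("simulated Ct tables recover planted relative levels", {
  lv <- data.frame(gene = "tgt", condition = c("wt", "dep"), level = c(1, 4))
  ct0 <- simulate_ct_table(lv, n_replicates = 2, noise_sd = 0,
                           seed = 5)
  res <- ddct(ct0, "tgt", "hrdB", "wt")
  expect_equal(res$relative_level[res$condition == "wt"], 1)
  expect_equal(res$relative_level[res$condition == "dep"], 4)

  lv05 <- data.frame(gene = "tgt", condition = c("wt", "dep"),
                     level = c(1, 0.5))
  res05 <- ddct(simulate_ct_table(lv05, 2, 0, seed = 5), "tgt", "hrdB", "wt")
  expect_equal(res05$relative_level[res05$condition == "dep"], 0.5)

  expect_error(simulate_ct_table(data.frame(gene = "t", condition = "wt",
                                            level = 0)),
               "positive")

  # with noise, the mean recovered level approaches truth
  levels_hat <- vapply(1:100, function(i) {
    ct <- simulate_ct_table(lv, n_replicates = 2, noise_sd = 0.1, seed = i)
    res <- ddct(ct, "tgt", "hrdB", "wt")
    res$relative_level[res$condition == "dep"]
  }, numeric(1))
  se <- sd(levels_hat) / sqrt(length(levels_hat))
  expect_lt(abs(mean(levels_hat) - 4), 3 * se + 0.05)
})
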