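make_cm <- function(m, conditions) {
  count_matrix(m, data.frame(sample = colnames(m), condition = conditions,
                             replicate = stats::ave(seq_along(conditions),
                                                    conditions,
                                                    FUN = seq_along)))
}

test_that("upper quartile matches the enumeration oracle", {
  expect_equal(upper_quartile(c(10, 20, 30, 40)), 40)
  expect_equal(upper_quartile(c(0, 0, 10, 20, 30, 40)), 40)
  set.seed(101)
  for (i in 1:50) {
    x <- rpois(sample(3:30, 1), 20)
    if (all(x == 0)) next
    expect_equal(upper_quartile(x), bf_upper_quartile(x))
  }
})

test_that("upper-quartile normalization equalizes samples and keeps zeros", {
  m <- matrix(c(10L, 20L, 30L, 40L, 0L, 0L,
                20L, 40L, 60L, 80L, 0L, 0L), ncol = 2,
              dimnames = list(sprintf("g%d", 1:6), c("a", "b")))
  cm <- make_cm(m, c("x", "y"))
  expect_error(normalize_upper_quartile(cm), NA)
  ex <- normalize_upper_quartile(cm)
  # scale invariance: b = 2a normalizes to identical columns
  expect_equal(ex$values[, "a"], ex$values[, "b"])
  expect_true(all(ex$values[m == 0] == 0))
  # the normalized upper quartile is the common reference scale
  uq_after <- apply(ex$values, 2, function(v) upper_quartile(v))
  expect_equal(unname(uq_after), rep(ex$reference_scale, 2))
  # identical samples stay identical
  m2 <- cbind(a = m[, 1], b = m[, 1])
  ex2 <- normalize_upper_quartile(make_cm(m2, c("x", "y")))
  expect_equal(ex2$values[, "a"], ex2$values[, "b"])
  # all-zero sample is named in the error
  m3 <- cbind(a = m[, 1], dead = 0L)
  expect_error(normalize_upper_quartile(make_cm(m3, c("x", "y"))), "dead")
})

expr_from_means <- function(mc, mt, reps = 3) {
  m <- cbind(matrix(rep(mc, reps), ncol = reps,
                    dimnames = list(names(mc), sprintf("c%d", 1:reps))),
             matrix(rep(mt, reps), ncol = reps,
                    dimnames = list(names(mc), sprintf("t%d", 1:reps))))
  structure(list(values = m,
                 samples = data.frame(sample = colnames(m),
                                      condition = rep(c("ctl", "trt"),
                                                      each = reps),
                                      replicate = rep(1:reps, 2)),
                 uq = rep(1, 2 * reps), reference_scale = 1),
            class = "expression_matrix")
}

test_that("log2 fold changes follow the treatment/control convention", {
  mc <- c(g1 = 100, g2 = 1, g3 = 100, g4 = 0)
  mt <- c(g1 = 100, g2 = 8, g3 = 271, g4 = 0)
  ex <- expr_from_means(mc, mt)
  fc <- log2_fold_change(ex, c("trt", "ctl"))
  expect_equal(fc$log2fc[fc$locus_tag == "g1"], 0)
  expect_equal(fc$log2fc[fc$locus_tag == "g2"], 3)
  # a 2.71-fold induction corresponds to log2 FC of about 1.44
  expect_equal(fc$log2fc[fc$locus_tag == "g3"], log2(2.71), tolerance = 1e-9)
  expect_equal(round(fc$log2fc[fc$locus_tag == "g3"], 2), 1.44)
  expect_true(is.na(fc$log2fc[fc$locus_tag == "g4"]))  # 0/0, no pseudocount

  # zero mean in one condition only: pseudocount 1 fallback, flagged
  mt2 <- c(g1 = 15, g2 = 8, g3 = 271, g4 = 0)
  mc2 <- c(g1 = 0, g2 = 1, g3 = 100, g4 = 2)
  fc2 <- log2_fold_change(expr_from_means(mc2, mt2), c("trt", "ctl"))
  expect_equal(fc2$log2fc[fc2$locus_tag == "g1"], 4)
  expect_true(fc2$pseudocount_flag[fc2$locus_tag == "g1"])

  # antisymmetry under contrast swap at pseudocount 0
  fc_f <- log2_fold_change(ex, c("trt", "ctl"), pseudocount = 0)
  fc_r <- log2_fold_change(ex, c("ctl", "trt"), pseudocount = 0)
  ok <- is.finite(fc_f$log2fc)
  expect_equal(fc_f$log2fc[ok], -fc_r$log2fc[ok])
})

test_that("Welch significance matches the closed form and handles degeneracy", {
  m <- rbind(
    flat = c(5, 5, 5, 5, 5, 5),
    big  = c(5, 5, 5, 500, 500, 500),
    var  = c(10, 20, 30, 200, 300, 400))
  colnames(m) <- sprintf("s%d", 1:6)
  ex <- structure(list(values = m,
                       samples = data.frame(sample = colnames(m),
                                            condition = rep(c("ctl", "trt"),
                                                            each = 3),
                                            replicate = rep(1:3, 2)),
                       uq = rep(1, 6), reference_scale = 1),
                  class = "expression_matrix")
  sig <- test_significance(ex, c("trt", "ctl"))
  expect_equal(sig$p_value[sig$locus_tag == "flat"], 1)
  # constant groups with different values: zero within-group variance
  expect_lt(sig$p_value[sig$locus_tag == "big"], 0.05)
  # non-degenerate gene agrees with the closed-form Welch oracle
  expect_equal(sig$p_value[sig$locus_tag == "var"],
               bf_welch_p(log2(m["var", 4:6] + 1), log2(m["var", 1:3] + 1)),
               tolerance = 1e-12)
  # q-values follow the step-up procedure computed by hand
  expect_equal(sig$q_value, bf_bh(sig$p_value))
  expect_equal(bf_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
})

test_that("SSG classification applies thresholds and the exemption rule", {
  diff <- data.frame(
    locus_tag = c("sco4667", "sco4676", "hupS", "border", "nosig"),
    log2fc = c(9.75, 1.22, log2(0.76), 1.5, 4),
    p_value = c(0.001, 0.001, 0.01, 0.001, 0.5))
  out <- classify_ssg(diff, exemption_list = "hupS")
  cls <- setNames(out$ssg_class, out$locus_tag)
  expect_equal(cls[["sco4667"]], "up")
  expect_equal(cls[["sco4676"]], "not_significant")  # inside the +/-1.5 band
  expect_equal(cls[["hupS"]], "down")   # exempt: p-value only, sign decides
  expect_equal(cls[["border"]], "not_significant")   # threshold is strict
  expect_equal(cls[["nosig"]], "not_significant")
  # the elimination band edge corresponds to a 2.83-fold change
  expect_equal(round(2^1.5, 2), 2.83)
})

test_that("summaries report genome percentages and condition specificity", {
  mk <- function(tags) data.frame(locus_tag = tags,
                                  ssg_class = rep("up", length(tags)))
  a <- mk(sprintf("a%03d", 1:552)); a$locus_tag[1:144] <- sprintf("sh%03d", 1:144)
  b <- mk(sprintf("b%03d", 1:214)); b$locus_tag[1:144] <- sprintf("sh%03d", 1:144)
  sm <- summarize_affected(list(down = a, up = b), n_total_genes = 7846)
  expect_equal(sm$per_contrast$n_affected, c(552, 214))
  expect_equal(sm$per_contrast$pct_of_genome, c(7.0, 2.7))
  expect_equal(sm$overlaps$n_a_specific, 408)
  expect_gt(sm$overlaps$pct_a_specific, 70)          # "more than 70%"
  expect_equal(sm$overlaps$n_b_specific, 70)
  expect_equal(floor(sm$overlaps$pct_b_specific), 32)
  # empty result set gives an all-zero summary
  sm0 <- summarize_affected(list(x = mk(character())[0, ]), 100)
  expect_equal(sm0$per_contrast$n_affected, 0)
  expect_error(summarize_affected(list(x = a), 0), "> 0")
})

test_that("classification recovers planted effects on synthetic counts", {
  d <- synthetic_design(seed = 77, genome_length = 2e5, n_genes = 180,
                        conditions = c(control = 3, trt = 3),
                        baseline_mean = 200, nb_dispersion = 0.05,
                        planted_clusters = data.frame(
                          condition = "trt", start = 1, end = 4e4,
                          direction = "up", log2_effect = 3, fraction = 0.5))
  ann <- simulate_annotation(d)
  sim <- simulate_counts(d, ann$genes)
  res <- run_diffexpr(sim$counts, "trt", "control")
  truth_up <- sim$truth$locus_tag
  called_up <- res$locus_tag[res$ssg_class == "up"]
  sens <- mean(truth_up %in% called_up)
  unaffected <- setdiff(ann$genes$locus_tag, truth_up)
  fpr <- mean(unaffected %in% res$locus_tag[res$ssg_class != "not_significant"])
  expect_gte(sens, 0.9)
  expect_lte(fpr, 0.05)
})
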