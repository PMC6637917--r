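test_that("promoter windows place the start codon at position 751", {
  set.seed(12)
  seq <- random_genome_string(3000)
  # plant ATG at 1601..1603 for a plus-strand gene starting at 1601
  substr(seq, 1601, 1603) <- "ATG"
  g <- genome_seq("c", seq)
  plus <- list(locus_tag = "p", start = 1601L, end = 2200L, strand = "+")
  w <- extract_promoter_window(g, plus)
  expect_equal(nchar(w), 960L)
  expect_equal(substr(w, 751, 753), "ATG")
  expect_equal(w, substr(seq, 1601 - 750, 1601 + 209))

  # boundary: gene starting at 751 yields bases 1..960 verbatim
  b <- list(locus_tag = "b", start = 751L, end = 1500L, strand = "+")
  expect_equal(extract_promoter_window(g, b), substr(seq, 1, 960))

  # minus strand: reverse complement; re-complementing recovers the slice
  minus <- list(locus_tag = "m", start = 1000L, end = 1800L, strand = "-")
  wm <- extract_promoter_window(g, minus)
  expect_equal(nchar(wm), 960L)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(wm)))
  expect_equal(rc, substr(seq, 1800 - 209, 1800 + 750))

  # insufficient flank is skipped with a warning, not an error
  short <- list(locus_tag = "s", start = 100L, end = 700L, strand = "+")
  expect_warning(res <- extract_promoter_window(g, short), "insufficient")
  expect_null(res)
})

test_that("AT profiles match brute-force window counts", {
  p_allA <- at_profile(strrep("A", 960))
  expect_length(p_allA$mean, 861L)
  expect_true(all(p_allA$mean == 100))
  expect_true(all(at_profile(strrep("GC", 480))$mean == 0))

  mixed <- paste0(strrep("A", 50), strrep("G", 910))
  pm <- at_profile(mixed)
  expect_equal(unname(pm$mean[1]), 50)
  expect_equal(unname(pm$mean[51]), 0)

  set.seed(23)
  s <- random_genome_string(960, gc = 0.7)
  expect_equal(unname(at_profile(s)$mean), bf_at_profile(s))

  # profile values bounded; length errors are named
  expect_true(all(pm$mean >= 0 & pm$mean <= 100))
  expect_error(at_profile(c(good = strrep("A", 960), bad = strrep("A", 959))),
               "bad")

  # complement invariance: the reverse complement mirrors the profile
  p_fwd <- at_profile(s)$mean
  p_rc <- at_profile(as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s))))$mean
  expect_equal(unname(p_rc), rev(unname(p_fwd)))

  # grand mean equals pooled windowed AT content (count conservation)
  two <- c(a = s, b = random_genome_string(960, gc = 0.7))
  prof <- at_profile(two)
  expect_equal(mean(prof$mean), mean(prof$per_seq))
})

test_that("random promoter and genomic sampling is deterministic and uniform", {
  set.seed(31)
  g <- genome_seq("c", random_genome_string(8e4, gc = 0.72))
  starts <- as.integer(seq(2000, 78000, length.out = 40))
  genes <- data.frame(locus_tag = sprintf("g%02d", 1:40), chrom_id = "c",
                      start = starts, end = starts + 500L,
                      strand = rep(c("+", "-"), 20), product = NA)
  # n = all eligible genes returns the full eligible set
  all_w <- sample_random_promoters(genes, g, n = 40, seed = 1)
  expect_setequal(names(all_w), genes$locus_tag)
  expect_true(all(nchar(all_w) == 960))
  # determinism, and seed sensitivity
  expect_identical(sample_random_promoters(genes, g, 10, seed = 7),
                   sample_random_promoters(genes, g, 10, seed = 7))
  expect_false(identical(names(sample_random_promoters(genes, g, 10, seed = 7)),
                         names(sample_random_promoters(genes, g, 10, seed = 8))))
  expect_error(sample_random_promoters(genes, g, 100, seed = 1), "fewer than")

  # overlap of independent draws behaves hypergeometrically
  ref <- names(sample_random_promoters(genes, g, 10, seed = 0))
  overlaps <- vapply(1:300, function(s) {
    length(intersect(ref, names(sample_random_promoters(genes, g, 10,
                                                        seed = s))))
  }, numeric(1))
  # mean overlap of two size-10 draws from 40 is 10*10/40 = 2.5
  expect_lt(abs(mean(overlaps) - 2.5), 3 * sd(overlaps) / sqrt(300))

  # random genomic draws: determinism, bounds, composition
  expect_identical(sample_random_genomic(g, 5, seed = 3),
                   sample_random_genomic(g, 5, seed = 3))
  expect_error(sample_random_genomic(g, 5, length = 9e4), "exceeds")
  draws <- sample_random_genomic(g, 66, seed = 4)
  at_mean <- mean(vapply(draws, function(s) {
    100 * mean(strsplit(s, "")[[1]] %in% c("A", "T"))
  }, numeric(1)))
  expect_lt(abs(at_mean - 28), 1.5)
})

test_that("positional comparisons report normality and t-test p-values", {
  mk_prof <- function(vals, label) {
    # single-window sequences so each per-sequence value is exact
    seqs <- vapply(vals, function(v) {
      paste0(strrep("A", v), strrep("G", 100 - v))
    }, character(1))
    at_profile(seqs, label)
  }
  a <- mk_prof(c(30, 32, 34, 36), "a")
  b <- mk_prof(c(20, 22, 24, 26), "b")
  cmp <- compare_positions(a, b, positions = 1)
  expect_equal(cmp$mean_a, 33)
  expect_equal(cmp$mean_b, 23)
  expect_equal(cmp$t_p, bf_welch_p(c(30, 32, 34, 36), c(20, 22, 24, 26)),
               tolerance = 1e-12)
  # identical sets: t statistic 0, p = 1
  same <- compare_positions(a, mk_prof(c(30, 32, 34, 36), "a2"), positions = 1)
  expect_equal(same$t_p, 1)
  # n < 3: normality is missing but the t-test still runs
  small <- compare_positions(mk_prof(c(30, 36), "s1"),
                             mk_prof(c(20, 26), "s2"), positions = 1)
  expect_true(is.na(small$normality_p_a))
  expect_false(is.na(small$t_p))
  expect_error(compare_positions(a, b, positions = 999), "position")
})
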