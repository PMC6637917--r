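# Independent brute-force oracles and shared fixtures for the suite.

# Upper quartile by candidate enumeration: the smallest nonzero value whose
# empirical CDF over the nonzero counts strictly exceeds 0.75.
bf_upper_quartile <- function(x) {
  nz <- x[x > 0]
  for (v in sort(unique(nz))) {
    if (mean(nz <= v) > 0.75) return(v)
  }
  max(nz)
}

# Per-window recount with explicit loops over positions.
bf_window_scan <- function(affected, all_pos, genome_length, window, step) {
  starts <- seq(1, genome_length, by = step)
  out <- data.frame(window_start = starts, n_total = 0L, n_affected = 0L)
  for (i in seq_along(starts)) {
    e <- min(starts[i] + window - 1, genome_length)
    for (p in all_pos) {
      if (p >= starts[i] && p <= e) out$n_total[i] <- out$n_total[i] + 1L
    }
    for (p in affected) {
      if (p >= starts[i] && p <= e) out$n_affected[i] <- out$n_affected[i] + 1L
    }
  }
  out$percent <- ifelse(out$n_total > 0, 100 * out$n_affected / out$n_total,
                        NA_real_)
  out
}

# Exhaustive densest-interval search with a double loop.
bf_densest <- function(starts, affected_flags, width) {
  best <- c(-1, -1, 0)  # n_affected, ratio, start
  for (i in seq_along(starts)) {
    na <- 0L; nt <- 0L
    for (j in seq_along(starts)) {
      if (starts[j] >= starts[i] && starts[j] <= starts[i] + width - 1) {
        nt <- nt + 1L
        if (affected_flags[j]) na <- na + 1L
      }
    }
    if (na > best[1] || (na == best[1] && na / nt > best[2])) {
      best <- c(na, na / nt, starts[i])
    }
  }
  list(n_affected = best[1], start = best[3])
}

# Benjamini-Hochberg step-up written out directly.
bf_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}

# Welch t p-value from the closed form.
bf_welch_p <- function(x, y) {
  v1 <- var(x) / length(x); v2 <- var(y) / length(y)
  t_stat <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
  2 * pt(-abs(t_stat), df)
}

# Windowed AT% by explicit per-window counting.
bf_at_profile <- function(seq, window = 100) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch) - window + 1
  vapply(seq_len(n), function(i) {
    100 * sum(ch[i:(i + window - 1)] %in% c("A", "T")) / window
  }, numeric(1))
}

random_genome_string <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# One shared desk-scale demo dataset + pipeline run, built once per session.
.fixtures <- new.env(parent = emptyenv())
demo_fixture <- function() {
  if (is.null(.fixtures$demo)) {
    dir <- file.path(tempdir(), "topoclust-demo")
    .fixtures$demo <- make_demo(seed = 42L, outdir = dir)
    .fixtures$out <- suppressWarnings(
      run_all(.fixtures$demo$paths$config, file.path(dir, "out")))
  }
  list(demo = .fixtures$demo, out = .fixtures$out)
}
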