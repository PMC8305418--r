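# Small simulation configuration for fast unit tests: 6 lines, 61 genes,
# 2 guides per gene (1 per semi-library).
tiny_config <- function(seed = 11, ...) {
  sim_config(
    seed = seed,
    lines_per_histotype = c(AD = 2L, SCLC = 2L, SCC = 2L),
    n_common_essential = 15L,
    n_histotype_specific = 4L,
    n_nonessential = 30L,
    n_amplified_neutral = 4L,
    guides_per_gene = 2L,
    count_depth_mean = 300,
    ...
  )
}

# One memoised tiny simulation shared by read-only tests.
tiny_sim_cache <- new.env(parent = emptyenv())
tiny_sim <- function() {
  if (is.null(tiny_sim_cache$sim)) {
    tiny_sim_cache$sim <- simulate_screen(tiny_config())
  }
  tiny_sim_cache$sim
}

# Pipeline runs at full default scale are expensive; memoise them so the
# acceptance tests for parameter recovery, copy-number rescue and
# end-to-end calling share one set of runs.
default_run_cache <- new.env(parent = emptyenv())
default_runs <- function(seeds = 1:3) {
  key <- paste(seeds, collapse = "_")
  if (is.null(default_run_cache[[key]])) {
    default_run_cache[[key]] <- lapply(seeds, function(s) {
      cfg <- run_config(outdir = file.path(tempdir(), paste0("sdrun", s)), seed = s)
      suppressMessages(suppressWarnings(cmd_run_all(cfg)))
    })
  }
  default_run_cache[[key]]
}

# Independent brute-force reimplementation of the histotype calling rule,
# used as an oracle: plain loops, no shared code with the package.
brute_force_calls <- function(mat, histotypes, D, min_fraction, candidates) {
  histos <- c("AD", "SCLC", "SCC")
  out <- list()
  for (h in histos) {
    lines_h <- names(histotypes)[histotypes == h]
    called <- character(0)
    for (g in candidates) {
      n_below <- 0
      for (l in lines_h) {
        v <- mat[g, l]
        if (!is.na(v) && v <= D) n_below <- n_below + 1
      }
      if (n_below / length(lines_h) >= min_fraction) called <- c(called, g)
    }
    out[[h]] <- called
  }
  out
}

# Exact upper-tail hypergeometric probability by direct enumeration of the
# sampling formula (independent of stats::phyper).
hyper_tail_enum <- function(k, K, N, n) {
  if (k <= 0) return(1)
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Naive Benjamini-Hochberg: sort, scale by m/rank, cumulative minimum from
# the largest rank down, restore input order.
bh_naive <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}
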