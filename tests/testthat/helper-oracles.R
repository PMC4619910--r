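# Independent brute-force oracles used across test files.

# Naive sliding-window scan: every window compared against every site.
scan_oracle <- function(sequence, seeds) {
  s <- chartr("U", "T", toupper(sequence))
  k <- nchar(seeds$site[1])
  hits <- list()
  for (pos in seq_len(max(0L, nchar(s) - k + 1L))) {
    win <- substr(s, pos, pos + k - 1L)
    for (i in seq_len(nrow(seeds))) {
      if (win == seeds$site[i]) {
        hits[[length(hits) + 1L]] <- data.frame(
          arm = seeds$arm[i], quality = seeds$quality[i], position = pos,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, c(hits, list(data.frame(arm = character(),
                                         quality = character(),
                                         position = integer()))))
}

# Benjamini-Hochberg by the step-up formula: min over the tail of p*m/rank.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(ord == i)
    tail_idx <- ord[seq(rank_i, m)]
    adj[i] <- min(1, min(p[tail_idx] * m / match(tail_idx, ord)))
  }
  adj
}

# Exact two-sided rank-sum p by direct enumeration, written independently
# of the package implementation (explicit loop over assignments).
wrs_enum_oracle <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  ranks <- rank(pooled)
  w_obs <- sum(ranks[seq_len(nx)])
  combos <- utils::combn(length(pooled), nx, simplify = FALSE)
  w_all <- vapply(combos, function(idx) sum(ranks[idx]), numeric(1))
  min(1, 2 * min(mean(w_all <= w_obs + 1e-9), mean(w_all >= w_obs - 1e-9)))
}

tiny_sim <- function(...) {
  args <- utils::modifyList(
    list(n_genes = 40, cliques_null = c(5), cliques_mir142 = c(4),
         n_de_genes = 6, utr_length_range = c(60L, 120L),
         planted_sites = "none", rng_seed = 101L),
    list(...))
  do.call(sim_config, args)
}
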