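# Independent oracles the test suite checks the implementation against.
# These deliberately use a different computational route than the package.

# Step-up Benjamini-Hochberg, written directly from the definition:
# q_(i) = min_{j >= i} p_(j) * m / j, capped at 1, mapped to input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(ps[i:m] * m / (i:m))
  }
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# One-way ANOVA per gene through R's linear-model machinery.
oracle_anova <- function(values, groups) {
  fit <- stats::anova(stats::lm(values ~ groups))
  list(F = fit$`F value`[1L], p = fit$`Pr(>F)`[1L])
}

# Brute-force connection score: plain sum of products and the explicit
# maximum pairing of sorted magnitudes.
oracle_score <- function(genes, q, ranks) {
  raw <- sum(q * ranks[genes])
  qs <- sort(abs(q), decreasing = TRUE)
  N <- length(ranks)
  raw / sum(qs * (N - seq_along(qs) + 1))
}

# Exact permutation null: enumerate every assignment of the signed-rank
# vector q to an ordered tuple of distinct genes, uniformly weighted.
# Returns P(|c_rand| >= |c_obs|). Feasible for small N and m.
oracle_exact_p <- function(q, ranks, c_obs) {
  N <- length(ranks)
  m <- length(q)
  gene_tuples <- function(avail, m) {
    if (m == 0L) return(list(integer(0)))
    out <- list()
    for (i in seq_along(avail)) {
      for (rest in gene_tuples(avail[-i], m - 1L)) {
        out[[length(out) + 1L]] <- c(avail[i], rest)
      }
    }
    out
  }
  tuples <- gene_tuples(seq_len(N), m)
  qs <- sort(abs(q), decreasing = TRUE)
  ms <- sum(qs * (N - seq_along(qs) + 1))
  cs <- vapply(tuples, function(tp) sum(q * ranks[tp]) / ms, numeric(1))
  mean(abs(cs) >= abs(c_obs) - 1e-12)
}

# Small helper: a valid derived-style signature over the given universe.
toy_signature <- function(universe, n_up = 3L, n_down = 3L,
                          id = "toy") {
  gene_signature(c(universe[seq_len(n_up)],
                   universe[n_up + seq_len(n_down)]),
                 c(seq.int(n_up, 1L), -seq.int(n_down, 1L)),
                 id, strict = TRUE)
}
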