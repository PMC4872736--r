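# Statistically significant connectivity mapping: signed-rank reference
# profiles, normalized connection scores, permutation p-values from random
# signatures, the expected-false-positive threshold and drug-level hit
# selection.

#' Convert differential statistics to a signed-rank profile
#'
#' Genes are ranked by the magnitude of their differential statistic: the
#' most extreme gene receives rank magnitude `N` (the universe size), the
#' least extreme magnitude 1. The sign of each gene's rank is the sign of
#' its statistic. Ties in magnitude are broken by lexicographic gene id;
#' genes with a statistic of exactly zero take the smallest magnitudes
#' with positive sign. Both conventions are deterministic so profile
#' construction is reproducible.
#'
#' @param stats Named numeric vector of per-gene differential statistics
#'   covering the whole gene universe; all values finite.
#' @param instance_id,perturbagen,cell_line,dose Instance metadata.
#' @return A `reference_profile`: list with `instance_id`, `perturbagen`,
#'   `cell_line`, `dose` and `signed_ranks` (named integer vector whose
#'   magnitudes are a permutation of `1..N`).
#' @export
build_reference_profile <- function(stats, instance_id = "instance",
                                    perturbagen = "perturbagen",
                                    cell_line = NA_character_,
                                    dose = NA_character_) {
  if (!is.numeric(stats) || is.null(names(stats)) ||
      anyDuplicated(names(stats))) {
    stop("stats must be a numeric vector named by unique gene ids",
         call. = FALSE)
  }
  if (any(!is.finite(stats))) {
    stop(sprintf("non-finite statistics for genes: %s",
                 paste(names(stats)[!is.finite(stats)], collapse = ", ")),
         call. = FALSE)
  }
  structure(list(instance_id = as.character(instance_id),
                 perturbagen = as.character(perturbagen),
                 cell_line = as.character(cell_line),
                 dose = dose,
                 signed_ranks = signed_ranks_from_stats(stats)),
            class = "reference_profile")
}

# Core signed-rank conversion shared by build_reference_profile() and the
# refset simulator.
signed_ranks_from_stats <- function(stats) {
  N <- length(stats)
  ord <- order(-abs(stats), names(stats))
  mag <- integer(N)
  mag[ord] <- seq.int(N, 1L)
  s <- ifelse(stats < 0, -1L, 1L) # zero statistics get positive sign
  r <- as.integer(mag * s)
  names(r) <- names(stats)
  r
}

#' Construct a reference set
#'
#' @param ranks Integer matrix of signed ranks, genes x instances, with
#'   gene rownames and instance colnames; each column's magnitudes must be
#'   a permutation of `1..N`.
#' @param index data.frame with one row per instance: `instance_id`,
#'   `perturbagen`, `cell_line` and optionally `dose`.
#' @param provenance Free-text origin note.
#' @return A `refset` object.
#' @export
refset <- function(ranks, index, provenance = "") {
  if (is.null(rownames(ranks)) || anyDuplicated(rownames(ranks))) {
    stop("rank matrix needs unique gene rownames", call. = FALSE)
  }
  if (nrow(index) != ncol(ranks)) {
    stop("index rows must match rank-matrix columns", call. = FALSE)
  }
  if (anyDuplicated(index$instance_id)) {
    stop("instance ids must be unique", call. = FALSE)
  }
  N <- nrow(ranks)
  a <- abs(ranks)
  if (any(a < 1L) || any(a > N) ||
      any(colSums(a) != N * (N + 1) / 2)) {
    stop("each profile's rank magnitudes must be a permutation of 1..N",
         call. = FALSE)
  }
  colnames(ranks) <- index$instance_id
  if (is.null(index$dose)) index$dose <- NA_character_
  structure(list(universe = rownames(ranks), ranks = ranks, index = index,
                 provenance = provenance),
            class = "refset")
}

#' @export
print.refset <- function(x, ...) {
  cat(sprintf("refset: %d instances x %d-gene universe (%d perturbagens)\n",
              ncol(x$ranks), nrow(x$ranks),
              length(unique(x$index$perturbagen))))
  invisible(x)
}

# Extract the signed-rank vector(s) behind a profile or refset.
rank_matrix <- function(ref) {
  if (inherits(ref, "refset")) return(ref$ranks)
  if (inherits(ref, "reference_profile")) {
    return(matrix(ref$signed_ranks,
                  dimnames = list(names(ref$signed_ranks),
                                  ref$instance_id)))
  }
  if (is.numeric(ref) && !is.null(names(ref))) {
    return(matrix(ref, dimnames = list(names(ref), "ref")))
  }
  stop("reference must be a refset, reference_profile or named rank vector",
       call. = FALSE)
}

# Maximum attainable raw score for a signature rank multiset against an
# N-gene universe: pair the sorted signature magnitudes with the top
# reference magnitudes N, N-1, ...
max_connection_score <- function(ranks, N) {
  q <- sort(abs(ranks), decreasing = TRUE)
  sum(q * (N - seq_along(q) + 1))
}

#' Connection score between a signature and a reference profile
#'
#' The raw score is the inner product `sum_i q_i * r(g_i)` of the
#' signature's signed ranks with the reference profile's signed ranks at
#' the signature genes. The normalized score divides by the maximum
#' attainable raw score, so `c` lies in `[-1, 1]`: `+1` when the
#' signature genes occupy the extreme reference positions with matching
#' signs and magnitude order (the drug mimics the signature), `-1` for
#' the exact reversal.
#'
#' @param sig A [gene_signature()].
#' @param ref A `reference_profile`, a named signed-rank vector, or a
#'   [refset()] (vectorized over instances).
#' @param drop_missing If `TRUE`, signature genes absent from the universe
#'   are dropped with a message and the maximum renormalized; the default
#'   is an error listing the missing ids.
#' @return For a single profile, a list with `raw`, `max_score`, `score`;
#'   for a refset, the same with vector `raw`/`score` named by instance.
#' @export
connection_score <- function(sig, ref, drop_missing = FALSE) {
  stopifnot(inherits(sig, "gene_signature"))
  R <- rank_matrix(ref)
  genes <- sig$entries$gene_id
  q <- as.numeric(sig$entries$rank)
  miss <- setdiff(genes, rownames(R))
  if (length(miss)) {
    if (!drop_missing) {
      stop(sprintf("signature genes missing from universe: %s",
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
    message(sprintf("dropping %d signature gene(s) absent from universe",
                    length(miss)))
    keep <- !(genes %in% miss)
    genes <- genes[keep]
    q <- q[keep]
    if (!length(genes)) stop("no signature genes left", call. = FALSE)
  }
  N <- nrow(R)
  ms <- max_connection_score(q, N)
  raw <- as.vector(q %*% R[genes, , drop = FALSE])
  if (ncol(R) > 1L) names(raw) <- colnames(R)
  list(raw = raw, max_score = ms, score = raw / ms)
}

# Stable small hash of a signature id, so per-signature child seeds do not
# depend on the order signatures are supplied in.
id_hash <- function(id) {
  h <- 0
  for (ch in utf8ToInt(id)) h <- (h * 31 + ch) %% 1048573
  h
}

# Sparse K x N matrix of random signatures: row k holds the observed
# signed-rank multiset, in random order, at m genes sampled uniformly
# without replacement from the universe. Scoring all K random signatures
# against every instance is then one sparse-dense matrix product.
random_signature_matrix <- function(ranks, N, K, seed) {
  m <- length(ranks)
  with_seed(seed, {
    G <- vapply(seq_len(K), function(k) sample.int(N, m), integer(m))
    Q <- vapply(seq_len(K), function(k) sample(ranks), numeric(m))
  })
  # G, Q are m x K; transpose the index layout into row-per-signature
  Matrix::sparseMatrix(i = rep(seq_len(K), each = m),
                       j = as.vector(G),
                       x = as.vector(Q),
                       dims = c(K, N))
}

# Shared worker: normalized observed scores and two-sided permutation
# p-values for one signature against all instances of a rank matrix.
permutation_scores <- function(sig, R, K, seed) {
  genes <- sig$entries$gene_id
  q <- as.numeric(sig$entries$rank)
  N <- nrow(R)
  if (length(genes) >= N) {
    stop("signature length must be smaller than the gene universe",
         call. = FALSE)
  }
  miss <- setdiff(genes, rownames(R))
  if (length(miss)) {
    stop(sprintf("signature genes missing from universe: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  ms <- max_connection_score(q, N)
  obs <- as.vector(q %*% R[genes, , drop = FALSE]) / ms
  W <- random_signature_matrix(q, N, K, seed)
  # row order of R is the j-index space of W
  cr <- abs(as.matrix(W %*% R)) / ms
  b <- colSums(cr >= matrix(abs(obs), nrow = K, ncol = length(obs),
                            byrow = TRUE))
  list(score = obs, p_value = (b + 1) / (K + 1))
}

#' Permutation p-value of a connection
#'
#' Draws `K` random signatures of the same length as `sig` by sampling
#' distinct genes uniformly from the universe and assigning them the
#' observed signed-rank multiset in random order, then reports the
#' two-sided empirical p-value
#' `(#\{|c_rand| >= |c_obs|\} + 1) / (K + 1)`, which is never zero and
#' never below `1/(K+1)`. Deterministic for a fixed seed.
#'
#' @inheritParams connection_score
#' @param K Number of random signatures (default 10000, matching the
#'   standard sscMap run).
#' @param seed Integer seed.
#' @return For a single profile a single p-value; for a refset a named
#'   vector of p-values, one per instance (all sharing the same random
#'   signature draw, as in the reference tool).
#' @export
permutation_pvalue <- function(sig, ref, K = 10000L, seed = 1L) {
  stopifnot(inherits(sig, "gene_signature"))
  K <- check_count(K, "K")
  R <- rank_matrix(ref)
  p <- permutation_scores(sig, R, K, seed)$p_value
  names(p) <- colnames(R)
  if (ncol(R) == 1L) unname(p) else p
}

#' Expected-false-positive significance threshold
#'
#' With an accepted false-positive rate of `fpr` connections per analysis
#' over `n_comparisons` reference profiles, the p-value cutoff is
#' `fpr / n_comparisons` (e.g. 1/3730 ~ 0.00027, i.e. -log10 = 3.572, for
#' the standard 3730-instance reference set).
#'
#' @param fpr Accepted false positives per analysis (default 1).
#' @param n_comparisons Number of reference profiles compared against.
#' @return List with `cutoff` and `neg_log10`.
#' @export
significance_threshold <- function(fpr = 1, n_comparisons) {
  check_scalar_num(fpr, "false_positives_per_analysis", lower = 0,
                   strict = TRUE)
  n_comparisons <- check_count(n_comparisons, "n_comparisons")
  cutoff <- fpr / n_comparisons
  if (cutoff > 1) cutoff <- 1
  list(cutoff = cutoff, neg_log10 = -log10(cutoff))
}

#' Connect signatures to a reference set
#'
#' Scores every (signature, instance) pair, attaches permutation p-values
#' (one shared random-signature draw per signature, seeded independently
#' of iteration order via [child_seed()]) and flags significance at the
#' [significance_threshold()] for `n_comparisons` = number of instances.
#'
#' @param signatures A list of [gene_signature()]s (e.g. from
#'   [build_signatures()]).
#' @param refset A [refset()].
#' @param K Random signatures per query signature.
#' @param seed Master integer seed.
#' @param fpr Accepted false positives per analysis.
#' @return data.frame sorted by ascending p with columns `signature_id`,
#'   `instance_id`, `perturbagen`, `cell_line`, `score`, `p_value`,
#'   `neg_log10_p`, `significant` (volcano-plot-ready).
#' @export
connect_all <- function(signatures, refset, K = 10000L, seed = 1L,
                        fpr = 1) {
  stopifnot(inherits(refset, "refset"))
  if (inherits(signatures, "gene_signature")) signatures <- list(signatures)
  K <- check_count(K, "K")
  cutoff <- significance_threshold(fpr, ncol(refset$ranks))$cutoff
  rows <- lapply(seq_along(signatures), function(i) {
    sig <- signatures[[i]]
    ps <- permutation_scores(sig, refset$ranks, K,
                             child_seed(seed, id_hash(sig$signature_id)))
    data.frame(signature_id = sig$signature_id,
               instance_id = refset$index$instance_id,
               perturbagen = refset$index$perturbagen,
               cell_line = refset$index$cell_line,
               score = ps$score,
               p_value = ps$p_value,
               neg_log10_p = -log10(ps$p_value),
               significant = ps$p_value <= cutoff,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, out$signature_id, out$instance_id), ]
  rownames(out) <- NULL
  attr(out, "cutoff") <- cutoff
  attr(out, "K") <- K
  out
}

#' Select drug hits from connection results
#'
#' A perturbagen is of interest when it has significant connections of the
#' required sign (default negative: the drug profile reverses the disease
#' signature) in at least `min_signatures` distinct query signatures.
#'
#' @param results Output of [connect_all()].
#' @param min_signatures Minimum number of distinct signatures with a
#'   significant same-sign connection (default 2).
#' @param direction `"negative"` (signature inverters, the repurposing
#'   candidates) or `"positive"` (mimics).
#' @return data.frame per perturbagen with `n_signatures`,
#'   `n_connections`, `best_p`, `mean_score` and logical `hit`, sorted by
#'   `best_p`.
#' @export
select_hits <- function(results, min_signatures = 2L,
                        direction = c("negative", "positive")) {
  direction <- match.arg(direction)
  min_signatures <- check_count(min_signatures, "min_signatures")
  keep <- results$significant &
    (if (direction == "negative") results$score < 0 else results$score > 0)
  sel <- results[keep, , drop = FALSE]
  if (nrow(sel) == 0L) {
    return(data.frame(perturbagen = character(0), n_signatures = integer(0),
                      n_connections = integer(0), best_p = numeric(0),
                      mean_score = numeric(0), hit = logical(0),
                      stringsAsFactors = FALSE))
  }
  parts <- split(sel, sel$perturbagen)
  out <- do.call(rbind, lapply(parts, function(d) {
    data.frame(perturbagen = d$perturbagen[1L],
               n_signatures = length(unique(d$signature_id)),
               n_connections = nrow(d),
               best_p = min(d$p_value),
               mean_score = mean(d$score),
               stringsAsFactors = FALSE)
  }))
  out$hit <- out$n_signatures >= min_signatures
  out <- out[order(out$best_p, out$perturbagen), ]
  rownames(out) <- NULL
  out
}

#' Volcano plot of connection results
#'
#' Connection score against `-log10` p-value, one point per (signature,
#' instance) pair, with the significance cutoff drawn as a horizontal
#' line.
#'
#' @param results Output of [connect_all()].
#' @param cutoff Significance cutoff; defaults to the one stored on
#'   `results`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_connections <- function(results, cutoff = attr(results, "cutoff"),
                             ...) {
  graphics::plot(results$score, results$neg_log10_p,
                 xlab = "connection score", ylab = "-log10 p",
                 pch = 19, cex = 0.5,
                 col = ifelse(results$significant, "red", "grey40"), ...)
  if (!is.null(cutoff)) graphics::abline(h = -log10(cutoff), col = "red",
                                         lty = 2)
  invisible(results)
}
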