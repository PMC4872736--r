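# Differential analysis across ordinal disease stages: per-gene one-way
# ANOVA, BH false-discovery control, adjacent-stage fold changes and the
# strict monotone-trend filter.

# Align the annotation to the matrix columns and return the stage factor.
stage_factor <- function(X, annotation) {
  if (is.null(colnames(X)) || is.null(rownames(X))) {
    stop("expression matrix needs gene rownames and sample colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(X))) stop("gene ids must be unique", call. = FALSE)
  idx <- match(colnames(X), annotation$sample_id)
  if (anyNA(idx)) {
    stop(sprintf("samples missing from annotation: %s",
                 paste(colnames(X)[is.na(idx)], collapse = ", ")),
         call. = FALSE)
  }
  g <- annotation$group[idx]
  if (!is.factor(g)) g <- factor(g)
  g <- droplevels(g)
  if (nlevels(g) < 2L) stop("need at least two stages", call. = FALSE)
  if (any(table(g) < 2L)) {
    stop("every stage needs at least two samples", call. = FALSE)
  }
  g
}

# Per-gene group means (LS-means of the one-factor design).
stage_means <- function(X, g) {
  ind <- stats::model.matrix(~ g - 1)
  M <- X %*% ind
  sweep(M, 2L, tabulate(g, nlevels(g)), "/")
}

#' Per-gene one-way ANOVA across disease stages
#'
#' Fixed-effects one-way ANOVA of each gene's log2 expression against the
#' stage factor, computed by vectorized sums of squares. A gene with zero
#' total variance (all samples identical) is degenerate and reported as
#' `F = 0`, `p = 1`, which keeps such genes out of any signature.
#'
#' @param X Numeric matrix, genes x samples, with gene rownames and sample
#'   colnames. No missing values.
#' @param annotation data.frame with columns `sample_id` and `group`; if
#'   `group` is a factor its level order is the stage order.
#' @return data.frame with columns `gene_id`, `F_statistic`, `p_value`.
#' @examples
#' coh <- simulate_expression_cohort(cohort_spec(n_genes = 100, seed = 2))
#' head(anova_per_gene(coh$expression, coh$annotation))
#' @export
anova_per_gene <- function(X, annotation) {
  if (anyNA(X)) stop("expression matrix contains missing values",
                     call. = FALSE)
  g <- stage_factor(X, annotation)
  k <- nlevels(g)
  n <- ncol(X)
  sizes <- tabulate(g, k)
  M <- stage_means(X, g)
  gm <- rowSums(X) / n
  ssb <- as.vector((M - gm)^2 %*% sizes)
  sst <- rowSums((X - gm)^2)
  ssw <- pmax(sst - ssb, 0)
  # degenerate when total variance is zero up to accumulated rounding
  degen <- sst <= 64 * n * (.Machine$double.eps * (abs(gm) + 1))^2
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  f[ssw == 0 & ssb > 0] <- Inf
  p <- stats::pf(f, k - 1, n - k, lower.tail = FALSE)
  f[degen] <- 0
  p[degen] <- 1
  data.frame(gene_id = rownames(X), F_statistic = f, p_value = p,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up BH false-discovery-rate adjustment,
#' `q_(i) = min_(j >= i) p_(j) * m / j` capped at 1 and mapped back to the
#' input order (the standard `stats::p.adjust` computation, with input
#' validation).
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1)) {
    stop("p-values must be numbers in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Adjacent-stage fold changes
#'
#' For each ordered pair of adjacent stages, the signed log2 fold change
#' `mean(stage k+1) - mean(stage k)`; with log2 input and a one-factor
#' design these are the least-squares-mean differences.
#'
#' @inheritParams anova_per_gene
#' @return Numeric matrix, genes x (stages - 1), columns `fc1`, `fc2`, ...
#' @export
adjacent_fold_changes <- function(X, annotation) {
  g <- stage_factor(X, annotation)
  M <- stage_means(X, g)
  k <- nlevels(g)
  fc <- M[, -1L, drop = FALSE] - M[, -k, drop = FALSE]
  colnames(fc) <- paste0("fc", seq_len(k - 1L))
  rownames(fc) <- rownames(X)
  fc
}

#' Full differential table across stages
#'
#' Combines [anova_per_gene()], [bh_fdr()] and [adjacent_fold_changes()]
#' into one per-gene table, adding the monotone trend sign (`+1` if all
#' adjacent fold changes are strictly positive, `-1` if all strictly
#' negative, else `0`) and `delta`, the net first-to-last stage shift used
#' for tie-breaking.
#'
#' @inheritParams anova_per_gene
#' @return data.frame with columns `gene_id`, `F_statistic`, `p_value`,
#'   `q_value`, `fc1..fc(k-1)`, `trend`, `delta`.
#' @export
differential_analysis <- function(X, annotation) {
  av <- anova_per_gene(X, annotation)
  fc <- adjacent_fold_changes(X, annotation)
  trend <- ifelse(rowSums(fc > 0) == ncol(fc), 1L,
                  ifelse(rowSums(fc < 0) == ncol(fc), -1L, 0L))
  out <- cbind(av,
               q_value = bh_fdr(av$p_value),
               as.data.frame(fc),
               trend = trend,
               delta = rowSums(fc))
  rownames(out) <- NULL
  out
}

#' Monotone-trend filter
#'
#' Retains genes significant at the FDR threshold whose expression moves
#' strictly in the same direction between every pair of adjacent stages
#' (a tie or reversal anywhere excludes the gene). Strict adjacent
#' monotonicity of the stage means implies monotonicity for every pairwise
#' stage comparison. Lists are ordered by ascending p-value; ties are
#' broken by larger absolute first-to-last shift, then gene id.
#'
#' @param diff A [differential_analysis()] table.
#' @param q_threshold FDR threshold on the omnibus ANOVA q-value
#'   (default 0.05).
#' @return List with character vectors `increasing` and `decreasing`.
#' @export
monotone_filter <- function(diff, q_threshold = 0.05) {
  check_scalar_num(q_threshold, "q_threshold", lower = 0)
  keep_order <- order(diff$p_value, -abs(diff$delta), diff$gene_id)
  d <- diff[keep_order, ]
  sig <- d$q_value <= q_threshold
  list(increasing = d$gene_id[sig & d$trend == 1L],
       decreasing = d$gene_id[sig & d$trend == -1L])
}

#' Restrict gene lists to a common universe
#'
#' Drops genes absent from `universe` (e.g. genes without a probe set on
#' every array platform of the reference set), preserving relative order.
#'
#' @param lists A list of character vectors (e.g. the output of
#'   [monotone_filter()]).
#' @param universe Non-empty character vector of retained gene ids.
#' @return The filtered lists; an empty result raises a warning, not an
#'   error.
#' @export
restrict_universe <- function(lists, universe) {
  if (length(universe) == 0L) stop("universe is empty", call. = FALSE)
  out <- lapply(lists, function(x) x[x %in% universe])
  for (nm in names(out)) {
    if (length(out[[nm]]) == 0L && length(lists[[nm]]) > 0L) {
      warning(sprintf("list '%s' is empty after universe restriction", nm),
              call. = FALSE)
    }
  }
  out
}
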