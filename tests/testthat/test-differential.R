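# Per-gene ANOVA, BH-FDR, adjacent fold changes and the monotone filter.

make_matrix <- function(values, gene_ids, sample_ids) {
  matrix(values, nrow = length(gene_ids), byrow = TRUE,
         dimnames = list(gene_ids, sample_ids))
}

three_group_ann <- function(n_per = 3) {
  data.frame(
    sample_id = sprintf("s%02d", seq_len(3 * n_per)),
    group = factor(rep(c("g1", "g2", "g3"), each = n_per),
                   levels = c("g1", "g2", "g3")))
}

test_that("one-way ANOVA matches the textbook example and the lm oracle", {
  ann <- three_group_ann()
  X <- make_matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9), "gA", ann$sample_id)
  av <- anova_per_gene(X, ann)
  # by hand: SSB = 54 (df 2), SSW = 6 (df 6) -> F = 27
  expect_equal(av$F_statistic, 27)
  expect_equal(av$p_value, stats::pf(27, 2, 6, lower.tail = FALSE))

  # random matrices agree with stats::anova to high relative tolerance
  set.seed(42)
  ann2 <- data.frame(
    sample_id = sprintf("s%02d", 1:11),
    group = factor(rep(c("a", "b", "c"), c(3, 4, 4))))
  for (i in 1:20) {
    X <- matrix(rnorm(5 * 11), 5, 11,
                dimnames = list(paste0("gene", 1:5), ann2$sample_id))
    av <- anova_per_gene(X, ann2)
    for (g in 1:5) {
      o <- oracle_anova(X[g, ], ann2$group)
      expect_equal(av$F_statistic[g], o$F, tolerance = 1e-10)
      expect_equal(av$p_value[g], o$p, tolerance = 1e-10)
    }
  }
})

test_that("zero-variance genes take the degenerate F = 0, p = 1 policy", {
  ann <- three_group_ann()
  X <- make_matrix(rep(5, 9), "flat", ann$sample_id)
  av <- anova_per_gene(X, ann)
  expect_equal(av$F_statistic, 0)
  expect_equal(av$p_value, 1)
})

test_that("BH q-values match the hand examples and an independent oracle", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(c(1, 1)), c(1, 1))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(c(0.5, NA)), "\\[0, 1\\]")

  set.seed(7)
  for (i in 1:25) {
    p <- runif(sample(3:200, 1))
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p))
    # nondecreasing when ordered by p
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("adjacent fold changes are the LS-mean stage differences", {
  ann <- data.frame(
    sample_id = sprintf("s%02d", 1:10),
    group = factor(rep(paste0("st", 1:5), each = 2),
                   levels = paste0("st", 1:5)))
  stage_mean_matrix <- function(means) {
    make_matrix(rep(means, each = 2), "g1", ann$sample_id)
  }
  expect_equal(unname(adjacent_fold_changes(
    stage_mean_matrix(c(1, 2, 3, 4, 5)), ann)[1, ]), rep(1, 4))
  expect_equal(unname(adjacent_fold_changes(
    stage_mean_matrix(c(5, 4, 3, 2, 1)), ann)[1, ]), rep(-1, 4))
  # a tied pair of stages breaks the monotone trend
  X <- stage_mean_matrix(c(1, 2, 2, 3, 4))
  expect_equal(unname(adjacent_fold_changes(X, ann)[1, ]), c(1, 0, 1, 1))
  d <- differential_analysis(X, ann)
  expect_identical(d$trend, 0L)
})

test_that("monotone filter recovers a noise-free planted cohort exactly", {
  coh <- simulate_expression_cohort(
    cohort_spec(n_genes = 300, n_up = 20, n_down = 20, noise_sd = 0,
                seed = 5))
  d <- differential_analysis(coh$expression, coh$annotation)
  lists <- monotone_filter(d)
  expect_setequal(lists$increasing, coh$truth$up)
  expect_setequal(lists$decreasing, coh$truth$down)
})

test_that("a single sign break excludes an otherwise significant gene", {
  ann <- data.frame(
    sample_id = sprintf("s%02d", 1:10),
    group = factor(rep(paste0("st", 1:5), each = 2),
                   levels = paste0("st", 1:5)))
  # strong monotone gene and a strong gene with one reversed step
  X <- rbind(
    mono = rep(c(1, 2, 3, 4, 5), each = 2),
    broken = rep(c(1, 2.5, 2.4, 4, 5), each = 2)
  ) + matrix(rnorm(20, sd = 0.01), 2, 10)
  colnames(X) <- ann$sample_id
  d <- differential_analysis(X, ann)
  lists <- monotone_filter(d, q_threshold = 0.05)
  expect_true("mono" %in% lists$increasing)
  expect_false("broken" %in% c(lists$increasing, lists$decreasing))
})

test_that("strict adjacent monotonicity implies all-pairs monotonicity", {
  coh <- simulate_expression_cohort(cohort_spec(n_genes = 400, seed = 3))
  d <- differential_analysis(coh$expression, coh$annotation)
  lists <- monotone_filter(d)
  g <- stage_factor <- coh$annotation$group
  M <- t(apply(coh$expression[c(lists$increasing, lists$decreasing), ,
                              drop = FALSE], 1,
               function(v) tapply(v, g, mean)))
  for (gene in lists$increasing) {
    means <- M[gene, ]
    pairs <- combn(length(means), 2)
    expect_true(all(means[pairs[2, ]] > means[pairs[1, ]]))
  }
  for (gene in lists$decreasing) {
    means <- M[gene, ]
    pairs <- combn(length(means), 2)
    expect_true(all(means[pairs[2, ]] < means[pairs[1, ]]))
  }
})

test_that("universe restriction drops exactly the missing genes in order", {
  lists <- list(increasing = c("a", "b", "c", "d"),
                decreasing = c("e", "f"))
  expect_identical(restrict_universe(lists, letters[1:6]), lists)
  half <- restrict_universe(lists, c("b", "d", "e"))
  expect_identical(half$increasing, c("b", "d"))
  expect_identical(half$decreasing, "e")
  expect_warning(expect_warning(restrict_universe(lists, "zzz_gene"),
                                "increasing"),
                 "decreasing")
  expect_error(restrict_universe(lists, character(0)), "empty")

  # set arithmetic against the planted truth
  coh <- simulate_expression_cohort(
    cohort_spec(n_genes = 300, n_up = 20, n_down = 20, noise_sd = 0,
                seed = 6))
  d <- differential_analysis(coh$expression, coh$annotation)
  lists <- monotone_filter(d)
  excluded <- c(coh$truth$up[1:5], coh$truth$down[1:5])
  universe <- setdiff(rownames(coh$expression), excluded)
  r <- restrict_universe(lists, universe)
  expect_equal(length(r$increasing), length(lists$increasing) - 5)
  expect_equal(length(r$decreasing), length(lists$decreasing) - 5)
})
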