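# Signed-rank reference profiles, connection scores, permutation p-values,
# the significance threshold and hit selection.

test_that("reference profile ranking follows the documented conventions", {
  rp <- build_reference_profile(c(A = 2.0, B = -1.5, E = 1.0, C = 0.5,
                                  D = -0.1))
  expect_identical(rp$signed_ranks[c("A", "B", "E", "C", "D")],
                   c(A = 5L, B = -4L, E = 3L, C = 2L, D = -1L))

  # all-negative stats: all ranks negative, magnitudes a permutation
  rn <- build_reference_profile(c(a = -3, b = -1, c = -2))$signed_ranks
  expect_true(all(rn < 0))
  expect_setequal(abs(rn), 1:3)

  # antisymmetry: negating the stats negates every rank
  s <- c(w = 1.2, x = -0.4, y = 2.2, z = 0.3)
  expect_identical(build_reference_profile(-s)$signed_ranks,
                   -build_reference_profile(s)$signed_ranks)

  # ties broken lexicographically, zeros positive at smallest magnitudes
  rt <- build_reference_profile(c(b = 1, a = 1, z = 0, y = 0))$signed_ranks
  expect_identical(rt, c(b = 3L, a = 4L, z = 1L, y = 2L))

  expect_error(build_reference_profile(c(a = 1, b = NA)), "non-finite")
})

test_that("connection score matches hand arithmetic and the extremes", {
  ranks <- c(A = 5L, B = -4L, E = 3L, C = 2L, D = -1L)
  sig <- gene_signature(c("C", "E"), c(2L, -1L))
  cs <- connection_score(sig, ranks)
  expect_equal(cs$raw, 1)
  expect_equal(cs$max_score, 14)
  expect_equal(cs$score, 1 / 14)

  # perfect match / perfect reversal on a one-gene signature
  ranksN <- structure(c(5L, 4L, -3L, 2L, 1L),
                      names = c("A", "B", "C", "D", "E"))
  expect_equal(connection_score(gene_signature("A", 1L), ranksN)$score, 1)
  expect_equal(connection_score(gene_signature("A", -1L), ranksN)$score, -1)

  expect_error(connection_score(gene_signature("nope", 1L), ranksN),
               "missing from universe")
  expect_message(
    cs2 <- connection_score(gene_signature(c("A", "nope"), c(1L, -1L)),
                            ranksN, drop_missing = TRUE),
    "dropping")
  expect_equal(cs2$score, 1)
})

test_that("scores agree with a brute-force oracle and stay in [-1, 1]", {
  set.seed(31)
  for (i in 1:50) {
    N <- sample(4:10, 1)
    m <- sample(2:3, 1)
    universe <- sprintf("u%02d", 1:N)
    ranks <- structure(as.integer(sample(N) * sample(c(-1L, 1L), N,
                                                     replace = TRUE)),
                       names = universe)
    genes <- sample(universe, m)
    q <- sample(c(-m:-1, 1:m), m)
    sig <- gene_signature(genes, q)
    cs <- connection_score(sig, ranks)
    expect_equal(cs$score, oracle_score(genes, q, ranks))
    expect_lte(abs(cs$score), 1)
  }
})

test_that("scores are invariant to relabelling non-signature genes", {
  universe <- sprintf("u%02d", 1:30)
  ranks <- structure(as.integer(sample(30) *
                                  sample(c(-1L, 1L), 30, replace = TRUE)),
                     names = universe)
  sig <- toy_signature(universe, 3, 3)
  base <- connection_score(sig, ranks)$score
  others <- setdiff(universe, sig$entries$gene_id)
  perm <- ranks
  perm[others] <- ranks[sample(others)]
  expect_equal(connection_score(sig, perm)$score, base)
})

test_that("negating signature signs negates scores, p-values unchanged", {
  universe <- sprintf("u%02d", 1:50)
  rs <- simulate_refset(refset_spec(n_instances = 8, universe = universe,
                                    seed = 21))$refset
  sig <- toy_signature(universe, 4, 4)
  neg <- gene_signature(sig$entries$gene_id, -sig$entries$rank, "neg")
  expect_equal(connection_score(neg, rs)$score,
               -connection_score(sig, rs)$score)
  expect_equal(permutation_pvalue(sig, rs, K = 400, seed = 3),
               permutation_pvalue(neg, rs, K = 400, seed = 3))
})

test_that("permutation p-values are bounded, deterministic and validated", {
  universe <- sprintf("u%02d", 1:40)
  ranks <- structure(seq.int(40L, 1L), names = universe)
  sig <- gene_signature(c("u01", "u02"), c(2L, 1L)) # perfect match, |c| = 1
  p <- permutation_pvalue(sig, ranks, K = 1000, seed = 2)
  expect_gte(p, 1 / 1001)
  expect_lte(p, 5 / 1001) # only exact ties at |c| = 1 can count
  expect_identical(p, permutation_pvalue(sig, ranks, K = 1000, seed = 2))
  big <- gene_signature(universe, c(seq.int(20L, 1L), -seq.int(20L, 1L)))
  expect_error(permutation_pvalue(big, ranks), "smaller than")
})

test_that("Monte-Carlo p matches full enumeration within binomial error", {
  # the N = 5, m = 2, ranks {+2, -1} case, exact null by enumeration
  universe <- sprintf("u%d", 1:5)
  ranks <- structure(c(2L, -4L, 1L, 5L, -3L), names = universe)
  sig <- gene_signature(c("u1", "u4"), c(2L, -1L))
  cs <- connection_score(sig, ranks)$score
  p_exact <- oracle_exact_p(c(2, -1), ranks, cs)
  K <- 10000
  p_mc <- permutation_pvalue(sig, ranks, K = K, seed = 17)
  tol <- 3 * sqrt(p_exact * (1 - p_exact) / K) + 2 / (K + 1)
  expect_lt(abs(p_mc - p_exact), tol)
})

test_that("significance threshold implements the 1/N arithmetic", {
  th <- significance_threshold(1, 3730)
  expect_equal(th$cutoff, 1 / 3730)
  expect_equal(th$neg_log10, -log10(1 / 3730))
  expect_equal(significance_threshold(1, 1)$cutoff, 1)
  expect_error(significance_threshold(1, 0), "n_comparisons")
})

test_that("connect_all produces one scored row per signature-instance pair", {
  universe <- sprintf("g%04d", 1:150)
  sigs <- build_signatures(universe[1:20], universe[21:40],
                           depths = c(5, 10, 15, 20))
  rs <- simulate_refset(refset_spec(n_instances = 12, universe = universe,
                                    seed = 3))$refset
  res <- connect_all(sigs, rs, K = 200, seed = 9)
  expect_equal(nrow(res), 4 * 12)
  expect_true(all(c("signature_id", "instance_id", "perturbagen",
                    "cell_line", "score", "p_value", "neg_log10_p",
                    "significant") %in% names(res)))
  expect_true(!is.unsorted(res$p_value))
  expect_equal(res$neg_log10_p, -log10(res$p_value))

  # per-signature results do not depend on the order signatures are given
  res_rev <- connect_all(rev(sigs), rs, K = 200, seed = 9)
  a <- res[order(res$signature_id, res$instance_id),
           c("signature_id", "instance_id", "score", "p_value")]
  b <- res_rev[order(res_rev$signature_id, res_rev$instance_id),
               c("signature_id", "instance_id", "score", "p_value")]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("hit selection requires >= 2 signatures of the right sign", {
  mk <- function(pert, sig, score, p, signif) {
    data.frame(signature_id = sig, instance_id = paste0(pert, "_i"),
               perturbagen = pert, cell_line = "CL1", score = score,
               p_value = p, neg_log10_p = -log10(p), significant = signif)
  }
  res <- rbind(
    mk("drugTwo", "top10", -0.8, 1e-4, TRUE),
    mk("drugTwo", "top20", -0.7, 2e-4, TRUE),
    mk("drugOne", "top10", -0.9, 1e-4, TRUE),
    mk("drugPos", "top10", 0.9, 1e-4, TRUE),
    mk("drugPos", "top20", 0.8, 1e-4, TRUE),
    mk("drugPos", "top30", 0.8, 1e-4, TRUE)
  )
  hits <- select_hits(res, min_signatures = 2, direction = "negative")
  expect_true(hits$hit[hits$perturbagen == "drugTwo"])
  expect_false(hits$hit[hits$perturbagen == "drugOne"])
  expect_false("drugPos" %in% hits$perturbagen) # sign gate
  pos <- select_hits(res, direction = "positive")
  expect_true(pos$hit[pos$perturbagen == "drugPos"])
})

test_that("refsets round-trip through the directory format", {
  universe <- sprintf("g%04d", 1:30)
  rs <- simulate_refset(refset_spec(n_instances = 4, universe = universe,
                                    seed = 12))$refset
  dir <- tempfile("refset_")
  write_refset_dir(rs, dir)
  back <- read_refset_dir(dir)
  expect_identical(back$ranks, rs$ranks)
  expect_identical(back$index$perturbagen, rs$index$perturbagen)
})
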