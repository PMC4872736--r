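# Validated specification objects for the synthetic-data generators.

#' Specify a staged expression cohort
#'
#' Describes a synthetic log2-scale expression cohort over ordinal disease
#' stages (default five: normal, low/medium/high-risk MDS, AML) with a set
#' of planted genes whose group means move strictly monotonely across
#' stages, among otherwise flat null genes.
#'
#' @param n_genes Number of genes simulated.
#' @param group_sizes Integer vector of samples per stage, in stage order;
#'   every group needs at least 2 samples.
#' @param group_labels Stage labels, ordered from least to most advanced
#'   disease.
#' @param n_up,n_down Number of planted monotonically increasing /
#'   decreasing genes.
#' @param step_effect Mean shift, in log2 units, between each pair of
#'   adjacent stages for planted genes (positive for increasing genes,
#'   its negation for decreasing genes).
#' @param noise_sd Gaussian noise standard deviation on the log2 scale.
#'   `0` gives a noise-free cohort, useful for exact-recovery checks.
#' @param baseline_mean Baseline log2 intensity of every gene at the first
#'   stage.
#' @param seed Integer seed; generation is fully deterministic given the
#'   spec.
#' @return A `cohort_spec` object (validated list).
#' @seealso [simulate_expression_cohort()]
#' @export
cohort_spec <- function(n_genes = 1000L,
                        group_sizes = rep(20L, 5L),
                        group_labels = c("normal", "low", "medium", "high",
                                         "AML"),
                        n_up = 50L, n_down = 50L,
                        step_effect = 1.0, noise_sd = 0.25,
                        baseline_mean = 7.0, seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes")
  n_up <- check_count(n_up, "n_up", min = 0L)
  n_down <- check_count(n_down, "n_down", min = 0L)
  if (n_up + n_down > n_genes) {
    spec_error("n_up_planted + n_down_planted", "must not exceed n_genes")
  }
  if (length(group_sizes) < 2L) {
    spec_error("group_sizes", "needs at least two stages")
  }
  group_sizes <- vapply(seq_along(group_sizes), function(i) {
    check_count(group_sizes[i], sprintf("group_sizes[%d]", i), min = 2L)
  }, integer(1))
  if (length(group_labels) != length(group_sizes) ||
      anyDuplicated(group_labels)) {
    spec_error("group_labels", "must be unique, one per group")
  }
  check_scalar_num(step_effect, "step_effect", lower = 0)
  check_scalar_num(noise_sd, "noise_sd", lower = 0)
  check_scalar_num(baseline_mean, "baseline_mean")
  seed <- check_count(seed, "seed", min = 0L)
  structure(list(n_genes = n_genes, group_sizes = group_sizes,
                 group_labels = as.character(group_labels),
                 n_up = n_up, n_down = n_down, step_effect = step_effect,
                 noise_sd = noise_sd, baseline_mean = baseline_mean,
                 seed = seed),
            class = "cohort_spec")
}

#' Specify a synthetic perturbagen reference set
#'
#' Describes a collection of perturbagen instances over a common gene
#' universe. Each non-planted instance has an i.i.d. standard-Gaussian
#' latent differential statistic per gene; planted "inverters" (profiles
#' reversing a query signature) and "mimics" (profiles reproducing it)
#' overwrite the latent statistic at the signature genes with
#' `-alpha * sign(rank)` (respectively `+alpha * sign(rank)`) plus Gaussian
#' noise of standard deviation `noise_sd`. Latent vectors are converted to
#' full signed-rank profiles exactly as [build_reference_profile()] does.
#'
#' @param n_instances Number of perturbagen instances.
#' @param universe Either a character vector of gene ids or an integer
#'   count, in which case ids `g0001...` are generated to match
#'   [simulate_expression_cohort()].
#' @param inverters,mimics Lists of planted connections. Each element is a
#'   list with fields `instance` (1-based instance index), `signature` (a
#'   [gene_signature()]) and `alpha` (effect strength, >= 0).
#' @param noise_sd Gaussian noise SD added at the planted signature genes.
#' @param seed Integer seed.
#' @return A `refset_spec` object.
#' @seealso [simulate_refset()]
#' @export
refset_spec <- function(n_instances = 100L, universe = 1000L,
                        inverters = list(), mimics = list(),
                        noise_sd = 1.0, seed = 1L) {
  n_instances <- check_count(n_instances, "n_instances")
  if (is.numeric(universe) && length(universe) == 1L) {
    universe <- make_gene_ids(check_count(universe, "universe"))
  }
  universe <- as.character(universe)
  if (anyDuplicated(universe)) spec_error("universe", "gene ids must be unique")
  check_scalar_num(noise_sd, "noise_sd", lower = 0)
  seed <- check_count(seed, "seed", min = 0L)
  check_planted <- function(lst, field) {
    for (pl in lst) {
      if (!all(c("instance", "signature", "alpha") %in% names(pl))) {
        spec_error(field, "entries need fields instance, signature, alpha")
      }
      idx <- check_count(pl$instance, paste0(field, "$instance"))
      if (idx > n_instances) {
        spec_error(field, "planted instance index exceeds n_instances")
      }
      if (!inherits(pl$signature, "gene_signature")) {
        spec_error(field, "signature must be a gene_signature")
      }
      missing <- setdiff(pl$signature$entries$gene_id, universe)
      if (length(missing)) {
        stop(sprintf("signature genes absent from universe: %s",
                     paste(missing, collapse = ", ")), call. = FALSE)
      }
      check_scalar_num(pl$alpha, paste0(field, "$alpha"), lower = 0)
    }
  }
  check_planted(inverters, "inverters")
  check_planted(mimics, "mimics")
  ids <- c(vapply(inverters, function(p) p$instance, numeric(1)),
           vapply(mimics, function(p) p$instance, numeric(1)))
  if (anyDuplicated(ids)) {
    spec_error("inverters/mimics", "planted instance indices must be distinct")
  }
  structure(list(n_instances = n_instances, universe = universe,
                 inverters = inverters, mimics = mimics,
                 noise_sd = noise_sd, seed = seed),
            class = "refset_spec")
}

#' Specify a single-agent dose-response experiment
#'
#' Ground truth follows the median-effect model: the fraction affected at
#' dose `D` is `fa(D) = (D/Dm)^m / (1 + (D/Dm)^m)`, so `Dm` is the dose of
#' half-maximal effect (the IC50) and `m` the sigmoidicity of the curve.
#'
#' @param drug Drug name used in the output table.
#' @param true_Dm Median-effect dose (micromolar), > 0.
#' @param true_slope Sigmoidicity `m`, > 0.
#' @param doses Positive dose grid (micromolar); the default is a six-point
#'   two-fold-style series centred on `true_Dm`.
#' @param n_reps Replicates per dose (including vehicle wells).
#' @param cv_noise Relative SD of the multiplicative Gaussian noise applied
#'   to the raw luminescence; `0` gives noise-free curves.
#' @param seed Integer seed.
#' @return A `dose_response_spec` object.
#' @seealso [simulate_dose_response()], [fit_median_effect()]
#' @export
dose_response_spec <- function(drug = "drugA", true_Dm = 2.0,
                               true_slope = 1.5,
                               doses = true_Dm *
                                 2^seq(-2.5, 2.5, length.out = 6),
                               n_reps = 3L, cv_noise = 0.05, seed = 1L) {
  check_scalar_num(true_Dm, "true_Dm", lower = 0, strict = TRUE)
  check_scalar_num(true_slope, "true_slope", lower = 0, strict = TRUE)
  if (!is.numeric(doses) || length(doses) < 1L || any(!is.finite(doses)) ||
      any(doses <= 0)) {
    spec_error("doses", "must be positive finite concentrations")
  }
  n_reps <- check_count(n_reps, "n_reps")
  check_scalar_num(cv_noise, "cv_noise", lower = 0)
  seed <- check_count(seed, "seed", min = 0L)
  structure(list(drug = as.character(drug), true_Dm = true_Dm,
                 true_slope = true_slope, doses = as.numeric(doses),
                 n_reps = n_reps, cv_noise = cv_noise, seed = seed),
            class = "dose_response_spec")
}

make_gene_ids <- function(n) {
  sprintf("g%0*d", max(4L, nchar(as.character(n))), seq_len(n))
}
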