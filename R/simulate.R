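# Seeded generators for every input the pipeline consumes: staged
# expression cohorts, perturbagen reference sets, and dose-response /
# combination viability tables, each with known planted ground truth.

#' Simulate a staged expression cohort with planted monotone genes
#'
#' Generates a log2-scale gene-by-sample matrix over ordered disease
#' stages. Planted increasing genes gain `step_effect` log2 units of mean
#' per adjacent stage, planted decreasing genes lose the same amount, and
#' null genes keep one common mean; i.i.d. Gaussian noise of SD
#' `spec$noise_sd` is added throughout. Output is bit-identical for a
#' fixed spec (including seed).
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `expression_cohort` with elements
#'   \describe{
#'     \item{expression}{numeric matrix, genes x samples, log2 scale;
#'       rownames are gene ids, colnames sample ids.}
#'     \item{annotation}{data.frame with `sample_id` and `group` (a factor
#'       whose levels carry the stage order).}
#'     \item{truth}{list with `up` and `down`: the planted gene-id sets.}
#'     \item{spec}{the input spec.}
#'   }
#' @examples
#' coh <- simulate_expression_cohort(cohort_spec(n_genes = 200, seed = 7))
#' dim(coh$expression)
#' @export
simulate_expression_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) spec <- do.call(cohort_spec, spec)
  k <- length(spec$group_sizes)
  gene_ids <- make_gene_ids(spec$n_genes)
  sample_ids <- unlist(lapply(seq_len(k), function(s) {
    sprintf("%s_%02d", spec$group_labels[s], seq_len(spec$group_sizes[s]))
  }))
  stage <- rep(seq_len(k), spec$group_sizes)
  with_seed(spec$seed, {
    planted <- sample(gene_ids, spec$n_up + spec$n_down)
    up <- sort(planted[seq_len(spec$n_up)])
    down <- sort(planted[spec$n_up + seq_len(spec$n_down)])
    mu <- matrix(spec$baseline_mean, nrow = spec$n_genes,
                 ncol = length(sample_ids),
                 dimnames = list(gene_ids, sample_ids))
    shift <- (stage - 1L) * spec$step_effect
    mu[up, ] <- mu[up, , drop = FALSE] +
      matrix(shift, length(up), length(sample_ids), byrow = TRUE)
    mu[down, ] <- mu[down, , drop = FALSE] -
      matrix(shift, length(down), length(sample_ids), byrow = TRUE)
    noise <- if (spec$noise_sd > 0) {
      matrix(stats::rnorm(length(mu), sd = spec$noise_sd), nrow(mu), ncol(mu))
    } else 0
    X <- mu + noise
  })
  ann <- data.frame(
    sample_id = sample_ids,
    group = factor(spec$group_labels[stage], levels = spec$group_labels),
    stringsAsFactors = FALSE
  )
  structure(list(expression = X, annotation = ann,
                 truth = list(up = up, down = down), spec = spec),
            class = "expression_cohort")
}

#' @export
print.expression_cohort <- function(x, ...) {
  cat(sprintf(
    "expression_cohort: %d genes x %d samples over %d stages (%s)\n",
    nrow(x$expression), ncol(x$expression), nlevels(x$annotation$group),
    paste(levels(x$annotation$group), collapse = " < ")))
  cat(sprintf("planted: %d increasing, %d decreasing; step %.3g log2/stage, noise sd %.3g\n",
              length(x$truth$up), length(x$truth$down),
              x$spec$step_effect, x$spec$noise_sd))
  invisible(x)
}

#' Simulate a signed-rank perturbagen reference set
#'
#' Draws a latent differential-expression statistic vector per instance
#' (standard Gaussian for nulls; planted inverters/mimics get
#' `-alpha`/`+alpha` times the sign of their target signature's ranks at
#' the signature genes, plus noise) and converts every instance to a full
#' signed-rank profile over the gene universe.
#'
#' @param spec A [refset_spec()].
#' @return A list with elements `refset` (a [refset()] object) and `truth`
#'   (data.frame of planted instances: `instance_id`, `role`,
#'   `signature_id`, `alpha`).
#' @export
simulate_refset <- function(spec) {
  if (!inherits(spec, "refset_spec")) spec <- do.call(refset_spec, spec)
  N <- length(spec$universe)
  n <- spec$n_instances
  inst_ids <- sprintf("inst_%04d", seq_len(n))
  with_seed(spec$seed, {
    stats <- matrix(stats::rnorm(N * n), N, n,
                    dimnames = list(spec$universe, inst_ids))
    plant <- function(pl, direction) {
      genes <- pl$signature$entries$gene_id
      s <- sign(pl$signature$entries$rank)
      stats[genes, pl$instance] <<- direction * pl$alpha * s +
        stats::rnorm(length(genes), sd = spec$noise_sd)
    }
    for (pl in spec$inverters) plant(pl, -1)
    for (pl in spec$mimics) plant(pl, +1)
    ranks <- apply(stats, 2L, signed_ranks_from_stats)
  })
  rownames(ranks) <- spec$universe
  index <- data.frame(
    instance_id = inst_ids,
    perturbagen = sprintf("pert_%04d", seq_len(n)),
    cell_line = rep(c("CL1", "CL2", "CL3"), length.out = n),
    dose = NA_character_,
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    instance_id = character(0), role = character(0),
    signature_id = character(0), alpha = numeric(0),
    stringsAsFactors = FALSE
  )
  for (pl in spec$inverters) {
    truth <- rbind(truth, data.frame(
      instance_id = inst_ids[pl$instance], role = "inverter",
      signature_id = pl$signature$signature_id, alpha = pl$alpha))
  }
  for (pl in spec$mimics) {
    truth <- rbind(truth, data.frame(
      instance_id = inst_ids[pl$instance], role = "mimic",
      signature_id = pl$signature$signature_id, alpha = pl$alpha))
  }
  list(refset = refset(ranks, index, provenance = "synthetic"),
       truth = truth)
}

# Fraction affected under the median-effect model.
median_effect_fa <- function(dose, Dm, m) {
  r <- (dose / Dm)^m
  r / (1 + r)
}

#' Simulate a single-agent viability table
#'
#' Viability follows the median-effect model of the spec
#' ([dose_response_spec()]): raw luminescence is
#' `1000 * (1 - fa(D)) * (1 + e)` with multiplicative Gaussian noise `e` of
#' SD `cv_noise`. Vehicle wells (dose 0) are included with viability
#' `1000 * (1 + e)`.
#'
#' @param spec A [dose_response_spec()].
#' @return A data.frame with columns `drug`, `dose`, `replicate`, `rlu`.
#' @examples
#' tab <- simulate_dose_response(dose_response_spec(cv_noise = 0))
#' head(tab)
#' @export
simulate_dose_response <- function(spec) {
  if (!inherits(spec, "dose_response_spec")) {
    spec <- do.call(dose_response_spec, spec)
  }
  doses <- c(0, spec$doses)
  fa <- c(0, median_effect_fa(spec$doses, spec$true_Dm, spec$true_slope))
  grid <- expand.grid(replicate = seq_len(spec$n_reps),
                      i = seq_along(doses))
  with_seed(spec$seed, {
    e <- if (spec$cv_noise > 0) {
      stats::rnorm(nrow(grid), sd = spec$cv_noise)
    } else 0
    rlu <- 1000 * (1 - fa[grid$i]) * (1 + e)
  })
  data.frame(drug = spec$drug, dose = doses[grid$i],
             replicate = grid$replicate, rlu = rlu,
             stringsAsFactors = FALSE)
}

# Solve for the fraction affected at a combination point (d1, d2) such
# that d1/Dx1(fa) + d2/Dx2(fa) = interaction, i.e. the Loewe-additivity
# equation scaled by the interaction multiplier. The left-hand side is
# strictly decreasing in fa, so the root is unique.
loewe_fa <- function(d1, d2, DmA, mA, DmB, mB, interaction) {
  g <- function(u) {
    # u = log(fa / (1 - fa))
    d1 / (DmA * exp(u / mA)) + d2 / (DmB * exp(u / mB)) - interaction
  }
  u <- stats::uniroot(g, lower = -60, upper = 60, tol = 1e-14)$root
  stats::plogis(u)
}

#' Simulate a drug-pair combination viability grid
#'
#' Builds a factorial dose grid (default the 5 x 5 design of 0, 0.25, 0.5,
#' 1 and 2 times each drug's IC50) whose interior points deviate from
#' Loewe additivity by a known `interaction` multiplier: the fraction
#' affected at `(d1, d2)` solves `d1/Dx1(fa) + d2/Dx2(fa) = interaction`
#' under the two single-agent median-effect curves. `interaction = 1`
#' yields an exactly Loewe-additive grid (downstream Combination Index 1
#' in the noise-free limit); values below 1 plant synergy, above 1
#' antagonism. Rows or columns with one dose equal to 0 reproduce the
#' single-agent curves.
#'
#' @param specA,specB [dose_response_spec()]s for the two drugs.
#' @param interaction Positive ground-truth Combination Index multiplier.
#' @param grid Non-negative multiples of each drug's `true_Dm` (IC50)
#'   forming the factorial design.
#' @param n_reps Replicates per grid point.
#' @param cv_noise Relative SD of multiplicative noise; default noise-free.
#' @param seed Integer seed.
#' @return A data.frame with columns `drug1`, `dose1`, `drug2`, `dose2`,
#'   `replicate`, `rlu` (vehicle rows have both doses 0).
#' @export
simulate_combination_grid <- function(specA, specB, interaction = 1,
                                      grid = c(0, 0.25, 0.5, 1, 2),
                                      n_reps = 3L, cv_noise = 0, seed = 1L) {
  if (!inherits(specA, "dose_response_spec")) {
    specA <- do.call(dose_response_spec, specA)
  }
  if (!inherits(specB, "dose_response_spec")) {
    specB <- do.call(dose_response_spec, specB)
  }
  check_scalar_num(interaction, "interaction", lower = 0, strict = TRUE)
  if (any(grid < 0)) spec_error("grid", "multiples must be >= 0")
  n_reps <- check_count(n_reps, "n_reps")
  check_scalar_num(cv_noise, "cv_noise", lower = 0)
  seed <- check_count(seed, "seed", min = 0L)

  pts <- expand.grid(m1 = grid, m2 = grid)
  pts$d1 <- pts$m1 * specA$true_Dm
  pts$d2 <- pts$m2 * specB$true_Dm
  pts$fa <- mapply(function(d1, d2) {
    if (d1 == 0 && d2 == 0) return(0)
    if (d2 == 0) return(median_effect_fa(d1, specA$true_Dm, specA$true_slope))
    if (d1 == 0) return(median_effect_fa(d2, specB$true_Dm, specB$true_slope))
    loewe_fa(d1, d2, specA$true_Dm, specA$true_slope,
             specB$true_Dm, specB$true_slope, interaction)
  }, pts$d1, pts$d2)

  rows <- expand.grid(replicate = seq_len(n_reps), i = seq_len(nrow(pts)))
  with_seed(seed, {
    e <- if (cv_noise > 0) stats::rnorm(nrow(rows), sd = cv_noise) else 0
    rlu <- 1000 * (1 - pts$fa[rows$i]) * (1 + e)
  })
  data.frame(drug1 = specA$drug, dose1 = pts$d1[rows$i],
             drug2 = specB$drug, dose2 = pts$d2[rows$i],
             replicate = rows$replicate, rlu = rlu,
             stringsAsFactors = FALSE)
}
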