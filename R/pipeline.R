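# End-to-end orchestration: simulate -> derive -> connect -> select ->
# synergy, with one flat configuration, structured stage logging and a
# provenance manifest.

#' Default demonstration pipeline configuration
#'
#' A complete synthetic run: a staged cohort with planted monotone genes,
#' a reference set with one planted inverter and one planted mimic of the
#' deepest derived signature, connectivity mapping with hit selection, and
#' a Loewe-deviating combination grid for synergy analysis.
#'
#' @param out_dir Output directory for artifacts and the manifest.
#' @param seed Master seed; stage seeds derive from it via [child_seed()].
#' @return A named list accepted by [run_pipeline()].
#' @export
demo_config <- function(out_dir = tempfile("sigconnect_run_"), seed = 1L) {
  list(
    out_dir = out_dir,
    seed = seed,
    stages = list(simulate = TRUE, derive = TRUE, connect = TRUE,
                  hits = TRUE, synergy = TRUE),
    cohort = list(n_genes = 1000L, group_sizes = rep(20L, 5L),
                  n_up = 50L, n_down = 50L, step_effect = 1.0,
                  noise_sd = 0.25),
    refset = list(n_instances = 100L, inverter_alpha = 3, mimic_alpha = 3,
                  noise_sd = 1.0),
    derive = list(q_threshold = 0.05, depths = c(10L, 20L, 30L, 40L, 50L)),
    connect = list(K = 2000L, fpr = 1),
    hits = list(min_signatures = 2L, direction = "negative"),
    synergy = list(Dm_A = 2.0, slope_A = 1.5, Dm_B = 0.5, slope_B = 2.0,
                   interaction = 0.6, grid = c(0, 0.25, 0.5, 1, 2),
                   n_reps = 3L, cv_noise = 0.02, band = 0.1)
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the layout of [demo_config()].
#' @return A configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$derive$depths)) {
    cfg$derive$depths <- as.integer(cfg$derive$depths)
  }
  cfg
}

stage_log <- function(stage, msg, ...) {
  message(sprintf("[%s] %s", stage, sprintf(msg, ...)))
}

run_stage <- function(stage, code) {
  stage_log(stage, "start")
  tryCatch(code, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order (simulate, derive, connect, hits,
#' synergy), writes every artifact as TSV under `config$out_dir`, and
#' records a JSON manifest with the configuration, stage seeds and an MD5
#' checksum of every produced file. Re-running the same configuration
#' reproduces identical artifacts and checksums. A stage failure halts
#' the run with the failing stage named; artifacts already written are
#' retained.
#'
#' @param config Configuration list (see [demo_config()] /
#'   [read_run_config()]).
#' @return Invisibly, the manifest list (also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  out_dir <- config$out_dir %||% stop("config$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  stages <- config$stages %||% list()
  enabled <- function(s) isTRUE(stages[[s]])
  artifacts <- character(0)
  keep <- function(path) artifacts <<- c(artifacts, path)
  seeds <- list()

  cohort <- NULL
  signatures <- NULL

  if (enabled("simulate") || enabled("derive") || enabled("connect")) {
    if (enabled("simulate")) {
      run_stage("simulate", {
        seeds$cohort <- child_seed(seed, 1L)
        cohort <- simulate_expression_cohort(do.call(cohort_spec, c(
          config$cohort, list(seed = seeds$cohort))))
        keep(write_expression_tsv(cohort$expression,
                                  file.path(out_dir, "expression.tsv")))
        keep(write_annotation_tsv(cohort$annotation,
                                  file.path(out_dir, "annotation.tsv")))
        truth <- data.frame(
          gene_id = c(cohort$truth$up, cohort$truth$down),
          direction = rep(c("up", "down"),
                          c(length(cohort$truth$up),
                            length(cohort$truth$down))))
        write_tsv(truth, file.path(out_dir, "cohort_truth.tsv"))
        keep(file.path(out_dir, "cohort_truth.tsv"))
        stage_log("simulate", "cohort: %d genes x %d samples",
                  nrow(cohort$expression), ncol(cohort$expression))
      })
    }
  }

  if (enabled("derive")) {
    run_stage("derive", {
      if (is.null(cohort)) {
        X <- read_expression_tsv(file.path(out_dir, "expression.tsv"))
        ann <- read_annotation_tsv(file.path(out_dir, "annotation.tsv"))
      } else {
        X <- cohort$expression
        ann <- cohort$annotation
      }
      diff <- differential_analysis(X, ann)
      write_tsv(diff, file.path(out_dir, "differential.tsv"))
      keep(file.path(out_dir, "differential.tsv"))
      lists <- monotone_filter(diff,
                               config$derive$q_threshold %||% 0.05)
      stage_log("derive", "monotone genes: %d increasing, %d decreasing",
                length(lists$increasing), length(lists$decreasing))
      signatures <- build_signatures(lists$increasing, lists$decreasing,
                                      config$derive$depths %||%
                                        c(10L, 20L, 30L, 40L, 50L))
      sig_dir <- file.path(out_dir, "signatures")
      dir.create(sig_dir, showWarnings = FALSE)
      for (sig in signatures) {
        keep(write_signature_tsv(
          sig, file.path(sig_dir, paste0(sig$signature_id, ".tsv"))))
      }
      stage_log("derive", "%d derivative signatures", length(signatures))
    })
  }

  results <- NULL
  if (enabled("connect")) {
    run_stage("connect", {
      if (is.null(signatures)) stop("no signatures available")
      deepest <- signatures[[length(signatures)]]
      seeds$refset <- child_seed(seed, 2L)
      rcfg <- config$refset %||% list()
      n_inst <- rcfg$n_instances %||% 100L
      sim <- simulate_refset(refset_spec(
        n_instances = n_inst,
        universe = rownames(if (is.null(cohort)) {
          read_expression_tsv(file.path(out_dir, "expression.tsv"))
        } else cohort$expression),
        inverters = list(list(instance = 1L, signature = deepest,
                              alpha = rcfg$inverter_alpha %||% 3)),
        mimics = list(list(instance = 2L, signature = deepest,
                           alpha = rcfg$mimic_alpha %||% 3)),
        noise_sd = rcfg$noise_sd %||% 1.0,
        seed = seeds$refset))
      write_tsv(sim$truth, file.path(out_dir, "refset_truth.tsv"))
      keep(file.path(out_dir, "refset_truth.tsv"))
      seeds$connect <- child_seed(seed, 3L)
      results <- connect_all(signatures, sim$refset,
                              K = config$connect$K %||% 10000L,
                              seed = seeds$connect,
                              fpr = config$connect$fpr %||% 1)
      write_tsv(results, file.path(out_dir, "connections.tsv"))
      keep(file.path(out_dir, "connections.tsv"))
      stage_log("connect", "%d connections, %d significant",
                nrow(results), sum(results$significant))
    })
  }

  if (enabled("hits")) {
    run_stage("hits", {
      if (is.null(results)) stop("no connection results available")
      hits <- select_hits(results,
                          config$hits$min_signatures %||% 2L,
                          config$hits$direction %||% "negative")
      write_tsv(hits, file.path(out_dir, "hits.tsv"))
      keep(file.path(out_dir, "hits.tsv"))
      stage_log("hits", "%d perturbagens selected, %d hits",
                nrow(hits), sum(hits$hit))
    })
  }

  if (enabled("synergy")) {
    run_stage("synergy", {
      scfg <- config$synergy %||% list()
      seeds$synergy <- child_seed(seed, 4L)
      specA <- dose_response_spec(drug = "drugA",
                                  true_Dm = scfg$Dm_A %||% 2.0,
                                  true_slope = scfg$slope_A %||% 1.5,
                                  cv_noise = scfg$cv_noise %||% 0.02,
                                  seed = child_seed(seeds$synergy, 1L))
      specB <- dose_response_spec(drug = "drugB",
                                  true_Dm = scfg$Dm_B %||% 0.5,
                                  true_slope = scfg$slope_B %||% 2.0,
                                  cv_noise = scfg$cv_noise %||% 0.02,
                                  seed = child_seed(seeds$synergy, 2L))
      tabA <- simulate_dose_response(specA)
      tabB <- simulate_dose_response(specB)
      combo <- simulate_combination_grid(
        specA, specB,
        interaction = scfg$interaction %||% 1,
        grid = scfg$grid %||% c(0, 0.25, 0.5, 1, 2),
        n_reps = scfg$n_reps %||% 3L,
        cv_noise = scfg$cv_noise %||% 0.02,
        seed = child_seed(seeds$synergy, 3L))
      keep(write_viability_tsv(combo, file.path(out_dir, "combination.tsv")))
      nvA <- normalize_viability(tabA)
      nvB <- normalize_viability(tabB)
      fitA <- fit_median_effect(nvA$dose, nvA$fa)
      fitB <- fit_median_effect(nvB$dose, nvB$fa)
      fits <- data.frame(drug = c(specA$drug, specB$drug),
                         Dm = c(fitA$Dm, fitB$Dm),
                         m = c(fitA$m, fitB$m),
                         r2 = c(fitA$r_squared, fitB$r_squared),
                         n = c(fitA$n_points, fitB$n_points))
      write_tsv(fits, file.path(out_dir, "median_effect_fits.tsv"))
      keep(file.path(out_dir, "median_effect_fits.tsv"))
      ci <- combination_index(combo, fitA, fitB,
                              band = scfg$band %||% 0.1)
      write_tsv(ci, file.path(out_dir, "combination_index.tsv"))
      keep(file.path(out_dir, "combination_index.tsv"))
      stage_log("synergy", "median interior CI = %.3f",
                stats::median(ci$CI, na.rm = TRUE))
    })
  }

  manifest <- list(
    package = "sigconnect",
    version = as.character(utils::packageVersion("sigconnect")),
    config = config[setdiff(names(config), "out_dir")],
    seeds = seeds,
    artifacts = lapply(stats::setNames(artifacts, basename(artifacts)),
                       function(p) unname(tools::md5sum(p)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
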