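#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis in one place so that all
#' numbers appearing in outputs trace back to the configuration. Defaults
#' follow the standard analysis settings: within-individual FDR 0.10, minimum
#' tested depth 8 reads, at least 1 alternative-supporting read, Bayes-factor
#' evidence thresholds 1 (discordant) and 10 (strong), 500-bp bins stepped by
#' 250 bp, and the |r| > 0.5 / p < 0.05 correlation screen.
#'
#' @param fdr Within-individual AShM calling FDR.
#' @param min_depth Minimum total depth for a per-individual test.
#' @param min_alt_reads Candidate-site filter threshold.
#' @param min_pdc_pairs Minimum heterozygous PDC pairs for BF candidacy.
#' @param bf_discordant,bf_strong Bayes-factor evidence thresholds.
#' @param bin_width,bin_step Binned-profile geometry (bp).
#' @param r_threshold,cor_alpha TF correlation screen rule.
#' @param priors An [ashm_priors()] object.
#' @param inference An [ashm_inference()] object.
#' @param sim A [sim_params()] object (used when the pipeline simulates its
#'   input instead of ingesting files).
#' @param counts_tsv,genotypes_vcf,cohort_tsv Optional input paths for the
#'   real-data route; when all three are `NULL` the pipeline simulates.
#' @param seed Master seed for the run.
#' @return A named list of class `ashm_config`.
#' @export
ashm_config <- function(fdr = 0.10, min_depth = 8L, min_alt_reads = 1L,
                        min_pdc_pairs = 2L, bf_discordant = 1,
                        bf_strong = 10, bin_width = 500L, bin_step = 250L,
                        r_threshold = 0.5, cor_alpha = 0.05,
                        priors = ashm_priors(), inference = ashm_inference(),
                        sim = sim_params(), counts_tsv = NULL,
                        genotypes_vcf = NULL, cohort_tsv = NULL, seed = 1L) {
  structure(list(fdr = fdr, min_depth = min_depth,
                 min_alt_reads = min_alt_reads,
                 min_pdc_pairs = min_pdc_pairs,
                 bf_discordant = bf_discordant, bf_strong = bf_strong,
                 bin_width = bin_width, bin_step = bin_step,
                 r_threshold = r_threshold, cor_alpha = cor_alpha,
                 priors = priors, inference = inference, sim = sim,
                 counts_tsv = counts_tsv, genotypes_vcf = genotypes_vcf,
                 cohort_tsv = cohort_tsv, seed = as.integer(seed)),
            class = "ashm_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Reads a flat YAML file whose keys mirror the arguments of
#' [ashm_config()], [ashm_priors()], [ashm_inference()] and [sim_params()]
#' (prior, inference and simulation keys live under `priors:`, `inference:`
#' and `sim:` blocks). Keys absent from the file keep their defaults, so the
#' file only needs to state what differs. The configuration round-trips:
#' values read from a file equal the values written.
#'
#' @param path YAML file path.
#' @return An `ashm_config` object.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  take <- function(block, ctor) {
    args <- raw[[block]]
    if (is.null(args)) return(ctor())
    if (block == "sim" && !is.null(args$scenario_mix)) {
      args$scenario_mix <- unlist(args$scenario_mix)
    }
    do.call(ctor, args)
  }
  top <- raw[setdiff(names(raw), c("priors", "inference", "sim"))]
  do.call(ashm_config, c(top, list(priors = take("priors", ashm_priors),
                                   inference = take("inference",
                                                    ashm_inference),
                                   sim = take("sim", sim_params))))
}

#' Run the full AShM analysis pipeline
#'
#' Executes the stages in order — simulate (or ingest), filter, call,
#' transitions, enrich — writing each stage's tables and a run manifest
#' (package version, seed, configuration hash, per-stage row counts) under
#' `out_dir`. A stage failure halts the run with an error naming the stage,
#' after writing the partial manifest. Reruns with the same configuration and
#' inputs are reproducible: deterministic stages are bit-identical and the
#' stochastic model fits are seed-controlled.
#'
#' @param config An [ashm_config()] object (or a YAML path for
#'   [load_config()]).
#' @param out_dir Output directory.
#' @return Invisibly, a list with the per-stage results and the manifest.
#' @export
run_pipeline <- function(config = ashm_config(), out_dir) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "ashm_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package = "ashmtwin",
    version = as.character(utils::packageVersion("ashmtwin")),
    seed = config$seed,
    config_hash = rlang::hash(config),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stages = list()
  )
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  run_stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      write_manifest()
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- c(list(status = "complete"), res$counts)
    write_manifest()
    res$value
  }

  ingest <- run_stage("simulate", function() {
    if (!is.null(config$counts_tsv)) {
      cohort <- read_cohort_tsv(config$cohort_tsv)
      counts <- load_counts(config$counts_tsv, config$genotypes_vcf, cohort,
                            validate = FALSE) # the filter stage validates
      genotypes <- read_genotypes_vcf(config$genotypes_vcf)
      truth <- NULL
    } else {
      sim <- config$sim
      sim$seed <- config$seed
      simulated <- simulate_cohort(sim)
      write_fixture_bundle(simulated, file.path(out_dir, "input"))
      cohort <- simulated$cohort
      counts <- simulated$counts
      genotypes <- simulated$genotypes
      truth <- simulated$truth
    }
    list(value = list(cohort = cohort, counts = counts,
                      genotypes = genotypes, truth = truth),
         counts = list(n_sites = dplyr::n_distinct(counts$site_id),
                       n_records = nrow(counts)))
  })

  filtered <- run_stage("filter", function() {
    records <- validate_count_records(ingest$counts, ingest$cohort)
    records <- filter_candidate_sites(records, config$min_alt_reads)
    records <- filter_wgs_concordance(records, ingest$genotypes,
                                      ingest$cohort)
    readr::write_tsv(records, file.path(out_dir, "filtered_counts.tsv"))
    list(value = records,
         counts = list(n_sites = dplyr::n_distinct(records$site_id),
                       n_records = nrow(records)))
  })

  called <- run_stage("call", function() {
    calls <- call_ashm(filtered, ingest$cohort, fdr = config$fdr,
                       min_depth = config$min_depth)
    readr::write_tsv(calls, file.path(out_dir, "individual_calls.tsv"))
    ashm_sites <- unique(calls$site_id[calls$is_ashm])
    inference <- config$inference
    inference$seed <- config$seed
    posteriors <- call_site_posteriors(filtered, ingest$cohort,
                                       sites = ashm_sites,
                                       priors = config$priors,
                                       settings = inference)
    readr::write_tsv(posteriors, file.path(out_dir, "site_posteriors.tsv"))
    jsonlite::write_json(
      list(priors = unclass(config$priors),
           inference = unclass(inference)),
      file.path(out_dir, "inference_settings.json"),
      auto_unbox = TRUE, pretty = TRUE)
    list(value = list(calls = calls, posteriors = posteriors,
                      ashm_sites = ashm_sites),
         counts = list(n_tested = sum(!is.na(calls$p_value)),
                       n_ashm_calls = sum(calls$is_ashm),
                       n_ashm_sites = length(ashm_sites),
                       n_posterior_fits = nrow(posteriors)))
  })

  transitions <- run_stage("transitions", function() {
    inference <- config$inference
    inference$seed <- config$seed
    res <- detect_transitions(called$calls, filtered, ingest$cohort,
                              priors = config$priors, settings = inference,
                              min_pdc_pairs = config$min_pdc_pairs,
                              bf_discordant = config$bf_discordant,
                              bf_strong = config$bf_strong)
    readr::write_tsv(res, file.path(out_dir, "transitions.tsv"))
    report <- transition_report(res, truth = ingest$truth$sites)
    list(value = list(results = res, report = report),
         counts = list(n_candidates = nrow(res),
                       n_discordant = sum(res$evidence != "none"),
                       n_strong = sum(res$evidence == "strong")))
  })

  enriched <- run_stage("enrich", function() {
    psy_sites <- transitions$results$site_id[
      transitions$results$evidence != "none"]
    contrast <- if (length(psy_sites) > 0) {
      alt_preference_contrast(called$calls, ingest$cohort, psy_sites)
    } else NULL
    if (!is.null(contrast)) {
      readr::write_tsv(contrast, file.path(out_dir, "alt_preference.tsv"))
    }
    list(value = list(alt_preference = contrast, psy_sites = psy_sites),
         counts = list(n_psy_sites = length(psy_sites)))
  })

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  write_manifest()
  invisible(list(ingest = ingest, filtered = filtered, called = called,
                 transitions = transitions, enrich = enriched,
                 manifest = manifest))
}
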