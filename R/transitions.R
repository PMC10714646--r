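#' Select candidate sites for disease-associated transition testing
#'
#' The Bayes-factor comparison is only informative for sites that (i) show an
#' AShM call in at least one individual of a phenotype-discordant (PDC) pair
#' and (ii) are heterozygous (carry count records) in at least `min_pdc_pairs`
#' PDC pairs.
#'
#' @param calls Per-individual call tibble from [call_ashm()].
#' @param cohort A [twin_cohort()].
#' @param min_pdc_pairs Minimum number of heterozygous PDC pairs (default 2).
#' @return Character vector of candidate site ids.
#' @export
select_bf_candidates <- function(calls, cohort, min_pdc_pairs = 2L) {
  stopifnot(inherits(cohort, "twin_cohort"))
  inds <- cohort_individuals(cohort)
  pdc_ids <- inds$individual_id[inds$pair_class == "PDC"]
  joined <- calls %>%
    filter(.data$individual_id %in% pdc_ids) %>%
    inner_join(select(inds, "individual_id", "pair_id"), by = "individual_id")
  stats <- joined %>%
    group_by(.data$site_id) %>%
    summarise(any_ashm = any(.data$is_ashm),
              n_pdc_pairs = dplyr::n_distinct(
                .data$pair_id[duplicated(.data$pair_id) |
                                duplicated(.data$pair_id, fromLast = TRUE)]),
              .groups = "drop")
  sort(stats$site_id[stats$any_ashm & stats$n_pdc_pairs >= min_pdc_pairs])
}

#' Bayes factor for a disease-associated AShM transition at one site
#'
#' Compares, over the individuals of phenotype-discordant (PDC) pairs only,
#' the status-effect model
#' `M1: logit(p_is) = beta0 + beta_s + gamma_i` against the reduced model
#' `M0: logit(p_is) = beta0 + gamma_i`, where `beta_s` is effect-coded
#' `+delta/2` (affected) / `-delta/2` (unaffected) with a proper
#' `delta ~ Normal(0, delta_sd^2)` prior (a fixed effect needs a proper prior
#' for the marginal likelihood to exist) and `gamma_i ~ Normal(0,
#' sigma_gamma^2)`, `sigma_gamma ~ Half-Normal`. The log Bayes factor is the
#' difference of log marginal likelihoods, each integrating over all
#' parameters.
#'
#' @param site_records Count records of one site.
#' @param cohort A [twin_cohort()].
#' @param priors An [ashm_priors()] object (`delta_sd` is the
#'   transition-effect prior scale).
#' @param settings An [ashm_inference()] object; both models are fitted with
#'   the same seed.
#' @return One-row tibble with `site_id`, `log_bf`, `bf`, `log_ml_m1`,
#'   `log_ml_m0`, `n_informative_pairs`, `skipped_reason`.
#' @export
bayes_factor <- function(site_records, cohort, priors = ashm_priors(),
                         settings = ashm_inference()) {
  stopifnot(inherits(cohort, "twin_cohort"))
  site_id <- unique(site_records$site_id)
  stopifnot(length(site_id) == 1)
  inds <- cohort_individuals(cohort)
  rec <- site_records %>%
    mutate(depth = .data$ref_reads + .data$alt_reads) %>%
    filter(.data$depth >= 1) %>%
    inner_join(select(inds, "individual_id", "pair_id", "pair_class",
                      "affected"),
               by = "individual_id") %>%
    filter(.data$pair_class == "PDC") %>%
    arrange(.data$individual_id)
  n_pairs <- dplyr::n_distinct(rec$pair_id)
  if (n_pairs < 2) {
    return(tibble(site_id = site_id, log_bf = NA_real_, bf = NA_real_,
                  log_ml_m1 = NA_real_, log_ml_m0 = NA_real_,
                  n_informative_pairs = n_pairs,
                  skipped_reason = "fewer_than_2_informative_pdc_pairs"))
  }
  s1 <- site_model_spec(rec$alt_reads, rec$depth, rec$affected,
                        model = "m1", priors = priors,
                        gh_nodes = settings$gh_nodes)
  s0 <- site_model_spec(rec$alt_reads, rec$depth, rec$affected,
                        model = "m0", priors = priors,
                        gh_nodes = settings$gh_nodes)
  f1 <- marginal_likelihood(s1, settings)
  f0 <- marginal_likelihood(s0, settings)
  log_bf <- f1$log_ml - f0$log_ml
  tibble(site_id = site_id, log_bf = log_bf, bf = exp(log_bf),
         log_ml_m1 = f1$log_ml, log_ml_m0 = f0$log_ml,
         n_informative_pairs = n_pairs, skipped_reason = NA_character_)
}

# per-pair transition pattern given both cotwins' calls
pair_transition <- function(aff_ashm, aff_dir, un_ashm, un_dir) {
  case_when(
    aff_ashm & !un_ashm ~ "gain",
    !aff_ashm & un_ashm ~ "loss",
    aff_ashm & un_ashm & aff_dir != un_dir ~ "flip",
    TRUE ~ "similar" # both same direction or both non-AShM
  )
}

#' Classify the AShM transition category of a site
#'
#' For each informative PDC pair (both cotwins called) the pattern is
#' * `gain` — AShM in the affected cotwin only,
#' * `loss` — AShM in the unaffected cotwin only,
#' * `flip` — both cotwins AShM with opposite directions,
#' * `similar` — both AShM with the same direction, or both non-AShM.
#'
#' The site category is the majority vote over informative pairs; ties (and
#' sites with no informative pair) are `unclassified`.
#'
#' @param site_calls [call_ashm()] rows for one site.
#' @param cohort A [twin_cohort()].
#' @return List with `category` and `pair_patterns` (named character vector
#'   per informative PDC pair).
#' @export
classify_transition <- function(site_calls, cohort) {
  stopifnot(inherits(cohort, "twin_cohort"))
  inds <- cohort_individuals(cohort)
  joined <- site_calls %>%
    inner_join(select(inds, "individual_id", "pair_id", "pair_class",
                      "affected"),
               by = "individual_id") %>%
    filter(.data$pair_class == "PDC")
  if (nrow(joined) == 0) {
    return(list(category = "unclassified", pair_patterns = character(0)))
  }
  per_pair <- joined %>%
    group_by(.data$pair_id) %>%
    filter(n() == 2L) %>%
    summarise(
      pattern = pair_transition(
        .data$is_ashm[.data$affected], .data$direction[.data$affected],
        .data$is_ashm[!.data$affected], .data$direction[!.data$affected]),
      .groups = "drop")
  if (nrow(per_pair) == 0) {
    return(list(category = "unclassified", pair_patterns = character(0)))
  }
  votes <- table(per_pair$pattern)
  winners <- names(votes)[votes == max(votes)]
  category <- if (length(winners) == 1) winners else "unclassified"
  list(category = category,
       pair_patterns = setNames(per_pair$pattern, per_pair$pair_id))
}

#' Detect disease-associated AShM transitions across candidate sites
#'
#' Runs [bayes_factor()] and [classify_transition()] for every candidate site
#' and applies the evidence thresholds: `BF > bf_discordant` (default 1) for
#' a discordant AShM site, `BF > bf_strong` (default 10) for strong evidence
#' of a disease-associated transition. The transition category is classified
#' from the per-individual calls independently of the BF (magnitude changes
#' without a pattern change can drive the BF) and reported only for sites
#' with evidence.
#'
#' @param calls Per-individual calls ([call_ashm()]).
#' @param records Filtered count tibble.
#' @param cohort A [twin_cohort()].
#' @param priors,settings Model settings; per-site seeds derive from
#'   `settings$seed`.
#' @param min_pdc_pairs Candidate-selection threshold ([select_bf_candidates()]).
#' @param bf_discordant,bf_strong Evidence thresholds on the BF scale.
#' @return Tibble with `site_id`, `log_bf`, `bf`, `evidence`
#'   (`none`/`discordant`/`strong`), `category`, `n_informative_pairs`,
#'   `pair_patterns` (compact string).
#' @export
detect_transitions <- function(calls, records, cohort,
                               priors = ashm_priors(),
                               settings = ashm_inference(),
                               min_pdc_pairs = 2L,
                               bf_discordant = 1, bf_strong = 10) {
  candidates <- select_bf_candidates(calls, cohort, min_pdc_pairs)
  if (length(candidates) == 0) {
    return(tibble(site_id = character(0), log_bf = numeric(0),
                  bf = numeric(0), evidence = character(0),
                  category = character(0), n_informative_pairs = integer(0),
                  pair_patterns = character(0)))
  }
  base_seed <- if (is.null(settings$seed)) 0L else as.integer(settings$seed)
  rows <- lapply(seq_along(candidates), function(i) {
    sid <- candidates[i]
    s <- settings
    s$seed <- (base_seed + 104729L + 7919L * i) %% .Machine$integer.max
    bf_row <- bayes_factor(filter(records, .data$site_id == sid), cohort,
                           priors = priors, settings = s)
    cls <- classify_transition(filter(calls, .data$site_id == sid), cohort)
    evidence <- if (is.na(bf_row$bf) || bf_row$bf <= bf_discordant) "none"
      else if (bf_row$bf > bf_strong) "strong" else "discordant"
    mutate(bf_row,
           evidence = evidence,
           category = ifelse(evidence == "none", NA_character_,
                             cls$category),
           pair_patterns = paste(names(cls$pair_patterns), cls$pair_patterns,
                                 sep = ":", collapse = ";")) %>%
      select("site_id", "log_bf", "bf", "evidence", "category",
             "n_informative_pairs", "pair_patterns")
  })
  bind_rows(rows)
}

#' Summarise transition results
#'
#' Tabulates evidence tiers and transition categories; the category counts
#' partition the set of sites with evidence
#' (`gain + loss + flip + similar + unclassified = total`). When simulation
#' ground truth is supplied, a confusion matrix of category versus true
#' scenario is attached.
#'
#' @param results [detect_transitions()] output.
#' @param truth Optional truth tibble with `site_id` and `scenario`.
#' @return List with `evidence_counts`, `category_counts`, `n_sites` and
#'   (when truth is given) `confusion`.
#' @export
transition_report <- function(results, truth = NULL) {
  ev_levels <- c("none", "discordant", "strong")
  cat_levels <- c("gain", "loss", "flip", "similar", "unclassified")
  evidence_counts <- table(factor(results$evidence, levels = ev_levels))
  with_ev <- filter(results, .data$evidence != "none")
  category_counts <- table(factor(with_ev$category, levels = cat_levels))
  out <- list(evidence_counts = evidence_counts,
              category_counts = category_counts,
              n_sites = nrow(results))
  if (!is.null(truth)) {
    joined <- inner_join(results, select(truth, "site_id", "scenario"),
                         by = "site_id")
    out$confusion <- table(
      category = factor(joined$category, levels = cat_levels),
      scenario = factor(joined$scenario,
                        levels = c("null", "stable_ashm", "gain", "loss",
                                   "flip")))
  }
  out
}
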