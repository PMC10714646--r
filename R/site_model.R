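#' Bayesian quantification of allelic imbalance at one site
#'
#' Fits the binomial mixed model
#' `alt_i ~ Binomial(n_i, plogis(beta0 + b_s(i) + gamma_i))` to the
#' heterozygous individuals of one site, where `beta0` is the logit-scale
#' degree of allele-specific hydroxymethylation, `b_s` a mean-zero two-level
#' disease-status random effect (effect-coded `+d/2` affected / `-d/2`
#' unaffected with `d ~ Normal(0, sigma_status^2)`), and `gamma_i` a per-twin
#' random effect. The posterior of `beta0` quantifies the imbalance; credible
#' intervals are empirical posterior quantiles, and the two-tailed posterior
#' p-value is the tail area of `beta0` beyond the balanced null
#' `logit(0.5) = 0` (see [posterior_tail_pvalue()]).
#'
#' Sites informative in fewer than two individuals are skipped with a reason
#' code (`skipped_reason`), carrying only the per-individual call.
#'
#' @param site_records Count records of a single site (one row per
#'   heterozygous individual).
#' @param cohort A [twin_cohort()].
#' @param priors An [ashm_priors()] object.
#' @param settings An [ashm_inference()] object; set `settings$seed` for
#'   reproducible draws.
#' @return One-row tibble with `site_id`, `n_obs`, `beta0_mean`,
#'   `beta0_q025`, `beta0_q50`, `beta0_q975`, `sigma_gamma_post`,
#'   `sigma_status_post`, `pp_pvalue`, `ci_level`, `log_ml`, `ess`,
#'   `skipped_reason`. The equally weighted posterior draws of `beta0` are
#'   attached as attribute `"beta0_samples"`.
#' @export
fit_site_model <- function(site_records, cohort, priors = ashm_priors(),
                           settings = ashm_inference()) {
  stopifnot(inherits(cohort, "twin_cohort"))
  site_id <- unique(site_records$site_id)
  stopifnot(length(site_id) == 1)
  rec <- site_records %>%
    mutate(depth = .data$ref_reads + .data$alt_reads) %>%
    filter(.data$depth >= 1) %>%
    inner_join(select(cohort$individuals, "individual_id", "affected"),
               by = "individual_id")
  skip_row <- function(reason) {
    tibble(site_id = site_id, n_obs = nrow(rec), beta0_mean = NA_real_,
           beta0_q025 = NA_real_, beta0_q50 = NA_real_, beta0_q975 = NA_real_,
           sigma_gamma_post = NA_real_, sigma_status_post = NA_real_,
           pp_pvalue = NA_real_, ci_level = 0.95, log_ml = NA_real_,
           ess = NA_real_, skipped_reason = reason)
  }
  if (nrow(rec) < 2) {
    return(skip_row("fewer_than_2_informative_individuals"))
  }
  spec <- site_model_spec(rec$alt_reads, rec$depth, rec$affected,
                          model = "quant", priors = priors,
                          gh_nodes = settings$gh_nodes)
  fit <- marginal_likelihood(spec, settings)
  b0 <- fit$draws[, spec$idx$beta0]
  w <- fit$weights
  samples <- sample(b0, settings$n_samples, replace = TRUE, prob = w)
  qs <- wquantile(b0, w, c(0.025, 0.5, 0.975))
  out <- tibble(
    site_id = site_id, n_obs = nrow(rec),
    beta0_mean = sum(w * b0),
    beta0_q025 = qs[1], beta0_q50 = qs[2], beta0_q975 = qs[3],
    sigma_gamma_post = sum(w * exp(fit$draws[, spec$idx$log_sigma_gamma])),
    sigma_status_post = sum(w * exp(fit$draws[, spec$idx$log_sigma_status])),
    pp_pvalue = posterior_tail_pvalue(samples),
    ci_level = 0.95, log_ml = fit$log_ml, ess = fit$ess,
    skipped_reason = NA_character_
  )
  attr(out, "beta0_samples") <- samples
  out
}

#' Two-tailed posterior tail p-value against allelic balance
#'
#' `p = min(1, 2 * min(Pr(beta0 <= 0), Pr(beta0 >= 0)))` estimated from
#' posterior draws; `logit(0.5) = 0` is the balanced null.
#'
#' @param beta0_samples Numeric vector of posterior draws (>= 1000
#'   recommended).
#' @return p-value in `[0, 1]`.
#' @export
posterior_tail_pvalue <- function(beta0_samples) {
  stopifnot(length(beta0_samples) > 0)
  min(1, 2 * min(mean(beta0_samples <= 0), mean(beta0_samples >= 0)))
}

#' Fit the site quantification model across many sites
#'
#' Maps [fit_site_model()] over sites. Per-site seeds are derived
#' deterministically from `settings$seed` so results are reproducible and
#' independent of site order.
#'
#' @param records Filtered count tibble (many sites).
#' @param cohort A [twin_cohort()].
#' @param sites Optional character vector restricting which sites to fit
#'   (default: all sites with >= 2 informative individuals).
#' @param priors,settings See [fit_site_model()].
#' @return Tibble with one row per fitted (or skipped) site.
#' @export
call_site_posteriors <- function(records, cohort, sites = NULL,
                                 priors = ashm_priors(),
                                 settings = ashm_inference()) {
  ids <- sort(unique(records$site_id))
  if (!is.null(sites)) ids <- intersect(ids, sites)
  base_seed <- if (is.null(settings$seed)) 0L else as.integer(settings$seed)
  res <- lapply(seq_along(ids), function(i) {
    s <- settings
    s$seed <- (base_seed + 7919L * i) %% .Machine$integer.max
    fit_site_model(filter(records, .data$site_id == ids[i]), cohort,
                   priors = priors, settings = s)
  })
  bind_rows(res)
}
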