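#' Simulation parameters for a synthetic twin 5hmC cohort
#'
#' Defines the generative model for allele-specific 5hmC read counts in an MZ
#' twin cohort. For every heterozygous (pair, site) combination each cotwin
#' receives a sequencing depth from a zero-truncated negative binomial, and the
#' alternative-allele read count is Binomial with success probability
#' `plogis(beta0(status) + gamma_i)`, where `beta0(status)` is the scenario's
#' logit-scale allelic imbalance for that disease status and `gamma_i` is a
#' per-individual, per-site Normal(0, `sigma_gamma`) random effect.
#'
#' Scenario truth (`true_beta0_unaffected`, `true_beta0_affected`):
#' * `null` — (0, 0)
#' * `stable_ashm` — (`beta0_stable`, `beta0_stable`)
#' * `gain` — (0, `effect_size`): AShM appears in the affected cotwin
#' * `loss` — (`effect_size`, 0): AShM disappears in the affected cotwin
#' * `flip` — (`+effect_size/2`, `-effect_size/2`): imbalance reverses sign,
#'   so the affected/unaffected difference is again `effect_size`
#'
#' The default cohort design (6 PDC + 4 PCC + 4 HCC pairs, 28 individuals)
#' mirrors a typical discordant-MZ-twin study layout.
#'
#' @param n_pdc_pairs,n_pcc_pairs,n_hcc_pairs Pair counts per concordance
#'   class.
#' @param n_sites Number of simulated SNP sites.
#' @param depth_mean Expected read depth per (site, individual).
#' @param depth_dispersion Negative-binomial dispersion `kappa` of depth
#'   (variance = `m + kappa * m^2`); `0` gives Poisson depth.
#' @param het_prob Probability that a pair is heterozygous at a site (MZ
#'   cotwins always share genotype).
#' @param sigma_gamma SD of the per-individual random effect (logit scale).
#' @param scenario_mix Named proportions over
#'   `c(null, stable_ashm, gain, loss, flip)`; must sum to 1.
#' @param effect_size Absolute logit-scale difference between affected and
#'   unaffected cotwins for transition scenarios.
#' @param beta0_stable Logit-scale imbalance of stable AShM sites.
#' @param seed RNG seed (integer).
#'
#' @return A validated `sim_params` list.
#' @export
sim_params <- function(n_pdc_pairs = 6, n_pcc_pairs = 4, n_hcc_pairs = 4,
                       n_sites = 500, depth_mean = 40, depth_dispersion = 0.15,
                       het_prob = 0.3, sigma_gamma = 0.3,
                       scenario_mix = c(null = 0.5, stable_ashm = 0.2,
                                        gain = 0.1, loss = 0.1, flip = 0.1),
                       effect_size = 2, beta0_stable = 2, seed = 1L) {
  scenarios <- c("null", "stable_ashm", "gain", "loss", "flip")
  if (is.null(names(scenario_mix)) ||
      !all(names(scenario_mix) %in% scenarios)) {
    stop("configuration error: scenario_mix must be named with a subset of {",
         paste(scenarios, collapse = ", "), "}")
  }
  mix <- setNames(numeric(length(scenarios)), scenarios)
  mix[names(scenario_mix)] <- scenario_mix
  if (any(mix < 0) || abs(sum(mix) - 1) > 1e-8) {
    stop("configuration error: scenario_mix proportions must be non-negative ",
         "and sum to 1 (got ", sum(mix), ")")
  }
  stopifnot(depth_mean > 0, depth_dispersion >= 0, sigma_gamma >= 0,
            het_prob >= 0, het_prob <= 1, n_sites >= 1)
  structure(list(
    n_pdc_pairs = n_pdc_pairs, n_pcc_pairs = n_pcc_pairs,
    n_hcc_pairs = n_hcc_pairs, n_sites = as.integer(n_sites),
    depth_mean = depth_mean, depth_dispersion = depth_dispersion,
    het_prob = het_prob, sigma_gamma = sigma_gamma, scenario_mix = mix,
    effect_size = effect_size, beta0_stable = beta0_stable,
    seed = as.integer(seed)
  ), class = "sim_params")
}

# zero-truncated depth draw: resample zeros so counted sites have >=1 read
rdepth <- function(n, mean, dispersion) {
  draw <- function(m) {
    if (dispersion > 0) rnbinom(m, mu = mean, size = 1 / dispersion)
    else rpois(m, mean)
  }
  x <- draw(n)
  while (any(x == 0L)) {
    idx <- which(x == 0L)
    x[idx] <- draw(length(idx))
  }
  x
}

#' Simulate a twin cohort with allele-specific 5hmC counts
#'
#' Generates a cohort, per-site scenario ground truth, heterozygosity
#' structure, genotypes, and binomially distributed allele-specific read
#' counts according to [sim_params()]. Homozygous (pair, site) combinations
#' emit no count record. Identical parameters and seed reproduce identical
#' output.
#'
#' @param params A [sim_params()] object.
#' @return An object of class `ashm_sim`: a list with
#' \describe{
#'   \item{cohort}{[twin_cohort()]}
#'   \item{counts}{tibble of allele count records (`site_id`, `chrom`, `pos`,
#'     `ref`, `alt`, `individual_id`, `ref_reads`, `alt_reads`)}
#'   \item{genotypes}{long tibble (`site_id`, `chrom`, `pos`, `ref`, `alt`,
#'     `individual_id`, `gt`)}
#'   \item{truth}{list of `sites` (per-site scenario and true logit means) and
#'     `gamma` (per site x individual random effects at heterozygous pairs)}
#'   \item{params}{the input parameters}
#' }
#' @export
#' @examples
#' sim <- simulate_cohort(sim_params(n_sites = 20, seed = 42))
#' sim$truth$sites
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  cohort <- cohort_from_design(params$n_pdc_pairs, params$n_pcc_pairs,
                               params$n_hcc_pairs)
  inds <- cohort_individuals(cohort)
  n_sites <- params$n_sites

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1),
                USE.NAMES = FALSE)
  sites <- tibble(
    site_id = sprintf("s%05d", seq_len(n_sites)),
    chrom = "chr1",
    pos = 1000L * seq_len(n_sites),
    ref = ref, alt = alt,
    scenario = sample(names(params$scenario_mix), n_sites, replace = TRUE,
                      prob = params$scenario_mix)
  )
  e <- params$effect_size
  b <- params$beta0_stable
  truth_sites <- sites %>%
    mutate(
      true_beta0_unaffected = case_when(
        .data$scenario == "null" ~ 0,
        .data$scenario == "stable_ashm" ~ b,
        .data$scenario == "gain" ~ 0,
        .data$scenario == "loss" ~ e,
        .data$scenario == "flip" ~ e / 2
      ),
      true_beta0_affected = case_when(
        .data$scenario == "null" ~ 0,
        .data$scenario == "stable_ashm" ~ b,
        .data$scenario == "gain" ~ e,
        .data$scenario == "loss" ~ 0,
        .data$scenario == "flip" ~ -e / 2
      )
    ) %>%
    select("site_id", "scenario", "true_beta0_unaffected",
           "true_beta0_affected")

  # heterozygosity is a pair-level property (MZ cotwins share genotype)
  pair_ids <- cohort$pairs$pair_id
  het <- matrix(runif(n_sites * length(pair_ids)) < params$het_prob,
                nrow = n_sites, dimnames = list(sites$site_id, pair_ids))

  het_long <- tibble(
    site_id = rep(sites$site_id, times = length(pair_ids)),
    pair_id = rep(pair_ids, each = n_sites),
    het = as.vector(het)
  )
  grid <- inner_join(het_long, inds, by = "pair_id",
                     relationship = "many-to-many") %>%
    inner_join(select(sites, "site_id", "chrom", "pos", "ref", "alt"),
               by = "site_id") %>%
    inner_join(truth_sites, by = "site_id") %>%
    arrange(.data$site_id, .data$individual_id)

  genotypes <- grid %>%
    mutate(gt = ifelse(.data$het, "0/1", "0/0")) %>%
    select("site_id", "chrom", "pos", "ref", "alt", "individual_id", "gt")

  counted <- filter(grid, .data$het)
  m <- nrow(counted)
  gamma <- rnorm(m, 0, params$sigma_gamma)
  depth <- rdepth(m, params$depth_mean, params$depth_dispersion)
  beta0 <- ifelse(counted$affected, counted$true_beta0_affected,
                  counted$true_beta0_unaffected)
  alt_reads <- rbinom(m, depth, plogis(beta0 + gamma))

  counts <- counted %>%
    mutate(ref_reads = depth - alt_reads, alt_reads = alt_reads) %>%
    select("site_id", "chrom", "pos", "ref", "alt", "individual_id",
           "ref_reads", "alt_reads")
  truth_gamma <- counted %>%
    mutate(gamma = gamma) %>%
    select("site_id", "individual_id", "gamma")

  structure(list(cohort = cohort, counts = counts, genotypes = genotypes,
                 truth = list(sites = truth_sites, gamma = truth_gamma),
                 params = params),
            class = "ashm_sim")
}

#' @export
print.ashm_sim <- function(x, ...) {
  cat("<ashm_sim> ", x$params$n_sites, " sites, ",
      nrow(x$cohort$individuals), " individuals, ",
      nrow(x$counts), " count records\n", sep = "")
  print(table(x$truth$sites$scenario))
  invisible(x)
}

#' Write a simulated cohort as a plain-text fixture bundle
#'
#' Serializes a [simulate_cohort()] result into the on-disk formats the
#' ingestion functions consume: `counts.tsv` (allele count table),
#' `genotypes.vcf` (VCF v4.2 with per-individual GT), `cohort.tsv`,
#' `truth_sites.tsv` and `truth_gamma.tsv`. The bundle round-trips losslessly
#' through [load_counts()] and [read_cohort_tsv()].
#'
#' @param sim An `ashm_sim` object.
#' @param dir Output directory (created if absent).
#' @return Named character vector of file paths, invisibly.
#' @export
write_fixture_bundle <- function(sim, dir) {
  stopifnot(inherits(sim, "ashm_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  paths <- c(
    counts = file.path(dir, "counts.tsv"),
    vcf = file.path(dir, "genotypes.vcf"),
    cohort = file.path(dir, "cohort.tsv"),
    truth_sites = file.path(dir, "truth_sites.tsv"),
    truth_gamma = file.path(dir, "truth_gamma.tsv")
  )
  readr::write_tsv(sim$counts, paths[["counts"]])
  write_cohort_tsv(sim$cohort, paths[["cohort"]])
  readr::write_tsv(sim$truth$sites, paths[["truth_sites"]])
  readr::write_tsv(sim$truth$gamma, paths[["truth_gamma"]])
  write_genotype_vcf(sim$genotypes, sim$cohort, paths[["vcf"]])
  invisible(paths)
}

# Minimal VCF v4.2 writer (GT-only FORMAT). Kept internal: real-data
# workflows bring their own VCF; this exists so fixtures stay plain text.
write_genotype_vcf <- function(genotypes, cohort, path) {
  inds <- cohort$individuals$individual_id
  wide <- genotypes %>%
    select("site_id", "chrom", "pos", "ref", "alt", "individual_id", "gt") %>%
    tidyr::pivot_wider(names_from = "individual_id", values_from = "gt")
  missing_ind <- setdiff(inds, names(wide))
  for (id in missing_ind) wide[[id]] <- "./."
  wide <- arrange(wide, .data$chrom, .data$pos)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=ashmtwin",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", inds), collapse = "\t")
  )
  body_mat <- cbind(wide$chrom, wide$pos, wide$site_id, wide$ref, wide$alt,
                    ".", "PASS", ".", "GT",
                    as.matrix(wide[, inds, drop = FALSE]))
  body <- apply(body_mat, 1, paste, collapse = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
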