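# shared fixture builders; everything is generated in code

# count table for a single site across the individuals of `cohort`
site_counts <- function(cohort, alt, ref, site_id = "s1") {
  inds <- cohort$individuals$individual_id
  alt_n <- as.integer(alt) # bind before tibble() so the allele columns
  ref_n <- as.integer(ref) # cannot mask the count arguments
  tibble::tibble(
    site_id = site_id, chrom = "chr1", pos = 100L, ref = "A", alt = "G",
    individual_id = inds[seq_along(alt_n)],
    ref_reads = ref_n, alt_reads = alt_n
  )
}

# one simulated site over PDC pairs with a disease-status logit difference
# `delta` (affected +delta/2, unaffected -delta/2 around beta0)
simulate_pdc_site <- function(seed, delta, beta0 = 0, depth = 60,
                              n_pairs = 6, sigma_gamma = 0.3,
                              dispersion = 0.15) {
  set.seed(seed)
  cohort <- cohort_from_design(n_pairs, 0, 0)
  inds <- cohort$individuals
  eta <- beta0 + ifelse(inds$affected, delta / 2, -delta / 2) +
    rnorm(nrow(inds), 0, sigma_gamma)
  n <- pmax(1L, rnbinom(nrow(inds), mu = depth, size = 1 / dispersion))
  a <- rbinom(nrow(inds), n, plogis(eta))
  list(records = tibble::tibble(site_id = "s1", chrom = "chr1", pos = 100L,
                                ref = "A", alt = "G",
                                individual_id = inds$individual_id,
                                ref_reads = n - a, alt_reads = a),
       cohort = cohort)
}

# many independent null/stable sites for one individual set (vectorized);
# returns a count tibble across `n_sites` sites and all cohort individuals
simulate_flat_sites <- function(seed, cohort, n_sites, beta0 = 0,
                                sigma_gamma = 0.3, depth_mean = 40,
                                dispersion = 0.15) {
  set.seed(seed)
  inds <- cohort$individuals$individual_id
  m <- n_sites * length(inds)
  n <- pmax(1L, rnbinom(m, mu = depth_mean, size = 1 / dispersion))
  a <- rbinom(m, n, plogis(beta0 + rnorm(m, 0, sigma_gamma)))
  tibble::tibble(
    site_id = rep(sprintf("s%05d", seq_len(n_sites)), each = length(inds)),
    chrom = "chr1", pos = rep(1000L * seq_len(n_sites), each = length(inds)),
    ref = "A", alt = "G",
    individual_id = rep(inds, times = n_sites),
    ref_reads = n - a, alt_reads = a
  )
}
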