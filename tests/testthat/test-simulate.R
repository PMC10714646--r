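test_that("cohort constructor enforces the twin-pair invariants", {
  expect_s3_class(cohort_from_design(6, 4, 4), "twin_cohort")
  coh <- cohort_from_design(6, 4, 4)
  expect_equal(nrow(coh$individuals), 28)
  cls <- table(coh$pairs$pair_class)
  expect_equal(as.integer(cls[c("PDC", "PCC", "HCC")]), c(6L, 4L, 4L))
  # a pair with three members is rejected
  bad <- data.frame(individual_id = c("a", "b", "c"), pair_id = "p",
                    affected = FALSE)
  expect_error(twin_cohort(bad), "exactly 2")
})

test_that("simulation is deterministic in the seed and varies across seeds", {
  p <- sim_params(n_sites = 40, seed = 11)
  s1 <- simulate_cohort(p)
  s2 <- simulate_cohort(sim_params(n_sites = 40, seed = 11))
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_cohort(sim_params(n_sites = 40, seed = 12))
  expect_false(identical(s1$counts, s3$counts))
})

test_that("invalid scenario mixes are configuration errors", {
  expect_error(sim_params(scenario_mix = c(null = 0.5, gain = 0.4)),
               "configuration error")
  expect_error(sim_params(scenario_mix = c(zzz = 1)), "configuration error")
  expect_error(sim_params(scenario_mix = c(null = 1.2, gain = -0.2)),
               "configuration error")
})

test_that("counts follow the stated generative law", {
  # pure-null cohort, no random effect: pooled alt fraction ~ 0.5
  s <- simulate_cohort(sim_params(n_sites = 200, seed = 5, sigma_gamma = 0,
                                  scenario_mix = c(null = 1),
                                  depth_mean = 50))
  tot <- sum(s$counts$ref_reads + s$counts$alt_reads)
  frac <- sum(s$counts$alt_reads) / tot
  mc_sd <- sqrt(0.25 / tot)
  expect_lt(abs(frac - 0.5), 3 * mc_sd)

  # stable imbalance beta0 = 2 -> per-site alt fraction ~ plogis(2) = 0.881
  s2 <- simulate_cohort(sim_params(n_sites = 30, seed = 6, sigma_gamma = 0,
                                   scenario_mix = c(stable_ashm = 1),
                                   beta0_stable = 2, depth_mean = 10000,
                                   depth_dispersion = 0))
  per_site <- tapply(s2$counts$alt_reads,
                     s2$counts$site_id, sum) /
    tapply(s2$counts$alt_reads + s2$counts$ref_reads, s2$counts$site_id, sum)
  expect_true(all(abs(per_site - plogis(2)) < 0.02))
})

test_that("law of large numbers: alt fraction converges to the logit mean", {
  s <- simulate_cohort(sim_params(n_sites = 50, seed = 8, depth_mean = 10000,
                                  depth_dispersion = 0, sigma_gamma = 0.4))
  joined <- merge(s$counts, s$truth$gamma, by = c("site_id", "individual_id"))
  joined <- merge(joined, s$truth$sites, by = "site_id")
  aff <- s$cohort$individuals$affected[
    match(joined$individual_id, s$cohort$individuals$individual_id)]
  mu <- plogis(ifelse(aff, joined$true_beta0_affected,
                      joined$true_beta0_unaffected) + joined$gamma)
  frac <- joined$alt_reads / (joined$alt_reads + joined$ref_reads)
  expect_lt(max(abs(frac - mu)), 0.02)
})

test_that("monozygotic cotwins always share genotype", {
  s <- simulate_cohort(sim_params(n_sites = 80, seed = 13))
  gt <- merge(s$genotypes, s$cohort$individuals, by = "individual_id")
  n_disc <- sum(tapply(gt$gt, interaction(gt$site_id, gt$pair_id),
                       function(x) length(unique(x)) > 1))
  expect_equal(n_disc, 0)
})

test_that("truth tables satisfy the scenario contracts", {
  s <- simulate_cohort(sim_params(n_sites = 300, seed = 21))
  tr <- s$truth$sites
  expect_equal(nrow(tr), 300)
  null <- tr[tr$scenario == "null", ]
  expect_true(all(null$true_beta0_unaffected == 0 &
                    null$true_beta0_affected == 0))
  flip <- tr[tr$scenario == "flip", ]
  expect_true(all(sign(flip$true_beta0_unaffected) ==
                    -sign(flip$true_beta0_affected)))
  gain <- tr[tr$scenario == "gain", ]
  expect_true(all(gain$true_beta0_unaffected == 0 &
                    abs(gain$true_beta0_affected) > 0))
})

test_that("fixture bundles round-trip losslessly", {
  s <- simulate_cohort(sim_params(n_sites = 25, seed = 31))
  dir <- withr::local_tempdir()
  paths <- write_fixture_bundle(s, dir)
  expect_true(all(file.exists(paths)))

  coh <- read_cohort_tsv(paths[["cohort"]])
  expect_equal(coh$individuals, s$cohort$individuals)

  counts <- load_counts(paths[["counts"]], paths[["vcf"]], coh)
  expect_equal(dplyr::select(counts, -"gt"), s$counts)

  truth <- readr::read_tsv(paths[["truth_sites"]], show_col_types = FALSE)
  expect_equal(nrow(truth), 25)

  # all count rows belong to heterozygous individuals by construction
  expect_true(all(counts$gt == "0/1"))
  # hom-ref sites are 0/0 for both cotwins in the VCF
  gt <- read_genotypes_vcf(paths[["vcf"]])
  hom <- gt[!(paste(gt$site_id, gt$individual_id) %in%
                paste(s$counts$site_id, s$counts$individual_id)), ]
  expect_true(all(hom$gt == "0/0"))
})
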