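mk_calls <- function(cohort, site_id, is_ashm, direction) {
  tibble::tibble(
    site_id = site_id,
    individual_id = cohort$individuals$individual_id[seq_along(is_ashm)],
    depth = 50L, alt_fraction = 0.5, p_value = 0.5, q_value = 0.5,
    direction = direction, is_ashm = is_ashm
  )
}

test_that("candidate selection requires PDC evidence and enough het pairs", {
  coh <- cohort_from_design(3, 1, 1)
  inds <- coh$individuals$individual_id
  pdc <- inds[1:6]; pcc <- inds[7:8]; hcc <- inds[9:10]
  mk <- function(site_id, ids, ashm_ids) {
    tibble::tibble(site_id = site_id, individual_id = ids, depth = 50L,
                   alt_fraction = 0.6, p_value = 0.1, q_value = 0.2,
                   direction = "none", is_ashm = ids %in% ashm_ids)
  }
  calls <- dplyr::bind_rows(
    mk("hcc_only", c(pdc, hcc), hcc[1]),       # AShM only in an HCC twin
    mk("good", pdc, pdc[1]),                   # AShM in a PDC twin, 3 pairs
    mk("one_pair", pdc[1:2], pdc[1])           # only one het PDC pair
  )
  expect_equal(select_bf_candidates(calls, coh), "good")
  expect_equal(select_bf_candidates(calls, coh, min_pdc_pairs = 7L),
               character(0))
})

test_that("Bayes factor matches the quadrature oracle and is invariant to
           relabeling", {
  d <- simulate_pdc_site(seed = 3, delta = 2, depth = 40, n_pairs = 2)
  bf <- bayes_factor(d$records, d$cohort,
                     settings = ashm_inference(seed = 6, n_draws = 8000))
  rec <- d$records
  aff <- d$cohort$individuals$affected[
    match(rec$individual_id, d$cohort$individuals$individual_id)]
  lbf_oracle <- oracle_log_bf(rec$alt_reads,
                              rec$alt_reads + rec$ref_reads, aff)
  expect_equal(bf$log_bf, lbf_oracle, tolerance = 0.1)

  # permuting record order leaves the BF unchanged (same seed)
  perm <- d$records[sample(nrow(d$records)), ]
  bf2 <- bayes_factor(perm, d$cohort,
                      settings = ashm_inference(seed = 6, n_draws = 8000))
  expect_equal(bf$log_bf, bf2$log_bf, tolerance = 1e-9)
})

test_that("sites with fewer than two informative PDC pairs are flagged", {
  d <- simulate_pdc_site(seed = 4, delta = 0, n_pairs = 1)
  bf <- bayes_factor(d$records, d$cohort)
  expect_true(is.na(bf$log_bf))
  expect_equal(bf$skipped_reason, "fewer_than_2_informative_pdc_pairs")
})

test_that("transition categories follow the per-pair definitions", {
  coh <- cohort_from_design(1, 0, 0) # affected cotwin is pdc01_1
  gain <- mk_calls(coh, "s", c(TRUE, FALSE), c("alt_hyper", "none"))
  expect_equal(classify_transition(gain, coh)$category, "gain")
  loss <- mk_calls(coh, "s", c(FALSE, TRUE), c("none", "ref_hyper"))
  expect_equal(classify_transition(loss, coh)$category, "loss")
  flip <- mk_calls(coh, "s", c(TRUE, TRUE), c("alt_hyper", "ref_hyper"))
  expect_equal(classify_transition(flip, coh)$category, "flip")
  sim1 <- mk_calls(coh, "s", c(TRUE, TRUE), c("alt_hyper", "alt_hyper"))
  expect_equal(classify_transition(sim1, coh)$category, "similar")
  sim2 <- mk_calls(coh, "s", c(FALSE, FALSE), c("none", "none"))
  expect_equal(classify_transition(sim2, coh)$category, "similar")
})

test_that("tied pair votes and uninformative sites are unclassified", {
  coh <- cohort_from_design(2, 0, 0)
  tied <- mk_calls(coh, "s",
                   c(TRUE, FALSE, FALSE, TRUE),
                   c("alt_hyper", "none", "none", "alt_hyper"))
  expect_equal(classify_transition(tied, coh)$category, "unclassified")
  none <- mk_calls(coh, "s", logical(0), character(0))
  expect_equal(classify_transition(none, coh)$category, "unclassified")
})

test_that("transition report partitions classified sites", {
  results <- tibble::tibble(
    site_id = sprintf("s%d", 1:6),
    log_bf = c(3, 0.5, -1, 2, 4, 1.2),
    bf = exp(log_bf),
    evidence = c("strong", "none", "none", "discordant", "strong",
                 "discordant"),
    category = c("gain", NA, NA, "loss", "flip", "similar"),
    n_informative_pairs = 3L, pair_patterns = ""
  )
  rep <- transition_report(results)
  expect_equal(sum(rep$category_counts), sum(results$evidence != "none"))
  expect_equal(rep$n_sites, 6)
  empty <- transition_report(results[0, ])
  expect_true(all(empty$category_counts == 0))
  truth <- tibble::tibble(site_id = results$site_id,
                          scenario = c("gain", "null", "null", "loss",
                                       "flip", "stable_ashm"))
  rep2 <- transition_report(results, truth)
  expect_equal(unname(rep2$confusion["gain", "gain"]), 1)
})
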