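test_that("cross-product odds ratios match hand arithmetic", {
  r <- fisher_or(710, 97, 484, 323)
  expect_equal(r$odds_ratio, (710 * 323) / (97 * 484), tolerance = 1e-12)
  expect_equal(r$odds_ratio, 4.885, tolerance = 1e-3)
  r2 <- fisher_or(30, 70, 100, 900)
  expect_equal(r2$odds_ratio, 27 / 7, tolerance = 1e-12)
  # zero cell: Haldane-Anscombe correction, flagged
  r3 <- fisher_or(0, 10, 5, 5)
  expect_true(r3$zero_cell)
  expect_equal(r3$odds_ratio, (0.5 * 5.5) / (10.5 * 5.5), tolerance = 1e-12)
  # CI contains the point estimate
  expect_true(r$ci_lo < r$odds_ratio && r$odds_ratio < r$ci_hi)
})

test_that("Fisher p-values match hypergeometric enumeration", {
  set.seed(3)
  for (i in 1:40) {
    a <- sample(0:12, 1); b <- sample(0:12, 1)
    c_ <- sample(0:12, 1); d <- sample(0:12, 1)
    if (a + b == 0 || c_ + d == 0) next
    expect_equal(fisher_or(a, b, c_, d)$p_value,
                 oracle_fisher_p(a, b, c_, d), tolerance = 1e-9)
  }
})

test_that("interval-overlap enrichment counts sites per label", {
  fg <- tibble::tibble(chrom = "chr1", pos = c(10L, 110L, 210L))
  bg <- tibble::tibble(chrom = "chr1", pos = c(10L, 110L, 210L, 310L,
                                               410L, 510L))
  ann <- tibble::tibble(chrom = "chr1",
                        start = c(0, 300), end = c(250, 600),
                        name = c("Enh", "Quies"))
  res <- fisher_enrichment(fg, bg, ann)
  enh <- res[res$label == "Enh", ]
  expect_equal(c(enh$a, enh$b, enh$c, enh$d), c(3, 0, 3, 3))
  quies <- res[res$label == "Quies", ]
  expect_equal(c(quies$a, quies$c), c(0, 3))
  expect_error(fisher_enrichment(fg[0, ], bg, ann), "empty foreground")
  expect_warning(fisher_enrichment(tibble::tibble(chrom = "chr2", pos = 5L),
                                   bg, ann), "absent from the background")
})

test_that("fixed-effect meta-analysis follows inverse-variance algebra", {
  one <- fisher_or(30, 70, 100, 900)
  single <- meta_enrichment(one)
  expect_equal(single$log_or, one$log_or, tolerance = 1e-9)
  expect_equal(single$se_log_or, one$se_log_or, tolerance = 1e-9)

  two <- dplyr::bind_rows(one, one)
  comb <- meta_enrichment(two)
  expect_equal(comb$log_or, one$log_or, tolerance = 1e-9)
  expect_equal(comb$se_log_or, one$se_log_or / sqrt(2), tolerance = 1e-9)

  # k identical studies shrink the se by sqrt(k) exactly
  for (k in c(3, 7)) {
    many <- dplyr::bind_rows(replicate(k, one, simplify = FALSE))
    expect_equal(meta_enrichment(many)$se_log_or, one$se_log_or / sqrt(k),
                 tolerance = 1e-9)
  }

  # equal-weight opposite effects cancel
  opp <- one
  opp$log_or <- -one$log_or
  expect_equal(meta_enrichment(dplyr::bind_rows(one, opp))$log_or, 0,
               tolerance = 1e-9)
  expect_lte(comb$se_log_or, min(two$se_log_or))
})

test_that("direction-consistency test shares the exact binomial kernel", {
  expect_equal(direction_consistency_test(10, 10), 2 / 1024)
  expect_equal(direction_consistency_test(5, 10), 1)
  for (n in c(6, 13, 40)) {
    same <- sample(0:n, 1)
    expect_equal(direction_consistency_test(same, n),
                 binomial_ashm_test(same, n - same)$p_value)
  }
  expect_error(direction_consistency_test(5, 0))
})

test_that("feature-effect directions are labelled by the sign rule", {
  effects <- tibble::tibble(site_id = sprintf("s%d", 1:6),
                            z = c(2, -1, 3, -2, 0, 1),
                            e_value = c(0.001, 0.005, 0.002, 0.003, 0.001,
                                        0.5))
  alt_levels <- tibble::tibble(site_id = sprintf("s%d", 1:6),
                               alt_level = c(0.8, 0.3, 0.2, 0.9, 0.7, 0.8))
  out <- suppressMessages(prepare_direction_counts(effects, alt_levels))
  # s6 fails the e-value filter; s5 has no direction (z = 0)
  expect_equal(out$n_total, 4)
  # same: s1 (z>0, alt>0.5), s2 (z<0, alt<0.5); opposite: s3, s4
  expect_equal(out$n_same, 2)
})

test_that("gene-set enrichment handles explicit and sampled backgrounds", {
  sets <- list(SETA = c("g1", "g2", "g3"), SETB = c("g8", "g9"))
  bg <- paste0("g", 1:100)
  res <- geneset_enrichment(c("g1", "g2", "g3"), sets, bg)
  # foreground identical to SETA maximizes its odds ratio
  a_row <- res[res$label == "SETA", ]
  expect_equal(c(a_row$a, a_row$b), c(3, 0))
  expect_gt(a_row$odds_ratio, res$odds_ratio[res$label == "SETB"])
  expect_equal(a_row$odds_ratio,
               fisher_or(3, 0, 3, 97)$odds_ratio)

  # sampled background is seed-deterministic
  spec <- list(universe = paste0("g", 1:5000), n = 500, seed = 42)
  r1 <- geneset_enrichment(c("g1", "g2"), list(S = paste0("g", 1:50)), spec)
  r2 <- geneset_enrichment(c("g1", "g2"), list(S = paste0("g", 1:50)), spec)
  expect_identical(r1, r2)

  # sets with no background member are skipped
  expect_message(
    out <- geneset_enrichment(c("g1"), list(EMPTY = "zz9"), bg),
    "skipped")
  expect_equal(nrow(out), 0)
})

test_that("GMT round trip preserves set membership", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("SETA\tdesc\tg1\tg2\tg3", "SETB\tdesc\tg4\tg5"), path)
  sets <- read_gmt(path)
  expect_equal(sort(names(sets)), c("SETA", "SETB"))
  expect_equal(sets$SETA, c("g1", "g2", "g3"))
})

test_that("TF correlation screen applies the |r| and p rule", {
  # perfectly linear effects are significant and positive
  scores <- tibble::tibble(tf = "TF1", site_id = sprintf("s%d", 1:5),
                           effect = seq(0.1, 0.5, by = 0.1))
  levels <- tibble::tibble(site_id = sprintf("s%d", 1:5),
                           alt_level = seq(0.2, 1, by = 0.2))
  out <- tf_correlation_screen(scores, levels)
  expect_equal(out$r, 1)
  expect_true(out$significant)
  expect_equal(out$sign, "positive")

  # fewer than three paired sites violates the precondition
  out2 <- tf_correlation_screen(scores[1:2, ], levels)
  expect_equal(nrow(out2), 0)

  # constant input is undefined and flagged
  const <- dplyr::mutate(scores, effect = 0.3)
  expect_message(out3 <- tf_correlation_screen(const, levels), "constant")
  expect_true(is.na(out3$r))
})

test_that("alt-preference contrast reproduces printed-proportion tables", {
  rec <- alt_preference_from_proportions(807, 0.88, 0.60)
  expect_equal(c(rec$a, rec$b, rec$c, rec$d), c(710, 97, 484, 323))
  expect_equal(rec$odds_ratio, 4.885, tolerance = 1e-3)
})
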