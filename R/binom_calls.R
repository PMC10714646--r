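#' Exact binomial test of allelic balance
#'
#' Two-sided exact binomial test of the alternative-allele read count against
#' a balanced proportion of 0.5. Because the null pmf is symmetric the
#' two-sided p-value is `min(1, 2 * pbinom(min(alt, ref), alt + ref, 0.5))`,
#' identical to `binom.test()` but vectorized. Direction is `alt_hyper` when
#' alt > ref, `ref_hyper` when alt < ref and `none` on ties.
#'
#' @param alt_reads,ref_reads Non-negative integer vectors (recycled to a
#'   common length). Rows with zero total depth are undefined and returned as
#'   `NA` with a message.
#' @return Tibble with `p_value` and `direction`.
#' @export
#' @examples
#' binomial_ashm_test(9, 1) # p = 22/1024
binomial_ashm_test <- function(alt_reads, ref_reads) {
  n <- length(alt_reads) ; m <- length(ref_reads)
  if (n != m) {
    len <- max(n, m)
    alt_reads <- rep_len(alt_reads, len)
    ref_reads <- rep_len(ref_reads, len)
  }
  stopifnot(all(alt_reads >= 0, na.rm = TRUE),
            all(ref_reads >= 0, na.rm = TRUE))
  total <- alt_reads + ref_reads
  zero <- !is.na(total) & total == 0L
  if (any(zero)) {
    message(sum(zero), " record(s) with zero total depth: test undefined, ",
            "returned NA")
  }
  p <- pmin(1, 2 * pbinom(pmin(alt_reads, ref_reads), total, 0.5))
  p[zero | is.na(total)] <- NA_real_
  direction <- case_when(
    is.na(total) | zero ~ NA_character_,
    alt_reads > ref_reads ~ "alt_hyper",
    alt_reads < ref_reads ~ "ref_hyper",
    TRUE ~ "none"
  )
  tibble(p_value = p, direction = direction)
}

#' Benjamini-Hochberg FDR adjustment with rejection flags
#'
#' Standard BH step-up procedure (via [stats::p.adjust()]); a hypothesis is
#' rejected when its adjusted q-value is strictly below `q`, matching an
#' "FDR less than 10%" calling rule.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @param q Nominal FDR level.
#' @return Tibble with `q_value` and `rejected`; zero rows for empty input.
#' @export
bh_fdr <- function(p_values, q = 0.10) {
  if (length(p_values) == 0) {
    return(tibble(q_value = numeric(0), rejected = logical(0)))
  }
  qv <- p.adjust(p_values, method = "BH")
  tibble(q_value = qv, rejected = !is.na(qv) & qv < q)
}

#' Per-individual AShM calling
#'
#' Applies the exact binomial allelic-balance test to every (site, individual)
#' record with depth at least `min_depth`, then controls the FDR at `fdr`
#' *within each individual* across that individual's tested sites
#' (Benjamini-Hochberg). A record is an AShM call (`is_ashm`) when its
#' q-value is below `fdr`; the reported `direction` is `none` unless the call
#' is significant. Records below `min_depth` are retained untested
#' (`p_value`/`q_value` `NA`, `is_ashm` `FALSE`).
#'
#' @param records Filtered allele count tibble.
#' @param cohort A [twin_cohort()] (used to validate individual ids).
#' @param fdr Nominal within-individual FDR (default 0.10).
#' @param min_depth Minimum total depth for a record to be tested (default 8).
#' @return Tibble of per-individual calls: `site_id`, `individual_id`,
#'   `depth`, `alt_fraction`, `p_value`, `q_value`, `direction`, `is_ashm`.
#' @export
call_ashm <- function(records, cohort, fdr = 0.10, min_depth = 8L) {
  stopifnot(inherits(cohort, "twin_cohort"))
  if (nrow(records) > 0) {
    validate_count_records(records, cohort)
  }
  calls <- records %>%
    mutate(depth = .data$ref_reads + .data$alt_reads,
           alt_fraction = ifelse(.data$depth > 0,
                                 .data$alt_reads / .data$depth, NA_real_),
           tested = .data$depth >= min_depth)
  tested_tab <- binomial_ashm_test(
    ifelse(calls$tested, calls$alt_reads, NA_integer_), calls$ref_reads)
  calls$p_value <- tested_tab$p_value
  calls$raw_direction <- tested_tab$direction
  calls <- calls %>%
    group_by(.data$individual_id) %>%
    mutate(q_value = {
      qv <- rep(NA_real_, dplyr::n())
      idx <- which(!is.na(.data$p_value))
      if (length(idx) > 0) qv[idx] <- p.adjust(.data$p_value[idx], "BH")
      qv
    }) %>%
    ungroup() %>%
    mutate(
      is_ashm = !is.na(.data$q_value) & .data$q_value < fdr &
        .data$depth >= min_depth,
      direction = ifelse(.data$is_ashm, .data$raw_direction, "none")
    ) %>%
    select("site_id", "individual_id", "depth", "alt_fraction", "p_value",
           "q_value", "direction", "is_ashm")
  calls
}

#' Within-pair AShM pattern at a site
#'
#' Classifies each (site, twin pair) with calls for both heterozygous cotwins
#' as `concordant` (both AShM with the same direction), `discordant` (exactly
#' one cotwin AShM, or both AShM with opposite directions) or `neither`.
#' Pairs with a missing cotwin call are `neither` (logged).
#'
#' @param calls Per-individual call tibble from [call_ashm()].
#' @param cohort A [twin_cohort()].
#' @return Tibble with `site_id`, `pair_id`, `pattern`.
#' @export
pair_pattern <- function(calls, cohort) {
  stopifnot(inherits(cohort, "twin_cohort"))
  joined <- calls %>%
    inner_join(select(cohort$individuals, "individual_id", "pair_id"),
               by = "individual_id")
  pat <- joined %>%
    group_by(.data$site_id, .data$pair_id) %>%
    summarise(
      n_calls = n(),
      n_ashm = sum(.data$is_ashm),
      same_dir = dplyr::n_distinct(.data$direction[.data$is_ashm]) == 1L,
      .groups = "drop"
    ) %>%
    mutate(pattern = case_when(
      .data$n_calls < 2L ~ "neither",
      .data$n_ashm == 2L & .data$same_dir ~ "concordant",
      .data$n_ashm == 2L & !.data$same_dir ~ "discordant",
      .data$n_ashm == 1L ~ "discordant",
      TRUE ~ "neither"
    ))
  n_missing <- sum(pat$n_calls < 2L)
  if (n_missing > 0) {
    message(n_missing, " (site, pair) combination(s) with a missing cotwin ",
            "call: pattern set to 'neither'")
  }
  select(pat, "site_id", "pair_id", "pattern")
}
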