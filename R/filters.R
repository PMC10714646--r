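#' Candidate-site filter: evidence for the alternative allele
#'
#' A locus only qualifies as a candidate polymorphic site for allele-specific
#' analysis if at least `min_alt_reads` (default 1) quality-filtered reads
#' support the alternative allele. Rows failing the rule are removed; sites
#' with no surviving row disappear entirely. The filter is idempotent and
#' commutes with [filter_wgs_concordance()].
#'
#' @param records Allele count tibble (see [read_count_tsv()]).
#' @param min_alt_reads Minimum alternative-allele read count per
#'   (site, individual) row.
#' @return Filtered tibble.
#' @export
filter_candidate_sites <- function(records, min_alt_reads = 1L) {
  out <- filter(records, .data$alt_reads >= min_alt_reads)
  dropped <- dplyr::n_distinct(records$site_id) -
    dplyr::n_distinct(out$site_id)
  if (dropped > 0) {
    message("candidate filter removed ", dropped,
            " site(s) with no alternative-allele support")
  }
  out
}

#' WGS-concordance and heterozygosity filter
#'
#' Retains only sites that were called in WGS genotyping and whose genotypes
#' are concordant within every MZ twin pair, then keeps the rows of
#' heterozygous individuals only (informative SNPs are those heterozygous in
#' at least one twin pair; homozygous individuals carry no allele-specific
#' information). Sites absent from the genotype call set are dropped with a
#' logged count, not an error.
#'
#' @param records Allele count tibble.
#' @param genotypes Long genotype tibble as returned by
#'   [read_genotypes_vcf()] (or the `gt` column already joined by
#'   [load_counts()] is ignored — the explicit table is authoritative).
#' @param cohort A [twin_cohort()].
#' @return Filtered tibble restricted to heterozygous individuals at
#'   genotype-concordant sites.
#' @export
filter_wgs_concordance <- function(records, genotypes, cohort) {
  stopifnot(inherits(cohort, "twin_cohort"))
  if (nrow(records) == 0) return(records)
  gt <- genotypes %>%
    select("site_id", "individual_id", "gt") %>%
    inner_join(select(cohort$individuals, "individual_id", "pair_id"),
               by = "individual_id")

  absent <- setdiff(unique(records$site_id), unique(gt$site_id))
  if (length(absent) > 0) {
    message(length(absent), " site(s) absent from the WGS call set; dropped")
  }

  # MZ concordance: both cotwins of every pair must carry the same genotype
  disc <- gt %>%
    group_by(.data$site_id, .data$pair_id) %>%
    summarise(discordant = dplyr::n_distinct(.data$gt) > 1L,
              .groups = "drop") %>%
    filter(.data$discordant)
  if (nrow(disc) > 0) {
    message(dplyr::n_distinct(disc$site_id),
            " site(s) with genotype-discordant cotwins; dropped")
  }

  het <- gt %>%
    filter(!(.data$site_id %in% disc$site_id), is_het_gt(.data$gt)) %>%
    select("site_id", "individual_id")

  semi_join(records, het, by = c("site_id", "individual_id"))
}
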