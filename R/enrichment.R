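#' Fisher enrichment of a 2x2 contingency table
#'
#' Core enrichment kernel: `a` foreground-in, `b` foreground-out, `c`
#' background-in, `d` background-out. The odds ratio is the cross-product
#' `(a*d)/(b*c)` (the quantity usually printed alongside Fisher tests in
#' epigenomic enrichment analyses, not the conditional MLE); when a zero cell
#' occurs the Haldane-Anscombe 0.5 correction is applied to OR and its
#' standard error and the result is flagged. The p-value is the two-sided
#' Fisher exact test.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @param label Optional annotation label carried through.
#' @return One-row tibble: `label`, `a`, `b`, `c`, `d`, `odds_ratio`,
#'   `log_or`, `se_log_or`, `ci_lo`, `ci_hi`, `p_value`, `zero_cell`.
#' @export
#' @examples
#' fisher_or(710, 97, 484, 323) # OR ~ 4.885
fisher_or <- function(a, b, c, d, label = NA_character_) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  zero_cell <- any(c(a, b, c, d) == 0)
  cc <- if (zero_cell) 0.5 else 0
  or <- ((a + cc) * (d + cc)) / ((b + cc) * (c + cc))
  log_or <- log(or)
  se <- sqrt(1 / (a + cc) + 1 / (b + cc) + 1 / (c + cc) + 1 / (d + cc))
  p <- fisher.test(matrix(c(a, b, c, d), nrow = 2, byrow = TRUE))$p.value
  tibble(label = label, a = a, b = b, c = c, d = d,
         odds_ratio = or, log_or = log_or, se_log_or = se,
         ci_lo = exp(log_or - 1.96 * se), ci_hi = exp(log_or + 1.96 * se),
         p_value = p, zero_cell = zero_cell)
}

#' Annotation enrichment of a foreground site set
#'
#' Tests, for every annotation label (e.g., each state of a ChromHMM 15-state
#' segmentation of one tissue), whether the proportion of foreground sites
#' falling in the annotation exceeds that of the background sites, with a
#' two-sided Fisher exact test. Membership is by interval overlap (BED
#' intervals are half-open on disk; positions are 1-based).
#'
#' @param foreground,background Site tables with `chrom` and `pos` (1-based),
#'   or `GRanges`. The background should contain the foreground (a warning is
#'   emitted otherwise); background counts are used as given.
#' @param annotation Labelled intervals: a `GRanges` with a `name` column
#'   (ChromHMM dialect), a BED4 path, or a data frame with `chrom`, `start`,
#'   `end` (0-based half-open), `name`.
#' @param adjust Add BH-adjusted q-values across labels (default TRUE; raw
#'   Fisher p-values are always reported).
#' @return Tibble with one [fisher_or()] row per label (plus `q_value`).
#' @export
fisher_enrichment <- function(foreground, background, annotation,
                              adjust = TRUE) {
  fg <- if (methods::is(foreground, "GRanges")) foreground
        else sites_as_granges(foreground)
  bg <- if (methods::is(background, "GRanges")) background
        else sites_as_granges(background)
  if (length(fg) == 0) stop("empty foreground site set")
  ann <- if (methods::is(annotation, "GRanges")) annotation
         else if (is.character(annotation)) read_bed(annotation)
         else as_interval_granges(annotation)
  labels <- if (!is.null(ann$name)) as.character(ann$name)
            else rep("annotation", length(ann))
  fg_in_bg <- suppressWarnings( # disjoint seqlevels just mean "not in bg"
    GenomicRanges::countOverlaps(fg, bg, type = "equal", maxgap = 0L))
  if (!all(fg_in_bg > 0)) {
    warning("foreground contains sites absent from the background")
  }
  res <- lapply(unique(labels), function(lab) {
    sub <- ann[labels == lab]
    a <- sum(suppressWarnings(IRanges::overlapsAny(fg, sub)))
    c_ <- sum(suppressWarnings(IRanges::overlapsAny(bg, sub)))
    fisher_or(a, length(fg) - a, c_, length(bg) - c_, label = lab)
  })
  out <- bind_rows(res)
  if (adjust) out$q_value <- p.adjust(out$p_value, "BH")
  out
}

#' Fixed-effect meta-analysis of enrichment results
#'
#' Combines per-tissue log odds ratios for one annotation label by
#' inverse-variance weighting (fixed-effect model, via
#' `metafor::rma.uni(method = "EE")`); a DerSimonian-Laird random-effects
#' model is available behind `method = "DL"`. The combined standard error of
#' the fixed-effect model never exceeds the smallest input standard error.
#'
#' @param results Tibble with `log_or` and `se_log_or` (one row per tissue),
#'   e.g. stacked [fisher_or()] rows for a single label.
#' @param method `"FE"` (fixed effect, default) or `"DL"` (random effects).
#' @return One-row tibble: `log_or`, `se_log_or`, `odds_ratio`, `ci_lo`,
#'   `ci_hi`, `p_value`, `k` (number of studies combined).
#' @export
meta_enrichment <- function(results, method = c("FE", "DL")) {
  method <- match.arg(method)
  ok <- is.finite(results$log_or) & is.finite(results$se_log_or) &
    results$se_log_or > 0
  if (!any(ok)) stop("no tissue result with a finite standard error")
  fit <- metafor::rma.uni(yi = results$log_or[ok],
                          sei = results$se_log_or[ok],
                          method = if (method == "FE") "EE" else "DL")
  tibble(log_or = as.numeric(fit$beta), se_log_or = fit$se,
         odds_ratio = exp(as.numeric(fit$beta)),
         ci_lo = exp(fit$ci.lb), ci_hi = exp(fit$ci.ub),
         p_value = fit$pval, k = sum(ok))
}

#' Direction-consistency binomial test
#'
#' Exact two-sided binomial test of whether the proportion of sites where the
#' alternative allele's effect on a chromatin feature (e.g., a histone-mark
#' signal) points in the same direction as its hydroxymethylation imbalance
#' differs from 0.5. Shares the exact-test kernel with
#' [binomial_ashm_test()].
#'
#' @param n_same Number of direction-consistent sites.
#' @param n_total Total sites tested (>= 1).
#' @return Two-sided exact binomial p-value.
#' @export
direction_consistency_test <- function(n_same, n_total) {
  stopifnot(n_total >= 1, n_same >= 0, n_same <= n_total)
  binomial_ashm_test(n_same, n_total - n_same)$p_value
}

#' Label same/opposite effect directions from feature-effect predictions
#'
#' Preprocessing for [direction_consistency_test()]: given per-site predicted
#' feature effects of the alternative allele (sign-preserving z-scores with
#' significance e-values, as produced by sequence-based chromatin models) and
#' the alternative-allele hydroxymethylation level, keeps sites with
#' `e_value < e_threshold` and labels a site `same` when the effect sign and
#' the hydroxymethylation side agree (`z > 0` with alt level above 0.5, or
#' `z < 0` with alt level below 0.5). Sites with a zero effect or an alt
#' level of exactly 0.5 carry no direction and are dropped with a message.
#'
#' @param effects Tibble with `site_id`, `z` and `e_value`.
#' @param alt_levels Tibble with `site_id` and `alt_level` (alternative-allele
#'   hydroxymethylation fraction in `[0, 1]`).
#' @param e_threshold Significance threshold on the e-value (default 0.01).
#' @return List with `n_same`, `n_total`, and the labelled per-site tibble.
#' @export
prepare_direction_counts <- function(effects, alt_levels,
                                     e_threshold = 0.01) {
  tab <- inner_join(effects, alt_levels, by = "site_id") %>%
    filter(.data$e_value < e_threshold)
  undirected <- tab$z == 0 | tab$alt_level == 0.5
  if (any(undirected)) {
    message(sum(undirected), " site(s) without a defined direction dropped")
  }
  tab <- filter(tab, !undirected)
  tab$same <- (tab$z > 0) == (tab$alt_level > 0.5)
  list(n_same = sum(tab$same), n_total = nrow(tab), table = tab)
}

#' Gene-set enrichment against a (sampled) background
#'
#' Fisher exact enrichment of a foreground gene list in each gene set, against
#' either an explicit background gene list or a seeded random sample from a
#' gene universe (emulating a background of randomly sampled SNP-associated
#' genes). Gene identifiers are harmonized by uppercasing before exact-string
#' matching. Sets with no background member after intersection are skipped
#' with a message.
#'
#' @param foreground_genes Character vector of foreground genes.
#' @param gene_sets Named list of character vectors, or a GMT file path.
#' @param background Character vector of background genes, or a sampling spec
#'   `list(universe =, n =, seed =)`.
#' @return Tibble with one [fisher_or()] row per gene set (plus `q_value`).
#' @export
geneset_enrichment <- function(foreground_genes, gene_sets, background) {
  if (is.character(gene_sets) && length(gene_sets) == 1) {
    gene_sets <- read_gmt(gene_sets)
  }
  fg <- unique(toupper(foreground_genes))
  if (is.list(background) && !is.null(background$universe)) {
    set.seed(background$seed)
    bg <- unique(toupper(sample(background$universe,
                                min(background$n,
                                    length(background$universe)))))
  } else {
    bg <- unique(toupper(background))
  }
  rows <- lapply(names(gene_sets), function(nm) {
    set <- unique(toupper(gene_sets[[nm]]))
    if (length(intersect(set, bg)) == 0) {
      message("gene set '", nm, "' has no background member; skipped")
      return(NULL)
    }
    a <- length(intersect(fg, set))
    c_ <- length(intersect(bg, set))
    fisher_or(a, length(fg) - a, c_, length(bg) - c_, label = nm)
  })
  out <- bind_rows(rows)
  if (nrow(out) > 0) out$q_value <- p.adjust(out$p_value, "BH")
  out
}

#' Read gene sets from a GMT file
#'
#' Uses `fgsea::gmtPathways()` when \pkg{fgsea} is installed, otherwise a
#' plain-text fallback (GMT: set name, description, then member genes,
#' tab-separated).
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE)) {
    return(fgsea::gmtPathways(path))
  }
  lines <- strsplit(readLines(path), "\t", fixed = TRUE)
  setNames(lapply(lines, function(x) x[-(1:2)]),
           vapply(lines, `[[`, character(1), 1))
}

#' Correlation screen between motif disruption and hydroxymethylation
#'
#' For each transcription factor with allele-specific binding scores at
#' `min_sites` or more sites, computes the Pearson correlation between the
#' absolute binding-affinity difference (`effect = |scoreRef - scoreAlt|`)
#' and the alternative-allele hydroxymethylation level, with a two-sided
#' t-based p-value. A TF is flagged significant when `|r| > r_threshold` and
#' `p < alpha`, and labelled by correlation sign.
#'
#' @param scores Tibble with `tf`, `site_id`, `effect` (see
#'   [pwm_allele_scores()]).
#' @param alt_levels Tibble with `site_id`, `alt_level`.
#' @param min_sites Minimum paired observations per TF (default 3).
#' @param r_threshold,alpha Significance rule (defaults 0.5 and 0.05).
#' @return Tibble with `tf`, `n`, `r`, `p_value`, `significant`, `sign`.
#' @export
tf_correlation_screen <- function(scores, alt_levels, min_sites = 3L,
                                  r_threshold = 0.5, alpha = 0.05) {
  tab <- inner_join(scores, alt_levels, by = "site_id")
  groups <- split(tab, tab$tf)
  rows <- bind_rows(lapply(names(groups), function(tf) {
    g <- groups[[tf]]
    if (nrow(g) < min_sites) return(NULL) # precondition: >= 3 paired sites
    constant <- sd(g$effect) == 0 || sd(g$alt_level) == 0
    if (constant) {
      message("TF '", tf, "' has a constant input vector: correlation ",
              "undefined")
      return(tibble(tf = tf, n = nrow(g), r = NA_real_, p_value = NA_real_))
    }
    ct <- cor.test(g$effect, g$alt_level)
    tibble(tf = tf, n = nrow(g), r = unname(ct$estimate),
           p_value = ct$p.value)
  }))
  if (nrow(rows) == 0) {
    return(tibble(tf = character(0), n = integer(0), r = numeric(0),
                  p_value = numeric(0), significant = logical(0),
                  sign = character(0)))
  }
  rows %>%
    mutate(significant = !is.na(.data$r) & abs(.data$r) > r_threshold &
             .data$p_value < alpha,
           sign = case_when(
             !.data$significant ~ "none",
             .data$r > 0 ~ "positive",
             TRUE ~ "negative")) %>%
    select("tf", "n", "r", "p_value", "significant", "sign")
}

#' Alternative-allele preference contrast between affected and unaffected
#'
#' Among disease-associated AShM sites, tests whether alternative alleles are
#' preferentially hydroxymethylated (mean alt fraction above 0.5) in affected
#' versus unaffected members of phenotype-discordant pairs: a 2x2 Fisher
#' contrast of (sites alt-hyper in affected) against (sites alt-hyper in
#' unaffected).
#'
#' `alt_preference_from_proportions()` builds the same contrast from printed
#' summary proportions (site count and alt-hyper percentages per group).
#'
#' @param calls Per-individual calls with `alt_fraction` ([call_ashm()]).
#' @param cohort A [twin_cohort()].
#' @param sites Character vector of site ids to contrast (e.g., BF > 1
#'   sites).
#' @return A [fisher_or()] row.
#' @export
alt_preference_contrast <- function(calls, cohort, sites) {
  stopifnot(inherits(cohort, "twin_cohort"))
  inds <- cohort_individuals(cohort)
  tab <- calls %>%
    filter(.data$site_id %in% sites) %>%
    inner_join(select(inds, "individual_id", "pair_class", "affected"),
               by = "individual_id") %>%
    filter(.data$pair_class == "PDC") %>%
    group_by(.data$site_id, .data$affected) %>%
    summarise(alt_hyper = mean(.data$alt_fraction) > 0.5, .groups = "drop")
  aff <- filter(tab, .data$affected)
  un <- filter(tab, !.data$affected)
  fisher_or(sum(aff$alt_hyper), sum(!aff$alt_hyper),
            sum(un$alt_hyper), sum(!un$alt_hyper),
            label = "alt_preference_affected_vs_unaffected")
}

#' @rdname alt_preference_contrast
#' @param n_sites Number of sites in each group.
#' @param prop_affected,prop_unaffected Proportion of sites alt-hyper in
#'   affected / unaffected individuals.
#' @export
alt_preference_from_proportions <- function(n_sites, prop_affected,
                                            prop_unaffected) {
  a <- round(n_sites * prop_affected)
  c_ <- round(n_sites * prop_unaffected)
  fisher_or(a, n_sites - a, c_, n_sites - c_,
            label = "alt_preference_affected_vs_unaffected")
}
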