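#' Monozygotic twin cohort
#'
#' A `twin_cohort` describes the individuals of a monozygotic (MZ) twin study:
#' each individual belongs to exactly one pair, and each pair is classified by
#' the disease status of its two members as
#' * `PDC` — phenotype-discordant (exactly one affected cotwin),
#' * `PCC` — disease-concordant (both affected),
#' * `HCC` — healthy-concordant (neither affected).
#'
#' @param individuals A data frame with columns `individual_id` (character),
#'   `pair_id` (character) and `affected` (logical).
#'
#' @return A `twin_cohort` object: a list with elements `individuals`
#'   (tibble, one row per individual) and `pairs` (tibble with `pair_id`,
#'   `pair_class`).
#' @export
#' @examples
#' twin_cohort(data.frame(
#'   individual_id = c("a1", "a2"), pair_id = "p1",
#'   affected = c(TRUE, FALSE)
#' ))
twin_cohort <- function(individuals) {
  individuals <- as_tibble(individuals)
  req <- c("individual_id", "pair_id", "affected")
  missing_cols <- setdiff(req, names(individuals))
  if (length(missing_cols) > 0) {
    stop("cohort table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  individuals <- individuals %>%
    mutate(
      individual_id = as.character(.data$individual_id),
      pair_id = as.character(.data$pair_id),
      affected = as.logical(.data$affected)
    )
  if (anyNA(individuals$affected)) stop("affected status must be TRUE/FALSE")
  if (anyDuplicated(individuals$individual_id)) {
    stop("duplicated individual_id in cohort")
  }
  pairs <- individuals %>%
    group_by(.data$pair_id) %>%
    summarise(n_members = n(), n_affected = sum(.data$affected)) %>%
    ungroup()
  if (any(pairs$n_members != 2L)) {
    bad <- pairs$pair_id[pairs$n_members != 2L]
    stop("every twin pair must have exactly 2 members; offending pair(s): ",
         paste(bad, collapse = ", "))
  }
  pairs <- pairs %>%
    mutate(pair_class = c("HCC", "PDC", "PCC")[.data$n_affected + 1L]) %>%
    select("pair_id", "pair_class")
  structure(list(individuals = individuals, pairs = pairs),
            class = "twin_cohort")
}

#' @export
print.twin_cohort <- function(x, ...) {
  tab <- table(x$pairs$pair_class)
  cat("<twin_cohort> ", nrow(x$individuals), " individuals in ",
      nrow(x$pairs), " MZ pairs (",
      paste(names(tab), tab, sep = "=", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Build a twin cohort from a study design
#'
#' Convenience constructor used by the simulator: creates `n_pdc + n_pcc +
#' n_hcc` MZ pairs with systematic identifiers. In PDC pairs the first cotwin
#' is the affected one.
#'
#' @param n_pdc,n_pcc,n_hcc Number of phenotype-discordant, disease-concordant
#'   and healthy-concordant pairs.
#' @return A [twin_cohort()].
#' @export
cohort_from_design <- function(n_pdc = 6, n_pcc = 4, n_hcc = 4) {
  mk <- function(class, n, offset) {
    if (n == 0) return(NULL)
    pair_id <- sprintf("%s%02d", tolower(class), seq_len(n))
    tibble(
      individual_id = as.vector(rbind(paste0(pair_id, "_1"),
                                      paste0(pair_id, "_2"))),
      pair_id = rep(pair_id, each = 2),
      affected = rep(switch(class,
        PDC = c(TRUE, FALSE), PCC = c(TRUE, TRUE), HCC = c(FALSE, FALSE)
      ), n)
    )
  }
  twin_cohort(bind_rows(mk("PDC", n_pdc), mk("PCC", n_pcc), mk("HCC", n_hcc)))
}

# long view: one row per individual with pair class attached
cohort_individuals <- function(cohort) {
  stopifnot(inherits(cohort, "twin_cohort"))
  left_join(cohort$individuals, cohort$pairs, by = "pair_id")
}

#' Read / write a cohort metadata table
#'
#' Plain TSV with columns `individual_id`, `pair_id`, `affected` (0/1).
#'
#' @param path File path.
#' @param cohort A [twin_cohort()].
#' @return `read_cohort_tsv()` returns a [twin_cohort()];
#'   `write_cohort_tsv()` returns `path` invisibly.
#' @export
read_cohort_tsv <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           individual_id = readr::col_character(),
                           pair_id = readr::col_character(),
                           affected = readr::col_integer()
                         ))
  twin_cohort(mutate(tab, affected = .data$affected == 1L))
}

#' @rdname read_cohort_tsv
#' @export
write_cohort_tsv <- function(cohort, path) {
  stopifnot(inherits(cohort, "twin_cohort"))
  tab <- mutate(cohort$individuals, affected = as.integer(.data$affected))
  readr::write_tsv(tab, path)
  invisible(path)
}
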