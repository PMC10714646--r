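#' Read an allele-specific count table
#'
#' The count TSV is the central exchange format: one row per
#' (site, individual) with columns `site_id`, `chrom`, `pos` (1-based, as in
#' VCF), `ref`, `alt` (single bases), `individual_id`, `ref_reads`,
#' `alt_reads`. Counts are assumed to be already base/mapping-quality filtered
#' by the upstream counting tool.
#'
#' @param path TSV file path.
#' @return A tibble of allele count records.
#' @export
read_count_tsv <- function(path) {
  if (!file.exists(path)) stop("count TSV not found: ", path)
  readr::read_tsv(path, show_col_types = FALSE, col_types = readr::cols(
    site_id = readr::col_character(),
    chrom = readr::col_character(),
    pos = readr::col_integer(),
    ref = readr::col_character(),
    alt = readr::col_character(),
    individual_id = readr::col_character(),
    ref_reads = readr::col_integer(),
    alt_reads = readr::col_integer()
  ))
}

#' Validate allele count records
#'
#' Checks the count-table contract: required columns, single-base distinct
#' alleles, non-negative integer read counts, and (when a cohort is given)
#' individual identifiers known to the cohort. Violations raise one error
#' listing the offending row numbers per problem.
#'
#' @param records Data frame of allele count records.
#' @param cohort Optional [twin_cohort()] to validate individual ids against.
#' @return The validated records as a tibble (invisible errors otherwise).
#' @export
validate_count_records <- function(records, cohort = NULL) {
  req <- c("site_id", "chrom", "pos", "ref", "alt", "individual_id",
           "ref_reads", "alt_reads")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols) > 0) {
    stop("count table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(records) == 0) return(as_tibble(records))
  bad <- list()
  snp_ok <- records$ref %in% c("A", "C", "G", "T") &
    records$alt %in% c("A", "C", "G", "T") & records$ref != records$alt
  if (!all(snp_ok)) bad$`non-SNP or identical alleles` <- which(!snp_ok)
  cnt_ok <- !is.na(records$ref_reads) & !is.na(records$alt_reads) &
    records$ref_reads >= 0 & records$alt_reads >= 0
  if (!all(cnt_ok)) bad$`negative or missing read counts` <- which(!cnt_ok)
  if (!is.null(cohort)) {
    known <- records$individual_id %in% cohort$individuals$individual_id
    if (!all(known)) bad$`unknown individual_id` <- which(!known)
  }
  if (length(bad) > 0) {
    msg <- vapply(names(bad), function(nm) {
      rows <- bad[[nm]]
      shown <- paste(head(rows, 10), collapse = ", ")
      if (length(rows) > 10) shown <- paste0(shown, ", ...")
      paste0(nm, " at row(s): ", shown)
    }, character(1))
    stop("invalid count records:\n  ", paste(msg, collapse = "\n  "))
  }
  as_tibble(records)
}

#' Read per-individual genotypes from a VCF
#'
#' Parses a VCF v4.2 through \pkg{vcfR} and returns a long genotype table
#' (`site_id`, `chrom`, `pos`, `ref`, `alt`, `individual_id`, `gt`). The VCF
#' `ID` column is used as `site_id` when present, otherwise `chrom:pos` is
#' synthesized. Multi-allelic records are excluded (biallelic SNPs only) with
#' a message.
#'
#' @param path VCF file path.
#' @return Long genotype tibble.
#' @export
read_genotypes_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    message("excluding ", sum(multi), " multi-allelic VCF record(s)")
  }
  site_id <- ifelse(is.na(fix$ID) | fix$ID == ".",
                    paste0(fix$CHROM, ":", fix$POS), fix$ID)
  keep <- !multi
  tab <- tibble(
    site_id = site_id[keep],
    chrom = fix$CHROM[keep],
    pos = as.integer(fix$POS[keep]),
    ref = fix$REF[keep],
    alt = fix$ALT[keep]
  )
  gtk <- gt[keep, , drop = FALSE]
  long <- tibble(
    site_id = rep(tab$site_id, times = ncol(gtk)),
    chrom = rep(tab$chrom, times = ncol(gtk)),
    pos = rep(tab$pos, times = ncol(gtk)),
    ref = rep(tab$ref, times = ncol(gtk)),
    alt = rep(tab$alt, times = ncol(gtk)),
    individual_id = rep(colnames(gtk), each = nrow(gtk)),
    gt = as.vector(gtk)
  )
  long
}

is_het_gt <- function(gt) {
  !is.na(gt) & gsub("|", "/", gt, fixed = TRUE) %in% c("0/1", "1/0")
}

#' Load and validate allele counts joined to genotypes
#'
#' Reads the count TSV and genotype VCF, validates records (single-base
#' alleles, non-negative counts, individuals known to the cohort; offending
#' row numbers are reported), and joins each count record to the matching
#' individual genotype (`gt` column, `NA` when the site or individual is
#' absent from the VCF).
#'
#' @param tsv_path Count TSV path (schema of [read_count_tsv()]).
#' @param vcf_path Genotype VCF path.
#' @param cohort A [twin_cohort()].
#' @param validate Run [validate_count_records()] (default TRUE); pipelines
#'   that validate as an explicit stage can defer it.
#' @return Validated count tibble with a `gt` column.
#' @export
load_counts <- function(tsv_path, vcf_path, cohort, validate = TRUE) {
  stopifnot(inherits(cohort, "twin_cohort"))
  records <- read_count_tsv(tsv_path)
  if (validate) records <- validate_count_records(records, cohort)
  genotypes <- read_genotypes_vcf(vcf_path)
  left_join(records,
            select(genotypes, "site_id", "individual_id", "gt"),
            by = c("site_id", "individual_id"))
}

#' Read a two-column chromosome sizes file
#'
#' @param path Tab-separated file: chromosome name, length.
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  tab <- read.delim(path, header = FALSE, col.names = c("chrom", "size"),
                    colClasses = c("character", "integer"))
  setNames(tab$size, tab$chrom)
}

#' Read BED intervals as GRanges
#'
#' Thin wrapper over `rtracklayer::import(format = "BED")`; BED is 0-based
#' half-open on disk, the returned `GRanges` follows Bioconductor's 1-based
#' closed convention.
#'
#' @param path BED3/BED4+ file path.
#' @return A `GRanges`; the BED name column (if any) is kept as `name`.
#' @export
read_bed <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("reading BED files requires the rtracklayer package")
  }
  rtracklayer::import(path, format = "BED")
}

# accepts a GRanges, a BED path, or a tibble with chrom/start/end
# (0-based half-open) and returns a GRanges
as_interval_granges <- function(x) {
  if (methods::is(x, "GRanges")) return(x)
  if (is.character(x) && length(x) == 1) return(read_bed(x))
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  gr <- GenomicRanges::GRanges(
    x$chrom, IRanges::IRanges(start = x$start + 1L, end = x$end))
  if ("name" %in% names(x)) gr$name <- x$name
  gr
}

# site table (chrom, pos 1-based) -> width-1 GRanges
sites_as_granges <- function(sites) {
  stopifnot(all(c("chrom", "pos") %in% names(sites)))
  GenomicRanges::GRanges(sites$chrom,
                         IRanges::IRanges(start = sites$pos, width = 1L))
}
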