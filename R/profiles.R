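#' Binned hydroxymethylation profile
#'
#' Tiles each chromosome with overlapping bins (default 500 bp wide, stepped
#' every 250 bp, 0-based half-open) and counts the reads overlapping each bin;
#' a read overlapping two bins contributes to both. The relative
#' hydroxymethylation score (`rhms`) is the bin count scaled to counts per
#' million total reads, so only relative comparisons on a shared bin grid are
#' meaningful.
#'
#' @param reads Read intervals: a `GRanges`, a BED3 path, or a data frame
#'   with `chrom`, `start`, `end` (0-based half-open).
#' @param genome_sizes Named vector of chromosome lengths, or the path of a
#'   two-column chrom-sizes file.
#' @param bin_width,step Bin width and step in bp.
#' @return Tibble with `chrom`, `start`, `end` (0-based half-open bin
#'   coordinates), `count` and `rhms`.
#' @export
#' @examples
#' reads <- tibble::tibble(chrom = "chr1", start = 600, end = 650)
#' binned_profile(reads, c(chr1 = 2000))
binned_profile <- function(reads, genome_sizes, bin_width = 500, step = 250) {
  if (is.character(genome_sizes) && length(genome_sizes) == 1) {
    genome_sizes <- read_chrom_sizes(genome_sizes)
  }
  stopifnot(!is.null(names(genome_sizes)), all(genome_sizes > 0))
  gr <- as_interval_granges(reads)

  unknown <- setdiff(unique(as.character(GenomicRanges::seqnames(gr))),
                     names(genome_sizes))
  if (length(unknown) > 0) {
    stop("read intervals on chromosome(s) absent from genome_sizes: ",
         paste(unknown, collapse = ", "))
  }
  # clip intervals that run past the chromosome end
  lens <- genome_sizes[as.character(GenomicRanges::seqnames(gr))]
  if (length(gr) > 0 && any(GenomicRanges::end(gr) > lens)) {
    warning(sum(GenomicRanges::end(gr) > lens),
            " interval(s) extend beyond the chromosome length; clipped")
    GenomicRanges::end(gr) <- pmin(GenomicRanges::end(gr), lens)
  }

  bins_per_chrom <- lapply(names(genome_sizes), function(chr) {
    len <- genome_sizes[[chr]]
    starts <- seq(0L, max(0L, len - 1L), by = step)
    tibble(chrom = chr, start = starts,
           end = pmin(starts + bin_width, len))
  })
  bins <- bind_rows(bins_per_chrom)
  bin_gr <- GenomicRanges::GRanges(
    bins$chrom, IRanges::IRanges(start = bins$start + 1L, end = bins$end))
  bins$count <- GenomicRanges::countOverlaps(bin_gr, gr)
  total <- length(gr)
  bins$rhms <- if (total > 0) bins$count * 1e6 / total else 0
  bins
}

#' Within-pair correlation of binned profiles
#'
#' Pearson correlation of `rhms` vectors on an identical bin grid; used to
#' quantify how similar the genome-wide hydroxymethylation landscapes of two
#' samples (typically MZ cotwins) are.
#'
#' @param profile_a,profile_b [binned_profile()] outputs on the same grid.
#' @return Pearson r, or `NA` when either profile is constant (correlation
#'   undefined).
#' @export
within_pair_correlation <- function(profile_a, profile_b) {
  same_grid <- nrow(profile_a) == nrow(profile_b) &&
    identical(profile_a$chrom, profile_b$chrom) &&
    identical(profile_a$start, profile_b$start)
  if (!same_grid) stop("profiles are not on the same bin grid")
  if (sd(profile_a$rhms) == 0 || sd(profile_b$rhms) == 0) {
    message("constant profile: within-pair correlation undefined")
    return(NA_real_)
  }
  cor(profile_a$rhms, profile_b$rhms)
}
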