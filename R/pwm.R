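#' Position weight matrix with min-max score scaling
#'
#' Container for an additive position weight matrix (PWM). A length-L
#' sequence is scored by summing the per-position weights of its bases; the
#' score is then scaled as a fraction of the motif's scoring range
#' (`(S - min) / (max - min)`, in `[0, 1]`), where `min`/`max` are the sums
#' of per-position minima/maxima — exactly computable for any additive
#' matrix. The consensus sequence always scores 1.
#'
#' @param mat Numeric matrix, 4 rows named `A`, `C`, `G`, `T`, one column per
#'   motif position.
#' @param id Motif identifier.
#' @return A `pwm` object.
#' @export
pwm_matrix <- function(mat, id = "motif") {
  stopifnot(is.matrix(mat), nrow(mat) == 4, ncol(mat) >= 1)
  if (is.null(rownames(mat))) rownames(mat) <- c("A", "C", "G", "T")
  stopifnot(setequal(rownames(mat), c("A", "C", "G", "T")))
  mat <- mat[c("A", "C", "G", "T"), , drop = FALSE]
  structure(list(id = id, mat = mat,
                 min_score = sum(apply(mat, 2, min)),
                 max_score = sum(apply(mat, 2, max))),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("<pwm> ", x$id, ": ", ncol(x$mat), " positions, score range [",
      signif(x$min_score, 4), ", ", signif(x$max_score, 4), "]\n", sep = "")
  invisible(x)
}

#' Motif length of a PWM
#' @param pwm A [pwm_matrix()] object.
#' @return Integer motif length.
#' @export
pwm_length <- function(pwm) ncol(pwm$mat)

#' Reverse-complement a PWM
#'
#' Reverses the position order and swaps complementary base rows, so scoring
#' a sequence with `pwm` equals scoring its reverse complement with
#' `rc_pwm(pwm)`.
#'
#' @param pwm A [pwm_matrix()] object.
#' @return The reverse-complement `pwm`.
#' @export
rc_pwm <- function(pwm) {
  mat <- pwm$mat[c("T", "G", "C", "A"), rev(seq_len(ncol(pwm$mat))),
                 drop = FALSE]
  rownames(mat) <- c("A", "C", "G", "T")
  pwm_matrix(mat, id = paste0(pwm$id, "_rc"))
}

reverse_complement <- function(seq) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "")[[1]]), collapse = "")
}

#' Scaled additive PWM score of one motif-length sequence
#'
#' Sums the per-position weights of the bases and scales the result as a
#' fraction of the motif's scoring range (`(S - min) / (max - min)`).
#' Returns `NA` when the window contains an ambiguous base; constant
#' matrices score 1 (every sequence attains the maximum).
#'
#' @param pwm A [pwm_matrix()] object.
#' @param seq Character scalar of length `pwm_length(pwm)` (A/C/G/T).
#' @return Scaled score in `[0, 1]`, or `NA`.
#' @export
pwm_score_scaled <- function(pwm, seq) {
  bases <- strsplit(seq, "")[[1]]
  stopifnot(length(bases) == pwm_length(pwm))
  if (!all(bases %in% c("A", "C", "G", "T"))) return(NA_real_)
  s <- sum(pwm$mat[cbind(match(bases, rownames(pwm$mat)),
                         seq_along(bases))])
  rng <- pwm$max_score - pwm$min_score
  if (rng == 0) return(1)
  (s - pwm$min_score) / rng
}

#' Allele-specific motif scores at a SNP
#'
#' Scores every motif window overlapping the SNP, on both strands, for the
#' reference and the alternative allele, and aggregates (max by default, the
#' motif-scan convention). Scores are min-max scaled to `[0, 1]`; the
#' reported `effect = |scoreRef - scoreAlt|` measures predicted allele-specific
#' binding disruption. Windows containing ambiguous bases are skipped; if all
#' windows are skipped the score is undefined (`NA`).
#'
#' @param pwm A [pwm_matrix()] object.
#' @param context Sequence context around the SNP (uppercase A/C/G/T/N).
#' @param snp_offset 1-based position of the SNP within `context`.
#' @param ref,alt Single-base alleles.
#' @param both_strands Score the minus strand as well (default TRUE).
#' @param aggregate `"max"` (default) or `"mean"` over windows/strands.
#' @return One-row tibble with `motif`, `score_ref`, `score_alt`, `effect`,
#'   `n_windows`.
#' @export
#' @examples
#' m <- pwm_matrix(matrix(c(2, 0, 0, 0, 0, 2, 0, 0), nrow = 4,
#'                 dimnames = list(c("A", "C", "G", "T"), NULL)))
#' pwm_allele_scores(m, "TTACTT", 3, "A", "G")
pwm_allele_scores <- function(pwm, context, snp_offset, ref, alt,
                              both_strands = TRUE, aggregate = c("max",
                                                                 "mean")) {
  aggregate <- match.arg(aggregate)
  L <- pwm_length(pwm)
  context <- toupper(context)
  n <- nchar(context)
  stopifnot(snp_offset >= 1, snp_offset <= n,
            nchar(ref) == 1, nchar(alt) == 1)
  if (n < L) stop("sequence context shorter than the motif")
  starts <- max(1, snp_offset - L + 1):min(snp_offset, n - L + 1)
  score_allele <- function(allele) {
    seq_allele <- paste0(substr(context, 1, snp_offset - 1), allele,
                         substr(context, snp_offset + 1, n))
    scores <- unlist(lapply(starts, function(s) {
      win <- substr(seq_allele, s, s + L - 1)
      out <- pwm_score_scaled(pwm, win)
      if (both_strands) out <- c(out, pwm_score_scaled(pwm,
                                                       reverse_complement(win)))
      out
    }))
    scores[!is.na(scores)]
  }
  sr <- score_allele(ref)
  sa <- score_allele(alt)
  if (length(sr) == 0 || length(sa) == 0) {
    message("all motif windows skipped (ambiguous bases): score undefined")
    return(tibble(motif = pwm$id, score_ref = NA_real_, score_alt = NA_real_,
                  effect = NA_real_, n_windows = 0L))
  }
  agg <- if (aggregate == "max") max else mean
  score_ref <- agg(sr)
  score_alt <- agg(sa)
  tibble(motif = pwm$id, score_ref = score_ref, score_alt = score_alt,
         effect = abs(score_ref - score_alt), n_windows = length(sr))
}

#' Read JASPAR-format position frequency matrices
#'
#' Parses the JASPAR plain-text PFM dialect (`>ID name` header followed by
#' four rows `A [ 3 5 ... ]`, or four bare count rows) and converts counts to
#' additive log2 odds weights against a uniform background with a
#' pseudocount.
#'
#' @param path JASPAR pfm file (may contain several motifs).
#' @param pseudocount Added to each count before normalization (default 1).
#' @param background Background base probability (default 0.25, uniform).
#' @return Named list of [pwm_matrix()] objects.
#' @export
read_jaspar_pfm <- function(path, pseudocount = 1, background = 0.25) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  headers <- grep("^>", lines)
  if (length(headers) == 0) headers <- 1L # headerless single motif
  motifs <- list()
  for (i in seq_along(headers)) {
    from <- headers[i]
    to <- if (i < length(headers)) headers[i + 1] - 1 else length(lines)
    block <- lines[from:to]
    has_header <- grepl("^>", block[1])
    id <- if (has_header) {
      strsplit(sub("^>\\s*", "", block[1]), "\\s+")[[1]][1]
    } else sprintf("motif%d", i)
    rows <- block[if (has_header) -1 else TRUE]
    if (length(rows) != 4) stop("expected 4 matrix rows for motif ", id)
    parse_row <- function(row) {
      row <- gsub("^[ACGT]\\s*", "", trimws(row))
      row <- gsub("[\\[\\]]", "", row, perl = TRUE)
      as.numeric(strsplit(trimws(row), "\\s+")[[1]])
    }
    counts <- do.call(rbind, lapply(rows, parse_row))
    base_order <- if (all(grepl("^[ACGT]", trimws(rows)))) {
      substr(trimws(rows), 1, 1)
    } else c("A", "C", "G", "T")
    rownames(counts) <- base_order
    counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
    freq <- sweep(counts + pseudocount, 2,
                  colSums(counts + pseudocount), "/")
    motifs[[id]] <- pwm_matrix(log2(freq / background), id = id)
  }
  motifs
}

#' Read MEME minimal-format motifs
#'
#' Parses MEME minimal motif files (`MOTIF name` blocks with a
#' `letter-probability matrix:` section, alphabet ACGT) and converts the
#' probabilities to additive log2 odds weights against the uniform
#' background, with a small regularizing pseudo-probability.
#'
#' @param path MEME minimal-format file.
#' @param background Background base probability (default 0.25).
#' @param eps Pseudo-probability added before taking logs (default 1e-3).
#' @return Named list of [pwm_matrix()] objects.
#' @export
read_meme <- function(path, background = 0.25, eps = 1e-3) {
  lines <- readLines(path)
  starts <- grep("^MOTIF\\b", lines)
  if (length(starts) == 0) stop("no MOTIF block found in ", path)
  motifs <- list()
  for (i in seq_along(starts)) {
    id <- strsplit(trimws(lines[starts[i]]), "\\s+")[[1]][2]
    j <- starts[i]
    while (j <= length(lines) &&
           !grepl("^letter-probability matrix", lines[j])) j <- j + 1
    if (j > length(lines)) stop("motif ", id, " lacks a probability matrix")
    w <- sub(".*w=\\s*(\\d+).*", "\\1", lines[j])
    L <- as.integer(w)
    rows <- lines[(j + 1):(j + L)]
    probs <- t(vapply(rows, function(r) {
      as.numeric(strsplit(trimws(r), "\\s+")[[1]][1:4])
    }, numeric(4), USE.NAMES = FALSE))
    mat <- t(probs) # 4 x L, rows A C G T (MEME column order)
    rownames(mat) <- c("A", "C", "G", "T")
    motifs[[id]] <- pwm_matrix(log2((mat + eps) / (background + eps)),
                               id = id)
  }
  motifs
}
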