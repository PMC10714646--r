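# 4-position toy motif with a clear consensus (ACGT)
toy_pwm <- function() {
  m <- matrix(c(
    2, -1, -1, -1,   # A
    -1, 2, -1, -1,   # C
    -1, -1, 2, -1,   # G
    -1, -1, -1, 2    # T
  ), nrow = 4, byrow = TRUE,
  dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm_matrix(m, id = "toy")
}

# brute-force scorer: enumerate all windows covering the SNP on both strands
brute_allele_score <- function(pwm, context, offset, allele) {
  seqs <- strsplit(context, "")[[1]]
  seqs[offset] <- allele
  context <- paste(seqs, collapse = "")
  L <- ncol(pwm$mat)
  rc <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }
  score1 <- function(win) {
    b <- strsplit(win, "")[[1]]
    if (!all(b %in% c("A", "C", "G", "T"))) return(NA_real_)
    s <- 0
    for (i in seq_len(L)) s <- s + pwm$mat[b[i], i]
    (s - pwm$min_score) / (pwm$max_score - pwm$min_score)
  }
  best <- -Inf
  for (start in 1:(nchar(context) - L + 1)) {
    if (start > offset || start + L - 1 < offset) next
    win <- substr(context, start, start + L - 1)
    for (s in c(score1(win), score1(rc(win)))) {
      if (!is.na(s)) best <- max(best, s)
    }
  }
  best
}

test_that("allele scores equal brute-force enumeration on a toy motif", {
  pwm <- toy_pwm()
  context <- "TTACGTAGC"
  for (offset in 3:6) {
    ref <- substr(context, offset, offset)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    got <- pwm_allele_scores(pwm, context, offset, ref, alt)
    expect_equal(got$score_ref, brute_allele_score(pwm, context, offset, ref),
                 tolerance = 1e-12)
    expect_equal(got$score_alt, brute_allele_score(pwm, context, offset, alt),
                 tolerance = 1e-12)
    expect_equal(got$effect, abs(got$score_ref - got$score_alt))
  }
})

test_that("identical alleles and degenerate matrices give zero effect", {
  pwm <- toy_pwm()
  same <- pwm_allele_scores(pwm, "TTACGTAGC", 4, "C", "C")
  expect_equal(same$effect, 0)
  flat <- pwm_matrix(matrix(1, 4, 3,
                            dimnames = list(c("A", "C", "G", "T"), NULL)))
  r <- pwm_allele_scores(flat, "AACGTAA", 4, "G", "T")
  expect_equal(r$score_ref, r$score_alt)
  expect_equal(r$effect, 0)
})

test_that("scaled scores stay in [0,1] and the consensus scores exactly 1", {
  set.seed(8)
  for (i in 1:10) {
    L <- sample(3:8, 1)
    m <- matrix(rnorm(4 * L), 4, L,
                dimnames = list(c("A", "C", "G", "T"), NULL))
    pwm <- pwm_matrix(m, id = "rand")
    consensus <- paste(rownames(m)[apply(m, 2, which.max)], collapse = "")
    expect_equal(pwm_score_scaled(pwm, consensus), 1)
    win <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                 collapse = "")
    s <- pwm_score_scaled(pwm, win)
    expect_gte(s, 0)
    expect_lte(s, 1)
  }
})

test_that("reverse-complement symmetry holds", {
  set.seed(9)
  for (i in 1:5) {
    L <- sample(4:7, 1)
    m <- matrix(rnorm(4 * L), 4, L,
                dimnames = list(c("A", "C", "G", "T"), NULL))
    pwm <- pwm_matrix(m)
    win <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                 collapse = "")
    rc_win <- paste(rev(strsplit(chartr("ACGT", "TGCA", win), "")[[1]]),
                    collapse = "")
    expect_equal(pwm_score_scaled(pwm, win),
                 pwm_score_scaled(rc_pwm(pwm), rc_win), tolerance = 1e-12)
  }
})

test_that("ambiguous bases skip windows and can void the score", {
  pwm <- toy_pwm()
  # every window that includes the SNP also includes an N: undefined
  expect_message(
    r <- pwm_allele_scores(pwm, "NNNNANNNN", 5, "A", "C"),
    "undefined")
  expect_true(is.na(r$effect))
  expect_equal(r$n_windows, 0L)
  # clean flank on one side: the surviving windows still score
  r2 <- pwm_allele_scores(pwm, "NNACGTAGC", 5, "G", "T")
  expect_false(is.na(r2$effect))
  expect_gt(r2$n_windows, 0L)
})

test_that("JASPAR pfm files parse into scoring-ready motifs", {
  path <- withr::local_tempfile(fileext = ".pfm")
  writeLines(c(
    ">MA0001 TESTTF",
    "A [ 10  0  0 ]",
    "C [  0 10  0 ]",
    "G [  0  0 10 ]",
    "T [  0  0  0 ]"
  ), path)
  motifs <- read_jaspar_pfm(path)
  expect_equal(names(motifs), "MA0001")
  pwm <- motifs[["MA0001"]]
  expect_equal(ncol(pwm$mat), 3)
  # consensus ACG scores 1 after min-max scaling
  expect_equal(pwm_score_scaled(pwm, "ACG"), 1)
  expect_lt(pwm_score_scaled(pwm, "TTT"), 0.05)
})

test_that("MEME minimal files parse into scoring-ready motifs", {
  path <- withr::local_tempfile(fileext = ".meme")
  writeLines(c(
    "MEME version 4", "", "ALPHABET= ACGT", "",
    "MOTIF TF_X", "",
    "letter-probability matrix: alength= 4 w= 3 nsites= 20 E= 0",
    " 0.970 0.010 0.010 0.010",
    " 0.010 0.970 0.010 0.010",
    " 0.010 0.010 0.010 0.970"
  ), path)
  motifs <- read_meme(path)
  expect_equal(names(motifs), "TF_X")
  expect_equal(ncol(motifs$TF_X$mat), 3)
  expect_equal(pwm_score_scaled(motifs$TF_X, "ACT"), 1)
})
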