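test_that("PWM construction validates input and bounds scores", {
  pwm <- toy_pwm()
  expect_equal(pwm$length, 4)
  expect_equal(pwm$max_score, sum(apply(pwm$mat, 2, max)))
  expect_error(pwm_model(matrix(0.25, 3, 4)), "4 rows")
  bad <- matrix(0.25, 4, 4); bad[1, 1] <- 0.9
  expect_error(pwm_model(bad), "sum to 1")
})

test_that("MEME minimal format round-trips a frequency matrix", {
  meme <- c("MEME version 4", "", "ALPHABET= ACGT", "",
            "strands: + -", "",
            "Background letter frequencies",
            "A 0.25 C 0.25 G 0.25 T 0.25", "",
            "MOTIF toy1", "letter-probability matrix: alength= 4 w= 3",
            " 0.970000 0.010000 0.010000 0.010000",
            " 0.010000 0.970000 0.010000 0.010000",
            " 0.010000 0.010000 0.970000 0.010000",
            "", "MOTIF toy2", "letter-probability matrix: alength= 4 w= 2",
            " 0.250000 0.250000 0.250000 0.250000",
            " 0.100000 0.200000 0.300000 0.400000")
  f <- tempfile(fileext = ".meme")
  writeLines(meme, f)
  pwms <- read_meme(f)
  expect_setequal(names(pwms), c("toy1", "toy2"))
  expect_equal(pwms$toy1$length, 3)
  expect_equal(unname(pwms$toy1$pfm[, 1]), c(0.97, 0.01, 0.01, 0.01))
  expect_equal(unname(pwms$toy2$pfm["T", 2]), 0.4)
})

test_that("best-match scanning honors strand symmetry and tie-breaks", {
  # a non-palindromic consensus AACG so the strands are distinguishable
  pwm <- toy_pwm(consensus = c("A", "A", "C", "G"))
  hit <- scan_best_match("TTAACGTT", pwm)
  expect_equal(hit$score, pwm$max_score)
  expect_equal(hit$position, 3)
  expect_equal(hit$strand, "+")
  # a window carrying only the reverse complement CGTT matches on the
  # minus strand with the identical score
  rc_hit <- scan_best_match("TTCGTTTT", pwm)
  expect_equal(rc_hit$score, pwm$max_score)
  expect_equal(rc_hit$strand, "-")
  expect_equal(rc_hit$position, 3)
  # ambiguous bases are skipped
  expect_true(is.finite(scan_best_match("NNACGTNN", pwm)$score))
  expect_error(scan_best_match("AC", pwm), "shorter")
})

test_that("scanning matches an exhaustive offset/strand oracle on an 8-mer", {
  set.seed(51)
  pfm <- matrix(stats::rexp(12), 4, 3)
  pfm <- sweep(pfm, 2, colSums(pfm), "/")
  pwm <- pwm_model(pfm, id = "rand")
  s <- "ACGTGCAT"
  got <- scan_best_match(s, pwm)
  # oracle: enumerate every substring on both strands
  best <- -Inf
  for (i in 1:(nchar(s) - 2)) {
    for (str in c("+", "-")) {
      sub <- substr(s, i, i + 2)
      if (str == "-") sub <- revcomp(sub)
      b <- match(strsplit(sub, "")[[1]], c("A", "C", "G", "T"))
      sc <- sum(pwm$mat[cbind(b, 1:3)])
      best <- max(best, sc)
    }
  }
  expect_equal(got$score, best)
})

test_that("allele deltas are computed at the stronger allele's placement", {
  # a 12-column consensus motif clears the 13-bit strong-match bar
  # (with the 0.8 pseudocount each consensus column is worth ~1.4 bits)
  cons <- c("A", "A", "C", "C", "G", "G", "T", "T", "A", "A", "C", "C")
  pwm <- toy_pwm(p = 0.999, L = 12, consensus = cons)
  expect_gt(pwm$max_score, 13)
  # ref window breaks the consensus at column 5 (G -> T); alt restores it
  ref_win <- paste0("TT", "AACCTGTTAACC", "TT")
  out <- allele_delta_pwm(ref_win, "G", 7, list(pwm), high_allele = "alt",
                          strong_threshold = 13)
  expect_equal(nrow(out), 1)
  # delta equals the log-odds gain of the substituted column
  gain <- unname(pwm$mat["G", 5] - pwm$mat["T", 5])
  expect_equal(out$delta, gain)
  expect_gt(out$score_high, 13)

  # antisymmetry in the allele labels
  out2 <- allele_delta_pwm(ref_win, "G", 7, list(pwm), high_allele = "ref",
                           strong_threshold = 13)
  expect_equal(out2$delta, -out$delta)

  # identical alleles give an empty delta list
  expect_equal(nrow(allele_delta_pwm(ref_win, "T", 7, list(pwm))), 0)

  # a variant outside every strong-match placement leaves delta 0
  far_win <- paste0("AACCGGTTAACC", "TTTT")
  far <- allele_delta_pwm(far_win, "A", 15, list(pwm),
                          high_allele = "alt", strong_threshold = 13)
  expect_equal(far$delta, 0)

  # an oversized insertion is skipped with a flag
  ins <- allele_delta_pwm("ACGT", paste(rep("A", 10), collapse = ""), 2,
                          list(pwm))
  expect_true(all(ins$skipped))
})

test_that("Inr likelihood delta follows the natural-exponent definition", {
  # two-position PWM whose natural-log score is 0 for the low allele
  # and ln 6 for the high allele: delta = 6 - 1 = 5
  target <- log(6) / log(2)  # bits equivalent of ln 6
  mat <- matrix(0, 4, 2, dimnames = list(c("A", "C", "G", "T"), NULL))
  mat["A", 1] <- target  # A scores ln6 nat; others 0
  pwm <- structure(list(id = "inr", mat = mat, background = rep(0.25, 4),
                        length = 2, max_score = target, min_score = 0),
                   class = "pwm_model")
  expect_equal(inr_likelihood_delta("AA", "CC", pwm), 5)
  # antisymmetry under swapping high/low
  expect_equal(inr_likelihood_delta("CC", "AA", pwm), -5)
  expect_equal(inr_likelihood_delta("AA", "AA", pwm), 0)
  expect_error(inr_likelihood_delta("A", "A", pwm), "shorter")
})

test_that("TATA scoring reproduces the published tiers", {
  expect_equal(tata_score("TATA"), 4L)
  expect_equal(tata_score("TTTA"), 2L)
  expect_equal(tata_score("TAAA"), 2L)
  expect_equal(tata_score("TTAA"), 1L)
  expect_equal(tata_score("TACG"), 0L)
  expect_error(tata_score("TAT"), "length-4")

  # enumeration of all 256 4-mers against the tier definition
  bases <- c("A", "C", "G", "T")
  all4 <- apply(expand.grid(bases, bases, bases, bases), 1, paste,
                collapse = "")
  got <- tata_score(all4)
  oracle <- vapply(all4, function(s) {
    b <- strsplit(s, "")[[1]]
    if (any(b %in% c("C", "G"))) return(0L)
    hd <- sum(b != c("T", "A", "T", "A"))
    c(4L, 2L, 1L, 0L, 0L)[hd + 1]
  }, integer(1), USE.NAMES = FALSE)
  expect_equal(got, oracle)
  # the A/T-restricted tiers respect reverse complementation of TATA
  # (revcomp of TATA is TATA under the A<->T alphabet)
  expect_equal(tata_score(revcomp("TATA")), 4L)
})

test_that("delta TATA takes the window maximum at each allele", {
  # high window contains TATA, low has TTTA at the same offset
  d <- tata_delta("GGTATAGG", "GGTTTAGG")
  expect_equal(d$delta, 2L)
  # windows with no qualifying 4-mer score zero on both sides
  d0 <- tata_delta("GGGGCCCC", "CCCCGGGG")
  expect_equal(d0$delta, 0L)
  expect_error(tata_delta("GGG", "CCC"), "shorter")
  # 10-bp windows vs a brute-force all-offset oracle
  set.seed(52)
  for (i in 1:10) {
    w1 <- paste(sample(c("A", "C", "G", "T"), 10, TRUE), collapse = "")
    w2 <- paste(sample(c("A", "C", "G", "T"), 10, TRUE), collapse = "")
    oracle_best <- function(w) max(vapply(1:7, function(j)
      tata_score(substr(w, j, j + 3)), integer(1)))
    expect_equal(tata_delta(w1, w2)$delta, oracle_best(w1) - oracle_best(w2))
  }
})

test_that("PWM match p-values equal exhaustive enumeration for short motifs", {
  set.seed(53)
  bases <- c("A", "C", "G", "T")
  for (L in c(3, 5)) {
    pfm <- matrix(stats::rexp(4 * L), 4, L)
    pfm <- sweep(pfm, 2, colSums(pfm), "/")
    pwm <- pwm_model(pfm, id = paste0("L", L))
    seqs <- apply(expand.grid(rep(list(bases), L)), 1, paste, collapse = "")
    scores <- vapply(seqs, function(s) {
      b <- match(strsplit(s, "")[[1]], bases)
      sum(pwm$mat[cbind(b, seq_len(L))])
    }, numeric(1))
    for (thr in quantile(scores, c(0.1, 0.5, 0.9, 1))) {
      expect_equal(pwm_match_pvalue(thr, pwm),
                   mean(scores >= thr - 1e-12), tolerance = 1e-9)
    }
  }
  pwm <- toy_pwm()
  expect_equal(pwm_match_pvalue(pwm$max_score + 1, pwm), 0)
  expect_equal(pwm_match_pvalue(pwm$min_score - 1, pwm), 1)
})

test_that("discretized p-value path brackets the exact answer for long motifs", {
  set.seed(54)
  L <- 12
  pfm <- matrix(stats::rexp(4 * L), 4, L)
  pfm <- sweep(pfm, 2, colSums(pfm), "/")
  pwm <- pwm_model(pfm, id = "long")
  thr <- 0.6 * pwm$max_score
  p_disc <- pwm_match_pvalue(thr, pwm, exact_max_length = 10, tol = 1e-6)
  p_exact <- pwm_match_pvalue(thr, pwm, exact_max_length = 12)
  # the bracket guarantee is absolute
  expect_lt(abs(p_disc - p_exact), 1e-5)
})

test_that("motif disruption enrichment flags a planted consensus breaker", {
  pwm <- toy_pwm(p = 0.9997, L = 5, consensus = c("A", "C", "G", "T", "A"))
  set.seed(55)
  rand_win <- function() paste(sample(c("A", "C", "G", "T"), 15, TRUE),
                               collapse = "")
  # QTL set: windows carrying the consensus, variant breaking it
  qtl <- tibble::tibble(
    ref_window = paste0("TTTT", "ACGTA", "TTTTTT"),
    alt_allele = "T", variant_offset = 7L)[rep(1, 12), ]
  bg <- tibble::tibble(
    ref_window = vapply(1:40, function(i) rand_win(), character(1)),
    alt_allele = "T", variant_offset = 7L)
  res <- motif_disruption_enrichment(qtl, bg, list(pwm), p_thresh = 0.01,
                                     min_bits = 0.5)
  expect_equal(res$n_qtl, 12)
  expect_true(res$enriched)

  # identical sets give fold 1; never-matching windows give zero counts
  res_eq <- motif_disruption_enrichment(qtl, qtl, list(pwm))
  expect_equal(res_eq$fold, 1)
  all_t <- tibble::tibble(ref_window = strrep("T", 15), alt_allele = "A",
                          variant_offset = 8L)
  res0 <- motif_disruption_enrichment(all_t, all_t, list(pwm))
  expect_equal(res0$n_qtl + res0$n_background, 0)
  expect_true(is.na(res0$fold))
})
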