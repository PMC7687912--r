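# Allele-level sequence effects: PWM scanning and delta scores at
# initiation-level QTLs, Initiator (Inr) likelihood differences and
# TATA-like element scoring at directionality QTLs, exact PWM match
# p-values, and per-motif disruption enrichment.

.BASES <- c("A", "C", "G", "T")

.seq_to_int <- function(sequence) {
  v <- match(strsplit(toupper(sequence), "")[[1]], .BASES)
  v  # NA for ambiguous bases
}

#' Reverse complement of a DNA string
#'
#' @param sequence Character string over A/C/G/T/N.
#' @return The reverse complement.
#' @export
revcomp <- function(sequence) {
  chartr("ACGTacgtN", "TGCAtgcaN",
         vapply(sequence, function(s)
           paste(rev(strsplit(s, "")[[1]]), collapse = ""), character(1),
           USE.NAMES = FALSE))
}

#' Build a log-odds PWM from a position frequency matrix
#'
#' Columns of the frequency matrix are smoothed with
#' `(f + pseudocount * background) / (1 + pseudocount)` and converted to
#' log2 odds (bits) against the background base frequencies.
#'
#' @param pfm 4 x L frequency matrix (rows A, C, G, T; columns sum
#'   to 1).
#' @param id Motif identifier.
#' @param background Background base frequencies (default uniform).
#' @param pseudocount Smoothing pseudocount (default 0.8).
#' @return Object of class `pwm_model`: list with `id`, `pfm`, `mat`
#'   (log2-odds), `background`, `length`, `max_score`, `min_score`.
#' @export
pwm_model <- function(pfm, id = "motif", background = rep(0.25, 4),
                      pseudocount = 0.8) {
  pfm <- as.matrix(pfm)
  if (nrow(pfm) != 4) abort("frequency matrix must have 4 rows (A,C,G,T)")
  if (any(pfm < 0)) abort("frequencies must be non-negative")
  if (any(abs(colSums(pfm) - 1) > 1e-6)) abort("columns must sum to 1")
  rownames(pfm) <- .BASES
  smoothed <- sweep(pfm + pseudocount * background, 2,
                    1 + pseudocount, "/")
  mat <- log2(smoothed / background)
  structure(list(id = id, pfm = pfm, mat = mat, background = background,
                 length = ncol(mat),
                 max_score = sum(apply(mat, 2, max)),
                 min_score = sum(apply(mat, 2, min))),
            class = "pwm_model")
}

#' @export
print.pwm_model <- function(x, ...) {
  cat(sprintf("<pwm_model> %s: %d columns, score range [%.2f, %.2f] bits\n",
              x$id, x$length, x$min_score, x$max_score))
  invisible(x)
}

#' Read motifs in MEME minimal format
#'
#' Parses the letter-probability matrices of a MEME minimal-format
#' file into [pwm_model()] objects.
#'
#' @param path Path to the MEME file.
#' @param background,pseudocount Passed to [pwm_model()].
#' @return Named list of `pwm_model` objects.
#' @export
read_meme <- function(path, background = rep(0.25, 4), pseudocount = 0.8) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MOTIF\\s+", lines)
  if (length(starts) == 0) abort("no MOTIF records found")
  out <- list()
  for (s in starts) {
    id <- strsplit(trimws(lines[s]), "\\s+")[[1]][2]
    hdr <- grep("^letter-probability matrix", lines[seq(s, length(lines))])[1]
    hdr <- s + hdr - 1
    rows <- list()
    i <- hdr + 1
    while (i <= length(lines) &&
           grepl("^\\s*[0-9.eE+-]+(\\s+[0-9.eE+-]+){3}\\s*$", lines[i])) {
      rows[[length(rows) + 1]] <-
        as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]])
      i <- i + 1
    }
    pfm <- t(do.call(rbind, rows))  # 4 x L
    out[[id]] <- pwm_model(pfm, id = id, background = background,
                           pseudocount = pseudocount)
  }
  out
}

.scan_scores <- function(seq_int, mat) {
  L <- ncol(mat)
  n <- length(seq_int) - L + 1
  if (n < 1) return(numeric(0))
  vapply(seq_len(n), function(i) {
    idx <- seq_int[i:(i + L - 1)]
    if (anyNA(idx)) return(NA_real_)
    sum(mat[cbind(idx, seq_len(L))])
  }, numeric(1))
}

#' Best PWM match over all offsets and both strands
#'
#' Maximum log-odds score over every placement of the motif on the
#' forward and reverse-complement strands.  Ties are broken leftmost,
#' forward strand first.  Placements covering ambiguous bases are
#' skipped.
#'
#' @param sequence DNA string, at least as long as the motif.
#' @param pwm A [pwm_model()].
#' @return List with `score`, `position` (1-based start on the forward
#'   strand), `strand`.
#' @export
scan_best_match <- function(sequence, pwm) {
  si <- .seq_to_int(sequence)
  L <- pwm$length
  if (length(si) < L) abort("sequence shorter than the motif")
  fwd <- .scan_scores(si, pwm$mat)
  # reverse strand: score the reverse complement, then map start
  # positions back to forward coordinates
  rc <- rev(5L - si)
  rc[is.na(rc)] <- NA_integer_
  rev_sc <- rev(.scan_scores(rc, pwm$mat))
  cand <- tibble(
    position = rep(seq_along(fwd), 2),
    strand = rep(c("+", "-"), each = length(fwd)),
    score = c(fwd, rev_sc))
  cand <- cand[!is.na(cand$score), ]
  if (nrow(cand) == 0)
    return(list(score = NA_real_, position = NA_integer_, strand = NA_character_))
  best <- max(cand$score)
  cand <- cand[cand$score == best, ]
  cand <- cand[order(cand$position, cand$strand != "+"), ]
  list(score = best, position = cand$position[1], strand = cand$strand[1])
}

.score_at <- function(sequence, pwm, position, strand) {
  si <- .seq_to_int(sequence)
  L <- pwm$length
  if (position < 1 || position + L - 1 > length(si)) return(NA_real_)
  idx <- si[position:(position + L - 1)]
  if (strand == "-") idx <- rev(5L - idx)
  if (anyNA(idx)) return(NA_real_)
  sum(pwm$mat[cbind(idx, seq_len(L))])
}

#' Allele-level PWM score differences at a variant
#'
#' Builds the alternate-allele window by substituting the alternate
#' allele into the reference window, scans both alleles against each
#' PWM, and for motifs with a strong match (score above
#' `strong_threshold` bits) in at least one allele reports
#' `delta = score_high - score_low`, where "high" is the allele
#' associated with the higher phenotype (stronger initiation for ti,
#' increased proximal-strand directionality for di).  Scores are
#' compared at the best-match placement of the stronger allele.
#' Substitutions longer than the window are skipped with a flag.
#'
#' @param ref_window Reference sequence window (typically 40 bp around
#'   the variant).
#' @param alt_allele Alternate-allele string.
#' @param variant_offset 1-based position of the reference allele
#'   within `ref_window`.
#' @param pwms List of [pwm_model()] objects.
#' @param high_allele Which allele carries the higher phenotype:
#'   `"ref"` or `"alt"`.
#' @param ref_len Length of the reference allele (default 1).
#' @param strong_threshold Strong-match threshold in bits (default 13).
#' @return Tibble with `motif`, `score_high`, `score_low`, `delta`,
#'   `position`, `strand`, `skipped`; identical alleles give an empty
#'   result.
#' @export
allele_delta_pwm <- function(ref_window, alt_allele, variant_offset,
                             pwms, high_allele = c("ref", "alt"),
                             ref_len = 1L, strong_threshold = 13) {
  high_allele <- match.arg(high_allele)
  if (!is.list(pwms) || inherits(pwms, "pwm_model")) pwms <- list(pwms)
  ref_allele <- substr(ref_window, variant_offset,
                       variant_offset + ref_len - 1L)
  if (nchar(alt_allele) > nchar(ref_window))
    return(tibble(motif = vapply(pwms, `[[`, character(1), "id"),
                  score_high = NA_real_, score_low = NA_real_,
                  delta = NA_real_, position = NA_integer_,
                  strand = NA_character_, skipped = TRUE))
  if (identical(toupper(ref_allele), toupper(alt_allele)))
    return(tibble(motif = character(), score_high = numeric(),
                  score_low = numeric(), delta = numeric(),
                  position = integer(), strand = character(),
                  skipped = logical()))
  alt_window <- paste0(substr(ref_window, 1, variant_offset - 1L),
                       alt_allele,
                       substr(ref_window, variant_offset + ref_len,
                              nchar(ref_window)))
  high_seq <- if (high_allele == "ref") ref_window else alt_window
  low_seq <- if (high_allele == "ref") alt_window else ref_window
  rows <- lapply(pwms, function(pwm) {
    bh <- scan_best_match(high_seq, pwm)
    bl <- scan_best_match(low_seq, pwm)
    if (is.na(bh$score) && is.na(bl$score)) return(NULL)
    if (max(bh$score, bl$score, na.rm = TRUE) <= strong_threshold)
      return(NULL)
    if (!is.na(bh$score) && (is.na(bl$score) || bh$score >= bl$score)) {
      pos <- bh$position; strand <- bh$strand
      s_high <- bh$score
      s_low <- .score_at(low_seq, pwm, pos, strand)
    } else {
      pos <- bl$position; strand <- bl$strand
      s_low <- bl$score
      s_high <- .score_at(high_seq, pwm, pos, strand)
    }
    tibble(motif = pwm$id, score_high = s_high, score_low = s_low,
           delta = s_high - s_low, position = pos, strand = strand,
           skipped = FALSE)
  })
  purrr::list_rbind(rows[!vapply(rows, is.null, logical(1))])
}

#' Initiator-element likelihood difference between alleles
#'
#' The Inr likelihood of a TSS window is the natural exponent of its
#' best forward-strand PWM match on the natural-log-odds scale; the
#' delta is `exp(score_high) - exp(score_low)` between the
#' increased-directionality and decreased-directionality alleles.
#' Applied to directionality QTLs within a few bp of an nTSS, on the
#' strand of that nTSS; pairs with `|delta| <= 5` are conventionally
#' filtered downstream.
#'
#' @param tss_window_high,tss_window_low TSS-window sequences for the
#'   high- and low-directionality alleles (strand-oriented).
#' @param inr_pwm A [pwm_model()] of the Initiator element (its bit
#'   scores are rescaled to natural log).
#' @return The likelihood difference (a single number).
#' @export
inr_likelihood_delta <- function(tss_window_high, tss_window_low, inr_pwm) {
  if (nchar(tss_window_high) < inr_pwm$length ||
      nchar(tss_window_low) < inr_pwm$length)
    abort("TSS window shorter than the Inr motif")
  nat <- function(w) {
    sc <- .scan_scores(.seq_to_int(w), inr_pwm$mat)
    max(sc, na.rm = TRUE) * log(2)
  }
  exp(nat(tss_window_high)) - exp(nat(tss_window_low))
}

#' TATA-like element score of a 4-mer
#'
#' A perfect `TATA` scores 4; a single A/T inversion (one position with
#' A and T swapped, e.g. `TTTA` or `TAAA`) scores 2; two inversions
#' (e.g. `TTAA`) score 1; anything else, including any 4-mer containing
#' C or G, scores 0.
#'
#' @param four_mer Character vector of length-4 strings over A/C/G/T.
#' @return Integer scores (4, 2, 1 or 0).
#' @export
tata_score <- function(four_mer) {
  vapply(toupper(four_mer), function(s) {
    if (nchar(s) != 4) abort("TATA scoring requires length-4 strings")
    b <- strsplit(s, "")[[1]]
    if (!all(b %in% .BASES)) abort("TATA scoring requires A/C/G/T strings")
    if (!all(b %in% c("A", "T"))) return(0L)
    hd <- sum(b != c("T", "A", "T", "A"))
    if (hd == 0) 4L else if (hd == 1) 2L else if (hd == 2) 1L else 0L
  }, integer(1), USE.NAMES = FALSE)
}

#' Delta TATA score between alleles
#'
#' Each allele's window (conventionally the 21-bp region 40-20 bp
#' upstream of the nTSS, strand-oriented) is scored as the maximum
#' [tata_score()] over all 4-mer offsets; the delta is the high- minus
#' the low-directionality allele score.
#'
#' @param window_high,window_low Upstream window sequences (length
#'   at least 4).
#' @return List with `score_high`, `score_low`, `delta`.
#' @export
tata_delta <- function(window_high, window_low) {
  best <- function(w) {
    if (nchar(w) < 4) abort("window shorter than 4 bp")
    offs <- seq_len(nchar(w) - 3)
    max(tata_score(substring(w, offs, offs + 3)))
  }
  h <- best(window_high)
  l <- best(window_low)
  list(score_high = h, score_low = l, delta = h - l)
}

#' Exact p-value of a PWM match score
#'
#' Probability that a random background sequence of the motif's length
#' scores at least `score`.  For motifs up to `exact_max_length`
#' columns the score distribution is built by exact dynamic programming
#' over column sums; longer motifs use a discretized dynamic program
#' whose step is refined automatically until the bracketing error drops
#' below `tol`.
#'
#' @param score Score threshold (bits).
#' @param pwm A [pwm_model()].
#' @param tol Maximum acceptable p-value bracket width for the
#'   discretized path (default 1e-6).
#' @param exact_max_length Maximum motif length for the exact path
#'   (default 10).
#' @return The p-value (`0` above the attainable maximum, `1` at or
#'   below the minimum).
#' @export
pwm_match_pvalue <- function(score, pwm, tol = 1e-6,
                             exact_max_length = 10) {
  if (score > pwm$max_score) return(0)
  if (score <= pwm$min_score) return(1)
  bg <- pwm$background
  L <- pwm$length
  if (L <= exact_max_length) {
    sums <- 0
    probs <- 1
    for (j in seq_len(L)) {
      sums <- rep(sums, each = 4) + pwm$mat[, j]
      probs <- rep(probs, each = 4) * bg
    }
    return(sum(probs[sums >= score - 1e-12]))
  }
  delta <- (pwm$max_score - pwm$min_score) / 1e4
  for (iter in 1:8) {
    ints <- floor(pwm$mat / delta)
    lo <- sum(apply(ints, 2, min))
    hi <- sum(apply(ints, 2, max))
    width <- hi - lo + 1L
    dist <- numeric(width)
    dist[1] <- 1
    offset <- lo
    cur_lo <- 0L
    for (j in seq_len(L)) {
      newdist <- numeric(width)
      for (b in 1:4) {
        k <- ints[b, j] - min(ints[, j])
        span <- seq_len(width - k)
        newdist[span + k] <- newdist[span + k] + bg[b] * dist[span]
      }
      dist <- newdist
      cur_lo <- cur_lo + min(ints[, j])
    }
    # dist[i] = P(integer sum == lo + i - 1)
    cum <- rev(cumsum(rev(dist)))
    p_at <- function(th_int) {
      i <- th_int - lo + 1L
      if (i <= 1) 1 else if (i > width) 0 else cum[i]
    }
    p_lo <- p_at(as.integer(ceiling(score / delta)))
    p_hi <- p_at(as.integer(ceiling(score / delta)) - L)
    if (p_hi - p_lo <= tol) return((p_hi + p_lo) / 2)
    delta <- delta / 4
  }
  (p_hi + p_lo) / 2
}

.pwm_score_threshold <- function(pwm, p_thresh) {
  # smallest score whose match p-value is below p_thresh (bisection)
  lo <- pwm$min_score
  hi <- pwm$max_score
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (pwm_match_pvalue(mid, pwm) < p_thresh) hi <- mid else lo <- mid
  }
  hi
}

#' Per-motif disruption counts and enrichment over background
#'
#' A variant disrupts a motif if at least one allele has a significant
#' match (match p-value below `p_thresh`) and the two alleles' best
#' scores differ by at least `min_bits` bits.  Counts are tallied for
#' the QTL set and for background variants (conventionally random SNPs
#' within 200 bp of element midpoints) and the fold is the rate ratio;
#' motifs exceeding `fold_report` are flagged enriched.
#'
#' @param qtl_alleles,background_alleles Tibbles with columns
#'   `ref_window`, `alt_allele`, `variant_offset` (and optionally
#'   `ref_len`).
#' @param pwms List of [pwm_model()] objects.
#' @param p_thresh Match significance threshold (default 0.01).
#' @param min_bits Minimum between-allele score difference
#'   (default 0.5).
#' @param fold_report Fold threshold for the `enriched` flag
#'   (default 1.2).
#' @return Tibble per motif: counts, rates, `fold`, `enriched`.
#' @export
motif_disruption_enrichment <- function(qtl_alleles, background_alleles,
                                        pwms, p_thresh = 0.01,
                                        min_bits = 0.5,
                                        fold_report = 1.2) {
  if (nrow(background_alleles) < nrow(qtl_alleles))
    warn("background smaller than the QTL set; rates still comparable but unstable")
  if (!is.list(pwms) || inherits(pwms, "pwm_model")) pwms <- list(pwms)
  thresholds <- vapply(pwms, .pwm_score_threshold, numeric(1),
                       p_thresh = p_thresh)
  count_set <- function(df) {
    vapply(seq_along(pwms), function(m) {
      pwm <- pwms[[m]]
      sum(vapply(seq_len(nrow(df)), function(i) {
        rl <- if ("ref_len" %in% names(df)) df$ref_len[i] else 1L
        ref_w <- df$ref_window[i]
        alt_w <- paste0(substr(ref_w, 1, df$variant_offset[i] - 1L),
                        df$alt_allele[i],
                        substr(ref_w, df$variant_offset[i] + rl,
                               nchar(ref_w)))
        s_ref <- scan_best_match(ref_w, pwm)$score
        s_alt <- scan_best_match(alt_w, pwm)$score
        !is.na(s_ref) && !is.na(s_alt) &&
          max(s_ref, s_alt) >= thresholds[m] &&
          abs(s_ref - s_alt) >= min_bits
      }, logical(1)))
    }, integer(1))
  }
  nq <- count_set(qtl_alleles)
  nb <- count_set(background_alleles)
  rate_q <- nq / nrow(qtl_alleles)
  rate_b <- nb / nrow(background_alleles)
  tibble(motif = vapply(pwms, `[[`, character(1), "id"),
         n_qtl = nq, n_background = nb,
         rate_qtl = rate_q, rate_background = rate_b,
         fold = ifelse(nq + nb == 0, NA_real_, rate_q / rate_b),
         enriched = !is.na(rate_q / rate_b) & rate_q / rate_b > fold_report)
}
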