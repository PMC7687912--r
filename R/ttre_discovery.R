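# Discovery of divergent transcribed regulatory elements (tTREs):
# per-strand nascent-TSS peak calling on the aggregate track, greedy
# divergent pairing within 300 bp, promoter/enhancer classification and
# ROC evaluation.

#' Sum stranded signals across samples
#'
#' @param signals A list of [stranded_signal()] tibbles.
#' @return A single aggregate [stranded_signal()].
#' @export
aggregate_signals <- function(signals) {
  all <- bind_rows(signals)
  agg <- dplyr::summarise(
    dplyr::group_by(all, .data$contig, .data$position, .data$strand),
    count = sum(.data$count), .groups = "drop")
  stranded_signal(agg$contig, agg$position, agg$strand, agg$count)
}

.merge_peaks <- function(pos, count, merge_window) {
  # cluster candidate bases whose neighbours are within merge_window,
  # keep the maximum-count base per cluster (leftmost on ties)
  o <- order(pos)
  pos <- pos[o]; count <- count[o]
  grp <- cumsum(c(TRUE, diff(pos) > merge_window))
  keep <- vapply(split(seq_along(pos), grp), function(i) {
    i[which.max(count[i])]
  }, integer(1))
  list(position = pos[keep], count = count[keep])
}

#' Call nascent TSS peaks per strand
#'
#' Candidate bases are those whose aggregate (summed-across-individuals)
#' count meets `min_count`; candidates within `merge_window` bp of each
#' other on the same strand are merged, keeping the maximum-count base
#' (leftmost on ties).  `min_rpm` expresses the threshold in reads per
#' million of the aggregate track instead (the two are mutually
#' exclusive; 0.5 RPM is a typical choice for deep aggregate tracks).
#'
#' @param signal Aggregate [stranded_signal()].
#' @param min_count Minimum aggregate count at the peak base (default 5).
#' @param merge_window Same-strand merge distance in bp (default 60).
#' @param min_rpm Optional RPM threshold overriding `min_count`.
#' @return Tibble of nTSSs: `contig`, `position`, `strand`, `count`,
#'   sorted by contig, strand, position.
#' @export
call_ntss <- function(signal, min_count = 5, merge_window = 60,
                      min_rpm = NULL) {
  if (!is.null(min_rpm)) {
    min_count <- min_rpm * sum(signal$count) / 1e6
  }
  if (min_count < 1) abort("min_count must be >= 1")
  cand <- dplyr::filter(signal, .data$count >= min_count)
  if (nrow(cand) == 0)
    return(tibble(contig = character(), position = integer(),
                  strand = character(), count = numeric()))
  out <- dplyr::group_by(cand, .data$contig, .data$strand)
  out <- dplyr::reframe(out, {
    m <- .merge_peaks(.data$position, .data$count, merge_window)
    tibble(position = m$position, count = m$count)
  })
  dplyr::arrange(as_tibble(out), .data$contig, .data$strand, .data$position)
}

#' Pair nTSSs into divergent bidirectional elements
#'
#' Each minus-strand nTSS is paired with a plus-strand nTSS strictly
#' downstream of it (divergent geometry) within `max_gap` bp.  Pairing
#' is greedy by ascending gap (ties broken by leftmost minus-strand
#' position); each nTSS is used at most once, and unpaired nTSSs are
#' discarded.
#'
#' @param ntss nTSS tibble from [call_ntss()].
#' @param max_gap Maximum distance between paired nTSSs (default 300).
#' @return tTRE tibble: `id`, `contig`, `minus_pos`, `plus_pos`,
#'   `midpoint` (floor of the mean), `width`, `class`
#'   (`"unclassified"`).
#' @export
pair_bidirectional <- function(ntss, max_gap = 300) {
  empty <- tibble(id = character(), contig = character(),
                  minus_pos = integer(), plus_pos = integer(),
                  midpoint = integer(), width = integer(),
                  class = character())
  if (nrow(ntss) == 0) return(empty)
  pairs <- purrr::list_rbind(lapply(split(ntss, ntss$contig), function(df) {
    minus <- df[df$strand == "-", ]
    plus <- df[df$strand == "+", ]
    if (nrow(minus) == 0 || nrow(plus) == 0) return(NULL)
    cand <- tidyr::expand_grid(m = seq_len(nrow(minus)), p = seq_len(nrow(plus)))
    cand$gap <- plus$position[cand$p] - minus$position[cand$m]
    cand <- cand[cand$gap > 0 & cand$gap <= max_gap, ]
    if (nrow(cand) == 0) return(NULL)
    cand <- cand[order(cand$gap, minus$position[cand$m]), ]
    used_m <- logical(nrow(minus)); used_p <- logical(nrow(plus))
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      if (!used_m[cand$m[i]] && !used_p[cand$p[i]]) {
        keep[i] <- TRUE
        used_m[cand$m[i]] <- TRUE
        used_p[cand$p[i]] <- TRUE
      }
    }
    cand <- cand[keep, ]
    tibble(contig = df$contig[1],
           minus_pos = minus$position[cand$m],
           plus_pos = plus$position[cand$p])
  }))
  if (is.null(pairs) || nrow(pairs) == 0) return(empty)
  pairs <- dplyr::arrange(pairs, .data$contig, .data$minus_pos)
  dplyr::mutate(pairs,
                id = sprintf("ttre%04d", dplyr::row_number()),
                midpoint = as.integer(floor((.data$minus_pos + .data$plus_pos) / 2)),
                width = .data$plus_pos - .data$minus_pos,
                class = "unclassified",
                .before = 1)
}

.nearest_tss_dist <- function(contig, position, tss) {
  # absolute distance from each query base to the nearest annotated TSS
  out <- rep(Inf, length(position))
  for (ct in unique(contig)) {
    ref <- sort(tss$position[tss$contig == ct])
    if (length(ref) == 0) next
    i <- which(contig == ct)
    idx <- findInterval(position[i], ref)
    lo <- ifelse(idx >= 1, abs(position[i] - ref[pmax(idx, 1)]), Inf)
    hi <- ifelse(idx < length(ref), abs(ref[pmin(idx + 1, length(ref))] -
                                          position[i]), Inf)
    out[i] <- pmin(lo, hi)
  }
  out
}

#' Classify elements by distance to annotated gene TSSs
#'
#' An element is a promoter if either of its nTSSs lies within
#' `promoter_dist` bp of an annotated TSS, an enhancer if both are more
#' than `enhancer_dist` bp from every annotated TSS, and unclassified
#' otherwise.
#'
#' @param ttres tTRE tibble.
#' @param annotated_tss Tibble from [read_tss_bed()] (needs `contig`,
#'   `position`).
#' @param promoter_dist Promoter distance threshold (default 500).
#' @param enhancer_dist Enhancer distance threshold (default 2000).
#' @return `ttres` with the `class` column filled in.
#' @export
classify_by_annotation <- function(ttres, annotated_tss,
                                   promoter_dist = 500,
                                   enhancer_dist = 2000) {
  if (nrow(annotated_tss) == 0) abort("annotated TSS list is empty")
  d_minus <- .nearest_tss_dist(ttres$contig, ttres$minus_pos, annotated_tss)
  d_plus <- .nearest_tss_dist(ttres$contig, ttres$plus_pos, annotated_tss)
  d <- pmin(d_minus, d_plus)
  ttres$class <- dplyr::case_when(
    d <= promoter_dist ~ "promoter",
    d > enhancer_dist ~ "enhancer",
    TRUE ~ "unclassified")
  ttres
}

#' Classify elements by transcript stability (CAGE-like) signal
#'
#' Collects depth-normalized stability counts in a window around each
#' nTSS on its strand, builds an empirical background from nTSSs at
#' least `background_dist` bp from any annotated TSS, assigns each nTSS
#' an empirical p-value `(1 + #{background >= observed}) / (B + 1)`, and
#' applies Benjamini-Hochberg at `fdr`.  An element is a promoter if
#' either nTSS has stability counts significantly above background,
#' otherwise an enhancer.
#'
#' @param ttres tTRE tibble.
#' @param stability_signal [stranded_signal()] of CAGE-like counts.
#' @param annotated_tss Annotated TSS tibble (for the background set).
#' @param fdr BH false-discovery rate (default 0.1).
#' @param background_dist Minimum distance from annotation for
#'   background nTSSs (default 1000).
#' @param window Half-width in bp of the per-nTSS collection window
#'   (default 25).
#' @return `ttres` with `class` set to `"promoter"` or `"enhancer"`.
#' @export
classify_by_stability <- function(ttres, stability_signal, annotated_tss,
                                  fdr = 0.1, background_dist = 1000,
                                  window = 25) {
  ntss <- tibble(
    ttre = rep(ttres$id, 2),
    contig = rep(ttres$contig, 2),
    position = c(ttres$minus_pos, ttres$plus_pos),
    strand = rep(c("-", "+"), each = nrow(ttres)))
  depth <- sum(stability_signal$count)
  if (depth == 0) {
    ttres$class <- "enhancer"
    return(ttres)
  }
  counts <- vapply(seq_len(nrow(ntss)), function(i) {
    s <- stability_signal
    sum(s$count[s$contig == ntss$contig[i] & s$strand == ntss$strand[i] &
                  abs(s$position - ntss$position[i]) <= window])
  }, numeric(1))
  ntss$rpm <- counts / (depth / 1e6)
  d <- .nearest_tss_dist(ntss$contig, ntss$position, annotated_tss)
  bg <- ntss$rpm[d >= background_dist]
  if (length(bg) == 0) abort("empty stability background set")
  p <- vapply(ntss$rpm, function(x) (1 + sum(bg >= x)) / (length(bg) + 1),
              numeric(1))
  sig <- p.adjust(p, method = "BH") < fdr
  prom <- unique(ntss$ttre[sig])
  ttres$class <- ifelse(ttres$id %in% prom, "promoter", "enhancer")
  ttres
}

#' ROC evaluation of region scores against standard region sets
#'
#' Computes true/false positive rates over all score thresholds, taking
#' the supplied positive regions as truth and the background regions as
#' negatives, with AUC by the trapezoid rule (equal to the
#' Mann-Whitney U statistic divided by n1*n2).
#'
#' @param region_scores Tibble with columns `region` and `score`.
#' @param positive_regions,background_regions Character vectors of
#'   region ids; must be disjoint.
#' @return List of class `erna_roc`: `curve` (tibble `threshold`,
#'   `fpr`, `tpr`) and `auc`.
#' @export
evaluate_roc <- function(region_scores, positive_regions,
                         background_regions) {
  if (length(positive_regions) == 0) abort("no positive regions")
  if (length(intersect(positive_regions, background_regions)) > 0)
    abort("positive and background regions must be disjoint")
  sc <- region_scores[region_scores$region %in%
                        c(positive_regions, background_regions), ]
  lab <- sc$region %in% positive_regions
  o <- order(sc$score, decreasing = TRUE)
  lab <- lab[o]; s <- sc$score[o]
  tp <- cumsum(lab); fp <- cumsum(!lab)
  # one point per distinct threshold
  last <- c(s[-1] != s[-length(s)], TRUE)
  curve <- tibble(threshold = s[last],
                  tpr = tp[last] / sum(lab),
                  fpr = fp[last] / sum(!lab))
  curve <- bind_rows(tibble(threshold = Inf, tpr = 0, fpr = 0), curve)
  auc <- sum(diff(curve$fpr) * (head(curve$tpr, -1) + tail(curve$tpr, -1)) / 2)
  structure(list(curve = curve, auc = auc), class = "erna_roc")
}

#' Per-individual strand-specific window counts at elements
#'
#' Sums 5' counts in midpoint-relative windows: plus-strand offsets
#' `[1, 250]` and minus-strand offsets `[-250, 0]`.  These windows are
#' the quantification units for both the initiation-level and the
#' directionality phenotypes and do not depend on element class.
#'
#' @param signals Named list of [stranded_signal()] per sample.
#' @param ttres tTRE tibble.
#' @param window Window half-size in bp (default 250).
#' @return List with matrices `plus` and `minus` (elements x samples).
#' @export
count_ttre_windows <- function(signals, ttres, window = 250) {
  n <- nrow(ttres)
  mk <- function() matrix(0, n, length(signals),
                          dimnames = list(ttres$id, names(signals)))
  plus <- mk(); minus <- mk()
  for (j in seq_along(signals)) {
    sig <- signals[[j]]
    for (ct in unique(ttres$contig)) {
      tt <- which(ttres$contig == ct)
      s <- sig[sig$contig == ct, ]
      if (nrow(s) == 0) next
      # elements are non-overlapping: locate each base's element by midpoint
      mids <- ttres$midpoint[tt]
      o <- order(mids)
      brks <- c(-Inf, mids[o][-1] - diff(mids[o]) / 2, Inf)
      idx <- tt[o][findInterval(s$position, brks)]
      off <- s$position - ttres$midpoint[idx]
      inplus <- s$strand == "+" & off >= 1 & off <= window
      inminus <- s$strand == "-" & off >= -window & off <= 0
      if (any(inplus)) {
        agg <- rowsum(s$count[inplus], idx[inplus])
        plus[as.integer(rownames(agg)), j] <-
          plus[as.integer(rownames(agg)), j] + agg[, 1]
      }
      if (any(inminus)) {
        agg <- rowsum(s$count[inminus], idx[inminus])
        minus[as.integer(rownames(agg)), j] <-
          minus[as.integer(rownames(agg)), j] + agg[, 1]
      }
    }
  }
  list(plus = plus, minus = minus)
}

#' Dominant strand of each element
#'
#' The dominant strand is the one with the higher window count summed
#' over individuals; it defines "downstream" when orienting promoter
#' profiles (the dominantly transcribed TSS, usually the gene's, points
#' downstream).
#'
#' @param window_counts Result of [count_ttre_windows()].
#' @return Character vector (`"+"`/`"-"`) per element; ties are `"+"`.
#' @export
dominant_strand <- function(window_counts) {
  ifelse(rowSums(window_counts$minus) > rowSums(window_counts$plus),
         "-", "+")
}

#' @export
print.erna_roc <- function(x, ...) {
  cat(sprintf("<erna_roc> AUC = %.4f over %d thresholds\n",
              x$auc, nrow(x$curve)))
  invisible(x)
}
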