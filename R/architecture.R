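# Positional and regional analyses of QTL placement within elements:
# the observed-vs-resampled positional profile, the bipartite
# center/core/NCNC/out/far-out partition, overlap enrichments, QQ/KS
# comparison of p-value distributions, and element-gene co-expression.

#' Midpoint-relative offsets of SNP positions
#'
#' Assigns each SNP to the element whose midpoint is nearest (elements
#' are assumed to have non-overlapping test windows) and returns the
#' signed offset, optionally flipped so the dominant strand points
#' downstream (used for promoter profiles).
#'
#' @param positions Tibble with `contig`, `pos`.
#' @param ttres tTRE tibble; may carry a `dominant` column
#'   (`"+"`/`"-"`) used when `orient = TRUE`.
#' @param span Maximum |offset| retained (default 2000).
#' @param orient Flip offsets at minus-dominant elements (default
#'   FALSE).
#' @return Tibble `contig`, `pos`, `element_id`, `offset`, with rows
#'   beyond `span` dropped.
#' @export
snp_offsets <- function(positions, ttres, span = 2000, orient = FALSE) {
  empty <- tibble(contig = character(), pos = integer(),
                  element_id = character(), offset = integer())
  if (nrow(positions) == 0) return(empty)
  out <- purrr::list_rbind(lapply(split(positions, positions$contig),
                                  function(df) {
    ct <- df$contig[1]
    tt <- ttres[ttres$contig == ct, ]
    if (nrow(tt) == 0) return(NULL)
    o <- order(tt$midpoint)
    mids <- tt$midpoint[o]
    brks <- if (length(mids) > 1) mids[-length(mids)] + diff(mids) / 2 else numeric()
    idx <- o[findInterval(df$pos, brks) + 1L]
    off <- df$pos - tt$midpoint[idx]
    if (orient && !is.null(tt$dominant))
      off <- ifelse(tt$dominant[idx] == "-", -off, off)
    tibble(contig = ct, pos = df$pos, element_id = tt$id[idx],
           offset = as.integer(off))
  }))
  if (is.null(out) || nrow(out) == 0) return(empty)
  out[abs(out$offset) <= span, , drop = FALSE]
}

#' Positional QTL enrichment profile with resampled background band
#'
#' Bins QTL offsets around element midpoints and compares each bin's
#' count to the distribution obtained by repeatedly drawing the same
#' number of SNPs from all SNPs in the same windows; the band is the
#' 0.5% and 99.5% quantile per bin (a 99% interval).
#'
#' @param qtl_positions Tibble with `contig`, `pos` for the QTL SNPs.
#' @param ttres tTRE tibble.
#' @param all_snp_positions Tibble with `contig`, `pos` for the
#'   background SNP universe.
#' @param n_resample Number of background resamples (default 10000; at
#'   least 1000 recommended for a stable 99% band).
#' @param bin Bin width in bp (default 10; use 1 for per-base
#'   profiles).
#' @param span Profile half-width in bp (default 2000).
#' @param orient Orient dominant strand downstream (default FALSE).
#' @return Object of class `enrichment_profile`: tibble with
#'   `offset` (bin midpoint), `observed`, `bg_mean`, `bg_lo`, `bg_hi`,
#'   and attributes `n_qtl`, `n_background`, `bin`, `n_resample`.
#' @export
positional_enrichment <- function(qtl_positions, ttres, all_snp_positions,
                                  n_resample = 10000, bin = 10,
                                  span = 2000, orient = FALSE) {
  qtl_off <- snp_offsets(qtl_positions, ttres, span, orient)$offset
  bg_off <- snp_offsets(all_snp_positions, ttres, span, orient)$offset
  if (length(qtl_off) == 0) abort("no QTLs within the profile span")
  breaks <- seq(-span, span + bin, by = bin) - 0.5
  nb <- length(breaks) - 1L
  bin_of <- function(x) findInterval(x, breaks)
  obs <- tabulate(bin_of(qtl_off), nbins = nb)
  n_q <- length(qtl_off)
  replace <- length(bg_off) < n_q
  if (replace) warn("fewer background SNPs than QTLs; sampling with replacement")
  bg_bins <- bin_of(bg_off)
  draws <- matrix(0L, n_resample, nb)
  for (r in seq_len(n_resample)) {
    draws[r, ] <- tabulate(sample(bg_bins, n_q, replace = replace),
                           nbins = nb)
  }
  prof <- tibble(
    offset = (head(breaks, -1) + tail(breaks, -1)) / 2,
    observed = obs,
    bg_mean = colMeans(draws),
    bg_lo = apply(draws, 2, quantile, probs = 0.005),
    bg_hi = apply(draws, 2, quantile, probs = 0.995))
  structure(prof, class = c("enrichment_profile", class(prof)),
            n_qtl = n_q, n_background = length(bg_off), bin = bin,
            n_resample = n_resample)
}

#' Peak offsets of an enrichment profile
#'
#' @param profile An [positional_enrichment()] result.
#' @param side `"both"` (default), `"negative"` or `"positive"`:
#'   restrict the search to one flank.
#' @return The offset of the maximum observed bin on the requested
#'   side(s) (leftmost on ties).
#' @export
profile_peak <- function(profile, side = c("both", "negative", "positive")) {
  side <- match.arg(side)
  df <- switch(side,
               both = profile,
               negative = profile[profile$offset < 0, ],
               positive = profile[profile$offset > 0, ])
  df$offset[which.max(df$observed)]
}

#' Assign midpoint-relative offsets to bipartite architecture regions
#'
#' Partitions the +/- `span` window of an element into: `center`
#' (midpoint +/- 25 bp), `core` (each nTSS +/- 25 bp), `ncnc`
#' (non-center-non-core space between them inside the element), `out`
#' (outside the cores but within the element bounds plus `out_margin`),
#' and `far_out` (beyond, up to `span`).  Precedence where regions
#' touch: center > core > ncnc > out > far_out, so the center wins at
#' narrow elements whose cores overlap it.
#'
#' @param offset Integer vector of midpoint-relative offsets
#'   (|offset| <= span).
#' @param minus_off,plus_off nTSS offsets relative to the midpoint
#'   (e.g. -70 and 70).
#' @param center_halfwidth,core_halfwidth Half-widths in bp (default 25
#'   each).
#' @param out_margin Margin beyond the outermost nTSS before `far_out`
#'   begins (default 200).
#' @param span Window half-width (default 2000).
#' @return Character vector of region labels.
#' @export
classify_region <- function(offset, minus_off, plus_off,
                            center_halfwidth = 25, core_halfwidth = 25,
                            out_margin = 200, span = 2000) {
  if (any(abs(offset) > span)) abort("offsets beyond the test window")
  in_center <- abs(offset) <= center_halfwidth
  in_core <- abs(offset - plus_off) <= core_halfwidth |
    abs(offset - minus_off) <= core_halfwidth
  inside <- offset >= minus_off & offset <= plus_off
  in_bounds <- offset >= minus_off - out_margin &
    offset <= plus_off + out_margin
  dplyr::case_when(
    in_center ~ "center",
    in_core ~ "core",
    inside ~ "ncnc",
    in_bounds ~ "out",
    TRUE ~ "far_out")
}

#' Per-region QTL frequency with Fisher tests against far_out
#'
#' Computes the QTL frequency (QTL SNPs / all SNPs) in each
#' architecture region and compares each region to `far_out` with a
#' two-sided Fisher's exact test on the 2x2 (region vs far_out) x
#' (QTL vs not) table.
#'
#' @param snps Tibble of background SNPs with a `region` column (see
#'   [classify_region()]) and a logical `is_qtl` column.
#' @return Tibble with `region`, `n_snps`, `n_qtls`, `frequency`,
#'   `odds_ratio`, `p` (NA for `far_out` itself); tests are skipped
#'   (NA) when there are no QTLs at all.
#' @export
regional_frequency_test <- function(snps) {
  counts <- dplyr::summarise(dplyr::group_by(snps, .data$region),
                             n_snps = dplyr::n(),
                             n_qtls = sum(.data$is_qtl), .groups = "drop")
  if (!"far_out" %in% counts$region) abort("no SNPs in the far_out region")
  counts$frequency <- counts$n_qtls / counts$n_snps
  fo <- counts[counts$region == "far_out", ]
  res <- lapply(seq_len(nrow(counts)), function(i) {
    if (counts$region[i] == "far_out" || sum(counts$n_qtls) == 0)
      return(list(or = NA_real_, p = NA_real_))
    tab <- matrix(c(counts$n_qtls[i], counts$n_snps[i] - counts$n_qtls[i],
                    fo$n_qtls, fo$n_snps - fo$n_qtls), nrow = 2,
                  byrow = TRUE)
    ft <- fisher.test(tab, alternative = "two.sided")
    list(or = unname(ft$estimate), p = ft$p.value)
  })
  counts$odds_ratio <- vapply(res, `[[`, numeric(1), "or")
  counts$p <- vapply(res, `[[`, numeric(1), "p")
  region_order <- c("center", "core", "ncnc", "out", "far_out")
  counts[order(match(counts$region, region_order)), ]
}

#' Overlap enrichment of a QTL element set against a background set
#'
#' Fold enrichment is the ratio of annotation-overlap rates between the
#' QTL-bearing and background element sets, with a two-sided Fisher's
#' exact test.
#'
#' @param qtl_elements Character vector of element ids with a QTL.
#' @param annotation_elements Elements carrying the annotation of
#'   interest.
#' @param background_elements Background element set (non-empty).
#' @return Tibble with overlap counts, rates, `fold` and `p`.
#' @export
overlap_enrichment <- function(qtl_elements, annotation_elements,
                               background_elements) {
  if (length(background_elements) == 0) abort("empty background set")
  q_in <- sum(qtl_elements %in% annotation_elements)
  b_in <- sum(background_elements %in% annotation_elements)
  rate_q <- q_in / length(qtl_elements)
  rate_b <- b_in / length(background_elements)
  tab <- matrix(c(q_in, length(qtl_elements) - q_in,
                  b_in, length(background_elements) - b_in),
                nrow = 2, byrow = TRUE)
  p <- fisher.test(tab, alternative = "two.sided")$p.value
  tibble(n_qtl = length(qtl_elements), qtl_overlap = q_in,
         n_background = length(background_elements),
         background_overlap = b_in,
         fold = ifelse(rate_b == 0, NA_real_, rate_q / rate_b), p = p)
}

#' QQ comparison of a p-value subset against the full distribution
#'
#' Produces -log10 quantile-quantile pairs of the subset against the
#' full set and a two-sided two-sample Kolmogorov-Smirnov test.
#'
#' @param p_subset,p_all Non-empty p-value vectors.
#' @return Object of class `qq_compare`: list with `points` (tibble
#'   `expected`, `observed` on the -log10 scale), `ks_stat`, `ks_p`.
#' @export
qq_compare <- function(p_subset, p_all) {
  if (length(p_subset) == 0 || length(p_all) == 0)
    abort("both p-value sets must be non-empty")
  probs <- stats::ppoints(length(p_subset))
  points <- tibble(
    expected = -log10(rev(quantile(p_all, probs, names = FALSE))),
    observed = -log10(rev(sort(p_subset))))
  ks <- suppressWarnings(ks.test(p_subset, p_all,
                                 alternative = "two.sided"))
  structure(list(points = points, ks_stat = unname(ks$statistic),
                 ks_p = ks$p.value),
            class = "qq_compare")
}

#' @export
print.qq_compare <- function(x, ...) {
  cat(sprintf("<qq_compare> KS D = %.4f, p = %.3g (%d quantiles)\n",
              x$ks_stat, x$ks_p, nrow(x$points)))
  invisible(x)
}

#' Element-gene co-expression across individuals
#'
#' Pearson correlation between element initiation phenotypes and gene
#' expression for every (element, gene) pair within `pairs_within` bp,
#' with the signed distance from the gene TSS to the element midpoint
#' (negative = element upstream of the gene, relative to the gene's
#' strand).
#'
#' @param ttre_phenotypes Elements x individuals matrix.
#' @param ttres tTRE tibble (positions of the phenotype rows).
#' @param expression_matrix Genes x individuals matrix (matching
#'   columns).
#' @param genes Tibble with `gene`, `contig`, `position`, `strand`.
#' @param pairs_within Maximum pairing distance in bp (default 1e6).
#' @return Tibble with `element_id`, `gene`, `distance`, `r`.
#' @export
ttre_gene_correlation <- function(ttre_phenotypes, ttres,
                                  expression_matrix, genes,
                                  pairs_within = 1e6) {
  common <- intersect(colnames(ttre_phenotypes), colnames(expression_matrix))
  if (length(common) < 3) abort("need at least three shared individuals")
  pairs <- purrr::list_rbind(lapply(unique(ttres$contig), function(ct) {
    ti <- which(ttres$contig == ct)
    gi <- which(genes$contig == ct)
    if (length(ti) == 0 || length(gi) == 0) return(NULL)
    grid <- tidyr::expand_grid(t = ti, g = gi)
    d <- ttres$midpoint[grid$t] - genes$position[grid$g]
    d <- ifelse(genes$strand[grid$g] == "-", -d, d)
    grid$distance <- as.integer(d)
    grid[abs(grid$distance) <= pairs_within, ]
  }))
  if (is.null(pairs) || nrow(pairs) == 0)
    return(tibble(element_id = character(), gene = character(),
                  distance = integer(), r = numeric()))
  x <- ttre_phenotypes[, common, drop = FALSE]
  y <- expression_matrix[, common, drop = FALSE]
  r <- vapply(seq_len(nrow(pairs)), function(i)
    cor(x[pairs$t[i], ], y[pairs$g[i], ]), numeric(1))
  tibble(element_id = ttres$id[pairs$t], gene = genes$gene[pairs$g],
         distance = pairs$distance, r = r)
}
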