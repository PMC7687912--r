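# Phenotype normalization: depth (RPM) scaling, a median-of-ratios
# reference distribution, quantile normalization onto it, and the
# directionality index.

#' Reads-per-million normalization over element windows
#'
#' Divides raw window counts by each sample's total element-window
#' counts in millions: `value = count / (total / 1e6)`.
#'
#' @param window_counts Elements x samples count matrix.
#' @param totals Per-sample totals; defaults to the column sums of
#'   `window_counts`.
#' @return Matrix of RPM values.
#' @export
rpm_normalize <- function(window_counts, totals = colSums(window_counts)) {
  if (any(totals <= 0)) abort("per-sample totals must be positive")
  sweep(window_counts, 2, totals / 1e6, "/")
}

#' Median-of-ratios size factors and reference distribution
#'
#' For each element, computes the ratio of each sample's count to the
#' element's mean count across samples; a sample's size factor is the
#' median of its ratios (rows that are all zero are excluded from the
#' factor computation).  The reference distribution is obtained by
#' scaling each sample by its factor, sorting each column, and averaging
#' across samples at each rank.
#'
#' @param mat Elements x samples matrix (at least two samples).
#' @return List with `size_factors` (per sample) and `reference`
#'   (sorted vector, one value per element rank).
#' @export
median_of_ratios_reference <- function(mat) {
  if (ncol(mat) < 2) abort("need at least two samples")
  if (any(colSums(mat != 0) == 0)) abort("a sample has all-zero counts")
  nonzero <- rowSums(mat != 0) > 0
  work <- mat[nonzero, , drop = FALSE]
  rowmean <- rowMeans(work)
  ratios <- work / rowmean
  size_factors <- apply(ratios, 2, median)
  scaled <- sweep(mat, 2, size_factors, "/")
  sorted <- apply(scaled, 2, sort)
  if (is.null(dim(sorted))) sorted <- matrix(sorted, nrow = 1)
  reference <- rowMeans(sorted)
  list(size_factors = size_factors, reference = reference)
}

.qn_column <- function(x, ref_sorted) {
  # ranks by first-occurrence, then average assigned reference values
  # within tie groups (deterministic tie handling)
  out <- ref_sorted[rank(x, ties.method = "first")]
  stats::ave(out, match(x, x), FUN = mean)
}

#' Quantile-normalize each sample onto a reference distribution
#'
#' Each column's values are replaced by the reference values at matching
#' ranks; tied input values receive the mean of the tied reference
#' values.  After normalization every column's sorted values equal the
#' sorted reference exactly (up to tie averaging), and the operation is
#' idempotent.
#'
#' @param mat Elements x samples matrix.
#' @param reference Numeric vector of length `nrow(mat)`; typically the
#'   `reference` element of [median_of_ratios_reference()].
#' @return Matrix of class-free quantile-normalized values with the
#'   `kind` attribute unset; see [phenotype_matrix()] for the assembled
#'   phenotype object.
#' @export
quantile_normalize <- function(mat, reference) {
  if (length(reference) != nrow(mat))
    abort("reference length must equal the number of rows")
  ref_sorted <- sort(reference)
  out <- apply(mat, 2, .qn_column, ref_sorted = ref_sorted)
  dimnames(out) <- dimnames(mat)
  out
}

#' Directionality index
#'
#' `DI = log2((plus + pseudocount) / (minus + pseudocount))`, the
#' log-ratio of plus-strand (midpoint-relative offsets 1..250) to
#' minus-strand (-250..0) window counts.  Positive values mean
#' plus-dominant initiation; swapping strands negates the index exactly.
#'
#' @param plus_window_count,minus_window_count Count matrices or
#'   vectors.
#' @param pseudocount Added to both counts (default 1); must be positive
#'   if any count is zero.
#' @return Directionality index values, same shape as the inputs.
#' @export
directionality_index <- function(plus_window_count, minus_window_count,
                                 pseudocount = 1) {
  if (pseudocount == 0 &&
      (any(plus_window_count == 0) || any(minus_window_count == 0)))
    abort("pseudocount must be positive when counts contain zeros")
  log2((plus_window_count + pseudocount) /
         (minus_window_count + pseudocount))
}

#' Assemble a normalized phenotype matrix
#'
#' For `kind = "level"`: plus and minus window counts are summed,
#' RPM-normalized per sample, and quantile-normalized onto the
#' median-of-ratios reference distribution of the RPM matrix.  For
#' `kind = "directionality"`: the directionality index is computed from
#' the raw counts (the ratio cancels depth) and quantile-normalized onto
#' the rank-wise mean of the sorted columns.
#'
#' @param window_counts Result of [count_ttre_windows()] (list with
#'   `plus` and `minus` matrices).
#' @param kind `"level"` or `"directionality"`.
#' @param pseudocount Pseudocount for the directionality index
#'   (default 1).
#' @return Elements x individuals matrix with attribute
#'   `kind`; no missing values.
#' @export
phenotype_matrix <- function(window_counts,
                             kind = c("level", "directionality"),
                             pseudocount = 1) {
  kind <- match.arg(kind)
  if (kind == "level") {
    total <- window_counts$plus + window_counts$minus
    rpm <- rpm_normalize(total)
    ref <- median_of_ratios_reference(rpm)$reference
    out <- quantile_normalize(rpm, ref)
  } else {
    di <- directionality_index(window_counts$plus, window_counts$minus,
                               pseudocount)
    ref <- rowMeans(apply(di, 2, sort))
    out <- quantile_normalize(di, ref)
  }
  attr(out, "kind") <- kind
  out
}

#' Average replicate columns down to one column per individual
#'
#' @param mat Elements x samples matrix.
#' @param samples Sample sheet (see [sim_samples()]) with `sample` and
#'   `individual`.
#' @return Elements x individuals matrix (mean across a sample's
#'   libraries).
#' @export
collapse_replicates <- function(mat, samples) {
  ind <- unique(samples$individual)
  out <- vapply(ind, function(i) {
    cols <- samples$sample[samples$individual == i]
    rowMeans(mat[, cols, drop = FALSE])
  }, numeric(nrow(mat)))
  dimnames(out) <- list(rownames(mat), ind)
  attr(out, "kind") <- attr(mat, "kind")
  out
}
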