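# Variably expressed elements: replicate-based rank-sum test and
# estimation of the variable fraction from the p-value distribution.

#' Test each element for variable expression across individuals
#'
#' For each element, compares absolute deviations from the pair mean
#' within replicate pairs against absolute deviations of individuals
#' from the across-sample mean, with a one-sided Wilcoxon rank-sum test
#' of the alternative that between-sample deviations are greater than
#' between-replicate deviations.  Computed on the quantile-normalized
#' phenotype matrix.
#'
#' @param phenotype_matrix Elements x samples matrix (replicate columns
#'   included).
#' @param pairing Tibble with columns `sample` and `replicate` naming
#'   pairs of columns that are technical/biological replicates of the
#'   same individual.
#' @return Tibble with `element` and `p`.
#' @export
variable_expression_test <- function(phenotype_matrix, pairing) {
  if (nrow(pairing) < 2) abort("need at least two replicate pairs")
  cols <- colnames(phenotype_matrix)
  if (!all(c(pairing$sample, pairing$replicate) %in% cols))
    abort("pairing references unknown columns")
  sample_cols <- setdiff(cols, pairing$replicate)
  if (length(sample_cols) < 3) abort("need at least three distinct samples")
  p <- vapply(seq_len(nrow(phenotype_matrix)), function(i) {
    x <- phenotype_matrix[i, ]
    rep_dev <- as.numeric(vapply(seq_len(nrow(pairing)), function(j) {
      pair <- x[c(pairing$sample[j], pairing$replicate[j])]
      abs(pair - mean(pair))
    }, numeric(2)))
    xs <- x[sample_cols]
    samp_dev <- abs(xs - mean(xs))
    if (all(c(rep_dev, samp_dev) == c(rep_dev, samp_dev)[1])) return(1)
    suppressWarnings(
      wilcox.test(samp_dev, rep_dev, alternative = "greater",
                  exact = FALSE, correct = TRUE)$p.value)
  }, numeric(1))
  tibble(element = rownames(phenotype_matrix) %||%
           as.character(seq_len(nrow(phenotype_matrix))), p = p)
}

#' Estimate the fraction of truly variable elements
#'
#' Storey-style estimator of the null proportion: the density of the
#' uniform portion of the p-value distribution, estimated as the mean
#' over a lambda grid of `#{p > lambda} / ((1 - lambda) * m)`, clipped
#' to `[0, 1]`.  The variable fraction is `1 - pi0`.
#'
#' @param pvals Vector of p-values in `[0, 1]`.
#' @param lambda_grid Grid of tail cutoffs (default `seq(0.5, 0.9, 0.1)`).
#' @return List with `pi0` and `fraction_variable`.
#' @export
estimate_variable_fraction <- function(pvals,
                                       lambda_grid = seq(0.5, 0.9, 0.1)) {
  if (length(pvals) == 0) abort("empty p-value vector")
  if (any(pvals < 0 | pvals > 1)) abort("p-values must lie in [0, 1]")
  m <- length(pvals)
  pi0 <- mean(vapply(lambda_grid,
                     function(l) sum(pvals > l) / ((1 - l) * m),
                     numeric(1)))
  pi0 <- min(max(pi0, 0), 1)
  list(pi0 = pi0, fraction_variable = 1 - pi0)
}
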