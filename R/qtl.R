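# cis-QTL mapping: PC covariates, vectorized OLS association, BH FDR,
# and the staggered-window local-minimum filter for likely-primary SNPs.

#' Principal-component covariates of a phenotype matrix
#'
#' Computes principal components over individuals from the
#' element-centered phenotype matrix via SVD.  Returned columns are
#' orthonormal individual scores with a deterministic sign convention:
#' the largest-magnitude loading of each component is positive.
#'
#' @param phenotype_matrix Elements x individuals matrix.
#' @param k Number of components (must be positive and less than the
#'   number of individuals).
#' @return Individuals x k matrix with orthonormal columns, plus an
#'   attribute `var_explained` (fraction of variance per component).
#' @export
compute_pcs <- function(phenotype_matrix, k) {
  if (k <= 0) abort("k must be positive")
  n <- ncol(phenotype_matrix)
  if (k >= n) abort("k must be less than the number of individuals")
  x <- t(phenotype_matrix - rowMeans(phenotype_matrix))
  sv <- svd(x, nu = k, nv = k)
  u <- sv$u
  for (j in seq_len(k)) {
    piv <- which.max(abs(sv$v[, j]))
    if (sv$v[piv, j] < 0) {
      u[, j] <- -u[, j]
      sv$v[, j] <- -sv$v[, j]
    }
  }
  rownames(u) <- colnames(phenotype_matrix)
  attr(u, "var_explained") <- (sv$d^2 / sum(sv$d^2))[seq_len(k)]
  u
}

.residualizer <- function(n, covariates = NULL) {
  # orthonormal basis of the intercept + covariate space
  x <- cbind(rep(1, n), covariates)
  qr.Q(qr(x))
}

.residualize <- function(v, basis) {
  v - basis %*% crossprod(basis, v)
}

#' Single variant-phenotype association by OLS
#'
#' Ordinary least squares of the phenotype on the allele dosage with
#' covariates: the dosage coefficient after residualizing both sides on
#' the covariates (plus intercept), its standard error, t statistic,
#' and two-sided p-value from the t distribution with `n - k - 2`
#' degrees of freedom (`k` covariates).
#'
#' @param dosage_vector Numeric dosages (0/1/2), non-constant.
#' @param phenotype_vector Numeric phenotype, same length.
#' @param covariates Optional individuals x k covariate matrix.
#' @return Tibble with `beta`, `se`, `t`, `p`, `df`.
#' @export
cis_association <- function(dosage_vector, phenotype_vector,
                            covariates = NULL) {
  n <- length(dosage_vector)
  k <- if (is.null(covariates)) 0L else ncol(covariates)
  if (n < k + 3) abort("too few individuals for the model")
  if (sd(dosage_vector) == 0) abort("constant dosage")
  basis <- .residualizer(n, covariates)
  g <- .residualize(dosage_vector, basis)
  y <- .residualize(phenotype_vector, basis)
  sgg <- sum(g^2)
  beta <- sum(g * y) / sgg
  df <- n - k - 2
  rss <- sum(y^2) - beta^2 * sgg
  se <- sqrt(max(rss, 0) / df / sgg)
  t <- beta / se
  tibble(beta = beta, se = se, t = t, p = 2 * pt(-abs(t), df), df = df)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up BH adjustment; q-values are monotone non-decreasing in p and
#' never smaller than p.
#'
#' @param pvals Vector of p-values in `[0, 1]`.
#' @return Vector of q-values in the input order.
#' @export
bh_fdr <- function(pvals) {
  p.adjust(pvals, method = "BH")
}

#' Map cis-QTLs between a genotype table and a phenotype matrix
#'
#' Tests every variant-element pair whose distance (variant position to
#' element midpoint) is at most `window`, using OLS with the supplied
#' principal-component covariates, then applies Benjamini-Hochberg
#' correction across all tests of the run.  Constant-dosage pairs are
#' skipped with a `skipped` flag rather than tested.  Missing dosages
#' are mean-imputed per variant beforehand.
#'
#' Defaults follow common practice for this assay: a 2-kb window and
#' FDR 0.1 for initiation-level (ti) and directionality (di)
#' phenotypes; use `window = 2e5, fdr = 0.05` for expression (e).
#'
#' @param genotypes A [genotype_table()].
#' @param phenotypes Elements x individuals matrix (see
#'   [phenotype_matrix()]); column names must match genotype samples.
#' @param element_positions Tibble with `id`, `contig`, `midpoint` for
#'   each phenotype row.
#' @param type Phenotype type label: `"ti"`, `"di"` or `"e"`.
#' @param window cis window in bp (default 2000).
#' @param fdr Significance threshold on q (default 0.1).
#' @param n_pcs Number of phenotype PCs used as covariates (default 0).
#' @param covariates Optional explicit covariate matrix overriding
#'   `n_pcs`.
#' @return Object of class `qtl_result`: list with `records` (tibble of
#'   all tested pairs: `variant_id`, `element_id`, `type`, `beta`,
#'   `se`, `t`, `p`, `q`, `distance`, `significant`), `n_tests`, `fdr`,
#'   `type`, `window`, `n_pcs`.
#' @export
map_cis_qtls <- function(genotypes, phenotypes, element_positions,
                         type = "ti", window = 2000, fdr = 0.1,
                         n_pcs = 0, covariates = NULL) {
  genotypes <- impute_dosages(genotypes)
  samples <- colnames(phenotypes)
  if (!all(samples %in% colnames(genotypes$dosages)))
    abort("phenotype columns missing from the genotype table")
  dos <- genotypes$dosages[, samples, drop = FALSE]
  v <- genotypes$variants
  if (is.null(covariates) && n_pcs > 0)
    covariates <- compute_pcs(phenotypes, n_pcs)
  n <- length(samples)
  k <- if (is.null(covariates)) 0L else ncol(covariates)
  basis <- .residualizer(n, covariates)

  # pair variants with elements within the cis window, per contig
  pairs <- purrr::list_rbind(lapply(
    split(seq_len(nrow(element_positions)), element_positions$contig),
    function(ei) {
      ct <- element_positions$contig[ei[1]]
      vi <- which(v$contig == ct)
      if (length(vi) == 0) return(NULL)
      grid <- tidyr::expand_grid(e = ei, vv = vi)
      grid$distance <- v$pos[grid$vv] -
        element_positions$midpoint[grid$e]
      grid[abs(grid$distance) <= window, ]
    }))
  if (is.null(pairs) || nrow(pairs) == 0) {
    warn("no variant-element pairs within the cis window")
    records <- tibble(variant_id = character(), element_id = character(),
                      type = character(), beta = numeric(), se = numeric(),
                      t = numeric(), p = numeric(), q = numeric(),
                      distance = integer(), significant = logical(),
                      skipped = logical())
    return(structure(list(records = records, n_tests = 0L, fdr = fdr,
                          type = type, window = window, n_pcs = k),
                     class = "qtl_result"))
  }

  yres <- apply(phenotypes, 1, .residualize, basis = basis)  # n x elements
  gres <- apply(dos, 1, .residualize, basis = basis)         # n x variants
  gnorm <- colSums(gres^2)
  df <- n - k - 2

  gi <- pairs$vv
  ei <- pairs$e
  skipped <- apply(dos[gi, , drop = FALSE], 1, sd) == 0
  sgg <- gnorm[gi]
  sgy <- colSums(gres[, gi, drop = FALSE] * yres[, ei, drop = FALSE])
  syy <- colSums(yres[, ei, drop = FALSE]^2)
  beta <- sgy / sgg
  rss <- pmax(syy - beta^2 * sgg, 0)
  se <- sqrt(rss / df / sgg)
  t <- beta / se
  p <- 2 * pt(-abs(t), df)
  beta[skipped] <- se[skipped] <- t[skipped] <- p[skipped] <- NA_real_
  q <- rep(NA_real_, length(p))
  q[!skipped] <- bh_fdr(p[!skipped])
  records <- tibble(
    variant_id = v$id[gi],
    element_id = element_positions$id[ei],
    type = type, beta = beta, se = se, t = t, p = p, q = q,
    distance = as.integer(pairs$distance),
    significant = !is.na(q) & q < fdr,
    skipped = skipped)
  structure(list(records = records, n_tests = sum(!skipped), fdr = fdr,
                 type = type, window = window, n_pcs = k),
            class = "qtl_result")
}

#' @export
print.qtl_result <- function(x, ...) {
  cat(sprintf(
    "<qtl_result> type=%s: %d tests, %d significant at FDR %.2g (%d PCs)\n",
    x$type, x$n_tests, sum(x$records$significant), x$fdr, x$n_pcs))
  invisible(x)
}

#' @describeIn map_cis_qtls Tidy the per-pair association records.
#' @param x A `qtl_result`.
#' @param ... Unused.
#' @method tidy qtl_result
#' @export
tidy.qtl_result <- function(x, ...) {
  x$records
}

#' @describeIn map_cis_qtls One-row summary of a mapping run.
#' @method glance qtl_result
#' @export
glance.qtl_result <- function(x, ...) {
  tibble(type = x$type, n_tests = x$n_tests,
         n_significant = sum(x$records$significant),
         n_variants = dplyr::n_distinct(x$records$variant_id),
         n_elements = dplyr::n_distinct(x$records$element_id),
         fdr = x$fdr, window = x$window, n_pcs = x$n_pcs)
}

#' Scan the number of PC covariates and keep the most productive
#'
#' Re-runs [map_cis_qtls()] for each candidate number of PCs and
#' returns the run maximizing the number of significant associations
#' (smallest k on ties), mirroring the common practice of choosing the
#' covariate count that yields the most discoveries.
#'
#' @inheritParams map_cis_qtls
#' @param k_grid Candidate PC counts (default 0, 2, 4, ..., 20).
#' @return The winning `qtl_result`, with attribute `scan` (tibble of
#'   `n_pcs`, `n_significant`).
#' @export
scan_pc_covariates <- function(genotypes, phenotypes, element_positions,
                               type = "ti", window = 2000, fdr = 0.1,
                               k_grid = seq(0, 20, 2)) {
  k_grid <- k_grid[k_grid < ncol(phenotypes) - 3]
  runs <- lapply(k_grid, function(k)
    map_cis_qtls(genotypes, phenotypes, element_positions, type = type,
                 window = window, fdr = fdr, n_pcs = k))
  nsig <- vapply(runs, function(r) sum(r$records$significant), integer(1))
  best <- runs[[which.max(nsig)]]
  attr(best, "scan") <- tibble(n_pcs = k_grid, n_significant = nsig)
  best
}

#' Local-minimum p-value filter for likely-primary SNPs
#'
#' The genome is split into `window`-bp windows staggered by `stagger`
#' bp, so each SNP lies in `window / stagger` different windows.  In
#' each window only the SNP with the strictly lowest p-value is kept;
#' if two or more SNPs tie for the minimum, none is kept from that
#' window.  A SNP survives if it is the unique minimum in at least one
#' of its windows.  Where a SNP appears in several records (one per
#' associated element), its best p-value is used for the competition
#' and all records of surviving SNPs are returned.
#'
#' @param records QTL record tibble including `variant_id`, `p`, and
#'   positions (`contig`, `pos`); see [map_cis_qtls()] and
#'   [add_variant_positions()].
#' @param window Window size in bp (default 5000).
#' @param stagger Stagger in bp (default 1000).
#' @return The subset of `records` belonging to surviving SNPs.
#' @export
local_min_filter <- function(records, window = 5000, stagger = 1000) {
  if (nrow(records) == 0) return(records)
  if (!all(c("contig", "pos") %in% names(records)))
    abort("records need 'contig' and 'pos' columns; see add_variant_positions()")
  snp <- dplyr::summarise(
    dplyr::group_by(records, .data$variant_id, .data$contig, .data$pos),
    p = min(.data$p, na.rm = TRUE), .groups = "drop")
  n_win <- as.integer(window / stagger)
  memb <- tidyr::expand_grid(i = seq_len(nrow(snp)), j = seq_len(n_win) - 1L)
  memb$win <- (snp$pos[memb$i] %/% as.integer(stagger)) - memb$j
  memb$contig <- snp$contig[memb$i]
  memb$p <- snp$p[memb$i]
  winners <- dplyr::group_by(memb, .data$contig, .data$win)
  winners <- dplyr::filter(winners,
                           .data$p == min(.data$p),
                           sum(.data$p == min(.data$p)) == 1)
  keep <- unique(snp$variant_id[dplyr::pull(dplyr::ungroup(winners), "i")])
  records[records$variant_id %in% keep, , drop = FALSE]
}

#' Attach variant genomic positions to QTL records
#'
#' @param records QTL record tibble with `variant_id`.
#' @param genotypes A [genotype_table()].
#' @return `records` with `contig` and `pos` columns added.
#' @export
add_variant_positions <- function(records, genotypes) {
  dplyr::left_join(records,
                   dplyr::select(genotypes$variants, "id", "contig", "pos"),
                   by = c(variant_id = "id"))
}
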