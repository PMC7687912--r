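# Synthetic-data generator: genotypes in Hardy-Weinberg proportions,
# stranded 5'-count tracks with planted divergent elements and genetic
# effects on initiation level (ti), directionality (di) and gene
# expression (e), plus truth tables so every downstream stage is
# testable without external data.

#' Simulation configuration
#'
#' Defaults emulate the study conditions of a population-scale
#' nascent-transcription panel: 67 individuals with 8 replicate pairs,
#' divergent elements whose initiation cores sit 70 bp either side of
#' the midpoint, ~2-fold total initiation effects between homozygotes for
#' planted level (ti) variants, and additive log-odds shifts of the
#' plus/minus strand allocation for planted directionality (di) variants.
#'
#' @param n_individuals Number of individuals (default 67).
#' @param n_replicate_pairs Individuals with a second, independently
#'   drawn library (default 8).
#' @param genome_length Named integer vector of contig lengths
#'   (default `c(chr1 = 1e6)`).
#' @param n_ttres Number of planted divergent elements (default 100).
#' @param core_offset Distance in bp from element midpoint to each nTSS
#'   (default 70).
#' @param tss_spread Geometric-decay scale (bp) of read positions around
#'   each nTSS (default 10).
#' @param baseline_mean Mean read count per element per strand (default 100).
#' @param ttre_lognorm_sd Log-normal sd of element-to-element baseline
#'   variation (default 0.5).
#' @param dispersion Negative-binomial dispersion of total counts
#'   (variance = mu + dispersion * mu^2); 0 gives Poisson (default 0.2).
#' @param ti_fold_hom Total fold change in initiation between opposite
#'   homozygotes at a planted ti variant (default 2).
#' @param di_logit_shift Additive shift of the log-odds of plus-strand
#'   allocation per alternate allele at a planted di variant (default 1).
#' @param e_beta Expression effect per alternate allele at a planted
#'   e variant, in expression units (default 1).
#' @param e_noise_sd Gaussian noise sd of expression (default 1).
#' @param n_null_genes Genes with no planted effect (default 20).
#' @param maf_range Range of allele frequencies for background variants
#'   (default `c(0.05, 0.5)`).
#' @param planted_maf_range Allele-frequency range for planted variants;
#'   planted variants are common (default `c(0.2, 0.5)`) so that recovery
#'   measures method power rather than genotype-sampling noise.
#' @param n_variants Number of background variants (default 2000).
#' @param n_ti,n_di,n_e Numbers of planted ti/di/e variants, each
#'   targeting a distinct element (defaults 30, 30, 10).
#' @param qtl_jitter Planted ti variants sit within `qtl_jitter` bp of
#'   the midpoint and di variants within `qtl_jitter` bp of one nTSS
#'   (default 10).
#' @param mask_fraction Fraction of variant windows emitted as a
#'   mappability mask (default 0).
#' @param mask_halfwidth Half-width in bp of each masked window
#'   (default 50).
#' @param seed Integer seed; every `simulate_*` function derives its
#'   stream from it, so a fixed seed yields a byte-identical fixture set.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 67, n_replicate_pairs = 8,
                       genome_length = c(chr1 = 1e6), n_ttres = 100,
                       core_offset = 70, tss_spread = 10,
                       baseline_mean = 100, ttre_lognorm_sd = 0.5,
                       dispersion = 0.2, ti_fold_hom = 2,
                       di_logit_shift = 1, e_beta = 1, e_noise_sd = 1,
                       n_null_genes = 20,
                       maf_range = c(0.05, 0.5),
                       planted_maf_range = c(0.2, 0.5),
                       n_variants = 2000, n_ti = 30, n_di = 30, n_e = 10,
                       qtl_jitter = 10, mask_fraction = 0,
                       mask_halfwidth = 50, seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$n_individuals < 2) abort("n_individuals must be >= 2")
  if (cfg$core_offset < 1) abort("core_offset must be >= 1")
  for (f in c("n_ttres", "tss_spread", "baseline_mean", "n_variants"))
    if (cfg[[f]] <= 0) abort(sprintf("%s must be positive", f))
  if (cfg$dispersion < 0) abort("dispersion must be >= 0")
  if (cfg$n_ti + cfg$n_di + cfg$n_e > cfg$n_ttres)
    abort("planted QTLs exceed the number of elements")
  structure(cfg, class = "sim_config")
}

# deterministic per-stage RNG streams derived from config$seed
.sim_seed <- function(config, offset) {
  set.seed((config$seed * 7L + offset) %% .Machine$integer.max)
}

#' Lay out planted elements and QTLs (the simulation truth table)
#'
#' Elements are placed on a 5-kb grid so their +/-2 kb test windows do
#' not overlap; each has a minus-strand nTSS at midpoint - core_offset
#' and a plus-strand nTSS at midpoint + core_offset.  Planted ti
#' variants sit at the element center, di variants at one of the two
#' initiation cores, and e variants within 200 bp of the midpoint with
#' a target gene placed within 200 kb.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_truth` with tibbles `ttres`, `qtls`,
#'   `genes`.
#' @export
simulate_truth <- function(config) {
  .sim_seed(config, 0L)
  spacing <- 5000L
  slots_per_contig <- pmax(0L, as.integer(floor(config$genome_length / spacing)) - 1L)
  if (sum(slots_per_contig) < config$n_ttres)
    abort("genome too short for the requested number of non-overlapping elements")
  slot_contig <- rep(names(config$genome_length), slots_per_contig)
  slot_index <- unlist(lapply(slots_per_contig, seq_len), use.names = FALSE)
  pick <- sort(sample(length(slot_contig), config$n_ttres))
  midpoint <- as.integer(slot_index[pick] * spacing -
                           spacing %/% 2L +
                           sample(-200:200, config$n_ttres, replace = TRUE))
  ttres <- tibble(
    id = sprintf("ttre%04d", seq_len(config$n_ttres)),
    contig = slot_contig[pick],
    midpoint = midpoint,
    minus_pos = midpoint - as.integer(config$core_offset),
    plus_pos = midpoint + as.integer(config$core_offset),
    class = "enhancer")

  n_planted <- config$n_ti + config$n_di + config$n_e
  targets <- sample(config$n_ttres, n_planted)
  type <- rep(c("ti", "di", "e"), c(config$n_ti, config$n_di, config$n_e))
  tt <- ttres[targets, ]
  jit <- function(n) sample(seq(-config$qtl_jitter, config$qtl_jitter), n,
                            replace = TRUE)
  pos <- integer(n_planted)
  pos[type == "ti"] <- tt$midpoint[type == "ti"] + jit(config$n_ti)
  di_strand <- sample(c("+", "-"), config$n_di, replace = TRUE)
  pos[type == "di"] <- ifelse(di_strand == "+",
                              tt$plus_pos[type == "di"],
                              tt$minus_pos[type == "di"]) + jit(config$n_di)
  pos[type == "e"] <- tt$midpoint[type == "e"] +
    sample(-200:200, config$n_e, replace = TRUE)
  effect <- c(rep(config$ti_fold_hom, config$n_ti),
              rep(config$di_logit_shift, config$n_di),
              rep(config$e_beta, config$n_e))
  core_strand <- rep(NA_character_, n_planted)
  core_strand[type == "di"] <- di_strand
  qtls <- tibble(
    variant_id = sprintf("planted_%s_%s", type, tt$id),
    contig = tt$contig, pos = as.integer(pos),
    target = tt$id, type = type, effect = effect,
    core_strand = core_strand)

  e_q <- qtls[qtls$type == "e", ]
  genes <- tibble(
    gene = sprintf("gene%03d", seq_len(config$n_e + config$n_null_genes)),
    contig = c(e_q$contig,
               sample(names(config$genome_length), config$n_null_genes,
                      replace = TRUE)),
    position = as.integer(c(
      pmin(pmax(e_q$pos + sample(-2e5:2e5, config$n_e, replace = TRUE), 1L),
           config$genome_length[e_q$contig] - 1L),
      vapply(sample(names(config$genome_length), config$n_null_genes,
                    replace = TRUE),
             function(ct) sample.int(config$genome_length[[ct]] - 1L, 1L),
             integer(1)))),
    strand = sample(c("+", "-"), config$n_e + config$n_null_genes,
                    replace = TRUE),
    driver = c(e_q$variant_id, rep(NA_character_, config$n_null_genes)))

  structure(list(ttres = ttres, qtls = qtls, genes = genes),
            class = "sim_truth")
}

#' Simulate genotypes in Hardy-Weinberg proportions
#'
#' Background variants are placed uniformly over the contigs with allele
#' frequencies drawn from `maf_range`; dosages are independent
#' Binomial(2, f) draws per individual.  If a truth table is supplied,
#' its planted variants are appended at their stated positions with
#' frequencies from `planted_maf_range`.
#'
#' @param config A [sim_config()].
#' @param truth Optional [simulate_truth()] output.
#' @return A [genotype_table()].
#' @export
simulate_genotypes <- function(config, truth = NULL) {
  if (config$n_individuals < 2) abort("n_individuals must be >= 2")
  .sim_seed(config, 1L)
  contigs <- sample(names(config$genome_length), config$n_variants,
                    replace = TRUE,
                    prob = config$genome_length / sum(config$genome_length))
  pos <- vapply(contigs,
                function(ct) sample.int(config$genome_length[[ct]] - 1L, 1L),
                integer(1))
  f <- runif(config$n_variants, config$maf_range[1], config$maf_range[2])
  variants <- tibble(id = sprintf("var%05d", seq_len(config$n_variants)),
                     contig = contigs, pos = as.integer(pos),
                     ref = "A", alt = "G", f = f)
  if (!is.null(truth)) {
    fp <- runif(nrow(truth$qtls), config$planted_maf_range[1],
                config$planted_maf_range[2])
    variants <- bind_rows(
      variants,
      tibble(id = truth$qtls$variant_id, contig = truth$qtls$contig,
             pos = truth$qtls$pos, ref = "A", alt = "G", f = fp))
    variants <- variants[!duplicated(variants[c("contig", "pos")]), ]
  }
  dos <- matrix(rbinom(nrow(variants) * config$n_individuals, 2L,
                       rep(variants$f, config$n_individuals)),
                nrow = nrow(variants),
                dimnames = list(variants$id,
                                sprintf("ind%03d", seq_len(config$n_individuals))))
  genotype_table(dplyr::select(variants, -"f"), dos)
}

#' Sample-sheet for a simulated panel
#'
#' @param config A [sim_config()].
#' @return Tibble with `sample`, `individual`, `replicate`; the first
#'   `n_replicate_pairs` individuals contribute a second library.
#' @export
sim_samples <- function(config) {
  ind <- sprintf("ind%03d", seq_len(config$n_individuals))
  reps <- ind[seq_len(min(config$n_replicate_pairs, config$n_individuals))]
  tibble(
    sample = c(ind, paste0(reps, "_rep2")),
    individual = c(ind, reps),
    replicate = c(rep(1L, length(ind)), rep(2L, length(reps))))
}

# two-sided geometric scatter of read positions around an nTSS
.scatter <- function(n, spread) {
  if (n == 0) return(integer())
  off <- rgeom(n, prob = 1 / max(spread, 1))
  off * sample(c(-1L, 1L), n, replace = TRUE)
}

#' Simulate per-sample stranded 5'-count tracks
#'
#' For each element and library, the total read count is negative
#' binomial with mean `2 * baseline_mean * m`, where for a ti-target
#' `m = ti_fold_hom^(dosage/2)` (so opposite homozygotes differ by the
#' configured fold).  Reads are allocated to the plus strand with
#' probability `plogis(qlogis(0.5) + di_logit_shift * dosage)` for
#' di-targets (0.5 otherwise), preserving total initiation, and
#' scattered around the strand's nTSS with two-sided geometric decay of
#' scale `tss_spread`.  Replicate libraries are independent draws from
#' identical means.
#'
#' @param config A [sim_config()].
#' @param genotypes A [genotype_table()] containing the planted variants.
#' @param truth A [simulate_truth()] output.
#' @return Named list of [stranded_signal()] tibbles, one per sample
#'   (see [sim_samples()]).
#' @export
simulate_procap <- function(config, genotypes, truth) {
  .sim_seed(config, 2L)
  tt <- truth$ttres
  ok <- vapply(split(tt$midpoint, tt$contig), function(m) {
    length(m) < 2 || all(diff(sort(m)) > 2 * config$core_offset)
  }, logical(1))
  if (!all(ok)) abort("planted elements overlap")
  samples <- sim_samples(config)
  n_tt <- nrow(tt)

  # per-element baseline (shared across individuals)
  base <- config$baseline_mean *
    exp(rnorm(n_tt, 0, config$ttre_lognorm_sd) -
          config$ttre_lognorm_sd^2 / 2)

  # per-element planted effects, as dosage vectors over individuals
  q <- truth$qtls
  ti_var <- setNames(q$variant_id[q$type == "ti"], q$target[q$type == "ti"])
  di_var <- setNames(q$variant_id[q$type == "di"], q$target[q$type == "di"])
  di_str <- setNames(q$core_strand[q$type == "di"], q$target[q$type == "di"])
  dos <- genotypes$dosages

  size <- if (config$dispersion > 0) 1 / config$dispersion else Inf
  out <- vector("list", nrow(samples))
  names(out) <- samples$sample
  for (s in seq_len(nrow(samples))) {
    ind <- samples$individual[s]
    m <- rep(1, n_tt)
    iv <- ti_var[tt$id]
    has_ti <- !is.na(iv)
    m[has_ti] <- config$ti_fold_hom^(dos[iv[has_ti], ind] / 2)
    p <- rep(0.5, n_tt)
    dv <- di_var[tt$id]
    has_di <- !is.na(dv)
    shift <- ifelse(di_str[tt$id[has_di]] == "+", 1, -1) *
      config$di_logit_shift * dos[dv[has_di], ind]
    p[has_di] <- plogis(qlogis(0.5) + shift)

    mu <- 2 * base * m
    total <- if (is.finite(size)) rnbinom(n_tt, mu = mu, size = size)
             else stats::rpois(n_tt, mu)
    plus_n <- rbinom(n_tt, total, p)
    minus_n <- total - plus_n

    pos_plus <- rep(tt$plus_pos, plus_n) + .scatter(sum(plus_n), config$tss_spread)
    pos_minus <- rep(tt$minus_pos, minus_n) - .scatter(sum(minus_n), config$tss_spread)
    ctg_plus <- rep(tt$contig, plus_n)
    ctg_minus <- rep(tt$contig, minus_n)
    df <- dplyr::count(
      tibble(contig = c(ctg_plus, ctg_minus),
             position = as.integer(c(pos_plus, pos_minus)),
             strand = rep(c("+", "-"), c(length(pos_plus), length(pos_minus)))),
      .data$contig, .data$position, .data$strand, name = "count")
    out[[s]] <- stranded_signal(df$contig, df$position, df$strand, df$count)
  }
  attr(out, "samples") <- samples
  out
}

#' Simulate a gene-by-individual expression matrix
#'
#' Expression is `intercept + beta * dosage + N(0, e_noise_sd)` for
#' genes with a planted driver variant, and intercept plus noise for
#' null genes.
#'
#' @param config A [sim_config()].
#' @param genotypes A [genotype_table()].
#' @param truth A [simulate_truth()] output.
#' @param intercept Baseline expression (default 10).
#' @return List with `expression` (gene x individual matrix) and
#'   `genes` (tibble of gene TSS positions and strands).
#' @export
simulate_expression <- function(config, genotypes, truth, intercept = 10) {
  .sim_seed(config, 3L)
  genes <- truth$genes
  ind <- sprintf("ind%03d", seq_len(config$n_individuals))
  expr <- matrix(rnorm(nrow(genes) * length(ind), intercept,
                       config$e_noise_sd),
                 nrow = nrow(genes), dimnames = list(genes$gene, ind))
  has_driver <- !is.na(genes$driver)
  if (any(has_driver)) {
    beta <- truth$qtls$effect[match(genes$driver[has_driver],
                                    truth$qtls$variant_id)]
    expr[has_driver, ] <- expr[has_driver, , drop = FALSE] +
      beta * genotypes$dosages[genes$driver[has_driver], ind, drop = FALSE]
  }
  list(expression = expr, genes = genes)
}

#' Simulate an allele-mappability mask
#'
#' Emits a configurable fraction of variant-centered windows as mask
#' intervals (merged where overlapping).
#'
#' @param config A [sim_config()].
#' @param genotypes A [genotype_table()].
#' @param fraction Fraction of variants masked (default
#'   `config$mask_fraction`).
#' @return Tibble with `contig`, `start`, `end` (0-based half-open).
#' @export
simulate_mask <- function(config, genotypes, fraction = config$mask_fraction) {
  .sim_seed(config, 4L)
  v <- genotypes$variants
  n_pick <- round(fraction * nrow(v))
  if (n_pick == 0)
    return(tibble(contig = character(), start = integer(), end = integer()))
  pick <- v[sort(sample(nrow(v), n_pick)), ]
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    pick$contig,
    IRanges::IRanges(start = pmax(pick$pos - config$mask_halfwidth, 0L) + 1L,
                     end = pick$pos + config$mask_halfwidth + 1L)))
  tibble(contig = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr) - 1L,
         end = GenomicRanges::end(gr))
}

#' Drop elements overlapping a mask
#'
#' @param ttres tTRE tibble.
#' @param mask Mask tibble (`contig`, `start`, `end`).
#' @param pad Extra bp around the element span (default 0).
#' @return The unmasked subset of `ttres`.
#' @export
filter_masked_ttres <- function(ttres, mask, pad = 0) {
  if (nrow(mask) == 0 || nrow(ttres) == 0) return(ttres)
  tgr <- GenomicRanges::GRanges(
    ttres$contig,
    IRanges::IRanges(start = ttres$minus_pos - pad + 1L,
                     end = ttres$plus_pos + pad + 1L))
  mgr <- GenomicRanges::GRanges(
    mask$contig, IRanges::IRanges(start = mask$start + 1L, end = mask$end))
  hit <- GenomicRanges::countOverlaps(tgr, mgr) > 0
  ttres[!hit, , drop = FALSE]
}

#' Simulate a complete panel
#'
#' Runs [simulate_truth()], [simulate_genotypes()], [simulate_procap()],
#' [simulate_expression()] and [simulate_mask()] under the config's
#' seed.
#'
#' @param config A [sim_config()].
#' @return List of class `erna_sim` with elements `config`, `truth`,
#'   `genotypes`, `signals`, `expression`, `genes`, `mask`, `samples`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  truth <- simulate_truth(config)
  genotypes <- simulate_genotypes(config, truth)
  signals <- simulate_procap(config, genotypes, truth)
  expr <- simulate_expression(config, genotypes, truth)
  mask <- simulate_mask(config, genotypes)
  structure(list(config = config, truth = truth, genotypes = genotypes,
                 signals = signals, expression = expr$expression,
                 genes = expr$genes, mask = mask,
                 samples = attr(signals, "samples")),
            class = "erna_sim")
}

#' Write simulated genotypes as a plain-text VCF
#'
#' Minimal VCF v4.2 writer (GT field only), used to serialize synthetic
#' panels as text fixtures.
#'
#' @param genotypes A [genotype_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_vcf_genotypes <- function(genotypes, path) {
  v <- genotypes$variants
  d <- genotypes$dosages
  gt <- matrix(c("0/0", "0/1", "1/1")[d + 1L], nrow = nrow(d))
  gt[is.na(d)] <- "./."
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", colnames(d)), collapse = "\t"))
  body <- paste(v$contig, v$pos + 1L, v$id, v$ref, v$alt, ".", "PASS", ".",
                "GT", apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  ord <- order(v$contig, v$pos)
  writeLines(c(header, body[ord]), path)
  invisible(path)
}

#' Write a simulated panel to disk as text fixtures
#'
#' Writes the VCF, per-sample bedGraph pairs, element/mask/gene BED
#' files, the expression matrix and the truth tables.
#'
#' @param sim A [simulate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf_genotypes(sim$genotypes, file.path(dir, "genotypes.vcf"))
  for (nm in names(sim$signals)) {
    write_bedgraph_pair(sim$signals[[nm]],
                        file.path(dir, paste0(nm, "_plus.bedGraph")),
                        file.path(dir, paste0(nm, "_minus.bedGraph")))
  }
  tt <- dplyr::mutate(sim$truth$ttres,
                      width = .data$plus_pos - .data$minus_pos)
  write_bed_ttres(tt, file.path(dir, "truth_ttres.bed"))
  readr::write_tsv(sim$truth$qtls, file.path(dir, "truth_qtls.tsv"))
  readr::write_tsv(as_tibble(sim$expression, rownames = "gene"),
                   file.path(dir, "expression.tsv"))
  g <- sim$genes
  gene_bed <- GenomicRanges::GRanges(
    g$contig, IRanges::IRanges(start = g$position + 1L, width = 1L),
    name = g$gene, score = 0L, strand = g$strand)
  rtracklayer::export(gene_bed, file.path(dir, "gene_tss.bed"), format = "BED")
  if (nrow(sim$mask) > 0) {
    mgr <- GenomicRanges::GRanges(
      sim$mask$contig,
      IRanges::IRanges(start = sim$mask$start + 1L, end = sim$mask$end))
    rtracklayer::export(mgr, file.path(dir, "mask.bed"), format = "BED")
  }
  readr::write_tsv(sim$samples, file.path(dir, "samples.tsv"))
  invisible(dir)
}
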