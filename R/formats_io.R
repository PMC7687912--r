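# I/O for the standard formats the pipeline touches, plus the shared
# coordinate convention: all internal coordinates are 0-based half-open
# (BED convention).  VCF positions are converted on read.

#' Construct a stranded 5'-end signal table
#'
#' A stranded signal is a sparse per-base count track: one row per
#' (contig, position, strand) with a positive integer count of 5' read
#' ends.  Positions are 0-based.  The plus and minus strands are
#' independent tracks.
#'
#' @param contig Character vector of contig names.
#' @param position Integer vector of 0-based base positions.
#' @param strand Character vector, `"+"` or `"-"`.
#' @param count Non-negative counts of 5' read ends at each base.
#' @return A tibble of class `stranded_signal` with columns
#'   `contig`, `position`, `strand`, `count`, sorted by contig, strand
#'   and position.
#' @export
stranded_signal <- function(contig = character(), position = integer(),
                            strand = character(), count = numeric()) {
  if (!all(strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  if (any(count < 0)) abort("counts must be non-negative")
  out <- tibble(
    contig = as.character(contig),
    position = as.integer(position),
    strand = as.character(strand),
    count = as.numeric(count)
  )
  out <- dplyr::arrange(out, .data$contig, .data$strand, .data$position)
  class(out) <- c("stranded_signal", class(out))
  out
}

.check_bedgraph_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(ln) || grepl("^(track|browser|#)", ln)) next
    f <- strsplit(ln, "[ \t]+")[[1]]
    if (length(f) < 4 || anyNA(suppressWarnings(as.numeric(f[2:4]))))
      abort(sprintf("malformed bedGraph line %d in '%s': %s", i, path, ln))
  }
  invisible(TRUE)
}

.read_bedgraph_strand <- function(path, strand, negated = FALSE) {
  .check_bedgraph_lines(path)
  gr <- try(rtracklayer::import(path, format = "bedGraph"), silent = TRUE)
  if (inherits(gr, "try-error")) {
    # empty files (or header-only) import as zero records
    info <- file.info(path)
    if (!is.na(info$size) && info$size == 0) {
      gr <- GenomicRanges::GRanges()
      S4Vectors::mcols(gr)$score <- numeric()
    } else {
      abort(sprintf("failed to read bedGraph '%s'", path))
    }
  }
  if (length(gr) == 0) {
    return(tibble(contig = character(), position = integer(),
                  strand = character(), count = numeric()))
  }
  score <- S4Vectors::mcols(gr)$score
  if (negated) score <- -score
  if (any(score < 0))
    abort(sprintf("negative counts in '%s' (is the minus-strand dialect 'negated'?)", path))
  if (!GenomicRanges::isDisjoint(gr))
    abort(sprintf("overlapping intervals in '%s'", path))
  widths <- GenomicRanges::width(gr)
  # expand half-open intervals to per-base 0-based positions
  tibble(
    contig = rep(as.character(GenomicRanges::seqnames(gr)), widths),
    position = unlist(lapply(seq_along(gr), function(i) {
      seq.int(GenomicRanges::start(gr)[i] - 1L,
              GenomicRanges::end(gr)[i] - 1L)
    }), use.names = FALSE),
    strand = strand,
    count = rep(score, widths)
  )
}

#' Read a pair of strand-specific bedGraph tracks
#'
#' Reads one bedGraph file per strand and expands the intervals into a
#' sparse per-base [stranded_signal()].  Total signal is conserved.  The
#' minus-strand file may store negated values (a common browser dialect);
#' set `minus_dialect = "negated"` in that case.
#'
#' @param path_plus,path_minus Paths to the plus- and minus-strand
#'   bedGraph files.
#' @param minus_dialect `"positive"` (default) if the minus file stores
#'   positive counts, `"negated"` if values are negated.
#' @return A [stranded_signal()] tibble.
#' @export
read_bedgraph_pair <- function(path_plus, path_minus,
                               minus_dialect = c("positive", "negated")) {
  minus_dialect <- match.arg(minus_dialect)
  plus <- .read_bedgraph_strand(path_plus, "+")
  minus <- .read_bedgraph_strand(path_minus, "-",
                                 negated = minus_dialect == "negated")
  both <- bind_rows(plus, minus)
  both <- dplyr::filter(both, .data$count > 0)
  stranded_signal(both$contig, both$position, both$strand, both$count)
}

.collapse_runs <- function(df) {
  # collapse consecutive equal-count bases into half-open intervals
  df <- dplyr::arrange(df, .data$contig, .data$position)
  if (nrow(df) == 0)
    return(tibble(contig = character(), start = integer(),
                  end = integer(), count = numeric()))
  brk <- c(TRUE, diff(df$position) != 1L |
                  df$count[-1] != df$count[-nrow(df)] |
                  df$contig[-1] != df$contig[-nrow(df)])
  grp <- cumsum(brk)
  dplyr::summarise(dplyr::group_by(df, grp = grp),
                   contig = .data$contig[1],
                   start = min(.data$position),
                   end = max(.data$position) + 1L,
                   count = .data$count[1], .groups = "drop")[, -1]
}

#' Write a stranded signal as a pair of bedGraph files
#'
#' Inverse of [read_bedgraph_pair()]: per-base counts are collapsed into
#' maximal equal-count intervals and written as bedGraph, one file per
#' strand.
#'
#' @param signal A [stranded_signal()].
#' @param path_plus,path_minus Output paths.
#' @param minus_dialect Write minus counts as positive values (default)
#'   or negated.
#' @return Invisibly, the two paths.
#' @export
write_bedgraph_pair <- function(signal, path_plus, path_minus,
                                minus_dialect = c("positive", "negated")) {
  minus_dialect <- match.arg(minus_dialect)
  for (s in c("+", "-")) {
    path <- if (s == "+") path_plus else path_minus
    runs <- .collapse_runs(signal[signal$strand == s, ])
    score <- runs$count
    if (s == "-" && minus_dialect == "negated") score <- -score
    if (nrow(runs) == 0) {
      writeLines(character(), path)
    } else {
      gr <- GenomicRanges::GRanges(
        runs$contig, IRanges::IRanges(start = runs$start + 1L, end = runs$end),
        score = score)
      rtracklayer::export(gr, path, format = "bedGraph")
    }
  }
  invisible(c(path_plus, path_minus))
}

#' Construct a genotype table
#'
#' @param variants Tibble with columns `id`, `contig`, `pos` (0-based),
#'   `ref`, `alt`.
#' @param dosages Integer matrix, variants x individuals, values in
#'   {0, 1, 2, NA}; rownames are variant ids.
#' @return A `genotype_table`: list with elements `variants` (tibble,
#'   including per-variant `maf`), `dosages` and `samples`.
#' @export
genotype_table <- function(variants, dosages) {
  stopifnot(nrow(variants) == nrow(dosages))
  if (is.null(colnames(dosages)))
    colnames(dosages) <- paste0("ind", seq_len(ncol(dosages)))
  rownames(dosages) <- variants$id
  f <- rowMeans(dosages, na.rm = TRUE) / 2
  variants$maf <- pmin(f, 1 - f)
  structure(list(variants = as_tibble(variants), dosages = dosages,
                 samples = colnames(dosages)),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("<genotype_table> %d variants x %d individuals\n",
              nrow(x$dosages), ncol(x$dosages)))
  print(utils::head(x$variants, 5))
  invisible(x)
}

#' Read diploid genotype dosages from a VCF
#'
#' Parses the GT field of a VCF into an alternate-allele dosage matrix.
#' Multi-allelic records are skipped with a warning; variants with minor
#' allele frequency not exceeding `maf_min` are dropped (the default
#' keeps variants with MAF greater than 5%).  Missing genotypes become
#' missing dosages.
#'
#' @param path Path to a VCF (v4.x) file with a GT field.
#' @param maf_min Minimum minor-allele frequency (exclusive); default 0.05.
#' @return A [genotype_table()].  Positions are converted to 0-based.
#' @export
read_vcf_dosages <- function(path, maf_min = 0.05) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (ncol(vcf@gt) < 2) abort("VCF has no sample columns")
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT %||% "")
  if (any(multi)) {
    warn(sprintf("skipping %d multi-allelic record(s)", sum(multi)))
    vcf <- vcf[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  dos <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                dimnames = dimnames(gt))
  alleles <- gsub("[|/]", "", gt)
  ok <- !is.na(gt) & !grepl("\\.", gt)
  dos[ok] <- stringr::str_count(alleles[ok], "1")
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <-
    paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  variants <- tibble(
    id = ids, contig = fix$CHROM, pos = as.integer(fix$POS) - 1L,
    ref = fix$REF, alt = fix$ALT)
  gtab <- genotype_table(variants, dos)
  keep <- !is.na(gtab$variants$maf) & gtab$variants$maf > maf_min
  gtab$variants <- gtab$variants[keep, , drop = FALSE]
  gtab$dosages <- gtab$dosages[keep, , drop = FALSE]
  gtab
}

#' Mean-impute missing dosages
#'
#' Missing dosages are replaced by the per-variant mean of the observed
#' dosages (standard matrix-QTL practice); the fraction imputed is
#' reported via a message.
#'
#' @param genotypes A [genotype_table()].
#' @return The genotype table with a complete dosage matrix.
#' @export
impute_dosages <- function(genotypes) {
  d <- genotypes$dosages
  nmiss <- sum(is.na(d))
  if (nmiss > 0) {
    mu <- rowMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 1]]
    message(sprintf("mean-imputed %d missing dosages (%.2f%%)",
                    nmiss, 100 * nmiss / length(d)))
    genotypes$dosages <- d
  }
  genotypes
}

#' Write tTREs as BED6
#'
#' The element span is the half-open interval from the minus-strand nTSS
#' to one past the plus-strand nTSS; the name field carries the element
#' id and class as `id;class`; score and strand columns are unused
#' (0 and ".").  Records are sorted before writing.
#'
#' @param ttres tTRE tibble (see [pair_bidirectional()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed_ttres <- function(ttres, path) {
  ttres <- dplyr::arrange(ttres, .data$contig, .data$minus_pos)
  if (nrow(ttres) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    ttres$contig,
    IRanges::IRanges(start = ttres$minus_pos + 1L, end = ttres$plus_pos + 1L),
    name = paste0(ttres$id, ";", ttres$class), score = 0L)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read tTREs from a BED6 file written by [write_bed_ttres()]
#'
#' @param path Path to the BED file.
#' @return A tTRE tibble with columns `id`, `contig`, `minus_pos`,
#'   `plus_pos`, `midpoint`, `width`, `class`.
#' @export
read_bed_ttres <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0 || !nzchar(first)) {
    return(tibble(id = character(), contig = character(),
                  minus_pos = integer(), plus_pos = integer(),
                  midpoint = integer(), width = integer(),
                  class = character()))
  }
  gr <- rtracklayer::import(path, format = "BED")
  name <- S4Vectors::mcols(gr)$name
  parts <- stringr::str_split_fixed(name, ";", 2)
  minus_pos <- GenomicRanges::start(gr) - 1L
  plus_pos <- GenomicRanges::end(gr) - 1L
  tibble(
    id = parts[, 1], contig = as.character(GenomicRanges::seqnames(gr)),
    minus_pos = minus_pos, plus_pos = plus_pos,
    midpoint = as.integer(floor((minus_pos + plus_pos) / 2)),
    width = plus_pos - minus_pos,
    class = ifelse(nzchar(parts[, 2]), parts[, 2], "unclassified"))
}

#' Write / read a QTL record table as TSV
#'
#' A plain TSV with a header; a round trip recovers the records exactly.
#'
#' @param records QTL record tibble (see [map_cis_qtls()]).
#' @param path File path.
#' @return `write_qtl_table()` returns `path` invisibly;
#'   `read_qtl_table()` returns the tibble.
#' @export
write_qtl_table <- function(records, path) {
  readr::write_tsv(records, path)
  invisible(path)
}

#' @rdname write_qtl_table
#' @export
read_qtl_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read an annotated TSS list from BED
#'
#' Expects BED6 with one single-base interval per TSS; the name column is
#' the gene id and the strand column the gene strand.
#'
#' @param path Path to the BED file.
#' @return Tibble with columns `gene`, `contig`, `position` (0-based),
#'   `strand`.
#' @export
read_tss_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  tibble(
    gene = S4Vectors::mcols(gr)$name %||% paste0("gene", seq_along(gr)),
    contig = as.character(GenomicRanges::seqnames(gr)),
    position = GenomicRanges::start(gr) - 1L,
    strand = as.character(GenomicRanges::strand(gr)))
}

#' Read a mask BED file of excluded regions
#'
#' @param path Path to the BED file.
#' @return Tibble with `contig`, `start`, `end` (0-based half-open).
#' @export
read_mask_bed <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0 || !nzchar(first))
    return(tibble(contig = character(), start = integer(), end = integer()))
  gr <- rtracklayer::import(path, format = "BED")
  tibble(contig = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr) - 1L,
         end = GenomicRanges::end(gr))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
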