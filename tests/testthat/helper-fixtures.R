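# Shared fixtures: a small simulated panel and toy building blocks.

small_config <- function(...) {
  defaults <- list(n_individuals = 30, n_replicate_pairs = 4,
                   genome_length = c(chr1 = 2e5), n_ttres = 20,
                   n_variants = 300, n_ti = 5, n_di = 5, n_e = 3,
                   n_null_genes = 5, seed = 42L)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# cached small panel (built once per test run)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_dataset(small_config())
    cache
  }
})

# a toy PWM with a sharp consensus ACGT
toy_pwm <- function(p = 0.97, id = "toy", L = 4,
                    consensus = c("A", "C", "G", "T")) {
  pfm <- matrix((1 - p) / 3, nrow = 4, ncol = L,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_len(L)) pfm[consensus[j], j] <- p
  pwm_model(pfm, id = id)
}

write_tmp_bedgraph <- function(lines) {
  f <- tempfile(fileext = ".bedGraph")
  writeLines(lines, f)
  f
}

write_tmp_vcf <- function(body, samples = c("s1", "s2", "s3")) {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    body), f)
  f
}
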