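# Shared fixtures. The full default bundle is expensive (a few seconds), so
# it is built lazily once per test run and memoised in this environment.
.fixture_env <- new.env(parent = emptyenv())

default_bundle <- function() {
  if (is.null(.fixture_env$bundle)) {
    .fixture_env$bundle <- simulate_xci(xcr_config(seed = 1))
  }
  .fixture_env$bundle
}

default_classification <- function() {
  if (is.null(.fixture_env$classes)) {
    b <- default_bundle()
    .fixture_env$classes <- classify_genes(b$counts, b$genes)
  }
  .fixture_env$classes
}

# a small, fast configuration used where the full population is unnecessary
small_config <- function(seed = 7) {
  xcr_config(
    seed = seed, n_genes = 120L, n_informative = 60L, n_escapees = 8L,
    n_reactivated = 15L, n_above_mecp2 = 2L, n_hypomethylated_promoters = 4L,
    n_tads = 12L, n_tads_enriched = 1L, n_tads_depleted = 1L,
    tad_enriched_n_react = 6L, tad_enriched_n_non = 1L,
    tad_depleted_n_non = 8L, background_cpg = 200L,
    chrom_length_bp = 20e6
  )
}

# hand-built allelic count table: one row per replicate
make_counts <- function(gene_id, condition, cast, bl6) {
  tibble::tibble(
    gene_id = gene_id,
    condition = condition,
    replicate = stats::ave(seq_along(gene_id),
                           paste(gene_id, condition), FUN = seq_along),
    cast = cast, bl6 = bl6
  )
}

# minimal gene tibble
make_genes <- function(gene_id, start, end, strand = "+", chrom = "chrX") {
  xreact:::validate_genes(tibble::tibble(
    gene_id = gene_id, name = gene_id, chrom = chrom,
    start = start, end = end, strand = strand
  ))
}

write_lines_tmp <- function(lines) {
  f <- tempfile()
  writeLines(lines, f)
  f
}
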