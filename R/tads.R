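#' Assign genes to TADs by TSS position
#'
#' A gene belongs to the TAD whose half-open interval `[start, end)` contains
#' its TSS; genes whose TSS falls in an inter-TAD gap are unassigned (`NA`).
#'
#' @param genes Gene tibble.
#' @param tads TAD tibble (`tad_id`, `chrom`, `start`, `end`), non-overlapping.
#' @return Tibble `gene_id`, `tad_id`.
#' @export
assign_genes_to_tads <- function(genes, tads) {
  tads <- arrange(tads, .data$start)
  if (nrow(tads) > 1 && any(tads$start[-1] < tads$end[-nrow(tads)])) {
    abort("TADs must be non-overlapping")
  }
  idx <- findInterval(genes$tss, tads$start)
  hit <- idx >= 1 & idx <= nrow(tads)
  hit[hit] <- genes$tss[hit] < tads$end[idx[hit]]
  tibble(gene_id = genes$gene_id,
         tad_id = ifelse(hit, tads$tad_id[pmax(idx, 1)], NA_character_))
}

#' Two-sided exact binomial test for one TAD
#'
#' Minimum-likelihood two-sided binomial test: the p value sums the null pmf
#' over every outcome no more likely than the observed count. The signed
#' -log10 p is positive when the TAD's reactivated fraction exceeds the
#' chromosome-wide fraction `p0`, negative when below, and 0 when equal.
#'
#' @param n_reactivated Observed reactivated genes in the TAD.
#' @param n_genes Classified genes in the TAD (>= 1).
#' @param p0 Chromosome-wide reactivated fraction, in (0, 1).
#' @param alpha Significance level for the flags.
#' @return A one-row tibble: `p_binomial`, `signed_minus_log10_p`,
#'   `significant_enriched`, `significant_depleted`.
#' @export
tad_binomial_test <- function(n_reactivated, n_genes, p0, alpha = 0.05) {
  if (p0 <= 0 || p0 >= 1) abort("p0 must lie strictly inside (0, 1)")
  stopifnot(n_genes >= 1, n_reactivated >= 0, n_reactivated <= n_genes)
  pmf <- dbinom(0:n_genes, n_genes, p0)
  # tolerance guards against ties broken by floating-point noise, as in the
  # standard implementation of the exact binomial test
  p <- min(1, sum(pmf[pmf <= pmf[n_reactivated + 1] * (1 + 1e-7)]))
  ratio <- n_reactivated / n_genes
  sign <- if (ratio > p0) 1 else if (ratio < p0) -1 else 0
  tibble(
    p_binomial = p,
    signed_minus_log10_p = sign * -log10(p),
    significant_enriched = p < alpha && ratio > p0,
    significant_depleted = p < alpha && ratio < p0
  )
}

#' Per-TAD enrichment and depletion of reactivated genes
#'
#' Counts classified genes (`reactivated` + `non_reactivated`; escapees and
#' uninformative genes excluded) per TAD and tests each TAD's reactivated
#' fraction against the chromosome-wide fraction with the two-sided exact
#' binomial test. No multiple-testing correction is applied by default,
#' mirroring the raw alpha = 0.05 convention of genome-browser style TAD
#' displays; set `adjust = TRUE` for BH-adjusted flags.
#'
#' @param classes `xcr_classification` tibble.
#' @param genes Gene tibble.
#' @param tads TAD tibble.
#' @param alpha Significance level.
#' @param adjust Apply Benjamini-Hochberg correction across TADs before
#'   flagging (default `FALSE`).
#' @return An `xcr_tad_enrichment` tibble with one row per TAD holding at
#'   least one classified gene: `tad_id`, `start`, `end`, `n_genes`,
#'   `n_reactivated`, `n_escapees`, `p_binomial`, `signed_minus_log10_p`,
#'   `significant_enriched`, `significant_depleted`.
#' @export
run_tad_enrichment <- function(classes, genes, tads, alpha = 0.05,
                               adjust = FALSE) {
  cl <- as_tibble(classes) %>% select("gene_id", "status")
  assignment <- assign_genes_to_tads(genes, tads) %>%
    left_join(cl, by = "gene_id") %>%
    filter(!is.na(.data$tad_id))
  classified <- filter(assignment,
                       .data$status %in% c("reactivated", "non_reactivated"))
  if (nrow(classified) == 0) {
    abort("no TAD contains classified (reactivated/non_reactivated) genes")
  }
  p0 <- mean(classified$status == "reactivated")
  per_tad <- classified %>%
    group_by(.data$tad_id) %>%
    summarise(n_genes = dplyr::n(),
              n_reactivated = sum(.data$status == "reactivated"),
              .groups = "drop")
  esc <- assignment %>%
    filter(.data$status == "escapee") %>%
    count(.data$tad_id, name = "n_escapees")
  tests <- purrr::map2(per_tad$n_reactivated, per_tad$n_genes,
                       function(k, m) tad_binomial_test(k, m, p0, alpha)) %>%
    bind_rows()
  out <- per_tad %>%
    bind_cols(tests) %>%
    left_join(esc, by = "tad_id") %>%
    mutate(n_escapees = tidyr::replace_na(.data$n_escapees, 0L)) %>%
    left_join(select(tads, "tad_id", "chrom", "start", "end"), by = "tad_id") %>%
    select("tad_id", "chrom", "start", "end", "n_genes", "n_reactivated",
           "n_escapees", "p_binomial", "signed_minus_log10_p",
           "significant_enriched", "significant_depleted") %>%
    arrange(.data$start)
  if (adjust) {
    padj <- p.adjust(out$p_binomial, method = "BH")
    ratio_above <- out$n_reactivated / out$n_genes > p0
    out$significant_enriched <- padj < alpha & ratio_above
    out$significant_depleted <- padj < alpha &
      out$n_reactivated / out$n_genes < p0
  }
  structure(out, class = c("xcr_tad_enrichment", class(out)),
            p0 = p0, alpha = alpha, adjust = adjust)
}

#' Per-TAD feature densities and enriched-vs-rest comparisons
#'
#' Aggregates repeat and CpG densities (counts per Mb, by element midpoint
#' for repeats) and optional mean track signal within each TAD, then compares
#' significantly enriched TADs against non-significant TADs with the
#' Mann-Whitney test for each aggregate. Depleted TADs are excluded from the
#' comparison groups. Comparisons with fewer than 2 TADs in a group are
#' skipped with a warning.
#'
#' @param tad_records `xcr_tad_enrichment` tibble.
#' @param repeats Repeat tibble.
#' @param cpg_sites CpG position tibble.
#' @param tracks Optional named list of signal-track tibbles.
#' @return A list with `summary` (per-TAD aggregates) and `comparisons`
#'   (Mann-Whitney results, enriched vs non-significant TADs).
#' @export
tad_feature_summary <- function(tad_records, repeats, cpg_sites,
                                tracks = NULL) {
  tr <- as_tibble(tad_records)
  mb <- (tr$end - tr$start) / 1e6
  count_in <- function(pos) {
    pos <- sort(pos)
    findInterval(tr$end - 1, pos) - findInterval(tr$start - 1, pos)
  }
  sine_mid <- with(filter(repeats, .data$repeat_class == "SINE"),
                   floor((start + end) / 2))
  line_mid <- with(filter(repeats, .data$repeat_class == "LINE"),
                   floor((start + end) / 2))
  summary <- tr %>%
    select("tad_id", "start", "end", "n_genes", "n_reactivated",
           "significant_enriched", "significant_depleted") %>%
    mutate(sine_per_mb = count_in(sine_mid) / mb,
           line_per_mb = count_in(line_mid) / mb,
           cpg_per_mb = count_in(cpg_sites$start) / mb)
  if (!is.null(tracks)) {
    for (nm in names(tracks)) {
      summary[[paste0("mean_", nm)]] <-
        track_mean(tracks[[nm]], tr$start, tr$end)
    }
  }
  enriched <- filter(summary, .data$significant_enriched)
  rest <- filter(summary, !.data$significant_enriched,
                 !.data$significant_depleted)
  feature_cols <- setdiff(names(summary)[vapply(summary, is.numeric, TRUE)],
                          c("start", "end", "n_genes", "n_reactivated"))
  comparisons <- purrr::map(feature_cols, function(fc) {
    a <- enriched[[fc]]; b <- rest[[fc]]
    if (length(a) < 2 || length(b) < 2) {
      warn(sprintf("skipping TAD comparison of '%s': a group has < 2 TADs", fc))
      return(NULL)
    }
    mann_whitney(a, b, mode = "auto", feature = fc,
                 labels = c("enriched", "non_significant"))
  }) %>% bind_rows()
  list(summary = summary, comparisons = comparisons)
}

#' Export signed TAD significance as a bedGraph-like tibble
#'
#' Genome-browser friendly: one record per TAD with the signed -log10 p.
#' Negative values are permitted here (this is a display track, not a
#' coverage track), so use [readr::write_tsv()] or [write_bedgraph_signed()]
#' to emit it.
#'
#' @param tad_records `xcr_tad_enrichment` tibble.
#' @return Tibble `chrom`, `start`, `end`, `value`.
#' @export
tad_signed_track <- function(tad_records) {
  tr <- as_tibble(tad_records)
  tibble(chrom = tr$chrom, start = tr$start, end = tr$end,
         value = tr$signed_minus_log10_p)
}

#' @rdname tad_signed_track
#' @param track Tibble `chrom`, `start`, `end`, `value` (values may be
#'   negative).
#' @param path Output path.
#' @export
write_bedgraph_signed <- function(track, path) {
  lines <- sprintf("%s\t%s\t%s\t%s", track$chrom,
                   format(track$start, scientific = FALSE, trim = TRUE),
                   format(track$end, scientific = FALSE, trim = TRUE),
                   format(track$value, scientific = FALSE, trim = TRUE))
  writeLines(lines, path)
  invisible(path)
}
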