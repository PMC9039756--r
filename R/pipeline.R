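#' Run the full synthetic-data analysis pipeline
#'
#' Orchestrates simulate -> classify -> features -> TADs -> methylation ->
#' overlap on a synthetic bundle, writing every stage output as TSV/BED/
#' bedGraph under `out_dir` and returning a manifest with content hashes.
#' The overlap stage compares the classification against gene lists derived
#' from the simulation's ground truth (a built-in positive control).
#'
#' @param config An [xcr_config()]; `seed` overrides its seed when given.
#' @param out_dir Output directory.
#' @param seed Optional integer overriding `config$seed`.
#' @param dry_run Validate the configuration and output location without
#'   simulating or writing anything.
#' @param alpha FDR / significance level used across stages.
#' @param quiet Suppress progress messages.
#' @return A list with `manifest` (tibble: stage, file, md5, n_rows),
#'   `results` (the in-memory stage results) and `params` (every parameter
#'   actually used). For dry runs, the validated `params` only.
#' @export
xcr_run_pipeline <- function(config = xcr_config(), out_dir,
                             seed = NULL, dry_run = FALSE, alpha = 0.05,
                             quiet = FALSE) {
  if (!is.null(seed)) {
    config$seed <- as.integer(seed)
    validate_config(config)
  }
  params <- c(unclass(config), alpha = alpha, out_dir = out_dir)
  if (is.null(out_dir) || !nzchar(out_dir)) {
    abort("out_dir must be a non-empty path")
  }
  if (dry_run) {
    validate_config(config)
    if (!quiet) inform("dry run: configuration valid; no files written")
    return(list(manifest = tibble(stage = character(), file = character(),
                                  md5 = character(), n_rows = integer()),
                results = NULL, params = params))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) inform(sprintf(...))
  manifest <- list()
  note <- function(stage, path, n_rows) {
    manifest[[length(manifest) + 1]] <<- tibble(
      stage = stage, file = basename(path),
      md5 = unname(tools::md5sum(path)), n_rows = n_rows)
  }

  say("simulating synthetic dataset (seed %d)", config$seed)
  bundle <- simulate_xci(config)
  paths <- write_xci_bundle(bundle, file.path(out_dir, "simulated"))
  for (nm in names(paths)) note("simulate", paths[[nm]], NA_integer_)

  say("classifying genes")
  classes <- classify_genes(bundle$counts, bundle$genes, alpha = alpha,
                            treated_condition = config$treated_condition)
  f <- file.path(out_dir, "classification.tsv")
  readr::write_tsv(as_tibble(classes), f); note("classify", f, nrow(classes))
  informative <- filter(as_tibble(classes), .data$status != "uninformative")
  profile <- delta_ratio_profile(bundle$counts,
                                 filter(bundle$genes,
                                        .data$gene_id %in% informative$gene_id),
                                 treated_condition = config$treated_condition)
  f <- file.path(out_dir, "delta_ratio.tsv")
  readr::write_tsv(profile, f); note("classify", f, nrow(profile))

  say("computing feature table")
  xist_tss <- bundle$genes$tss[bundle$genes$name == "Xist"]
  features <- build_feature_table(
    bundle$genes, classes, bundle$repeats, bundle$cpg,
    tracks = bundle$tracks,
    xist_tss = if (length(xist_tss) == 1) xist_tss else NULL)
  f <- file.path(out_dir, "features.tsv")
  readr::write_tsv(features, f); note("features", f, nrow(features))
  comparisons <- compare_classes(
    features, classes,
    feature_names = c("cpg_upstream_2kb", "sine_100kb", "line_100kb",
                      "line_full_length_100kb", "line_short_100kb",
                      "dist_nearest_escapee_bp"))
  f <- file.path(out_dir, "feature_comparisons.tsv")
  readr::write_tsv(comparisons, f); note("features", f, nrow(comparisons))

  say("testing TAD enrichment")
  tad_records <- run_tad_enrichment(classes, bundle$genes, bundle$tads,
                                    alpha = alpha)
  f <- file.path(out_dir, "tad_enrichment.tsv")
  readr::write_tsv(as_tibble(tad_records), f); note("tads", f, nrow(tad_records))
  f <- file.path(out_dir, "tad_signed_log10p.bedGraph")
  write_bedgraph_signed(tad_signed_track(tad_records), f)
  note("tads", f, nrow(tad_records))

  say("analysing promoter methylation")
  promoters <- promoter_regions(bundle$genes)
  meth <- aggregate_methylation(bundle$methylation, promoters)
  diff <- differential_methylation(meth,
                                   treated_condition = config$treated_condition,
                                   alpha = alpha)
  f <- file.path(out_dir, "differential_methylation.tsv")
  readr::write_tsv(as_tibble(diff), f); note("methylation", f, nrow(diff))

  say("computing truth-list overlaps")
  truth_lists <- list(
    gene_list(bundle$truth$genes$name[bundle$truth$genes$class == "reactivated"],
              "truth_reactivated"),
    gene_list(bundle$truth$genes$name[bundle$truth$genes$class == "escapee"],
              "truth_escapee"))
  overlaps <- multi_overlap_report(classes, truth_lists)
  f <- file.path(out_dir, "overlaps.tsv")
  readr::write_tsv(overlaps, f); note("overlap", f, nrow(overlaps))

  f <- file.path(out_dir, "params.yaml")
  yaml::write_yaml(params, f); note("pipeline", f, NA_integer_)

  list(manifest = bind_rows(manifest),
       results = list(bundle = bundle, classes = classes, profile = profile,
                      features = features, comparisons = comparisons,
                      tads = tad_records, methylation = diff,
                      overlaps = overlaps),
       params = params)
}
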