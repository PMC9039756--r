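#' Count CpG sites in the upstream promoter bin
#'
#' Counts CpG positions whose start lies in the strand-aware window
#' `[tss - window_bp, tss)` (half-open at the TSS).
#'
#' @param genes Gene tibble.
#' @param cpg_sites CpG position tibble (`chrom`, `start`; BED convention).
#' @param window_bp Upstream window width in bp (default 2000).
#' @return Tibble `gene_id`, `cpg_upstream`.
#' @export
count_cpg_upstream <- function(genes, cpg_sites, window_bp = 2000) {
  win <- tss_window(genes, upstream = window_bp, downstream = 0)
  pos <- sort(cpg_sites$start)
  tibble(
    gene_id = genes$gene_id,
    cpg_upstream = findInterval(win$end - 1, pos) -
      findInterval(win$start - 1, pos)
  )
}

#' Count repeat elements around the TSS
#'
#' An element is counted when its midpoint, `floor((start + end) / 2)`, lies
#' in the closed window `[tss - window_bp, tss + window_bp]`.
#'
#' @param genes Gene tibble.
#' @param repeats Repeat tibble (see [read_repeat_bed()]).
#' @param repeat_class `"SINE"`, `"LINE"`, or `NULL` to count every element.
#' @param window_bp Half-width of the window (default 100,000).
#' @return Tibble `gene_id`, `n_repeats`.
#' @export
count_repeats_near_tss <- function(genes, repeats, repeat_class = NULL,
                                   window_bp = 100000) {
  if (!is.null(repeat_class)) {
    repeats <- filter(repeats, .data$repeat_class == !!repeat_class)
  }
  mid <- sort(floor((repeats$start + repeats$end) / 2))
  tibble(
    gene_id = genes$gene_id,
    n_repeats = findInterval(genes$tss + window_bp, mid) -
      findInterval(genes$tss - window_bp - 1, mid)
  )
}

#' Stratify LINE elements by size or evolutionary age
#'
#' Size mode splits LINEs into full-length (`length_bp >= full_length_min_bp`)
#' and short elements; age mode splits by `age_rank` (1 = youngest).
#'
#' @param repeats Repeat tibble.
#' @param by `"size"` or `"age"`.
#' @param full_length_min_bp Full-length cutoff in bp (default 6000).
#' @return A named list of repeat tibbles (`full_length`/`short`, or
#'   `age_<rank>` per rank).
#' @export
stratify_lines <- function(repeats, by = c("size", "age"),
                           full_length_min_bp = 6000) {
  by <- match.arg(by)
  lines <- filter(repeats, .data$repeat_class == "LINE")
  if (by == "size") {
    list(full_length = filter(lines, .data$length_bp >= full_length_min_bp),
         short = filter(lines, .data$length_bp < full_length_min_bp))
  } else {
    missing_age <- which(is.na(lines$age_rank))
    if (length(missing_age) > 0) {
      abort(sprintf(
        "age stratification needs age_rank on every LINE; missing for %d element(s) (first at %s:%s)",
        length(missing_age), lines$chrom[missing_age[1]],
        format(lines$start[missing_age[1]], scientific = FALSE)))
    }
    split(lines, paste0("age_", lines$age_rank))
  }
}

#' Distance from each gene's TSS to the nearest anchor TSS
#'
#' A gene that is itself an anchor is excluded from its own anchor set.
#' With no (remaining) anchors the distance is `NA`.
#'
#' @param genes Gene tibble.
#' @param anchors Tibble with `gene_id` and `tss` (e.g. the escapee subset of
#'   the gene table), or a bare numeric vector of anchor positions.
#' @return Tibble `gene_id`, `dist_bp`.
#' @export
distance_to_nearest <- function(genes, anchors) {
  if (is.numeric(anchors)) {
    anchors <- tibble(gene_id = NA_character_, tss = anchors)
  }
  dist <- purrr::map_dbl(seq_len(nrow(genes)), function(i) {
    pos <- anchors$tss[is.na(anchors$gene_id) |
                         anchors$gene_id != genes$gene_id[i]]
    if (length(pos) == 0) return(NA_real_)
    min(abs(genes$tss[i] - pos))
  })
  tibble(gene_id = genes$gene_id, dist_bp = dist)
}

#' Average signal profile around TSSs or along scaled gene bodies
#'
#' In `"tss"` mode the signal is averaged per `bin_bp` bin over
#' `[tss - flank_bp, tss + flank_bp)`, strand-oriented (minus-strand genes are
#' reversed) and then averaged across genes. In `"scaled_body"` mode each
#' flank is binned at `bin_bp` and the gene body is rescaled to
#' `n_body_bins` bins; genes shorter than `n_body_bins` bases are skipped
#' with a warning.
#'
#' @param genes Gene tibble (non-empty).
#' @param track Signal-track tibble.
#' @param mode `"tss"` or `"scaled_body"`.
#' @param flank_bp Flank width (default 3000).
#' @param bin_bp Bin width in the flanks / TSS window (default 50).
#' @param n_body_bins Number of body bins in `"scaled_body"` mode.
#' @return Tibble `bin`, `position` (bp offset from the TSS, or a scaled
#'   coordinate label), `mean_signal`, plus `n_genes` as an attribute-free
#'   column carried in every row.
#' @export
metagene_profile <- function(genes, track, mode = c("tss", "scaled_body"),
                             flank_bp = 3000, bin_bp = 50, n_body_bins = 100) {
  mode <- match.arg(mode)
  if (nrow(genes) == 0) abort("metagene_profile needs at least one gene")
  if (mode == "tss") {
    n_bins <- 2 * flank_bp / bin_bp
    profs <- purrr::map(seq_len(nrow(genes)), function(i) {
      lo <- genes$tss[i] - flank_bp
      starts <- lo + bin_bp * (seq_len(n_bins) - 1)
      keep <- starts >= 0
      v <- rep(NA_real_, n_bins)
      v[keep] <- track_mean(track, starts[keep], starts[keep] + bin_bp)
      if (genes$strand[i] == "-") v <- rev(v)
      v
    })
    mat <- do.call(rbind, profs)
    tibble(
      bin = seq_len(n_bins),
      position = -flank_bp + bin_bp * (seq_len(n_bins) - 1) + bin_bp / 2,
      mean_signal = colMeans(mat, na.rm = TRUE),
      n_genes = nrow(genes)
    )
  } else {
    body_len <- genes$end - genes$start
    short <- body_len < n_body_bins
    if (any(short)) {
      warn(sprintf("skipping %d gene(s) shorter than %d bp in scaled-body profile",
                   sum(short), n_body_bins))
      genes <- genes[!short, ]
    }
    if (nrow(genes) == 0) abort("no genes long enough for the scaled-body profile")
    n_flank <- flank_bp / bin_bp
    profs <- purrr::map(seq_len(nrow(genes)), function(i) {
      g_start <- genes$start[i]; g_end <- genes$end[i]
      left_starts <- g_start - flank_bp + bin_bp * (seq_len(n_flank) - 1)
      body_edges <- round(seq(g_start, g_end, length.out = n_body_bins + 1))
      right_starts <- g_end + bin_bp * (seq_len(n_flank) - 1)
      starts <- c(left_starts, body_edges[-(n_body_bins + 1)], right_starts)
      ends <- c(left_starts + bin_bp, body_edges[-1], right_starts + bin_bp)
      keep <- starts >= 0 & ends > starts
      v <- rep(NA_real_, length(starts))
      v[keep] <- track_mean(track, starts[keep], ends[keep])
      if (genes$strand[i] == "-") v <- rev(v)
      v
    })
    mat <- do.call(rbind, profs)
    n_total <- 2 * n_flank + n_body_bins
    segment <- c(rep("upstream", n_flank), rep("body", n_body_bins),
                 rep("downstream", n_flank))
    tibble(
      bin = seq_len(n_total),
      position = segment,
      mean_signal = colMeans(mat, na.rm = TRUE),
      n_genes = nrow(genes)
    )
  }
}

#' Assemble the per-gene feature table
#'
#' Computes, for every annotated gene: CpG count in the upstream 2 kb, SINE
#' and LINE counts (total, full-length/short LINEs, and per age rank) within
#' +/-100 kb of the TSS, distance to the nearest escapee TSS and to the Xist
#' TSS, and, optionally, the mean signal of each supplied track in the
#' TSS +/- 3 kb window.
#'
#' @param genes Gene tibble.
#' @param classes `xcr_classification` tibble (used for the escapee anchors).
#' @param repeats Repeat tibble.
#' @param cpg_sites CpG position tibble.
#' @param tracks Optional named list of signal-track tibbles.
#' @param xist_tss Optional Xist TSS position (bp).
#' @param cpg_window_bp,repeat_window_bp Window sizes.
#' @return A feature tibble with one row per gene.
#' @export
build_feature_table <- function(genes, classes, repeats, cpg_sites,
                                tracks = NULL, xist_tss = NULL,
                                cpg_window_bp = 2000,
                                repeat_window_bp = 100000) {
  out <- count_cpg_upstream(genes, cpg_sites, cpg_window_bp) %>%
    rename(cpg_upstream_2kb = "cpg_upstream")
  out$sine_100kb <- count_repeats_near_tss(genes, repeats, "SINE",
                                           repeat_window_bp)$n_repeats
  out$line_100kb <- count_repeats_near_tss(genes, repeats, "LINE",
                                           repeat_window_bp)$n_repeats
  strata <- stratify_lines(repeats, by = "size")
  out$line_full_length_100kb <-
    count_repeats_near_tss(genes, strata$full_length, NULL,
                           repeat_window_bp)$n_repeats
  out$line_short_100kb <-
    count_repeats_near_tss(genes, strata$short, NULL,
                           repeat_window_bp)$n_repeats
  lines <- filter(repeats, .data$repeat_class == "LINE")
  if (nrow(lines) > 0 && !all(is.na(lines$age_rank))) {
    for (a in sort(unique(lines$age_rank[!is.na(lines$age_rank)]))) {
      out[[paste0("line_age", a, "_100kb")]] <-
        count_repeats_near_tss(genes, filter(lines, .data$age_rank == a),
                               NULL, repeat_window_bp)$n_repeats
    }
  }
  esc_ids <- as_tibble(classes) %>%
    filter(.data$status == "escapee") %>%
    pull(.data$gene_id)
  anchors <- genes %>%
    filter(.data$gene_id %in% esc_ids) %>%
    select("gene_id", "tss")
  out$dist_nearest_escapee_bp <- if (nrow(anchors) > 0) {
    distance_to_nearest(genes, anchors)$dist_bp
  } else {
    NA_real_
  }
  out$dist_to_xist_bp <- if (!is.null(xist_tss)) {
    abs(genes$tss - xist_tss)
  } else {
    NA_real_
  }
  if (!is.null(tracks)) {
    win <- tss_window(genes, upstream = 3000, downstream = 3000)
    for (nm in names(tracks)) {
      out[[paste0("mean_", nm, "_tss3kb")]] <-
        track_mean(tracks[[nm]], pmax(0, win$start), win$end)
    }
  }
  out
}

#' Compare per-gene features between reactivated and non-reactivated genes
#'
#' Runs a two-sided Mann-Whitney test per feature between genes called
#' `reactivated` and `non_reactivated` (escapees and uninformative genes are
#' excluded). Features with fewer than 2 values in a group are skipped with
#' a warning.
#'
#' @param features Feature tibble from [build_feature_table()].
#' @param classes `xcr_classification` tibble.
#' @param feature_names Columns of `features` to compare; defaults to every
#'   numeric feature column.
#' @param mode Mann-Whitney mode (see [mann_whitney()]).
#' @return A tibble of group comparisons, one row per feature.
#' @export
compare_classes <- function(features, classes, feature_names = NULL,
                            mode = "auto") {
  cl <- as_tibble(classes) %>% select("gene_id", "status")
  joined <- left_join(features, cl, by = "gene_id")
  if (is.null(feature_names)) {
    feature_names <- setdiff(names(features)[vapply(features, is.numeric, TRUE)],
                             "gene_id")
  }
  res <- purrr::map(feature_names, function(fn) {
    a <- joined[[fn]][joined$status == "reactivated"]
    b <- joined[[fn]][joined$status == "non_reactivated"]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2) {
      warn(sprintf("skipping comparison of '%s': a class has < 2 values", fn))
      return(NULL)
    }
    mann_whitney(a, b, mode = mode, feature = fn,
                 labels = c("reactivated", "non_reactivated"))
  })
  bind_rows(res)
}
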