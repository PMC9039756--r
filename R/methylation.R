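#' Promoter regions around gene TSSs
#'
#' One region per gene, `[tss - flank_bp, tss + flank_bp)`, clipped at 0.
#'
#' @param genes Gene tibble.
#' @param flank_bp Promoter half-width (default 1000; must be > 0).
#' @return Region registry tibble: `region_id`, `gene_id`, `chrom`, `start`,
#'   `end`, `strand`.
#' @export
promoter_regions <- function(genes, flank_bp = 1000) {
  if (flank_bp <= 0) abort("promoter flank_bp must be positive (empty region)")
  tibble(
    region_id = paste0(genes$gene_id, "_promoter"),
    gene_id = genes$gene_id,
    chrom = genes$chrom,
    start = pmax(0, genes$tss - flank_bp),
    end = genes$tss + flank_bp,
    strand = genes$strand
  )
}

#' Aggregate site-level methylation counts over regions
#'
#' Sums per-site MeD-seq style counts into per-region counts for each sample.
#' Sites falling in no region are ignored; overlapping regions each receive
#' the counts of their own sites.
#'
#' @param sites Site-level methylation tibble (`pos`, `sample_id`,
#'   `condition`, `count`).
#' @param regions Region registry from [promoter_regions()] (needs
#'   `region_id`, `start`, `end`).
#' @return Region-level tibble: `region_id`, `sample_id`, `condition`,
#'   `count` (complete over regions x samples, zero-filled).
#' @export
aggregate_methylation <- function(sites, regions) {
  samples <- distinct(sites, .data$sample_id, .data$condition)
  pos_u <- sort(unique(sites$pos))
  reg <- regions[order(regions$start), ]
  idx <- findInterval(pos_u, reg$start)
  # walk back over preceding regions to honour overlaps; regions deeper than
  # 10-fold stacked overlap are not supported
  maps <- purrr::map(0:9, function(back) {
    j <- idx - back
    ok <- j >= 1 & j <= nrow(reg)
    ok[ok] <- pos_u[ok] < reg$end[j[ok]] & pos_u[ok] >= reg$start[j[ok]]
    if (!any(ok)) return(NULL)
    tibble(pos = pos_u[ok], region_id = reg$region_id[j[ok]])
  })
  map_tbl <- bind_rows(maps)
  agg <- sites %>%
    dplyr::inner_join(map_tbl, by = "pos", relationship = "many-to-many") %>%
    group_by(.data$region_id, .data$sample_id, .data$condition) %>%
    summarise(count = sum(.data$count), .groups = "drop")
  tidyr::expand_grid(region_id = regions$region_id, samples) %>%
    left_join(agg, by = c("region_id", "sample_id", "condition")) %>%
    mutate(count = tidyr::replace_na(.data$count, 0)) %>%
    select("region_id", "sample_id", "condition", "count")
}

#' Normalize methylation counts to counts per million region reads
#'
#' @param counts Region-level methylation tibble (`region_id`, `sample_id`,
#'   `condition`, `count`).
#' @return The input with an added `cpm` column; errors if a sample has zero
#'   total counts.
#' @export
normalize_methylation <- function(counts) {
  totals <- counts %>%
    group_by(.data$sample_id) %>%
    summarise(total = sum(.data$count), .groups = "drop")
  zero <- totals$sample_id[totals$total == 0]
  if (length(zero) > 0) {
    abort(sprintf("sample(s) with zero total methylation counts: %s",
                  paste(zero, collapse = ", ")))
  }
  counts %>%
    left_join(totals, by = "sample_id") %>%
    mutate(cpm = .data$count / .data$total * 1e6) %>%
    select(-"total")
}

#' Differential promoter methylation between two conditions
#'
#' Pools replicate counts per region and condition and tests equality of the
#' region's share of the sample total (chi-square with continuity correction;
#' Fisher's exact test when any expected cell count falls below 5). P values
#' are BH-adjusted over all tested regions; `significantly_lower` flags
#' regions with `fdr < alpha` and a lower normalized rate in the treated
#' condition. Regions with zero pooled counts in both conditions are skipped
#' and reported as untested (`NA` p).
#'
#' @param counts Region-level methylation tibble.
#' @param control_condition,treated_condition Condition names.
#' @param alpha FDR level.
#' @return An `xcr_diff_methylation` tibble: `region_id`,
#'   `control_normalized_rate`, `treated_normalized_rate` (pooled CPM),
#'   `log2_fold`, `p_value`, `fdr`, `significantly_lower`.
#' @export
differential_methylation <- function(counts, control_condition = "control",
                                     treated_condition = "tomato_high",
                                     alpha = 0.05) {
  pooled <- counts %>%
    filter(.data$condition %in% c(control_condition, treated_condition)) %>%
    group_by(.data$region_id, .data$condition) %>%
    summarise(count = sum(.data$count), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "condition", values_from = "count",
                       values_fill = 0)
  if (!all(c(control_condition, treated_condition) %in% names(pooled))) {
    abort("both conditions must be present in the methylation counts")
  }
  a <- as.numeric(pooled[[control_condition]])
  b <- as.numeric(pooled[[treated_condition]])
  tot_a <- sum(a)
  tot_b <- sum(b)
  rate_a <- a / tot_a * 1e6
  rate_b <- b / tot_b * 1e6
  # vectorised 2x2 chi-square with continuity correction on
  # (region count vs rest-of-sample count) x (control vs treated)
  rest_a <- tot_a - a
  rest_b <- tot_b - b
  nn <- tot_a + tot_b
  num <- nn * pmax(0, abs(a * rest_b - b * rest_a) - nn / 2)^2
  den <- as.numeric(a + b) * (rest_a + rest_b) * tot_a * tot_b
  p <- ifelse(den > 0, pchisq(num / den, df = 1, lower.tail = FALSE), NA_real_)
  expected_min <- pmin((a + b) * tot_a, (a + b) * tot_b) / nn
  small <- which(!is.na(p) & expected_min < 5 & (a + b) > 0)
  for (i in small) {
    p[i] <- stats::fisher.test(matrix(c(a[i], rest_a[i], b[i], rest_b[i]),
                                      nrow = 2))$p.value
  }
  p[a + b == 0] <- NA_real_
  fdr <- rep(NA_real_, length(p))
  tested <- !is.na(p)
  fdr[tested] <- p.adjust(p[tested], method = "BH")
  out <- tibble(
    region_id = pooled$region_id,
    control_normalized_rate = rate_a,
    treated_normalized_rate = rate_b,
    log2_fold = log2((b + 0.5) / (tot_b + 1) * (tot_a + 1) / (a + 0.5)),
    p_value = p,
    fdr = fdr,
    significantly_lower = tested & fdr < alpha & rate_b < rate_a
  )
  structure(out, class = c("xcr_diff_methylation", class(out)),
            alpha = alpha,
            control_condition = control_condition,
            treated_condition = treated_condition)
}

#' Hierarchical clustering of promoter methylation profiles
#'
#' Average-linkage hierarchical clustering on Euclidean distances between
#' per-region z-scored normalized rates, cut at k = 2. The class-purity score
#' is the larger fraction of reactivated promoters captured by a single
#' cluster; its significance is assessed by permuting the class labels.
#'
#' @param normalized Region-level methylation tibble with a `cpm` column
#'   (see [normalize_methylation()]).
#' @param regions Region registry (maps `region_id` to `gene_id`).
#' @param classes `xcr_classification` tibble.
#' @param n_permutations Label permutations for the purity null (default 1000).
#' @param conditions Conditions whose samples enter the clustering; default
#'   all present.
#' @return A list: `order` (dendrogram order of region ids), `cluster`
#'   (named cluster labels at k = 2), `purity`, `permutation_p`, `n_regions`.
#'   With a constant rate matrix, `purity` and `permutation_p` are `NA`.
#' @export
cluster_promoters <- function(normalized, regions, classes,
                              n_permutations = 1000, conditions = NULL) {
  if (!is.null(conditions)) {
    normalized <- filter(normalized, .data$condition %in% conditions)
  }
  wide <- normalized %>%
    select("region_id", "sample_id", "cpm") %>%
    tidyr::pivot_wider(names_from = "sample_id", values_from = "cpm")
  mat <- as.matrix(wide[, -1])
  rownames(mat) <- wide$region_id
  if (nrow(mat) < 4) abort("promoter clustering needs at least 4 regions")
  sds <- apply(mat, 1, stats::sd)
  if (all(sds == 0) || stats::sd(as.numeric(mat)) == 0) {
    return(list(order = wide$region_id, cluster = NULL, purity = NA_real_,
                permutation_p = NA_real_, n_regions = nrow(mat)))
  }
  z <- (mat - rowMeans(mat)) / ifelse(sds > 0, sds, 1)
  hc <- hclust(dist(z), method = "average")
  cl <- cutree(hc, k = 2)
  gene_of <- setNames(regions$gene_id, regions$region_id)
  status_of <- setNames(as_tibble(classes)$status, as_tibble(classes)$gene_id)
  is_react <- unname(status_of[gene_of[rownames(mat)]] == "reactivated")
  is_react[is.na(is_react)] <- FALSE
  purity_of <- function(lab) {
    if (sum(lab) == 0) return(NA_real_)
    max(vapply(1:2, function(k) sum(lab & cl == k), 1) / sum(lab))
  }
  obs <- purity_of(is_react)
  perm <- vapply(seq_len(n_permutations), function(i) {
    purity_of(sample(is_react))
  }, 1)
  list(order = rownames(mat)[hc$order],
       cluster = cl,
       purity = obs,
       permutation_p = (1 + sum(perm >= obs, na.rm = TRUE)) / (1 + n_permutations),
       n_regions = nrow(mat))
}

#' Methylation of the DNA flanking repeat elements, by gene class
#'
#' For every repeat element whose midpoint lies within `near_window_bp` of a
#' classified (reactivated or non-reactivated) gene's TSS, sums methylation
#' counts over the two flanks `[start - flank_bp, start)` and
#' `[end, end + flank_bp)` (the repeat body itself is excluded), normalizes
#' per sample and divides by the number of CpG sites in the flanks, giving a
#' per-site methylation level (MeD-seq counts scale with local CpG content,
#' so the raw flank sum would measure CpG density rather than methylation
#' status). Elements without any flank CpG site carry no methylation
#' information and are dropped. The per-element levels near reactivated vs
#' near non-reactivated genes are then compared with the Mann-Whitney test,
#' separately per repeat class. Elements near genes of both classes are
#' assigned to the class of the nearest TSS.
#'
#' @param repeats Repeat tibble.
#' @param sites Site-level methylation tibble.
#' @param classes `xcr_classification` tibble.
#' @param genes Gene tibble.
#' @param flank_bp Flank width (default 1000).
#' @param near_window_bp Assignment window around TSSs (default 100,000).
#' @param conditions Conditions averaged into the per-element rate; default
#'   all present.
#' @return A list: `elements` (per-element flank rates and assigned class)
#'   and `comparisons` (one Mann-Whitney row per repeat class; classes with
#'   a single element are skipped with a warning).
#' @export
repeat_flank_methylation <- function(repeats, sites, classes, genes,
                                     flank_bp = 1000, near_window_bp = 100000,
                                     conditions = NULL) {
  cl <- as_tibble(classes) %>%
    filter(.data$status %in% c("reactivated", "non_reactivated")) %>%
    select("gene_id", "status")
  anchor <- genes %>%
    filter(.data$gene_id %in% cl$gene_id) %>%
    left_join(cl, by = "gene_id") %>%
    arrange(.data$tss)
  if (nrow(anchor) == 0) abort("no classified genes to anchor repeat flanks")
  mid <- floor((repeats$start + repeats$end) / 2)
  near_idx <- nearest_sorted(anchor$tss, mid)
  near_dist <- abs(anchor$tss[near_idx] - mid)
  keep <- near_dist <= near_window_bp
  el <- repeats[keep, ]
  el$near_class <- anchor$status[near_idx[keep]]

  if (!is.null(conditions)) {
    sites <- filter(sites, .data$condition %in% conditions)
  }
  sample_totals <- sites %>%
    group_by(.data$sample_id) %>%
    summarise(total = sum(.data$count), .groups = "drop")
  n_samples <- nrow(sample_totals)
  # per-sample cumulative site counts allow O(log n) flank sums
  rate <- numeric(nrow(el))
  n_sites <- numeric(nrow(el))
  for (s in seq_len(n_samples)) {
    ss <- sites[sites$sample_id == sample_totals$sample_id[s], ]
    ss <- ss[order(ss$pos), ]
    cum <- c(0, cumsum(ss$count))
    sum_in <- function(lo, hi) {
      cum[findInterval(hi - 1, ss$pos) + 1] - cum[findInterval(lo - 1, ss$pos) + 1]
    }
    flank_counts <- sum_in(el$start - flank_bp, el$start) +
      sum_in(el$end, el$end + flank_bp)
    rate <- rate + flank_counts / sample_totals$total[s] * 1e6 / n_samples
    if (s == 1) {
      site_in <- function(lo, hi) {
        findInterval(hi - 1, ss$pos) - findInterval(lo - 1, ss$pos)
      }
      n_sites <- site_in(el$start - flank_bp, el$start) +
        site_in(el$end, el$end + flank_bp)
    }
  }
  el$flank_sites <- n_sites
  el$flank_rate <- ifelse(n_sites > 0, rate / n_sites, NA_real_)
  el <- el[!is.na(el$flank_rate), ]

  comparisons <- purrr::map(unique(repeats$repeat_class), function(k) {
    a <- el$flank_rate[el$repeat_class == k & el$near_class == "reactivated"]
    b <- el$flank_rate[el$repeat_class == k & el$near_class == "non_reactivated"]
    if (length(a) < 2 || length(b) < 2) {
      warn(sprintf("skipping flank comparison for %s: a class has < 2 elements", k))
      return(NULL)
    }
    mann_whitney(a, b, mode = "normal", feature = paste0(k, "_flank_methylation"),
                 labels = c("near_reactivated", "near_non_reactivated"))
  }) %>% bind_rows()
  list(elements = as_tibble(el), comparisons = comparisons)
}

#' Index of the nearest value in a sorted vector
#' @keywords internal
nearest_sorted <- function(sorted_pos, query) {
  idx <- findInterval(query, sorted_pos)
  lo <- pmax(idx, 1)
  hi <- pmin(idx + 1, length(sorted_pos))
  ifelse(abs(query - sorted_pos[lo]) <= abs(sorted_pos[hi] - query), lo, hi)
}
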