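#' Allelic ratio of cast over total expression
#'
#' @param cast,bl6 Non-negative count vectors.
#' @return `cast / (cast + bl6)`; `NA` where the total is zero.
#' @export
allelic_ratio <- function(cast, bl6) {
  total <- cast + bl6
  ifelse(total > 0, cast / total, NA_real_)
}

#' @keywords internal
validate_counts <- function(counts) {
  req <- c("gene_id", "condition", "replicate", "cast", "bl6")
  missing <- setdiff(req, names(counts))
  if (length(missing) > 0) {
    abort(sprintf("count table missing columns: %s", paste(missing, collapse = ", ")))
  }
  if (any(counts$cast < 0) || any(counts$bl6 < 0) ||
      any(counts$cast != round(counts$cast)) || any(counts$bl6 != round(counts$bl6))) {
    abort("cast/bl6 counts must be non-negative integers")
  }
  key <- paste(counts$gene_id, counts$condition, counts$replicate)
  if (anyDuplicated(key) > 0) {
    abort("duplicate (gene_id, condition, replicate) rows in count table")
  }
  invisible(counts)
}

#' Informative-coverage filter for allelic analysis
#'
#' A gene is allelically informative when its mean total allelic coverage
#' (cast + bl6, averaged over replicates) reaches `min_allelic_reads` in
#' every listed condition.
#'
#' @param counts Allelic count tibble (`gene_id`, `condition`, `replicate`,
#'   `cast`, `bl6`).
#' @param min_allelic_reads Minimum mean total allelic reads per condition.
#' @param conditions Conditions that must all pass; defaults to every
#'   condition present in `counts`.
#' @return Character vector of informative `gene_id`s.
#' @export
filter_informative <- function(counts, min_allelic_reads = 10,
                               conditions = NULL) {
  validate_counts(counts)
  if (is.null(conditions)) conditions <- unique(counts$condition)
  unknown <- setdiff(conditions, unique(counts$condition))
  if (length(unknown) > 0) {
    abort(sprintf("unknown condition(s): %s", paste(unknown, collapse = ", ")))
  }
  counts %>%
    filter(.data$condition %in% conditions) %>%
    group_by(.data$gene_id, .data$condition) %>%
    summarise(mean_total = mean(.data$cast + .data$bl6), .groups = "drop") %>%
    group_by(.data$gene_id) %>%
    summarise(pass = all(.data$mean_total >= min_allelic_reads) &&
                dplyr::n_distinct(.data$condition) == length(conditions),
              .groups = "drop") %>%
    filter(.data$pass) %>%
    pull(.data$gene_id)
}

#' Call escapees from control allelic ratios
#'
#' A gene escapes X inactivation when its mean control cast ratio (the
#' per-replicate ratio `cast / (cast + bl6)`, averaged over replicates)
#' reaches `escape_ratio_threshold`.
#'
#' @param counts Allelic count tibble.
#' @param informative_genes Character vector of informative gene ids.
#' @param escape_ratio_threshold Ratio cutoff (default 0.10, following the
#'   convention of the escapee literature).
#' @param control_condition Name of the untreated condition.
#' @return Character vector of escapee `gene_id`s.
#' @export
classify_escapees <- function(counts, informative_genes,
                              escape_ratio_threshold = 0.10,
                              control_condition = "control") {
  counts %>%
    filter(.data$gene_id %in% informative_genes,
           .data$condition == control_condition) %>%
    mutate(ratio = allelic_ratio(.data$cast, .data$bl6)) %>%
    group_by(.data$gene_id) %>%
    summarise(mean_ratio = mean(.data$ratio, na.rm = TRUE), .groups = "drop") %>%
    filter(!is.nan(.data$mean_ratio),
           .data$mean_ratio >= escape_ratio_threshold) %>%
    pull(.data$gene_id)
}

# ---- beta-binomial likelihood machinery ------------------------------------

#' @keywords internal
dbetabinom_log <- function(k, n, prob, rho) {
  if (rho < 1e-10) {
    return(dbinom(k, n, prob, log = TRUE))
  }
  a <- prob * (1 - rho) / rho
  b <- (1 - prob) * (1 - rho) / rho
  lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @keywords internal
bb_loglik_profile <- function(cast, tot, rho) {
  # maximised beta-binomial log likelihood over the cast fraction, at fixed
  # overdispersion rho (Brent search on the logit scale)
  keep <- tot > 0
  cast <- cast[keep]; tot <- tot[keep]
  if (length(cast) == 0) return(0)
  nll <- function(lp) -sum(dbetabinom_log(cast, tot, plogis(lp), rho))
  fit <- optimize(nll, interval = c(-16, 16), tol = 1e-8)
  p_hat <- clamp(sum(cast) / sum(tot), 1e-7, 1 - 1e-7)
  -min(fit$objective, nll(qlogis(p_hat)))
}

#' Moment-based shared overdispersion of allelic fractions
#'
#' Pools the Kleinman moment estimator of the beta-binomial intraclass
#' correlation over every (gene, condition) cell with at least two
#' informative replicates. With three replicates per condition a per-gene
#' dispersion estimate is unstable; the shared estimate borrows strength
#' across the whole table.
#'
#' @param counts Allelic count tibble (typically restricted to the genes and
#'   conditions entering the test).
#' @return A single overdispersion estimate in `[0, 0.5]`.
#' @export
estimate_overdispersion <- function(counts) {
  num <- 0; den <- 0
  cells <- split(counts, paste(counts$gene_id, counts$condition))
  for (d in cells) {
    n <- d$cast + d$bl6
    k <- d$cast[n > 0]; n <- n[n > 0]
    if (length(n) < 2) next
    p <- sum(k) / sum(n)
    if (p <= 0 || p >= 1) next
    x2 <- sum((k - n * p)^2 / (n * p * (1 - p)))
    r <- length(n)
    num <- num + (x2 / (r - 1) - 1) * (r - 1)
    den <- den + (mean(n) - 1) * (r - 1)
  }
  if (den <= 0) return(0)
  clamp(num / den, 0, 0.5)
}

#' @keywords internal
bb_fit_gene <- function(cast1, tot1, cast2, tot2, rho) {
  # H1: free cast fraction per condition; H0: shared fraction; the shared
  # overdispersion rho is supplied (profile LRT), LRT ~ chisq(1)
  l1 <- bb_loglik_profile(cast1, tot1, rho) + bb_loglik_profile(cast2, tot2, rho)
  l0 <- bb_loglik_profile(c(cast1, cast2), c(tot1, tot2), rho)
  lrt <- max(0, 2 * (l1 - l0))
  pchisq(lrt, df = 1, lower.tail = FALSE)
}

#' Per-gene reactivation test between two conditions
#'
#' Tests, for each informative non-escapee gene, whether the cast (Xi) allelic
#' fraction differs between a treated and a control condition. The default
#' method is a beta-binomial likelihood-ratio test: under the alternative each
#' condition has its own cast fraction, under the null the fraction is common,
#' and replicate overdispersion enters through a single moment-based estimate
#' shared across genes (see [estimate_overdispersion()]; with three
#' replicates per condition a free per-gene dispersion is too unstable to
#' rank genes reliably, so the test borrows strength across the table, in the
#' spirit of the moderated-dispersion practice of count-based differential
#' expression). P values come from the asymptotic chi-square(1) null and are
#' BH-adjusted across tested genes. A gene is called reactivated when its FDR
#' is below `alpha` and its treated-minus-control pooled ratio difference is
#' positive. `method = "fisher"` replaces the LRT with a Fisher exact test on
#' replicate-pooled counts.
#'
#' @param counts Allelic count tibble.
#' @param genes_tested Character vector of gene ids to test (informative
#'   non-escapees).
#' @param treated_condition,control_condition Condition names.
#' @param alpha FDR level for the reactivated call.
#' @param method `"betabinom"` (default) or `"fisher"`.
#' @return A tibble with one row per tested gene: `gene_id`,
#'   `control_cast_ratio`, `treated_cast_ratio`, `delta_ratio` (pooled
#'   treated minus control ratio), `p_value`, `fdr`, `reactivated`.
#' @export
test_reactivation <- function(counts, genes_tested,
                              treated_condition = "tomato_high",
                              control_condition = "control",
                              alpha = 0.05,
                              method = c("betabinom", "fisher")) {
  method <- match.arg(method)
  validate_counts(counts)
  sub <- counts %>%
    filter(.data$gene_id %in% genes_tested,
           .data$condition %in% c(treated_condition, control_condition))
  rho <- if (method == "betabinom") estimate_overdispersion(sub) else 0
  nested <- split(sub, sub$gene_id)
  res <- purrr::map(nested, function(d) {
    ctrl <- d[d$condition == control_condition, ]
    trt <- d[d$condition == treated_condition, ]
    tot_c <- sum(ctrl$cast) + sum(ctrl$bl6)
    tot_t <- sum(trt$cast) + sum(trt$bl6)
    r_c <- if (tot_c > 0) sum(ctrl$cast) / tot_c else NA_real_
    r_t <- if (tot_t > 0) sum(trt$cast) / tot_t else NA_real_
    if (tot_c == 0 || tot_t == 0) {
      p <- NA_real_
    } else if (method == "fisher") {
      tab <- matrix(c(sum(trt$cast), sum(trt$bl6),
                      sum(ctrl$cast), sum(ctrl$bl6)), nrow = 2)
      p <- stats::fisher.test(tab)$p.value
    } else {
      p <- bb_fit_gene(ctrl$cast, ctrl$cast + ctrl$bl6,
                       trt$cast, trt$cast + trt$bl6, rho)
    }
    tibble(gene_id = d$gene_id[1], control_cast_ratio = r_c,
           treated_cast_ratio = r_t,
           delta_ratio = r_t - r_c, p_value = p)
  }) %>% bind_rows()
  if (nrow(res) == 0) {
    return(tibble(gene_id = character(), control_cast_ratio = numeric(),
                  treated_cast_ratio = numeric(), delta_ratio = numeric(),
                  p_value = numeric(), fdr = numeric(), reactivated = logical()))
  }
  res$fdr <- NA_real_
  tested <- !is.na(res$p_value)
  res$fdr[tested] <- p.adjust(res$p_value[tested], method = "BH")
  res$reactivated <- !is.na(res$fdr) & res$fdr < alpha &
    !is.na(res$delta_ratio) & res$delta_ratio > 0
  res
}

#' Classify every annotated X-linked gene
#'
#' Runs the full allelic-classification pipeline: informative filter, escapee
#' calling from control ratios, and the reactivation test on informative
#' non-escapees. Every annotated gene receives exactly one status:
#' `uninformative`, `escapee`, `reactivated` or `non_reactivated`.
#'
#' @param counts Allelic count tibble.
#' @param genes Gene tibble (see [read_gene_table()]).
#' @param min_reads Informative-filter threshold (mean total allelic reads
#'   per condition).
#' @param escape_threshold Control cast-ratio cutoff for escapees.
#' @param treated_condition,control_condition Conditions compared by the
#'   reactivation test.
#' @param alpha FDR level.
#' @param method Test method, `"betabinom"` or `"fisher"`.
#' @param conditions Conditions required by the informative filter (default:
#'   all conditions present).
#' @return An `xcr_classification` tibble with one row per annotated gene:
#'   `gene_id`, `name`, `tss`, `status`, `control_cast_ratio`,
#'   `treated_cast_ratio`, `delta_ratio`, `p_value`, `fdr`.
#' @export
classify_genes <- function(counts, genes, min_reads = 10,
                           escape_threshold = 0.10,
                           treated_condition = "tomato_high",
                           control_condition = "control",
                           alpha = 0.05,
                           method = c("betabinom", "fisher"),
                           conditions = NULL) {
  method <- match.arg(method)
  informative <- filter_informative(counts, min_reads, conditions)
  informative <- intersect(informative, genes$gene_id)
  escapees <- classify_escapees(counts, informative, escape_threshold,
                                control_condition)
  tested <- setdiff(informative, escapees)
  res <- test_reactivation(counts, tested, treated_condition,
                           control_condition, alpha, method)
  esc_ratios <- counts %>%
    filter(.data$gene_id %in% escapees) %>%
    group_by(.data$gene_id, .data$condition) %>%
    summarise(ratio = sum(.data$cast) / pmax(sum(.data$cast + .data$bl6), 1),
              .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "condition", values_from = "ratio")
  out <- genes %>%
    select("gene_id", "name", "tss") %>%
    left_join(res, by = "gene_id") %>%
    mutate(status = dplyr::case_when(
      .data$gene_id %in% escapees ~ "escapee",
      !.data$gene_id %in% informative ~ "uninformative",
      .data$reactivated ~ "reactivated",
      TRUE ~ "non_reactivated"
    ))
  if (nrow(esc_ratios) > 0 && control_condition %in% names(esc_ratios)) {
    idx <- match(out$gene_id, esc_ratios$gene_id)
    esc_ctrl <- esc_ratios[[control_condition]][idx]
    esc_trt <- if (treated_condition %in% names(esc_ratios)) {
      esc_ratios[[treated_condition]][idx]
    } else {
      NA_real_
    }
    is_esc <- out$status == "escapee"
    out$control_cast_ratio[is_esc] <- esc_ctrl[is_esc]
    out$treated_cast_ratio[is_esc] <- esc_trt[is_esc]
    out$delta_ratio[is_esc] <- (esc_trt - esc_ctrl)[is_esc]
  }
  out <- select(out, "gene_id", "name", "tss", "status",
                "control_cast_ratio", "treated_cast_ratio", "delta_ratio",
                "p_value", "fdr")
  structure(out,
            class = c("xcr_classification", class(out)),
            alpha = alpha, method = method,
            treated_condition = treated_condition,
            control_condition = control_condition,
            min_reads = min_reads, escape_threshold = escape_threshold)
}

#' Rank reactivated genes and count those above a reference
#'
#' Reactivated genes are ordered by ascending p value, ties broken by
#' descending `delta_ratio`, then by `gene_id`.
#'
#' @param classes An `xcr_classification` tibble (or any tibble with
#'   `gene_id`, `status`, `p_value`, `delta_ratio`).
#' @param reference_gene_id Gene id of the reference (must be reactivated).
#' @return A list with `ranking` (the ordered tibble of reactivated genes,
#'   with a `rank` column) and `n_above_reference` (count strictly above the
#'   reference).
#' @export
rank_reactivated <- function(classes, reference_gene_id) {
  re <- filter(as_tibble(classes), .data$status == "reactivated")
  if (!reference_gene_id %in% re$gene_id) {
    abort(sprintf("reference gene '%s' is not in the reactivated set",
                  reference_gene_id))
  }
  re <- re[order(re$p_value, -re$delta_ratio, re$gene_id), ]
  re$rank <- seq_len(nrow(re))
  list(ranking = re,
       n_above_reference = re$rank[re$gene_id == reference_gene_id] - 1L)
}

#' Treated-minus-control allelic ratio profile along the chromosome
#'
#' For each listed gene, the difference between the replicate-pooled cast
#' ratio in the treated and the control condition, ordered by TSS.
#'
#' @param counts Allelic count tibble.
#' @param genes Gene tibble restricted to the genes to profile (typically
#'   the informative set).
#' @param treated_condition,control_condition Condition names.
#' @return A tibble `gene_id`, `tss`, `control_ratio`, `treated_ratio`,
#'   `delta_ratio`, sorted by `tss`.
#' @export
delta_ratio_profile <- function(counts, genes,
                                treated_condition = "tomato_high",
                                control_condition = "control") {
  pooled <- counts %>%
    filter(.data$gene_id %in% genes$gene_id,
           .data$condition %in% c(treated_condition, control_condition)) %>%
    group_by(.data$gene_id, .data$condition) %>%
    summarise(total = sum(.data$cast + .data$bl6), cast = sum(.data$cast),
              .groups = "drop") %>%
    mutate(ratio = ifelse(.data$total > 0, .data$cast / .data$total, NA_real_)) %>%
    select("gene_id", "condition", "ratio") %>%
    tidyr::pivot_wider(names_from = "condition", values_from = "ratio")
  genes %>%
    select("gene_id", "tss") %>%
    left_join(pooled, by = "gene_id") %>%
    rename(control_ratio = !!control_condition,
           treated_ratio = !!treated_condition) %>%
    mutate(delta_ratio = .data$treated_ratio - .data$control_ratio) %>%
    arrange(.data$tss)
}
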