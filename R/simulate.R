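#' Simulation configuration for the synthetic X-reactivation dataset
#'
#' Defaults emulate the population structure of the study system: 2,612
#' X-linked genes of which 447 carry sufficient allelic coverage, 45 escapees,
#' 86 genes reactivated in the strongest-reporter (tomato_high) condition with
#' 7 planted effects strictly stronger than the designated reference gene
#' ("Mecp2"), 16 hypomethylated reactivated-gene promoters, and a TAD
#' landscape with 4 reactivation-enriched and 1 reactivation-depleted domain.
#'
#' @param seed Integer seed; every simulated quantity is a deterministic
#'   function of the configuration plus this seed.
#' @param chrom Chromosome name.
#' @param chrom_length_bp Chromosome length (default 171 Mb, the approximate
#'   mouse X length).
#' @param n_genes,n_informative,n_escapees,n_reactivated Class sizes.
#' @param n_above_mecp2 Number of reactivated genes planted with effects
#'   strictly stronger than the reference gene.
#' @param n_hypomethylated_promoters Reactivated-gene promoters planted with
#'   lower methylation in the treated condition.
#' @param n_replicates Biological replicates per condition.
#' @param conditions Condition names; `treated_condition` must be one of them.
#' @param treated_condition The condition in which reactivated genes have an
#'   elevated cast fraction.
#' @param mean_total_reads_per_gene Mean total allelic reads per replicate for
#'   informative genes (negative-binomial mean).
#' @param mean_total_reads_uninformative Same, for uninformative genes.
#' @param nb_dispersion Negative-binomial size parameter of per-replicate
#'   totals.
#' @param cast_fraction_inactive Cast (Xi) fraction of silenced genes.
#' @param cast_fraction_escapee_range Range of control cast fractions for
#'   escapees.
#' @param cast_fraction_reactivated_high Range of treated cast fractions for
#'   reactivated genes; effect tiers (bulk, reference, above-reference) are
#'   placed inside this range.
#' @param cpg_mean_reactivated,cpg_mean_non Poisson means of planted CpG
#'   counts in the upstream-2kb window, by class.
#' @param sine_mean_reactivated,sine_mean_non,line_mean_reactivated,line_mean_non
#'   Poisson means of planted SINE/LINE elements within +/-100 kb of the TSS.
#' @param escapee_proximity_bias Fraction of escapees placed in TADs that
#'   contain reactivated genes (drives the distance-to-escapee contrast).
#' @param n_tads,n_tads_enriched,n_tads_depleted TAD landscape.
#' @param tad_enriched_n_react,tad_enriched_n_non Reactivated/non-reactivated
#'   genes planted per enriched TAD.
#' @param tad_depleted_n_non Non-reactivated genes planted in the depleted TAD.
#' @param meth_site_depth Mean MeD-seq count per CpG site per sample at rate 1.
#' @param meth_hypomethylation_fold Multiplier on promoter-site methylation
#'   rates of hypomethylated promoters in the treated condition.
#' @param meth_global_treated_factor Genome-wide methylation-rate multiplier
#'   in the treated condition (global demethylation; cancels under
#'   per-sample normalization).
#' @param background_cpg Number of background CpG sites scattered over the
#'   chromosome.
#' @return A validated list of class `xcr_config`.
#' @export
xcr_config <- function(seed = 1L,
                       chrom = "chrX",
                       chrom_length_bp = 171e6,
                       n_genes = 2612L,
                       n_informative = 447L,
                       n_escapees = 45L,
                       n_reactivated = 86L,
                       n_above_mecp2 = 7L,
                       n_hypomethylated_promoters = 16L,
                       n_replicates = 3L,
                       conditions = c("control", "tomato_low", "tomato_med",
                                      "tomato_high"),
                       treated_condition = "tomato_high",
                       mean_total_reads_per_gene = 300,
                       mean_total_reads_uninformative = 1,
                       nb_dispersion = 50,
                       cast_fraction_inactive = 0.001,
                       cast_fraction_escapee_range = c(0.12, 0.50),
                       cast_fraction_reactivated_high = c(0.08, 0.30),
                       cpg_mean_reactivated = 30,
                       cpg_mean_non = 12,
                       sine_mean_reactivated = 25,
                       sine_mean_non = 15,
                       line_mean_reactivated = 8,
                       line_mean_non = 18,
                       escapee_proximity_bias = 0.75,
                       n_tads = 112L,
                       n_tads_enriched = 4L,
                       n_tads_depleted = 1L,
                       tad_enriched_n_react = 8L,
                       tad_enriched_n_non = 2L,
                       tad_depleted_n_non = 20L,
                       meth_site_depth = 15,
                       meth_hypomethylation_fold = 0.4,
                       meth_global_treated_factor = 0.8,
                       background_cpg = 3000L) {
  cfg <- as.list(environment())
  class(cfg) <- "xcr_config"
  validate_config(cfg)
  cfg
}

#' @keywords internal
validate_config <- function(cfg) {
  with(cfg, {
    if (n_escapees + n_reactivated > n_informative || n_informative > n_genes) {
      abort("infeasible config: need n_escapees + n_reactivated <= n_informative <= n_genes")
    }
    if (n_reactivated > 0 && n_above_mecp2 >= n_reactivated) {
      abort("infeasible config: n_above_mecp2 must be < n_reactivated")
    }
    if (n_reactivated == 0 && n_above_mecp2 != 0) {
      abort("infeasible config: n_above_mecp2 must be 0 when n_reactivated is 0")
    }
    if (n_hypomethylated_promoters > n_reactivated) {
      abort("infeasible config: more hypomethylated promoters than reactivated genes")
    }
    fr <- c(cast_fraction_inactive, cast_fraction_escapee_range,
            cast_fraction_reactivated_high)
    if (any(fr < 0 | fr > 1)) abort("infeasible config: fractions must lie in [0, 1]")
    if (cast_fraction_inactive >= cast_fraction_escapee_range[1]) {
      abort("infeasible config: cast_fraction_inactive must lie below the escapee range")
    }
    if (!treated_condition %in% conditions) {
      abort("treated_condition must be one of conditions")
    }
    if (n_tads_enriched + n_tads_depleted > n_tads) {
      abort("infeasible config: more special TADs than TADs")
    }
  })
  invisible(cfg)
}

#' Read/write a simulation configuration as YAML
#' @param path YAML file path.
#' @return For `read_xcr_config()`, an `xcr_config` list.
#' @export
read_xcr_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(xcr_config, vals)
}

#' @rdname read_xcr_config
#' @param config An `xcr_config` list.
#' @export
write_xcr_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# distribute `total` items over `n` slots: at most one each when possible,
# otherwise near-evenly with the remainder assigned to random slots
spread_over <- function(total, n) {
  if (n == 0) return(integer(0))
  counts <- integer(n)
  if (total <= n) {
    counts[sample.int(n, total)] <- 1L
  } else {
    base <- total %/% n
    counts[] <- base
    extra <- total - base * n
    if (extra > 0) {
      idx <- sample.int(n, extra)
      counts[idx] <- counts[idx] + 1L
    }
  }
  counts
}

#' Simulate a complete synthetic X-reactivation dataset
#'
#' Generates gene annotation, allelic counts, repeat and CpG annotation, TADs,
#' signal tracks, site-level methylation counts and the ground truth, with the
#' planted class structure described in [xcr_config()]. Totals per gene and
#' replicate are negative binomial; cast reads given the total are binomial
#' with the gene/condition cast fraction; methylation counts are Poisson.
#' Output is bit-identical for identical (config, seed).
#'
#' @param config An [xcr_config()] list.
#' @return A list (class `xcr_bundle`) with elements `config`, `genes`,
#'   `counts`, `cpg`, `repeats`, `tads`, `tracks` (named list of signal-track
#'   tibbles), `methylation` (site-level counts) and `truth` (list:
#'   `genes`, `tad_enriched`, `tad_depleted`, `hypomethylated`,
#'   `reference_gene`, `xist_gene`).
#' @export
simulate_xci <- function(config = xcr_config()) {
  validate_config(config)
  withr::local_seed(config$seed)
  L <- config$chrom_length_bp
  chrom <- config$chrom

  ## ---- TAD landscape -------------------------------------------------------
  w <- rgamma(config$n_tads, shape = 4, rate = 1)
  bounds <- round(cumsum(w) / sum(w) * L)
  tads <- tibble(
    tad_id = sprintf("TAD%03d", seq_len(config$n_tads)),
    chrom = chrom,
    start = c(0, bounds[-config$n_tads]),
    end = bounds
  )
  n_special <- config$n_tads_enriched + config$n_tads_depleted
  special <- sample.int(config$n_tads, n_special)
  enriched_idx <- special[seq_len(config$n_tads_enriched)]
  depleted_idx <- setdiff(special, enriched_idx)
  plain_idx <- setdiff(seq_len(config$n_tads), special)

  ## ---- per-TAD class composition ------------------------------------------
  react_tad <- integer(config$n_tads)
  per_enriched <- if (config$n_tads_enriched > 0) {
    min(config$tad_enriched_n_react,
        config$n_reactivated %/% max(1L, config$n_tads_enriched))
  } else 0L
  react_tad[enriched_idx] <- per_enriched
  react_rest <- config$n_reactivated - sum(react_tad)
  react_tad[plain_idx] <- spread_over(react_rest, length(plain_idx))

  nonreact_total <- config$n_informative - config$n_escapees - config$n_reactivated
  nonreact_tad <- integer(config$n_tads)
  nonreact_tad[depleted_idx] <- min(config$tad_depleted_n_non,
                                    nonreact_total %/% max(1L, length(depleted_idx) + 1L))
  nonreact_tad[enriched_idx] <- min(config$tad_enriched_n_non,
                                    max(0L, (nonreact_total - sum(nonreact_tad)) %/%
                                          max(1L, config$n_tads_enriched + 1L)))
  nonreact_rest <- nonreact_total - sum(nonreact_tad)
  nonreact_tad[plain_idx] <- nonreact_tad[plain_idx] +
    spread_over(nonreact_rest, length(plain_idx))

  esc_tad <- integer(config$n_tads)
  react_bearing <- which(react_tad > 0)
  n_bias <- round(config$escapee_proximity_bias * config$n_escapees)
  if (length(react_bearing) > 0 && n_bias > 0) {
    picks <- sample(react_bearing, n_bias, replace = TRUE)
    esc_tad <- esc_tad + tabulate(picks, nbins = config$n_tads)
  } else {
    n_bias <- 0L
  }
  if (config$n_escapees - n_bias > 0) {
    picks <- sample.int(config$n_tads, config$n_escapees - n_bias, replace = TRUE)
    esc_tad <- esc_tad + tabulate(picks, nbins = config$n_tads)
  }

  n_uninf <- config$n_genes - config$n_informative
  uninf_tad <- tabulate(
    sample.int(config$n_tads, n_uninf, replace = TRUE,
               prob = tads$end - tads$start),
    nbins = config$n_tads
  )

  ## ---- gene placement ------------------------------------------------------
  per_tad <- purrr::map(seq_len(config$n_tads), function(t) {
    cls <- c(rep("reactivated", react_tad[t]),
             rep("non_reactivated", nonreact_tad[t]),
             rep("escapee", esc_tad[t]),
             rep("uninformative", uninf_tad[t]))
    g <- length(cls)
    if (g == 0) return(NULL)
    pos <- sort(floor(runif(g, tads$start[t], tads$end[t] - 1)))
    tibble(tss = pos, class = sample(cls), tad_id = tads$tad_id[t])
  })
  placed <- bind_rows(per_tad) %>% arrange(.data$tss)
  n <- nrow(placed)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  len <- round(clamp(rlnorm(n, log(2e4), 0.8), 2000, 2e5))
  start <- ifelse(strand == "+", placed$tss, pmax(0, placed$tss - len + 1))
  end <- ifelse(strand == "+", pmin(L, placed$tss + len), placed$tss + 1)
  genes <- tibble(
    gene_id = sprintf("XG%04d", seq_len(n)),
    name = sprintf("XG%04d", seq_len(n)),
    chrom = chrom, start = start, end = end, strand = strand
  ) %>% derive_tss_tes()
  stopifnot(all(genes$tss == placed$tss))
  class_vec <- placed$class

  react_ids <- genes$gene_id[class_vec == "reactivated"]
  esc_ids <- genes$gene_id[class_vec == "escapee"]
  reference_gene <- NA_character_
  above_ids <- character()
  if (length(react_ids) > 0) {
    reference_gene <- sample(react_ids, 1)
    genes$name[genes$gene_id == reference_gene] <- "Mecp2"
    above_ids <- sample(setdiff(react_ids, reference_gene), config$n_above_mecp2)
  }
  xist_gene <- NA_character_
  if (length(esc_ids) > 0) {
    xist_gene <- sample(esc_ids, 1)
    genes$name[genes$gene_id == xist_gene] <- "Xist"
  }

  ## ---- true cast fractions -------------------------------------------------
  f0 <- config$cast_fraction_inactive
  lo <- config$cast_fraction_reactivated_high[1]
  hi <- config$cast_fraction_reactivated_high[2]
  span <- hi - lo
  frac <- matrix(f0, nrow = n, ncol = length(config$conditions),
                 dimnames = list(genes$gene_id, config$conditions))
  esc_f <- runif(length(esc_ids), config$cast_fraction_escapee_range[1],
                 config$cast_fraction_escapee_range[2])
  frac[esc_ids, ] <- esc_f  # escapees are expressed from the Xi throughout
  if (length(react_ids) > 0) {
    bulk_ids <- setdiff(react_ids, c(reference_gene, above_ids))
    # effect tiers inside the configured range: bulk in the lower 20%,
    # the reference gene at 55%, above-reference genes in the top 15%
    frac[bulk_ids, config$treated_condition] <-
      runif(length(bulk_ids), lo, lo + 0.2 * span)
    frac[reference_gene, config$treated_condition] <- lo + 0.55 * span
    frac[above_ids, config$treated_condition] <-
      runif(length(above_ids), lo + 0.85 * span, hi)
  }

  mu <- ifelse(class_vec == "uninformative",
               config$mean_total_reads_uninformative,
               config$mean_total_reads_per_gene)

  truth_genes <- tibble(
    gene_id = genes$gene_id, name = genes$name, class = class_vec,
    tad_id = placed$tad_id, tss = genes$tss, mean_reads = mu
  )
  for (cond in config$conditions) {
    truth_genes[[paste0("f_", cond)]] <- frac[, cond]
  }
  hypo_ids <- if (length(react_ids) > 0) {
    sample(react_ids, config$n_hypomethylated_promoters)
  } else character()
  truth_genes$hypomethylated <- truth_genes$gene_id %in% hypo_ids

  ## ---- allelic counts ------------------------------------------------------
  counts <- draw_counts(truth_genes, config)

  ## ---- CpG sites -----------------------------------------------------------
  cpg_mean <- ifelse(class_vec == "reactivated",
                     config$cpg_mean_reactivated, config$cpg_mean_non)
  n_cpg <- rpois(n, cpg_mean)
  win <- tss_window(genes, upstream = 2000, downstream = 0)
  cpg_pos <- unlist(purrr::map(seq_len(n), function(i) {
    if (n_cpg[i] == 0) return(numeric(0))
    floor(runif(n_cpg[i], win$start[i], win$end[i]))
  }))
  bg <- floor(runif(config$background_cpg, 0, L))
  cpg <- tibble(chrom = chrom, start = sort(unique(c(cpg_pos, bg)))) %>%
    mutate(end = .data$start + 1)

  ## ---- repeats -------------------------------------------------------------
  repeats <- draw_repeats(genes, class_vec, config)

  ## ---- signal tracks -------------------------------------------------------
  tracks <- draw_tracks(genes, class_vec, config)

  ## ---- methylation ---------------------------------------------------------
  methylation <- draw_methylation(cpg, genes, class_vec, hypo_ids, config)

  structure(list(
    config = config, genes = genes, counts = counts, cpg = cpg,
    repeats = repeats, tads = tads, tracks = tracks, methylation = methylation,
    truth = list(
      genes = truth_genes,
      tad_enriched = tads$tad_id[enriched_idx],
      tad_depleted = tads$tad_id[depleted_idx],
      hypomethylated = hypo_ids,
      reference_gene = reference_gene,
      xist_gene = xist_gene
    )
  ), class = "xcr_bundle")
}

#' @keywords internal
draw_counts <- function(truth_genes, config) {
  n <- nrow(truth_genes)
  if (all(truth_genes$mean_reads == 0)) {
    warn("all gene read means are zero; emitting all-zero counts")
  }
  grid <- tidyr::expand_grid(
    gene_idx = seq_len(n),
    condition = config$conditions,
    replicate = seq_len(config$n_replicates)
  )
  mu <- truth_genes$mean_reads[grid$gene_idx]
  f <- purrr::map2_dbl(grid$gene_idx, grid$condition,
                       function(i, cond) truth_genes[[paste0("f_", cond)]][i])
  total <- rnbinom(nrow(grid), size = config$nb_dispersion, mu = mu)
  total[mu == 0] <- 0L
  cast <- rbinom(nrow(grid), size = total, prob = f)
  tibble(
    gene_id = truth_genes$gene_id[grid$gene_idx],
    condition = grid$condition,
    replicate = grid$replicate,
    cast = cast,
    bl6 = total - cast
  )
}

#' @keywords internal
draw_repeats <- function(genes, class_vec, config) {
  n <- nrow(genes)
  L <- config$chrom_length_bp
  sine_mean <- ifelse(class_vec == "reactivated",
                      config$sine_mean_reactivated, config$sine_mean_non)
  line_mean <- ifelse(class_vec == "reactivated",
                      config$line_mean_reactivated, config$line_mean_non)
  n_sine <- rpois(n, sine_mean)
  n_line <- rpois(n, line_mean)
  line_families <- c("L1Md_T", "L1Md_A", "L1_Mus", "Lx", "L2")

  mk <- function(counts, kind) {
    gene_idx <- rep(seq_len(n), counts)
    total <- length(gene_idx)
    if (total == 0) return(NULL)
    mid <- clamp(floor(runif(total, genes$tss[gene_idx] - 1e5,
                             genes$tss[gene_idx] + 1e5)),
                 5000, L - 8000)
    if (kind == "SINE") {
      len <- sample(100:400, total, replace = TRUE)
      fam <- sample(c("B1", "B2", "B4", "MIR"), total, replace = TRUE)
      age <- rep(NA_integer_, total)
    } else {
      full <- runif(total) < 0.3
      len <- ifelse(full, round(runif(total, 6000, 7000)),
                    round(runif(total, 500, 5999)))
      age <- sample.int(5, total, replace = TRUE)
      fam <- line_families[age]
    }
    start <- mid - len %/% 2
    tibble(chrom = config$chrom, start = start, end = start + len,
           repeat_class = kind, family = fam, age_rank = age,
           length_bp = len,
           strand = sample(c("+", "-"), total, replace = TRUE))
  }
  bind_rows(mk(n_sine, "SINE"), mk(n_line, "LINE")) %>%
    arrange(.data$start)
}

# accumulate (cell, value) contributions onto a regular grid track
grid_track <- function(chrom, cell_idx, values, bin_bp) {
  agg <- tibble(cell = cell_idx, value = values) %>%
    group_by(.data$cell) %>%
    summarise(value = sum(.data$value), .groups = "drop") %>%
    arrange(.data$cell)
  tibble(chrom = chrom, start = agg$cell * bin_bp,
         end = (agg$cell + 1) * bin_bp, value = agg$value)
}

#' @keywords internal
draw_tracks <- function(genes, class_vec, config) {
  n <- nrow(genes)
  bin <- 500
  flank_cells <- -6:5  # covers tss +/- 3 kb at 500 bp
  tss_cell <- genes$tss %/% bin
  expressed <- class_vec != "uninformative"
  silenced <- class_vec %in% c("non_reactivated", "uninformative")

  tss_track <- function(amp) {
    cells <- pmax(0, rep(tss_cell, each = length(flank_cells)) +
                    rep(flank_cells, times = n))
    shape <- exp(-(flank_cells + 0.5)^2 / 8)
    vals <- rep(amp, each = length(flank_cells)) * rep(shape, times = n)
    grid_track(config$chrom, cells, vals, bin)
  }
  body_track <- function(amp) {
    cell_lo <- genes$start %/% bin
    cell_hi <- (genes$end - 1) %/% bin
    n_cells <- cell_hi - cell_lo + 1
    cells <- unlist(purrr::map(seq_len(n), function(i) cell_lo[i]:cell_hi[i]))
    vals <- rep(amp, times = n_cells)
    grid_track(config$chrom, cells, vals, bin)
  }

  list(
    ctcf = tss_track(rgamma(n, 4, 1)),
    rad21 = tss_track(rgamma(n, 3, 1)),
    h3k4me3 = tss_track(ifelse(expressed, 8, 1) * rgamma(n, 4, 4)),
    h3k27me3 = tss_track(ifelse(silenced, 5, 0.5) * rgamma(n, 4, 4)),
    xist_chart = body_track(
      dplyr::case_when(class_vec == "escapee" ~ 0.5,
                       class_vec == "reactivated" ~ 3,
                       TRUE ~ 6) * rgamma(n, 8, 8))
  )
}

#' @keywords internal
draw_methylation <- function(cpg, genes, class_vec, hypo_ids, config) {
  n_sites <- nrow(cpg)
  base_rate <- rgamma(n_sites, shape = 8, rate = 8)
  pos <- cpg$start

  in_promoter_of <- function(ids) {
    if (length(ids) == 0) return(rep(FALSE, n_sites))
    sel <- genes[genes$gene_id %in% ids, ]
    hit <- rep(FALSE, n_sites)
    p_start <- sel$tss - 1000
    p_end <- sel$tss + 1000
    o <- order(p_start)
    p_start <- p_start[o]; p_end <- p_end[o]
    idx <- findInterval(pos, p_start)
    # promoter windows are 2 kb; checking a handful of preceding windows
    # suffices because TSSs are further apart than that in practice
    for (back in 0:3) {
      j <- idx - back
      ok <- j >= 1
      hit[ok] <- hit[ok] | (pos[ok] < p_end[j[ok]] & pos[ok] >= p_start[j[ok]])
    }
    hit
  }

  informative_ids <- genes$gene_id[class_vec != "uninformative"]
  in_inf_prom <- in_promoter_of(informative_ids)
  in_hypo_prom <- in_promoter_of(hypo_ids)

  cond_factor <- setNames(rep(1, length(config$conditions)), config$conditions)
  cond_factor[config$treated_condition] <- config$meth_global_treated_factor

  samples <- tidyr::expand_grid(condition = config$conditions,
                                replicate = seq_len(config$n_replicates)) %>%
    mutate(sample_id = paste0(.data$condition, "_", .data$replicate)) %>%
    bind_rows(tibble(condition = "male_xa", replicate = 1L,
                     sample_id = "male_xa_1"))

  out <- purrr::pmap(samples, function(condition, replicate, sample_id) {
    if (condition == "male_xa") {
      rate <- base_rate
      rate[in_inf_prom] <- rate[in_inf_prom] * 0.1
    } else {
      rate <- base_rate * cond_factor[[condition]]
      if (condition == config$treated_condition) {
        rate[in_hypo_prom] <- rate[in_hypo_prom] * config$meth_hypomethylation_fold
      }
    }
    tibble(chrom = cpg$chrom, pos = pos, sample_id = sample_id,
           condition = condition,
           count = rpois(n_sites, config$meth_site_depth * rate))
  }) %>% bind_rows()
  out
}

#' Redraw allelic counts over a fixed ground truth
#'
#' Produces a fresh noise realisation of the allelic count table for the
#' ground truth of a previous [simulate_xci()] run (useful for calibration
#' and power studies).
#'
#' @param config The [xcr_config()] used for the original run.
#' @param truth The `truth` element of an `xcr_bundle`.
#' @param new_seed Seed for the fresh counts.
#' @return An allelic count tibble.
#' @export
regenerate_counts <- function(config, truth, new_seed) {
  if (nrow(truth$genes) != config$n_genes) {
    abort("truth/config mismatch: gene counts differ")
  }
  if (!all(paste0("f_", config$conditions) %in% names(truth$genes))) {
    abort("truth/config mismatch: missing per-condition cast fractions")
  }
  withr::local_seed(new_seed)
  draw_counts(truth$genes, config)
}

#' Write a simulated bundle to disk
#'
#' Emits the gene table, allelic counts, CpG BED, repeat BED, TAD BED, one
#' bedGraph per signal track, the site-level methylation table and the
#' ground-truth table, all in the package's standard text formats.
#'
#' @param bundle An `xcr_bundle` from [simulate_xci()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_xci_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  paths <- c(
    genes = p("genes.tsv"), counts = p("allelic_counts.tsv"),
    cpg = p("cpg_sites.bed"), repeats = p("repeats.bed"),
    tads = p("tads.bed"), methylation = p("methylation_sites.tsv"),
    truth = p("ground_truth.tsv")
  )
  readr::write_tsv(select(bundle$genes, "gene_id", "name", "chrom", "start",
                          "end", "strand"), paths[["genes"]])
  readr::write_tsv(bundle$counts, paths[["counts"]])
  write_bed(select(bundle$cpg, "chrom", "start", "end"), paths[["cpg"]])
  write_repeat_bed(bundle$repeats, paths[["repeats"]])
  write_bed(bundle$tads %>% select("chrom", "start", "end", name = "tad_id"),
            paths[["tads"]])
  readr::write_tsv(bundle$methylation, paths[["methylation"]])
  readr::write_tsv(bundle$truth$genes, paths[["truth"]])
  for (nm in names(bundle$tracks)) {
    paths[[paste0("track_", nm)]] <- p(paste0(nm, ".bedGraph"))
    write_bedgraph(bundle$tracks[[nm]], paths[[paste0("track_", nm)]])
  }
  invisible(paths)
}
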