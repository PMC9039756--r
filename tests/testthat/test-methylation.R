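sites_tbl <- function(pos, sample_id, condition, count) {
  tibble::tibble(chrom = "chrX", pos = pos, sample_id = sample_id,
                 condition = condition, count = count)
}

test_that("promoter regions are symmetric TSS windows with distinct ids", {
  g <- make_genes(c("a", "b"), c(10000, 10000), c(20000, 20000))
  pr <- promoter_regions(g, 1000)
  expect_equal(pr$start, c(9000, 9000))
  expect_equal(pr$end, c(11000, 11000))
  expect_equal(anyDuplicated(pr$region_id), 0)  # shared TSS, distinct regions
  expect_error(promoter_regions(g, 0), "positive")
})

test_that("aggregation sums site counts within regions and zero-fills", {
  regions <- tibble::tibble(region_id = c("r1", "r2"),
                            start = c(100, 500), end = c(200, 600))
  sites <- sites_tbl(c(150, 160, 550, 900), "s1", "control", c(3, 4, 5, 9))
  agg <- aggregate_methylation(sites, regions)
  expect_equal(agg$count[agg$region_id == "r1"], 7)
  expect_equal(agg$count[agg$region_id == "r2"], 5)  # site at 900 ignored

  # a region with no sites appears with count 0
  regions2 <- rbind(regions, tibble::tibble(region_id = "r3",
                                            start = 5000, end = 6000))
  agg2 <- aggregate_methylation(sites, regions2)
  expect_equal(agg2$count[agg2$region_id == "r3"], 0)

  # overlapping regions each receive their own sites
  regions3 <- tibble::tibble(region_id = c("a", "b"),
                             start = c(100, 140), end = c(200, 240))
  agg3 <- aggregate_methylation(sites_tbl(150, "s1", "control", 2), regions3)
  expect_equal(agg3$count, c(2, 2))
})

test_that("normalization is scale invariant and rejects empty samples", {
  counts <- tibble::tibble(
    region_id = rep(c("r1", "r2"), 2),
    sample_id = rep(c("s1", "s2"), each = 2),
    condition = "control",
    count = c(250, 750, 500, 1500))
  norm <- normalize_methylation(counts)
  expect_equal(norm$cpm[norm$sample_id == "s1"],
               norm$cpm[norm$sample_id == "s2"])  # s2 = 2 x s1
  expect_equal(norm$cpm[norm$region_id == "r1" & norm$sample_id == "s1"],
               250 / 1000 * 1e6)

  single <- tibble::tibble(region_id = "r1", sample_id = "s1",
                           condition = "control", count = 42)
  expect_equal(normalize_methylation(single)$cpm, 1e6)

  counts$count[counts$sample_id == "s2"] <- 0
  expect_error(normalize_methylation(counts), "s2")
})

test_that("differential methylation calls a strong drop and matches the Fisher oracle", {
  mk <- function(r1_ctrl, r1_trt) {
    tibble::tibble(
      region_id = rep(c("r1", "bulk"), each = 4),
      sample_id = rep(paste0("s", 1:4), 2),
      condition = rep(c("control", "control", "tomato_high", "tomato_high"), 2),
      count = c(r1_ctrl / 2, r1_ctrl / 2, r1_trt / 2, r1_trt / 2,
                (1e6 - r1_ctrl) / 2, (1e6 - r1_ctrl) / 2,
                (1e6 - r1_trt) / 2, (1e6 - r1_trt) / 2))
  }
  dm <- tidy(differential_methylation(mk(500, 100)))
  r1 <- dm[dm$region_id == "r1", ]
  oracle <- fisher.test(matrix(c(500, 1e6 - 500, 100, 1e6 - 100),
                               nrow = 2))$p.value
  expect_lt(oracle, 1e-6)
  expect_true(r1$significantly_lower)
  expect_lt(r1$p_value, 1e-6)
  expect_lt(r1$treated_normalized_rate, r1$control_normalized_rate)

  # identical pooled tables: p ~ 1, nothing called
  dm0 <- tidy(differential_methylation(mk(500, 500)))
  expect_gt(dm0$p_value[dm0$region_id == "r1"], 0.9)
  expect_false(any(dm0$significantly_lower))
})

test_that("chi-square p values track prop.test and Fisher handles small counts", {
  set.seed(21)
  for (i in 1:50) {
    a <- rpois(1, 400) + 10; b <- rpois(1, 300) + 10
    ta <- 5e5; tb <- 6e5
    counts <- tibble::tibble(
      region_id = rep(c("r", "rest"), each = 2),
      sample_id = rep(c("c1", "t1"), 2),
      condition = rep(c("control", "tomato_high"), 2),
      count = c(a, b, ta - a, tb - b))
    dm <- tidy(differential_methylation(counts))
    ours <- dm$p_value[dm$region_id == "r"]
    ref <- suppressWarnings(
      prop.test(c(a, b), c(ta, tb), correct = TRUE))$p.value
    expect_equal(ours, ref, tolerance = 1e-9)
  }

  # tiny pooled counts route through Fisher's exact test
  tiny <- tibble::tibble(
    region_id = rep(c("r", "rest"), each = 2),
    sample_id = rep(c("c1", "t1"), 2),
    condition = rep(c("control", "tomato_high"), 2),
    count = c(3, 0, 1000, 1200))
  dm <- tidy(differential_methylation(tiny))
  ref <- fisher.test(matrix(c(3, 1000, 0, 1200), nrow = 2))$p.value
  expect_equal(dm$p_value[dm$region_id == "r"], ref, tolerance = 1e-12)

  # regions empty in both conditions are reported untested
  empty <- tibble::tibble(
    region_id = rep(c("r", "rest"), each = 2),
    sample_id = rep(c("c1", "t1"), 2),
    condition = rep(c("control", "tomato_high"), 2),
    count = c(0, 0, 1000, 1200))
  dm <- tidy(differential_methylation(empty))
  expect_true(is.na(dm$p_value[dm$region_id == "r"]))
})

test_that("promoter clustering separates planted blocks but not weak signal", {
  set.seed(8)
  # two blocks with opposite condition patterns (per-region z-scoring removes
  # level differences, so the planted signal must live in the profile shape)
  n_r <- 12; n_n <- 24; n_s <- 6
  pat_down <- rep(c(300, 100), each = n_s / 2)  # drops in the second half
  pat_up <- rep(c(100, 300), each = n_s / 2)
  mat_rates <- rbind(
    matrix(rep(pat_down, each = n_r), n_r) + rnorm(n_r * n_s, 0, 5),
    matrix(rep(pat_up, each = n_n), n_n) + rnorm(n_n * n_s, 0, 5))
  regions <- tibble::tibble(region_id = paste0("r", 1:(n_r + n_n)),
                            gene_id = paste0("g", 1:(n_r + n_n)))
  classes <- tibble::tibble(gene_id = regions$gene_id,
                            status = rep(c("reactivated", "non_reactivated"),
                                         c(n_r, n_n)))
  norm <- tibble::tibble(
    region_id = rep(regions$region_id, n_s),
    sample_id = rep(paste0("s", 1:n_s), each = n_r + n_n),
    condition = "control",
    cpm = as.numeric(mat_rates))
  res <- cluster_promoters(norm, regions, classes, n_permutations = 200)
  expect_equal(res$purity, 1)
  expect_lt(res$permutation_p, 0.01)

  # constant matrix: purity undefined
  norm$cpm <- 5
  res0 <- cluster_promoters(norm, regions, classes, n_permutations = 50)
  expect_true(is.na(res0$purity))

  expect_error(cluster_promoters(norm[norm$region_id %in%
                                        regions$region_id[1:2], ],
                                 regions, classes), "at least 4")
})

test_that("default-bundle promoter clustering reproduces the negative finding", {
  b <- default_bundle()
  cl <- default_classification()
  keep <- tidy(cl)$gene_id[tidy(cl)$status %in% c("reactivated",
                                                  "non_reactivated")]
  regions <- promoter_regions(b$genes[b$genes$gene_id %in% keep, ])
  agg <- aggregate_methylation(b$methylation, regions)
  norm <- normalize_methylation(agg)
  res <- cluster_promoters(norm, regions, cl, n_permutations = 200)
  # hypomethylation touches only a minority of reactivated promoters, so a
  # 2-way cut must not collect the reactivated class into one cluster
  expect_gte(res$permutation_p, 0.05)
})

test_that("repeat flank methylation is computed per element and compared per class", {
  b <- default_bundle()
  cl <- default_classification()
  res <- repeat_flank_methylation(b$repeats, b$methylation, cl, b$genes,
                                  conditions = c("control", "tomato_high"))
  expect_setequal(unique(res$comparisons$feature),
                  c("SINE_flank_methylation", "LINE_flank_methylation"))
  expect_true(all(res$elements$flank_rate >= 0))
  expect_true(all(res$elements$near_class %in%
                    c("reactivated", "non_reactivated")))

  # no flank effect is planted: comparisons should be null at seed 1
  expect_true(all(res$comparisons$p_value > 0.05))
})

test_that("a single repeat element yields a warning, not a comparison", {
  b <- default_bundle()
  cl <- default_classification()
  one <- b$repeats[which(b$repeats$repeat_class == "SINE")[1], ]
  expect_warning(res <- repeat_flank_methylation(one, b$methylation, cl,
                                                 b$genes), "< 2 elements")
  expect_equal(nrow(res$comparisons), 0)
})
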