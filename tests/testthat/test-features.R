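cpg_at <- function(pos) tibble::tibble(chrom = "chrX", start = pos,
                                       end = pos + 1)

test_that("upstream CpG counting is half-open at the TSS and strand-aware", {
  g <- make_genes("g", 10000, 20000, "+")
  expect_equal(count_cpg_upstream(g, cpg_at(c(8100, 9000, 9999)))$cpg_upstream, 3)
  expect_equal(count_cpg_upstream(g, cpg_at(10000))$cpg_upstream, 0)  # TSS itself
  expect_equal(count_cpg_upstream(g, cpg_at(7999))$cpg_upstream, 0)   # outside
  expect_equal(count_cpg_upstream(g, cpg_at(8000))$cpg_upstream, 1)   # boundary in

  gm <- make_genes("g", 5000, 10001, "-")  # tss = 10000, upstream to the right
  expect_equal(count_cpg_upstream(gm, cpg_at(c(10001, 12000, 12001)))$cpg_upstream, 2)

  empty <- tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric())
  expect_equal(count_cpg_upstream(g, empty)$cpg_upstream, 0)
})

test_that("repeat counting uses the midpoint rule on a closed window", {
  g <- make_genes("g", 1e6, 1.1e6, "+")  # tss = 1e6
  reps <- tibble::tibble(
    chrom = "chrX",
    start = c(1e6 - 100000 - 50, 1e6 + 100000 - 50, 1e6 + 100000 + 1, 1e6),
    end = c(1e6 - 100000 + 50, 1e6 + 100000 + 50, 1e6 + 100000 + 201, 1e6 + 100),
    repeat_class = c("SINE", "SINE", "SINE", "LINE"))
  # midpoints: tss-1e5 (in, closed), tss+1e5 (in), tss+1e5+101 (out), tss+50 (in, LINE)
  expect_equal(count_repeats_near_tss(g, reps, "SINE")$n_repeats, 2)
  expect_equal(count_repeats_near_tss(g, reps, "LINE")$n_repeats, 1)
  expect_equal(count_repeats_near_tss(g, reps, NULL)$n_repeats, 3)
})

test_that("class-filtered repeat counts sum to the unfiltered count", {
  b <- default_bundle()
  g <- b$genes[seq(1, nrow(b$genes), by = 40), ]
  s <- count_repeats_near_tss(g, b$repeats, "SINE")$n_repeats
  l <- count_repeats_near_tss(g, b$repeats, "LINE")$n_repeats
  all_ <- count_repeats_near_tss(g, b$repeats, NULL)$n_repeats
  expect_equal(s + l, all_)
})

test_that("LINE stratification respects the 6 kb boundary and the age contract", {
  reps <- tibble::tibble(
    chrom = "chrX", start = c(0, 0, 0), end = c(6000, 5999, 300),
    repeat_class = c("LINE", "LINE", "SINE"),
    family = c("L1Md_T", "L2", "B1"),
    age_rank = c(1L, 5L, NA), length_bp = c(6000, 5999, 300),
    strand = "+")
  strata <- stratify_lines(reps, by = "size")
  expect_equal(nrow(strata$full_length), 1)  # 6000 bp is full length (>=)
  expect_equal(nrow(strata$short), 1)
  expect_false("SINE" %in% c(strata$full_length$repeat_class,
                             strata$short$repeat_class))

  by_age <- stratify_lines(reps, by = "age")
  expect_named(by_age, c("age_1", "age_5"))

  reps$age_rank[1] <- NA
  expect_error(stratify_lines(reps, by = "age"), "age_rank")
})

test_that("distance to nearest anchor excludes self and is 1-Lipschitz", {
  genes <- make_genes(c("g", "e1", "e2"), c(5e6, 4e6, 7.5e6),
                      c(5.01e6, 4.01e6, 7.51e6))
  anchors <- genes[genes$gene_id != "g", c("gene_id", "tss")]
  expect_equal(distance_to_nearest(genes[1, ], anchors)$dist_bp, 1e6)

  # an anchor gene measuring its own distance skips itself
  expect_equal(distance_to_nearest(genes[2, ], anchors)$dist_bp, 3.5e6)
  only_self <- anchors[anchors$gene_id == "e1", ]
  expect_true(is.na(distance_to_nearest(genes[2, ], only_self)$dist_bp))

  # bare positions work too (e.g. the Xist locus)
  expect_equal(distance_to_nearest(genes[1, ], 6e6)$dist_bp, 1e6)

  # 1-Lipschitz: moving the TSS by d changes the distance by at most d
  set.seed(5)
  apos <- sort(runif(10, 0, 1e7))
  for (i in 1:20) {
    t1 <- runif(1, 0, 1e7); d <- runif(1, 0, 1e5)
    g1 <- make_genes("q", t1, t1 + 10)
    g2 <- make_genes("q", t1 + d, t1 + d + 10)
    d1 <- distance_to_nearest(g1, apos)$dist_bp
    d2 <- distance_to_nearest(g2, apos)$dist_bp
    expect_lte(abs(d1 - d2), d + 1e-6)
  }
})

test_that("metagene profiles conserve constant tracks and average linearly", {
  const_track <- function(value) tibble::tibble(chrom = "chrX", start = 0,
                                                end = 1e6, value = value)
  g1 <- make_genes("a", 5e5, 5e5 + 2e4, "+")
  g2 <- make_genes("b", 3e5, 3e5 + 2e4, "-")
  p1 <- metagene_profile(g1, const_track(4))
  expect_true(all(abs(p1$mean_signal - 4) < 1e-12))

  # linearity: two genes on constant tracks c1 and c2 average to (c1 + c2)/2
  # (emulated by averaging two single-gene profiles on different tracks)
  p2 <- metagene_profile(g2, const_track(10))
  expect_true(all(abs((p1$mean_signal + p2$mean_signal) / 2 - 7) < 1e-12))

  # strand mirroring: a delta of signal upstream of the TSS lands in the
  # same profile bin for a + gene and its - twin
  delta_plus <- tibble::tibble(chrom = "chrX", start = 5e5 - 1000,
                               end = 5e5 - 950, value = 8)
  gp <- make_genes("p", 5e5, 5e5 + 1e4, "+")
  gm <- make_genes("m", 5e5 - 1e4, 5e5 + 1, "-")  # tss = 5e5
  delta_minus <- tibble::tibble(chrom = "chrX", start = 5e5 + 951,
                                end = 5e5 + 1001, value = 8)
  pp <- metagene_profile(gp, delta_plus)
  pm <- metagene_profile(gm, delta_minus)
  expect_equal(which.max(pp$mean_signal), which.max(pm$mean_signal))
  # the one-base closed/open asymmetry of the mirrored window can shift a
  # single base across a bin edge, so equality is up to 1/bin_bp
  expect_equal(max(pp$mean_signal), max(pm$mean_signal), tolerance = 0.05)

  expect_error(metagene_profile(g1[0, ], const_track(1)), "at least one gene")
})

test_that("scaled-body profiles skip too-short genes and conserve constants", {
  track <- tibble::tibble(chrom = "chrX", start = 0, end = 1e6, value = 3)
  genes <- rbind(make_genes("long", 4e5, 4.5e5, "+"),
                 make_genes("tiny", 1e5, 1e5 + 50, "+"))
  expect_warning(p <- metagene_profile(genes, track, mode = "scaled_body"),
                 "shorter")
  expect_true(all(abs(p$mean_signal - 3) < 1e-12))
  expect_equal(unique(p$n_genes), 1)
  expect_equal(sum(p$position == "body"), 100)
})

test_that("class comparisons on the default bundle recover the planted directions", {
  b <- default_bundle()
  cl <- default_classification()
  ft <- build_feature_table(b$genes, cl, b$repeats, b$cpg)
  cmp <- compare_classes(ft, cl,
                         feature_names = c("cpg_upstream_2kb", "sine_100kb",
                                           "line_100kb"))
  cpg <- cmp[cmp$feature == "cpg_upstream_2kb", ]
  expect_lt(cpg$p_value, 0.01)
  expect_equal(cpg$direction, "reactivated")
  expect_equal(cmp$direction[cmp$feature == "sine_100kb"], "reactivated")
  expect_equal(cmp$direction[cmp$feature == "line_100kb"], "non_reactivated")

  # full-length + short LINE counts partition the LINE count
  expect_equal(ft$line_full_length_100kb + ft$line_short_100kb, ft$line_100kb)
})

test_that("comparisons with a degenerate class are skipped with a warning", {
  ft <- tibble::tibble(gene_id = c("a", "b", "c"), x = c(1, 2, 3))
  cl <- tibble::tibble(gene_id = c("a", "b", "c"),
                       status = c("reactivated", "non_reactivated",
                                  "non_reactivated"))
  expect_warning(out <- compare_classes(ft, cl, "x"), "< 2 values")
  expect_equal(nrow(out), 0)
})
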