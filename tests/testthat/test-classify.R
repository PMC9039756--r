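test_that("allelic_ratio handles the basic arithmetic and the 0/0 case", {
  expect_equal(allelic_ratio(5, 5), 0.5)
  expect_equal(allelic_ratio(0, 10), 0)
  expect_equal(allelic_ratio(19, 81), 0.19)
  expect_true(is.na(allelic_ratio(0, 0)))
  expect_equal(allelic_ratio(c(1, 0), c(1, 0)), c(0.5, NA))
})

test_that("informative filter requires the mean coverage in every condition", {
  counts <- rbind(
    make_counts(rep("keep", 6), rep(c("control", "treated"), each = 3),
                cast = c(2, 2, 3, 2, 1, 3), bl6 = c(10, 9, 10, 10, 10, 10)),
    make_counts(rep("drop", 6), rep(c("control", "treated"), each = 3),
                cast = c(2, 2, 3, 1, 1, 0), bl6 = c(10, 9, 10, 1, 0, 0))
  )
  kept <- filter_informative(counts, min_allelic_reads = 10)
  expect_equal(kept, "keep")
  expect_error(filter_informative(counts, 10, conditions = "nope"),
               "unknown condition")
})

test_that("escapee calling averages per-replicate control ratios and is threshold-monotone", {
  counts <- rbind(
    make_counts(rep("esc", 3), "control", cast = c(20, 25, 15),
                bl6 = c(80, 75, 85)),
    make_counts(rep("sil", 3), "control", cast = c(1, 1, 1),
                bl6 = c(99, 99, 99))
  )
  expect_equal(classify_escapees(counts, c("esc", "sil"), 0.10), "esc")
  expect_equal(classify_escapees(counts, c("esc", "sil"), 0.20), "esc")
  expect_equal(classify_escapees(counts, c("esc", "sil"), 0.21), character(0))

  # monotone: raising the threshold never adds escapees
  b <- default_bundle()
  inf <- filter_informative(b$counts)
  prev <- classify_escapees(b$counts, inf, 0.05)
  for (thr in c(0.10, 0.20, 0.40)) {
    cur <- classify_escapees(b$counts, inf, thr)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("reactivation LRT calls a strong shift and respects null and direction", {
  strong <- rbind(
    make_counts(rep("g", 3), "control", cast = c(1, 0, 2), bl6 = c(99, 100, 98)),
    make_counts(rep("g", 3), "tomato_high", cast = c(30, 28, 33),
                bl6 = c(70, 72, 67))
  )
  # independent oracle: Fisher exact on the pooled 2x2 table
  oracle <- fisher.test(matrix(c(91, 209, 3, 297), nrow = 2))$p.value
  expect_lt(oracle, 1e-6)
  res <- test_reactivation(strong, "g")
  expect_true(res$reactivated)
  expect_lt(res$p_value, 1e-6)

  ident <- rbind(
    make_counts(rep("g", 3), "control", cast = c(5, 6, 4), bl6 = c(95, 94, 96)),
    make_counts(rep("g", 3), "tomato_high", cast = c(5, 6, 4),
                bl6 = c(95, 94, 96))
  )
  res <- test_reactivation(ident, "g")
  expect_gt(res$p_value, 0.9)
  expect_false(res$reactivated)

  # strong shift downward: significant but not called (direction filter)
  down <- rbind(
    make_counts(rep("g", 3), "control", cast = c(30, 28, 33), bl6 = c(70, 72, 67)),
    make_counts(rep("g", 3), "tomato_high", cast = c(1, 0, 2),
                bl6 = c(99, 100, 98))
  )
  res <- test_reactivation(down, "g")
  expect_lt(res$p_value, 1e-4)
  expect_false(res$reactivated)
  expect_lt(res$delta_ratio, 0)
})

test_that("a gene with zero coverage in one condition gets a missing p, not an error", {
  counts <- rbind(
    make_counts(rep("g", 3), "control", cast = c(0, 0, 0), bl6 = c(0, 0, 0)),
    make_counts(rep("g", 3), "tomato_high", cast = c(3, 3, 3), bl6 = c(7, 7, 7))
  )
  res <- test_reactivation(counts, "g")
  expect_true(is.na(res$p_value))
  expect_false(res$reactivated)
})

test_that("beta-binomial LRT agrees with the pooled Fisher oracle on random small-count genes", {
  set.seed(42)
  n_genes <- 200
  agree <- logical(n_genes)
  for (i in seq_len(n_genes)) {
    null_gene <- i %% 2 == 0
    p1 <- runif(1, 0.02, 0.25)
    p2 <- if (null_gene) p1 else min(0.9, p1 + runif(1, 0.15, 0.45))
    tot <- rpois(6, 40) + 5
    cast <- rbinom(6, tot, rep(c(p1, p2), each = 3))
    counts <- rbind(
      make_counts(rep("g", 3), "control", cast[1:3], tot[1:3] - cast[1:3]),
      make_counts(rep("g", 3), "tomato_high", cast[4:6], tot[4:6] - cast[4:6])
    )
    lrt_p <- test_reactivation(counts, "g")$p_value
    fisher_p <- fisher.test(matrix(c(sum(cast[4:6]), sum(tot[4:6] - cast[4:6]),
                                     sum(cast[1:3]), sum(tot[1:3] - cast[1:3])),
                                   nrow = 2))$p.value
    agree[i] <- (lrt_p < 0.05) == (fisher_p < 0.05)
  }
  expect_gte(mean(agree), 0.95)
})

test_that("every annotated gene receives exactly one status and counts partition", {
  cl <- tidy(default_classification())
  b <- default_bundle()
  expect_equal(nrow(cl), nrow(b$genes))
  expect_equal(anyDuplicated(cl$gene_id), 0)
  expect_true(all(cl$status %in% c("uninformative", "escapee", "reactivated",
                                   "non_reactivated")))
  expect_equal(sum(table(cl$status)), xcr_config()$n_genes)
})

test_that("delta ratios stay within [-1, 1] and ratios within [0, 1]", {
  cl <- tidy(default_classification())
  ok <- !is.na(cl$delta_ratio)
  expect_true(all(cl$delta_ratio[ok] >= -1 & cl$delta_ratio[ok] <= 1))
  for (col in c("control_cast_ratio", "treated_cast_ratio")) {
    v <- cl[[col]][!is.na(cl[[col]])]
    expect_true(all(v >= 0 & v <= 1))
  }
})

test_that("rank_reactivated orders by p, breaks ties by delta, and counts strictly above", {
  cl <- tibble::tibble(
    gene_id = c("a", "b", "c"),
    status = "reactivated",
    p_value = c(1e-8, 1e-4, 1e-2),
    delta_ratio = c(0.3, 0.2, 0.1)
  )
  expect_equal(rank_reactivated(cl, "b")$n_above_reference, 1)
  expect_equal(rank_reactivated(cl, "a")$n_above_reference, 0)
  cl$p_value <- c(1e-4, 1e-4, 1e-2)  # tie: larger delta wins
  expect_equal(rank_reactivated(cl, "b")$n_above_reference, 1)
  cl$status <- c("reactivated", "non_reactivated", "reactivated")
  expect_error(rank_reactivated(cl, "b"), "not in the reactivated set")
})

test_that("delta_ratio_profile pools replicates and orders by TSS", {
  genes <- make_genes(c("g2", "g1"), c(5000, 1000), c(6000, 2000))
  counts <- rbind(
    make_counts(rep("g1", 3), "control", c(1, 1, 1), c(99, 99, 99)),
    make_counts(rep("g1", 3), "tomato_high", c(21, 21, 21), c(79, 79, 79)),
    make_counts(rep("g2", 3), "control", c(20, 20, 20), c(80, 80, 80)),
    make_counts(rep("g2", 3), "tomato_high", c(20, 20, 20), c(80, 80, 80))
  )
  prof <- delta_ratio_profile(counts, genes)
  expect_equal(prof$gene_id, c("g1", "g2"))  # sorted by TSS
  expect_equal(prof$delta_ratio, c(0.20, 0), tolerance = 1e-12)
  expect_true(all(abs(prof$delta_ratio) <= 1))
})

test_that("the fisher method is exposed and matches fisher.test on pooled counts", {
  counts <- rbind(
    make_counts(rep("g", 2), "control", c(2, 1), c(48, 49)),
    make_counts(rep("g", 2), "tomato_high", c(9, 12), c(41, 38))
  )
  res <- test_reactivation(counts, "g", method = "fisher")
  expected <- fisher.test(matrix(c(21, 79, 3, 97), nrow = 2))$p.value
  expect_equal(res$p_value, expected, tolerance = 1e-12)
})
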