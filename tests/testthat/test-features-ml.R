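test_that("matched nulls keep chromosome and length and avoid the exclusion set", {
  set.seed(12)
  g <- toy_genome(c(chr1 = 5e5, chr2 = 3e5))
  dsbs <- random_intervals(g, 120, max_len = 800)
  nulls <- sample_matched_nulls(dsbs, exclude = dsbs, seed = 4)
  expect_identical(as.character(GenomicRanges::seqnames(nulls)),
                   as.character(GenomicRanges::seqnames(dsbs)))
  expect_identical(GenomicRanges::width(nulls), GenomicRanges::width(dsbs))
  expect_identical(count_overlapping(nulls, dsbs), 0L)
  expect_identical(nulls, sample_matched_nulls(dsbs, exclude = dsbs, seed = 4))
})

test_that("a single feasible placement is found and infeasibility is an error", {
  g <- genome(c(chr = 100))
  dsb <- gr0("chr", 20, 30, g)
  exclude <- gr0("chr", 0, 90, g)   # only start 90 leaves a length-10 region free
  null <- sample_matched_nulls(dsb, exclude = exclude, seed = 1)
  expect_identical(GenomicRanges::start(null) - 1L, 90L)
  blocked <- gr0("chr", 0, 100, g)
  expect_error(sample_matched_nulls(dsb, exclude = blocked, seed = 1,
                                    max_attempts = 50),
               "no exclusion-free placement")
})

test_that("feature matrices carry labels and hand-computed signal/distance values", {
  g <- toy_genome()
  real <- gr0("chrA", 0, 10, g)
  null <- gr0("chrA", 5000, 5010, g)
  track <- gr0(c("chrA", "chrA"), c(0, 4), c(4, 10), g, score = c(1, 2.5))
  fm <- build_feature_matrix(real, null, tracks = list(t1 = track), mode = "signal")
  expect_identical(levels(fm$label), c("null", "real"))
  expect_equal(fm$t1, c(1.9, 0))
  fs <- build_feature_matrix(real, null, tracks = list(t1 = track), mode = "sum")
  expect_equal(fs$t1, c(19, 0))
  const <- gr0("chrA", 0, 10000, g, score = 1)
  expect_equal(build_feature_matrix(real, null, tracks = list(k = const),
                                    mode = "signal")$k, c(1, 1))
  feats <- gr0("chrA", c(5, 6000), c(8, 6100), g)
  fd <- build_feature_matrix(real, null, feature_sets = list(f = feats),
                             mode = "distance")
  expect_equal(fd$f, c(0, 990))
  # chromosomes without the feature get a genome-scale sentinel, not NA
  real2 <- gr0("chrB", 0, 10, g)
  fd2 <- build_feature_matrix(real2, null, feature_sets = list(f = feats),
                              mode = "distance")
  expect_equal(fd2$f[1], 5000)  # chrB length
  expect_false(anyNA(fd2$f))
  expect_error(build_feature_matrix(real, null, tracks = list(track)), "named")
})

test_that("feature matrices round-trip as TSV", {
  g <- toy_genome()
  fm <- build_feature_matrix(gr0("chrA", c(0, 50), c(10, 80), g),
                             gr0("chrA", c(500, 900), c(510, 930), g),
                             tracks = list(a = gr0("chrA", 0, 100, g, score = 2)),
                             mode = "signal")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_matrix(fm, path)
  back <- read_feature_matrix(path)
  expect_equal(back$a, fm$a)
  expect_identical(as.character(back$label), as.character(fm$label))
  expect_identical(attr(back, "mode"), "signal")
})

test_that("PR-AUC step integration matches hand enumeration", {
  # scores desc: 0.9(+), 0.8(-), 0.6(+), 0.4(+), 0.3(-)
  # recall steps 1/3 -> 2/3 -> 1 at precisions 1, 2/3, 3/4
  positive <- c(TRUE, FALSE, TRUE, TRUE, FALSE)
  score <- c(0.9, 0.8, 0.6, 0.4, 0.3)
  expect_equal(breakmark:::pr_auc(positive, score), 1 / 3 + 2 / 9 + 1 / 4)
  # tied scores collapse to one threshold
  expect_equal(breakmark:::pr_auc(c(TRUE, FALSE), c(0.5, 0.5)), 0.5)
  # perfect ranking
  expect_equal(breakmark:::pr_auc(c(TRUE, TRUE, FALSE), c(3, 2, 1)), 1)
})

test_that("a perfectly separating feature yields near-perfect AUROC", {
  set.seed(6)
  fm <- data.frame(label = factor(rep(c("real", "null"), each = 50),
                                  levels = c("null", "real")),
                   sep = c(rnorm(50, 10), rnorm(50, 0)),
                   noise = rnorm(100))
  rep <- train_evaluate(fm, n_trees = 300, seed = 2)
  expect_gte(rep$auroc, 0.99)
  expect_gte(rep$pr_auc, 0.95)
  expect_true(all(rep$class_errors < 0.1))
  expect_identical(rownames(rep$importance)[which.max(
    rep$importance[, "MeanDecreaseAccuracy"])], "sep")
})

test_that("AUROC is stable under monotone transforms of a feature column", {
  # tree splits are order-based, but the forest implementation draws split
  # points between adjacent values, so agreement is approximate
  set.seed(44)
  fm <- data.frame(label = factor(rep(c("real", "null"), each = 100),
                                  levels = c("null", "real")),
                   x = c(rnorm(100, 1.5), rnorm(100, 0)),
                   y = rnorm(200))
  a <- train_evaluate(fm, n_trees = 500, seed = 5)
  fm$x <- exp(fm$x)   # strictly monotone
  b <- train_evaluate(fm, n_trees = 500, seed = 5)
  expect_equal(a$auroc, b$auroc, tolerance = 0.05)
})

test_that("shuffled labels give chance-level AUROC", {
  set.seed(10)
  n <- 60
  base <- data.frame(x1 = rnorm(2 * n), x2 = rnorm(2 * n), x3 = rnorm(2 * n))
  aurocs <- vapply(1:5, function(s) {
    fm <- cbind(label = factor(sample(rep(c("real", "null"), n)),
                               levels = c("null", "real")), base)
    train_evaluate(fm, n_trees = 300, seed = s)$auroc
  }, numeric(1))
  expect_lt(abs(mean(aurocs) - 0.5), 0.1)
})

test_that("degenerate classifier inputs are rejected", {
  fm <- data.frame(label = factor(rep("real", 30), levels = c("null", "real")),
                   x = rnorm(30))
  expect_error(train_evaluate(fm), "both classes")
  fm2 <- data.frame(label = factor(rep(c("real", "null"), c(25, 5)),
                                   levels = c("null", "real")),
                    x = rnorm(30))
  expect_error(train_evaluate(fm2), "10 rows")
})

test_that("held-out evaluation is available alongside out-of-bag", {
  set.seed(3)
  fm <- data.frame(label = factor(rep(c("real", "null"), each = 80),
                                  levels = c("null", "real")),
                   sep = c(rnorm(80, 5), rnorm(80, 0)))
  rep <- train_evaluate(fm, n_trees = 200, seed = 7, holdout = 0.3)
  expect_false(rep$oob)
  expect_gte(rep$auroc, 0.95)
})
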