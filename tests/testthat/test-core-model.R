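test_that("overlap counting follows half-open BED semantics", {
  g <- toy_genome()
  expect_identical(count_overlapping(gr0("chrA", 100, 200, g),
                                     gr0("chrA", 150, 160, g)), 1L)
  # an interval ending where the next starts shares no base
  expect_identical(count_overlapping(gr0("chrA", 100, 200, g),
                                     gr0("chrA", 200, 300, g)), 0L)
  expect_identical(count_overlapping(gr0("chrA", 100, 200, g),
                                     GenomicRanges::GRanges()), 0L)
  # min_overlap_bp: 100-200 vs 195-300 share 5 bases
  q <- gr0("chrA", 100, 200, g); r <- gr0("chrA", 195, 300, g)
  expect_identical(count_overlapping(q, r, min_overlap_bp = 5), 1L)
  expect_identical(count_overlapping(q, r, min_overlap_bp = 6), 0L)
})

test_that("each query interval is counted at most once", {
  g <- toy_genome()
  q <- gr0("chrA", 100, 500, g)
  r <- gr0(rep("chrA", 3), c(120, 200, 300), c(150, 260, 380), g)
  expect_identical(count_overlapping(q, r), 1L)
})

test_that("overlap counting matches the all-pairs brute force on random sets", {
  set.seed(41)
  g <- toy_genome()
  for (rep in 1:30) {
    q <- random_intervals(g, sample.int(60, 1))
    r <- random_intervals(g, sample.int(60, 1))
    m <- sample(c(1, 1, 5, 50), 1)
    expect_identical(count_overlapping(q, r, m), brute_count_overlapping(q, r, m))
  }
})

test_that("overlap count is bounded and monotone in the reference", {
  set.seed(7)
  g <- toy_genome()
  q <- random_intervals(g, 80)
  r <- random_intervals(g, 40)
  prev <- 0L
  for (k in c(5, 15, 40)) {
    cur <- count_overlapping(q, r[seq_len(k)])
    expect_gte(cur, prev)
    expect_lte(cur, length(q))
    prev <- cur
  }
})

test_that("mismatched genomes are a configuration error", {
  q <- gr0("chrA", 0, 10, genome(c(chrA = 100)))
  r <- gr0("chrA", 0, 10, genome(c(chrA = 200)))
  expect_error(count_overlapping(q, r), "different genomes")
})

test_that("nearest_gap returns 0 on overlap, the edge gap otherwise, NA off-chromosome", {
  g <- toy_genome()
  ref <- gr0(c("chrA", "chrA"), c(150, 250), c(160, 260), g)
  q <- gr0(c("chrA", "chrA", "chrB"), c(100, 200, 0), c(200, 240, 10), g)
  expect_identical(nearest_gap(q, ref), c(0L, 10L, NA_integer_))
  expect_identical(nearest_gap(gr0("chrA", 100, 200, g),
                               gr0("chrA", 250, 260, g)), 50L)
  expect_error(nearest_gap(q, GenomicRanges::GRanges()), "empty")
})

test_that("nearest_gap is invariant under coordinate reflection", {
  set.seed(11)
  g <- genome(c(chrA = 10000))
  L <- 10000
  for (rep in 1:10) {
    q <- random_intervals(g, 20, max_len = 100)
    r <- random_intervals(g, 10, max_len = 100)
    reflect <- function(x) gr0("chrA", L - GenomicRanges::end(x),
                               L - (GenomicRanges::start(x) - 1), g)
    expect_identical(nearest_gap(q, r), nearest_gap(reflect(q), reflect(r)))
  }
})

test_that("shuffle preserves chromosome, length multiset and stays in bounds", {
  set.seed(3)
  g <- toy_genome()
  x <- random_intervals(g, 150)
  y <- shuffle_intervals(x, seed = 99)
  expect_identical(as.character(GenomicRanges::seqnames(y)),
                   as.character(GenomicRanges::seqnames(x)))
  expect_identical(GenomicRanges::width(y), GenomicRanges::width(x))
  expect_true(all(GenomicRanges::start(y) >= 1))
  expect_true(all(GenomicRanges::end(y) <=
                    unclass(g)[as.character(GenomicRanges::seqnames(y))]))
  # deterministic given the seed
  expect_identical(y, shuffle_intervals(x, seed = 99))
  expect_false(identical(y, shuffle_intervals(x, seed = 100)))
})

test_that("an interval as long as its chromosome has a single placement", {
  g <- genome(c(chrA = 10))
  x <- gr0("chrA", 0, 10, g)
  y <- shuffle_intervals(x, seed = 1)
  expect_identical(GenomicRanges::start(y), 1L)
  expect_identical(GenomicRanges::end(y), 10L)
  expect_error(shuffle_intervals(gr0("chrA", 0, 10), genome(c(chrA = 5))),
               "longer")
})

test_that("shuffle starts are uniform over enumerable placements", {
  # chromosome of length 4, interval of length 2: valid starts {0, 1, 2}
  g <- genome(c(chrA = 4))
  x <- gr0("chrA", 0, 2, g)
  starts <- vapply(1:3000, function(s)
    GenomicRanges::start(shuffle_intervals(x, seed = s)) - 1L, integer(1))
  counts <- tabulate(starts + 1L, nbins = 3)
  expect_identical(sum(counts), 3000L)
  expect_gt(chisq.test(counts)$p.value, 0.01)
})

test_that("the fast merged-interval counter agrees with count_overlapping", {
  set.seed(17)
  g <- toy_genome()
  for (rep in 1:20) {
    q <- random_intervals(g, 50)
    r <- random_intervals(g, 30)
    idx <- breakmark:::overlap_index(r, g)
    fast <- breakmark:::count_overlapping_fast(
      idx, as.character(GenomicRanges::seqnames(q)),
      GenomicRanges::start(q) - 1, GenomicRanges::width(q))
    expect_identical(fast, count_overlapping(q, r))
  }
})
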