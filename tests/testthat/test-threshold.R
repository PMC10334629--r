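test_that("binQuantiles takes the k-th largest PCC per bin", {
  # one bin: PCCs 0.1..1.0, cutoff 0.2 -> k = 2 -> 0.9
  s <- makePairStats(seq(0.1, 1, 0.1), rep(20L, 10))
  t1 <- binQuantiles(s, binSize = 10, cutoff = 0.2, minBinCount = 1)
  expect_identical(nrow(binTable(t1)), 1L)
  expect_equal(binTable(t1)$q_thresh, 0.9)
  expect_identical(binTable(t1)$n_pairs, 10L)

  # single PCC, tiny cutoff: k = ceil(0.005 * 1) = 1
  s2 <- makePairStats(0.5, 20L)
  t2 <- binQuantiles(s2, binSize = 10, cutoff = 0.005, minBinCount = 1)
  expect_equal(binTable(t2)$q_thresh, 0.5)

  # a sparse bin vanishes from the table while dense bins survive
  s3 <- makePairStats(runif(70), c(rep(15L, 10), rep(40L, 60)))
  t3 <- binQuantiles(s3, binSize = 10, cutoff = 0.1, minBinCount = 50)
  expect_identical(nrow(binTable(t3)), 1L)
  expect_identical(binTable(t3)$bin_low, 35)
})

test_that("bins partition the observed count range and honour minBinCount", {
  set.seed(9)
  counts <- sample(20:75, 300, replace = TRUE)
  s <- makePairStats(runif(300, -1, 1), counts)
  tab <- binTable(binQuantiles(s, binSize = 10, cutoff = 0.1, minBinCount = 1))
  expect_equal(tab$bin_low, seq(20, 70, 10))
  expect_equal(tab$bin_high[-nrow(tab)], seq(29, 69, 10))
  expect_equal(tab$bin_high[nrow(tab)], max(counts))
  expect_equal(tab$x_rep, (tab$bin_low + tab$bin_high) / 2)
  expect_equal(sum(tab$n_pairs), 300L)

  expect_error(binQuantiles(makePairStats(0.5, 20L), binSize = 10,
                            cutoff = 0.2, minBinCount = 50),
               "minBinCount", class = "slidenet_data_error")
})

test_that("sliding-threshold fit recovers known parameters", {
  truth <- c(alpha = 0.9, eta = 2, lambda = 8, beta = 50)
  x <- seq(10, 200, 10)
  q <- truth[1] - 1 / (truth[2] + truth[3] * exp(-x / truth[4]))
  tab <- new("BinQuantileTable", binSize = 10L, cutoff = 0.01,
             minBinCount = 1L,
             bins = data.frame(bin_low = x, bin_high = x, x_rep = x,
                               n_pairs = 1000L, q_thresh = q))
  model <- fitThresholdCurve(tab)
  expect_lt(max(abs(thresholdAt(model, x) - q)), 1e-6)
  expect_gt(rSquared(model), 1 - 1e-12)

  # constant table: flat curve, reachable with lambda -> 0
  tabC <- new("BinQuantileTable", binSize = 10L, cutoff = 0.01,
              minBinCount = 1L,
              bins = data.frame(bin_low = x, bin_high = x, x_rep = x,
                                n_pairs = 1000L, q_thresh = 0.5))
  flat <- fitThresholdCurve(tabC)
  expect_lt(max(abs(thresholdAt(flat, x) - 0.5)), 1e-6)
})

test_that("fit needs four bins and is deterministic", {
  x <- c(10, 20, 30)
  tab <- new("BinQuantileTable", binSize = 10L, cutoff = 0.01,
             minBinCount = 1L,
             bins = data.frame(bin_low = x, bin_high = x, x_rep = x,
                               n_pairs = 100L, q_thresh = c(0.9, 0.8, 0.7)))
  expect_error(fitThresholdCurve(tab), "4", class = "slidenet_numeric_error")

  t5 <- generateNullQuantiles(c(5, 10, 20, 40, 80), reps = 2000,
                              cutoff = 0.05, seed = 3)
  m1 <- fitThresholdCurve(t5)
  m2 <- fitThresholdCurve(t5)
  expect_identical(thresholdParams(m1), thresholdParams(m2))
})

test_that("thresholdAt follows the closed form and its asymptote", {
  m <- makeModel(0.9, 2, 8, 50)
  expect_equal(thresholdAt(m, 0), 0.9 - 1 / 10)
  expect_lt(abs(thresholdAt(m, 1e9) - (0.9 - 1 / 2)), 1e-6)

  flat <- makeModel(0.9, 2, 0, 50)
  expect_equal(thresholdAt(flat, c(0, 7, 5000)), rep(0.4, 3))

  # with lambda > 0 the threshold strictly decreases in x
  grid <- seq(0, 500, length.out = 2000)
  expect_true(all(diff(thresholdAt(m, grid)) < 0))
})

test_that("selectEdges applies the >= rule at each pair's own count", {
  m08 <- makeModel(0.8 + 1 / 2, 2, 0, 50)   # flat at 0.8
  s <- makePairStats(c(0.79, 0.80, 0.95), c(10L, 20L, 30L))
  e <- selectEdges(s, m08)
  expect_identical(nrow(e), 2L)

  # identical pcc, different counts: only the high-count pair clears a
  # decreasing curve with f(5) > 0.6 >= f(500)
  m <- makeModel(0.9, 2, 8, 50)
  expect_gt(thresholdAt(m, 5), 0.6)
  expect_lte(thresholdAt(m, 500), 0.6)
  s2 <- makePairStats(c(0.6, 0.6), c(5L, 500L), minPairs = 3L)
  e2 <- selectEdges(s2, m)
  expect_identical(nrow(e2), 1L)
  expect_identical(pairedCounts(s2)[e2$Source, e2$Target], 500L)

  sEmpty <- makePairStats(c(NA_real_, NA_real_), c(2L, 2L))
  expect_identical(nrow(selectEdges(sEmpty, m)), 0L)
})

test_that("weighted selection attaches the pcc and output is sorted", {
  m <- makeModel(0.5 + 1 / 2, 2, 0, 50)  # flat at 0.5
  s <- makePairStats(c(0.9, 0.2, 0.7), c(30L, 30L, 30L))
  e <- selectEdges(s, m, weighted = TRUE)
  expect_identical(names(e), c("Source", "Target", "Weight"))
  expect_identical(nrow(e), 2L)
  expect_true(!is.unsorted(e$Source))
  expect_setequal(e$Weight, c(0.9, 0.7))
})

test_that("raising the cutoff never loses edges", {
  set.seed(21)
  x <- randomMaskedMatrix(40, 60, missingRate = 0.2)
  s <- pairwisePCC(x)
  edgeCount <- vapply(c(0.01, 0.02, 0.05, 0.1), function(p) {
    bins <- binQuantiles(s, binSize = 5, cutoff = p, minBinCount = 10)
    nrow(selectEdges(s, fitThresholdCurve(bins)))
  }, numeric(1))
  expect_true(all(diff(edgeCount) >= 0))
})

test_that("a flat curve at the bin quantile selects about the cutoff share", {
  set.seed(8)
  r <- runif(400, -1, 1)
  s <- makePairStats(r, rep(50L, 400))
  p <- 0.05
  tab <- binQuantiles(s, binSize = 10, cutoff = p, minBinCount = 1)
  qth <- binTable(tab)$q_thresh
  model <- makeModel(qth + 1 / 2, 2, 0, 50)  # flat exactly at q_thresh
  nSel <- nrow(selectEdges(s, model))
  expect_identical(nSel, sum(r >= qth))              # brute-force tie set
  expect_gte(nSel, ceiling(p * 400))
})

test_that("edge lists round-trip through disk and reject bad rows", {
  e <- data.frame(Source = c("a", "b"), Target = c("b", "c"),
                  Weight = c(0.9, 0.85))
  f <- withr::local_tempfile(fileext = ".csv")
  writeEdgeList(e, f)
  expect_equal(readEdgeList(f), e)

  writeLines(c("Source,Target", "a,b", "c"), f)
  expect_error(readEdgeList(f), "line 3", class = "slidenet_data_error")
  writeLines(c("foo,bar", "a,b"), f)
  expect_error(readEdgeList(f), "header", class = "slidenet_data_error")
})
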