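test_that("windows abut the element and there are always 21 of them", {
  el <- data.frame(start = 100000, end = 101000)
  w <- build_windows(el, window_scheme(), chrom_length = 1e6)
  expect_equal(nrow(w), 21)
  expect_equal(w$offset, -10:10)
  expect_equal(unlist(w[w$offset == 0, c("start", "end")], use.names = FALSE),
               c(100000, 101000))
  expect_equal(unlist(w[w$offset == -1, c("start", "end")],
                      use.names = FALSE), c(98000, 100000))
  expect_equal(unlist(w[w$offset == 1, c("start", "end")],
                      use.names = FALSE), c(101000, 103000))
  expect_equal(unlist(w[w$offset == -10, c("start", "end")],
                      use.names = FALSE), c(80000, 82000))
  # flanks tile without gaps
  expect_true(all(w$end[-21] >= w$start[-1] - 0))
})

test_that("windows clamp to chromosome bounds, some to zero width", {
  w <- build_windows(data.frame(start = 500, end = 1500), window_scheme(),
                     chrom_length = 1e6)
  expect_equal(nrow(w), 21)
  expect_true(all(w$start >= 0 & w$end <= 1e6))
  expect_true(any(w$end == w$start))             # fully clamped windows
  expect_equal(unlist(w[w$offset == -1, c("start", "end")],
                      use.names = FALSE), c(0, 500))
})

test_that("masking removes exactly the covered sub-intervals", {
  w <- data.frame(offset = 0, start = 1000, end = 3000)
  none <- mask_elements(w, data.frame(start = 5000, end = 6000))
  expect_equal(none[, c("start", "end")], data.frame(start = 1000, end = 3000))
  full <- mask_elements(w, data.frame(start = 500, end = 3500))
  expect_equal(nrow(full), 0)
  half <- mask_elements(w, data.frame(start = 2000, end = 3000))
  expect_equal(half[, c("start", "end")], data.frame(start = 1000, end = 2000))

  # monotonicity: masking more elements never increases unmasked length
  set.seed(1)
  for (r in 1:20) {
    win <- data.frame(offset = 0, start = 0, end = 2000)
    others <- data.frame(start = sort(sample(0:1900, 4)))
    others$end <- others$start + sample(50:400, 4, replace = TRUE)
    len <- function(o) {
      m <- mask_elements(win, o)
      sum(m$end - m$start)
    }
    lens <- vapply(1:4, function(k) len(others[1:k, , drop = FALSE]), 0)
    expect_true(all(diff(lens) <= 1e-9))
  }
})

test_that("signal aggregation equals a brute-force per-base mean", {
  tr <- data.frame(start = c(0, 1000), end = c(1000, 2000),
                   signalValue = c(2, 4))
  iv <- data.frame(start = 0, end = 2000)
  expect_equal(aggregate_signal(tr, iv), 3)        # half 2, half 4
  expect_equal(aggregate_signal(tr, data.frame(start = 100, end = 200)), 2)
  expect_equal(aggregate_signal(data.frame(start = 0, end = 5000,
                                           signalValue = 5),
                                data.frame(start = 100, end = 300)), 5)
  expect_equal(aggregate_signal(tr, data.frame(start = 3000, end = 4000)), 0)
  expect_equal(aggregate_signal(tr, iv[0, , drop = FALSE]), 0)

  set.seed(7)
  for (r in 1:10) {
    starts <- sort(sample(0:80, 4)) * 10
    track <- data.frame(start = starts,
                        end = starts + sample(1:8, 4, replace = TRUE) * 10)
    track <- track[c(TRUE, track$start[-1] >= cummax(track$end)[-4]), ]
    track$signalValue <- round(stats::runif(nrow(track), 0.5, 5), 2)
    ivs <- data.frame(start = c(50, 500), end = c(450, 810))
    expect_equal(aggregate_signal(track, ivs), oracle_aggregate(track, ivs),
                 tolerance = 1e-12)
  }
})

test_that("featurize produces 7 x 21 matrices in canonical marker order", {
  empty_tracks <- stats::setNames(lapply(epi_markers(), function(m)
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               signalValue = numeric(0))), epi_markers())
  el <- data.frame(id = "E1", chrom = "chr1", start = 100000, end = 101000)
  m0 <- featurize(el, empty_tracks, chrom_length = 1e6)
  expect_equal(dim(m0), c(7, 21))
  expect_equal(rownames(m0), epi_markers())
  expect_true(all(m0 == 0))
  expect_error(featurize(el, empty_tracks[1:5], chrom_length = 1e6),
               "missing marker")

  # planted central enrichment dominates its row
  tracks <- empty_tracks
  w <- build_windows(el, chrom_length = 1e6)
  tracks$CTCF <- data.frame(chrom = "chr1", start = w$start, end = w$end,
                            signalValue = ifelse(w$offset == 0, 9, 1))
  m1 <- featurize(el, tracks, chrom_length = 1e6)
  expect_equal(unname(which.max(m1["CTCF", ])), 11)
  expect_equal(unname(m1["CTCF", "0"]), 9)
  expect_true(all(m1[setdiff(epi_markers(), "CTCF"), ] == 0))

  # masking zeroes out signal under a neighbouring element
  other <- data.frame(start = 101000, end = 103000)  # covers window +1
  m2 <- featurize(el, tracks, other_elements = other, chrom_length = 1e6)
  expect_equal(unname(m2["CTCF", "1"]), 0)
  expect_equal(unname(m2["CTCF", "2"]), 1)
})

test_that("normalization is train-fitted, bounded and order-invariant", {
  set.seed(11)
  mats <- lapply(1:6, function(i)
    matrix(stats::rnorm(7 * 21, mean = i), 7, 21,
           dimnames = list(epi_markers(), -10:10)))
  st <- fit_normalization(mats)
  tr <- lapply(mats, apply_normalization, stats = st)
  vals <- unlist(tr)
  expect_true(all(vals >= 0 & vals <= 1))
  expect_equal(max(vals), 1)               # training max maps to 1
  expect_equal(min(vals), 0)               # training min maps to 0
  # order invariance
  st2 <- fit_normalization(mats[c(4, 2, 6, 1, 3, 5)])
  expect_equal(st$mean, st2$mean)
  expect_equal(st$min, st2$min)
  # out-of-range test data is clipped, stats untouched
  big <- matrix(100, 7, 21, dimnames = list(epi_markers(), -10:10))
  expect_true(all(apply_normalization(big, st) <= 1))
  expect_equal(st$max, st2$max)
  # constant marker maps to zero
  const <- lapply(1:3, function(i)
    matrix(rep(c(2, stats::rnorm(6)), 21), 7, 21,
           dimnames = list(epi_markers(), -10:10)))
  stc <- fit_normalization(const)
  expect_true(all(apply_normalization(const[[1]], stc)[1, ] == 0))
  expect_error(fit_normalization(list()), "empty")
})
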