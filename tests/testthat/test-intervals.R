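test_that("strand modes yield the contracted track counts and contents", {
  f <- data.frame(seqid = "c", source = "x", ftype = "g",
                  start = c(1, 100), end = c(50, 150),
                  strand = c("plus", "minus"), stringsAsFactors = FALSE)
  all3 <- split_strand_tracks(f, "all")
  expect_equal(names(all3), c("minus", "plus", "fused"))
  expect_equal(vapply(all3, nrow, 0L), c(minus = 1L, plus = 1L, fused = 2L))

  both <- split_strand_tracks(f, "both")
  expect_equal(vapply(both, nrow, 0L), c(minus = 1L, plus = 1L))

  expect_equal(names(split_strand_tracks(f, "minus")), "minus")
  expect_equal(names(split_strand_tracks(f, "plus")), "plus")
  expect_equal(names(split_strand_tracks(f, "fused")), "fused")
  expect_error(split_strand_tracks(f, "sideways"), "valid modes")
})

test_that("unstranded features route only to fused tracks, with a warning", {
  f <- data.frame(seqid = "c", source = "x", ftype = "g",
                  start = 1:5, end = 11:15,
                  strand = "unstranded", stringsAsFactors = FALSE)
  expect_equal(nrow(split_strand_tracks(f, "fused")$fused), 5L)
  expect_warning(tr <- split_strand_tracks(f, "both"), "unstranded")
  expect_equal(vapply(tr, nrow, 0L), c(minus = 0L, plus = 0L))
})

test_that("interval merging unions overlaps and is idempotent", {
  expect_equal(merge_intervals(c(100, 150), c(200, 250)),
               data.frame(start = 100, end = 250))
  expect_equal(merge_intervals(10, 20), data.frame(start = 10, end = 20))
  # book-ended intervals merge to one canonical interval
  expect_equal(merge_intervals(c(1, 6), c(5, 9)),
               data.frame(start = 1, end = 9))
  expect_equal(nrow(merge_intervals(numeric(), numeric())), 0L)

  set.seed(11)
  for (rep in 1:5) {
    s <- sample.int(10000, 500, replace = TRUE)
    e <- pmin(s + sample.int(400, 500, replace = TRUE), 10000)
    m <- merge_intervals(s, e)
    expect_equal(sum(m$end - m$start + 1), sum(bitmap_coverage(s, e, 10000)))
    expect_true(all(diff(m$start) > 0))
    expect_true(all(m$start[-1] > m$end[-nrow(m)] + 1))  # canonical, disjoint
    expect_identical(merge_intervals(m$start, m$end), m)
  }
})

test_that("windows tile the sequence exactly", {
  expect_equal(tile_windows(100, 40),
               data.frame(start = c(1, 41, 81), end = c(40, 80, 100),
                          span = c(40, 40, 20)))
  expect_equal(tile_windows(80, 40),
               data.frame(start = c(1, 41), end = c(40, 80),
                          span = c(40, 40)))
  expect_warning(w1 <- tile_windows(30, 40), "single window")
  expect_equal(w1, data.frame(start = 1, end = 30, span = 30))

  set.seed(3)
  for (rep in 1:20) {
    L <- sample.int(100000, 1)
    W <- sample.int(L, 1)
    w <- tile_windows(L, W)
    expect_equal(sum(w$span), L)
    expect_equal(w$start, c(1, head(w$end, -1) + 1))  # no gaps, no overlap
    expect_true(all(w$span >= 1 & w$span <= W))
    expect_true(all(w$span[-nrow(w)] == W))  # only final window may be short
  }
})

test_that("region windows tile exactly the region", {
  w <- tile_windows(1e6, 300, region = list(start = 1001, end = 2000))
  expect_equal(w$start[1], 1001)
  expect_equal(max(w$end), 2000)
  expect_equal(sum(w$span), 1000)
})

test_that("densities follow 100*covered/span with floor or ceiling", {
  w <- tile_windows(40000, 40000)
  full <- density_track(merge_intervals(1, 40000), w)
  expect_equal(full$values, 100L)
  expect_equal(density_track(merge_intervals(1, 40000), w,
                             rounding = "ceil")$values, 100L)

  part <- merge_intervals(1001, 1200)  # 200 bases, raw 0.5%
  expect_equal(density_track(part, w, rounding = "ceil")$values, 1L)
  expect_equal(density_track(part, w, rounding = "floor")$values, 0L)
})

test_that("per-window coverage matches the per-base bitmap oracle", {
  set.seed(101)
  for (rep in 1:10) {
    L <- sample(5000:100000, 1)
    n <- sample.int(1000, 1)
    f <- random_features(n, L)
    W <- sample(c(100, 1000, 7919), 1)
    w <- suppressWarnings(tile_windows(L, W))
    for (mode in c("minus", "plus", "both", "fused", "all")) {
      tracks <- suppressWarnings(split_strand_tracks(f, mode))
      for (tf in tracks) {
        m <- merge_intervals(tf$start, tf$end)
        got <- window_coverage(m, w)
        expect_identical(got, oracle_window_cover(tf$start, tf$end, w, L))
        # conservation: clipped coverage sums to the merged total
        expect_equal(sum(got), sum(pmin(m$end, L) - m$start + 1))
      }
    }
  }
})

test_that("density is order-invariant and ceil dominates floor by <= 1", {
  set.seed(5)
  L <- 50000
  f <- random_features(300, L)
  w <- tile_windows(L, 1000)
  m1 <- merge_intervals(f$start, f$end)
  perm <- sample(nrow(f))
  m2 <- merge_intervals(f$start[perm], f$end[perm])
  expect_identical(m1, m2)
  fl <- density_track(m1, w, rounding = "floor")$values
  ce <- density_track(m1, w, rounding = "ceil")$values
  expect_true(all(ce >= fl))
  expect_true(all(ce - fl <= 1))
  expect_true(all(fl >= 0 & ce <= 100))
})

test_that("fused coverage is bounded by the strand coverages", {
  set.seed(23)
  L <- 30000
  f <- random_features(400, L)
  w <- tile_windows(L, 777)
  cov_of <- function(mode, label) {
    tf <- suppressWarnings(split_strand_tracks(f, mode))[[label]]
    window_coverage(merge_intervals(tf$start, tf$end), w)
  }
  plus <- cov_of("plus", "plus")
  minus <- cov_of("minus", "minus")
  fused <- cov_of("fused", "fused")
  expect_true(all(fused >= pmax(plus, minus)))
  # unstranded features can push fused above plus+minus, but never past span
  strands_only <- plus + minus
  unstr <- f[f$strand == "unstranded", ]
  un_cov <- window_coverage(merge_intervals(unstr$start, unstr$end), w)
  expect_true(all(fused <= pmin(w$span, strands_only + un_cov)))
  expect_true(all(fused <= w$span))
})

test_that("GC density excludes ambiguous bases from the denominator", {
  w8 <- tile_windows(8, 8)
  expect_equal(gc_track("GGGGCCCC", w8)$values, 100L)
  expect_equal(gc_track("ATATATAT", w8)$values, 0L)
  expect_equal(gc_track("ACGTNNNN", w8)$values, 50L)  # 2 GC / 4 non-N
  expect_equal(gc_track("NNNNNNNN", w8)$values, 0L)   # all-N: 0, not NaN
  expect_equal(gc_track("acgtnnnn", w8)$values, 50L)  # case-insensitive

  w <- tile_windows(12, 4)
  tr <- gc_track("GGGGATATACGT", w, rounding = "floor")
  expect_equal(tr$values, c(100L, 0L, 50L))
  expect_equal(tr$ftype, "GC%")
  expect_error(gc_track(NA_character_, w8), "FASTA")
})

test_that("auto window sizing fits the longest chromosome in the budget", {
  opts <- dm_options(tmargin = 0, bmargin = 0)
  # fixed vertical chrome under these opts: seqid label + track labels
  avail <- function(maxpx) maxpx - (opts$ft_size + 8 + 70)
  px <- 1000 + (opts$ft_size + 8) + 70  # so available is exactly 1000
  expect_equal(auto_window_size(1e6, px, opts), 1000)
  expect_equal(auto_window_size(1e6 + 1, px, opts), 1001)
  expect_error(auto_window_size(1e6, 10, opts), "no room")

  set.seed(9)
  for (rep in 1:20) {
    lens <- sample.int(1e8, sample(1:5, 1))
    maxpx <- sample(200:2000, 1)
    W <- auto_window_size(lens, maxpx, opts)
    expect_lte(ceiling(max(lens) / W), avail(maxpx))
  }
})
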