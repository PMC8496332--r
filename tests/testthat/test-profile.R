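test_that("terminus conventions follow strand polarity", {
  fr <- frags("chr1", 100, 200, "+")
  expect_equal(terminus_position(fr, "five_prime")$pos, 100)
  expect_equal(terminus_position(fr, "three_prime")$pos, 199)
  rv <- frags("chr1", 100, 200, "-")
  expect_equal(terminus_position(rv, "five_prime")$pos, 199)
  expect_equal(terminus_position(rv, "three_prime")$pos, 100)
})

test_that("end aggregation orients offsets by synthesis direction", {
  dyad <- point_features("chr1", 150)
  p <- aggregate_ends(frags("chr1", 100, 200, "+"), dyad, "five_prime", 100)
  expect_equal(p$offset[p$count == 1], -50)
  expect_equal(sum(p$count), 1)

  ## Crick-strand flip: raw offset +49 becomes -49
  m <- aggregate_ends(frags("chr1", 100, 200, "-"), dyad, "five_prime", 100)
  expect_equal(m$offset[m$count == 1], -49)
  raw <- aggregate_ends(frags("chr1", 100, 200, "-"), dyad, "five_prime", 100,
                        orient_by_fragment_strand = FALSE)
  expect_equal(raw$offset[raw$count == 1], 49)

  empty <- aggregate_ends(frags("chr1", 100, 200, "+")[0, ], dyad,
                          "five_prime", 100)
  expect_equal(sum(empty$count), 0)
  expect_error(aggregate_ends(frags("chr1", 100, 200, "+"), dyad[0, ]),
               "empty feature set")
})

test_that("a terminus near several features counts toward each", {
  feats <- point_features("chr1", c(120, 160))
  fr <- frags("chr1", 140, 260, "+")            # 5' end at 140
  p <- aggregate_ends(fr, feats, "five_prime", 100)
  expect_equal(sum(p$count), 2)                 # +20 and -20
  expect_equal(p$count[match(c(-20, 20), p$offset)], c(1, 1))
  near <- aggregate_ends(fr, feats, "five_prime", 100, nearest_only = TRUE)
  expect_equal(sum(near$count), 1)
  ## distance tie: the feature earlier in position order wins
  expect_equal(near$offset[near$count == 1], 20)
})

test_that("count conservation holds across smoothing", {
  set.seed(5)
  feats <- point_features("chr1", sample(500:9500, 20))
  s <- sample(0:9800, 200, replace = TRUE)
  fr <- frags("chr1", s, s + sample(80:250, 200, replace = TRUE),
              sample(c("+", "-"), 200, replace = TRUE))
  p <- aggregate_ends(fr, feats, "five_prime", 100)
  term <- terminus_position(fr, "five_prime")
  mids <- feature_midpoints(feats)
  pairs <- sum(vapply(term$pos, function(t) sum(abs(t - mids) <= 100), 0))
  expect_equal(sum(p$count), pairs)
  ## smoothing preserves the total when no mass sits within window-1 of the
  ## grid edges (edge truncation is the only source of leakage)
  pz <- p
  pz$value[abs(pz$offset) > 96] <- 0
  expect_equal(sum(smooth_profile(pz, 5)$value), sum(pz$value))
})

test_that("smoothing matches hand-computed moving averages", {
  delta <- aggregate_ends(frags("chr1", c(200, 200, 200, 200, 200),
                                rep(300, 5), rep("+", 5)),
                          point_features("chr1", 200), "five_prime", 10)
  expect_equal(sum(delta$count), 5)             # height-5 delta at offset 0
  sm <- smooth_profile(delta, 5)
  expect_equal(sm$value[match(-2:2, sm$offset)], rep(1, 5))
  expect_equal(sum(sm$value), 5)
  ## window 1 is the identity; constants are unchanged
  expect_equal(smooth_profile(delta, 1)$value, delta$value)
  flat <- delta; flat$value <- rep(2, length(flat$value))
  expect_equal(smooth_profile(flat, 5)$value, flat$value)
  expect_error(smooth_profile(delta, 4), "odd")
})

test_that("median normalisation enforces its postcondition and errors on zeros", {
  set.seed(8)
  feats <- point_features("chr1", sample(500:9500, 10))
  s <- sample(0:9800, 500, replace = TRUE)
  fr <- frags("chr1", s, s + 100, sample(c("+", "-"), 500, replace = TRUE))
  p <- smooth_profile(aggregate_ends(fr, feats, "five_prime", 150), 5)
  np <- normalize_to_median(p, 100)
  expect_equal(stats::median(np$value[abs(np$offset) <= 100]), 1)
  ## idempotence
  expect_equal(normalize_to_median(np, 100)$value, np$value)
  zero <- aggregate_ends(fr[0, ], feats, "five_prime", 150)
  expect_error(normalize_to_median(zero, 100), "sparse")
  expect_error(normalize_to_median(aggregate_ends(fr, feats, flank = 50), 100),
               "cover")
})

test_that("peak and trough locations break ties toward the smallest offset", {
  p <- aggregate_ends(frags("chr1", 100, 200, "+"), point_features("chr1", 150),
                      "five_prime", 20)
  p$value <- rep(1, length(p$offset))
  expect_equal(peak_location(p)$offset, -20)
  expect_equal(trough_location(p)$offset, -20)
  p$value[match(c(-10, 10), p$offset)] <- 3
  expect_equal(peak_location(p)$offset, -10)
  expect_equal(peak_location(p)$height, 3)
  p$value[match(5, p$offset)] <- -1
  expect_equal(trough_location(p)$offset, 5)
})

test_that("profile shifts report peak and count-weighted mean displacement", {
  mk <- function(pos) {
    aggregate_ends(frags("chr1", pos, pos + 100, "+"),
                   point_features("chr1", 500), "five_prime", 100)
  }
  a <- mk(460)                                   # 5' offset -40
  expect_equal(profile_shift(a, a)$peak_shift, 0)
  b <- mk(475)                                   # shifted +15
  sh <- profile_shift(a, b)
  expect_equal(sh$peak_shift, 15)
  expect_equal(sh$mean_shift, 15)
  bad <- aggregate_ends(frags("chr1", 460, 560, "+"),
                        point_features("chr1", 500), "five_prime", 50)
  expect_error(profile_shift(a, bad), "grids")
})

test_that("oriented profiles are invariant under mirror reflection", {
  set.seed(13)
  for (rep in 1:5) {
    n <- 50
    s <- sample(200:4000, n)
    fr <- frags("chr1", s, s + sample(60:200, n, replace = TRUE),
                sample(c("+", "-"), n, replace = TRUE))
    feats <- point_features("chr1", sample(300:4000, 8))
    p <- aggregate_ends(fr, feats, "five_prime", 100)
    M <- 9001                                     # odd: base x -> M - 1 - x
    mir <- frags("chr1", M - fr$end, M - fr$start,
                 ifelse(fr$strand == "+", "-", "+"))
    mfeats <- point_features("chr1", M - 1 - feature_midpoints(feats))
    mp <- aggregate_ends(mir, mfeats, "five_prime", 100)
    expect_equal(mp$count, p$count)
  }
})
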