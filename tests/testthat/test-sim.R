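fork_row <- function(origin, direction, start, end, t0 = 0) {
  data.frame(cell = 1, chrom = "chr1", origin = origin, direction = direction,
             start_time = t0, end_time = t0 + (end - start) / 1500,
             start = start, end = end, complete = TRUE,
             stringsAsFactors = FALSE)
}

test_that("a lone efficient origin replicates the chromosome with two forks", {
  g <- make_toy_genome(1, 60000)
  ori <- make_origins(g, data.frame(chrom = "chr1", pos = 30000), 1, 5, 0)
  p <- sim_params(t_harvest = 5 + 30000 / 1500 + 1)   # enough for 30 kb arms
  fk <- simulate_forks(g, ori, p, n_cells = 3, seed = 2)
  expect_equal(nrow(fk), 6)                            # two forks per cell
  for (cell in 1:3) {
    f <- fk[fk$cell == cell, ]
    expect_setequal(f$direction, c("L", "R"))
    expect_equal(sort(c(f$start, f$end)), c(0, 30000, 30000, 60000))
    expect_true(all(f$complete))
  }
  expect_error(
    simulate_forks(g, make_origins(g, data.frame(chrom = "chr1", pos = 30000),
                                   0, 5, 0), p, 1),
    "efficiency > 0")
})

test_that("late origins are passively replicated at the analytic race rate", {
  g <- make_toy_genome(1, 100000)
  p <- sim_params(t_harvest = 80)
  n_cells <- 400
  d <- 10000 / p$fork_speed            # fork travel time A -> B, 6.67 min
  for (dt in c(4, 20)) {
    ori <- make_origins(g, data.frame(chrom = "chr1", pos = c(45000, 55000)),
                        c(1, 1), c(20, 20 + dt), time_sd = 2)
    fk <- simulate_forks(g, ori, p, n_cells = n_cells, seed = 5 + dt)
    fired_b <- sum(fk$origin == 55000 & fk$direction == "L") / n_cells
    analytic <- pnorm((d - dt) / sqrt(2^2 + 2^2))  # P(T_B < T_A + d)
    expect_lt(abs(fired_b - analytic), 0.08)
  }
})

test_that("priming spacings and Pol alpha tracts follow their distributions", {
  set.seed(9)
  f <- fork_row(50000, "L", 0, 50000)
  pr <- synthesize_fragments(f, sim_params(priming_spacing_sd = 0))
  expect_equal(unique(diff(pr$q)), 165)
  expect_equal(pr$q[1], 165)

  pr20 <- synthesize_fragments(f, sim_params(pol_alpha_min = 20,
                                             pol_alpha_max = 20))
  expect_true(all(pr20$la == 20))

  ## empirical tract-length mean over ~1e5 draws: (10 + 35) / 2 = 22.5
  big <- synthesize_fragments(fork_row(0, "R", 0, 1.7e7), sim_params())
  expect_gt(nrow(big), 1e5)
  expect_lt(abs(mean(big$la) - 22.5), 0.1)

  ## impossible truncation is rejected
  expect_error(synthesize_fragments(f, sim_params(priming_spacing_mean = 10,
                                                  priming_spacing_sd = 0)),
               "minimum fragment size")
})

test_that("nick translation is an identity at 0 cycles and deterministic in the limit", {
  pen <- numeric(1000)
  p1 <- sim_params(p_continue = 1, displace_min = 1, displace_max = 1)
  expect_equal(nick_translate(100, pen, p1, 0), 100)
  expect_equal(nick_translate(100, pen, p1, 10), 110)
  expect_equal(nick_translate(c(100, 200), pen, p1, 10, dir = c(1L, -1L)),
               c(110, 190))
  ## an impassable barrier absorbs the junction
  pen2 <- numeric(1000); pen2[501] <- Inf       # base 500 impassable
  expect_equal(nick_translate(490, pen2, p1, 1000), 500)
  expect_equal(nick_translate(490, pen2, p1, 1e6), 500)
  ## bound clamps advancement
  expect_equal(nick_translate(100, pen, p1, 50, bound = 120), 120)
})

test_that("halting positions match a brute-force Markov-chain enumeration", {
  ## deterministic 1-nt steps through a piecewise-constant pass profile:
  ## the junction halts at the first failed cycle, so
  ## P(halt at start + k) = prod_{j<k} p(j) * (1 - p(k)), truncated at the
  ## cycle budget.
  pen <- rep(c(0, 0.7, 0.2), times = c(8, 6, 20))
  params <- sim_params(p_continue = 0.9, displace_min = 1, displace_max = 1)
  budget <- 25
  pj <- 0.9 * exp(-pen)                          # pass prob at base j (0-based)
  exact <- numeric(budget + 1)                   # halt after k advances
  for (k in 0:budget) {
    surv <- if (k == 0) 1 else prod(pj[1:k])
    exact[k + 1] <- if (k == budget) surv else surv * (1 - pj[k + 1])
  }
  set.seed(123)
  n_mc <- 20000
  finals <- nick_translate(rep(0, n_mc), pen, params, budget)
  emp <- tabulate(finals + 1, nbins = budget + 1)
  ## total variation distance between simulated and enumerated distributions
  tv <- sum(abs(emp / n_mc - exact)) / 2
  expect_lt(tv, 0.02)
  expect_equal(sum(emp), n_mc)
})

test_that("fragments tile each fork's replicated interval exactly once", {
  nuc <- make_nucleosome_map(make_toy_genome(1, 50000), seed = 21)
  sim <- small_sim(n_cells = 6, seed = 31, nucleosomes = nuc)
  fr <- sim$fragments
  for (cell in unique(fr$cell)) {
    fks <- sim$forks[sim$forks$cell == cell, ]
    for (fi in seq_len(nrow(fks))) {
      f <- fks[fi, ]
      if (f$end <= f$start) next
      b <- fr[fr$cell == cell & fr$fork == fi, ]
      b <- b[order(b$start), ]
      expect_equal(b$start[1], f$start)
      expect_equal(b$end[nrow(b)], f$end)
      if (nrow(b) > 1)
        expect_equal(b$start[-1], b$end[-nrow(b)])   # no gaps, no overlaps
    }
  }
})

test_that("fragment strand follows fork direction (Watson left, Crick right)", {
  sim <- small_sim(n_cells = 4, seed = 17)
  fr <- sim$fragments
  for (cell in unique(fr$cell)) {
    fks <- sim$forks[sim$forks$cell == cell, ]
    dirs <- fks$direction[fr$fork[fr$cell == cell]]
    expect_true(all(fr$strand[fr$cell == cell] ==
                      ifelse(dirs == "L", "+", "-")))
  }
})

test_that("junctions never retreat and stay within their fragment's span", {
  sim <- small_sim(n_cells = 5, seed = 51,
                   nucleosomes = make_nucleosome_map(make_toy_genome(1, 50000),
                                                     seed = 2))
  fr <- sim$fragments
  expect_true(all(fr$start < fr$end))
  expect_true(all(fr$start >= 0 & fr$end <= 50000))
  lib <- harvest_library(sim)
  expect_true(all(!duplicated(lib$name)))
})

test_that("with no post-replicative cycles, depletion duration leaves the library unchanged", {
  ## no ligation RNG and no post-NT RNG: runs with 5- vs 60-min depletion
  ## windows consume identical random streams and must agree byte-for-byte
  g <- make_toy_genome(1, 40000)
  ori <- central_origin(g)
  mk <- function(tdep, th) {
    p <- sim_params(post_nt_rate = 0, p_ligate = 0, t_depletion_start = tdep,
                    t_harvest = th)
    harvest_library(simulate_okseq(g, ori, p, n_cells = 8, seed = 77))
  }
  a <- mk(20, 25)   # 5-min depletion
  b <- mk(0, 25)    # full-length depletion, same harvest
  expect_identical(a$start, b$start)
  expect_identical(a$end, b$end)
  expect_identical(a$strand, b$strand)
})

test_that("simulations are deterministic and per-cell streams are counter-stable", {
  s1 <- small_sim(n_cells = 5, seed = 19)
  s2 <- small_sim(n_cells = 5, seed = 19)
  expect_identical(s1$fragments, s2$fragments)
  expect_identical(s1$tracts, s2$tracts)
  ## growing n_cells must not reshuffle earlier cells
  s3 <- small_sim(n_cells = 7, seed = 19)
  expect_identical(s3$fragments[s3$fragments$cell <= 5, ], s1$fragments)
})

test_that("unfinished forks are flagged incomplete and truncated at harvest", {
  g <- make_toy_genome(1, 100000)
  ori <- central_origin(g, mean_time = 5, time_sd = 0)
  p <- sim_params(t_harvest = 15)                # 10 min * 1500 bp = 15 kb arms
  fk <- simulate_forks(g, ori, p, n_cells = 2, seed = 3)
  expect_true(all(!fk$complete))
  expect_true(all(fk$end - fk$start == 15000))
})

test_that("simulator config files round-trip bit-exactly", {
  p <- sim_params(fork_speed = 1234.5, p_ligate = 1 / 3, post_nt_rate = 0.77,
                  t_depletion_start = 10, t_harvest = 33.25,
                  nt_after_primer = FALSE)
  path <- tempfile(fileext = ".toml")
  write_sim_config(p, path)
  expect_identical(read_sim_config(path), p)
  bad <- tempfile(); writeLines("no_such_key = 1", bad)
  expect_error(read_sim_config(bad), "unknown config key")
})
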