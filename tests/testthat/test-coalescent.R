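test_that("degenerate panels behave", {
  traj <- const_traj(100)
  chrom <- chromosome_spec(1, 1, 1e5, 0)
  withr::with_seed(1, {
    p <- simulate_panel(4, chrom, traj)
    expect_equal(length(p$positions), 0)
    expect_equal(dim(p$alleles), c(4, 0))
  })
  expect_error(simulate_panel(1, chrom, traj), "at least 2")
})

test_that("every emitted site is segregating with valid positions", {
  withr::with_seed(2, {
    p <- simulate_panel(12, tiny_chrom(mu = 1e-6), scenario_traj())
    S <- length(p$positions)
    expect_gt(S, 0)
    cs <- colSums(p$alleles)
    expect_true(all(cs > 0 & cs < 12))
    expect_true(all(diff(p$positions) > 0))
    expect_true(all(p$positions >= 1 & p$positions <= 1e5))
  })
})

test_that("segregating sites match Watterson's expectation (n = 2, no recomb)", {
  ne <- 100; mu <- 2.5e-8; L <- 1e6
  chrom <- chromosome_spec(1, genetic_length_cm = 1e-9,
                           physical_length_bp = L, mutation_rate = mu)
  withr::with_seed(3, {
    S <- replicate(500, length(simulate_panel(2, chrom, const_traj(ne))$positions))
  })
  expected <- 4 * ne * mu * L  # theta * a_1 * L = 10
  se <- sd(S) / sqrt(length(S))
  expect_lt(abs(mean(S) - expected), 3 * se)
})

test_that("E[S] is invariant to the recombination rate at matched theta", {
  ne <- 50; mu <- 1e-7; L <- 1e5
  withr::with_seed(4, {
    S0 <- replicate(800, length(simulate_panel(
      6, chromosome_spec(1, 1e-9, L, mu), const_traj(ne))$positions))
    S1 <- replicate(800, length(simulate_panel(
      6, chromosome_spec(1, 20, L, mu), const_traj(ne))$positions))
  })
  se <- sqrt(var(S0) / 800 + var(S1) / 800)
  expect_lt(abs(mean(S0) - mean(S1)), 3 * se)
})

test_that("pairwise TMRCA within a larger sample is Exp(1 / (2 Ne))", {
  ne <- 100
  traj <- const_traj(ne)
  withr::with_seed(5, {
    tm <- replicate(2000, {
      tr <- coaldrop:::sample_first_tree(10, traj)
      # time at which leaves 1 and 2 first share an ancestor
      anc1 <- integer(0); x <- 1L
      while (x != 0L) { anc1 <- c(anc1, x); x <- tr$parent[x] }
      x <- 2L
      while (!x %in% anc1) x <- tr$parent[x]
      tr$time[x]
    })
  })
  ks <- suppressWarnings(ks.test(tm, stats::pexp, rate = 1 / (2 * ne)))
  expect_gt(ks$p.value, 0.001)
})

test_that("site frequency spectrum follows theta / i (n = 10, constant Ne)", {
  ne <- 100; mu <- 2e-7; L <- 5e4; n <- 10
  chrom <- chromosome_spec(1, 1e-9, L, mu)
  theta_L <- 4 * ne * mu * L
  withr::with_seed(6, {
    counts <- matrix(0, 1000, n - 1)
    for (r in 1:1000) {
      p <- simulate_panel(n, chrom, const_traj(ne))
      if (length(p$positions))
        counts[r, ] <- tabulate(colSums(p$alleles), nbins = n - 1)
    }
  })
  for (i in seq_len(n - 1)) {
    se <- sd(counts[, i]) / sqrt(nrow(counts))
    expect_lt(abs(mean(counts[, i]) - theta_L / i), 3 * se + 1e-9)
  }
})

test_that("ms dialect round-trips exactly", {
  chrom <- chromosome_spec(1, 1, 100, 1e-4)
  txt <- c("//", "segsites: 2", "positions: 0.25 0.75", "01", "10")
  p <- read_ms_panel(txt, chrom)
  expect_equal(p$positions, c(25, 75))
  expect_equal(p$alleles, rbind(c(0L, 1L), c(1L, 0L)))

  empty <- read_ms_panel(c("segsites: 0"), chrom)
  expect_equal(length(empty$positions), 0)
  expect_equal(write_ms_panel(empty)[2], "segsites: 0")

  one <- read_ms_panel(c("segsites: 1", "positions: 0.5", "1", "0"), chrom)
  expect_equal(length(strsplit(write_ms_panel(one)[3], " ")[[1]]), 2)

  withr::with_seed(7, {
    sim <- simulate_panel(8, tiny_chrom(mu = 1e-6), scenario_traj())
    back <- read_ms_panel(write_ms_panel(sim), sim$chromosome)
    expect_identical(back$alleles, sim$alleles)
    expect_equal(back$positions, sim$positions)
  })
})

test_that("ms parser reports malformed input with line numbers", {
  chrom <- chromosome_spec(1, 1, 1000, 1e-4)
  expect_error(read_ms_panel(c("segsites: 2", "positions: 0.1 0.2",
                               "01", "0"), chrom), "line 4")
  expect_error(read_ms_panel(c("segsites: 2", "positions: 0.1 0.2",
                               "01", "0x"), chrom), "non-binary")
  expect_error(read_ms_panel(c("segsites: 3", "positions: 0.1 0.2",
                               "010"), chrom), "3 numeric positions")
  expect_error(read_ms_panel(c("positions: 0.1"), chrom), "segsites")
  # position ties bump to the next free coordinate
  p <- read_ms_panel(c("segsites: 2", "positions: 0.5001 0.5002",
                       "01", "10"), chromosome_spec(1, 1, 100, 1e-4))
  expect_equal(p$positions, c(50, 51))
})
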