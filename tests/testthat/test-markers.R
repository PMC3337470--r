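# synthetic site index (no pipeline needed): frequencies with a rare-skewed
# shape similar to a neutral spectrum
fake_index <- function(n_sites, n_chr = 3, seed = 1) {
  withr::with_seed(seed, {
    chr <- sort(sample.int(n_chr, n_sites, replace = TRUE))
    freq <- rbeta(n_sites, 0.4, 1.2)
    freq <- pmin(pmax(freq, 1 / 200), 1 - 1 / 200)
    idx <- data.frame(site = seq_len(n_sites), chr = chr,
                      local = unlist(lapply(split(chr, chr), seq_along)) - 1L,
                      pos = unlist(lapply(split(chr, chr),
                                          function(x) sort(sample.int(1e6, length(x))))),
                      freq = freq)
    class(idx) <- c("site_index", "data.frame")
    idx
  })
}

test_that("maf folds frequencies", {
  expect_equal(maf(0.7), 0.3)
  expect_equal(maf(c(0.5, 0, 1)), c(0.5, 0, 0))
  expect_error(maf(1.2), ">= 0")
})

test_that("chips have exactly the configured sizes and uniform MAF", {
  idx <- fake_index(1e5)
  withr::with_seed(2, {
    chips <- sample_chips(idx, c(small = 1e4, big = 5e4))
    expect_equal(lengths(chips), c(small = 1e4L, big = 5e4L))
    expect_true(all(!duplicated(chips$small)))
    # chip MAF distribution matches the source distribution
    d <- suppressWarnings(ks.test(maf(idx$freq[chips$small]),
                                  maf(idx$freq)))$statistic
    expect_lt(d, 0.02)
    # full-density chip returns every site
    all_sites <- sample_chips(idx[1:500, ], c(full = 500L))
    expect_equal(all_sites$full, 1:500)
  })
  expect_error(sample_chips(idx, c(x = 2e5)), "exceeds")
})

test_that("chip allocation across chromosomes is proportional", {
  idx <- fake_index(3e4, n_chr = 3)
  withr::with_seed(3, chips <- sample_chips(idx, c(c1 = 3000L)))
  got <- table(idx$chr[match(chips$c1, idx$site)])
  want <- table(idx$chr) / nrow(idx) * 3000
  expect_true(all(abs(got - want) <= 1))
})

test_that("nested chips are subsets", {
  idx <- fake_index(2e4)
  withr::with_seed(4, {
    chips <- sample_chips(idx, c(big = 5000L, small = 500L), nested = TRUE)
    expect_true(all(chips$small %in% chips$big))
    expect_error(sample_chips(idx, c(small = 10L, big = 100L), nested = TRUE),
                 "non-increasing")
  })
})

test_that("candidate QTL respect the MAF restriction rule", {
  idx <- fake_index(2e4)
  withr::with_seed(5, {
    q <- sample_candidate_qtl(idx, 1000, maf_threshold = 0.30)
    expect_length(q$sites, 1000)
    expect_lte(max(maf(idx$freq[match(q$sites, idx$site)])), 0.30)

    # no threshold, n = all sites: identity
    all_q <- sample_candidate_qtl(idx, nrow(idx), NULL)
    expect_equal(all_q$sites, idx$site)

    # eligibility equals a linear-scan filter oracle
    oracle <- idx$site[sapply(seq_len(nrow(idx)), function(i) {
      f <- idx$freq[i]
      f > 0 && f < 1 && min(f, 1 - f) <= 0.30
    })]
    expect_true(all(q$sites %in% oracle))
    expect_error(sample_candidate_qtl(idx, length(oracle) + 1, 0.30),
                 "eligible")
  })
})

test_that("the restriction holds for every seed", {
  idx <- fake_index(5000, seed = 6)
  for (s in 1:100) {
    withr::with_seed(s, q <- sample_candidate_qtl(idx, 300, 0.25))
    expect_lte(max(maf(idx$freq[match(q$sites, idx$site)])), 0.25)
  }
})

test_that("chip/QTL overlap matches the hypergeometric expectation", {
  idx <- fake_index(2e4, seed = 7)
  withr::with_seed(7, {
    ov <- replicate(200, {
      chip <- sample_chips(idx, c(a = 2000L))$a
      q <- sample_candidate_qtl(idx, 1000, NULL)
      length(intersect(chip, q$sites))
    })
  })
  expected <- 2000 * 1000 / 2e4
  expect_lt(abs(mean(ov) - expected), 3 * sd(ov) / sqrt(length(ov)))
})

test_that("dosage extraction agrees with unpacked bits", {
  res <- small_run()
  idx <- res$index
  withr::with_seed(8, {
    sites <- sort(sample(idx$site, 50))
    rows <- sort(sample(nrow(res$ped), 10))
    dos <- genotype_dosage(res$genomes, idx, sites, rows)
    loc <- coaldrop:::site_locations(idx, sites)
    for (r in seq_along(rows)) {
      for (j in seq_along(sites)) {
        ch <- res$genomes$chromosomes[[loc$chr[j]]]
        bit_sum <- unpack_gamete(ch$pat[[rows[r]]])[loc$local[j] + 1] +
          unpack_gamete(ch$mat[[rows[r]]])[loc$local[j] + 1]
        expect_equal(dos[r, j], bit_sum, ignore_attr = TRUE)
      }
    }
    # column means / 2 are cohort allele frequencies (base generation)
    base <- which(res$ped$generation == 0)
    dos_b <- genotype_dosage(res$genomes, idx, sites, base)
    expect_equal(colMeans(dos_b) / 2,
                 idx$freq[match(sites, idx$site)],
                 ignore_attr = TRUE)
  })
  expect_error(genotype_dosage(res$genomes, idx, max(idx$site) + 1),
               "unknown")
})
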