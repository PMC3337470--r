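test_that("crossover counts are Poisson(rate x length)", {
  expect_length(draw_crossovers(0), 0)
  withr::with_seed(1, {
    n_xo <- replicate(2e4, length(draw_crossovers(100)))
    se <- sd(n_xo) / sqrt(length(n_xo))
    expect_lt(abs(mean(n_xo) - 1), 3 * se)
    # chi-square goodness of fit against Poisson(1)
    obs <- tabulate(pmin(n_xo, 4) + 1, nbins = 5)
    pr <- c(dpois(0:3, 1), 1 - ppois(3, 1))
    chi <- suppressWarnings(chisq.test(obs, p = pr))
    expect_gt(chi$p.value, 0.001)
    # positions are uniform
    pos <- unlist(replicate(3000, draw_crossovers(100), simplify = FALSE))
    expect_gt(suppressWarnings(ks.test(pos, "punif", 0, 100))$p.value, 0.001)
  })
})

test_that("cM positions map to the first site at/after the bp threshold", {
  chrom <- chromosome_spec(1, 100, 1000, 1e-4)
  pp <- c(10, 250, 251, 600, 999)
  expect_equal(cm_to_site_index(0, chrom, pp), 0L)
  expect_equal(cm_to_site_index(100, chrom, pp), 5L)  # past last site
  expect_equal(cm_to_site_index(25, chrom, pp), 1L)   # bp 250 == site 2
  withr::with_seed(2, {
    for (i in 1:100) {
      pos <- sort(sample(1:1000, 20))
      cm <- runif(1, 0, 100)
      bp <- cm / 100 * 1000
      oracle <- sum(pos < bp)  # linear scan
      expect_equal(cm_to_site_index(cm, chrom, pos), oracle)
    }
  })
})

test_that("base gametes are mosaics of panel haplotypes", {
  withr::with_seed(3, {
    panel <- with_map_length(
      simulate_panel(10, tiny_chrom(cm = 0.01, mu = 2e-6), const_traj(100)),
      cm = 300)
    S <- length(panel$positions)
    expect_gt(S, 10)
    for (r in 1:20) {
      g <- unpack_gamete(make_base_gamete(panel))
      # column membership: every allele exists in the panel at that site
      for (j in seq_len(S))
        expect_true(g[j] %in% panel$alleles[, j])
    }
  })
  expect_error(make_base_gamete(
    structure(list(n = 0), class = "haplotype_panel")), "empty")
})

test_that("base-generation frequencies track panel frequencies", {
  withr::with_seed(4, {
    panel <- with_map_length(
      simulate_panel(40, tiny_chrom(cm = 0.01, mu = 2e-6), const_traj(150)),
      cm = 50)
    n_gam <- 800
    counts <- integer(length(panel$positions))
    for (r in seq_len(n_gam))
      counts <- counts + unpack_gamete(make_base_gamete(panel))
    p_panel <- colMeans(panel$alleles)
    p_base <- counts / n_gam
    se <- sqrt(p_panel * (1 - p_panel) / n_gam)
    expect_true(all(abs(p_base - p_panel) < 4 * se + 1e-9))
  })
})

test_that("meiosis transmits parental alleles (Mendelian consistency)", {
  chrom <- chromosome_spec(1, 100, 1e5, 1e-6)
  pos <- sort(sample(1:1e5, 400))
  withr::with_seed(5, {
    # homozygous parent: offspring gamete identical
    h <- pack_gamete(random_gamete_bits(400))
    par_hom <- diploid_genome(list(h), list(h))
    g <- meiosis(par_hom, 1, chrom, pos)
    expect_identical(g$words, h$words)

    # heterozygous parent: each site from one of the two gametes
    pa <- random_gamete_bits(400); ma <- random_gamete_bits(400)
    par <- diploid_genome(list(pack_gamete(pa)), list(pack_gamete(ma)))
    for (r in 1:30) {
      g <- unpack_gamete(meiosis(par, 1, chrom, pos))
      expect_true(all(g == pa | g == ma))
    }
  })
})

test_that("transmission at a heterozygous site is fair", {
  chrom <- chromosome_spec(1, 100, 1e4, 1e-6)
  pos <- c(2500, 7500)
  par <- diploid_genome(list(pack_gamete(c(1L, 0L))),
                        list(pack_gamete(c(0L, 1L))))
  withr::with_seed(6, {
    n <- 1e4
    hits <- 0
    for (r in seq_len(n))
      hits <- hits + unpack_gamete(meiosis(par, 1, chrom, pos))[1]
    se <- sqrt(0.25 / n)
    expect_lt(abs(hits / n - 0.5), 3 * se)
  })
})

test_that("gene drop is Mendelian-consistent and creates no new alleles", {
  withr::with_seed(7, {
    panel <- with_map_length(
      simulate_panel(30, tiny_chrom(cm = 0.01, mu = 2e-6), const_traj(100)),
      cm = 100)
    ped <- generate_pedigree(4, 2, 3, 3)
    genomes <- drop_genomes(ped, list(panel))
    S <- length(panel$positions)
    idx <- build_site_index(genomes)
    dos <- genotype_dosage(genomes, idx, idx$site)
    expect_true(all(dos %in% 0:2))

    # dosage equals the sum of the two unpacked gametes
    i <- sample(nrow(ped), 1)
    ch <- genomes$chromosomes[[1]]
    expect_equal(dos[i, ],
                 unpack_gamete(ch$pat[[i]]) + unpack_gamete(ch$mat[[i]]),
                 ignore_attr = TRUE)

    # trio consistency at every site for every non-base individual
    for (i in which(ped$sire != 0)) {
      s <- match(ped$sire[i], ped$id); d <- match(ped$dam[i], ped$id)
      kid_p <- unpack_gamete(ch$pat[[i]])
      kid_m <- unpack_gamete(ch$mat[[i]])
      sp <- unpack_gamete(ch$pat[[s]]); sm <- unpack_gamete(ch$mat[[s]])
      dp <- unpack_gamete(ch$pat[[d]]); dm <- unpack_gamete(ch$mat[[d]])
      expect_true(all(kid_p == sp | kid_p == sm))
      expect_true(all(kid_m == dp | kid_m == dm))
    }

    # no-mutation invariant: alleles absent in the base stay absent
    base <- which(ped$generation == 0)
    base_count <- colSums(dos[base, , drop = FALSE])
    later <- dos[-base, , drop = FALSE]
    expect_true(all(later[, base_count == 0] == 0))
    fixed <- base_count == 2 * length(base)
    expect_true(all(later[, fixed] == 2))
  })
})

test_that("allele-frequency drift has no systematic trend", {
  withr::with_seed(8, {
    panel <- with_map_length(
      simulate_panel(40, tiny_chrom(cm = 0.01, mu = 1e-6), const_traj(200)),
      cm = 100)
    ped <- generate_pedigree(6, 4, 5, 2)
    genomes <- drop_genomes(ped, list(panel))
    idx <- build_site_index(genomes)
    common <- idx$site[idx$freq > 0.1 & idx$freq < 0.9]
    dos <- genotype_dosage(genomes, idx, common)
    gens <- sort(unique(ped$generation))
    freq_by_gen <- t(sapply(gens, function(g)
      colMeans(dos[ped$generation == g, , drop = FALSE]) / 2))
    # per-site regression slope of frequency on generation, centred on 0
    slopes <- apply(freq_by_gen, 2, function(f)
      coef(lm(f ~ gens))[2])
    expect_lt(abs(mean(slopes)), 3 * sd(slopes) / sqrt(length(slopes)))
  })
})
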