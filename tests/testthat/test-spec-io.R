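test_that("the shipped scenario file carries every scenario parameter", {
  spec <- default_scenario_spec()
  expect_equal(spec$genome$n_chromosomes, 30L)
  expect_equal(spec$genome$genetic_length_cm, 100)
  expect_equal(spec$genome$physical_length_bp, 1e8)
  expect_equal(spec$genome$mutation_rate, 2.5e-8)
  expect_equal(spec$demography$anchors[, 1], c(0, 1000, 10000, 100000),
               ignore_attr = TRUE)
  expect_equal(spec$demography$anchors[, 2], c(100, 1256, 4350, 43500),
               ignore_attr = TRUE)
  expect_equal(spec$haplotypes$n_haplotypes, 4000L)
  expect_equal(spec$pedigree$n_generations, 10L)
  expect_equal(spec$pedigree$n_sires, 50L)
  expect_equal(spec$pedigree$dams_per_sire, 10L)
  expect_equal(spec$pedigree$offspring_per_dam, 2L)
  expect_equal(spec$gene_drop$crossover_rate_per_cm, 0.01)
  expect_equal(spec$chips$densities,
               c(Chip60k = 60000L, Chip300k = 300000L))
  expect_equal(spec$qtl$n_candidates, 9000L)
  expect_equal(spec$qtl$maf_threshold, 0.30)
  expect_equal(spec$traits$heritability, 0.25)
  expect_equal(spec$traits$gamma_shape, 0.4)
  expect_equal(spec$traits$gamma_scale, 1.66)
  expect_equal(spec$traits$gamma_subset, 900L)
  expect_equal(spec$split$training_generations, c(3L, 4L))
  expect_equal(spec$split$validation_generations, c(5L, 7L, 9L))
  expect_equal(spec$split$validation_size, 500L)
})

test_that("parse -> emit -> parse is a fixpoint", {
  spec <- default_scenario_spec()
  again <- parse_spec(write_spec(spec))
  expect_equal(unclass(again), unclass(spec))
})

test_that("the parser names offending keys and lines", {
  expect_error(parse_spec(c("[genome]", "bogus_key = 1")), "bogus_key")
  expect_error(parse_spec(c("x = 1")), "outside any section")
  expect_error(parse_spec(c("[genome]", "n_chromosomes = two")), "number")
  expect_error(parse_spec(character(0)), "demography.anchor")
  expect_error(parse_spec(c("[demography]", "anchor = 5")), "<time> <Ne>")
  expect_error(parse_spec(c("[demography]", "anchor = 0 100",
                            "[split]", "training_generations = 40")),
               "outside 0..9")
})

test_that("scale_spec shrinks sequence and chips but not the pedigree", {
  spec <- scale_spec(default_scenario_spec(), 0.01)
  expect_equal(spec$genome$physical_length_bp, 1e6)
  expect_equal(spec$genome$genetic_length_cm, 1)
  expect_equal(spec$chips$densities, c(Chip60k = 600L, Chip300k = 3000L))
  expect_equal(spec$qtl$n_candidates, 9000L)
  expect_equal(spec$pedigree$n_generations, 10L)
  expect_equal(spec$genome$chromosomes[[5]]$physical_length_bp, 1e6)
})

test_that("training/validation split follows the generation rules", {
  withr::with_seed(1, ped <- generate_pedigree(6, 3, 3, 2))
  withr::with_seed(2, {
    sp <- write_split(ped, 2:3, c(4, 5), 5)
    expect_equal(nrow(sp$training), 2 * 18)
    expect_true(all(sp$training$generation %in% 2:3))
    expect_equal(vapply(sp$validation, nrow, 1L), c(gen4 = 5L, gen5 = 5L))
    expect_false(any(duplicated(sp$validation$gen4$id)))
    # sample size equal to the generation size returns the whole generation
    whole <- write_split(ped, 2, 5, 18)
    expect_setequal(whole$validation$gen5$id, ped$id[ped$generation == 5])
    expect_error(write_split(ped, 2, 5, 19), "cannot sample")
  })
})

test_that("writers produce consistent genotype, phased and VCF views", {
  res <- small_run()
  dir <- res$out_dir
  idx <- res$index
  chip <- res$chips$ChipA

  gt <- data.table::fread(file.path(dir, "genotypes_ChipA.txt"),
                          data.table = FALSE)
  ph <- data.table::fread(file.path(dir, "phased_ChipA.txt"),
                          data.table = FALSE)
  expect_equal(nrow(gt), nrow(res$ped))
  expect_equal(ncol(gt), length(chip) + 1)
  expect_equal(nrow(ph), 2 * nrow(res$ped))

  # dosage file equals the sum of the two phased rows
  summed <- ph[ph$strand == "P", -(1:2)] + ph[ph$strand == "M", -(1:2)]
  expect_equal(as.matrix(gt[, -1]), as.matrix(summed), ignore_attr = TRUE)

  # VCF: phase bars everywhere, dosages match the genotype file
  vcf <- readLines(file.path(dir, "chip_ChipA.vcf"))
  body <- vcf[!startsWith(vcf, "#")]
  expect_equal(length(body), length(chip))
  fields <- strsplit(body, "\t")
  expect_true(all(vapply(fields, function(f)
    all(grepl("^[01]\\|[01]$", f[-(1:9)])), TRUE)))
  vcf_dos <- t(vapply(fields, function(f) {
    gtv <- f[-(1:9)]
    as.integer(substr(gtv, 1, 1)) + as.integer(substr(gtv, 3, 3))
  }, integer(nrow(res$ped))))
  ord <- order(match(paste0("site", chip),
                     vapply(fields, `[`, "", 3)))
  expect_equal(unname(as.matrix(gt[, -1])), unname(t(vcf_dos)[, ord]))

  # header-only VCF for an empty site set
  f <- withr::local_tempfile(fileext = ".vcf")
  export_vcf(res$genomes, idx, integer(0), f)
  expect_true(all(startsWith(readLines(f), "#")))

  # sequence file covers all sites
  seq_ph <- data.table::fread(file.path(dir, "sequence_phased.txt"),
                              nrows = 2, data.table = FALSE)
  expect_equal(ncol(seq_ph), nrow(idx) + 2)
})

test_that("a trivial all-ancestral genome writes an all-zero row", {
  chrom <- chromosome_spec(1, 1, 100, 1e-4)
  ped <- data.frame(id = 1L, sire = 0L, dam = 0L, sex = "M",
                    generation = 0L)
  class(ped) <- c("pedigree", "data.frame")
  g0 <- pack_gamete(c(0L, 0L, 0L))
  genomes <- structure(list(
    chromosomes = list(list(pat = list(g0), mat = list(g0), n_sites = 3L,
                            chromosome = chrom, positions = c(10, 50, 90))),
    ped = ped), class = "gene_drop_result")
  idx <- build_site_index(genomes)
  f <- withr::local_tempfile(fileext = ".txt")
  write_genotypes(genomes, idx, idx$site, f)
  got <- read.delim(f)
  expect_equal(unname(unlist(got)), c(1L, 0L, 0L, 0L))
})

test_that("manifest counts match the files and reruns are byte-identical", {
  res <- small_run()
  dir <- res$out_dir
  for (i in seq_len(nrow(res$manifest))) {
    f <- file.path(dir, res$manifest$file[i])
    expect_true(file.exists(f))
    if (grepl("\\.(txt|tsv)$", f) && !grepl("pedigree", f)) {
      tab <- data.table::fread(f, data.table = FALSE)
      expect_equal(nrow(tab), res$manifest$rows[i])
      expect_equal(ncol(tab), res$manifest$cols[i])
    }
  }

  spec <- small_spec()
  d1 <- withr::local_tempdir("rerun1")
  d2 <- withr::local_tempdir("rerun2")
  run_simulation(spec, d1, seed = 5)
  run_simulation(spec, d2, seed = 5)
  f1 <- sort(list.files(d1))
  expect_equal(f1, sort(list.files(d2)))
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
  # different seed changes the outputs
  d3 <- withr::local_tempdir("rerun3")
  run_simulation(spec, d3, seed = 6)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "site_index.txt"))),
                         unname(tools::md5sum(file.path(d3, "site_index.txt")))))
})

test_that("sequence toggle controls the manifest", {
  spec <- small_spec()
  spec$output$sequence <- FALSE
  spec$output$phased <- FALSE
  spec$output$vcf <- FALSE
  d <- withr::local_tempdir("notoggle")
  res <- run_simulation(spec, d, seed = 3)
  expect_false("sequence_phased.txt" %in% res$manifest$file)
  expect_false(any(grepl("phased_", res$manifest$file)))
})

test_that("the CLI drives simulate, validate and stats", {
  spec_file <- system.file("extdata", "livestock_scenario.spec",
                           package = "coaldrop")
  expect_message(coaldrop_cli(c("validate", spec_file)), "specification OK")
  d <- withr::local_tempdir("cli")
  tiny <- small_spec()
  f <- withr::local_tempfile(fileext = ".spec")
  write_spec(tiny, f)
  expect_message(coaldrop_cli(c("simulate", f, "--out", d, "--seed", "4")),
                 "wrote")
  expect_output(coaldrop_cli(c("stats", d)), "run_report")
  expect_equal(coaldrop_cli(character(0)), 1L, ignore_attr = TRUE)
})
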