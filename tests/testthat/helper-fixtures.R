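# Shared fixtures. Everything is generated in code under fixed seeds; the
# heavier shared objects are built lazily and cached for the whole run.

scenario_traj <- function() {
  ne_trajectory(c(0, 1000, 10000, 100000), c(100, 1256, 4350, 43500))
}

const_traj <- function(ne = 100) ne_trajectory(0, ne)

# a small chromosome for fast panels
tiny_chrom <- function(L = 1e5, cm = 1, mu = 1e-6) {
  chromosome_spec(1, genetic_length_cm = cm, physical_length_bp = L,
                  mutation_rate = mu)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, force(expr), envir = .fixture_cache)
  .fixture_cache[[key]]
}

# A small but complete run shared across io/markers/traits/sumstats tests:
# 2 chromosomes, 6-generation pedigree of 240, ~1e3 sites.
small_run <- function() {
  cached("small_run", {
    spec <- small_spec()
    withr::with_seed(424242, {
      dir <- file.path(tempdir(), "coaldrop-small-run")
      run_simulation(spec, dir, seed = 99)
    })
  })
}

small_spec <- function() {
  spec <- unclass(default_scenario_spec())
  spec$genome$n_chromosomes <- 2L
  spec$genome$physical_length_bp <- 2e5
  spec$genome$genetic_length_cm <- 5
  spec$genome$mutation_rate <- 1e-6
  # flat recent history keeps the fixture fast; the scenario demography is
  # exercised by the demography/coalescent/acceptance tests
  spec$demography$anchors <- cbind(c(0, 500), c(200, 800))
  spec$pedigree$n_generations <- 6L
  spec$pedigree$n_sires <- 5L
  spec$pedigree$dams_per_sire <- 4L
  spec$haplotypes$n_haplotypes <- 40L
  spec$chips$densities <- c(ChipA = 80L, ChipB = 400L)
  spec$qtl$n_candidates <- 120L
  spec$traits$gamma_subset <- 12L
  spec$split$training_generations <- 2:3
  spec$split$validation_generations <- c(4L, 5L)
  spec$split$validation_size <- 10L
  spec$output$sequence <- TRUE
  spec$output$phased <- TRUE
  spec$output$vcf <- TRUE
  coaldrop:::finalize_spec(spec)
}

random_gamete_bits <- function(n) sample(0:1, n, replace = TRUE)

# re-label a panel with a different genetic map length (the panel itself
# only depends on the map through the coalescent stage; downstream code
# reads genetic_length_cm for crossover placement, so this lets tests use
# many-crossover maps without paying for a recombination-heavy coalescent)
with_map_length <- function(panel, cm) {
  ch <- panel$chromosome
  panel$chromosome <- chromosome_spec(ch$index, cm, ch$physical_length_bp,
                                      ch$mutation_rate)
  panel
}
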