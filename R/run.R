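# Seed substreams: one master seed, per-(stage, index) derived seeds so
# any stage can be regenerated independently and runs are reproducible.
derive_seed <- function(master, stage, index = 0L) {
  m <- 2147483647  # 2^31 - 1
  stage_id <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((((master %% m) * 48271) %% m + stage_id * 7919 + index * 104729) %% m)
}

#' Write training/validation id lists
#'
#' The training set is every individual of the training generations; each
#' validation set is a uniform sample without replacement of
#' `validation_size` ids from its generation.
#'
#' @param ped a `pedigree`.
#' @param training_generations,validation_generations 0-based generation
#'   labels.
#' @param validation_size animals sampled per validation generation.
#' @return list with `training` (data.frame id, generation) and
#'   `validation` (named list of data.frames, one per generation).
#' @export
write_split <- function(ped, training_generations, validation_generations,
                        validation_size) {
  train <- ped[ped$generation %in% training_generations, c("id", "generation")]
  if (nrow(train) == 0 && length(training_generations))
    stop("no individuals in training generations ",
         paste(training_generations, collapse = ", "))
  val <- lapply(validation_generations, function(g) {
    ids <- ped$id[ped$generation == g]
    if (length(ids) < validation_size)
      stop("generation ", g, " has ", length(ids),
           " individuals; cannot sample ", validation_size)
    data.frame(id = sort(sample(ids, validation_size)), generation = g)
  })
  names(val) <- paste0("gen", validation_generations)
  rownames(train) <- NULL
  list(training = train, validation = val)
}

# unpack the alleles of one gamete at given 0-based local sites
gamete_alleles <- function(g, local) {
  .cpp_dosage(g$words, g$words, g$n_sites, local) %/% 2L
}

site_locations <- function(index, sites) {
  pos <- match(sites, index$site)
  if (anyNA(pos)) stop("unknown global site id")
  list(chr = index$chr[pos], local = index$local[pos], pos = index$pos[pos])
}

#' Write a genotype dosage file
#'
#' One row per individual: `id` then the 0/1/2 derived-allele dosages in
#' site order, tab-delimited with a header.
#'
#' @param genomes a `gene_drop_result`.
#' @param index the run's `site_index`.
#' @param sites global site ids (chip or full sequence).
#' @param path output file.
#' @param chunk individuals per write block.
#' @return invisibly `c(rows, cols)` of the written table.
#' @export
write_genotypes <- function(genomes, index, sites, path, chunk = 500L) {
  loc <- site_locations(index, sites)
  n <- nrow(genomes$ped)
  header <- c("id", paste0("site", sites))
  first <- TRUE
  for (lo in seq(1L, n, by = chunk)) {
    rows <- lo:min(lo + chunk - 1L, n)
    d <- genotype_dosage(genomes, index, sites, rows)
    dt <- data.table::data.table(id = genomes$ped$id[rows])
    dt <- cbind(dt, data.table::as.data.table(d))
    data.table::setnames(dt, header)
    data.table::fwrite(dt, path, sep = "\t", append = !first,
                       col.names = first)
    first <- FALSE
  }
  invisible(c(n, length(sites) + 1L))
}

#' Write phased alleles
#'
#' Two rows per individual (paternal then maternal): `id`, `strand`
#' (`P`/`M`) and the 0/1 alleles at the requested sites.
#'
#' @inheritParams write_genotypes
#' @return invisibly `c(rows, cols)`.
#' @export
write_phased <- function(genomes, index, sites, path, chunk = 500L) {
  loc <- site_locations(index, sites)
  n <- nrow(genomes$ped)
  chr_of <- vapply(genomes$chromosomes, function(ch) ch$chromosome$index, 1L)
  header <- c("id", "strand", paste0("site", sites))
  first <- TRUE
  for (lo in seq(1L, n, by = chunk)) {
    rows <- lo:min(lo + chunk - 1L, n)
    block <- matrix(0L, nrow = 2L * length(rows), ncol = length(sites))
    for (c_i in unique(match(loc$chr, chr_of))) {
      ch <- genomes$chromosomes[[c_i]]
      cols <- which(loc$chr == chr_of[c_i])
      for (r in seq_along(rows)) {
        i <- rows[r]
        block[2L * r - 1L, cols] <- gamete_alleles(ch$pat[[i]], loc$local[cols])
        block[2L * r, cols] <- gamete_alleles(ch$mat[[i]], loc$local[cols])
      }
    }
    dt <- data.table::data.table(
      id = rep(genomes$ped$id[rows], each = 2L),
      strand = rep(c("P", "M"), length(rows)))
    dt <- cbind(dt, data.table::as.data.table(block))
    data.table::setnames(dt, header)
    data.table::fwrite(dt, path, sep = "\t", append = !first,
                       col.names = first)
    first <- FALSE
  }
  invisible(c(2L * n, length(sites) + 2L))
}

#' @rdname write_phased
#' @details `write_sequence()` is `write_phased()` over every segregating
#'   site in the genome.
#' @export
write_sequence <- function(genomes, index, path, chunk = 200L) {
  write_phased(genomes, index, index$site, path, chunk)
}

#' Export phased genotypes as VCF
#'
#' Minimal VCF 4.2 with placeholder alleles (REF=A, ALT=T; the simulator
#' tracks ancestral/derived state, not nucleotides), contig headers per
#' chromosome and phased `GT` (`paternal|maternal`).
#'
#' @inheritParams write_genotypes
#' @return invisibly the path.
#' @export
export_vcf <- function(genomes, index, sites, path) {
  loc <- site_locations(index, sites)
  ord <- order(loc$chr, loc$pos)
  sites <- sites[ord]
  loc <- lapply(loc, `[`, ord)
  ped <- genomes$ped
  chr_of <- vapply(genomes$chromosomes, function(ch) ch$chromosome$index, 1L)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=coaldrop",
    vapply(genomes$chromosomes, function(ch)
      sprintf("##contig=<ID=%d,length=%d>", ch$chromosome$index,
              as.integer(ch$chromosome$physical_length_bp)), ""),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", paste0("ind", ped$id)), collapse = "\t"))
  gt <- matrix("", nrow = length(sites), ncol = nrow(ped))
  for (c_i in unique(match(loc$chr, chr_of))) {
    ch <- genomes$chromosomes[[c_i]]
    rows <- which(loc$chr == chr_of[c_i])
    for (i in seq_len(nrow(ped))) {
      p <- gamete_alleles(ch$pat[[i]], loc$local[rows])
      m <- gamete_alleles(ch$mat[[i]], loc$local[rows])
      gt[rows, i] <- paste0(p, "|", m)
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  if (length(sites)) {
    body <- cbind(loc$chr, as.integer(loc$pos), paste0("site", sites),
                  "A", "T", ".", "PASS", ".", "GT", gt)
    utils::write.table(body, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Run a full simulation
#'
#' Executes the pipeline in fixed stage order - demography, coalescent
#' (or ms import), pedigree, gene drop, site index, chips, candidate
#' QTL, traits, split, writers - with one derived seed per stage, and
#' writes every output plus a `manifest.tsv` with per-file row/column
#' counts and the master seed.  Identical spec + seed gives a
#' byte-identical output tree.
#'
#' @param spec a `sim_spec` (see [parse_spec()]).
#' @param out_dir output directory (created if needed).
#' @param seed master seed overriding the spec's `[output] seed`.
#' @param scale optional desk-scale factor passed to [scale_spec()].
#' @return invisibly, a list with the in-memory run objects (`ped`,
#'   `panels`, `genomes`, `index`, `chips`, `qtl`, `traits`, `split`,
#'   `manifest`).
#' @export
run_simulation <- function(spec, out_dir, seed = NULL, scale = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  if (!is.null(scale)) spec <- scale_spec(spec, scale)
  master <- as.integer(seed %||% spec$output$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  note <- function(file, rows, cols)
    manifest[[length(manifest) + 1L]] <<-
      data.frame(file = file, rows = rows, cols = cols)

  # pedigree ----------------------------------------------------------
  set.seed(derive_seed(master, "pedigree"))
  ped <- if (spec$pedigree$source == "internal") {
    p <- spec$pedigree
    generate_pedigree(p$n_generations, p$n_sires, p$dams_per_sire,
                      p$offspring_per_dam)
  } else read_pedigree(spec$pedigree$path)
  write_pedigree(ped, file.path(out_dir, "pedigree.txt"))
  note("pedigree.txt", nrow(ped), 4L)

  # haplotypes --------------------------------------------------------
  panels <- vector("list", spec$genome$n_chromosomes)
  for (c_i in seq_along(panels)) {
    chrom <- spec$genome$chromosomes[[c_i]]
    panels[[c_i]] <- if (spec$haplotypes$source == "coalescent") {
      set.seed(derive_seed(master, "coalescent", c_i))
      simulate_panel(spec$haplotypes$n_haplotypes, chrom,
                     spec$demography$trajectory)
    } else {
      read_ms_panel(spec$haplotypes$files[c_i], chrom)
    }
  }

  # gene drop ---------------------------------------------------------
  set.seed(derive_seed(master, "drop"))
  model <- recomb_model(spec$gene_drop$crossover_rate_per_cm)
  genomes <- drop_genomes(ped, panels, model, crossover_log = TRUE)

  index <- build_site_index(genomes)
  data.table::fwrite(index, file.path(out_dir, "site_index.txt"), sep = "\t")
  note("site_index.txt", nrow(index), ncol(index))

  # chips and QTL ------------------------------------------------------
  set.seed(derive_seed(master, "chips"))
  chips <- sample_chips(index, spec$chips$densities, spec$chips$nested)
  for (nm in names(chips)) {
    loc <- site_locations(index, chips[[nm]])
    map <- data.frame(chip = nm, chr = loc$chr, pos = loc$pos,
                      site = chips[[nm]])
    f <- paste0("chip_", nm, "_map.txt")
    data.table::fwrite(map, file.path(out_dir, f), sep = "\t")
    note(f, nrow(map), ncol(map))
  }
  set.seed(derive_seed(master, "qtl", 1L))
  qtl_unres <- sample_candidate_qtl(index, spec$qtl$n_candidates, NULL)
  set.seed(derive_seed(master, "qtl", 2L))
  qtl_res <- sample_candidate_qtl(index, spec$qtl$n_candidates,
                                  spec$qtl$maf_threshold)
  qsets <- list(unrestricted = qtl_unres, restricted = qtl_res)
  for (nm in names(qsets)) {
    loc <- site_locations(index, qsets[[nm]]$sites)
    map <- data.frame(set = nm, chr = loc$chr, pos = loc$pos,
                      site = qsets[[nm]]$sites,
                      maf = maf(index$freq[match(qsets[[nm]]$sites, index$site)]))
    f <- paste0("qtl_", nm, "_map.txt")
    data.table::fwrite(map, file.path(out_dir, f), sep = "\t")
    note(f, nrow(map), ncol(map))
  }

  # traits -------------------------------------------------------------
  set.seed(derive_seed(master, "traits"))
  tr <- spec$traits
  traits <- build_four_traits(genomes, index, qtl_unres, qtl_res,
                              h2 = tr$heritability,
                              gamma_shape = tr$gamma_shape,
                              gamma_scale = tr$gamma_scale,
                              gamma_subset = tr$gamma_subset)
  for (nm in names(traits$models)) {
    m <- traits$models[[nm]]
    tab <- data.frame(id = traits$values$id,
                      generation = traits$values$generation,
                      breeding_value = traits$values[[paste0("bv_", nm)]],
                      phenotype = traits$values[[paste0("phen_", nm)]])
    f <- paste0("trait_", nm, ".txt")
    data.table::fwrite(tab, file.path(out_dir, f), sep = "\t")
    note(f, nrow(tab), ncol(tab))
    loc <- site_locations(index, m$loci)
    eff <- data.frame(site = m$loci, chr = loc$chr, pos = loc$pos,
                      effect = m$effects)
    f <- paste0("qtl_effects_", nm, ".txt")
    data.table::fwrite(eff, file.path(out_dir, f), sep = "\t")
    note(f, nrow(eff), ncol(eff))
  }
  scaling <- data.frame(
    trait = names(traits$models),
    n_loci = vapply(traits$models, function(m) length(m$loci), 1L),
    sigma2_a = vapply(traits$models, function(m) m$sigma2_a, 1),
    sigma2_a_uncentered = vapply(traits$models,
                                 function(m) m$sigma2_a_uncentered, 1),
    sigma_e = vapply(traits$models, function(m) m$sigma_e, 1),
    h2_configured = vapply(traits$models, function(m)
      m$sigma2_a / (m$sigma2_a + m$sigma_e^2), 1))
  data.table::fwrite(scaling, file.path(out_dir, "trait_scaling.txt"),
                     sep = "\t")
  note("trait_scaling.txt", nrow(scaling), ncol(scaling))

  # genotype / phased / sequence outputs -------------------------------
  for (nm in names(chips)) {
    f <- paste0("genotypes_", nm, ".txt")
    dim <- write_genotypes(genomes, index, chips[[nm]],
                           file.path(out_dir, f))
    note(f, dim[1], dim[2])
    if (spec$output$phased) {
      f <- paste0("phased_", nm, ".txt")
      dim <- write_phased(genomes, index, chips[[nm]], file.path(out_dir, f))
      note(f, dim[1], dim[2])
    }
    if (spec$output$vcf) {
      f <- paste0("chip_", nm, ".vcf")
      export_vcf(genomes, index, chips[[nm]], file.path(out_dir, f))
      note(f, length(chips[[nm]]), nrow(ped) + 9L)
    }
  }
  if (spec$output$sequence) {
    dim <- write_sequence(genomes, index, file.path(out_dir, "sequence_phased.txt"))
    note("sequence_phased.txt", dim[1], dim[2])
  }

  # split ---------------------------------------------------------------
  set.seed(derive_seed(master, "split"))
  split <- write_split(ped, spec$split$training_generations,
                       spec$split$validation_generations,
                       spec$split$validation_size)
  data.table::fwrite(split$training, file.path(out_dir, "training_ids.txt"),
                     sep = "\t")
  note("training_ids.txt", nrow(split$training), 2L)
  for (nm in names(split$validation)) {
    f <- paste0("validation_", nm, "_ids.txt")
    data.table::fwrite(split$validation[[nm]], file.path(out_dir, f),
                       sep = "\t")
    note(f, nrow(split$validation[[nm]]), 2L)
  }

  # audit summary + manifest -------------------------------------------
  audit <- data.frame(
    key = c("master_seed", "n_individuals", "n_segregating_sites",
            "crossovers", "cm_simulated"),
    value = c(master, nrow(ped), nrow(index),
              attr(genomes, "crossovers") %||% NA,
              attr(genomes, "cm_total") %||% NA))
  data.table::fwrite(audit, file.path(out_dir, "run_audit.txt"), sep = "\t")
  note("run_audit.txt", nrow(audit), 2L)

  mf <- do.call(rbind, manifest)
  mf$master_seed <- master
  data.table::fwrite(mf, file.path(out_dir, "manifest.tsv"), sep = "\t")

  invisible(list(spec = spec, ped = ped, panels = panels, genomes = genomes,
                 index = index, chips = chips,
                 qtl = qsets, traits = traits, split = split, manifest = mf,
                 out_dir = out_dir))
}
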