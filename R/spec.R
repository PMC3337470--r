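#' Simulation specification files
#'
#' A whole run is controlled by one plain-text file with INI-style
#' sections and `key = value` lines (`#` comments allowed).  Repeated
#' keys are only allowed where documented (`anchor`, `chip`).  The
#' grammar:
#'
#' ```
#' [genome]      n_chromosomes, genetic_length_cm, physical_length_bp,
#'               mutation_rate
#' [demography]  anchor = <time> <Ne>   (one per line, time ascending),
#'               generation_interval (years per generation, default 1)
#' [haplotypes]  source = coalescent | ms; n_haplotypes; files (ms mode,
#'               one path per chromosome)
#' [pedigree]    source = internal | file; n_generations, n_sires,
#'               dams_per_sire, offspring_per_dam; path (file mode)
#' [gene_drop]   crossover_rate_per_cm (default 0.01)
#' [chips]       chip = <name> <density>  (one per line); nested = yes|no
#' [qtl]         n_candidates; maf_threshold
#' [traits]      heritability; gamma_shape; gamma_scale; gamma_subset
#' [split]       training_generations; validation_generations;
#'               validation_size
#' [output]      seed; sequence, phased, vcf = yes|no
#' ```
#'
#' The packaged file `livestock_scenario.spec` (see
#' `system.file("extdata", "livestock_scenario.spec", package =
#' "coaldrop")`) encodes the ten-replicate livestock scenario: 30
#' chromosomes of 100 cM / 1e8 bp, mutation rate 2.5e-8, Holstein-like
#' Ne decline (100 / 1256 / 4350 / 43,500), 4000 base haplotypes, the
#' 50-sire x 10-dam x 2-offspring pedigree over 10 generations, 60k and
#' 300k SNP chips, 9000 candidate QTL with a 0.30 MAF cap on the
#' restricted set, gamma(0.4, 1.66) effects with a 900-locus subset and
#' heritability 0.25.
#'
#' @param path file path, connection, or character vector of lines.
#' @return a `sim_spec` object (nested named list).
#' @export
parse_spec <- function(path) {
  lines <- if (is.character(path) &&
               (length(path) != 1 || !file.exists(path))) path
           else readLines(path)
  raw <- sub("#.*$", "", lines)
  section <- NA_character_
  spec <- empty_spec()
  seen <- character(0)
  for (i in seq_along(raw)) {
    ln <- trimws(raw[i])
    if (!nzchar(ln)) next
    if (grepl("^\\[.+\\]$", ln)) {
      section <- sub("^\\[(.+)\\]$", "\\1", ln)
      if (!section %in% names(spec))
        stop("line ", i, ": unknown section [", section, "]")
      next
    }
    if (is.na(section)) stop("line ", i, ": key outside any section")
    kv <- regmatches(ln, regexec("^([A-Za-z_]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(kv) != 3) stop("line ", i, ": expected 'key = value'")
    key <- kv[2]; val <- trimws(kv[3])
    spec <- set_spec_key(spec, section, key, val, i)
    seen <- c(seen, paste0(section, ".", key))
  }
  required <- c("demography.anchor")
  missing <- setdiff(required, unique(seen))
  if (length(missing))
    stop("missing required key(s): ", paste(missing, collapse = ", "))
  finalize_spec(spec)
}

empty_spec <- function() {
  list(
    genome = list(n_chromosomes = 1L, genetic_length_cm = 100,
                  physical_length_bp = 1e8, mutation_rate = 2.5e-8),
    demography = list(anchors = NULL, generation_interval = 1),
    haplotypes = list(source = "coalescent", n_haplotypes = 4000L,
                      files = character(0)),
    pedigree = list(source = "internal", n_generations = 10L,
                    n_sires = 50L, dams_per_sire = 10L,
                    offspring_per_dam = 2L, path = NA_character_),
    gene_drop = list(crossover_rate_per_cm = 0.01),
    chips = list(densities = integer(0), nested = FALSE),
    qtl = list(n_candidates = 9000L, maf_threshold = 0.30),
    traits = list(heritability = 0.25, gamma_shape = 0.4,
                  gamma_scale = 1.66, gamma_subset = 900L),
    split = list(training_generations = integer(0),
                 validation_generations = integer(0),
                 validation_size = 500L),
    output = list(seed = 1L, sequence = FALSE, phased = FALSE, vcf = FALSE)
  )
}

num1 <- function(val, key, i) {
  x <- suppressWarnings(as.numeric(val))
  if (is.na(x)) stop("line ", i, ": key '", key, "' needs a number, got '",
                     val, "'")
  x
}

yesno <- function(val, key, i) {
  if (!val %in% c("yes", "no", "true", "false"))
    stop("line ", i, ": key '", key, "' needs yes/no")
  val %in% c("yes", "true")
}

set_spec_key <- function(spec, section, key, val, i) {
  s <- spec[[section]]
  bad <- function() stop("line ", i, ": unknown key '", key,
                         "' in section [", section, "]")
  if (section == "demography" && key == "anchor") {
    parts <- as.numeric(strsplit(val, "\\s+")[[1]])
    if (length(parts) != 2 || anyNA(parts))
      stop("line ", i, ": anchor needs '<time> <Ne>'")
    s$anchors <- rbind(s$anchors, parts)
  } else if (section == "chips" && key == "chip") {
    parts <- strsplit(val, "\\s+")[[1]]
    if (length(parts) != 2)
      stop("line ", i, ": chip needs '<name> <density>'")
    d <- as.integer(num1(parts[2], key, i))
    s$densities[parts[1]] <- d
  } else if (section == "chips" && key == "nested") {
    s$nested <- yesno(val, key, i)
  } else if (section == "haplotypes" && key == "source") {
    if (!val %in% c("coalescent", "ms"))
      stop("line ", i, ": haplotype source must be coalescent|ms")
    s$source <- val
  } else if (section == "haplotypes" && key == "files") {
    s$files <- strsplit(val, "\\s+")[[1]]
  } else if (section == "pedigree" && key == "source") {
    if (!val %in% c("internal", "file"))
      stop("line ", i, ": pedigree source must be internal|file")
    s$source <- val
  } else if (section == "pedigree" && key == "path") {
    s$path <- val
  } else if (section == "split" &&
             key %in% c("training_generations", "validation_generations")) {
    s[[key]] <- as.integer(strsplit(val, "\\s+")[[1]])
  } else if (section == "output" && key %in% c("sequence", "phased", "vcf")) {
    s[[key]] <- yesno(val, key, i)
  } else if (key %in% names(s)) {
    x <- num1(val, key, i)
    s[[key]] <- if (is.integer(s[[key]])) as.integer(x) else x
  } else bad()
  spec[[section]] <- s
  spec
}

finalize_spec <- function(spec) {
  a <- spec$demography$anchors
  traj <- ne_trajectory(a[, 1], a[, 2], spec$demography$generation_interval)
  spec$demography$trajectory <- traj
  g <- spec$genome
  spec$genome$chromosomes <- lapply(seq_len(g$n_chromosomes), function(i)
    chromosome_spec(i, g$genetic_length_cm, g$physical_length_bp,
                    g$mutation_rate))
  if (spec$haplotypes$source == "ms" &&
      length(spec$haplotypes$files) != g$n_chromosomes)
    stop("need one ms file per chromosome (",
         length(spec$haplotypes$files), " given, ", g$n_chromosomes,
         " chromosomes)")
  if (spec$pedigree$source == "file" && is.na(spec$pedigree$path))
    stop("pedigree source 'file' needs a path")
  if (spec$haplotypes$n_haplotypes < 2)
    stop("need at least 2 base haplotypes")
  h2 <- spec$traits$heritability
  if (h2 <= 0 || h2 >= 1) stop("heritability must lie in (0, 1)")
  n_gen <- if (spec$pedigree$source == "internal")
    spec$pedigree$n_generations else NA_integer_
  if (!is.na(n_gen)) {
    gens <- c(spec$split$training_generations,
              spec$split$validation_generations)
    if (length(gens) && any(gens < 0 | gens >= n_gen))
      stop("split references generation(s) ",
           paste(gens[gens < 0 | gens >= n_gen], collapse = ", "),
           " outside 0..", n_gen - 1)
  }
  class(spec) <- "sim_spec"
  spec
}

#' Emit a specification in normalized form
#'
#' `parse_spec(write_spec(spec))` is a fixpoint: parsing the emitted text
#' reproduces the spec exactly.
#'
#' @param spec a `sim_spec`.
#' @param path optional file path; omit to get the lines.
#' @return invisibly, the character vector of lines.
#' @export
write_spec <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE, digits = 15)
  yn <- function(x) if (x) "yes" else "no"
  g <- spec$genome; d <- spec$demography; h <- spec$haplotypes
  p <- spec$pedigree; ch <- spec$chips; q <- spec$qtl; tr <- spec$traits
  sp <- spec$split; o <- spec$output
  lines <- c(
    "[genome]",
    paste("n_chromosomes =", g$n_chromosomes),
    paste("genetic_length_cm =", fmt(g$genetic_length_cm)),
    paste("physical_length_bp =", fmt(g$physical_length_bp)),
    paste("mutation_rate =", format(g$mutation_rate, digits = 15)),
    "",
    "[demography]",
    apply(d$anchors, 1, function(r) paste("anchor =", fmt(r[1]), fmt(r[2]))),
    paste("generation_interval =", fmt(d$generation_interval)),
    "",
    "[haplotypes]",
    paste("source =", h$source),
    paste("n_haplotypes =", h$n_haplotypes),
    if (length(h$files)) paste("files =", paste(h$files, collapse = " ")),
    "",
    "[pedigree]",
    paste("source =", p$source),
    if (p$source == "internal") c(
      paste("n_generations =", p$n_generations),
      paste("n_sires =", p$n_sires),
      paste("dams_per_sire =", p$dams_per_sire),
      paste("offspring_per_dam =", p$offspring_per_dam)
    ) else paste("path =", p$path),
    "",
    "[gene_drop]",
    paste("crossover_rate_per_cm =", fmt(spec$gene_drop$crossover_rate_per_cm)),
    "",
    "[chips]",
    if (length(ch$densities))
      paste("chip =", names(ch$densities), ch$densities),
    paste("nested =", yn(ch$nested)),
    "",
    "[qtl]",
    paste("n_candidates =", q$n_candidates),
    paste("maf_threshold =", fmt(q$maf_threshold)),
    "",
    "[traits]",
    paste("heritability =", fmt(tr$heritability)),
    paste("gamma_shape =", fmt(tr$gamma_shape)),
    paste("gamma_scale =", fmt(tr$gamma_scale)),
    paste("gamma_subset =", tr$gamma_subset),
    "",
    "[split]",
    if (length(sp$training_generations))
      paste("training_generations =",
            paste(sp$training_generations, collapse = " ")),
    if (length(sp$validation_generations))
      paste("validation_generations =",
            paste(sp$validation_generations, collapse = " ")),
    paste("validation_size =", sp$validation_size),
    "",
    "[output]",
    paste("seed =", o$seed),
    paste("sequence =", yn(o$sequence)),
    paste("phased =", yn(o$phased)),
    paste("vcf =", yn(o$vcf)))
  lines <- unlist(lines)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' @export
print.sim_spec <- function(x, ...) {
  cat("<sim_spec>",
      x$genome$n_chromosomes, "chromosomes x",
      format(x$genome$physical_length_bp, scientific = TRUE), "bp;",
      x$haplotypes$n_haplotypes, "base haplotypes;",
      if (x$pedigree$source == "internal")
        paste0(x$pedigree$n_generations, "-generation internal pedigree")
      else paste("pedigree from", x$pedigree$path),
      "\n")
  invisible(x)
}

#' The packaged livestock scenario specification
#'
#' @return a `sim_spec` parsed from the shipped scenario file.
#' @export
default_scenario_spec <- function() {
  parse_spec(system.file("extdata", "livestock_scenario.spec",
                         package = "coaldrop", mustWork = TRUE))
}

#' Scale a specification down for desk-size runs
#'
#' Multiplies each chromosome's physical length, its genetic length (the
#' model's cM-bp map is uniform, so the per-bp recombination rate is
#' preserved - scale 0.01 keeps the scenario's 1 cM/Mb) and every chip
#' density by `factor`.  Pedigree, QTL counts and trait settings are
#' kept, so the audit quantities are unchanged.  The seed is left alone.
#'
#' @param spec a `sim_spec`.
#' @param factor fraction in (0, 1].
#' @return the scaled `sim_spec`.
#' @export
scale_spec <- function(spec, factor) {
  stopifnot(inherits(spec, "sim_spec"), factor > 0, factor <= 1)
  spec$genome$physical_length_bp <-
    max(1, round(spec$genome$physical_length_bp * factor))
  spec$genome$genetic_length_cm <- spec$genome$genetic_length_cm * factor
  spec$chips$densities <-
    vapply(spec$chips$densities,
           function(d) max(1L, as.integer(round(d * factor))), 1L)
  g <- spec$genome
  spec$genome$chromosomes <- lapply(seq_len(g$n_chromosomes), function(i)
    chromosome_spec(i, g$genetic_length_cm, g$physical_length_bp,
                    g$mutation_rate))
  spec
}
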