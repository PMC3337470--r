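#' Count segregating sites
#'
#' @param panels a `haplotype_panel` or list of them.
#' @return list with `per_chromosome` (named integer vector) and `total`.
#' @export
count_segregating <- function(panels) {
  if (inherits(panels, "haplotype_panel")) panels <- list(panels)
  per <- vapply(panels, function(p) length(p$positions), 1L)
  names(per) <- vapply(panels, function(p)
    paste0("chr", p$chromosome$index), "")
  list(per_chromosome = per, total = sum(per))
}

#' Realized heritability
#'
#' Centered sample variance ratio `var(a) / var(y)` - the conventional
#' audit statistic, deliberately different from the uncentered
#' `a'a/(n-1)` used for residual scaling; the two are reported side by
#' side in run reports so the scaling convention stays visible.
#'
#' @param a breeding values.
#' @param y phenotypes.
#' @return the variance ratio.
#' @export
realized_heritability <- function(a, y) {
  if (length(a) < 2 || length(a) != length(y))
    stop("need matching vectors of length >= 2")
  if (stats::var(y) == 0) return(0)
  stats::var(a) / stats::var(y)
}

#' Crossover rate estimate
#'
#' Total crossovers divided by total cM simulated, from the gene-drop
#' crossover log (events per cM; multiply by 100 for a percentage).
#'
#' @param crossovers total crossover count.
#' @param cm_total total cM of meioses simulated.
#' @return events per cM.
#' @export
crossover_rate_estimate <- function(crossovers, cm_total) {
  if (cm_total <= 0) stop("empty meiosis log")
  crossovers / cm_total
}

#' Audit a finished run from its output files
#'
#' Recomputes the headline figures of a run directory from the files
#' alone (no in-memory state): individual and site counts, per-chip
#' sizes, QTL set sizes and maximum MAF, per-trait configured and
#' realized (base-generation) heritability, crossover rate, split sizes.
#'
#' @param out_dir a directory written by [run_simulation()].
#' @return a `run_report` list.
#' @export
run_report <- function(out_dir) {
  rd <- function(f) data.table::fread(file.path(out_dir, f), sep = "\t",
                                      data.table = FALSE)
  ped <- utils::read.table(file.path(out_dir, "pedigree.txt"),
                           col.names = c("id", "sire", "dam", "sex"))
  index <- rd("site_index.txt")
  audit <- rd("run_audit.txt")
  aud <- function(k) audit$value[audit$key == k]
  scaling <- rd("trait_scaling.txt")

  chips <- list.files(out_dir, "^chip_.*_map\\.txt$")
  chip_sizes <- vapply(chips, function(f) nrow(rd(f)), 1L)
  names(chip_sizes) <- sub("^chip_(.*)_map\\.txt$", "\\1", chips)

  qtl_files <- list.files(out_dir, "^qtl_(un)?restricted_map\\.txt$")
  qtl <- lapply(qtl_files, rd)
  names(qtl) <- sub("^qtl_(.*)_map\\.txt$", "\\1", qtl_files)

  traits <- list.files(out_dir, "^trait_.*\\.txt$")
  traits <- traits[traits != "trait_scaling.txt"]
  h2_real <- vapply(traits, function(f) {
    tv <- rd(f)
    base <- tv[tv$generation == 0, ]
    realized_heritability(base$breeding_value, base$phenotype)
  }, 1)
  names(h2_real) <- sub("^trait_(.*)\\.txt$", "\\1", traits)

  val_files <- list.files(out_dir, "^validation_.*_ids\\.txt$")
  structure(list(
    n_individuals = nrow(ped),
    n_segregating_sites = nrow(index),
    sites_per_chromosome = table(index$chr),
    chip_sizes = chip_sizes,
    qtl_sizes = vapply(qtl, nrow, 1L),
    qtl_max_maf = vapply(qtl, function(q) max(q$maf), 1),
    h2_configured = stats::setNames(scaling$h2_configured, scaling$trait),
    h2_realized_base = h2_real,
    sigma2_a = stats::setNames(scaling$sigma2_a, scaling$trait),
    sigma_e = stats::setNames(scaling$sigma_e, scaling$trait),
    crossover_rate = aud("crossovers") / aud("cm_simulated"),
    training_size = nrow(rd("training_ids.txt")),
    validation_sizes = vapply(val_files, function(f) nrow(rd(f)), 1L),
    master_seed = aud("master_seed")
  ), class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n",
      " individuals: ", x$n_individuals,
      "; segregating sites: ", x$n_segregating_sites, "\n",
      " chips: ", paste(names(x$chip_sizes), x$chip_sizes, collapse = ", "),
      "\n",
      " QTL sets: ", paste(names(x$qtl_sizes), x$qtl_sizes, collapse = ", "),
      " (max MAF ", paste(names(x$qtl_max_maf),
                          sprintf("%.3f", x$qtl_max_maf), collapse = ", "),
      ")\n",
      " configured h2: ", paste(sprintf("%.3f", x$h2_configured),
                                collapse = " "), "\n",
      " realized base h2: ", paste(sprintf("%.3f", x$h2_realized_base),
                                   collapse = " "), "\n",
      " crossovers per cM: ", sprintf("%.4f", x$crossover_rate), "\n",
      " split: ", x$training_size, " training; ",
      paste(x$validation_sizes, collapse = "+"), " validation\n", sep = "")
  invisible(x)
}
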