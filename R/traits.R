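#' Trait specification
#'
#' The four scenario traits share an additive model and differ in the
#' candidate-QTL source and effect distribution:
#' * `PolyUnres` — every unrestricted candidate QTL gets a N(0, 1)
#'   allele-substitution effect;
#' * `GammaUnres` — a random subset (scenario: 900 of 9000) gets
#'   `|effect| ~ Gamma(shape, scale)` with a fair sign flip;
#' * `PolyRes`, `GammaRes` — the same two constructions on the
#'   MAF-restricted candidate set.
#'
#' @param name trait name.
#' @param qtl_source `"unrestricted"` or `"restricted"`.
#' @param effect_distribution `"normal"` or `"gamma"`.
#' @param n_effect_loci for gamma traits, the subset size; `NULL` means
#'   all loci of the source set.
#' @param heritability target h-squared in (0, 1).
#' @param gamma_shape,gamma_scale gamma parameters (scenario: 0.4, 1.66).
#' @return an object of class `trait_spec`.
#' @export
trait_spec <- function(name, qtl_source = c("unrestricted", "restricted"),
                       effect_distribution = c("normal", "gamma"),
                       n_effect_loci = NULL, heritability = 0.25,
                       gamma_shape = 0.4, gamma_scale = 1.66) {
  qtl_source <- match.arg(qtl_source)
  effect_distribution <- match.arg(effect_distribution)
  stopifnot(heritability > 0, heritability < 1)
  structure(list(name = name, qtl_source = qtl_source,
                 effect_distribution = effect_distribution,
                 n_effect_loci = n_effect_loci,
                 heritability = heritability,
                 gamma_shape = gamma_shape, gamma_scale = gamma_scale),
            class = "trait_spec")
}

#' Sample allele-substitution effects
#'
#' Normal traits assign a N(0, 1) effect to every locus of the candidate
#' set.  Gamma traits first draw a uniform subset of `n_effect_loci`
#' loci, then `|effect| ~ Gamma(shape, scale)` with a 50% chance of
#' either sign; loci outside the subset carry no effect and are excluded
#' from the returned model.
#'
#' @param spec a [trait_spec()].
#' @param qtl a `qtl_set` (the matching candidate set).
#' @return list with `loci` (global site ids, sorted) and `effects`.
#' @export
sample_effects <- function(spec, qtl) {
  loci <- qtl$sites
  if (spec$effect_distribution == "gamma") {
    k <- spec$n_effect_loci %||% length(loci)
    if (k > length(loci))
      stop("effect-locus subset (", k, ") larger than candidate set (",
           length(loci), ")")
    loci <- sort(loci[sample.int(length(loci), k)])
    mag <- stats::rgamma(k, shape = spec$gamma_shape, scale = spec$gamma_scale)
    eff <- mag * sample(c(-1, 1), k, replace = TRUE)
  } else {
    if (!is.null(spec$n_effect_loci) &&
        spec$n_effect_loci != length(loci))
      stop("normal traits use every candidate locus")
    eff <- stats::rnorm(length(loci))
  }
  list(loci = loci, effects = eff)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Additive breeding values
#'
#' `a_i = sum_j dosage_ij * effect_j` - the plain additive genetic model,
#' dosage counting copies of the derived allele.
#'
#' @param dosage individuals x loci matrix of 0/1/2.
#' @param effects allele-substitution effects, one per column.
#' @return numeric vector of breeding values.
#' @export
breeding_values <- function(dosage, effects) {
  stopifnot(ncol(dosage) == length(effects))
  drop(dosage %*% effects)
}

#' Base-generation genetic variance
#'
#' The scaling denominator is the uncentered mean square `a'a / (n - 1)`
#' over base-generation breeding values - exactly the published formula,
#' not the centered sample variance.  Set `centered = TRUE` for the
#' conventional variance (reported side by side in run audits).
#'
#' @param a_base breeding values of the base generation (n >= 2).
#' @param centered subtract the mean first?
#' @return the variance estimate.
#' @export
base_genetic_variance <- function(a_base, centered = FALSE) {
  n <- length(a_base)
  if (n < 2) stop("need at least 2 base individuals")
  if (centered) a_base <- a_base - mean(a_base)
  sum(a_base^2) / (n - 1)
}

#' Residual standard deviation for a target heritability
#'
#' Solves `sigma_a^2 / (sigma_a^2 + sigma_e^2) = h2` for `sigma_e`, so
#' the configured heritability holds exactly by construction.
#'
#' @param sigma2_a base genetic variance (> 0).
#' @param h2 target heritability in (0, 1).
#' @return the residual standard deviation.
#' @export
residual_sd <- function(sigma2_a, h2) {
  stopifnot(h2 > 0, h2 < 1)
  if (sigma2_a <= 0)
    stop("no genetic variance to scale against (sigma2_a = ", sigma2_a, ")")
  sqrt(sigma2_a * (1 - h2) / h2)
}

#' Phenotypes from breeding values
#'
#' `y_i = a_i + e_i` with `e_i ~ N(0, sigma_e^2)`; one residual draw per
#' individual, the same `sigma_e` for every generation (the scaling is
#' done once, against the base generation).
#'
#' @param a breeding values.
#' @param sigma_e residual standard deviation (>= 0).
#' @return numeric vector of phenotypes.
#' @export
phenotypes <- function(a, sigma_e) {
  stopifnot(sigma_e >= 0)
  a + stats::rnorm(length(a), sd = sigma_e)
}

#' Build the four scenario traits
#'
#' Runs the whole trait stage in the documented fixed order (PolyUnres,
#' GammaUnres, PolyRes, GammaRes): effect sampling, breeding values for
#' every individual, residual scaling against the base generation via
#' [base_genetic_variance()] and [residual_sd()], then phenotypes.
#'
#' @param genomes a `gene_drop_result`.
#' @param index the run's `site_index`.
#' @param qtl_unres,qtl_res the unrestricted and restricted `qtl_set`s.
#' @param h2 target heritability (scenario: 0.25).
#' @param gamma_shape,gamma_scale gamma effect parameters (0.4, 1.66).
#' @param gamma_subset gamma effect-locus count (scenario: 900).
#' @param center_bv_for_scaling breeding values are defined as deviations
#'   from the population mean, so by default the base-generation mean is
#'   subtracted before `a'a/(n - 1)` is evaluated (making it the sample
#'   variance).  Set to `FALSE` to feed raw dosage-coded scores into the
#'   formula; the resulting variance inflation by the squared mean is
#'   reported either way as `sigma2_a_uncentered`.
#' @return a `trait_table`: list of four `trait_model`s (spec, loci,
#'   effects, `sigma2_a`, `sigma_e`) and a data.frame `values` with id,
#'   generation, and per-trait breeding value `bv_<trait>` and phenotype
#'   `phen_<trait>` columns.
#' @export
build_four_traits <- function(genomes, index, qtl_unres, qtl_res,
                              h2 = 0.25, gamma_shape = 0.4,
                              gamma_scale = 1.66, gamma_subset = 900,
                              center_bv_for_scaling = TRUE) {
  specs <- list(
    trait_spec("PolyUnres", "unrestricted", "normal", heritability = h2),
    trait_spec("GammaUnres", "unrestricted", "gamma", gamma_subset, h2,
               gamma_shape, gamma_scale),
    trait_spec("PolyRes", "restricted", "normal", heritability = h2),
    trait_spec("GammaRes", "restricted", "gamma", gamma_subset, h2,
               gamma_shape, gamma_scale))
  base_rows <- which(genomes$ped$generation == 0L)
  values <- data.frame(id = genomes$ped$id,
                       generation = genomes$ped$generation)
  models <- vector("list", length(specs))
  names(models) <- vapply(specs, function(s) s$name, "")
  for (s in specs) {
    qtl <- if (s$qtl_source == "unrestricted") qtl_unres else qtl_res
    eff <- sample_effects(s, qtl)
    dosage <- genotype_dosage(genomes, index, eff$loci)
    a <- breeding_values(dosage, eff$effects)
    if (center_bv_for_scaling) a <- a - mean(a[base_rows])
    sigma2_a <- base_genetic_variance(a[base_rows])
    sigma_e <- residual_sd(sigma2_a, s$heritability)
    y <- phenotypes(a, sigma_e)
    models[[s$name]] <- structure(
      list(spec = s, loci = eff$loci, effects = eff$effects,
           sigma2_a = sigma2_a,
           sigma2_a_uncentered = base_genetic_variance(
             breeding_values(dosage[base_rows, , drop = FALSE],
                             eff$effects)),
           sigma_e = sigma_e),
      class = "trait_model")
    values[[paste0("bv_", s$name)]] <- a
    values[[paste0("phen_", s$name)]] <- y
  }
  structure(list(models = models, values = values), class = "trait_table")
}

#' @export
print.trait_model <- function(x, ...) {
  cat(sprintf("<trait_model> %s: %d loci, sigma2_a = %.4g, sigma_e = %.4g, h2 = %.3g\n",
              x$spec$name, length(x$loci), x$sigma2_a, x$sigma_e,
              x$sigma2_a / (x$sigma2_a + x$sigma_e^2)))
  invisible(x)
}
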