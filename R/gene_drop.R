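#' Crossover model for gene dropping
#'
#' Crossovers during meiosis are Poisson along the genetic map with no
#' interference: the scenario default of `rate_per_cm = 0.01` realises 1
#' recombination event per 100 cM on average (Haldane's model).
#'
#' @param rate_per_cm probability of a crossover per cM (> 0).
#' @return an object of class `recomb_model`.
#' @export
recomb_model <- function(rate_per_cm = 0.01) {
  stopifnot(rate_per_cm > 0)
  structure(list(rate_per_cm = rate_per_cm), class = "recomb_model")
}

#' Draw crossover positions for one meiosis
#'
#' Count ~ Poisson(rate * length), positions i.i.d. uniform, returned
#' sorted (cM coordinates).
#'
#' @param genetic_length_cm map length in cM.
#' @param model a [recomb_model()].
#' @return sorted numeric vector of crossover positions in cM.
#' @export
draw_crossovers <- function(genetic_length_cm, model = recomb_model()) {
  stopifnot(genetic_length_cm >= 0)
  n <- stats::rpois(1, model$rate_per_cm * genetic_length_cm)
  sort(stats::runif(n, 0, genetic_length_cm))
}

#' Map a genetic position to a site index
#'
#' Uses the uniform cM-to-bp map (constant recombination rate along the
#' chromosome): the cM fraction of the map is converted to a bp
#' threshold, and the 0-based index of the first segregating site at or
#' beyond that threshold is returned.  A position mapping past the last
#' site returns `n_sites` (a no-op breakpoint, dropped by callers).
#'
#' @param pos_cm position(s) in cM, within `[0, genetic_length]`.
#' @param chrom a [chromosome_spec()].
#' @param panel_positions sorted bp coordinates of the segregating sites.
#' @return 0-based site indices.
#' @export
cm_to_site_index <- function(pos_cm, chrom, panel_positions) {
  stopifnot(all(pos_cm >= 0), all(pos_cm <= chrom$genetic_length_cm))
  bp <- pos_cm / chrom$genetic_length_cm * chrom$physical_length_bp
  # count of sites with coordinate strictly below the threshold
  k <- findInterval(bp, panel_positions)
  hit <- k >= 1 & panel_positions[pmax(k, 1L)] == bp
  as.integer(k - hit)
}

# collapse crossover site indices to net breakpoints: an even number of
# crossovers between two adjacent sites cancels
net_breakpoints <- function(idx, n_sites) {
  idx <- idx[idx > 0L & idx < n_sites]
  if (!length(idx)) return(integer(0))
  tab <- table(idx)
  sort(as.integer(names(tab)[tab %% 2L == 1L]))
}

#' Sample one base-generation gamete from a haplotype panel
#'
#' Base individuals of the pedigree stand at the most recent generation
#' of the ancestral population: each of their gametes is a mosaic of the
#' panel haplotypes, with crossovers drawn along the genetic map and each
#' inter-crossover segment copied from an independently, uniformly chosen
#' panel haplotype (with replacement).
#'
#' @param panel a `haplotype_panel`.
#' @param model a [recomb_model()].
#' @return a `packed_gamete` over the panel's sites.
#' @export
make_base_gamete <- function(panel, model = recomb_model()) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (panel$n < 1) stop("empty haplotype panel")
  chrom <- panel$chromosome
  S <- length(panel$positions)
  cuts <- cm_to_site_index(draw_crossovers(chrom$genetic_length_cm, model),
                           chrom, panel$positions)
  cuts <- unique(cuts[cuts > 0L & cuts < S])
  bounds <- c(0L, cuts, S)
  out <- integer(S)
  for (i in seq_len(length(bounds) - 1L)) {
    lo <- bounds[i] + 1L; hi <- bounds[i + 1L]
    if (hi >= lo) {
      h <- sample.int(panel$n, 1L)
      out[lo:hi] <- panel$alleles[h, lo:hi]
    }
  }
  pack_gamete(out)
}

#' Diploid genome container
#'
#' One paternal and one maternal [pack_gamete()] per chromosome.
#'
#' @param paternal,maternal lists of `packed_gamete`, one per chromosome.
#' @return an object of class `diploid_genome`.
#' @export
diploid_genome <- function(paternal, maternal) {
  stopifnot(length(paternal) == length(maternal))
  for (i in seq_along(paternal))
    stopifnot(paternal[[i]]$n_sites == maternal[[i]]$n_sites)
  structure(list(paternal = paternal, maternal = maternal),
            class = "diploid_genome")
}

#' Meiosis: produce one gamete from a diploid parent
#'
#' Draws crossovers on the genetic map, converts them to site indices
#' (crossovers falling between the same pair of adjacent sites cancel
#' pairwise) and builds the recombinant of the parent's two gametes with
#' a fair-coin starting strand, all on the packed representation.
#'
#' @param parent a [diploid_genome()].
#' @param chrom_index which chromosome.
#' @param chrom the matching [chromosome_spec()].
#' @param panel_positions bp positions of the chromosome's sites.
#' @param model a [recomb_model()].
#' @return a `packed_gamete`; attribute `"n_crossovers"` carries the raw
#'   crossover count for rate audits.
#' @export
meiosis <- function(parent, chrom_index, chrom, panel_positions,
                    model = recomb_model()) {
  pat <- parent$paternal[[chrom_index]]
  mat <- parent$maternal[[chrom_index]]
  xo <- draw_crossovers(chrom$genetic_length_cm, model)
  idx <- cm_to_site_index(xo, chrom, panel_positions)
  bp <- net_breakpoints(idx, pat$n_sites)
  g <- recombine(pat, mat, bp, start_with = sample(0:1, 1L))
  attr(g, "n_crossovers") <- length(xo)
  g
}

# fast internal meiosis on raw gametes (no wrapper objects); returns
# list(words, n_xo)
meiosis_raw <- function(pat_words, mat_words, n_sites, chrom,
                        panel_positions, model) {
  n_xo <- stats::rpois(1, model$rate_per_cm * chrom$genetic_length_cm)
  if (n_xo == 0L) {
    return(list(words = if (stats::runif(1) < 0.5) pat_words else mat_words,
                n_xo = 0L))
  }
  xo <- stats::runif(n_xo, 0, chrom$genetic_length_cm)
  idx <- cm_to_site_index(xo, chrom, panel_positions)
  bp <- net_breakpoints(idx, n_sites)
  res <- .cpp_recombine(pat_words, mat_words, n_sites, bp,
                        if (stats::runif(1) < 0.5) 0L else 1L)
  list(words = res$words, n_xo = n_xo)
}

#' Drop haplotypes through a pedigree
#'
#' Base individuals receive two independent [make_base_gamete()] draws
#' per chromosome; every other individual receives one [meiosis()] gamete
#' from its sire (paternal) and one from its dam (maternal), processed in
#' pedigree order.  No mutation occurs during the drop, so any allele
#' absent from the base generation stays absent.
#'
#' @param ped a `pedigree`.
#' @param panels list of `haplotype_panel`, one per chromosome.
#' @param model a [recomb_model()].
#' @param crossover_log if `TRUE`, record the total crossover count and
#'   cM simulated (attributes `"crossovers"`, `"cm_total"`).
#' @return a `gene_drop_result`: per chromosome, lists `pat` and `mat` of
#'   packed gametes indexed by pedigree row, plus `n_sites` and the
#'   chromosome specs.
#' @export
drop_genomes <- function(ped, panels, model = recomb_model(),
                         crossover_log = FALSE) {
  viol <- validate_pedigree(ped)
  if (length(viol)) stop("invalid pedigree: ", viol[1])
  n_ind <- nrow(ped)
  n_chr <- length(panels)
  row_of <- match(ped$sire, ped$id)  # NA for base
  drow <- match(ped$dam, ped$id)
  xo_total <- 0; cm_total <- 0

  chrs <- vector("list", n_chr)
  for (c_i in seq_len(n_chr)) {
    panel <- panels[[c_i]]
    chrom <- panel$chromosome
    S <- length(panel$positions)
    pat <- vector("list", n_ind)
    mat <- vector("list", n_ind)
    pos <- panel$positions
    for (i in seq_len(n_ind)) {
      if (ped$sire[i] == 0L) {
        pat[[i]] <- make_base_gamete(panel, model)
        mat[[i]] <- make_base_gamete(panel, model)
      } else {
        si <- row_of[i]; di <- drow[i]
        gp <- meiosis_raw(pat[[si]]$words, mat[[si]]$words, S, chrom, pos,
                          model)
        gm <- meiosis_raw(pat[[di]]$words, mat[[di]]$words, S, chrom, pos,
                          model)
        if (crossover_log) {
          xo_total <- xo_total + gp$n_xo + gm$n_xo
          cm_total <- cm_total + 2 * chrom$genetic_length_cm
        }
        pat[[i]] <- new_packed_gamete(S, gp$words)
        mat[[i]] <- new_packed_gamete(S, gm$words)
      }
    }
    chrs[[c_i]] <- list(pat = pat, mat = mat, n_sites = S, chromosome = chrom,
                        positions = panel$positions)
  }
  out <- structure(list(chromosomes = chrs, ped = ped), class = "gene_drop_result")
  if (crossover_log) {
    attr(out, "crossovers") <- xo_total
    attr(out, "cm_total") <- cm_total
  }
  out
}

#' @export
print.gene_drop_result <- function(x, ...) {
  cat(sprintf("<gene_drop_result> %d individuals x %d chromosomes (%s sites)\n",
              nrow(x$ped), length(x$chromosomes),
              paste(vapply(x$chromosomes, function(ch) ch$n_sites, 1L),
                    collapse = "+")))
  invisible(x)
}

#' Extract one individual's diploid genome
#'
#' @param genomes a `gene_drop_result`.
#' @param id pedigree id.
#' @return a [diploid_genome()].
#' @export
individual_genome <- function(genomes, id) {
  i <- match(id, genomes$ped$id)
  if (is.na(i)) stop("id ", id, " not in pedigree")
  diploid_genome(lapply(genomes$chromosomes, function(ch) ch$pat[[i]]),
                 lapply(genomes$chromosomes, function(ch) ch$mat[[i]]))
}
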