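#' Minor allele frequency
#'
#' @param freq allele frequency (or vector) in `[0, 1]`.
#' @return `min(freq, 1 - freq)`, elementwise.
#' @export
maf <- function(freq) {
  stopifnot(all(freq >= 0 & freq <= 1))
  pmin(freq, 1 - freq)
}

#' Build the genome-wide site index
#'
#' Gathers every segregating site across chromosomes into one table with
#' a global site id, and computes each site's derived-allele frequency in
#' the base generation of the pedigree (the cohort downstream variance
#' scaling actually sees), not in the ancestral panel.
#'
#' @param genomes a `gene_drop_result` from [drop_genomes()].
#' @return a `site_index` data.frame with columns `site` (global id,
#'   1-based), `chr`, `local` (0-based index within the chromosome),
#'   `pos` (bp) and `freq` (derived-allele frequency among base-generation
#'   gametes).
#' @export
build_site_index <- function(genomes) {
  base_rows <- which(genomes$ped$generation == 0L)
  n_gam <- 2L * length(base_rows)
  tabs <- lapply(seq_along(genomes$chromosomes), function(c_i) {
    ch <- genomes$chromosomes[[c_i]]
    counts <- .cpp_bit_counts(lapply(c(ch$pat[base_rows], ch$mat[base_rows]),
                                     function(g) g$words),
                              ch$n_sites)
    data.frame(chr = ch$chromosome$index,
               local = seq_len(ch$n_sites) - 1L,
               pos = ch$positions,
               freq = counts / n_gam)
  })
  out <- do.call(rbind, tabs)
  out <- cbind(site = seq_len(nrow(out)), out)
  class(out) <- c("site_index", "data.frame")
  out
}

#' Sample SNP chips
#'
#' Each chip is an independent uniform sample without replacement of the
#' requested number of sites from all segregating sites, allocated across
#' chromosomes proportionally to their site counts (largest-remainder
#' rounding), and returned sorted by position.  With `nested = TRUE`
#' each chip after the first is drawn from the previous (denser chips
#' must then come first).
#'
#' @param index a `site_index`.
#' @param densities named integer vector: chip name -> total SNP count.
#' @param nested sample lower-density chips inside the densest one.
#' @return named list of integer vectors of global site ids.
#' @export
sample_chips <- function(index, densities, nested = FALSE) {
  total <- nrow(index)
  if (any(densities > total))
    stop("chip density ", max(densities), " exceeds the ", total,
         " available segregating sites")
  if (is.null(names(densities)))
    names(densities) <- paste0("chip", seq_along(densities))
  chr_ids <- split(index$site, index$chr)
  chr_sizes <- lengths(chr_ids)
  pick <- function(pool_ids, pool_sizes, n) {
    # largest-remainder allocation across chromosomes
    quota <- n * pool_sizes / sum(pool_sizes)
    base <- floor(quota)
    rem <- n - sum(base)
    if (rem > 0) {
      extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1
    }
    unlist(lapply(seq_along(pool_ids), function(i) {
      ids <- pool_ids[[i]]
      ids[sample.int(length(ids), base[i])]
    }), use.names = FALSE)
  }
  out <- vector("list", length(densities))
  names(out) <- names(densities)
  pool <- chr_ids
  for (k in seq_along(densities)) {
    ids <- sort(pick(pool, lengths(pool), densities[k]))
    out[[k]] <- ids
    if (nested) {
      if (k < length(densities) && densities[k + 1] > densities[k])
        stop("nested chips require non-increasing densities")
      pool <- split(ids, index$chr[match(ids, index$site)])
    }
  }
  out
}

#' Sample candidate QTL
#'
#' Uniform sample without replacement from the eligible sites: all sites
#' when `maf_threshold` is `NULL`, otherwise the sites segregating in the
#' base generation whose base-generation minor allele frequency does not
#' exceed the threshold (inclusive rule, `MAF <= threshold`).
#'
#' @param index a `site_index`.
#' @param n number of candidate QTL.
#' @param maf_threshold maximum minor allele frequency, or `NULL` for no
#'   restriction.
#' @return a `qtl_set`: list with `sites` (sorted global ids) and
#'   `maf_threshold`.
#' @export
sample_candidate_qtl <- function(index, n, maf_threshold = NULL) {
  eligible <- if (is.null(maf_threshold)) {
    index$site
  } else {
    stopifnot(maf_threshold > 0, maf_threshold <= 0.5)
    index$site[index$freq > 0 & index$freq < 1 &
                 maf(index$freq) <= maf_threshold]
  }
  if (length(eligible) < n)
    stop("only ", length(eligible), " eligible sites for ", n,
         " candidate QTL")
  structure(list(sites = sort(eligible[sample.int(length(eligible), n)]),
                 maf_threshold = maf_threshold),
            class = "qtl_set")
}

#' @export
print.qtl_set <- function(x, ...) {
  cat(sprintf("<qtl_set> %d sites%s\n", length(x$sites),
              if (is.null(x$maf_threshold)) ""
              else sprintf(", MAF <= %.2f", x$maf_threshold)))
  invisible(x)
}

#' Genotype dosage matrix
#'
#' Counts of the derived allele (0/1/2) per individual at the requested
#' global sites, extracted from the packed gametes.
#'
#' @param genomes a `gene_drop_result`.
#' @param index the `site_index` of the run.
#' @param sites global site ids.
#' @param rows pedigree rows to include (default all).
#' @return integer matrix, individuals x sites; rownames are pedigree ids,
#'   colnames the global site ids.
#' @export
genotype_dosage <- function(genomes, index, sites, rows = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(genomes$ped))
  pos <- match(sites, index$site)
  if (anyNA(pos)) stop("unknown global site id")
  chr <- index$chr[pos]
  local <- index$local[pos]
  out <- matrix(0L, nrow = length(rows), ncol = length(sites),
                dimnames = list(genomes$ped$id[rows], sites))
  chr_index <- match(chr, vapply(genomes$chromosomes,
                                 function(ch) ch$chromosome$index, 1L))
  for (c_i in unique(chr_index)) {
    ch <- genomes$chromosomes[[c_i]]
    cols <- which(chr_index == c_i)
    loc <- local[cols]
    for (r in seq_along(rows)) {
      i <- rows[r]
      out[r, cols] <- .cpp_dosage(ch$pat[[i]]$words, ch$mat[[i]]$words,
                                  ch$n_sites, loc)
    }
  }
  out
}
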