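#' Chromosome description
#'
#' The default values are the livestock scenario chromosome: 100 cM over
#' roughly 1e8 bp with a per-site mutation rate of 2.5e-8 per generation.
#' The per-bp recombination rate (Morgans/bp) is derived from the genetic
#' and physical lengths and assumed uniform along the chromosome.
#'
#' @param index 1-based chromosome number.
#' @param genetic_length_cm genetic map length in centimorgans.
#' @param physical_length_bp physical length in base pairs.
#' @param mutation_rate per-site, per-generation mutation rate.
#' @return an object of class `chromosome_spec`.
#' @export
chromosome_spec <- function(index = 1L, genetic_length_cm = 100,
                            physical_length_bp = 1e8,
                            mutation_rate = 2.5e-8) {
  stopifnot(index >= 1, genetic_length_cm > 0, physical_length_bp > 0,
            mutation_rate >= 0)
  structure(list(
    index = as.integer(index),
    genetic_length_cm = genetic_length_cm,
    physical_length_bp = physical_length_bp,
    mutation_rate = mutation_rate,
    recomb_per_bp = (genetic_length_cm / 100) / physical_length_bp
  ), class = "chromosome_spec")
}

#' @export
print.chromosome_spec <- function(x, ...) {
  cat(sprintf("<chromosome_spec> chr%d: %.4g cM / %.4g bp, mu = %.3g\n",
              x$index, x$genetic_length_cm, x$physical_length_bp,
              x$mutation_rate))
  invisible(x)
}

new_haplotype_panel <- function(chrom, positions, alleles) {
  stopifnot(inherits(chrom, "chromosome_spec"))
  positions <- as.numeric(positions)
  if (length(positions) != ncol(alleles))
    stop("positions and allele columns disagree")
  if (length(positions) > 0) {
    if (any(diff(positions) <= 0))
      stop("site positions must be strictly increasing")
    if (positions[1] < 1 || positions[length(positions)] > chrom$physical_length_bp)
      stop("site positions outside [1, physical_length]")
  }
  structure(list(chromosome = chrom, positions = positions,
                 alleles = alleles, n = nrow(alleles)),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("<haplotype_panel> %d haplotypes x %d segregating sites (chr%d)\n",
              x$n, length(x$positions), x$chromosome$index))
  invisible(x)
}

# ---- internal genealogy machinery -----------------------------------------
#
# Trees over n leaves are stored as parent/time vectors of length 2n - 1
# (leaves 1..n at time 0).  The sequential simulator keeps one marginal
# tree and never materialises the ancestral recombination graph.

# Sample the genealogy at the left end of the chromosome: a plain
# time-inhomogeneous coalescent on n lineages.
sample_first_tree <- function(n, traj) {
  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes)
  time <- numeric(n_nodes)
  active <- seq_len(n)
  t <- 0
  nxt <- n + 1L
  for (k in seq(n, 2L)) {
    t <- invert_inverse_ne(traj, t, 2 * stats::rexp(1) / (k * (k - 1) / 2))
    pick <- sort(sample.int(k, 2L))
    parent[active[pick]] <- nxt
    time[nxt] <- t
    # O(1) active-set update: merged pair replaced by the new node, the
    # freed slot refilled from position k (only slots 1..k-1 stay live)
    active[pick[1L]] <- nxt
    active[pick[2L]] <- active[k]
    nxt <- nxt + 1L
  }
  list(parent = parent, time = time)
}

tree_branch_lengths <- function(tree) {
  bl <- numeric(length(tree$parent))
  has_par <- tree$parent != 0L
  bl[has_par] <- tree$time[tree$parent[has_par]] - tree$time[has_par]
  bl
}

# Leaves below each of the given nodes; kids index built from the parent
# vector on demand.
descendant_leaves <- function(tree, nodes, n_leaves) {
  n_nodes <- length(tree$parent)
  # children in contiguous blocks: ord groups node ids by parent
  ord <- order(tree$parent)
  first <- integer(n_nodes)   # start of each parent's block in ord
  cnt <- tabulate(tree$parent, nbins = n_nodes)
  first[] <- cumsum(c(sum(tree$parent == 0L), cnt[-n_nodes])) + 1L
  stack <- integer(n_nodes)
  out <- integer(n_leaves)
  lapply(nodes, function(v) {
    sp <- 1L; stack[1L] <- v; no <- 0L
    while (sp > 0L) {
      x <- stack[sp]; sp <- sp - 1L
      if (x <= n_leaves) {
        no <- no + 1L; out[no] <- x
      } else {
        f <- first[x]
        for (j in seq_len(cnt[x])) {
          sp <- sp + 1L; stack[sp] <- ord[f + j - 1L]
        }
      }
    }
    sort(out[seq_len(no)])
  })
}

# Re-coalescence time of a lineage floating up from t_r against the k(t)
# branches of `tree` crossing time t, with hazard k(t) / (2 Ne(t)).
# When smc_prime is FALSE (plain SMC) the pruned stretch of branch `b`
# between t_r and its old parent is removed from both the rate and the
# candidate set.
float_and_coalesce <- function(tree, traj, t_r, b, smc_prime, n_leaves) {
  int_times <- sort(tree$time[(n_leaves + 1L):length(tree$time)])
  prune_top <- if (smc_prime) -Inf else tree$time[tree$parent[b]]
  idx <- findInterval(t_r, int_times)
  bounds <- if (idx < length(int_times))
    int_times[(idx + 1L):length(int_times)] else numeric(0)
  # old-tree lineage count just above t_r, decremented at each node time
  # crossed; prune_top is itself a node time, so epochs need no extra cut
  # for the plain-SMC variant - its count is just one lower below it
  k <- max(n_leaves - idx, 1L)
  E <- stats::rexp(1)
  t <- t_r
  F_t <- inv_ne_cum(traj, t)
  for (tb in bounds) {
    kk <- if (!smc_prime && t < prune_top) max(k - 1L, 1L) else k
    F_tb <- inv_ne_cum(traj, tb)
    h <- F_tb - F_t
    if (kk * h / 2 >= E) return(invert_inverse_ne(traj, t, 2 * E / kk))
    E <- E - kk * h / 2
    t <- tb
    F_t <- F_tb
    k <- max(k - 1L, 1L)
  }
  kk <- if (!smc_prime && t < prune_top) max(k - 1L, 1L) else k
  invert_inverse_ne(traj, t, 2 * E / kk)
}

# Branches of the tree crossing time t (root's open-ended lineage counts
# when t is above the root).
branches_crossing <- function(tree, t) {
  has_par <- tree$parent != 0L
  cross <- which(has_par & tree$time <= t & tree$time[pmax(tree$parent, 1L)] > t)
  root <- which(!has_par)
  if (t >= tree$time[root]) cross <- c(cross, root)
  cross
}

# One subtree-prune-regraft update at a recombination breakpoint.
# Returns the updated tree, or NULL for an invisible event.
spr_update <- function(tree, traj, smc_prime, n_leaves) {
  bl <- tree_branch_lengths(tree)
  total <- sum(bl)
  x <- stats::runif(1, 0, total)
  cum <- cumsum(bl)
  b <- findInterval(x, cum, left.open = TRUE) + 1L
  t_r <- tree$time[b] + (x - (if (b > 1L) cum[b - 1L] else 0))

  t_c <- float_and_coalesce(tree, traj, t_r, b, smc_prime, n_leaves)
  cross <- branches_crossing(tree, t_c)
  if (!smc_prime) cross <- setdiff(cross, b)
  target <- cross[sample.int(length(cross), 1L)]
  if (target == b) return(NULL)   # re-coalesced with its own old lineage

  p <- tree$parent[b]
  g <- tree$parent[p]
  sib <- setdiff(which(tree$parent == p), b)
  tree$parent[sib] <- g
  if (target == p) target <- sib
  tree$parent[p] <- tree$parent[target]
  tree$parent[target] <- p
  tree$parent[b] <- p
  tree$time[p] <- t_c
  tree
}

#' Simulate a haplotype panel under the Markovian coalescent
#'
#' Generates `n_haplotypes` phased haplotypes for one chromosome.  The
#' genealogy at the left end of the chromosome is drawn from the
#' time-inhomogeneous coalescent defined by `traj`; the simulator then
#' walks left to right, placing recombination breakpoints at exponential
#' distances driven by the current tree's total branch length and
#' updating the marginal genealogy by subtree-prune-regraft at each one
#' (the SMC' approximation: the detached lineage may re-coalesce with any
#' branch of the old tree, including its own, which yields an invisible
#' event).  Mutations fall on each marginal tree at rate `mutation_rate`
#' per site per generation over the non-recombining segment; each
#' mutation creates one segregating site at a uniformly drawn integer
#' coordinate (collisions redrawn), derived allele coded 1.
#'
#' @param n_haplotypes number of haplotypes to sample (>= 2).
#' @param chrom a [chromosome_spec()].
#' @param traj an [ne_trajectory()].
#' @param smc_prime if `FALSE`, use the plain SMC variant in which the
#'   detached lineage may not re-coalesce with its former branch (for
#'   testing the approximation; default `TRUE`).
#' @param tree_log if `TRUE`, attach attribute `"tree_log"`: one row per
#'   non-recombining segment with its bp range, marginal tree height and
#'   total branch length (used by validation tests and QC reports).
#' @return a `haplotype_panel`: positions (bp) plus an
#'   `n_haplotypes x n_sites` 0/1 matrix; every column is segregating.
#' @export
simulate_panel <- function(n_haplotypes, chrom, traj, smc_prime = TRUE,
                           tree_log = FALSE) {
  stopifnot(inherits(chrom, "chromosome_spec"), inherits(traj, "ne_trajectory"))
  n <- as.integer(n_haplotypes)
  if (n < 2L) stop("need at least 2 haplotypes")
  L <- chrom$physical_length_bp
  if (L <= 0) stop("physical length must be positive")
  mu <- chrom$mutation_rate
  r_bp <- chrom$recomb_per_bp

  tree <- sample_first_tree(n, traj)
  pos <- 0
  site_pos <- numeric(0)
  site_leaves <- list()
  used <- new.env(hash = TRUE, parent = emptyenv())
  tlog <- if (tree_log) list() else NULL

  while (pos < L) {
    bl <- tree_branch_lengths(tree)
    total <- sum(bl)
    d <- if (r_bp > 0) stats::rexp(1, rate = total * r_bp) else Inf
    seg_end <- min(pos + d, L)
    seg_len <- seg_end - pos

    if (mu > 0 && seg_len > 0) {
      n_mut <- stats::rpois(1, mu * seg_len * total)
      if (n_mut > 0) {
        branches <- sample.int(length(bl), n_mut, replace = TRUE, prob = bl)
        coords <- numeric(n_mut)
        ok <- logical(n_mut)
        for (j in seq_len(n_mut)) {
          # redraw on coordinate collision (finite-sites guard); after
          # repeated collisions scan forward for a free coordinate and
          # drop the mutation if the segment is saturated
          cc <- NA_real_
          for (try in 1:100) {
            cand <- min(L, floor(stats::runif(1, pos, seg_end)) + 1)
            if (is.null(used[[as.character(cand)]])) { cc <- cand; break }
          }
          if (is.na(cc)) {
            cand <- min(L, floor(pos) + 1)
            top <- min(L, ceiling(seg_end))
            while (cand <= top && !is.null(used[[as.character(cand)]]))
              cand <- cand + 1
            if (cand <= top) cc <- cand
          }
          if (!is.na(cc)) {
            assign(as.character(cc), TRUE, envir = used)
            coords[j] <- cc
            ok[j] <- TRUE
          }
        }
        site_pos <- c(site_pos, coords[ok])
        site_leaves <- c(site_leaves,
                         descendant_leaves(tree, branches[ok], n))
      }
    }

    if (tree_log)
      tlog[[length(tlog) + 1L]] <-
        c(start = pos, end = seg_end, height = max(tree$time),
          total_length = total)
    if (seg_end >= L) break
    pos <- seg_end
    upd <- spr_update(tree, traj, smc_prime, n)
    if (!is.null(upd)) tree <- upd
  }

  S <- length(site_pos)
  ord <- order(site_pos)
  alleles <- matrix(0L, nrow = n, ncol = S)
  for (j in seq_len(S)) alleles[site_leaves[[ord[j]]], j] <- 1L
  panel <- new_haplotype_panel(chrom, site_pos[ord], alleles)
  if (tree_log)
    attr(panel, "tree_log") <- as.data.frame(do.call(rbind, tlog))
  panel
}

#' Pairwise time to most recent common ancestor
#'
#' Utility used in validation: simulates the coalescence time of a sample
#' of two lineages under the trajectory (no sequence is generated).
#'
#' @inheritParams simulate_panel
#' @return a single time in generations.
#' @keywords internal
sample_pair_tmrca <- function(traj) {
  draw_waiting_time(traj, 0, 1)
}
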