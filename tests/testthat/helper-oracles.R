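# Independent oracles used to check the implementation. These are kept
# deliberately naive (site-by-site loops, full-ARG event simulation,
# numerical quadrature) and never share code with the package internals.

# site-by-site mosaic of two allele vectors; breakpoints are 0-based site
# indices with half-open semantics (site >= k switches source)
naive_mosaic <- function(a_bits, b_bits, breakpoints, start_with) {
  n <- length(a_bits)
  src <- if (start_with == 0) list(a_bits, b_bits) else list(b_bits, a_bits)
  out <- integer(n)
  cur <- 1L
  prev <- 0L
  for (k in c(breakpoints, n)) {
    if (k > prev) out[(prev + 1L):k] <- src[[cur]][(prev + 1L):k]
    cur <- 3L - cur
    prev <- k
  }
  out
}

# hazard CDF of the first coalescence time for `pair_rate` pairs under a
# trajectory, by adaptive quadrature of 1/Ne (independent of the closed
# form in the package)
waiting_time_cdf_quad <- function(traj, t_grid, pair_rate) {
  H <- vapply(t_grid, function(tt) {
    if (tt == 0) return(0)
    stats::integrate(function(s) 1 / ne_at(traj, s), 0, tt,
                     rel.tol = 1e-9, subdivisions = 500L)$value
  }, 1)
  1 - exp(-pair_rate / 2 * H)
}

# --- brute-force Hudson ancestral recombination graph (constant Ne) ----
#
# Lineages carry explicit ancestral-segment lists on [0, 1]; coalescence
# rate 1/(2 Ne) per pair, recombination rate r_total * hull length per
# lineage.  Tracks the marginal genealogy height at given positions.
# Returns the MRCA time per tracked position.
hudson_arg_heights <- function(n, ne, r_total, positions = c(0, 1)) {
  lineages <- lapply(seq_len(n), function(i)
    list(segs = matrix(c(0, 1), 1), carry = rep(TRUE, length(positions))))
  counts <- rep(n, length(positions))
  heights <- rep(NA_real_, length(positions))
  t <- 0
  while (any(is.na(heights))) {
    k <- length(lineages)
    hulls <- vapply(lineages, function(l)
      max(l$segs[, 2]) - min(l$segs[, 1]), 1)
    rate_rec <- r_total * sum(hulls)
    rate_coal <- k * (k - 1) / 2 / (2 * ne)
    t <- t + stats::rexp(1, rate_rec + rate_coal)
    if (stats::runif(1) < rate_rec / (rate_rec + rate_coal)) {
      i <- sample.int(k, 1, prob = hulls)
      l <- lineages[[i]]
      u <- stats::runif(1, min(l$segs[, 1]), max(l$segs[, 2]))
      left <- right <- matrix(numeric(0), 0, 2)
      for (s in seq_len(nrow(l$segs))) {
        lo <- l$segs[s, 1]; hi <- l$segs[s, 2]
        if (hi <= u) left <- rbind(left, c(lo, hi))
        else if (lo >= u) right <- rbind(right, c(lo, hi))
        else { left <- rbind(left, c(lo, u)); right <- rbind(right, c(u, hi)) }
      }
      if (nrow(left) == 0 || nrow(right) == 0) next  # breakpoint outside material
      lineages[[i]] <- list(segs = left, carry = l$carry & positions < u)
      lineages[[k + 1L]] <- list(segs = right, carry = l$carry & positions >= u)
    } else {
      pick <- sample.int(k, 2)
      l1 <- lineages[[pick[1]]]; l2 <- lineages[[pick[2]]]
      both <- l1$carry & l2$carry
      counts[both] <- counts[both] - 1L
      done <- both & counts == 1L & is.na(heights)
      heights[done] <- t
      merged <- list(segs = rbind(l1$segs, l2$segs),
                     carry = (l1$carry | l2$carry) & counts > 1L)
      lineages[[pick[1]]] <- merged
      lineages[[pick[2]]] <- NULL
      # drop lineages with no carried positions and no chance to matter
      keep <- vapply(lineages, function(l) any(l$carry), TRUE)
      if (!all(keep) && sum(keep) >= 1) lineages <- lineages[keep]
    }
  }
  heights
}

# marginal tree height at the right end of a chromosome from the SMC'
# walker (no mutations needed)
smc_right_end_height <- function(n, chrom, traj, smc_prime = TRUE) {
  p <- simulate_panel(n, chrom, traj, smc_prime = smc_prime,
                      tree_log = TRUE)
  log <- attr(p, "tree_log")
  log$height[nrow(log)]
}
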