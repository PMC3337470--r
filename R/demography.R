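#' Piecewise-linear effective population size history
#'
#' The coalescent stage needs Ne as a function of time before the present.
#' The history is given as anchors `(time, Ne)` with linear interpolation
#' between anchors and constant extrapolation beyond the last one.  The
#' shipped livestock scenario uses Ne = 100 now, 1256 at 1000, 4350 at
#' 10,000 and 43,500 at 100,000 generations ago, a trajectory estimated
#' for the Holstein cattle population.
#'
#' Times are interpreted as generations.  If a history is given in years,
#' `generation_interval` divides the times (years per generation); the
#' default of 1 treats years and generations as interchangeable.
#'
#' @param time numeric vector of times before present, strictly
#'   increasing, starting at 0.
#' @param ne effective population sizes (> 0), one per time.
#' @param generation_interval years per generation used to rescale `time`.
#' @return an object of class `ne_trajectory`.
#' @examples
#' traj <- ne_trajectory(c(0, 1000, 10000, 100000), c(100, 1256, 4350, 43500))
#' ne_at(traj, c(0, 500, 1000, 2e5))
#' @export
ne_trajectory <- function(time, ne, generation_interval = 1) {
  time <- as.numeric(time) / generation_interval
  ne <- as.numeric(ne)
  if (length(time) != length(ne) || length(time) < 1L)
    stop("need matching, non-empty time and ne vectors")
  if (time[1] != 0)
    stop("the first anchor must be at time 0")
  if (any(diff(time) <= 0))
    stop("anchor times must be strictly increasing")
  if (any(ne <= 0) || any(!is.finite(ne)))
    stop("all Ne values must be positive and finite")
  K <- length(time)
  slope <- if (K > 1) diff(ne) / diff(time) else numeric(0)
  # cumulative integral of 1/Ne from 0 to each anchor, in closed form
  cum <- numeric(K)
  for (i in seq_len(K - 1)) {
    cum[i + 1] <- cum[i] + if (abs(slope[i]) < 1e-12 * ne[i]) {
      (time[i + 1] - time[i]) / ne[i]
    } else {
      log(ne[i + 1] / ne[i]) / slope[i]
    }
  }
  structure(list(time = time, ne = ne, slope = slope, cum_inv = cum),
            class = "ne_trajectory")
}

# F(t) = integral of 1/Ne from 0 to t, scalar t >= 0 (fast internal path)
inv_ne_cum <- function(traj, t) {
  time <- traj$time; ne <- traj$ne
  K <- length(time)
  i <- findInterval(t, time)
  if (i >= K) return(traj$cum_inv[K] + (t - time[K]) / ne[K])
  m <- traj$slope[i]
  traj$cum_inv[i] + if (abs(m) < 1e-12 * ne[i]) {
    (t - time[i]) / ne[i]
  } else {
    log((ne[i] + m * (t - time[i])) / ne[i]) / m
  }
}

#' @export
print.ne_trajectory <- function(x, ...) {
  cat("<ne_trajectory> ", length(x$time), " anchors\n", sep = "")
  print(data.frame(time = x$time, ne = x$ne), row.names = FALSE)
  invisible(x)
}

#' Evaluate Ne(t)
#'
#' Linear interpolation between anchors; constant beyond the last anchor.
#'
#' @param traj an [ne_trajectory()].
#' @param t non-negative time(s) before present, in generations.
#' @return Ne at each `t`.
#' @export
ne_at <- function(traj, t) {
  stopifnot(inherits(traj, "ne_trajectory"))
  if (any(t < 0)) stop("time before present must be >= 0")
  time <- traj$time; ne <- traj$ne
  K <- length(time)
  i <- pmin(findInterval(t, time), K - 1L)
  if (K == 1L) return(rep(ne, length(t)))
  pmin(pmax(ne[i] + traj$slope[i] * (t - time[i]),
            pmin(ne[i], ne[i + 1L])),
       pmax(ne[i], ne[i + 1L])) -> out
  out[t >= time[K]] <- ne[K]
  out
}

#' Integral of 1/Ne(t)
#'
#' Computes `int_{t0}^{t1} dt / Ne(t)` in closed form: on a linear segment
#' with slope m it is `log(Ne(t1)/Ne(t0)) / m`, on a flat segment
#' `(t1 - t0) / Ne`.  This is the quantity whose inverse gives
#' coalescence waiting times under a time-varying population size.
#'
#' @param traj an [ne_trajectory()].
#' @param t0,t1 interval bounds, `0 <= t0 <= t1`.
#' @return the (dimensionless) integral.
#' @export
integrated_inverse_ne <- function(traj, t0, t1) {
  stopifnot(inherits(traj, "ne_trajectory"))
  if (t0 < 0 || t1 < t0) stop("need 0 <= t0 <= t1")
  if (t1 == t0) return(0)
  inv_ne_cum(traj, t1) - inv_ne_cum(traj, t0)
}

# Smallest t1 >= t0 with integrated_inverse_ne(traj, t0, t1) == target.
# Always solvable because Ne is constant (finite) past the last anchor.
invert_inverse_ne <- function(traj, t0, target) {
  stopifnot(target >= 0)
  if (target == 0) return(t0)
  G <- inv_ne_cum(traj, t0) + target
  time <- traj$time; ne <- traj$ne; cum <- traj$cum_inv
  K <- length(time)
  if (G >= cum[K]) return(time[K] + (G - cum[K]) * ne[K])
  i <- findInterval(G, cum)
  rem <- G - cum[i]
  m <- traj$slope[i]
  if (abs(m) < 1e-12 * ne[i]) return(time[i] + rem * ne[i])
  # rem = log(ne1 / ne_i) / m  =>  ne1 = ne_i * exp(m * rem)
  time[i] + ne[i] * (exp(m * rem) - 1) / m
}

#' Draw a coalescence waiting time under Ne(t)
#'
#' The hazard of coalescence at time t for `pair_rate` unordered lineage
#' pairs is `pair_rate / (2 Ne(t))` (diploid Wright-Fisher scaling).  A
#' standard-exponential deviate is inverted through the integrated hazard
#' segment by segment, so the draw is exact for the piecewise-linear
#' trajectory - no time discretisation.
#'
#' @param traj an [ne_trajectory()].
#' @param t_now current time before present (generations).
#' @param pair_rate number of unordered lineage pairs, `k (k - 1) / 2`
#'   (more generally any positive rate multiplier of `1 / (2 Ne)`).
#' @param u optional standard-exponential deviate; by default drawn from
#'   R's random number stream.
#' @return the waiting time `dt` (generations) until the event.
#' @export
draw_waiting_time <- function(traj, t_now, pair_rate, u = stats::rexp(1)) {
  stopifnot(inherits(traj, "ne_trajectory"))
  if (t_now < 0) stop("t_now must be >= 0")
  if (pair_rate <= 0) stop("pair_rate must be positive")
  # integral of hazard = (pair_rate / 2) * integral of 1/Ne; match to u
  t_event <- invert_inverse_ne(traj, t_now, 2 * u / pair_rate)
  t_event - t_now
}
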