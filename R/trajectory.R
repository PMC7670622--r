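#' Epoch boundary times
#'
#' The boundary between the interval with \eqn{i} ancestral lineages and the
#' one with \eqn{i - 1} sits at
#' \deqn{T_i = \sum_{k=i}^{n} \frac{\theta_k}{k(k-1)}, \quad i = 2, \dots, n,}
#' in units of expected mutations per site (divide by \eqn{\mu} for
#' generations).  \eqn{T_2} is the expected time to the sample's most recent
#' common ancestor; the sequence is non-increasing in \eqn{i} and strictly
#' decreasing when every \eqn{\theta_k > 0}.
#'
#' @param theta An [epoch_theta()].
#' @return Numeric vector \code{T[i]} for \code{i = 2..n} (so \code{T[1]} is
#'   \eqn{T_2}, the oldest boundary).
#' @export
epoch_times <- function(theta) {
  stopifnot(inherits(theta, "epoch_theta"))
  k <- 2:theta$n
  rev(cumsum(rev(theta$theta / (k * (k - 1)))))
}

#' Effective-size step function from fitted thetas
#'
#' Converts a theta vector into the piecewise-constant trajectory
#' \eqn{N_e(T) = \theta_i / (4\mu)} on \eqn{(T_i, T_{i-1}]}, with the most
#' recent interval \eqn{(0, T_n]} taking \eqn{\theta_n / (4\mu)}.  Times are
#' in expected mutations per site until rescaled with [scale_to_years()].
#'
#' @param theta An [epoch_theta()].
#' @param mu Mutation rate per site per generation.
#' @param b Optional subsample index carried along for bookkeeping.
#' @return An object of class \code{"ne_trajectory"}: \code{boundaries}
#'   (\eqn{T_2, \dots, T_n}, decreasing), \code{sizes} (diploid \eqn{N_e}
#'   aligned to \code{boundaries}), \code{units} and \code{b}.
#' @export
ne_trajectory <- function(theta, mu, b = NA_integer_) {
  stopifnot(inherits(theta, "epoch_theta"))
  if (length(mu) != 1L || !is.finite(mu) || mu <= 0) stop("'mu' must be > 0")
  structure(list(boundaries = epoch_times(theta),
                 sizes = theta$theta / (4 * mu),
                 units = "mutations", mu = mu, b = b),
            class = "ne_trajectory")
}

#' Rescale trajectory times to years
#'
#' Times in expected mutations per site become
#' \code{time / mu * year_per_generation} years; sizes are unchanged.
#'
#' @param traj An \code{ne_trajectory} in mutation units.
#' @param mu Mutation rate per site per generation.
#' @param year_per_generation Generation time in years (1 gives time in
#'   generations).
#' @return The trajectory with \code{units = "years"}.
#' @export
scale_to_years <- function(traj, mu, year_per_generation = 24) {
  stopifnot(inherits(traj, "ne_trajectory"))
  if (mu <= 0 || year_per_generation <= 0)
    stop("'mu' and 'year_per_generation' must be > 0")
  if (traj$units != "mutations")
    stop("trajectory has already been rescaled")
  traj$boundaries <- traj$boundaries / mu * year_per_generation
  traj$units <- "years"
  traj
}

#' Evaluate a step trajectory at given times
#'
#' Exact step-function evaluation: a time strictly inside interval
#' \eqn{(T_i, T_{i-1}]} returns that interval's \eqn{N_e}; times older than
#' \eqn{T_2} extend the oldest size (the flat ancient tail), times in
#' \eqn{(0, T_n]} take the most recent size.
#'
#' @param traj An \code{ne_trajectory}.
#' @param times Positive times in the trajectory's units.
#' @return Numeric vector of \eqn{N_e} values.
#' @export
evaluate_trajectory <- function(traj, times) {
  stopifnot(inherits(traj, "ne_trajectory"))
  if (any(times <= 0)) stop("trajectory is undefined at times <= 0")
  knots <- rev(traj$boundaries)        # ascending: T_n .. T_2
  vals <- rev(traj$sizes)              # aligned:   N_n .. N_2
  # the k-lineage interval is (T_{k+1}, T_k] and carries N_k, so a time in
  # (knots[j], knots[j+1]] takes vals[j + 1]
  idx <- findInterval(times, knots, left.open = TRUE) + 1L
  vals[pmin(idx, length(vals))]
}

#' Summarize a trajectory ensemble
#'
#' Evaluates every replicate's step function on a common log-spaced time
#' grid and reports the pointwise median (the final estimate) together with
#' percentile bands.  By default the grid runs over 300 log-spaced points
#' from the 2.5th percentile of the replicates' most recent boundaries
#' \eqn{T_n^b} to the 97.5th percentile of their oldest boundaries
#' \eqn{T_2^b} — the span where most replicates actually resolve history.
#'
#' @param trajs List of \code{ne_trajectory} objects in common units.
#' @param probs Band percentiles; the defaults give 95\% (2.5/97.5) and
#'   75\% (12.5/87.5) intervals.
#' @param grid_points Number of grid points.
#' @param time_grid Optional explicit time grid (overrides the automatic
#'   span).
#' @return A data frame with columns \code{time}, \code{Ne_median} and one
#'   \code{Ne_<pct>} column per requested percentile; attribute
#'   \code{units}.
#' @export
summarize_ensemble <- function(trajs, probs = c(0.025, 0.125, 0.875, 0.975),
                               grid_points = 300L, time_grid = NULL) {
  if (!length(trajs)) stop("empty trajectory ensemble")
  stopifnot(all(vapply(trajs, inherits, TRUE, "ne_trajectory")))
  units <- unique(vapply(trajs, `[[`, "", "units"))
  if (length(units) != 1L) stop("trajectories have mixed time units")
  if (is.null(time_grid)) {
    t_lo <- quantile(vapply(trajs, function(t) min(t$boundaries), 0), 0.025,
                     names = FALSE, type = 7)
    t_hi <- quantile(vapply(trajs, function(t) max(t$boundaries), 0), 0.975,
                     names = FALSE, type = 7)
    if (t_hi <= t_lo) t_hi <- t_lo * (1 + 1e-6)
    time_grid <- exp(seq(log(t_lo), log(t_hi), length.out = grid_points))
  }
  M <- vapply(trajs, evaluate_trajectory, numeric(length(time_grid)),
              times = time_grid)
  M <- matrix(M, nrow = length(time_grid))
  out <- data.frame(time = time_grid,
                    Ne_median = apply(M, 1L, median))
  for (p in sort(probs))
    out[[sprintf("Ne_%s", format(100 * p, trim = TRUE))]] <-
      apply(M, 1L, quantile, probs = p, type = 7, names = FALSE)
  attr(out, "units") <- units
  out
}
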