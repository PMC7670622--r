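#' Piecewise demographic model
#'
#' A single panmictic population whose diploid size is piecewise constant
#' (optionally with exponential segments) over time.  Internally the model
#' is stored in coalescent-simulator ("ms") scaling: times in units of
#' \eqn{4 N_0} generations, sizes relative to a reference \eqn{N_0}, growth
#' rates per \eqn{4 N_0} generations (positive = population growing forward
#' in time, hence shrinking into the past).
#'
#' @param time Segment start times in generations before present, strictly
#'   increasing from 0.
#' @param size Diploid population size at each segment start.
#' @param growth Per-segment exponential growth rate (per \eqn{4 N_0}
#'   generations, ms convention); default 0 (piecewise constant).
#' @param N0 Reference diploid size; defaults to the present-day size.
#' @return An object of class \code{"demographic_model"} with fields
#'   \code{N0} and \code{segments} (data frame \code{t}, \code{x},
#'   \code{g} in ms scaling).
#' @seealso [ms_model()] for building a model directly from ms-style
#'   \code{-eN}/\code{-eG} events, [model_presets()] for ready-made models.
#' @export
demographic_model <- function(time, size, growth = 0, N0 = size[1L]) {
  if (length(time) != length(size)) stop("'time' and 'size' lengths differ")
  if (time[1L] != 0) stop("first segment must start at time 0")
  if (is.unsorted(time, strictly = TRUE)) stop("'time' must be strictly increasing")
  if (any(size <= 0) || N0 <= 0) stop("population sizes must be > 0")
  growth <- rep_len(growth, length(time))
  seg <- data.frame(t = time / (4 * N0), x = size / N0, g = growth)
  validate_segments(seg)
  structure(list(N0 = N0, segments = seg), class = "demographic_model")
}

#' Demographic model from ms-style events
#'
#' Builds a [demographic_model()] from a list of size-change events in the
#' conventions of Hudson's \code{ms}: \code{eN(t, x)} sets the relative size
#' to \code{x} at scaled time \code{t} (and growth to 0); \code{eG(t, g)}
#' sets the growth rate to \code{g} at time \code{t}, the size at \code{t}
#' being carried over continuously from the preceding trajectory.  Times in
#' \eqn{4 N_0} generations, most recent first.
#'
#' @param N0 Reference diploid size.
#' @param events List of \code{list("eN", t, x)} / \code{list("eG", t, g)}
#'   entries, sorted by time.
#' @return A \code{demographic_model}.
#' @export
ms_model <- function(N0, events) {
  seg <- data.frame(t = 0, x = 1, g = 0)
  times <- vapply(events, function(e) as.numeric(e[[2L]]), 0)
  if (is.unsorted(times)) stop("events must be sorted by time")
  for (e in events) {
    type <- e[[1L]]
    t <- as.numeric(e[[2L]])
    v <- as.numeric(e[[3L]])
    if (type == "eN") {
      new <- data.frame(t = t, x = v, g = 0)
    } else if (type == "eG") {
      new <- data.frame(t = t, x = size_at(seg, t), g = v)
    } else stop("unknown event type: ", type)
    seg <- if (t == 0) new else rbind(seg[seg$t < t, ], new)
  }
  validate_segments(seg)
  structure(list(N0 = N0, segments = seg), class = "demographic_model")
}

validate_segments <- function(seg) {
  if (any(seg$x <= 0)) stop("relative sizes must be > 0")
  if (seg$g[nrow(seg)] < 0)
    stop("final (oldest) segment cannot have negative growth: the coalescent ",
         "rate would vanish into the past and lineages might never coalesce")
  invisible(seg)
}

# relative size x(tau) at scaled time tau
size_at <- function(seg, tau) {
  j <- findInterval(tau, seg$t)
  j <- pmax(j, 1L)
  seg$x[j] * exp(-seg$g[j] * (tau - seg$t[j]))
}

#' Population size at a time point
#'
#' Diploid effective size of a demographic model at given times — the
#' "truth curve" against which inferred trajectories are compared in
#' simulation studies.
#'
#' @param model A \code{demographic_model}.
#' @param time_years Times in years before present.
#' @param year_per_generation Generation time in years.
#' @return Diploid sizes at \code{time_years}.
#' @export
population_size <- function(model, time_years, year_per_generation = 24) {
  stopifnot(inherits(model, "demographic_model"))
  tau <- time_years / (year_per_generation * 4 * model$N0)
  model$N0 * size_at(model$segments, tau)
}

#' @export
print.demographic_model <- function(x, ...) {
  cat(sprintf("Demographic model: N0 = %.1f diploids, %d segment(s)\n",
              x$N0, nrow(x$segments)))
  print(x$segments, row.names = FALSE)
  invisible(x)
}

#' Demographic model presets
#'
#' Ready-made single-population models used throughout the package's
#' simulation studies, decoded from their standard coalescent-simulator
#' command lines (mutation rate \eqn{1.2\times 10^{-8}} per bp per
#' generation):
#' \describe{
#'   \item{zigzag}{alternating 10-fold expansions and contractions
#'     (theta = 7156 per 10 Mb, so \eqn{N_0 \approx 14908});
#'     \code{-eN 0 5 -eG 0.000582262 1318.18 -eG 0.00232905 -329.546
#'     -eG 0.00931619 82.3865 -eG 0.0372648 -20.5966 -eG 0.149059 5.14916
#'     -eN 0.596236 0.5}}
#'   \item{sharpCEU}{European-like history with an out-of-Africa bottleneck
#'     (theta = 7.156e-4 per bp)}
#'   \item{sharpYRI}{African-like history (theta = 1e-3 per bp)}
#'   \item{constant}{flat N = 10000 diploids}
#' }
#'
#' @param mu Mutation rate used to decode theta into \eqn{N_0}.
#' @return Named list of \code{demographic_model} objects.
#' @export
model_presets <- function(mu = 1.2e-8) {
  zig_N0 <- 7156.0 / (4 * mu * 1e7)          # theta printed per 10 Mb
  ceu_N0 <- 0.0007156 / (4 * mu)             # theta per bp
  yri_N0 <- 0.001 / (4 * mu)
  list(
    zigzag = ms_model(zig_N0, list(
      list("eN", 0, 5),
      list("eG", 0.000582262, 1318.18),
      list("eG", 0.00232905, -329.546),
      list("eG", 0.00931619, 82.3865),
      list("eG", 0.0372648, -20.5966),
      list("eG", 0.149059, 5.14916),
      list("eN", 0.596236, 0.5))),
    sharpCEU = ms_model(ceu_N0, list(
      list("eN", 0.0, 10.8300726663),
      list("eN", 0.00116452394261, 1.08300726663),
      list("eN", 0.0174678591392, 0.216601453326),
      list("eN", 0.0465809577045, 1.08300726663),
      list("eN", 0.0873392956959, 3.24902179989),
      list("eN", 0.232904788522, 1.08300726663))),
    sharpYRI = ms_model(yri_N0, list(
      list("eN", 0.0, 8.25),
      list("eN", 0.0025, 0.825),
      list("eN", 0.0416666666667, 2.475),
      list("eN", 0.166666666667, 0.825))),
    constant = demographic_model(time = 0, size = 10000)
  )
}

# Draw the scaled waiting time to the next coalescence for k lineages
# starting at scaled time tau0, by inverting the integrated hazard across
# segments.  Rate at tau is k(k-1) / x(tau) per unit of 4*N0 generations.
draw_coal_interval <- function(seg, tau0, k) {
  u <- rexp(1L)
  R <- k * (k - 1)
  ns <- nrow(seg)
  j <- max(findInterval(tau0, seg$t), 1L)
  from <- tau0
  repeat {
    tj <- seg$t[j]; xj <- seg$x[j]; gj <- seg$g[j]
    end <- if (j < ns) seg$t[j + 1L] else Inf
    if (gj == 0) {
      H <- R * (end - from) / xj
      if (u <= H) return(from + u * xj / R - tau0)
    } else {
      e_from <- exp(gj * (from - tj))
      e_end <- if (is.finite(end)) exp(gj * (end - tj)) else
        (if (gj > 0) Inf else 0)
      H <- R * (e_end - e_from) / (xj * gj)   # positive for either sign of gj
      if (u <= H) {
        tau <- tj + log(e_from + gj * xj * u / R) / gj
        return(tau - tau0)
      }
    }
    u <- u - H
    j <- j + 1L
    from <- end
    if (j > ns) stop("coalescent rate vanished before all lineages merged")
  }
}

# One coalescent tree: total branch length per descendant-count class,
# in scaled time units (4*N0 generations)
sim_tree_classes <- function(seg, n) {
  desc <- rep(1L, n)
  tau <- 0
  lens <- numeric(n - 1L)
  for (k in n:2) {
    w <- draw_coal_interval(seg, tau, k)
    tb <- tabulate(desc, nbins = n - 1L)
    lens <- lens + tb * w
    ij <- sample.int(k, 2L)
    desc[ij[1L]] <- desc[ij[1L]] + desc[ij[2L]]
    desc <- desc[-ij[2L]]
    tau <- tau + w
  }
  lens
}

#' Simulate an SFS under the coalescent
#'
#' Simulates independent coalescent genealogies (no recombination) under a
#' piecewise-constant / exponential-growth demography via time-rescaled
#' exponential waiting times and uniform pair merging.  The \code{L} sites
#' are divided into \code{blocks} independent locus blocks, one tree per
#' block; mutations fall on each branch as Poisson(branch length in
#' generations x mu x block sites) and are assigned to the branch's
#' descendant-count class (infinite-sites: every mutation is a new site).
#' Uses the current RNG state.
#'
#' @param model A \code{demographic_model}.
#' @param n Sample size (haploids), >= 2.
#' @param L Total number of assayed sites.
#' @param mu Mutation rate per site per generation.
#' @param blocks Number of independent genealogies the sites are spread
#'   over (more blocks = less linkage-like variance between classes).
#' @return An unfolded \code{sfs} with \code{L} total sites.
#' @export
simulate_coalescent_sfs <- function(model, n, L, mu, blocks = 1000L) {
  stopifnot(inherits(model, "demographic_model"))
  n <- as.integer(n)
  if (n < 2L) stop("'n' must be >= 2")
  if (L < 1) stop("'L' must be >= 1")
  if (mu <= 0) stop("'mu' must be > 0")
  blocks <- max(1L, min(as.integer(blocks), L))
  sites <- rep(floor(L / blocks), blocks)
  sites[seq_len(L - sum(sites))] <- sites[seq_len(L - sum(sites))] + 1
  xi <- numeric(n - 1L)
  gen_scale <- 4 * model$N0 * mu
  for (blk in seq_len(blocks)) {
    lens <- sim_tree_classes(model$segments, n)
    xi <- xi + rpois(n - 1L, lens * gen_scale * sites[blk])
  }
  eta0 <- L - sum(xi)
  if (eta0 < 0)
    stop("more mutations than sites: infinite-sites approximation broke down ",
         "(theta per site too large)")
  sfs(c(eta0, xi), n = n, folded = FALSE)
}

#' Simulate an SFS from the inference model itself
#'
#' Draws per-class site counts as a single multinomial of size \code{L}
#' over the class probabilities implied by a theta vector.  This is
#' exactly the data-generating process assumed by the composite
#' likelihood, so parameter-recovery tests using it are unconfounded by
#' linkage or model misspecification.
#'
#' @param theta An [epoch_theta()].
#' @param L Total number of sites (>= 1).
#' @param folded Generate a folded spectrum?
#' @return An \code{sfs}.
#' @export
simulate_skyline_sfs <- function(theta, L, folded = FALSE) {
  stopifnot(inherits(theta, "epoch_theta"))
  if (L < 1) stop("'L' must be >= 1 (l_n must be positive)")
  shape <- sfs(c(L, numeric(if (folded) theta$n %/% 2L else theta$n - 1L)),
               n = theta$n, folded = folded)
  p <- class_probabilities(theta, shape)
  counts <- drop(rmultinom(1L, size = L, prob = p$p_full))
  sfs(counts, n = theta$n, folded = folded)
}

#' Monte-Carlo oracle for the expected SFS
#'
#' Brute-force check of the closed-form expected spectrum: simulates
#' skyline coalescent trees in which the interval with \eqn{k} lineages is
#' exponential with mean \eqn{\theta_k / (k(k-1))} (in expected mutations
#' per site), accumulates branch length per descendant-count class, and
#' returns per-class means with Monte-Carlo standard errors.  The mean for
#' class \eqn{i} estimates \eqn{E[\xi_i]} from [expected_sfs()].
#'
#' @param theta An [epoch_theta()].
#' @param trees Number of independent trees (>= 1).
#' @return List with \code{mean} and \code{se}, each of length
#'   \code{n - 1}.
#' @export
oracle_expected_sfs <- function(theta, trees = 1e5) {
  stopifnot(inherits(theta, "epoch_theta"))
  trees <- as.integer(trees)
  if (trees < 1L) stop("'trees' must be >= 1")
  n <- theta$n
  k <- 2:n
  # all interval lengths drawn up front (mutation units)
  W <- matrix(rexp(trees * (n - 1L)), trees, n - 1L)
  W <- sweep(W, 2L, theta$theta / (k * (k - 1)), `*`)
  tot <- matrix(0, trees, n - 1L)
  for (tr in seq_len(trees)) {
    desc <- rep(1L, n)
    acc <- numeric(n - 1L)
    for (kk in n:2) {
      acc <- acc + tabulate(desc, nbins = n - 1L) * W[tr, kk - 1L]
      ij <- sample.int(kk, 2L)
      desc[ij[1L]] <- desc[ij[1L]] + desc[ij[2L]]
      desc <- desc[-ij[2L]]
    }
    tot[tr, ] <- acc
  }
  list(mean = colMeans(tot), se = apply(tot, 2L, sd) / sqrt(trees))
}
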