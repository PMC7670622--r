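#' Per-interval scaled mutation rates
#'
#' The multi-epoch skyline model assigns one scaled mutation rate
#' \eqn{\theta_k = 4 N_k \mu} to the coalescent interval during which the
#' sample has \eqn{k} ancestral lineages, \eqn{k = 2, \dots, n}.  Breakpoints
#' are positions from \eqn{\{1, \dots, n-2\}}: breakpoint \eqn{j} allows
#' \eqn{\theta_{j+1}} and \eqn{\theta_{j+2}} to differ; any two consecutive
#' thetas not separated by a breakpoint are constrained equal (they belong to
#' the same group), so the model has \code{length(breakpoints) + 1} free
#' parameters.
#'
#' @param n Sample size (haploids).
#' @param theta Either the full vector \eqn{(\theta_2, \dots, \theta_n)}
#'   (length \code{n - 1}, constant within groups), or one value per group
#'   (length \code{length(breakpoints) + 1}), expanded across groups.
#' @param breakpoints Sorted positions in \eqn{1..n-2}.
#' @return An object of class \code{"epoch_theta"} with fields \code{n},
#'   \code{theta} (full length \code{n - 1}) and \code{breakpoints}.
#' @export
epoch_theta <- function(n, theta, breakpoints = integer()) {
  n <- as.integer(n)
  if (n < 2L) stop("'n' must be >= 2")
  breakpoints <- sort(unique(as.integer(breakpoints)))
  if (length(breakpoints) && (min(breakpoints) < 1L || max(breakpoints) > n - 2L))
    stop(sprintf("breakpoints must lie in 1..%d", n - 2L))
  g <- theta_groups(n, breakpoints)
  theta <- as.numeric(theta)
  if (length(theta) == max(g)) {
    theta <- theta[g]
  } else if (length(theta) != n - 1L) {
    stop(sprintf("'theta' must have length %d (full) or %d (per group)",
                 n - 1L, max(g)))
  }
  if (any(!is.finite(theta)) || any(theta <= 0))
    stop("all theta values must be finite and > 0")
  # consecutive thetas within a group must be equal
  same <- g[-1L] == g[-length(g)]
  if (any(same & abs(theta[-1L] - theta[-length(theta)]) >
            1e-9 * pmax(theta[-1L], theta[-length(theta)])))
    stop("theta values differ within a group not separated by a breakpoint")
  structure(list(n = n, theta = theta, breakpoints = breakpoints),
            class = "epoch_theta")
}

# group index (1-based, oldest-first over entries theta_2..theta_n) implied
# by a breakpoint set: breakpoint j splits entries j and j+1
theta_groups <- function(n, breakpoints) {
  cumsum(c(1L, as.integer(seq_len(n - 2L) %in% breakpoints)))
}

#' @export
print.epoch_theta <- function(x, ...) {
  g <- theta_groups(x$n, x$breakpoints)
  cat(sprintf("epoch_theta: n = %d, %d group(s), %d breakpoint(s)\n",
              x$n, max(g), length(x$breakpoints)))
  cat("  theta range:", format(range(x$theta), digits = 4), "\n")
  invisible(x)
}

# cache of expected-SFS design matrices, keyed by (n, folded)
.sfs_matrix_cache <- new.env(parent = emptyenv())

# Design matrix A with E[xi] = A %*% theta: A[i, k-1] =
# C(n-i-1, k-2) / ((k-1) * C(n-1, k-1)), rows i = 1..n-1 (or folded rows).
# Computed in log space so it is stable for n in the thousands.
sfs_matrix <- function(n, folded = FALSE) {
  key <- paste0(n, if (folded) "F" else "U")
  if (!is.null(.sfs_matrix_cache[[key]])) return(.sfs_matrix_cache[[key]])
  i <- seq_len(n - 1L)
  k <- 2:n
  logA <- outer(i, k, function(ii, kk)
    lchoose(n - ii - 1, kk - 2) - log(kk - 1) - lchoose(n - 1, kk - 1))
  A <- exp(logA)
  if (folded) {
    h <- n %/% 2L
    Af <- matrix(0, h, n - 1L)
    for (r in seq_len(h)) {
      Af[r, ] <- A[r, ] + if (n - r != r) A[n - r, ] else 0
    }
    A <- Af
  }
  .sfs_matrix_cache[[key]] <- A
  A
}

#' Expected site frequency spectrum under the skyline model
#'
#' Per-site expected counts of each polymorphic class under the multi-epoch
#' coalescent:
#' \deqn{E[\xi_i] = \sum_{k=2}^{n} \frac{\theta_k}{k-1}
#'   \frac{{n-i-1 \choose k-2}}{{n-1 \choose k-1}}, \quad i = 1, \dots, n-1,}
#' the expectation of mutations on branches with \eqn{i} descendants when the
#' population size is constant within each coalescent interval.  With all
#' \eqn{\theta_k = \theta} this reduces to the classical \eqn{\theta / i}.
#' Folded expectations collapse classes \eqn{i} and \eqn{n-i}.
#'
#' @param theta An [epoch_theta()].
#' @param folded Return folded class expectations?
#' @return Numeric vector of expected per-site counts for polymorphic
#'   classes (\code{1..n-1} unfolded, \code{1..floor(n/2)} folded).
#' @export
expected_sfs <- function(theta, folded = FALSE) {
  stopifnot(inherits(theta, "epoch_theta"))
  drop(sfs_matrix(theta$n, folded) %*% theta$theta)
}

#' Model class probabilities for an SFS shape
#'
#' Converts the expected per-site polymorphic counts into a probability
#' vector over the SFS classes of a given spectrum: \eqn{p_i = E[class_i]}
#' for polymorphic classes and \eqn{p_0 = 1 - \sum_{i \ge 1} E[class_i]}
#' (the monomorphic class absorbs the remainder; this requires the per-site
#' polymorphism probability to be < 1).  When the spectrum carries a mask,
#' the vector is restricted to the unmasked classes and renormalized.
#'
#' @param theta An [epoch_theta()].
#' @param shape An \code{sfs} supplying n, folded flag and mask (counts are
#'   not used).
#' @return List with \code{p} (probabilities over unmasked classes, summing
#'   to 1), \code{classes} (their class indices, starting at 0) and
#'   \code{p_full} (the unmasked construction over all classes).
#' @export
class_probabilities <- function(theta, shape) {
  stopifnot(inherits(theta, "epoch_theta"), inherits(shape, "sfs"))
  if (theta$n != shape$n) stop("sample size mismatch between theta and sfs")
  E <- expected_sfs(theta, folded = shape$folded)
  s <- sum(E)
  if (s >= 1)
    stop("per-site polymorphic probability >= 1; theta too large for the ",
         "per-site multinomial interpretation")
  p_full <- c(1 - s, E)
  classes <- 0:n_poly_classes(shape)
  keep <- !(classes %in% shape$masked_bins)
  p <- p_full[keep]
  p <- p / sum(p)
  list(p = p, classes = classes[keep], p_full = p_full)
}

#' Composite log-likelihood of an SFS
#'
#' Multinomial composite likelihood treating sites as independent:
#' \deqn{L_n = l_n! \prod_i p_i^{\eta_i} / \eta_i!}
#' with the product over all unmasked classes (including monomorphic) and
#' \eqn{l_n} the total of the unmasked counts.  Returned on the log scale,
#' multinomial constant included, so values are comparable across runs.
#' Linkage between sites is ignored, as in all SFS composite-likelihood
#' methods.
#'
#' @param x An \code{sfs}.
#' @param p Either the list returned by [class_probabilities()] (its mask
#'   must match \code{x}) or a bare probability vector over the unmasked
#'   classes of \code{x}.
#' @return Log composite likelihood; \code{-Inf} if some observed class has
#'   zero probability.
#' @export
composite_loglik <- function(x, p) {
  stopifnot(inherits(x, "sfs"))
  classes <- 0:n_poly_classes(x)
  keep <- !(classes %in% x$masked_bins)
  if (is.list(p)) {
    if (!identical(p$classes, classes[keep]))
      stop("class probabilities do not match the spectrum's shape/mask")
    p <- p$p
  }
  if (length(p) != sum(keep))
    stop(sprintf("expected %d probabilities for this spectrum, got %d",
                 sum(keep), length(p)))
  eta <- x$counts[keep]
  l <- sum(eta)
  obs <- eta > 0
  if (any(obs & p <= 0)) return(-Inf)
  lgamma(l + 1) - sum(lgamma(eta + 1)) + sum(eta[obs] * log(p[obs]))
}

#' Saturated composite log-likelihood
#'
#' The multinomial maximum over unconstrained probabilities,
#' \eqn{p_i = \eta_i / l_n}; an upper bound for any model-constrained fit of
#' the same spectrum.
#'
#' @param x An \code{sfs}.
#' @return Log likelihood at the empirical class frequencies.
#' @export
saturated_loglik <- function(x) {
  classes <- 0:n_poly_classes(x)
  keep <- !(classes %in% x$masked_bins)
  eta <- x$counts[keep]
  composite_loglik(x, eta / sum(eta))
}
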