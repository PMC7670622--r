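#' Site frequency spectrum
#'
#' Container for an observed site frequency spectrum (SFS): per-class site
#' counts \eqn{\eta_i} for a sample of \code{n} haploid sequences, including
#' the monomorphic class \eqn{\eta_0}.  An unfolded spectrum indexes classes
#' by derived-allele count \eqn{i = 0, \dots, n-1}; a folded spectrum by
#' minor-allele count \eqn{i = 0, \dots, \lfloor n/2 \rfloor}.  The total
#' number of assayed sites \eqn{l_n} is the sum of all counts.
#'
#' If an unfolded vector of length \code{n + 1} is supplied, the fixed-derived
#' class \code{n} is indistinguishable from monomorphic without an outgroup
#' and is absorbed into class 0.
#'
#' @param counts Non-negative integer vector of per-class site counts,
#'   starting at class 0 (monomorphic).
#' @param n Sample size in haploid sequences (>= 2).
#' @param folded Logical; is \code{counts} indexed by minor-allele count?
#' @param masked_bins Integer vector of polymorphic class indices excluded
#'   from all likelihood computations (never class 0).
#' @return An object of class \code{"sfs"}.
#' @examples
#' x <- sfs(c(9990, 6, 3, 1), n = 4)
#' fold_sfs(x)
#' @export
sfs <- function(counts, n, folded = FALSE, masked_bins = integer()) {
  if (length(n) != 1L || !is.finite(n) || n != round(n) || n < 2)
    stop("sample size 'n' must be a single integer >= 2")
  n <- as.integer(n)
  counts <- as.numeric(counts)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("'counts' must be non-negative integers")
  if (folded) {
    nc <- n %/% 2L + 1L
    if (length(counts) != nc)
      stop(sprintf("folded spectrum for n = %d requires %d classes (0..%d), got %d",
                   n, nc, nc - 1L, length(counts)))
  } else {
    if (length(counts) == n + 1L) {
      counts[1L] <- counts[1L] + counts[n + 1L]
      counts <- counts[seq_len(n)]
    }
    if (length(counts) != n)
      stop(sprintf("unfolded spectrum for n = %d requires %d classes (0..%d), got %d",
                   n, n, n - 1L, length(counts)))
  }
  if (sum(counts) <= 0) stop("total site count l_n must be positive")
  x <- structure(list(n = n, counts = counts, folded = folded,
                      masked_bins = integer()),
                 class = "sfs")
  if (length(masked_bins)) x <- mask_sfs(x, masked_bins)
  x
}

# number of polymorphic classes in the spectrum's shape
n_poly_classes <- function(x) length(x$counts) - 1L

#' Total number of assayed sites
#'
#' @param x An \code{sfs} object.
#' @param unmasked_only If \code{TRUE}, exclude masked classes (this is the
#'   \eqn{l_n} entering the composite likelihood when a mask is set).
#' @return Numeric scalar.
#' @export
total_sites <- function(x, unmasked_only = FALSE) {
  stopifnot(inherits(x, "sfs"))
  if (unmasked_only && length(x$masked_bins))
    sum(x$counts[-(x$masked_bins + 1L)])
  else sum(x$counts)
}

#' Fold an unfolded spectrum
#'
#' Collapses derived-allele classes \eqn{i} and \eqn{n-i} into the
#' minor-allele class \eqn{i}: \eqn{\eta_i = \xi_i + \xi_{n-i}} for
#' \eqn{1 \le i < n/2}, with \eqn{\eta_{n/2} = \xi_{n/2}} (not doubled) when
#' \code{n} is even.  Total site count is conserved.  Masked bins are mapped
#' through the same collapse.
#'
#' @param x An unfolded \code{sfs}.
#' @return A folded \code{sfs}.
#' @export
fold_sfs <- function(x) {
  stopifnot(inherits(x, "sfs"))
  if (x$folded) stop("spectrum is already folded")
  n <- x$n
  h <- n %/% 2L
  out <- numeric(h + 1L)
  out[1L] <- x$counts[1L]
  for (i in seq_len(h)) {
    out[i + 1L] <- x$counts[i + 1L] +
      if (n - i != i && n - i <= n - 1L) x$counts[n - i + 1L] else 0
  }
  mb <- sort(unique(pmin(x$masked_bins, n - x$masked_bins)))
  sfs(out, n = n, folded = TRUE, masked_bins = mb)
}

#' Mask SFS classes
#'
#' Marks polymorphic classes as excluded from all likelihood computations
#' (e.g. singletons, whose calls are least reliable).  Counts are retained
#' but flagged; class probabilities are renormalized over the unmasked
#' classes and masked counts drop out of \eqn{l_n}.
#'
#' @param x An \code{sfs}.
#' @param bins Positive class indices to mask (class 0 is never maskable).
#' @return The \code{sfs} with \code{masked_bins} set (replacing any
#'   previous mask).
#' @export
mask_sfs <- function(x, bins) {
  stopifnot(inherits(x, "sfs"))
  bins <- sort(unique(as.integer(bins)))
  K <- n_poly_classes(x)
  if (any(bins < 1L) || any(bins > K))
    stop(sprintf("mask bins must lie in 1..%d (class 0 is never maskable)", K))
  if (length(bins) == K)
    stop("masking every polymorphic class leaves no information")
  x$masked_bins <- bins
  x
}

#' Split an SFS into training and testing subsamples
#'
#' Draws \code{round(fraction * l_n)} sites without replacement from the
#' \eqn{l_n} observed sites (a multivariate hypergeometric draw over the
#' classes, monomorphic sites included) to form a training spectrum; the
#' remaining sites form the testing spectrum.  This subsampling, rather than
#' bootstrap resampling, is what makes held-out goodness of fit meaningful.
#'
#' Uses the current RNG state; call \code{set.seed()} for reproducibility.
#'
#' @param x An \code{sfs}.
#' @param fraction Training fraction in (0, 1); default 2/3.
#' @return \code{list(training=, testing=)}, both inheriting \code{n},
#'   folded flag and mask from \code{x}.
#' @export
split_sfs <- function(x, fraction = 2 / 3) {
  stopifnot(inherits(x, "sfs"))
  if (length(fraction) != 1L || !is.finite(fraction) ||
      fraction <= 0 || fraction >= 1)
    stop("'fraction' must lie strictly between 0 and 1")
  l <- sum(x$counts)
  k <- round(fraction * l)
  if (k < 1 || k >= l)
    stop("training subsample would be empty or exhaust all sites")
  # sequential conditional hypergeometric draws
  train <- numeric(length(x$counts))
  rem_total <- l
  rem_draw <- k
  for (j in seq_along(x$counts)) {
    if (rem_draw <= 0) break
    m <- x$counts[j]
    train[j] <- rhyper(1L, m, rem_total - m, rem_draw)
    rem_total <- rem_total - m
    rem_draw <- rem_draw - train[j]
  }
  test <- x$counts - train
  list(
    training = sfs(train, n = x$n, folded = x$folded, masked_bins = x$masked_bins),
    testing  = sfs(test,  n = x$n, folded = x$folded, masked_bins = x$masked_bins)
  )
}

#' @export
print.sfs <- function(x, ...) {
  cat(sprintf("Site frequency spectrum: n = %d haploids, %s, %s sites\n",
              x$n, if (x$folded) "folded" else "unfolded",
              format(sum(x$counts), big.mark = ",")))
  K <- n_poly_classes(x)
  cat(sprintf("  %d polymorphic classes, %s segregating sites\n",
              K, format(sum(x$counts[-1L]), big.mark = ",")))
  if (length(x$masked_bins))
    cat("  masked classes:", paste(x$masked_bins, collapse = ", "), "\n")
  invisible(x)
}
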