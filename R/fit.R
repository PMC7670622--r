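#' Inference configuration
#'
#' Settings for the subsample-ensemble inference.  Defaults follow the
#' method's standard operating point: B = 200 subsample replicates, a 2/3
#' training fraction, and four candidate breakpoint counts of roughly 1/4,
#' 1/2, 3/4 and all of the \eqn{n - 2} possible positions.
#'
#' @param B Number of subsample replicates (>= 1).
#' @param training_fraction Fraction of sites in each training subsample,
#'   in (0, 1).
#' @param candidate_m Strictly increasing candidate breakpoint counts; if
#'   \code{NULL}, derived from the sample size at run time via
#'   [default_breakpoint_counts()].
#' @param mu Mutation rate per site per generation.
#' @param year_per_generation Generation time in years.
#' @param seed Master RNG seed; every random draw in a run derives from it.
#' @param theta_floor Lower bound for any fitted theta (keeps logs finite).
#' @param greedy_threshold Training log-likelihood gain required to accept
#'   one more breakpoint during the within-replicate stepwise search
#'   (default 1.92, the 5\% chi-squared(1) half-deviance criterion — each
#'   extra breakpoint is one extra free parameter and must earn a
#'   significant likelihood-ratio improvement).
#' @param grid_points Number of log-spaced time points in ensemble summaries.
#' @return An object of class \code{"inference_config"}.
#' @export
inference_config <- function(B = 200L, training_fraction = 2 / 3,
                             candidate_m = NULL, mu = 1.2e-8,
                             year_per_generation = 24, seed = 1L,
                             theta_floor = 1e-12, greedy_threshold = 1.92,
                             grid_points = 300L) {
  B <- as.integer(B)
  if (B < 1L) stop("'B' must be >= 1")
  if (training_fraction <= 0 || training_fraction >= 1)
    stop("'training_fraction' must lie strictly between 0 and 1")
  if (!is.null(candidate_m)) {
    candidate_m <- as.integer(candidate_m)
    if (any(candidate_m < 0L)) stop("candidate breakpoint counts must be >= 0")
    if (is.unsorted(candidate_m, strictly = TRUE))
      stop("'candidate_m' must be strictly increasing")
  }
  if (mu <= 0) stop("'mu' must be > 0")
  if (year_per_generation <= 0) stop("'year_per_generation' must be > 0")
  structure(list(B = B, training_fraction = training_fraction,
                 candidate_m = candidate_m, mu = mu,
                 year_per_generation = year_per_generation,
                 seed = as.integer(seed), theta_floor = theta_floor,
                 greedy_threshold = greedy_threshold,
                 grid_points = as.integer(grid_points)),
            class = "inference_config")
}

#' Default candidate breakpoint counts
#'
#' Four counts approximately equal to 1/4, 1/2, 3/4 and all of the
#' \eqn{n - 2} possible breakpoint positions.
#'
#' @param n Sample size (haploids).
#' @return Sorted unique integer vector.
#' @export
default_breakpoint_counts <- function(n) {
  n <- as.integer(n)
  if (n < 3L) return(0L)
  m <- c(as.integer(round(c(1, 2, 3) / 4 * (n - 2))), n - 2L)
  sort(unique(pmax(m, 0L)))
}

#' Randomly sample candidate breakpoint positions
#'
#' Picks \code{m} positions uniformly without replacement from the full set
#' \eqn{\{1, \dots, n-2\}}.  The fitted model's breakpoints are then
#' restricted to this random subset — the model-space constraint (in the
#' spirit of random feature subsetting in random forests) that, together
#' with site subsampling, controls overfitting.
#'
#' @param n Sample size (haploids).
#' @param m Number of positions to draw, \code{0 <= m <= n - 2}.
#' @return Sorted integer vector of length \code{m}.
#' @export
sample_breakpoints <- function(n, m) {
  n <- as.integer(n); m <- as.integer(m)
  if (m < 0L || m > n - 2L)
    stop(sprintf("'m' must lie in 0..%d for n = %d", n - 2L, n))
  if (m == 0L) return(integer())
  sort(sample.int(n - 2L, m))
}

# Precomputed pieces shared by every optimization on one training spectrum.
fit_context <- function(x, theta_floor = 1e-12) {
  A <- sfs_matrix(x$n, x$folded)
  classes <- 0:n_poly_classes(x)
  keep <- !(classes %in% x$masked_bins)
  eta_u <- x$counts[keep]
  l <- sum(eta_u)
  if (l <= 0) stop("training spectrum has no unmasked sites")
  poly_keep <- keep[-1L]              # unmasked polymorphic rows of A
  seg <- sum(x$counts[-1L][poly_keep])
  # Watterson-style moment start: polymorphic fraction / harmonic number
  theta0 <- max(seg / l / sum(1 / seq_len(x$n - 1L)), theta_floor * 10)
  list(n = x$n, A = A, keep = keep, eta_u = eta_u, l = l,
       logC = lgamma(l + 1) - sum(lgamma(eta_u + 1)),
       theta0 = theta0, floor = theta_floor, n_unmasked = sum(keep))
}

# Maximize the composite log-likelihood over per-group log-thetas for one
# fixed grouping.  Analytic gradient; L-BFGS-B with the theta floor as a box
# bound.  The feasibility constraint sum(E) < 1 is handled by a steep linear
# penalty (the optimum sits far inside the feasible region for any per-site
# theta of realistic magnitude).
fit_grouping <- function(ctx, breakpoints, x0 = NULL) {
  g <- theta_groups(ctx$n, breakpoints)
  G <- max(g)
  Ag <- t(rowsum(t(ctx$A), g))        # poly-classes x groups
  keep <- ctx$keep; eta_u <- ctx$eta_u; l <- ctx$l
  fn <- function(x) {
    E <- drop(Ag %*% exp(x))
    s <- sum(E)
    if (!is.finite(s) || s >= 0.999) return(-1e10 * (1 + s))
    p <- c(1 - s, E)[keep]
    ctx$logC + sum(eta_u * log(p)) - l * log(sum(p))
  }
  gr <- function(x) {
    th <- exp(x)
    W <- Ag * rep(th, each = nrow(Ag))     # dE/dx_g
    s <- sum(Ag %*% th)
    if (!is.finite(s) || s >= 0.999) return(-1e10 * colSums(W))
    D <- rbind(-colSums(W), W)[keep, , drop = FALSE]
    p <- c(1 - s, drop(Ag %*% th))[keep]
    drop(crossprod(D, eta_u / p)) - (l / sum(p)) * colSums(D)
  }
  if (is.null(x0)) x0 <- rep(log(ctx$theta0), G)
  x0 <- pmin(pmax(x0, log(ctx$floor)), 0)
  opt <- optim(x0, fn, gr, method = "L-BFGS-B",
               lower = log(ctx$floor), upper = 0,
               control = list(fnscale = -1, maxit = 500L, factr = 4.5e6))
  list(loglik = opt$value, group_theta = exp(opt$par),
       breakpoints = breakpoints, groups = g,
       convergence = opt$convergence)
}

#' Fit grouped thetas to a training SFS
#'
#' Maximizes the training composite log-likelihood over theta groupings
#' whose breakpoints are restricted to the supplied candidate positions.
#' The search is greedy forward selection: start from the single-epoch model
#' (no breakpoints), then repeatedly add the candidate breakpoint whose
#' inclusion — with all group thetas re-optimized — most increases the
#' training log-likelihood.  A breakpoint is one extra free parameter, so it
#' is accepted only when the gain exceeds \code{config$greedy_threshold}
#' (default 1.92, the likelihood-ratio criterion); the search also stops at
#' the identifiability cap (number of unmasked SFS classes, monomorphic
#' included).  Ties are broken by the smallest breakpoint position.
#'
#' @param training Training \code{sfs}.
#' @param candidates Candidate breakpoint positions (from
#'   [sample_breakpoints()]).
#' @param config An [inference_config()] (only \code{theta_floor} is used
#'   here).
#' @return An object of class \code{"fitted_model"}: \code{theta}
#'   ([epoch_theta()] whose breakpoints are a subset of the candidates),
#'   \code{candidates}, \code{train_loglik}, \code{loglik_path} (training
#'   log-likelihood after each accepted breakpoint) and \code{b}
#'   (subsample index, \code{NA} outside [run_ensemble()]).
#' @export
fit_thetas <- function(training, candidates, config = inference_config()) {
  stopifnot(inherits(training, "sfs"))
  candidates <- sort(unique(as.integer(candidates)))
  if (length(candidates) && (min(candidates) < 1L ||
                             max(candidates) > training$n - 2L))
    stop(sprintf("candidate breakpoints must lie in 1..%d", training$n - 2L))
  ctx <- fit_context(training, config$theta_floor)
  cap <- ctx$n_unmasked                 # max distinct theta groups
  cur <- fit_grouping(ctx, integer())
  path <- cur$loglik
  repeat {
    rem <- setdiff(candidates, cur$breakpoints)
    if (!length(rem) || length(cur$breakpoints) + 1L >= cap) break
    best <- NULL
    for (cand in rem) {                 # ascending: ties go to smallest
      bp <- sort(c(cur$breakpoints, cand))
      f <- fit_grouping(ctx, bp, x0 = warm_start(ctx$n, cur, bp))
      if (is.null(best) || f$loglik > best$loglik) best <- f
    }
    if (best$loglik > cur$loglik + config$greedy_threshold) {
      cur <- best
      path <- c(path, cur$loglik)
    } else break
  }
  theta <- epoch_theta(ctx$n, cur$group_theta[cur$groups],
                       breakpoints = cur$breakpoints)
  structure(list(theta = theta, candidates = candidates,
                 train_loglik = cur$loglik, loglik_path = path,
                 folded = training$folded,
                 masked_bins = training$masked_bins, b = NA_integer_),
            class = "fitted_model")
}

# starting values for a refined grouping, copied from the groups of the
# current fit (each new group inherits the value at its first member entry)
warm_start <- function(n, cur, new_bp) {
  g_new <- theta_groups(n, new_bp)
  full <- log(cur$group_theta)[cur$groups]
  full[match(seq_len(max(g_new)), g_new)]
}

#' Held-out goodness of fit of a fitted model
#'
#' Composite log-likelihood of a testing SFS under the class probabilities
#' implied by a fitted theta vector.  Used as the goodness-of-fit measure
#' in breakpoint-count selection.
#'
#' @param model A \code{fitted_model}.
#' @param testing Testing \code{sfs}; must match the training spectrum's
#'   sample size, folded flag and mask.
#' @return Log composite likelihood.
#' @export
evaluate_model <- function(model, testing) {
  stopifnot(inherits(model, "fitted_model"), inherits(testing, "sfs"))
  if (testing$n != model$theta$n || testing$folded != model$folded ||
      !identical(testing$masked_bins, model$masked_bins))
    stop("testing spectrum shape/mask does not match the fitted model")
  composite_loglik(testing, class_probabilities(model$theta, testing))
}

#' Select the number of breakpoints from held-out fit
#'
#' Given the mean held-out log-likelihood \eqn{G_m} for each candidate
#' breakpoint count, scans candidates in increasing order and advances to a
#' larger \eqn{m} only when its \eqn{G_m} exceeds the \eqn{G} of every
#' smaller candidate by more than 1.92 (the 95\% chi-squared half-deviance
#' threshold for one extra parameter); otherwise the current (smaller)
#' candidate is kept.  With no justified advance the smallest candidate is
#' chosen — complexity must earn its keep out of sample.
#'
#' @param G Named numeric vector of mean test log-likelihoods; names (or
#'   \code{m}) give the candidate counts.
#' @param m Candidate counts, parallel to \code{G}.
#' @param threshold Improvement threshold (default 1.92).
#' @return The chosen breakpoint count (integer).
#' @export
select_breakpoint_count <- function(G, m = as.integer(names(G)),
                                    threshold = 1.92) {
  if (!length(G)) stop("no candidate breakpoint counts supplied")
  if (length(m) != length(G) || anyNA(m)) stop("invalid candidate counts")
  o <- order(m)
  G <- G[o]; m <- m[o]
  chosen <- m[1L]
  for (j in seq_along(m)[-1L]) {
    if (all(G[j] > G[seq_len(j - 1L)] + threshold)) chosen <- m[j]
  }
  as.integer(chosen)
}

#' Run the subsample-ensemble inference
#'
#' For each of B replicates: split the SFS into training and testing
#' subsamples; for every candidate breakpoint count m, draw m random
#' candidate positions, fit the grouped thetas on the training spectrum and
#' score the fit on the testing spectrum.  The mean test log-likelihood over
#' replicates gives \eqn{G_m}; the breakpoint count is selected with
#' [select_breakpoint_count()] and the B models already fitted at the chosen
#' m form the inference ensemble (no refit).
#'
#' Every replicate gets a pre-assigned child seed derived from the master
#' seed, so results are independent of execution order.  A replicate whose
#' fit fails is retried with a fresh child seed at most 3 times.
#'
#' @param x Observed \code{sfs}.
#' @param config An [inference_config()].
#' @return An object of class \code{"sfs_ensemble"}: \code{models} (list of
#'   B \code{fitted_model}s at the chosen m), \code{G} (named mean test
#'   log-likelihoods), \code{chosen_m}, \code{candidate_m},
#'   \code{test_loglik} (B x length(m) matrix), \code{child_seeds} and
#'   \code{config}.
#' @export
run_ensemble <- function(x, config = inference_config()) {
  stopifnot(inherits(x, "sfs"))
  if (sum(x$counts[-1L]) == 0) stop("spectrum has no polymorphic sites")
  cand_m <- config$candidate_m
  if (is.null(cand_m)) cand_m <- default_breakpoint_counts(x$n)
  cand_m <- cand_m[cand_m <= x$n - 2L]
  if (!length(cand_m)) stop("no usable candidate breakpoint counts")
  B <- config$B
  set.seed(config$seed)
  seed_pool <- matrix(sample.int(2147483646L, B * 4L), nrow = B)
  models <- vector("list", B)
  test_ll <- matrix(NA_real_, B, length(cand_m),
                    dimnames = list(NULL, cand_m))
  used_seed <- integer(B)
  for (b in seq_len(B)) {
    done <- FALSE
    for (r in 1:4) {
      res <- tryCatch({
        set.seed(seed_pool[b, r])
        sp <- split_sfs(x, config$training_fraction)
        fits <- vector("list", length(cand_m))
        lls <- numeric(length(cand_m))
        for (j in seq_along(cand_m)) {
          bp <- sample_breakpoints(x$n, cand_m[j])
          f <- fit_thetas(sp$training, bp, config)
          f$b <- b
          fits[[j]] <- f
          lls[j] <- evaluate_model(f, sp$testing)
        }
        list(fits = fits, lls = lls)
      }, error = function(e) e)
      if (!inherits(res, "error")) {
        models[[b]] <- res$fits
        test_ll[b, ] <- res$lls
        used_seed[b] <- seed_pool[b, r]
        done <- TRUE
        break
      }
    }
    if (!done)
      stop(sprintf("replicate %d failed after 3 retries: %s",
                   b, conditionMessage(res)))
  }
  G <- colMeans(test_ll)
  chosen <- select_breakpoint_count(G, cand_m)
  j <- match(chosen, cand_m)
  structure(list(models = lapply(models, `[[`, j), G = G,
                 chosen_m = chosen, candidate_m = cand_m,
                 test_loglik = test_ll, child_seeds = used_seed,
                 config = config, n = x$n, folded = x$folded,
                 masked_bins = x$masked_bins),
            class = "sfs_ensemble")
}

#' @export
print.sfs_ensemble <- function(x, ...) {
  cat(sprintf("SFS subsample ensemble: B = %d replicates, n = %d (%s)\n",
              length(x$models), x$n, if (x$folded) "folded" else "unfolded"))
  cat("  mean test log-likelihood by breakpoint count:\n")
  for (j in seq_along(x$G))
    cat(sprintf("    m = %4d : G = %.3f%s\n", x$candidate_m[j], x$G[j],
                if (x$candidate_m[j] == x$chosen_m) "  (chosen)" else ""))
  invisible(x)
}
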