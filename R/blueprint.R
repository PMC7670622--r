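#' Read a blueprint configuration file
#'
#' A blueprint is a plain-text \code{key: value} run description holding the
#' observed SFS and all inference settings.  Recognized keys:
#' \describe{
#'   \item{popid}{label for the run (string)}
#'   \item{nseq}{sample size n in haploid sequences}
#'   \item{total_sites}{total assayed sites \eqn{l_n} (monomorphic +
#'     polymorphic)}
#'   \item{folded}{\code{true}/\code{false}}
#'   \item{sfs}{whitespace-separated counts for classes \eqn{1..n-1}
#'     (unfolded) or \eqn{1..\lfloor n/2\rfloor} (folded); class 0 is
#'     computed as \code{total_sites} minus their sum}
#'   \item{mask_bins}{optional comma-separated class indices to mask}
#'   \item{pct_training}{training fraction, default 2/3}
#'   \item{n_subsamples}{ensemble size B, default 200}
#'   \item{breakpoint_counts}{candidate breakpoint counts, default
#'     \code{default_breakpoint_counts(nseq)}}
#'   \item{mu}{mutation rate per site per generation}
#'   \item{year_per_generation}{generation time in years, default 24}
#'   \item{seed}{master RNG seed}
#'   \item{output_prefix}{prefix for output files}
#' }
#' Lines starting with \code{#} and blank lines are ignored.
#'
#' @param path Path to the blueprint file.
#' @return \code{list(sfs=, config=, popid=, output_prefix=)}.
#' @seealso [write_blueprint()]
#' @export
read_blueprint <- function(path) {
  if (!file.exists(path)) stop("blueprint file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  hit <- regexpr(":", lines, fixed = TRUE)
  if (any(hit < 0)) stop("blueprint line without 'key: value': ",
                         lines[which(hit < 0)[1L]])
  keys <- trimws(substr(lines, 1L, hit - 1L))
  vals <- trimws(substr(lines, hit + 1L, nchar(lines)))
  if (anyDuplicated(keys)) stop("duplicate blueprint key: ",
                                keys[duplicated(keys)][1L])
  kv <- stats::setNames(as.list(vals), keys)

  need <- function(key) {
    if (is.null(kv[[key]])) stop("blueprint is missing required key '", key, "'")
    kv[[key]]
  }
  num <- function(key, default = NULL) {
    v <- kv[[key]]
    if (is.null(v)) {
      if (is.null(default)) stop("blueprint is missing required key '", key, "'")
      return(default)
    }
    out <- suppressWarnings(as.numeric(v))
    if (is.na(out)) stop("blueprint key '", key, "' is not numeric: ", v)
    out
  }

  n <- num("nseq")
  L <- num("total_sites")
  folded <- tolower(need("folded")) %in% c("true", "t", "1", "yes")
  poly <- suppressWarnings(as.numeric(strsplit(need("sfs"), "[[:space:],]+")[[1L]]))
  poly <- poly[!is.na(poly)]
  expect_len <- if (folded) n %/% 2 else n - 1
  if (length(poly) != expect_len)
    stop(sprintf("blueprint key 'sfs': expected %d %s class counts for nseq = %d, got %d",
                 expect_len, if (folded) "folded" else "unfolded", n, length(poly)))
  if (any(poly < 0)) stop("blueprint key 'sfs' contains negative counts")
  eta0 <- L - sum(poly)
  if (eta0 < 0)
    stop("blueprint key 'total_sites' is smaller than the sum of the 'sfs' counts")
  mask <- kv[["mask_bins"]]
  mask <- if (is.null(mask) || !nzchar(mask)) integer() else
    as.integer(strsplit(mask, "[[:space:],]+")[[1L]])
  x <- sfs(c(eta0, poly), n = n, folded = folded, masked_bins = mask)

  bc <- kv[["breakpoint_counts"]]
  bc <- if (is.null(bc) || !nzchar(bc)) default_breakpoint_counts(as.integer(n))
        else as.integer(strsplit(bc, "[[:space:],]+")[[1L]])
  cfg <- inference_config(
    B = as.integer(num("n_subsamples", 200)),
    training_fraction = num("pct_training", 2 / 3),
    candidate_m = bc,
    mu = num("mu"),
    year_per_generation = num("year_per_generation", 24),
    seed = as.integer(num("seed", 1))
  )
  list(sfs = x, config = cfg,
       popid = if (is.null(kv[["popid"]])) "pop" else kv[["popid"]],
       output_prefix = if (is.null(kv[["output_prefix"]])) "stairsfs" else kv[["output_prefix"]])
}

#' Write a blueprint configuration file
#'
#' Inverse of [read_blueprint()]: the round trip reproduces the SFS counts
#' bit-exactly and real-valued settings to 17 significant digits.
#'
#' @param x An \code{sfs}.
#' @param config An [inference_config()].
#' @param path Output path.
#' @param popid Run label.
#' @param output_prefix Output prefix recorded in the file.
#' @return \code{path}, invisibly.
#' @export
write_blueprint <- function(x, config, path, popid = "pop",
                            output_prefix = "stairsfs") {
  stopifnot(inherits(x, "sfs"))
  fmt <- function(v) format(v, digits = 17, scientific = TRUE, trim = TRUE)
  lines <- c(
    paste0("popid: ", popid),
    paste0("nseq: ", x$n),
    paste0("total_sites: ", format(sum(x$counts), scientific = FALSE)),
    paste0("folded: ", tolower(x$folded)),
    paste0("sfs: ", paste(format(x$counts[-1L], scientific = FALSE, trim = TRUE),
                          collapse = " ")),
    paste0("mask_bins: ", paste(x$masked_bins, collapse = ",")),
    paste0("pct_training: ", fmt(config$training_fraction)),
    paste0("n_subsamples: ", config$B),
    paste0("breakpoint_counts: ", paste(config$candidate_m, collapse = ",")),
    paste0("mu: ", fmt(config$mu)),
    paste0("year_per_generation: ", fmt(config$year_per_generation)),
    paste0("seed: ", config$seed),
    paste0("output_prefix: ", output_prefix)
  )
  writeLines(lines, path)
  invisible(path)
}
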