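#' End-to-end inference from a blueprint or SFS
#'
#' Runs the full pipeline: subsample the SFS into training/testing pairs,
#' fit breakpoint-constrained theta vectors for every candidate breakpoint
#' count, select the count by held-out goodness of fit, convert the chosen
#' ensemble into effective-size trajectories in years, and summarize them
#' into a median curve with 75\% and 95\% percentile bands.
#'
#' When \code{out_prefix} is set, three files are written:
#' \code{<prefix>.summary.tsv} (columns \code{time_years Ne_median Ne_2.5
#' Ne_12.5 Ne_87.5 Ne_97.5}), \code{<prefix>.thetas.tsv} (per-replicate
#' fitted thetas) and \code{<prefix>.manifest.json} (config echo, master
#' and child seeds, the \eqn{G_m} table and chosen m — enough to reproduce
#' the run exactly).
#'
#' @param x An \code{sfs}, or the path of a blueprint file.
#' @param config An [inference_config()]; ignored (taken from the file)
#'   when \code{x} is a blueprint path.
#' @param out_prefix Optional output file prefix; overrides the blueprint's
#'   \code{output_prefix} when given.
#' @param quiet Suppress the G_m log table?
#' @return List with \code{summary} (data frame in years),
#'   \code{ensemble} (the \code{sfs_ensemble}), \code{trajectories} and
#'   \code{manifest}.
#' @export
run_full_inference <- function(x, config = NULL, out_prefix = NULL,
                               quiet = FALSE) {
  popid <- "pop"
  if (is.character(x)) {
    bp <- read_blueprint(x)
    if (is.null(out_prefix)) out_prefix <- bp$output_prefix
    popid <- bp$popid
    config <- bp$config
    x <- bp$sfs
  }
  stopifnot(inherits(x, "sfs"))
  if (is.null(config)) stop("an inference_config is required")
  ens <- run_ensemble(x, config)
  if (!quiet) {
    message(sprintf("[%s] classes in likelihood: %s", popid,
                    paste(setdiff(0:n_poly_classes(x), x$masked_bins),
                          collapse = " ")))
    for (j in seq_along(ens$G))
      message(sprintf("[%s] G(m = %d) = %.4f%s", popid, ens$candidate_m[j],
                      ens$G[j],
                      if (ens$candidate_m[j] == ens$chosen_m) "  <- chosen" else ""))
  }
  trajs <- lapply(ens$models, function(m)
    scale_to_years(ne_trajectory(m$theta, config$mu, b = m$b),
                   config$mu, config$year_per_generation))
  summ <- summarize_ensemble(trajs, grid_points = config$grid_points)
  manifest <- list(
    package = "stairsfs",
    version = as.character(utils::packageVersion("stairsfs")),
    popid = popid,
    n = x$n, folded = x$folded, masked_bins = x$masked_bins,
    total_sites = sum(x$counts),
    seed = config$seed, child_seeds = ens$child_seeds,
    B = config$B, training_fraction = config$training_fraction,
    candidate_m = ens$candidate_m, G = unname(ens$G),
    chosen_m = ens$chosen_m,
    mu = config$mu, year_per_generation = config$year_per_generation,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  if (!is.null(out_prefix)) {
    write_summary_tsv(summ, paste0(out_prefix, ".summary.tsv"))
    th <- do.call(rbind, lapply(ens$models, function(m)
      data.frame(b = m$b, k = 2:x$n, theta = m$theta$theta)))
    write.table(th, paste0(out_prefix, ".thetas.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, paste0(out_prefix, ".manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(summary = summ, ensemble = ens, trajectories = trajs,
       manifest = manifest)
}

#' Write an ensemble summary as TSV
#'
#' @param summary Data frame from [summarize_ensemble()] (in years).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_summary_tsv <- function(summary, path) {
  out <- summary
  names(out)[names(out) == "time"] <- "time_years"
  write.table(format(out, digits = 10, trim = TRUE), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
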