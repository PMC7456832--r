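#' Percentile bootstrap confidence interval for the indirect effect
#'
#' Nonparametric case resampling: whole records (treatment, mediator, outcome,
#' and confounders jointly) are drawn with replacement, and the complete
#' estimation pipeline — propensity model fits, truncation caps, Q-model, and
#' total effect — is re-run on every resample so the interval reflects the
#' uncertainty of all nuisance fits. Interval endpoints are the symmetric
#' nearest-rank order statistics of the resampled indirect estimates: ranks
#' \code{k} and \code{n_resamples + 1 - k} with
#' \code{k = ceiling(n_resamples * (1 - level) / 2)} (the 25th and 976th of
#' 1000 resamples at the 95% level).
#'
#' A resample that loses a treatment arm is redrawn, up to 100 retries per
#' resample, after which an error is raised.
#'
#' @param dataset Data frame with \code{X}, \code{M}, \code{Y}, confounders.
#' @param spec An \code{\link{estimation_spec}} naming the method whose
#'   indirect effect is bootstrapped.
#' @param n_resamples Number of with-replacement resamples (>= 2).
#'   Default 1000.
#' @param level Confidence level in (0, 1). Default 0.95.
#' @param seed Integer seed; identical (dataset, spec, seed) triples give
#'   identical intervals.
#' @return An object of class \code{bootstrap_result} with fields
#'   \code{point_estimate}, \code{lower}, \code{upper}, \code{n_resamples},
#'   \code{level}, \code{significant} (TRUE when 0 falls outside the
#'   interval), and \code{resamples} (the resampled indirect estimates).
#' @examples
#' dat <- generate_dataset(path_coefficients(a = 0.39, b = 0.59),
#'                         seed = 3, sample_size = 200)
#' percentile_bootstrap(dat, estimation_spec("regression"),
#'                      n_resamples = 50, seed = 11)
#' @export
percentile_bootstrap <- function(dataset, spec, n_resamples = 1000,
                                 level = 0.95, seed) {
  stopifnot(inherits(spec, "estimation_spec"))
  if (n_resamples < 2) stop("n_resamples must be >= 2", call. = FALSE)
  if (!(level > 0 && level < 1)) stop("level must lie in (0, 1)", call. = FALSE)
  if (missing(seed) || is.null(seed)) stop("seed must be provided", call. = FALSE)
  check_two_arms(dataset)

  point <- estimate_one(dataset, spec)$indirect_hat

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))
  n <- nrow(dataset)
  draws <- numeric(n_resamples)
  for (r in seq_len(n_resamples)) {
    for (attempt in seq_len(100L)) {
      idx <- sample.int(n, n, replace = TRUE)
      resample <- dataset[idx, , drop = FALSE]
      if (length(unique(resample$X)) >= 2L) break
      if (attempt == 100L) {
        stop("could not draw a resample containing both treatment arms",
             call. = FALSE)
      }
    }
    draws[r] <- estimate_one(resample, spec)$indirect_hat
  }
  ci <- percentile_interval(draws, level)
  structure(list(point_estimate = point, lower = ci[1], upper = ci[2],
                 n_resamples = as.integer(n_resamples), level = level,
                 significant = (0 < ci[1] || 0 > ci[2]),
                 resamples = draws),
            class = "bootstrap_result")
}

# symmetric nearest-rank percentile interval on a vector of resampled
# estimates; shared convention with weight truncation
percentile_interval <- function(draws, level) {
  sorted <- sort(draws)
  n <- length(sorted)
  k <- min(max(1L, as.integer(ceiling(n * (1 - level) / 2))), n)
  c(sorted[k], sorted[n + 1L - k])
}

#' @export
print.bootstrap_result <- function(x, digits = 4, ...) {
  cat(sprintf("Indirect effect %.*f, %d%% percentile bootstrap CI [%.*f, %.*f] (%d resamples)%s\n",
              digits, x$point_estimate, round(100 * x$level),
              digits, x$lower, digits, x$upper, x$n_resamples,
              if (x$significant) " *" else ""))
  invisible(x)
}
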