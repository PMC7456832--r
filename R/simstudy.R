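#' Bias, MSE, and relative bias of a set of estimates
#'
#' Bias is the mean estimate minus the truth. MSE is the mean squared
#' deviation from the truth, which decomposes exactly into the variance of
#' the estimates about their own mean (1/R normalization) plus squared bias.
#' Relative bias is \code{100 * bias / truth}, undefined (\code{NA}) when the
#' truth is zero.
#'
#' @param estimates Non-empty numeric vector of replication estimates.
#' @param truth Finite numeric scalar: the true parameter value.
#' @return A list with \code{bias}, \code{mse}, \code{relative_bias_pct},
#'   and \code{var_estimate} (the variance-about-mean component, the
#'   alternative dispersion reading of MSE).
#' @examples
#' bias_and_mse(c(1, 2, 3), truth = 1)  # bias 1, mse 5/3
#' @export
bias_and_mse <- function(estimates, truth) {
  if (length(estimates) == 0L) stop("empty estimate vector", call. = FALSE)
  if (!is.finite(truth)) stop("truth must be finite", call. = FALSE)
  bias <- mean(estimates) - truth
  mse <- mean((estimates - truth)^2)
  var_est <- mean((estimates - mean(estimates))^2)
  list(bias = bias, mse = mse,
       relative_bias_pct = if (truth != 0) 100 * bias / truth else NA_real_,
       var_estimate = var_est)
}

#' Configure a Monte Carlo study
#'
#' @param grid A \code{condition_grid} (see \code{\link{build_condition_grid}}).
#' @param batteries Named list of estimation batteries, each a list of
#'   \code{\link{estimation_spec}} objects. Default: the two-confounder and
#'   one-confounder batteries.
#' @param replications Replications per condition (>= 1). Default 1000.
#' @param master_seed Master seed from which every replication seed derives.
#' @param bootstrap Compute percentile bootstrap CIs inside each replication
#'   (off by default; bias/MSE do not need them).
#' @param n_resamples,level Bootstrap settings. Defaults 1000 and 0.95.
#' @param sample_size Overrides every condition's sample size when non-NULL.
#' @param keep_replications Retain the replication-level records in the
#'   output. Default \code{FALSE}.
#' @return An object of class \code{study_config}.
#' @export
study_config <- function(grid, batteries = list(
                           two_confounder = two_confounder_battery(),
                           one_confounder = one_confounder_battery()),
                         replications = 1000, master_seed = 1,
                         bootstrap = FALSE, n_resamples = 1000, level = 0.95,
                         sample_size = NULL, keep_replications = FALSE) {
  stopifnot(inherits(grid, "condition_grid"))
  if (replications < 1) stop("replications must be >= 1", call. = FALSE)
  if (length(batteries) == 0L || any(vapply(batteries, length, integer(1)) == 0L)) {
    stop("batteries must be non-empty", call. = FALSE)
  }
  if (is.null(names(batteries)) || any(names(batteries) == "")) {
    names(batteries) <- paste0("battery", seq_along(batteries))
  }
  structure(list(grid = grid, batteries = batteries,
                 replications = as.integer(replications),
                 master_seed = as.integer(master_seed),
                 bootstrap = isTRUE(bootstrap),
                 n_resamples = as.integer(n_resamples), level = level,
                 sample_size = sample_size,
                 keep_replications = isTRUE(keep_replications)),
            class = "study_config")
}

#' Run all replications of one simulation condition
#'
#' Generates \code{config$replications} fresh datasets (seeds derived from the
#' master seed, the condition's position in the grid, and the replication
#' index), applies every estimation specification in every battery, and
#' aggregates bias, MSE, relative bias, and — when the bootstrap is enabled —
#' CI coverage of the true indirect effect. A replication whose estimation
#' fails (e.g., a degenerate weight model) is logged, counted, and excluded
#' rather than aborting the condition.
#'
#' @param condition A \code{\link{simulation_condition}}.
#' @param config A \code{\link{study_config}}.
#' @param condition_index Position of the condition in its grid (drives seed
#'   derivation). Default 1.
#' @return A data frame of per-(battery, spec) summaries with columns
#'   \code{condition_id, a, b, c_prime, d, f, g, h, battery, method,
#'   spec_label, truth, mean_estimate, bias, mse, var_estimate,
#'   relative_bias_pct, coverage, R, n_failed}; when
#'   \code{config$keep_replications} is TRUE the replication-level records are
#'   attached as attribute \code{"replications"}.
#' @export
run_condition <- function(condition, config, condition_index = 1L) {
  stopifnot(inherits(condition, "simulation_condition"),
            inherits(config, "study_config"))
  cf <- condition$coefficients
  truth <- true_effects(cf)$indirect
  n <- if (is.null(config$sample_size)) condition$sample_size else config$sample_size
  R <- config$replications

  spec_table <- battery_spec_table(config$batteries)
  records <- vector("list", R)
  n_failed <- 0L
  for (r in seq_len(R)) {
    seed <- replication_seed(config$master_seed, condition_index, r)
    rec <- tryCatch({
      dat <- generate_dataset(condition, seed = seed, sample_size = n)
      est <- estimate_batteries(dat, config$batteries)
      if (config$bootstrap) {
        cis <- mapply(function(battery, i) {
          spec <- config$batteries[[battery]][[i]]
          bs <- percentile_bootstrap(dat, spec,
                                     n_resamples = config$n_resamples,
                                     level = config$level,
                                     seed = seed + 1L)
          c(bs$lower, bs$upper)
        }, est$battery, est$spec_index)
        est$ci_lower <- cis[1, ]
        est$ci_upper <- cis[2, ]
      }
      est$condition_id <- condition$id
      est$replication <- r
      est$seed <- seed
      est
    }, error = function(e) {
      message(sprintf("replication %d of %s failed (seed %d): %s",
                      r, condition$id, seed, conditionMessage(e)))
      NULL
    })
    if (is.null(rec)) n_failed <- n_failed + 1L else records[[r]] <- rec
  }
  records <- do.call(rbind, records)
  if (is.null(records)) {
    stop("every replication of condition ", condition$id, " failed",
         call. = FALSE)
  }

  summaries <- lapply(seq_len(nrow(spec_table)), function(i) {
    sel <- records$battery == spec_table$battery[i] &
      records$spec_index == spec_table$spec_index[i]
    est <- records$indirect_hat[sel]
    stats <- bias_and_mse(est, truth)
    coverage <- if (config$bootstrap) {
      mean(records$ci_lower[sel] <= truth & truth <= records$ci_upper[sel])
    } else NA_real_
    data.frame(condition_id = condition$id,
               a = cf$a, b = cf$b, c_prime = cf$c_prime,
               d = cf$d, f = cf$f, g = cf$g, h = cf$h,
               battery = spec_table$battery[i],
               method = spec_table$method[i],
               spec_label = spec_table$spec_label[i],
               truth = truth, mean_estimate = mean(est),
               bias = stats$bias, mse = stats$mse,
               var_estimate = stats$var_estimate,
               relative_bias_pct = stats$relative_bias_pct,
               coverage = coverage, R = length(est), n_failed = n_failed,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, summaries)
  rownames(out) <- NULL
  if (config$keep_replications) attr(out, "replications") <- records
  out
}

battery_spec_table <- function(batteries) {
  rows <- lapply(names(batteries), function(bname) {
    specs <- batteries[[bname]]
    data.frame(battery = bname, spec_index = seq_along(specs),
               method = vapply(specs, `[[`, character(1), "method"),
               spec_label = vapply(specs, `[[`, character(1), "label"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

estimate_batteries <- function(dataset, batteries) {
  total_hat <- estimate_total_effect(dataset)
  rows <- lapply(names(batteries), function(bname) {
    specs <- batteries[[bname]]
    est <- do.call(rbind, lapply(seq_along(specs), function(i) {
      df <- as.data.frame(estimate_one(dataset, specs[[i]], total_hat))
      df$spec_index <- i
      df
    }))
    est$battery <- bname
    est
  })
  do.call(rbind, rows)
}

#' Run the full Monte Carlo study over a condition grid
#'
#' @param config A \code{\link{study_config}}.
#' @param verbose Print one progress line per condition. Default \code{FALSE}.
#' @return Concatenated \code{\link{run_condition}} summaries over all
#'   conditions, in grid order.
#' @examples
#' \donttest{
#' grid <- build_condition_grid(a_levels = 0.59, b_levels = 0.59,
#'   cprime_levels = 0, dm_levels = 0.59, gx_levels = 0)
#' cfg <- study_config(grid, replications = 20, master_seed = 1,
#'                     sample_size = 200)
#' run_study(cfg)
#' }
#' @export
run_study <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  out <- lapply(seq_along(config$grid), function(i) {
    if (verbose) message("condition ", config$grid[[i]]$id)
    tryCatch(run_condition(config$grid[[i]], config, condition_index = i),
             error = function(e) {
               warning("condition ", config$grid[[i]]$id, " failed: ",
                       conditionMessage(e), call. = FALSE)
               NULL
             })
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Zero-confounding simulation check
#'
#' Runs the no-confounding condition (d = f = g = h = 0) at the configured
#' replication count and flags any method whose absolute relative bias for
#' the indirect effect exceeds the 10% acceptability bound. With no
#' confounding every method, including plain regression, should recover the
#' product \code{a * b}.
#'
#' @param a,b,c_prime Structural paths of the check condition. Defaults
#'   a = 0.39, b = 0.59, c' = 0 (true indirect 0.2301).
#' @param replications Replications. Default 500.
#' @param master_seed Seed. Default 1.
#' @param sample_size Records per dataset. Default 500.
#' @param batteries Batteries to check. Default: the two-confounder battery.
#' @param threshold_pct Relative-bias acceptability bound. Default 10.
#' @return Data frame with one row per spec: \code{method, spec_label, truth,
#'   mean_estimate, bias, relative_bias_pct, pass}.
#' @export
zero_confounding_check <- function(a = 0.39, b = 0.59, c_prime = 0,
                                   replications = 500, master_seed = 1,
                                   sample_size = 500,
                                   batteries = list(two_confounder = two_confounder_battery()),
                                   threshold_pct = 10) {
  cond <- simulation_condition(
    "zero_confounding",
    path_coefficients(a = a, b = b, c_prime = c_prime,
                      d = 0, f = 0, g = 0, h = 0),
    sample_size)
  cfg <- study_config(new_condition_grid(list(cond)), batteries = batteries,
                      replications = replications, master_seed = master_seed)
  res <- run_condition(cond, cfg)
  out <- res[, c("method", "spec_label", "truth", "mean_estimate", "bias",
                 "relative_bias_pct")]
  out$pass <- is.na(out$relative_bias_pct) |
    abs(out$relative_bias_pct) <= threshold_pct
  rownames(out) <- NULL
  out
}

#' Write a study summary table to CSV
#'
#' @param summary Data frame from \code{\link{run_study}} or
#'   \code{\link{run_condition}}.
#' @param path File path.
#' @export
write_study_summary <- function(summary, path) {
  utils::write.csv(summary, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
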