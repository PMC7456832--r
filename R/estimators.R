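#' Specify one estimation method and its confounder sets
#'
#' @param method One of \code{"regression"}, \code{"ipw"},
#'   \code{"ipw_truncated"}, \code{"seq_g"}, \code{"dr_seq_g"}.
#' @param outcome_confounders Confounder columns entering the outcome / Q
#'   model (ignored by the IPW methods, whose outcome model contains only
#'   treatment and mediator).
#' @param propensity_confounders Confounder columns entering the mediator
#'   propensity (weight) model; used by the IPW and doubly robust methods only.
#' @param label Optional label distinguishing variants of the same method
#'   (e.g., the three doubly robust misspecification variants). Defaults to
#'   \code{method}.
#' @param estimator Optional custom function \code{(dataset, spec, total_hat)}
#'   returning an \code{effect_estimates} object, overriding the built-in
#'   dispatch (useful for sentinel or experimental estimators in study runs).
#' @return An object of class \code{estimation_spec}.
#' @export
estimation_spec <- function(method = c("regression", "ipw", "ipw_truncated",
                                       "seq_g", "dr_seq_g"),
                            outcome_confounders = character(),
                            propensity_confounders = character(),
                            label = NULL, estimator = NULL) {
  method <- match.arg(method)
  stopifnot(is.null(estimator) || is.function(estimator))
  structure(list(method = method,
                 outcome_confounders = as.character(outcome_confounders),
                 propensity_confounders = as.character(propensity_confounders),
                 label = if (is.null(label)) method else as.character(label),
                 estimator = estimator),
            class = "estimation_spec")
}

#' The two-confounder (correctly specified) estimation battery
#'
#' Five specifications, each using both measured confounders everywhere they
#' appear: regression with adjustment, IPW, IPW with truncated weights,
#' sequential g-estimation, and doubly robust sequential g-estimation.
#'
#' @param confounders Confounder column names. Default \code{c("C1", "C2")}.
#' @return List of \code{\link{estimation_spec}} objects.
#' @export
two_confounder_battery <- function(confounders = c("C1", "C2")) {
  list(
    estimation_spec("regression", outcome_confounders = confounders),
    estimation_spec("ipw", propensity_confounders = confounders),
    estimation_spec("ipw_truncated", propensity_confounders = confounders),
    estimation_spec("seq_g", outcome_confounders = confounders),
    estimation_spec("dr_seq_g", outcome_confounders = confounders,
                    propensity_confounders = confounders)
  )
}

#' The one-confounder (misspecified) estimation battery
#'
#' Seven specifications omitting the second confounder: regression, IPW,
#' IPW-truncated, and sequential g-estimation each use \code{C1} only, and
#' the doubly robust method contributes three variants — \code{C2} omitted
#' from the propensity model only, from the outcome (Q) model only, or from
#' both.
#'
#' @param kept The confounder retained in misspecified models. Default
#'   \code{"C1"}.
#' @param full The full confounder set. Default \code{c("C1", "C2")}.
#' @return List of 7 \code{\link{estimation_spec}} objects.
#' @export
one_confounder_battery <- function(kept = "C1", full = c("C1", "C2")) {
  list(
    estimation_spec("regression", outcome_confounders = kept),
    estimation_spec("ipw", propensity_confounders = kept),
    estimation_spec("ipw_truncated", propensity_confounders = kept),
    estimation_spec("seq_g", outcome_confounders = kept),
    estimation_spec("dr_seq_g", outcome_confounders = full,
                    propensity_confounders = kept,
                    label = "dr_seq_g_med_misspec"),
    estimation_spec("dr_seq_g", outcome_confounders = kept,
                    propensity_confounders = full,
                    label = "dr_seq_g_out_misspec"),
    estimation_spec("dr_seq_g", outcome_confounders = kept,
                    propensity_confounders = kept,
                    label = "dr_seq_g_both_misspec")
  )
}

#' Unadjusted total treatment effect
#'
#' Least-squares slope of the outcome on the randomized treatment, with
#' intercept and no covariates. All methods share this total effect; their
#' indirect estimates differ only through the direct effect they remove.
#'
#' @param dataset Data frame with columns \code{X} and \code{Y}.
#' @param outcome,treatment Column names.
#' @return Numeric scalar: the estimated total effect.
#' @export
estimate_total_effect <- function(dataset, outcome = "Y", treatment = "X") {
  check_columns(dataset, c(outcome, treatment))
  check_two_arms(dataset, treatment)
  fit <- stats::lm(model_formula(outcome, treatment), data = dataset)
  unname(stats::coef(fit)[treatment])
}

check_two_arms <- function(dataset, treatment = "X") {
  if (length(unique(dataset[[treatment]])) < 2L) {
    stop("dataset contains a single treatment arm", call. = FALSE)
  }
  invisible(TRUE)
}

#' Construct an effect-estimates record
#'
#' Container returned by every estimator: the shared total effect, the
#' method's direct (controlled direct) effect, and their difference as the
#' indirect effect, plus the nuisance mediator and treatment-mediator
#' coefficients. Mostly used internally, but exported so custom estimators
#' plugged into \code{\link{estimation_spec}} can return the same structure.
#'
#' @param method Method identifier.
#' @param label Spec label. Defaults to \code{method}.
#' @param total_hat,direct_hat Finite estimates; \code{indirect_hat} is set to
#'   their difference exactly.
#' @param b_hat,a_hat Optional nuisance coefficients (mediator coefficient of
#'   the outcome/Q model; slope of M on X).
#' @return An object of class \code{effect_estimates}.
#' @export
effect_estimates <- function(method, label = method, total_hat, direct_hat,
                             b_hat = NA_real_, a_hat = NA_real_) {
  if (!is.finite(total_hat) || !is.finite(direct_hat)) {
    stop("total and direct estimates must be finite", call. = FALSE)
  }
  new_effect_estimates(method, label, total_hat, direct_hat, b_hat, a_hat)
}

new_effect_estimates <- function(method, label, total_hat, direct_hat,
                                 b_hat = NA_real_, a_hat = NA_real_) {
  structure(list(method = method, label = label,
                 total_hat = total_hat, direct_hat = direct_hat,
                 indirect_hat = total_hat - direct_hat,
                 b_hat = b_hat, a_hat = a_hat),
            class = "effect_estimates")
}

#' @export
print.effect_estimates <- function(x, digits = 4, ...) {
  cat(sprintf("%s: total = %.*f, direct (CDE) = %.*f, indirect = %.*f\n",
              x$label, digits, x$total_hat, digits, x$direct_hat,
              digits, x$indirect_hat))
  invisible(x)
}

#' @export
as.data.frame.effect_estimates <- function(x, ...) {
  data.frame(method = x$method, spec_label = x$label, total_hat = x$total_hat,
             direct_hat = x$direct_hat, indirect_hat = x$indirect_hat,
             b_hat = x$b_hat, a_hat = x$a_hat, stringsAsFactors = FALSE)
}

# slope of M on X (closed-form simple OLS), reported for diagnostics
# alongside every estimate
fit_a_path <- function(dataset, mediator = "M", treatment = "X") {
  x <- dataset[[treatment]]
  stats::cov(dataset[[mediator]], x) / stats::var(x)
}

check_full_rank <- function(fit) {
  if (anyNA(stats::coef(fit))) {
    stop("degenerate design: collinear regressors dropped from ",
         deparse(stats::formula(fit)), call. = FALSE)
  }
  invisible(fit)
}

#' Regression with adjustment
#'
#' Ordinary least squares of the outcome on treatment, mediator, and the
#' specified confounders; the treatment coefficient is the adjusted direct
#' effect and the indirect effect is total minus direct.
#'
#' @param dataset Data frame with \code{X}, \code{M}, \code{Y}, confounders.
#' @param spec An \code{\link{estimation_spec}} with
#'   \code{method = "regression"}; its \code{outcome_confounders} enter the
#'   regression.
#' @param total_hat Optional precomputed total effect (shared across methods);
#'   computed from the dataset when missing.
#' @return An \code{effect_estimates} object.
#' @export
regression_adjusted_direct <- function(dataset, spec = estimation_spec("regression"),
                                       total_hat = NULL) {
  stopifnot(spec$method == "regression")
  confs <- spec$outcome_confounders
  check_columns(dataset, c("X", "M", "Y", confs))
  check_two_arms(dataset)
  if (is.null(total_hat)) total_hat <- estimate_total_effect(dataset)
  fit <- stats::lm(model_formula("Y", c("X", "M", confs)), data = dataset)
  check_full_rank(fit)
  cf <- stats::coef(fit)
  new_effect_estimates("regression", spec$label, total_hat,
                       unname(cf["X"]), b_hat = unname(cf["M"]),
                       a_hat = fit_a_path(dataset))
}

#' Inverse propensity weighting for the mediator
#'
#' Builds stabilized mediator weights from \code{spec$propensity_confounders}
#' (see \code{\link{mediator_weights}}), optionally truncated at the 1st/99th
#' percentiles, then fits the weighted outcome model \code{Y ~ M + X} — the
#' confounder adjustment is carried entirely by the weights. The treatment
#' coefficient is the direct effect.
#'
#' @inheritParams regression_adjusted_direct
#' @param spec An \code{\link{estimation_spec}} with \code{method} \code{"ipw"}
#'   or \code{"ipw_truncated"}.
#' @param truncate Truncate the weights at the percentile caps. Defaults to
#'   \code{TRUE} when \code{spec$method == "ipw_truncated"}.
#' @param lower_pct,upper_pct Truncation percentiles. Defaults 1 and 99.
#' @return An \code{effect_estimates} object.
#' @export
ipw_direct <- function(dataset, spec = estimation_spec("ipw"),
                       truncate = spec$method == "ipw_truncated",
                       total_hat = NULL, lower_pct = 1, upper_pct = 99) {
  stopifnot(spec$method %in% c("ipw", "ipw_truncated"))
  check_columns(dataset, c("X", "M", "Y", spec$propensity_confounders))
  check_two_arms(dataset)
  if (is.null(total_hat)) total_hat <- estimate_total_effect(dataset)
  w <- mediator_weights(dataset, spec$propensity_confounders)
  if (truncate) w <- truncate_weights(w, lower_pct, upper_pct)
  dat <- dataset
  dat$.w <- w
  fit <- stats::lm(Y ~ M + X, data = dat, weights = .w)
  check_full_rank(fit)
  cf <- stats::coef(fit)
  new_effect_estimates(spec$method, spec$label, total_hat,
                       unname(cf["X"]), b_hat = unname(cf["M"]),
                       a_hat = fit_a_path(dataset))
}

#' Sequential g-estimation of the controlled direct effect
#'
#' Two steps: (1) the Q-model regresses the outcome on treatment, mediator,
#' and the specified confounders by OLS, yielding the mediator coefficient
#' \eqn{\beta_M}; (2) the mediator's contribution is removed from the outcome
#' and the residualized outcome \eqn{Y - \beta_M M} is regressed on treatment
#' alone, whose slope is the controlled direct effect. The residual-outcome
#' regression contains no covariates because treatment is randomized.
#'
#' @inheritParams regression_adjusted_direct
#' @param spec An \code{\link{estimation_spec}} with \code{method = "seq_g"};
#'   \code{outcome_confounders} enter the Q-model.
#' @param weights Optional per-record weights for the Q-model (used by the
#'   doubly robust method); \code{NULL} fits an unweighted Q-model.
#' @return An \code{effect_estimates} object.
#' @export
sequential_g_direct <- function(dataset, spec = estimation_spec("seq_g"),
                                total_hat = NULL, weights = NULL) {
  stopifnot(spec$method %in% c("seq_g", "dr_seq_g"))
  confs <- spec$outcome_confounders
  check_columns(dataset, c("X", "M", "Y", confs))
  check_two_arms(dataset)
  if (is.null(total_hat)) total_hat <- estimate_total_effect(dataset)
  dat <- dataset
  if (is.null(weights)) {
    q_fit <- stats::lm(model_formula("Y", c("X", "M", confs)), data = dat)
  } else {
    check_weights(weights)
    dat$.w <- weights
    q_fit <- stats::lm(model_formula("Y", c("X", "M", confs)), data = dat,
                       weights = .w)
  }
  check_full_rank(q_fit)
  beta_m <- unname(stats::coef(q_fit)["M"])
  dat$.Yres <- dat$Y - beta_m * dat$M
  out_fit <- stats::lm(.Yres ~ X, data = dat)  # final stage unweighted
  psi <- unname(stats::coef(out_fit)["X"])
  new_effect_estimates(spec$method, spec$label, total_hat, psi,
                       b_hat = beta_m, a_hat = fit_a_path(dataset))
}

#' Doubly robust sequential g-estimation
#'
#' Combines the two nuisance models: mediator propensity weights are built
#' from \code{spec$propensity_confounders}, the Q-model (outcome on
#' treatment, mediator, \code{spec$outcome_confounders}) is fitted by
#' weighted least squares with those weights, and the residualized outcome is
#' regressed on treatment alone, unweighted. The estimate remains consistent
#' when either the propensity model or the outcome model alone omits a
#' confounder; the three one-confounder misspecification variants are
#' expressed purely through the two confounder lists in \code{spec}.
#'
#' @inheritParams regression_adjusted_direct
#' @param spec An \code{\link{estimation_spec}} with
#'   \code{method = "dr_seq_g"}.
#' @param truncate Truncate the propensity weights before the Q-model.
#'   Default \code{FALSE}.
#' @param weight_final_stage If \code{TRUE}, also weight the residual-outcome
#'   regression. Default \code{FALSE} (weights enter the Q-model only).
#' @return An \code{effect_estimates} object.
#' @export
doubly_robust_direct <- function(dataset, spec = estimation_spec("dr_seq_g"),
                                 total_hat = NULL, truncate = FALSE,
                                 weight_final_stage = FALSE) {
  stopifnot(spec$method == "dr_seq_g")
  check_columns(dataset, c("X", "M", "Y", spec$outcome_confounders,
                           spec$propensity_confounders))
  check_two_arms(dataset)
  if (is.null(total_hat)) total_hat <- estimate_total_effect(dataset)
  w <- mediator_weights(dataset, spec$propensity_confounders)
  if (truncate) w <- truncate_weights(w)
  if (!weight_final_stage) {
    return(sequential_g_direct(dataset, spec, total_hat = total_hat,
                               weights = w))
  }
  dat <- dataset
  dat$.w <- w
  q_fit <- stats::lm(model_formula("Y", c("X", "M", spec$outcome_confounders)),
                     data = dat, weights = .w)
  check_full_rank(q_fit)
  beta_m <- unname(stats::coef(q_fit)["M"])
  dat$.Yres <- dat$Y - beta_m * dat$M
  psi <- unname(stats::coef(stats::lm(.Yres ~ X, data = dat,
                                      weights = .w))["X"])
  new_effect_estimates("dr_seq_g", spec$label, total_hat, psi,
                       b_hat = beta_m, a_hat = fit_a_path(dataset))
}

#' Indirect effect as total minus direct
#'
#' @param total_hat,direct_hat Finite numeric scalars.
#' @return \code{total_hat - direct_hat}.
#' @export
indirect_effect <- function(total_hat, direct_hat) {
  if (!is.finite(total_hat) || !is.finite(direct_hat)) {
    stop("total and direct estimates must be finite", call. = FALSE)
  }
  total_hat - direct_hat
}

#' Apply a battery of estimation specifications to one dataset
#'
#' Computes the shared unadjusted total effect once, then dispatches each
#' specification to its estimator, so the methods' indirect estimates differ
#' only through the direct effect.
#'
#' @param dataset Data frame with \code{X}, \code{M}, \code{Y}, confounders.
#' @param specs Non-empty list of \code{\link{estimation_spec}} objects.
#' @return A data frame with one row per spec and columns
#'   \code{method, spec_label, total_hat, direct_hat, indirect_hat, b_hat,
#'   a_hat}.
#' @examples
#' dat <- generate_dataset(path_coefficients(a = 0.39, b = 0.59,
#'   d = 0.59, f = 0.59), seed = 7, sample_size = 500)
#' estimate_all_methods(dat, two_confounder_battery())
#' @export
estimate_all_methods <- function(dataset, specs) {
  if (!is.list(specs) || length(specs) == 0L ||
      !all(vapply(specs, inherits, logical(1), "estimation_spec"))) {
    stop("specs must be a non-empty list of estimation_spec objects",
         call. = FALSE)
  }
  total_hat <- estimate_total_effect(dataset)
  rows <- lapply(specs, function(spec) {
    est <- estimate_one(dataset, spec, total_hat)
    as.data.frame(est)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

estimate_one <- function(dataset, spec, total_hat = NULL) {
  if (!is.null(spec$estimator)) return(spec$estimator(dataset, spec, total_hat))
  switch(spec$method,
         regression = regression_adjusted_direct(dataset, spec, total_hat),
         ipw = ipw_direct(dataset, spec, truncate = FALSE, total_hat = total_hat),
         ipw_truncated = ipw_direct(dataset, spec, truncate = TRUE,
                                    total_hat = total_hat),
         seq_g = sequential_g_direct(dataset, spec, total_hat),
         dr_seq_g = doubly_robust_direct(dataset, spec, total_hat),
         stop("unknown method: ", spec$method, call. = FALSE))
}

#' Write an estimates table to CSV
#'
#' @param estimates Data frame from \code{\link{estimate_all_methods}},
#'   optionally carrying \code{ci_lower,ci_upper,significant} columns.
#' @param path File path.
#' @export
write_estimates <- function(estimates, path) {
  utils::write.csv(estimates, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
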