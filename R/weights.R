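#' Stabilized inverse-propensity weights for a continuous mediator
#'
#' Fits two ordinary least squares models for the mediator — a numerator model
#' on treatment alone and a denominator model on treatment plus the supplied
#' confounders — and weights each record by the ratio of normal densities
#' \deqn{w_i = \phi(M_i \mid X_i) / \phi(M_i \mid X_i, C_i),}
#' each density evaluated at the record's observed mediator value using that
#' model's fitted value and residual standard error. The ratio captures the
#' additional prediction contributed by the confounders over treatment alone
#' (stabilized weights); with no confounders the two models coincide and every
#' weight is exactly 1.
#'
#' @param dataset Data frame with the treatment, mediator, and confounder
#'   columns.
#' @param confounders Character vector of confounder column names used in the
#'   denominator model (possibly empty).
#' @param mediator,treatment Column names. Defaults \code{"M"} and \code{"X"}.
#' @return Numeric vector of positive weights, one per record.
#' @examples
#' dat <- generate_dataset(path_coefficients(a = 0.39, d = 0.59, f = 0.59),
#'                         seed = 1, sample_size = 200)
#' w <- mediator_weights(dat, c("C1", "C2"))
#' summary(w)
#' @export
mediator_weights <- function(dataset, confounders = character(),
                             mediator = "M", treatment = "X") {
  check_columns(dataset, c(mediator, treatment, confounders))
  if (nrow(dataset) < length(confounders) + 2L) {
    stop("too few records to fit the propensity models", call. = FALSE)
  }
  num_fit <- stats::lm(model_formula(mediator, treatment), data = dataset)
  den_fit <- stats::lm(model_formula(mediator, c(treatment, confounders)),
                       data = dataset)
  sd_num <- stats::sigma(num_fit)
  sd_den <- stats::sigma(den_fit)
  m_scale <- max(stats::sd(dataset[[mediator]]), .Machine$double.eps)
  if (!is.finite(sd_den) || sd_den <= 1e-8 * m_scale) {
    stop("degenerate denominator model: residual standard error is zero",
         call. = FALSE)
  }
  m <- dataset[[mediator]]
  w <- stats::dnorm(m, mean = stats::fitted(num_fit), sd = sd_num) /
    stats::dnorm(m, mean = stats::fitted(den_fit), sd = sd_den)
  check_weights(w)
  w
}

#' Inverse-propensity weights for a binary mediator
#'
#' Logistic-regression analogue of \code{\link{mediator_weights}}: records
#' with \code{M = 1} receive \eqn{P[M=1|X] / P[M=1|X,C]} and records with
#' \code{M = 0} receive \eqn{(1-P[M=1|X]) / (1-P[M=1|X,C])}, with the
#' numerator probabilities from a treatment-only model.
#'
#' @inheritParams mediator_weights
#' @return Numeric vector of positive weights.
#' @export
binary_mediator_weights <- function(dataset, confounders = character(),
                                    mediator = "M", treatment = "X") {
  check_columns(dataset, c(mediator, treatment, confounders))
  m <- dataset[[mediator]]
  if (!all(m %in% c(0, 1))) {
    stop("binary mediator weights require M in {0, 1}", call. = FALSE)
  }
  num_fit <- stats::glm(model_formula(mediator, treatment), data = dataset,
                        family = stats::binomial())
  den_fit <- stats::glm(model_formula(mediator, c(treatment, confounders)),
                        data = dataset, family = stats::binomial())
  p_num <- stats::fitted(num_fit)
  p_den <- stats::fitted(den_fit)
  eps <- sqrt(.Machine$double.eps)
  if (any(p_den < eps | p_den > 1 - eps)) {
    stop("positivity violation: denominator probability of 0 or 1",
         call. = FALSE)
  }
  w <- ifelse(m == 1, p_num / p_den, (1 - p_num) / (1 - p_den))
  check_weights(w)
  w
}

#' Truncate (winsorize) a weight vector at percentile caps
#'
#' Computes nearest-rank empirical percentiles of the weight vector itself and
#' caps values outside them: entries below the lower cap are raised to it,
#' entries above the upper cap are lowered to it, everything else is left
#' untouched. Caps come from the current vector, not pooled across
#' replications, and truncating twice equals truncating once.
#'
#' @param weights Numeric vector of positive weights.
#' @param lower_pct,upper_pct Percentile cut points in [0, 100],
#'   \code{lower_pct < upper_pct}. Defaults 1 and 99.
#' @return Numeric vector of the same length, order preserved.
#' @examples
#' truncate_weights(c(0.01, rep(1, 98), 100))
#' @export
truncate_weights <- function(weights, lower_pct = 1, upper_pct = 99) {
  if (length(weights) == 0L) stop("empty weight vector", call. = FALSE)
  if (!(lower_pct >= 0 && lower_pct < upper_pct && upper_pct <= 100)) {
    stop("require 0 <= lower_pct < upper_pct <= 100", call. = FALSE)
  }
  check_weights(weights)
  sorted <- sort(weights)
  lo <- sorted[nearest_rank(lower_pct / 100, length(weights))]
  hi <- sorted[nearest_rank(upper_pct / 100, length(weights))]
  pmin(pmax(weights, lo), hi)
}

# nearest-rank order statistic for probability p in [0, 1]: the smallest rank
# whose empirical CDF reaches p, clamped to [1, n]
nearest_rank <- function(p, n) {
  min(max(1L, as.integer(ceiling(p * n))), n)
}

check_weights <- function(w) {
  bad <- which(!is.finite(w) | w <= 0)
  if (length(bad)) {
    stop("non-finite or non-positive weight at record(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  invisible(w)
}

check_columns <- function(dataset, cols) {
  missing_cols <- setdiff(cols, names(dataset))
  if (length(missing_cols)) {
    stop("columns not found in dataset: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

model_formula <- function(response, predictors) {
  rhs <- if (length(predictors)) paste(predictors, collapse = " + ") else "1"
  stats::as.formula(paste(response, "~", rhs), env = baseenv())
}

#' Write per-record weight diagnostics to CSV
#'
#' Columns: \code{record_index,weight,weight_truncated}.
#'
#' @param weights Untruncated weight vector.
#' @param path File path.
#' @param lower_pct,upper_pct Truncation percentiles for the comparison column.
#' @export
write_weight_diagnostics <- function(weights, path, lower_pct = 1,
                                     upper_pct = 99) {
  utils::write.csv(
    data.frame(record_index = seq_along(weights), weight = weights,
               weight_truncated = truncate_weights(weights, lower_pct, upper_pct)),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
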