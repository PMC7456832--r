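#' Structural path coefficients of the generating model
#'
#' Bundles the unstandardized regression coefficients of the single-mediator
#' structural model with two measured confounders (\code{C1}, \code{C2}) and
#' one unmeasured standard-normal confounder \code{U}:
#' \deqn{C_1 = gX + kU + e_3, \quad C_2 = hX + nU + e_4,}
#' \deqn{M = aX + dC_1 + fC_2 + e_1, \quad Y = c'X + bM + tU + e_2,}
#' where \code{X} is a randomized binary treatment and all error terms and
#' \code{U} are independent standard normal.
#'
#' @param a Effect of treatment on the mediator (X -> M).
#' @param b Effect of the mediator on the outcome (M -> Y).
#' @param c_prime Controlled direct effect of treatment on the outcome (X -> Y).
#' @param d,f Effects of the measured confounders on the mediator (C1 -> M,
#'   C2 -> M).
#' @param g,h Effects of treatment on the measured confounders (X -> C1,
#'   X -> C2); zero makes the confounders baseline, nonzero makes them
#'   post-treatment.
#' @param k,n_coef,t Effects of the unmeasured confounder on C1, C2, and Y.
#'   Default 1.
#' @return An object of class \code{path_coefficients} (a named list).
#' @examples
#' path_coefficients(a = 0.59, b = 0.59, c_prime = 0, d = 0.59, f = 0.59,
#'                   g = 0.59, h = 0.59)
#' @export
path_coefficients <- function(a = 0, b = 0, c_prime = 0, d = 0, f = 0,
                              g = 0, h = 0, k = 1, n_coef = 1, t = 1) {
  coefs <- list(a = a, b = b, c_prime = c_prime, d = d, f = f,
                g = g, h = h, k = k, n_coef = n_coef, t = t)
  bad <- !vapply(coefs, function(x) is.numeric(x) && length(x) == 1L && is.finite(x),
                 logical(1))
  if (any(bad)) {
    stop("path coefficients must be finite scalars: ",
         paste(names(coefs)[bad], collapse = ", "), call. = FALSE)
  }
  structure(lapply(coefs, as.numeric), class = "path_coefficients")
}

#' @export
print.path_coefficients <- function(x, ...) {
  cat("Structural path coefficients:\n")
  print(unlist(x))
  invisible(x)
}

#' A single simulation condition
#'
#' @param id Character condition identifier, unique within a grid.
#' @param coefficients A \code{\link{path_coefficients}} object.
#' @param sample_size Number of records per generated dataset (>= 4).
#' @return An object of class \code{simulation_condition}.
#' @export
simulation_condition <- function(id, coefficients, sample_size = 500) {
  stopifnot(inherits(coefficients, "path_coefficients"))
  if (!is.numeric(sample_size) || length(sample_size) != 1L ||
      sample_size < 4 || sample_size != round(sample_size)) {
    stop("sample_size must be an integer >= 4", call. = FALSE)
  }
  structure(list(id = as.character(id), coefficients = coefficients,
                 sample_size = as.integer(sample_size)),
            class = "simulation_condition")
}

new_condition_grid <- function(conditions) {
  ids <- vapply(conditions, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("condition ids must be unique", call. = FALSE)
  structure(conditions, class = "condition_grid")
}

#' @export
print.condition_grid <- function(x, ...) {
  cat("Condition grid with", length(x), "conditions\n")
  print(utils::head(as.data.frame(x), 6))
  if (length(x) > 6) cat("...\n")
  invisible(x)
}

#' @export
as.data.frame.condition_grid <- function(x, ...) {
  rows <- lapply(x, function(cond) {
    cf <- cond$coefficients
    data.frame(id = cond$id, a = cf$a, b = cf$b, c_prime = cf$c_prime,
               d = cf$d, f = cf$f, g = cf$g, h = cf$h, k = cf$k,
               n = cf$n_coef, t = cf$t, sample_size = cond$sample_size,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build the factorial grid of simulation conditions
#'
#' Forms the full Cartesian product of the supplied factor levels. The two
#' confounder-to-mediator paths are set jointly (\code{d = f}) and the two
#' treatment-to-confounder paths jointly (\code{g = h}); the unmeasured
#' confounder paths are fixed at \code{k = n = t = 1}. With the default
#' levels this yields the 243-condition design (3 levels of \code{a}, \code{b},
#' \code{c'}, \code{d = f}, and \code{g = h}).
#'
#' @param a_levels Levels of the X -> M path. Default \code{c(0.14, 0.39, 0.59)}.
#' @param b_levels Levels of the M -> Y path. Default \code{c(0, 0.14, 0.59)}.
#' @param cprime_levels Levels of the direct X -> Y path.
#'   Default \code{c(0, 0.14, 0.59)}.
#' @param dm_levels Joint levels of the C1 -> M and C2 -> M paths (d = f).
#'   Default \code{c(0.14, 0.39, 0.59)}.
#' @param gx_levels Joint levels of the X -> C1 and X -> C2 paths (g = h).
#'   Default \code{c(0, 0.14, 0.59)}.
#' @param sample_size Records per dataset. Default 500.
#' @return A \code{condition_grid}: an ordered list of
#'   \code{\link{simulation_condition}} objects with zero-padded ids assigned
#'   over the lexicographic order of (a, b, c_prime, d, g).
#' @examples
#' grid <- build_condition_grid()
#' length(grid)  # 243
#' @export
build_condition_grid <- function(a_levels = c(0.14, 0.39, 0.59),
                                 b_levels = c(0, 0.14, 0.59),
                                 cprime_levels = c(0, 0.14, 0.59),
                                 dm_levels = c(0.14, 0.39, 0.59),
                                 gx_levels = c(0, 0.14, 0.59),
                                 sample_size = 500) {
  levels <- list(a = a_levels, b = b_levels, c_prime = cprime_levels,
                 d = dm_levels, g = gx_levels)
  empty <- vapply(levels, length, integer(1)) == 0L
  if (any(empty)) {
    stop("empty factor level list: ", paste(names(levels)[empty], collapse = ", "),
         call. = FALSE)
  }
  # lexicographic order of (a, b, c_prime, d, g): last factor varies fastest
  combos <- expand.grid(g = sort(gx_levels), d = sort(dm_levels),
                        c_prime = sort(cprime_levels), b = sort(b_levels),
                        a = sort(a_levels), KEEP.OUT.ATTRS = FALSE)
  combos <- combos[, c("a", "b", "c_prime", "d", "g")]
  width <- max(3L, nchar(nrow(combos)))
  conditions <- lapply(seq_len(nrow(combos)), function(i) {
    row <- combos[i, ]
    simulation_condition(
      id = sprintf(paste0("cond%0", width, "d"), i),
      coefficients = path_coefficients(a = row$a, b = row$b,
                                       c_prime = row$c_prime,
                                       d = row$d, f = row$d,
                                       g = row$g, h = row$g),
      sample_size = sample_size)
  })
  new_condition_grid(conditions)
}

#' Build the opposite-sign confounder-path grid
#'
#' The 12 supplementary conditions exploring confounder-to-mediator paths of
#' opposite (or jointly negative) signs: the six \code{(d, f)} pairs
#' \{(-0.14, 0.14), (0.14, -0.14), (-0.14, -0.14), (-0.59, 0.59),
#' (0.59, -0.59), (-0.59, -0.59)\} crossed with \code{b} in \{0, 0.59\}, all
#' with \code{a = 0.59}, \code{c' = 0}, and \code{g = h = d}.
#'
#' @param sample_size Records per dataset. Default 500.
#' @return A \code{condition_grid} of 12 conditions with ids \code{sign01} ...
#'   \code{sign12}.
#' @export
build_sign_condition_grid <- function(sample_size = 500) {
  df_pairs <- list(c(-0.14, 0.14), c(0.14, -0.14), c(-0.14, -0.14),
                   c(-0.59, 0.59), c(0.59, -0.59), c(-0.59, -0.59))
  b_levels <- c(0, 0.59)
  conditions <- list()
  i <- 0L
  for (b in b_levels) {
    for (pair in df_pairs) {
      i <- i + 1L
      conditions[[i]] <- simulation_condition(
        id = sprintf("sign%02d", i),
        coefficients = path_coefficients(a = 0.59, b = b, c_prime = 0,
                                         d = pair[1], f = pair[2],
                                         g = pair[1], h = pair[1]),
        sample_size = sample_size)
    }
  }
  new_condition_grid(conditions)
}

#' Generate one synthetic dataset from a simulation condition
#'
#' Draws \code{X ~ Bernoulli(0.5)} (randomized treatment), independent
#' standard-normal \code{U} and errors \code{e1}-\code{e4}, and builds the
#' confounders, mediator, and outcome from the structural equations. The
#' unmeasured confounder \code{U} is retained in the output for diagnostics
#' only; estimators never read it.
#'
#' @param condition A \code{\link{simulation_condition}}, or a
#'   \code{\link{path_coefficients}} object (then \code{sample_size} must be
#'   given).
#' @param seed Integer seed; the same (condition, seed) pair always yields an
#'   identical dataset.
#' @param sample_size Overrides the condition's sample size if supplied.
#' @return A data frame with columns \code{X, C1, C2, U, M, Y}.
#' @examples
#' cond <- simulation_condition("demo",
#'   path_coefficients(a = 0.39, b = 0.59, d = 0.59, f = 0.59), 500)
#' dat <- generate_dataset(cond, seed = 1)
#' @export
generate_dataset <- function(condition, seed, sample_size = NULL) {
  if (inherits(condition, "path_coefficients")) {
    if (is.null(sample_size)) {
      stop("sample_size required when passing bare coefficients", call. = FALSE)
    }
    condition <- simulation_condition("adhoc", condition, sample_size)
  }
  stopifnot(inherits(condition, "simulation_condition"))
  if (missing(seed) || is.null(seed)) stop("seed must be provided", call. = FALSE)
  n <- if (is.null(sample_size)) condition$sample_size else as.integer(sample_size)
  if (n < 1) stop("sample_size must be positive", call. = FALSE)
  cf <- condition$coefficients
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))
  X  <- stats::rbinom(n, 1L, 0.5)
  U  <- stats::rnorm(n)
  e1 <- stats::rnorm(n)
  e2 <- stats::rnorm(n)
  e3 <- stats::rnorm(n)
  e4 <- stats::rnorm(n)
  C1 <- cf$g * X + cf$k * U + e3
  C2 <- cf$h * X + cf$n_coef * U + e4
  M  <- cf$a * X + cf$d * C1 + cf$f * C2 + e1
  Y  <- cf$c_prime * X + cf$b * M + cf$t * U + e2
  data.frame(X = X, C1 = C1, C2 = C2, U = U, M = M, Y = Y)
}

#' True total, controlled direct, and indirect effects
#'
#' Path tracing on the generating model: the controlled direct effect is
#' \code{c'}; all treatment influence on \code{Y} through \code{M} sums to
#' \code{b(a + dg + fh)} (the direct X -> M path plus the X -> C1 -> M and
#' X -> C2 -> M paths); the total effect is their sum. With baseline
#' confounders (\code{g = h = 0}) the indirect effect reduces to the familiar
#' product \code{a*b}.
#'
#' @param coefficients A \code{\link{path_coefficients}} object.
#' @return A list of class \code{true_effects} with fields \code{total},
#'   \code{cde}, and \code{indirect} (\code{indirect = total - cde} exactly).
#' @examples
#' true_effects(path_coefficients(a = 0.59, b = 0.59, d = 0.59, f = 0.59,
#'                                g = 0.59, h = 0.59))$indirect  # 0.758858
#' @export
true_effects <- function(coefficients) {
  stopifnot(inherits(coefficients, "path_coefficients"))
  cf <- coefficients
  indirect <- cf$b * (cf$a + cf$d * cf$g + cf$f * cf$h)
  structure(list(total = cf$c_prime + indirect, cde = cf$c_prime,
                 indirect = indirect),
            class = "true_effects")
}

#' Derive a per-replication random seed
#'
#' Deterministic counter scheme mapping (master seed, condition index,
#' replication index) to a 31-bit seed, so replications can run in any order
#' or in parallel and still reproduce.
#'
#' @param master_seed Integer master seed of the study.
#' @param condition_index 1-based index of the condition within its grid.
#' @param replication Replication number (1-based). Default 1.
#' @return An integer in [1, 2^31 - 2].
#' @export
replication_seed <- function(master_seed, condition_index, replication = 1L) {
  m <- 2147483647  # 2^31 - 1, prime
  s <- (as.numeric(master_seed) %% m) * 1000003 +
    as.numeric(condition_index) * 10007 +
    as.numeric(replication)
  as.integer(s %% (m - 1)) + 1L
}

#' Write or read a generated dataset as CSV
#'
#' Round-trips the canonical column layout \code{X,C1,C2,U,M,Y}.
#' User-supplied tables only need \code{X}, \code{M}, \code{Y}, and any
#' confounder columns.
#'
#' @param dataset Data frame to write.
#' @param path File path.
#' @return \code{write_dataset} returns \code{path} invisibly;
#'   \code{read_dataset} returns a data frame.
#' @export
write_dataset <- function(dataset, path) {
  utils::write.csv(dataset, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  dat <- utils::read.csv(path)
  required <- c("X", "M", "Y")
  missing_cols <- setdiff(required, names(dat))
  if (length(missing_cols)) {
    stop("dataset is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!all(dat$X %in% c(0, 1))) {
    stop("treatment column X must be binary 0/1", call. = FALSE)
  }
  dat
}

#' Export a condition grid to CSV
#'
#' Columns: \code{id,a,b,c_prime,d,f,g,h,k,n,t,sample_size}.
#'
#' @param grid A \code{condition_grid}.
#' @param path File path.
#' @export
write_condition_grid <- function(grid, path) {
  utils::write.csv(as.data.frame(grid), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
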