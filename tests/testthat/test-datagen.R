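test_that("factorial grid enumerates the Cartesian product with unique ids", {
  grid <- build_condition_grid()
  expect_s3_class(grid, "condition_grid")
  expect_length(grid, 243)
  df <- as.data.frame(grid)
  expect_false(anyDuplicated(df$id) > 0)
  expect_true(all(df$d == df$f))
  expect_true(all(df$g == df$h))
  expect_true(all(df$k == 1 & df$n == 1 & df$t == 1))
  expect_true(all(df$sample_size == 500))

  # degenerate and two-level products
  expect_length(build_condition_grid(0.59, 0.14, 0, 0.39, 0), 1)
  expect_length(build_condition_grid(c(0.14, 0.59), c(0, 0.59), c(0, 0.59),
                                     c(0.14, 0.59), c(0, 0.59)), 32)
  expect_error(build_condition_grid(a_levels = numeric()), "empty")
})

test_that("grid ids follow lexicographic (a, b, c_prime, d, g) order", {
  df <- as.data.frame(build_condition_grid())
  ord <- order(df$a, df$b, df$c_prime, df$d, df$g)
  expect_identical(ord, seq_len(nrow(df)))
  expect_identical(df$id[1], "cond001")
  # deterministic: rebuilding gives the identical table
  expect_identical(df, as.data.frame(build_condition_grid()))
})

test_that("opposite-sign grid holds the 12 stated conditions", {
  grid <- build_sign_condition_grid()
  expect_length(grid, 12)
  df <- as.data.frame(grid)
  expect_true(all(df$a == 0.59))
  expect_true(all(df$c_prime == 0))
  expect_true(all(df$g == df$d & df$h == df$d))
  expect_setequal(df$b, c(0, 0.59))
  pairs <- unique(df[, c("d", "f")])
  expected <- data.frame(d = c(-0.14, 0.14, -0.14, -0.59, 0.59, -0.59),
                         f = c(0.14, -0.14, -0.14, 0.59, -0.59, -0.59))
  expect_equal(nrow(pairs), 6)
  expect_true(all(apply(expected, 1, function(p)
    any(pairs$d == p["d"] & pairs$f == p["f"]))))
})

test_that("dataset generation is deterministic, binary-treated, and complete", {
  cond <- simulation_condition("c", path_coefficients(a = 0.59, b = 0.59,
                                                      d = 0.39, f = 0.39,
                                                      g = 0.14, h = 0.14), 500)
  d1 <- generate_dataset(cond, seed = 7)
  d2 <- generate_dataset(cond, seed = 7)
  d3 <- generate_dataset(cond, seed = 8)
  expect_identical(d1, d2)
  expect_false(identical(d1, d3))
  expect_equal(nrow(d1), 500)
  expect_named(d1, c("X", "C1", "C2", "U", "M", "Y"))
  expect_true(all(d1$X %in% c(0, 1)))
  expect_false(anyNA(d1))
  expect_true(all(is.finite(as.matrix(d1))))
  expect_error(generate_dataset(cond), "seed")
  expect_error(simulation_condition("c", path_coefficients(), 2), "sample_size")
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_dataset(path_coefficients(), seed = 1, sample_size = 50))
  expect_identical(.Random.seed, before)
})

test_that("null model yields independence and the stated variances", {
  dat <- generate_dataset(path_coefficients(), seed = 11, sample_size = 100000)
  expect_lt(abs(cor(dat$X, dat$Y)), 0.05)
  expect_lt(abs(cor(dat$X, dat$M)), 0.05)
  # C1 = U + e3 and Y = U + e2: two independent unit-variance terms
  expect_equal(var(dat$C1), 2, tolerance = 0.05)
  expect_equal(var(dat$Y), 2, tolerance = 0.05)
})

test_that("large-sample slopes match the structural coefficients", {
  dat <- generate_dataset(path_coefficients(a = 0.59), seed = 5,
                          sample_size = 100000)
  slope <- coef(lm(M ~ X, data = dat))["X"]
  expect_equal(unname(slope), 0.59, tolerance = 0.02 / 0.59)

  # consistency oracle: unadjusted Y-on-X slope vs path-traced total effect
  cf <- path_coefficients(a = 0.39, b = 0.59, c_prime = 0.14, d = 0.59,
                          f = 0.59, g = 0.59, h = 0.59)
  dat <- generate_dataset(cf, seed = 6, sample_size = 100000)
  fit <- summary(lm(Y ~ X, data = dat))
  est <- fit$coefficients["X", "Estimate"]
  se <- fit$coefficients["X", "Std. Error"]
  expect_lt(abs(est - true_effects(cf)$total), 3 * se)
})

test_that("path tracing gives total, CDE, and indirect effects", {
  expect_equal(true_effects(path_coefficients(a = 1, b = 0, d = 2, g = 3))$indirect, 0)
  te <- true_effects(path_coefficients(a = 0.59, b = 0.59, c_prime = 0,
                                       d = 0.59, f = 0.59, g = 0.59, h = 0.59))
  expect_equal(te$indirect, 0.59 * (0.59 + 2 * 0.59^2))
  expect_equal(round(te$indirect, 3), 0.759)
  expect_identical(te$indirect, te$total - te$cde)
  expect_equal(true_effects(path_coefficients(a = 0.39, b = 0.59))$indirect,
               0.2301)
  expect_error(path_coefficients(a = Inf), "finite")
})

test_that("replication seeds are deterministic, in range, and distinct", {
  s <- replication_seed(1, 1, 1)
  expect_identical(s, replication_seed(1, 1, 1))
  many <- c(vapply(1:50, function(r) replication_seed(42, 3, r), integer(1)),
            vapply(1:50, function(cond) replication_seed(42, cond, 7), integer(1)))
  expect_true(all(many >= 1 & many < 2^31 - 1))
  expect_false(anyDuplicated(many[1:50]) > 0)
})

test_that("datasets and grids round-trip through CSV", {
  dat <- small_dataset(n = 50)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(dat, path)
  expect_identical(readLines(path, n = 1), "X,C1,C2,U,M,Y")
  back <- read_dataset(path)
  expect_equal(back, dat, tolerance = 1e-12)

  gpath <- withr::local_tempfile(fileext = ".csv")
  write_condition_grid(build_sign_condition_grid(), gpath)
  expect_identical(readLines(gpath, n = 1),
                   "id,a,b,c_prime,d,f,g,h,k,n,t,sample_size")
  expect_equal(nrow(read.csv(gpath)), 12)

  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(X = c(0, 2), M = 1:2, Y = 1:2), bad, row.names = FALSE)
  expect_error(read_dataset(bad), "binary")
})
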