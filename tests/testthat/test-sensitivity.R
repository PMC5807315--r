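make_samples <- function(m, defaults = default_parameters()) {
  # wrap a plain matrix as a parameter_samples object for evaluate_samples
  structure(list(matrix = m,
                 bounds = rbind(lo = apply(m, 2, min),
                                hi = apply(m, 2, max)),
                 defaults = defaults, excluded = character(), seed = NA),
            class = "parameter_samples")
}

test_that("LHS samples are bounded, stratified and seed-reproducible", {
  n <- 40
  s <- lhs_sample(n_samples = n, seed = 11)
  m <- s$matrix
  expect_equal(dim(m), c(n, 40L))
  d <- unclass(default_parameters())
  expect_true(all(sweep(m, 2, d[colnames(m)] / 2, ">=")))
  expect_true(all(sweep(m, 2, 2 * d[colnames(m)], "<=")))
  expect_equal(unname(s$bounds[, "k2"]), c(20, 80))
  # stratification: exactly one draw per equal-width bin of [d/2, 2d]
  for (j in c("k0", "k2", "e_md", "K3")) {
    u <- (m[, j] - d[[j]] / 2) / (2 * d[[j]] - d[[j]] / 2)
    expect_equal(sort(unique(ceiling(u * n))), 1:n)
  }
  s2 <- lhs_sample(n_samples = n, seed = 11)
  expect_identical(s$matrix, s2$matrix)
  s3 <- lhs_sample(n_samples = n, seed = 12)
  expect_false(identical(s$matrix, s3$matrix))
})

test_that("LHS leaves the caller's RNG stream untouched", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(lhs_sample(n_samples = 10, seed = 5))
  expect_identical(runif(1), before)
})

test_that("a zero-default parameter cannot be sampled unless excluded", {
  p0 <- glucosome_parameters(k_as = 0)
  expect_error(lhs_sample(p0, n_samples = 10, seed = 1), "default 0")
  s <- lhs_sample(p0, n_samples = 10, seed = 1, exclude = "k_as")
  expect_false("k_as" %in% colnames(s$matrix))
  expect_error(lhs_sample(n_samples = 10, seed = 1, exclude = "nope"),
               "unknown parameter")
})

test_that("evaluate_samples returns the end-time products per sample row", {
  d <- unclass(default_parameters())
  m <- matrix(rep(d, each = 3), nrow = 3,
              dimnames = list(NULL, names(d)))
  out <- evaluate_samples(make_samples(m), scenario = "LARGE", t_end = 10)
  expect_equal(dim(out), c(3L, 3L))
  expect_equal(out[1, ], out[2, ])
  ref <- product_levels_at(simulate_pathway(scenario = "LARGE",
                                            n_points = 101), 10)
  expect_equal(unname(out[1, ]), unname(ref), tolerance = 1e-6)
  expect_true(all(is.finite(out)) && all(out >= 0))
})

test_that("doubling the glycolytic-product degradation rate lowers P3", {
  base <- product_levels_at(simulate_pathway(scenario = "LARGE",
                                             n_points = 101), 10)
  pert <- product_levels_at(
    simulate_pathway(params = glucosome_parameters(delta_f = 1),
                     scenario = "LARGE", n_points = 101), 10)
  expect_lt(pert[["P3"]], base[["P3"]])
})

test_that("PRCC of a monotone identity with nothing to control for is 1", {
  set.seed(3)
  x <- matrix(runif(50), dimnames = list(NULL, "a"))
  tab <- prcc(x, matrix(x[, 1], dimnames = list(NULL, "y")))
  expect_equal(tab$prcc, 1)
  expect_equal(tab$p_value, 0)
  expect_true(tab$sensitive)
})

test_that("PRCC matches the explicit residualization oracle", {
  set.seed(42)
  n <- 200
  X <- matrix(runif(n * 5), n, 5, dimnames = list(NULL, letters[1:5]))
  y <- 2 * X[, 1] - 3 * X[, 2]^2 + X[, 3] * X[, 4] + rnorm(n, sd = 0.3)
  tab <- prcc(X, matrix(y, dimnames = list(NULL, "y")))
  expect_equal(tab$prcc, oracle_prcc(X, y), tolerance = 1e-10)
})

test_that("PRCC is invariant under strictly monotone parameter transforms", {
  set.seed(8)
  n <- 150
  X <- matrix(runif(n * 4), n, 4, dimnames = list(NULL, letters[1:4]))
  y <- X[, 1] - X[, 2] + rnorm(n, sd = 0.2)
  t1 <- prcc(X, matrix(y, dimnames = list(NULL, "y")))
  X2 <- X
  X2[, 1] <- exp(X2[, 1])
  X2[, 3] <- X2[, 3]^3
  t2 <- prcc(X2, matrix(y, dimnames = list(NULL, "y")))
  expect_equal(t1$prcc, t2$prcc, tolerance = 1e-12)
})

test_that("an inert parameter shows no partial correlation", {
  set.seed(5)
  n <- 1000
  X <- matrix(runif(n * 5), n, 5,
              dimnames = list(NULL, c(letters[1:4], "inert")))
  y <- X[, 1] + 0.5 * X[, 2] - X[, 3] + 0.2 * X[, 4] + rnorm(n, sd = 0.1)
  tab <- prcc(X, matrix(y, dimnames = list(NULL, "y")))
  inert <- tab[tab$parameter == "inert", ]
  expect_lt(abs(inert$prcc), 0.1)
  expect_gt(inert$p_value, 0.01)
  expect_false(inert$sensitive)
})

test_that("a constant parameter column yields an NA, non-sensitive PRCC with a warning", {
  set.seed(6)
  n <- 50
  X <- matrix(runif(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "flat")))
  X[, "flat"] <- 1
  y <- X[, 1] + rnorm(n, sd = 0.1)
  expect_warning(tab <- prcc(X, matrix(y, dimnames = list(NULL, "y"))),
                 "constant")
  flat <- tab[tab$parameter == "flat", ]
  expect_true(is.na(flat$prcc))
  expect_false(flat$sensitive)
})

test_that("sensitivity classification needs both magnitude and significance", {
  tab <- data.frame(parameter = c("a", "b", "c"), product = "P1",
                    prcc = c(0.3, 0.15, -0.5),
                    p_value = c(0.001, 1e-6, 0.5))
  tab <- classify_sensitive(tab, threshold = 0.2, alpha = 0.01)
  expect_equal(tab$sensitive, c(TRUE, FALSE, FALSE))
})

test_that("prcc rejects too-small sample counts", {
  X <- matrix(runif(20), 5, 4, dimnames = list(NULL, letters[1:4]))
  expect_error(prcc(X, matrix(runif(5))), "n_samples")
})

test_that("finite-difference sensitivities have the expected signs at the defaults", {
  fd <- finite_difference_sensitivity("delta_f", scenario = "LARGE")
  expect_lt(fd[["P3"]], 0)
  fd2 <- finite_difference_sensitivity("k_p", scenario = "LARGE")
  expect_gt(fd2[["P1"]], 0)
})
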