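make_toy_dataset <- function(n, seed = 1, noise = 0, beta = NULL) {
  set.seed(seed)
  x <- matrix(stats::runif(n * 8, 0, 2), n, 8,
              dimnames = list(NULL, stentml:::FEATURE_NAMES))
  if (is.null(beta)) beta <- seq(0.5, 4, length.out = 8)
  y <- 2 + drop(x %*% beta) + stats::rnorm(n, sd = noise)
  make_dataset(as.data.frame(x), y)
}

test_that("linear regression recovers exact linear maps and constants", {
  ds <- make_toy_dataset(40, seed = 2, noise = 0)
  fit <- fit_lr(ds)
  expect_equal(unname(fit$coefficients),
               c(2, seq(0.5, 4, length.out = 8)), tolerance = 1e-8)
  expect_equal(predict(fit, ds), ds$y, tolerance = 1e-8)

  const <- make_dataset(as.data.frame(matrix(stats::runif(160), 20, 8,
    dimnames = list(NULL, stentml:::FEATURE_NAMES))), rep(5, 20))
  fitc <- fit_lr(const)
  expect_equal(unname(fitc$coefficients[1]), 5, tolerance = 1e-10)
  expect_equal(unname(fitc$coefficients[-1]), rep(0, 8), tolerance = 1e-8)
})

test_that("linear regression matches the normal-equations oracle", {
  ds <- make_toy_dataset(20, seed = 3, noise = 0.3)
  fit <- fit_lr(ds)
  X <- cbind(1, ds$x)
  beta_ne <- solve(t(X) %*% X, t(X) %*% ds$y)
  expect_equal(unname(fit$coefficients), unname(drop(beta_ne)), tolerance = 1e-8)
  expect_equal(predict(fit, ds), drop(X %*% beta_ne), tolerance = 1e-8)
})

test_that("rank-deficient designs fall back with a warning", {
  ds <- make_toy_dataset(25, seed = 4, noise = 0.1)
  ds$x[, "area_f"] <- ds$x[, "area_a"]   # exact collinearity
  expect_warning(fit <- fit_lr(ds), "rank-deficient")
  expect_true(all(is.finite(predict(fit, ds))))
})

test_that("linear regression recovers known coefficients within 3 SE", {
  beta <- c(1.5, -2, 0.8, 3, -0.5, 1, 2.5, -1.2)
  hits <- 0
  for (rep_i in 1:100) {
    set.seed(1000 + rep_i)
    x <- matrix(stats::rnorm(60 * 8), 60, 8,
                dimnames = list(NULL, stentml:::FEATURE_NAMES))
    y <- 1 + drop(x %*% beta) + stats::rnorm(60, sd = 0.5)
    fit <- fit_lr(make_dataset(as.data.frame(x), y))
    se <- summary(fit$lm)$coefficients[-1, "Std. Error"]
    est <- fit$coefficients[-1]
    if (all(abs(est - beta) <= 3 * se)) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("SVR respects the insensitive tube on noiseless linear data", {
  ds <- make_toy_dataset(30, seed = 5, noise = 0)
  spec <- model_spec("SVR", "linear", cost = 100, epsilon = 0.01)
  fit <- fit_svr(ds, spec)
  resid <- abs(predict(fit, ds) - ds$y)
  # residuals bounded by the tube width (on the standardized target scale)
  expect_lt(max(resid / stats::sd(ds$y)), 0.01 + 0.01)

  const <- make_dataset(as.data.frame(matrix(stats::runif(160), 20, 8,
    dimnames = list(NULL, stentml:::FEATURE_NAMES))), rep(5, 20))
  for (k in c("linear", "polynomial", "rbf")) {
    fitc <- fit_svr(const, model_spec("SVR", k))
    expect_equal(predict(fitc, const), rep(5, 20), tolerance = 1e-6)
  }
})

test_that("SVR matches an independent QP solve of the dual", {
  set.seed(6)
  x1 <- sort(stats::runif(15, -2, 2))
  y <- sin(x1) + 0.1 * stats::rnorm(15)
  C <- 10; eps <- 0.05; gamma <- 0.5
  ds <- make_dataset(pad_single_feature(x1), y)

  for (kern in c("linear", "rbf")) {
    kfun <- if (kern == "linear") function(u, v) sum(u * v)
            else function(u, v) exp(-gamma * sum((u - v)^2))
    fit <- fit_svr(ds, model_spec("SVR", kern, cost = C, epsilon = eps,
                                  gamma = gamma, scaling = FALSE,
                                  solver_tolerance = 1e-7))
    oracle <- svr_qp_oracle(matrix(x1, ncol = 1), y, C, eps, kfun)
    grid <- seq(-2, 2, length.out = 21)
    expect_equal(predict(fit, as.matrix(pad_single_feature(grid))),
                 oracle$predict(matrix(grid, ncol = 1)), tolerance = 1e-4)
  }
})

test_that("standardized SVR predictions are invariant to feature rescaling", {
  fx <- make_fixture("small", seed = 2)
  ds <- make_dataset(fx$features, fx$labels)
  tr <- segment_split(ds, 9)
  for (kern in c("linear", "polynomial", "rbf")) {
    spec <- model_spec("SVR", kern, scaling = TRUE)
    p1 <- predict(fit_svr(tr$train, spec), tr$test)
    scaled <- tr
    scale_by <- rep(c(1000, 0.001), length.out = 8)
    scaled$train$x <- sweep(tr$train$x, 2, scale_by, "*")
    scaled$test$x <- sweep(tr$test$x, 2, scale_by, "*")
    p2 <- predict(fit_svr(scaled$train, spec), scaled$test)
    expect_equal(p1, p2, tolerance = 1e-6)
  }
})

test_that("evaluation arithmetic follows the percentage-error definition", {
  ds <- make_toy_dataset(10, seed = 7, noise = 0)
  fit <- fit_lr(ds)
  rep0 <- evaluate_model(fit, ds)
  expect_equal(rep0$bias, 0, tolerance = 1e-6)
  expect_equal(rep0$error_range, c(0, 0), tolerance = 1e-6)
  expect_equal(rep0$max_area_diff, 0, tolerance = 1e-6)

  # hand-computed three-slice report via a mocked perfect model
  truth <- c(4, 5, 8)
  preds <- c(5, 4.5, 8)
  mock <- structure(list(preds = preds), class = "mock_model")
  predict.mock_model <- function(object, newdata, ...) object$preds
  registerS3method("predict", "mock_model", predict.mock_model,
                   envir = asNamespace("stats"))
  td <- make_toy_dataset(3, seed = 8)
  td$y <- truth
  reph <- evaluate_model(mock, td)
  expect_equal(reph$per_slice_pct_error, c(25, -10, 0))
  expect_equal(reph$bias, 5)
  expect_equal(reph$error_range, c(-10, 25))
  expect_equal(reph$max_area_diff, 1)
  expect_true(reph$bias >= reph$error_range[1] && reph$bias <= reph$error_range[2])

  # scale consistency: doubling pred and true keeps % errors, doubles areas
  td2 <- td; td2$y <- 2 * truth
  mock2 <- structure(list(preds = 2 * preds), class = "mock_model")
  rep2 <- evaluate_model(mock2, td2)
  expect_equal(rep2$per_slice_pct_error, reph$per_slice_pct_error)
  expect_equal(rep2$max_area_diff, 2 * reph$max_area_diff)

  td$y[2] <- -1
  expect_error(evaluate_model(fit, td), "positive")
})

test_that("segment and random splits implement the protocol", {
  fx <- make_fixture("small", seed = 3)
  ds <- make_dataset(fx$features, fx$labels)
  sp <- segment_split(ds, 9)
  expect_equal(nrow(sp$train$x), 9)
  expect_equal(nrow(sp$test$x), 3)
  expect_identical(sp$train$slice_index, 1:9)
  expect_error(segment_split(ds, 0), "n_train")
  expect_error(segment_split(ds, 12), "n_train")

  r1 <- random_split(ds, 8, seed = 4)
  r2 <- random_split(ds, 8, seed = 4)
  expect_identical(r1$train$slice_index, r2$train$slice_index)
  expect_identical(sort(c(r1$train$slice_index, r1$test$slice_index)), 1:12)
  r3 <- random_split(ds, 11, seed = 4)
  expect_equal(length(r3$test$y), 1)
})

test_that("feature subgroups select the canonical columns", {
  fx <- make_fixture("small", seed = 5)
  ds <- make_dataset(fx$features, fx$labels)
  expect_equal(ncol(subgroup(ds, "all")$x), 8)
  expect_identical(colnames(subgroup(ds, "stretch")$x),
                   c("area_l", "arclength_c", "arclength_f"))
  expect_identical(colnames(subgroup(ds, "calcification")$x),
                   c("area_c", "angle_c", "thickness_c"))
  expect_error(subgroup(ds, "lipid"), "arg")
  broken <- ds
  broken$x <- ds$x[, setdiff(colnames(ds$x), "thickness_c")]
  expect_error(subgroup(broken, "calcification"), "thickness_c")
})

test_that("group comparison reproduces hand-computed ANOVA and t statistics", {
  # textbook three-group one-way ANOVA, computed by hand from the
  # between/within mean squares
  g1 <- c(6, 8, 4, 5, 3, 4)
  g2 <- c(8, 12, 9, 11, 6, 8)
  g3 <- c(13, 9, 11, 8, 7, 12)
  grand <- mean(c(g1, g2, g3))
  ssb <- 6 * ((mean(g1) - grand)^2 + (mean(g2) - grand)^2 + (mean(g3) - grand)^2)
  ssw <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2) + sum((g3 - mean(g3))^2)
  f_hand <- (ssb / 2) / (ssw / 15)
  st <- compare_groups(list(a = g1, b = g2, c = g3))
  expect_equal(st$anova$F, f_hand, tolerance = 1e-10)
  expect_equal(st$anova$df_between, 2)
  expect_equal(st$anova$df_within, 15)

  # pooled-variance t statistic by hand
  sp2 <- (5 * stats::var(g1) + 5 * stats::var(g2)) / 10
  t_hand <- (mean(g1) - mean(g2)) / sqrt(sp2 * (1 / 6 + 1 / 6))
  pw <- st$pairwise
  expect_equal(pw$t[pw$group1 == "a" & pw$group2 == "b"], t_hand,
               tolerance = 1e-10)

  # identical error vectors: F = 0 and t = 0
  same <- compare_groups(list(x = g1, y = g1, z = g1))
  expect_equal(same$anova$F, 0)
  expect_equal(same$pairwise$t, rep(0, 3))

  expect_error(compare_groups(list(g1)), "two groups")
  expect_error(compare_groups(list(a = 1, b = 2)), "two observations")
})
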