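#' Assemble a regression dataset
#'
#' Pairs the eight pre-stenting features with the post-stenting lumen
#' area labels.
#'
#' @param features data frame containing the eight canonical feature
#'   columns (`area_a`, `area_f`, `area_c`, `area_l`, `angle_c`,
#'   `thickness_c`, `arclength_c`, `arclength_f`) and optionally
#'   `slice_index`.
#' @param y numeric vector of post-stenting lumen areas, mm^2.
#' @return Object of class `stent_dataset`: list with `x` (numeric matrix,
#'   named columns), `y`, `slice_index`.
#' @export
make_dataset <- function(features, y) {
  stopifnot(is.data.frame(features), nrow(features) == length(y))
  missing_cols <- setdiff(FEATURE_NAMES, names(features))
  if (length(missing_cols))
    stop("missing feature column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  x <- as.matrix(features[, FEATURE_NAMES])
  if (anyNA(x) || anyNA(y)) stop("dataset contains missing values", call. = FALSE)
  idx <- if ("slice_index" %in% names(features)) features$slice_index
         else seq_len(nrow(features))
  structure(list(x = x, y = as.numeric(y), slice_index = idx),
            class = "stent_dataset")
}

#' @export
print.stent_dataset <- function(x, ...) {
  cat(sprintf("<stent_dataset> %d slices x %d features\n",
              nrow(x$x), ncol(x$x)))
  invisible(x)
}

dataset_subset <- function(data, rows) {
  structure(list(x = data$x[rows, , drop = FALSE], y = data$y[rows],
                 slice_index = data$slice_index[rows]),
            class = "stent_dataset")
}

#' Model specification for the regression stage
#'
#' @param family `"LR"` (ordinary least squares) or `"SVR"`
#'   (epsilon-insensitive support vector regression, soft-margin form).
#' @param kernel SVR kernel: `"linear"`, `"polynomial"` or `"rbf"`.
#' @param cost soft-margin regularization weight C (> 0).
#' @param epsilon half-width of the insensitive tube (on standardized
#'   targets when `scaling = TRUE`).
#' @param degree polynomial kernel degree.
#' @param gamma kernel scale for polynomial/rbf kernels; `NULL` uses
#'   1/n_features (on standardized features this is the usual
#'   1/(n_features * variance) heuristic).
#' @param scaling standardize features and target before fitting
#'   (predictions are returned on the original scale).
#' @param solver_tolerance termination tolerance of the SVR solver.
#' @param seed stored for reproducibility metadata (the solvers used are
#'   deterministic).
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(family = c("SVR", "LR"),
                       kernel = c("rbf", "linear", "polynomial"),
                       cost = 1, epsilon = 0.1, degree = 3, gamma = NULL,
                       scaling = TRUE, solver_tolerance = 0.001, seed = 1L) {
  family <- match.arg(family)
  kernel <- match.arg(kernel)
  stopifnot(cost > 0, epsilon >= 0, degree >= 1,
            is.null(gamma) || gamma > 0, solver_tolerance > 0)
  structure(list(family = family,
                 kernel = if (family == "SVR") kernel else NULL,
                 cost = cost, epsilon = epsilon, degree = degree,
                 gamma = gamma, scaling = scaling,
                 solver_tolerance = solver_tolerance, seed = as.integer(seed)),
            class = "model_spec")
}

#' Fit the linear regression model
#'
#' Ordinary least squares with an intercept (the correction term), fitted
#' on the raw feature scale. A rank-deficient design yields the pivoted
#' least-squares solution with the aliased coefficients set to zero, with
#' a warning.
#'
#' @param train a [make_dataset()] object.
#' @return Object of class `stent_lr`.
#' @export
fit_lr <- function(train) {
  stopifnot(inherits(train, "stent_dataset"))
  if (nrow(train$x) < ncol(train$x) + 1)
    stop("need at least n_features + 1 training rows", call. = FALSE)
  df <- data.frame(train$x, y = train$y)
  fit <- stats::lm(y ~ ., data = df)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    warning("rank-deficient design; aliased coefficients set to zero")
    cf[is.na(cf)] <- 0
  }
  structure(list(coefficients = cf, lm = fit,
                 features = colnames(train$x)),
            class = "stent_lr")
}

#' @export
predict.stent_lr <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "stent_dataset")) newdata$x else as.matrix(newdata)
  x <- x[, object$features, drop = FALSE]
  drop(cbind(1, x) %*% object$coefficients)
}

#' Fit a support vector regression model
#'
#' Epsilon-insensitive SVR in the standard soft-margin form (slack
#' variables with weight `cost`), with linear, polynomial or radial basis
#' function kernel. Features and target are standardized before fitting
#' when the spec requests it; predictions are de-standardized. The solver
#' (libsvm via \pkg{e1071}) is deterministic for given data and spec.
#'
#' @param train a [make_dataset()] object.
#' @param spec a [model_spec()] with `family = "SVR"`.
#' @return Object of class `stent_svr`.
#' @export
fit_svr <- function(train, spec = model_spec("SVR", "rbf")) {
  stopifnot(inherits(train, "stent_dataset"), inherits(spec, "model_spec"))
  if (spec$family != "SVR") stop("spec is not an SVR spec", call. = FALSE)
  kern <- switch(spec$kernel, linear = "linear", polynomial = "polynomial",
                 rbf = "radial")
  gamma <- if (is.null(spec$gamma)) 1 / ncol(train$x) else spec$gamma
  if (stats::sd(train$y) < 1e-12) {
    # degenerate constant target: every kernel predicts the constant
    return(structure(list(svm = NULL, constant = train$y[1], spec = spec,
                          features = colnames(train$x)),
                     class = "stent_svr"))
  }
  # constant columns cannot be standardized by libsvm; drop scaling for them
  scale_flags <- if (isTRUE(spec$scaling))
    apply(train$x, 2, function(v) stats::sd(v) > 1e-12) else FALSE
  fit <- e1071::svm(x = train$x, y = train$y, type = "eps-regression",
                    kernel = kern, cost = spec$cost, epsilon = spec$epsilon,
                    gamma = gamma, degree = spec$degree, coef0 = 0,
                    scale = scale_flags, tolerance = spec$solver_tolerance)
  structure(list(svm = fit, spec = spec, features = colnames(train$x)),
            class = "stent_svr")
}

#' @export
predict.stent_svr <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "stent_dataset")) newdata$x else as.matrix(newdata)
  x <- x[, object$features, drop = FALSE]
  if (is.null(object$svm)) return(rep(object$constant, nrow(x)))
  unname(stats::predict(object$svm, x))
}

#' Evaluate a fitted model on a test set
#'
#' Per-slice signed percentage errors `100 * (pred - true) / true`, their
#' mean (the bias), their range, and the maximum absolute area difference.
#'
#' @param model a fitted `stent_lr` or `stent_svr`.
#' @param test a [make_dataset()] object with positive labels.
#' @param label optional name recorded in the report.
#' @return Object of class `evaluation_report`: list with
#'   `per_slice_pct_error`, `bias`, `error_range` (min, max),
#'   `max_area_diff`, `n_test`, `label`.
#' @export
evaluate_model <- function(model, test, label = NULL) {
  stopifnot(inherits(test, "stent_dataset"), length(test$y) >= 1)
  if (any(test$y <= 0)) stop("labels must be positive areas", call. = FALSE)
  pred <- stats::predict(model, test)
  err <- 100 * (pred - test$y) / test$y
  if (any(!is.finite(err))) stop("non-finite prediction errors", call. = FALSE)
  structure(list(per_slice_pct_error = err,
                 bias = mean(err),
                 error_range = c(min(err), max(err)),
                 max_area_diff = max(abs(pred - test$y)),
                 predictions = pred, truth = test$y,
                 slice_index = test$slice_index,
                 n_test = length(err), label = label),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report>%s %d test slices\n",
              if (!is.null(x$label)) paste0(" [", x$label, "]") else "",
              x$n_test))
  cat(sprintf("  bias %+.2f%%; range [%+.2f%%, %+.2f%%]; max area diff %.3f mm^2\n",
              x$bias, x$error_range[1], x$error_range[2], x$max_area_diff))
  invisible(x)
}

#' Segment train/test split
#'
#' The first `n_train` slices (in axial order) form the training set and
#' the remainder the test set, matching the segment protocol (90 training
#' and 30 test slices for a 120-slice vessel).
#'
#' @param data a [make_dataset()] object.
#' @param n_train number of leading training rows (0 < n_train < n).
#' @return List with `train` and `test` datasets.
#' @export
segment_split <- function(data, n_train = 90) {
  stopifnot(inherits(data, "stent_dataset"))
  n <- nrow(data$x)
  if (n_train <= 0 || n_train >= n)
    stop("n_train must satisfy 0 < n_train < n", call. = FALSE)
  list(train = dataset_subset(data, seq_len(n_train)),
       test = dataset_subset(data, seq.int(n_train + 1, n)))
}

#' Random train/test split
#'
#' Uniform random subset without replacement, seeded and deterministic.
#'
#' @inheritParams segment_split
#' @param seed integer seed.
#' @return List with `train` and `test` datasets.
#' @export
random_split <- function(data, n_train, seed = 1L) {
  stopifnot(inherits(data, "stent_dataset"))
  n <- nrow(data$x)
  if (n_train <= 0 || n_train >= n)
    stop("n_train must satisfy 0 < n_train < n", call. = FALSE)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  tr <- sort(sample.int(n, n_train))
  list(train = dataset_subset(data, tr),
       test = dataset_subset(data, setdiff(seq_len(n), tr)))
}

#' Feature subgroups
#'
#' Column-filters a dataset to the stretch features (`area_l`,
#' `arclength_c`, `arclength_f`), the calcification features (`area_c`,
#' `angle_c`, `thickness_c`), or all eight features.
#'
#' @param data a [make_dataset()] object.
#' @param group `"all"`, `"stretch"` or `"calcification"`.
#' @return A filtered `stent_dataset`.
#' @export
subgroup <- function(data, group = c("all", "stretch", "calcification")) {
  stopifnot(inherits(data, "stent_dataset"))
  group <- match.arg(group)
  cols <- switch(group,
                 all = FEATURE_NAMES,
                 stretch = c("area_l", "arclength_c", "arclength_f"),
                 calcification = c("area_c", "angle_c", "thickness_c"))
  missing_cols <- setdiff(cols, colnames(data$x))
  if (length(missing_cols))
    stop("dataset lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  structure(list(x = data$x[, cols, drop = FALSE], y = data$y,
                 slice_index = data$slice_index),
            class = "stent_dataset")
}

#' Compare prediction-error groups
#'
#' One-way fixed-effects ANOVA across the per-slice signed percentage
#' errors of two or more evaluation reports, plus two-sided pooled-variance
#' t-tests for every pair. Significance threshold 0.05.
#'
#' @param reports named list of `evaluation_report` objects (or numeric
#'   error vectors).
#' @return List with `anova` (`F`, `p`, degrees of freedom) and `pairwise`
#'   (data frame of `t`, `p` per pair).
#' @export
compare_groups <- function(reports) {
  errs <- lapply(reports, function(r)
    if (inherits(r, "evaluation_report")) r$per_slice_pct_error else as.numeric(r))
  if (length(errs) < 2) stop("need at least two groups", call. = FALSE)
  if (any(vapply(errs, length, integer(1)) < 2))
    stop("each group needs at least two observations", call. = FALSE)
  nm <- names(errs)
  if (is.null(nm)) nm <- paste0("group", seq_along(errs))
  df <- data.frame(err = unlist(errs),
                   grp = factor(rep(nm, vapply(errs, length, integer(1))),
                                levels = nm))
  av <- stats::anova(stats::lm(err ~ grp, data = df))
  pairs <- utils::combn(seq_along(errs), 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    tt <- stats::t.test(errs[[i]], errs[[j]], var.equal = TRUE)
    data.frame(group1 = nm[i], group2 = nm[j],
               t = unname(tt$statistic), p = tt$p.value)
  }))
  list(anova = list(F = av$`F value`[1], p = av$`Pr(>F)`[1],
                    df_between = av$Df[1], df_within = av$Df[2]),
       pairwise = pw, alpha = 0.05)
}
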