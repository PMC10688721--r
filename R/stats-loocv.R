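#' Leave-one-out cross-validated classifier scores
#'
#' For each eye, a ridge logistic model is fitted on the remaining n - 1
#' eyes and the held-out eye receives its out-of-fold linear predictor.
#' Standardization and (when requested) penalty selection happen inside
#' each training fold, so the held-out eye's features and label never
#' influence its own score.
#'
#' The penalty policy is either a fixed `lambda` (default 1.0 on
#' standardized features) or, with `lambda_policy = "cv"`, an inner
#' stratified 5-fold cross-validation within each training fold choosing
#' the `lambda_grid` value with the smallest out-of-fold binomial
#' deviance.
#'
#' @param table Cohort tibble with a `sex` column (both levels present),
#'   optionally `id`, and the feature columns.
#' @param lambda_policy `"fixed"` or `"cv"`.
#' @param lambda Penalty used under the fixed policy.
#' @param lambda_grid Candidate penalties under the CV policy.
#' @param features Feature columns; defaults to the 54 canonical names.
#' @param positive Positive class label (default `"female"`).
#' @param inner_seed Seed for the inner CV fold assignment (used only
#'   under the CV policy).
#' @return Tibble with columns `id`, `sex`, `score` (out-of-fold linear
#'   predictor) and `lambda` (penalty used in that fold).
#' @export
loocv_scores <- function(table, lambda_policy = c("fixed", "cv"),
                         lambda = 1, lambda_grid = 10^seq(-2, 3, by = 1),
                         features = fundus_feature_names(),
                         positive = "female", inner_seed = 1L) {
  lambda_policy <- match.arg(lambda_policy)
  stopifnot("sex" %in% names(table))
  missing <- setdiff(features, names(table))
  if (length(missing) > 0) {
    stop(sprintf("table is missing feature column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  n <- nrow(table)
  if (n < 10) stop("need at least 10 rows for leave-one-out scoring",
                   call. = FALSE)
  x <- as.matrix(table[, features])
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) {
    stop("feature columns contain missing or non-finite values", call. = FALSE)
  }
  y <- encode_binary(table$sex, positive)
  if (length(unique(y)) < 2) {
    stop("both classes must be present", call. = FALSE)
  }
  ids <- if ("id" %in% names(table)) table$id else as.character(seq_len(n))

  score <- numeric(n)
  lam_used <- numeric(n)
  for (i in seq_len(n)) {
    xt <- x[-i, , drop = FALSE]
    yt <- y[-i]
    if (length(unique(yt)) < 2) {
      stop("a leave-one-out training fold lost one class entirely",
           call. = FALSE)
    }
    lam <- if (lambda_policy == "fixed") {
      lambda
    } else {
      select_lambda_cv(xt, yt, lambda_grid, seed = inner_seed + i)
    }
    fit <- suppressWarnings(
      fit_ridge_logistic(xt, yt, lambda = lam, positive = "1")
    )
    score[i] <- predict(fit, x[i, , drop = FALSE])
    lam_used[i] <- lam
  }
  tibble::tibble(id = ids, sex = table$sex, score = score, lambda = lam_used)
}

## inner stratified k-fold CV: pick the grid lambda with the smallest
## held-out binomial deviance
select_lambda_cv <- function(x, y, lambda_grid, k = 5, seed = 1L) {
  folds <- with_seed(seed, stratified_folds(y, k))
  dev <- vapply(lambda_grid, function(lam) {
    d <- 0
    for (f in seq_len(k)) {
      test <- folds == f
      if (!any(test) || length(unique(y[!test])) < 2) next
      fit <- suppressWarnings(
        fit_ridge_logistic(x[!test, , drop = FALSE], y[!test],
                           lambda = lam, positive = "1")
      )
      p <- predict(fit, x[test, , drop = FALSE], type = "response")
      p <- pmin(1 - 1e-12, pmax(1e-12, p))
      d <- d - 2 * sum(y[test] * log(p) + (1 - y[test]) * log(1 - p))
    }
    d
  }, numeric(1))
  lambda_grid[which.min(dev)]
}

stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}
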