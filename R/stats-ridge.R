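#' Ridge (L2-regularized) binomial logistic regression
#'
#' Maximizes the penalized binomial log-likelihood
#' \deqn{\sum_i [y_i \eta_i - \log(1 + e^{\eta_i})] - \lambda \sum_j \beta_j^2}
#' over the coefficients, where \eqn{\eta_i} is the linear predictor of
#' row i. The intercept is unpenalized; predictors are standardized to
#' mean 0, SD 1 on the training rows (the penalty is applied on that
#' scale) and the standardization constants are stored in the fit. With
#' `lambda = 0` the fit coincides with ordinary maximum-likelihood
#' logistic regression.
#'
#' The concave objective is maximized by damped Newton iterations
#' (step-halving whenever a full step fails to improve the objective),
#' declared converged when the gradient's maximum absolute entry falls
#' below `tol`. With `lambda = 0` and separable classes the coefficients
#' diverge; this is reported as non-convergence (with a warning), never
#' silently clipped.
#'
#' @param x Numeric matrix (or data frame of numeric columns), n rows of
#'   p predictors, n >= 4.
#' @param y Binary labels: logical, 0/1, or a two-level factor/character
#'   vector; `positive` names the class coded 1.
#' @param lambda Nonnegative penalty.
#' @param positive Label of the positive class when `y` is not already
#'   0/1 (default `"female"`).
#' @param standardize Standardize predictors before penalizing
#'   (default `TRUE`).
#' @param max_iter,tol Newton iteration cap and gradient tolerance.
#' @return An object of class `ridge_logit` with elements `intercept`,
#'   `coefficients` (standardized scale), `lambda`, `center`, `scale`,
#'   `converged`, `iterations`, `objective`.
#' @export
fit_ridge_logistic <- function(x, y, lambda = 1, positive = "female",
                               standardize = TRUE, max_iter = 200,
                               tol = 1e-8) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y01 <- encode_binary(y, positive)
  n <- nrow(x); p <- ncol(x)
  if (n < 4) stop("need at least 4 rows", call. = FALSE)
  if (length(y01) != n) stop("x and y lengths differ", call. = FALSE)
  if (length(unique(y01)) < 2) {
    stop("both classes must be present in y", call. = FALSE)
  }
  if (lambda < 0) stop("lambda must be nonnegative", call. = FALSE)

  if (standardize) {
    center <- colMeans(x)
    scale <- apply(x, 2, stats::sd)
    scale[scale == 0] <- 1       # constant columns carry no information
  } else {
    center <- rep(0, p)
    scale <- rep(1, p)
  }
  z <- sweep(sweep(x, 2, center), 2, scale, "/")
  zi <- cbind(1, z)

  objective <- function(beta) {
    eta <- drop(zi %*% beta)
    ## numerically stable log(1 + e^eta) = max(eta, 0) + log1p(e^-|eta|)
    log1pe <- pmax(eta, 0) + log1p(exp(-abs(eta)))
    sum(y01 * eta - log1pe) - lambda * sum(beta[-1]^2)
  }

  beta <- c(stats::qlogis(mean(y01)), rep(0, p))
  obj <- objective(beta)
  converged <- FALSE
  iter <- 0L
  pen <- c(0, rep(2 * lambda, p))
  repeat {
    iter <- iter + 1L
    eta <- drop(zi %*% beta)
    mu <- stats::plogis(eta)
    grad <- drop(crossprod(zi, y01 - mu)) - pen * beta
    if (max(abs(grad)) < tol) {
      converged <- TRUE
      break
    }
    if (iter > max_iter) break
    w <- pmax(mu * (1 - mu), 1e-12)
    hess <- crossprod(zi * w, zi)
    diag(hess) <- diag(hess) + pen
    step <- tryCatch(solve(hess, grad), error = function(e) NULL)
    if (is.null(step)) break
    ## damping: halve until the objective improves
    t <- 1
    repeat {
      cand <- beta + t * step
      ocand <- objective(cand)
      if (is.finite(ocand) && ocand >= obj - 1e-12) break
      t <- t / 2
      if (t < 1e-10) break
    }
    if (t < 1e-10) break
    beta <- cand
    obj <- ocand
  }
  ## with lambda = 0 and separable classes the likelihood is maximized
  ## only as the coefficients diverge; the gradient still vanishes along
  ## the way, so detect separation by all residuals collapsing to zero
  if (lambda == 0 &&
      max(abs(y01 - stats::plogis(drop(zi %*% beta)))) < 1e-6) {
    converged <- FALSE
    warning(paste(
      "lambda = 0 with (quasi-)separable classes: the unpenalized MLE",
      "diverges; coefficients reported at the last iterate"
    ), call. = FALSE)
  } else if (!converged) {
    warning("ridge logistic fit did not converge", call. = FALSE)
  }
  structure(
    list(intercept = unname(beta[1]),
         coefficients = rlang::set_names(unname(beta[-1]), colnames(x)),
         lambda = lambda, center = center, scale = scale,
         positive = if (is.character(positive)) positive else "1",
         converged = converged, iterations = iter, objective = obj,
         n = n),
    class = "ridge_logit"
  )
}

encode_binary <- function(y, positive) {
  if (is.logical(y)) return(as.numeric(y))
  if (is.numeric(y)) {
    if (!all(y %in% c(0, 1))) stop("numeric y must be 0/1", call. = FALSE)
    return(as.numeric(y))
  }
  as.numeric(as.character(y) == positive)
}

#' @export
print.ridge_logit <- function(x, ...) {
  cat(sprintf(
    "ridge_logit: %d predictors, lambda = %g, %sconverged in %d iterations\n",
    length(x$coefficients), x$lambda, if (x$converged) "" else "NOT ",
    x$iterations
  ))
  invisible(x)
}

#' Predict from a ridge logistic fit
#'
#' @param object A `ridge_logit` fit.
#' @param newdata Matrix or data frame with the training columns.
#' @param type `"link"` for the linear predictor (default; the score used
#'   for ROC analysis) or `"response"` for probabilities.
#' @param ... Unused.
#' @return Numeric vector.
#' @export
predict.ridge_logit <- function(object, newdata, type = c("link", "response"),
                                ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata[, names(object$coefficients), drop = FALSE])
  storage.mode(x) <- "double"
  z <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  eta <- object$intercept + drop(z %*% object$coefficients)
  if (type == "response") stats::plogis(eta) else eta
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a ridge logistic fit
#'
#' @param x A `ridge_logit` fit.
#' @param ... Unused.
#' @return Tibble with `term` and `estimate` (standardized scale; the
#'   intercept first).
#' @method tidy ridge_logit
#' @export
tidy.ridge_logit <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", names(x$coefficients)),
    estimate = c(x$intercept, unname(x$coefficients))
  )
}

#' Glance at a ridge logistic fit
#'
#' @param x A `ridge_logit` fit.
#' @param ... Unused.
#' @return One-row tibble with `lambda`, `n`, `n_predictors`,
#'   `converged`, `iterations`, `objective`.
#' @method glance ridge_logit
#' @export
glance.ridge_logit <- function(x, ...) {
  tibble::tibble(
    lambda = x$lambda, n = x$n, n_predictors = length(x$coefficients),
    converged = x$converged, iterations = x$iterations,
    objective = x$objective
  )
}
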