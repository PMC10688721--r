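#' ROC curve and AUROC
#'
#' The AUROC is computed by tie-aware pair counting:
#' `(concordant + 0.5 * tied) / (n_pos * n_neg)`, equivalently the
#' midrank Mann-Whitney statistic divided by `n_pos * n_neg`, which
#' equals the trapezoidal area under the tie-aware ROC curve.
#'
#' @param scores Numeric classifier scores (higher = more
#'   positive-like).
#' @param labels Class labels, same length; both classes must occur.
#' @param positive Label of the positive class (default `"female"`).
#' @return An object of class `fundus_roc`: list with `auroc`, `roc`
#'   (tibble of `fpr`, `tpr` at every distinct threshold), `scores`,
#'   `labels`, `positive`, `n_pos`, `n_neg`.
#' @export
#' @examples
#' roc_auc(c(2, 4, 1, 3), c("female", "female", "male", "male"))
roc_auc <- function(scores, labels, positive = "female") {
  scores <- as.numeric(scores)
  y <- encode_binary(labels, positive)
  if (length(scores) != length(y)) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present to form an ROC curve", call. = FALSE)
  }
  u <- u_statistic(scores[y == 1], scores[y == 0])
  auroc <- u / (n_pos * n_neg)

  ## tie-aware ROC: one point per distinct threshold, descending
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]
  ss <- scores[ord]
  keep <- c(ss[-length(ss)] != ss[-1], TRUE)   # last index of each tie block
  tpr <- c(0, cumsum(ys)[keep] / n_pos)
  fpr <- c(0, cumsum(1 - ys)[keep] / n_neg)
  structure(
    list(auroc = auroc, roc = tibble::tibble(fpr = fpr, tpr = tpr),
         scores = scores, labels = y, positive = positive,
         n_pos = n_pos, n_neg = n_neg),
    class = "fundus_roc"
  )
}

#' @export
print.fundus_roc <- function(x, ...) {
  cat(sprintf("fundus_roc: AUROC = %.3f (%d positive, %d negative)\n",
              x$auroc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Glance at an ROC result
#'
#' @param x A `fundus_roc`.
#' @param ... Unused.
#' @return One-row tibble with `auroc`, `n_pos`, `n_neg`.
#' @method glance fundus_roc
#' @export
glance.fundus_roc <- function(x, ...) {
  tibble::tibble(auroc = x$auroc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Plot an ROC curve
#'
#' @param object A `fundus_roc`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fundus_roc
#' @export
autoplot.fundus_roc <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("AUROC = %.1f%%", 100 * object$auroc)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Paired DeLong comparison of two correlated AUROCs
#'
#' Compares the AUROCs of two score vectors evaluated on the same eyes
#' with the same labels, using the placement-value (structural
#' components) covariance estimate for correlated ROC curves:
#' `z = (A_a - A_b) / SE` with the standard-normal two-sided p-value.
#' When the estimated variance of the difference is zero (e.g. identical
#' score vectors) the difference is reported as 0 with p = 1.
#'
#' @param scores_a,scores_b Numeric score vectors over the same eyes.
#' @param labels Class labels shared by both.
#' @param positive Positive class label.
#' @return One-row tibble with `auroc_a`, `auroc_b`, `delta_auroc`, `z`,
#'   `p_value`.
#' @export
delong_paired <- function(scores_a, scores_b, labels, positive = "female") {
  y <- encode_binary(labels, positive)
  if (length(scores_a) != length(y) || length(scores_b) != length(y)) {
    stop("paired comparison needs scores and labels of equal length",
         call. = FALSE)
  }
  pos <- which(y == 1); neg <- which(y == 0)
  m <- length(pos); n <- length(neg)
  if (m == 0 || n == 0) {
    stop("both classes must be present", call. = FALSE)
  }

  comp <- function(s) {
    ## placement values via midranks: V10_i = P(s_i > S_neg) + 0.5 P(=),
    ## V01_j analogously against the positives
    sp <- s[pos]; sn <- s[neg]
    r_all <- rank(c(sp, sn))
    v10 <- (r_all[seq_len(m)] - rank(sp)) / n
    v01 <- 1 - (r_all[m + seq_len(n)] - rank(sn)) / m
    list(auc = mean(v10), v10 = v10, v01 = v01)
  }
  a <- comp(scores_a)
  b <- comp(scores_b)
  s10 <- stats::cov(cbind(a$v10, b$v10))
  s01 <- stats::cov(cbind(a$v01, b$v01))
  svar <- s10 / m + s01 / n
  var_diff <- svar[1, 1] + svar[2, 2] - 2 * svar[1, 2]
  delta <- a$auc - b$auc
  if (var_diff <= 0 || !is.finite(var_diff)) {
    return(tibble::tibble(auroc_a = a$auc, auroc_b = b$auc,
                          delta_auroc = 0, z = 0, p_value = 1))
  }
  z <- delta / sqrt(var_diff)
  tibble::tibble(
    auroc_a = a$auc, auroc_b = b$auc, delta_auroc = delta, z = z,
    p_value = 2 * stats::pnorm(-abs(z))
  )
}

#' Holm step-down adjustment
#'
#' Step-down familywise-error control: sort the p-values ascending,
#' multiply the i-th smallest by `(m - i + 1)`, enforce monotonicity and
#' cap at 1, then restore the input order. Delegates to
#' [stats::p.adjust()].
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @export
#' @examples
#' holm_adjust(c(0.01, 0.04))
holm_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "holm")
}
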