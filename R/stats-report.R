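#' Per-grade sex-discrimination analysis
#'
#' The full statistical stage over a four-grade longitudinal cohort:
#' for each grade, a Mann-Whitney p-value per fundus parameter
#' (unadjusted: the screening is exploratory) and the leave-one-out
#' cross-validated ridge logistic AUROC with its ROC curve; across
#' grades, paired DeLong comparisons of consecutive-grade AUROCs on the
#' eyes common to both grades, Holm-adjusted over the family of
#' consecutive pairs.
#'
#' @param cohort Tibble with columns `id`, `sex`, `grade` and the 54
#'   canonical feature columns (one row per eye per grade), or a named
#'   list of per-grade tibbles.
#' @param lambda_policy,lambda,lambda_grid,inner_seed Passed to
#'   [loocv_scores()].
#' @param positive Positive class label.
#' @return An object of class `fundus_sex_report`: list with tibbles
#'   `auroc` (grade, n, auroc), `pvalues` (feature x grade, long),
#'   `delong` (consecutive-pair comparisons with raw and Holm-adjusted
#'   p), `scores` (per-eye out-of-fold scores), and list `roc` of
#'   [roc_auc()] objects keyed by grade.
#' @export
per_grade_analysis <- function(cohort, lambda_policy = "fixed", lambda = 1,
                               lambda_grid = 10^seq(-2, 3, by = 1),
                               positive = "female", inner_seed = 1L) {
  if (is.data.frame(cohort)) {
    stopifnot("grade" %in% names(cohort))
    tables <- split(cohort, cohort$grade)
  } else {
    tables <- cohort
  }
  grades <- names(tables)

  per_grade <- purrr::imap(tables, function(tab, g) {
    sc <- loocv_scores(tab, lambda_policy = lambda_policy, lambda = lambda,
                       lambda_grid = lambda_grid, positive = positive,
                       inner_seed = inner_seed)
    list(
      scores = dplyr::bind_cols(tibble::tibble(grade = g), sc),
      roc = roc_auc(sc$score, sc$sex, positive = positive),
      pvals = dplyr::bind_cols(tibble::tibble(grade = g),
                               mw_screen(tab))
    )
  })

  auroc <- purrr::imap_dfr(per_grade, function(x, g) {
    tibble::tibble(grade = g, n = length(x$roc$labels), auroc = x$roc$auroc)
  })
  scores <- purrr::map_dfr(per_grade, "scores")
  pvalues <- purrr::map_dfr(per_grade, "pvals")

  delong <- NULL
  if (length(grades) >= 2) {
    delong <- purrr::map_dfr(seq_len(length(grades) - 1), function(i) {
      g1 <- grades[i]; g2 <- grades[i + 1]
      s1 <- per_grade[[g1]]$scores
      s2 <- per_grade[[g2]]$scores
      common <- intersect(s1$id, s2$id)
      s1 <- s1[match(common, s1$id), ]
      s2 <- s2[match(common, s2$id), ]
      if (!all(s1$sex == s2$sex)) {
        stop(sprintf("sex labels of shared ids differ between grades %s and %s",
                     g1, g2), call. = FALSE)
      }
      dplyr::bind_cols(
        tibble::tibble(grade_a = g2, grade_b = g1, n = length(common)),
        delong_paired(s2$score, s1$score, s1$sex, positive = positive)
      )
    })
    delong$p_holm <- holm_adjust(delong$p_value)
  }

  structure(
    list(auroc = auroc, pvalues = pvalues, delong = delong, scores = scores,
         roc = purrr::map(per_grade, "roc"),
         lambda_policy = lambda_policy, lambda = lambda, positive = positive),
    class = "fundus_sex_report"
  )
}

#' @export
print.fundus_sex_report <- function(x, ...) {
  cat("Per-grade sex-discrimination report\n")
  cat(sprintf("  penalty policy: %s%s\n", x$lambda_policy,
              if (x$lambda_policy == "fixed") sprintf(" (lambda = %g)", x$lambda) else ""))
  for (i in seq_len(nrow(x$auroc))) {
    cat(sprintf("  grade %s: LOOCV AUROC = %.1f%% (n = %d)\n",
                x$auroc$grade[i], 100 * x$auroc$auroc[i], x$auroc$n[i]))
  }
  if (!is.null(x$delong)) {
    for (i in seq_len(nrow(x$delong))) {
      cat(sprintf("  DeLong %s vs %s: dAUROC = %+.3f, p = %.4f (Holm %.4f)\n",
                  x$delong$grade_a[i], x$delong$grade_b[i],
                  x$delong$delta_auroc[i], x$delong$p_value[i],
                  x$delong$p_holm[i]))
    }
  }
  invisible(x)
}

#' Tidy a per-grade report
#'
#' @param x A `fundus_sex_report`.
#' @param ... Unused.
#' @return The long feature-by-grade Mann-Whitney p-value tibble.
#' @method tidy fundus_sex_report
#' @export
tidy.fundus_sex_report <- function(x, ...) x$pvalues

#' Glance at a per-grade report
#'
#' @param x A `fundus_sex_report`.
#' @param ... Unused.
#' @return The per-grade AUROC tibble.
#' @method glance fundus_sex_report
#' @export
glance.fundus_sex_report <- function(x, ...) x$auroc

#' Overlaid per-grade ROC curves
#'
#' @param object A `fundus_sex_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fundus_sex_report
#' @export
autoplot.fundus_sex_report <- function(object, ...) {
  df <- purrr::imap_dfr(object$roc, function(r, g) {
    dplyr::bind_cols(tibble::tibble(grade = g), r$roc)
  })
  labs <- sprintf("%s y (AUROC %.1f%%)", object$auroc$grade,
                  100 * object$auroc$auroc)
  names(labs) <- object$auroc$grade
  df$grade <- factor(df$grade, levels = object$auroc$grade, labels = labs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                   color = .data$grade)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  color = "Grade") +
    ggplot2::theme_minimal()
}

#' Feature-by-grade p-value map
#'
#' Tile map of the Mann-Whitney screening p-values, shaded by the
#' conventional exploratory thresholds (p < 0.05, p < 0.1).
#'
#' @param report A `fundus_sex_report`.
#' @return A ggplot.
#' @export
plot_pvalue_map <- function(report) {
  stopifnot(inherits(report, "fundus_sex_report"))
  df <- report$pvalues
  df$feature <- factor(df$feature, levels = rev(fundus_feature_names()))
  df$band <- cut(df$p_value, c(-Inf, 0.05, 0.1, Inf),
                 labels = c("p < 0.05", "p < 0.1", "n.s."))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$grade, y = .data$feature,
                                   fill = .data$band)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::scale_fill_manual(values = c("p < 0.05" = "#c0392b",
                                          "p < 0.1" = "#27ae60",
                                          "n.s." = "grey85")) +
    ggplot2::labs(x = "Grade (years)", y = NULL, fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 6))
}
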