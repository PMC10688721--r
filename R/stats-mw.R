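#' Mann-Whitney U test for a sex difference in one parameter
#'
#' Computes the midrank U statistic for `group_a` against `group_b` (U =
#' number of pairs where the a-value exceeds the b-value, ties counting
#' half) and a two-sided p-value. With `exact = TRUE` (the default for
#' combined sample sizes up to 12) the p-value is the permutation tail
#' probability `P(|U - n_a n_b / 2| >= |u_obs - n_a n_b / 2|)` over all
#' group assignments, which handles ties correctly. Otherwise the normal
#' approximation with tie-corrected variance and a 0.5 continuity
#' correction is used. When every value in both groups is identical the
#' p-value is 1.
#'
#' @param group_a,group_b Nonempty numeric vectors.
#' @param exact Force (`TRUE`) or suppress (`FALSE`) exact enumeration;
#'   `NULL` enumerates when `length(group_a) + length(group_b) <= 12`.
#' @return One-row tibble with columns `statistic` (U for `group_a`) and
#'   `p_value`.
#' @export
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))
mann_whitney <- function(group_a, group_b, exact = NULL) {
  a <- as.numeric(group_a)
  b <- as.numeric(group_b)
  if (length(a) == 0 || length(b) == 0) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  if (any(!is.finite(c(a, b)))) {
    stop("groups must not contain missing or infinite values", call. = FALSE)
  }
  na <- length(a); nb <- length(b)
  u <- u_statistic(a, b)
  if (is.null(exact)) exact <- (na + nb) <= 12
  if (stats::var(c(a, b)) == 0) {
    return(tibble::tibble(statistic = u, p_value = 1))
  }
  mu <- na * nb / 2
  if (exact) {
    pooled <- c(a, b)
    idx <- utils::combn(na + nb, na)
    us <- apply(idx, 2, function(ii) u_statistic(pooled[ii], pooled[-ii]))
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
  } else {
    n <- na + nb
    ties <- table(c(a, b))
    correction <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- (na * nb / 12) * ((n + 1) - correction)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(max(0, z), lower.tail = FALSE))
    }
  }
  tibble::tibble(statistic = u, p_value = p)
}

## midrank U: pairs (a_i, b_j) with a_i > b_j, ties half
u_statistic <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

#' Mann-Whitney screening of every feature in a cohort table
#'
#' Runs [mann_whitney()] (female vs male) for each feature column,
#' unadjusted for multiplicity (the screening stage is exploratory by
#' design).
#'
#' @param table Cohort tibble with a `sex` column and feature columns.
#' @param features Character vector of feature columns; defaults to the
#'   54 canonical names.
#' @param exact Passed to [mann_whitney()].
#' @return Tibble with columns `feature`, `statistic`, `p_value`.
#' @export
mw_screen <- function(table, features = fundus_feature_names(), exact = FALSE) {
  stopifnot("sex" %in% names(table), all(features %in% names(table)))
  f <- table$sex == "female"
  purrr::map_dfr(rlang::set_names(features), function(col) {
    mann_whitney(table[[col]][f], table[[col]][!f], exact = exact)
  }, .id = "feature")
}
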