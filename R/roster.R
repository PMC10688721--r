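#' Filter an enrollment roster down to the analysis set
#'
#' Applies the enrollment filters in order: keep consented students, drop
#' those excluded for truancy or transfer, then drop eyes whose fundus
#' parameters could not be measured. The count after each step is
#' attached as attribute `"counts"` and printed by the returned tibble's
#' companion [roster_counts()].
#'
#' @param records Tibble with columns `id` (unique), `consented`,
#'   `excluded_truancy_transfer`, `eye_unmeasurable` (logical flags).
#' @return Tibble of retained records, with attribute `"counts"`.
#' @export
#' @examples
#' r <- tibble::tibble(
#'   id = 1:4, consented = c(TRUE, TRUE, TRUE, FALSE),
#'   excluded_truancy_transfer = c(FALSE, TRUE, FALSE, FALSE),
#'   eye_unmeasurable = c(FALSE, FALSE, TRUE, FALSE)
#' )
#' filter_roster(r)
filter_roster <- function(records) {
  need <- c("id", "consented", "excluded_truancy_transfer", "eye_unmeasurable")
  missing <- setdiff(need, names(records))
  if (length(missing) > 0) {
    stop(sprintf("roster is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(records$id) > 0) {
    stop("roster ids must be unique", call. = FALSE)
  }
  consented <- dplyr::filter(records, .data$consented)
  retained <- dplyr::filter(consented, !.data$excluded_truancy_transfer)
  measurable <- dplyr::filter(retained, !.data$eye_unmeasurable)
  counts <- tibble::tibble(
    step = c("enrolled", "consented", "not_excluded", "measurable"),
    n = c(nrow(records), nrow(consented), nrow(retained), nrow(measurable))
  )
  structure(measurable, counts = counts)
}

#' Per-step counts of a filtered roster
#'
#' @param filtered Result of [filter_roster()].
#' @return Tibble with columns `step`, `n`.
#' @export
roster_counts <- function(filtered) {
  attr(filtered, "counts")
}

#' Build a roster with given exclusion counts
#'
#' Convenience constructor for a roster with `n_enrolled` students of
#' whom `n_consented` consented, `n_excluded` (of the consented) were
#' excluded for truancy or transfer, and `n_unmeasurable` further eyes
#' could not be measured.
#'
#' @param n_enrolled,n_consented,n_excluded,n_unmeasurable Counts.
#' @return A roster tibble suitable for [filter_roster()].
#' @export
#' @examples
#' nrow(filter_roster(make_roster(144, 122, 6, 7)))
make_roster <- function(n_enrolled, n_consented, n_excluded, n_unmeasurable) {
  stopifnot(n_consented <= n_enrolled,
            n_excluded + n_unmeasurable <= n_consented)
  consented <- c(rep(TRUE, n_consented), rep(FALSE, n_enrolled - n_consented))
  excluded <- rep(FALSE, n_enrolled)
  excluded[seq_len(n_excluded)] <- TRUE
  unmeasurable <- rep(FALSE, n_enrolled)
  unmeasurable[n_excluded + seq_len(n_unmeasurable)] <- TRUE
  tibble::tibble(
    id = sprintf("P%03d", seq_len(n_enrolled)),
    consented = consented,
    excluded_truancy_transfer = excluded,
    eye_unmeasurable = unmeasurable
  )
}
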