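## run code under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Draw a synthetic cohort feature table
#'
#' Samples `n_female + n_male` eyes from the per-sex multivariate normal
#' distributions of the configuration. Deterministic given `cfg$seed`.
#' Female rows come first; ids are `"F001"`, ..., `"M001"`, ....
#'
#' @param cfg A [sim_config()].
#' @return Tibble with columns `id`, `sex` (`"female"` / `"male"`) and
#'   the 54 canonical feature columns.
#' @export
#' @examples
#' generate_feature_table(default_sim_config(10.5, n_female = 5, n_male = 5))
generate_feature_table <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  nm <- fundus_feature_names()
  d <- diag(cfg$feature_sds)
  sigma <- d %*% cfg$correlation %*% d
  with_seed(cfg$seed, {
    xf <- MASS::mvrnorm(cfg$n_female, cfg$feature_means_f, sigma)
    xm <- MASS::mvrnorm(cfg$n_male, cfg$feature_means_m, sigma)
    x <- rbind(xf, xm)
    colnames(x) <- nm
    dplyr::bind_cols(
      tibble::tibble(
        id = c(sprintf("F%03d", seq_len(cfg$n_female)),
               sprintf("M%03d", seq_len(cfg$n_male))),
        sex = rep(c("female", "male"), c(cfg$n_female, cfg$n_male))
      ),
      tibble::as_tibble(x)
    )
  })
}

#' Simulate a four-grade longitudinal cohort
#'
#' One feature table per grade with a common set of subject ids across
#' grades (the same children measured annually), so that per-grade
#' classifiers can be compared on paired out-of-fold scores.
#' Grade-specific sex-effect strengths follow [default_sim_config()]
#' unless `effect_scale` supplies one multiplier per grade. Draws are
#' independent across grades given sex.
#'
#' @param grades Numeric vector of grades (years).
#' @param n_female,n_male Eyes per sex.
#' @param effect_scale Optional numeric vector, one effect multiplier per
#'   grade.
#' @param seed Integer seed.
#' @return Tibble with columns `id`, `sex`, `grade` and the 54 feature
#'   columns; `length(grades) * (n_female + n_male)` rows.
#' @export
simulate_longitudinal_cohort <- function(grades = c(8.5, 9.5, 10.5, 11.5),
                                         n_female = 56, n_male = 53,
                                         effect_scale = NULL, seed = 1L) {
  if (!is.null(effect_scale) && length(effect_scale) != length(grades)) {
    stop("effect_scale must have one multiplier per grade", call. = FALSE)
  }
  purrr::imap_dfr(rlang::set_names(grades, grades), function(g, key) {
    i <- match(g, grades)
    cfg <- default_sim_config(
      grade = if (is.null(effect_scale)) g else NULL,
      n_female = n_female, n_male = n_male,
      effect_scale = if (is.null(effect_scale)) NULL else effect_scale[i],
      seed = seed + 1000L * i
    )
    tab <- generate_feature_table(cfg)
    dplyr::bind_cols(tab[, c("id", "sex")],
                     tibble::tibble(grade = g),
                     tab[, fundus_feature_names()])
  })
}

#' Read / write cohort feature tables as CSV
#'
#' The on-disk layout is one row per eye with an `id` column, a `sex`
#' column (`female` / `male`), optionally `grade`, and the 54 canonical
#' feature columns in order. `read_feature_csv()` validates the header
#' and reports any missing feature column by name.
#'
#' @param path File path.
#' @return `read_feature_csv()` returns a tibble;
#'   `write_feature_csv()` returns `path` invisibly.
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(c("id", "sex", fundus_feature_names()), names(df))
  if (length(missing) > 0) {
    stop(sprintf("feature CSV %s is missing column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  keep <- c("id", "sex", intersect("grade", names(df)), fundus_feature_names())
  tibble::as_tibble(df[, keep])
}

#' @param table A cohort tibble as produced by [generate_feature_table()].
#' @rdname read_feature_csv
#' @export
write_feature_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
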