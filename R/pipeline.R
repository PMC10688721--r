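#' @importFrom rlang .data
NULL

#' Run the full synthetic-to-report pipeline
#'
#' Orchestrates the three stages on disk: `simulate` renders a small set
#' of eyes (PNG + landmark JSON) and draws per-grade feature tables;
#' `extract` re-measures the rendered eyes into a feature CSV; `analyze`
#' runs the per-grade statistical report over the simulated cohort.
#' Every output file records the seed and a configuration hash, and a
#' rerun with the same configuration reproduces the outputs
#' byte-identically.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed driving every random draw.
#' @param n_rendered Number of eyes to render and re-measure.
#' @param n_female,n_male Cohort size per sex per grade.
#' @param grades Grades (years) to simulate.
#' @param lambda_policy,lambda Penalty policy for the analysis stage.
#' @param cfg A [measurement_config()].
#' @param verbose Log progress to stderr.
#' @return (Invisibly) a list with the report, the paths written, and
#'   the per-eye extraction table.
#' @export
run_pipeline <- function(out_dir, seed = 1L, n_rendered = 4,
                         n_female = 56, n_male = 53,
                         grades = c(8.5, 9.5, 10.5, 11.5),
                         lambda_policy = "fixed", lambda = 1,
                         cfg = measurement_config(), verbose = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  run_info <- list(
    seed = seed,
    config_hash = config_hash(list(seed, n_rendered, n_female, n_male,
                                   grades, lambda_policy, lambda,
                                   unclass(cfg)))
  )

  ## simulate: rendered eyes with ground truth, then re-extract
  say("simulate: rendering %d eyes", n_rendered)
  sim_cfg <- default_sim_config(grade = utils::tail(grades, 1), seed = seed)
  eye_rows <- purrr::map_dfr(seq_len(n_rendered), function(i) {
    sex <- if (i %% 2 == 1) "female" else "male"
    eye <- render_fundus_image(sample_eye_parameters(sim_cfg, sex, seed + i))
    img_path <- file.path(out_dir, sprintf("eye_%02d.png", i))
    lm_path <- file.path(out_dir, sprintf("eye_%02d_landmarks.json", i))
    write_fundus_png(eye$image, img_path)
    write_landmarks(eye$landmarks, lm_path)
    tibble::tibble(id = sprintf("E%02d", i), sex = sex,
                   image = img_path, landmarks = lm_path)
  })

  say("extract: measuring %d rendered eyes", n_rendered)
  extracted <- extract_features_batch(eye_rows, cfg)
  extracted_path <- file.path(out_dir, "extracted_features.csv")
  utils::write.csv(dplyr::bind_cols(extracted, run_info["seed"]),
                   extracted_path, row.names = FALSE)

  say("analyze: simulating %d-grade cohort (%d + %d per grade)",
      length(grades), n_female, n_male)
  cohort <- simulate_longitudinal_cohort(
    grades = grades, n_female = n_female, n_male = n_male, seed = seed
  )
  cohort_path <- file.path(out_dir, "cohort_features.csv")
  write_feature_csv(cohort, cohort_path)

  report <- per_grade_analysis(cohort, lambda_policy = lambda_policy,
                               lambda = lambda, inner_seed = seed)
  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(
    list(
      seed = run_info$seed, config_hash = run_info$config_hash,
      auroc = report$auroc, pvalues = report$pvalues,
      delong = report$delong
    ),
    report_path, digits = NA, auto_unbox = TRUE, dataframe = "rows"
  )
  utils::write.csv(report$auroc, file.path(out_dir, "auroc.csv"),
                   row.names = FALSE)
  utils::write.csv(
    tidyr::pivot_wider(report$pvalues[, c("feature", "grade", "p_value")],
                       names_from = "grade", values_from = "p_value"),
    file.path(out_dir, "pvalue_matrix.csv"), row.names = FALSE
  )
  if (!is.null(report$delong)) {
    utils::write.csv(report$delong, file.path(out_dir, "delong.csv"),
                     row.names = FALSE)
  }
  say("report written to %s", report_path)
  invisible(list(
    report = report, extracted = extracted,
    paths = c(report = report_path, cohort = cohort_path,
              extracted = extracted_path),
    run_info = run_info
  ))
}

## order-stable hash of the run configuration (no external digest
## dependency: sum of a serialized byte stream is enough to detect a
## changed configuration in logs)
config_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  sprintf("%08x", sum(as.integer(raw)) %% .Machine$integer.max)
}

#' Import a deposited raw-data export
#'
#' Reads a CSV export of the deposited per-eye raw data table. The
#' expected layout is one row per eye per grade with columns `id`, `sex`
#' (`female` / `male`), `grade` (8.5, 9.5, 10.5 or 11.5) and the 54
#' canonical feature columns of [fundus_feature_names()]; any missing
#' column is reported by name. The returned tibble feeds directly into
#' [per_grade_analysis()].
#'
#' @param path CSV path.
#' @return Cohort tibble with `id`, `sex`, `grade` and the 54 features.
#' @export
read_s2_csv <- function(path) {
  tab <- read_feature_csv(path)
  if (!"grade" %in% names(tab)) {
    stop("deposited-data export must contain a grade column", call. = FALSE)
  }
  tab
}
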