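#' Run the full shift-network analysis pipeline
#'
#' Wires the stages end to end: obtain a panel (simulate a synthetic one, or
#' ingest roster/survey CSVs), compute per-shift metrics, stratify them into
#' the longitudinal series with night-minus-day contrasts, run the QAP panel
#' with its boxplot summary, compute response rates when an attendance file
#' is present, export one sociogram, and write a JSON run manifest recording
#' the resolved configuration, seeds and bookkeeping counts. Identical
#' configuration (including seeds) produces identical artifacts.
#'
#' @param config A named list, or path to a JSON file with the same shape:
#'   either `simulate` (arguments to [synthetic_config()]; `seed` required)
#'   or `input_dir` (directory with `roster.csv` / `surveys.csv`, optionally
#'   `attendance.csv`); `out_dir`; optional `threshold` (default 1), `qap`
#'   (`n_permutations`, `seed` -- required, `binary`, `alpha`), and
#'   `sociogram` (`week`, `shift`, `relation`; defaults to the shift-point
#'   with maximal density for `medication_advice`).
#' @param out_dir Output directory, overriding `config$out_dir`.
#' @return Named list of artifact paths, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) abort("`config` must be a list or a JSON file path.")
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) abort("An output directory is required.")
  has_sim <- !is.null(config$simulate)
  has_in <- !is.null(config$input_dir)
  if (has_sim == has_in) {
    abort("Exactly one of `simulate` or `input_dir` must be given.")
  }
  qap_cfg <- config$qap %||% list()
  if (is.null(qap_cfg$seed)) {
    abort("`qap$seed` is required (no stage may consume unlogged randomness).")
  }
  if (has_sim && is.null(config$simulate$seed)) {
    abort("`simulate$seed` is required.")
  }
  threshold <- config$threshold %||% 1L
  alpha <- qap_cfg$alpha %||% 0.05
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  counts <- list()

  if (has_sim) {
    sim_args <- config$simulate
    if (!is.null(sim_args$role_counts)) {
      sim_args$role_counts <- unlist(sim_args$role_counts)
    }
    for (f in c("base_logit", "overlap_lambda")) {
      if (!is.null(sim_args[[f]])) sim_args[[f]] <- unlist(sim_args[[f]])
    }
    cfg <- do.call(synthetic_config, sim_args)
    dataset <- generate_dataset(cfg)
    data_dir <- file.path(out_dir, "data")
    paths$data <- write_dataset(dataset, data_dir)
    networks <- read_dataset(data_dir)
    attendance_path <- paths$data$attendance
  } else {
    networks <- read_dataset(config$input_dir)
    attendance_path <- file.path(config$input_dir, "attendance.csv")
  }
  counts$shift_points <- length(networks)

  metrics <- dataset_metrics(networks, threshold = threshold)
  counts$metric_rows <- nrow(metrics)
  counts$skipped_metrics <- nrow(attr(metrics, "skipped") %||% tibble::tibble())
  flat <- metrics |>
    dplyr::mutate(
      top_in_degree_roles = purrr::map_chr(.data$top_in_degree_roles,
                                           paste, collapse = "|"),
      stars = purrr::map_chr(.data$stars, paste, collapse = "|"),
      isolates = purrr::map_chr(.data$isolates, paste, collapse = "|")
    ) |>
    dplyr::select(-"in_degree")
  paths$metrics <- file.path(out_dir, "metrics.csv")
  readr::write_csv(flat, paths$metrics)

  indeg <- metrics |>
    dplyr::select("shift_id", "week", "shift", "relation", "in_degree") |>
    tidyr::unnest("in_degree")
  paths$in_degree <- file.path(out_dir, "in_degree.csv")
  readr::write_csv(indeg, paths$in_degree)

  series <- build_series(metrics)
  paths$series <- file.path(out_dir, "series.csv")
  readr::write_csv(
    dplyr::select(tibble::as_tibble(series),
                  -dplyr::any_of(c("top_in_degree_roles", "stars",
                                   "isolates", "in_degree"))),
    paths$series
  )
  contrasts <- shift_contrasts(series)
  paths$contrasts <- file.path(out_dir, "contrasts.csv")
  readr::write_csv(contrasts, paths$contrasts)

  panel <- qap_panel(networks,
                     n_permutations = qap_cfg$n_permutations %||% 1000L,
                     seed = qap_cfg$seed,
                     binary = qap_cfg$binary %||% FALSE,
                     threshold = threshold)
  counts$qap_results <- nrow(panel)
  counts$skipped_qap <- nrow(attr(panel, "skipped") %||% tibble::tibble())
  paths$qap <- file.path(out_dir, "qap.csv")
  readr::write_csv(tibble::as_tibble(panel), paths$qap)
  qsum <- summarize_qap_panel(panel, alpha = alpha)
  paths$qap_summary <- file.path(out_dir, "qap_summary.csv")
  readr::write_csv(tibble::as_tibble(qsum), paths$qap_summary)

  if (file.exists(attendance_path)) {
    attendance <- readr::read_csv(attendance_path,
                                  col_types = readr::cols(
                                    shift_id = readr::col_character(),
                                    .default = readr::col_integer()
                                  ))
    rates <- response_rates(attendance)
    paths$response_rates <- file.path(out_dir, "response_rates.csv")
    readr::write_csv(rates, paths$response_rates)
  }

  soc_cfg <- config$sociogram %||% list()
  soc_relation <- soc_cfg$relation %||% "medication_advice"
  target_id <- if (!is.null(soc_cfg$week) && !is.null(soc_cfg$shift)) {
    sprintf("W%02d_%s", as.integer(soc_cfg$week), soc_cfg$shift)
  } else {
    best <- metrics |>
      dplyr::filter(.data$relation == soc_relation) |>
      dplyr::slice_max(.data$density_pct, n = 1, with_ties = FALSE)
    best$shift_id[1]
  }
  if (!is.null(target_id) && target_id %in% names(networks)) {
    spec <- export_sociogram(networks[[target_id]], soc_relation,
                             out_dir = file.path(out_dir, "sociograms"),
                             threshold = threshold,
                             layout_seed = soc_cfg$layout_seed %||% 42L)
    paths$sociogram <- as.list(spec$files)
  } else {
    warn(sprintf("Sociogram shift-point '%s' not found; skipping export.",
                 target_id %||% "?"))
  }

  manifest <- list(
    package = "shiftnet",
    version = as.character(utils::packageVersion("shiftnet")),
    config = config,
    conventions = list(
      tie_threshold = threshold,
      symmetrization = "union",
      quartile_type = 7,
      p_value = "add-one Monte Carlo; exact proportion when exhaustive",
      alpha = alpha
    ),
    counts = counts
  )
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
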