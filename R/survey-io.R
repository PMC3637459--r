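#' Read a shift roster file
#'
#' Rosters are UTF-8 comma-delimited files with header
#' `shift_id,date,shift,person_id,role`. The `shift` field accepts `day` /
#' `night` or the survey-block labels `AM` / `PM` (mapped to day / night).
#' File order is preserved as the canonical node order within each shift.
#'
#' @param path Path to a roster CSV.
#' @return A tibble with columns `shift_id`, `date`, `shift`, `person_id`,
#'   `role` covering all shifts in the file; filter on `shift_id` for a
#'   single roster.
#' @export
read_roster <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  required <- c("shift_id", "date", "shift", "person_id", "role")
  if (!all(required %in% names(df))) {
    abort(sprintf("Roster file must have columns: %s",
                  paste(required, collapse = ", ")))
  }
  df <- df[required]
  shift_map <- c(AM = "day", PM = "night", day = "day", night = "night")
  bad_shift <- which(!df$shift %in% names(shift_map))
  if (length(bad_shift)) {
    abort(sprintf("Row %d: shift '%s' is not one of AM, PM, day, night.",
                  bad_shift[1], df$shift[bad_shift[1]]))
  }
  df$shift <- unname(shift_map[df$shift])
  bad_role <- which(!df$role %in% role_types())
  if (length(bad_role)) {
    abort(sprintf("Row %d: unknown role '%s'.", bad_role[1], df$role[bad_role[1]]))
  }
  dup <- df |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$shift_id, .data$person_id) |>
    dplyr::filter(dplyr::n() > 1) |>
    dplyr::ungroup()
  if (nrow(dup)) {
    abort(sprintf("Row %d: duplicate person_id '%s' within shift '%s'.",
                  dup$.row[2], dup$person_id[1], dup$shift_id[1]))
  }
  df
}

#' Write rosters to the roster CSV dialect
#'
#' @param roster Roster tibble (one or many shifts) with `shift_id`, `date`,
#'   `shift`, `person_id`, `role` columns.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_roster <- function(roster, path) {
  readr::write_csv(roster[c("shift_id", "date", "shift", "person_id", "role")],
                   path)
  invisible(path)
}

#' Read survey responses for one shift
#'
#' Survey files are long CSVs with header
#' `shift_id,respondent,relation,target,frequency`, one row per reported
#' (respondent, relation, target) frequency. The top Likert category `10+`
#' ("more than 10") is parsed as 10. Pairs not listed for a respondent who
#' appears in the file default to frequency 0; rostered members with no rows
#' at all are nonrespondents.
#'
#' @param path Path to a survey CSV.
#' @param roster Roster tibble for the shift(s) the responses belong to;
#'   rows referencing persons outside the roster are rejected.
#' @return A tibble `shift_id, respondent, relation, target, frequency`
#'   with integer frequencies in 0..10.
#' @export
read_surveys <- function(path, roster) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  required <- c("shift_id", "respondent", "relation", "target", "frequency")
  if (!all(required %in% names(df))) {
    abort(sprintf("Survey file must have columns: %s",
                  paste(required, collapse = ", ")))
  }
  df <- df[required]
  if (nrow(df) == 0) {
    return(tibble::tibble(shift_id = character(), respondent = character(),
                          relation = character(), target = character(),
                          frequency = integer()))
  }
  freq_chr <- trimws(df$frequency)
  freq <- ifelse(freq_chr == "10+", 10L, suppressWarnings(as.integer(freq_chr)))
  bad <- which(is.na(freq) | freq < 0L | freq > 10L)
  if (length(bad)) {
    abort(sprintf("Row %d: frequency '%s' is not an integer in 0..10 or '10+'.",
                  bad[1], df$frequency[bad[1]]))
  }
  df$frequency <- freq
  selfrow <- which(df$respondent == df$target)
  if (length(selfrow)) {
    abort(sprintf("Row %d: respondent and target are the same person ('%s').",
                  selfrow[1], df$respondent[selfrow[1]]))
  }
  bad_rel <- which(!df$relation %in% relation_types())
  if (length(bad_rel)) {
    abort(sprintf("Row %d: unknown relation '%s'.",
                  bad_rel[1], df$relation[bad_rel[1]]))
  }
  key <- paste(df$shift_id, df$respondent)
  roster_key <- paste(roster$shift_id, roster$person_id)
  bad_resp <- which(!key %in% roster_key)
  if (length(bad_resp)) {
    abort(sprintf("Row %d: respondent '%s' is not on the roster for shift '%s'.",
                  bad_resp[1], df$respondent[bad_resp[1]], df$shift_id[bad_resp[1]]))
  }
  tkey <- paste(df$shift_id, df$target)
  bad_tgt <- which(!tkey %in% roster_key)
  if (length(bad_tgt)) {
    abort(sprintf("Row %d: target '%s' is not on the roster for shift '%s'.",
                  bad_tgt[1], df$target[bad_tgt[1]], df$shift_id[bad_tgt[1]]))
  }
  df
}

#' Abstract survey responses into per-shift network matrices
#'
#' Builds the three directed weighted matrices for one shift: `W[i, j]` is
#' respondent `i`'s reported frequency toward `j`. Rostered members with no
#' survey rows for a relation are nonrespondents for that relation: their
#' rows are marked missing (`NA`), distinct from zero. All three relation
#' matrices are always produced; a relation with no responses at all yields
#' an all-missing matrix.
#'
#' @param responses Survey tibble from [read_surveys()], all belonging to
#'   `roster`'s shift.
#' @param roster Roster tibble for a single shift (defines node order).
#' @return A `shift_network_set`.
#' @export
build_networks <- function(responses, roster) {
  sid <- unique(roster$shift_id)
  if (length(sid) != 1) abort("`roster` must cover exactly one shift.")
  if (nrow(responses) && !all(responses$shift_id == sid)) {
    abort("All responses must belong to the roster's shift.")
  }
  dup <- responses |>
    dplyr::count(.data$respondent, .data$relation, .data$target) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    abort(sprintf(
      "Duplicate survey rows for respondent '%s', relation '%s', target '%s'; refusing to overwrite.",
      dup$respondent[1], dup$relation[1], dup$target[1]
    ))
  }
  ids <- roster$person_id
  n <- length(ids)
  matrices <- list()
  missing <- list()
  for (rel in relation_types()) {
    rows <- responses[responses$relation == rel, ]
    respondents <- unique(rows$respondent)
    W <- matrix(NA_integer_, n, n, dimnames = list(ids, ids))
    W[match(respondents, ids), ] <- 0L
    if (nrow(rows)) {
      W[cbind(match(rows$respondent, ids), match(rows$target, ids))] <-
        rows$frequency
    }
    diag(W) <- NA_integer_
    matrices[[rel]] <- W
    missing[[rel]] <- setdiff(ids, respondents)
  }
  new_shift_network_set(roster, matrices, missing)
}

#' Per-shift and pooled survey response rates
#'
#' Standard response-rate bookkeeping for shift-based sociometric surveys:
#' per shift, `B` people completed the survey, `C` refused, and `D` were
#' present but not located, giving rate = 100 B / (B + C + D). The pooled
#' overall rate divides total completions by total eligible (not the mean of
#' per-shift rates). Percentages are rounded to one decimal, half away from
#' zero.
#'
#' @param attendance Tibble with columns `shift_id`, `completed`, `refused`,
#'   `not_located` (counts >= 0, per-shift sum >= 1).
#' @return The attendance tibble with a `rate` column appended, plus a final
#'   pooled row with `shift_id = "overall"`.
#' @export
#' @examples
#' response_rates(tibble::tibble(
#'   shift_id = c("May 6 AM", "May 27 AM"),
#'   completed = c(10, 13), refused = c(1, 0), not_located = c(3, 0)
#' ))
response_rates <- function(attendance) {
  required <- c("shift_id", "completed", "refused", "not_located")
  if (!all(required %in% names(attendance))) {
    abort(sprintf("`attendance` must have columns: %s",
                  paste(required, collapse = ", ")))
  }
  counts <- attendance[c("completed", "refused", "not_located")]
  if (any(as.matrix(counts) < 0, na.rm = TRUE) || anyNA(counts)) {
    abort("Counts must be nonnegative and non-missing.")
  }
  eligible <- attendance$completed + attendance$refused + attendance$not_located
  if (any(eligible < 1)) {
    abort(sprintf("Shift '%s' has zero eligible personnel (B + C + D = 0).",
                  attendance$shift_id[which(eligible < 1)[1]]))
  }
  per_shift <- attendance |>
    dplyr::mutate(rate = round_half_away(100 * .data$completed /
                                           (.data$completed + .data$refused +
                                              .data$not_located), 1))
  pooled <- per_shift |>
    dplyr::summarise(
      shift_id = "overall",
      completed = sum(.data$completed),
      refused = sum(.data$refused),
      not_located = sum(.data$not_located)
    ) |>
    dplyr::mutate(rate = round_half_away(100 * .data$completed /
                                           (.data$completed + .data$refused +
                                              .data$not_located), 1))
  dplyr::bind_rows(per_shift, pooled)
}

#' Write a synthetic panel as roster / survey / attendance / truth files
#'
#' Emits the same CSV dialects [read_roster()] and [read_surveys()] consume
#' (respondents' zero frequencies are written explicitly so respondent
#' status round-trips), an attendance file for [response_rates()] in which
#' nonrespondents are split between refusals and not-located, and a JSON
#' truth file recording the seed and generator parameters.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @param refusal_share Of nonrespondents, the probability a given one is
#'   recorded as a refusal rather than not-located.
#' @return Named list of file paths, invisibly.
#' @export
write_dataset <- function(dataset, dir, refusal_share = 0.82) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rosters <- dplyr::bind_rows(dataset$rosters)
  roster_path <- file.path(dir, "roster.csv")
  write_roster(rosters, roster_path)

  surveys <- purrr::map(dataset$networks, networks_to_survey_rows) |>
    dplyr::bind_rows()
  survey_path <- file.path(dir, "surveys.csv")
  readr::write_csv(surveys, survey_path)

  set.seed(sub_seed(dataset$config$seed, 0L, "day", stage = 4L))
  attendance <- purrr::imap(dataset$networks, function(nset, id) {
    nr <- length(dataset$nonrespondents[[id]])
    refused <- if (nr) rbinom(1, nr, refusal_share) else 0L
    tibble::tibble(
      shift_id = id,
      completed = nrow(nset$roster) - nr,
      refused = refused,
      not_located = nr - refused
    )
  }) |>
    dplyr::bind_rows()
  attendance_path <- file.path(dir, "attendance.csv")
  readr::write_csv(attendance, attendance_path)

  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(
      seed = dataset$config$seed,
      parameters = dataset$truth$parameters,
      nonrespondents = dataset$nonrespondents,
      pool = dataset$truth$pool
    ),
    truth_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(list(roster = roster_path, surveys = survey_path,
                 attendance = attendance_path, truth = truth_path))
}

# Long survey rows (including explicit zeros) for every respondent row of
# every relation matrix in a shift_network_set.
networks_to_survey_rows <- function(nset) {
  ids <- nset$roster$person_id
  purrr::imap(nset$matrices, function(W, rel) {
    observed <- rownames(W)[rowSums(!is.na(W)) > 0]
    if (!length(observed)) return(NULL)
    expand.grid(respondent = observed, target = ids,
                stringsAsFactors = FALSE) |>
      dplyr::filter(.data$respondent != .data$target) |>
      dplyr::mutate(
        shift_id = nset$shift_id,
        relation = rel,
        frequency = W[cbind(.data$respondent, .data$target)],
        .before = 1
      ) |>
      dplyr::select("shift_id", "respondent", "relation", "target", "frequency") |>
      dplyr::arrange(.data$respondent, .data$target)
  }) |>
    dplyr::bind_rows()
}

#' Read a written panel back into per-shift network sets
#'
#' Inverse of [write_dataset()]: reads the roster and survey files from
#' `dir` and rebuilds one `shift_network_set` per shift.
#'
#' @param dir Directory containing `roster.csv` and `surveys.csv`.
#' @return Named list of `shift_network_set`, keyed by shift_id.
#' @export
read_dataset <- function(dir) {
  roster <- read_roster(file.path(dir, "roster.csv"))
  # Week index: rank of ISO week of the shift date (a Tuesday-overnight /
  # Wednesday-day pair shares its week); falls back to shift_id rank when
  # dates do not parse.
  dates <- suppressWarnings(as.Date(roster$date))
  roster$week <- if (anyNA(dates)) {
    dplyr::dense_rank(roster$shift_id)
  } else {
    dplyr::dense_rank(format(dates, "%G-%V"))
  }
  surveys <- read_surveys(file.path(dir, "surveys.csv"), roster)
  shift_ids <- unique(roster$shift_id)
  nets <- purrr::map(shift_ids, function(sid) {
    build_networks(surveys[surveys$shift_id == sid, ],
                   roster[roster$shift_id == sid, ])
  })
  setNames(nets, shift_ids)
}
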