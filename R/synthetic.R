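#' Configuration for the synthetic shift-network generator
#'
#' Defines the study design the generator emulates: a three-month (12-week)
#' panel of day and night emergency-department shifts, each staffed from a
#' stable per-role personnel pool, with three communication relations
#' surveyed per shift on a 0-10+ frequency scale, and per-person survey
#' nonresponse.
#'
#' Ties are drawn independently per ordered pair (i, j), i != j, and relation
#' r with log-odds
#' \deqn{\eta = \beta_r + s_{ri} + s_{rj} + \lambda_r z_{ij} + \delta \cdot 1[\mathrm{night}]}
#' where `beta_r` is `base_logit[r]`, `s_r.` are per-person, per-relation
#' latent sociabilities (SD `sociability_sd`) drawn once per person so they
#' persist across weeks, `z_ij` is a dyad-level standard-normal factor shared
#' by all three relations (`overlap_lambda` controls how strongly each
#' relation loads on it, hence the inter-relation QAP correlation), and
#' `delta = night_density_offset >= 0` raises night-shift density. Positive
#' ties receive integer weights `min(10, 1 + Poisson(weight_mean - 1))`,
#' capping at 10 to mirror the survey's "10+" category.
#'
#' @param n_weeks Number of study weeks (default 12).
#' @param role_counts Named integer vector: personnel per role on each shift.
#'   Names must come from [role_types()]. Defaults sum to a 19-member roster.
#' @param base_logit Named numeric, per-relation baseline tie log-odds.
#' @param night_density_offset Additive log-odds for night shifts (>= 0).
#' @param sociability_sd SD of the per-person, per-relation sociability.
#' @param overlap_lambda Named numeric, per-relation loading on the shared
#'   dyadic factor; the product of two loadings governs that pair's expected
#'   matrix correlation.
#' @param weight_mean Mean of the positive-weight distribution before the
#'   cap at 10; must be >= 1.
#' @param nonresponse_rate Probability a rostered person returns no survey.
#' @param pool_factor Pool size per role as a multiple of the per-shift count;
#'   sampling each week from a fixed pool creates repeat respondents.
#' @param seed Integer RNG seed; fixes all generator output bit-for-bit.
#' @return A validated list of class `synthetic_config`.
#' @export
#' @examples
#' cfg <- synthetic_config(seed = 1)
#' nrow(generate_roster(cfg, week = 1, shift = "day"))
synthetic_config <- function(n_weeks = 12L,
                             role_counts = c(
                               AMD = 2L, RMD = 3L, SRN = 6L, TRN = 1L,
                               CRN = 1L, PCT = 3L, HUC = 1L, RC = 1L,
                               TRAMRN = 1L
                             ),
                             base_logit = c(
                               problem_solving = -0.8,
                               medication_advice = -2.0,
                               socializing = -0.6
                             ),
                             night_density_offset = 0.6,
                             sociability_sd = 0.6,
                             overlap_lambda = c(
                               problem_solving = 1.0,
                               medication_advice = 1.0,
                               socializing = 1.0
                             ),
                             weight_mean = 3,
                             nonresponse_rate = 0.18,
                             pool_factor = 2.5,
                             seed = 1L) {
  if (!is.numeric(n_weeks) || n_weeks < 1) abort("`n_weeks` must be >= 1.")
  bad_roles <- setdiff(names(role_counts), role_types())
  if (length(bad_roles)) {
    abort(sprintf("Unknown role name(s) in role_counts: %s",
                  paste(bad_roles, collapse = ", ")))
  }
  if (any(role_counts < 0) || sum(role_counts) < 2) {
    abort("`role_counts` must be nonnegative and sum to >= 2.")
  }
  base_logit <- expand_per_relation(base_logit, "base_logit")
  overlap_lambda <- expand_per_relation(overlap_lambda, "overlap_lambda")
  if (night_density_offset < 0) abort("`night_density_offset` must be >= 0.")
  if (sociability_sd < 0) abort("`sociability_sd` must be >= 0.")
  if (weight_mean < 1) abort("`weight_mean` must be >= 1.")
  if (nonresponse_rate < 0 || nonresponse_rate > 1) {
    abort("`nonresponse_rate` must be in [0, 1].")
  }
  if (pool_factor < 1) abort("`pool_factor` must be >= 1.")
  if (is.null(seed) || !is.numeric(seed) || is.na(seed)) {
    abort("An integer `seed` is required.")
  }
  structure(
    list(
      n_weeks = as.integer(n_weeks),
      role_counts = role_counts[role_counts > 0],
      base_logit = base_logit,
      night_density_offset = night_density_offset,
      sociability_sd = sociability_sd,
      overlap_lambda = overlap_lambda,
      weight_mean = weight_mean,
      nonresponse_rate = nonresponse_rate,
      pool_factor = pool_factor,
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

# Recycle a scalar over relations, or validate a fully named vector.
expand_per_relation <- function(x, what) {
  rels <- relation_types()
  if (length(x) == 1L && is.null(names(x))) {
    return(setNames(rep(as.numeric(x), 3), rels))
  }
  if (is.null(names(x)) && length(x) == 3L) names(x) <- rels
  if (!setequal(names(x), rels)) {
    abort(sprintf("`%s` must be a scalar or named per relation (%s).",
                  what, paste(rels, collapse = ", ")))
  }
  setNames(as.numeric(x[rels]), rels)
}

# Fixed personnel pool per role, with per-person per-relation sociabilities.
# Deterministic in config$seed; the same pool backs every week, so rosters
# share members across weeks (repeat-respondent structure).
personnel_pool <- function(config) {
  set.seed(sub_seed(config$seed, 0L, "day", stage = 0L))
  pools <- purrr::imap(as.list(config$role_counts), function(count, role) {
    size <- max(count, ceiling(config$pool_factor * count))
    tibble::tibble(
      person_id = sprintf("%s%02d", role, seq_len(size)),
      role = role
    )
  })
  pool <- dplyr::bind_rows(pools)
  soc <- matrix(
    rnorm(nrow(pool) * 3, sd = config$sociability_sd),
    ncol = 3, dimnames = list(NULL, paste0("soc_", relation_types()))
  )
  dplyr::bind_cols(pool, tibble::as_tibble(soc))
}

#' Generate the roster for one shift
#'
#' Samples, for each role, the configured number of personnel from that
#' role's fixed pool. Pools are shared across weeks, so members recur across
#' shifts. Output is deterministic in `(config$seed, week, shift)`.
#'
#' @param config A [synthetic_config()].
#' @param week Week index (1-based).
#' @param shift `"day"` or `"night"`.
#' @return A tibble with columns `shift_id`, `week`, `shift`, `date`,
#'   `person_id`, `role`, plus latent sociability columns used by
#'   [generate_networks()]. Row order is the canonical node order.
#' @export
generate_roster <- function(config, week, shift) {
  stopifnot(inherits(config, "synthetic_config"))
  check_shift(shift)
  pool <- personnel_pool(config)
  set.seed(sub_seed(config$seed, week, shift, stage = 1L))
  members <- pool |>
    dplyr::group_by(.data$role) |>
    dplyr::group_modify(function(df, key) {
      k <- config$role_counts[[key$role]]
      df[sort(sample.int(nrow(df), k)), ]
    }) |>
    dplyr::ungroup()
  # Wednesday day shifts and the preceding Tuesday overnight, weekly.
  base_date <- as.Date("2009-05-06") + 7 * (week - 1)
  shift_date <- format(if (shift == "day") base_date else base_date - 1)
  members |>
    dplyr::mutate(
      shift_id = sprintf("W%02d_%s", week, shift),
      week = as.integer(week),
      shift = !!shift,
      date = shift_date,
      .before = 1
    ) |>
    dplyr::arrange(match(.data$role, role_types()), .data$person_id)
}

#' Generate the three communication networks for one roster
#'
#' Draws directed tie indicators and 1-10 frequency weights for each relation
#' under the latent-factor model described in [synthetic_config()]. The
#' dyad-level factor `z_ij` is symmetric in (i, j) and shared across
#' relations; sociabilities are taken from the roster columns when present
#' (so they persist across weeks) and drawn fresh otherwise.
#'
#' @param config A [synthetic_config()].
#' @param roster A roster tibble from [generate_roster()] (or any tibble with
#'   `person_id` and `role`), size >= 2.
#' @param shift `"day"` or `"night"`; night shifts add
#'   `night_density_offset` to every tie's log-odds.
#' @return A `shift_network_set` with no missing rows (apply
#'   [apply_nonresponse()] for the observed-data version).
#' @export
generate_networks <- function(config, roster, shift) {
  stopifnot(inherits(config, "synthetic_config"))
  check_shift(shift)
  n <- nrow(roster)
  if (n < 2) abort("Roster must have >= 2 members to generate networks.")
  week <- if ("week" %in% names(roster)) roster$week[[1]] else 0L
  set.seed(sub_seed(config$seed, week, shift, stage = 2L))
  rels <- relation_types()
  soc_cols <- paste0("soc_", rels)
  if (all(soc_cols %in% names(roster))) {
    soc <- as.matrix(roster[soc_cols])
  } else {
    soc <- matrix(rnorm(n * 3, sd = config$sociability_sd), ncol = 3,
                  dimnames = list(NULL, soc_cols))
  }
  z <- matrix(0, n, n)
  z[upper.tri(z)] <- rnorm(n * (n - 1) / 2)
  z <- z + t(z)
  off <- if (shift == "night") config$night_density_offset else 0
  matrices <- setNames(vector("list", 3), rels)
  for (k in seq_along(rels)) {
    r <- rels[k]
    eta <- config$base_logit[[r]] +
      outer(soc[, k], soc[, k], `+`) +
      config$overlap_lambda[[r]] * z + off
    p <- stats::plogis(eta)
    tie <- matrix(rbinom(n * n, 1L, as.vector(p)), n, n)
    w <- matrix(0L, n, n)
    npos <- sum(tie == 1L)
    if (npos > 0) {
      w[tie == 1L] <- pmin(10L, 1L + rpois(npos, config$weight_mean - 1))
    }
    diag(w) <- NA_integer_
    dimnames(w) <- list(roster$person_id, roster$person_id)
    matrices[[r]] <- w
  }
  new_shift_network_set(roster, matrices)
}

#' Generate a full synthetic study panel
#'
#' One roster and one three-relation network set per shift-point
#' (`n_weeks` weeks x day/night), plus the latent truth used to generate
#' them. Nonresponse is applied afterwards with [apply_nonresponse()] so the
#' complete-data panel remains available for parameter-recovery checks.
#'
#' @param config A [synthetic_config()].
#' @param apply_nonresponse If `TRUE` (default), mark each rostered person a
#'   nonrespondent with probability `config$nonresponse_rate` and blank their
#'   outgoing rows.
#' @return A `synthetic_dataset`: list with `config`, `rosters`, `networks`
#'   (both named by shift_id), `truth` (pool with latent sociabilities, seed,
#'   parameters) and `nonrespondents` (named list of person ids).
#' @export
generate_dataset <- function(config, apply_nonresponse = TRUE) {
  stopifnot(inherits(config, "synthetic_config"))
  grid <- tidyr::expand_grid(week = seq_len(config$n_weeks),
                             shift = c("day", "night"))
  rosters <- purrr::pmap(grid, function(week, shift) {
    generate_roster(config, week, shift)
  })
  networks <- purrr::map2(rosters, grid$shift, function(roster, shift) {
    generate_networks(config, roster, shift)
  })
  ids <- purrr::map_chr(rosters, ~ .x$shift_id[[1]])
  dataset <- structure(
    list(
      config = config,
      rosters = setNames(rosters, ids),
      networks = setNames(networks, ids),
      truth = list(
        seed = config$seed,
        parameters = unclass(config),
        pool = personnel_pool(config)
      ),
      nonrespondents = setNames(rep(list(character()), length(ids)), ids)
    ),
    class = "synthetic_dataset"
  )
  if (apply_nonresponse) dataset <- apply_nonresponse(dataset) else dataset
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset> %d shift-points (%d weeks x day/night), %d-member rosters, seed %d\n",
    length(x$networks), x$config$n_weeks, sum(x$config$role_counts),
    x$config$seed
  ))
  cat(sprintf("  nonrespondents: %d of %d person-shifts\n",
              sum(lengths(x$nonrespondents)),
              sum(purrr::map_int(x$rosters, nrow))))
  invisible(x)
}

#' Apply per-person survey nonresponse to a synthetic panel
#'
#' For each shift-point, each rostered person is independently marked a
#' nonrespondent with probability `rate`; a nonrespondent's outgoing row is
#' marked missing (`NA`, not zero) in all three matrices, while incoming
#' reports from respondents are retained. Deterministic in the dataset's
#' seed.
#'
#' @param dataset A `synthetic_dataset`.
#' @param rate Nonresponse probability; defaults to the dataset config's
#'   `nonresponse_rate`.
#' @return The dataset with `networks` rows blanked and `nonrespondents`
#'   filled in.
#' @export
apply_nonresponse <- function(dataset, rate = NULL) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  rate <- rate %||% dataset$config$nonresponse_rate
  if (rate < 0 || rate > 1) abort("`rate` must be in [0, 1].")
  for (id in names(dataset$networks)) {
    nset <- dataset$networks[[id]]
    set.seed(sub_seed(dataset$config$seed, nset$week, nset$shift, stage = 3L))
    nr <- nset$roster$person_id[
      runif(nrow(nset$roster)) < rate
    ]
    dataset$nonrespondents[[id]] <- nr
    if (length(nr)) {
      for (rel in names(nset$matrices)) {
        nset$matrices[[rel]][nr, ] <- NA_integer_
        nset$missing[[rel]] <- nr
      }
      dataset$networks[[id]] <- nset
    }
  }
  dataset
}

#' Calibrate the overlap loading to a target inter-relation correlation
#'
#' Simulates complete-data shift networks over a grid of common
#' `overlap_lambda` values, measures the mean weighted matrix correlation
#' between a relation pair, and linearly interpolates to the loading whose
#' expected correlation matches `target_r`. Expected correlation is monotone
#' increasing in the loading product, so interpolation on a bracketing grid
#' is sufficient.
#'
#' @param config A [synthetic_config()]; its `overlap_lambda` is ignored and
#'   replaced by each grid value in turn.
#' @param target_r Target expected matrix correlation (default 0.4).
#' @param pair Length-2 character vector of relations to calibrate against.
#' @param lambda_grid Increasing grid of candidate common loadings.
#' @param n_shifts Simulated shifts per grid point (large-replicate mean).
#' @return The config with all three `overlap_lambda` entries set to the
#'   calibrated value; the grid and its simulated means are attached as
#'   attribute `"calibration"`.
#' @export
calibrate_overlap <- function(config, target_r = 0.4,
                              pair = c("problem_solving", "socializing"),
                              lambda_grid = seq(0, 6, by = 1),
                              n_shifts = 60L) {
  stopifnot(inherits(config, "synthetic_config"))
  if (length(pair) != 2L) abort("`pair` must name two relations.")
  purrr::walk(pair, check_relation)
  mean_r <- purrr::map_dbl(lambda_grid, function(lam) {
    cfg <- config
    cfg$overlap_lambda[] <- lam
    rs <- purrr::map_dbl(seq_len(n_shifts), function(i) {
      cfg_i <- cfg
      cfg_i$seed <- sub_seed(config$seed, i, "day", stage = 5L)
      roster <- generate_roster(cfg_i, week = i, shift = "day")
      nset <- generate_networks(cfg_i, roster, shift = "day")
      matrix_correlation(nset$matrices[[pair[1]]], nset$matrices[[pair[2]]])
    })
    mean(rs)
  })
  if (target_r > max(mean_r) || target_r < min(mean_r)) {
    abort(sprintf(
      "target_r = %.2f outside the achievable range [%.3f, %.3f] on this grid.",
      target_r, min(mean_r), max(mean_r)
    ))
  }
  lambda_hat <- stats::approx(mean_r, lambda_grid, xout = target_r,
                              ties = "ordered")$y
  out <- config
  out$overlap_lambda[] <- lambda_hat
  attr(out, "calibration") <- tibble::tibble(
    lambda = lambda_grid, mean_r = mean_r,
    target_r = target_r, lambda_hat = lambda_hat
  )
  out
}
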