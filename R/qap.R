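#' Matrix correlation between two same-roster networks
#'
#' Pearson correlation computed over the jointly observed off-diagonal cells
#' of two square matrices on the same node set in the same order. Cells
#' missing in either matrix (nonrespondent rows) are excluded pairwise. By
#' default the weighted (valued) matrices are correlated; `binary = TRUE`
#' dichotomizes both at `threshold` first.
#'
#' @param X,Y Square numeric matrices of equal dimension, rows/columns in
#'   the same roster order.
#' @param binary Correlate tie indicators instead of frequencies.
#' @param threshold Dichotomization threshold when `binary = TRUE`.
#' @return Pearson correlation in \[-1, 1\].
#' @export
matrix_correlation <- function(X, Y, binary = FALSE, threshold = 1L) {
  check_qap_matrices(X, Y)
  v <- qap_cell_vectors(X, Y, binary, threshold)
  pearson_or_abort(v$x, v$y)
}

check_qap_matrices <- function(X, Y) {
  if (!is.matrix(X) || !is.matrix(Y) || nrow(X) != ncol(X) ||
      nrow(Y) != ncol(Y) || nrow(X) != nrow(Y)) {
    abort("`X` and `Y` must be square matrices of the same dimension.")
  }
  if (!is.null(rownames(X)) && !is.null(rownames(Y)) &&
      !identical(rownames(X), rownames(Y))) {
    abort("`X` and `Y` must share the same roster order (row names differ).")
  }
  invisible(TRUE)
}

# Jointly observed off-diagonal cells as paired vectors.
qap_cell_vectors <- function(X, Y, binary, threshold) {
  off <- row(X) != col(X)
  keep <- off & !is.na(X) & !is.na(Y)
  x <- as.numeric(X[keep])
  y <- as.numeric(Y[keep])
  if (binary) {
    x <- as.numeric(x >= threshold)
    y <- as.numeric(y >= threshold)
  }
  list(x = x, y = y)
}

pearson_or_abort <- function(x, y) {
  if (length(x) < 3) {
    abort("Undefined correlation: fewer than 3 jointly observed off-diagonal cells.")
  }
  sx <- sd(x)
  sy <- sd(y)
  if (sx == 0 || sy == 0) {
    abort("Undefined correlation: zero variance in at least one matrix.")
  }
  sum((x - mean(x)) * (y - mean(y))) / ((length(x) - 1) * sx * sy)
}

#' Quadratic assignment procedure (QAP) test
#'
#' Tests association between two networks on the same roster with a
#' restricted permutation test: each permutation applies one random node
#' relabeling `pi` simultaneously to the rows and columns of `Y`
#' (`Y[pi(i), pi(j)]`), which preserves the autocorrelational structure of
#' the network while breaking its alignment with `X`. Missingness travels
#' with the permuted nodes and cells are excluded pairwise after alignment.
#'
#' For rosters of `exhaustive_cap` or fewer nodes all `n!` relabelings are
#' enumerated and p-values are exact proportions (the identity relabeling
#' included). Otherwise `n_permutations` relabelings are sampled uniformly
#' and the conservative add-one estimate is used:
#' `p_ge = (1 + #\{r_perm >= r_obs\}) / (1 + n_permutations)`, `p_le`
#' analogously, and `p_two_sided = min(1, 2 min(p_ge, p_le))`.
#'
#' @inheritParams matrix_correlation
#' @param n_permutations Monte-Carlo sample size (>= 99).
#' @param seed Integer seed for the permutation draw (required in
#'   Monte-Carlo mode; recorded in the result either way).
#' @param exhaustive_cap Largest `n` for which full enumeration replaces
#'   sampling (default 7, i.e. up to 5040 relabelings).
#' @return An object of class `qap_test` with fields `r_obs`, `p_ge`,
#'   `p_le`, `p_two_sided`, `n_permutations`, `method`, `seed`, `n_nodes`,
#'   `n_cells`, and the permutation-distribution summary `perm_quantiles`.
#' @seealso [qap_panel()] for applying the test across a study panel;
#'   [tidy.qap_test()] / [glance.qap_test()] for tibble output.
#' @export
#' @examples
#' set.seed(7)
#' X <- matrix(rpois(49, 2), 7, 7); diag(X) <- NA
#' Y <- matrix(rpois(49, 2), 7, 7); diag(Y) <- NA
#' qap_test(X, Y, n_permutations = 199, seed = 1)
qap_test <- function(X, Y, n_permutations = 1000L, seed = NULL,
                     binary = FALSE, threshold = 1L, exhaustive_cap = 7L) {
  check_qap_matrices(X, Y)
  n <- nrow(X)
  r_obs <- matrix_correlation(X, Y, binary, threshold)
  exhaustive <- n <= exhaustive_cap
  if (!exhaustive) {
    if (n_permutations < 99) abort("`n_permutations` must be >= 99.")
    if (is.null(seed)) abort("A `seed` is required for Monte-Carlo QAP.")
  }
  perms <- if (exhaustive) {
    all_permutations(n)
  } else {
    set.seed(as.integer(seed))
    t(replicate(n_permutations, sample.int(n)))
  }
  r_perm <- apply(perms, 1L, function(p) {
    v <- qap_cell_vectors(X, Y[p, p, drop = FALSE], binary, threshold)
    if (length(v$x) < 3 || sd(v$x) == 0 || sd(v$y) == 0) return(NA_real_)
    sum((v$x - mean(v$x)) * (v$y - mean(v$y))) /
      ((length(v$x) - 1) * sd(v$x) * sd(v$y))
  })
  r_perm <- r_perm[!is.na(r_perm)]
  eps <- 1e-10
  if (exhaustive) {
    p_ge <- mean(r_perm >= r_obs - eps)
    p_le <- mean(r_perm <= r_obs + eps)
    n_used <- length(r_perm)
  } else {
    n_used <- length(r_perm)
    p_ge <- (1 + sum(r_perm >= r_obs - eps)) / (1 + n_used)
    p_le <- (1 + sum(r_perm <= r_obs + eps)) / (1 + n_used)
  }
  structure(
    list(
      r_obs = r_obs,
      p_ge = p_ge,
      p_le = p_le,
      p_two_sided = min(1, 2 * min(p_ge, p_le)),
      n_permutations = n_used,
      method = if (exhaustive) "exhaustive" else "monte_carlo",
      seed = if (exhaustive) NA_integer_ else as.integer(seed),
      n_nodes = n,
      n_cells = sum(row(X) != col(X) & !is.na(X) & !is.na(Y)),
      binary = binary,
      perm_quantiles = quantile(r_perm, c(0, 0.025, 0.25, 0.5, 0.75, 0.975, 1),
                                names = TRUE)
    ),
    class = "qap_test"
  )
}

#' @export
print.qap_test <- function(x, ...) {
  cat(sprintf(
    "QAP test (%s, %d permutations%s)\n  r_obs = %.4f, p_two_sided = %.4g (p_ge = %.4g, p_le = %.4g)\n  %d nodes, %d jointly observed cells, %s correlation\n",
    x$method, x$n_permutations,
    if (is.na(x$seed)) "" else sprintf(", seed %d", x$seed),
    x$r_obs, x$p_two_sided, x$p_ge, x$p_le,
    x$n_nodes, x$n_cells, if (x$binary) "binary" else "valued"
  ))
  invisible(x)
}

#' Tidy a QAP test into a one-row tibble
#'
#' @param x A `qap_test`.
#' @param ... Unused.
#' @return One-row tibble with the observed correlation, tail and two-sided
#'   p-values, permutation count, method and seed.
#' @method tidy qap_test
#' @export
tidy.qap_test <- function(x, ...) {
  tibble::tibble(
    r_obs = x$r_obs,
    p_two_sided = x$p_two_sided,
    p_ge = x$p_ge,
    p_le = x$p_le,
    n_permutations = x$n_permutations,
    method = x$method,
    seed = x$seed
  )
}

#' One-row model summary of a QAP test
#'
#' @inheritParams tidy.qap_test
#' @return One-row tibble with network size, cell count and correlation mode
#'   alongside the headline statistics.
#' @method glance qap_test
#' @export
glance.qap_test <- function(x, ...) {
  tibble::tibble(
    n_nodes = x$n_nodes,
    n_cells = x$n_cells,
    binary = x$binary,
    r_obs = x$r_obs,
    p_two_sided = x$p_two_sided,
    n_permutations = x$n_permutations,
    method = x$method
  )
}

#' QAP tests across a study panel
#'
#' Runs [qap_test()] for every shift-point and every requested relation
#' pair, keeping day and night shifts separate. A 12-week day/night design
#' yields 24 results per pair, 72 in total for all three pairs. Shift-points
#' that fail preconditions (degenerate matrices, too few observed cells) are
#' reported in the `skipped` attribute, never silently dropped.
#'
#' @param networks A `synthetic_dataset` or (named) list of
#'   `shift_network_set`.
#' @param pairs `"all"` for the three unordered relation pairs, or a list of
#'   length-2 character vectors.
#' @param n_permutations,binary,threshold,exhaustive_cap Passed to
#'   [qap_test()].
#' @param seed Integer panel seed; each test gets a sub-seed derived from it
#'   and its (week, shift, pair) cell, and that sub-seed is recorded in the
#'   row.
#' @return A tibble of class `qap_panel`: one row per shift-point x pair
#'   with `r_obs`, p-values, permutation count, method and seed.
#' @export
qap_panel <- function(networks, pairs = "all", n_permutations = 1000L,
                      seed = 1L, binary = FALSE, threshold = 1L,
                      exhaustive_cap = 7L) {
  nets <- as_network_list(networks)
  if (!length(nets)) abort("At least one shift-point is required.")
  if (identical(pairs, "all")) {
    rels <- relation_types()
    pairs <- list(c(rels[1], rels[2]), c(rels[1], rels[3]), c(rels[2], rels[3]))
  }
  skipped <- list()
  rows <- purrr::imap(nets, function(nset, id) {
    purrr::imap(pairs, function(pair, k) {
      test_seed <- sub_seed(seed, nset$week %||% 0L,
                            nset$shift %||% "day", stage = 10L + k)
      res <- tryCatch(
        qap_test(nset$matrices[[pair[1]]], nset$matrices[[pair[2]]],
                 n_permutations = n_permutations, seed = test_seed,
                 binary = binary, threshold = threshold,
                 exhaustive_cap = exhaustive_cap),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        skipped[[length(skipped) + 1]] <<- tibble::tibble(
          shift_id = id, pair = paste(pair, collapse = "~"),
          reason = conditionMessage(res)
        )
        return(NULL)
      }
      dplyr::bind_cols(
        tibble::tibble(
          shift_id = id, week = nset$week, shift = nset$shift,
          pair = paste(pair, collapse = "~"),
          relation_a = pair[1], relation_b = pair[2],
          n_nodes = res$n_nodes
        ),
        tidy(res)
      )
    }) |> dplyr::bind_rows()
  }) |>
    dplyr::bind_rows()
  if (length(skipped)) {
    skipped <- dplyr::bind_rows(skipped)
    warn(sprintf("%d shift-point x pair combination(s) skipped; see attr(x, \"skipped\").",
                 nrow(skipped)))
    attr(rows, "skipped") <- skipped
  }
  class(rows) <- c("qap_panel", class(rows))
  rows
}
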