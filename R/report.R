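#' Stratify shift metrics into a week x shift x relation series
#'
#' Arranges per-shift metric rows into the complete longitudinal design.
#' Missing shift-points are kept as explicit `NA` rows, never interpolated,
#' so gaps in data collection stay visible. Duplicate
#' (week, shift, relation) records are an error.
#'
#' @param metrics A tibble of [shift_metrics()] rows (e.g. from
#'   [dataset_metrics()]).
#' @return A tibble of class `metrics_series`, one row per
#'   week x shift x relation over the observed week range.
#' @export
build_series <- function(metrics) {
  required <- c("week", "shift", "relation", "density_pct")
  if (!all(required %in% names(metrics)) || nrow(metrics) < 1) {
    abort("`metrics` must contain at least one shift_metrics() row.")
  }
  dup <- metrics |>
    dplyr::count(.data$week, .data$shift, .data$relation) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    abort(sprintf("Duplicate metrics for week %s, %s shift, relation %s.",
                  dup$week[1], dup$shift[1], dup$relation[1]))
  }
  series <- metrics |>
    tidyr::complete(
      week = tidyr::full_seq(.data$week, 1),
      shift = c("day", "night"),
      relation = relation_types()
    ) |>
    dplyr::arrange(.data$week, .data$shift, .data$relation)
  class(series) <- c("metrics_series", class(series))
  series
}

#' Night-minus-day density contrasts per week and relation
#'
#' @param series A `metrics_series` from [build_series()] (or any tibble
#'   with week, shift, relation, density_pct).
#' @return Tibble `week, relation, density_day, density_night,
#'   night_minus_day`; the contrast is `NA` when either shift is missing.
#' @export
shift_contrasts <- function(series) {
  series |>
    dplyr::select("week", "shift", "relation", "density_pct") |>
    tidyr::pivot_wider(names_from = "shift", values_from = "density_pct",
                       names_prefix = "density_") |>
    dplyr::mutate(night_minus_day = .data$density_night - .data$density_day) |>
    dplyr::arrange(.data$week, .data$relation)
}

#' Boxplot summaries of a QAP correlation panel
#'
#' Order statistics of the observed correlations per relation pair and
#' day/night shift, the ingredients of the classic six-boxplot display:
#' median (midpoint convention for even counts), quartiles by the inclusive
#' linear-interpolation convention (`stats::quantile` type 7), minimum,
#' maximum, the number of underlying correlations, and how many were
#' significant at `alpha` (two-sided).
#'
#' @param panel A `qap_panel` tibble.
#' @param alpha Two-sided significance level (default 0.05).
#' @return Tibble with one row per pair x shift group, of class
#'   `qap_summary`; the quartile convention is recorded in
#'   `attr(, "quartile_type")`.
#' @export
summarize_qap_panel <- function(panel, alpha = 0.05) {
  if (!nrow(panel)) abort("`panel` is empty.")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  groups <- panel |>
    dplyr::group_by(.data$pair, .data$shift) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = median(.data$r_obs),
      q1 = quantile(.data$r_obs, 0.25, type = 7, names = FALSE),
      q3 = quantile(.data$r_obs, 0.75, type = 7, names = FALSE),
      min = min(.data$r_obs),
      max = max(.data$r_obs),
      n_significant = sum(.data$p_two_sided < alpha),
      .groups = "drop"
    ) |>
    dplyr::mutate(alpha = alpha)
  empty <- groups$n == 0
  if (any(empty)) {
    warn("Empty pair x shift group(s) omitted from the summary.")
    groups <- groups[!empty, ]
  }
  attr(groups, "quartile_type") <- 7L
  class(groups) <- c("qap_summary", class(groups))
  groups
}

#' Export a sociogram of one shift relation
#'
#' Builds the node-link specification of the classic sociogram: node size is
#' an affine map of normalized in-degree centrality (larger = more targeted,
#' the "stars"), edge width an affine map of reported frequency 1..10
#' (thicker = more communication), and members with no tie in the
#' symmetrized network are flagged isolates and assigned a separate layout
#' group placed apart from the connected component. The canonical outputs
#' are GraphML and Graphviz DOT files carrying all attributes; rendering is
#' a thin optional layer on top (see [autoplot.sociogram_spec()]).
#'
#' @param network A `shift_network_set`.
#' @param relation One of [relation_types()].
#' @param out_dir Directory for the exported files (created if needed);
#'   `NULL` to skip writing and return the spec only.
#' @param basename File stem; defaults to `<shift_id>_<relation>`.
#' @param threshold Tie threshold for edges and isolate detection.
#' @param layout_seed Seed for the force-directed layout (recorded in the
#'   spec so layouts reproduce).
#' @param size_range,width_range Output ranges of the affine node-size and
#'   edge-width maps.
#' @return An object of class `sociogram_spec`: tibbles `nodes` (id, role,
#'   in_degree, size, isolate, x, y) and `edges` (source, target, weight,
#'   width), the igraph `graph`, file paths, and layout seed.
#' @export
export_sociogram <- function(network, relation, out_dir = NULL,
                             basename = NULL, threshold = 1L,
                             layout_seed = 42L,
                             size_range = c(6, 30),
                             width_range = c(0.5, 5)) {
  stopifnot(inherits(network, "shift_network_set"))
  check_relation(relation)
  if (is.null(network$matrices[[relation]])) {
    abort(sprintf("Relation '%s' absent from network set.", relation))
  }
  W <- network$matrices[[relation]]
  indeg <- in_degree_centrality(network, relation, threshold)
  dn <- dichotomize_symmetrize(network, relation, threshold)
  adj <- dn$adj
  adj[is.na(adj)] <- FALSE
  isolates <- rowSums(adj) == 0

  idx <- which(!is.na(W) & W >= threshold, arr.ind = TRUE)
  edges <- tibble::tibble(
    source = rownames(W)[idx[, 1]],
    target = colnames(W)[idx[, 2]],
    weight = W[idx]
  ) |>
    dplyr::arrange(.data$source, .data$target)
  # Affine maps over fixed domains so sizes/widths are comparable across
  # shifts: in-degree on [0, 1], frequency on [1, 10].
  edges$width <- width_range[1] +
    (edges$weight - 1) / 9 * diff(width_range)
  nodes <- tibble::tibble(
    id = indeg$person_id,
    role = indeg$role,
    in_degree = dplyr::coalesce(indeg$in_degree, 0),
    isolate = unname(isolates)
  )
  nodes$size <- size_range[1] + nodes$in_degree * diff(size_range)

  # DOT has no boolean attribute type; carry the isolate flag as 0/1.
  g <- igraph::graph_from_data_frame(
    edges, directed = TRUE,
    vertices = dplyr::mutate(nodes, isolate = as.integer(.data$isolate))
  )
  set.seed(as.integer(layout_seed))
  xy <- igraph::layout_with_fr(g)
  # Isolates form their own layout group, stacked apart (upper left).
  iso <- nodes$isolate
  if (any(iso) && any(!iso)) {
    xy[iso, 1] <- min(xy[!iso, 1]) - 2
    xy[iso, 2] <- max(xy[!iso, 2]) + seq_len(sum(iso)) * 0.8
  }
  nodes$x <- xy[, 1]
  nodes$y <- xy[, 2]
  igraph::V(g)$x <- xy[, 1]
  igraph::V(g)$y <- xy[, 2]

  files <- character()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    basename <- basename %||%
      sprintf("%s_%s", network$shift_id %||% "shift", relation)
    graphml <- file.path(out_dir, paste0(basename, ".graphml"))
    dot <- file.path(out_dir, paste0(basename, ".dot"))
    igraph::write_graph(g, graphml, format = "graphml")
    igraph::write_graph(g, dot, format = "dot")
    files <- c(graphml = graphml, dot = dot)
  }
  structure(
    list(
      nodes = nodes,
      edges = edges,
      graph = g,
      relation = relation,
      shift_id = network$shift_id,
      layout_seed = as.integer(layout_seed),
      threshold = threshold,
      files = files
    ),
    class = "sociogram_spec"
  )
}

#' @export
print.sociogram_spec <- function(x, ...) {
  cat(sprintf(
    "<sociogram_spec> %s / %s: %d nodes (%d isolates), %d edges%s\n",
    x$shift_id %||% "?", x$relation, nrow(x$nodes), sum(x$nodes$isolate),
    nrow(x$edges),
    if (length(x$files)) sprintf("; written: %s",
                                 paste(basename(x$files), collapse = ", "))
    else ""
  ))
  invisible(x)
}
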