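#' Dyadic network density
#'
#' The proportion of observable dyads (unordered pairs of distinct members)
#' that carry a communication tie, expressed as a percentage. On a 4-member
#' team where 5 of the 6 possible dyads communicate, density is
#' 5/6 = 83.3%. Dyads excluded for missingness (both directions unobserved)
#' are removed from the denominator.
#'
#' @param network A `dyad_network` (see [dichotomize_symmetrize()]).
#' @return Density percentage in \[0, 100\].
#' @export
#' @examples
#' net <- dyad_network(LETTERS[1:4],
#'   list(c("C","A"), c("C","B"), c("C","D"), c("D","A"), c("D","B")))
#' network_density(net) # 83.3
network_density <- function(network) {
  stopifnot(inherits(network, "dyad_network"))
  n <- nrow(network$roster)
  if (n < 2) abort("Density is undefined for networks with fewer than 2 members.")
  up <- network$adj[upper.tri(network$adj)]
  possible <- sum(!is.na(up))
  if (possible == 0) {
    abort("Density is undefined: no observable dyads (all surveys missing).")
  }
  100 * sum(up, na.rm = TRUE) / possible
}

#' Freeman degree centralization
#'
#' Network-level concentration of ties on the symmetrized binary network:
#' the sum over members of (maximum degree - member's degree), divided by
#' the maximum that sum can attain on any network of the same size,
#' `(n - 1)(n - 2)` -- realized by a star. Expressed as a percentage: 0 for
#' regular networks (everyone equally connected), 100 for a perfect star.
#'
#' Unobservable dyads (both directions missing) contribute no tie to either
#' member's degree.
#'
#' @param network A `dyad_network`.
#' @return Centralization percentage in \[0, 100\].
#' @export
#' @examples
#' net <- dyad_network(LETTERS[1:4],
#'   list(c("C","A"), c("C","B"), c("C","D"), c("D","A"), c("D","B")))
#' degree_centralization(net) # 33.33...
degree_centralization <- function(network) {
  stopifnot(inherits(network, "dyad_network"))
  n <- nrow(network$roster)
  if (n < 3) {
    abort("Degree centralization is undefined for fewer than 3 members.")
  }
  adj <- network$adj
  adj[is.na(adj)] <- FALSE
  deg <- rowSums(adj)
  100 * sum(max(deg) - deg) / ((n - 1) * (n - 2))
}

#' Normalized in-degree centrality
#'
#' For each member, the number of colleagues who reported initiating
#' communication toward them (incoming arcs with frequency at or above the
#' threshold), standardized by the number of potential senders: rostered
#' members other than the target whose survey row is observed. A member every
#' respondent reports toward scores 1; an isolate scores 0. Members with no
#' potential senders get `NA` (flagged undefined).
#'
#' @param network A `shift_network_set`.
#' @param relation One of [relation_types()].
#' @param threshold Minimum frequency that counts as a tie (default 1).
#' @return A tibble `person_id, role, in_degree_raw, potential_senders,
#'   in_degree` with `in_degree` in \[0, 1\].
#' @export
in_degree_centrality <- function(network, relation, threshold = 1L) {
  stopifnot(inherits(network, "shift_network_set"))
  check_relation(relation)
  W <- network$matrices[[relation]]
  n <- nrow(W)
  if (n < 2) abort("In-degree is undefined for fewer than 2 members.")
  row_observed <- unname(rowSums(!is.na(W)) > 0)
  incoming <- unname(colSums(W >= threshold & !is.na(W)))
  senders <- sum(row_observed) - row_observed  # exclude self when observed
  tibble::tibble(
    person_id = network$roster$person_id,
    role = network$roster$role,
    in_degree_raw = as.integer(incoming),
    potential_senders = as.integer(senders),
    in_degree = ifelse(senders > 0, incoming / senders, NA_real_)
  )
}

#' Freeman-style in-degree centralization
#'
#' Concentration of the in-degree distribution at the network level:
#' `100 * sum_j(din_max - din_j) / (n - 1)^2` on binary incoming arcs, the
#' standard directed-degree denominator (attained when one member receives
#' from everyone and nobody else receives at all). Missing sender rows are
#' ignored consistently with [in_degree_centrality()].
#'
#' @inheritParams in_degree_centrality
#' @return Percentage in \[0, 100\].
#' @export
in_degree_centralization <- function(network, relation, threshold = 1L) {
  stopifnot(inherits(network, "shift_network_set"))
  check_relation(relation)
  W <- network$matrices[[relation]]
  n <- nrow(W)
  if (n < 3) {
    abort("In-degree centralization is undefined for fewer than 3 members.")
  }
  din <- colSums(W >= threshold & !is.na(W))
  100 * sum(max(din) - din) / ((n - 1)^2)
}

#' Stars and isolates of one relation network
#'
#' Isolates are members with no tie in the symmetrized binary network --
#' drawn unattached in a sociogram. Stars are the members with maximal
#' in-degree (the most frequent targets of communication, often read as
#' powerful or influential); all maximizers are reported, never an arbitrary
#' tie-break, and a network with no ties has no stars.
#'
#' @inheritParams in_degree_centrality
#' @return List with character vectors `stars` and `isolates`.
#' @export
stars_and_isolates <- function(network, relation, threshold = 1L) {
  stopifnot(inherits(network, "shift_network_set"))
  check_relation(relation)
  dn <- dichotomize_symmetrize(network, relation, threshold)
  adj <- dn$adj
  adj[is.na(adj)] <- FALSE
  isolates <- dn$roster$person_id[rowSums(adj) == 0]
  indeg <- in_degree_centrality(network, relation, threshold)
  any_tie <- any(indeg$in_degree_raw > 0)
  stars <- if (any_tie) {
    indeg$person_id[indeg$in_degree_raw == max(indeg$in_degree_raw)]
  } else {
    character()
  }
  list(stars = stars, isolates = isolates)
}

#' All shift-level metrics for one or more relations
#'
#' One row per relation: dyadic density, Freeman degree centralization,
#' in-degree centralization, the role(s) of the member(s) with highest
#' in-degree, isolates, and the count of dyads excluded for missingness.
#' Per-member in-degrees are nested in the `in_degree` list-column.
#'
#' @param network A `shift_network_set`.
#' @param relations Relations to compute (default all three).
#' @param threshold Tie threshold (default 1).
#' @return A tibble with one row per relation.
#' @export
shift_metrics <- function(network, relations = relation_types(), threshold = 1L) {
  stopifnot(inherits(network, "shift_network_set"))
  purrr::map(relations, function(rel) {
    dn <- dichotomize_symmetrize(network, rel, threshold)
    indeg <- in_degree_centrality(network, rel, threshold)
    si <- stars_and_isolates(network, rel, threshold)
    top_roles <- unique(indeg$role[indeg$person_id %in% si$stars])
    n <- nrow(network$roster)
    tibble::tibble(
      shift_id = network$shift_id,
      week = network$week,
      shift = network$shift,
      relation = rel,
      n = n,
      density_pct = network_density(dn),
      centralization_pct = if (n >= 3) degree_centralization(dn) else NA_real_,
      in_degree_centralization_pct =
        if (n >= 3) in_degree_centralization(network, rel, threshold) else NA_real_,
      top_in_degree_roles = list(top_roles),
      stars = list(si$stars),
      isolates = list(si$isolates),
      excluded_dyads = dn$excluded_dyads,
      in_degree = list(indeg)
    )
  }) |>
    dplyr::bind_rows()
}

#' Shift metrics for every shift-point of a panel
#'
#' Applies [shift_metrics()] across a full panel. Shift-points where a
#' relation is undefined (for example, no returned surveys at all) are
#' reported in the `skipped` attribute rather than silently dropped.
#'
#' @param networks A `synthetic_dataset` or a (named) list of
#'   `shift_network_set`.
#' @param threshold Tie threshold (default 1).
#' @return A tibble of per-(shift-point x relation) metric rows; skipped
#'   combinations, if any, in `attr(, "skipped")`.
#' @export
dataset_metrics <- function(networks, threshold = 1L) {
  nets <- as_network_list(networks)
  skipped <- list()
  rows <- purrr::imap(nets, function(nset, id) {
    purrr::map(relation_types(), function(rel) {
      tryCatch(
        shift_metrics(nset, rel, threshold),
        error = function(e) {
          skipped[[length(skipped) + 1]] <<-
            tibble::tibble(shift_id = id, relation = rel,
                           reason = conditionMessage(e))
          NULL
        }
      )
    }) |> dplyr::bind_rows()
  }) |>
    dplyr::bind_rows()
  if (length(skipped)) {
    skipped <- dplyr::bind_rows(skipped)
    warn(sprintf("%d shift x relation combination(s) skipped; see attr(x, \"skipped\").",
                 nrow(skipped)))
    attr(rows, "skipped") <- skipped
  }
  rows
}

# Accept a synthetic_dataset or plain list of shift_network_set.
as_network_list <- function(networks) {
  if (inherits(networks, "synthetic_dataset")) return(networks$networks)
  if (inherits(networks, "shift_network_set")) {
    return(setNames(list(networks), networks$shift_id))
  }
  if (is.list(networks) &&
      all(purrr::map_lgl(networks, inherits, "shift_network_set"))) {
    if (is.null(names(networks))) {
      names(networks) <- purrr::map_chr(networks, ~ .x$shift_id %||% NA_character_)
    }
    return(networks)
  }
  abort("Expected a synthetic_dataset or a list of shift_network_set objects.")
}
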