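#' Construct a per-shift multiplex network set
#'
#' Bundles a shift roster with one directed weighted adjacency matrix per
#' communication relation. Cell `W[i, j]` holds the frequency (0-10) that
#' respondent `i` reported initiating communication toward colleague `j`
#' during the shift; the diagonal is structurally absent (`NA`). Rows of
#' rostered members who returned no survey are marked missing (`NA`), which
#' is distinct from an all-zero row.
#'
#' @param roster A tibble with at least `person_id` and `role` columns
#'   (optionally `shift_id`, `week`, `shift`, `date`). Row order is canonical
#'   and defines matrix row/column order.
#' @param matrices Named list of square integer matrices, one per relation in
#'   [relation_types()], with dimnames equal to `roster$person_id`.
#' @param missing Person ids with no returned survey: either a character
#'   vector (applied to all relations) or a named list per relation.
#' @return An object of class `shift_network_set`.
#' @seealso [build_networks()], [generate_networks()], [dichotomize_symmetrize()]
#' @export
new_shift_network_set <- function(roster, matrices, missing = character()) {
  stopifnot(is.data.frame(roster), nrow(roster) >= 1)
  if (anyDuplicated(roster$person_id)) {
    abort("Roster person_ids must be unique.")
  }
  ids <- roster$person_id
  n <- length(ids)
  if (!is.list(matrices) || is.null(names(matrices))) {
    abort("`matrices` must be a named list of matrices.")
  }
  if (!is.list(missing)) {
    missing <- setNames(rep(list(as.character(missing)), length(matrices)),
                        names(matrices))
  }
  for (rel in names(matrices)) {
    W <- matrices[[rel]]
    if (!is.matrix(W) || nrow(W) != n || ncol(W) != n) {
      abort(sprintf("Matrix for relation '%s' must be %d x %d (roster size).",
                    rel, n, n))
    }
    if (is.null(dimnames(W))) {
      dimnames(W) <- list(ids, ids)
    } else if (!identical(rownames(W), ids) || !identical(colnames(W), ids)) {
      abort(sprintf("Dimnames of matrix '%s' must match roster order.", rel))
    }
    diag(W) <- NA_integer_
    storage.mode(W) <- "integer"
    off <- W[row(W) != col(W)]
    if (any(!is.na(off) & (off < 0L | off > 10L))) {
      abort(sprintf("Matrix '%s' has entries outside 0..10.", rel))
    }
    bad <- setdiff(missing[[rel]], ids)
    if (length(bad)) {
      abort(sprintf("Missing ids not on roster: %s", paste(bad, collapse = ", ")))
    }
    W[missing[[rel]], ] <- NA_integer_
    matrices[[rel]] <- W
  }
  structure(
    list(
      roster = tibble::as_tibble(roster),
      matrices = matrices,
      missing = missing,
      shift_id = if ("shift_id" %in% names(roster)) roster$shift_id[[1]] else NA_character_,
      week = if ("week" %in% names(roster)) roster$week[[1]] else NA_integer_,
      shift = if ("shift" %in% names(roster)) roster$shift[[1]] else NA_character_
    ),
    class = "shift_network_set"
  )
}

#' @export
print.shift_network_set <- function(x, ...) {
  n_missing <- lengths(x$missing)
  cat(sprintf(
    "<shift_network_set> %s: %d members, relations: %s\n",
    x$shift_id %||% "?", nrow(x$roster),
    paste(sprintf("%s (%d missing rows)", names(x$matrices), n_missing),
          collapse = ", ")
  ))
  invisible(x)
}

#' Construct a dyadic (undirected, binary) network
#'
#' A `dyad_network` records presence or absence of a communication tie on
#' each unordered pair of distinct members. It is the container on which
#' dyadic density and Freeman degree centralization are defined. Usually
#' produced by [dichotomize_symmetrize()]; this constructor builds one
#' directly from a tie list, which is convenient for worked examples and
#' tests.
#'
#' @param members Character vector of unique member ids (canonical order).
#' @param ties List of length-2 character vectors (or a 2-column matrix),
#'   each an unordered pair of distinct members with a tie.
#' @param roles Optional character vector of roles, recycled against members.
#' @param relation,threshold,rule Provenance metadata describing how the
#'   dyadic network was derived.
#' @return An object of class `dyad_network`.
#' @export
#' @examples
#' # Four team members; every dyad tied except A-B
#' net <- dyad_network(
#'   c("A", "B", "C", "D"),
#'   list(c("C", "A"), c("C", "B"), c("C", "D"), c("D", "A"), c("D", "B"))
#' )
#' network_density(net)       # 83.3
#' degree_centralization(net) # 33.33
dyad_network <- function(members, ties = list(), roles = NULL,
                         relation = NA_character_, threshold = 1L,
                         rule = "union") {
  if (anyDuplicated(members)) abort("`members` must be unique.")
  n <- length(members)
  adj <- matrix(FALSE, n, n, dimnames = list(members, members))
  if (is.matrix(ties)) ties <- asplit(ties, 1)
  for (tie in ties) {
    tie <- as.character(tie)
    if (length(tie) != 2L || tie[1] == tie[2]) {
      abort("Each tie must be a pair of two distinct members.")
    }
    if (!all(tie %in% members)) {
      abort(sprintf("Tie references unknown member: %s", paste(tie, collapse = "-")))
    }
    adj[tie[1], tie[2]] <- TRUE
    adj[tie[2], tie[1]] <- TRUE
  }
  diag(adj) <- NA
  roster <- tibble::tibble(
    person_id = members,
    role = if (is.null(roles)) NA_character_ else rep_len(roles, n)
  )
  new_dyad_network(roster, adj, relation, threshold, rule)
}

new_dyad_network <- function(roster, adj, relation, threshold, rule) {
  diag(adj) <- NA
  up <- upper.tri(adj)
  structure(
    list(
      roster = tibble::as_tibble(roster),
      adj = adj,
      relation = relation,
      threshold = threshold,
      rule = rule,
      excluded_dyads = sum(is.na(adj[up]))
    ),
    class = "dyad_network"
  )
}

#' @export
print.dyad_network <- function(x, ...) {
  up <- upper.tri(x$adj)
  cat(sprintf(
    "<dyad_network> %d members, %d of %d observable dyads tied (%d excluded)%s\n",
    nrow(x$roster), sum(x$adj[up], na.rm = TRUE), sum(!is.na(x$adj[up])),
    x$excluded_dyads,
    if (is.na(x$relation)) "" else sprintf(", relation: %s", x$relation)
  ))
  invisible(x)
}

#' Dichotomize and symmetrize one relation of a shift network set
#'
#' Reduces a directed weighted matrix to the dyadic presence/absence network
#' used for density and centralization. A dyad \{i, j\} carries a tie if
#' either reported frequency reaches the threshold (`W[i,j] >= threshold` or
#' `W[j,i] >= threshold`) among non-missing entries -- the union rule. Dyads
#' where both directions are missing (both members nonrespondents) are
#' unobservable: they are excluded from the possible-dyad count and tallied
#' in `excluded_dyads` rather than treated as absent.
#'
#' @param network A [new_shift_network_set()] object.
#' @param relation One of [relation_types()].
#' @param threshold Minimum reported frequency that constitutes a tie
#'   (default 1, the minimal reading of "presence").
#' @return A `dyad_network`.
#' @export
dichotomize_symmetrize <- function(network, relation, threshold = 1L) {
  stopifnot(inherits(network, "shift_network_set"))
  check_relation(relation)
  W <- network$matrices[[relation]]
  if (is.null(W)) abort(sprintf("Relation '%s' absent from network set.", relation))
  observed_rows <- rowSums(!is.na(W)) > 0
  if (!any(observed_rows)) {
    abort(sprintf(
      "Undefined network: all rows missing for relation '%s' (no returned surveys).",
      relation
    ))
  }
  A <- W >= threshold
  A0 <- A
  A0[is.na(A0)] <- FALSE
  U <- A0 | t(A0)
  observable <- (!is.na(A)) | t(!is.na(A))
  U[!observable] <- NA
  new_dyad_network(network$roster, U, relation, threshold, "union")
}
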