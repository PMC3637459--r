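# Fixtures and independent oracles used across the suite. Oracles are
# deliberately written with different algorithms than the implementation
# (loops and stats::cor instead of vectorized matrix code and the internal
# Pearson) so agreement is evidence, not tautology.

`%||%` <- function(a, b) if (is.null(a)) b else a

# The 4-member worked example: every dyad tied except A-B.
figure_dyad <- function() {
  dyad_network(
    c("A", "B", "C", "D"),
    list(c("C", "A"), c("C", "B"), c("C", "D"), c("D", "A"), c("D", "B"))
  )
}

# Directed weighted version of the same shift (A and B returned all-zero
# surveys; C and D reported the frequencies).
figure_nset <- function() {
  ids <- c("A", "B", "C", "D")
  W <- matrix(0L, 4, 4, dimnames = list(ids, ids))
  W["C", "A"] <- 2L; W["C", "B"] <- 1L; W["C", "D"] <- 3L
  W["D", "A"] <- 1L; W["D", "B"] <- 2L
  diag(W) <- NA_integer_
  roster <- tibble::tibble(
    shift_id = "W08_day", week = 8L, shift = "day",
    person_id = ids, role = c("SRN", "PCT", "CRN", "RMD")
  )
  new_shift_network_set(
    roster,
    list(problem_solving = W, medication_advice = W, socializing = W)
  )
}

# Build a shift_network_set from one matrix reused across relations.
nset_from_matrix <- function(W, missing = character()) {
  ids <- if (is.null(rownames(W))) paste0("P", seq_len(nrow(W))) else rownames(W)
  dimnames(W) <- list(ids, ids)
  roster <- tibble::tibble(person_id = ids,
                           role = rep_len(role_types(), length(ids)))
  new_shift_network_set(
    roster,
    list(problem_solving = W, medication_advice = W, socializing = W),
    missing = missing
  )
}

random_weight_matrix <- function(n, seed, p = 0.5) {
  set.seed(seed)
  W <- matrix(ifelse(runif(n * n) < p, sample(1:10, n * n, TRUE), 0L), n, n)
  diag(W) <- NA_integer_
  storage.mode(W) <- "integer"
  W
}

# Dyad network from an upper-triangle tie indicator vector (row-major over
# dyads (1,2), (1,3), ..., (n-1,n)); used to enumerate all tie sets.
dyad_from_bits <- function(n, bits) {
  ids <- LETTERS[seq_len(n)]
  pairs <- utils::combn(n, 2)
  ties <- lapply(which(bits == 1L), function(k) ids[pairs[, k]])
  dyad_network(ids, ties)
}

# --- independent oracles -------------------------------------------------

oracle_density <- function(dn) {
  ids <- dn$roster$person_id
  present <- 0L; possible <- 0L
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i < j && !is.na(dn$adj[i, j])) {
      possible <- possible + 1L
      if (dn$adj[i, j]) present <- present + 1L
    }
  }
  100 * present / possible
}

oracle_centralization <- function(dn) {
  adj <- dn$adj
  adj[is.na(adj)] <- FALSE
  n <- nrow(adj)
  deg <- integer(n)
  for (i in seq_len(n)) deg[i] <- sum(adj[i, ])
  100 * sum(max(deg) - deg) / ((n - 1) * (n - 2))
}

oracle_in_degree <- function(W, threshold = 1L) {
  n <- nrow(W)
  observed <- vapply(seq_len(n), function(i) any(!is.na(W[i, ])), logical(1))
  sapply(seq_len(n), function(j) {
    senders <- setdiff(which(observed), j)
    if (!length(senders)) return(NA_real_)
    hits <- sum(vapply(senders, function(i) {
      !is.na(W[i, j]) && W[i, j] >= threshold
    }, logical(1)))
    hits / length(senders)
  })
}

# Heap's algorithm: a different enumeration order than the implementation's
# recursive generator.
heap_permutations <- function(n) {
  out <- vector("list", factorial(n))
  count <- 0L
  a <- seq_len(n)
  rec <- function(k) {
    if (k == 1L) {
      count <<- count + 1L
      out[[count]] <<- a
      return(invisible())
    }
    for (i in seq_len(k)) {
      rec(k - 1L)
      j <- if (k %% 2L == 0L) i else 1L
      tmp <- a[j]; a[j] <<- a[k]; a[k] <<- tmp
    }
  }
  rec(n)
  out
}

# Exact QAP tail probabilities by full enumeration, using stats::cor.
oracle_qap_exact <- function(X, Y) {
  off <- row(X) != col(X)
  r_of <- function(Yp) {
    keep <- off & !is.na(X) & !is.na(Yp)
    stats::cor(X[keep], Yp[keep])
  }
  r_obs <- r_of(Y)
  rs <- vapply(heap_permutations(nrow(X)), function(p) r_of(Y[p, p]), numeric(1))
  list(
    r_obs = r_obs,
    p_ge = mean(rs >= r_obs - 1e-10),
    p_le = mean(rs <= r_obs + 1e-10)
  )
}
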