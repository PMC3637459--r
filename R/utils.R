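# Internal helpers shared across modules.

# Round half away from zero (base round() is banker's rounding).
round_half_away <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# Deterministic sub-seed for a (week, shift, stage) cell, kept within 32-bit
# integer range so set.seed() accepts it.
sub_seed <- function(seed, week, shift, stage = 0L) {
  s <- (as.numeric(seed) %% 1e6) * 1000 +
    week * 17 + (shift == "night") * 7 + stage * 3
  as.integer(s %% .Machine$integer.max)
}

check_shift <- function(shift) {
  if (!is.character(shift) || length(shift) != 1L || !shift %in% c("day", "night")) {
    abort("`shift` must be \"day\" or \"night\".")
  }
  shift
}

check_relation <- function(relation) {
  if (!is.character(relation) || length(relation) != 1L ||
      !relation %in% relation_types()) {
    abort(paste0(
      "`relation` must be one of: ",
      paste(relation_types(), collapse = ", "), "."
    ))
  }
  relation
}

# All permutations of 1..n as an n! x n integer matrix (row = one permutation).
# Used for exhaustive QAP enumeration at small n; guarded by a cap upstream.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- r + seq_len(nrow(sub))
    out[rows, k] <- n
    out[rows, -k] <- sub
    r <- r + nrow(sub)
  }
  out
}
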