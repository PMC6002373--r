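# Independent brute-force oracles, deliberately written with plain set
# operations (no membership matrices) so they share no code with the
# implementation they check.

# resolvability by exhaustive enumeration over character sets
oracle_resolvability <- function(members, order = 2) {
  ids <- names(members)
  m <- length(ids)
  subset_of <- function(a, b) all(a %in% b)
  per <- data.frame(stm_id = ids, unique_frac = NA_real_,
                    two_frac = NA_real_, stringsAsFactors = FALSE)
  for (a in seq_len(m)) {
    others <- setdiff(seq_len(m), a)
    if (order == 2) {
      ncand <- sapply(others, function(b) {
        obs <- union(members[[a]], members[[b]])
        need <- setdiff(obs, members[[a]])
        sum(sapply(others, function(t) {
          subset_of(need, members[[t]]) && subset_of(members[[t]], obs)
        }))
      })
    } else {
      prs <- utils::combn(others, 2)
      ncand <- sapply(seq_len(ncol(prs)), function(p) {
        obs <- Reduce(union, members[c(a, prs[, p])])
        need <- setdiff(obs, members[[a]])
        cnt <- 0L
        for (q1 in seq_along(others)) for (q2 in seq_along(others)) {
          if (q2 <= q1) next
          t1 <- members[[others[q1]]]; t2 <- members[[others[q2]]]
          if (subset_of(t1, obs) && subset_of(t2, obs) &&
              subset_of(need, union(t1, t2))) cnt <- cnt + 1L
        }
        cnt
      })
    }
    per$unique_frac[a] <- mean(ncand == 1)
    per$two_frac[a] <- mean(ncand == 2)
  }
  per
}

# random STM set: k-subsets sampled without replacement from a pool
random_stm_members <- function(n_stm, n_spike = 10, k = 3) {
  pool <- LETTERS[seq_len(n_spike)]
  seen <- character(0)
  members <- list()
  while (length(members) < n_stm) {
    s <- sort(sample(pool, k))
    key <- paste(s, collapse = "")
    if (key %in% seen) next
    seen <- c(seen, key)
    members[[length(members) + 1L]] <- s
  }
  names(members) <- vapply(members, paste, character(1), collapse = "-")
  members
}
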