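#' Build a set of sample tracking mixes (STMs)
#'
#' An STM is an unordered set of k spike-in controls used as a combinatorial
#' sample identifier. An `stm_set` is a named list of character vectors;
#' members are stored sorted so two STMs with equal member sets are the
#' same STM regardless of input order.
#'
#' @param members a list of character vectors (the member spike-in ids of
#'   each STM), or a single character vector for one STM.
#' @param ids optional character vector of STM ids. When omitted, ids are
#'   generated as the sorted members joined by `"-"`, which is stable and
#'   collision-free.
#' @return An object of class `stm_set`: a named list of sorted member
#'   vectors.
#' @examples
#' stm_set(list(c("A", "C", "B"), c("D", "E", "F")))
#' @export
stm_set <- function(members, ids = NULL) {
  if (is.character(members)) members <- list(members)
  members <- lapply(members, function(m) sort(unique(as.character(m))))
  if (any(lengths(members) == 0)) stop("every STM needs at least one member")
  if (is.null(ids)) {
    ids <- vapply(members, paste, character(1), collapse = "-")
  }
  ids <- as.character(ids)
  if (length(ids) != length(members)) stop("one id per STM required")
  keys <- vapply(members, paste, character(1), collapse = "\r")
  if (anyDuplicated(keys)) {
    stop("two STMs have identical member sets: ",
         paste(ids[duplicated(keys) | duplicated(keys, fromLast = TRUE)],
               collapse = ", "))
  }
  if (anyDuplicated(ids)) {
    stop("STM ids must be unique: duplicated ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(members) <- ids
  structure(members, class = "stm_set")
}

#' @export
print.stm_set <- function(x, ...) {
  cat("stm_set with", length(x), "STMs (k =",
      paste(sort(unique(lengths(x))), collapse = ","), ")\n")
  show <- utils::head(seq_along(x), 6L)
  for (i in show) {
    cat("  ", names(x)[i], ": {", paste(x[[i]], collapse = ", "), "}\n",
        sep = "")
  }
  if (length(x) > 6L) cat("  ... and", length(x) - 6L, "more\n")
  invisible(x)
}

#' @export
`[.stm_set` <- function(x, i) {
  structure(unclass(x)[i], class = "stm_set")
}

#' Enumerate all k-subset STMs of a spike-in set
#'
#' Generates every distinct unordered combination of `k` spike-ins, i.e.
#' `choose(n, k)` STMs from `n` controls. Twelve controls yield 220 ternary
#' STMs; combining 6 per mix yields 924; 16 controls with k = 7 exceed
#' 10,000. Output order is deterministic: lexicographic on the sorted
#' member lists.
#'
#' @param spikein_ids character vector of unique spike-in ids (or a
#'   [spikein_panel()]).
#' @param k mix cardinality (number of controls per STM); the conventional
#'   choice is 3.
#' @return An [stm_set()] of all `choose(length(spikein_ids), k)` STMs,
#'   with auto-generated ids.
#' @examples
#' length(enumerate_stms(letters[1:12], 3)) # 220
#' @export
enumerate_stms <- function(spikein_ids, k) {
  if (inherits(spikein_ids, "spikein_panel")) {
    spikein_ids <- spikein_ids$spikein_id
  }
  spikein_ids <- as.character(spikein_ids)
  if (anyDuplicated(spikein_ids)) stop("spike-in ids must be unique")
  n <- length(spikein_ids)
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k <= 0L || k > n) {
    stop("k must be an integer in [1, ", n, "], got ", k)
  }
  ids <- sort(spikein_ids)
  combs <- utils::combn(ids, k, simplify = FALSE)
  stm_set(combs)
}

#' Members of one STM
#'
#' @param stms an [stm_set()].
#' @param id an STM id present in `stms`.
#' @return Character vector of member spike-in ids.
#' @export
stm_members <- function(stms, id) {
  if (!id %in% names(stms)) stop("unknown STM id: ", id)
  stms[[id]]
}

# logical membership matrix, rows = STMs, cols = union of member ids
stm_membership_matrix <- function(stms, universe = NULL) {
  if (is.null(universe)) universe <- sort(unique(unlist(stms)))
  m <- matrix(FALSE, length(stms), length(universe),
              dimnames = list(names(stms), universe))
  for (i in seq_along(stms)) m[i, stms[[i]]] <- TRUE
  m
}
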