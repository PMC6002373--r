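#' Design a plate layout of STMs under an adjacency constraint
#'
#' Assigns one STM per well of an `n_rows` x `n_cols` plate so that wells
#' adjacent in the same row or the same column never share a spike-in
#' control. This guards the layout against the most common physical
#' mix-up modes (neighbouring-well pipetting errors and row/column shifts):
#' any such event produces an STM pattern distinguishable from the intended
#' one. Diagonal neighbours are deliberately unconstrained.
#'
#' The solver is a seeded randomized greedy fill in row-major order with
#' backtracking; when the backtrack budget is exhausted it restarts from a
#' fresh random order, up to `max_restarts` times. The same
#' `(candidate_stms, dims, seed)` always yields the same layout. If no
#' complete layout is found within the budget the function fails with an
#' error (condition class `stmtrack_no_layout`) rather than returning a
#' partial plate.
#'
#' @param candidate_stms an [stm_set()] of candidate mixes, e.g. from
#'   [enumerate_stms()].
#' @param n_rows,n_cols plate dimensions; defaults 8 x 12 (a standard
#'   96-well plate).
#' @param seed integer seed controlling the randomized search; `NULL` uses
#'   the current RNG state (and is then only reproducible externally).
#' @param allow_reuse if `TRUE` an STM may occupy several wells (multi-plate
#'   designs); by default every STM is used at most once.
#' @param max_restarts,max_backtracks search budget.
#' @return A `plate_layout`: list with `wells` (character matrix of STM ids,
#'   `dimnames` = row letters / column numbers) and `stms` (the candidate
#'   set).
#' @examples
#' stms <- enumerate_stms(default_spikein_panel(), 3)
#' layout <- design_layout(stms, 8, 12, seed = 1)
#' nrow(validate_layout(layout)) # 0
#' @export
design_layout <- function(candidate_stms, n_rows = 8, n_cols = 12,
                          seed = NULL, allow_reuse = FALSE,
                          max_restarts = 100L, max_backtracks = 2000L) {
  stopifnot(inherits(candidate_stms, "stm_set"))
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 1L || n_cols < 1L) stop("plate dimensions must be positive")
  n_wells <- n_rows * n_cols
  m <- length(candidate_stms)
  if (!allow_reuse && m < n_wells) {
    no_layout_error(sprintf(
      "only %d candidate STMs for %d wells (reuse disabled)", m, n_wells))
  }
  # pairwise conflict matrix: TRUE where two STMs share >= 1 member
  memb <- stm_membership_matrix(candidate_stms)
  conflict <- tcrossprod(memb * 1) > 0

  with_seed(seed, {
    for (restart in seq_len(max_restarts)) {
      res <- greedy_fill(conflict, n_rows, n_cols, allow_reuse,
                         max_backtracks)
      if (!is.null(res)) {
        wells <- matrix(names(candidate_stms)[res], n_rows, n_cols,
                        byrow = TRUE,
                        dimnames = list(row_letters(n_rows),
                                        as.character(seq_len(n_cols))))
        return(structure(list(wells = wells, stms = candidate_stms),
                         class = "plate_layout"))
      }
    }
    no_layout_error(sprintf(
      "no layout found for %dx%d plate after %d restarts", n_rows, n_cols,
      max_restarts))
  })
}

no_layout_error <- function(msg) {
  stop(structure(class = c("stmtrack_no_layout", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# one randomized greedy pass with backtracking; wells in row-major order
greedy_fill <- function(conflict, n_rows, n_cols, allow_reuse,
                        max_backtracks) {
  m <- nrow(conflict)
  n_wells <- n_rows * n_cols
  assigned <- integer(n_wells)            # candidate index per well, 0 = none
  used <- rep(FALSE, m)
  cand <- vector("list", n_wells)         # shuffled feasible list per well
  ptr <- integer(n_wells)
  backtracks <- 0L
  w <- 1L
  while (w >= 1L && w <= n_wells) {
    if (is.null(cand[[w]])) {
      row <- (w - 1L) %/% n_cols
      col <- (w - 1L) %% n_cols
      ok <- if (allow_reuse) rep(TRUE, m) else !used
      if (col > 0L) ok <- ok & !conflict[, assigned[w - 1L]]
      if (row > 0L) ok <- ok & !conflict[, assigned[w - n_cols]]
      idx <- which(ok)
      cand[[w]] <- if (length(idx) > 1L) sample(idx) else idx
      ptr[w] <- 0L
    }
    if (assigned[w] > 0L) {               # stepping back over this well
      used[assigned[w]] <- FALSE
      assigned[w] <- 0L
    }
    ptr[w] <- ptr[w] + 1L
    if (ptr[w] > length(cand[[w]])) {     # exhausted: backtrack
      cand[w] <- list(NULL)
      backtracks <- backtracks + 1L
      if (backtracks > max_backtracks) return(NULL)
      w <- w - 1L
    } else {
      assigned[w] <- cand[[w]][ptr[w]]
      used[assigned[w]] <- TRUE
      w <- w + 1L
    }
  }
  if (w < 1L) NULL else assigned
}

#' Validate a plate layout
#'
#' Checks every row- and column-adjacent well pair for shared spike-in
#' members and every STM for duplicated placement. A valid layout returns
#' a zero-row data frame.
#'
#' @param layout a `plate_layout` (from [design_layout()] or
#'   [read_plate_layout()]).
#' @return Data frame of violations with columns `type`
#'   (`"adjacent_share"` or `"duplicate_stm"`), `well_a`, `well_b` and
#'   `detail` (shared members or the duplicated STM id).
#' @export
validate_layout <- function(layout) {
  stopifnot(inherits(layout, "plate_layout"))
  wells <- layout$wells
  stms <- layout$stms
  present <- wells[!is.na(wells)]
  unknown <- setdiff(present, names(stms))
  if (length(unknown)) {
    stop("layout references STM ids missing from the panel: ",
         paste(unknown, collapse = ", "))
  }
  out <- list()
  nr <- nrow(wells); nc <- ncol(wells)
  wname <- function(r, c) paste0(rownames(wells)[r], colnames(wells)[c])
  check_pair <- function(r1, c1, r2, c2) {
    a <- wells[r1, c1]; b <- wells[r2, c2]
    if (is.na(a) || is.na(b)) return(NULL)
    shared <- intersect(stms[[a]], stms[[b]])
    if (length(shared)) {
      data.frame(type = "adjacent_share", well_a = wname(r1, c1),
                 well_b = wname(r2, c2),
                 detail = paste(shared, collapse = ";"),
                 stringsAsFactors = FALSE)
    }
  }
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (c < nc) out[[length(out) + 1L]] <- check_pair(r, c, r, c + 1L)
    if (r < nr) out[[length(out) + 1L]] <- check_pair(r, c, r + 1L, c)
  }
  dup <- names(which(table(present) > 1L))
  for (d in dup) {
    pos <- which(wells == d, arr.ind = TRUE)
    out[[length(out) + 1L]] <- data.frame(
      type = "duplicate_stm",
      well_a = wname(pos[1, 1], pos[1, 2]),
      well_b = wname(pos[2, 1], pos[2, 2]),
      detail = d, stringsAsFactors = FALSE)
  }
  out <- Filter(Negate(is.null), out)
  if (!length(out)) {
    return(data.frame(type = character(), well_a = character(),
                      well_b = character(), detail = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' @export
print.plate_layout <- function(x, ...) {
  cat("plate_layout:", nrow(x$wells), "x", ncol(x$wells), "wells,",
      length(x$stms), "candidate STMs\n")
  print(x$wells, quote = FALSE)
  invisible(x)
}

row_letters <- function(n) {
  if (n <= 26L) return(LETTERS[seq_len(n)])
  # AA, AB, ... beyond 26 rows (rare but defined)
  c(LETTERS, as.vector(outer(LETTERS, LETTERS,
                             function(a, b) paste0(a, b))))[seq_len(n)]
}

#' Parse a well name like "A1" or "h12"
#'
#' Case-insensitive; zero-padding in the column number is tolerated.
#'
#' @param well character vector of well names.
#' @return Data frame with integer `row` and `col` (1-based).
#' @export
parse_well <- function(well) {
  m <- regmatches(toupper(well), regexec("^([A-Z]+)0*([0-9]+)$",
                                         toupper(well)))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) stop("malformed well name(s): ",
                     paste(well[bad], collapse = ", "))
  letters_part <- vapply(m, `[`, character(1), 2L)
  row <- vapply(strsplit(letters_part, ""), function(ch) {
    sum((match(ch, LETTERS)) * 26L^(rev(seq_along(ch)) - 1L))
  }, numeric(1))
  data.frame(row = as.integer(row),
             col = as.integer(vapply(m, `[`, character(1), 3L)))
}

#' Read / write a plate layout CSV
#'
#' The interchange format has columns `well` ("A1".."H12"; letter = row,
#' number = column, 1-based from the top-left), `stm_id`, and `members`
#' (semicolon-joined spike-in ids).
#'
#' @param path file path.
#' @param n_rows,n_cols plate dimensions; inferred from the well names when
#'   omitted.
#' @return `read_plate_layout()` returns a `plate_layout`;
#'   `write_plate_layout()` returns `path` invisibly.
#' @export
read_plate_layout <- function(path, n_rows = NULL, n_cols = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("well", "stm_id", "members")
  if (!all(need %in% names(df))) {
    stop("layout file ", path, " must have columns ",
         paste(need, collapse = ", "))
  }
  rc <- parse_well(df$well)
  if (is.null(n_rows)) n_rows <- max(rc$row)
  if (is.null(n_cols)) n_cols <- max(rc$col)
  if (any(rc$row > n_rows | rc$col > n_cols)) {
    stop("well coordinates outside the ", n_rows, "x", n_cols, " grid")
  }
  members <- strsplit(df$members, ";", fixed = TRUE)
  keep <- !duplicated(df$stm_id)
  stms <- stm_set(members[keep], ids = df$stm_id[keep])
  wells <- matrix(NA_character_, n_rows, n_cols,
                  dimnames = list(row_letters(n_rows),
                                  as.character(seq_len(n_cols))))
  wells[cbind(rc$row, rc$col)] <- df$stm_id
  structure(list(wells = wells, stms = stms), class = "plate_layout")
}

#' @rdname read_plate_layout
#' @param layout a `plate_layout`.
#' @export
write_plate_layout <- function(layout, path) {
  stopifnot(inherits(layout, "plate_layout"))
  wells <- layout$wells
  idx <- which(!is.na(wells), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  ids <- wells[idx]
  df <- data.frame(
    well = paste0(rownames(wells)[idx[, 1]], colnames(wells)[idx[, 2]]),
    stm_id = ids,
    members = vapply(ids, function(i) paste(layout$stms[[i]], collapse = ";"),
                     character(1)),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}
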