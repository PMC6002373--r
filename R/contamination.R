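#' Estimate carry-over from majority/minority STM reads
#'
#' Quantifies the fraction of a library's material that originated from a
#' contaminating sample, from the reads on spike-ins exclusive to the
#' minority (contaminating) STM versus those exclusive to the majority
#' STM. Spike-ins shared by both mixes cannot be attributed to either
#' sample and are excluded from numerator and denominator alike; because
#' both sides lose shared members symmetrically, no rescaling for the
#' number of excluded members is needed.
#'
#' @param sample_counts named numeric vector of feature counts for the
#'   contaminated sample.
#' @param majority_members,minority_members character vectors of spike-in
#'   ids (member sets of the two STMs), or STM ids resolved against `stms`.
#' @param stms optional [stm_set()] used to resolve STM ids passed as
#'   single strings.
#' @return The carry-over estimate in `[0, 1]`: minority-exclusive reads /
#'   (majority-exclusive + minority-exclusive reads); 0 when there are no
#'   minority-exclusive reads.
#' @examples
#' cnt <- c(A = 1000, B = 900, C = 1100, D = 10, E = 12)
#' estimate_carryover(cnt, c("A","B","C"), c("C","D","E")) # 22/1922
#' @export
estimate_carryover <- function(sample_counts, majority_members,
                               minority_members, stms = NULL) {
  resolve <- function(x) {
    if (!is.null(stms) && length(x) == 1L && x %in% names(stms)) stms[[x]]
    else as.character(x)
  }
  maj <- sort(unique(resolve(majority_members)))
  mino <- sort(unique(resolve(minority_members)))
  if (identical(maj, mino)) {
    stop("majority and minority STMs are identical")
  }
  shared <- intersect(maj, mino)
  maj_ex <- setdiff(maj, shared)
  min_ex <- setdiff(mino, shared)
  if (length(min_ex) == 0L || length(maj_ex) == 0L) {
    stop("undefined estimate: one STM is a subset of the other ",
         "(no exclusive members on one side)")
  }
  cnt <- function(id) {
    v <- sample_counts[id]
    v[is.na(v)] <- 0
    sum(v)
  }
  num <- cnt(min_ex)
  den <- cnt(maj_ex) + num
  if (num == 0) return(0)
  num / den
}

#' Raw minority-read fraction
#'
#' The proportion of all spike-in reads in a sample carried by the
#' minority STM's exclusive members, without the majority-side
#' renormalization of [estimate_carryover()]. Comparable to headline
#' contamination percentages quoted against whole-library spike-in totals.
#'
#' @inheritParams estimate_carryover
#' @param spike_features all spike-in feature ids in the panel (defaults
#'   to the union of both member sets).
#' @return Fraction in `[0, 1]`.
#' @export
raw_minority_fraction <- function(sample_counts, majority_members,
                                  minority_members, spike_features = NULL,
                                  stms = NULL) {
  resolve <- function(x) {
    if (!is.null(stms) && length(x) == 1L && x %in% names(stms)) stms[[x]]
    else as.character(x)
  }
  maj <- resolve(majority_members)
  mino <- resolve(minority_members)
  if (is.null(spike_features)) spike_features <- union(maj, mino)
  cnt <- function(id) {
    v <- sample_counts[id]
    v[is.na(v)] <- 0
    sum(v)
  }
  tot <- cnt(spike_features)
  if (tot == 0) return(0)
  cnt(setdiff(mino, maj)) / tot
}

#' Trace candidate source samples of a minority STM
#'
#' Returns every design sample whose expected STM equals the minority STM
#' observed in a contaminated library. An empty result indicates
#' contamination from outside the experiment (or a mis-specified design).
#'
#' @param minority_stm_id STM id.
#' @param design an [experiment_design()].
#' @return Character vector of sample ids (possibly empty).
#' @export
trace_sources <- function(minority_stm_id, design) {
  stopifnot(inherits(design, "experiment_design"))
  ds <- design$samples
  ds$sample_id[!is.na(ds$expected_stm_id) &
                 ds$expected_stm_id == minority_stm_id]
}

#' Single-source STMs compatible with an observed spike-in superset
#'
#' Given a contaminated sample whose own (target) STM is known and the
#' full set of spike-ins observed in it, finds every other STM in the set
#' that could alone explain the extra spike-ins: a candidate T must
#' contain all observed non-target members and contribute nothing outside
#' the observed set, i.e. `(observed \\ target) <= T <= observed`.
#'
#' @param target_stm_id id of the sample's own STM (must be in `stms`).
#' @param observed_members character vector of all spike-in ids observed
#'   in the sample; must be a superset of the target members.
#' @param stms an [stm_set()].
#' @return Character vector of candidate STM ids (excluding the target).
#' @export
candidate_sources_for <- function(target_stm_id, observed_members, stms) {
  stopifnot(inherits(stms, "stm_set"))
  if (!target_stm_id %in% names(stms)) {
    stop("target STM ", target_stm_id, " not in the STM set")
  }
  target <- stms[[target_stm_id]]
  observed <- sort(unique(as.character(observed_members)))
  if (!all(target %in% observed)) {
    stop("observed members must contain all target STM members")
  }
  extra <- setdiff(observed, target)
  if (length(extra) == 0L) return(character(0))
  ok <- vapply(names(stms), function(id) {
    if (id == target_stm_id) return(FALSE)
    m <- stms[[id]]
    all(extra %in% m) && all(m %in% observed)
  }, logical(1))
  names(stms)[ok]
}

#' Score contamination events from STM calls
#'
#' Expands every minority STM of every call into a `ContaminationEvent`
#' row: shared and exclusive members, supporting reads, carry-over
#' estimates and candidate source samples. Each minority STM is scored
#' independently against the same majority; when the exclusive members of
#' two events overlap, reads are attributed to both and the events are
#' flagged. Events supported by fewer than `min_support` exclusive-member
#' reads get `confidence = "low"`.
#'
#' @param calls list of [call_sample()] results.
#' @param design an [experiment_design()].
#' @param counts count matrix (features x samples) the calls were made
#'   from.
#' @param min_support reads on minority-exclusive members below which an
#'   event is low-confidence (default 3).
#' @return Data frame with one row per (sample, minority STM) event:
#'   `sample_id`, `majority_stm`, `minority_stm`, `shared_members`,
#'   `exclusive_members`, `support_reads`, `carryover_estimate`,
#'   `raw_minority_fraction`, `candidate_sources`, `confidence`,
#'   `overlapping_exclusive`.
#' @export
contamination_events <- function(calls, design, counts, min_support = 3L) {
  stopifnot(inherits(design, "experiment_design"), is.matrix(counts))
  stms <- design$stms
  spike_features <- unique(unlist(stms))
  rows <- list()
  for (cl in calls) {
    if (length(cl$minority_stms) == 0L) next
    sc <- stats::setNames(counts[, cl$sample_id], rownames(counts))
    maj <- stms[[cl$majority_stm]]
    excl_sets <- lapply(cl$minority_stms,
                        function(id) setdiff(stms[[id]], maj))
    for (j in seq_along(cl$minority_stms)) {
      mid <- cl$minority_stms[j]
      mino <- stms[[mid]]
      shared <- intersect(maj, mino)
      excl <- excl_sets[[j]]
      support <- sum(sc[excl], na.rm = TRUE)
      overlap <- length(excl_sets) > 1L &&
        any(vapply(excl_sets[-j], function(e) length(intersect(e, excl)) > 0,
                   logical(1)))
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = cl$sample_id,
        majority_stm = cl$majority_stm,
        minority_stm = mid,
        shared_members = paste(shared, collapse = ";"),
        exclusive_members = paste(excl, collapse = ";"),
        support_reads = unname(support),
        carryover_estimate = estimate_carryover(sc, maj, mino),
        raw_minority_fraction = raw_minority_fraction(
          sc, maj, mino, spike_features = spike_features),
        candidate_sources = paste(trace_sources(mid, design),
                                  collapse = ";"),
        confidence = if (support < min_support) "low" else "ok",
        overlapping_exclusive = overlap,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(
      sample_id = character(), majority_stm = character(),
      minority_stm = character(), shared_members = character(),
      exclusive_members = character(), support_reads = numeric(),
      carryover_estimate = numeric(), raw_minority_fraction = numeric(),
      candidate_sources = character(), confidence = character(),
      overlapping_exclusive = logical(), stringsAsFactors = FALSE))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Source resolvability of an STM set
#'
#' Quantifies how often a hypothetical cross-contamination event could be
#' traced back to a unique source, given only the observed union of
#' spike-ins. For `order = 2` (one contaminating sample), every ordered
#' (target, source) pair defines an event whose observation is the union
#' of both member sets; the event is uniquely resolvable when
#' [candidate_sources_for()] returns exactly the true source, and
#' two-candidate when exactly two STMs could explain it. For `order = 3`
#' (two contaminating samples) the candidates are unordered pairs of STMs
#' (both distinct from the target) whose union covers all non-target
#' observed members without exceeding the observed set; the event is
#' uniquely resolvable when exactly one such pair exists.
#'
#' Fractions are computed per target STM and then averaged (mean and SD
#' across targets); pooled fractions over all events are also reported.
#'
#' @param stms an [stm_set()] with at least `order` STMs.
#' @param order 2 or 3: total number of samples involved in the event.
#' @return An object of class `resolvability_summary`: list with
#'   `order`, `per_target` (data frame: `stm_id`, `unique_frac`,
#'   `two_frac`, `other_frac`, `n_events`), `mean_unique`, `sd_unique`,
#'   `mean_two`, `sd_two`, `pooled_unique`, `pooled_two`.
#' @export
resolvability_analysis <- function(stms, order = 2) {
  stopifnot(inherits(stms, "stm_set"))
  if (!order %in% c(2, 3)) stop("order must be 2 or 3")
  m <- length(stms)
  if (m < order) stop("need at least ", order, " STMs")
  memb <- stm_membership_matrix(stms)   # logical, STMs x spike-ins
  ids <- names(stms)

  per <- lapply(seq_len(m), function(a) {
    others <- setdiff(seq_len(m), a)
    if (order == 2) {
      # candidates for (target a, source b): T != a with
      # (obs \ target) <= T <= obs, obs = members(a) | members(b)
      res <- vapply(others, function(b) {
        obs <- memb[a, ] | memb[b, ]
        need <- obs & !memb[a, ]
        sum(vapply(others, function(t) {
          all(memb[t, ] <= obs) && all(need <= memb[t, ])
        }, logical(1)))
      }, numeric(1))
      n_ev <- length(res)
      data.frame(stm_id = ids[a],
                 unique_frac = mean(res == 1),
                 two_frac = mean(res == 2),
                 other_frac = mean(res > 2 | res == 0),
                 n_events = n_ev, stringsAsFactors = FALSE)
    } else {
      pairs <- utils::combn(others, 2L)
      res <- vapply(seq_len(ncol(pairs)), function(p) {
        b <- pairs[1L, p]; cc <- pairs[2L, p]
        obs <- memb[a, ] | memb[b, ] | memb[cc, ]
        need <- obs & !memb[a, ]
        # STMs that fit inside the observed set
        sub <- others[vapply(others, function(t) all(memb[t, ] <= obs),
                             logical(1))]
        if (length(sub) < 2L) return(0)
        cand_pairs <- utils::combn(sub, 2L)
        sum(vapply(seq_len(ncol(cand_pairs)), function(q) {
          u <- memb[cand_pairs[1L, q], ] | memb[cand_pairs[2L, q], ]
          all(need <= u)
        }, logical(1)))
      }, numeric(1))
      data.frame(stm_id = ids[a],
                 unique_frac = mean(res == 1),
                 two_frac = mean(res == 2),
                 other_frac = mean(res > 2 | res == 0),
                 n_events = length(res), stringsAsFactors = FALSE)
    }
  })
  per <- do.call(rbind, c(per, list(make.row.names = FALSE)))
  all_unique <- sum(per$unique_frac * per$n_events) / sum(per$n_events)
  all_two <- sum(per$two_frac * per$n_events) / sum(per$n_events)
  structure(list(order = order, per_target = per,
                 mean_unique = mean(per$unique_frac),
                 sd_unique = stats::sd(per$unique_frac),
                 mean_two = mean(per$two_frac),
                 sd_two = stats::sd(per$two_frac),
                 pooled_unique = all_unique,
                 pooled_two = all_two),
            class = "resolvability_summary")
}

#' @export
print.resolvability_summary <- function(x, ...) {
  cat(sprintf(
    "resolvability (order %d, %d target STMs):\n", x$order,
    nrow(x$per_target)))
  cat(sprintf("  uniquely resolvable: %.1f%% +/- %.1f%% (across STMs)\n",
              100 * x$mean_unique, 100 * x$sd_unique))
  cat(sprintf("  two candidates:      %.1f%% +/- %.1f%%\n",
              100 * x$mean_two, 100 * x$sd_two))
  invisible(x)
}
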