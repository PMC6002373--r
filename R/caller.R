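#' Describe an experiment design
#'
#' Maps each sample to its expected STM (or to none, for unspiked samples
#' and non-template controls) and carries the STM definitions used in the
#' experiment. STM calling screens against the STMs actually used in an
#' experiment rather than a full combinatorial panel, which avoids false
#' composite detections from overlapping member sets.
#'
#' @param samples data frame with columns `sample_id`, optional `well`, and
#'   `expected_stm_id` (`NA` or `""` for unspiked samples).
#' @param stms an [stm_set()] containing at least every expected STM.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(samples, stms) {
  stopifnot(is.data.frame(samples), inherits(stms, "stm_set"))
  if (!all(c("sample_id", "expected_stm_id") %in% names(samples))) {
    stop("samples needs columns sample_id and expected_stm_id")
  }
  samples$sample_id <- as.character(samples$sample_id)
  samples$expected_stm_id <- as.character(samples$expected_stm_id)
  samples$expected_stm_id[samples$expected_stm_id %in% c("", "NA")] <- NA
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample ids in design")
  }
  exp_ids <- samples$expected_stm_id[!is.na(samples$expected_stm_id)]
  missing <- setdiff(exp_ids, names(stms))
  if (length(missing)) {
    stop("expected STMs absent from the STM set: ",
         paste(missing, collapse = ", "))
  }
  if (!"well" %in% names(samples)) samples$well <- NA_character_
  structure(list(samples = samples[c("sample_id", "well", "expected_stm_id")],
                 stms = stms),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  n_spiked <- sum(!is.na(x$samples$expected_stm_id))
  cat("experiment_design:", nrow(x$samples), "samples (", n_spiked,
      "spiked ),", length(x$stms), "STMs\n")
  print(utils::head(x$samples))
  invisible(x)
}

#' Detect STMs present in one sample's counts
#'
#' An STM is scored present only when every one of its member spike-ins is
#' supported by at least `min_reads` reads; its cumulative count is the sum
#' of the member counts. Requiring all k members jointly makes stray single
#' reads from index cross-talk (typically supporting one isolated control)
#' insufficient to fake a mix.
#'
#' @param sample_counts named numeric vector of feature counts for one
#'   sample (spike-in features identified by name; other features ignored).
#' @param candidate_stms an [stm_set()] of STMs to screen for.
#' @param min_reads minimum reads per member spike-in (default 1).
#' @return Data frame with columns `stm_id` and `cumulative`, sorted by
#'   cumulative count descending, ties broken by `stm_id` ascending.
#' @examples
#' stms <- stm_set(list(c("A","B","C"), c("D","E","F")))
#' detect_stms(c(A = 100, B = 90, C = 110, D = 0, E = 0, F = 0), stms)
#' @export
detect_stms <- function(sample_counts, candidate_stms, min_reads = 1L) {
  stopifnot(inherits(candidate_stms, "stm_set"))
  if (length(candidate_stms) == 0L) stop("candidate STM set is empty")
  min_reads <- as.integer(min_reads)
  if (is.na(min_reads) || min_reads < 1L) stop("min_reads must be >= 1")
  cnt <- function(id) {
    v <- sample_counts[id]
    v[is.na(v)] <- 0
    unname(v)
  }
  present <- vapply(candidate_stms,
                    function(m) all(cnt(m) >= min_reads), logical(1))
  ids <- names(candidate_stms)[present]
  cum <- vapply(candidate_stms[present],
                function(m) sum(cnt(m)), numeric(1))
  ord <- order(-cum, ids)
  data.frame(stm_id = ids[ord], cumulative = unname(cum[ord]),
             stringsAsFactors = FALSE)
}

#' Call the STM content of one sample
#'
#' Runs [detect_stms()] and splits detections into the majority STM (the
#' one with the highest cumulative read count, which assigns the sample's
#' identity) and minority STMs (evidence of cross-contamination). A sample
#' with a single detected STM is considered uncontaminated. An exact tie
#' for the majority is broken lexicographically on the STM id and flagged.
#'
#' @inheritParams detect_stms
#' @param design an [experiment_design()] supplying the candidate STM set,
#'   or an [stm_set()] directly.
#' @param candidates with an [experiment_design()], `"design"` (default)
#'   screens only the STMs expected by some sample of the experiment;
#'   `"panel"` widens the screen to every STM in the design's set. The
#'   narrow default avoids false composite detections assembled from the
#'   overlapping member sets of unused mixes.
#' @param sample_id optional label carried into the result.
#' @param low_support_reads majority cumulative counts below this value set
#'   the `low_support` flag (the call is still made; see Details).
#' @details A sample whose majority matches its design but rests on very
#'   few reads is reported as a normal call with `low_support = TRUE`
#'   rather than rejected: no principled read cutoff exists below the
#'   per-member `min_reads` rule, so the flag defers judgement to the
#'   analyst.
#' @return An object of class `stm_call`: list with `sample_id`,
#'   `detected` (the [detect_stms()] frame), `majority_stm`,
#'   `minority_stms`, `total_spikein_reads`, `total_reads`, and `flags`
#'   (`no_stm`, `ambiguous_majority`, `low_support`).
#' @export
call_sample <- function(sample_counts, design, min_reads = 1L,
                        sample_id = NA_character_,
                        low_support_reads = 10L,
                        candidates = c("design", "panel")) {
  candidates <- match.arg(candidates)
  stms <- if (inherits(design, "experiment_design")) {
    if (candidates == "design") design_candidate_stms(design)
    else design$stms
  } else design
  det <- detect_stms(sample_counts, stms, min_reads)
  all_stms <- if (inherits(design, "experiment_design")) design$stms
  else design
  spike_features <- intersect(names(sample_counts), unique(unlist(all_stms)))
  total_spike <- sum(sample_counts[spike_features])
  majority <- NA_character_
  minorities <- character(0)
  ambiguous <- FALSE
  if (nrow(det)) {
    top <- det$cumulative == det$cumulative[1L]
    ambiguous <- sum(top) > 1L
    majority <- det$stm_id[1L]          # already id-sorted within ties
    minorities <- det$stm_id[-1L]
  }
  structure(list(
    sample_id = sample_id,
    detected = det,
    majority_stm = majority,
    minority_stms = minorities,
    total_spikein_reads = unname(total_spike),
    total_reads = sum(sample_counts),
    flags = list(no_stm = nrow(det) == 0L,
                 ambiguous_majority = ambiguous,
                 low_support = nrow(det) > 0L &&
                   det$cumulative[1L] < low_support_reads)),
    class = "stm_call")
}

#' @export
print.stm_call <- function(x, ...) {
  cat("stm_call", if (!is.na(x$sample_id)) paste0("[", x$sample_id, "]"),
      ": majority =", x$majority_stm,
      if (length(x$minority_stms))
        paste0("; minorities = ", paste(x$minority_stms, collapse = ",")),
      "\n")
  invisible(x)
}

#' Call STMs for every sample of a count table
#'
#' @param table count matrix, features as rows, samples as columns (see
#'   [read_count_table()]).
#' @inheritParams call_sample
#' @param candidates `"design"` or `"panel"`, see [call_sample()].
#' @return Named list of [call_sample()] results, one per sample column.
#' @export
call_samples <- function(table, design, min_reads = 1L,
                         low_support_reads = 10L,
                         candidates = c("design", "panel")) {
  stopifnot(is.matrix(table))
  candidates <- match.arg(candidates)
  calls <- lapply(colnames(table), function(s) {
    call_sample(stats::setNames(table[, s], rownames(table)), design,
                min_reads = min_reads, sample_id = s,
                low_support_reads = low_support_reads,
                candidates = candidates)
  })
  stats::setNames(calls, colnames(table))
}

# the STMs actually expected by some sample of the experiment
design_candidate_stms <- function(design) {
  used <- unique(stats::na.omit(design$samples$expected_stm_id))
  design$stms[used]
}

#' Verify sample identity and resolve swaps
#'
#' Compares each sample's majority STM with the design. A sample whose
#' majority equals its expected STM and that carries no minority STM is
#' `ok`. A mismatching majority that equals the expected STM of another
#' design sample is a `swapped` sample, with that other sample proposed as
#' the true label; a majority matching no design sample is
#' `unexpected_stm`. Minority STMs add `contaminated` (combined as
#' `swapped+contaminated` where both apply). Unspiked samples in which a
#' full STM is nevertheless detected are flagged `unexpected_stm`. Swap
#' proposals form a partial permutation: when two samples would claim the
#' same relabel both are downgraded to `ambiguous`.
#'
#' @param calls list of [call_sample()] results (e.g. from
#'   [call_samples()]).
#' @param design an [experiment_design()]; expected STMs must be unique
#'   across samples.
#' @return A data frame of class `track_report` with one row per call:
#'   `sample_id`, `well`, `expected_stm`, `majority_stm`, `minority_stms`
#'   (semicolon-joined), `status`, `proposed_relabel`,
#'   `total_spikein_reads`, `low_support`.
#' @export
verify_and_resolve <- function(calls, design) {
  stopifnot(inherits(design, "experiment_design"))
  ds <- design$samples
  exp_ids <- ds$expected_stm_id[!is.na(ds$expected_stm_id)]
  if (anyDuplicated(exp_ids)) {
    stop("invalid design: expected STM assigned to more than one sample: ",
         paste(unique(exp_ids[duplicated(exp_ids)]), collapse = ", "))
  }
  stm_to_sample <- stats::setNames(
    ds$sample_id[!is.na(ds$expected_stm_id)], exp_ids)

  rows <- lapply(calls, function(cl) {
    sid <- cl$sample_id
    i <- match(sid, ds$sample_id)
    expected <- if (is.na(i)) NA_character_ else ds$expected_stm_id[i]
    maj <- cl$majority_stm
    has_min <- length(cl$minority_stms) > 0L
    relabel <- NA_character_
    if (cl$flags$ambiguous_majority) {
      status <- "ambiguous"
    } else if (is.na(expected)) {
      # unspiked / NTC: a fully supported STM should never appear
      status <- if (is.na(maj)) "ok" else "unexpected_stm"
    } else if (is.na(maj)) {
      status <- "no_stm"
    } else if (maj == expected) {
      status <- if (has_min) "contaminated" else "ok"
    } else {
      relabel <- unname(stm_to_sample[maj])
      if (is.na(relabel)) {
        status <- "unexpected_stm"
      } else {
        status <- if (has_min) "swapped+contaminated" else "swapped"
      }
    }
    data.frame(sample_id = sid,
               well = if (is.na(i)) NA_character_ else ds$well[i],
               expected_stm = expected,
               majority_stm = maj,
               minority_stms = paste(cl$minority_stms, collapse = ";"),
               status = status,
               proposed_relabel = relabel,
               total_spikein_reads = cl$total_spikein_reads,
               low_support = cl$flags$low_support,
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  dup <- rep$proposed_relabel[!is.na(rep$proposed_relabel)]
  dup <- unique(dup[duplicated(dup)])
  if (length(dup)) {
    hit <- !is.na(rep$proposed_relabel) & rep$proposed_relabel %in% dup
    rep$status[hit] <- "ambiguous"
    rep$proposed_relabel[hit] <- NA_character_
  }
  class(rep) <- c("track_report", "data.frame")
  rep
}

#' @export
print.track_report <- function(x, ...) {
  cat("track_report:", nrow(x), "samples;",
      sum(x$status == "ok"), "ok,",
      sum(grepl("swapped", x$status)), "swapped,",
      sum(grepl("contaminated", x$status)), "contaminated\n")
  print(as.data.frame(x))
  invisible(x)
}

#' Within-STM spike-in shares and their relation to amplicon G+C
#'
#' For every spike-in, computes the mean (over the samples whose expected
#' STM contains it) of its share of the sample's total spike-in reads.
#' With k-member mixes dosed equimolarly the unbiased expectation is 1/k;
#' systematic departures reflect amplification bias. The summary also
#' reports the Pearson correlation of mean share with amplicon G+C
#' fraction, the standard diagnostic for GC-dependent PCR efficiency
#' (negative r: GC-rich controls are under-detected).
#'
#' @param table count matrix, features as rows, samples as columns.
#' @param design an [experiment_design()].
#' @param panel a [spikein_panel()] providing `gc_fraction`.
#' @return A data frame of class `spikein_bias_summary` with columns
#'   `spikein_id`, `gc_fraction`, `mean_share`, `sd_share`, `n_samples`,
#'   and attributes `pearson_r` and `p_value`.
#' @export
spikein_bias_summary <- function(table, design, panel) {
  stopifnot(is.matrix(table), inherits(design, "experiment_design"),
            inherits(panel, "spikein_panel"))
  if (length(unique(panel$gc_fraction)) < 3L) {
    stop("need >= 3 spike-ins with distinct gc_fraction")
  }
  spike_ids <- intersect(rownames(table), panel$spikein_id)
  if (sum(table[spike_ids, , drop = FALSE]) == 0) {
    stop("no spike-in reads in any sample; bias summary is empty")
  }
  ds <- design$samples
  shares <- lapply(panel$spikein_id, function(sp) {
    vals <- numeric(0)
    for (i in seq_len(nrow(ds))) {
      stm <- ds$expected_stm_id[i]
      if (is.na(stm) || !sp %in% design$stms[[stm]]) next
      s <- ds$sample_id[i]
      if (!s %in% colnames(table)) next
      tot <- sum(table[spike_ids, s])
      if (tot > 0) vals <- c(vals, table[sp, s] / tot)
    }
    vals
  })
  out <- data.frame(
    spikein_id = panel$spikein_id,
    gc_fraction = panel$gc_fraction,
    mean_share = vapply(shares, function(v) {
      if (length(v)) mean(v) else NA_real_
    }, numeric(1)),
    sd_share = vapply(shares, function(v) {
      if (length(v) > 1L) stats::sd(v) else NA_real_
    }, numeric(1)),
    n_samples = lengths(shares),
    stringsAsFactors = FALSE)
  keep <- !is.na(out$mean_share)
  ct <- stats::cor.test(out$gc_fraction[keep], out$mean_share[keep])
  attr(out, "pearson_r") <- unname(ct$estimate)
  attr(out, "p_value") <- ct$p.value
  class(out) <- c("spikein_bias_summary", "data.frame")
  out
}

#' @export
print.spikein_bias_summary <- function(x, ...) {
  cat("spikein_bias_summary: Pearson r(gc, mean share) =",
      format(attr(x, "pearson_r"), digits = 3),
      "(p =", format(attr(x, "p_value"), digits = 3), ")\n")
  print(as.data.frame(x))
  invisible(x)
}
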