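#' Construct a spike-in panel
#'
#' A spike-in panel describes the synthetic 16S rRNA gene controls available
#' for building sample tracking mixes (STMs). Each control has a unique id,
#' the G+C fraction of its sequenced amplicon (used to model PCR
#' amplification bias), and optionally its nucleotide sequence.
#'
#' @param spikein_id character vector of unique control ids.
#' @param gc_fraction numeric vector in `[0, 1]`, amplicon G+C fraction.
#' @param sequence optional character vector of nucleotide sequences
#'   (IUPAC codes); `NA` entries are allowed.
#' @return A data frame of class `spikein_panel` with columns
#'   `spikein_id`, `gc_fraction` and (if supplied) `sequence`.
#' @examples
#' spikein_panel(c("sp01", "sp02"), c(0.48, 0.55))
#' @export
spikein_panel <- function(spikein_id, gc_fraction, sequence = NULL) {
  spikein_id <- as.character(spikein_id)
  if (anyDuplicated(spikein_id)) {
    stop("spike-in ids must be unique: duplicated ",
         paste(unique(spikein_id[duplicated(spikein_id)]), collapse = ", "))
  }
  gc_fraction <- as.numeric(gc_fraction)
  if (length(gc_fraction) != length(spikein_id)) {
    stop("gc_fraction must have one value per spike-in")
  }
  if (any(!is.finite(gc_fraction)) || any(gc_fraction < 0 | gc_fraction > 1)) {
    stop("gc_fraction values must lie in [0, 1]")
  }
  panel <- data.frame(spikein_id = spikein_id, gc_fraction = gc_fraction,
                      stringsAsFactors = FALSE)
  if (!is.null(sequence)) {
    sequence <- toupper(as.character(sequence))
    ok <- is.na(sequence) | !grepl("[^ACGTRYSWKMBDHVN]", sequence)
    if (!all(ok)) {
      stop("sequence for ", paste(spikein_id[!ok], collapse = ", "),
           " contains non-IUPAC characters")
    }
    panel$sequence <- sequence
  }
  class(panel) <- c("spikein_panel", "data.frame")
  panel
}

#' Default synthetic spike-in panel
#'
#' A synthetic 12-control panel whose G+C fractions span the range typical
#' of 16S V3 amplicons (0.45-0.61) plus one G+C-rich control at 0.67. With
#' the default GC-bias strength of [simulate_experiment()], mean within-STM
#' shares across all ternary STMs span roughly 24-41% around the unbiased
#' expectation of 33.3%, emulating the detection-rate spread seen in real
#' spike-in panels. The ids and G+C values are synthetic, not those of any
#' published control set.
#'
#' @return A [spikein_panel()] with 12 controls.
#' @examples
#' default_spikein_panel()
#' @export
default_spikein_panel <- function() {
  spikein_panel(
    spikein_id = sprintf("sp%02d", 1:12),
    gc_fraction = c(round(seq(0.45, 0.61, length.out = 11), 3), 0.67)
  )
}

#' Read / write a spike-in panel TSV
#'
#' The panel interchange format is a tab-separated file with columns
#' `spikein_id`, `gc_fraction` and optionally `sequence`.
#'
#' @param path file path.
#' @return `read_spikein_panel()` returns a [spikein_panel()];
#'   `write_spikein_panel()` returns `path` invisibly.
#' @export
read_spikein_panel <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("spikein_id", "gc_fraction")
  if (!all(need %in% names(df))) {
    stop("panel file ", path, " must have columns ",
         paste(need, collapse = ", "))
  }
  spikein_panel(df$spikein_id, df$gc_fraction,
                sequence = if ("sequence" %in% names(df)) df$sequence)
}

#' @rdname read_spikein_panel
#' @param panel a [spikein_panel()].
#' @export
write_spikein_panel <- function(panel, path) {
  utils::write.table(as.data.frame(panel), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate synthetic spike-in reference sequences
#'
#' Fills the `sequence` column of a panel with random sequences whose G+C
#' content matches each control's `gc_fraction`. Independently drawn random
#' sequences of this length are far below any realistic identity threshold
#' (pairwise identity around 40-55%), so they behave like the artificial
#' variable regions of real spike-in controls: mutually unambiguous
#' references for read classification.
#'
#' @param panel a [spikein_panel()].
#' @param length sequence length in nt (default 150, a typical merged
#'   V3 amplicon scale for testing).
#' @param seed integer seed for reproducibility, or `NULL` to use the
#'   current RNG state.
#' @return The panel with a `sequence` column filled in.
#' @export
synthesize_spikein_sequences <- function(panel, length = 150, seed = NULL) {
  stopifnot(inherits(panel, "spikein_panel"), length >= 10)
  with_seed(seed, {
    seqs <- vapply(panel$gc_fraction, function(gc) {
      p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
      paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
    }, character(1))
    panel$sequence <- seqs
  })
  panel
}

# Run code under a temporary RNG state; seed = NULL leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}
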