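#' Global percent identity between two sequences
#'
#' End-to-end (Needleman-Wunsch) alignment identity: matched columns
#' divided by all alignment columns, terminal gaps included. IUPAC
#' ambiguity codes match compatibly (two columns match when their base
#' sets intersect; `N` matches anything); gap columns never match. The
#' alignment itself is computed with \pkg{Biostrings} under a simple
#' match/mismatch scheme with affine gaps.
#'
#' @param seq_a,seq_b nucleotide strings (IUPAC alphabet, non-empty).
#' @param match,mismatch,gap_open,gap_extend alignment scores (defaults
#'   +1 / -1 / -2 / -1).
#' @return Identity fraction in `[0, 1]`; symmetric in its arguments.
#' @examples
#' global_identity("ACGTACGT", "ACGTACGT") # 1
#' @export
global_identity <- function(seq_a, seq_b, match = 1, mismatch = -1,
                            gap_open = 2, gap_extend = 1) {
  seq_a <- toupper(as.character(seq_a))
  seq_b <- toupper(as.character(seq_b))
  if (nchar(seq_a) == 0 || nchar(seq_b) == 0) {
    stop("sequences must be non-empty")
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(seq_a), Biostrings::DNAString(seq_b),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = match, mismatch = mismatch, baseOnly = FALSE),
    gapOpening = gap_open, gapExtension = gap_extend)
  alignment_identity(as.character(Biostrings::alignedPattern(aln)),
                     as.character(Biostrings::alignedSubject(aln)))
}

# identity over the columns of an already-aligned pair
alignment_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  matches <- sum(mapply(iupac_match, ca, cb))
  matches / length(ca)
}

iupac_match <- local({
  map <- NULL
  function(x, y) {
    if (is.null(map)) map <<- strsplit(Biostrings::IUPAC_CODE_MAP, "")
    if (x == "-" || y == "-") return(FALSE)
    sx <- map[[x]]; sy <- map[[y]]
    if (is.null(sx) || is.null(sy)) return(FALSE)
    length(intersect(sx, sy)) > 0L
  }
})

#' Classify amplicon reads against spike-in references
#'
#' Aligns each read globally against every reference and assigns it to the
#' unique best-identity reference when that identity reaches
#' `min_identity` (default 0.97, the conventional species-level amplicon
#' threshold). A read whose best identity is tied between references, or
#' below the threshold, is left unassigned.
#'
#' @param reads a named character vector, a `Biostrings::DNAStringSet`, or
#'   a path to a FASTA/FASTQ file.
#' @param refs references in the same accepted forms, or a
#'   [spikein_panel()] with sequences; ids must be unique.
#' @param min_identity assignment threshold in `[0, 1]`.
#' @return List with `assignments` (data frame: `read_id`, `best_ref`,
#'   `identity`, `tie`) and `counts` (named integer vector of assigned
#'   reads per reference).
#' @export
classify_reads <- function(reads, refs, min_identity = 0.97) {
  reads <- as_named_sequences(reads, "read")
  refs <- as_named_sequences(refs, "ref")
  if (anyDuplicated(names(refs))) stop("duplicate reference ids")
  if (length(refs) == 0L) stop("no references supplied")
  if (min_identity < 0 || min_identity > 1) {
    stop("min_identity must be in [0, 1]")
  }
  id_mat <- vapply(refs, function(r) {
    vapply(reads, global_identity, numeric(1), seq_b = r)
  }, numeric(length(reads)))
  id_mat <- matrix(id_mat, nrow = length(reads),
                   dimnames = list(names(reads), names(refs)))
  best <- apply(id_mat, 1L, max)
  tie <- apply(id_mat, 1L, function(v) sum(v == max(v)) > 1L)
  best_ref <- colnames(id_mat)[apply(id_mat, 1L, which.max)]
  assigned <- best >= min_identity & !tie
  best_ref[!assigned] <- NA_character_
  assignments <- data.frame(read_id = names(reads), best_ref = best_ref,
                            identity = unname(best), tie = unname(tie),
                            stringsAsFactors = FALSE)
  counts <- table(factor(best_ref, levels = names(refs)))
  list(assignments = assignments,
       counts = stats::setNames(as.integer(counts), names(refs)))
}

#' Build a count table by classifying reads from several samples
#'
#' @param read_sets named list of per-sample read sets (each in any form
#'   [classify_reads()] accepts).
#' @param refs references, as in [classify_reads()].
#' @param min_identity assignment threshold.
#' @return Integer count matrix, references as rows, samples as columns,
#'   directly usable by [call_samples()].
#' @export
classify_samples <- function(read_sets, refs, min_identity = 0.97) {
  stopifnot(is.list(read_sets), !is.null(names(read_sets)))
  cols <- lapply(read_sets, function(rs) {
    classify_reads(rs, refs, min_identity)$counts
  })
  tab <- do.call(cbind, cols)
  colnames(tab) <- names(read_sets)
  storage.mode(tab) <- "integer"
  tab
}

as_named_sequences <- function(x, prefix) {
  if (inherits(x, "spikein_panel")) {
    if (is.null(x$sequence) || anyNA(x$sequence)) {
      stop("panel has no sequences; see synthesize_spikein_sequences()")
    }
    return(stats::setNames(x$sequence, x$spikein_id))
  }
  if (methods::is(x, "DNAStringSet") || methods::is(x, "QualityScaledDNAStringSet")) {
    out <- as.character(x)
    if (is.null(names(out))) names(out) <- paste0(prefix, seq_along(out))
    return(out)
  }
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    fmt <- if (grepl("\\.f(ast)?q$", x, ignore.case = TRUE)) "fastq"
    else "fasta"
    ss <- Biostrings::readDNAStringSet(x, format = fmt)
    out <- as.character(ss)
    names(out) <- sub("\\s.*$", "", names(out))
    return(out)
  }
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0(prefix, seq_along(x))
    return(x)
  }
  stop("cannot interpret ", class(x)[1], " as sequences")
}
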