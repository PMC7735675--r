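#' Default gap/missing character set
#'
#' Symbols treated as gap or missing data when computing gappyness and when
#' excluding cells from character-state counts. The set is matched
#' case-insensitively and always contains `-`. `N` denotes an unknown base
#' and is included only for nucleotide data; `X` (unknown residue), `?` and
#' `*` are included for both. `.` is normalized to `-` at read time by the
#' stockholm and maf parsers, so it never reaches classification.
#'
#' @param seq_type `"nucleotide"` or `"amino_acid"`.
#' @return Character vector of gap symbols.
#' @export
default_gap_chars <- function(seq_type = c("nucleotide", "amino_acid")) {
  seq_type <- match.arg(seq_type)
  if (seq_type == "nucleotide") c("-", "?", "*", "X", "N") else c("-", "?", "*", "X")
}

resolve_gap_chars <- function(aln, gap_chars = NULL) {
  if (!is.null(gap_chars)) {
    gap_chars <- unique(c("-", toupper(as.character(gap_chars))))
    return(gap_chars)
  }
  default_gap_chars(resolve_seq_type(aln))
}

#' Gappyness of one alignment column
#'
#' The fraction of taxa showing a gap/missing symbol at the column. Computed
#' as an exact count ratio, so threshold comparisons at values like 9/10 are
#' not subject to floating-point surprises beyond ordinary division.
#'
#' @param column Character vector: one symbol per taxon.
#' @param gap_chars Gap symbol set (matched case-insensitively).
#' @return Fraction in `[0, 1]`.
#' @examples
#' site_gappyness(c("A", "-", "C", "T"))
#' @export
site_gappyness <- function(column, gap_chars = default_gap_chars("nucleotide")) {
  if (length(column) == 0L) tk_stop("empty_column", "column has no taxa")
  mean(toupper(column) %in% toupper(gap_chars))
}

#' Classify one alignment column
#'
#' A site is *parsimony-informative* when at least two character states each
#' occur in at least two taxa; *constant* when exactly one state occurs in at
#' least two taxa (singleton states are ignored); *other* when no state
#' reaches two taxa (including all-gap columns). Gap symbols never count as
#' character states; case is folded before counting, so softmasked
#' lowercase residues do not create spurious states. Every non-gap symbol —
#' including IUPAC ambiguity codes left out of the gap set — counts as its
#' own state.
#'
#' @param column Character vector: one symbol per taxon.
#' @param gap_chars Gap symbol set.
#' @return One of `"parsimony-informative"`, `"constant"`, `"other"`.
#' @examples
#' classify_site(c("A", "A", "B", "B"))  # parsimony-informative
#' classify_site(c("A", "A", "A", "B"))  # constant
#' classify_site(c("A", "B", "C", "D"))  # other
#' @export
classify_site <- function(column, gap_chars = default_gap_chars("nucleotide")) {
  if (length(column) == 0L) tk_stop("empty_column", "column has no taxa")
  states <- toupper(column)
  states <- states[!states %in% toupper(gap_chars)]
  if (length(states) == 0L) return("other")
  counts <- tabulate(factor(states))
  k <- sum(counts >= 2L)
  if (k >= 2L) "parsimony-informative" else if (k == 1L) "constant" else "other"
}

#' Classify every column of an alignment
#'
#' Columns are classified independently of one another; permuting taxon
#' order does not change the result.
#'
#' @param aln An [alignment()].
#' @param gap_chars Gap symbol set, or `NULL` to use
#'   [default_gap_chars()] for the (detected) sequence type.
#' @return A data frame with one row per column: `position` (1-based),
#'   `classification`, `gappyness`.
#' @export
classify_alignment <- function(aln, gap_chars = NULL) {
  L <- alignment_length(aln)
  if (L == 0L) {
    return(data.frame(position = integer(0), classification = character(0),
                      gappyness = numeric(0)))
  }
  gap_chars <- resolve_gap_chars(aln, gap_chars)
  m <- toupper(as_char_matrix(aln))
  is_gap <- matrix(m %in% toupper(gap_chars), nrow = nrow(m))
  gappyness <- colMeans(is_gap)
  classification <- vapply(seq_len(L), function(j) {
    states <- m[!is_gap[, j], j]
    if (length(states) == 0L) return("other")
    counts <- tabulate(factor(states))
    k <- sum(counts >= 2L)
    if (k >= 2L) "parsimony-informative" else if (k == 1L) "constant" else "other"
  }, character(1L))
  data.frame(position = seq_len(L), classification = classification,
             gappyness = gappyness)
}
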