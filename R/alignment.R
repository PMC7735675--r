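#' Construct an alignment object
#'
#' An `alignment` is the package's in-memory representation of a multiple
#' sequence alignment: an ordered set of unique taxon labels and one
#' equal-length character sequence per taxon. Gap characters are kept exactly
#' as read; case is preserved on input and output and only folded internally
#' during site classification.
#'
#' @param taxa Character vector of unique taxon labels.
#' @param seqs Character vector of aligned sequences, one per taxon, all of
#'   identical length (which may be zero).
#' @param seq_type One of `"auto"`, `"nucleotide"`, `"amino_acid"`. With
#'   `"auto"` the type is resolved lazily by [detect_sequence_type()] when a
#'   gap-character set is needed.
#' @return An object of class `alignment` with elements `taxa`, `seqs` and
#'   `seq_type`.
#' @examples
#' aln <- alignment(c("t1", "t2"), c("A-CT", "AGCT"))
#' alignment_length(aln)
#' @export
alignment <- function(taxa, seqs, seq_type = c("auto", "nucleotide", "amino_acid")) {
  seq_type <- match.arg(seq_type)
  taxa <- as.character(taxa)
  seqs <- as.character(seqs)
  if (length(taxa) < 1L || length(taxa) != length(seqs)) {
    tk_stop("malformed_alignment",
            "an alignment needs >= 1 taxon and one sequence per taxon")
  }
  if (anyDuplicated(taxa)) {
    dup <- taxa[duplicated(taxa)][1L]
    tk_stop("duplicate_taxon", sprintf("duplicate taxon label: '%s'", dup))
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L) {
    tk_stop("malformed_alignment",
            sprintf("ragged alignment: sequence lengths %s",
                    paste(unique(lens), collapse = ", ")))
  }
  structure(list(taxa = taxa, seqs = seqs, seq_type = seq_type),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("<alignment> %d taxa x %d columns (%s)\n",
              length(x$taxa), alignment_length(x), x$seq_type))
  show <- utils::head(seq_along(x$taxa), 6L)
  w <- max(nchar(x$taxa[show]))
  for (i in show) {
    s <- x$seqs[i]
    if (nchar(s) > 50L) s <- paste0(substr(s, 1L, 50L), "...")
    cat(sprintf("  %-*s %s\n", w, x$taxa[i], s))
  }
  if (length(x$taxa) > 6L) cat(sprintf("  ... %d more taxa\n", length(x$taxa) - 6L))
  invisible(x)
}

#' Number of columns in an alignment
#' @param aln An [alignment()].
#' @return Integer alignment length (columns).
#' @export
alignment_length <- function(aln) {
  stopifnot(inherits(aln, "alignment"))
  nchar(aln$seqs[1L])
}

#' Number of taxa in an alignment
#' @param aln An [alignment()].
#' @return Integer number of sequences.
#' @export
n_taxa <- function(aln) {
  stopifnot(inherits(aln, "alignment"))
  length(aln$taxa)
}

# taxa x columns character matrix; rownames are taxon labels
as_char_matrix <- function(aln) {
  L <- alignment_length(aln)
  if (L == 0L) {
    return(matrix(character(0), nrow = n_taxa(aln), ncol = 0L,
                  dimnames = list(aln$taxa, NULL)))
  }
  m <- do.call(rbind, strsplit(aln$seqs, "", fixed = TRUE))
  rownames(m) <- aln$taxa
  m
}

# rebuild an alignment from a character matrix (possibly 0 columns)
from_char_matrix <- function(m, taxa, seq_type = "auto") {
  seqs <- if (ncol(m) == 0L) rep("", length(taxa)) else apply(m, 1L, paste0, collapse = "")
  alignment(taxa, unname(seqs), seq_type)
}

#' Subset alignment columns
#'
#' @param aln An [alignment()].
#' @param keep Logical vector of length `alignment_length(aln)` (or an integer
#'   index vector) selecting columns to retain, in original order.
#' @return A new `alignment` with the selected columns; taxa unchanged.
#' @export
subset_columns <- function(aln, keep) {
  m <- as_char_matrix(aln)
  if (is.logical(keep)) {
    stopifnot(length(keep) == ncol(m))
    keep <- which(keep)
  }
  from_char_matrix(m[, keep, drop = FALSE], aln$taxa, aln$seq_type)
}

#' Detect whether an alignment is nucleotide or amino acid
#'
#' Counts the fraction of non-gap characters (case-folded) that fall in the
#' nucleotide set `A, C, G, T, U, N`. If that fraction exceeds the threshold,
#' the alignment is called nucleotide, otherwise amino acid. The default
#' threshold of 0.80 tolerates IUPAC ambiguity codes in DNA while rarely
#' misclassifying protein sequences.
#'
#' @param aln An [alignment()].
#' @param threshold Fraction in (0, 1); default 0.80.
#' @return `"nucleotide"` or `"amino_acid"`.
#' @export
detect_sequence_type <- function(aln, threshold = 0.80) {
  chars <- toupper(unlist(strsplit(aln$seqs, "", fixed = TRUE), use.names = FALSE))
  chars <- chars[!chars %in% c("-", ".", "?", "*", " ")]
  if (length(chars) == 0L) {
    tk_stop("sequence_type_undetermined",
            "cannot determine sequence type: alignment contains only gap characters")
  }
  frac <- mean(chars %in% c("A", "C", "G", "T", "U", "N"))
  if (frac > threshold) "nucleotide" else "amino_acid"
}

# resolve "auto" seq_type to a concrete one (used to pick default gap set)
resolve_seq_type <- function(aln) {
  if (aln$seq_type != "auto") return(aln$seq_type)
  detect_sequence_type(aln)
}
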