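#' Trimming modes
#'
#' The five site-retention strategies:
#' \describe{
#'   \item{`kpi`}{keep only parsimony-informative sites}
#'   \item{`kpic`}{keep parsimony-informative and constant sites}
#'   \item{`gappy`}{keep sites whose gappyness is strictly below the
#'     threshold (default 0.9); this is the default strategy}
#'   \item{`kpi-gappy`}{`kpi` and `gappy` combined (intersection)}
#'   \item{`kpic-gappy`}{`kpic` and `gappy` combined (intersection)}
#' }
#'
#' @return Character vector of mode names.
#' @export
trim_modes <- function() c("kpi", "kpic", "gappy", "kpi-gappy", "kpic-gappy")

canonical_mode <- function(mode) {
  m <- gsub("_", "-", tolower(mode), fixed = TRUE)
  if (!m %in% trim_modes()) {
    tk_stop("unknown_mode", sprintf("unknown trimming mode: '%s'", mode))
  }
  m
}

#' Keep-or-trim decision for one site
#'
#' Applies a trimming mode's rule to a site's classification and gappyness.
#' The gappyness comparison is strict: a site is kept under the gappy rule
#' only if `gappyness < g`, so a 10-taxon column with 9 gaps (gappyness
#' exactly 0.9) is removed at the default threshold.
#'
#' @param classification `"parsimony-informative"`, `"constant"` or
#'   `"other"` (vectorized).
#' @param gappyness Fraction(s) in `[0, 1]`.
#' @param mode A mode from [trim_modes()].
#' @param g Gappyness threshold in `[0, 1]`; default 0.9.
#' @return Logical: `TRUE` to keep the site.
#' @export
keep_site <- function(classification, gappyness, mode = "gappy", g = 0.9) {
  mode <- canonical_mode(mode)
  stopifnot(is.numeric(g), length(g) == 1L, g >= 0, g <= 1)
  pi_ <- classification == "parsimony-informative"
  pic <- pi_ | classification == "constant"
  low_gap <- gappyness < g
  switch(mode,
    "kpi"        = pi_,
    "kpic"       = pic,
    "gappy"      = low_gap,
    "kpi-gappy"  = pi_ & low_gap,
    "kpic-gappy" = pic & low_gap
  )
}

#' Trim an alignment
#'
#' Classifies every column, applies the chosen mode's keep rule, and returns
#' the trimmed alignment together with a per-site log covering every input
#' column in order. Kept columns appear in their original order; taxa are
#' never removed. If no column survives, the result carries a zero-length
#' alignment and a warning is emitted (not an error, so batch pipelines over
#' many genes keep running).
#'
#' @param aln An [alignment()].
#' @param mode A mode from [trim_modes()]; default `"gappy"`.
#' @param g Gappyness threshold in `[0, 1]`; default 0.9. Sites are kept
#'   under the gappy rule iff gappyness is strictly less than `g`.
#' @param gap_chars Gap symbol set, or `NULL` for [default_gap_chars()] of
#'   the detected sequence type.
#' @return A `trim_result`: list with `trimmed` (the trimmed [alignment()]),
#'   `log` (data frame: `position`, `kept`, `classification`, `gappyness`),
#'   `mode`, `g`.
#' @examples
#' aln <- alignment(c("t1", "t2", "t3", "t4"),
#'                  c("AAA-", "AAA-", "BAC-", "BAG-"))
#' res <- trim(aln, mode = "kpi")
#' res$trimmed$seqs
#' @export
trim <- function(aln, mode = "gappy", g = 0.9, gap_chars = NULL) {
  stopifnot(inherits(aln, "alignment"))
  mode <- canonical_mode(mode)
  if (!is.numeric(g) || length(g) != 1L || is.na(g) || g < 0 || g > 1) {
    tk_stop("bad_threshold", "gappyness threshold must be a number in [0, 1]")
  }
  cls <- classify_alignment(aln, gap_chars)
  kept <- if (nrow(cls) == 0L) logical(0) else
    keep_site(cls$classification, cls$gappyness, mode, g)
  trimmed <- subset_columns(aln, kept)
  if (alignment_length(aln) > 0L && !any(kept)) {
    tk_warn("empty_trim_result",
            sprintf("no sites survive trimming (mode %s, g = %g)", mode, g))
  }
  structure(list(
    trimmed = trimmed,
    log = data.frame(position = cls$position, kept = kept,
                     classification = cls$classification,
                     gappyness = cls$gappyness),
    mode = mode, g = g
  ), class = "trim_result")
}

#' @export
print.trim_result <- function(x, ...) {
  cat(sprintf("<trim_result> mode %s (g = %g): %d of %d sites kept\n",
              x$mode, x$g, sum(x$log$kept), nrow(x$log)))
  invisible(x)
}

#' Write the per-site trimming log
#'
#' One row per input column, in ascending position order, with four
#' space-separated fields: 1-based position, `keep` or `trim`, the site
#' classification (`parsimony-informative`, `constant`, `other`), and the
#' site gappyness with 4 decimal places.
#'
#' @param result A `trim_result` from [trim()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_log <- function(result, path) {
  stopifnot(inherits(result, "trim_result"))
  log <- result$log
  lines <- sprintf("%d %s %s %.4f", log$position,
                   ifelse(log$kept, "keep", "trim"),
                   log$classification, log$gappyness)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
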