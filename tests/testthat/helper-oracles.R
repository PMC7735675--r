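# Independent oracles. These restate definitions directly and share no code
# with the implementation paths they check.

# Count-based site classification straight from the definition: a state is a
# non-gap symbol (case-folded); parsimony-informative iff >= 2 states occur
# in >= 2 taxa; constant iff exactly 1 does; other iff none does.
oracle_classify <- function(column, gap_chars = c("-", "?", "*", "X", "N")) {
  s <- toupper(column)
  s <- s[!(s %in% toupper(gap_chars))]
  n_with_two <- 0L
  for (st in unique(s)) {
    if (sum(s == st) >= 2L) n_with_two <- n_with_two + 1L
  }
  if (n_with_two >= 2L) "parsimony-informative"
  else if (n_with_two == 1L) "constant"
  else "other"
}

# Brute-force normalized RF via explicitly enumerated splits (ape::prop.part
# provides the clade enumeration; canonicalization and the symmetric
# difference are computed here from first principles).
oracle_nrf <- function(t1, t2) {
  splits_of <- function(tr) {
    tips <- sort(tr$tip.label)
    pp <- ape::prop.part(tr)
    labs <- attr(pp, "labels")
    keys <- vapply(pp, function(idx) {
      side <- sort(labs[idx])
      if (tips[1] %in% side) side <- setdiff(tips, side)
      paste(side, collapse = "|")
    }, character(1))
    sizes <- vapply(pp, length, integer(1))
    n <- length(tips)
    unique(keys[sizes >= 2 & sizes <= n - 2])
  }
  s1 <- splits_of(t1)
  s2 <- splits_of(t2)
  if (length(s1) + length(s2) == 0) return(0)
  (sum(!s1 %in% s2) + sum(!s2 %in% s1)) / (length(s1) + length(s2))
}
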