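# Fixture builders shared across test files. All randomness is locally
# seeded so tests are reproducible.

# Random alignment with mixed-case residues and gaps. Labels are kept to
# <= 10 chars when strict_labels = TRUE (strict phylip's field width).
random_alignment <- function(n_taxa, L, seed, strict_labels = FALSE,
                             alphabet = c("A", "C", "G", "T", "a", "c", "-")) {
  set.seed(seed)
  labels <- if (strict_labels) {
    sprintf("tx%d_%s", seq_len(n_taxa),
            replicate(n_taxa, paste0(sample(letters, 3), collapse = "")))
  } else {
    sprintf("taxon_%d_%s", seq_len(n_taxa),
            replicate(n_taxa, paste0(sample(letters, sample(1:12, 1)), collapse = "")))
  }
  seqs <- replicate(n_taxa,
                    paste0(sample(alphabet, L, replace = TRUE), collapse = ""))
  alignment(labels, seqs)
}

# Random designed alignment (known ground truth) for property tests.
random_designed <- function(seed, n_taxa = NULL, n_cols = NULL) {
  set.seed(seed)
  if (is.null(n_taxa)) n_taxa <- sample(4:12, 1)
  if (is.null(n_cols)) n_cols <- sample(5:15, 1)
  specs <- data.frame(
    classification = sample(c("parsimony-informative", "constant", "other"),
                            n_cols, replace = TRUE),
    gappyness = stats::runif(n_cols))
  make_designed_alignment(n_taxa, specs, seed = seed + 1)
}

# Random binary tree with distinct branch lengths and support labels.
random_support_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$node.label <- as.character(sample(50:100, tr$Nnode, replace = TRUE))
  tr
}
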