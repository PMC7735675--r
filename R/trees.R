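#' Parse a newick string
#'
#' Thin wrapper over `ape::read.tree()` that adds position-aware validation:
#' unbalanced parentheses are reported with the character offset of the
#' first imbalance. Branch lengths and numeric internal-node labels
#' (e.g. bootstrap support) are preserved.
#'
#' @param text A newick string (single tree).
#' @return An `ape::phylo` tree.
#' @examples
#' tr <- parse_newick("((a:1,b:1)90:1,(c:1,d:1)85:1);")
#' average_bipartition_support(tr)
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  depth <- 0L
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) {
      tk_stop("parse_error",
              sprintf("newick: unmatched ')' at offset %d", i))
    }
  }
  if (depth != 0L) {
    tk_stop("parse_error",
            sprintf("newick: %d unclosed '(' at end of string", depth))
  }
  tr <- tryCatch(ape::read.tree(text = text), error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(tr)) {
    tk_stop("parse_error", "newick: string did not parse as a tree")
  }
  if (anyDuplicated(tr$tip.label)) {
    tk_stop("parse_error", "newick: duplicate leaf labels")
  }
  tr
}

#' Serialize a tree to newick
#' @param tree An `ape::phylo` tree.
#' @return A newick string.
#' @export
serialize_newick <- function(tree) ape::write.tree(tree)

# tip-label sets below every node, by node id (postorder accumulation)
tip_descendants <- function(tree) {
  n_tip <- length(tree$tip.label)
  desc <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) desc[[i]] <- tree$tip.label[i]
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(edges))) {
    desc[[edges[k, 1L]]] <- c(desc[[edges[k, 1L]]], desc[[edges[k, 2L]]])
  }
  desc
}

# canonical key for one side of a split: the side NOT containing the
# reference leaf (smallest label), sorted; keyed with an unprintable sep
split_key <- function(side, all_tips, ref = min(all_tips)) {
  if (ref %in% side) side <- setdiff(all_tips, side)
  paste(sort(side), collapse = "\x1f")
}

#' Non-trivial bipartitions of a tree
#'
#' Each internal edge of the (implicitly unrooted) tree splits the leaf set
#' in two; trivial splits that cut off a single leaf are excluded, as is the
#' duplicate split a rooted tree's root edge induces. Splits are returned as
#' canonical keys (the side not containing the lexicographically smallest
#' leaf, sorted).
#'
#' @param tree An `ape::phylo` tree.
#' @return Character vector of canonical split keys; the leaf sides are
#'   available in the `"sides"` attribute as a list of character vectors.
#' @export
bipartitions <- function(tree) {
  tips <- tree$tip.label
  n <- length(tips)
  desc <- tip_descendants(tree)
  n_tip <- n
  keys <- character(0)
  sides <- list()
  for (node in seq.int(n_tip + 1L, n_tip + tree$Nnode)) {
    side <- desc[[node]]
    if (length(side) < 2L || length(side) > n - 2L) next
    key <- split_key(side, tips)
    if (!key %in% keys) {
      keys <- c(keys, key)
      sides[[length(sides) + 1L]] <- sort(side)
    }
  }
  structure(keys, sides = sides)
}

#' Normalized Robinson-Foulds distance
#'
#' The symmetric difference of the two trees' non-trivial bipartition sets,
#' divided by the total number of bipartitions in both trees (for two fully
#' binary unrooted trees that denominator is `2 * (n - 3)`). 0 means
#' identical topologies; 1 means no shared bipartition. Non-binary trees
#' degrade gracefully: the denominator is the total internal-split count of
#' both trees, and two identical star trees give 0.
#'
#' @param t1,t2 `ape::phylo` trees over the same leaf set.
#' @return Fraction in `[0, 1]`.
#' @export
normalized_rf <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    tk_stop("leaf_set_mismatch", "trees have different leaf sets")
  }
  s1 <- as.character(bipartitions(t1))
  s2 <- as.character(bipartitions(t2))
  denom <- length(s1) + length(s2)
  if (denom == 0L) return(0)
  rf <- sum(!s1 %in% s2) + sum(!s2 %in% s1)
  rf / denom
}

#' Average bipartition support
#'
#' The arithmetic mean of the numeric support values (e.g. bootstrap
#' percentages) attached to a tree's internal nodes. Nodes without a
#' numeric label (including an unlabeled root) are skipped.
#'
#' @param tree An `ape::phylo` tree with numeric internal-node labels.
#' @return Mean support value.
#' @export
average_bipartition_support <- function(tree) {
  labs <- tree$node.label
  vals <- suppressWarnings(as.numeric(labs))
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) {
    tk_stop("no_support_values", "tree carries no numeric internal-node support values")
  }
  mean(vals)
}

# edge-to-key map on the unrooted tree: internal edges keyed by split,
# terminal edges by leaf label; returns data.frame(key, length)
edge_length_table <- function(tree) {
  tree <- ape::unroot(tree)
  if (is.null(tree$edge.length)) {
    tk_stop("topology_mismatch", "tree has no branch lengths")
  }
  tips <- tree$tip.label
  n_tip <- length(tips)
  desc <- tip_descendants(tree)
  keys <- character(nrow(tree$edge))
  for (k in seq_len(nrow(tree$edge))) {
    child <- tree$edge[k, 2L]
    if (child <= n_tip) {
      keys[k] <- paste0("leaf\x1f", tips[child])
    } else {
      side <- desc[[child]]
      keys[k] <- if (length(side) > length(tips) - 2L) NA_character_ else
        split_key(side, tips)
    }
  }
  out <- data.frame(key = keys, length = tree$edge.length,
                    stringsAsFactors = FALSE)
  out[!is.na(out$key), , drop = FALSE]
}

#' Spearman correlation of branch lengths between topology-matched trees
#'
#' Pairs branch lengths edge-by-edge — internal edges matched by the
#' bipartition they induce, terminal edges by their leaf label — and returns
#' the Spearman rank correlation of the paired lengths. The two trees must
#' have identical leaf sets and identical bipartition sets (i.e. the test
#' tree's topology is constrained to the reference), otherwise a
#' `topology_mismatch` error is raised: comparing lengths across different
#' topologies is not meaningful.
#'
#' @param t_ref,t_test `ape::phylo` trees with branch lengths, identical
#'   leaf sets and identical topologies.
#' @return Spearman rho in `[-1, 1]`.
#' @export
branch_length_rho <- function(t_ref, t_test) {
  if (!setequal(t_ref$tip.label, t_test$tip.label)) {
    tk_stop("leaf_set_mismatch", "trees have different leaf sets")
  }
  if (!setequal(as.character(bipartitions(t_ref)),
                as.character(bipartitions(t_test)))) {
    tk_stop("topology_mismatch",
            "trees have different topologies; branch lengths cannot be paired")
  }
  e_ref <- edge_length_table(t_ref)
  e_test <- edge_length_table(t_test)
  if (anyDuplicated(e_ref$key) || anyDuplicated(e_test$key) ||
      !setequal(e_ref$key, e_test$key)) {
    tk_stop("topology_mismatch", "edge sets of the two trees cannot be paired")
  }
  x <- e_ref$length
  y <- e_test$length[match(e_ref$key, e_test$key)]
  rx <- rank(x)
  ry <- rank(y)
  # exact anchors: identical or perfectly reversed rankings are common in
  # practice (untrimmed vs trimmed gene trees) and should not pick up
  # floating-point noise from the general formula
  if (identical(rx, ry)) return(1)
  if (identical(rx, length(ry) + 1 - ry)) return(-1)
  stats::cor(x, y, method = "spearman")
}
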