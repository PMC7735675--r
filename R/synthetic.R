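#' Design an alignment with known per-column classifications
#'
#' Builds an alignment column by column so that each column classifies
#' (under [classify_site()] with the default gap set) exactly as requested,
#' with gappyness as close to the requested target as the classification
#' allows. Realizability limits: a parsimony-informative column needs at
#' least 4 non-gap cells (two states in two taxa each), a constant column at
#' least 2, and an "other" column can hold at most one cell per alphabet
#' symbol (every non-gap state must be a singleton) unless it is fully
#' gapped. The requested gappyness is therefore snapped to the nearest
#' realizable fraction; the realized values are returned.
#'
#' @param n_taxa Number of taxa (>= 4 for parsimony-informative columns).
#' @param specs Data frame with columns `classification`
#'   (`"parsimony-informative"`, `"constant"`, `"other"`) and `gappyness`
#'   (target fraction in `[0, 1]`), one row per column.
#' @param seed Integer seed; the same seed always yields the same alignment.
#' @param alphabet Residue alphabet used to fill columns; default the DNA
#'   bases (N is excluded because the default nucleotide gap set treats it
#'   as missing).
#' @return List with `alignment` (an [alignment()] with taxa `t1..tn`) and
#'   `expected` (data frame: `position`, `classification`, `gappyness` as
#'   realized).
#' @examples
#' specs <- data.frame(
#'   classification = c("parsimony-informative", "constant", "other"),
#'   gappyness = c(0, 0, 0.5))
#' fx <- make_designed_alignment(6, specs, seed = 1)
#' classify_alignment(fx$alignment)
#' @export
make_designed_alignment <- function(n_taxa, specs, seed,
                                    alphabet = c("A", "C", "G", "T")) {
  stopifnot(n_taxa >= 1L, nrow(specs) >= 1L)
  specs$classification <- vapply(as.character(specs$classification),
                                 canonical_classification, character(1L))
  with_seed(seed, {
    cols <- vector("list", nrow(specs))
    realized <- numeric(nrow(specs))
    for (i in seq_len(nrow(specs))) {
      built <- build_column(n_taxa, specs$classification[i],
                            specs$gappyness[i], alphabet)
      cols[[i]] <- built$column
      realized[i] <- built$gappyness
    }
    m <- do.call(cbind, cols)
    aln <- from_char_matrix(m, paste0("t", seq_len(n_taxa)), "nucleotide")
    list(alignment = aln,
         expected = data.frame(position = seq_len(nrow(specs)),
                               classification = specs$classification,
                               gappyness = realized))
  })
}

canonical_classification <- function(x) {
  x <- gsub("_", "-", tolower(x), fixed = TRUE)
  if (x %in% c("pi", "parsimony-informative")) return("parsimony-informative")
  if (x %in% c("constant", "other")) return(x)
  tk_stop("spec_infeasible", sprintf("unknown column classification: '%s'", x))
}

build_column <- function(n, classification, gap_target, alphabet) {
  if (classification == "parsimony-informative") {
    if (n < 4L || length(alphabet) < 2L) {
      tk_stop("spec_infeasible",
              "parsimony-informative columns need >= 4 taxa and >= 2 states")
    }
    feasible_gaps <- 0:(n - 4L)
  } else if (classification == "constant") {
    if (n < 2L) tk_stop("spec_infeasible", "constant columns need >= 2 taxa")
    feasible_gaps <- 0:(n - 2L)
  } else {
    # "other": all non-gap states singletons, or fully gapped
    feasible_gaps <- c(max(0L, n - length(alphabet)):(n - 1L), n)
  }
  n_gap <- feasible_gaps[which.min(abs(feasible_gaps - gap_target * n))]
  gap_rows <- if (n_gap > 0L) sample.int(n, n_gap) else integer(0)
  fill_rows <- setdiff(seq_len(n), gap_rows)
  col <- rep("-", n)
  k <- length(fill_rows)
  if (k > 0L) {
    if (classification == "parsimony-informative") {
      states <- sample(alphabet, 2L)
      # two of each guaranteed, remainder split at random between the two
      assign <- c(rep(states, each = 2L), sample(states, k - 4L, replace = TRUE))
      col[fill_rows] <- sample(assign)
    } else if (classification == "constant") {
      col[fill_rows] <- sample(alphabet, 1L)
    } else {
      col[fill_rows] <- sample(alphabet, k)
    }
  }
  list(column = col, gappyness = n_gap / n)
}

#' Write a ground-truth sidecar for a designed alignment
#'
#' TSV with one row per column (`position`, `classification`, `gappyness`),
#' for test harnesses that consume fixtures from disk.
#'
#' @param expected The `expected` data frame from
#'   [make_designed_alignment()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ground_truth <- function(expected, path) {
  utils::write.table(expected, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# run code with a temporarily seeded RNG, restoring the caller's state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Evolutionary model for the sequence simulator
#'
#' Collects the parameters of the substitution-plus-indel process. The
#' nucleotide defaults are: stationary frequencies 0.1, 0.2, 0.3, 0.4 for
#' T, C, A, G; all-equal exchangeabilities (override via
#' `exchangeabilities` for a general time-reversible scheme); insertion and
#' deletion rates each 5% of the substitution rate; indel lengths drawn from
#' a power law with exponent 1.7 truncated at 500. Amino-acid models default
#' to uniform frequencies over the 20 residues and indel rates of 1%.
#'
#' @param seq_type `"nucleotide"` or `"amino_acid"`.
#' @param state_freqs Named numeric vector of stationary frequencies
#'   (must sum to 1); default as above.
#' @param exchangeabilities Symmetric matrix of relative exchange rates
#'   (diagonal ignored), dimnames matching the states; `NULL` for all-equal.
#' @param indel_rate Insertion rate and deletion rate, each relative to a
#'   substitution rate of 1 per site.
#' @param indel_exponent Power-law exponent `a` for indel lengths.
#' @param indel_max Truncation point `M` of the indel length law.
#' @return An `evolution_model` list.
#' @export
evolution_model <- function(seq_type = c("nucleotide", "amino_acid"),
                            state_freqs = NULL,
                            exchangeabilities = NULL,
                            indel_rate = NULL,
                            indel_exponent = 1.7,
                            indel_max = 500L) {
  seq_type <- match.arg(seq_type)
  if (is.null(state_freqs)) {
    state_freqs <- if (seq_type == "nucleotide") {
      c(T = 0.1, C = 0.2, A = 0.3, G = 0.4)
    } else {
      f <- rep(1 / 20, 20)
      names(f) <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
      f
    }
  }
  if (is.null(indel_rate)) {
    indel_rate <- if (seq_type == "nucleotide") 0.05 else 0.01
  }
  if (is.null(names(state_freqs)) || any(state_freqs < 0) ||
      abs(sum(state_freqs) - 1) > 1e-8) {
    tk_stop("model_error", "state_freqs must be named, non-negative, and sum to 1")
  }
  states <- names(state_freqs)
  ns <- length(states)
  if (is.null(exchangeabilities)) {
    exchangeabilities <- matrix(1, ns, ns, dimnames = list(states, states))
  }
  if (!all(dim(exchangeabilities) == ns) ||
      any(exchangeabilities[upper.tri(exchangeabilities)] < 0)) {
    tk_stop("model_error", "exchangeabilities must be a non-negative square matrix")
  }
  if (indel_rate < 0 || indel_exponent <= 1 || indel_max < 1L) {
    tk_stop("model_error", "invalid indel parameters")
  }
  # GTR-style rate matrix q_ij = r_ij * pi_j, scaled to 1 substitution/site
  q <- exchangeabilities * rep(state_freqs, each = ns)
  diag(q) <- 0
  diag(q) <- -rowSums(q)
  mu <- -sum(state_freqs * diag(q))
  q <- q / mu
  structure(list(seq_type = seq_type, states = states,
                 state_freqs = state_freqs, q = q,
                 leave_rates = -diag(q),
                 indel_rate = indel_rate,
                 indel_exponent = indel_exponent,
                 indel_max = as.integer(indel_max)),
            class = "evolution_model")
}

#' Sample indel lengths from a truncated power law
#'
#' Lengths are drawn with probability proportional to `len^(-a)` on
#' `1..max_len`. With the default exponent 1.7 single-residue indels
#' dominate, but occasional long events occur up to the truncation point.
#'
#' @param n Number of draws.
#' @param a Exponent (> 1); default 1.7.
#' @param max_len Truncation point; default 500.
#' @return Integer vector of lengths in `[1, max_len]`.
#' @export
sample_indel_length <- function(n = 1L, a = 1.7, max_len = 500L) {
  stopifnot(a > 1, max_len >= 1L)
  if (max_len == 1L) return(rep(1L, n))
  w <- (seq_len(max_len))^(-a)
  sample.int(max_len, n, replace = TRUE, prob = w)
}

#' Simulate sequence evolution with indels along a tree
#'
#' Evolves a root sequence (drawn from the model's stationary frequencies)
#' down every branch of the tree under a continuous-time process in which
#' substitutions, insertions and deletions share one event queue
#' (Gillespie-style event sampling, with thinning for state-dependent
#' substitution rates). Branch lengths are in expected substitutions per
#' site. Insertions create new homology columns; the returned alignment
#' contains a column for every site surviving in at least one leaf, with
#' `-` marking lineages in which the site was deleted or never existed.
#'
#' @param tree An `ape::phylo` tree with non-negative branch lengths.
#' @param root_length Length of the root sequence (default 1000, a common
#'   simulated-gene scale).
#' @param model An [evolution_model()].
#' @param seed Integer seed; identical seeds give identical alignments.
#' @return An [alignment()] over the tree's leaf labels.
#' @export
evolve_sequences <- function(tree, root_length = 1000L,
                             model = evolution_model(), seed = 1L) {
  stopifnot(inherits(tree, "phylo"), root_length >= 1L)
  if (is.null(tree$edge.length) || any(tree$edge.length < 0)) {
    tk_stop("model_error", "tree must have non-negative branch lengths")
  }
  with_seed(seed, {
    n_tip <- length(tree$tip.label)
    root <- n_tip + 1L
    # global homology registry: ordered vector of site ids
    registry <- new.env(parent = emptyenv())
    registry$order <- seq_len(root_length)
    registry$next_id <- root_length + 1L
    root_seq <- list(
      ids = seq_len(root_length),
      states = sample(model$states, root_length, replace = TRUE,
                      prob = model$state_freqs))
    children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
    leaf_seqs <- vector("list", n_tip)
    recurse <- function(node, seq) {
      for (k in children[[as.character(node)]]) {
        child <- tree$edge[k, 2L]
        child_seq <- evolve_branch(seq, tree$edge.length[k], model, registry)
        if (child <= n_tip) leaf_seqs[[child]] <<- child_seq
        else recurse(child, child_seq)
      }
    }
    recurse(root, root_seq)
    assemble_alignment(leaf_seqs, tree$tip.label, registry)
  })
}

# one Gillespie pass along a single branch of length t (subs/site)
evolve_branch <- function(seq, t, model, registry) {
  if (t == 0) return(seq)
  states <- seq$states
  ids <- seq$ids
  max_leave <- max(model$leave_rates)
  time <- 0
  repeat {
    L <- length(states)
    r_sub <- max_leave * L          # thinned candidate rate
    r_ins <- model$indel_rate * (L + 1L)
    r_del <- model$indel_rate * L
    total <- r_sub + r_ins + r_del
    if (total <= 0) break
    time <- time + stats::rexp(1L, total)
    if (time > t) break
    u <- stats::runif(1L) * total
    if (u < r_sub) {
      site <- sample.int(L, 1L)
      from <- states[site]
      leave <- model$leave_rates[from]
      if (stats::runif(1L) < leave / max_leave) {
        rates <- model$q[from, ]
        rates[from] <- 0
        states[site] <- sample(model$states, 1L, prob = rates)
      }
    } else if (u < r_sub + r_ins) {
      len <- sample_indel_length(1L, model$indel_exponent, model$indel_max)
      pos <- sample.int(L + 1L, 1L) - 1L          # insert after this position
      new_ids <- seq.int(registry$next_id, length.out = len)
      registry$next_id <- registry$next_id + len
      anchor <- if (pos == 0L) {
        if (L == 0L) 0L else match(ids[1L], registry$order) - 1L
      } else {
        match(ids[pos], registry$order)
      }
      registry$order <- append(registry$order, new_ids, after = anchor)
      new_states <- sample(model$states, len, replace = TRUE,
                           prob = model$state_freqs)
      ids <- append(ids, new_ids, after = pos)
      states <- append(states, new_states, after = pos)
    } else {
      if (L == 0L) next
      len <- sample_indel_length(1L, model$indel_exponent, model$indel_max)
      start <- sample.int(L, 1L)
      drop <- start:min(L, start + len - 1L)
      ids <- ids[-drop]
      states <- states[-drop]
    }
  }
  list(ids = ids, states = states)
}

assemble_alignment <- function(leaf_seqs, tip_labels, registry) {
  present <- sort(unique(unlist(lapply(leaf_seqs, `[[`, "ids"))))
  cols <- registry$order[registry$order %in% present]
  m <- matrix("-", nrow = length(tip_labels), ncol = length(cols),
              dimnames = list(tip_labels, NULL))
  for (i in seq_along(leaf_seqs)) {
    hit <- match(leaf_seqs[[i]]$ids, cols)
    m[i, hit] <- leaf_seqs[[i]]$states
  }
  from_char_matrix(m, tip_labels,
                   if (nrow(m) > 0 && ncol(m) > 0) "auto" else "auto")
}
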