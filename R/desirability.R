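#' Desirability rescaling of a metric
#'
#' Rescales a distribution of metric values linearly to `[0, 1]`, oriented
#' so the preferred extreme maps to 1. For a metric where low values are
#' best (e.g. a tree distance), the anchors are `A = max(values)` and
#' `B = min(values)`; for a metric where high values are best (e.g. mean
#' bootstrap support), `A = min(values)` and `B = max(values)`. Each value
#' `Y` maps to `(Y - A) / (B - A)`, clamped to `[0, 1]`. When every value is
#' identical (`A == B`) all values map to 1: no strategy can be penalized on
#' a metric that does not discriminate.
#'
#' @param values Numeric vector (non-empty).
#' @param direction `"low_is_best"` or `"high_is_best"`.
#' @return Numeric vector of desirabilities in `[0, 1]`.
#' @examples
#' desirability(c(0.2, 0.5, 0.8), "low_is_best")   # 1.0 0.5 0.0
#' desirability(c(70, 85, 100), "high_is_best")    # 0.0 0.5 1.0
#' @export
desirability <- function(values, direction = c("low_is_best", "high_is_best")) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(values), length(values) >= 1L, !anyNA(values))
  if (direction == "low_is_best") {
    a <- max(values); b <- min(values)
  } else {
    a <- min(values); b <- max(values)
  }
  if (a == b) return(rep(1, length(values)))
  pmin(1, pmax(0, (values - a) / (b - a)))
}

#' Rank trimming strategies by integrated desirability
#'
#' For each gene (alignment), the per-strategy accuracy metric (normalized
#' RF, low is best) and support metric (average bipartition support, high is
#' best) are each rescaled with [desirability()] across the strategies, the
#' two desirabilities are integrated into one score, and strategies are
#' ranked per gene by descending integrated score (ties get their average
#' rank). Strategies are then ordered overall by their mean per-gene rank
#' (ascending); the mean integrated score is also reported and can be used
#' as the ordering criterion instead.
#'
#' @param scores Data frame with columns `gene`, `strategy`, `nrf`, `abs`;
#'   at least 2 strategies per gene.
#' @param integration `"arithmetic"` (default; mean of the two
#'   desirabilities, robust to a single zero) or `"geometric"`.
#' @param order_by `"mean_rank"` (default) or `"mean_score"`.
#' @return A `strategy_ranking` list: `per_gene` (data frame with `gene`,
#'   `strategy`, `nrf`, `abs`, `d_nrf`, `d_abs`, `integrated`, `rank`) and
#'   `summary` (data frame with `strategy`, `mean_rank`, `mean_integrated`,
#'   ordered best first).
#' @export
integrate_and_rank <- function(scores,
                               integration = c("arithmetic", "geometric"),
                               order_by = c("mean_rank", "mean_score")) {
  integration <- match.arg(integration)
  order_by <- match.arg(order_by)
  need <- c("gene", "strategy", "nrf", "abs")
  if (!all(need %in% names(scores))) {
    tk_stop("bad_scores", sprintf("scores must have columns: %s",
                                  paste(need, collapse = ", ")))
  }
  per_gene <- do.call(rbind, lapply(split(scores, scores$gene), function(df) {
    if (nrow(df) < 2L) {
      tk_stop("bad_scores",
              sprintf("gene '%s' has fewer than 2 strategies", df$gene[1L]))
    }
    df$d_nrf <- desirability(df$nrf, "low_is_best")
    df$d_abs <- desirability(df$abs, "high_is_best")
    df$integrated <- if (integration == "arithmetic") {
      (df$d_nrf + df$d_abs) / 2
    } else {
      sqrt(df$d_nrf * df$d_abs)
    }
    df$rank <- rank(-df$integrated, ties.method = "average")
    df
  }))
  rownames(per_gene) <- NULL
  mean_rank <- tapply(per_gene$rank, per_gene$strategy, mean)
  mean_integrated <- tapply(per_gene$integrated, per_gene$strategy, mean)
  summary <- data.frame(strategy = names(mean_rank),
                        mean_rank = as.numeric(mean_rank),
                        mean_integrated = as.numeric(mean_integrated),
                        stringsAsFactors = FALSE)
  ord <- if (order_by == "mean_rank") order(summary$mean_rank)
         else order(-summary$mean_integrated)
  summary <- summary[ord, , drop = FALSE]
  rownames(summary) <- NULL
  structure(list(per_gene = per_gene, summary = summary),
            class = "strategy_ranking")
}

#' @export
print.strategy_ranking <- function(x, ...) {
  cat(sprintf("<strategy_ranking> %d strategies x %d genes\n",
              nrow(x$summary), length(unique(x$per_gene$gene))))
  print(x$summary)
  invisible(x)
}

#' Write a strategy-ranking report as TSV
#'
#' @param ranking A `strategy_ranking` from [integrate_and_rank()].
#' @param scores_path Path for the per-gene score table (TSV).
#' @param summary_path Optional path for the overall mean-rank table (TSV).
#' @return Invisibly, `scores_path`.
#' @export
write_strategy_report <- function(ranking, scores_path, summary_path = NULL) {
  stopifnot(inherits(ranking, "strategy_ranking"))
  utils::write.table(ranking$per_gene, scores_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(summary_path)) {
    utils::write.table(ranking$summary, summary_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(scores_path)
}
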