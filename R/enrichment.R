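# Sort-seq enrichment: variants are scored by the log2 ratio of their
# relative frequency in the FACS-sorted pool to that in the input pool, with
# a pseudocount so absence is finite. The statistic is the minimal standard
# choice for sorted/unsorted count pairs; the ranking, not the absolute
# score, is what downstream candidate selection uses.

#' Variant enrichment between input and sorted pools
#'
#' For each replicate, computes
#' `score(v) = log2[(sorted_v + pc) / (sum(sorted) + pc * n)] -
#'             log2[(input_v + pc) / (sum(input) + pc * n)]`
#' over the union of variants seen in either pool (absent = 0), and ranks
#' descending by score, ties broken by higher sorted count then by
#' variant id. Scores depend on relative frequencies only, so they are
#' invariant to rescaling either pool's depth (exactly so in the
#' small-pseudocount limit).
#'
#' @param counts Long tibble with columns `variant_id`, `pool` (`"input"` or
#'   `"sorted"`), `count`, and optionally `replicate` (default 1).
#' @param pseudocount Positive pseudocount (default 0.5).
#' @param rank_by `"enrichment"` (default) ranks by the score;
#'   `"frequency"` ranks by sorted-pool frequency alone.
#' @return A tibble of class `enrichment_tbl`: `replicate`, `variant_id`,
#'   `input_count`, `sorted_count`, `score`, `rank` (1 = most enriched;
#'   ranks are a permutation of 1..n within each replicate).
#' @export
enrichment_scores <- function(counts, pseudocount = 0.5,
                              rank_by = c("enrichment", "frequency")) {
  rank_by <- match.arg(rank_by)
  if (pseudocount <= 0) abort("`pseudocount` must be positive.")
  counts <- as_tibble(counts)
  stopifnot(all(c("variant_id", "pool", "count") %in% names(counts)))
  if (!all(counts$pool %in% c("input", "sorted"))) {
    abort("`pool` must be 'input' or 'sorted'.")
  }
  if (!"replicate" %in% names(counts)) counts$replicate <- 1L

  wide <- counts |>
    group_by(.data$replicate, .data$pool, .data$variant_id) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "pool", values_from = "count",
                       values_fill = 0L)
  if (!all(c("input", "sorted") %in% names(wide))) {
    abort("both an input and a sorted pool are required.")
  }
  out <- rename(wide, input_count = "input", sorted_count = "sorted")
  out <- out |>
    group_by(.data$replicate) |>
    group_modify(function(df, key) {
      n <- nrow(df)
      ti <- sum(df$input_count); ts <- sum(df$sorted_count)
      if (ti == 0 || ts == 0) {
        abort(paste0("empty pool in replicate ", key$replicate[1], "."))
      }
      pc <- pseudocount
      score <- log2((df$sorted_count + pc) / (ts + pc * n)) -
        log2((df$input_count + pc) / (ti + pc * n))
      key_metric <- if (rank_by == "enrichment") score else
        df$sorted_count / ts
      o <- order(-key_metric, -df$sorted_count, df$variant_id)
      df$score <- score
      df$rank <- integer(n); df$rank[o] <- seq_len(n)
      df
    }) |>
    ungroup() |>
    arrange(.data$replicate, .data$rank)
  class(out) <- c("enrichment_tbl", class(out))
  out
}

#' Aggregate variant ranks across replicates
#'
#' @param scores An [enrichment_scores()] table covering one or more
#'   replicates.
#' @param top_k Rank cutoff per replicate (default 10).
#' @param mode `"union"` (default): variants ranked within `top_k` in at
#'   least one replicate, annotated with how many replicates support each;
#'   `"intersection"`: only variants within `top_k` in every replicate.
#' @return A tibble with columns `variant_id`, `n_replicates`, `best_rank`,
#'   `mean_rank`, sorted by support then best rank.
#' @export
rank_aggregate <- function(scores, top_k = 10L, mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  if (top_k < 1L) abort("`top_k` must be >= 1.")
  stopifnot(is.data.frame(scores),
            all(c("replicate", "variant_id", "rank") %in% names(scores)))
  n_rep <- n_distinct(scores$replicate)
  hits <- scores |>
    filter(.data$rank <= top_k) |>
    group_by(.data$variant_id) |>
    summarise(n_replicates = n_distinct(.data$replicate),
              best_rank = min(.data$rank),
              mean_rank = mean(.data$rank)) |>
    arrange(desc(.data$n_replicates), .data$best_rank, .data$variant_id)
  if (mode == "intersection") hits <- filter(hits, .data$n_replicates == n_rep)
  hits
}

#' @exportS3Method generics::glance
glance.enrichment_tbl <- function(x, ...) {
  tibble(n_replicates = n_distinct(x$replicate),
         n_variants = n_distinct(x$variant_id),
         max_score = max(x$score), min_score = min(x$score))
}

#' @exportS3Method ggplot2::autoplot
autoplot.enrichment_tbl <- function(object, highlight = character(), ...) {
  df <- as_tibble(object) |>
    mutate(highlighted = .data$variant_id %in% highlight)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$score,
                                   colour = .data$highlighted)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~ .data$replicate, labeller = ggplot2::label_both) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "#b2182b"),
                                 guide = "none") +
    ggplot2::labs(x = "rank", y = expression(log[2] ~ enrichment)) +
    ggplot2::theme_minimal()
}
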