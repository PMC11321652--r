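# On- vs off-target specificity. A site is summarised by one number: its
# maximum per-position A-to-G frequency over the protospacer (matching how
# per-site editing is usually plotted), background-subtracted against an
# untreated control.

#' Site-level editing frequency
#'
#' Maximum per-position substitution frequency across the site's protospacer
#' positions (or a supplied position set). A `position` argument selects a
#' single position instead of taking the maximum.
#'
#' @param table An [allele_table()] quantified over the site.
#' @param positions Positions to consider; default the protospacer positions
#'   that fall inside the table's quantification window.
#' @param position Optional single position overriding the max-reduction.
#' @param from_base,to_base Substitution type (default A-to-G).
#' @return A single frequency in `[0, 1]` (0 when no applicable position).
#' @export
site_frequency <- function(table, positions = NULL, position = NULL,
                           from_base = "A", to_base = "G") {
  stopifnot(inherits(table, "allele_tbl"))
  fv <- per_position_frequencies(table, from_base, to_base)
  if (!is.null(position)) {
    row <- fv[fv$position == position, ]
    if (nrow(row) == 0L || !row$applicable) {
      abort(paste0("position ", position, " is not an applicable ",
                   from_base, " position."))
    }
    return(row$frequency)
  }
  spec <- at_spec(table)
  positions <- positions %||%
    intersect(window_positions(at_window(table)),
              seq_len(spec$protospacer_length))
  vals <- fv$frequency[fv$position %in% positions & fv$applicable]
  if (length(vals) == 0L) return(0)
  max(vals)
}

#' On- versus off-target specificity summary
#'
#' Subtracts untreated-control background from every site
#' (`net = max(freq - control_freq, 0)`) and reports, per editor, the net
#' on-target frequency, the off-target total, and the specificity ratio
#' `net_on / (net_on + sum(net_OT))` — 1 when all off-targets are clean and
#' the on-target edits, `NA` (not defined) when nothing edits at all.
#'
#' @param results A tibble with columns `site_id`, `role` (`"on_target"` /
#'   `"off_target"`), `editor_id`, `freq`, and optionally `control_freq`
#'   (default 0). Exactly one on-target row per editor.
#' @return A tibble, one row per editor: `editor_id`, `n_offtarget`,
#'   `net_on`, `total_net_offtarget`, `max_net_offtarget`,
#'   `specificity_ratio`.
#' @export
specificity_summary <- function(results) {
  results <- as_tibble(results)
  stopifnot(all(c("site_id", "role", "editor_id", "freq") %in% names(results)))
  if (!all(results$role %in% c("on_target", "off_target", "control_locus"))) {
    abort("`role` must be on_target, off_target or control_locus.")
  }
  if (!"control_freq" %in% names(results)) results$control_freq <- 0
  if (any(results$freq < 0 | results$freq > 1) ||
      any(results$control_freq < 0 | results$control_freq > 1)) {
    abort("frequencies must lie in [0, 1].")
  }
  results <- results |>
    filter(.data$role != "control_locus") |>
    mutate(net_freq = pmax(.data$freq - .data$control_freq, 0))
  results |>
    group_by(.data$editor_id) |>
    group_modify(function(df, key) {
      on <- df[df$role == "on_target", ]
      ot <- df[df$role == "off_target", ]
      if (nrow(on) != 1L) {
        abort(paste0("editor '", key$editor_id[1],
                     "' must have exactly one on_target site."))
      }
      denom <- on$net_freq + sum(ot$net_freq)
      tibble(n_offtarget = nrow(ot),
             net_on = on$net_freq,
             total_net_offtarget = sum(ot$net_freq),
             max_net_offtarget = if (nrow(ot)) max(ot$net_freq) else 0,
             specificity_ratio = if (denom == 0) NA_real_ else
               on$net_freq / denom)
    }) |>
    ungroup()
}
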